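# Ground-truthed synthetic phosphoproteomics generator and mock predictor.
#
# The generator emulates: tryptic phosphopeptides from a random proteome,
# b/y fragment spectra with phospho neutral losses and log-normal intensity
# noise, retention times from a hydrophobicity-index model with a
# site-position-dependent phospho shift (so positional isomers have
# distinct true RTs), controllable deletion of site-determining ions
# (positional-isomer ambiguity), reversed-peptide decoys, and false target
# matches (spectrum generated from a different peptide than the one
# claimed). Every source of randomness flows through the single seed.

# sample() treats a length-1 numeric x as 1:x; this does not.
sample_safe <- function(x, size = 1L) x[sample.int(length(x), size)]

KD_INDEX <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AA_FREQ <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.053, C = 0.025, Q = 0.040,
  E = 0.063, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
  M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
  Y = 0.032, V = 0.073
)

#' Simulation configuration
#'
#' Defines the synthetic study conditions. Noise parameters: `peak_cv`
#' (log-normal CV of fragment intensities), `rt_jitter_sd` (minutes, on the
#' observed RT), `predictor_noise_sd` (applied by the mock predictor to RT
#' in minutes and to log-intensities), `ion_dropout` (probability that a
#' theoretical fragment is absent from the spectrum).
#'
#' @param n_proteins Number of random proteins.
#' @param n_psms Number of PSMs to generate.
#' @param phospho_rate Fraction of PSMs carrying at least one phospho.
#' @param multi_phospho_rate Fraction of phospho PSMs carrying two groups.
#' @param ambiguity_fraction Fraction of PSMs whose site-determining ions
#'   are deleted from the spectrum.
#' @param peak_cv,rt_jitter_sd,predictor_noise_sd,ion_dropout Noise levels
#'   (see above).
#' @param decoy_fraction Fraction of PSMs that are reversed-peptide decoys.
#' @param false_target_rate Fraction of target PSMs whose claimed peptide
#'   differs from the peptide that generated the spectrum.
#' @param n_samples,n_groups Quantity channels and their group structure.
#' @param seed Integer seed driving all randomness.
#' @return List of class `phos_simconfig`.
#' @export
simulation_config <- function(n_proteins = 20L, n_psms = 1000L,
                              phospho_rate = 1.0, multi_phospho_rate = 0.15,
                              ambiguity_fraction = 0.3, peak_cv = 0.3,
                              rt_jitter_sd = 0.5, predictor_noise_sd = 0.3,
                              ion_dropout = 0.15, decoy_fraction = 0.5,
                              false_target_rate = 0.1, n_samples = 4L,
                              n_groups = 2L, seed = 20230101L) {
  fractions <- c(phospho_rate, multi_phospho_rate, ambiguity_fraction,
                 decoy_fraction, false_target_rate, ion_dropout)
  if (any(fractions < 0 | fractions > 1))
    stop("rates/fractions must lie in [0,1]")
  if (any(c(peak_cv, rt_jitter_sd, predictor_noise_sd) < 0))
    stop("noise standard deviations must be >= 0")
  structure(as.list(environment()), class = "phos_simconfig")
}

#' Generate a random proteome and its tryptic phosphopeptide candidates
#'
#' Proteins of length 100-500 with natural-ish residue frequencies;
#' tryptic digestion (cleave after K/R, not before P) plus single
#' missed-cleavage products; peptides retained at length 7-30 with at
#' least one S/T/Y.
#'
#' @param config A [simulation_config()].
#' @return List with `proteome` (named character vector) and `peptides`
#'   (data frame: `peptide`, `protein_id`).
#' @export
generate_proteome <- function(config) {
  set.seed(config$seed)
  proteome <- stats::setNames(
    vapply(seq_len(config$n_proteins), function(i) {
      len <- sample(100:500, 1)
      paste(sample(names(AA_FREQ), len, replace = TRUE, prob = AA_FREQ),
            collapse = "")
    }, ""),
    sprintf("PROT%03d", seq_len(config$n_proteins)))
  peps <- lapply(names(proteome), function(id) {
    frags <- digest_tryptic(proteome[[id]])
    if (!length(frags)) return(NULL)
    data.frame(peptide = frags, protein_id = id, stringsAsFactors = FALSE)
  })
  peptides <- do.call(rbind, peps)
  peptides <- peptides[!duplicated(peptides$peptide), , drop = FALSE]
  rownames(peptides) <- NULL
  list(proteome = proteome, peptides = peptides)
}

#' In-silico tryptic digestion
#'
#' Cleaves after K/R except before P; returns fully cleaved peptides and
#' single missed-cleavage products, filtered to length 7-30 with >= 1
#' S/T/Y residue.
#'
#' @param protein_seq Protein sequence string.
#' @return Character vector of peptides.
#' @export
digest_tryptic <- function(protein_seq) {
  aa <- strsplit(protein_seq, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  base <- substring(protein_seq, starts, ends)
  missed <- if (length(base) > 1)
    paste0(base[-length(base)], base[-1]) else character(0)
  out <- c(base, missed)
  len <- nchar(out)
  has_sty <- grepl("[STY]", out)
  unique(out[len >= 7 & len <= 30 & has_sty])
}

#' Hydrophobicity-model retention time of a peptide isoform
#'
#' Base RT is an affine function of the summed Kyte-Doolittle indices; each
#' phospho group adds a site-position-dependent offset (drawn once per run,
#' passed in as `phospho_offsets`) so positional isomers elute at distinct
#' true RTs.
#'
#' @param peptide Peptide string.
#' @param phospho_positions Integer phospho positions.
#' @param phospho_offsets Numeric vector of per-position RT offsets
#'   (minutes), indexed by site position.
#' @return RT in minutes (>= 2).
#' @export
model_rt <- function(peptide, phospho_positions, phospho_offsets) {
  kd <- sum(KD_INDEX[strsplit(peptide, "")[[1]]])
  rt <- 60 + 1.2 * kd
  if (length(phospho_positions))
    rt <- rt + sum(phospho_offsets[phospho_positions])
  max(2, rt)
}

# Deterministic relative base intensity for theoretical fragments: a smooth
# bell over the fragment index, attenuated for 2+ and neutral-loss ions.
ion_base_intensity <- function(frags, peptide_length) {
  rel <- frags$index / peptide_length
  center <- ifelse(frags$series == "b", 0.45, 0.55)
  v <- exp(-4 * (rel - center)^2)
  v <- v * ifelse(frags$charge == 2L, 0.45, 1)
  v * ifelse(frags$loss, 0.35, 1)
}

# Site-determining peak deletion: m/z values of the true isoform's ions not
# shared (within tol) with at least one competing isoform.
site_determining_mz <- function(true_iso, competitors, charge, tol = 0.02) {
  tf <- theoretical_fragments(true_iso, charge)
  out <- numeric(0)
  for (comp in competitors) {
    cf <- theoretical_fragments(comp, charge)
    uniq <- vapply(tf$mz, function(m) !any(abs(cf$mz - m) <= tol),
                   logical(1))
    out <- c(out, tf$mz[uniq])
  }
  unique(out)
}

#' Generate synthetic spectra, PSMs and ground truth
#'
#' @param peptide_pool Data frame from [generate_proteome()]
#'   (`$peptides`).
#' @param config A [simulation_config()].
#' @return List with `spectra` (named list of [spectrum()]), `psms` (list
#'   of [psm_record()]), `truth` (list: per-PSM data frame `psm_truth`
#'   with source peptide/positions and role flags, `library` a
#'   [ground_truth_library()], `phospho_offsets`, `config`).
#' @export
generate_spectra <- function(peptide_pool, config) {
  set.seed(config$seed + 1L)
  peps <- peptide_pool$peptide
  prot <- stats::setNames(peptide_pool$protein_id, peps)
  sty_count <- stats::setNames(
    vapply(strsplit(peps, ""), function(a) sum(a %in% STY), integer(1)),
    peps)
  # Site-position-dependent phospho RT shift: a positional trend (0.7
  # min/residue) plus a small once-per-run random component, so any two
  # positional isomers have true RTs separated by at least ~0.7 min per
  # residue of site distance.
  phospho_offsets <- 0.7 * (seq_len(30) - 15.5) +
    stats::rnorm(30, 0, 0.2)
  n <- config$n_psms
  spectra <- vector("list", n)
  psms <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    src_pep <- sample_safe(peps)
    has_phos <- stats::runif(1) < config$phospho_rate
    k <- if (!has_phos) 0L
    else if (sty_count[src_pep] >= 2 &&
             stats::runif(1) < config$multi_phospho_rate) 2L else 1L
    sty_pos <- which(strsplit(src_pep, "")[[1]] %in% STY)
    true_pos <- sort(sample_safe(sty_pos, k))
    charge <- sample(2:3, 1, prob = c(0.6, 0.4))
    true_iso <- phospho_isoform(src_pep, true_pos)

    # spectrum from the source isoform
    frags <- theoretical_fragments(true_iso, charge)
    base <- ion_base_intensity(frags, nchar(src_pep))
    detect <- stats::runif(nrow(frags)) >= config$ion_dropout
    inten <- base * exp(stats::rnorm(nrow(frags), 0, config$peak_cv)) *
      detect * 1e4
    keep <- inten > 0
    peak_mz <- frags$mz[keep]
    peak_int <- inten[keep]
    ambiguous <- k >= 1 && stats::runif(1) < config$ambiguity_fraction
    if (ambiguous) {
      competitors <- Filter(
        function(x) !identical(x$phospho_positions, true_pos),
        lapply(combn_safe(sty_pos, k),
               function(p) phospho_isoform(src_pep, p)))
      if (length(competitors)) {
        del <- site_determining_mz(true_iso, competitors, charge)
        if (length(del)) {
          hit <- vapply(peak_mz, function(m) any(abs(del - m) <= 0.02),
                        logical(1))
          peak_mz <- peak_mz[!hit]
          peak_int <- peak_int[!hit]
        }
      } else ambiguous <- FALSE
    }
    n_noise <- sample(5:20, 1)
    noise_mz <- stats::runif(n_noise, 100, max(frags$mz) + 50)
    noise_int <- 1e4 * exp(stats::rnorm(n_noise, -2.5, 0.5))
    pk <- cbind(c(peak_mz, noise_mz), c(peak_int, noise_int))
    rte <- max(1, model_rt(src_pep, true_pos, phospho_offsets) +
                 stats::rnorm(1, 0, config$rt_jitter_sd))

    # role: decoy / false target / true target
    is_decoy <- stats::runif(1) < config$decoy_fraction
    is_true_target <- !is_decoy &&
      stats::runif(1) >= config$false_target_rate
    if (is_true_target) {
      claimed_pep <- src_pep
      claimed_prot <- prot[[src_pep]]
    } else if (is_decoy) {
      other <- sample_safe(peps[sty_count >= max(1L, k)])
      nn <- nchar(other)
      claimed_pep <- paste0(
        paste(rev(strsplit(substr(other, 1, nn - 1), "")[[1]]),
              collapse = ""),
        substr(other, nn, nn))
      claimed_prot <- paste0("REV_", prot[[other]])
      if (!grepl("[STY]", substr(claimed_pep, 1, nchar(claimed_pep) - 1)) &&
          k > 0) {
        # reversal left all S/T/Y at the C-terminal K/R (impossible); skip
        claimed_pep <- other
      }
    } else {
      pool <- peps[peps != src_pep & sty_count >= max(1L, k)]
      claimed_pep <- sample_safe(pool)
      claimed_prot <- prot[[claimed_pep]]
    }
    claimed_sty <- which(strsplit(claimed_pep, "")[[1]] %in% STY)
    k_claim <- min(k, length(claimed_sty))
    claimed_pos <- if (k_claim > 0) sort(sample_safe(claimed_sty, k_claim))
                   else integer(0)
    claimed_iso <- phospho_isoform(claimed_pep, claimed_pos)
    z_claim <- charge
    prec_mz <- isoform_mz(claimed_iso, z_claim) *
      (1 + stats::rnorm(1, 0, 3e-6))

    sid <- sprintf("syn%05d", i)
    spectra[[i]] <- spectrum(sid, prec_mz, z_claim, rte, pk)

    # simulated engine score: noisy function of the claimed isoform's
    # actual match quality
    cf <- theoretical_fragments(claimed_iso, z_claim)
    pkmz <- spectra[[i]]$peaks[, 1]
    frac <- mean(vapply(cf$mz, function(m) any(abs(pkmz - m) <= 0.02),
                        logical(1)))
    escore <- max(0, 40 * frac + stats::rnorm(1, 0, 6))
    dscore <- abs(stats::rnorm(1, 0, 3)) + 5 * frac
    quant <- stats::setNames(
      stats::rlnorm(config$n_samples, log(10), 0.5),
      sprintf("s%d", seq_len(config$n_samples)))
    psms[[i]] <- psm_record(
      spectrum_id = sid, peptide = claimed_pep,
      variable_mods = if (k_claim > 0)
        mods_table(claimed_pos, MASS_PHOSPHO, "Phospho") else empty_mods(),
      charge = z_claim,
      engine_scores = c(score = escore, delta_score = dscore),
      is_decoy = is_decoy, protein_ids = claimed_prot, quantity = quant)
    truth_rows[[i]] <- data.frame(
      spectrum_id = sid, source_peptide = src_pep,
      true_positions = position_key(true_pos),
      claimed_peptide = claimed_pep,
      is_decoy = is_decoy, is_true_target = is_true_target,
      ambiguous = ambiguous, stringsAsFactors = FALSE)
  }
  psm_truth <- do.call(rbind, truth_rows)
  lib_src <- psm_truth[!duplicated(paste0(psm_truth$source_peptide, "|",
                                          psm_truth$true_positions)), ]
  library <- ground_truth_library(
    lib_src$source_peptide,
    lapply(strsplit(lib_src$true_positions, ";"), as.integer))
  names(spectra) <- vapply(spectra, function(s) s$spectrum_id, "")
  list(spectra = spectra, psms = psms,
       truth = list(psm_truth = psm_truth, library = library,
                    phospho_offsets = phospho_offsets, config = config))
}

#' Mock RT / fragment-intensity predictor
#'
#' Stands in for an external deep-learning predictor. For every isoform of
#' each PSM's claimed peptide it predicts: RT from the same
#' position-dependent hydrophobicity model that generated the data (plus
#' Gaussian noise of `noise_sd` minutes), and fragment intensities from the
#' deterministic generative intensity pattern of that isoform (log-normal
#' noise of sd `noise_sd`). With `uninformative = TRUE` all isoforms
#' receive identical constant predictions.
#'
#' @param psms List of [psm_record()]s.
#' @param truth Truth list from [generate_spectra()].
#' @param noise_sd Predictor noise (see above); defaults to the config's
#'   `predictor_noise_sd`.
#' @param uninformative Emit constant outputs (default FALSE).
#' @param seed Seed for the predictor noise; defaults to config seed + 2.
#' @return Named list: spectrum_id -> (named list: [position_key()] ->
#'   [prediction_record()]).
#' @export
mock_predictor <- function(psms, truth, noise_sd = NULL,
                           uninformative = FALSE, seed = NULL) {
  cfg <- truth$config
  if (is.null(noise_sd)) noise_sd <- cfg$predictor_noise_sd
  if (is.null(seed)) seed <- cfg$seed + 2L
  set.seed(seed)
  offsets <- truth$phospho_offsets
  out <- vector("list", length(psms))
  names(out) <- vapply(psms, function(p) p$spectrum_id, "")
  for (j in seq_along(psms)) {
    psm <- psms[[j]]
    isoforms <- if (phospho_count(psm) >= 1)
      enumerate_isoforms(psm) else list(phospho_isoform(psm$peptide,
                                                        integer(0)))
    preds <- vector("list", length(isoforms))
    names(preds) <- vapply(isoforms, function(x) pred_key(position_key(x)),
                           "")
    # Intensity-prediction error is peptide-level, not isoform-level: the
    # same ion label gets the same error across competing isoforms, so SS
    # differences between isomers reflect m/z alignment, not noise.
    label_noise <- new.env(parent = emptyenv())
    for (iso in isoforms) {
      key <- pred_key(position_key(iso))
      if (uninformative) {
        # constant outputs: flat intensity on the primary b/y ions (whose
        # label sets coincide across positional isomers) and a fixed RT,
        # so neither feature can distinguish isoforms
        frags <- theoretical_fragments(iso, psm$charge)
        frags <- frags[!frags$loss, , drop = FALSE]
        preds[[key]] <- prediction_record(
          iso, 60, stats::setNames(rep(0.5, nrow(frags)), frags$label))
        next
      }
      rtp <- max(1, model_rt(iso$peptide, iso$phospho_positions, offsets) +
                   stats::rnorm(1, 0, noise_sd))
      frags <- theoretical_fragments(iso, psm$charge)
      noise <- vapply(frags$label, function(lb) {
        if (is.null(label_noise[[lb]]))
          label_noise[[lb]] <- exp(stats::rnorm(1, 0, noise_sd))
        label_noise[[lb]]
      }, numeric(1))
      inten <- ion_base_intensity(frags, nchar(iso$peptide)) * noise
      inten <- inten / max(inten)
      preds[[key]] <- prediction_record(
        iso, rtp, stats::setNames(inten, frags$label))
    }
    out[[psm$spectrum_id]] <- preds
  }
  out
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_proteome()],
#' [generate_spectra()] and [mock_predictor()].
#'
#' @param config A [simulation_config()].
#' @param uninformative_predictor Use constant predictor outputs.
#' @return List with `proteome`, `peptides`, `spectra`, `psms`, `truth`,
#'   `predictions`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config(),
                             uninformative_predictor = FALSE) {
  pro <- generate_proteome(config)
  gen <- generate_spectra(pro$peptides, config)
  preds <- mock_predictor(gen$psms, gen$truth,
                          uninformative = uninformative_predictor)
  list(proteome = pro$proteome, peptides = pro$peptides,
       spectra = gen$spectra, psms = gen$psms, truth = gen$truth,
       predictions = preds, config = config)
}
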