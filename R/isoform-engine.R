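# Positional-isomer enumeration, theoretical b/y fragment m/z (with the
# phosphopeptide H3PO4 neutral loss), and alignment of predicted and
# experimental peaks into comparable intensity vectors.

# combn() treats a length-1 numeric x as seq_len(x); this does not.
combn_safe <- function(x, m) {
  if (length(x) == 1L) {
    if (m != 1L) stop("cannot choose ", m, " from 1 element")
    return(list(x))
  }
  utils::combn(x, m, simplify = FALSE)
}

#' Canonical fragment-ion label
#'
#' @param series `"b"` or `"y"`.
#' @param index Fragment index (1..n-1).
#' @param charge Fragment charge (1 or 2).
#' @param loss `TRUE` when the ion carries a H3PO4 neutral loss.
#' @return Character label such as `"b3_z1"` or `"y5_z2_nl"`.
#' @export
ion_label <- function(series, index, charge, loss = FALSE) {
  paste0(series, index, "_z", charge, ifelse(loss, "_nl", ""))
}

#' Enumerate phosphosite positional isoforms of a PSM
#'
#' All C(n, k) placements of the PSM's k phospho groups over its n S/T/Y
#' residues, in deterministic lexicographic order by position tuple. When
#' the count exceeds `max_isoforms` only the engine-reported isoform is
#' returned and the result is flagged unlocalizable by enumeration (as
#' attribute `"unlocalizable"`).
#'
#' @param psm A [psm_record()] with at least one phospho group.
#' @param max_isoforms Combinatorial guard (default 512).
#' @return List of [phospho_isoform()]; attribute `unlocalizable` is `TRUE`
#'   when the cap was hit.
#' @export
enumerate_isoforms <- function(psm, max_isoforms = 512L) {
  k <- phospho_count(psm)
  if (k < 1) stop("PSM has no phospho group: ", psm$spectrum_id)
  aa <- strsplit(psm$peptide, "")[[1]]
  candidates <- which(aa %in% STY)
  n <- length(candidates)
  if (k > n)
    stop("inconsistent PSM ", psm$spectrum_id, ": ", k,
         " phospho groups but only ", n, " S/T/Y residues")
  om <- other_mods(psm)
  total <- choose(n, k)
  if (total > max_isoforms) {
    iso <- list(phospho_isoform(psm$peptide, reported_phospho_positions(psm),
                                om))
    attr(iso, "unlocalizable") <- TRUE
    return(iso)
  }
  combos <- combn_safe(candidates, k)
  iso <- lapply(combos, function(pos)
    phospho_isoform(psm$peptide, pos, om))
  attr(iso, "unlocalizable") <- FALSE
  iso
}

# Per-residue mass vector of an isoform, mods added at their positions.
# N-terminal mods (position 0) are folded into residue 1 so that b ions
# carry them, matching the chemistry of an N-terminal tag.
residue_mass_vector <- function(isoform) {
  aa <- strsplit(isoform$peptide, "")[[1]]
  m <- unname(RESIDUE_MASS[aa])
  if (any(is.na(m)))
    stop("unknown residue in peptide ", isoform$peptide)
  if (length(isoform$phospho_positions))
    m[isoform$phospho_positions] <- m[isoform$phospho_positions] + MASS_PHOSPHO
  om <- isoform$other_mods
  if (nrow(om)) {
    pos <- ifelse(om$position == 0L, 1L, om$position)
    for (i in seq_len(nrow(om))) m[pos[i]] <- m[pos[i]] + om$mass_delta[i]
  }
  m
}

#' Neutral monoisotopic mass of a peptide isoform
#' @param isoform A [phospho_isoform()].
#' @return Neutral mass in Da.
#' @export
isoform_neutral_mass <- function(isoform) {
  sum(residue_mass_vector(isoform)) + MASS_H2O
}

#' Precursor m/z of a peptide isoform
#' @param isoform A [phospho_isoform()].
#' @param charge Precursor charge.
#' @return m/z in Th.
#' @export
isoform_mz <- function(isoform, charge) {
  (isoform_neutral_mass(isoform) + charge * MASS_PROTON) / charge
}

#' Theoretical b/y fragment ions of an isoform
#'
#' b1..b(n-1) and y1..y(n-1) at charge 1 (and charge 2 when the precursor
#' charge is >= 2), each additionally with a single H3PO4 neutral loss when
#' the fragment carries at least one phospho group. m/z values follow
#' standard fragment arithmetic from summed monoisotopic residue masses.
#'
#' @param isoform A [phospho_isoform()].
#' @param charge Precursor charge (controls whether 2+ fragments are
#'   generated).
#' @return Data frame with columns `label`, `series`, `index`, `charge`,
#'   `loss`, `mz`.
#' @export
theoretical_fragments <- function(isoform, charge = 2L) {
  om <- isoform$other_mods
  key <- paste(isoform$peptide, position_key(isoform), min(charge, 2L),
               if (nrow(om)) paste(om$position, om$mass_delta,
                                   collapse = ","),
               sep = "|")
  cached <- .frag_cache[[key]]
  if (!is.null(cached)) return(cached)
  m <- residue_mass_vector(isoform)
  n <- length(m)
  if (n < 2) stop("peptide too short to fragment: ", isoform$peptide)
  idx <- seq_len(n - 1L)
  suffix <- rev(cumsum(rev(m)))                # suffix[i] = sum m[i..n]
  b_neutral <- cumsum(m)[idx]                  # b_i: residues 1..i
  y_neutral <- suffix[n - idx + 1L] + MASS_H2O # y_i: residues n-i+1..n
  pp <- isoform$phospho_positions
  has_phos_b <- if (length(pp)) idx >= min(pp) else rep(FALSE, n - 1L)
  has_phos_y <- if (length(pp)) idx >= n + 1L - max(pp)
                else rep(FALSE, n - 1L)
  charges <- if (charge >= 2L) c(1L, 2L) else 1L
  series <- c(rep("b", n - 1L), rep("y", n - 1L))
  index <- c(idx, idx)
  neutral <- c(b_neutral, y_neutral)
  has_phos <- c(has_phos_b, has_phos_y)
  ser_all <- idx_all <- chg_all <- loss_all <- mz_all <- NULL
  for (z in charges) {
    ser_all <- c(ser_all, series, series[has_phos])
    idx_all <- c(idx_all, index, index[has_phos])
    chg_all <- c(chg_all, rep(z, length(index) + sum(has_phos)))
    loss_all <- c(loss_all, rep(FALSE, length(index)),
                  rep(TRUE, sum(has_phos)))
    mz_all <- c(mz_all, (neutral + z * MASS_PROTON) / z,
                (neutral[has_phos] - MASS_H3PO4 + z * MASS_PROTON) / z)
  }
  out <- data.frame(
    label = ion_label(ser_all, idx_all, chg_all, loss_all),
    series = ser_all, index = idx_all, charge = chg_all, loss = loss_all,
    mz = mz_all, stringsAsFactors = FALSE)
  n_cached <- get0(".count", .frag_cache, ifnotfound = 0L)
  if (n_cached > 30000L) {          # bound memory on long multi-run sessions
    rm(list = ls(.frag_cache), envir = .frag_cache)
    n_cached <- 0L
  }
  .frag_cache[[key]] <- out
  assign(".count", n_cached + 1L, .frag_cache)
  out
}

# Memoization store for theoretical_fragments: the same isoform is scored
# repeatedly across localization methods and feature assembly.
.frag_cache <- new.env(parent = emptyenv())

#' Align predicted and experimental peaks over a theoretical ion list
#'
#' Builds the paired intensity vectors Ip/Ie used by the spectrum-similarity
#' scores: one slot per theoretical ion. Experimental peaks are assigned
#' greedily, most intense first, each consumable once, to the nearest-by-m/z
#' unassigned theoretical ion within `tol_da` (ties broken toward the lower
#' m/z ion). Ip is the predictor's intensity for the slot's label (0 when
#' the predictor did not emit it).
#'
#' @param theoretical Data frame from [theoretical_fragments()].
#' @param prediction A [prediction_record()] (or a named numeric vector of
#'   predicted intensities keyed by ion label).
#' @param spec A [spectrum()].
#' @param tol_da Fragment matching tolerance in Da (default 0.02).
#' @return List with `ion_labels`, `Ip`, `Ie` (equal-length numeric
#'   vectors), class `phos_aligned`.
#' @export
align_peaks <- function(theoretical, prediction, spec, tol_da = 0.02) {
  if (tol_da <= 0) stop("tol_da must be positive")
  if (nrow(spec$peaks) == 0) stop("empty spectrum: ", spec$spectrum_id)
  pred <- if (inherits(prediction, "phos_prediction"))
    prediction$predicted_peaks else prediction
  nt <- nrow(theoretical)
  Ie <- numeric(nt)
  tmz <- theoretical$mz
  pk <- spec$peaks
  ord <- order(pk[, 2], decreasing = TRUE)
  assigned <- logical(nt)
  for (j in ord) {
    d <- abs(tmz - pk[j, 1])
    d[assigned] <- Inf
    best <- which(d <= tol_da)
    if (!length(best)) next
    # nearest m/z; tie -> lower-m/z ion
    best <- best[order(d[best], tmz[best])][1]
    Ie[best] <- pk[j, 2]
    assigned[best] <- TRUE
  }
  Ip <- unname(pred[theoretical$label])
  Ip[is.na(Ip)] <- 0
  structure(list(ion_labels = theoretical$label, Ip = Ip, Ie = Ie),
            class = "phos_aligned")
}
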