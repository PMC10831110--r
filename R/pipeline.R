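# Pipeline orchestration: localize -> rescore -> filter -> quantify, the
# benchmark runner used for method comparisons on ground-truthed data,
# PSM annotation export, and the run manifest.

#' Localize a whole PSM set
#'
#' Applies [localize()] to every PSM. Non-phosphorylated PSMs pass through
#' with a single trivial "isoform" (no sites, probability 1) so that mixed
#' sets can be rescored uniformly.
#'
#' @param psms List of [psm_record()]s.
#' @param spectra Named list of [spectrum()]s keyed by spectrum id.
#' @param predictions Output of [mock_predictor()] or
#'   [read_prediction_table()].
#' @param method,rt_mode,ss_method,tol_da,max_isoforms See [localize()].
#' @return List of `phos_localization`, parallel to `psms`.
#' @export
localize_all <- function(psms, spectra, predictions, method = 4L,
                         rt_mode = "RTR", ss_method = "Entropy",
                         tol_da = 0.02, max_isoforms = 512L) {
  lapply(psms, function(psm) {
    spec <- spectra[[psm$spectrum_id]]
    if (is.null(spec)) stop("no spectrum for PSM ", psm$spectrum_id)
    preds <- predictions[[psm$spectrum_id]]
    if (is.null(preds))
      stop("no predictions for spectrum ", psm$spectrum_id)
    if (phospho_count(psm) >= 1) {
      localize(psm, spec, preds, method = method, rt_mode = rt_mode,
               ss_method = ss_method, tol_da = tol_da,
               max_isoforms = max_isoforms)
    } else {
      pred <- preds[[pred_key("")]]
      if (is.null(pred))
        stop("missing prediction for unmodified peptide of spectrum ",
             psm$spectrum_id)
      iso <- phospho_isoform(psm$peptide, integer(0), other_mods(psm))
      frags <- theoretical_fragments(iso, spec$precursor_charge)
      pair <- align_peaks(frags, pred, spec, tol_da)
      ss <- spectrum_similarity(pair, ss_method)
      rt <- rt_scores(pred$predicted_rt, max(spec$observed_rt, 0.01))
      base <- binomial_isoform_score(iso, spec, tol_da, frags = frags)
      tab <- data.frame(positions = "", base = base, ss = ss,
                        drt = rt$drt, rtr = rt$rtr, combined = base,
                        probability = 1, stringsAsFactors = FALSE)
      structure(list(spectrum_id = psm$spectrum_id, peptide = psm$peptide,
                     chosen = 1L, table = tab,
                     site_probabilities = numeric(0), method = method,
                     unlocalizable = FALSE),
                class = "phos_localization")
    }
  })
}

#' Read a predictor output table
#'
#' The pluggable predictor interface: a TSV with columns `spectrum_id`,
#' `positions` ([position_key()] of the isoform; empty for unmodified),
#' `peptide`, `predicted_rt` (minutes) and `peaks`
#' (semicolon-separated `label:intensity`, intensities in \[0,1\]).
#'
#' @param path Path to the TSV.
#' @return Named list spectrum_id -> (named list position key ->
#'   [prediction_record()]).
#' @export
read_prediction_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(positions = "character"))
  out <- list()
  for (i in seq_len(nrow(df))) {
    pairs <- strsplit(df$peaks[i], ";", fixed = TRUE)[[1]]
    kv <- strsplit(pairs, ":", fixed = TRUE)
    peaks <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                             vapply(kv, `[`, "", 1L))
    pos <- if (nzchar(df$positions[i]))
      as.integer(strsplit(df$positions[i], ";")[[1]]) else integer(0)
    iso <- phospho_isoform(df$peptide[i], pos)
    sid <- as.character(df$spectrum_id[i])
    out[[sid]][[pred_key(df$positions[i])]] <-
      prediction_record(iso, df$predicted_rt[i], peaks)
  }
  out
}

#' Write a predictor output table
#'
#' @param predictions Structure as returned by [mock_predictor()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(predictions, path) {
  rows <- list()
  for (sid in names(predictions)) {
    for (key in names(predictions[[sid]])) {
      p <- predictions[[sid]][[key]]
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum_id = sid,
        positions = if (key == ".unmod") "" else key,
        peptide = p$isoform$peptide,
        predicted_rt = p$predicted_rt,
        peaks = paste(sprintf("%s:%.6f", names(p$predicted_peaks),
                              p$predicted_peaks), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages run in order localize -> rescore -> filter -> quantify; each
#' later stage can be disabled via `stages`. Identical config and inputs
#' yield identical outputs.
#'
#' @param config Nested list (or path to a YAML file): `inputs` (either
#'   `simulate`, a list of [simulation_config()] arguments, or file paths
#'   `mgf`, `psm_table`, `psm_dialect`, `predictions`, `fasta`),
#'   `localize` (`method`, `rt_mode`, `ss_method`, `tol_da`), `rescore`
#'   (`folds`, `iterations`, `seed`, `use_dl_features`, `export_pin`),
#'   `filter` (`psm_q_max`, `peptide_q_max`, `min_site_prob`), `quantify`
#'   (`min_per_group`, `sample_groups`), `stages` (character subset of
#'   `c("rescore", "filter", "quantify")`), `out_dir` (optional; when set,
#'   stage tables and the manifest are written as TSV/JSON).
#' @return List with `localized`, `rescored`, `confident`, `site_table`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("rescore", "filter", "quantify")
  loc_cfg <- config$localize %||% list()
  input_hashes <- character(0)

  if (!is.null(config$inputs$simulate)) {
    sim <- simulate_dataset(do.call(simulation_config,
                                    config$inputs$simulate))
    spectra <- sim$spectra; psms <- sim$psms
    predictions <- sim$predictions
    proteome <- sim$proteome
  } else {
    ins <- config$inputs
    for (f in c("mgf", "psm_table", "predictions"))
      if (is.null(ins[[f]]))
        stop("pipeline aborted at stage 'localize': missing input '", f, "'")
    input_hashes <- vapply(
      unlist(ins[c("mgf", "psm_table", "predictions", "fasta")]),
      function(p) unname(tools::md5sum(p)), "")
    sp <- read_mgf(ins$mgf)
    spectra <- stats::setNames(sp, vapply(sp, function(s) s$spectrum_id, ""))
    psms <- read_psm_table(ins$psm_table,
                           ins$psm_dialect %||% "generic_tsv")
    predictions <- read_prediction_table(ins$predictions)
    proteome <- if (!is.null(ins$fasta)) read_protein_fasta(ins$fasta)
                else NULL
  }

  localized <- tryCatch(
    localize_all(psms, spectra, predictions,
                 method = loc_cfg$method %||% 4L,
                 rt_mode = loc_cfg$rt_mode %||% "RTR",
                 ss_method = loc_cfg$ss_method %||% "Entropy",
                 tol_da = loc_cfg$tol_da %||% 0.02),
    error = function(e)
      stop("pipeline aborted at stage 'localize': ", conditionMessage(e)))
  features <- assemble_feature_table(localized, psms, spectra,
                                     loc_cfg$tol_da %||% 0.02)

  rescored <- confident <- site_table <- NULL
  if ("rescore" %in% stages) {
    rcfg <- config$rescore %||% list()
    rescored <- tryCatch(
      semi_supervised_rescore(features, folds = rcfg$folds %||% 3L,
                              iterations = rcfg$iterations %||% 10L,
                              seed = rcfg$seed %||% 20230101L,
                              use_dl_features =
                                rcfg$use_dl_features %||% TRUE),
      error = function(e)
        stop("pipeline aborted at stage 'rescore': ", conditionMessage(e)))
    if (!is.null(rcfg$export_pin)) write_pin(features, rcfg$export_pin)
  }
  if ("filter" %in% stages && !is.null(rescored)) {
    fcfg <- config$filter %||% list()
    filtered <- filter_confident(rescored,
                                 psm_q_max = fcfg$psm_q_max %||% 0.01,
                                 peptide_q_max = fcfg$peptide_q_max %||% 0.01,
                                 min_site_prob = fcfg$min_site_prob %||% 0.75)
    confident <- filtered[filtered$passes, , drop = FALSE]
  }
  if ("quantify" %in% stages && !is.null(confident) &&
      !is.null(proteome)) {
    qcfg <- config$quantify %||% list()
    phos <- confident[nzchar(confident$positions), , drop = FALSE]
    site_table <- tryCatch({
      st <- sum_by_15mer(expand_per_site(
        collapse_modified_sequences(phos)), proteome)
      st <- normalize_site_table(st)
      if (!is.null(qcfg$sample_groups))
        st <- quantifiability_filter(st, unlist(qcfg$sample_groups),
                                     qcfg$min_per_group %||% 0L)
      st
    }, error = function(e)
      stop("pipeline aborted at stage 'quantify': ", conditionMessage(e)))
  }

  manifest <- list(
    config = config,
    versions = list(
      package = as.character(utils::packageVersion("phosloc")),
      r = paste(R.version$major, R.version$minor, sep = ".")),
    seed = config$rescore$seed %||% 20230101L,
    input_hashes = as.list(input_hashes),
    counts = list(
      spectra = length(spectra),
      psms = length(psms),
      localized = length(localized),
      rescored = if (is.null(rescored)) NULL else nrow(rescored),
      confident = if (is.null(confident)) NULL else nrow(confident),
      sites = if (is.null(site_table)) NULL else nrow(site_table)))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    loc_tab <- do.call(rbind, lapply(localized, localization_summary))
    utils::write.table(loc_tab, file.path(config$out_dir, "localized.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rescored))
      utils::write.table(rescored[, setdiff(names(rescored), "matched_ions")],
                         file.path(config$out_dir, "rescored.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(confident))
      utils::write.table(confident[, setdiff(names(confident),
                                             "matched_ions")],
                         file.path(config$out_dir, "confident.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(site_table))
      utils::write.table(site_table,
                         file.path(config$out_dir, "site_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(localized = localized, rescored = rescored, confident = confident,
       site_table = site_table, manifest = manifest)
}

#' Per-PSM annotation export
#'
#' Machine-readable annotation of rescored PSMs (matched ions, spectrum
#' similarity, RTR, site probabilities) suitable for external spectrum
#' viewers.
#'
#' @param rescored Rescored feature table.
#' @param spectra Named list of [spectrum()]s.
#' @param path Optional JSON output path.
#' @return List of per-PSM annotation records (invisibly when written).
#' @export
annotate_psm_report <- function(rescored, spectra, path = NULL) {
  if (nrow(rescored) == 0) {
    warning("empty PSM set; writing empty annotation report")
    ann <- list()
  } else {
    ann <- lapply(seq_len(nrow(rescored)), function(i) {
      sid <- rescored$spectrum_id[i]
      if (is.null(spectra[[sid]])) stop("unknown spectrum_id: ", sid)
      ions <- rescored$matched_ions[i]
      ion_rows <- if (nzchar(ions)) {
        kv <- strsplit(strsplit(ions, ";")[[1]], ":")
        lapply(kv, function(x) list(label = x[1],
                                    intensity = as.numeric(x[2])))
      } else list()
      list(spectrum_id = sid,
           peptide = rescored$peptide[i],
           positions = rescored$positions[i],
           discriminant = rescored$discriminant[i] %||NA% NA,
           q_value = rescored$q_value[i] %||NA% NA,
           ss = rescored$ss[i], rtr = rescored$rtr[i],
           min_site_probability = rescored$min_site_probability[i],
           matched_ions = ion_rows)
    })
  }
  if (!is.null(path))
    jsonlite::write_json(ann, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  invisible(ann)
}

#' Benchmark localization / rescoring method combinations
#'
#' Runs the standard method comparison on a ground-truthed synthetic
#' dataset: Method 1 (base localization score only), Method 4 (base score
#' x spectrum similarity x RTR), Method 5 (Method 1 localization +
#' rescoring without deep-learning features) and Method 7 (Method 4
#' localization + rescoring with deep-learning features). Each method's
#' identified set is its 1% FDR set (engine score for Methods 1/4,
#' rescored discriminant for Methods 5/7); correctly localized PSMs are
#' counted at an FLR ceiling over the correct-sequence phospho PSMs of
#' that set, sorted by site probability.
#'
#' @param sim Output of [simulate_dataset()].
#' @param flr_level FLR ceiling for the headline counts (default 0.01).
#' @param fdr_max Identification FDR ceiling (default 0.01).
#' @param folds,iterations,seed Rescoring parameters.
#' @return List: `counts` (named vector of correct PSMs at the FLR level
#'   per method), `flr_at_075` (method 4 FLR at site probability >= 0.75),
#'   `false_target_fraction` (among method 7 PSMs at `fdr_max`),
#'   `accuracy` (named top-1 site accuracies for methods 1 and 4 over
#'   true-sequence PSMs), plus the per-method evaluation tables.
#' @export
benchmark_methods <- function(sim, flr_level = 0.01, fdr_max = 0.01,
                              folds = 3L, iterations = 10L,
                              seed = 20230101L) {
  truth <- sim$truth$psm_truth
  lib <- sim$truth$library
  loc1 <- localize_all(sim$psms, sim$spectra, sim$predictions, method = 1L)
  loc4 <- localize_all(sim$psms, sim$spectra, sim$predictions, method = 4L)
  ft1 <- assemble_feature_table(loc1, sim$psms, sim$spectra)
  ft4 <- assemble_feature_table(loc4, sim$psms, sim$spectra)

  eval_table <- function(ft) {
    stopifnot(identical(ft$spectrum_id, truth$spectrum_id))
    ft$correct_sequence <- !ft$is_decoy &
      ft$peptide == truth$source_peptide
    ft$probability <- NA_real_
    ft$correct <- mark_correct_vec(ft$peptide, ft$positions, lib) &
      ft$correct_sequence
    ft
  }
  probs <- function(locs) vapply(locs, function(l)
    l$table$probability[l$chosen], numeric(1))
  ft1 <- eval_table(ft1); ft1$probability <- probs(loc1)
  ft4 <- eval_table(ft4); ft4$probability <- probs(loc4)

  count_at_flr <- function(df, sel) {
    df <- df[sel & df$correct_sequence & nzchar(df$positions), ,
             drop = FALSE]
    if (!nrow(df)) return(0L)
    correct_psms_at_flr(flr_curve(df), flr_level)
  }
  ft1 <- add_q_values(ft1, "engine_score", "engine_q")
  ft4 <- add_q_values(ft4, "engine_score", "engine_q")
  n1 <- count_at_flr(ft1, !ft1$is_decoy & ft1$engine_q <= fdr_max)
  n4 <- count_at_flr(ft4, !ft4$is_decoy & ft4$engine_q <= fdr_max)

  r5 <- semi_supervised_rescore(ft1, folds, iterations, seed,
                                use_dl_features = FALSE)
  r7 <- semi_supervised_rescore(ft4, folds, iterations, seed,
                                use_dl_features = TRUE)
  n5 <- count_at_flr(r5, !r5$is_decoy & r5$q_value <= fdr_max)
  n7 <- count_at_flr(r7, !r7$is_decoy & r7$q_value <= fdr_max)

  # FLR at the 0.75 site-probability cutoff, method 4 localization, over
  # all correct-sequence phospho PSMs
  cs4 <- ft4[ft4$correct_sequence & nzchar(ft4$positions), , drop = FALSE]
  flr075 <- if (nrow(cs4))
    unname(attr(flr_curve(cs4), "cutoff_flr")["0.75"]) else NA_real_

  acc <- c(
    m1 = mean(ft1$correct[ft1$correct_sequence & nzchar(ft1$positions)]),
    m4 = mean(ft4$correct[ft4$correct_sequence & nzchar(ft4$positions)]))

  acc7 <- r7[!r7$is_decoy & r7$q_value <= fdr_max, , drop = FALSE]
  truth_true <- stats::setNames(truth$is_true_target, truth$spectrum_id)
  ftf <- if (nrow(acc7))
    mean(!truth_true[acc7$spectrum_id]) else NA_real_

  list(counts = c(m1 = n1, m4 = n4, m5 = n5, m7 = n7),
       flr_at_075 = flr075, false_target_fraction = ftf,
       accuracy = acc, tables = list(m1 = ft1, m4 = ft4, m5 = r5, m7 = r7))
}

# Vectorized library matching.
mark_correct_vec <- function(peptide, positions, library) {
  paste0(peptide, "|", positions) %in% library$key
}
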