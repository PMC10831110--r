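# Ground-truth correctness matching and false localization rate (FLR)
# computation for synthetic-library benchmarking. FLR = FL / (TL + FL),
# where TL and FL count true and false localizations above a cutoff; a PSM
# is true only when all of its chosen sites match a library entry.

#' Mark a localization as correct against a ground-truth library
#'
#' @param peptide Identified peptide sequence.
#' @param positions Chosen phospho positions (integer vector or
#'   [position_key()] string).
#' @param library A [ground_truth_library()].
#' @return `TRUE` iff (peptide, positions) is a library entry.
#' @export
mark_correct <- function(peptide, positions, library) {
  key <- if (is.character(positions) && length(positions) == 1L)
    paste0(peptide, "|", positions)
  else paste0(peptide, "|", position_key(positions))
  key %in% library$key
}

#' FLR curve over ranked localization results
#'
#' Results are sorted by site localization probability in descending order
#' (ties broken by spectrum id for determinism, all tied records included
#' at a cutoff); cumulative TL, FL and FLR are reported at every rank.
#'
#' @param results Data frame with columns `probability`, `correct`
#'   (logical) and optionally `spectrum_id`; typically the
#'   [localization_summary()] rows of PSMs with correctly identified
#'   sequence, with `correct` from [mark_correct()].
#' @param prob_cutoffs Probability cutoffs at which FLR is additionally
#'   reported (default 0.5, 0.75, 0.9, 0.99).
#' @return The sorted data frame with `TL`, `FL`, `flr` columns; attribute
#'   `"cutoff_flr"` holds the named FLR-at-cutoff vector (NA when no
#'   record reaches a cutoff).
#' @export
flr_curve <- function(results, prob_cutoffs = c(0.5, 0.75, 0.9, 0.99)) {
  if (nrow(results) == 0) stop("no localization results to evaluate")
  tie <- results$spectrum_id %||% seq_len(nrow(results))
  ord <- order(-results$probability, tie)
  df <- results[ord, , drop = FALSE]
  df$TL <- cumsum(df$correct)
  df$FL <- cumsum(!df$correct)
  df$flr <- df$FL / (df$TL + df$FL)
  cutoff_flr <- vapply(prob_cutoffs, function(cc) {
    idx <- which(df$probability >= cc)
    if (!length(idx)) NA_real_ else df$flr[max(idx)]
  }, numeric(1))
  names(cutoff_flr) <- as.character(prob_cutoffs)
  attr(df, "cutoff_flr") <- cutoff_flr
  df
}

#' Correctly localized PSMs at an FLR level
#'
#' @param curve Output of [flr_curve()].
#' @param flr_level FLR ceiling (e.g. 0.01).
#' @return Maximum TL over prefixes whose FLR is <= `flr_level` (0 when no
#'   prefix qualifies).
#' @export
correct_psms_at_flr <- function(curve, flr_level = 0.01) {
  ok <- curve$flr <= flr_level
  if (!any(ok)) return(0L)
  max(curve$TL[ok])
}
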