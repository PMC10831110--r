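# Pluggable base site-localization score. The reference implementation is a
# binomial score in the phosphoRS family: spectra are filtered to the 10
# most intense peaks per 100 Th, each theoretical ion is matched within the
# fragment tolerance, and the score is -10*log10 of the cumulative binomial
# tail P(X >= k) where k is the number of matched ions and p the chance of
# a random peak landing in one matching window. Externally computed base
# scores (e.g. phosphoRS output) can be attached instead via a 3-column TSV
# adapter.

#' Filter a spectrum to its most intense peaks per 100 Th window
#'
#' @param spec A [spectrum()].
#' @param per_window Peaks retained per 100 Th window (default 10).
#' @return The spectrum with filtered peak list.
#' @export
filter_top_peaks <- function(spec, per_window = 10L) {
  pk <- spec$peaks
  if (nrow(pk) == 0) return(spec)
  win <- floor(pk[, 1] / 100)
  keep <- unlist(lapply(split(seq_len(nrow(pk)), win), function(idx) {
    idx[order(pk[idx, 2], decreasing = TRUE)][seq_len(min(per_window,
                                                          length(idx)))]
  }), use.names = FALSE)
  spec$peaks <- pk[sort(keep), , drop = FALSE]
  spec
}

# log10 of the upper binomial tail P(X >= k), stable in log space.
log10_binom_tail <- function(k, n, p) {
  if (k <= 0) return(0)
  stats::pbinom(k - 1L, n, p, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Binomial base localization score for one isoform
#'
#' Higher scores indicate better-supported isoforms; a spectrum with no
#' matching ions scores 0. The per-window match probability is
#' `n_peaks * 2 * tol_da / span` of the filtered spectrum.
#'
#' @param isoform A [phospho_isoform()].
#' @param spec A [spectrum()].
#' @param tol_da Fragment matching tolerance in Da.
#' @param per_window Peak-filter depth per 100 Th (default 10).
#' @param filtered Optional pre-filtered spectrum (to amortize filtering
#'   across isoforms of one PSM).
#' @param frags Optional precomputed [theoretical_fragments()] table.
#' @return Nonnegative numeric score on a -10*log10 scale.
#' @export
binomial_isoform_score <- function(isoform, spec, tol_da = 0.02,
                                   per_window = 10L, filtered = NULL,
                                   frags = NULL) {
  if (nrow(spec$peaks) == 0) stop("empty spectrum: ", spec$spectrum_id)
  fs <- if (is.null(filtered)) filter_top_peaks(spec, per_window) else filtered
  pk <- fs$peaks
  if (nrow(pk) == 0) return(0)
  if (is.null(frags))
    frags <- theoretical_fragments(isoform, spec$precursor_charge)
  # primary b/y ions only: neutral-loss counts differ across isoforms and
  # would bias the trial count n between otherwise indistinguishable
  # candidates
  frags <- frags[!frags$loss, , drop = FALSE]
  n <- nrow(frags)
  mz <- pk[, 1]
  k <- sum(vapply(frags$mz, function(t) any(abs(mz - t) <= tol_da),
                  logical(1)))
  if (k == 0) return(0)
  span <- max(mz) - min(mz)
  if (span <= 0) span <- 100
  p <- min(0.5, max(1e-6, nrow(pk) * 2 * tol_da / span))
  max(0, -10 * log10_binom_tail(k, n, p))
}

#' Read externally computed base localization scores
#'
#' TSV adapter for phosphoRS-style output with columns `spectrum_id`,
#' `positions` (semicolon-separated 1-based sites) and `score`. Duplicate
#' rows for one isoform keep the maximum score (with a warning); rows for
#' unknown spectra are skipped with a warning.
#'
#' @param path Path to the TSV.
#' @param known_spectrum_ids Optional character vector of valid spectrum
#'   ids; rows outside it are skipped.
#' @return Data frame with columns `spectrum_id`, `positions`, `score`,
#'   keyed for lookup by [localize()].
#' @export
external_base_scores <- function(path, known_spectrum_ids = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("spectrum_id", "positions", "score")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("base-score table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("base-score table is empty (base scores required)")
  df$spectrum_id <- as.character(df$spectrum_id)
  if (!is.null(known_spectrum_ids)) {
    unknown <- !df$spectrum_id %in% known_spectrum_ids
    if (any(unknown)) {
      warning(sum(unknown), " base-score row(s) for unknown spectra skipped")
      df <- df[!unknown, , drop = FALSE]
    }
  }
  key <- paste0(df$spectrum_id, "|", df$positions)
  if (anyDuplicated(key)) {
    warning("duplicate base-score rows; keeping the maximum per isoform")
    df <- do.call(rbind, lapply(split(df, key), function(g)
      g[which.max(g$score), , drop = FALSE]))
  }
  rownames(df) <- paste0(df$spectrum_id, "|", df$positions)
  df
}
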