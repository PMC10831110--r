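# Combination of the base localization score with the deep-learning-derived
# spectrum-similarity and retention-time scores, base-10 softmax site
# probabilities, and per-PSM isoform selection.
#
# Method 1: base score only.           Method 2: base x SS factor.
# Method 3: base x RT factor.          Method 4: base x SS x RT factors.
# SS factor  = ss_i / max_i(ss_i); RT factor = rtr_i / max_i(rtr_i) (RTR
# mode) or min_i(drt_i) / drt_i (DRT mode), maxima/minima taken over the
# isoforms of one PSM.

DRT_FLOOR <- 0.01  # minutes; keeps min/drt defined on exact RT matches

#' Combine base, spectrum-similarity and RT scores into adjusted scores
#'
#' @param scores Data frame (or list) with numeric columns `base`, `ss`,
#'   `drt`, `rtr`, one row per isoform of a single PSM.
#' @param method Integer 1-4 selecting which factors enter.
#' @param rt_mode `"RTR"` or `"DRT"`.
#' @return Numeric vector of combined scores, one per isoform.
#' @export
combine_scores <- function(scores, method = 4L, rt_mode = c("RTR", "DRT")) {
  rt_mode <- match.arg(toupper(rt_mode), c("RTR", "DRT"))
  scores <- as.data.frame(scores)
  if (nrow(scores) == 0) stop("no isoform scores to combine")
  if (!method %in% 1:4) stop("method must be 1, 2, 3 or 4")
  out <- scores$base
  if (method %in% c(2L, 4L)) {
    mx <- max(scores$ss)
    if (mx <= 0) {
      warning("all spectrum-similarity scores are 0; SS factor neutralized")
      ssf <- rep(1, nrow(scores))
    } else ssf <- scores$ss / mx
    out <- out * ssf
  }
  if (method %in% c(3L, 4L)) {
    rtf <- if (rt_mode == "RTR") {
      mx <- max(scores$rtr)
      if (mx <= 0) rep(1, nrow(scores)) else scores$rtr / mx
    } else {
      drt <- pmax(scores$drt, DRT_FLOOR)
      min(drt) / drt
    }
    out <- out * rtf
  }
  out
}

#' Base-10 softmax site probabilities
#'
#' Probability_i = 10^(Score_i/10) / sum_j 10^(Score_j/10), computed in log
#' space for numerical stability.
#'
#' @param combined Numeric vector of combined scores (finite, >= 0).
#' @return Numeric probabilities summing to 1.
#' @export
softmax_probabilities <- function(combined) {
  if (any(!is.finite(combined)) || any(combined < 0))
    stop("combined scores must be finite and nonnegative")
  x <- combined * log(10) / 10
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

#' Localize the phosphosites of one PSM
#'
#' Enumerates the PSM's positional isoforms, scores each (base score,
#' spectrum similarity against its prediction, DRT/RTR against the observed
#' RT), combines the scores per `method`, applies the base-10 softmax, and
#' selects the isoform with the largest probability (ties broken by
#' lexicographically smallest position tuple). Marginal per-site
#' probabilities are the sums of probabilities of isoforms containing each
#' site.
#'
#' @param psm A [psm_record()] with >= 1 phospho group.
#' @param spec The matching [spectrum()].
#' @param predictions Named list of [prediction_record()]s keyed by
#'   [position_key()] of each isoform (must cover every enumerated
#'   isoform).
#' @param base_scores Optional named numeric vector of externally computed
#'   base scores keyed by [position_key()]; when `NULL` the bundled
#'   binomial score is used.
#' @param method Localization method 1-4 (see [combine_scores()]).
#' @param rt_mode `"RTR"` or `"DRT"`.
#' @param ss_method One of [SS_METHODS] (default `"Entropy"`).
#' @param tol_da Fragment matching tolerance in Da.
#' @param max_isoforms Enumeration cap (see [enumerate_isoforms()]).
#' @return List of class `phos_localization`: `spectrum_id`, `peptide`,
#'   `chosen` (row index), `table` (per-isoform data frame with columns
#'   `positions`, `base`, `ss`, `drt`, `rtr`, `combined`, `probability`),
#'   `site_probabilities` (named numeric), `method`, `unlocalizable`.
#' @export
localize <- function(psm, spec, predictions, base_scores = NULL,
                     method = 4L, rt_mode = "RTR", ss_method = "Entropy",
                     tol_da = 0.02, max_isoforms = 512L) {
  isoforms <- enumerate_isoforms(psm, max_isoforms)
  keys <- vapply(isoforms, position_key, "")
  filtered <- filter_top_peaks(spec)
  rows <- vector("list", length(isoforms))
  for (i in seq_along(isoforms)) {
    iso <- isoforms[[i]]
    key <- keys[i]
    pred <- predictions[[key]]
    if (is.null(pred))
      stop("missing prediction for isoform ", psm$peptide, " [", key,
           "] of spectrum ", psm$spectrum_id)
    frags <- theoretical_fragments(iso, spec$precursor_charge)
    base <- if (is.null(base_scores)) {
      binomial_isoform_score(iso, spec, tol_da, filtered = filtered,
                             frags = frags)
    } else {
      if (is.na(base_scores[key]))
        stop("missing base score for isoform ", key)
      unname(base_scores[key])
    }
    pair <- align_peaks(frags, pred, spec, tol_da)
    ss <- spectrum_similarity(pair, ss_method)
    rt <- rt_scores(pred$predicted_rt, max(spec$observed_rt, DRT_FLOOR))
    rows[[i]] <- data.frame(positions = key, base = base, ss = ss,
                            drt = rt$drt, rtr = rt$rtr,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$combined <- combine_scores(tab, method, rt_mode)
  tab$probability <- softmax_probabilities(tab$combined)
  # argmax probability; ties -> lexicographically smallest position tuple,
  # which is the enumeration order.
  chosen <- which(tab$probability >= max(tab$probability) - 1e-12)[1]
  all_sites <- sort(unique(unlist(lapply(isoforms,
                                         function(x) x$phospho_positions))))
  site_prob <- vapply(all_sites, function(s) {
    sum(tab$probability[vapply(isoforms,
                               function(x) s %in% x$phospho_positions,
                               logical(1))])
  }, numeric(1))
  names(site_prob) <- as.character(all_sites)
  structure(
    list(spectrum_id = psm$spectrum_id, peptide = psm$peptide,
         chosen = chosen, table = tab,
         site_probabilities = site_prob, method = method,
         unlocalizable = isTRUE(attr(isoforms, "unlocalizable"))),
    class = "phos_localization"
  )
}

#' Chosen-isoform summary of a localization result
#'
#' @param loc A `phos_localization` from [localize()].
#' @return One-row data frame: `spectrum_id`, `peptide`, `positions`,
#'   `probability` (of the chosen isoform), `min_site_probability`
#'   (minimum marginal over the chosen isoform's sites), `ss`, `rtr`,
#'   `drt`, `base`.
#' @export
localization_summary <- function(loc) {
  row <- loc$table[loc$chosen, , drop = FALSE]
  sites <- strsplit(row$positions, ";")[[1]]
  min_marg <- if (length(sites)) min(loc$site_probabilities[sites]) else NA_real_
  data.frame(spectrum_id = loc$spectrum_id, peptide = loc$peptide,
             positions = row$positions, probability = row$probability,
             min_site_probability = min_marg,
             ss = row$ss, rtr = row$rtr, drt = row$drt, base = row$base,
             stringsAsFactors = FALSE)
}
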