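# The six spectrum-similarity scores and the two retention-time difference
# scores. Entropy scores follow spectral-entropy similarity semantics:
# similarity = 1 - (2*S_AB - S_A - S_B)/ln 4 on sum-normalized spectra, the
# merged spectrum being the average of the two normalized spectra, with
# optional intensity weighting (I' = I^w, w = 0.25 + 0.5*S when S < 1.5)
# applied per spectrum before merging.

#' Supported spectrum-similarity methods
#' @export
SS_METHODS <- c("DP", "srDP", "SA", "PCC", "unwEntropy", "Entropy")

shannon_entropy <- function(p) {
  # p need not be normalized here; callers pass sum-normalized vectors.
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log(p))
}

sum_normalize <- function(x) {
  s <- sum(x)
  if (s <= 0) return(x)
  x / s
}

entropy_weight <- function(S) if (S < 1.5) 0.25 + S * 0.5 else 1

weighted_normalize <- function(x) {
  p <- sum_normalize(x)
  w <- entropy_weight(shannon_entropy(p))
  sum_normalize(p^w)
}

entropy_similarity <- function(a, b, weighted = FALSE) {
  p <- if (weighted) weighted_normalize(a) else sum_normalize(a)
  e <- if (weighted) weighted_normalize(b) else sum_normalize(b)
  s_p <- shannon_entropy(p)
  s_e <- shannon_entropy(e)
  s_pe <- shannon_entropy((p + e) / 2)
  1 - (2 * s_pe - s_p - s_e) / log(4)
}

#' Spectrum similarity between predicted and experimental intensities
#'
#' Scores the agreement of the aligned intensity vectors Ip (predicted) and
#' Ie (experimental). Methods: `DP` normalized dot product, `srDP` dot
#' product of square-root intensities, `SA` spectral contrast angle
#' (1 - 2*arccos(unit(Ip).unit(Ie))/pi), `PCC` Pearson correlation,
#' `unwEntropy` spectral entropy similarity on sum-normalized spectra,
#' `Entropy` the same on intensity-weighted spectra. All but PCC lie in
#' \[0,1\]; PCC lies in \[-1,1\]. An all-zero vector on either side yields 0;
#' a constant vector yields PCC 0.
#'
#' @param pair A `phos_aligned` object from [align_peaks()], or a list with
#'   numeric `Ip` and `Ie` of equal length.
#' @param method One of [SS_METHODS].
#' @return Numeric similarity score.
#' @export
spectrum_similarity <- function(pair, method = "Entropy") {
  if (!method %in% SS_METHODS)
    stop("unknown spectrum-similarity method: ", method)
  a <- pair$Ip; b <- pair$Ie
  if (length(a) != length(b) || length(a) == 0)
    stop("Ip and Ie must be nonempty vectors of equal length")
  if (all(a == 0) || all(b == 0)) return(0)
  switch(method,
    DP = sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
    srDP = {
      sa <- sqrt(a); sb <- sqrt(b)
      sum(sa * sb) / sqrt(sum(a) * sum(b))
    },
    SA = {
      ua <- a / sqrt(sum(a^2)); ub <- b / sqrt(sum(b^2))
      d <- min(1, max(-1, sum(ua * ub)))
      1 - 2 * acos(d) / pi
    },
    PCC = {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) 0
      else stats::cor(a, b)
    },
    unwEntropy = entropy_similarity(a, b, weighted = FALSE),
    Entropy = entropy_similarity(a, b, weighted = TRUE)
  )
}

#' Retention-time difference scores
#'
#' DRT = |RTp - RTe| (minutes; closer to 0 is better) and
#' RTR = min(RTp, RTe)/max(RTp, RTe) (closer to 1 is better).
#'
#' @param rtp Predicted RT in minutes (> 0).
#' @param rte Observed RT in minutes (> 0).
#' @return List with `drt` and `rtr`.
#' @export
rt_scores <- function(rtp, rte) {
  if (!is.finite(rtp) || !is.finite(rte) || rtp <= 0 || rte <= 0)
    stop("retention times must be positive and finite (minutes)")
  list(drt = abs(rtp - rte), rtr = min(rtp, rte) / max(rtp, rte))
}
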