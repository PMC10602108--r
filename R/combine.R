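#' Harmonic mean of p-values
#'
#' The community-level test statistic: `J / sum(1/p)`.  Small values are
#' more significant; the statistic is dominated by the smallest individual
#' p-values.  Its significance is assessed against permutation replicates,
#' never against an asymptotic distribution.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return the harmonic mean (numeric scalar).
#' @export
harmonicMeanStat <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  length(pvals) / sum(1 / pvals)
}

#' Cauchy combination of p-values
#'
#' Combines possibly correlated p-values: `T = sum(w * tan((0.5 - p) * pi))`
#' and the combined p-value is `0.5 - atan(T)/pi`.  Valid under arbitrary
#' dependence in the tail.  P-values numerically at 1 are clipped to
#' `1 - 1e-15`, and at 0 to `1e-15`.
#'
#' @param pvals numeric vector of p-values.
#' @param weights non-negative weights, normalized to sum to 1 (default
#'   equal).
#' @return combined p-value (numeric scalar).
#' @export
cauchyCombine <- function(pvals, weights = NULL) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  if (is.null(weights)) weights <- rep(1 / length(pvals), length(pvals))
  if (length(weights) != length(pvals) || any(weights < 0))
    stop("weights must be non-negative and match pvals in length")
  weights <- weights / sum(weights)
  p <- pmin(pmax(pvals, 1e-15), 1 - 1e-15)
  stat <- sum(weights * tan((0.5 - p) * pi))
  0.5 - atan(stat) / pi
}

#' Benjamini-Hochberg adjustment and detection
#'
#' Step-up BH q-values with the detected set at a nominal FDR level.
#'
#' @param pvals numeric vector of p-values (NAs allowed; excluded and
#'   returned as NA).
#' @param q nominal FDR level, default 0.2.
#' @return list with `qvalues` (same length/order as `pvals`) and
#'   `detected` (integer indices with q-value at most `q`).
#' @export
bhAdjust <- function(pvals, q = 0.2) {
  qv <- p.adjust(pvals, method = "BH")
  list(qvalues = qv, detected = which(!is.na(qv) & qv <= q))
}
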