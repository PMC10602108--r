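#' Select the reference taxon of a merged study
#'
#' Every other taxon is compared to the reference in the pairwise logistic
#' model, so the reference must be well measured by both protocols.  The
#' choice is the taxon with the largest mean relative abundance across both
#' data sources: each source's mean relative abundance is computed over its
#' own sequenced samples (relative abundances within that source over the
#' retained taxa), and the two source means are averaged unweighted.  Only
#' taxa with non-zero mean abundance in both sources are eligible, so the
#' reference is among the top abundant taxa in each source.  Ties break to
#' the lexicographically smaller taxon ID.
#'
#' @param study a [MergedStudy-class] (normally after filtering).
#' @return the reference taxon ID (character scalar).
#' @export
selectReferenceTaxon <- function(study) {
  mra <- function(m) {
    rows <- rowSums(!is.na(m)) > 0
    m <- m[rows, , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    m[is.na(m)] <- 0
    ra <- m / pmax(rowSums(m), .Machine$double.eps)
    colMeans(ra)
  }
  r16 <- mra(study@counts16s)
  rsm <- mra(study@countsSMS)
  if (is.null(r16) || is.null(rsm)) {
    one <- if (is.null(r16)) rsm else r16
    return(names(one)[order(-one, names(one))][1])
  }
  eligible <- r16 > 0 & rsm > 0
  if (!any(eligible))
    stop("no taxon observed in both sources; integration impossible")
  score <- (r16 + rsm) / 2
  score[!eligible] <- -Inf
  ord <- order(-score, names(score))
  ref <- names(score)[ord[1]]
  if (sum(score == score[ref]) > 1)
    message("reference-taxon tie broken lexicographically: ", ref)
  ref
}
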