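#' Single-source rare-taxon filter
#'
#' Removes taxa present (non-zero) in fewer than `threshold` of the
#' samples.  "Fewer than" is strict: a taxon present in exactly
#' `threshold` of samples is kept.
#'
#' @param t a [TaxaCountTable-class].
#' @param threshold presence fraction, default 0.2.
#' @return list with `table` (filtered [TaxaCountTable-class]) and `report`
#'   (data.frame: taxon, presence fraction, kept flag, reason code).
#' @export
locomFilter <- function(t, threshold = 0.2) {
  m <- counts(t)
  frac <- colMeans(m > 0)
  kept <- frac >= threshold
  report <- data.frame(taxon = colnames(m), presence = unname(frac),
                       kept = unname(kept),
                       reason = ifelse(kept, "kept",
                                       "presence_below_threshold"),
                       stringsAsFactors = FALSE)
  if (!any(kept)) stop("all taxa dropped; consider lowering the threshold")
  out <- new("TaxaCountTable", counts = m[, kept, drop = FALSE],
             source = t@source, isRelative = t@isRelative)
  list(table = out, report = report)
}

#' Integrative rare-taxon filter
#'
#' A taxon is analyzable when enough samples carry information on it from at
#' least one source.  It is kept if (a) the fraction of samples with a
#' non-zero count in at least one source that sequenced them exceeds
#' `threshold` (pooled presence), or (b) it passes
#' the single-source presence filter within either source alone -- the
#' single-source rule covers the case where one source's data for the taxon
#' consist entirely of zeros.
#'
#' @param study a [MergedStudy-class].
#' @param threshold presence fraction, default 0.2.
#' @return list with `study` (filtered [MergedStudy-class]) and `report`
#'   (data.frame with per-rule presence fractions and reason codes).
#' @export
com2seqFilter <- function(study, threshold = 0.2) {
  m16 <- study@counts16s
  msm <- study@countsSMS
  pos16 <- !is.na(m16) & m16 > 0
  possm <- !is.na(msm) & msm > 0
  seqAny <- !is.na(m16) | !is.na(msm)
  pooled <- colSums(pos16 | possm) / pmax(1, colSums(seqAny))
  f16 <- colSums(pos16) / pmax(1, colSums(!is.na(m16)))
  fsm <- colSums(possm) / pmax(1, colSums(!is.na(msm)))
  f16[colSums(!is.na(m16)) == 0] <- NA
  fsm[colSums(!is.na(msm)) == 0] <- NA
  kept <- pooled > threshold |
    (!is.na(f16) & f16 >= threshold) | (!is.na(fsm) & fsm >= threshold)
  reason <- ifelse(pooled > threshold, "pooled_presence",
            ifelse(kept, "single_source_presence", "presence_below_threshold"))
  report <- data.frame(taxon = colnames(m16), pooled = unname(pooled),
                       presence16s = unname(f16), presenceSMS = unname(fsm),
                       kept = unname(kept), reason = reason,
                       stringsAsFactors = FALSE)
  if (!any(kept)) stop("all taxa dropped; consider lowering the threshold")
  out <- new("MergedStudy",
             counts16s = m16[, kept, drop = FALSE],
             countsSMS = msm[, kept, drop = FALSE],
             stratum = study@stratum, metadata = study@metadata,
             traitName = study@traitName,
             covariateNames = study@covariateNames,
             relative = study@relative)
  list(study = out, report = report)
}
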