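#' Single-source differential-abundance analysis
#'
#' The single-source special case of the estimating-equation machinery: the
#' rare-taxon presence filter, the reference taxon with the largest mean
#' relative abundance in this source, count-scheme weights (the other
#' source's weights are zero), unstratified trait-residual permutation, and
#' the harmonic-mean community test.
#'
#' @param t a [TaxaCountTable-class].
#' @inheritParams com2seq
#' @return a [Com2seqResult-class].
#' @export
locomSingle <- function(t, meta, trait, covariates = character(),
                        nPerm = 10000, seed = 1, filterThreshold = 0.2,
                        fdr = 0.2, sparseMin = 5) {
  t16s <- if (tableSource(t) == "16S") t else NULL
  tsms <- if (tableSource(t) == "SMS") t else NULL
  study <- mergeSources(t16s, tsms, meta, trait, covariates)
  flt <- .singleFilter(study, filterThreshold)
  study <- flt$study
  ref <- selectReferenceTaxon(study)
  traitMat <- .designMatrix(study@metadata, study@traitName)
  covMat <- .designMatrix(study@metadata, study@covariateNames)
  plan <- buildPermutationPlan(traitMat, covMat, stratum(study),
                               nPerm = nPerm, seed = seed, scheme = "one")
  res <- .eeEngine(study, plan, ref, covMat = covMat, fdr = fdr,
                   sparseMin = sparseMin,
                   method = sprintf("single-source (%s)", tableSource(t)))
  res@filterReport <- flt$report
  res
}

# single-source presence filter applied through the merged representation
.singleFilter <- function(study, threshold) {
  m16 <- study@counts16s
  msm <- study@countsSMS
  present <- function(m) {
    seqd <- colSums(!is.na(m))
    frac <- colSums(!is.na(m) & m > 0) / pmax(1, seqd)
    frac[seqd == 0] <- NA
    frac
  }
  f <- ifelse(is.na(present(m16)), present(msm), present(m16))
  kept <- !is.na(f) & f >= threshold
  if (!any(kept)) stop("all taxa dropped; consider lowering the threshold")
  report <- data.frame(taxon = colnames(m16), presence = unname(f),
                       kept = unname(kept),
                       reason = ifelse(kept, "kept",
                                       "presence_below_threshold"),
                       stringsAsFactors = FALSE)
  out <- new("MergedStudy", counts16s = m16[, kept, drop = FALSE],
             countsSMS = msm[, kept, drop = FALSE],
             stratum = study@stratum, metadata = study@metadata,
             traitName = study@traitName,
             covariateNames = study@covariateNames,
             relative = study@relative)
  list(study = out, report = report)
}

#' Build the augmented (pooled) count table
#'
#' Union of samples and taxa across the two sources; cells measured by both
#' sources hold the sum of the two read counts, cells measured by one source
#' copy its count (no depth rescaling), and cells measured by neither are
#' filled with zeros.  The zero-filling is what makes the pooled-count
#' comparator invalid under partial overlap when the trait distribution
#' differs between strata.
#'
#' @param t16s,tsms [TaxaCountTable-class] objects.
#' @return list with `counts` (union matrix) and `provenance` (character
#'   matrix: "pooled", "16S", "SMS", or "zero_filled").
#' @export
augmentedTable <- function(t16s, tsms) {
  samples <- union(sampleIDs(t16s), sampleIDs(tsms))
  taxa <- union(taxonIDs(t16s), taxonIDs(tsms))
  a16 <- matrix(NA_real_, length(samples), length(taxa),
                dimnames = list(samples, taxa))
  asm <- a16
  a16[sampleIDs(t16s), taxonIDs(t16s)] <- counts(t16s)
  asm[sampleIDs(tsms), taxonIDs(tsms)] <- counts(tsms)
  pooled <- ifelse(is.na(a16), 0, a16) + ifelse(is.na(asm), 0, asm)
  prov <- matrix("zero_filled", length(samples), length(taxa),
                 dimnames = list(samples, taxa))
  prov[!is.na(a16) & !is.na(asm)] <- "pooled"
  prov[!is.na(a16) & is.na(asm)] <- "16S"
  prov[is.na(a16) & !is.na(asm)] <- "SMS"
  list(counts = pooled, provenance = prov)
}

#' Pooled-count comparator (Com-count)
#'
#' Pools the two tables into the augmented table ([augmentedTable()]) and
#' runs the single-source analysis on it: single-source presence filter,
#' count-scheme weights, unstratified permutation (the augmented table has a
#' single stratum by construction).  Kept as described because its failure
#' mode under partial overlap -- zero-filled cells correlating with the
#' trait -- is part of what the benchmark measures; its results also tend to
#' be dominated by the deeper-sequenced source.
#'
#' @inheritParams com2seq
#' @return a [Com2seqResult-class].
#' @export
comCount <- function(t16s, tsms, meta, trait, covariates = character(),
                     nPerm = 10000, seed = 1, filterThreshold = 0.2,
                     fdr = 0.2, sparseMin = 5) {
  aug <- augmentedTable(t16s, tsms)
  keep <- rowSums(aug$counts) > 0
  tab <- taxaCountTable(aug$counts[keep, , drop = FALSE], source = "16S")
  res <- locomSingle(tab, meta, trait, covariates, nPerm = nPerm,
                     seed = seed, filterThreshold = filterThreshold,
                     fdr = fdr, sparseMin = sparseMin)
  res@method <- "Com-count"
  res
}

#' P-value-combination comparator (Com-p)
#'
#' Runs the single-source analysis separately on each table (each with its
#' own filter and reference taxon), Cauchy-combines the two p-values at each
#' overlapping taxon, passes single-source taxa through unchanged, applies
#' BH to the pooled p-value list, and Cauchy-combines all per-taxon p-values
#' (equal weights) into the community-level p-value.  Structurally its
#' global p-value can never be more significant than the most significant
#' taxon p-value, and taxa failing both single-source filters are absent.
#'
#' @inheritParams com2seq
#' @return a [Com2seqResult-class] (`globalStat` is `NA`; the global test is
#'   a p-value combination, not permutation-based).
#' @export
comP <- function(t16s, tsms, meta, trait, covariates = character(),
                 nPerm = 10000, seed = 1, filterThreshold = 0.2,
                 fdr = 0.2, sparseMin = 5) {
  r16 <- locomSingle(t16s, meta, trait, covariates, nPerm = nPerm,
                     seed = seed, filterThreshold = filterThreshold,
                     fdr = fdr, sparseMin = sparseMin)
  rsm <- locomSingle(tsms, meta, trait, covariates, nPerm = nPerm,
                     seed = seed + 1L, filterThreshold = filterThreshold,
                     fdr = fdr, sparseMin = sparseMin)
  p16 <- setNames(taxonResults(r16)$p.omnibus, taxonResults(r16)$taxon)
  psm <- setNames(taxonResults(rsm)$p.omnibus, taxonResults(rsm)$taxon)
  p16 <- p16[!is.na(p16)]
  psm <- psm[!is.na(psm)]
  taxa <- union(names(p16), names(psm))
  comb <- vapply(taxa, function(j) {
    ps <- c(p16[j], psm[j])
    ps <- ps[!is.na(ps)]
    if (length(ps) == 2) cauchyCombine(ps) else ps
  }, numeric(1))
  adj <- bhAdjust(comb, q = fdr)
  tt <- data.frame(taxon = taxa,
                   p.16s = unname(p16[taxa]), p.sms = unname(psm[taxa]),
                   p.omnibus = unname(comb), qvalue = adj$qvalues,
                   detected = seq_along(taxa) %in% adj$detected,
                   stringsAsFactors = FALSE)
  new("Com2seqResult", method = "Com-p", taxonTable = tt,
      globalP = cauchyCombine(comb), globalStat = NA_real_,
      referenceTaxon = c(referenceTaxon(r16), referenceTaxon(rsm)),
      nPerm = nPerm, fdrNominal = fdr, filterReport = data.frame())
}
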