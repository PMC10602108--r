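#' @import methods
#' @importFrom stats lm.fit median p.adjust plogis qlogis rbinom rgamma
#'   rmultinom rnorm runif complete.cases ks.test quantile setNames
#' @importFrom utils read.delim write.table head
#' @importFrom Rcpp sourceCpp
#' @useDynLib com2seq, .registration = TRUE
NULL

#' One source's taxa count table
#'
#' Samples-by-taxa matrix of read counts (or relative abundances) from a
#' single sequencing source, 16S amplicon ("16S") or shotgun metagenomics
#' ("SMS").  Rows are samples, columns are taxa; row and column names carry
#' the IDs.  In relative-abundance mode each row sums to one.
#'
#' @slot counts numeric matrix, samples x taxa, non-negative; rownames are
#'   sample IDs, colnames are taxon IDs.
#' @slot source character, "16S" or "SMS".
#' @slot isRelative logical; `TRUE` when entries are proportions rather than
#'   read counts.
#' @export
setClass("TaxaCountTable",
  representation(counts = "matrix", source = "character",
                 isRelative = "logical"),
  prototype(isRelative = FALSE))

setValidity("TaxaCountTable", function(object) {
  m <- object@counts
  msg <- character()
  if (!is.numeric(m)) msg <- c(msg, "counts must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have sample rownames and taxon colnames")
  if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate sample IDs")
  if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate taxon IDs")
  if (any(!is.finite(m)) || any(m < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  if (!object@source %in% c("16S", "SMS"))
    msg <- c(msg, "source must be '16S' or 'SMS'")
  if (nrow(m) > 0 && any(rowSums(m) == 0))
    msg <- c(msg, "samples with zero library size are not allowed")
  if (isTRUE(object@isRelative) && nrow(m) > 0 &&
      any(abs(rowSums(m) - 1) > 1e-8))
    msg <- c(msg, "relative-abundance rows must sum to 1 (tol 1e-8)")
  if (length(msg)) msg else TRUE
})

#' Union-aligned two-source study
#'
#' Both count tables aligned to the union of samples and the union of taxa.
#' Cells a source did not measure are `NA` (sample not sequenced by that
#' source, or taxon absent from that source's table) -- never zero: an
#' observed zero count is data, a missing cell is not.  Each sample carries a
#' stratum label recording which sources sequenced it.
#'
#' @slot counts16s,countsSMS numeric matrices over the union index; `NA`
#'   marks cells with no measurement.
#' @slot stratum factor over samples with levels BOTH, S16_ONLY, SMS_ONLY.
#' @slot metadata data.frame, one row per union sample (sample IDs as
#'   rownames) holding the trait and any covariates.
#' @slot traitName,covariateNames names of the metadata columns used as the
#'   trait and as confounding covariates.
#' @slot relative logical of length 2: is each source's table proportions?
#' @export
setClass("MergedStudy",
  representation(counts16s = "matrix", countsSMS = "matrix",
                 stratum = "factor", metadata = "data.frame",
                 traitName = "character", covariateNames = "character",
                 relative = "logical"))

setValidity("MergedStudy", function(object) {
  msg <- character()
  n <- nrow(object@counts16s)
  if (!identical(dim(object@counts16s), dim(object@countsSMS)))
    msg <- c(msg, "the two aligned matrices must have identical dimensions")
  if (!identical(rownames(object@counts16s), rownames(object@countsSMS)) ||
      !identical(colnames(object@counts16s), colnames(object@countsSMS)))
    msg <- c(msg, "the two aligned matrices must share dimnames")
  if (length(object@stratum) != n)
    msg <- c(msg, "one stratum label per sample is required")
  if (!all(levels(object@stratum) == c("BOTH", "S16_ONLY", "SMS_ONLY")))
    msg <- c(msg, "stratum levels must be BOTH, S16_ONLY, SMS_ONLY")
  if (nrow(object@metadata) != n)
    msg <- c(msg, "metadata must have one row per sample")
  has16 <- rowSums(!is.na(object@counts16s)) > 0
  hasSMS <- rowSums(!is.na(object@countsSMS)) > 0
  want <- factor(ifelse(has16 & hasSMS, "BOTH",
                 ifelse(has16, "S16_ONLY", "SMS_ONLY")),
                 levels = c("BOTH", "S16_ONLY", "SMS_ONLY"))
  if (n > 0 && !identical(as.character(want), as.character(object@stratum)))
    msg <- c(msg, "stratum labels inconsistent with measurement missingness")
  if (length(msg)) msg else TRUE
})

#' Differential-abundance test result
#'
#' Per-taxon and community-level results from any of the analysis pipelines
#' (integrative, pooled-count, p-value-combination, single-source).
#'
#' @slot method label of the pipeline that produced the result.
#' @slot taxonTable data.frame with one row per analyzed taxon: per-scheme
#'   p-values (`p.count`, `p.ra` where available), omnibus p-value
#'   (`p.omnibus`), BH q-value, and detection flag at the nominal FDR.
#' @slot globalP community-level p-value.
#' @slot globalStat observed harmonic-mean statistic (or `NA` where the
#'   global test is a p-value combination rather than permutation-based).
#' @slot referenceTaxon taxon all others were compared to (per source run
#'   for the p-value-combination pipeline, collapsed to a label).
#' @slot nPerm number of permutation replicates used.
#' @slot fdrNominal nominal FDR used for the detection flag.
#' @slot filterReport data.frame of kept/dropped taxa with reason codes.
#' @export
setClass("Com2seqResult",
  representation(method = "character", taxonTable = "data.frame",
                 globalP = "numeric", globalStat = "numeric",
                 referenceTaxon = "character", nPerm = "numeric",
                 fdrNominal = "numeric", filterReport = "data.frame"))

setValidity("Com2seqResult", function(object) {
  msg <- character()
  p <- object@taxonTable$p.omnibus
  if (!is.null(p) && length(p) && (any(p <= 0, na.rm = TRUE) ||
                                   any(p > 1, na.rm = TRUE)))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(object@globalP) == 1 && !is.na(object@globalP) &&
      (object@globalP <= 0 || object@globalP > 1))
    msg <- c(msg, "global p-value must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
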