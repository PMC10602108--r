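#' Merge 16S and SMS tables into a union-aligned study
#'
#' Aligns both count tables to the union of their samples and the union of
#' their taxa (matching is by exact ID string), assigns each sample to a
#' stratum (`BOTH`, `S16_ONLY`, `SMS_ONLY`) according to which sources
#' sequenced it, and attaches the metadata.  Cells a source did not measure
#' become `NA`: a sample not sequenced by a source is missing data, not a
#' zero count.  Samples lacking metadata (or a trait value) are dropped with
#' a warning.
#'
#' @param t16s,tsms [TaxaCountTable-class] objects for the two sources.
#'   Either may be `NULL` for a degenerate single-source study.
#' @param meta data.frame of sample metadata, sample IDs as rownames.
#' @param trait name of the trait column in `meta` (may name several columns
#'   for a multivariate trait).
#' @param covariates character vector of confounder column names in `meta`
#'   (default none).
#' @return a [MergedStudy-class] object.
#' @export
mergeSources <- function(t16s, tsms, meta, trait, covariates = character()) {
  if (is.null(t16s) && is.null(tsms)) stop("both sources are NULL")
  if (!is.null(t16s) && tableSource(t16s) != "16S")
    stop("t16s must have source '16S'")
  if (!is.null(tsms) && tableSource(tsms) != "SMS")
    stop("tsms must have source 'SMS'")
  s16 <- if (is.null(t16s)) character() else sampleIDs(t16s)
  ssm <- if (is.null(tsms)) character() else sampleIDs(tsms)
  # canonical (sorted) sample order so that permutation inference does not
  # depend on the order samples appear in the input tables
  samples <- sort(union(s16, ssm))
  if (length(samples) == 0) stop("empty sample union")
  taxa <- union(if (is.null(t16s)) character() else taxonIDs(t16s),
                if (is.null(tsms)) character() else taxonIDs(tsms))

  miss <- setdiff(c(trait, covariates), colnames(meta))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  keep <- samples %in% rownames(meta)
  if (any(!keep))
    warning(sum(!keep), " sample(s) without metadata dropped: ",
            paste(head(samples[!keep]), collapse = ", "))
  samples <- samples[keep]
  md <- meta[samples, c(trait, covariates), drop = FALSE]
  ok <- complete.cases(md[, trait, drop = FALSE])
  if (any(!ok)) {
    warning(sum(!ok), " sample(s) with missing trait dropped")
    samples <- samples[ok]
    md <- md[ok, , drop = FALSE]
  }
  if (length(samples) == 0) stop("no samples with usable metadata")

  align <- function(tab) {
    m <- matrix(NA_real_, length(samples), length(taxa),
                dimnames = list(samples, taxa))
    if (!is.null(tab)) {
      rows <- intersect(samples, sampleIDs(tab))
      m[rows, taxonIDs(tab)] <- counts(tab)[rows, , drop = FALSE]
    }
    m
  }
  m16 <- align(t16s)
  msm <- align(tsms)
  has16 <- samples %in% s16
  hasSMS <- samples %in% ssm
  strat <- factor(ifelse(has16 & hasSMS, "BOTH",
                  ifelse(has16, "S16_ONLY", "SMS_ONLY")),
                  levels = c("BOTH", "S16_ONLY", "SMS_ONLY"))
  rownames(md) <- samples
  new("MergedStudy", counts16s = m16, countsSMS = msm, stratum = strat,
      metadata = md, traitName = trait,
      covariateNames = as.character(covariates),
      relative = c(if (is.null(t16s)) FALSE else isRelative(t16s),
                   if (is.null(tsms)) FALSE else isRelative(tsms)))
}

#' Split a merged study back into its source tables
#'
#' Inverse of [mergeSources()]: recovers each source's table restricted to
#' the samples it sequenced and the taxa present in that source's original
#' table (columns that are all-`NA` for the source are removed).
#'
#' @param study a [MergedStudy-class].
#' @param source `"16S"` or `"SMS"`.
#' @return a [TaxaCountTable-class], or `NULL` when the source has no samples.
#' @export
splitSource <- function(study, source = c("16S", "SMS")) {
  source <- match.arg(source)
  m <- counts(study, source)
  rows <- rowSums(!is.na(m)) > 0
  if (!any(rows)) return(NULL)
  m <- m[rows, , drop = FALSE]
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  taxaCountTable(m, source = source,
                 relative = study@relative[if (source == "16S") 1 else 2])
}
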