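#' @rdname TaxaCountTable-class
#' @param object,x a `TaxaCountTable`, `MergedStudy` or `Com2seqResult`.
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname TaxaCountTable-class
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @rdname TaxaCountTable-class
#' @export
setGeneric("taxonIDs", function(object) standardGeneric("taxonIDs"))

#' @rdname TaxaCountTable-class
#' @export
setGeneric("tableSource", function(object) standardGeneric("tableSource"))

#' @rdname TaxaCountTable-class
#' @export
setGeneric("isRelative", function(object) standardGeneric("isRelative"))

#' @rdname MergedStudy-class
#' @export
setGeneric("stratum", function(object) standardGeneric("stratum"))

#' @rdname Com2seqResult-class
#' @export
setGeneric("taxonResults", function(object) standardGeneric("taxonResults"))

#' @rdname Com2seqResult-class
#' @export
setGeneric("globalPValue", function(object) standardGeneric("globalPValue"))

#' @rdname Com2seqResult-class
#' @export
setGeneric("detectedTaxa", function(object, ...) standardGeneric("detectedTaxa"))

#' @rdname Com2seqResult-class
#' @export
setGeneric("referenceTaxon", function(object) standardGeneric("referenceTaxon"))

#' @name counts,TaxaCountTable-method
#' @rdname TaxaCountTable-class
#' @param ... unused.
setMethod("counts", "TaxaCountTable", function(object, ...) object@counts)

#' @rdname TaxaCountTable-class
setMethod("sampleIDs", "TaxaCountTable",
          function(object) rownames(object@counts))

#' @rdname TaxaCountTable-class
setMethod("taxonIDs", "TaxaCountTable",
          function(object) colnames(object@counts))

#' @rdname TaxaCountTable-class
setMethod("tableSource", "TaxaCountTable", function(object) object@source)

#' @rdname TaxaCountTable-class
setMethod("isRelative", "TaxaCountTable", function(object) object@isRelative)

#' @rdname MergedStudy-class
#' @param source which source's aligned matrix to return.
setMethod("counts", "MergedStudy", function(object, source = c("16S", "SMS"), ...) {
  source <- match.arg(source)
  if (source == "16S") object@counts16s else object@countsSMS
})

#' @rdname MergedStudy-class
setMethod("sampleIDs", "MergedStudy",
          function(object) rownames(object@counts16s))

#' @rdname MergedStudy-class
setMethod("taxonIDs", "MergedStudy",
          function(object) colnames(object@counts16s))

#' @rdname MergedStudy-class
setMethod("stratum", "MergedStudy", function(object) object@stratum)

#' @rdname Com2seqResult-class
setMethod("taxonResults", "Com2seqResult", function(object) object@taxonTable)

#' @rdname Com2seqResult-class
setMethod("globalPValue", "Com2seqResult", function(object) object@globalP)

#' @rdname Com2seqResult-class
#' @param fdr optional FDR level overriding the one stored in the object.
setMethod("detectedTaxa", "Com2seqResult", function(object, fdr = NULL, ...) {
  tt <- object@taxonTable
  if (is.null(fdr)) return(tt$taxon[which(tt$detected)])
  tt$taxon[which(!is.na(tt$qvalue) & tt$qvalue <= fdr)]
})

#' @rdname Com2seqResult-class
setMethod("referenceTaxon", "Com2seqResult",
          function(object) object@referenceTaxon)

setMethod("show", "TaxaCountTable", function(object) {
  cat(sprintf("TaxaCountTable [%s%s]: %d samples x %d taxa\n",
              object@source, if (object@isRelative) ", relative" else "",
              nrow(object@counts), ncol(object@counts)))
  if (nrow(object@counts) && !object@isRelative)
    cat(sprintf("  library sizes: median %s (range %s-%s)\n",
                format(median(rowSums(object@counts))),
                format(min(rowSums(object@counts))),
                format(max(rowSums(object@counts)))))
})

setMethod("show", "MergedStudy", function(object) {
  tab <- table(object@stratum)
  cat(sprintf("MergedStudy: %d samples x %d taxa\n",
              nrow(object@counts16s), ncol(object@counts16s)))
  cat(sprintf("  strata: BOTH=%d, 16S-only=%d, SMS-only=%d\n",
              tab["BOTH"], tab["S16_ONLY"], tab["SMS_ONLY"]))
  cat(sprintf("  trait: %s; covariates: %s\n", object@traitName,
              if (length(object@covariateNames))
                paste(object@covariateNames, collapse = ", ") else "none"))
})

setMethod("show", "Com2seqResult", function(object) {
  cat(sprintf("%s result: %d taxa tested, reference '%s'\n", object@method,
              nrow(object@taxonTable),
              paste(object@referenceTaxon, collapse = "/")))
  cat(sprintf("  global p-value: %.4g (%d permutations)\n",
              object@globalP, object@nPerm))
  det <- object@taxonTable$taxon[which(object@taxonTable$detected)]
  cat(sprintf("  detected at FDR %.0f%%: %d taxon/taxa%s\n",
              100 * object@fdrNominal, length(det),
              if (length(det) && length(det) <= 8)
                paste0(" (", paste(det, collapse = ", "), ")") else ""))
})
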