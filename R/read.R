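#' Construct a TaxaCountTable from a matrix
#'
#' Validates and wraps a samples-by-taxa matrix.  Samples with zero library
#' size are removed with a warning (a row of all zeros carries no
#' compositional information and would break the relative-abundance
#' normalization); samples below `minLibSize` total reads are likewise
#' dropped.
#'
#' @param counts numeric matrix, samples in rows (rownames = sample IDs),
#'   taxa in columns (colnames = taxon IDs).
#' @param source `"16S"` or `"SMS"`.
#' @param relative logical; `TRUE` if entries are proportions (rows must sum
#'   to 1).
#' @param minLibSize minimum library size; samples below it are dropped with
#'   a warning.  Default 0, i.e. only all-zero rows are rejected.  Studies
#'   often apply a sequencing-QC threshold such as 5,000 reads here.
#' @return a [TaxaCountTable-class] object.
#' @export
taxaCountTable <- function(counts, source = c("16S", "SMS"),
                           relative = FALSE, minLibSize = 0) {
  source <- match.arg(source)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample rownames and taxon colnames")
  if (any(!is.finite(counts)))
    stop("counts contain non-finite entries")
  if (any(counts < 0))
    stop("negative entries at ",
         paste(head(which(counts < 0)), collapse = ", "))
  libs <- rowSums(counts)
  drop <- libs == 0 | (!relative & libs < minLibSize)
  if (any(drop)) {
    warning(sum(drop), " sample(s) dropped for library size ",
            if (minLibSize > 0) paste0("< ", minLibSize) else "of zero",
            ": ", paste(head(rownames(counts)[drop]), collapse = ", "))
    counts <- counts[!drop, , drop = FALSE]
  }
  if (nrow(counts) == 0) stop("no samples left after library-size filtering")
  new("TaxaCountTable", counts = counts, source = source,
      isRelative = isTRUE(relative))
}

#' Read a taxa count table from TSV or BIOM
#'
#' TSV layout: rectangular table, header row of taxon IDs, first column
#' sample IDs (set `transpose = TRUE` for the taxa-as-rows dialect).  Files
#' ending in `.biom` are read with the biomformat package.
#'
#' @param path file path.
#' @param transpose logical; `TRUE` if the file stores taxa as rows and
#'   samples as columns.
#' @inheritParams taxaCountTable
#' @return a [TaxaCountTable-class] object.
#' @export
readCountTable <- function(path, source = c("16S", "SMS"), relative = FALSE,
                           transpose = FALSE, minLibSize = 0) {
  source <- match.arg(source)
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading .biom files requires the biomformat package")
    m <- as(biomformat::biom_data(biomformat::read_biom(path)), "matrix")
    m <- t(m)  # biom stores taxa x samples
  } else {
    df <- tryCatch(read.delim(path, row.names = 1, check.names = FALSE),
                   error = function(e)
                     stop("malformed table in '", path, "': ",
                          conditionMessage(e)))
    bad <- which(!vapply(df, is.numeric, logical(1)))
    if (length(bad))
      stop("non-numeric column(s) in '", path, "': ",
           paste(colnames(df)[bad], collapse = ", "))
    m <- as.matrix(df)
  }
  if (transpose) m <- t(m)
  taxaCountTable(m, source = source, relative = relative,
                 minLibSize = minLibSize)
}

#' Read a sample metadata table
#'
#' TSV with sample IDs in the first column; remaining columns hold the trait
#' and covariates.
#'
#' @param path file path.
#' @return data.frame with sample IDs as rownames.
#' @export
readSampleMetadata <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  if (anyDuplicated(rownames(df))) stop("duplicate sample IDs in metadata")
  df
}

#' Write a count table or result table as TSV
#'
#' @param x a `TaxaCountTable`, `Com2seqResult`, or data.frame.
#' @param path output file path.
#' @export
writeTSV <- function(x, path) {
  if (is(x, "TaxaCountTable")) {
    df <- data.frame(sample = rownames(x@counts), x@counts,
                     check.names = FALSE)
  } else if (is(x, "Com2seqResult")) {
    df <- x@taxonTable
  } else df <- as.data.frame(x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
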