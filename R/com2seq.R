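#' Integrative differential-abundance test for paired 16S and SMS tables
#'
#' The full integrative pipeline: merge the two sources on the union of
#' samples and taxa, filter rare taxa on pooled presence, pick the reference
#' taxon (largest mean relative abundance across both sources), fit every
#' remaining taxon's logistic estimating equation under both the count and
#' relative-abundance weight schemes, test each taxon's trait effect against
#' the across-taxa median by stratified trait-residual permutation, combine
#' the two schemes into an omnibus p-value calibrated on the shared
#' permutations, and test the community-level null with the harmonic mean of
#' taxon p-values assessed on the same permutations.  Taxa observed in only
#' one source are fitted with the count scheme on that source alone; when
#' either input carries relative abundances instead of counts, only the
#' relative-abundance scheme is used.
#'
#' @param t16s,tsms [TaxaCountTable-class] objects (either may be `NULL`,
#'   which reduces the analysis to the single remaining source).
#' @param meta data.frame of sample metadata, sample IDs as rownames.
#' @param trait name(s) of the trait column(s) in `meta`; a factor is
#'   expanded to indicator columns and multi-column traits are tested
#'   jointly via the squared norm of centered coefficients.
#' @param covariates character vector of confounder columns in `meta`.
#' @param nPerm number of permutation replicates (default 10,000 as
#'   appropriate for global tests; reduce for exploration).
#' @param seed integer RNG seed for the permutation plan.
#' @param permScheme `"three"` (stratify on BOTH / 16S-only / SMS-only; the
#'   valid choice under partial overlap), `"two"`, or `"one"`.
#' @param filterThreshold presence fraction for the rare-taxon filter.
#' @param fdr nominal FDR for the detection flag (0.2 in benchmarking,
#'   0.1 typical for real studies).
#' @param omnibus `"minp"` (permutation-calibrated minimum of the scheme
#'   p-values; default) or `"cauchy"`.
#' @param sparseMin positive-measurement count below which a taxon is fitted
#'   with the bias-corrected EE.
#' @return a [Com2seqResult-class].
#' @examples
#' sim <- simulateStudy(simConfig(J = 40, n = 40, effectSize = 1,
#'                                nCausal = 6, seed = 7))
#' res <- com2seq(sim$t16s, sim$tsms, sim$meta, trait = "trait",
#'                nPerm = 200, seed = 1)
#' res
#' @export
com2seq <- function(t16s, tsms, meta, trait, covariates = character(),
                    nPerm = 10000, seed = 1,
                    permScheme = c("three", "two", "one"),
                    filterThreshold = 0.2, fdr = 0.2,
                    omnibus = c("minp", "cauchy"), sparseMin = 5) {
  permScheme <- match.arg(permScheme)
  omnibus <- match.arg(omnibus)
  study <- mergeSources(t16s, tsms, meta, trait, covariates)
  flt <- com2seqFilter(study, threshold = filterThreshold)
  study <- flt$study
  ref <- selectReferenceTaxon(study)
  traitMat <- .designMatrix(study@metadata, study@traitName)
  covMat <- .designMatrix(study@metadata, study@covariateNames)
  plan <- buildPermutationPlan(traitMat, covMat, stratum(study),
                               nPerm = nPerm, seed = seed,
                               scheme = permScheme)
  res <- .eeEngine(study, plan, ref, covMat = covMat, fdr = fdr,
                   omnibus = omnibus, sparseMin = sparseMin,
                   method = sprintf("Com-2seq (%s-stratum permutation)",
                                    permScheme))
  res@filterReport <- flt$report
  res
}
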