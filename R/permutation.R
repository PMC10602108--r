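#' Build a stratified trait-residual permutation plan
#'
#' Permutation replicates are generated by residual permutation: the trait
#' is regressed on the covariates (ordinary least squares with intercept;
#' the trait itself when there are none), the residuals are shuffled only
#' within sample strata, and the fitted values are added back.  Restricting
#' the shuffling to strata defined by which sources sequenced each sample
#' preserves the sample structure of a partially overlapping design; pooling
#' strata (`"two"`, `"one"`) is provided for comparison and is known to
#' break type-I error control when the trait distribution differs across
#' strata.
#'
#' Replicate 0 is always the identity (the observed trait).
#'
#' @param trait numeric vector or matrix (samples x trait columns); factors
#'   should be expanded to indicator columns beforehand.
#' @param covariates optional numeric matrix of confounders (samples x q).
#' @param strata factor of per-sample stratum labels (e.g. the
#'   [stratum()] of a [MergedStudy-class]).
#' @param nPerm number of permutation replicates (at least 1).
#' @param seed integer RNG seed; plans are byte-identical for a fixed seed.
#' @param scheme `"three"` keeps the strata as given; `"two"` pools the two
#'   single-source strata; `"one"` shuffles globally.
#' @return object of class `PermutationPlan`: list with `replicateTraits`
#'   (samples x d x (nPerm+1) array), `residuals`, `fitted`, `strata`
#'   (the pooled labels actually used), `nPerm`, `seed`, `scheme`.
#' @export
buildPermutationPlan <- function(trait, covariates = NULL, strata,
                                 nPerm, seed,
                                 scheme = c("three", "two", "one")) {
  scheme <- match.arg(scheme)
  tr <- as.matrix(trait)
  n <- nrow(tr)
  if (nPerm < 1) stop("nPerm must be at least 1")
  strata <- as.factor(strata)
  if (length(strata) != n) stop("strata must label every sample")
  lab <- as.character(strata)
  if (scheme == "two")
    lab[lab %in% c("S16_ONLY", "SMS_ONLY")] <- "SINGLE"
  if (scheme == "one") lab[] <- "ALL"
  lab <- factor(lab)
  small <- names(which(table(lab) < 2))
  if (length(small))
    warning("stratum/strata of size < 2 (residuals fixed): ",
            paste(small, collapse = ", "))

  if (is.null(covariates) || NCOL(covariates) == 0) {
    fit <- matrix(colMeans(tr), n, ncol(tr), byrow = TRUE)
  } else {
    X <- cbind(1, as.matrix(covariates))
    fit <- X %*% qr.coef(qr(X), tr)
  }
  res <- tr - fit

  d <- ncol(tr)
  out <- array(NA_real_, c(n, d, nPerm + 1))
  out[, , 1] <- tr
  idx <- split(seq_len(n), lab)
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(nPerm)) {
    perm <- seq_len(n)
    for (g in idx) if (length(g) > 1) perm[g] <- g[sample.int(length(g))]
    out[, , b + 1] <- fit + res[perm, , drop = FALSE]
  }
  structure(list(replicateTraits = out, residuals = res, fitted = fit,
                 strata = lab, nPerm = nPerm, seed = seed, scheme = scheme),
            class = "PermutationPlan")
}
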