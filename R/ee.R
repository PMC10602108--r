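#' Solve one taxon's weighted logistic estimating equation
#'
#' Finds the root of the weighted quasi-score
#' `sum_i w_i (y_i/(y_i + yref_i) - mu_i) x_i = 0` with
#' `logit(mu) = x' theta`, where the design `x` holds the source-indicator
#' intercepts and any covariates.  Under the count scheme the weight is
#' `y + yref` (measurements with zero total contribute nothing); under the
#' relative-abundance scheme the weight is 1 and zero-total measurements are
#' excluded (their fraction is undefined).  The root is found by damped
#' Newton with step halving, started at the pooled logit, gradient tolerance
#' `tol`.  On divergence or apparent separation the solver falls back to the
#' bias-corrected equation (see [biasCorrectedEE()]) and flags it.
#'
#' @param y,yref non-negative numeric vectors of the taxon's and the
#'   reference taxon's counts, one entry per (sample, source) measurement.
#' @param design numeric matrix of regressors per measurement (source
#'   indicator columns and covariates), including the trait.
#' @param scheme `"count"` or `"ra"`.
#' @param tol gradient convergence tolerance, 1e-8 by default; internally
#'   scaled by the mean weight so count- and unit-weight problems converge
#'   at the same relative precision.
#' @param maxit maximum Newton iterations.
#' @param checkCoef how many trailing design columns are screened for
#'   separation (absolute coefficient above 10 triggers the corrected EE);
#'   defaults to all columns.  Pipelines restrict the screen to the trait
#'   and covariate columns, since source intercepts of rare taxa are
#'   legitimately large.
#' @return list with `coef` (named coefficient vector), `converged`,
#'   `biasCorrected` (TRUE when the corrected EE was used), and
#'   `nContributing` (measurements with positive weight).
#' @export
solveTaxonEE <- function(y, yref, design, scheme = c("count", "ra"),
                         checkCoef = ncol(as.matrix(design)),
                         tol = 1e-8, maxit = 100) {
  scheme <- match.arg(scheme)
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (length(y) != length(yref) || length(y) != nrow(X))
    stop("y, yref and design must agree in length")
  tot <- y + yref
  w <- if (scheme == "count") tot else as.numeric(tot > 0)
  r <- ifelse(tot > 0, y / pmax(tot, 1), 0)
  if (all(w == 0) || all(y[w > 0] == 0))
    stop("taxon unanalyzable: no contributing measurements")
  fit <- cppEEFit(X, r, w, firth = FALSE, allowFallback = TRUE,
                  dCheck = checkCoef, tol = tol, maxit = maxit)
  coef <- drop(fit$beta)
  names(coef) <- colnames(X)
  list(coef = coef, converged = fit$status < 2,
       biasCorrected = fit$status == 1, nContributing = fit$nUsed)
}

#' Solve the bias-corrected (Firth-type) estimating equation
#'
#' Same model as [solveTaxonEE()], with the weighted logistic score
#' augmented by the Jeffreys-prior correction term (Firth penalization of
#' the weighted IRLS problem).  The corrected solution exists and is finite
#' even under complete separation, which makes it the right equation for
#' taxa with sparse count data -- by default the pipelines switch to it when
#' a taxon has fewer than 5 positive measurements, or when the plain
#' equation diverges.
#'
#' @inheritParams solveTaxonEE
#' @return as [solveTaxonEE()]; `biasCorrected` is always `TRUE`.
#' @export
biasCorrectedEE <- function(y, yref, design, scheme = c("count", "ra"),
                            tol = 1e-8, maxit = 100) {
  scheme <- match.arg(scheme)
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  tot <- y + yref
  w <- if (scheme == "count") tot else as.numeric(tot > 0)
  r <- ifelse(tot > 0, y / pmax(tot, 1), 0)
  if (all(w == 0) || all(y[w > 0] == 0))
    stop("taxon unanalyzable: no contributing measurements")
  fit <- cppEEFit(X, r, w, firth = TRUE, allowFallback = FALSE,
                  dCheck = 0L, tol = tol, maxit = maxit)
  coef <- drop(fit$beta)
  names(coef) <- colnames(X)
  list(coef = coef, converged = fit$status < 2, biasCorrected = TRUE,
       nContributing = fit$nUsed)
}

#' Fit all non-reference taxa of a merged study under one weight scheme
#'
#' Observed-data fits only (no permutation): per taxon, the source
#' intercepts `eta` (absorbing taxon- and source-specific bias), the trait
#' and covariate effects `beta`, and the trait effect centered by the
#' across-taxa median.  Taxa observed in only one source are fitted with the
#' count scheme and that source's rows only, whatever scheme is requested,
#' and flagged.
#'
#' @param study a filtered [MergedStudy-class].
#' @param ref reference taxon ID (default [selectReferenceTaxon()]).
#' @param scheme `"count"` or `"ra"`.
#' @param sparseMin taxa with fewer positive measurements than this use the
#'   bias-corrected EE.
#' @return data.frame: taxon, scheme used, `eta.16s`, `eta.sms`, trait and
#'   covariate coefficients, `centered.beta` (trait effect minus the
#'   across-taxa median, exactly median-zero), `biasCorrected`, `converged`,
#'   `n.contributing`.
#' @export
fitAllTaxa <- function(study, ref = selectReferenceTaxon(study),
                       scheme = c("count", "ra"), sparseMin = 5) {
  scheme <- match.arg(scheme)
  if (any(study@relative) && scheme == "count")
    stop("count weights are unavailable in relative-abundance mode")
  m16 <- study@counts16s
  msm <- study@countsSMS
  testTaxa <- setdiff(colnames(m16), ref)
  rows16 <- which(study@stratum %in% c("BOTH", "S16_ONLY"))
  rowsSMS <- which(study@stratum %in% c("BOTH", "SMS_ONLY"))
  sampleOf <- c(rows16, rowsSMS)
  srcOf <- rep(1:2, c(length(rows16), length(rowsSMS)))
  Y <- rbind(m16[rows16, , drop = FALSE], msm[rowsSMS, , drop = FALSE])
  covMat <- .designMatrix(study@metadata,
                          c(study@traitName, study@covariateNames))
  covMeas <- covMat[sampleOf, , drop = FALSE]

  one <- function(j) {
    yj <- Y[, j]
    yr <- Y[, ref]
    keep <- !is.na(yj) & !is.na(yr)
    obs16 <- any(yj[keep & srcOf == 1] > 0)
    obsSMS <- any(yj[keep & srcOf == 2] > 0)
    if (!obs16 && !obsSMS)
      return(data.frame(taxon = j, scheme = NA_character_,
                        eta.16s = NA_real_, eta.sms = NA_real_,
                        beta = NA_real_, biasCorrected = NA,
                        converged = FALSE, n.contributing = 0L))
    use <- keep & ((srcOf == 1 & obs16) | (srcOf == 2 & obsSMS))
    sch <- if (obs16 && obsSMS) scheme else "count"
    if (any(study@relative)) sch <- "ra"
    X <- cbind(i16 = as.numeric(srcOf == 1), iSMS = as.numeric(srcOf == 2),
               covMeas)[use, , drop = FALSE]
    cols <- c(obs16, obsSMS, rep(TRUE, ncol(covMeas)))
    X <- X[, cols, drop = FALSE]
    nPos <- sum(yj[use] > 0)
    f <- if (nPos < sparseMin)
      biasCorrectedEE(yj[use], yr[use], X, scheme = sch)
    else
      solveTaxonEE(yj[use], yr[use], X, scheme = sch,
                   checkCoef = ncol(covMeas))
    co <- f$coef
    data.frame(taxon = j, scheme = sch,
               eta.16s = if (obs16) co[["i16"]] else NA_real_,
               eta.sms = if (obsSMS) co[["iSMS"]] else NA_real_,
               beta = unname(co[colnames(covMeas)[1]]),
               biasCorrected = f$biasCorrected, converged = f$converged,
               n.contributing = f$nContributing)
  }
  out <- do.call(rbind, lapply(testTaxa, one))
  rownames(out) <- NULL
  out$centered.beta <- out$beta - median(out$beta, na.rm = TRUE)
  attr(out, "reference") <- ref
  out
}
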