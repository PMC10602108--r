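# Shared estimating-equation/permutation engine.
#
# All analysis pipelines (integrative, single-source, pooled-count) reduce to
# the same computation: stack one measurement per (sample, source) pair,
# fit every non-reference taxon's weighted logistic EE for the observed trait
# and for every permutation replicate, median-center the trait coefficients
# across taxa per replicate, and convert squared centered effects into
# rank-based permutation p-values.  The omnibus statistic is the minimum of
# the two scheme-wise p-values, calibrated against the per-replicate minima
# computed on the same permutations, so the dependence between the count and
# relative-abundance schemes is preserved.  The community-level statistic is
# the harmonic mean of the per-replicate taxon p-values, again calibrated on
# the same permutations.

# expand metadata columns into a numeric design matrix (factors -> dummies)
.designMatrix <- function(df, cols) {
  if (length(cols) == 0) return(NULL)
  parts <- lapply(cols, function(cn) {
    v <- df[[cn]]
    if (is.numeric(v)) {
      matrix(v, ncol = 1, dimnames = list(NULL, cn))
    } else {
      f <- factor(v)
      mm <- diag(nlevels(f))[as.integer(f), -1, drop = FALSE]
      colnames(mm) <- paste0(cn, ".", levels(f)[-1])
      mm
    }
  })
  do.call(cbind, parts)
}

# rank-based permutation p-values for one scheme.
# S: J x B1 statistics (larger = more extreme); rows of NA stay NA.
.permPValues <- function(S) {
  B1 <- ncol(S)
  P <- matrix(NA_real_, nrow(S), B1)
  for (j in seq_len(nrow(S))) {
    s <- S[j, ]
    if (anyNA(s)) next
    P[j, ] <- (B1 - rank(s, ties.method = "min") + 1) / B1
  }
  P
}

# squared median-centered trait effects per replicate.
# beta: (J*d) x B1 from cppEEBatch; avail: logical J.
.centeredStats <- function(beta, d, J, avail) {
  B1 <- ncol(beta)
  S <- matrix(NA_real_, J, B1)
  if (!any(avail)) return(S)
  arr <- array(beta, c(d, J, B1))
  for (b in seq_len(B1)) {
    bm <- arr[, avail, b, drop = FALSE]
    dim(bm) <- c(d, sum(avail))
    med <- apply(bm, 1, median)
    S[avail, b] <- colSums((bm - med)^2)
  }
  S
}

.vecCauchy <- function(p1, p2) {
  clip <- function(p) pmin(pmax(p, 1e-15), 1 - 1e-15)
  stat <- 0.5 * (tan((0.5 - clip(p1)) * pi) + tan((0.5 - clip(p2)) * pi))
  0.5 - atan(stat) / pi
}

# Core engine.  study must already be filtered; ref is the reference taxon.
# plan is a PermutationPlan over the study's samples (same order).
.eeEngine <- function(study, plan, ref, covMat = NULL, fdr = 0.2,
                      omnibus = c("minp", "cauchy"), sparseMin = 5,
                      tol = 1e-8, maxit = 100, method = "Com-2seq") {
  omnibus <- match.arg(omnibus)
  m16 <- study@counts16s
  msm <- study@countsSMS
  taxa <- colnames(m16)
  if (!ref %in% taxa) stop("reference taxon not in the study")
  testTaxa <- setdiff(taxa, ref)
  J <- length(testTaxa)
  if (J == 0) stop("no taxa to test besides the reference")
  relMode <- any(study@relative)

  rows16 <- which(study@stratum %in% c("BOTH", "S16_ONLY"))
  rowsSMS <- which(study@stratum %in% c("BOTH", "SMS_ONLY"))
  sampleOf <- c(rows16, rowsSMS)
  srcOf <- rep(1:2, c(length(rows16), length(rowsSMS)))
  m <- length(sampleOf)

  Y <- rbind(m16[rows16, , drop = FALSE], msm[rowsSMS, , drop = FALSE])
  yref <- Y[, ref]
  Yt <- Y[, testTaxa, drop = FALSE]
  tot <- Yt + yref
  resp <- Yt / tot
  resp[!is.finite(resp)] <- 0
  resp[is.na(resp)] <- 0

  pos <- !is.na(Yt) & Yt > 0
  obs16 <- colSums(pos[srcOf == 1, , drop = FALSE]) > 0
  obsSMS <- colSums(pos[srcOf == 2, , drop = FALSE]) > 0
  dual <- obs16 & obsSMS
  analyzable <- obs16 | obsSMS

  # a source contributes to a taxon only if it observed the taxon at all;
  # otherwise its intercept is not estimable and its rows are dropped
  srcMaskMat <- matrix(1, m, J)
  srcMaskMat[srcOf == 1, !obs16] <- 0
  srcMaskMat[srcOf == 2, !obsSMS] <- 0

  validTot <- !is.na(tot) & tot > 0
  wcount <- tot
  wcount[is.na(wcount)] <- 0
  wcount <- wcount * srcMaskMat
  wra <- (validTot * 1) * srcMaskMat

  covMeas <- if (is.null(covMat)) NULL else covMat[sampleOf, , drop = FALSE]
  Xfix <- cbind(i16 = as.numeric(srcOf == 1), iSMS = as.numeric(srcOf == 2))
  if (!is.null(covMeas)) Xfix <- cbind(Xfix, covMeas)
  p0 <- ncol(Xfix)
  fixMask <- matrix(1L, J, p0)
  fixMask[, 1] <- as.integer(obs16)
  fixMask[, 2] <- as.integer(obsSMS)

  d <- dim(plan$replicateTraits)[2]
  B1 <- dim(plan$replicateTraits)[3]
  trMeas <- plan$replicateTraits[sampleOf, , , drop = FALSE]
  trMeas <- matrix(trMeas, m, d * B1)

  nPos <- colSums(pos * srcMaskMat > 0)
  forceFirth <- as.integer(nPos < sparseMin)

  runScheme <- function(w, avail) {
    if (!any(avail)) return(list(S = matrix(NA_real_, J, B1),
                                 P = matrix(NA_real_, J, B1),
                                 beta0 = rep(NA_real_, J * d),
                                 status = NULL))
    w2 <- w
    w2[, !avail] <- 0
    fit <- cppEEBatch(Xfix, trMeas, d, resp, w2, fixMask, forceFirth,
                      tol, maxit)
    ok <- avail & apply(fit$status, 1, function(s) all(s < 2))
    S <- .centeredStats(fit$beta, d, J, ok)
    list(S = S, P = .permPValues(S), beta0 = fit$beta[, 1],
         status = fit$status[, 1], ok = ok)
  }

  if (relMode) {
    count <- NULL
    ra <- runScheme(wra, analyzable)
  } else {
    count <- runScheme(wcount, analyzable)
    ra <- runScheme(wra, dual)
  }

  Pcount <- if (is.null(count)) matrix(NA_real_, J, B1) else count$P
  Pra <- ra$P
  hasC <- !is.na(Pcount[, 1])
  hasR <- !is.na(Pra[, 1])
  tested <- hasC | hasR

  M <- matrix(NA_real_, J, B1)
  if (omnibus == "minp" || is.null(count)) {
    M[hasC, ] <- Pcount[hasC, , drop = FALSE]
    both <- hasC & hasR
    M[both, ] <- pmin(Pcount[both, , drop = FALSE], Pra[both, , drop = FALSE])
    M[hasR & !hasC, ] <- Pra[hasR & !hasC, , drop = FALSE]
    Pomni <- matrix(NA_real_, J, B1)
    for (j in which(tested))
      Pomni[j, ] <- rank(M[j, ], ties.method = "max") / B1
  } else {
    Pomni <- matrix(NA_real_, J, B1)
    both <- hasC & hasR
    Pomni[both, ] <- .vecCauchy(Pcount[both, , drop = FALSE],
                                Pra[both, , drop = FALSE])
    Pomni[hasC & !hasR, ] <- Pcount[hasC & !hasR, , drop = FALSE]
    Pomni[hasR & !hasC, ] <- Pra[hasR & !hasC, , drop = FALSE]
  }

  if (!any(tested)) stop("no analyzable taxa after fitting")
  hm <- vapply(seq_len(B1), function(b) {
    p <- Pomni[tested, b]
    length(p) / sum(1 / p)
  }, numeric(1))
  globalP <- sum(hm <= hm[1]) / B1
  globalStat <- hm[1]

  adj <- bhAdjust(Pomni[, 1], q = fdr)
  bc <- if (is.null(count) || d > 1) rep(NA_real_, J) else count$beta0
  br <- if (d > 1) rep(NA_real_, J) else ra$beta0
  tt <- data.frame(taxon = testTaxa,
                   observed.16S = obs16, observed.SMS = obsSMS,
                   n.positive = nPos,
                   beta.count = if (d == 1) bc else NA_real_,
                   beta.ra = if (d == 1) br else NA_real_,
                   p.count = Pcount[, 1], p.ra = Pra[, 1],
                   p.omnibus = Pomni[, 1], qvalue = adj$qvalues,
                   detected = seq_len(J) %in% adj$detected,
                   stringsAsFactors = FALSE, row.names = NULL)
  new("Com2seqResult", method = method, taxonTable = tt,
      globalP = globalP, globalStat = globalStat,
      referenceTaxon = ref, nPerm = B1 - 1, fdrNominal = fdr,
      filterReport = data.frame())
}
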