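#' Simulation configuration for paired biased count tables
#'
#' Parameterizes the generative model for paired 16S/SMS taxa count data:
#' per-sample baseline compositions from a Dirichlet around a skewed mean
#' profile (community overdispersion `theta`), trait and confounder effects
#' spiked into causal taxa, source-specific multiplicative bias factors
#' (log-scale `gamma`), and Dirichlet-Multinomial read counts per source
#' (measurement overdispersion `tau`, truncated-normal library sizes).
#'
#' Causal mechanisms: `M1` samples `nCausal` moderately abundant taxa (mean
#' relative abundance above `abundantRA`), `M2` takes the most abundant
#' `nCausal` taxa, `M3` samples `nCausal` rare taxa with mean relative
#' abundance inside `rareBand`.  Per source, `nMissingCausalPerSource`
#' causal taxa (non-overlapping between sources) and a fraction
#' `missingFracNoncausal` of non-causal taxa get bias factor `gammaMissing`
#' (-5), i.e. are effectively unmeasured by that source; the most abundant
#' taxon gets bias factor 1 in both sources and is never designated missing;
#' all other bias factors are N(0, `gammaSD`^2).
#'
#' @param J number of taxa (856 at full scale).
#' @param n number of samples (100 at full scale; 50/50 cases/controls).
#' @param mechanism "M1", "M2" or "M3".
#' @param effectSize log-scale trait effect `beta` on causal taxa; 0 for the
#'   null.
#' @param theta community (between-sample) overdispersion, default 0.01.
#' @param tau per-source measurement overdispersion, scalar or length 2,
#'   default 0.01 (0.001 gives the low-deviation regime).
#' @param nu1 16S mean library size, default 10,000.
#' @param depthRatio SMS-to-16S mean-depth ratio: 10 gives the 1:10 design,
#'   1 equal depths.
#' @param overlap "COMPLETE" (all samples sequenced by both sources) or
#'   "PARTIAL" (fixed stratum composition 40/40/20 with case counts 15/30/5
#'   at n = 100, scaled proportionally for other n).
#' @param confounder logical; add a continuous confounder drawn U(-1,1) for
#'   controls and U(0,2) for cases, acting on `nConfounderTaxa` taxa with
#'   effect `betaConfounder` = log 1.5.
#' @param nCausal number of causal taxa; default 20 (M1), 5 (M2), 50 (M3).
#' @param nMissingCausalPerSource causal taxa designated missing per source;
#'   default scales the full-size values 5 (M1), 2 (M2), 5 (M3) in
#'   proportion to `nCausal`.
#' @param missingFracNoncausal fraction of non-causal taxa designated
#'   missing per source, default 0.2.
#' @param gammaMissing,gammaSD bias factor for missing taxa (-5) and SD of
#'   the remaining bias factors (0.5).
#' @param nConfounderTaxa,betaConfounder confounder-associated taxa count
#'   (5) and effect (log 1.5).
#' @param abundantRA,rareBand abundance bands defining mechanism
#'   eligibility.
#' @param baselineSigma log-normal sigma of the synthetic mean profile.
#' @param seed integer RNG seed.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(J = 856, n = 100, mechanism = c("M1", "M2", "M3"),
                      effectSize = 0, theta = 0.01, tau = 0.01,
                      nu1 = 10000, depthRatio = 10,
                      overlap = c("COMPLETE", "PARTIAL"),
                      confounder = FALSE, nCausal = NULL,
                      nMissingCausalPerSource = NULL,
                      missingFracNoncausal = 0.2, gammaMissing = -5,
                      gammaSD = 0.5, nConfounderTaxa = 5,
                      betaConfounder = log(1.5), abundantRA = 0.005,
                      rareBand = c(5e-4, 1e-3), baselineSigma = 2,
                      seed = 1) {
  mechanism <- match.arg(mechanism)
  overlap <- match.arg(overlap)
  if (theta <= 0 || any(tau < 0)) stop("theta must be > 0 and tau >= 0")
  if (J < 10) stop("J must be at least 10")
  if (n %% 2 != 0) stop("n must be even (balanced cases/controls)")
  full <- c(M1 = 20, M2 = 5, M3 = 50)
  fullMiss <- c(M1 = 5, M2 = 2, M3 = 5)
  if (is.null(nCausal)) nCausal <- unname(full[mechanism])
  if (is.null(nMissingCausalPerSource))
    nMissingCausalPerSource <-
      max(1L, round(nCausal * fullMiss[mechanism] / full[mechanism]))
  if (2 * nMissingCausalPerSource > nCausal)
    stop("missing-causal sets (one per source, non-overlapping) exceed ",
         "the causal set")
  tau <- rep(tau, length.out = 2)
  structure(list(J = J, n = n, mechanism = mechanism,
                 effectSize = effectSize, theta = theta, tau = tau,
                 nu1 = nu1, depthRatio = depthRatio, overlap = overlap,
                 confounder = confounder, nCausal = nCausal,
                 nMissingCausalPerSource = nMissingCausalPerSource,
                 missingFracNoncausal = missingFracNoncausal,
                 gammaMissing = gammaMissing, gammaSD = gammaSD,
                 nConfounderTaxa = nConfounderTaxa,
                 betaConfounder = betaConfounder,
                 abundantRA = abundantRA, rareBand = rareBand,
                 baselineSigma = baselineSigma, seed = seed),
            class = "SimConfig")
}

#' Desk-scale simulation preset
#'
#' The reduced problem size used for benchmarking on a single CPU: J = 60
#' taxa, n = 60 samples, 10 causal taxa for M1 with 2 designated missing per
#' source.  All other parameters as [simConfig()].
#'
#' @param ... overrides passed to [simConfig()].
#' @export
deskConfig <- function(...) {
  args <- list(...)
  defaults <- list(J = 60, n = 60, nCausal = 10,
                   nMissingCausalPerSource = 2)
  if (!is.null(args$mechanism) && args$mechanism != "M1" &&
      is.null(args$nCausal)) {
    defaults$nCausal <- if (args$mechanism == "M2") 5 else 4
    defaults$nMissingCausalPerSource <- 1
  }
  do.call(simConfig, utils::modifyList(defaults, args))
}

# draw with RNG state isolated and restored
.withSeed <- function(seed, expr) {
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Synthesize a baseline composition profile
#'
#' The mean profile is built from sorted log-normal draws (sigma =
#' `baselineSigma`) normalized to sum 1, redrawn until the abundance bands
#' needed by the causal mechanisms are populated (`minAbundant` taxa above
#' `abundantRA`, `minRare` inside `rareBand`); taxa are ordered by
#' decreasing abundance.  Per-sample baselines are then drawn from a
#' Dirichlet with this mean and overdispersion `theta` (concentration
#' `(1 - theta)/theta`, the usual microbiome Dirichlet-Multinomial
#' convention).
#'
#' @param J taxa count.
#' @param theta community overdispersion.
#' @param n number of per-sample baselines to draw.
#' @param seed RNG seed.
#' @param meanRA optional user-supplied mean profile (positive, will be
#'   normalized); skips synthesis.
#' @param sigma log-normal sigma of the synthetic profile.
#' @param minAbundant,minRare feasibility constraints on the two bands.
#' @param abundantRA,rareBand band definitions.
#' @return list with `meanRA` (length J, sums to 1, decreasing) and
#'   `baselines` (n x J, rows sum to 1).
#' @export
makeBaseline <- function(J, theta, n, seed, meanRA = NULL, sigma = 2,
                         minAbundant = 20, minRare = 50,
                         abundantRA = 0.005, rareBand = c(5e-4, 1e-3)) {
  if (J < 10) stop("J must be at least 10")
  .withSeed(seed, {
    if (is.null(meanRA)) {
      ok <- FALSE
      for (try in seq_len(200)) {
        x <- sort(exp(rnorm(J, 0, sigma)), decreasing = TRUE)
        pi0 <- x / sum(x)
        if (sum(pi0 > abundantRA) >= minAbundant &&
            sum(pi0 > rareBand[1] & pi0 < rareBand[2]) >= minRare) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not satisfy mechanism feasibility constraints; ",
             "consider a larger J or looser bands")
      meanRA <- pi0
    } else {
      if (length(meanRA) != J || any(meanRA <= 0))
        stop("meanRA must be length J and strictly positive")
      meanRA <- meanRA / sum(meanRA)
    }
    conc <- meanRA * (1 - theta) / theta
    g <- matrix(rgamma(n * J, shape = rep(conc, each = n)), n, J)
    baselines <- g / pmax(rowSums(g), .Machine$double.xmin)
    list(meanRA = meanRA, baselines = baselines)
  })
}

#' Select causal (and confounder-associated) taxa
#'
#' @param mechanism "M1", "M2" or "M3".
#' @param meanRA mean relative-abundance profile.
#' @param nCausal causal-set size.
#' @param seed RNG seed.
#' @param confounder logical; also sample `nConfounderTaxa`
#'   confounder-associated taxa (abundance above `abundantRA`, disjoint from
#'   the causal set).
#' @param nConfounderTaxa,abundantRA,rareBand see [simConfig()].
#' @return list with integer vectors `causal` and `confounderTaxa`.
#' @export
selectCausalSets <- function(mechanism, meanRA, nCausal, seed,
                             confounder = FALSE, nConfounderTaxa = 5,
                             abundantRA = 0.005, rareBand = c(5e-4, 1e-3)) {
  .withSeed(seed, {
    eligible <- switch(mechanism,
      M1 = which(meanRA > abundantRA),
      M2 = order(meanRA, decreasing = TRUE)[seq_len(nCausal)],
      M3 = which(meanRA > rareBand[1] & meanRA < rareBand[2]))
    if (length(eligible) < nCausal)
      stop("only ", length(eligible), " taxa eligible for ", mechanism,
           " but ", nCausal, " causal taxa requested")
    causal <- if (mechanism == "M2") eligible else
      sort(sample(eligible, nCausal))
    confTaxa <- integer()
    if (confounder) {
      pool <- setdiff(which(meanRA > abundantRA), causal)
      if (length(pool) < nConfounderTaxa)
        stop("not enough abundant non-causal taxa for the confounder set")
      confTaxa <- sort(sample(pool, nConfounderTaxa))
    }
    list(causal = causal, confounderTaxa = confTaxa)
  })
}

#' Draw source-specific bias factors
#'
#' @param J taxa count.
#' @param meanRA mean profile (identifies the most abundant taxon).
#' @param causal integer indices of causal taxa.
#' @param nMissingPerSource causal taxa designated missing in each source
#'   (two non-overlapping sets).
#' @param missingFracNoncausal fraction of non-causal taxa designated
#'   missing, independently per source.
#' @param gammaSD,gammaMissing see [simConfig()].
#' @param seed RNG seed.
#' @return list with `gamma1`, `gamma2` (length J) and integer vectors
#'   `missing16s`, `missingSMS`.
#' @export
drawBiasFactors <- function(J, meanRA, causal, nMissingPerSource,
                            missingFracNoncausal = 0.2, gammaSD = 0.5,
                            gammaMissing = -5, seed = 1) {
  .withSeed(seed, {
    top <- which.max(meanRA)
    gamma1 <- rnorm(J, 0, gammaSD)
    gamma2 <- rnorm(J, 0, gammaSD)
    gamma1[top] <- 1
    gamma2[top] <- 1
    candCausal <- setdiff(causal, top)
    if (2 * nMissingPerSource > length(candCausal))
      stop("not enough causal taxa to designate missing sets")
    pick <- sample(candCausal, 2 * nMissingPerSource)
    miss16 <- pick[seq_len(nMissingPerSource)]
    missSMS <- pick[nMissingPerSource + seq_len(nMissingPerSource)]
    nonc <- setdiff(seq_len(J), c(causal, top))
    m16n <- sample(nonc, round(missingFracNoncausal * length(nonc)))
    msmn <- sample(nonc, round(missingFracNoncausal * length(nonc)))
    miss16 <- sort(c(miss16, m16n))
    missSMS <- sort(c(missSMS, msmn))
    gamma1[miss16] <- gammaMissing
    gamma2[missSMS] <- gammaMissing
    list(gamma1 = gamma1, gamma2 = gamma2,
         missing16s = miss16, missingSMS = missSMS)
  })
}

#' Expected observed relative abundances per sample and source
#'
#' Spikes trait and confounder effects into the per-sample baselines,
#' imposes the source bias factors, and renormalizes each (sample, source)
#' composition to sum 1 (the normalization realizes the per-sample
#' normalization constant of the bias model).
#'
#' @param baselines n x J per-sample baseline compositions.
#' @param gamma length-J log bias factors for this source.
#' @param trait length-n trait values.
#' @param confounderValues length-n confounder values (or NULL).
#' @param causal,confounderTaxa integer index vectors.
#' @param effectSize,betaConfounder log-scale effects.
#' @return n x J matrix of expected relative abundances, rows sum to 1.
#' @export
expectedRA <- function(baselines, gamma, trait, confounderValues = NULL,
                       causal = integer(), confounderTaxa = integer(),
                       effectSize = 0, betaConfounder = log(1.5)) {
  n <- nrow(baselines)
  J <- ncol(baselines)
  b1 <- numeric(J); b1[causal] <- effectSize
  b2 <- numeric(J); b2[confounderTaxa] <- betaConfounder
  if (is.null(confounderValues)) confounderValues <- numeric(n)
  expo <- outer(trait, b1) + outer(confounderValues, b2) +
    matrix(gamma, n, J, byrow = TRUE)
  if (any(!is.finite(expo))) stop("non-finite exponent in the bias model")
  p <- exp(expo) * baselines
  p / pmax(rowSums(p), .Machine$double.xmin)
}

#' Draw Dirichlet-Multinomial read counts
#'
#' Per sample: library size from N(depthMean, (depthMean/3)^2) left-
#' truncated at 2,000 (rejection sampling, rounded to integer), taxon
#' proportions from a Dirichlet with mean equal to the sample's expected
#' composition and overdispersion `tau` (concentration `(1 - tau)/tau`),
#' then multinomial counts.  `tau = 0` gives pure multinomial sampling.
#'
#' @param p n x J expected compositions (rows sum to 1).
#' @param tau measurement overdispersion.
#' @param depthMean mean library size.
#' @param seed RNG seed.
#' @param minDepth truncation point, default 2,000.
#' @return n x J integer count matrix (row sums = drawn library sizes).
#' @export
drawCounts <- function(p, tau, depthMean, seed, minDepth = 2000) {
  .withSeed(seed, {
    n <- nrow(p)
    J <- ncol(p)
    libs <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        x <- rnorm(1, depthMean, depthMean / 3)
        if (x >= minDepth) break
      }
      libs[i] <- as.integer(round(x))
    }
    out <- matrix(0L, n, J)
    for (i in seq_len(n)) {
      q <- p[i, ]
      if (tau > 0) {
        g <- rgamma(J, shape = q * (1 - tau) / tau)
        if (sum(g) <= 0) g <- q
        q <- g / sum(g)
      }
      out[i, ] <- as.integer(rmultinom(1, libs[i], q))
    }
    out
  })
}

# fixed partial-overlap composition at n = 100, scaled proportionally
.partialComposition <- function(n) {
  base <- c(both = 40, s16 = 40, sms = 20,
            bothCase = 15, s16Case = 30, smsCase = 5)
  scaled <- base * n / 100
  if (any(abs(scaled - round(scaled)) > 1e-9))
    stop("PARTIAL overlap requires n such that the 40/40/20 stratum ",
         "composition (cases 15/30/5) scales to integers; got n = ", n)
  as.integer(round(scaled))
}

#' Simulate a paired 16S/SMS study
#'
#' Runs the full generative model of [simConfig()]: balanced binary trait
#' (exactly n/2 cases), optional confounder, synthetic baseline profile,
#' causal/confounder taxon sets, source bias factors with designated-missing
#' taxa, expected compositions, and Dirichlet-Multinomial counts per source;
#' assembles the two count tables according to the overlap design, with
#' truth labels attached.
#'
#' @param config a `SimConfig` from [simConfig()] or [deskConfig()].
#' @return list of class `SimulatedStudy`: `t16s`, `tsms`
#'   ([TaxaCountTable-class]), `meta` (data.frame with `trait` and, when
#'   enabled, `confounder`), and `truth` (taxon IDs of causal,
#'   confounder-associated and per-source missing sets, plus the bias
#'   factors and mean profile).
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cf <- config
  seeds <- .withSeed(cf$seed, sample.int(.Machine$integer.max, 8))
  taxa <- sprintf("T%04d", seq_len(cf$J))
  samples <- sprintf("S%04d", seq_len(cf$n))

  # stratum and case assignment
  if (cf$overlap == "PARTIAL") {
    comp <- .partialComposition(cf$n)
    strat <- rep(c("BOTH", "S16_ONLY", "SMS_ONLY"), comp[1:3])
    case <- unlist(mapply(function(tot, cs) rep(1:0, c(cs, tot - cs)),
                          comp[1:3], comp[4:6], SIMPLIFY = FALSE))
    ord <- .withSeed(seeds[1], sample.int(cf$n))
    strat <- strat[ord]
    trait <- case[ord]
  } else {
    strat <- rep("BOTH", cf$n)
    trait <- .withSeed(seeds[1], sample(rep(1:0, cf$n / 2)))
  }
  confVals <- NULL
  if (cf$confounder)
    confVals <- .withSeed(seeds[2],
      ifelse(trait == 1, runif(cf$n, 0, 2), runif(cf$n, -1, 1)))

  minAb <- (if (cf$mechanism == "M1") cf$nCausal else 0) +
    (if (cf$confounder) cf$nConfounderTaxa else 0)
  minRare <- if (cf$mechanism == "M3") cf$nCausal else 0
  bl <- makeBaseline(cf$J, cf$theta, cf$n, seeds[3],
                     sigma = cf$baselineSigma, minAbundant = minAb,
                     minRare = minRare, abundantRA = cf$abundantRA,
                     rareBand = cf$rareBand)
  sets <- selectCausalSets(cf$mechanism, bl$meanRA, cf$nCausal, seeds[4],
                           confounder = cf$confounder,
                           nConfounderTaxa = cf$nConfounderTaxa,
                           abundantRA = cf$abundantRA,
                           rareBand = cf$rareBand)
  bias <- drawBiasFactors(cf$J, bl$meanRA, sets$causal,
                          cf$nMissingCausalPerSource,
                          cf$missingFracNoncausal, cf$gammaSD,
                          cf$gammaMissing, seeds[5])

  spike <- function(gamma) {
    expectedRA(bl$baselines, gamma, trait, confVals,
               causal = if (cf$effectSize != 0) sets$causal else integer(),
               confounderTaxa = sets$confounderTaxa,
               effectSize = cf$effectSize,
               betaConfounder = cf$betaConfounder)
  }
  p16 <- spike(bias$gamma1)
  psm <- spike(bias$gamma2)
  c16 <- drawCounts(p16, cf$tau[1], cf$nu1, seeds[6])
  csm <- drawCounts(psm, cf$tau[2], cf$nu1 * cf$depthRatio, seeds[7])
  dimnames(c16) <- dimnames(csm) <- list(samples, taxa)

  in16 <- strat %in% c("BOTH", "S16_ONLY")
  inSMS <- strat %in% c("BOTH", "SMS_ONLY")
  t16s <- taxaCountTable(c16[in16, , drop = FALSE], source = "16S")
  tsms <- taxaCountTable(csm[inSMS, , drop = FALSE], source = "SMS")
  meta <- data.frame(row.names = samples, trait = trait)
  if (cf$confounder) meta$confounder <- confVals

  structure(list(
    t16s = t16s, tsms = tsms, meta = meta,
    truth = list(causal = taxa[sets$causal],
                 confounderTaxa = taxa[sets$confounderTaxa],
                 missing16s = taxa[bias$missing16s],
                 missingSMS = taxa[bias$missingSMS],
                 meanRA = setNames(bl$meanRA, taxa),
                 gamma1 = setNames(bias$gamma1, taxa),
                 gamma2 = setNames(bias$gamma2, taxa),
                 stratum = setNames(strat, samples),
                 config = cf)),
    class = "SimulatedStudy")
}
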