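test_that("baseline profiles are reproducible, normalized and Dirichlet-consistent", {
  b1 <- makeBaseline(J = 60, theta = 0.01, n = 50, seed = 3,
                     minAbundant = 10, minRare = 0)
  b2 <- makeBaseline(J = 60, theta = 0.01, n = 50, seed = 3,
                     minAbundant = 10, minRare = 0)
  expect_identical(b1, b2)
  expect_equal(sum(b1$meanRA), 1)
  expect_true(all(diff(b1$meanRA) <= 0))  # sorted by abundance
  expect_equal(rowSums(b1$baselines), rep(1, 50))

  # law of large numbers: mean of many sampled baselines approaches the mean
  big <- makeBaseline(J = 20, theta = 0.01, n = 10000, seed = 4,
                      minAbundant = 0, minRare = 0)
  expect_lt(max(abs(colMeans(big$baselines) - big$meanRA)), 0.005)

  # small-theta limit: per-sample baselines collapse onto the mean
  tight <- makeBaseline(J = 20, theta = 1e-6, n = 200, seed = 5,
                        minAbundant = 0, minRare = 0)
  dev <- abs(sweep(tight$baselines, 2, tight$meanRA))
  expect_lt(max(dev), 0.01)
})

test_that("causal-set mechanisms respect their abundance bands", {
  b <- makeBaseline(J = 856, theta = 0.01, n = 2, seed = 11)
  m1 <- selectCausalSets("M1", b$meanRA, 20, seed = 1)
  expect_length(m1$causal, 20)
  expect_true(all(b$meanRA[m1$causal] > 0.005))

  m2 <- selectCausalSets("M2", b$meanRA, 5, seed = 1)
  expect_identical(m2$causal, 1:5)  # taxa are sorted by abundance

  m3 <- selectCausalSets("M3", b$meanRA, 50, seed = 1)
  expect_length(m3$causal, 50)
  expect_true(all(b$meanRA[m3$causal] > 5e-4 & b$meanRA[m3$causal] < 1e-3))

  withConf <- selectCausalSets("M1", b$meanRA, 20, seed = 2,
                               confounder = TRUE)
  expect_length(withConf$confounderTaxa, 5)
  expect_length(intersect(withConf$causal, withConf$confounderTaxa), 0)
  expect_true(all(b$meanRA[withConf$confounderTaxa] > 0.005))

  expect_error(selectCausalSets("M3", b$meanRA[1:10] / sum(b$meanRA[1:10]),
                                50, seed = 1), "eligible")
})

test_that("bias factors follow the designated-missing rules", {
  b <- makeBaseline(J = 200, theta = 0.01, n = 2, seed = 2,
                    minAbundant = 20, minRare = 0)
  causal <- selectCausalSets("M1", b$meanRA, 20, seed = 3)$causal
  bias <- drawBiasFactors(200, b$meanRA, causal, nMissingPerSource = 5,
                          seed = 4)
  missC16 <- intersect(bias$missing16s, causal)
  missCsm <- intersect(bias$missingSMS, causal)
  expect_length(missC16, 5)
  expect_length(missCsm, 5)
  expect_length(intersect(missC16, missCsm), 0)
  expect_equal(unname(bias$gamma1[bias$missing16s]),
               rep(-5, length(bias$missing16s)))
  expect_equal(unname(bias$gamma2[bias$missingSMS]),
               rep(-5, length(bias$missingSMS)))
  # most abundant taxon is efficiently captured by both sources
  top <- which.max(b$meanRA)
  expect_equal(bias$gamma1[top], 1)
  expect_equal(bias$gamma2[top], 1)
  expect_false(top %in% c(bias$missing16s, bias$missingSMS))
  # about 20% of non-causal taxa are missing per source
  nonc <- setdiff(seq_len(200), c(causal, top))
  expect_equal(length(setdiff(bias$missing16s, causal)),
               round(0.2 * length(nonc)))
})

test_that("expected compositions renormalize the spiked, biased baselines", {
  b <- makeBaseline(J = 15, theta = 0.01, n = 6, seed = 6,
                    minAbundant = 0, minRare = 0)
  trait <- rep(0:1, each = 3)
  # no effects, no bias: identity
  p <- expectedRA(b$baselines, gamma = rep(0, 15), trait = trait)
  expect_equal(p, b$baselines, tolerance = 1e-12)
  # rows sum to one with arbitrary effects
  p2 <- expectedRA(b$baselines, gamma = rnorm(15), trait = trait,
                   causal = c(2, 5), effectSize = 1.2)
  expect_equal(rowSums(p2), rep(1, 6))
  # boosting one taxon's exponent raises it and lowers all others
  g <- rep(0, 15)
  g2 <- g
  g2[4] <- log(2)
  pa <- expectedRA(b$baselines, g, trait)
  pb <- expectedRA(b$baselines, g2, trait)
  expect_true(all(pb[, 4] > pa[, 4]))
  expect_true(all(pb[, -4] < pa[, -4]))
})

test_that("count draws respect library-size truncation and the DM mean", {
  p <- matrix(rep(c(0.7, 0.2, 0.08, 0.02), 50), 50, 4, byrow = TRUE)
  cts <- drawCounts(p, tau = 0.01, depthMean = 3000, seed = 8)
  expect_true(all(rowSums(cts) >= 2000))
  expect_equal(dim(cts), c(50, 4))
  # moment check: empirical composition matches the expectation
  big <- drawCounts(matrix(rep(c(0.5, 0.3, 0.2), 5000), 5000, 3,
                           byrow = TRUE),
                    tau = 0.01, depthMean = 5000, seed = 9)
  expect_lt(max(abs(colMeans(big / rowSums(big)) - c(0.5, 0.3, 0.2))),
            0.005)
  # tau = 0 is pure multinomial (no extra spread)
  m0 <- drawCounts(matrix(rep(c(0.5, 0.5), 2000), 2000, 2, byrow = TRUE),
                   tau = 0, depthMean = 4000, seed = 10)
  fr <- m0[, 1] / rowSums(m0)
  expect_lt(abs(var(fr) / mean(0.25 / rowSums(m0)) - 1), 0.2)
})

test_that("simulated studies honor the overlap designs", {
  cfgP <- simConfig(J = 60, n = 60, overlap = "PARTIAL", nCausal = 10,
                    nMissingCausalPerSource = 2, seed = 13)
  sim <- simulateStudy(cfgP)
  strat <- sim$truth$stratum
  expect_equal(as.integer(table(strat)[c("BOTH", "S16_ONLY", "SMS_ONLY")]),
               c(24L, 24L, 12L))
  tr <- sim$meta$trait
  names(tr) <- rownames(sim$meta)
  expect_equal(sum(tr[names(strat)[strat == "BOTH"]]), 9)
  expect_equal(sum(tr[names(strat)[strat == "S16_ONLY"]]), 18)
  expect_equal(sum(tr[names(strat)[strat == "SMS_ONLY"]]), 3)
  expect_equal(sum(tr), 30)
  # tables contain exactly the sequenced samples
  expect_length(sampleIDs(sim$t16s), 48)
  expect_length(sampleIDs(sim$tsms), 36)
  expect_error(simulateStudy(simConfig(J = 30, n = 34, nCausal = 5,
                                       nMissingCausalPerSource = 1,
                                       overlap = "PARTIAL")),
               "scales to integers")

  cfgC <- simConfig(J = 40, n = 30, overlap = "COMPLETE", nCausal = 5,
                    nMissingCausalPerSource = 1, depthRatio = 10,
                    seed = 14)
  simC <- simulateStudy(cfgC)
  expect_length(sampleIDs(simC$t16s), 30)
  expect_length(sampleIDs(simC$tsms), 30)
  # depth ratio: SMS libraries are roughly 10x deeper
  ratio <- mean(rowSums(counts(simC$tsms))) / mean(rowSums(counts(simC$t16s)))
  expect_gt(ratio, 6)
  expect_lt(ratio, 14)
})

test_that("simulation is deterministic and designated-missing taxa vanish", {
  cfg <- simConfig(J = 40, n = 40, effectSize = 1, nCausal = 6,
                   nMissingCausalPerSource = 2, seed = 21)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(counts(s1$t16s), counts(s2$t16s))
  expect_identical(s1$truth$causal, s2$truth$causal)
})

test_that("designated-missing taxa vanish from their source at full scale", {
  sim <- simulateStudy(simConfig(J = 856, n = 30, effectSize = 0,
                                 seed = 23))
  ra16 <- counts(sim$t16s) / rowSums(counts(sim$t16s))
  expect_lt(max(colMeans(ra16[, sim$truth$missing16s, drop = FALSE])), 1e-3)
  rasm <- counts(sim$tsms) / rowSums(counts(sim$tsms))
  expect_lt(max(colMeans(rasm[, sim$truth$missingSMS, drop = FALSE])), 1e-3)
})

test_that("confounder values follow the shifted-uniform design", {
  cfg <- simConfig(J = 40, n = 200, confounder = TRUE, nCausal = 5,
                   nMissingCausalPerSource = 1, seed = 17)
  sim <- simulateStudy(cfg)
  cv <- sim$meta$confounder
  tr <- sim$meta$trait
  expect_true(all(cv[tr == 0] >= -1 & cv[tr == 0] <= 1))
  expect_true(all(cv[tr == 1] >= 0 & cv[tr == 1] <= 2))
  expect_length(sim$truth$confounderTaxa, 5)
})
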