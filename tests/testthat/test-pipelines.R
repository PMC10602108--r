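test_that("the integrative pipeline is deterministic under a fixed seed", {
  sim <- quickSim(seed = 2, beta = 0.5)
  r1 <- com2seq(sim$t16s, sim$tsms, sim$meta, "trait", nPerm = 100,
                seed = 5)
  r2 <- com2seq(sim$t16s, sim$tsms, sim$meta, "trait", nPerm = 100,
                seed = 5)
  expect_identical(taxonResults(r1), taxonResults(r2))
  expect_identical(globalPValue(r1), globalPValue(r2))
  tt <- taxonResults(r1)
  expect_true(all(tt$p.omnibus > 0 & tt$p.omnibus <= 1, na.rm = TRUE))
  expect_gte(min(tt$p.omnibus, na.rm = TRUE), 1 / 101)
  expect_identical(sort(detectedTaxa(r1)),
                   sort(tt$taxon[!is.na(tt$qvalue) & tt$qvalue <= 0.2]))
})

test_that("results are invariant to sample and taxon input ordering", {
  sim <- quickSim(seed = 3, beta = 1)
  r1 <- com2seq(sim$t16s, sim$tsms, sim$meta, "trait", nPerm = 80,
                seed = 9)
  m16 <- counts(sim$t16s)
  msm <- counts(sim$tsms)
  set.seed(1)
  so <- sample(nrow(m16))
  to <- sample(ncol(m16))
  t16b <- taxaCountTable(m16[so, to], "16S")
  tsmb <- taxaCountTable(msm[, to], "SMS")
  r2 <- com2seq(t16b, tsmb, sim$meta, "trait", nPerm = 80, seed = 9)
  t1 <- taxonResults(r1)
  t2 <- taxonResults(r2)
  t2 <- t2[match(t1$taxon, t2$taxon), ]
  expect_equal(t1$beta.count, t2$beta.count, tolerance = 1e-9)
  expect_equal(t1$p.omnibus, t2$p.omnibus, tolerance = 1e-12)
  expect_equal(globalPValue(r1), globalPValue(r2), tolerance = 1e-12)
})

test_that("with one empty source the integrative test reduces to single-source", {
  sim <- quickSim(seed = 4, beta = 1)
  joint <- com2seq(sim$t16s, NULL, sim$meta, "trait", nPerm = 150,
                   seed = 12)
  single <- locomSingle(sim$t16s, sim$meta, "trait", nPerm = 150,
                        seed = 12)
  tj <- taxonResults(joint)
  ts <- taxonResults(single)
  ts <- ts[match(tj$taxon, ts$taxon), ]
  expect_equal(tj$beta.count, ts$beta.count, tolerance = 1e-6)
  expect_equal(tj$p.omnibus, ts$p.omnibus, tolerance = 1e-12)
  expect_equal(globalPValue(joint), globalPValue(single),
               tolerance = 1e-12)
  # and the relative-abundance scheme is unavailable throughout
  expect_true(all(is.na(tj$p.ra)))
})

test_that("taxa observed in one source fall back to count weights", {
  sim <- quickSim(seed = 6, beta = 0)
  # blank one moderately common taxon out of the SMS table entirely
  msm <- counts(sim$tsms)
  pick <- colnames(msm)[5]
  msm <- msm[, colnames(msm) != pick]
  res <- com2seq(sim$t16s, taxaCountTable(msm, "SMS"), sim$meta, "trait",
                 nPerm = 60, seed = 3)
  row <- taxonResults(res)[taxonResults(res)$taxon == pick, ]
  if (nrow(row) == 1) {  # survives the filter via the 16S rule
    expect_false(row$observed.SMS)
    expect_true(is.na(row$p.ra))
    expect_equal(row$p.omnibus, row$p.count, tolerance = 1e-12)
  } else skip("taxon dropped by the filter in this draw")
})

test_that("the augmented table pools, copies and zero-fills correctly", {
  fx <- tinyPair()
  aug <- augmentedTable(fx$t16, fx$tsm)
  expect_equal(aug$counts["B", "t1"], 20 + 100)
  expect_equal(aug$counts["A", "t1"], 10)        # copied from 16S
  expect_equal(aug$counts["D", "t2"], 180)       # copied from SMS
  expect_identical(aug$provenance["B", "t1"], "pooled")
  expect_identical(aug$provenance["A", "t2"], "16S")
  # no zero-filled cells here (full taxon overlap), so fabricate one
  t16b <- taxaCountTable(cmat(c(1, 2), "A", c("u", "v")), "16S")
  tsmb <- taxaCountTable(cmat(c(3, 4), "B", c("v", "w")), "SMS")
  aug2 <- augmentedTable(t16b, tsmb)
  expect_identical(aug2$provenance["A", "w"], "zero_filled")
  expect_equal(aug2$counts["A", "w"], 0)
})

test_that("pooling two identical sources equals doubling a single source", {
  sim <- quickSim(seed = 9, beta = 0.5)
  t <- sim$t16s
  tsm <- taxaCountTable(counts(t), "SMS")  # same counts labelled SMS
  pooled <- comCount(t, tsm, sim$meta, "trait", nPerm = 100, seed = 8)
  single <- locomSingle(t, sim$meta, "trait", nPerm = 100, seed = 8)
  tp <- taxonResults(pooled)
  ts <- taxonResults(single)
  ts <- ts[match(tp$taxon, ts$taxon), ]
  # doubled counts leave the weighted EE root unchanged
  expect_equal(tp$beta.count, ts$beta.count, tolerance = 1e-8)
  expect_equal(tp$p.omnibus, ts$p.omnibus, tolerance = 1e-12)
})

test_that("Com-p combines per-taxon p-values and misses doubly-filtered taxa", {
  sim <- quickSim(seed = 10, beta = 1)
  res <- comP(sim$t16s, sim$tsms, sim$meta, "trait", nPerm = 100,
              seed = 15)
  r16 <- locomSingle(sim$t16s, sim$meta, "trait", nPerm = 100, seed = 15)
  rsm <- locomSingle(sim$tsms, sim$meta, "trait", nPerm = 100, seed = 16)
  tt <- taxonResults(res)
  p16 <- setNames(taxonResults(r16)$p.omnibus, taxonResults(r16)$taxon)
  psm <- setNames(taxonResults(rsm)$p.omnibus, taxonResults(rsm)$taxon)
  # overlapping taxa carry the Cauchy combination of the two source p-values
  overl <- intersect(names(p16), names(psm))
  expect_true(length(overl) > 0)
  for (j in overl[1:min(5, length(overl))])
    expect_equal(tt$p.omnibus[tt$taxon == j],
                 cauchyCombine(c(p16[[j]], psm[[j]])), tolerance = 1e-12)
  # taxa analyzed by neither single-source run are absent
  expect_identical(sort(tt$taxon), sort(union(names(p16), names(psm))))
  # global p cannot beat the best taxon p (structural property)
  expect_gte(globalPValue(res), min(tt$p.omnibus) * 0.999)
})

test_that("relative-abundance mode uses only the RA scheme", {
  sim <- quickSim(seed = 12)
  m <- counts(sim$tsms)
  rel <- taxaCountTable(m / rowSums(m), "SMS", relative = TRUE)
  res <- com2seq(sim$t16s, rel, sim$meta, "trait", nPerm = 60, seed = 2)
  tt <- taxonResults(res)
  expect_true(all(is.na(tt$p.count)))
  expect_true(all(tt$p.omnibus == tt$p.ra | is.na(tt$p.ra)))
})

test_that("confounder adjustment enters the design and the residual shuffle", {
  cfg <- simConfig(J = 30, n = 40, effectSize = 0, confounder = TRUE,
                   nCausal = 5, nMissingCausalPerSource = 1, seed = 31)
  sim <- simulateStudy(cfg)
  res <- com2seq(sim$t16s, sim$tsms, sim$meta, "trait",
                 covariates = "confounder", nPerm = 60, seed = 4)
  expect_s4_class(res, "Com2seqResult")
  expect_true(globalPValue(res) > 0 && globalPValue(res) <= 1)
})

test_that("benchmark harness aggregates, labels and reproduces", {
  cfg <- simConfig(J = 25, n = 30, effectSize = 1, nCausal = 4,
                   nMissingCausalPerSource = 1, seed = 5)
  b1 <- runReplicates(cfg, methods = c("com2seq", "single16s"),
                      nReps = 2, nPerm = 40, seed = 77)
  b2 <- runReplicates(cfg, methods = c("com2seq", "single16s"),
                      nReps = 2, nPerm = 40, seed = 77)
  expect_identical(b1, b2)
  expect_identical(colnames(b1)[3], "power")
  expect_true(all(b1$sensitivity >= 0 & b1$sensitivity <= 1))

  null <- runReplicates(simConfig(J = 25, n = 30, effectSize = 0,
                                  nCausal = 4,
                                  nMissingCausalPerSource = 1, seed = 6),
                        methods = "com2seq", nReps = 1, nPerm = 40,
                        seed = 78)
  expect_identical(colnames(null)[3], "typeIError")
  expect_true(null$typeIError %in% c(0, 1))
  expect_true(is.na(null$sensitivity))

  long <- summarizeBenchmarks(list(b1, null))
  expect_true(all(c("scenario", "method", "metric", "value") %in%
                  colnames(long)))
  expect_error(summarizeBenchmarks(list()), "empty")
  f <- tempfile(fileext = ".tsv")
  summarizeBenchmarks(b1, path = f)
  rt <- read.delim(f)
  expect_equal(rt$value, long$value[long$scenario == rt$scenario[1]],
               tolerance = 1e-12)
})
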