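test_that("TSV round trip preserves a count table and drops empty samples", {
  m <- cmat(c(1, 2, 3, 4,
              5, 0, 6, 7,
              8, 9, 10, 0), c("s1", "s2", "s3"),
            c("taxA", "taxB", "taxC", "taxD"))
  f <- tempfile(fileext = ".tsv")
  writeTSV(taxaCountTable(m, "16S"), f)
  tab <- readCountTable(f, source = "16S")
  expect_identical(counts(tab), m)
  expect_identical(sampleIDs(tab), c("s1", "s2", "s3"))

  m0 <- rbind(m, s4 = c(0, 0, 0, 0))
  expect_warning(tab0 <- taxaCountTable(m0, "16S"), "zero")
  expect_identical(sampleIDs(tab0), c("s1", "s2", "s3"))

  expect_error(taxaCountTable(m - 2, "16S"), "negative")
})

test_that("relative-abundance tables validate row sums", {
  p <- cmat(c(0.2, 0.8, 0.5, 0.5), c("a", "b"), c("t1", "t2"))
  tab <- taxaCountTable(p, "SMS", relative = TRUE)
  expect_true(isRelative(tab))
  bad <- p
  bad[1, 1] <- 0.3
  expect_error(taxaCountTable(bad, "SMS", relative = TRUE), "sum to 1")
})

test_that("library-size threshold drops shallow samples with a warning", {
  m <- cmat(c(6000, 1000, 2000, 500), c("deep", "shallow"), c("t1", "t2"))
  expect_warning(tab <- taxaCountTable(m, "16S", minLibSize = 5000),
                 "library size")
  expect_identical(sampleIDs(tab), "deep")
})

test_that("merging assigns strata from source membership", {
  fx <- tinyPair()
  st <- mergeSources(fx$t16, fx$tsm, fx$meta, trait = "trait")
  expect_identical(sort(sampleIDs(st)), c("A", "B", "C", "D"))
  s <- setNames(as.character(stratum(st)), sampleIDs(st))
  expect_identical(s[["A"]], "S16_ONLY")
  expect_identical(s[["B"]], "BOTH")
  expect_identical(s[["C"]], "S16_ONLY")
  expect_identical(s[["D"]], "SMS_ONLY")
  # missing cells are NA, not zero
  expect_true(all(is.na(counts(st, "SMS")["A", ])))
  expect_false(anyNA(counts(st, "SMS")["B", ]))
})

test_that("identical sample sets give all-BOTH strata", {
  m <- cmat(1:6, c("a", "b"), c("t1", "t2", "t3"))
  t16 <- taxaCountTable(m, "16S")
  tsm <- taxaCountTable(m + 1, "SMS")
  meta <- data.frame(row.names = c("a", "b"), trait = c(0, 1))
  st <- mergeSources(t16, tsm, meta, "trait")
  expect_true(all(stratum(st) == "BOTH"))
})

test_that("disjoint taxon sets union with missing flags on the complement", {
  t16 <- taxaCountTable(cmat(1:10, c("a", "b"), paste0("x", 1:5)), "16S")
  tsm <- taxaCountTable(cmat(1:14, c("a", "b"), paste0("y", 1:7)), "SMS")
  meta <- data.frame(row.names = c("a", "b"), trait = c(0, 1))
  st <- mergeSources(t16, tsm, meta, "trait")
  expect_length(taxonIDs(st), 12)
  expect_true(all(is.na(counts(st, "16S")[, paste0("y", 1:7)])))
  expect_true(all(is.na(counts(st, "SMS")[, paste0("x", 1:5)])))
  expect_true(all(stratum(st) == "BOTH"))
})

test_that("merge then split recovers each source's table", {
  fx <- tinyPair()
  st <- mergeSources(fx$t16, fx$tsm, fx$meta, "trait")
  back16 <- splitSource(st, "16S")
  backSMS <- splitSource(st, "SMS")
  expect_identical(counts(back16)[sampleIDs(fx$t16), taxonIDs(fx$t16)],
                   counts(fx$t16))
  expect_identical(counts(backSMS)[sampleIDs(fx$tsm), taxonIDs(fx$tsm)],
                   counts(fx$tsm))
})

test_that("merging errors on duplicate or unusable input", {
  fx <- tinyPair()
  expect_error(mergeSources(fx$t16, fx$t16, fx$meta, "trait"), "source")
  expect_error(mergeSources(fx$t16, fx$tsm, fx$meta, "not_a_column"),
               "lacks column")
  expect_warning(
    mergeSources(fx$t16, fx$tsm,
                 fx$meta[c("A", "B"), , drop = FALSE], "trait"),
    "without metadata")
})

test_that("single-source presence filter uses a strict 'fewer than' rule", {
  n <- 100
  m <- matrix(0, n, 3, dimnames = list(sprintf("s%03d", 1:n),
                                       c("keep20", "drop19", "all")))
  m[1:20, "keep20"] <- 1
  m[1:19, "drop19"] <- 1
  m[, "all"] <- 5
  tab <- taxaCountTable(m, "16S")
  res <- locomFilter(tab, threshold = 0.2)
  expect_identical(taxonIDs(res$table), c("keep20", "all"))
  expect_identical(res$report$reason[res$report$taxon == "drop19"],
                   "presence_below_threshold")
  # idempotent, and identity when everything is common
  again <- locomFilter(res$table, threshold = 0.2)
  expect_identical(counts(again$table), counts(res$table))
})

test_that("integrative filter keeps pooled-presence and single-source taxa", {
  # 16S sequences all 100 samples; SMS only the last 40
  n <- 100
  samples <- sprintf("s%03d", 1:n)
  smsSamples <- samples[61:100]
  taxa <- c("pooled30", "smsOnly25", "rare", "ref")
  m16 <- matrix(0, n, 4, dimnames = list(samples, taxa))
  msm <- matrix(0, 40, 4, dimnames = list(smsSamples, taxa))
  # pooled30: non-zero in 30 distinct samples across sources
  m16[1:20, "pooled30"] <- 1
  msm[11:20, "pooled30"] <- 1   # s071..s080, disjoint from the 16S hits
  # smsOnly25: all zeros in 16S, present in 25% of the 40 SMS samples
  # (10 of 100 pooled, so only the single-source rule saves it)
  msm[1:10, "smsOnly25"] <- 2
  # rare: 15% in 16S, 10% of SMS, 19% pooled -- fails every rule
  m16[1:15, "rare"] <- 1
  msm[31:34, "rare"] <- 1
  m16[, "ref"] <- 50
  msm[, "ref"] <- 500
  meta <- data.frame(row.names = samples, trait = rep(0:1, n / 2))
  st <- mergeSources(taxaCountTable(m16, "16S"),
                     taxaCountTable(msm, "SMS"), meta, "trait")
  res <- com2seqFilter(st, threshold = 0.2)
  kept <- taxonIDs(res$study)
  expect_true("pooled30" %in% kept)      # 0.30 pooled > 0.20
  expect_true("smsOnly25" %in% kept)     # single-source rule on SMS
  expect_false("rare" %in% kept)         # 0.15 pooled, 0.15/0.10 single
  expect_identical(
    res$report$reason[res$report$taxon == "smsOnly25"],
    "single_source_presence")
  # idempotent
  again <- com2seqFilter(res$study, threshold = 0.2)
  expect_identical(taxonIDs(again$study), kept)
})

test_that("reference taxon maximizes the cross-source mean relative abundance", {
  samples <- c("a", "b")
  taxa <- c("big", "mid", "x16only")
  m16 <- cmat(c(60, 30, 10,
                60, 30, 10), samples, taxa)
  msm <- cmat(c(50, 45, 5,
                50, 45, 5) * 10, samples, taxa)
  msm[, "x16only"] <- 0
  m16[, "x16only"] <- 600   # hugely abundant but absent from SMS
  meta <- data.frame(row.names = samples, trait = c(0, 1))
  st <- mergeSources(taxaCountTable(m16, "16S"),
                     taxaCountTable(msm, "SMS"), meta, "trait")
  expect_identical(selectReferenceTaxon(st), "big")

  # invariant to library-size scaling and sample order
  st2 <- mergeSources(taxaCountTable(m16[c(2, 1), ] * 7, "16S"),
                      taxaCountTable(msm, "SMS"), meta, "trait")
  expect_identical(selectReferenceTaxon(st2), "big")

  # tie breaks to the lexicographically smaller ID
  m16tie <- cmat(c(50, 50, 50, 50), samples, c("zeta", "alpha"))
  msmtie <- cmat(c(30, 30, 30, 30), samples, c("zeta", "alpha"))
  sttie <- mergeSources(taxaCountTable(m16tie, "16S"),
                        taxaCountTable(msmtie, "SMS"), meta, "trait")
  expect_message(ref <- selectReferenceTaxon(sttie), "tie")
  expect_identical(ref, "alpha")
})
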