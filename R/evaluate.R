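#' Replicate-level benchmark of the analysis pipelines
#'
#' Repeatedly simulates a study from `config`, runs each requested method,
#' and aggregates the four operating characteristics: rejection rate of the
#' community-level test at `level` (type-I error when `effectSize = 0`,
#' power otherwise), mean fraction of causal taxa detected (sensitivity),
#' and mean false-discovery proportion at the nominal FDR (a replicate with
#' no detections contributes 0).  Sensitivity is computed against all causal
#' taxa -- a causal taxon lost to a method's filter counts as missed, since
#' salvaging filtered taxa is part of what integration buys.  Per-replicate
#' seeds derive deterministically from `seed`.
#'
#' @param config a `SimConfig`.
#' @param methods subset of `"com2seq"` (= `"com2seq_three"`),
#'   `"com2seq_two"`, `"com2seq_one"`, `"comcount"`, `"comp"`,
#'   `"single16s"`, `"singlesms"`.
#' @param nReps simulation replicates.
#' @param nPerm permutation replicates per analysis.
#' @param seed master seed.
#' @param fdr nominal FDR for taxon-level detection (0.2 in the benchmark).
#' @param level nominal level of the community-level test (0.05).
#' @return data.frame of class `BenchmarkResult`: one row per method with
#'   rejection/sensitivity/FDR rates, Monte-Carlo standard errors
#'   (`sqrt(r(1-r)/nReps)`), and failure counts; the scenario is attached as
#'   an attribute.
#' @export
runReplicates <- function(config, methods = c("com2seq", "single16s",
                                              "singlesms"),
                          nReps = 100, nPerm = 500, seed = 1,
                          fdr = 0.2, level = 0.05) {
  known <- c("com2seq", "com2seq_three", "com2seq_two", "com2seq_one",
             "comcount", "comp", "single16s", "singlesms")
  if (!all(methods %in% known))
    stop("unknown method(s): ",
         paste(setdiff(methods, known), collapse = ", "))
  simSeeds <- .withSeed(seed, sample.int(2^31 - 2, nReps))
  permSeeds <- .withSeed(seed + 1L, sample.int(2^31 - 2, nReps))
  null <- config$effectSize == 0

  runOne <- function(method, sim, ps) {
    cov <- intersect("confounder", colnames(sim$meta))
    switch(method,
      com2seq = ,
      com2seq_three = com2seq(sim$t16s, sim$tsms, sim$meta, "trait", cov,
                              nPerm = nPerm, seed = ps, fdr = fdr),
      com2seq_two = com2seq(sim$t16s, sim$tsms, sim$meta, "trait", cov,
                            nPerm = nPerm, seed = ps, permScheme = "two",
                            fdr = fdr),
      com2seq_one = com2seq(sim$t16s, sim$tsms, sim$meta, "trait", cov,
                            nPerm = nPerm, seed = ps, permScheme = "one",
                            fdr = fdr),
      comcount = comCount(sim$t16s, sim$tsms, sim$meta, "trait", cov,
                          nPerm = nPerm, seed = ps, fdr = fdr),
      comp = comP(sim$t16s, sim$tsms, sim$meta, "trait", cov,
                  nPerm = nPerm, seed = ps, fdr = fdr),
      single16s = locomSingle(sim$t16s, sim$meta, "trait", cov,
                              nPerm = nPerm, seed = ps, fdr = fdr),
      singlesms = locomSingle(sim$tsms, sim$meta, "trait", cov,
                              nPerm = nPerm, seed = ps, fdr = fdr))
  }

  rej <- sens <- fdp <- matrix(NA_real_, nReps, length(methods),
                               dimnames = list(NULL, methods))
  for (i in seq_len(nReps)) {
    cf <- config
    cf$seed <- simSeeds[i]
    sim <- simulateStudy(cf)
    causal <- sim$truth$causal
    for (m in methods) {
      res <- tryCatch(runOne(m, sim, permSeeds[i]),
                      error = function(e) {
                        warning("replicate ", i, ", method ", m,
                                " failed: ", conditionMessage(e))
                        NULL
                      })
      if (is.null(res)) next
      rej[i, m] <- as.numeric(globalPValue(res) <= level)
      det <- detectedTaxa(res)
      if (!null) sens[i, m] <- mean(causal %in% det)
      # under the null no spiking occurred, so any detection is false
      fdp[i, m] <- if (length(det) == 0) 0 else
        if (null) 1 else mean(!det %in% causal)
    }
  }
  rate <- function(x) colMeans(x, na.rm = TRUE)
  se <- function(r, nOk) sqrt(r * (1 - r) / pmax(1, nOk))
  nOk <- colSums(!is.na(rej))
  rj <- rate(rej)
  sn <- if (null) rep(NA_real_, length(methods)) else rate(sens)
  fd <- rate(fdp)
  out <- data.frame(method = methods, nReps = unname(nOk),
                    rejectionRate = unname(rj),
                    rejectionSE = unname(se(rj, nOk)),
                    sensitivity = unname(sn),
                    sensitivitySE = unname(se(sn, nOk)),
                    empiricalFDR = unname(fd),
                    empiricalFDRSE = unname(se(fd, nOk)),
                    nFailed = as.integer(nReps - nOk),
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(out)[3] <- if (null) "typeIError" else "power"
  colnames(out)[4] <- if (null) "typeIErrorSE" else "powerSE"
  attr(out, "scenario") <- config
  class(out) <- c("BenchmarkResult", class(out))
  out
}

#' Combine benchmark results into a long comparison table
#'
#' @param results list of `BenchmarkResult` data.frames (or a single one).
#' @param path optional TSV output path.
#' @return long-format data.frame: scenario label, method, metric, value,
#'   standard error.
#' @export
summarizeBenchmarks <- function(results, path = NULL) {
  if (inherits(results, "BenchmarkResult")) results <- list(results)
  if (length(results) == 0) stop("empty benchmark list")
  longOne <- function(r) {
    cf <- attr(r, "scenario")
    lab <- sprintf("%s_beta%g_%s_tau%g_ratio%g", cf$mechanism,
                   cf$effectSize, cf$overlap, cf$tau[1], cf$depthRatio)
    metrics <- setdiff(colnames(r),
                       c("method", "nReps", "nFailed",
                         grep("SE$", colnames(r), value = TRUE)))
    do.call(rbind, lapply(metrics, function(mt) {
      data.frame(scenario = lab, method = r$method, metric = mt,
                 value = r[[mt]], se = r[[paste0(mt, "SE")]],
                 nReps = r$nReps, stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, lapply(results, longOne))
  rownames(out) <- NULL
  if (!is.null(path)) writeTSV(out, path)
  out
}

#' Bar plot of benchmark metrics
#'
#' @param summary long table from [summarizeBenchmarks()].
#' @param metric which metric to plot.
#' @param nominal optional nominal-level reference line.
#' @return a ggplot object.
#' @export
plotBenchmark <- function(summary, metric = "typeIError", nominal = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotBenchmark requires ggplot2")
  df <- summary[summary$metric == metric & !is.na(summary$value), ]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$method,
                                         y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - 2 * .data$se,
                                        ymax = .data$value + 2 * .data$se),
                           width = 0.25) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::theme_bw()
  if (!is.null(nominal))
    gg <- gg + ggplot2::geom_hline(yintercept = nominal,
                                   linetype = "dashed", colour = "grey40")
  gg
}
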