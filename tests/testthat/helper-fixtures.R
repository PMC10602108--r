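# Small deterministic fixtures built in code.

# counts matrix with named dims
cmat <- function(x, samples, taxa) {
  matrix(x, nrow = length(samples), byrow = TRUE,
         dimnames = list(samples, taxa))
}

# a small paired study with overlapping samples {B} and full taxon overlap
tinyPair <- function() {
  t16 <- taxaCountTable(cmat(c(10, 30, 5,
                               20, 20, 10,
                               15, 25, 5), c("A", "B", "C"),
                            c("t1", "t2", "t3")), source = "16S")
  tsm <- taxaCountTable(cmat(c(100, 300, 40,
                               220, 180, 110), c("B", "D"),
                            c("t1", "t2", "t3")), source = "SMS")
  meta <- data.frame(row.names = c("A", "B", "C", "D"),
                     trait = c(0, 1, 0, 1))
  list(t16 = t16, tsm = tsm, meta = meta)
}

# simulate a complete-overlap paired study quickly
quickSim <- function(seed = 1, J = 30, n = 40, beta = 0, ...) {
  simulateStudy(simConfig(J = J, n = n, effectSize = beta,
                          nCausal = 5, nMissingCausalPerSource = 1,
                          seed = seed, ...))
}

# independent oracle: maximize the weighted logistic quasi-likelihood by
# general-purpose optimisation (never touches the package Newton solver)
oracleWLogit <- function(y, yref, X, scheme = "count") {
  tot <- y + yref
  w <- if (scheme == "count") tot else as.numeric(tot > 0)
  r <- ifelse(tot > 0, y / pmax(tot, 1), 0)
  keep <- w > 0
  w <- w[keep]; r <- r[keep]; X <- X[keep, , drop = FALSE]
  negll <- function(b) {
    eta <- drop(X %*% b)
    -sum(w * (r * eta - log1p(exp(pmin(eta, 700)))))
  }
  fit <- optim(rep(0, ncol(X)), negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  fit$par
}
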