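# Shared catalog (loading regenerates reference sequences; do it once)
.cat_env <- new.env()
testCatalog <- function() {
  if (is.null(.cat_env$cat)) .cat_env$cat <- loadCatalog()
  .cat_env$cat
}

readFixture <- function(name) {
  utils::read.table(pgxFixture(name), header = TRUE, sep = "\t",
    comment.char = "#", quote = "", stringsAsFactors = FALSE,
    check.names = FALSE)
}

# Independent brute-force MEC oracle: naive loops over every site
# assignment; deliberately shares no code with the package's solver.
oracleMec <- function(obs) {
  k <- ncol(obs)
  best <- Inf
  for (code in 0:(2^(k - 1) - 1)) {
    h <- c(0L, as.integer(intToBits(code))[seq_len(k - 1)])
    cost <- 0L
    for (r in seq_len(nrow(obs))) {
      c1 <- 0L; c2 <- 0L
      for (j in seq_len(k)) {
        if (is.na(obs[r, j])) next
        if (obs[r, j] != h[j]) c1 <- c1 + 1L
        if (obs[r, j] != 1L - h[j]) c2 <- c2 + 1L
      }
      cost <- cost + min(c1, c2)
    }
    if (cost < best) best <- cost
  }
  best
}

# random MEC instance: k sites, n fragments, truth hap + noise
randomMecInstance <- function(k, n, flipProb = 0.05) {
  truth <- c(0L, sample(0:1, k - 1L, replace = TRUE))
  obs <- matrix(NA_integer_, n, k)
  for (r in seq_len(n)) {
    span <- sort(sample.int(k, 2L))
    idx <- span[1]:span[2]
    hap <- sample(0:1, 1L)
    al <- if (hap == 0L) truth[idx] else 1L - truth[idx]
    flip <- stats::runif(length(idx)) < flipProb
    al[flip] <- 1L - al[flip]
    obs[r, idx] <- al
  }
  obs[rowSums(!is.na(obs)) > 0L, , drop = FALSE]
}
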