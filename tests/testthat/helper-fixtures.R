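# Small, fast simulation settings used across unit tests. Full-size
# defaults are exercised in test-acceptance.R.
smallParams <- function(seed = 1L, ...) {
  SimulationParams(seed = seed, nProbes = 300L, nGenes = 250L,
                   nAltered = 100L, nMirnas = 40L, ...)
}

conditionOf <- function(se) {
  as.character(SummarizedExperiment::colData(se)$condition)
}

samplesIn <- function(se, cond) {
  colnames(se)[conditionOf(se) == cond]
}

# Independent brute-force seed-site scan: sliding substring comparison for
# each of the four canonical patterns, then longest-type subsumption by
# flank inspection. Used as the oracle for seedSites().
bruteSites <- function(mirna, utr) {
  rc <- function(x) chartr("ACGU", "UGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  core <- rc(substr(mirna, 2, 7))
  m8c <- rc(substr(mirna, 8, 8))
  L <- nchar(utr)
  win <- function(len) {
    if (L < len) return(integer())
    p <- seq_len(L - len + 1)
    p[substring(utr, p, p + len - 1) == switch(as.character(len),
        "8" = paste0(m8c, core, "A"),
        "6" = core)]
  }
  pos8 <- win(8)
  p7 <- seq_len(max(0, L - 6))
  m8pos <- p7[substring(utr, p7, p7 + 6) == paste0(m8c, core)]
  a1pos <- p7[substring(utr, p7, p7 + 6) == paste0(core, "A")]
  sixpos <- win(6)
  m8only <- setdiff(m8pos, pos8)
  noM8Before <- function(pos) vapply(pos, function(p)
    p == 1 || substr(utr, p - 1, p - 1) != m8c, logical(1))
  noAAfterCore <- function(pos) vapply(pos, function(p)
    p + 6 > L || substr(utr, p + 6, p + 6) != "A", logical(1))
  a1only <- a1pos[noM8Before(a1pos)]
  sixonly <- sixpos[noM8Before(sixpos) & noAAfterCore(sixpos)]
  out <- rbind(
    if (length(pos8)) data.frame(start = pos8 - 1L, type = "8mer"),
    if (length(m8only)) data.frame(start = m8only - 1L, type = "7mer-m8"),
    if (length(a1only)) data.frame(start = a1only - 1L, type = "7mer-A1"),
    if (length(sixonly)) data.frame(start = sixonly - 1L, type = "6mer"))
  if (is.null(out)) data.frame(start = integer(), type = character())
  else out[order(out$start), , drop = FALSE]
}

randomRnaString <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Direct-summation hypergeometric tails from binomial coefficients,
# independent of the log-space implementation.
enumTails <- function(K, n, N) {
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  j <- lo:hi
  pmf <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  list(j = j, over = rev(cumsum(rev(pmf))), under = cumsum(pmf))
}
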