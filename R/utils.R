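#' @importFrom methods new is validObject slot show setValidity
#' @importFrom stats rnorm rnbinom runif cor pt qnorm pnorm dnorm cor.test
#'   p.adjust prcomp hclust as.dist rbinom
#' @importFrom utils write.table read.delim modifyList
NULL

# Derive independent per-stage RNG substreams from one user-facing seed.
# Seeds are kept below 2^31 - 1 (R integers are 32-bit).
stageSeed <- function(seed, stage) {
  stages <- c("expression", "mirna", "utr", "bootstrap", "pipeline")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483629L)
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.assertScalarCount <- function(x, name, min = 1) {
  if (length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop(name, " must be a single integer >= ", min)
}

.assertProportion <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(name, " must be a proportion in [0, 1]")
}

.assertRange <- function(x, name, lo = 0) {
  if (length(x) != 2 || any(is.na(x)) || x[1] > x[2] || any(x <= lo))
    stop(name, " must be an ordered pair (low <= high) above ", lo)
}
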