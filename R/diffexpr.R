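#' Summarize probe intensities to gene level
#'
#' Collapses a probe-by-sample intensity matrix to genes by averaging the
#' log2 intensities of each gene's probes per sample.
#'
#' @param se a \code{SummarizedExperiment} with a linear-scale
#'   \code{"exprs"} assay and a \code{rowData()$gene} probe-to-gene map, or
#'   a positive matrix (then \code{geneMap} is required).
#' @param geneMap character vector mapping each probe (row) to one gene.
#' @return A gene-by-sample matrix of log2 intensities.
#' @examples
#' m <- matrix(2^c(6, 8), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
#' summarizeProbes(m, geneMap = c("g1", "g1"))  # mean(6, 8) = 7
#' @export
summarizeProbes <- function(se, geneMap = NULL) {
  if (is(se, "SummarizedExperiment")) {
    if (is.null(geneMap)) geneMap <- SummarizedExperiment::rowData(se)$gene
    se <- SummarizedExperiment::assay(se, "exprs")
  }
  if (is.null(geneMap) || !length(geneMap)) stop("probe->gene map is empty")
  if (length(geneMap) != nrow(se))
    stop("geneMap must have one entry per probe")
  if (any(se <= 0)) stop("intensities must be strictly positive")
  x <- log2(as.matrix(se))
  out <- rowsum(x, geneMap, reorder = TRUE)
  cnt <- table(geneMap)
  out / as.vector(cnt[rownames(out)])
}

# Vectorized Welch two-sample t-test on rows; returns Delta (B - A), t, df, p.
# Degenerate rows (zero variance in both groups) get p = 0 when the means
# differ and p = 1 otherwise.
.rowWelch <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  delta <- m2 - m1
  tt <- delta / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  zero <- se2 == 0
  p[zero] <- ifelse(delta[zero] != 0, 0, 1)
  list(delta = delta, t = tt, df = df, p = p)
}

#' Two-group differential expression contrast
#'
#' Per-gene two-sample test on log2 intensities. The log2 fold change is
#' the mean of group B minus the mean of group A, so positive values mean
#' higher expression in \code{groupB}. The default test moderates the
#' per-gene variance across genes by empirical Bayes (limma's
#' \code{lmFit}/\code{eBayes}), the standard choice for designs with few
#' replicates per group; \code{method = "welch"} gives the unmoderated
#' Welch two-sample t-test instead. The fold change is identical under
#' both methods.
#'
#' @param geneMatrix gene-by-sample log2 intensity matrix (e.g. from
#'   [summarizeProbes()]).
#' @param groupA,groupB disjoint character vectors of sample (column)
#'   names, each of length >= 2. \code{groupA} is the reference.
#' @param fcThreshold,pThreshold,qThreshold thresholds recorded in the
#'   result and used for the \code{de} flag column (see [callDE()]).
#' @param method \code{"moderated"} (default) or \code{"welch"}.
#' @return A [ContrastResult][result-classes] (DFrame) with columns
#'   \code{gene}, \code{log2fc}, \code{fc} (= 2^log2fc), \code{p}, \code{q}
#'   (Benjamini-Hochberg) and \code{de}.
#' @export
runContrast <- function(geneMatrix, groupA, groupB, fcThreshold = 1.3,
                        pThreshold = 0.05, qThreshold = 0.05,
                        method = c("moderated", "welch")) {
  method <- match.arg(method)
  geneMatrix <- as.matrix(geneMatrix)
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ", paste(intersect(groupA, groupB), collapse = ", "))
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 samples")
  missing <- setdiff(c(groupA, groupB), colnames(geneMatrix))
  if (length(missing))
    stop("samples not in matrix: ", paste(missing, collapse = ", "))
  a <- geneMatrix[, groupA, drop = FALSE]
  b <- geneMatrix[, groupB, drop = FALSE]
  if (method == "moderated") {
    design <- cbind(Intercept = 1,
                    B = rep(c(0, 1), c(length(groupA), length(groupB))))
    fit <- limma::eBayes(limma::lmFit(cbind(a, b), design))
    delta <- fit$coefficients[, "B"]
    p <- fit$p.value[, "B"]
    # degenerate rows (no residual variance anywhere) fall back to the
    # zero-variance convention of the Welch path
    bad <- !is.finite(p)
    p[bad] <- ifelse(delta[bad] != 0, 0, 1)
  } else {
    w <- .rowWelch(a, b)
    delta <- w$delta
    p <- w$p
  }
  q <- bhAdjust(p)
  de <- 2^abs(delta) > fcThreshold & p < pThreshold & q < qThreshold
  out <- S4Vectors::DataFrame(
    gene = rownames(geneMatrix), log2fc = unname(delta),
    fc = unname(2^delta), p = unname(p), q = unname(q), de = unname(de),
    row.names = rownames(geneMatrix))
  metadata(out) <- list(groupA = groupA, groupB = groupB,
                        fcThreshold = fcThreshold, pThreshold = pThreshold,
                        qThreshold = qThreshold, method = method)
  new("ContrastResult", out)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")} with input
#' validation: p-values are sorted ascending, \code{q_(i) =
#' min_(j>=i) p_(j) * m / j}, restored to input order and clamped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted q-values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is called DE when \code{2^|log2fc| > fcThreshold} (strict, linear
#' scale, two-sided), \code{p < pThreshold} and \code{q < qThreshold}.
#'
#' @param result a [ContrastResult][result-classes].
#' @param fcThreshold,pThreshold,qThreshold strict thresholds (> 0).
#' @return Character vector of DE gene ids.
#' @export
callDE <- function(result, fcThreshold = 1.3, pThreshold = 0.05,
                   qThreshold = 0.05) {
  if (any(c(fcThreshold, pThreshold, qThreshold) <= 0))
    stop("thresholds must be positive")
  keep <- 2^abs(result$log2fc) > fcThreshold &
    result$p < pThreshold & result$q < qThreshold
  result$gene[keep]
}
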