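#' Normalize small-RNA counts to reads per million
#'
#' \code{rpm[i, s] = counts[i, s] / librarySize[s] * 1e6}. When the library
#' size is the column sum, each column of the result sums to one million.
#' Library sizes exceeding the column sum are permitted (e.g. spike-ins or
#' reads assigned outside the miRNA annotation).
#'
#' @param counts a non-negative integer matrix (miRNA x sample) or a
#'   \code{SummarizedExperiment} with a \code{"counts"} assay and an
#'   optional \code{colData()$librarySize}.
#' @param librarySize positive per-sample library sizes; defaults to the
#'   column sums (or the \code{colData} column when \code{counts} is a
#'   \code{SummarizedExperiment}).
#' @return A numeric rpm matrix with the dimnames of \code{counts}.
#' @examples
#' m <- matrix(c(200, 150), 1, 2,
#'             dimnames = list("mir-a", c("s1", "s2")))
#' normalizeRpm(m, librarySize = c(1e6, 5e5))
#' @export
normalizeRpm <- function(counts, librarySize = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    if (is.null(librarySize) &&
        "librarySize" %in% colnames(SummarizedExperiment::colData(counts)))
      librarySize <- SummarizedExperiment::colData(counts)$librarySize
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(librarySize)) librarySize <- colSums(counts)
  if (length(librarySize) != ncol(counts))
    stop("librarySize must have one entry per sample")
  if (any(librarySize <= 0)) stop("library sizes must be positive")
  sweep(counts, 2, librarySize, "/") * 1e6
}

#' Screen miRNAs by fold change and abundance
#'
#' Applies the two-filter small-RNA screen: a miRNA passes when its
#' group-mean rpm fold change reaches \code{fcThreshold} in either
#' direction and the larger of the two group means exceeds
#' \code{rpmThreshold}. The fold change is computed as
#' \code{(mean rpm in the second group + pseudocount) /
#' (mean rpm in the first group + pseudocount)}, so swapping the groups
#' inverts it exactly.
#'
#' @param rpm a numeric rpm matrix (miRNA x sample), e.g. from
#'   [normalizeRpm()].
#' @param groups a factor or character vector with exactly two levels,
#'   named by sample (or in column order when unnamed); the first level is
#'   the reference (denominator) group.
#' @param fcThreshold ratio-scale fold-change threshold (default 1.8).
#' @param rpmThreshold abundance threshold on the larger group mean
#'   (default 200 rpm).
#' @param pseudocount rpm pseudocount guarding against division by zero.
#' @return A [MirnaScreenResult][result-classes] (DFrame) with per-miRNA
#'   group means, \code{fc}, \code{direction} (\code{up/down/none}) and
#'   \code{pass}; thresholds are stored in \code{metadata()}.
#' @examples
#' rpm <- rbind("mir-a" = c(500, 500, 250, 250),
#'              "mir-b" = c(50, 50, 10, 10))
#' colnames(rpm) <- c("c1", "c2", "p1", "p2")
#' g <- factor(rep(c("control", "perturbed"), each = 2))
#' screenMirnas(rpm, g)
#' @export
screenMirnas <- function(rpm, groups, fcThreshold = 1.8, rpmThreshold = 200,
                         pseudocount = 0.5) {
  rpm <- as.matrix(rpm)
  if (!is.null(names(groups))) {
    if (!all(names(groups) %in% colnames(rpm)))
      stop("group map names unknown samples: ",
           paste(setdiff(names(groups), colnames(rpm)), collapse = ", "))
    rpm <- rpm[, names(groups), drop = FALSE]
  } else if (length(groups) != ncol(rpm)) {
    stop("groups must cover every sample")
  }
  groups <- factor(groups, levels = unique(as.character(groups)))
  if (nlevels(groups) != 2 || any(tabulate(groups) == 0))
    stop("exactly two non-empty groups are required")
  if (fcThreshold <= 1) stop("fcThreshold must exceed 1")

  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  mean1 <- rowMeans(rpm[, groups == g1, drop = FALSE])
  mean2 <- rowMeans(rpm[, groups == g2, drop = FALSE])
  fc <- (mean2 + pseudocount) / (mean1 + pseudocount)
  direction <- ifelse(fc >= fcThreshold, "up",
                      ifelse(fc <= 1 / fcThreshold, "down", "none"))
  pass <- direction != "none" & pmax(mean1, mean2) > rpmThreshold

  out <- S4Vectors::DataFrame(
    mirna = rownames(rpm), meanRpm1 = unname(mean1),
    meanRpm2 = unname(mean2), fc = unname(fc),
    direction = unname(direction), pass = unname(pass),
    row.names = rownames(rpm))
  metadata(out) <- list(groups = c(g1, g2), fcThreshold = fcThreshold,
                        rpmThreshold = rpmThreshold,
                        pseudocount = pseudocount)
  new("MirnaScreenResult", out)
}
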