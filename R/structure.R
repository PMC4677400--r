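#' @importFrom Rcpp sourceCpp
#' @useDynLib miRescue, .registration = TRUE
NULL

#' Pairwise sample distances from an expression matrix
#'
#' Computes the distance between sample expression profiles: either
#' correlation distance (1 minus the Pearson correlation of log2 probe
#' vectors, the default) or Euclidean distance.
#'
#' @param mat probe-by-sample numeric matrix (log2 scale).
#' @param method \code{"correlation"} or \code{"euclidean"}.
#' @return A symmetric sample-by-sample distance matrix with zero
#'   diagonal.
#' @export
sampleDistance <- function(mat, method = c("correlation", "euclidean")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (ncol(mat) < 3) stop("at least 3 samples are required")
  if (method == "correlation") {
    sds <- apply(mat, 2, stats::sd)
    if (any(sds == 0))
      stop("constant sample vector: correlation distance undefined for ",
           paste(colnames(mat)[sds == 0], collapse = ", "))
    d <- 1 - cor(mat)
  } else {
    d <- as.matrix(stats::dist(t(mat)))
  }
  diag(d) <- 0
  d
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of a sample distance matrix with average
#' (UPGMA, default) or complete linkage. Ties are resolved
#' deterministically by the underlying \code{stats::hclust}
#' implementation, so identical input yields an identical tree.
#'
#' @param distance symmetric distance matrix or \code{dist} object.
#' @param linkage \code{"average"} or \code{"complete"}.
#' @return An \code{hclust} tree.
#' @export
clusterSamples <- function(distance, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (is.matrix(distance)) {
    if (!isSymmetric(unname(distance), tol = 1e-8))
      stop("distance matrix must be symmetric")
    distance <- as.dist(distance)
  }
  hclust(distance, method = linkage)
}

# Extract each internal node of an hclust tree as a bitmask over samples
# (bit i set = sample i in the clade), in merge order.
.cladeMasksR <- function(hc) {
  n <- length(hc$labels)
  masks <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    m <- 0
    for (child in hc$merge[i, ]) {
      m <- bitwOr(m, if (child < 0) bitwShiftL(1L, -child - 1L)
                     else masks[child])
    }
    masks[i] <- m
  }
  masks
}

.maskMembers <- function(mask, labels) {
  paste(labels[bitwAnd(bitwShiftR(mask, seq_along(labels) - 1L), 1L) == 1L],
        collapse = ",")
}

#' Multiscale-bootstrap probit fit for AU probabilities
#'
#' Fits the multiscale-bootstrap model to per-scale bootstrap proportions
#' of one clade: with \code{z_r = qnorm(1 - BP_r)}, a weighted least
#' squares fit of \code{z_r = v*sqrt(r) + c/sqrt(r)} over the scales
#' \code{r} gives the approximately unbiased probability
#' \code{AU = 100 * (1 - pnorm(v - c))}. Proportions are clamped to
#' \code{[1/(2*nBoot), 1 - 1/(2*nBoot)]} before the probit transform;
#' weights are the delta-method precisions
#' \code{nBoot * dnorm(z)^2 / (BP*(1-BP))}. A clade observed in every
#' resample at every scale is reported as AU = 100, one never observed as
#' AU = 0; both carry a degenerate-fit flag since the regression is not
#' identifiable there.
#'
#' @param bp numeric vector of raw bootstrap proportions, one per scale.
#' @param scales the relative resample sizes r (same length).
#' @param nBoot bootstrap replicates per scale.
#' @return A list with \code{au} (0-100), \code{v}, \code{c} and
#'   \code{degenerate}.
#' @export
auFit <- function(bp, scales, nBoot) {
  if (length(bp) != length(scales) || length(scales) < 2)
    stop("need one bootstrap proportion per scale, and at least 2 scales")
  if (all(bp >= 1))
    return(list(au = 100, v = NA_real_, c = NA_real_, degenerate = TRUE))
  if (all(bp <= 0))
    return(list(au = 0, v = NA_real_, c = NA_real_, degenerate = TRUE))
  eps <- 1 / (2 * nBoot)
  bpc <- pmin(pmax(bp, eps), 1 - eps)
  z <- qnorm(1 - bpc)
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  w <- nBoot * dnorm(z)^2 / (bpc * (1 - bpc))
  fit <- stats::lm.wfit(X, z, w)
  v <- fit$coefficients[1]; cc <- fit$coefficients[2]
  list(au = unname(100 * (1 - pnorm(v - cc))), v = unname(v),
       c = unname(cc), degenerate = FALSE)
}

#' Sample dendrogram with approximately unbiased bootstrap support
#'
#' Clusters samples and assesses the support of every clade by multiscale
#' feature bootstrap: probes (rows) are resampled with replacement at a
#' grid of relative sizes \code{r}, samples are reclustered on each
#' resample, and the per-scale proportions of resampled trees containing
#' each observed clade are combined by the probit regression of [auFit()]
#' into an AU probability. BP is the plain bootstrap proportion at
#' \code{r = 1}. Both are reported on a 0-100 scale.
#'
#' @param mat probe-by-sample log2 matrix (at most 30 samples).
#' @param nBoot bootstrap replicates per scale (default 1000).
#' @param scales relative resample sizes (default 0.5 to 1.4 in steps of
#'   0.1; resample size is \code{round(r * nrow(mat))}).
#' @param distMethod,linkage see [sampleDistance()] and
#'   [clusterSamples()].
#' @param seed optional RNG seed for the resampling.
#' @return An [AuClustering-class] object.
#' @export
auBootstrap <- function(mat, nBoot = 1000L, scales = seq(0.5, 1.4, by = 0.1),
                        distMethod = c("correlation", "euclidean"),
                        linkage = c("average", "complete"),
                        seed = NULL) {
  distMethod <- match.arg(distMethod)
  linkage <- match.arg(linkage)
  mat <- as.matrix(mat)
  if (length(scales) < 2) stop("at least 2 scales are required")
  if (ncol(mat) > 30) stop("at most 30 samples are supported")
  if (!is.null(seed)) set.seed(seed)

  hc <- clusterSamples(sampleDistance(mat, distMethod), linkage)
  masks <- .cladeMasksR(hc)
  sizes <- as.integer(round(scales * nrow(mat)))
  counts <- msBootCounts(mat, sizes, as.integer(nBoot), as.integer(masks),
                         distMethod == "correlation", linkage == "average")
  bpMat <- counts / nBoot
  iOne <- which.min(abs(scales - 1))

  fits <- apply(bpMat, 1, auFit, scales = scales, nBoot = nBoot)
  nodes <- S4Vectors::DataFrame(
    members = vapply(masks, .maskMembers, character(1), labels = hc$labels),
    height = hc$height,
    bp = 100 * bpMat[, iOne],
    au = vapply(fits, `[[`, numeric(1), "au"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate"))
  new("AuClustering", tree = unclass(hc), nodes = nodes,
      nBoot = as.integer(nBoot), scales = as.numeric(scales),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Retrieve AU support for a specific sample set
#'
#' @param x an [AuClustering-class].
#' @param members character vector of sample ids.
#' @return The clade's AU value, or \code{NA} if the clade is not a node
#'   of the observed tree.
#' @export
cladeAU <- function(x, members) {
  key <- vapply(strsplit(x@nodes$members, ","), function(m)
    paste(sort(m), collapse = ","), character(1))
  i <- match(paste(sort(members), collapse = ","), key)
  if (is.na(i)) NA_real_ else x@nodes$au[i]
}

#' Principal component analysis of expression profiles
#'
#' PCA of log2 expression with samples as observations and probes as
#' variables: probes are centered across samples, no scaling is applied,
#' and the decomposition is by SVD (\code{stats::prcomp}). Variance
#' fractions are percentages of the total variance over all components.
#'
#' @param mat probe-by-sample log2 matrix.
#' @return A [PcaResult-class] object.
#' @export
pcaExpression <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("at least 2 samples are required")
  if (nrow(unique(t(mat))) < 2)
    stop("fewer than 2 distinct samples")
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  vf <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  new("PcaResult", scores = pc$x, loadings = pc$rotation,
      varianceFraction = vf)
}

#' Select probes with the highest absolute loadings
#'
#' Ranks probes by |loading| along one principal component and keeps the
#' top \code{ceiling(quantile * P)}. Reports the selection's share of the
#' total absolute-loading mass and, when a probe-to-gene map is given,
#' the number of unique genes covered.
#'
#' @param pca a [PcaResult-class].
#' @param component component index (default 1).
#' @param quantile top fraction of probes to keep, in (0, 1].
#' @param geneMap optional character vector mapping probes to genes,
#'   named by probe id (or aligned with the loading rows).
#' @return A [ProbeSelection-class] object.
#' @export
selectTopLoadings <- function(pca, component = 1L, quantile = 0.10,
                              geneMap = NULL) {
  if (component > ncol(pca@loadings)) stop("component does not exist")
  if (quantile <= 0 || quantile > 1) stop("quantile must be in (0, 1]")
  l <- abs(pca@loadings[, component])
  probes <- rownames(pca@loadings)
  if (is.null(probes)) probes <- paste0("probe", seq_along(l))
  nSel <- as.integer(ceiling(quantile * length(l)))
  ord <- order(l, probes, decreasing = c(TRUE, FALSE), method = "radix")
  sel <- probes[ord[seq_len(nSel)]]
  wf <- sum(l[ord[seq_len(nSel)]]) / sum(l)
  nGenes <- NA_integer_
  if (!is.null(geneMap)) {
    g <- if (!is.null(names(geneMap))) geneMap[sel] else
      geneMap[match(sel, probes)]
    nGenes <- length(unique(g))
  }
  new("ProbeSelection", probes = sel, quantile = quantile,
      weightFraction = wf, nGenes = nGenes)
}

#' Export an AU-annotated dendrogram as Newick
#'
#' Writes the clustering as a Newick tree with \code{AU|BP} internal node
#' labels (both on the 0-100 scale, rounded to one decimal).
#'
#' @param x an [AuClustering-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
exportNewick <- function(x, path) {
  hc <- clusterTree(x)
  phy <- ape::as.phylo(hc)
  parts <- ape::prop.part(phy)
  labs <- phy$tip.label
  partKeys <- vapply(parts, function(i)
    paste(sort(labs[i]), collapse = ","), character(1))
  nodeKeys <- vapply(strsplit(x@nodes$members, ","), function(m)
    paste(sort(m), collapse = ","), character(1))
  idx <- match(partKeys, nodeKeys)
  phy$node.label <- ifelse(is.na(idx), "",
    sprintf("%.1f|%.1f", x@nodes$au[idx], x@nodes$bp[idx]))
  ape::write.tree(phy, file = path)
  invisible(path)
}
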