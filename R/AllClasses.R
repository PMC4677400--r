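#' @import methods
#' @importClassesFrom S4Vectors DFrame
NULL

#' Parameters of the synthetic rescue-experiment generator
#'
#' Holds every tunable of the synthetic-data generator: problem sizes,
#' planted effect sizes, the rescue fraction and its inverse-modulation
#' rate, target-flag odds, and small-RNA library settings. Defaults mirror
#' the structure of a three-condition miRNA rescue study: ~8000 genes
#' altered by the perturbation, 60% of the altered set rescued by the
#' treatment, 98.7% of rescued genes inversely modulated, and a small-RNA
#' screen with 6 down- and 2 up-regulated planted miRNAs.
#'
#' @slot seed integer master seed; all per-stage substreams derive from it.
#' @slot nProbes,nGenes,nReplicates,nAltered problem sizes. The first
#'   \code{nGenes} probes map 1:1 onto genes; remaining probes are assigned
#'   uniformly at random (surjective probe-to-gene map).
#' @slot rescueFraction proportion of altered genes whose expression is
#'   pushed back toward control levels by the treatment.
#' @slot inverseRate proportion of rescued genes whose treatment effect has
#'   the opposite sign of the perturbation effect.
#' @slot effectLog2Range range of |log2| perturbation effect magnitudes.
#' @slot rescueGainRange range of the rescue gain kappa in (0,1]; the
#'   treatment effect is -kappa*delta (inverse) or +kappa*delta.
#' @slot noiseSd log2-scale Gaussian noise standard deviation (microarray
#'   -like noise).
#' @slot baselineMean,baselineSd log2 baseline intensity distribution.
#' @slot targetOdds odds ratio of target-flag assignment in the
#'   up-then-rescued gene class versus elsewhere.
#' @slot targetBaseRate baseline target-flag probability.
#' @slot nMirnas,nPlantedDown,nPlantedUp,mirnaLibrarySize small-RNA screen
#'   sizes: miRNA count, planted down/up-regulated miRNAs, reads per sample.
#' @slot mirnaDispersion negative-binomial dispersion of simulated counts;
#'   0 gives the noise-free limit (expected counts).
#'
#' @seealso [simulateExpression()], [simulateMirnaCounts()], [simulateUtrs()]
#' @export
setClass("SimulationParams", representation(
  seed = "integer",
  nProbes = "integer",
  nGenes = "integer",
  nReplicates = "integer",
  nAltered = "integer",
  rescueFraction = "numeric",
  inverseRate = "numeric",
  effectLog2Range = "numeric",
  rescueGainRange = "numeric",
  noiseSd = "numeric",
  baselineMean = "numeric",
  baselineSd = "numeric",
  targetOdds = "numeric",
  targetBaseRate = "numeric",
  nMirnas = "integer",
  nPlantedDown = "integer",
  nPlantedUp = "integer",
  mirnaLibrarySize = "numeric",
  mirnaDispersion = "numeric"
))

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (object@nAltered > object@nGenes)
    msg <- c(msg, "nAltered must not exceed nGenes")
  if (object@nProbes < object@nGenes)
    msg <- c(msg, "nProbes must be >= nGenes (probe->gene map is surjective)")
  if (object@nReplicates < 1) msg <- c(msg, "nReplicates must be >= 1")
  for (p in c("rescueFraction", "inverseRate", "targetBaseRate"))
    if (slot(object, p) < 0 || slot(object, p) > 1)
      msg <- c(msg, paste(p, "must lie in [0, 1]"))
  r <- object@effectLog2Range
  if (length(r) != 2 || r[1] > r[2] || any(r <= 0))
    msg <- c(msg, "effectLog2Range must be an ordered pair of positive values")
  g <- object@rescueGainRange
  if (length(g) != 2 || g[1] > g[2] || any(g <= 0) || g[2] > 1)
    msg <- c(msg, "rescueGainRange must be an ordered pair in (0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@mirnaLibrarySize <= 0)
    msg <- c(msg, "mirnaLibrarySize must be positive")
  if (object@mirnaDispersion < 0)
    msg <- c(msg, "mirnaDispersion must be >= 0")
  if (object@nPlantedDown + object@nPlantedUp > object@nMirnas)
    msg <- c(msg, "planted miRNAs exceed nMirnas")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' @param seed master seed (integer).
#' @param nProbes,nGenes,nReplicates,nAltered problem sizes.
#' @param rescueFraction proportion of altered genes rescued by treatment.
#' @param inverseRate proportion of rescued genes with sign-inverted
#'   treatment effect.
#' @param effectLog2Range,rescueGainRange effect-size ranges (pairs).
#' @param noiseSd,baselineMean,baselineSd log2-scale noise and baseline.
#' @param targetOdds,targetBaseRate target-flag model.
#' @param nMirnas,nPlantedDown,nPlantedUp,mirnaLibrarySize,mirnaDispersion
#'   small-RNA screen settings.
#' @return A [SimulationParams-class] object.
#' @examples
#' sp <- SimulationParams(seed = 7, nGenes = 100, nProbes = 120,
#'                        nAltered = 40)
#' sp
#' @export
SimulationParams <- function(seed = 1L,
                             nProbes = 20000L,
                             nGenes = 15000L,
                             nReplicates = 3L,
                             nAltered = 8000L,
                             rescueFraction = 0.60,
                             inverseRate = 0.987,
                             effectLog2Range = c(0.5, 2.0),
                             rescueGainRange = c(0.6, 1.0),
                             noiseSd = 0.25,
                             baselineMean = 8.0,
                             baselineSd = 1.5,
                             targetOdds = 3.0,
                             targetBaseRate = 0.05,
                             nMirnas = 300L,
                             nPlantedDown = 6L,
                             nPlantedUp = 2L,
                             mirnaLibrarySize = 5e5,
                             mirnaDispersion = 0.1) {
  new("SimulationParams",
      seed = as.integer(seed), nProbes = as.integer(nProbes),
      nGenes = as.integer(nGenes), nReplicates = as.integer(nReplicates),
      nAltered = as.integer(nAltered), rescueFraction = rescueFraction,
      inverseRate = inverseRate, effectLog2Range = as.numeric(effectLog2Range),
      rescueGainRange = as.numeric(rescueGainRange), noiseSd = noiseSd,
      baselineMean = baselineMean, baselineSd = baselineSd,
      targetOdds = targetOdds, targetBaseRate = targetBaseRate,
      nMirnas = as.integer(nMirnas), nPlantedDown = as.integer(nPlantedDown),
      nPlantedUp = as.integer(nPlantedUp),
      mirnaLibrarySize = mirnaLibrarySize,
      mirnaDispersion = mirnaDispersion)
}

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams\n")
  cat("  seed:", object@seed, "\n")
  cat("  probes x genes:", object@nProbes, "x", object@nGenes,
      "| replicates/condition:", object@nReplicates, "\n")
  cat("  altered genes:", object@nAltered,
      "| rescue fraction:", object@rescueFraction,
      "| inverse rate:", object@inverseRate, "\n")
  cat("  miRNAs:", object@nMirnas, "( planted", object@nPlantedDown,
      "down /", object@nPlantedUp, "up )\n")
})

#' Manifest of planted ground truth
#'
#' Records every effect planted by the synthetic-data generators so that
#' recovery tests can compare pipeline output against truth: the altered
#' genes and their signed log2 perturbation effects, the rescued subset and
#' its treatment effects, per-gene target flags, planted miRNA effects, and
#' planted UTR seed sites. Slots not touched by a given generator are left
#' empty.
#'
#' @slot alteredGenes DFrame with columns \code{gene}, \code{delta}
#'   (signed log2 perturbation effect).
#' @slot rescuedGenes DFrame with columns \code{gene}, \code{y}
#'   (treatment effect) and \code{inverse} (logical).
#' @slot targetFlags named logical vector over genes.
#' @slot plantedMirnas DFrame with columns \code{mirna}, \code{direction},
#'   \code{fold}, \code{baseRpm}.
#' @slot utrSites DFrame with columns \code{transcript}, \code{start}
#'   (0-based), \code{type} for planted seed-match sites.
#' @slot params the [SimulationParams-class] echo.
#' @slot seed integer seed echo.
#' @export
setClass("SyntheticTruth", representation(
  alteredGenes = "DFrame",
  rescuedGenes = "DFrame",
  targetFlags = "logical",
  plantedMirnas = "DFrame",
  utrSites = "DFrame",
  params = "SimulationParams",
  seed = "integer"
))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (nrow(object@rescuedGenes) &&
      !all(object@rescuedGenes$gene %in% object@alteredGenes$gene))
    msg <- c(msg, "rescued genes must be a subset of altered genes")
  if (nrow(object@alteredGenes) && !all(is.finite(object@alteredGenes$delta)))
    msg <- c(msg, "planted effects must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth (seed", object@seed, ")\n")
  cat("  altered genes:", nrow(object@alteredGenes),
      "| rescued:", nrow(object@rescuedGenes), "\n")
  cat("  target flags set:", sum(object@targetFlags), "of",
      length(object@targetFlags), "\n")
  cat("  planted miRNAs:", nrow(object@plantedMirnas),
      "| planted UTR sites:", nrow(object@utrSites), "\n")
})

#' Accessors for SyntheticTruth
#'
#' @param x a [SyntheticTruth-class] object.
#' @return \code{alteredGenes}/\code{rescuedGenes} return DFrames of planted
#'   effects; \code{targetFlags} a named logical vector; \code{plantedMirnas}
#'   the planted miRNA table.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
alteredGenes <- function(x) x@alteredGenes
#' @rdname truth-accessors
#' @export
rescuedGenes <- function(x) x@rescuedGenes
#' @rdname truth-accessors
#' @export
targetFlags <- function(x) x@targetFlags
#' @rdname truth-accessors
#' @export
plantedMirnas <- function(x) x@plantedMirnas

#' Result classes backed by DFrame
#'
#' \code{MirnaScreenResult}, \code{ContrastResult} and \code{QuadrantTable}
#' are thin extensions of \code{S4Vectors::DFrame}: ordinary column access
#' (\code{$}, \code{[[}) works, while class identity carries the analysis
#' semantics and thresholds in \code{metadata()}.
#'
#' @name result-classes
#' @aliases MirnaScreenResult-class ContrastResult-class QuadrantTable-class
NULL

#' @rdname result-classes
#' @export
setClass("MirnaScreenResult", contains = "DFrame")

#' @rdname result-classes
#' @export
setClass("ContrastResult", contains = "DFrame")

#' @rdname result-classes
#' @export
setClass("QuadrantTable", contains = "DFrame")

setValidity("QuadrantTable", function(object) {
  need <- c("gene", "x", "y", "quadrant")
  if (!all(need %in% colnames(object)))
    return("QuadrantTable requires columns gene, x, y, quadrant")
  TRUE
})

#' Principal component analysis of an expression matrix
#'
#' Samples are observations and probes variables; probes are centered
#' across samples and no scaling is applied. Variance fractions are in
#' percent of total variance; loadings have unit Euclidean norm per
#' component.
#'
#' @slot scores sample x component score matrix.
#' @slot loadings probe x component loading matrix (unit columns).
#' @slot varianceFraction percent of total variance per component.
#' @export
setClass("PcaResult", representation(
  scores = "matrix",
  loadings = "matrix",
  varianceFraction = "numeric"
))

setValidity("PcaResult", function(object) {
  if (ncol(object@scores) != ncol(object@loadings))
    return("scores and loadings must agree in component count")
  if (any(object@varianceFraction < -1e-8))
    return("variance fractions must be non-negative")
  TRUE
})

setMethod("show", "PcaResult", function(object) {
  k <- min(3L, length(object@varianceFraction))
  cat("PcaResult:", nrow(object@scores), "samples x",
      nrow(object@loadings), "probes\n")
  cat("  variance explained:",
      paste0("PC", seq_len(k), " = ",
             sprintf("%.1f%%", object@varianceFraction[seq_len(k)]),
             collapse = ", "), "\n")
})

#' @rdname PcaResult-class
#' @param x a \code{PcaResult}.
#' @export
pcaScores <- function(x) x@scores
#' @rdname PcaResult-class
#' @export
pcaLoadings <- function(x) x@loadings
#' @rdname PcaResult-class
#' @export
varianceFraction <- function(x) x@varianceFraction

#' High-loading probe selection along one principal component
#'
#' @slot probes selected probe ids, ranked by decreasing |loading|.
#' @slot quantile the selection quantile (top fraction of probes).
#' @slot weightFraction sum of |loading| over selected probes divided by
#'   the total |loading| mass.
#' @slot nGenes number of unique genes the selected probes map to (NA when
#'   no probe-to-gene map was supplied).
#' @export
setClass("ProbeSelection", representation(
  probes = "character",
  quantile = "numeric",
  weightFraction = "numeric",
  nGenes = "integer"
))

setMethod("show", "ProbeSelection", function(object) {
  cat("ProbeSelection: top", sprintf("%.0f%%", 100 * object@quantile),
      "by |loading| ->", length(object@probes), "probes\n")
  cat("  weight fraction:", sprintf("%.3f", object@weightFraction))
  if (!is.na(object@nGenes)) cat(" | unique genes:", object@nGenes)
  cat("\n")
})

#' @rdname ProbeSelection-class
#' @param x a \code{ProbeSelection}.
#' @export
selectedProbes <- function(x) x@probes
#' @rdname ProbeSelection-class
#' @export
weightFraction <- function(x) x@weightFraction

#' Sample dendrogram with multiscale-bootstrap support
#'
#' Wraps an average-linkage (or complete-linkage) \code{hclust} tree over
#' samples together with per-clade bootstrap support: BP, the ordinary
#' bootstrap proportion at scale 1, and AU, the approximately unbiased
#' probability from the multiscale-bootstrap probit fit. Both are reported
#' on a 0-100 scale.
#'
#' @slot tree the \code{hclust} object (list form).
#' @slot nodes DFrame with one row per internal node: \code{members}
#'   (comma-separated sample ids), \code{height}, \code{bp}, \code{au},
#'   \code{degenerate} (logical fit flag).
#' @slot nBoot bootstrap replicates per scale.
#' @slot scales relative resample sizes.
#' @slot seed RNG seed used.
#' @export
setClass("AuClustering", representation(
  tree = "list",
  nodes = "DFrame",
  nBoot = "integer",
  scales = "numeric",
  seed = "integer"
))

setMethod("show", "AuClustering", function(object) {
  cat("AuClustering over", length(object@tree$labels), "samples;",
      nrow(object@nodes), "internal nodes\n")
  cat("  nBoot:", object@nBoot, "x", length(object@scales), "scales\n")
  df <- object@nodes
  for (i in seq_len(nrow(df)))
    cat(sprintf("  {%s}  AU=%.1f BP=%.1f\n", df$members[i], df$au[i],
                df$bp[i]))
})

#' @rdname AuClustering-class
#' @param x an \code{AuClustering}.
#' @return \code{auValues}/\code{bpValues} return per-node support values
#'   named by the comma-separated member sets; \code{clusterTree} the
#'   underlying \code{hclust}.
#' @export
auValues <- function(x) {
  stats::setNames(x@nodes$au, x@nodes$members)
}
#' @rdname AuClustering-class
#' @export
bpValues <- function(x) {
  stats::setNames(x@nodes$bp, x@nodes$members)
}
#' @rdname AuClustering-class
#' @export
clusterTree <- function(x) {
  structure(x@tree, class = "hclust")
}
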