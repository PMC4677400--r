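#' Build the fold-change quadrant table for rescue analysis
#'
#' Intersects two DE gene sets (perturbed vs control; treated vs
#' perturbed) and places each gene by its pair of log2 fold changes:
#' \code{x} from the first contrast and \code{y} from the second.
#' Quadrant labels follow the rescue-figure convention, which is mirrored
#' relative to the mathematical one: \strong{QII} is x>0, y<0 (up under
#' perturbation, down under treatment) and \strong{QIV} is x<0, y>0; QI is
#' x>0, y>0 and QIII x<0, y<0. QII and QIV together are the inversely
#' modulated (rescued) genes.
#'
#' @param contrast1,contrast2 [ContrastResult][result-classes] objects
#'   for perturbed-vs-control and treated-vs-perturbed.
#' @param de1,de2 DE gene id sets for the two contrasts (defaults: the
#'   contrasts' own \code{de} flags).
#' @param targets optional character vector of target gene ids; adds an
#'   \code{isTarget} column.
#' @return A [QuadrantTable][result-classes] (DFrame) over the
#'   intersection with columns \code{gene, x, y, quadrant} and optionally
#'   \code{isTarget}.
#' @export
buildQuadrantTable <- function(contrast1, contrast2,
                               de1 = callDE(contrast1),
                               de2 = callDE(contrast2),
                               targets = NULL) {
  genes <- intersect(de1, de2)
  i1 <- match(genes, contrast1$gene)
  i2 <- match(genes, contrast2$gene)
  if (anyNA(i1) || anyNA(i2))
    stop("genes in the intersection lack a fold change in a contrast")
  x <- contrast1$log2fc[i1]
  y <- contrast2$log2fc[i2]
  quadrant <- ifelse(x > 0, ifelse(y > 0, "QI", "QII"),
                     ifelse(y < 0, "QIII", "QIV"))
  out <- S4Vectors::DataFrame(gene = genes, x = x, y = y,
                              quadrant = quadrant, row.names = genes)
  if (!is.null(targets)) out$isTarget <- genes %in% targets
  new("QuadrantTable", out)
}

#' Quadrant counts of a QuadrantTable
#'
#' @param table a [QuadrantTable][result-classes].
#' @return Named integer vector over QI..QIV.
#' @export
quadrantCounts <- function(table) {
  quads <- c("QI", "QII", "QIII", "QIV")
  stats::setNames(vapply(quads, function(qd)
    sum(table$quadrant == qd), integer(1)), quads)
}

#' Rescue summary metrics
#'
#' Summarizes a quadrant table against the size of the perturbation DE
#' set: the fraction of altered genes whose expression responds to the
#' treatment, the fraction of responders that are inversely modulated
#' (QII + QIV), and the Pearson correlation of the two log2 fold changes
#' (with a two-sided t-approximation p-value). Strong rescue shows a
#' large inverse fraction and strongly negative correlation.
#'
#' @param table a [QuadrantTable][result-classes].
#' @param nAltered size of the first contrast's DE set (>= table size).
#' @return A list with \code{nAltered}, \code{nIntersect},
#'   \code{fractionAffected}, \code{fractionInverse}, \code{pearsonR},
#'   \code{pearsonP} and \code{quadrantCounts}. The correlation is
#'   \code{NA} when the table has fewer than 2 genes.
#' @export
rescueMetrics <- function(table, nAltered) {
  nInt <- nrow(table)
  if (nAltered < nInt) stop("nAltered must be >= the intersection size")
  qc <- quadrantCounts(table)
  inv <- if (nInt > 0) (qc[["QII"]] + qc[["QIV"]]) / nInt else NA_real_
  if (nInt >= 2) {
    ct <- cor.test(table$x, table$y, method = "pearson",
                   alternative = "two.sided")
    r <- unname(ct$estimate); pv <- ct$p.value
  } else {
    r <- NA_real_; pv <- NA_real_
  }
  list(nAltered = nAltered, nIntersect = nInt,
       fractionAffected = if (nAltered > 0) nInt / nAltered else NA_real_,
       fractionInverse = inv, pearsonR = r, pearsonP = pv,
       quadrantCounts = qc)
}
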