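#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Mature miR-19a sequence
#'
#' The mature dre-miR-19a sequence used as the default miRNA throughout the
#' package (seed region = positions 2-8, \code{GUGCAAA}).
#' @export
MIR19A <- "UGUGCAAAUCUAUGCAAAACUGA"

# Gene-level planted truth, shared by the expression and UTR generators so
# that target flags agree between the two. All draws come from the
# "expression" substream in a fixed order; callers needing further
# randomness must reseed their own substream afterwards.
.geneTruth <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  set.seed(stageSeed(params@seed, "expression"))
  nG <- params@nGenes
  genes <- sprintf("gene%05d", seq_len(nG))

  mu <- rnorm(nG, params@baselineMean, params@baselineSd)
  alteredIdx <- sort(sample.int(nG, params@nAltered))
  sgn <- sample(c(-1, 1), params@nAltered, replace = TRUE)
  mag <- runif(params@nAltered, params@effectLog2Range[1],
               params@effectLog2Range[2])
  delta <- sgn * mag

  # The treatment reverses the dominant axis of perturbation variance:
  # rescue is assigned to the most strongly altered genes, so that treated
  # profiles move globally back toward control (dendrogram / PC1 geometry).
  nRescued <- round(params@rescueFraction * params@nAltered)
  ord <- order(abs(delta), decreasing = TRUE)
  rescuedPos <- sort(ord[seq_len(nRescued)])   # positions within altered set
  kappa <- if (nRescued) runif(nRescued, params@rescueGainRange[1],
                               params@rescueGainRange[2]) else numeric()
  nInverse <- round(params@inverseRate * nRescued)
  inverse <- rep(FALSE, nRescued)
  if (nRescued) inverse[sample.int(nRescued, nInverse)] <- TRUE
  y <- ifelse(inverse, -1, 1) * kappa * delta[rescuedPos]

  # Target flags with the stated odds ratio favouring up-then-rescued genes.
  upRescued <- logical(nG)
  upRescued[alteredIdx[rescuedPos][delta[rescuedPos] > 0]] <- TRUE
  baseOdds <- params@targetBaseRate / (1 - params@targetBaseRate)
  pClass <- (params@targetOdds * baseOdds) / (1 + params@targetOdds * baseOdds)
  pFlag <- ifelse(upRescued, pClass, params@targetBaseRate)
  flags <- stats::rbinom(nG, 1L, pFlag) == 1L
  names(flags) <- genes

  # Surjective probe->gene map: 1:1 head, then uniform assignment.
  extra <- params@nProbes - nG
  probeGene <- c(seq_len(nG),
                 if (extra > 0) sample.int(nG, extra, replace = TRUE))

  list(genes = genes, mu = mu, alteredIdx = alteredIdx, delta = delta,
       rescuedPos = rescuedPos, kappa = kappa, inverse = inverse, y = y,
       flags = flags, probeGene = probeGene)
}

.truthObject <- function(params, gt,
                         plantedMirnas = S4Vectors::DataFrame(),
                         utrSites = S4Vectors::DataFrame()) {
  rescuedGene <- gt$genes[gt$alteredIdx[gt$rescuedPos]]
  new("SyntheticTruth",
      alteredGenes = S4Vectors::DataFrame(
        gene = gt$genes[gt$alteredIdx], delta = gt$delta),
      rescuedGenes = S4Vectors::DataFrame(
        gene = rescuedGene, y = gt$y, inverse = gt$inverse),
      targetFlags = gt$flags,
      plantedMirnas = plantedMirnas,
      utrSites = utrSites,
      params = params,
      seed = params@seed)
}

#' Simulate a three-condition expression experiment with planted rescue
#'
#' Generates a probe-by-sample intensity matrix over three conditions
#' (control, perturbed, perturbed + treatment) with a planted structure:
#' a set of altered genes carries a signed log2 perturbation effect delta;
#' a \code{rescueFraction} of them (the most strongly altered) additionally
#' receives a treatment effect \code{y = -kappa*delta} (sign-inverted, for
#' the \code{inverseRate} majority) or \code{+kappa*delta}. Probe log2
#' intensity is \code{mu_g + delta_g*[perturbed or treated] + y_g*[treated]
#' + N(0, noiseSd)}; the returned assay is on the linear scale (2^log2).
#'
#' @param params a [SimulationParams-class] object.
#' @return A list with elements \code{se} (a
#'   \code{SummarizedExperiment}; assay \code{"exprs"}, \code{rowData()$gene}
#'   the probe-to-gene map, \code{colData()$condition}) and \code{truth}
#'   (a [SyntheticTruth-class]).
#' @examples
#' sim <- simulateExpression(SimulationParams(seed = 7, nGenes = 50,
#'   nProbes = 60, nAltered = 20, nMirnas = 20))
#' sim$se
#' nrow(rescuedGenes(sim$truth))
#' @export
simulateExpression <- function(params) {
  gt <- .geneTruth(params)
  nRep <- params@nReplicates
  conds <- c("control", "perturbed", "treated")
  condition <- factor(rep(conds, each = nRep), levels = conds)
  samples <- paste(condition, rep(seq_len(nRep), times = 3), sep = "_")

  nG <- params@nGenes
  deltaFull <- numeric(nG); deltaFull[gt$alteredIdx] <- gt$delta
  yFull <- numeric(nG); yFull[gt$alteredIdx[gt$rescuedPos]] <- gt$y

  geneSignal <- outer(gt$mu, rep(1, length(samples))) +
    outer(deltaFull, as.numeric(condition %in% c("perturbed", "treated"))) +
    outer(yFull, as.numeric(condition == "treated"))
  log2mat <- geneSignal[gt$probeGene, , drop = FALSE] +
    matrix(rnorm(params@nProbes * length(samples), 0, params@noiseSd),
           params@nProbes)
  probes <- sprintf("probe%05d", seq_len(params@nProbes))
  dimnames(log2mat) <- list(probes, samples)

  se <- SummarizedExperiment(
    assays = list(exprs = 2^log2mat),
    rowData = S4Vectors::DataFrame(probe = probes,
                                   gene = gt$genes[gt$probeGene],
                                   row.names = probes),
    colData = S4Vectors::DataFrame(condition = condition,
                                   row.names = samples))
  list(se = se, truth = .truthObject(params, gt))
}

#' Simulate small-RNA sequencing counts with planted fold changes
#'
#' Generates a miRNA-by-sample matrix of negative-binomial counts over two
#' groups (control, perturbed). Planted miRNAs change by a fold of at least
#' 2 between groups at an abundance above 200 rpm; two decoys each fail
#' exactly one screening filter (a 3-fold change at 50 rpm; an abundant
#' miRNA with fold 1); the remaining background miRNAs are unchanged and
#' kept below 100 rpm so that the fold-change/abundance screen is
#' identifiable under count noise. Setting \code{mirnaDispersion = 0}
#' yields the noise-free limit (rounded expected counts).
#'
#' @param params a [SimulationParams-class] object.
#' @return A list with \code{se} (a \code{SummarizedExperiment}; assay
#'   \code{"counts"}, \code{colData()} columns \code{group} and
#'   \code{librarySize}) and \code{truth} (a [SyntheticTruth-class] whose
#'   \code{plantedMirnas} table has columns \code{mirna}, \code{direction}
#'   in \code{down/up/decoy}, \code{fold}, \code{baseRpm} and
#'   \code{passExpected}).
#' @export
simulateMirnaCounts <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  if (params@mirnaLibrarySize <= 0) stop("library size must be positive")
  set.seed(stageSeed(params@seed, "mirna"))

  nM <- params@nMirnas
  mirnas <- sprintf("mirna-%03d", seq_len(nM))
  nPl <- params@nPlantedDown + params@nPlantedUp
  special <- sample.int(nM, nPl + 2L)           # planted + 2 decoys
  plantedIdx <- special[seq_len(nPl)]
  decoyIdx <- special[nPl + 1:2]

  # control / perturbed expected rpm per miRNA
  ctrlRpm <- numeric(nM); pertRpm <- numeric(nM)
  bg <- setdiff(seq_len(nM), special)
  bgRpm <- stats::rlnorm(length(bg), log(15), 1.2)
  while (any(bgRpm >= 100))                     # background stays < 100 rpm
    bgRpm[bgRpm >= 100] <- stats::rlnorm(sum(bgRpm >= 100), log(15), 1.2)
  ctrlRpm[bg] <- pertRpm[bg] <- bgRpm

  fold <- runif(nPl, 4, 6)
  abund <- runif(nPl, 500, 3000)
  dirs <- c(rep("down", params@nPlantedDown), rep("up", params@nPlantedUp))
  down <- dirs == "down"
  ctrlRpm[plantedIdx[down]] <- abund[down]
  pertRpm[plantedIdx[down]] <- abund[down] / fold[down]
  pertRpm[plantedIdx[!down]] <- abund[!down]
  ctrlRpm[plantedIdx[!down]] <- abund[!down] / fold[!down]

  # decoy 1: strong fold, too scarce; decoy 2: abundant, no fold change
  ctrlRpm[decoyIdx[1]] <- 50; pertRpm[decoyIdx[1]] <- 50 / 3
  ctrlRpm[decoyIdx[2]] <- pertRpm[decoyIdx[2]] <- 1000

  nRep <- params@nReplicates
  group <- factor(rep(c("control", "perturbed"), each = nRep),
                  levels = c("control", "perturbed"))
  samples <- paste(group, rep(seq_len(nRep), 2), sep = "_")
  libSize <- params@mirnaLibrarySize
  muMat <- cbind(matrix(ctrlRpm, nM, nRep), matrix(pertRpm, nM, nRep)) /
    1e6 * libSize
  counts <- if (params@mirnaDispersion > 0) {
    matrix(rnbinom(length(muMat), mu = muMat,
                   size = 1 / params@mirnaDispersion), nM)
  } else {
    round(muMat)
  }
  dimnames(counts) <- list(mirnas, samples)

  planted <- S4Vectors::DataFrame(
    mirna = c(mirnas[plantedIdx], mirnas[decoyIdx]),
    direction = c(dirs, "decoy", "decoy"),
    fold = c(fold, 3, 1),
    baseRpm = c(abund, 50, 1000),
    passExpected = c(rep(TRUE, nPl), FALSE, FALSE))

  gt <- list(genes = character(), mu = numeric(), alteredIdx = integer(),
             delta = numeric(), rescuedPos = integer(), kappa = numeric(),
             inverse = logical(), y = numeric(),
             flags = stats::setNames(logical(), character()),
             probeGene = integer())
  truth <- .truthObject(params, gt, plantedMirnas = planted)

  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(group = group,
                                   librarySize = rep(libSize, 2 * nRep),
                                   row.names = samples))
  list(se = se, truth = truth)
}

.normalizeRna <- function(x) {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  if (any(!strsplit(paste(x, collapse = ""), "")[[1]] %in%
          c("A", "C", "G", "U")))
    stop("sequence contains characters outside {A, C, G, U, T}")
  x
}

.rcRna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

# Canonical site patterns for a miRNA: the 6mer core is the reverse
# complement of seed positions 2-7; m8 adds complementarity to position 8
# upstream of the core; A1 adds an A downstream.
.sitePatterns <- function(mirna) {
  mirna <- .normalizeRna(mirna)
  if (nchar(mirna) < 8) stop("miRNA sequence must be at least 8 nt")
  core <- .rcRna(substr(mirna, 2, 7))
  m8 <- .rcRna(substr(mirna, 8, 8))
  list(core = core, m8 = m8,
       sevenM8 = paste0(m8, core),
       sevenA1 = paste0(core, "A"),
       eightMer = paste0(m8, core, "A"))
}

.randomRna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

#' Simulate 3'UTR sequences with planted miRNA seed-match sites
#'
#' Generates one random-composition RNA 3'UTR per gene. Genes carrying a
#' target flag (shared with [simulateExpression()] for the same
#' \code{params}) receive one planted canonical site (8mer or 7mer-m8) at a
#' recorded position; all other sequence, and every non-target UTR, is
#' rejection-sampled to contain no 7mer-or-longer canonical match to the
#' given miRNA (6mers may occur).
#'
#' @param params a [SimulationParams-class] object.
#' @param mirnaSequence mature miRNA sequence (RNA alphabet; T is accepted
#'   and read as U), length >= 8. Default [MIR19A].
#' @param utrLengthRange integer range of UTR lengths (nt).
#' @return A list with \code{utrs} (a named \code{RNAStringSet}) and
#'   \code{truth} (a [SyntheticTruth-class] with planted sites in
#'   \code{@utrSites}: transcript, 0-based \code{start}, \code{type}).
#' @export
simulateUtrs <- function(params, mirnaSequence = MIR19A,
                         utrLengthRange = c(200L, 400L)) {
  pat <- .sitePatterns(mirnaSequence)
  gt <- .geneTruth(params)
  set.seed(stageSeed(params@seed, "utr"))
  nG <- params@nGenes
  lens <- sample(seq(utrLengthRange[1], utrLengthRange[2]), nG,
                 replace = TRUE)

  hasLongSite <- function(s)
    grepl(pat$sevenM8, s, fixed = TRUE) || grepl(pat$sevenA1, s, fixed = TRUE)
  cleanRna <- function(n) {
    s <- .randomRna(n)
    while (hasLongSite(s)) s <- .randomRna(n)
    s
  }

  seqs <- character(nG)
  sitePos <- rep(NA_integer_, nG)
  siteType <- rep(NA_character_, nG)
  for (i in seq_len(nG)) {
    s <- cleanRna(lens[i])
    if (gt$flags[i]) {
      type <- sample(c("8mer", "7mer-m8"), 1)
      site <- if (type == "8mer") pat$eightMer else pat$sevenM8
      w <- nchar(site)
      start <- sample.int(nchar(s) - w, 1)     # 1-based insertion point
      s2 <- paste0(substr(s, 1, start - 1), site,
                   substr(s, start + w, nchar(s)))
      # a planted 7mer-m8 must not be promoted to an 8mer by a chance A
      if (type == "7mer-m8") {
        nxt <- start + w
        if (nxt <= nchar(s2) && substr(s2, nxt, nxt) == "A")
          s2 <- paste0(substr(s2, 1, nxt - 1), "G",
                       substr(s2, nxt + 1, nchar(s2)))
      }
      s <- s2
      sitePos[i] <- start - 1L                 # report 0-based
      siteType[i] <- type
    }
    seqs[i] <- s
  }
  utrs <- Biostrings::RNAStringSet(seqs)
  names(utrs) <- gt$genes
  flagged <- which(gt$flags)
  truth <- .truthObject(params, gt,
    utrSites = S4Vectors::DataFrame(transcript = gt$genes[flagged],
                                    start = sitePos[flagged],
                                    type = siteType[flagged]))
  list(utrs = utrs, truth = truth)
}
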