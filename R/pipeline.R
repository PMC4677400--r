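#' Assemble a pipeline configuration
#'
#' Builds the configuration list consumed by [runPipeline()]: either
#' simulation parameters (the default) or file paths to user data, plus
#' every stage threshold. Values given in \code{...} override the
#' defaults; a YAML file can be loaded with [readPipelineConfig()].
#'
#' @param seed master seed; forwarded to the simulation parameters.
#' @param simulate generate inputs with the synthetic-data module
#'   (default) instead of reading files.
#' @param params a [SimulationParams-class] used when simulating.
#' @param ... overrides for the defaults: \code{mirnaFcThreshold} (1.8),
#'   \code{rpmThreshold} (200), \code{deFcThreshold} (1.3),
#'   \code{pThreshold}/\code{qThreshold} (0.05), \code{loadingQuantile}
#'   (0.10), \code{nBoot} (1000), \code{scales}, \code{conditions}
#'   (control, perturbed, treated), \code{mirnaSequence} ([MIR19A]),
#'   and, for file input, \code{countsFile}, \code{countGroupsFile},
#'   \code{exprFile}, \code{conditionsFile}, \code{probeGeneFile},
#'   \code{utrFile}.
#' @return A named list.
#' @export
pipelineConfig <- function(seed = 1L, simulate = TRUE, params = NULL, ...) {
  cfg <- list(
    seed = as.integer(seed), simulate = simulate, params = params,
    mirnaFcThreshold = 1.8, rpmThreshold = 200,
    deFcThreshold = 1.3, pThreshold = 0.05, qThreshold = 0.05,
    loadingQuantile = 0.10, nBoot = 1000L, scales = seq(0.5, 1.4, by = 0.1),
    conditions = c("control", "perturbed", "treated"),
    mirnaSequence = MIR19A,
    countsFile = NULL, countGroupsFile = NULL, exprFile = NULL,
    conditionsFile = NULL, probeGeneFile = NULL, utrFile = NULL)
  cfg <- modifyList(cfg, list(...))
  if (length(unique(cfg$conditions)) != 3)
    stop("three distinct condition names are required")
  thr <- c(cfg$mirnaFcThreshold, cfg$rpmThreshold, cfg$deFcThreshold,
           cfg$pThreshold, cfg$qThreshold, cfg$loadingQuantile)
  if (any(thr <= 0)) stop("thresholds must be positive")
  if (is.null(cfg$params)) cfg$params <- SimulationParams(seed = cfg$seed)
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipelineConfig()].
#' @param seed optional seed override.
#' @return The configuration list.
#' @export
readPipelineConfig <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  do.call(pipelineConfig, y)
}

.stageLog <- function(lines, msg) {
  message(msg)
  c(lines, msg)
}

#' Run the full rescue-quantification pipeline
#'
#' Orchestrates every stage on one configuration: simulate (or load)
#' small-RNA counts, the three-condition expression matrix and UTRs;
#' rpm-normalize and screen miRNAs; summarize probes and run the two DE
#' contrasts; build the quadrant table and rescue metrics; predict seed-
#' match targets and their per-quadrant enrichment; cluster samples with
#' AU bootstrap support and run PCA with top-loading selection. The run
#' is fully determined by the configuration and its seed.
#'
#' @param config a configuration from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @param outdir optional output directory; when given, every stage table
#'   (TSV), the Newick dendrogram, a run log and \code{report.json} are
#'   written there.
#' @return The pipeline report (named list; see [writeReport()]).
#' @examples
#' cfg <- pipelineConfig(seed = 7,
#'   params = SimulationParams(seed = 7, nProbes = 400, nGenes = 300,
#'                             nAltered = 120, nMirnas = 40),
#'   nBoot = 100)
#' \donttest{rep <- runPipeline(cfg)}
#' @export
runPipeline <- function(config, outdir = NULL) {
  log <- character()
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(df, name) if (!is.null(outdir))
    writeTableTSV(df, file.path(outdir, name))

  ## ---- inputs -----------------------------------------------------------
  truth <- NULL
  if (isTRUE(config$simulate)) {
    log <- .stageLog(log, sprintf("simulate: seed %d", config$params@seed))
    simM <- simulateMirnaCounts(config$params)
    simE <- simulateExpression(config$params)
    simU <- simulateUtrs(config$params, config$mirnaSequence)
    countsSE <- simM$se
    exprSE <- simE$se
    utrs <- simU$utrs
    truth <- list(mirna = simM$truth, expression = simE$truth,
                  utr = simU$truth)
    if (!is.null(outdir)) {
      writeMatrixTSV(SummarizedExperiment::assay(countsSE, "counts"),
                     file.path(outdir, "mirna_counts.tsv"), "mirna")
      writeMatrixTSV(SummarizedExperiment::assay(exprSE, "exprs"),
                     file.path(outdir, "expression.tsv"), "probe")
      Biostrings::writeXStringSet(utrs, file.path(outdir, "utrs.fa"))
    }
    counts <- SummarizedExperiment::assay(countsSE, "counts")
    countGroups <- stats::setNames(
      as.character(SummarizedExperiment::colData(countsSE)$group),
      colnames(countsSE))
    librarySize <- SummarizedExperiment::colData(countsSE)$librarySize
    exprs <- SummarizedExperiment::assay(exprSE, "exprs")
    conditions <- stats::setNames(
      as.character(SummarizedExperiment::colData(exprSE)$condition),
      colnames(exprSE))
    probeGene <- SummarizedExperiment::rowData(exprSE)$gene
  } else {
    if (is.null(config$countsFile) || is.null(config$countGroupsFile))
      stop("mirna_screen inputs missing: countsFile / countGroupsFile ",
           "(or enable simulation)")
    if (is.null(config$exprFile) || is.null(config$conditionsFile) ||
        is.null(config$probeGeneFile))
      stop("diffexpr inputs missing: exprFile / conditionsFile / ",
           "probeGeneFile (or enable simulation)")
    counts <- readMatrixTSV(config$countsFile)
    countGroups <- readGroupsTSV(config$countGroupsFile)
    librarySize <- NULL
    exprs <- readMatrixTSV(config$exprFile)
    conditions <- readGroupsTSV(config$conditionsFile)
    pg <- readGroupsTSV(config$probeGeneFile)
    probeGene <- unname(pg[rownames(exprs)])
    utrs <- if (!is.null(config$utrFile))
      Biostrings::readRNAStringSet(config$utrFile) else NULL
  }

  ## ---- miRNA screen -----------------------------------------------------
  log <- .stageLog(log, sprintf(
    "mirna_screen: fc >= %.2f, rpm > %g", config$mirnaFcThreshold,
    config$rpmThreshold))
  rpm <- normalizeRpm(counts, librarySize)
  screen <- screenMirnas(rpm, countGroups,
                         fcThreshold = config$mirnaFcThreshold,
                         rpmThreshold = config$rpmThreshold)
  emit(screen, "mirna_screen.tsv")

  ## ---- differential expression ------------------------------------------
  cond <- config$conditions
  log <- .stageLog(log, sprintf(
    "diffexpr: FC > %g, p < %g, FDR < %g", config$deFcThreshold,
    config$pThreshold, config$qThreshold))
  geneMat <- summarizeProbes(exprs, probeGene)
  grp <- function(g) names(conditions)[conditions == g]
  contrast1 <- runContrast(geneMat, grp(cond[1]), grp(cond[2]),
                           config$deFcThreshold, config$pThreshold,
                           config$qThreshold)
  contrast2 <- runContrast(geneMat, grp(cond[2]), grp(cond[3]),
                           config$deFcThreshold, config$pThreshold,
                           config$qThreshold)
  de1 <- callDE(contrast1, config$deFcThreshold, config$pThreshold,
                config$qThreshold)
  de2 <- callDE(contrast2, config$deFcThreshold, config$pThreshold,
                config$qThreshold)
  emit(contrast1, "contrast_perturbed_vs_control.tsv")
  emit(contrast2, "contrast_treated_vs_perturbed.tsv")

  ## ---- targets ----------------------------------------------------------
  predicted <- NULL
  if (!is.null(utrs)) {
    log <- .stageLog(log, "targets: canonical 8mer/7mer-m8 rule")
    predicted <- predictTargets(config$mirnaSequence, utrs)
  }

  ## ---- rescue quadrants -------------------------------------------------
  log <- .stageLog(log, "rescue_quadrant: intersect DE sets")
  qt <- buildQuadrantTable(contrast1, contrast2, de1, de2,
                           targets = predicted)
  rescue <- rescueMetrics(qt, nAltered = length(de1))
  emit(qt, "quadrant_table.tsv")

  enrichment <- NULL
  if (!is.null(predicted)) {
    enrichment <- quadrantEnrichment(qt, predicted,
                                     background = rownames(geneMat))
    emit(enrichment, "quadrant_enrichment.tsv")
  }

  ## ---- global structure -------------------------------------------------
  log <- .stageLog(log, sprintf(
    "global_structure: AU bootstrap %d x %d scales", config$nBoot,
    length(config$scales)))
  log2mat <- log2(exprs)
  clustering <- auBootstrap(log2mat, nBoot = config$nBoot,
                            scales = config$scales,
                            seed = stageSeed(config$seed, "bootstrap"))
  if (!is.null(outdir))
    exportNewick(clustering, file.path(outdir, "dendrogram.nwk"))
  pca <- pcaExpression(log2mat)
  sel <- selectTopLoadings(pca, component = 1L,
                           quantile = config$loadingQuantile,
                           geneMap = stats::setNames(probeGene,
                                                     rownames(exprs)))

  ## ---- truth recovery ---------------------------------------------------
  recovery <- NULL
  if (!is.null(truth)) {
    planted <- truth$mirna@plantedMirnas
    plantedSet <- planted$mirna[planted$passExpected]
    passSet <- screen$mirna[screen$pass]
    deltaTrue <- alteredGenes(truth$expression)
    strong <- deltaTrue$gene[abs(deltaTrue$delta) >= 1]
    recovery <- list(
      screenExact = setequal(passSet, plantedSet),
      deRecallStrongAltered = if (length(strong))
        length(intersect(de1, strong)) / length(strong) else NA_real_,
      plantedRescueFraction = config$params@rescueFraction,
      plantedInverseRate = config$params@inverseRate)
  }

  ctAu <- cladeAU(clustering, names(conditions)[conditions %in%
                                                  cond[c(1, 3)]])
  report <- list(
    seed = config$seed,
    thresholds = list(mirnaFc = config$mirnaFcThreshold,
                      rpm = config$rpmThreshold, deFc = config$deFcThreshold,
                      p = config$pThreshold, q = config$qThreshold,
                      loadingQuantile = config$loadingQuantile),
    mirnaScreen = list(nPass = sum(screen$pass),
                       nUp = sum(screen$pass & screen$direction == "up"),
                       nDown = sum(screen$pass & screen$direction == "down"),
                       passSet = sort(screen$mirna[screen$pass])),
    de = list(nDePerturbedVsControl = length(de1),
              nDeTreatedVsPerturbed = length(de2)),
    rescue = rescue[c("nAltered", "nIntersect", "fractionAffected",
                      "fractionInverse", "pearsonR", "pearsonP")],
    quadrantCounts = as.list(rescue$quadrantCounts),
    enrichment = if (!is.null(enrichment)) lapply(
      split(as.data.frame(enrichment), enrichment$quadrant), as.list),
    nPredictedTargets = if (!is.null(predicted)) length(predicted),
    pca = list(varianceFractions = varianceFraction(pca)[1:2],
               selectionWeightFraction = weightFraction(sel),
               nSelectedProbes = length(selectedProbes(sel)),
               nSelectedGenes = sel@nGenes),
    clustering = list(nodes = as.list(auValues(clustering)),
                      controlTreatedAU = ctAu),
    truthRecovery = recovery)

  if (!is.null(outdir)) {
    writeLines(log, file.path(outdir, "run.log"))
    writeReport(report, file.path(outdir, "report.json"))
  }
  report
}

.reportRequired <- c("seed", "thresholds", "mirnaScreen", "de", "rescue",
                     "quadrantCounts", "pca", "clustering")

#' Validate a pipeline report
#'
#' Checks the presence of every required section and of the rescue
#' metrics fields.
#'
#' @param report a report list from [runPipeline()].
#' @return \code{TRUE}, invisibly; errors otherwise.
#' @export
validateReport <- function(report) {
  missing <- setdiff(.reportRequired, names(report))
  if (length(missing))
    stop("report is missing sections: ", paste(missing, collapse = ", "))
  needed <- c("nAltered", "nIntersect", "fractionAffected",
              "fractionInverse", "pearsonR")
  miss2 <- setdiff(needed, names(report$rescue))
  if (length(miss2))
    stop("rescue metrics missing: ", paste(miss2, collapse = ", "))
  invisible(TRUE)
}

#' Write a pipeline report as JSON
#'
#' Serializes the report with fixed float precision (10 significant
#' digits); undefined values (NA/NaN) become JSON null.
#'
#' @param report a report list from [runPipeline()] (validated first).
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeReport <- function(report, path) {
  validateReport(report)
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = I(10),
                           na = "null", null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a pipeline report
#'
#' @param path JSON report path.
#' @return The report as a list.
#' @export
readReport <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
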