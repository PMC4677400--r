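test_that("generators are deterministic under a fixed seed", {
  p <- smallParams(seed = 7)
  e1 <- simulateExpression(p); e2 <- simulateExpression(p)
  expect_identical(SummarizedExperiment::assay(e1$se),
                   SummarizedExperiment::assay(e2$se))
  expect_identical(alteredGenes(e1$truth), alteredGenes(e2$truth))
  m1 <- simulateMirnaCounts(p); m2 <- simulateMirnaCounts(p)
  expect_identical(SummarizedExperiment::assay(m1$se),
                   SummarizedExperiment::assay(m2$se))
  u1 <- simulateUtrs(p); u2 <- simulateUtrs(p)
  expect_identical(as.character(u1$utrs), as.character(u2$utrs))
})

test_that("rescue bookkeeping matches the requested fractions", {
  p0 <- smallParams(seed = 3, rescueFraction = 0)
  expect_identical(nrow(rescuedGenes(simulateExpression(p0)$truth)), 0L)

  tr <- simulateExpression(smallParams(seed = 3))$truth
  expect_identical(nrow(rescuedGenes(tr)), 60L)
  expect_true(all(rescuedGenes(tr)$gene %in% alteredGenes(tr)$gene))

  # default-size manifest: |rescued| = round(0.60 * 8000)
  trBig <- simulateExpression(SimulationParams(seed = 7))$truth
  expect_identical(nrow(rescuedGenes(trBig)), 4800L)
})

test_that("planted effects are recoverable from the noise-free matrices", {
  p <- smallParams(seed = 11, noiseSd = 0)
  sim <- simulateExpression(p)
  x <- log2(SummarizedExperiment::assay(sim$se, "exprs"))
  cond <- conditionOf(sim$se)
  geneRows <- seq_len(250)              # probes 1..nGenes map 1:1 onto genes
  dHat <- rowMeans(x[geneRows, cond == "perturbed"]) -
    rowMeans(x[geneRows, cond == "control"])
  tr <- alteredGenes(sim$truth)
  gid <- sub("probe", "gene", rownames(x)[geneRows])
  idx <- match(tr$gene, gid)
  expect_equal(unname(dHat[idx]), tr$delta, tolerance = 1e-10)
  expect_true(all(abs(dHat[-idx]) < 1e-10))
  yHat <- rowMeans(x[geneRows, cond == "treated"]) -
    rowMeans(x[geneRows, cond == "perturbed"])
  rg <- rescuedGenes(sim$truth)
  expect_equal(unname(yHat[match(rg$gene, gid)]), rg$y, tolerance = 1e-10)
})

test_that("target flags realize the planted odds ratio", {
  tr <- simulateExpression(SimulationParams(seed = 5))$truth
  fl <- targetFlags(tr)
  rg <- rescuedGenes(tr)
  alt <- alteredGenes(tr)
  upRescued <- rg$gene[alt$delta[match(rg$gene, alt$gene)] > 0]
  inClass <- names(fl) %in% upRescued
  tab <- table(inClass, fl)
  orHat <- (tab["TRUE", "TRUE"] / tab["TRUE", "FALSE"]) /
    (tab["FALSE", "TRUE"] / tab["FALSE", "FALSE"])
  expect_gt(orHat, 3 * 0.8)
  expect_lt(orHat, 3 * 1.2)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(SimulationParams(nProbes = 100, nGenes = 200), "nProbes")
  expect_error(SimulationParams(nReplicates = 0), "nReplicates")
  expect_error(SimulationParams(nAltered = 300, nGenes = 200,
                                nProbes = 300), "nAltered")
  expect_error(SimulationParams(rescueFraction = 1.2), "rescueFraction")
  expect_error(SimulationParams(mirnaLibrarySize = 0), "mirnaLibrarySize")
  expect_error(simulateUtrs(smallParams(), mirnaSequence = "UGUGCAXAA"),
               "alphabet|characters")
  expect_error(simulateUtrs(smallParams(), mirnaSequence = "UGUGCA"),
               "at least 8")
})

test_that("probe-to-gene map is surjective with a 1:1 head", {
  sim <- simulateExpression(smallParams(seed = 2))
  map <- SummarizedExperiment::rowData(sim$se)$gene
  expect_identical(length(map), 300L)
  expect_identical(sort(unique(map)), sort(unique(map[seq_len(250)])))
  expect_identical(length(unique(map)), 250L)  # every gene covered
})

test_that("planted miRNA truth has the stated structure", {
  sim <- simulateMirnaCounts(smallParams(seed = 9))
  planted <- plantedMirnas(sim$truth)
  expect_identical(sum(planted$passExpected), 8L)       # 6 down + 2 up
  expect_identical(sum(planted$direction == "down"), 6L)
  expect_identical(sum(planted$direction == "up"), 2L)
  expect_true(all(planted$fold[planted$passExpected] >= 2))
  expect_true(all(planted$baseRpm[planted$passExpected] > 200))
  # decoys fail exactly one filter each by construction
  decoys <- planted[planted$direction == "decoy", ]
  expect_identical(nrow(decoys), 2L)
  expect_true(any(decoys$fold >= 2 & decoys$baseRpm < 200))
  expect_true(any(decoys$fold < 1.8 & decoys$baseRpm > 200))
})

test_that("decoys never pass the screen in the noise-free limit", {
  sim <- simulateMirnaCounts(smallParams(seed = 13, mirnaDispersion = 0))
  rpm <- normalizeRpm(sim$se)
  g <- stats::setNames(
    as.character(SummarizedExperiment::colData(sim$se)$group),
    colnames(sim$se))
  sc <- screenMirnas(rpm, g)
  planted <- plantedMirnas(sim$truth)
  expect_setequal(sc$mirna[sc$pass], planted$mirna[planted$passExpected])
  expect_false(any(planted$mirna[planted$direction == "decoy"] %in%
                     sc$mirna[sc$pass]))
})

test_that("planted UTR sites sit at their recorded offsets", {
  p <- smallParams(seed = 4)
  sim <- simulateUtrs(p)
  sites <- sim$truth@utrSites
  expect_gt(nrow(sites), 0)
  seqs <- as.character(sim$utrs)
  pat <- miRescue:::.sitePatterns(MIR19A)
  for (i in seq_len(nrow(sites))) {
    s <- seqs[[sites$transcript[i]]]
    expected <- if (sites$type[i] == "8mer") pat$eightMer else pat$sevenM8
    got <- substr(s, sites$start[i] + 1, sites$start[i] + nchar(expected))
    expect_identical(got, expected)
  }
  # every planted site contains the reverse complement of miRNA pos 2-8
  expect_true(all(vapply(sites$transcript, function(tx)
    grepl(pat$sevenM8, seqs[[tx]], fixed = TRUE), logical(1))))
})

test_that("non-flagged UTRs carry no 7mer-or-longer site", {
  sim <- simulateUtrs(smallParams(seed = 6))
  fl <- targetFlags(sim$truth)
  nonTargets <- names(fl)[!fl]
  sites <- seedSites(MIR19A, sim$utrs[nonTargets])
  expect_identical(sum(sites$type %in% c("7mer-m8", "7mer-A1", "8mer")), 0L)
})
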