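test_that("correlation distance has the expected boundary values", {
  s <- rnorm(50)
  m <- cbind(a = s, b = s, c = -s + mean(s) * 2, d = rnorm(50))
  m[, "c"] <- -(s - mean(s)) + mean(s)           # exactly anticorrelated
  d <- sampleDistance(m)
  expect_equal(d["a", "b"], 0)                   # identical profiles
  expect_equal(d["a", "c"], 2)                   # r = -1 boundary
  expect_equal(d, t(d))                          # symmetry
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_error(sampleDistance(cbind(a = s, b = s, k = rep(1, 50))),
               "constant")
  expect_error(sampleDistance(m[, 1:2]), "3 samples")
})

test_that("euclidean distance option matches dist()", {
  set.seed(1)
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(sampleDistance(m, "euclidean"),
               as.matrix(dist(t(m))), ignore_attr = TRUE)
})

test_that("hierarchical clustering merges nearest samples first", {
  d <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- clusterSamples(d)
  expect_identical(sort(hc$labels[-hc$merge[1, ]]), c("A", "B"))
  expect_identical(nrow(hc$merge), 2L)           # n - 1 internal nodes
  # a duplicated sample joins its twin at height 0
  set.seed(2)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, c("s1", "s2", "s3", "s4")))
  m[, "s4"] <- m[, "s1"]
  hc2 <- clusterSamples(sampleDistance(m))
  i <- which(apply(hc2$merge, 1, function(r) all(r < 0)) &
               hc2$height < 1e-12)
  expect_true(length(i) >= 1)
  expect_error(clusterSamples(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("the probit fit reproduces the BP in the flat-scale regime", {
  scales <- seq(0.5, 1.4, by = 0.1)
  f50 <- auFit(rep(0.5, 10), scales, nBoot = 1000)
  expect_equal(f50$au, 50, tolerance = 1e-8)
  f55 <- auFit(rep(0.55, 10), scales, nBoot = 1000)
  expect_lt(abs(f55$au - 55), 5)
  # saturated clades
  expect_equal(auFit(rep(1, 10), scales, 1000)$au, 100)
  expect_true(auFit(rep(1, 10), scales, 1000)$degenerate)
  expect_equal(auFit(rep(0, 10), scales, 1000)$au, 0)
  expect_error(auFit(rep(0.5, 3), scales, 1000), "per scale")
})

test_that("AU bootstrap is deterministic and finds planted clusters", {
  set.seed(10)
  base <- rnorm(200)                              # shared probe baseline
  sig <- rnorm(200, 0, 2)                         # group-specific profile
  m <- matrix(rnorm(200 * 6, 0, 0.5), 200) + base
  m[, 4:6] <- m[, 4:6] + sig
  colnames(m) <- c(paste0("x", 1:3), paste0("y", 1:3))
  au1 <- auBootstrap(m, nBoot = 200, seed = 99)
  au2 <- auBootstrap(m, nBoot = 200, seed = 99)
  expect_identical(auValues(au1), auValues(au2))
  expect_identical(bpValues(au1), bpValues(au2))
  expect_gte(cladeAU(au1, paste0("x", 1:3)), 95)
  expect_gte(cladeAU(au1, paste0("y", 1:3)), 95)
  expect_true(all(au1@nodes$bp >= 0 & au1@nodes$bp <= 100))
  expect_true(all(au1@nodes$au >= 0 & au1@nodes$au <= 100))
  # the root is present in every resample
  expect_equal(cladeAU(au1, colnames(m)), 100)
})

test_that("PCA variance fractions behave like a decomposition", {
  # exact rank-1 data: one direction carries all the variance
  u <- rnorm(40); v <- c(1, 2, 3, 4, 5)
  m1 <- outer(u, v)
  rownames(m1) <- paste0("p", 1:40); colnames(m1) <- paste0("s", 1:5)
  pca1 <- pcaExpression(m1)
  expect_equal(varianceFraction(pca1)[1], 100, tolerance = 1e-8)

  set.seed(3)
  m <- matrix(rnorm(200), 40, 5,
              dimnames = list(paste0("p", 1:40), paste0("s", 1:5)))
  pca <- pcaExpression(m)
  expect_equal(sum(varianceFraction(pca)), 100, tolerance = 1e-8)
  # loadings are unit vectors
  expect_equal(unname(colSums(pcaLoadings(pca)^2)),
               rep(1, ncol(pcaLoadings(pca))), tolerance = 1e-8)
  # Parseval: score distances reproduce centered-data distances
  dScores <- dist(pcaScores(pca))
  dData <- dist(t(m - rowMeans(m)))
  expect_equal(as.numeric(dScores), as.numeric(dData), tolerance = 1e-8)
  expect_error(pcaExpression(m[, 1, drop = FALSE]), "2 samples")
  expect_error(pcaExpression(cbind(a = u, b = u)), "distinct")
})

test_that("top-loading selection reports exact weight fractions", {
  L <- matrix(c(4, 3, 2, 1), 4, 1,
              dimnames = list(paste0("p", 1:4), "PC1"))
  pca <- methods::new("PcaResult", scores = matrix(0, 2, 1),
                      loadings = L, varianceFraction = 100)
  sel <- selectTopLoadings(pca, quantile = 0.25)
  expect_identical(selectedProbes(sel), "p1")
  expect_equal(weightFraction(sel), 0.4)         # 4 / (4+3+2+1)
  expect_equal(weightFraction(selectTopLoadings(pca, quantile = 1)), 1)
  # uniform loadings: weight fraction equals the quantile
  Lu <- matrix(rep(0.5, 10), 10, 1,
               dimnames = list(paste0("p", 1:10), "PC1"))
  pcaU <- methods::new("PcaResult", scores = matrix(0, 2, 1),
                       loadings = Lu, varianceFraction = 100)
  expect_equal(weightFraction(selectTopLoadings(pcaU, quantile = 0.10)),
               0.10)
  expect_error(selectTopLoadings(pca, quantile = 0), "quantile")
  expect_error(selectTopLoadings(pca, component = 5), "component")
})

test_that("top-loading selection is equivariant under probe permutation", {
  set.seed(6)
  l <- rnorm(20)
  L <- matrix(l, 20, 1, dimnames = list(sprintf("p%02d", 1:20), "PC1"))
  perm <- sample(20)
  Lp <- L[perm, , drop = FALSE]
  pcaA <- methods::new("PcaResult", scores = matrix(0, 2, 1),
                       loadings = L, varianceFraction = 100)
  pcaB <- methods::new("PcaResult", scores = matrix(0, 2, 1),
                       loadings = Lp, varianceFraction = 100)
  sA <- selectTopLoadings(pcaA, quantile = 0.25)
  sB <- selectTopLoadings(pcaB, quantile = 0.25)
  expect_setequal(selectedProbes(sA), selectedProbes(sB))
  expect_equal(weightFraction(sA), weightFraction(sB))
})

test_that("Newick export carries AU/BP node labels", {
  set.seed(11)
  m <- matrix(rnorm(600), 100, 6) + rnorm(100)
  m[, 4:6] <- m[, 4:6] + rnorm(100, 0, 2)
  colnames(m) <- paste0("s", 1:6)
  au <- auBootstrap(m, nBoot = 100, seed = 1)
  path <- tempfile(fileext = ".nwk")
  exportNewick(au, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, colnames(m))
  expect_true(any(grepl("\\|", phy$node.label)))
})
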