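test_that("seed sites of miR-19a are classified by their flanks", {
  # seed (pos 2-8) = GUGCAAA; 7mer-m8 = UUUGCAC, 8mer = UUUGCACA
  s8 <- seedSites(MIR19A, c(tx = "GGAUUUGCACAGG"))
  expect_identical(nrow(s8), 1L)
  expect_identical(s8$type, "8mer")
  expect_identical(s8$start, 3L)
  expect_identical(s8$end, 11L)

  # 7mer-m8 not followed by A
  s7 <- seedSites(MIR19A, c(tx = "GGAUUUGCACGG"))
  expect_identical(s7$type, "7mer-m8")
  expect_identical(s7$start, 3L)

  # UTR equal to the 7mer-m8 pattern exactly: position 0
  sMin <- seedSites(MIR19A, c(tx = "UUUGCAC"))
  expect_identical(sMin$type, "7mer-m8")
  expect_identical(sMin$start, 0L)

  # 7mer-A1 (core + A, no m8 match upstream) and plain 6mer
  sA1 <- seedSites(MIR19A, c(tx = "GGUUGCACAGG"))
  expect_identical(sA1$type, "7mer-A1")
  s6 <- seedSites(MIR19A, c(tx = "GGUUGCACGG"))
  expect_identical(s6$type, "6mer")

  # no occurrence of any pattern
  expect_identical(nrow(seedSites(MIR19A, c(tx = "AAAAAAAAAA"))), 0L)
  expect_error(seedSites(MIR19A, c(tx = "ANXA")), "characters")
  expect_error(seedSites("ACGU", c(tx = "ACGU")), "at least 8")
})

test_that("T is accepted and read as U", {
  sd <- seedSites(MIR19A, c(tx = "GGATTTGCACAGG"))
  expect_identical(sd$type, "8mer")
})

test_that("seed sites match an independent brute-force scan", {
  set.seed(42)
  for (i in 1:300) {
    utr <- randomRnaString(sample(60:120, 1))
    got <- as.data.frame(seedSites(MIR19A, c(tx = utr)))[, c("start", "type")]
    want <- bruteSites(MIR19A, utr)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got[order(got$start), , drop = FALSE],
                     want[, c("start", "type"), drop = FALSE])
  }
})

test_that("target prediction applies the stringency rule", {
  utrs <- c(strong = "GGAUUUGCACAGG",       # one 8mer
            weak = "GGUUGCACGG",            # 6mer only
            none = "AAAACCCCGGGG")
  expect_identical(predictTargets(MIR19A, utrs), "strong")
  expect_identical(predictTargets(MIR19A, utrs, minSites = 2), character(0))
  expect_identical(
    predictTargets(MIR19A, utrs, siteTypes = c("6mer", "7mer-A1")), "weak")
  expect_error(predictTargets(MIR19A, character(0)), "empty")
})

test_that("hypergeometric tails are exact on enumerable cases", {
  expect_equal(hypergeomTail(4, K = 4, n = 5, N = 10, "over"), 6 / 252,
               tolerance = 1e-14)
  # under tail at k = 0 is the no-success probability
  expect_equal(hypergeomTail(0, K = 3, n = 4, N = 10, "under"),
               choose(7, 4) / choose(10, 4), tolerance = 1e-14)
  expect_equal(hypergeomTail(0, K = 0, n = 4, N = 10, "under"), 1)
  expect_equal(hypergeomTail(0, K = 3, n = 4, N = 10, "over"), 1)
  expect_error(hypergeomTail(5, K = 4, n = 5, N = 10), "min")
  expect_error(hypergeomTail(1, K = 11, n = 5, N = 10), "inconsistent")
})

test_that("hypergeometric tails agree with the distribution function", {
  set.seed(9)
  for (i in 1:50) {
    N <- sample(5:200, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    ks <- max(0, n - (N - K)):min(K, n)
    k <- ks[sample.int(length(ks), 1)]
    expect_equal(hypergeomTail(k, K, n, N, "under"),
                 phyper(k, K, N - K, n), tolerance = 1e-12)
    expect_equal(hypergeomTail(k, K, n, N, "over"),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("quadrant enrichment computes both tails per quadrant", {
  genes <- sprintf("g%03d", 1:100)
  qII <- genes[1:20]
  table <- methods::new("QuadrantTable", S4Vectors::DataFrame(
    gene = qII, x = 1, y = -1, quadrant = "QII", row.names = qII))
  targets <- c(genes[1:8], genes[95:96])   # 8 of 20 in QII, 10 overall
  enr <- quadrantEnrichment(table, targets, genes)
  row <- enr[enr$quadrant == "QII", ]
  expect_identical(row$N, 100L); expect_identical(row$K, 10L)
  expect_identical(row$n, 20L); expect_identical(row$k, 8L)
  expect_equal(row$pOver, hypergeomTail(8, 10, 20, 100, "over"))
  # empty quadrants carry no evidence
  empty <- enr[enr$quadrant == "QI", ]
  expect_equal(empty$pOver, 1); expect_equal(empty$pUnder, 1)
})

test_that("degenerate target sets and stray ids are handled", {
  genes <- sprintf("g%03d", 1:50)
  table <- methods::new("QuadrantTable", S4Vectors::DataFrame(
    gene = genes[1:10], x = 1, y = -1, quadrant = "QII",
    row.names = genes[1:10]))
  # targets = background: every quadrant has k = n, over tail is 1
  enr <- quadrantEnrichment(table, genes, genes)
  expect_true(all(enr$pOver == 1))
  expect_warning(quadrantEnrichment(table, c(genes[1], "stray"), genes),
                 "dropped")
  suppressWarnings(
    expect_error(quadrantEnrichment(table, genes[1], genes[20:50]),
                 "subset"))
})
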