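test_that("sigma-scores match hand evaluation of both forms", {
  r2 <- sqrt(2)
  # group A: mean 10, sample var 4; group B: mean 4, sample var 4
  m <- matrix(c(10 - r2, 10 + r2, 4 - r2, 4 + r2), 1, 4,
              dimnames = list("g", paste0("c", 1:4)))
  lab <- c("A", "A", "B", "B")
  tab <- sigmaScores(m, lab, form = "dprime")
  expect_equal(tab$sigma, 6 / sqrt((4 + 4) / 2))   # = 3.0
  expect_equal(unname(tab$meanA), 10); expect_equal(unname(tab$varB), 4)
  lit <- sigmaScores(m, lab, form = "literal")
  expect_equal(lit$sigma, 6 / ((4 + 4) / 2))       # = 1.5
})

test_that("sigma-score symmetries and degenerate cases", {
  set.seed(20)
  m <- matrix(rpois(200, 20), 10, 20,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))
  lab <- rep(c("A", "B"), each = 10)
  tab <- sigmaScores(m, lab)
  # group swap leaves sigma unchanged
  swapped <- sigmaScores(m, ifelse(lab == "A", "B", "A"))
  expect_equal(swapped$sigma, tab$sigma)
  # adding a constant to every cell leaves sigma unchanged
  expect_equal(sigmaScores(m + 100, lab)$sigma, tab$sigma)
  # identical groups: sigma 0 everywhere
  ident <- cbind(m[, 1:10], m[, 1:10])
  expect_equal(sigmaScores(ident, lab)$sigma, rep(0, 10))
  # zero pooled variance with nonzero difference: infinite sentinel
  deg <- matrix(c(1, 1, 5, 5, 2, 2, 2, 2), 2, 4, byrow = TRUE,
                dimnames = list(c("gInf", "gZero"), paste0("c", 1:4)))
  dt <- sigmaScores(deg, c("A", "A", "B", "B"))
  expect_equal(dt$sigma, c(Inf, 0))
  expect_error(sigmaScores(m[, 1:3], c("A", "A", "B")), ">= 2 cells")
})

test_that("genes rank by descending sigma with lexicographic ties", {
  tab <- S4Vectors::DataFrame(gene = c("a", "b", "c"), sigma = c(3, 1, 2))
  rk <- rankGenes(tab)
  expect_equal(rk$gene, c("a", "c", "b"))
  expect_equal(rk$rank, 1:3)
  ties <- S4Vectors::DataFrame(gene = c("z", "m", "a"), sigma = c(1, 1, 1))
  expect_equal(rankGenes(ties)$gene, c("a", "m", "z"))
  inf <- S4Vectors::DataFrame(gene = c("fin", "inf"), sigma = c(1e6, Inf))
  expect_equal(rankGenes(inf)$gene[1], "inf")
})

test_that("proportional shuffling preserves group sizes and is uniform", {
  lab <- rep(c("A", "B"), c(60, 43))
  sh <- proportionalShuffle(lab, seed = 1)
  expect_equal(as.vector(table(sh)[c("A", "B")]), c(60L, 43L))
  expect_identical(proportionalShuffle(lab, seed = 5),
                   proportionalShuffle(lab, seed = 5))
  # each cell lands in A with frequency nA / n
  lab2 <- rep(c("A", "B"), c(3, 7))
  set.seed(2)
  freq <- rowMeans(vapply(1:10000, function(i)
    proportionalShuffle(lab2) == "A", logical(10)))
  expect_equal(unname(freq), rep(0.3, 10), tolerance = 0.12)
})

test_that("rank-sum test matches exact enumeration and known values", {
  out <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$U, 0)
  expect_equal(out$log10P, log10(0.1))
  expect_equal(out$method, "exact")
  # identical multisets: p = 1 (tied, normal path, z = 0)
  same <- rankSumTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$log10P, 0)
  expect_error(rankSumTest(numeric(0), 1), "non-empty")
})

test_that("rank-sum exact path agrees with brute-force enumeration", {
  set.seed(21)
  for (nx in c(2, 3, 5, 7)) {
    for (ny in c(2, 4, 7)) {
      x <- sample(seq_len(50), nx)
      y <- sample(setdiff(seq_len(50), x), ny)
      got <- rankSumTest(x, y)
      want <- bruteForceRankSum(x, y)
      expect_equal(got$U, want$U)
      expect_equal(10^got$log10P, want$p, tolerance = 1e-12)
    }
  }
})

test_that("log-space normal approximation reaches extreme p-values", {
  # complete separation at 250 vs 250: U = 62500, sd = sqrt(62500 * 501/12)
  out <- rankSumTest(seq_len(250) + 1000, seq_len(250))
  expect_equal(out$U, 62500)
  expect_equal(out$method, "normal")
  z <- 31250 / sqrt(62500 * 501 / 12)
  expect_equal(z, 19.35, tolerance = 0.001)
  expect_equal(out$log10P, -82.65, tolerance = 0.01)
  # ... which an off-log computation could not represent
  expect_lt(out$log10P, log10(.Machine$double.xmin) + 300)
})

test_that("shuffle separation test flags planted structure and not null data", {
  sim <- simulateTwoPopulations(simConfig(
    nGenes = 1000, nCellsPerGroup = c(40, 40), nMarkerGenes = 300,
    foldChange = 8, seed = 22))
  expr <- filterExpressedGenes(tpmNormalize(sim$counts))
  res <- shuffleSeparationTest(expr, k = 250, nShuffles = 10, seed = 23)
  expect_s4_class(res, "ShuffleTestResult")
  expect_equal(testVerdict(res), "distinct")
  expect_lt(median(log10PValues(res)), -70)
  # null: the two populations share one distribution
  simN <- simulateTwoPopulations(simConfig(
    nGenes = 1000, nCellsPerGroup = c(40, 40), nMarkerGenes = 0, seed = 24))
  exprN <- filterExpressedGenes(tpmNormalize(simN$counts))
  resN <- shuffleSeparationTest(exprN, k = 250, nShuffles = 10, seed = 25)
  expect_equal(testVerdict(resN), "similar")
  expect_true(all(log10PValues(resN) > -10))
  expect_error(shuffleSeparationTest(expr, nShuffles = 0), "nShuffles")
  expect_warning(shuffleSeparationTest(exprN[1:100, ], k = 250,
                                       nShuffles = 2, seed = 1), "clamped")
})

test_that("planted markers are enriched in the top-ranked genes", {
  sim <- simulateTwoPopulations(simConfig(
    nGenes = 2000, nCellsPerGroup = c(65, 65), nMarkerGenes = 150,
    foldChange = 8, seed = 26))
  expr <- tpmNormalize(sim$counts)
  rk <- rankGenes(sigmaScores(expr))
  top <- rk$gene[seq_len(150)]
  markers <- sim$truth@markerGenes$gene
  overlap <- length(intersect(top, markers))
  # hypergeometric tail for the observed overlap among 2004 genes
  pHyper <- phyper(overlap - 1, length(markers), nrow(expr) - length(markers),
                   150, lower.tail = FALSE)
  expect_lt(pHyper, 1e-10)
  # and rank-based AUC of marker membership (P(marker outranks non-marker))
  isMarker <- rk$gene %in% markers
  revRank <- rank(-rk$rank)
  u <- sum(revRank[isMarker]) - sum(isMarker) * (sum(isMarker) + 1) / 2
  auc <- u / (sum(isMarker) * sum(!isMarker))
  expect_gt(auc, 0.95)
})

test_that("pairwise Pearson on variable genes separates the populations", {
  set.seed(27)
  m <- matrix(10^runif(300, 1, 3), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:10)))
  m[1:10, 6:10] <- m[1:10, 6:10] * 20
  m <- m * matrix(runif(300, 0.8, 1.2), 30, 10)
  twin <- cbind(m, m[, 1, drop = FALSE] * 1)
  colnames(twin)[11] <- "c1copy"
  r <- pairwisePearson(twin, paste0("g", 1:30))
  expect_equal(unname(r["c1", "c1copy"]), 1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 11))
  lab <- rep(c("A", "B"), each = 5)
  r2 <- pairwisePearson(m, paste0("g", 1:30), orderBy = lab)
  within <- c(r2[1:5, 1:5][upper.tri(diag(5))],
              r2[6:10, 6:10][upper.tri(diag(5))])
  between <- as.vector(r2[1:5, 6:10])
  expect_gt(mean(within), mean(between))
  expect_error(pairwisePearson(m, "g1"), "2 variable genes")
})
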