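test_that("tag reads split into UMI then barcode, extra cycles ignored", {
  expect_equal(as.list(parseBarcodeRead("ACGTACGGATCC")),
               list(umi = "ACGTAC", barcode = "GGATCC"))
  expect_equal(parseBarcodeRead("ACGTACGGATCCT")$barcode, "GGATCC")
  expect_error(parseBarcodeRead("ACGTACGGAT"), "shorter")
  out <- parseBarcodeRead(c("AAACCCGGGTTT", "TTTGGGCCCAAA"))
  expect_equal(out$umi, c("AAACCC", "TTTGGG"))
})

test_that("UMI collapsing counts distinct tags and caps at the UMI space", {
  reads <- S4Vectors::DataFrame(
    barcode = rep("BC1", 3), gene = rep("geneA", 3),
    umi = c("AAAAAA", "AAAAAA", "CCCCCC"))
  sce <- collapseUMIs(reads)
  expect_equal(unname(SummarizedExperiment::assay(sce)["geneA", "BC1"]), 2L)
  empty <- collapseUMIs(reads[0, ], genes = "geneA", cells = "BC1")
  expect_equal(unname(SummarizedExperiment::assay(empty)["geneA", "BC1"]), 0L)
  # 5000 reads cannot carry more than 4^6 = 4096 distinct 6-nt UMIs
  set.seed(1)
  umis <- sample(allKmers(6), 5000, replace = TRUE)
  many <- S4Vectors::DataFrame(barcode = "BC1", gene = "geneA", umi = umis)
  expect_lte(unname(SummarizedExperiment::assay(collapseUMIs(many))[1, 1]),
             4096L)
  full <- S4Vectors::DataFrame(barcode = "BC1", gene = "geneA",
                               umi = c(allKmers(6), allKmers(6)[1:904]))
  expect_equal(unname(SummarizedExperiment::assay(collapseUMIs(full))[1, 1]),
               4096L)
})

test_that("collapsed counts never exceed read counts, equal iff all UMIs distinct", {
  set.seed(2)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    reads <- S4Vectors::DataFrame(
      barcode = "BC", gene = sample(c("g1", "g2"), n, replace = TRUE),
      umi = sample(allKmers(3), n, replace = TRUE))
    sce <- collapseUMIs(reads)
    for (g in unique(reads$gene)) {
      sub <- reads[reads$gene == g, ]
      cnt <- SummarizedExperiment::assay(sce)[g, "BC"]
      expect_lte(cnt, nrow(sub))
      expect_equal(cnt == nrow(sub), !anyDuplicated(sub$umi) > 0)
    }
  }
})

test_that("tpm normalization scales each cell to one million", {
  m <- matrix(c(1, 3), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  tpm <- tpmNormalize(m)
  expect_equal(as.vector(tpm), c(250000, 750000))
  single <- matrix(7, 1, 1, dimnames = list("g1", "c1"))
  expect_equal(as.vector(tpmNormalize(single)), 1e6)
  set.seed(3)
  big <- matrix(rpois(600, 5), 30, 20)
  expect_equal(unname(colSums(tpmNormalize(big))), rep(1e6, 20))
})

test_that("zero cells are excluded with a warning, not silently dropped", {
  m <- matrix(c(5, 5, 0, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("ok", "empty")))
  sce <- makeCountSce(m)
  expect_warning(out <- tpmNormalize(sce), "empty")
  expect_equal(colnames(out), "ok")
  expect_equal(S4Vectors::metadata(out)$excludedCells, "empty")
})

test_that("spike-ins are excluded from the tpm denominator by default", {
  m <- matrix(c(90, 10), 2, 1, dimnames = list(c("g1", "ERCC-1"), "c1"))
  sce <- makeCountSce(m, geneClass = c("endogenous", "spikein"))
  tpm <- SummarizedExperiment::assay(tpmNormalize(sce), "tpm")
  expect_equal(unname(tpm["g1", 1]), 1e6)           # denominator: endogenous only
  expect_equal(unname(tpm["ERCC-1", 1]), 10 / 90 * 1e6)
  tpmAll <- SummarizedExperiment::assay(tpmNormalize(sce,
                                                     includeSpikeIns = TRUE),
                                        "tpm")
  expect_equal(unname(colSums(tpmAll)), 1e6)
})

test_that("expression filter is strict and not renormalized", {
  # a gene sitting at tpm exactly 5.0 in every cell is dropped
  counts <- matrix(c(1, 199996, 3,
                     1, 199999, 0), 3, 2,
                   dimnames = list(c("at5", "big", "sometimes"),
                                   c("c1", "c2")))
  tpm <- tpmNormalize(counts)
  expect_equal(unname(tpm["at5", ]), c(5, 5))
  kept <- filterExpressedGenes(tpm, threshold = 5)
  expect_false("at5" %in% rownames(kept))
  # retained if any single cell exceeds the threshold
  expect_true("sometimes" %in% rownames(kept))
  # values untouched (no renormalization)
  expect_equal(kept["big", ], tpm["big", ])
  # threshold 0 drops only all-zero genes
  z <- rbind(tpm, none = c(0, 0))
  expect_setequal(rownames(filterExpressedGenes(z, threshold = 0)),
                  c("at5", "big", "sometimes"))
  # filtering is idempotent
  expect_equal(filterExpressedGenes(kept, threshold = 5), kept)
})

test_that("log-z transform standardizes genes and zeroes constant rows", {
  set.seed(4)
  tpm <- matrix(10^runif(60, 0, 4), 6, 10,
                dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  tpm[3, ] <- 50  # constant gene
  z <- logZMatrix(tpm)
  expect_equal(unname(rowMeans(z[-3, ])), rep(0, 5))
  expect_equal(unname(apply(z[-3, ], 1, sd)), rep(1, 5))
  expect_equal(unname(z[3, ]), rep(0, 10))
  # monotone transform preserves per-gene cell ordering
  expect_equal(order(z[1, ]), order(tpm[1, ]))
  expect_error(logZMatrix(tpm, genes = character(0)), "non-empty")
  expect_error(logZMatrix(tpm, genes = "nope"), "not present")
})
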