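test_that("two-population generator produces the configured shape and flags", {
  cfg <- simConfig(nGenes = 5000, nCellsPerGroup = c(65, 65),
                   nMarkerGenes = 300, foldChange = 8, seed = 1)
  sim <- simulateTwoPopulations(cfg)
  expect_equal(dim(sim$counts), c(5004L, 130L))  # + 4 class marker genes
  expect_equal(sum(SummarizedExperiment::rowData(sim$counts)$isMarker), 300L)
  expect_equal(nrow(sim$truth@markerGenes), 300L)
  expect_equal(as.vector(table(sim$truth@cellLabels)[c("glut", "GABA")]),
               c(65L, 65L))
  expect_true(all(SummarizedExperiment::assay(sim$counts, "counts") >= 0))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- simConfig(nGenes = 200, nCellsPerGroup = c(10, 10),
                   nMarkerGenes = 20, seed = 42)
  a <- simulateTwoPopulations(cfg)
  b <- simulateTwoPopulations(cfg)
  expect_identical(SummarizedExperiment::assay(a$counts, "counts"),
                   SummarizedExperiment::assay(b$counts, "counts"))
  d <- spikeInDesign(c(s1 = 100, s2 = 1000), nSamples = 3)
  expect_identical(
    SummarizedExperiment::assay(simulateSpikeInPlate(d, 0.2, seed = 9)),
    SummarizedExperiment::assay(simulateSpikeInPlate(d, 0.2, seed = 9)))
  pairA <- simulateMitoPair(c(60), genomeLength = 2000, seed = 5)
  pairB <- simulateMitoPair(c(60), genomeLength = 2000, seed = 5)
  expect_identical(as.character(pairA$genomeB), as.character(pairB$genomeB))
  t1 <- simulateTuningDataset(3, nTrials = 8, seed = 7)
  t2 <- simulateTuningDataset(3, nTrials = 8, seed = 7)
  expect_identical(t1$traces$value, t2$traces$value)
})

test_that("fold change one yields no group-dependent marker expression", {
  cfg <- simConfig(nGenes = 500, nCellsPerGroup = c(80, 80),
                   nMarkerGenes = 100, foldChange = 1, seed = 3)
  sim <- simulateTwoPopulations(cfg)
  m <- SummarizedExperiment::assay(sim$counts, "counts")
  markers <- sim$truth@markerGenes$gene
  lab <- sim$truth@cellLabels
  ratio <- sum(m[markers, lab == "glut"]) / sum(m[markers, lab == "GABA"])
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
  expect_equal(unique(sim$truth@markerGenes$foldChange), 1)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(simConfig(nGenes = 0), "nGenes")
  expect_error(simConfig(foldChange = 0), "foldChange")
  expect_error(simConfig(captureEfficiency = 1.2), "captureEfficiency")
  expect_error(simConfig(nMarkerGenes = 50, nGenes = 10), "nMarkerGenes")
  expect_error(simConfig(nCellsPerGroup = 10), "nCellsPerGroup")
})

test_that("spike-in detection counts follow the binomial capture model", {
  # one species, 5 molecules: over many independent samples the detected
  # count distribution must match Binomial(5, p) (UMI collisions among <= 5
  # molecules in a 4096 UMI space are rare enough not to distort the pmf)
  p <- 0.3
  d <- spikeInDesign(c(sp = 5), nSamples = 20000)
  sce <- simulateSpikeInPlate(d, p, seed = 11)
  detected <- as.vector(SummarizedExperiment::assay(sce))
  emp <- tabulate(detected + 1L, nbins = 6L) / length(detected)
  expect_lt(max(abs(emp - dbinom(0:5, 5, p))), 0.015)
})

test_that("spike-in plate honours the efficiency limits", {
  d <- spikeInDesign(c(a = 50, b = 500), nSamples = 4)
  expect_true(all(SummarizedExperiment::assay(
    simulateSpikeInPlate(d, 0, seed = 1)) == 0))
  # efficiency 1, 3 molecules: mean unique-UMI count matches the collision
  # expectation 4096 * (1 - (1 - 1/4096)^3)
  d3 <- spikeInDesign(c(sp = 3), nSamples = 20000)
  obs <- mean(SummarizedExperiment::assay(simulateSpikeInPlate(d3, 1,
                                                               seed = 2)))
  expected <- 4096 * (1 - (1 - 1 / 4096)^3)
  expect_equal(obs, expected, tolerance = 0.001)
  expect_error(simulateSpikeInPlate(d, 1.5, seed = 1), "efficiency")
})

test_that("marker-contamination planting matches the estimator algebra", {
  cfg <- simConfig(nGenes = 300, nCellsPerGroup = c(50, 50),
                   nMarkerGenes = 0, seed = 8)
  sim <- simulateTwoPopulations(cfg)
  # fraction 0 leaves the matrix untouched
  un <- simulateMarkerContamination(sim$counts, sim$truth, 0)
  expect_identical(SummarizedExperiment::assay(un$counts, "counts"),
                   SummarizedExperiment::assay(sim$counts, "counts"))
  # fraction 0.5: opposite-class marker level equals own-class level in
  # expectation, so the per-cell estimate centres on 0.5
  half <- simulateMarkerContamination(sim$counts, sim$truth, 0.5, seed = 9)
  est <- estimateMarkerContamination(tpmNormalize(half$counts))
  gs <- S4Vectors::metadata(est)$groupSummary
  expect_equal(unname(gs$glut["mean"]), 0.5, tolerance = 0.02)
  expect_error(
    simulateMarkerContamination(sim$counts, sim$truth, 0.1,
                                markers = list(gaba = "NotAGene",
                                               glut = "Slc17a7")),
    "NotAGene")
})

test_that("planted homology blocks behave around the masking threshold", {
  # a single 60-nt block: exactly one maximal shared run, of length 60
  pair <- simulateMitoPair(c(60), genomeLength = 3000, k = 40, seed = 2)
  shared <- bruteSharedKmers(as.character(pair$genomeA),
                             as.character(pair$genomeB), 40)
  expect_length(shared, (60 - 40 + 1) * 2)  # both strands of the single run
  # no blocks: no shared 40-mer at all
  pairEmpty <- simulateMitoPair(integer(0), genomeLength = 3000, seed = 3)
  expect_length(bruteSharedKmers(as.character(pairEmpty$genomeA),
                                 as.character(pairEmpty$genomeB), 40), 0)
  # a 39-nt block is invisible to 40-mer masking
  pair39 <- simulateMitoPair(c(39), genomeLength = 3000, k = 40, seed = 4)
  masked <- maskSharedKmers(pair39$genomeA, pair39$genomeB, k = 40)
  expect_identical(as.character(maskedSequence(masked)),
                   as.character(pair39$genomeB))
  expect_error(simulateMitoPair(c(500), genomeLength = 400, seed = 1),
               "block length")
})

test_that("barcode hopping moves rat reads onto mouse barcodes at the set rate", {
  pair <- simulateMitoPair(integer(0), genomeLength = 2000, seed = 6)
  genomes <- list(mouse = pair$genomeA, rat = pair$genomeB)
  noHop <- simulateCrossSpeciesReads(genomes, nMouseCells = 4, nRatCells = 2,
                                     readsPerCell = 500, hopRate = 0, seed = 1)
  md <- S4Vectors::metadata(noHop)
  expect_false(any(noHop$barcode[noHop$trueSpecies == "rat"] %in%
                     md$mouseBarcodes))
  allHop <- simulateCrossSpeciesReads(genomes, nMouseCells = 1, nRatCells = 1,
                                      readsPerCell = 500, hopRate = 1,
                                      seed = 2)
  md2 <- S4Vectors::metadata(allHop)
  expect_true(all(allHop$barcode[allHop$trueSpecies == "rat"] ==
                    md2$mouseBarcodes))
  r <- 0.05
  some <- simulateCrossSpeciesReads(genomes, nMouseCells = 4, nRatCells = 2,
                                    readsPerCell = 10000, hopRate = r,
                                    seed = 3)
  md3 <- S4Vectors::metadata(some)
  hopped <- mean(some$barcode[some$trueSpecies == "rat"] %in%
                   md3$mouseBarcodes)
  expect_equal(hopped, r, tolerance = 0.2)
})

test_that("tuning generator enforces the trial minimum and class mix", {
  expect_error(simulateTuningDataset(2, nTrials = 7, seed = 1),
               "at least 8 trials")
  expect_error(simulateTuningDataset(2, classMix = c(HS = 0.7, LS = 0.7,
                                                     none = 0), seed = 1),
               "sum to 1")
  tun <- simulateTuningDataset(4, classMix = c(HS = 1, LS = 0, none = 0),
                               nTrials = 8, seed = 5)
  expect_true(all(tun$truth == "HS"))
  # 8 directions x 2 stimuli x 8 trials x 12 frames per cell
  expect_equal(nrow(tun$traces), 4 * 2 * 8 * 8 * 12)
  expect_setequal(unique(tun$traces$direction), seq(0, 315, by = 45))
})
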