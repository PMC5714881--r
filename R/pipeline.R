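# End-to-end orchestration: simulate -> quantify -> spike-in QC ->
# contamination -> differential expression -> tuning, with a machine-readable
# report. This is the package's single entry point for a full synthetic run.

#' Build a pipeline configuration
#'
#' All stage parameters with their defaults; every default that the underlying
#' method defines mirrors the corresponding analysis parameter (tpm > 5
#' filter, k = 40 masking, 43-nt reads, top-250 genes, minimum biological
#' CV = 50 percent, tuning ratio 4, 8 directions with >= 8 trials). The
#' configuration round-trips losslessly through YAML
#' (\code{\link{writePipelineConfig}} / \code{\link{readPipelineConfig}}).
#'
#' @param seed master seed; stage seeds are derived from it deterministically.
#' @param stages character subset of
#'   \code{c("simulate","quantify","qc","contamination","de","tuning")}.
#' @param nGenes,nCellsPerGroup,nMarkerGenes,foldChange,nbDispersion
#'   two-population generator parameters (demo-scale defaults).
#' @param tpmThreshold expression filter threshold.
#' @param spikeTotal,spikeEfficiency,spikeSamples spike-in plate parameters.
#' @param contaminationFraction planted ambient marker-contamination fraction.
#' @param hopRate,ratReads barcode-hopping rate and rat reads per cell.
#' @param maskK masking k-mer length.
#' @param deTopK,deShuffles separation-test parameters.
#' @param tuningCells,tuningAmplitude,tuningNoise tuning generator parameters.
#' @return a list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1,
                           stages = c("simulate", "quantify", "qc",
                                      "contamination", "de", "tuning"),
                           nGenes = 5000, nCellsPerGroup = c(65, 65),
                           nMarkerGenes = 300, foldChange = 8,
                           nbDispersion = 0.5, tpmThreshold = 5,
                           spikeTotal = 10000, spikeEfficiency = 0.13,
                           spikeSamples = 8, contaminationFraction = 0.015,
                           hopRate = 0.001, ratReads = 20000, maskK = 40,
                           deTopK = 250, deShuffles = 20, tuningCells = 20,
                           tuningAmplitude = 0.5, tuningNoise = 0.1) {
  cfg <- list(seed = as.integer(seed), stages = stages, nGenes = nGenes,
              nCellsPerGroup = nCellsPerGroup, nMarkerGenes = nMarkerGenes,
              foldChange = foldChange, nbDispersion = nbDispersion,
              tpmThreshold = tpmThreshold, spikeTotal = spikeTotal,
              spikeEfficiency = spikeEfficiency, spikeSamples = spikeSamples,
              contaminationFraction = contaminationFraction,
              hopRate = hopRate, ratReads = ratReads, maskK = maskK,
              deTopK = deTopK, deShuffles = deShuffles,
              tuningCells = tuningCells, tuningAmplitude = tuningAmplitude,
              tuningNoise = tuningNoise)
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

#' @rdname pipelineConfig
#' @param config a pipeline configuration.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipelineConfig, raw[setdiff(names(raw), character(0))])
  cfg
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data and
#' returns (optionally writes as JSON) a machine-readable report: spike-in
#' detection efficiency, contamination medians and group means, variable-gene
#' count, the distinct/similar separation verdict and the tuning call table.
#' Every stage seed derives from the master seed, so the same configuration
#' reproduces the report exactly.
#'
#' @param config a \code{\link{pipelineConfig}} (or path to a YAML config).
#' @param outDir optional directory for \code{report.json} and intermediate
#'   plain-text outputs.
#' @return the report, a nested list.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seeds <- list(simulate = config$seed, spike = config$seed + 1000L,
                contamination = config$seed + 2000L,
                reads = config$seed + 3000L, de = config$seed + 4000L,
                tuning = config$seed + 5000L)
  report <- list(parameters = unclass(config), seeds = seeds)
  on <- function(stage) stage %in% config$stages

  sim <- NULL
  if (on("simulate") || on("quantify") || on("contamination") || on("de")) {
    sim <- runStage("simulate", {
      cfg <- simConfig(nGenes = config$nGenes,
                       nCellsPerGroup = config$nCellsPerGroup,
                       nMarkerGenes = config$nMarkerGenes,
                       foldChange = config$foldChange,
                       nbDispersion = config$nbDispersion,
                       contaminationFraction = config$contaminationFraction,
                       hopRate = config$hopRate, seed = seeds$simulate)
      simulateTwoPopulations(cfg)
    })
    report$simulate <- list(nGenes = nrow(sim$counts),
                            nCells = ncol(sim$counts),
                            nMarkers = nrow(sim$truth@markerGenes))
  }

  expr <- NULL
  if (on("quantify")) {
    expr <- runStage("quantify", {
      contaminated <- simulateMarkerContamination(
        sim$counts, sim$truth, config$contaminationFraction,
        seed = seeds$contamination)
      sim$counts <- contaminated$counts
      sim$truth <- contaminated$truth
      filterExpressedGenes(tpmNormalize(sim$counts),
                           threshold = config$tpmThreshold)
    })
    report$quantify <- list(genesRetained = nrow(expr),
                            tpmThreshold = config$tpmThreshold)
  }

  if (on("qc")) {
    report$qc <- runStage("qc", {
      design <- defaultSpikeInDesign(totalMolecules = config$spikeTotal,
                                     nSamples = config$spikeSamples)
      plate <- simulateSpikeInPlate(design, config$spikeEfficiency,
                                    seed = seeds$spike)
      eff <- detectionEfficiency(plate, design)
      fit <- fitTechnicalNoise(plate)
      corsum <- sampleCorrelations(
        tpmNormalize(plate, includeSpikeIns = TRUE))
      hv <- if (!is.null(expr))
        callVariableGenes(SummarizedExperiment::assay(expr, "tpm"),
                          fitTechnicalNoise(
                            sweep(SummarizedExperiment::assay(plate, "counts"),
                                  2,
                                  pmax(colSums(
                                    SummarizedExperiment::assay(plate,
                                                                "counts")), 1),
                                  "/") * 1e6))
      else character(0)
      list(pooledEfficiency = eff$pooled,
           detectP1of5 = detectionProbability(5, eff$pooled),
           noiseFit = list(a1 = fit@a1, a0 = fit@a0),
           spikeCorrelationMean = corsum$mean,
           spikeCorrelationSd = corsum$sd,
           nVariableGenes = length(hv))
    })
  }

  if (on("contamination")) {
    report$contamination <- runStage("contamination", {
      pair <- simulateMitoPair(sharedBlocks = c(60, 200), genomeLength = 8000,
                               k = config$maskK, seed = seeds$contamination)
      masked <- maskSharedKmers(pair$genomeA, pair$genomeB, k = config$maskK)
      reads <- simulateCrossSpeciesReads(
        list(mouse = pair$genomeA, rat = pair$genomeB), nMouseCells = 8,
        nRatCells = 2, readsPerCell = config$ratReads,
        hopRate = config$hopRate, seed = seeds$reads)
      mp <- mapReadsExact(reads, masked)
      md <- S4Vectors::metadata(reads)
      hits <- mp$hitsPerBarcode
      mouseHits <- hits[md$mouseBarcodes]; mouseHits[is.na(mouseHits)] <- 0
      names(mouseHits) <- md$mouseBarcodes
      ratHits <- hits[md$ratBarcodes]; ratHits[is.na(ratHits)] <- 0
      cross <- estimateCrossContamination(mouseHits, ratHits)
      marker <- estimateMarkerContamination(tpmNormalize(sim$counts))
      gs <- S4Vectors::metadata(marker)$groupSummary
      list(crossMedianPct = 100 * S4Vectors::metadata(cross)$median,
           estimatedHopRate = S4Vectors::metadata(cross)$totalMouseHits /
             S4Vectors::metadata(cross)$totalRatHits,
           trueHopRate = config$hopRate,
           markerGroupMeans = lapply(gs, function(x) unname(x["mean"])),
           trueContaminationFraction = config$contaminationFraction)
    })
  }

  if (on("de")) {
    report$de <- runStage("de", {
      dat <- if (!is.null(expr)) expr else tpmNormalize(sim$counts)
      res <- shuffleSeparationTest(dat, k = config$deTopK,
                                   nShuffles = config$deShuffles,
                                   seed = seeds$de)
      list(verdict = res@verdict, medianLog10P = median(res@log10P),
           k = res@k, nShuffles = res@nShuffles)
    })
  }

  if (on("tuning")) {
    report$tuning <- runStage("tuning", {
      tun <- simulateTuningDataset(config$tuningCells,
                                   responseAmplitude = config$tuningAmplitude,
                                   noiseSd = config$tuningNoise,
                                   seed = seeds$tuning)
      calls <- classifyTuningCells(tun$traces)
      acc <- mean((calls$call == tun$truth[calls$cell])[
        tun$truth[calls$cell] %in% c("HS", "LS")])
      list(calls = as.list(table(calls$call)),
           recoveryOfTunedCells = acc)
    })
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
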