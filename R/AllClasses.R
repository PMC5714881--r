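#' @import methods
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom IRanges IRanges
NULL

#' Simulation configuration for the two-population patch-seq generator
#'
#' Houses every knob of the synthetic patch-seq experiment: matrix dimensions,
#' marker-gene planting, negative-binomial noise, spike-in capture, ambient
#' contamination, barcode hopping and read-tag geometry. Defaults mirror the
#' study conditions of the experiments the package models: 5,000 genes,
#' 65 + 65 cells, 300 marker genes at 8-fold change, NB dispersion 0.5,
#' capture efficiency 13%, 43-nt reads with a 6-nt UMI and 6-nt cell barcode.
#'
#' @slot nGenes number of endogenous genes.
#' @slot nCellsPerGroup integer vector of cells per population (>= 2 groups).
#' @slot nMarkerGenes number of planted differentially expressed genes.
#' @slot foldChange fold change applied to marker genes in the first group.
#' @slot nbDispersion negative-binomial dispersion phi (variance = mu + phi mu^2).
#' @slot meanExpressionRange log-uniform range of per-gene mean molecule counts.
#' @slot captureEfficiency per-molecule detection probability.
#' @slot contaminationFraction ambient marker-contamination fraction.
#' @slot hopRate barcode-hopping probability per read.
#' @slot readLength,umiLength,barcodeLength read-tag geometry (43 / 6 / 6 nt).
#' @slot classMarkers plant GABAergic/glutamatergic class marker genes
#'   (Gad1, Gad2, Slc32a1 / Slc17a7) on top of the generic markers.
#' @slot seed integer seed making every draw reproducible.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nGenes = "integer", nCellsPerGroup = "integer", nMarkerGenes = "integer",
  foldChange = "numeric", nbDispersion = "numeric",
  meanExpressionRange = "numeric", captureEfficiency = "numeric",
  contaminationFraction = "numeric", hopRate = "numeric",
  readLength = "integer", umiLength = "integer", barcodeLength = "integer",
  classMarkers = "logical", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (length(object@nCellsPerGroup) < 2L || any(object@nCellsPerGroup < 1L))
    msg <- c(msg, "nCellsPerGroup needs >= 2 positive group sizes")
  if (object@nMarkerGenes < 0L || object@nMarkerGenes > object@nGenes)
    msg <- c(msg, "nMarkerGenes must lie in [0, nGenes]")
  if (object@foldChange <= 0) msg <- c(msg, "foldChange must be > 0")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
  if (length(object@meanExpressionRange) != 2L ||
      any(object@meanExpressionRange <= 0) ||
      diff(object@meanExpressionRange) < 0)
    msg <- c(msg, "meanExpressionRange must be an increasing positive pair")
  for (p in c("captureEfficiency", "contaminationFraction", "hopRate")) {
    v <- slot(object, p)
    if (is.na(v) || v < 0 || v > 1) msg <- c(msg, paste(p, "must be in [0, 1]"))
  }
  if (object@readLength < 1L || object@umiLength < 1L || object@barcodeLength < 1L)
    msg <- c(msg, "read/umi/barcode lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param nGenes,nCellsPerGroup,nMarkerGenes,foldChange,nbDispersion,
#'   meanExpressionRange,captureEfficiency,contaminationFraction,hopRate,
#'   readLength,umiLength,barcodeLength,classMarkers,seed see
#'   \linkS4class{SimConfig}.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nGenes = 200, nCellsPerGroup = c(10, 10), seed = 1)
#' @export
simConfig <- function(nGenes = 5000, nCellsPerGroup = c(65, 65),
                      nMarkerGenes = 300, foldChange = 8, nbDispersion = 0.5,
                      meanExpressionRange = c(0.1, 100),
                      captureEfficiency = 0.13, contaminationFraction = 0.015,
                      hopRate = 1.45e-4, readLength = 43, umiLength = 6,
                      barcodeLength = 6, classMarkers = TRUE, seed = 1) {
  obj <- new("SimConfig", nGenes = as.integer(nGenes),
             nCellsPerGroup = as.integer(nCellsPerGroup),
             nMarkerGenes = as.integer(nMarkerGenes),
             foldChange = as.numeric(foldChange),
             nbDispersion = as.numeric(nbDispersion),
             meanExpressionRange = as.numeric(meanExpressionRange),
             captureEfficiency = as.numeric(captureEfficiency),
             contaminationFraction = as.numeric(contaminationFraction),
             hopRate = as.numeric(hopRate), readLength = as.integer(readLength),
             umiLength = as.integer(umiLength),
             barcodeLength = as.integer(barcodeLength),
             classMarkers = isTRUE(classMarkers), seed = as.integer(seed))
  msg <- validObject(obj, test = TRUE)
  if (!isTRUE(msg)) stop("invalid SimConfig: ", paste(msg, collapse = "; "),
                         call. = FALSE)
  obj
}

#' Ground truth recorded by the synthetic-data generators
#'
#' @slot cellLabels population label per generated cell.
#' @slot markerGenes DataFrame with columns \code{gene} and \code{foldChange}.
#' @slot trueEfficiency,trueHopRate scalar truths (NA when not applicable).
#' @slot trueContamination per-cell planted contamination fraction.
#' @slot trueTuning per-cell tuning class ("HS", "LS" or "none").
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  cellLabels = "character", markerGenes = "DataFrame",
  trueEfficiency = "numeric", trueHopRate = "numeric",
  trueContamination = "numeric", trueTuning = "character"))

setValidity("GroundTruth", function(object) {
  if (length(object@trueContamination) &&
      length(object@trueContamination) != length(object@cellLabels))
    return("trueContamination must have one entry per cell")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@cellLabels), "cells")
  if (length(object@cellLabels))
    cat(" (", paste(names(table(object@cellLabels)),
                    table(object@cellLabels), sep = ":", collapse = ", "), ")",
        sep = "")
  cat("\n  planted markers:", nrow(object@markerGenes), "\n")
  if (!is.na(object@trueEfficiency))
    cat("  true efficiency:", object@trueEfficiency, "\n")
  if (!is.na(object@trueHopRate))
    cat("  true hop rate:", object@trueHopRate, "\n")
})

#' Known spike-in input amounts
#'
#' The ground truth for detection-efficiency estimation: how many molecules of
#' each synthetic spike RNA species were added to each sample.
#'
#' @slot molecules numeric matrix, species x samples, of spiked molecule counts.
#' @exportClass SpikeInDesign
setClass("SpikeInDesign", representation(molecules = "matrix"))

setValidity("SpikeInDesign", function(object) {
  m <- object@molecules
  if (any(m < 0) || any(m != round(m))) return("molecule counts must be non-negative integers")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("species ids (rownames) must be present and unique")
  TRUE
})

#' Construct a SpikeInDesign
#'
#' @param molecules per-species molecule counts: a named vector (recycled over
#'   \code{nSamples} samples, the equal-spiking design) or a species x samples
#'   matrix with rownames.
#' @param nSamples number of samples when \code{molecules} is a vector.
#' @return a \linkS4class{SpikeInDesign}.
#' @examples
#' d <- spikeInDesign(c(ERCC1 = 5, ERCC2 = 50), nSamples = 4)
#' @export
spikeInDesign <- function(molecules, nSamples = 1L) {
  if (!is.matrix(molecules)) {
    if (is.null(names(molecules)))
      names(molecules) <- sprintf("spike%03d", seq_along(molecules))
    molecules <- matrix(molecules, nrow = length(molecules), ncol = nSamples,
                        dimnames = list(names(molecules),
                                        sprintf("sample%02d", seq_len(nSamples))))
  }
  obj <- new("SpikeInDesign", molecules = molecules)
  msg <- validObject(obj, test = TRUE)
  if (!isTRUE(msg)) stop("invalid SpikeInDesign: ", msg, call. = FALSE)
  obj
}

#' ERCC-like default spike-in design
#'
#' A dilution-series design: species amounts follow a geometric series over a
#' wide dynamic range (as in the ERCC mixes), scaled so each sample receives
#' \code{totalMolecules} molecules in total, spiked equally into every sample.
#'
#' @param nSpecies number of spike species (92 as in the ERCC set).
#' @param totalMolecules total molecules per sample across species.
#' @param nSamples number of samples.
#' @param dynamicRange ratio between the most and least abundant species.
#' @return a \linkS4class{SpikeInDesign}.
#' @export
defaultSpikeInDesign <- function(nSpecies = 92, totalMolecules = 1e4,
                                 nSamples = 8, dynamicRange = 1e3) {
  w <- dynamicRange^(seq(0, 1, length.out = nSpecies))
  n <- round(w / sum(w) * totalMolecules)
  names(n) <- sprintf("ERCC-%04d", seq_len(nSpecies))
  spikeInDesign(n, nSamples = nSamples)
}

setMethod("show", "SpikeInDesign", function(object) {
  m <- object@molecules
  cat("SpikeInDesign:", nrow(m), "species x", ncol(m), "samples;",
      "molecules/sample:", paste(unique(colSums(m)), collapse = ", "), "\n")
})

#' @describeIn spikeInDesign total spiked molecules per sample.
#' @param design a \linkS4class{SpikeInDesign}.
#' @export
spikedMolecules <- function(design) design@molecules

#' A genome masked of k-mers shared with a reference
#'
#' Result of \code{\link{maskSharedKmers}}: the target genome with every
#' position covered by a k-mer also present in the reference (either strand)
#' replaced by N, plus the masked intervals.
#'
#' @slot source the original target sequence.
#' @slot masked the masked sequence (N at masked positions).
#' @slot maskedRanges IRanges of masked intervals (1-based, closed).
#' @slot k the k-mer length used.
#' @exportClass MaskedGenome
setClass("MaskedGenome", representation(
  source = "DNAString", masked = "DNAString", maskedRanges = "IRanges",
  k = "integer"))

setMethod("show", "MaskedGenome", function(object) {
  cat("MaskedGenome: ", length(object@masked), " nt, k = ", object@k, ", ",
      sum(IRanges::width(object@maskedRanges)), " masked positions in ",
      length(object@maskedRanges), " interval(s)\n", sep = "")
})

#' @describeIn maskSharedKmers masked sequence accessor.
#' @export
maskedSequence <- function(x) x@masked

#' @describeIn maskSharedKmers masked intervals accessor (IRanges).
#' @export
maskedRanges <- function(x) x@maskedRanges

#' Technical-noise fit on spike-ins
#'
#' Parameters of the mean/CV^2 technical-noise relation
#' CV^2(g) = a1 / mu(g) + a0 fitted across spike-in species, used as the null
#' when calling genes whose expression variability exceeds technical noise.
#'
#' @slot a1 coefficient of the 1/mean term (shot-noise-like component).
#' @slot a0 asymptotic CV^2 offset at high expression.
#' @slot fitSpecies species used for the fit (above the low-mean cutoff).
#' @slot minBioCV minimum biological CV used downstream (default 0.5).
#' @exportClass NoiseFit
setClass("NoiseFit", representation(
  a1 = "numeric", a0 = "numeric", fitSpecies = "character",
  minBioCV = "numeric"))

setMethod("show", "NoiseFit", function(object) {
  cat(sprintf("NoiseFit: CV^2 = %.4g/mu + %.4g  (%d species, minBioCV = %g)\n",
              object@a1, object@a0, length(object@fitSpecies), object@minBioCV))
})

#' Result of the sigma-score label-shuffle separation test
#'
#' @slot originalTopK sigma-scores of the top-k ranked genes under the
#'   original labels (infinite sentinels excluded, see \code{nInfinite}).
#' @slot shuffleTopK list of top-k sigma-score vectors, one per reshuffle.
#' @slot U,log10P per-reshuffle Mann-Whitney U and two-sided log10 p comparing
#'   original vs shuffled top-k score sets.
#' @slot k,nShuffles test dimensions.
#' @slot nInfinite number of infinite-sigma sentinels excluded from score sets.
#' @slot verdict "distinct", "similar" or "indeterminate".
#' @exportClass ShuffleTestResult
setClass("ShuffleTestResult", representation(
  originalTopK = "numeric", shuffleTopK = "list", U = "numeric",
  log10P = "numeric", k = "integer", nShuffles = "integer",
  nInfinite = "integer", verdict = "character"))

setMethod("show", "ShuffleTestResult", function(object) {
  cat("ShuffleTestResult: top-", object@k, " sigma-scores vs ",
      object@nShuffles, " proportional reshuffles\n", sep = "")
  cat(sprintf("  log10 p: median %.2f (range %.2f .. %.2f)\n",
              median(object@log10P), min(object@log10P), max(object@log10P)))
  cat("  verdict:", object@verdict, "\n")
})

#' @describeIn shuffleSeparationTest verdict accessor.
#' @export
testVerdict <- function(x) x@verdict

#' @describeIn shuffleSeparationTest per-reshuffle log10 p accessor.
#' @export
log10PValues <- function(x) x@log10P
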