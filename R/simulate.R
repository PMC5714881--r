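# Synthetic-data generators: every input the pipeline consumes, with recorded
# ground truth, so each estimator can be validated by parameter recovery.

#' Simulate a two-population patch-seq count matrix
#'
#' Draws molecule counts per gene per cell from a negative binomial
#' (variance = mu + phi mu^2) with per-gene mean levels sampled log-uniformly
#' over \code{meanExpressionRange}. A random subset of \code{nMarkerGenes}
#' genes has its mean multiplied by \code{foldChange} in the first population
#' only. When \code{classMarkers} is set, four neuronal class marker genes are
#' appended: Slc17a7 expressed only in the first (glutamatergic) population and
#' Gad1/Gad2/Slc32a1 only in the second (GABAergic) population, with zero
#' baseline in the opposite class so that pure cells carry no opposite-class
#' marker molecules.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a list with \code{counts}, a
#'   \link[SingleCellExperiment]{SingleCellExperiment} (assay \code{"counts"},
#'   \code{rowData} columns \code{geneClass}, \code{isMarker},
#'   \code{foldChange}; \code{colData} columns \code{population},
#'   \code{species}), and \code{truth}, a \linkS4class{GroundTruth}.
#' @examples
#' sim <- simulateTwoPopulations(simConfig(nGenes = 100,
#'   nCellsPerGroup = c(8, 8), nMarkerGenes = 10, seed = 1))
#' dim(sim$counts)
#' @export
simulateTwoPopulations <- function(config) {
  stopifnot(is(config, "SimConfig"))
  withSeed(config@seed, {
    nG <- config@nGenes
    sizes <- config@nCellsPerGroup[1:2]
    nC <- sum(sizes)
    labels <- rep(c("glut", "GABA"), sizes)
    geneIds <- sprintf("gene%05d", seq_len(nG))
    baseMu <- 10^runif(nG, log10(config@meanExpressionRange[1]),
                       log10(config@meanExpressionRange[2]))
    markerIdx <- sort(sample.int(nG, config@nMarkerGenes))
    fc <- rep(1, nG)
    fc[markerIdx] <- config@foldChange
    muA <- baseMu * fc
    muB <- baseMu

    if (config@classMarkers) {
      cm <- data.frame(gene = c("Slc17a7", "Gad1", "Gad2", "Slc32a1"),
                       muA = c(800, 0, 0, 0), muB = c(0, 600, 500, 300))
      geneIds <- c(geneIds, cm$gene)
      muA <- c(muA, cm$muA); muB <- c(muB, cm$muB)
      fc <- c(fc, rep(NA_real_, 4))
    }
    size <- 1 / config@nbDispersion
    drawGroup <- function(mu, n) {
      m <- matrix(0L, length(mu), n)
      pos <- mu > 0
      m[pos, ] <- rnbinom(sum(pos) * n, mu = rep(mu[pos], n), size = size)
      m
    }
    counts <- cbind(drawGroup(muA, sizes[1]), drawGroup(muB, sizes[2]))
    dimnames(counts) <- list(geneIds, sprintf("cell%03d", seq_len(nC)))

    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      rowData = S4Vectors::DataFrame(
        geneClass = rep("endogenous", length(geneIds)),
        isMarker = seq_along(geneIds) %in% markerIdx,
        foldChange = ifelse(seq_along(geneIds) %in% markerIdx,
                            config@foldChange, 1),
        row.names = geneIds),
      colData = S4Vectors::DataFrame(population = labels,
                                     species = rep("mouse", nC),
                                     row.names = colnames(counts)))
    truth <- new("GroundTruth",
                 cellLabels = labels,
                 markerGenes = S4Vectors::DataFrame(
                   gene = geneIds[markerIdx],
                   foldChange = rep(config@foldChange, length(markerIdx))),
                 trueEfficiency = NA_real_, trueHopRate = NA_real_,
                 trueContamination = rep(0, nC),
                 trueTuning = character(0))
    list(counts = sce, truth = truth)
  })
}

#' Simulate a spike-in plate with per-molecule binomial capture
#'
#' Each spiked molecule is independently detected with probability
#' \code{efficiency}; every detected molecule receives a UMI drawn uniformly
#' from the 4^\code{umiLength} UMI space, and the returned value per species
#' per sample is the number of distinct UMIs (so UMI collisions are simulated
#' explicitly, not assumed absent).
#'
#' @param design a \linkS4class{SpikeInDesign}.
#' @param efficiency per-molecule detection probability.
#' @param nSamples optional; defaults to the design's sample count.
#' @param umiLength UMI length in nt (default 6).
#' @param seed integer seed.
#' @return a \link[SingleCellExperiment]{SingleCellExperiment} of unique-UMI
#'   counts (species x samples) with \code{rowData$geneClass == "spikein"} and
#'   the true efficiency recorded in \code{metadata()$trueEfficiency}.
#' @examples
#' sce <- simulateSpikeInPlate(spikeInDesign(c(A = 100, B = 1000), 4), 0.13,
#'                             seed = 1)
#' @export
simulateSpikeInPlate <- function(design, efficiency, nSamples = NULL,
                                 umiLength = 6, seed = 1) {
  stopifnot(is(design, "SpikeInDesign"))
  checkProbability(efficiency, "efficiency")
  mols <- design@molecules
  if (!is.null(nSamples)) {
    if (ncol(mols) == 1L)
      mols <- mols[, rep(1L, nSamples), drop = FALSE]
    else mols <- mols[, seq_len(nSamples), drop = FALSE]
    colnames(mols) <- sprintf("sample%02d", seq_len(ncol(mols)))
  }
  umiSpace <- 4^umiLength
  withSeed(seed, {
    detected <- matrix(rbinom(length(mols), size = as.vector(mols),
                              prob = efficiency),
                       nrow = nrow(mols), dimnames = dimnames(mols))
    uniqueUmis <- matrix(0L, nrow(mols), ncol(mols), dimnames = dimnames(mols))
    nz <- which(detected > 0)
    uniqueUmis[nz] <- vapply(detected[nz], function(d)
      length(unique.default(sample.int(umiSpace, d, replace = TRUE))), 0L)
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = uniqueUmis),
      rowData = S4Vectors::DataFrame(geneClass = rep("spikein", nrow(mols)),
                                     row.names = rownames(mols)),
      metadata = list(trueEfficiency = efficiency, umiLength = umiLength))
  })
}

#' Plant ambient marker contamination at a known fraction
#'
#' Adds opposite-class marker molecules to each cell so that the marker-based
#' contamination estimator (\code{\link{estimateMarkerContamination}}) has
#' expected value \code{fraction}: for a glutamatergic cell with Slc17a7 count
#' S, each GABAergic marker receives Poisson molecules with mean
#' S * fraction / (1 - fraction) (and symmetrically for GABAergic cells), so
#' that in expectation G / (S + G) = fraction.
#'
#' @param sce count SingleCellExperiment with a \code{population} column in
#'   \code{colData} using labels "glut" / "GABA".
#' @param truth the matching \linkS4class{GroundTruth}; updated and returned.
#' @param fraction target contamination fraction in [0, 1).
#' @param markers list with elements \code{gaba} and \code{glut} naming the
#'   marker genes (defaults Gad1/Gad2/Slc32a1 and Slc17a7).
#' @param seed integer seed.
#' @return list with the contaminated \code{counts} and updated \code{truth}.
#' @export
simulateMarkerContamination <- function(sce, truth, fraction,
                                        markers = list(
                                          gaba = c("Gad1", "Gad2", "Slc32a1"),
                                          glut = "Slc17a7"),
                                        seed = 1) {
  checkProbability(fraction, "fraction")
  if (fraction >= 1) stop("'fraction' must be < 1", call. = FALSE)
  allMarkers <- unlist(markers, use.names = FALSE)
  missing <- setdiff(allMarkers, rownames(sce))
  if (length(missing))
    stop("unknown marker gene id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (fraction == 0) return(list(counts = sce, truth = truth))
  counts <- SummarizedExperiment::assay(sce, "counts")
  pop <- SummarizedExperiment::colData(sce)$population
  odds <- fraction / (1 - fraction)
  withSeed(seed, {
    for (j in seq_len(ncol(counts))) {
      if (pop[j] == "glut") {
        own <- sum(counts[markers$glut, j])
        lam <- own * odds
        counts[markers$gaba, j] <- counts[markers$gaba, j] +
          rpois(length(markers$gaba), lam)
      } else {
        own <- mean(counts[markers$gaba, j])
        lam <- own * odds
        counts[markers$glut, j] <- counts[markers$glut, j] +
          rpois(length(markers$glut), lam)
      }
    }
    SummarizedExperiment::assay(sce, "counts") <- counts
    truth@trueContamination <- rep(fraction, ncol(counts))
    list(counts = sce, truth = truth)
  })
}

# Brute-force scan for target positions covered by a k-mer shared with the
# reference (either reference strand). Used by the rejection check; the tests
# carry their own independent scan.
sharedKmerCover <- function(reference, target, k) {
  refSet <- unique(c(seqKmers(reference, k), seqKmers(revComp(reference), k)))
  tk <- seqKmers(target, k)
  if (!length(tk)) return(logical(nchar(target)))
  hit <- tk %in% refSet
  cov <- logical(nchar(target))
  for (i in which(hit)) cov[i:(i + k - 1L)] <- TRUE
  cov
}

#' Simulate a pair of mitochondrial-like genomes with planted homology
#'
#' Generates two random sequences (e.g. a mouse and a rat mitochondrial
#' genome stand-in) sharing planted exact copies of the requested lengths at
#' random non-overlapping positions. A rejection check guarantees that no
#' shared k-mer of length >= \code{k} exists other than inside planted blocks
#' of length >= \code{k}, so blocks shorter than \code{k} are invisible to
#' \code{\link{maskSharedKmers}}.
#'
#' @param sharedBlocks integer vector of planted exact-homology block lengths
#'   (may be empty).
#' @param genomeLength length of each genome in nt.
#' @param k homology threshold guarded by the rejection check (default 40).
#' @param seed integer seed.
#' @param maxTries rejection-sampling attempts before giving up.
#' @return list with \code{genomeA}, \code{genomeB}
#'   (\link[Biostrings]{DNAString}) and \code{blocks}, a data.frame of planted
#'   block positions (1-based start in each genome, length).
#' @export
simulateMitoPair <- function(sharedBlocks = c(60, 200), genomeLength = 16300,
                             k = 40, seed = 1, maxTries = 50) {
  sharedBlocks <- as.integer(sharedBlocks)
  if (any(sharedBlocks >= genomeLength))
    stop("each block length must be < genomeLength", call. = FALSE)
  placeBlocks <- function(lens, L) {
    # sample non-overlapping (with 1-nt gaps) start positions, longest first
    ord <- order(lens, decreasing = TRUE)
    taken <- integer(0)
    starts <- integer(length(lens))
    for (i in ord) {
      ok <- FALSE
      for (try in 1:200) {
        s <- sample.int(L - lens[i] + 1L, 1L)
        span <- (s - 1L):(s + lens[i])  # include 1-nt flanks
        if (!any(span %in% taken)) { ok <- TRUE; break }
      }
      if (!ok) stop("blocks cannot be placed without overlap", call. = FALSE)
      taken <- c(taken, span)
      starts[i] <- s
    }
    starts
  }
  withSeed(seed, {
    for (try in seq_len(maxTries)) {
      a <- randomDNA(1, genomeLength)
      b <- randomDNA(1, genomeLength)
      startsA <- startsB <- integer(0)
      if (length(sharedBlocks)) {
        startsA <- placeBlocks(sharedBlocks, genomeLength)
        startsB <- placeBlocks(sharedBlocks, genomeLength)
        for (i in seq_along(sharedBlocks)) {
          block <- substring(a, startsA[i], startsA[i] + sharedBlocks[i] - 1L)
          substr(b, startsB[i], startsB[i] + sharedBlocks[i] - 1L) <- block
        }
      }
      # rejection check: shared k-mer cover of B must equal the planted
      # >=k blocks exactly
      cov <- sharedKmerCover(a, b, k)
      want <- logical(genomeLength)
      for (i in seq_along(sharedBlocks)) {
        if (sharedBlocks[i] >= k)
          want[startsB[i]:(startsB[i] + sharedBlocks[i] - 1L)] <- TRUE
      }
      if (identical(cov, want)) {
        return(list(genomeA = Biostrings::DNAString(a),
                    genomeB = Biostrings::DNAString(b),
                    blocks = data.frame(length = sharedBlocks,
                                        startA = startsA, startB = startsB)))
      }
    }
    stop("failed to generate a clean genome pair in ", maxTries, " tries",
         call. = FALSE)
  })
}

#' Simulate a cross-species barcoded read set with barcode hopping
#'
#' Draws error-free reads of length \code{readLength} from each cell's own
#' species' mitochondrial genome (uniform start position, random strand).
#' Each rat-origin read is reassigned to a uniformly chosen mouse cell barcode
#' with probability \code{hopRate}, emulating cross-contamination between
#' barcoded libraries during pooled processing. True origins are recorded.
#'
#' @param genomes list with \code{mouse} and \code{rat} genome sequences
#'   (DNAString or character).
#' @param nMouseCells,nRatCells cells per species.
#' @param readsPerCell reads drawn per cell.
#' @param hopRate per-read barcode-hopping probability.
#' @param readLength,umiLength,barcodeLength tag geometry (43 / 6 / 6 nt).
#' @param seed integer seed.
#' @return a \link[S4Vectors]{DataFrame} with columns \code{sequence},
#'   \code{umi}, \code{barcode}, \code{trueSpecies}, \code{trueCell};
#'   \code{metadata()} records barcode-to-cell maps and the true hop rate.
#' @export
simulateCrossSpeciesReads <- function(genomes, nMouseCells = 8, nRatCells = 2,
                                      readsPerCell = 10000, hopRate = 1.45e-4,
                                      readLength = 43, umiLength = 6,
                                      barcodeLength = 6, seed = 1) {
  checkProbability(hopRate, "hopRate")
  gm <- as.character(genomes$mouse); gr <- as.character(genomes$rat)
  if (readLength > nchar(gm) || readLength > nchar(gr))
    stop("readLength must not exceed the genome length", call. = FALSE)
  withSeed(seed, {
    nCells <- nMouseCells + nRatCells
    barcodes <- randomDNA(nCells * 4L, barcodeLength)
    barcodes <- unique(barcodes)[seq_len(nCells)]
    cellIds <- c(sprintf("mouse%02d", seq_len(nMouseCells)),
                 sprintf("rat%02d", seq_len(nRatCells)))
    species <- rep(c("mouse", "rat"), c(nMouseCells, nRatCells))
    drawReads <- function(genome, n) {
      rc <- revComp(genome)
      starts <- sample.int(nchar(genome) - readLength + 1L, n, replace = TRUE)
      fwd <- runif(n) < 0.5
      out <- character(n)
      out[fwd] <- substring(genome, starts[fwd], starts[fwd] + readLength - 1L)
      out[!fwd] <- substring(rc, starts[!fwd], starts[!fwd] + readLength - 1L)
      out
    }
    seqs <- character(0); bc <- character(0); cell <- character(0)
    for (i in seq_len(nCells)) {
      g <- if (species[i] == "mouse") gm else gr
      seqs <- c(seqs, drawReads(g, readsPerCell))
      bc <- c(bc, rep(barcodes[i], readsPerCell))
      cell <- c(cell, rep(cellIds[i], readsPerCell))
    }
    trueSpecies <- rep(species, each = readsPerCell)
    # barcode hopping: rat-origin reads land on a random mouse barcode
    ratReads <- which(trueSpecies == "rat")
    hop <- ratReads[runif(length(ratReads)) < hopRate]
    if (length(hop))
      bc[hop] <- barcodes[sample.int(nMouseCells, length(hop), replace = TRUE)]
    reads <- S4Vectors::DataFrame(
      sequence = seqs,
      umi = randomDNA(length(seqs), umiLength),
      barcode = bc, trueSpecies = trueSpecies, trueCell = cell)
    S4Vectors::metadata(reads) <- list(
      barcodeMap = setNames(barcodes, cellIds),
      mouseBarcodes = barcodes[species == "mouse"],
      ratBarcodes = barcodes[species == "rat"],
      trueHopRate = hopRate)
    reads
  })
}

#' Simulate dF/F-ready calcium traces for speed-tuning classification
#'
#' Per cell, stimulus (high-speed and low-speed drifting gratings), direction
#' (8 directions, 0--315 degrees) and trial, generates a raw fluorescence
#' trace consisting of a 2-s mean-luminance gray baseline and a 4-s grating
#' response window at 2 frames/s (so 4 baseline + 8 stimulus frames). Tuned
#' cells respond with \code{responseAmplitude} (in dF/F units) to every
#' direction of their preferred stimulus only; Gaussian noise of standard
#' deviation \code{noiseSd} (dF/F units) is added to every frame.
#'
#' @param nCells number of cells.
#' @param classMix named proportions over \code{c("HS","LS","none")},
#'   summing to 1.
#' @param responseAmplitude evoked response in dF/F units.
#' @param noiseSd per-frame noise in dF/F units.
#' @param nTrials trials per (stimulus, direction); at least 8.
#' @param baselineF raw baseline fluorescence level (arbitrary units).
#' @param seed integer seed.
#' @return list with \code{traces}, a long-format data.frame (columns
#'   \code{cell}, \code{stimulus}, \code{direction}, \code{trial},
#'   \code{phase}, \code{frame}, \code{value}), and \code{truth}, the per-cell
#'   tuning class.
#' @export
simulateTuningDataset <- function(nCells, classMix = c(HS = 0.3, LS = 0.2,
                                                       none = 0.5),
                                  responseAmplitude = 0.5, noiseSd = 0.1,
                                  nTrials = 8, baselineF = 100, seed = 1) {
  if (abs(sum(classMix) - 1) > 1e-8)
    stop("'classMix' proportions must sum to 1", call. = FALSE)
  if (nTrials < 8)
    stop("at least 8 trials per stimulus and direction are required",
         call. = FALSE)
  frameRate <- 2                       # frames per second
  nBase <- 2 * frameRate               # 2-s gray baseline
  nStim <- 4 * frameRate               # 4-s grating
  dirs <- seq(0, 315, by = 45)
  stims <- c("HS", "LS")
  withSeed(seed, {
    classes <- sample(names(classMix), nCells, replace = TRUE,
                      prob = classMix)
    perTrace <- nBase + nStim
    nRows <- nCells * length(stims) * length(dirs) * nTrials * perTrace
    grid <- expand.grid(frame = seq_len(perTrace), trial = seq_len(nTrials),
                        direction = dirs, stimulus = stims,
                        cell = sprintf("cell%03d", seq_len(nCells)),
                        stringsAsFactors = FALSE)
    grid$phase <- ifelse(grid$frame <= nBase, "baseline", "stimulus")
    cellClass <- classes[match(grid$cell, sprintf("cell%03d", seq_len(nCells)))]
    evoked <- as.numeric(grid$phase == "stimulus" & cellClass == grid$stimulus) *
      responseAmplitude
    grid$value <- baselineF * (1 + evoked + rnorm(nRows, sd = noiseSd))
    list(traces = grid[, c("cell", "stimulus", "direction", "trial", "phase",
                           "frame", "value")],
         truth = setNames(classes, sprintf("cell%03d", seq_len(nCells))))
  })
}
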