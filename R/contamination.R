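# Contamination estimators: cross-species barcode contamination via masked
# genome mapping, and marker-based tissue contamination from expression.

#' Mask every k-mer of a target genome shared with a reference
#'
#' Replaces with N every position of \code{target} covered by a k-mer that
#' occurs exactly in \code{reference} (either strand). After masking, target
#' and reference share no exact k-mer on either strand, so error-free reads of
#' length >= k + 1 drawn from the reference can never map to the masked target
#' by exact matching. With the default k = 40 and 43-nt reads this reproduces
#' the construction where all homologous identical stretches between the two
#' mitochondrial genomes are made shorter than 40 bases so that reads of the
#' reference species cannot map to the target species' genome.
#'
#' @param reference the reference genome (DNAString or character): the genome
#'   whose reads must not map to the target.
#' @param target the genome to mask.
#' @param k k-mer length (default 40).
#' @return a \linkS4class{MaskedGenome}.
#' @export
maskSharedKmers <- function(reference, target, k = 40) {
  stopifnot(k >= 1)
  ref <- toupper(as.character(reference))
  tgt <- toupper(as.character(target))
  refSet <- unique(c(seqKmers(ref, k), seqKmers(revComp(ref), k)))
  n <- nchar(tgt)
  cov <- logical(n)
  if (n >= k && length(refSet)) {
    tk <- seqKmers(tgt, k)
    hit <- which(tk %in% refSet)
    for (i in hit) cov[i:(i + k - 1L)] <- TRUE
  }
  maskedSeq <- tgt
  if (any(cov)) {
    chars <- strsplit(tgt, "", fixed = TRUE)[[1]]
    chars[cov] <- "N"
    maskedSeq <- paste(chars, collapse = "")
  }
  ranges <- IRanges::reduce(IRanges::IRanges(which(cov), width = 1L))
  new("MaskedGenome", source = Biostrings::DNAString(tgt),
      masked = Biostrings::DNAString(maskedSeq),
      maskedRanges = ranges, k = as.integer(k))
}

#' Map reads to a genome by exact full-length matching
#'
#' A desk-scale stand-in for an aligner run: a read hits iff its full
#' sequence occurs exactly in the genome or its reverse complement. Reads or
#' genome positions containing N never match (N is not a wildcard), so reads
#' spanning masked positions cannot hit.
#'
#' @param reads a DataFrame/data.frame with columns \code{sequence} and
#'   \code{barcode} (as from \code{\link{simulateCrossSpeciesReads}}), or a
#'   character vector of sequences (then a single unnamed barcode is assumed).
#' @param genome a DNAString, character sequence or
#'   \linkS4class{MaskedGenome} (its masked sequence is used).
#' @return list with \code{hitsPerBarcode} (named integer, all barcodes
#'   present in the input), \code{hit} (logical per read) and
#'   \code{totalReads}.
#' @export
mapReadsExact <- function(reads, genome) {
  if (is(genome, "MaskedGenome")) genome <- genome@masked
  g <- toupper(as.character(genome))
  if (is.character(reads)) reads <- S4Vectors::DataFrame(
    sequence = reads, barcode = rep("all", length(reads)))
  seqs <- toupper(as.character(reads$sequence))
  bcs <- as.character(reads$barcode)
  lens <- unique(nchar(seqs))
  hit <- logical(length(seqs))
  clean <- !grepl("N", seqs, fixed = TRUE)
  for (L in lens) {
    if (L > nchar(g)) next
    # genome k-mer set, both strands, excluding k-mers spanning N
    km <- c(seqKmers(g, L), seqKmers(revComp(g), L))
    km <- km[!grepl("N", km, fixed = TRUE)]
    sel <- nchar(seqs) == L & clean
    hit[sel] <- seqs[sel] %in% km
  }
  perBc <- tapply(hit, bcs, sum)
  hitsPerBarcode <- setNames(as.integer(perBc), names(perBc))
  list(hitsPerBarcode = hitsPerBarcode, hit = hit,
       totalReads = length(seqs))
}

#' Estimate cross-species barcode contamination
#'
#' Given per-cell counts of reads mapped to the masked rat mitochondrial
#' genome, the contamination of each mouse cell is its mapped-read count as a
#' fraction of all mapped rat mitochondrial reads of the rat cell(s) combined.
#' Only reads that truly originate from the rat libraries can map (the masking
#' construction forbids mouse reads from mapping), so these fractions measure
#' barcode hopping between libraries during pooled processing.
#'
#' @param mouseHits named numeric: mapped reads on the masked rat genome per
#'   mouse cell.
#' @param ratHits named numeric: mapped reads per rat cell (summed over all
#'   rat cells for the denominator).
#' @return a \link[S4Vectors]{DataFrame} with per-mouse-cell \code{fraction};
#'   \code{metadata()} carries \code{median}, \code{totalRatHits} and
#'   \code{totalMouseHits}.
#' @export
estimateCrossContamination <- function(mouseHits, ratHits) {
  totalRat <- sum(ratHits)
  if (totalRat <= 0)
    stop("no mapped rat reads: cross-contamination undefined", call. = FALSE)
  frac <- mouseHits / totalRat
  out <- S4Vectors::DataFrame(cell = names(mouseHits), hits = mouseHits,
                              fraction = as.numeric(frac))
  S4Vectors::metadata(out) <- list(median = median(as.numeric(frac)),
                                   totalRatHits = totalRat,
                                   totalMouseHits = sum(mouseHits))
  out
}

#' Estimate marker-based tissue contamination
#'
#' Estimates harvest contamination from opposite-class neuronal marker
#' expression. With S = tpm(Slc17a7) and G the GABAergic marker level
#' (by default the arithmetic mean of the tpm of Gad1, Gad2 and Slc32a1),
#' the GABAergic contamination of a glutamatergic cell is
#' 1 - S / (S + G) = G / (S + G), and the glutamatergic contamination of a
#' GABAergic cell is 1 - G / (S + G) = S / (S + G). Cells with S + G = 0 are
#' reported as NA. The estimate is scale-invariant per cell, so counts and tpm
#' give identical values.
#'
#' @param expr a SingleCellExperiment with a \code{tpm} (or \code{counts})
#'   assay, or a matrix.
#' @param cellClass "GABA"/"glut" per cell; defaults to
#'   \code{colData(expr)$population}.
#' @param gabaMarkers,glutMarkers marker gene sets (defaults
#'   Gad1/Gad2/Slc32a1 and Slc17a7).
#' @param gabaAggregate combine the GABAergic marker tpms by their
#'   \code{"mean"} (default) or \code{"sum"} (treating them as one pooled
#'   pseudo-gene; differs from the mean by a factor of 3).
#' @return a \link[S4Vectors]{DataFrame} with per-cell \code{class} and
#'   \code{contamination}; \code{metadata()$groupSummary} holds mean and SEM
#'   per class.
#' @export
estimateMarkerContamination <- function(expr, cellClass = NULL,
                                        gabaMarkers = c("Gad1", "Gad2",
                                                        "Slc32a1"),
                                        glutMarkers = "Slc17a7",
                                        gabaAggregate = c("mean", "sum")) {
  gabaAggregate <- match.arg(gabaAggregate)
  if (is(expr, "SummarizedExperiment")) {
    a <- SummarizedExperiment::assayNames(expr)
    m <- SummarizedExperiment::assay(expr, if ("tpm" %in% a) "tpm" else "counts")
    if (is.null(cellClass))
      cellClass <- SummarizedExperiment::colData(expr)$population
  } else m <- as.matrix(expr)
  if (is.null(cellClass))
    stop("'cellClass' is required when 'expr' carries no population column",
         call. = FALSE)
  missing <- setdiff(c(gabaMarkers, glutMarkers), rownames(m))
  if (length(missing))
    stop("marker gene(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  G <- if (gabaAggregate == "mean")
    colMeans(m[gabaMarkers, , drop = FALSE])
  else colSums(m[gabaMarkers, , drop = FALSE])
  S <- colSums(m[glutMarkers, , drop = FALSE])
  tot <- S + G
  est <- ifelse(tot == 0, NA_real_,
                ifelse(cellClass == "glut", G / tot, S / tot))
  out <- S4Vectors::DataFrame(cell = colnames(m), class = cellClass,
                              contamination = as.numeric(est))
  summ <- lapply(split(est, cellClass), function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v))
  })
  S4Vectors::metadata(out) <- list(groupSummary = summ)
  out
}
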