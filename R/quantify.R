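# CEL-seq-style quantification: tag parsing, UMI collapsing, tpm
# normalization, expression filtering and the log/z transform used downstream.

#' Parse the UMI and cell barcode from a tag read
#'
#' CEL-seq tag reads carry the 6-nt unique molecular identifier first,
#' immediately followed by the 6-nt cell barcode; sequencing cycles beyond
#' the tag (the 13th base of a 13-cycle tag read) are ignored.
#'
#' @param raw character vector of raw tag-read sequences.
#' @param umiLength,barcodeLength tag geometry (defaults 6 and 6 nt).
#' @return a \link[S4Vectors]{DataFrame} with columns \code{umi} and
#'   \code{barcode}.
#' @examples
#' parseBarcodeRead("ACGTACGGATCC")
#' @export
parseBarcodeRead <- function(raw, umiLength = 6, barcodeLength = 6) {
  need <- umiLength + barcodeLength
  short <- nchar(raw) < need
  if (any(short))
    stop("tag read(s) shorter than umiLength + barcodeLength: ",
         paste(which(short), collapse = ", "), call. = FALSE)
  S4Vectors::DataFrame(umi = substring(raw, 1L, umiLength),
                       barcode = substring(raw, umiLength + 1L, need))
}

#' Collapse reads to molecule counts by distinct UMIs
#'
#' The molecule count per (cell, gene) is the number of distinct UMI strings
#' observed (exact string match, no error correction), which removes
#' amplification duplicates. Counts are therefore capped by the UMI-space
#' cardinality 4^umiLength.
#'
#' @param reads a data.frame/DataFrame with columns \code{barcode},
#'   \code{gene} and \code{umi} (one row per mapped read).
#' @param genes optional gene universe for the row order; defaults to the
#'   genes observed.
#' @param cells optional barcode universe for the column order.
#' @return a \link[SingleCellExperiment]{SingleCellExperiment} with an integer
#'   \code{counts} assay (genes x barcodes).
#' @export
collapseUMIs <- function(reads, genes = NULL, cells = NULL) {
  reads <- as.data.frame(reads)
  stopifnot(all(c("barcode", "gene", "umi") %in% colnames(reads)))
  if (is.null(genes)) genes <- sort(unique(reads$gene))
  if (is.null(cells)) cells <- sort(unique(reads$barcode))
  counts <- matrix(0L, length(genes), length(cells),
                   dimnames = list(genes, cells))
  if (nrow(reads)) {
    key <- paste(reads$gene, reads$barcode, sep = "\r")
    nUmi <- tapply(reads$umi, key, function(u) length(unique.default(u)))
    parts <- strsplit(names(nUmi), "\r", fixed = TRUE)
    gi <- match(vapply(parts, `[[`, "", 1L), genes)
    ci <- match(vapply(parts, `[[`, "", 2L), cells)
    keep <- !is.na(gi) & !is.na(ci)
    counts[cbind(gi[keep], ci[keep])] <- as.integer(nUmi[keep])
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(geneClass = rep("endogenous",
                                                   length(genes)),
                                   row.names = genes))
}

#' Normalize molecule counts to transcripts per million (tpm)
#'
#' Because CEL-seq retains one molecule per transcript, counts are normalized
#' as transcripts per million: tpm(g, c) = 1e6 * count(g, c) / sum of counts
#' in cell c over the normalization gene set. Spike-in rows
#' (\code{rowData$geneClass == "spikein"}) are excluded from the denominator
#' by default, since the endogenous fraction varies per cell; set
#' \code{includeSpikeIns = TRUE} (or pass a matrix of spike-ins only) to
#' normalize over all rows.
#'
#' @param x a SingleCellExperiment with a \code{counts} assay, or a counts
#'   matrix.
#' @param includeSpikeIns include spike-in rows in the denominator.
#' @return the input with an added \code{tpm} assay (cells whose denominator
#'   is zero are dropped with a warning and listed in
#'   \code{metadata()$excludedCells}).
#' @export
tpmNormalize <- function(x, includeSpikeIns = FALSE) {
  mat <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else as.matrix(x)
  denomRows <- rep(TRUE, nrow(mat))
  if (is(x, "SummarizedExperiment") && !includeSpikeIns) {
    gc <- SummarizedExperiment::rowData(x)$geneClass
    if (!is.null(gc) && any(gc == "endogenous"))
      denomRows <- gc == "endogenous"
  }
  denom <- colSums(mat[denomRows, , drop = FALSE])
  bad <- denom == 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with zero counts in the normalization set ",
            "excluded: ", paste(colnames(mat)[bad], collapse = ", "),
            call. = FALSE)
  }
  tpm <- sweep(mat[, !bad, drop = FALSE], 2, denom[!bad], "/") * 1e6
  if (is(x, "SummarizedExperiment")) {
    x <- x[, !bad]
    SummarizedExperiment::assay(x, "tpm") <- tpm
    S4Vectors::metadata(x)$excludedCells <- colnames(mat)[bad]
    x
  } else tpm
}

#' Filter genes by a tpm expression threshold
#'
#' Genes with tpm strictly greater than \code{threshold} are retained for
#' further analysis (a gene sitting exactly at the threshold in every cell is
#' dropped). The default aggregation retains a gene if any cell exceeds the
#' threshold; \code{aggregate = "mean"} instead requires the across-cell mean
#' tpm to exceed it. tpm values are not renormalized after filtering.
#'
#' @param x a SingleCellExperiment with a \code{tpm} assay, or a tpm matrix.
#' @param threshold tpm threshold (default 5, strict inequality).
#' @param aggregate "any" (default) or "mean".
#' @return the input restricted to retained genes.
#' @export
filterExpressedGenes <- function(x, threshold = 5,
                                 aggregate = c("any", "mean")) {
  stopifnot(threshold >= 0)
  aggregate <- match.arg(aggregate)
  tpm <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "tpm") else as.matrix(x)
  keep <- switch(aggregate,
                 any  = apply(tpm > threshold, 1, any),
                 mean = rowMeans(tpm) > threshold)
  x[keep, , drop = FALSE]
}

#' Per-gene log-transformed z-scores
#'
#' Transforms expression as x = log10(tpm + 1) and standardizes each gene
#' across cells: z = (x - mean) / sd. Genes constant across cells (zero sd)
#' return all-zero rows.
#'
#' @param x a SingleCellExperiment with a \code{tpm} assay, or a tpm matrix.
#' @param genes optional gene subset (must be present).
#' @return a numeric matrix (genes x cells) of z-scores.
#' @export
logZMatrix <- function(x, genes = NULL) {
  tpm <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "tpm") else as.matrix(x)
  if (!is.null(genes)) {
    if (!length(genes)) stop("'genes' must be non-empty", call. = FALSE)
    missing <- setdiff(genes, rownames(tpm))
    if (length(missing))
      stop("genes not present: ", paste(missing, collapse = ", "),
           call. = FALSE)
    tpm <- tpm[genes, , drop = FALSE]
  }
  lg <- log10(tpm + 1)
  mu <- rowMeans(lg)
  sdv <- sqrt(rowVarsBase(lg))
  z <- (lg - mu) / sdv
  z[sdv == 0 | is.na(sdv), ] <- 0
  z
}
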