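# Plain-text interchange: MatrixMarket count matrices with TSV sidecars,
# FASTA genomes, FASTQ read sets (tags encoded in the read name) and BED
# masked intervals.

#' Write a count matrix as MatrixMarket with TSV sidecars
#'
#' Writes \code{matrix.mtx} (1-based sparse MatrixMarket), \code{genes.tsv}
#' (gene id + class flag) and \code{barcodes.tsv} (barcode + metadata
#' columns) into \code{dir}.
#'
#' @param sce a SingleCellExperiment with a \code{counts} assay.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCountMatrix <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(SummarizedExperiment::assay(sce, "counts"),
                      sparse = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(m, mtx)
  rd <- as.data.frame(SummarizedExperiment::rowData(sce))
  genes <- data.frame(gene = rownames(sce),
                      geneClass = if ("geneClass" %in% colnames(rd))
                        rd$geneClass else "endogenous")
  utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  barcodes <- cbind(data.frame(barcode = colnames(sce)), cd)
  utils::write.table(barcodes, file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(mtx, file.path(dir, c("genes.tsv", "barcodes.tsv"))))
}

#' Read a count matrix written by \code{\link{writeCountMatrix}}
#'
#' @param dir directory holding \code{matrix.mtx}, \code{genes.tsv} and
#'   \code{barcodes.tsv}.
#' @return a SingleCellExperiment with a \code{counts} assay.
#' @export
readCountMatrix <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"))
  barcodes <- utils::read.delim(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(genes$gene, barcodes$barcode)
  storage.mode(m) <- "integer"
  cd <- barcodes[, setdiff(colnames(barcodes), "barcode"), drop = FALSE]
  rownames(cd) <- barcodes$barcode
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(
      geneClass = genes$geneClass, row.names = genes$gene),
    colData = S4Vectors::DataFrame(cd))
}

#' Write genome sequences as FASTA
#'
#' @param genomes named list of DNAString/character sequences.
#' @param path output FASTA path.
#' @export
writeGenomeFasta <- function(genomes, path) {
  set <- Biostrings::DNAStringSet(vapply(genomes, as.character, ""))
  names(set) <- names(genomes)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA path.
#' @return named list of character sequences.
#' @export
readGenomeFasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.list(as.character(set)), names(set))
}

#' Write masked intervals as BED
#'
#' Intervals are written 0-based, half-open, as is conventional for BED.
#'
#' @param masked a \linkS4class{MaskedGenome}.
#' @param path output BED path.
#' @param name sequence name for the first BED column.
#' @export
writeMaskedBed <- function(masked, path, name = "target") {
  r <- masked@maskedRanges
  df <- data.frame(chrom = name, start = IRanges::start(r) - 1L,
                   end = IRanges::end(r))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a barcoded read set as FASTQ
#'
#' The UMI, cell barcode and true origin are encoded in the read name as
#' \code{read<i>:<umi>:<barcode>:<trueSpecies>:<trueCell>}; qualities are
#' written as constant high quality since synthetic reads are error-free.
#'
#' @param reads a DataFrame from \code{\link{simulateCrossSpeciesReads}}.
#' @param path output FASTQ path.
#' @export
writeReadsFastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(as.character(reads$sequence))
  names(set) <- sprintf("read%d:%s:%s:%s:%s", seq_len(nrow(reads)),
                        reads$umi, reads$barcode, reads$trueSpecies,
                        reads$trueCell)
  Biostrings::writeXStringSet(set, path, format = "fastq")
  invisible(path)
}

#' Read a FASTQ read set written by \code{\link{writeReadsFastq}}
#'
#' @param path FASTQ path.
#' @return a \link[S4Vectors]{DataFrame} with sequence, umi, barcode and true
#'   origin columns.
#' @export
readReadsFastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  parts <- strsplit(names(set), ":", fixed = TRUE)
  S4Vectors::DataFrame(
    sequence = unname(as.character(set)),
    umi = vapply(parts, `[`, "", 2L),
    barcode = vapply(parts, `[`, "", 3L),
    trueSpecies = vapply(parts, `[`, "", 4L),
    trueCell = vapply(parts, `[`, "", 5L))
}
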