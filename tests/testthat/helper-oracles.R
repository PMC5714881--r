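# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities by brute force or closed form,
# without calling the package paths they check.

# Brute-force Mann-Whitney: enumerate every assignment of the pooled values
# into groups of sizes (nx, ny), compute the U distribution, and return the
# two-sided exact p for the observed split.
bruteForceRankSum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  uStat <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  uObs <- uStat(seq_len(nx))
  combos <- utils::combn(nx + ny, nx)
  uAll <- apply(combos, 2, uStat)
  pLow <- mean(uAll <= uObs)
  pHigh <- mean(uAll >= uObs)
  list(U = uObs, p = min(1, 2 * min(pLow, pHigh)))
}

# Brute-force scan for k-mers shared between two sequences, considering both
# strands of the first sequence. Returns the shared k-mer strings.
bruteSharedKmers <- function(a, b, k) {
  km <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  aSet <- unique(c(km(a), km(rc(a))))
  bSet <- unique(c(km(b), km(rc(b))))
  intersect(aSet, bSet)
}

# Small count SingleCellExperiment with named genes/cells.
makeCountSce <- function(counts, population = NULL,
                         geneClass = rep("endogenous", nrow(counts))) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%02d", seq_len(ncol(counts)))
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(population)) cd$population <- population
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(geneClass = geneClass,
                                   row.names = rownames(counts)),
    colData = cd)
}

# All 4^k DNA k-mers (k small).
allKmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}
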