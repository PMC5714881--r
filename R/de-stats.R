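# Differential expression machinery: per-gene sigma-scores, descending
# ranking, proportional label shuffling, a top-k Mann-Whitney separation test
# with a distinct/similar verdict, and the variable-gene correlation
# structure.

resolveLabels <- function(x, labels) {
  if (is.null(labels)) {
    if (is(x, "SummarizedExperiment"))
      labels <- SummarizedExperiment::colData(x)$population
    if (is.null(labels)) stop("'labels' are required", call. = FALSE)
  }
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2L)
    stop("exactly two groups are required, got: ",
         paste(groups, collapse = ", "), call. = FALSE)
  labels
}

exprMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    a <- SummarizedExperiment::assayNames(x)
    SummarizedExperiment::assay(x, if ("tpm" %in% a) "tpm" else "counts")
  } else as.matrix(x)
}

#' Per-gene sigma-scores between two cell populations
#'
#' Compares the mean and variance of expression (tpm) of all cells between
#' two groups. The default \code{dprime} form is the dimensionally consistent
#' sigma(g) = |meanA - meanB| / sqrt((varA + varB) / 2); the \code{literal}
#' form divides by the variance average itself, (varA + varB) / 2. Variances
#' are sample variances (n - 1). Genes with zero pooled variance get sigma = 0
#' when the mean difference is also zero and an infinite sentinel (ranked
#' first) otherwise.
#'
#' @param x expression matrix (genes x cells) or SingleCellExperiment with a
#'   \code{tpm} assay.
#' @param labels two-group label per cell (defaults to
#'   \code{colData(x)$population}).
#' @param form "dprime" (default) or "literal".
#' @return a \link[S4Vectors]{DataFrame} (one row per gene) with columns
#'   \code{gene}, \code{meanA}, \code{meanB}, \code{varA}, \code{varB},
#'   \code{sigma}; \code{metadata()} records the form and group names.
#' @export
sigmaScores <- function(x, labels = NULL, form = c("dprime", "literal")) {
  form <- match.arg(form)
  m <- exprMatrix(x)
  labels <- resolveLabels(x, labels)
  stopifnot(length(labels) == ncol(m))
  groups <- unique(labels)
  a <- m[, labels == groups[1], drop = FALSE]
  b <- m[, labels == groups[2], drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    stop("each group needs >= 2 cells for the variance", call. = FALSE)
  meanA <- rowMeans(a); meanB <- rowMeans(b)
  varA <- rowVarsBase(a); varB <- rowVarsBase(b)
  pooled <- (varA + varB) / 2
  delta <- abs(meanA - meanB)
  sigma <- switch(form,
                  dprime = delta / sqrt(pooled),
                  literal = delta / pooled)
  sigma[pooled == 0 & delta == 0] <- 0
  sigma[pooled == 0 & delta > 0] <- Inf
  out <- S4Vectors::DataFrame(gene = rownames(m), meanA = meanA,
                              meanB = meanB, varA = varA, varB = varB,
                              sigma = as.numeric(sigma))
  S4Vectors::metadata(out) <- list(form = form, groups = groups)
  out
}

#' Rank genes by sigma-score, descending
#'
#' Rank 1 is the largest sigma; infinite sentinels rank before any finite
#' score; ties are broken by gene id lexicographic order so the ranking is
#' deterministic.
#'
#' @param table a sigma-score \link[S4Vectors]{DataFrame} from
#'   \code{\link{sigmaScores}}.
#' @return the table with a \code{rank} column added, rows in rank order.
#' @export
rankGenes <- function(table) {
  ord <- order(-table$sigma, table$gene)
  table <- table[ord, ]
  table$rank <- seq_len(nrow(table))
  table
}

#' Proportional random relabeling of two groups
#'
#' Shuffles cells between the two groups in a proportional and random
#' fashion: a uniformly random relabeling that preserves the original group
#' sizes exactly.
#'
#' @param labels two-group label vector.
#' @param seed optional integer seed.
#' @return a relabeled vector with the same group sizes.
#' @export
proportionalShuffle <- function(labels, seed = NULL) {
  withSeed(seed, sample(labels))
}

#' Mann-Whitney U rank-sum test with a log-space p-value
#'
#' Computes the Mann-Whitney U statistic (for the first sample) and the
#' two-sided p-value on the log10 scale. For small samples without ties
#' (nA * nB <= 10000) the exact null distribution is used; otherwise the
#' tie-corrected normal approximation is evaluated in log space through the
#' log survival function of the standard normal, so extreme values such as
#' p = 1e-83 remain representable.
#'
#' @param x,y numeric score vectors (non-empty).
#' @param exactMax use the exact distribution when nA * nB is at most this
#'   and there are no ties (default 10000).
#' @return list with \code{U}, \code{log10P} (two-sided) and \code{method}.
#' @export
rankSumTest <- function(x, y, exactMax = 10000) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty",
                                     call. = FALSE)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  hasTies <- any(ties > 1)
  if (!hasTies && nx * ny <= exactMax) {
    pl <- pwilcox(U, nx, ny)
    pu <- pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(pl, pu))
    return(list(U = U, log10P = log10(p), method = "exact"))
  }
  N <- nx + ny
  tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(nx * ny / 12 * ((N + 1) - tieAdj))
  if (sigma == 0) return(list(U = U, log10P = 0, method = "normal"))
  z <- (U - nx * ny / 2) / sigma
  logp <- log(2) + pnorm(-abs(z), log.p = TRUE)
  list(U = U, log10P = min(logp / log(10), 0), method = "normal")
}

#' Top-k sigma-score separation test against proportional shuffles
#'
#' Tests whether two cell populations are transcriptionally distinct: genes
#' are ranked by sigma-score under the original labels, cells are then
#' reshuffled between the groups proportionally and the sigma-scores
#' recomputed, and the top-k score sets of the original and each shuffled
#' labeling (each labeling's own top-k) are compared by the Mann-Whitney U
#' test. The verdict is "distinct" when the median log10 p over reshuffles is
#' below \code{distinctThresholdLog10} (populations separate far beyond any
#' shuffled labeling, the p < 1e-70 band), "similar" when every reshuffle
#' stays above \code{similarFloorLog10} (the 1 > p > 1e-10 band), and
#' "indeterminate" otherwise. Infinite-sigma sentinels are excluded from the
#' score sets and counted.
#'
#' @param x expression matrix or SingleCellExperiment (\code{tpm} assay).
#' @param labels two-group label per cell.
#' @param k number of top-ranked genes compared (default 250, clamped to the
#'   gene count with a warning).
#' @param nShuffles number of proportional reshuffles (default 100).
#' @param seed integer seed for the reshuffles.
#' @param form sigma-score form, see \code{\link{sigmaScores}}.
#' @param distinctThresholdLog10,similarFloorLog10 verdict bands (defaults
#'   -70 and -10).
#' @return a \linkS4class{ShuffleTestResult}.
#' @export
shuffleSeparationTest <- function(x, labels = NULL, k = 250, nShuffles = 100,
                                  seed = 1, form = c("dprime", "literal"),
                                  distinctThresholdLog10 = -70,
                                  similarFloorLog10 = -10) {
  form <- match.arg(form)
  if (nShuffles < 1) stop("'nShuffles' must be >= 1", call. = FALSE)
  m <- exprMatrix(x)
  labels <- resolveLabels(x, labels)
  if (nrow(m) < 2) stop("need >= 2 genes", call. = FALSE)
  if (k > nrow(m)) {
    warning("k clamped from ", k, " to the number of genes (", nrow(m), ")",
            call. = FALSE)
    k <- nrow(m)
  }
  topScores <- function(lab) {
    tab <- rankGenes(sigmaScores(m, lab, form = form))
    s <- tab$sigma[seq_len(k)]
    list(scores = s[is.finite(s)], nInf = sum(is.infinite(s)))
  }
  orig <- topScores(labels)
  withSeed(seed, {
    U <- numeric(nShuffles); lp <- numeric(nShuffles)
    shuf <- vector("list", nShuffles)
    for (i in seq_len(nShuffles)) {
      sh <- topScores(sample(labels))
      shuf[[i]] <- sh$scores
      rs <- rankSumTest(orig$scores, sh$scores)
      U[i] <- rs$U; lp[i] <- rs$log10P
    }
    verdict <- if (median(lp) < distinctThresholdLog10) "distinct"
      else if (all(lp > similarFloorLog10)) "similar"
      else "indeterminate"
    new("ShuffleTestResult", originalTopK = orig$scores, shuffleTopK = shuf,
        U = U, log10P = lp, k = as.integer(k),
        nShuffles = as.integer(nShuffles),
        nInfinite = as.integer(orig$nInf), verdict = verdict)
  })
}

#' Cell-by-cell Pearson correlation on variable genes
#'
#' The pairwise Pearson correlation of the log-normalized z-score expression
#' (log10(tpm + 1), standardized per gene) of the most variable genes, with
#' cells ordered by population label for heat-map display. Cells with a
#' constant profile over the selected genes get NA correlations.
#'
#' @param x expression matrix or SingleCellExperiment with a \code{tpm}
#'   assay.
#' @param variableGenes gene subset (>= 2 genes).
#' @param orderBy optional label per cell used to order rows/columns.
#' @return cells x cells correlation matrix.
#' @export
pairwisePearson <- function(x, variableGenes, orderBy = NULL) {
  if (length(variableGenes) < 2)
    stop("need >= 2 variable genes", call. = FALSE)
  z <- logZMatrix(x, variableGenes)
  if (is.null(orderBy) && is(x, "SummarizedExperiment"))
    orderBy <- SummarizedExperiment::colData(x)$population
  if (!is.null(orderBy)) z <- z[, order(orderBy), drop = FALSE]
  constant <- apply(z, 2, function(v) sd(v) == 0 || is.na(sd(v)))
  r <- suppressWarnings(cor(z))
  r[constant, ] <- NA; r[, constant] <- NA
  diag(r) <- ifelse(constant, NA, 1)
  r
}
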