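# Spike-in quality control: detection efficiency, the per-molecule detection
# model, technical-noise fitting, variable-gene calling and sample
# correlation summaries.

#' Spike-in detection efficiency
#'
#' The fraction of spiked molecules that were detected:
#' efficiency = sum(detected molecules) / sum(spiked molecules), reported per
#' sample and pooled. Pooling weights samples by their spiked molecule totals
#' (the pooled value is the grand ratio, not the mean of per-sample ratios).
#'
#' @param observed counts of detected spike-in molecules: a
#'   SingleCellExperiment (\code{counts} assay) or matrix, species x samples.
#' @param design the matching \linkS4class{SpikeInDesign}.
#' @return list with \code{perSample} (named numeric), \code{pooled}
#'   (scalar) and \code{perSpecies} (detected fraction per species, pooled
#'   over samples).
#' @export
detectionEfficiency <- function(observed, design) {
  obs <- if (is(observed, "SummarizedExperiment"))
    SummarizedExperiment::assay(observed, "counts") else as.matrix(observed)
  mols <- design@molecules
  missing <- setdiff(rownames(obs), rownames(mols))
  if (length(missing))
    stop("design does not cover species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  mols <- mols[rownames(obs), seq_len(ncol(obs)), drop = FALSE]
  if (sum(mols) == 0)
    stop("zero spiked molecules: efficiency undefined", call. = FALSE)
  perSample <- colSums(obs) / colSums(mols)
  names(perSample) <- colnames(obs)
  perSpecies <- rowSums(obs) / rowSums(mols)
  list(perSample = perSample, pooled = sum(obs) / sum(mols),
       perSpecies = perSpecies)
}

#' Probability of detecting at least one of n spiked molecules
#'
#' Under independent per-molecule capture with probability \code{efficiency},
#' the chance that a species spiked at \code{n} molecules is detected at all
#' is 1 - (1 - efficiency)^n. At an efficiency of 12.5 percent this gives a
#' roughly even chance (48.7 percent) of detecting 1 molecule out of 5.
#'
#' @param n number of spiked molecules (vectorized, >= 0).
#' @param efficiency per-molecule detection probability.
#' @return detection probability, same length as \code{n}.
#' @examples
#' detectionProbability(5, 0.125)
#' @export
detectionProbability <- function(n, efficiency) {
  checkCount(n, "n", positive = FALSE)
  checkProbability(efficiency, "efficiency")
  1 - (1 - efficiency)^n
}

#' Fit the per-molecule efficiency from an empirical detection curve
#'
#' Least-squares inversion of the detection curve f(n) = 1 - (1 - p)^n given
#' empirical (molecule count, detected fraction) pairs; with a single pair the
#' fit is the exact algebraic inversion p = 1 - (1 - f)^(1/n).
#'
#' @param nCopies spiked molecule counts (>= 1).
#' @param detectedFraction observed detection frequencies in [0, 1].
#' @return the fitted per-molecule efficiency.
#' @examples
#' fitDetectionEfficiency(5, 0.5)   # ~0.1294
#' @export
fitDetectionEfficiency <- function(nCopies, detectedFraction) {
  stopifnot(length(nCopies) == length(detectedFraction), length(nCopies) >= 1)
  checkCount(nCopies, "nCopies")
  if (any(detectedFraction > 1) || any(detectedFraction < 0))
    stop("detected fractions must lie in [0, 1]", call. = FALSE)
  if (all(detectedFraction == 0)) return(0)
  sse <- function(p) sum((detectedFraction - (1 - (1 - p)^nCopies))^2)
  opt <- optimize(sse, c(0, 1), tol = 1e-12)
  # polish: exact inversion dominates with one pair
  if (length(nCopies) == 1L)
    return(1 - (1 - detectedFraction)^(1 / nCopies))
  opt$minimum
}

#' Fit the technical-noise mean/CV^2 relation on spike-ins
#'
#' Fits CV^2(g) = a1 / mu(g) + a0 across spike-in species (added equally to
#' each sample, so their variability is purely technical), using a
#' gamma-family generalized linear model with identity link on species above
#' a low-mean quantile cutoff. For Poisson molecule counts a1 is ~1 and a0 ~0;
#' a1 is expressed in the units of the supplied means.
#'
#' @param spikeExpr spike-in expression matrix (species x samples), counts or
#'   tpm; a SingleCellExperiment's \code{tpm} (or \code{counts}) assay is used
#'   if given.
#' @param minMeanQuantile fit only species above this quantile of mean
#'   expression (default 0.4).
#' @param minBioCV minimum biological CV stored for downstream variable-gene
#'   calling (default 0.5, i.e. CV = 50 percent).
#' @return a \linkS4class{NoiseFit}.
#' @export
fitTechnicalNoise <- function(spikeExpr, minMeanQuantile = 0.4,
                              minBioCV = 0.5) {
  m <- if (is(spikeExpr, "SummarizedExperiment")) {
    a <- SummarizedExperiment::assayNames(spikeExpr)
    SummarizedExperiment::assay(spikeExpr,
                                if ("tpm" %in% a) "tpm" else "counts")
  } else as.matrix(spikeExpr)
  if (ncol(m) < 2) stop("need >= 2 samples", call. = FALSE)
  mu <- rowMeans(m)
  cv2 <- rowVarsBase(m) / mu^2
  ok <- mu > 0 & is.finite(cv2)
  if (sum(ok) < 2) stop("need >= 2 spike species with positive mean",
                        call. = FALSE)
  mu <- mu[ok]; cv2 <- cv2[ok]
  if (all(abs(cv2) < 1e-12))
    return(new("NoiseFit", a1 = 0, a0 = 0, fitSpecies = names(mu),
               minBioCV = minBioCV))
  use <- mu >= quantile(mu, minMeanQuantile)
  if (length(unique(mu[use])) < 2)
    stop("degenerate fit: all fitted species have equal mean", call. = FALSE)
  df <- data.frame(cv2 = cv2[use], invMu = 1 / mu[use])
  fit <- tryCatch(
    stats::glm(cv2 ~ invMu, data = df,
               family = stats::Gamma(link = "identity"),
               start = c(max(mean(df$cv2) / 2, 1e-8),
                         max(stats::coef(stats::lm(cv2 ~ invMu, df))[2], 1e-8))),
    error = function(e) stats::lm(cv2 ~ invMu, data = df))
  cf <- stats::coef(fit)
  new("NoiseFit", a1 = unname(cf[2]), a0 = unname(cf[1]),
      fitSpecies = names(mu)[use], minBioCV = minBioCV)
}

#' Call genes whose expression variability exceeds technical noise
#'
#' For each gene the observed CV^2 is tested against the technical expectation
#' a1 / mu + a0 inflated by a minimum biological CV^2 (default CV = 50
#' percent): the variance ratio times (n - 1) is referred to a chi-square
#' distribution with n - 1 degrees of freedom, and p-values are adjusted by
#' Benjamini-Hochberg across genes.
#'
#' @param expr expression matrix (genes x cells) on the same scale as the
#'   noise fit, or a SingleCellExperiment (\code{tpm} assay preferred).
#' @param fit a \linkS4class{NoiseFit}.
#' @param minBioCV minimum biological CV; defaults to the fit's value.
#' @param fdr Benjamini-Hochberg false-discovery-rate cutoff (default 0.1).
#' @return character vector of variable gene ids (possibly empty).
#' @export
callVariableGenes <- function(expr, fit, minBioCV = NULL, fdr = 0.1) {
  stopifnot(is(fit, "NoiseFit"))
  if (is.null(minBioCV)) minBioCV <- fit@minBioCV
  m <- if (is(expr, "SummarizedExperiment")) {
    a <- SummarizedExperiment::assayNames(expr)
    SummarizedExperiment::assay(expr, if ("tpm" %in% a) "tpm" else "counts")
  } else as.matrix(expr)
  if (!nrow(m) || ncol(m) < 2) return(character(0))
  n <- ncol(m)
  mu <- rowMeans(m)
  v <- rowVarsBase(m)
  # null variance: technical noise at this mean plus the minimum biological CV^2
  nullVar <- mu^2 * (fit@a0 + minBioCV^2) + fit@a1 * mu
  ok <- mu > 0 & nullVar > 0
  stat <- v[ok] * (n - 1) / nullVar[ok]
  p <- pchisq(stat, df = n - 1, lower.tail = FALSE)
  padj <- p.adjust(p, method = "BH")
  names(which(padj <= fdr))
}

#' Pairwise Pearson correlations between samples
#'
#' Pearson r for every sample pair on tpm (linear) or log10(tpm + 1) values,
#' with a mean and standard deviation summary over the distinct pairs.
#' Constant samples yield undefined correlations, reported as NA.
#'
#' @param expr expression matrix (genes x samples) or SingleCellExperiment
#'   with a \code{tpm} assay.
#' @param scale "linear" or "log10".
#' @return list with \code{correlations} (samples x samples), \code{mean} and
#'   \code{sd} over the upper-triangle pairs (NAs removed).
#' @export
sampleCorrelations <- function(expr, scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  m <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "tpm") else as.matrix(expr)
  if (ncol(m) < 2) stop("need >= 2 samples", call. = FALSE)
  if (scale == "log10") m <- log10(m + 1)
  constant <- apply(m, 2, function(x) sd(x) == 0 || is.na(sd(x)))
  r <- suppressWarnings(cor(m))
  r[constant, ] <- NA; r[, constant] <- NA
  diag(r) <- ifelse(constant, NA, 1)
  pairs <- r[upper.tri(r)]
  list(correlations = r, mean = mean(pairs, na.rm = TRUE),
       sd = sd(pairs, na.rm = TRUE))
}
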