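# Internal helpers shared across modules.

#' @importFrom stats rnbinom rbinom rpois rnorm runif sd var cor quantile
#'   median pnorm pchisq p.adjust pwilcox optimize setNames
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs under the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

rowMeansBase <- function(m) rowMeans(m)

# Row variances with the n-1 denominator, without a matrixStats dependency.
rowVarsBase <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# All k-mers of a character sequence, as a character vector (empty if too short).
seqKmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

randomDNA <- function(n, length) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * length, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

checkProbability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

checkCount <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && all(!is.na(x)) && all(x == round(x)) &&
    all(x >= if (positive) 1 else 0)
  if (!ok)
    stop(sprintf("'%s' must contain %s integers", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  invisible(x)
}
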