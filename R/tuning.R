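# Speed-tuning classification of imaged cells from dF/F grating responses.

#' Fractional fluorescence change relative to a gray-screen baseline
#'
#' dF/F(t) = (F(t) - F0) / F0 with F0 the mean raw fluorescence over the
#' 2-s mean-luminance gray window preceding the stimulus.
#'
#' @param stimulus raw fluorescence over the stimulus window.
#' @param baseline raw fluorescence over the preceding gray baseline window.
#' @return dF/F values over the stimulus window.
#' @examples
#' computeDFF(c(150, 160), baseline = c(100, 100))
#' @export
computeDFF <- function(stimulus, baseline) {
  if (!length(baseline)) stop("baseline window is empty", call. = FALSE)
  f0 <- mean(baseline)
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline mean must be positive", call. = FALSE)
  (stimulus - f0) / f0
}

#' Trial-averaged response for one stimulus and direction
#'
#' The per-direction response is the mean over trials of the mean
#' stimulus-window dF/F; at least 8 trials are required.
#'
#' @param dff trials in rows: a matrix (trials x frames) or a list of per-trial
#'   dF/F vectors.
#' @param minTrials minimum trial count (default 8).
#' @return scalar mean response.
#' @export
trialAverage <- function(dff, minTrials = 8) {
  if (is.list(dff)) dff <- do.call(rbind, lapply(dff, as.numeric))
  if (is.null(dim(dff))) dff <- matrix(dff, nrow = 1)
  if (nrow(dff) < minTrials)
    stop("at least ", minTrials, " trials are required, got ", nrow(dff),
         call. = FALSE)
  mean(rowMeans(dff))
}

#' Sum of trial-averaged responses over the 8 grating directions
#'
#' Responses may be negative and are not rectified before summing.
#'
#' @param responses named numeric of per-direction responses; all 8 directions
#'   (0, 45, ..., 315 degrees) must be present.
#' @return the arithmetic sum.
#' @export
directionSum <- function(responses) {
  dirs <- seq(0, 315, by = 45)
  if (length(responses) != 8 ||
      (!is.null(names(responses)) &&
       !setequal(as.numeric(names(responses)), dirs)))
    stop("responses for all 8 directions (0-315 deg) are required",
         call. = FALSE)
  sum(responses)
}

#' Classify a cell as high-speed or low-speed tuned
#'
#' A cell is tuned to one speed stimulus if its summed response is at least
#' \code{ratio} (default 4) times higher than for the other; cells responding
#' significantly to both stimuli are excluded. A negative competing sum is
#' floored at 0 before the ratio comparison, so any positive response beats a
#' negative one. Vectorized over cells.
#'
#' @param sumHS,sumLS summed dF/F responses over the 8 directions for the
#'   high- and low-speed stimulus.
#' @param sigHS,sigLS logical significance flags per stimulus (used only for
#'   the dual-responder exclusion).
#' @param ratio tuning ratio (> 1, default 4).
#' @return character vector with values "HS", "LS", "untuned" or
#'   "excluded_dual".
#' @examples
#' classifySpeedTuning(4.1, 1.0)  # "HS"
#' @export
classifySpeedTuning <- function(sumHS, sumLS, sigHS = FALSE, sigLS = FALSE,
                                ratio = 4) {
  if (ratio <= 1) stop("'ratio' must be > 1", call. = FALSE)
  n <- max(length(sumHS), length(sumLS))
  sumHS <- rep_len(sumHS, n); sumLS <- rep_len(sumLS, n)
  sigHS <- rep_len(sigHS, n); sigLS <- rep_len(sigLS, n)
  hsFloor <- pmax(sumHS, 0); lsFloor <- pmax(sumLS, 0)
  call <- rep("untuned", n)
  call[sumHS > 0 & sumHS >= ratio * lsFloor] <- "HS"
  call[sumLS > 0 & sumLS >= ratio * hsFloor] <- "LS"
  call[sigHS & sigLS] <- "excluded_dual"
  call
}

#' Classify all cells of a tuning dataset
#'
#' End-to-end tuning analysis on long-format traces (as produced by
#' \code{\link{simulateTuningDataset}}): per cell, stimulus, direction and
#' trial the stimulus-window dF/F is computed against the trial's own gray
#' baseline, trial-averaged per direction, summed over the 8 directions, and
#' the cell classified by \code{\link{classifySpeedTuning}}. A stimulus counts
#' as significant for the dual-responder exclusion when its summed response
#' exceeds \code{zThreshold} times the standard deviation expected for the sum
#' under baseline noise (estimated from the per-frame baseline dF/F
#' fluctuations).
#'
#' Because the 4-fold ratio rule compares only the two sums, it is blind to
#' their absolute size; \code{requireSignificant} (default TRUE) therefore
#' additionally demands that the winning stimulus itself be significant, so
#' unresponsive cells are called untuned rather than by the sign of their
#' noise.
#'
#' @param traces long-format data.frame with columns \code{cell},
#'   \code{stimulus}, \code{direction}, \code{trial}, \code{phase},
#'   \code{frame}, \code{value}.
#' @param ratio tuning ratio (default 4).
#' @param zThreshold significance threshold in baseline-noise SD units
#'   (default 3).
#' @param requireSignificant demand a significant winning response for a
#'   tuned call.
#' @return a \link[S4Vectors]{DataFrame} with per-cell \code{sumHS},
#'   \code{sumLS}, \code{sigHS}, \code{sigLS} and \code{call}.
#' @export
classifyTuningCells <- function(traces, ratio = 4, zThreshold = 3,
                                requireSignificant = TRUE) {
  stopifnot(all(c("cell", "stimulus", "direction", "trial", "phase", "frame",
                  "value") %in% colnames(traces)))
  cells <- unique(traces$cell)
  res <- lapply(cells, function(cl) {
    tc <- traces[traces$cell == cl, ]
    sums <- c(HS = NA_real_, LS = NA_real_)
    noise <- c(HS = NA_real_, LS = NA_real_)
    for (st in c("HS", "LS")) {
      ts <- tc[tc$stimulus == st, ]
      dirs <- sort(unique(ts$direction))
      perDir <- numeric(length(dirs)); names(perDir) <- dirs
      baseSd <- numeric(0); nTrials <- NA_integer_
      nStimFrames <- NA_integer_; nBaseFrames <- NA_integer_
      for (d in seq_along(dirs)) {
        td <- ts[ts$direction == dirs[d], ]
        trials <- sort(unique(td$trial))
        nTrials <- length(trials)
        trialMeans <- vapply(trials, function(tr) {
          tt <- td[td$trial == tr, ]
          bl <- tt$value[tt$phase == "baseline"][order(tt$frame[tt$phase == "baseline"])]
          stw <- tt$value[tt$phase == "stimulus"][order(tt$frame[tt$phase == "stimulus"])]
          nStimFrames <<- length(stw)
          nBaseFrames <<- length(bl)
          dff <- computeDFF(stw, bl)
          baseSd <<- c(baseSd, sd(computeDFF(bl, bl)))
          mean(dff)
        }, 0)
        if (nTrials < 8)
          stop("cell ", cl, ", stimulus ", st, ", direction ", dirs[d],
               ": fewer than 8 trials", call. = FALSE)
        perDir[d] <- mean(trialMeans)
      }
      sums[st] <- directionSum(perDir)
      # expected SD of the 8-direction sum of trial-averaged responses under
      # baseline noise alone; a trial's mean dF/F carries both the
      # stimulus-window noise and the error of estimating F0 from the short
      # baseline window
      frameSd <- mean(baseSd, na.rm = TRUE)
      noise[st] <- frameSd *
        sqrt(length(dirs) * (1 / nStimFrames + 1 / nBaseFrames) / nTrials)
    }
    sig <- !is.na(noise) & noise > 0 & sums > zThreshold * noise
    S4Vectors::DataFrame(cell = cl, sumHS = sums[["HS"]],
                         sumLS = sums[["LS"]], sigHS = sig[["HS"]],
                         sigLS = sig[["LS"]])
  })
  out <- do.call(rbind, res)
  out$call <- classifySpeedTuning(out$sumHS, out$sumLS, out$sigHS, out$sigLS,
                                  ratio = ratio)
  if (requireSignificant) {
    out$call[out$call == "HS" & !out$sigHS] <- "untuned"
    out$call[out$call == "LS" & !out$sigLS] <- "untuned"
  }
  out
}
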