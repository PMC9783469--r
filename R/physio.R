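#' @include AllGenerics.R
NULL

#' Zero-phase low-pass filter a physiological trace
#'
#' Applies an order-`order` Butterworth low-pass filter forward and backward
#' (zero net phase shift), the standard preprocessing before PPG peak
#' detection. Defaults: 5 Hz cutoff, third order.
#'
#' @param trace a [PhysioTrace-class].
#' @param cutoff cutoff frequency in Hz; must lie below the Nyquist rate.
#' @param order filter order (>= 1).
#' @return A [PhysioTrace-class] of identical length and sampling rate.
#' @examples
#' tr <- PhysioTrace(sin(2 * pi * 1 * seq(0, 30, by = 0.01)), 100)
#' filt <- lowpassFilter(tr)
#' @export
lowpassFilter <- function(trace, cutoff = 5, order = 3) {
  stopifnot(is(trace, "PhysioTrace"))
  fs <- trace@samplingRate
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2)
    paStop(sprintf("cutoff must lie in (0, Nyquist = %g Hz)", fs / 2),
           "pa_invalid_parameter")
  if (order < 1)
    paStop("filter order must be >= 1", "pa_invalid_parameter")
  # filtfilt needs a few filter lengths of data to settle its edge transients
  if (length(trace@samples) <= 3 * (order + 1))
    paStop("trace too short for the filter warm-up length", "pa_too_short")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # demean first: filtfilt edge transients otherwise scale with the offset
  m <- mean(trace@samples)
  y <- signal::filtfilt(bf, trace@samples - m) + m
  initialize(trace, samples = as.numeric(y))
}

#' Estimate the heartbeat period from the autocorrelation
#'
#' Locates the highest autocorrelation peak of the (typically filtered) PPG
#' trace at lags inside a physiological heart-rate band and returns the
#' corresponding period. The band excludes the trivial zero-lag peak and
#' harmonics; a peak is only accepted if its autocorrelation exceeds
#' `minCorr`, so structureless (white-noise) traces fail.
#'
#' @param trace a [PhysioTrace-class]; use the low-pass filtered trace.
#' @param hrRange plausible heart-rate range in beats per minute,
#'   default `c(40, 150)`.
#' @param minCorr minimum autocorrelation for an acceptable peak (default
#'   0.15).
#' @return The heartbeat period in seconds.
#' @export
estimateCycle <- function(trace, hrRange = c(40, 150), minCorr = 0.15) {
  stopifnot(is(trace, "PhysioTrace"))
  fs <- trace@samplingRate
  lagMin <- 60 / hrRange[2]
  lagMax <- 60 / hrRange[1]
  if (duration(trace) < 4 * lagMax)
    paStop(sprintf("trace must last at least 4 x the longest plausible cycle (%.1f s)",
                   4 * lagMax), "pa_too_short")
  x <- trace@samples - mean(trace@samples)
  if (sd(x) == 0)
    paStop("no autocorrelation peak in the heart-rate band (constant trace)",
           "pa_cycle_not_found")
  nlag <- ceiling(lagMax * fs) + 1L
  ac <- as.numeric(stats::acf(x, lag.max = nlag, plot = FALSE,
                              demean = FALSE)$acf)
  lags <- (seq_along(ac) - 1) / fs
  # local maxima strictly inside the band
  i <- which(lags >= lagMin & lags <= lagMax)
  i <- i[i > 1 & i < length(ac)]
  isPeak <- ac[i] > ac[i - 1] & ac[i] >= ac[i + 1]
  cand <- i[isPeak & ac[i] >= minCorr]
  if (!length(cand))
    paStop("no autocorrelation peak in the heart-rate band",
           "pa_cycle_not_found")
  lags[cand[which.max(ac[cand])]]
}

# local maxima with topographic prominence and a minimum-distance rule
# (greedy, by descending height). Returns sorted sample indices.
.findPeaks <- function(x, minDist, minProminence) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lo <- if (i > 1L) min(x[1:(i - 1)]) else h
    hi <- if (i < n) min(x[(i + 1):n]) else h
    left <- which(x[seq_len(i - 1L)] > h)
    right <- which(x[seq.int(i + 1L, n)] > h)
    leftBase <- if (length(left)) min(x[(max(left) + 1L):(i - 1L)]) else lo
    rightBase <- if (length(right)) min(x[(i + 1L):(i + min(right) - 1L)]) else hi
    h - max(leftBase, rightBase)
  }, numeric(1))
  cand <- cand[prom >= minProminence]
  if (!length(cand)) return(integer(0))
  # enforce the minimum distance, keeping taller peaks first
  keep <- logical(length(x))
  for (i in cand[order(x[cand], decreasing = TRUE)]) {
    lo <- max(1L, i - minDist); hi <- min(length(x), i + minDist)
    if (!any(keep[lo:hi])) keep[i] <- TRUE
  }
  which(keep)
}

#' Detect heartbeat peaks in a PPG trace
#'
#' The full peak-detection procedure: low-pass filter the trace (zero-phase
#' Butterworth, 5 Hz, third order), estimate the heartbeat period from the
#' autocorrelation of the filtered signal, then find local maxima with a
#' minimum peak separation of 70% of that period. A prominence floor (25% of
#' the filtered signal's interquartile range) rejects dicrotic-notch
#' secondary maxima. Peak times are returned on the fMRI clock using the
#' trace's `startTime`. Detection is invariant to positive rescaling and to
#' adding a constant.
#'
#' @param trace a PPG [PhysioTrace-class].
#' @param cutoff,order passed to [lowpassFilter()].
#' @param hrRange passed to [estimateCycle()].
#' @param minDistanceFrac minimum peak separation as a fraction of the
#'   cycle estimate (default 0.7).
#' @param prominenceFrac prominence floor as a fraction of the filtered
#'   signal's IQR (default 0.25).
#' @return A [PeakSeries-class].
#' @examples
#' sim <- generatePPG(simConfig(duration = 60, seed = 7))
#' pk <- detectPeaks(sim$trace)
#' @export
detectPeaks <- function(trace, cutoff = 5, order = 3, hrRange = c(40, 150),
                        minDistanceFrac = 0.7, prominenceFrac = 0.25) {
  stopifnot(is(trace, "PhysioTrace"))
  if (trace@channel != "ppg")
    paStop("peak detection expects a PPG channel", "pa_invalid_parameter")
  filt <- lowpassFilter(trace, cutoff = cutoff, order = order)
  x <- filt@samples
  if (sd(x) <= 1e-10 * (abs(mean(x)) + 1))
    paStop("fewer than 3 peaks found (constant trace)",
           "pa_insufficient_beats")
  cycle <- estimateCycle(filt, hrRange = hrRange)
  fs <- trace@samplingRate
  idx <- .findPeaks(x, minDist = floor(minDistanceFrac * cycle * fs),
                    minProminence = prominenceFrac * IQR(x))
  if (length(idx) < 3L)
    paStop("fewer than 3 peaks found", "pa_insufficient_beats")
  t0 <- trace@startTime
  PeakSeries(peakTimes = t0 + (idx - 1) / fs, cycleEstimate = cycle,
             bounds = c(t0, t0 + (length(x) - 1) / fs))
}

#' Ultrashort-window RMSSD heart-rate variability
#'
#' Computes the root mean square of successive inter-beat-interval
#' differences over contiguous non-overlapping windows (default 20 s) and
#' compares the maximum with a threshold (default 50 ms, one slice
#' acquisition duration). If the maximum stays below the threshold, the
#' heart rate is stable enough that no within-scan correction is needed.
#' Peaks within half a cycle of the recording boundary (when known) are
#' excluded; a window with fewer than 3 peaks is flagged missing and
#' excluded from the maximum. A trailing partial window is evaluated when it
#' still holds at least 3 peaks.
#'
#' @param peaks a [PeakSeries-class].
#' @param windowLength window length in seconds (default 20).
#' @param threshold pass/fail threshold in milliseconds (default 50).
#' @return An [HrvReport-class].
#' @examples
#' pk <- PeakSeries(c(0, 1, 2.1, 3.1), cycleEstimate = 1)
#' rmssdHrv(pk)  # RMSSD 100 ms, fails the 50 ms threshold
#' @export
rmssdHrv <- function(peaks, windowLength = 20, threshold = 50) {
  stopifnot(is(peaks, "PeakSeries"))
  pt <- peaks@peakTimes
  if (all(is.finite(peaks@bounds))) {
    half <- 0.5 * peaks@cycleEstimate
    pt <- pt[pt >= peaks@bounds[1] + half & pt <= peaks@bounds[2] - half]
  }
  if (length(pt) < 3L)
    paStop("need at least 3 usable peaks for RMSSD", "pa_insufficient_beats")
  t0 <- pt[1]
  starts <- seq(t0, max(pt), by = windowLength)
  rmssd <- vapply(starts, function(w) {
    p <- pt[pt >= w & pt < w + windowLength]
    if (length(p) < 3L) return(NA_real_)
    1000 * sqrt(mean(diff(diff(p))^2))
  }, numeric(1))
  ok <- rmssd[!is.na(rmssd)]
  if (!length(ok))
    paStop("no window holds at least 3 peaks", "pa_insufficient_beats")
  new("HrvReport", windowLength = windowLength, windowStarts = starts,
      rmssd = rmssd, maxRmssd = max(ok), threshold = threshold,
      passes = max(ok) < threshold)
}
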