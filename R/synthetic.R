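#' @include roi.R
NULL

#' Default waveform template parameters
#'
#' Per-class parameters of the skewed-transient templates: extremum time in
#' cycle fraction (artery -0.15: blood reaches the brain 0.1-0.2 s before
#' the fingertip PPG peak at a 1 s cycle; vein 0.0: venous dip at the PPG
#' peak; csf +0.05: CSF maximum just after the peak), sign (-1 blood dip,
#' +1 CSF rise), amplitude in percent (1.5 for every class: classes differ
#' in timing and sign, not modulation depth), and onset/return widths in
#' cycle fraction (steep arrival, shallow return).
#'
#' @return Named list of per-class parameter lists.
#' @export
defaultTemplateParams <- function() {
  base <- list(onsetWidth = 0.08, returnWidth = 0.18, amplitude = 1.5)
  list(
    artery = c(list(extremumTime = -0.15, sign = -1), base),
    vein   = c(list(extremumTime =  0.00, sign = -1), base),
    csf    = c(list(extremumTime =  0.05, sign = +1), base),
    null   = list(extremumTime = NA_real_, sign = 0, amplitude = 0,
                  onsetWidth = base$onsetWidth, returnWidth = base$returnWidth))
}

#' Cardiac waveform template
#'
#' A smooth 1-cycle-periodic waveform: a skewed-Gaussian transient with a
#' steep onset (width `onsetWidth`) and a shallow return (width
#' `returnWidth`), of the stated sign and extremum time, in percent
#' modulation. The null class is identically zero.
#'
#' @param class one of `"artery"`, `"vein"`, `"csf"`, `"null"`.
#' @param params parameter list as in [defaultTemplateParams()]; defaults to
#'   that class's default.
#' @return A function of cycle fraction (vectorized, periodic).
#' @examples
#' w <- waveformTemplate("artery")
#' w(c(-0.15, 0, 0.5))
#' @export
waveformTemplate <- function(class = c("artery", "vein", "csf", "null"),
                             params = NULL) {
  class <- match.arg(class)
  p <- if (is.null(params)) defaultTemplateParams()[[class]] else params
  if (class == "null" || p$sign == 0 || p$amplitude == 0)
    return(function(frac) rep(0, length(frac)))
  force(p)
  function(frac) {
    d <- ((frac - p$extremumTime + 0.5) %% 1) - 0.5
    w <- ifelse(d < 0, p$onsetWidth, p$returnWidth)
    p$sign * p$amplitude * exp(-d^2 / (2 * w^2))
  }
}

# default class layout: artery / vein / csf / null repeating along the
# linear voxel index, so every slice carries all classes in equal shares.
.defaultClassMap <- function(grid) {
  cls <- c("artery", "vein", "csf", "null")
  array(cls[(seq_len(prod(grid)) - 1L) %% 4L + 1L], dim = grid)
}

#' Synthetic-dataset configuration
#'
#' Builds a [SimConfig-class] with the fast-SMS study conditions as
#' defaults: 60 bpm with 10 ms beat-to-beat jitter, 220 s of 100 Hz PPG, an
#' 8 x 8 x 40 grid acquired as 5 simultaneous groups of 8 slices (TR
#' 250 ms, 50 ms acquisition windows, 878 volumes), a repeating
#' artery/vein/csf/null class layout, 1% Gaussian noise (which puts
#' template voxels in the reliable regime, median R-squared near 70; see
#' [calibrateNoiseSd()]) and a slow linear drift.
#'
#' @param heartRate mean heart rate in beats per minute (default 60).
#' @param jitterSd beat-to-beat Gaussian jitter SD in seconds (default 0.01).
#' @param lfAmp fractional amplitude of the slow inter-beat-interval
#'   modulation (default 0.015, i.e. the period wanders by 1.5%). Real heart
#'   rates drift slowly (autonomic regulation); this drift is what sweeps
#'   each slice's sampling phases across the whole cardiac cycle when the
#'   nominal rate is commensurate with the TR. It leaves RMSSD essentially
#'   untouched (successive-interval differences from the slow term are
#'   sub-millisecond).
#' @param lfFreq frequency of the slow modulation in Hz (default 0.01).
#' @param duration physio recording duration in seconds (default 220).
#' @param physioFs physio sampling rate in Hz (default 100).
#' @param grid integer(3) image dimensions (default `c(8, 8, 40)`).
#' @param timing an [AcquisitionTiming-class]; default
#'   `sliceOffsetsSMS(0.25, grid[3], mb, 878)` with `mb = grid[3] / 5`.
#' @param classMap 3D character array over `grid`; default repeating layout.
#' @param templateParams per-class template parameters.
#' @param noiseSd Gaussian noise SD in percent (default 1.0).
#' @param driftSlope linear drift in percent per volume (default 0.002).
#' @param seed integer random seed (default 1).
#' @return A [SimConfig-class].
#' @export
simConfig <- function(heartRate = 60, jitterSd = 0.01, lfAmp = 0.015,
                      lfFreq = 0.01, duration = 220,
                      physioFs = 100, grid = c(8L, 8L, 40L), timing = NULL,
                      classMap = NULL, templateParams = defaultTemplateParams(),
                      noiseSd = 1.0, driftSlope = 0.002, seed = 1L) {
  grid <- as.integer(grid)
  if (is.null(timing)) {
    nGroups <- 5L
    mb <- if (grid[3] %% nGroups == 0L) grid[3] %/% nGroups else 1L
    timing <- sliceOffsetsSMS(0.25, grid[3], mb, nVolumes = 878L)
  }
  if (is.null(classMap)) classMap <- .defaultClassMap(grid)
  new("SimConfig", heartRate = heartRate, jitterSd = jitterSd,
      lfAmp = lfAmp, lfFreq = lfFreq,
      duration = duration, physioFs = physioFs, grid = grid, timing = timing,
      classMap = classMap, templateParams = templateParams,
      noiseSd = noiseSd, driftSlope = driftSlope, seed = as.integer(seed))
}

#' Calibrate the generator noise to a target reliability
#'
#' Closed-form calibration of the sample-level noise SD that yields an
#' expected even/odd zero-referenced R-squared near `targetR2` for a
#' template voxel. With per-bin signal power P summed over B bins and
#' per-bin-mean noise SD s, E\[SSres\] = 2 B s^2 and E\[SSdata\] = P + B s^2,
#' so the target is met at `s^2 = P (100 - targetR2) / (B (100 + targetR2))`;
#' the sample-level SD follows from the expected number of samples per bin
#' and parity.
#'
#' @param cfg a [SimConfig-class] (geometry, heart rate, templates).
#' @param targetR2 target reliability (default 70).
#' @param class template class to calibrate against (default `"artery"`).
#' @param window epoch window used by the alignment (default `c(-0.5, 1)`).
#' @param nDrop volumes dropped before alignment (default 3).
#' @return Sample-level noise SD in percent.
#' @export
calibrateNoiseSd <- function(cfg, targetR2 = 70, class = "artery",
                             window = c(-0.5, 1), nDrop = 3) {
  stopifnot(is(cfg, "SimConfig"))
  cycle <- 60 / cfg@heartRate
  sliceDur <- cfg@timing@sliceDuration
  nb <- ceiling((window[2] - window[1]) * cycle / sliceDur - 1e-9)
  centers <- window[1] * cycle + (seq_len(nb) - 0.5) * sliceDur
  tmpl <- waveformTemplate(class, cfg@templateParams[[class]])
  P <- sum(tmpl(centers / cycle)^2)
  sBin2 <- P * (100 - targetR2) / (nb * (100 + targetR2))
  nSamples <- cfg@timing@nVolumes - nDrop
  perBinParity <- nSamples * (window[2] - window[1]) / (nb * 2)
  sqrt(sBin2 * perBinParity)
}

#' Generate a synthetic PPG trace with known beat times
#'
#' Inter-beat intervals are `60 / heartRate` modulated by a slow
#' low-frequency term (autonomic heart-rate drift, amplitude `lfAmp`,
#' frequency `lfFreq`) plus i.i.d. Gaussian jitter (`jitterSd`). Each beat
#' renders a stereotyped pulse: a symmetric systolic lobe whose maximum
#' sits exactly at the beat time, a decay shoulder and a small dicrotic
#' bump (fast upstroke, slow decay overall). Additive Gaussian noise is
#' scaled to the pulse amplitude. The symmetric lobe keeps the pulse
#' maximum in place under zero-phase low-pass filtering, so detected and
#' true peak times are directly comparable.
#'
#' @param cfg a [SimConfig-class]; uses `heartRate`, `jitterSd`, `lfAmp`,
#'   `lfFreq`, `duration`, `physioFs` and `seed`.
#' @param noiseSd additive noise SD as a fraction of pulse amplitude
#'   (default 0.05).
#' @return A list with `trace` (a [PhysioTrace-class]) and `truePeakTimes`
#'   (numeric seconds).
#' @examples
#' sim <- generatePPG(simConfig(duration = 30, seed = 3))
#' length(sim$truePeakTimes)
#' @export
generatePPG <- function(cfg, noiseSd = 0.05) {
  stopifnot(is(cfg, "SimConfig"))
  cycle <- 60 / cfg@heartRate
  if (cfg@duration < 10 * cycle)
    paStop("duration must cover at least 10 beats", "pa_invalid_parameter")
  set.seed(cfg@seed)
  nBeats <- ceiling(cfg@duration / cycle) + 2L
  tNominal <- (seq_len(nBeats) - 1) * cycle
  ibi <- cycle * (1 + cfg@lfAmp * sin(2 * pi * cfg@lfFreq * tNominal)) +
    rnorm(nBeats, 0, cfg@jitterSd)
  if (any(ibi < 0.5 * cycle))
    paStop("jitter so large that beats overlap", "pa_generation_error")
  beats <- 0.5 * cycle + cumsum(c(0, ibi))
  beats <- beats[beats < cfg@duration - 0.25 * cycle]
  tt <- (seq_len(round(cfg@duration * cfg@physioFs)) - 1) / cfg@physioFs
  x <- numeric(length(tt))
  lobeSd <- 0.07 * cycle
  for (b in beats) {
    d <- tt - b
    span <- d > -0.5 * cycle & d < 0.95 * cycle
    ds <- d[span]
    pulse <- exp(-ds^2 / (2 * lobeSd^2)) +
      0.35 * exp(-(ds - 0.30 * cycle)^2 / (2 * (0.15 * cycle)^2)) +
      0.15 * exp(-(ds - 0.50 * cycle)^2 / (2 * (0.08 * cycle)^2))
    x[span] <- x[span] + pulse
  }
  x <- x + rnorm(length(x), 0, noiseSd)
  list(trace = PhysioTrace(x, samplingRate = cfg@physioFs, startTime = 0,
                           channel = "ppg"),
       truePeakTimes = beats)
}

#' Generate a synthetic 4D fMRI run locked to known heartbeats
#'
#' Each voxel's sample at volume v, slice s is its class template evaluated
#' at the cycle fraction of the acquisition time `v * tr + sliceOffset(s)`
#' relative to the nearest preceding true heartbeat, on a baseline of 100,
#' plus a linear drift and Gaussian noise. Null-class voxels carry noise and
#' drift only.
#'
#' @param cfg a [SimConfig-class].
#' @param truePeaks true heartbeat times; generated from `cfg` when NULL.
#' @return A list with `img` (4D array), `truth` (a [GroundTruth-class])
#'   and `trace` (the PPG [PhysioTrace-class] when peaks were generated
#'   here, else NULL).
#' @export
generateFmri <- function(cfg, truePeaks = NULL) {
  stopifnot(is(cfg, "SimConfig"))
  trace <- NULL
  if (is.null(truePeaks)) {
    sim <- generatePPG(cfg)
    truePeaks <- sim$truePeakTimes
    trace <- sim$trace
  }
  tm <- cfg@timing
  scanDur <- (tm@nVolumes - 1L) * tm@tr + max(tm@sliceOffsets)
  if (max(truePeaks) < scanDur - 2 * 60 / cfg@heartRate)
    warning("true peaks end well before the scan does; late volumes wrap to the last beat")
  cycle <- 60 / cfg@heartRate
  d <- c(cfg@grid, tm@nVolumes)
  img <- array(0, dim = d)
  classes <- c("artery", "vein", "csf", "null")
  tmplFuns <- lapply(setNames(classes, classes), function(cl)
    waveformTemplate(cl, cfg@templateParams[[cl]]))
  volStart <- (seq_len(tm@nVolumes) - 1L) * tm@tr
  drift <- cfg@driftSlope * (seq_len(tm@nVolumes) - 1L)
  set.seed(cfg@seed + 1L)
  nxy <- d[1] * d[2]
  for (z in seq_len(d[3])) {
    tt <- volStart + tm@sliceOffsets[z]
    i0 <- pmax(findInterval(tt, truePeaks), 1L)
    frac <- (tt - truePeaks[i0]) / cycle
    slab <- matrix(0, nxy, tm@nVolumes)
    cls <- as.vector(cfg@classMap[, , z])
    for (cl in classes) {
      rows <- which(cls == cl)
      if (!length(rows)) next
      w <- tmplFuns[[cl]](frac)
      slab[rows, ] <- matrix(w, length(rows), tm@nVolumes, byrow = TRUE)
    }
    slab <- 100 + slab +
      matrix(drift, nxy, tm@nVolumes, byrow = TRUE) +
      matrix(rnorm(nxy * tm@nVolumes, 0, cfg@noiseSd), nxy)
    img[, , z, ] <- array(slab, dim = c(d[1], d[2], tm@nVolumes))
  }
  tp <- cfg@templateParams
  truth <- new("GroundTruth", truePeakTimes = truePeaks,
               classMap = cfg@classMap,
               extremumTime = vapply(tp, function(p)
                 as.numeric(p$extremumTime), 0)[classes],
               extremumSign = vapply(tp, function(p)
                 as.numeric(p$sign), 0)[classes],
               amplitude = vapply(tp, function(p)
                 as.numeric(p$amplitude), 0)[classes],
               templateParams = tp)
  list(img = img, truth = truth, trace = trace)
}

#' Generate a complete synthetic dataset in memory
#'
#' Convenience wrapper: PPG trace plus 4D volume from one configuration,
#' fully deterministic under the configuration seed.
#'
#' @param cfg a [SimConfig-class].
#' @return A list with `trace`, `truePeakTimes`, `img`, `truth`, `config`.
#' @seealso [writeSimulatedDataset()] to emit the BIDS-like file layout.
#' @export
simulateDataset <- function(cfg = simConfig()) {
  ppg <- generatePPG(cfg)
  fm <- generateFmri(cfg, ppg$truePeakTimes)
  list(trace = ppg$trace, truePeakTimes = ppg$truePeakTimes, img = fm$img,
       truth = fm$truth, config = cfg)
}

#' Steady-state spoiled gradient-echo signal and its sensitivities
#'
#' The spoiled gradient-echo signal
#' `S = m0 sin(a) (1 - E1) / (1 - cos(a) E1) exp(-TE / T2*)` with
#' `E1 = exp(-TR / T1)`, and the analytic sensitivities `|dS/dT1|` and
#' `|dS/dT2*|`. Used to compare the T1 and T2* sensitivity of acquisition
#' protocols (the fast SMS protocol is more T1- and less T2*-sensitive than
#' a conventional resting-state protocol at reference tissue values).
#'
#' @param t1 longitudinal relaxation time (s).
#' @param t2star effective transverse relaxation time (s).
#' @param tr repetition time (s).
#' @param te echo time (s).
#' @param flipDeg flip angle in degrees, in (0, 180).
#' @param m0 equilibrium magnetization (default 1).
#' @return A list with `signal`, `dT1` (= |dS/dT1|) and `dT2star`
#'   (= |dS/dT2*|).
#' @examples
#' gradientEchoSignal(t1 = 1.3, t2star = 0.04, tr = 0.25, te = 0.0116,
#'                    flipDeg = 48)
#' @export
gradientEchoSignal <- function(t1, t2star, tr, te, flipDeg, m0 = 1) {
  if (any(c(t1, t2star, tr) <= 0) || te < 0)
    paStop("t1, t2star, tr must be positive and te non-negative",
           "pa_invalid_parameter")
  if (flipDeg <= 0 || flipDeg >= 180)
    paStop("flip angle must lie in (0, 180) degrees", "pa_invalid_parameter")
  a <- flipDeg * pi / 180
  E1 <- exp(-tr / t1)
  E2 <- exp(-te / t2star)
  f <- (1 - E1) / (1 - cos(a) * E1)
  S <- m0 * sin(a) * f * E2
  # dS/dT1 via dE1/dT1 = (tr / t1^2) E1 and df/dE1 = (cos(a) - 1)/(1 - cos(a) E1)^2
  dfdE1 <- (cos(a) - 1) / (1 - cos(a) * E1)^2
  dT1 <- m0 * sin(a) * E2 * dfdE1 * (tr / t1^2) * E1
  dT2 <- S * te / t2star^2
  list(signal = S, dT1 = abs(dT1), dT2star = abs(dT2))
}
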