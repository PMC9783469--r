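# PPG filtering, cycle estimation, peak detection and RMSSD

test_that("lowpass filter passes the band, kills stopband per Butterworth roll-off, preserves DC", {
  fs <- 100
  tt <- seq(0, 30, by = 1 / fs)
  # passband: 0.1 Hz sinusoid survives within 1% RMS
  tr <- PhysioTrace(sin(2 * pi * 0.1 * tt), fs)
  out <- lowpassFilter(tr, cutoff = 5, order = 3)
  mid <- seq(5 * fs, 25 * fs)   # steady-state section
  expect_lt(sqrt(mean((samples(out)[mid] - samples(tr)[mid])^2)) /
              sqrt(mean(samples(tr)[mid]^2)), 0.01)

  # stopband: 20 Hz sinusoid attenuated at least per two-pass 3rd-order
  # roll-off; oracle = squared Butterworth magnitude at the prewarped ratio
  tr20 <- PhysioTrace(sin(2 * pi * 20 * tt), fs)
  out20 <- lowpassFilter(tr20, cutoff = 5, order = 3)
  meas <- sqrt(mean(samples(out20)[mid]^2)) / sqrt(mean(samples(tr20)[mid]^2))
  r <- tan(pi * 20 / fs) / tan(pi * 5 / fs)   # bilinear prewarping
  oracle <- 1 / (1 + r^(2 * 3))               # |H|^2: forward + backward pass
  expect_lt(meas, 1 / (2 * (20 / 5)^3))       # at least the nominal roll-off
  expect_lt(abs(log(meas / oracle)), log(2))  # within 2x of the exact oracle

  # DC gain 1: constant in, same constant out
  trc <- PhysioTrace(rep(7.5, 500), fs)
  expect_equal(samples(lowpassFilter(trc)), rep(7.5, 500), tolerance = 1e-8)
})

test_that("lowpass filter is zero-phase on a symmetric pulse and validates input", {
  fs <- 100
  tt <- seq(0, 20, by = 1 / fs)
  pulse <- exp(-(tt - 10)^2 / (2 * 0.3^2))
  out <- lowpassFilter(PhysioTrace(pulse, fs))
  expect_lte(abs(which.max(samples(out)) - which.max(pulse)), 1)

  expect_error(lowpassFilter(PhysioTrace(pulse, fs), cutoff = 50),
               class = "pa_invalid_parameter")
  expect_error(lowpassFilter(PhysioTrace(pulse, fs), cutoff = 60),
               class = "pa_invalid_parameter")
  expect_error(lowpassFilter(PhysioTrace(rnorm(5), fs)),
               class = "pa_too_short")
})

test_that("autocorrelation cycle estimate recovers the period and rejects noise", {
  fs <- 100
  tt <- seq(0, 60, by = 1 / fs)
  train <- function(period) {
    ph <- (tt %% period) / period
    exp(-((ph - 0.5)^2) / (2 * 0.05^2))
  }
  expect_equal(estimateCycle(PhysioTrace(train(1), fs)), 1, tolerance = 0.01)

  set.seed(42)
  x <- train(60 / 72) + rnorm(length(tt), 0, 0.1)
  expect_equal(estimateCycle(PhysioTrace(x, fs)), 60 / 72, tolerance = 0.02)

  set.seed(43)
  expect_error(estimateCycle(PhysioTrace(rnorm(length(tt)), fs)),
               class = "pa_cycle_not_found")
  expect_error(estimateCycle(PhysioTrace(rep(1, length(tt)), fs)),
               class = "pa_cycle_not_found")
  expect_error(estimateCycle(PhysioTrace(train(1)[1:300], fs)),
               class = "pa_too_short")
})

test_that("peak detection recovers every generated beat to sample precision", {
  # jitter-free generator: one detected peak per true beat, within 1 sample
  cfg <- simConfig(jitterSd = 0, seed = 21)
  sim <- generatePPG(cfg, noiseSd = 0)
  pk <- detectPeaks(sim$trace)
  expect_gte(length(pk), 219)
  expect_lte(length(pk), 221)
  expect_equal(length(pk), length(sim$truePeakTimes))
  off <- peakOffsets(peakTimes(pk), sim$truePeakTimes)
  expect_lte(max(abs(off)), 1 / samplingRate(sim$trace) + 1e-9)

  # jittered + noisy: every peak within 20 ms, none missed or added
  cfgJ <- simConfig(jitterSd = 0.03, seed = 22)
  simJ <- generatePPG(cfgJ, noiseSd = 0.10)
  pkJ <- detectPeaks(simJ$trace)
  expect_equal(length(pkJ), length(simJ$truePeakTimes))
  offJ <- peakOffsets(peakTimes(pkJ), simJ$truePeakTimes)
  expect_lt(max(abs(offJ)), 0.020)
  expect_lt(abs(mean(offJ)), 0.005)   # near-zero bias

  expect_error(detectPeaks(PhysioTrace(rep(1, 5000), 100)),
               class = "pa_insufficient_beats")
})

test_that("peak detection is invariant to positive scaling and offsets", {
  sim <- generatePPG(simConfig(seed = 23), noiseSd = 0.05)
  pk0 <- detectPeaks(sim$trace)
  shifted <- PhysioTrace(3.7 * samples(sim$trace) + 120,
                         samplingRate(sim$trace))
  pk1 <- detectPeaks(shifted)
  expect_equal(peakTimes(pk1), peakTimes(pk0))
})

test_that("peak times are mapped to the fMRI clock via startTime", {
  sim <- generatePPG(simConfig(seed = 24), noiseSd = 0)
  tr <- PhysioTrace(samples(sim$trace), samplingRate(sim$trace),
                    startTime = -2.5)
  pk <- detectPeaks(tr)
  pk0 <- detectPeaks(sim$trace)
  expect_equal(peakTimes(pk), peakTimes(pk0) - 2.5, tolerance = 1e-9)
})

test_that("RMSSD matches hand-computed and analytic values", {
  # constant IBIs: zero RMSSD, passes
  pk <- PeakSeries(seq(0, 60, by = 1), cycleEstimate = 1)
  rep0 <- rmssdHrv(pk)
  expect_true(all(rep0@rmssd[!is.na(rep0@rmssd)] == 0))
  expect_identical(rep0@passes, TRUE)

  # IBIs 1.0, 1.1, 1.0 in one window: diffs 0.1, -0.1 -> RMSSD 100 ms, fails
  pk1 <- PeakSeries(c(0, 1, 2.1, 3.1), cycleEstimate = 1)
  rep1 <- rmssdHrv(pk1)
  expect_equal(rep1@maxRmssd, 100)
  expect_identical(rep1@passes, FALSE)

  # i.i.d. jitter sigma: RMSSD -> sigma * sqrt(2) within 15% at 200 beats
  set.seed(7)
  sigma <- 0.01
  pk2 <- PeakSeries(cumsum(c(0, 1 + rnorm(200, 0, sigma))), cycleEstimate = 1)
  rep2 <- rmssdHrv(pk2)
  bruteRmssd <- 1000 * sqrt(mean(diff(diff(peakTimes(pk2)))^2))
  expect_lt(abs(mean(rep2@rmssd, na.rm = TRUE) - 1000 * sigma * sqrt(2)) /
              (1000 * sigma * sqrt(2)), 0.15)
  expect_lt(rep2@maxRmssd, 50)
  expect_identical(rep2@passes, TRUE)
  # and the generator's own jitter passes the threshold on a full run
  sim <- generatePPG(simConfig(seed = 25))
  rep3 <- rmssdHrv(detectPeaks(sim$trace))
  expect_lt(rep3@maxRmssd, 50)
  expect_gt(sum(!is.na(rep3@rmssd)), 5)
  # brute-force check on one window of the hand case
  expect_equal(bruteRmssd, 1000 * sqrt(mean(diff(diff(peakTimes(pk2)))^2)))
})

test_that("windows with fewer than 3 peaks are flagged missing and excluded", {
  # 20 peaks in window 1, a single peak in window 2, many in window 3
  pk <- PeakSeries(c(0:19, 30, 41:60), cycleEstimate = 1)
  rep <- rmssdHrv(pk, windowLength = 20)
  expect_true(any(is.na(rep@rmssd)))
  expect_false(is.na(rep@maxRmssd))
  # 2 + 2 peaks: no window reaches 3 peaks
  expect_error(rmssdHrv(PeakSeries(c(0, 1, 30, 31), cycleEstimate = 1),
                        windowLength = 20),
               class = "pa_insufficient_beats")
})
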