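# percent modulation, slice timing, peak-relative binning and reliability

test_that("percent modulation drops volumes, zero-means and detrends", {
  out <- percentModulation(rep(500, 10), nDrop = 3)
  expect_length(out, 7)
  expect_equal(out, rep(0, 7), tolerance = 1e-12)

  x <- c(100, 100, 100, 100, 102, 98, 100)
  out2 <- percentModulation(x, nDrop = 3)
  expect_length(out2, 4)
  expect_equal(sum(out2), 0, tolerance = 1e-10)
  tIdx <- seq_along(out2)
  expect_equal(unname(coef(lm(out2 ~ tIdx))[2]), 0, tolerance = 1e-10)

  expect_error(percentModulation(c(1, 2, 3), nDrop = 3), class = "pa_too_short")
  expect_error(percentModulation(c(1, 2, 3, 4, 5), nDrop = 3),
               class = "pa_too_short")

  # background voxel (non-positive mean) is masked, not an error
  m <- rbind(rep(100, 10), rep(0, 10), c(rep(-5, 10)))
  pm <- percentModulation(m, nDrop = 3)
  expect_false(anyNA(pm[1, ]))
  expect_true(all(is.na(pm[2, ])))
  expect_true(all(is.na(pm[3, ])))

  # a pure linear drift on a positive baseline detrends to ~zero
  drift <- 100 + 0.01 * (0:99)
  expect_lt(max(abs(percentModulation(drift, nDrop = 3))), 1e-8)
})

test_that("SMS slice offsets reproduce the acquisition geometries", {
  tm <- sliceOffsetsSMS(0.25, 40, 8, nVolumes = 878)
  expect_equal(sort(unique(sliceOffsets(tm))), c(0, 0.05, 0.10, 0.15, 0.20))
  expect_equal(tm@sliceDuration, 0.05)
  # slices of one multiband group share an offset: 8 slices per group
  expect_true(all(table(sliceOffsets(tm)) == 8))

  tm2 <- sliceOffsetsSMS(2, 45, 1, nVolumes = 240)
  expect_length(unique(sliceOffsets(tm2)), 45)
  expect_equal(unique(round(diff(sort(sliceOffsets(tm2))), 6)),
               round(2 / 45, 6))
  expect_equal(tm2@sliceDuration, 2 / 45, tolerance = 1e-12)

  tm3 <- sliceOffsetsSMS(1, 6, 6, nVolumes = 10)
  expect_true(all(sliceOffsets(tm3) == 0))

  expect_error(sliceOffsetsSMS(1, 7, 2), class = "pa_geometry_error")
})

test_that("zero-referenced R2 matches its displayed formula", {
  expect_equal(reliabilityR2(c(3, 4), c(3, 4)), 100)
  expect_equal(reliabilityR2(c(3, 4), c(0, 0)), 0)
  expect_equal(reliabilityR2(c(3, 4), c(3, 0)), 36)
  expect_equal(reliabilityR2(c(3, 4), c(-3, -4)), -300)
  expect_true(is.na(reliabilityR2(c(0, 0), c(1, 2))))
  expect_error(reliabilityR2(1:3, 1:2), class = "pa_invalid_parameter")
})

test_that("binned waveform reproduces a beat-locked sinusoid at any slice offset", {
  # the core correctness oracle: with a perfectly periodic heartbeat the
  # sampling comb lands on bin centers, so a noiseless cosine of the
  # cardiac phase is reproduced exactly at the populated bins
  pkT <- seq(0.5, 219.5, by = 1)
  pk <- PeakSeries(pkT, cycleEstimate = 1, bounds = c(0, 220))
  tm <- sliceOffsetsSMS(0.25, 40, 8, nVolumes = 878)
  for (z in c(1L, 2L, 3L, 4L, 5L)) {     # one slice per acquisition group
    tt <- seq.int(3, tm@nVolumes - 1) * tm@tr + sliceOffsets(tm)[z]
    i0 <- pmax(findInterval(tt, pkT), 1L)
    frac <- tt - pkT[i0]
    vox <- new("VoxelSeries", values = cos(2 * pi * frac),
               acquisitionTimes = tt, voxelIndex = c(0L, 0L, z - 1L))
    ar <- alignToPeaks(vox, pk, tm)
    use <- ar@countsEven > 0
    expect_lt(max(abs(ar@evenMean[use] -
                        cos(2 * pi * ar@binCentersFrac[use]))), 0.01)
    expect_gt(ar@r2, 99)
  }
  # with a drifting heart every bin fills and the waveform still tracks the
  # cosine to within the in-bin averaging error
  cfg <- simConfig(seed = 31)
  ppg <- generatePPG(cfg, noiseSd = 0)
  pkd <- PeakSeries(ppg$truePeakTimes, cycleEstimate = 1,
                    bounds = c(0, cfg@duration))
  tt <- seq.int(3, 877) * 0.25
  i0 <- pmax(findInterval(tt, ppg$truePeakTimes), 1L)
  vox <- new("VoxelSeries", values = cos(2 * pi * (tt - ppg$truePeakTimes[i0])),
             acquisitionTimes = tt)
  ar <- alignToPeaks(vox, pkd, tm)
  expect_true(all(ar@countsEven > 0))
  expect_lt(max(abs(ar@evenMean - cos(2 * pi * ar@binCentersFrac))), 0.05)
  expect_gt(ar@r2, 99)
})

test_that("a 50 ms window and a 1 s heartbeat give 20 bins per cycle", {
  cfg <- simConfig(seed = 31)
  ppg <- generatePPG(cfg, noiseSd = 0)
  pk <- PeakSeries(ppg$truePeakTimes, cycleEstimate = 1)
  tm <- cfg@timing
  tt <- seq.int(3, tm@nVolumes - 1) * tm@tr
  vox <- new("VoxelSeries", values = sin(tt), acquisitionTimes = tt)
  ar <- alignToPeaks(vox, pk, tm)
  core <- ar@binCentersFrac >= 0 & ar@binCentersFrac < 1
  expect_equal(sum(core), 20)
  expect_equal(length(ar@binCentersS), 31)  # centers spanning [-0.5, 1.0]
})

test_that("pure-noise voxels score far below the reliability threshold", {
  sh <- sharedSim()
  r2null <- r2Values(sh$ca)[sh$cls == "null"]
  r2null <- r2null[!is.na(r2null)]
  expect_gt(length(r2null), 100)
  # independent oracle: R2 of two i.i.d. noise vectors concentrates near
  # -100 (E[SSres] = 2 E[SSdata]); far below any reliability threshold
  set.seed(99)
  oracle <- replicate(2000, reliabilityR2(rnorm(30), rnorm(30)))
  expect_lt(abs(median(oracle) - (-100)), 15)
  expect_gte(mean(r2null < 30), 0.95)
  expect_lt(median(r2null), -50)
})

test_that("every sample lands in at most two beat windows and counts add up", {
  # brute-force assignment count oracle on a small case
  set.seed(5)
  pkT <- cumsum(c(2, 1 + rnorm(30, 0, 0.02)))
  pk <- PeakSeries(pkT, cycleEstimate = 1)
  tm <- AcquisitionTiming(tr = 0.25, sliceOffsets = 0, sliceDuration = 0.05,
                          nVolumes = 140)
  tt <- seq.int(3, 139) * 0.25
  vox <- new("VoxelSeries", values = rnorm(length(tt)),
             acquisitionTimes = tt)
  ar <- alignToPeaks(vox, pk, tm)
  brute <- sum(vapply(tt, function(t) {
    rel <- (t - pkT)
    sum(rel >= -0.5 & rel < 1.0)
  }, numeric(1)))
  expect_equal(sum(ar@countsEven) + sum(ar@countsOdd), brute)
  maxPerSample <- max(vapply(tt, function(t) {
    rel <- (t - pkT)
    sum(rel >= -0.5 & rel < 1.0)
  }, numeric(1)))
  expect_lte(maxPerSample, 2)
})

test_that("swapping the even/odd convention barely moves reliable-voxel r2", {
  # needs a long run (>= 400 beats) so each half is well averaged
  cfg <- simConfig(grid = c(2L, 2L, 40L), duration = 440, seed = 33)
  sim <- simulateDataset(cfg)
  ca <- alignVolume(sim$img, detectPeaks(sim$trace), cfg@timing)
  cls <- rowClasses(ca, sim$truth)
  a <- SummarizedExperiment::assays(ca)
  r2 <- r2Values(ca)
  swap <- vapply(seq_len(nrow(ca)), function(i) {
    y <- as.numeric(a$oddMean[i, ]); f <- as.numeric(a$evenMean[i, ])
    ok <- is.finite(y) & is.finite(f)
    if (sum(ok) < 2 || sum(y[ok]^2) == 0) return(NA_real_)
    reliabilityR2(y[ok], f[ok])
  }, numeric(1))
  rel <- which(!is.na(r2) & r2 > 50)
  expect_gt(length(rel), 50)
  # the typical reliable voxel moves by a few points; individual voxels can
  # move more because swapping exchanges the reference power sum(y^2)
  expect_lt(median(abs(swap[rel] - r2[rel])), 5)
  expect_lt(quantile(abs(swap[rel] - r2[rel]), 0.95), 15)
  nul <- which(cls == "null" & !is.na(r2))
  expect_lt(abs(median(swap[nul]) - median(r2[nul])), 15)
})

test_that("volume alignment validates geometry and masks degenerate input", {
  sh <- sharedSim()
  cfg <- sh$cfg
  expect_error(alignVolume(sh$sim$img[, , 1:10, ], sh$peaks, cfg@timing),
               class = "pa_geometry_error")
  expect_error(alignVolume(sh$sim$img[, , , 1:100], sh$peaks, cfg@timing),
               class = "pa_geometry_error")
  badMask <- array(TRUE, dim = c(2, 2, 2))
  expect_error(alignVolume(sh$sim$img, sh$peaks, cfg@timing, mask = badMask),
               class = "pa_geometry_error")

  zeroImg <- array(0, dim = c(2, 2, 40, 878))
  caz <- alignVolume(zeroImg, sh$peaks, cfg@timing)
  expect_true(all(is.na(r2Values(caz))))
  expect_true(all(!SummarizedExperiment::rowData(caz)$valid))

  # mask restricts the rows
  msk <- array(FALSE, dim = cfg@grid)
  msk[1, 1, ] <- TRUE
  cam <- alignVolume(sh$sim$img, sh$peaks, cfg@timing, mask = msk)
  expect_equal(nrow(cam), 40L)
})

test_that("template voxels are reliable and core bins fully covered at study scale", {
  sh <- sharedSim()
  r2 <- r2Values(sh$ca)
  expect_true(all(SummarizedExperiment::rowData(sh$ca)$coreComplete))
  med <- tapply(r2, sh$cls, median, na.rm = TRUE)
  expect_gt(med[["artery"]], 50)
  expect_gt(med[["vein"]], 50)
  expect_gt(med[["csf"]], 50)
  # generator labels separate reliable template voxels from null voxels
  expect_gt(mean(r2[sh$cls != "null"] > 50, na.rm = TRUE), 0.8)
  expect_gt(mean(r2[sh$cls == "null"] < 30, na.rm = TRUE), 0.95)
})

test_that("resting-state geometry recovers template signs", {
  # conventional sequential acquisition: TR 2 s, 45 slices, 240 volumes;
  # heart rate 66 bpm (a realistic, TR-incommensurate rate). Each slice is
  # sampled only once per 2 s here, so per-bin averages pool ~6 samples;
  # noise is set so the shape (not just the noise) dominates the bins, as
  # in the well-averaged resting recordings this geometry mimics.
  tm <- sliceOffsetsSMS(2, 45, 1, nVolumes = 240)
  cfg <- simConfig(heartRate = 66, duration = 480, grid = c(2L, 2L, 45L),
                   timing = tm, noiseSd = 0.5, seed = 41)
  sim <- simulateDataset(cfg)
  pk <- detectPeaks(sim$trace)
  ca <- alignVolume(sim$img, pk, tm)
  cls <- rowClasses(ca, sim$truth)
  a <- SummarizedExperiment::assays(ca)
  r2 <- r2Values(ca)
  sel <- which(cls %in% c("artery", "csf") & !is.na(r2) & r2 > 30)
  expect_gt(length(sel), 20)
  signs <- vapply(sel, function(i) {
    y <- as.numeric(a$evenMean[i, ])
    y[!is.finite(y)] <- 0
    if (abs(max(y)) >= abs(min(y))) 1 else -1
  }, numeric(1))
  want <- ifelse(cls[sel] == "csf", 1, -1)
  expect_gt(mean(signs == want), 0.9)
})
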