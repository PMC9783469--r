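# shared fixtures, all generated in code

# a small but fully realistic SMS dataset, shared across test files
smallSimConfig <- function(seed = 11, ...) {
  simConfig(grid = c(4L, 4L, 40L), seed = seed, ...)
}

# simulate + align once per session; reused by alignment/model/roi tests
sharedSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- smallSimConfig()
      sim <- simulateDataset(cfg)
      pk <- detectPeaks(sim$trace)
      ca <- alignVolume(sim$img, pk, cfg@timing)
      rd <- SummarizedExperiment::rowData(ca)
      cls <- sim$truth@classMap[cbind(rd$i + 1, rd$j + 1, rd$k + 1)]
      cache <<- list(cfg = cfg, sim = sim, peaks = pk, ca = ca, cls = cls)
    }
    cache
  }
})

# voxel classes of a CardiacAlignment's rows against a GroundTruth
rowClasses <- function(ca, truth) {
  rd <- SummarizedExperiment::rowData(ca)
  truth@classMap[cbind(rd$i + 1, rd$j + 1, rd$k + 1)]
}

# match each detected peak to the nearest true peak; returns offsets (s)
peakOffsets <- function(detected, truth) {
  vapply(detected, function(t) {
    d <- t - truth
    d[which.min(abs(d))]
  }, numeric(1))
}

# a class template minus its full-cycle mean: percent modulation zero-means
# every voxel series, so aligned waveforms estimate the centered template
centeredTemplate <- function(class, grid) {
  w <- waveformTemplate(class)
  w(grid) - mean(w(seq(0, 1, length.out = 2048)))
}

# orthonormalized pair of skewed-transient components on a grid
# (used by the rank-2 model tests and the acceptance checks)
canonicalPair <- function(grid = cycleFractionGrid()) {
  a <- waveformTemplate("artery")(grid)
  b <- waveformTemplate("csf")(grid)
  u1 <- a / sqrt(sum(a^2))
  b2 <- b - sum(b * u1) * u1
  u2 <- b2 / sqrt(sum(b2^2))
  cbind(u1, u2)
}

# rank-2 even/odd waveform pair with noise calibrated (closed form) so the
# median even/odd zero-referenced R2 is near `targetR2`
rank2Halves <- function(nVox = 2000, grid = cycleFractionGrid(),
                        targetR2 = 70, seed = 1) {
  set.seed(seed)
  U <- canonicalPair(grid)
  B <- cbind(rnorm(nVox, 0, 1), rnorm(nVox, 0, 0.5))
  S <- B %*% t(U)
  G <- length(grid)
  P <- median(rowSums(S^2))
  sigma <- sqrt(P * (100 - targetR2) / (G * (100 + targetR2)))
  list(signal = S,
       even = S + matrix(rnorm(nVox * G, 0, sigma), nVox),
       odd = S + matrix(rnorm(nVox * G, 0, sigma), nVox),
       components = U, betasTrue = B, sigma = sigma)
}
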