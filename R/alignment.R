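#' @include physio.R
NULL

#' Percent modulation with linear detrending
#'
#' Drops the first `nDrop` volumes, converts the remaining series to percent
#' modulation around its temporal mean, `100 * (x - mean) / mean`, and
#' removes the least-squares linear trend. The output has zero mean and zero
#' linear trend. A voxel whose temporal mean is zero or negative (background)
#' is masked (all-NA output), not an error.
#'
#' @param x numeric vector (one voxel's raw series) or a matrix with one row
#'   per voxel and one column per volume.
#' @param nDrop number of initial volumes to discard (default 3).
#' @return The same shape as `x` minus the dropped volumes; masked rows/
#'   vectors are NA.
#' @examples
#' percentModulation(c(100, 100, 100, 100, 102, 98, 100))
#' @export
percentModulation <- function(x, nDrop = 3) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) <= nDrop + 2)
    paStop(sprintf("series length must exceed nDrop + 2 = %d", nDrop + 2),
           "pa_too_short")
  X <- X[, (nDrop + 1):ncol(X), drop = FALSE]
  m <- rowMeans(X)
  bad <- !is.finite(m) | m <= 0
  pm <- 100 * (X / m - 1)
  # least-squares line removal, all rows at once
  nT <- ncol(X)
  D <- cbind(1, seq_len(nT))
  beta <- solve(crossprod(D), crossprod(D, t(pm)))   # 2 x voxels
  pm <- pm - t(D %*% beta)
  pm[bad, ] <- NA_real_
  if (vec) as.numeric(pm) else pm
}

#' Slice offsets for SMS (multiband) and sequential acquisitions
#'
#' Builds the [AcquisitionTiming-class] for an acquisition of `nSlices`
#' slices measured in `nSlices / mbFactor` simultaneous groups: group g
#' (0-based) is acquired at offset `g * tr / nGroups`, slice s belongs to
#' group `s %% nGroups`, and each group occupies one acquisition window of
#' `tr / nGroups` seconds. `mbFactor = 1` yields an ascending sequential
#' acquisition.
#'
#' @param tr repetition time (s).
#' @param nSlices number of slices; must be divisible by `mbFactor`.
#' @param mbFactor multiband (simultaneous-slice) factor.
#' @param nVolumes number of volumes in the run.
#' @return An [AcquisitionTiming-class].
#' @examples
#' sliceOffsetsSMS(0.25, 40, 8, nVolumes = 878)  # 5 groups, 50 ms windows
#' @export
sliceOffsetsSMS <- function(tr, nSlices, mbFactor, nVolumes = 1L) {
  if (nSlices %% mbFactor != 0)
    paStop("nSlices must be divisible by mbFactor", "pa_geometry_error")
  nGroups <- nSlices %/% mbFactor
  sliceDur <- tr / nGroups
  offsets <- ((seq_len(nSlices) - 1L) %% nGroups) * sliceDur
  AcquisitionTiming(tr = tr, sliceOffsets = offsets,
                    sliceDuration = sliceDur, nVolumes = nVolumes)
}

#' Construct a VoxelSeries from a raw voxel time course
#'
#' Convenience constructor: applies [percentModulation()] and attaches the
#' acquisition time of each retained volume (volume start + the voxel's
#' slice offset).
#'
#' @param raw raw voxel series, one value per volume.
#' @param timing an [AcquisitionTiming-class]; `timing@nVolumes` must equal
#'   `length(raw)`.
#' @param slice 0-based slice index of the voxel.
#' @param voxelIndex 0-based integer(3) grid position.
#' @param nDrop initial volumes to discard (default 3).
#' @return A [VoxelSeries-class] (values NA if the voxel is masked).
#' @export
voxelSeries <- function(raw, timing, slice, voxelIndex = c(0L, 0L, 0L),
                        nDrop = 3) {
  stopifnot(is(timing, "AcquisitionTiming"))
  if (length(raw) != timing@nVolumes)
    paStop("length(raw) must equal timing@nVolumes", "pa_geometry_error")
  vals <- percentModulation(raw, nDrop = nDrop)
  tt <- (seq.int(nDrop, timing@nVolumes - 1L)) * timing@tr +
    timing@sliceOffsets[slice + 1L]
  new("VoxelSeries", values = vals, acquisitionTimes = tt,
      voxelIndex = as.integer(voxelIndex))
}

#' Zero-referenced reliability R-squared
#'
#' The test-retest reliability between the even-beat (`even`, y) and
#' odd-beat (`odd`, f) average waveforms,
#' `100 * (1 - sum((y - f)^2) / sum(y^2))`. The reference is zero rather
#' than the mean (the percent-modulation waveforms are already zero-mean, so
#' a mean reference would be arbitrary). The score is at most 100 and
#' unbounded below. Pairs with a missing value in either half are dropped
#' (pairwise-complete). If `sum(y^2)` is zero the reliability is undefined
#' and NA is returned (the voxel is masked).
#'
#' @param even,odd equal-length numeric vectors of per-bin amplitudes.
#' @return The reliability score (or NA).
#' @examples
#' reliabilityR2(c(3, 4), c(3, 0))  # 100 * (1 - 16/25) = 36
#' @export
reliabilityR2 <- function(even, odd) {
  if (length(even) != length(odd))
    paStop("even and odd must have equal length", "pa_invalid_parameter")
  use <- is.finite(even) & is.finite(odd)
  y <- even[use]; f <- odd[use]
  if (length(y) < 2L)
    paStop("need at least 2 complete bins", "pa_too_short")
  ssData <- sum(y^2)
  if (ssData == 0) return(NA_real_)
  100 * (1 - sum((y - f)^2) / ssData)
}

# Assign each sample time to (peak, bin, parity) triples. A sample
# contributes to every peak whose window contains it; with the default
# window (-0.5, 1.0) that is at most two peaks. Bins are fixed-width
# (sliceDuration) intervals in seconds relative to each peak, with centers
# on the multiples of the slice duration so that an acquisition grid
# commensurate with the heartbeat lands on bin centers. Samples past a
# beat's own interval still land in the late bins of that beat (no
# censoring at the next peak). Returns parallel vectors.
.assignSamples <- function(times, pk, cycle, window, sliceDur) {
  lo <- window[1] * cycle
  hi <- window[2] * cycle
  nb <- as.integer(floor((hi - lo) / sliceDur + 1e-9)) + 1L
  i0 <- findInterval(times, pk)
  sample <- integer(0); bin <- integer(0); even <- logical(0)
  for (shift in -2:1) {
    j <- i0 + shift
    valid <- j >= 1L & j <= length(pk)
    rel <- rep(NA_real_, length(times))
    rel[valid] <- times[valid] - pk[j[valid]]
    keep <- valid & rel >= lo & rel < hi
    if (!any(keep)) next
    b <- as.integer(round((rel[keep] - lo) / sliceDur)) + 1L
    b[b > nb] <- nb
    sample <- c(sample, which(keep))
    bin <- c(bin, b)
    even <- c(even, (j[keep] - 1L) %% 2L == 0L)
  }
  list(sample = sample, bin = bin, even = even, nBins = nb,
       binCentersS = lo + (seq_len(nb) - 1L) * sliceDur)
}

#' Align one voxel's samples to heartbeat peaks
#'
#' Assigns every retained sample its time relative to each heartbeat peak
#' whose epoch window (default cycle fraction -0.5 to +1.0) contains it,
#' pools the samples into fixed-width bins (one slice-acquisition window
#' wide, in seconds relative to the peak), and averages separately over
#' even- and odd-indexed beats. The zero-referenced reliability R² between
#' the two averages is computed over bins populated in both halves.
#'
#' @param voxel a [VoxelSeries-class].
#' @param peaks a [PeakSeries-class] with at least 10 peaks.
#' @param timing an [AcquisitionTiming-class] (provides the bin width).
#' @param window epoch window in cycle fraction, default `c(-0.5, 1)`.
#' @return An [AlignedResponse-class]; `r2` is NA when the voxel is masked
#'   (all bins missing or zero data power).
#' @export
alignToPeaks <- function(voxel, peaks, timing, window = c(-0.5, 1)) {
  stopifnot(is(voxel, "VoxelSeries"), is(peaks, "PeakSeries"),
            is(timing, "AcquisitionTiming"))
  if (length(peaks) < 10L)
    paStop("need at least 10 heartbeat peaks", "pa_insufficient_beats")
  cycle <- peaks@cycleEstimate
  asg <- .assignSamples(voxel@acquisitionTimes, peaks@peakTimes, cycle,
                        window, timing@sliceDuration)
  nb <- asg$nBins
  v <- voxel@values
  col <- ifelse(asg$even, 1L, 2L)
  ok <- is.finite(v[asg$sample])
  sums <- counts <- matrix(0, nb, 2)  # columns: even, odd
  for (p in 1:2) {
    sel <- which(col == p & ok)
    if (length(sel)) {
      b <- asg$bin[sel]
      vv <- v[asg$sample[sel]]
      sums[, p] <- vapply(seq_len(nb), function(bb) sum(vv[b == bb]), 0)
      counts[, p] <- tabulate(b, nbins = nb)
    }
  }
  evenMean <- ifelse(counts[, 1] > 0, sums[, 1] / counts[, 1], NaN)
  oddMean <- ifelse(counts[, 2] > 0, sums[, 2] / counts[, 2], NaN)
  centers <- asg$binCentersS
  frac <- centers / cycle
  core <- frac >= 0 & frac < 1
  complete <- all(counts[core, ] > 0)
  both <- counts[, 1] > 0 & counts[, 2] > 0
  r2 <- if (sum(both) >= 2 && any(is.finite(v)))
    reliabilityR2(evenMean[both], oddMean[both]) else NA_real_
  new("AlignedResponse", binCentersS = centers, binCentersFrac = frac,
      evenMean = evenMean, oddMean = oddMean,
      countsEven = counts[, 1], countsOdd = counts[, 2],
      r2 = r2, cycleEstimate = cycle, window = as.numeric(window),
      coreComplete = complete)
}

#' Align a whole 4D volume to heartbeat peaks
#'
#' Vectorized application of the cardiac alignment across all in-mask
#' voxels: per slice, the retained volumes are converted to percent
#' modulation, detrended, and pooled into even/odd per-bin averages using
#' that slice's acquisition offset. Returns a [CardiacAlignment-class]
#' (a `SummarizedExperiment`) with one row per voxel and one column per bin.
#' The per-voxel reliability `r2` is set to NA (masked) for background
#' voxels (non-positive mean) and for slices whose core-cycle bins
#' (fraction 0-1) are not fully populated in both halves.
#'
#' @param fmri 4D numeric array (or `RNifti` image) x-y-slice-volume.
#' @param peaks a [PeakSeries-class].
#' @param timing an [AcquisitionTiming-class]; `nVolumes` must match
#'   `dim(fmri)[4]` and `nSlices` must match `dim(fmri)[3]`.
#' @param mask optional 3D logical array on the same grid.
#' @param window epoch window in cycle fraction, default `c(-0.5, 1)`.
#' @param nDrop initial volumes to discard (default 3).
#' @return A [CardiacAlignment-class].
#' @examples
#' \donttest{
#' sim <- simulateDataset(simConfig(grid = c(4L, 4L, 4L),
#'   timing = sliceOffsetsSMS(0.25, 4, 1, 400), duration = 110, seed = 1))
#' ca <- alignVolume(sim$img, detectPeaks(sim$trace), sim$config@timing)
#' }
#' @export
alignVolume <- function(fmri, peaks, timing, mask = NULL,
                        window = c(-0.5, 1), nDrop = 3) {
  stopifnot(is(peaks, "PeakSeries"), is(timing, "AcquisitionTiming"))
  fmri <- unclass(fmri)
  d <- dim(fmri)
  if (length(d) != 4L)
    paStop("fmri must be a 4D array", "pa_geometry_error")
  if (d[4] != timing@nVolumes)
    paStop(sprintf("fmri has %d volumes but timing declares %d",
                   d[4], timing@nVolumes), "pa_geometry_error")
  if (d[3] != timing@nSlices)
    paStop(sprintf("fmri has %d slices but timing declares %d",
                   d[3], timing@nSlices), "pa_geometry_error")
  if (!is.null(mask) && !identical(dim(mask), d[1:3]))
    paStop("mask grid does not match the fMRI grid", "pa_geometry_error")
  if (length(peaks) < 10L)
    paStop("need at least 10 heartbeat peaks", "pa_insufficient_beats")
  cycle <- peaks@cycleEstimate
  nxy <- d[1] * d[2]
  tIdx <- seq.int(nDrop, d[4] - 1L)
  em <- om <- ce <- co <- NULL
  rows <- list()
  for (z in seq_len(d[3])) {
    sel <- if (is.null(mask)) rep(TRUE, nxy) else as.vector(mask[, , z])
    if (!any(sel)) next
    X <- matrix(fmri[, , z, ], nrow = nxy)[sel, , drop = FALSE]
    pm <- percentModulation(X, nDrop = nDrop)
    times <- tIdx * timing@tr + timing@sliceOffsets[z]
    asg <- .assignSamples(times, peaks@peakTimes, cycle, window,
                          timing@sliceDuration)
    nb <- asg$nBins
    # indicator matrices: samples x bins, one per parity
    Aev <- matrix(0, length(times), nb)
    Aod <- matrix(0, length(times), nb)
    ie <- asg$even
    Aev[cbind(asg$sample[ie], asg$bin[ie])] <-
      Aev[cbind(asg$sample[ie], asg$bin[ie])] + 1
    Aod[cbind(asg$sample[!ie], asg$bin[!ie])] <-
      Aod[cbind(asg$sample[!ie], asg$bin[!ie])] + 1
    nEv <- colSums(Aev); nOd <- colSums(Aod)
    pm0 <- pm; pm0[!is.finite(pm0)] <- 0
    evMean <- sweep(pm0 %*% Aev, 2, pmax(nEv, 1), "/")
    odMean <- sweep(pm0 %*% Aod, 2, pmax(nOd, 1), "/")
    evMean[, nEv == 0] <- NaN
    odMean[, nOd == 0] <- NaN
    masked <- !is.finite(pm[, 1])
    evMean[masked, ] <- NaN
    odMean[masked, ] <- NaN
    frac <- asg$binCentersS / cycle
    core <- frac >= 0 & frac < 1
    complete <- all(nEv[core] > 0) && all(nOd[core] > 0)
    both <- nEv > 0 & nOd > 0
    r2 <- rep(NA_real_, nrow(evMean))
    if (sum(both) >= 2) {
      y <- evMean[, both, drop = FALSE]
      f <- odMean[, both, drop = FALSE]
      ssData <- rowSums(y^2)
      ssRes <- rowSums((y - f)^2)
      r2 <- ifelse(is.finite(ssData) & ssData > 0,
                   100 * (1 - ssRes / ssData), NA_real_)
    }
    if (!complete) r2[] <- NA_real_
    vox <- which(sel) - 1L
    rows[[z]] <- list(
      i = vox %% d[1], j = vox %/% d[1], k = rep(z - 1L, length(vox)),
      r2 = r2, valid = !masked, complete = rep(complete, length(vox)),
      evMean = evMean, odMean = odMean,
      cEv = matrix(nEv, nrow(evMean), nb, byrow = TRUE),
      cOd = matrix(nOd, nrow(evMean), nb, byrow = TRUE),
      centers = asg$binCentersS)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    paStop("no in-mask voxels", "pa_geometry_error")
  centers <- rows[[1]]$centers
  rowDat <- S4Vectors::DataFrame(
    i = unlist(lapply(rows, `[[`, "i")),
    j = unlist(lapply(rows, `[[`, "j")),
    k = unlist(lapply(rows, `[[`, "k")),
    slice = unlist(lapply(rows, `[[`, "k")),
    r2 = unlist(lapply(rows, `[[`, "r2")),
    valid = unlist(lapply(rows, `[[`, "valid")),
    coreComplete = unlist(lapply(rows, `[[`, "complete")))
  frac <- centers / cycle
  colDat <- S4Vectors::DataFrame(binCenterS = centers, binCenterFrac = frac,
                                 core = frac >= 0 & frac < 1)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(
      evenMean = do.call(rbind, lapply(rows, `[[`, "evMean")),
      oddMean = do.call(rbind, lapply(rows, `[[`, "odMean")),
      countsEven = do.call(rbind, lapply(rows, `[[`, "cEv")),
      countsOdd = do.call(rbind, lapply(rows, `[[`, "cOd"))),
    rowData = rowDat, colData = colDat,
    metadata = list(cycleEstimate = cycle, window = as.numeric(window),
                    timing = timing, dim3 = d[1:3], nDrop = nDrop))
  new("CardiacAlignment", se)
}

#' Extract one voxel's AlignedResponse from a CardiacAlignment
#'
#' @param ca a [CardiacAlignment-class].
#' @param row row index (voxel) in `ca`.
#' @return An [AlignedResponse-class].
#' @export
alignedResponse <- function(ca, row) {
  stopifnot(is(ca, "CardiacAlignment"))
  md <- S4Vectors::metadata(ca)
  cd <- SummarizedExperiment::colData(ca)
  rd <- SummarizedExperiment::rowData(ca)
  a <- SummarizedExperiment::assays(ca)
  new("AlignedResponse",
      binCentersS = cd$binCenterS, binCentersFrac = cd$binCenterFrac,
      evenMean = as.numeric(a$evenMean[row, ]),
      oddMean = as.numeric(a$oddMean[row, ]),
      countsEven = as.numeric(a$countsEven[row, ]),
      countsOdd = as.numeric(a$countsOdd[row, ]),
      r2 = rd$r2[row], cycleEstimate = md$cycleEstimate,
      window = md$window, coreComplete = rd$coreComplete[row])
}
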