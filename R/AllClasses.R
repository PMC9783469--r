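#' @import methods
#' @importFrom stats approx coef fft lm median quantile rnorm sd setNames var IQR
#' @importFrom utils read.table write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment rowData colData assays
#' @importFrom S4Vectors DataFrame metadata
NULL

# structured error helper: every user-facing failure carries a condition class
# so callers (and the CLI) can dispatch on the error kind.
paStop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "pulseAlign_error")))
}

#' PhysioTrace: a uniformly sampled physiological recording
#'
#' Holds one channel of a physiological recording (typically the
#' photoplethysmography signal from a fingertip pulse oximeter), with its
#' sampling rate and the time offset of the first sample relative to the
#' first fMRI volume (the shared clock used throughout the package).
#'
#' @slot samples numeric vector of amplitudes (arbitrary units).
#' @slot samplingRate sampling frequency in Hz (> 0).
#' @slot startTime time of the first sample in seconds on the fMRI clock;
#'   may be negative when the recording starts before the first volume.
#' @slot channel one of `"ppg"`, `"ecg"`, `"respiration"`.
#' @export
setClass("PhysioTrace",
  representation(samples = "numeric", samplingRate = "numeric",
                 startTime = "numeric", channel = "character"),
  prototype(startTime = 0, channel = "ppg"),
  validity = function(object) {
    msg <- NULL
    if (length(object@samples) == 0L)
      msg <- c(msg, "samples must be non-empty")
    if (!all(is.finite(object@samples)))
      msg <- c(msg, "all samples must be finite")
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
      msg <- c(msg, "samplingRate must be a single positive number")
    if (length(object@startTime) != 1L || !is.finite(object@startTime))
      msg <- c(msg, "startTime must be a single finite number")
    if (!object@channel %in% c("ppg", "ecg", "respiration"))
      msg <- c(msg, "channel must be one of 'ppg', 'ecg', 'respiration'")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a PhysioTrace
#'
#' @param samples numeric amplitudes.
#' @param samplingRate sampling frequency in Hz.
#' @param startTime seconds of sample 1 relative to fMRI volume 1 (default 0).
#' @param channel channel type, default `"ppg"`.
#' @return A [PhysioTrace-class] object.
#' @examples
#' tr <- PhysioTrace(sin(2 * pi * seq(0, 10, by = 0.01)), samplingRate = 100)
#' duration(tr)
#' @export
PhysioTrace <- function(samples, samplingRate, startTime = 0, channel = "ppg") {
  new("PhysioTrace", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate),
      startTime = as.numeric(startTime), channel = channel)
}

#' PeakSeries: detected heartbeat peak times
#'
#' Heartbeat (systolic PPG) peak times on the fMRI clock together with the
#' autocorrelation-derived heartbeat period. Peak indexing starts at 0 in
#' time order; the even half is indices 0, 2, 4, ... (the convention used for
#' the even/odd split throughout).
#'
#' @slot peakTimes strictly increasing peak times in seconds (fMRI clock).
#' @slot cycleEstimate heartbeat period in seconds from the autocorrelation.
#' @slot bounds numeric(2), start/end of the recording the peaks came from
#'   (used to exclude incomplete edge beats from HRV windows); may be NA.
#' @export
setClass("PeakSeries",
  representation(peakTimes = "numeric", cycleEstimate = "numeric",
                 bounds = "numeric"),
  prototype(bounds = c(NA_real_, NA_real_)),
  validity = function(object) {
    msg <- NULL
    if (length(object@peakTimes) < 2L)
      msg <- c(msg, "need at least 2 peaks")
    d <- diff(object@peakTimes)
    if (any(d <= 0))
      msg <- c(msg, "peakTimes must be strictly increasing")
    if (length(object@cycleEstimate) != 1L || !is.finite(object@cycleEstimate) ||
        object@cycleEstimate <= 0)
      msg <- c(msg, "cycleEstimate must be a single positive number")
    else if (length(d) && min(d) < 0.7 * object@cycleEstimate - 1e-9)
      msg <- c(msg, "consecutive peaks closer than 70% of the cycle estimate")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a PeakSeries
#'
#' @param peakTimes strictly increasing seconds on the fMRI clock.
#' @param cycleEstimate heartbeat period in seconds.
#' @param bounds optional numeric(2) recording start/end on the same clock.
#' @return A [PeakSeries-class] object.
#' @export
PeakSeries <- function(peakTimes, cycleEstimate,
                       bounds = c(NA_real_, NA_real_)) {
  new("PeakSeries", peakTimes = as.numeric(peakTimes),
      cycleEstimate = as.numeric(cycleEstimate), bounds = as.numeric(bounds))
}

#' HrvReport: ultrashort-window RMSSD heart-rate variability
#'
#' RMSSD (root mean square of successive inter-beat-interval differences) per
#' contiguous non-overlapping window, the maximum across windows, and whether
#' the recording passes a stated threshold (default 50 ms, one slice
#' acquisition duration: below it no within-scan heart-rate correction is
#' needed).
#'
#' @slot windowLength window length in seconds.
#' @slot windowStarts start time of each window (seconds, fMRI clock).
#' @slot rmssd RMSSD per window in milliseconds; NA flags a window with
#'   fewer than 3 peaks (excluded from the maximum).
#' @slot maxRmssd maximum RMSSD over non-missing windows, in ms.
#' @slot threshold pass/fail threshold in ms.
#' @slot passes TRUE iff `maxRmssd < threshold`.
#' @export
setClass("HrvReport",
  representation(windowLength = "numeric", windowStarts = "numeric",
                 rmssd = "numeric", maxRmssd = "numeric",
                 threshold = "numeric", passes = "logical"),
  validity = function(object) {
    msg <- NULL
    if (any(object@rmssd < 0, na.rm = TRUE))
      msg <- c(msg, "rmssd must be non-negative")
    ok <- object@rmssd[!is.na(object@rmssd)]
    if (length(ok) && abs(object@maxRmssd - max(ok)) > 1e-9)
      msg <- c(msg, "maxRmssd must equal the maximum over non-missing windows")
    if (is.null(msg)) TRUE else msg
  })

#' AcquisitionTiming: TR, slice offsets and slice duration
#'
#' Describes when each slice of a volume is acquired within one TR.
#' Simultaneously excited slices (one multiband group) share an identical
#' offset; `sliceDuration` is the width of one acquisition window and the
#' native temporal bin width of the cardiac-gated waveforms.
#'
#' @slot tr repetition time in seconds.
#' @slot nSlices number of slices.
#' @slot sliceOffsets acquisition offset of each slice within one TR (s).
#' @slot sliceDuration width of one slice-group acquisition window (s).
#' @slot nVolumes number of volumes in the run.
#' @export
setClass("AcquisitionTiming",
  representation(tr = "numeric", nSlices = "integer", sliceOffsets = "numeric",
                 sliceDuration = "numeric", nVolumes = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@tr <= 0) msg <- c(msg, "tr must be positive")
    if (object@sliceDuration <= 0)
      msg <- c(msg, "sliceDuration must be positive")
    if (length(object@sliceOffsets) != object@nSlices)
      msg <- c(msg, "sliceOffsets must have one entry per slice")
    if (any(object@sliceOffsets < 0 | object@sliceOffsets >= object@tr))
      msg <- c(msg, "slice offsets must lie in [0, tr)")
    if (object@nVolumes < 1L) msg <- c(msg, "nVolumes must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an AcquisitionTiming
#'
#' @param tr repetition time (s).
#' @param sliceOffsets per-slice offsets within one TR (s).
#' @param sliceDuration acquisition window width (s); default the smallest
#'   positive gap between distinct offsets (or `tr` for a single group).
#' @param nVolumes number of volumes.
#' @return An [AcquisitionTiming-class] object.
#' @seealso [sliceOffsetsSMS()] for the common SMS/sequential geometries.
#' @export
AcquisitionTiming <- function(tr, sliceOffsets, sliceDuration = NULL,
                              nVolumes) {
  if (is.null(sliceDuration)) {
    u <- sort(unique(sliceOffsets))
    sliceDuration <- if (length(u) > 1L) min(diff(u)) else tr
  }
  new("AcquisitionTiming", tr = as.numeric(tr),
      nSlices = length(sliceOffsets), sliceOffsets = as.numeric(sliceOffsets),
      sliceDuration = as.numeric(sliceDuration),
      nVolumes = as.integer(nVolumes))
}

#' VoxelSeries: one voxel's percent-modulation time course
#'
#' A detrended percent-modulation signal for one voxel together with the
#' acquisition time of each retained volume (volume start + slice offset).
#'
#' @slot values percent-modulation values, one per retained volume.
#' @slot acquisitionTimes seconds per retained volume, strictly increasing
#'   with constant step TR.
#' @slot voxelIndex integer(3), 0-based (i, j, k) grid position.
#' @export
setClass("VoxelSeries",
  representation(values = "numeric", acquisitionTimes = "numeric",
                 voxelIndex = "integer"),
  prototype(voxelIndex = c(0L, 0L, 0L)),
  validity = function(object) {
    msg <- NULL
    if (length(object@values) != length(object@acquisitionTimes))
      msg <- c(msg, "values and acquisitionTimes must have equal length")
    d <- diff(object@acquisitionTimes)
    if (length(d) && (any(d <= 0) || diff(range(d)) > 1e-6))
      msg <- c(msg, "acquisitionTimes must increase with a constant step")
    if (length(object@voxelIndex) != 3L)
      msg <- c(msg, "voxelIndex must be length 3")
    if (is.null(msg)) TRUE else msg
  })

#' AlignedResponse: one voxel's cardiac-gated waveform
#'
#' Per-bin even- and odd-beat average waveforms relative to the PPG peak,
#' with sample counts and the zero-referenced reliability R².
#'
#' @slot binCentersS bin centers in seconds relative to the PPG peak.
#' @slot binCentersFrac bin centers as cycle fraction
#'   (`binCentersS / cycleEstimate`).
#' @slot evenMean,oddMean per-bin mean percent modulation over samples
#'   assigned to even-/odd-indexed beats (NaN where the bin is empty).
#' @slot countsEven,countsOdd samples per bin in each half.
#' @slot r2 zero-referenced reliability, `100 * (1 - sum((y-f)^2)/sum(y^2))`
#'   over bins populated in both halves; unbounded below, at most 100.
#' @slot cycleEstimate heartbeat period (s).
#' @slot window epoch window in cycle fraction, e.g. `c(-0.5, 1)`.
#' @slot coreComplete TRUE iff every core-cycle bin (fraction 0–1) is
#'   populated in both halves.
#' @export
setClass("AlignedResponse",
  representation(binCentersS = "numeric", binCentersFrac = "numeric",
                 evenMean = "numeric", oddMean = "numeric",
                 countsEven = "numeric", countsOdd = "numeric",
                 r2 = "numeric", cycleEstimate = "numeric",
                 window = "numeric", coreComplete = "logical"),
  validity = function(object) {
    n <- length(object@binCentersS)
    lens <- c(length(object@binCentersFrac), length(object@evenMean),
              length(object@oddMean), length(object@countsEven),
              length(object@countsOdd))
    msg <- NULL
    if (any(lens != n)) msg <- c(msg, "per-bin slots must share one length")
    if (!is.na(object@r2) && object@r2 > 100 + 1e-9)
      msg <- c(msg, "r2 cannot exceed 100")
    if (is.null(msg)) TRUE else msg
  })

#' CardiacAlignment: cardiac-gated waveforms for a whole volume
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one row
#' per in-mask voxel and one column per temporal bin. Assays: `evenMean`,
#' `oddMean`, `countsEven`, `countsOdd`. Row data: voxel indices (`i`, `j`,
#' `k`, 0-based), `slice` (0-based), `r2`, `coreComplete`, `valid`.
#' Column data: `binCenterS`, `binCenterFrac`, `core`. Metadata: the
#' [AcquisitionTiming-class], the cycle estimate, epoch window, 3D grid
#' dimensions and the number of dropped volumes.
#'
#' @export
setClass("CardiacAlignment", contains = "SummarizedExperiment")

#' WaveformMatrix: reliability-scaled waveforms on the cycle-fraction grid
#'
#' The voxels-by-time matrix entering the SVD: each retained row is a
#' waveform resampled onto a standardized cycle-fraction grid, unit-
#' normalized and multiplied by its reliability R², so row norms equal the
#' R² and the most reliable responses dominate the decomposition. Rows with
#' R² <= 0 (or undefined) are pruned.
#'
#' @slot matrix numeric matrix, voxels x grid points.
#' @slot grid cycle-fraction grid (columns).
#' @slot r2 reliability per retained row.
#' @slot voxelIds indices of retained rows in the source object.
#' @slot sourceParity `"odd"` or `"even"`: which half the rows came from.
#' @export
setClass("WaveformMatrix",
  representation(matrix = "matrix", grid = "numeric", r2 = "numeric",
                 voxelIds = "integer", sourceParity = "character"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@matrix) != length(object@grid))
      msg <- c(msg, "grid length must match matrix columns")
    if (nrow(object@matrix) != length(object@r2))
      msg <- c(msg, "one r2 per row required")
    nrm <- sqrt(rowSums(object@matrix^2))
    if (length(nrm) && any(abs(nrm - abs(object@r2)) > 1e-6 * pmax(1, abs(object@r2))))
      msg <- c(msg, "each row's norm must equal its |r2|")
    if (!object@sourceParity %in% c("odd", "even"))
      msg <- c(msg, "sourceParity must be 'odd' or 'even'")
    if (is.null(msg)) TRUE else msg
  })

#' SvdModel: SVD of a waveform matrix
#'
#' Thin SVD M = U D V' of a [WaveformMatrix-class] (rows voxels, columns
#' time). `components` holds the unit-norm time courses (right singular
#' vectors, one column per component) with a deterministic sign rule:
#' each component is flipped so its value at cycle fraction 0 is negative
#' (blood compartments dip at the PPG peak). `spatialWeights` holds the
#' per-voxel weights (left singular vectors).
#'
#' @slot components grid x k matrix of orthonormal time courses.
#' @slot singularValues non-negative, descending.
#' @slot spatialWeights voxels x k matrix.
#' @slot grid cycle-fraction grid.
#' @slot nSelected number of components selected by cross-validation
#'   (NA until [cvVarianceExplained()] is consulted).
#' @export
setClass("SvdModel",
  representation(components = "matrix", singularValues = "numeric",
                 spatialWeights = "matrix", grid = "numeric",
                 nSelected = "integer"),
  prototype(nSelected = NA_integer_),
  validity = function(object) {
    msg <- NULL
    k <- ncol(object@components)
    if (length(object@singularValues) != k)
      msg <- c(msg, "one singular value per component required")
    if (is.unsorted(rev(object@singularValues)))
      msg <- c(msg, "singular values must be descending")
    if (any(object@singularValues < -1e-12))
      msg <- c(msg, "singular values must be non-negative")
    G <- crossprod(object@components)
    if (k && max(abs(G - diag(k))) > 1e-6)
      msg <- c(msg, "components must be orthonormal")
    if (is.null(msg)) TRUE else msg
  })

#' CanonicalComponents: cross-subject canonical time courses
#'
#' Canonical waveform components obtained by a second-level SVD over the
#' per-subject components (leave-one-subject-out), on the common
#' cycle-fraction grid. Sign rule: each component's value at cycle
#' fraction 0 is negative.
#'
#' @slot components grid x k orthonormal matrix.
#' @slot grid cycle-fraction grid.
#' @slot trainingSubjects identifiers of the subjects entering the SVD.
#' @slot signConvention human-readable statement of the sign rule.
#' @export
setClass("CanonicalComponents",
  representation(components = "matrix", grid = "numeric",
                 trainingSubjects = "character", signConvention = "character"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@components) != length(object@grid))
      msg <- c(msg, "components must live on the grid")
    k <- ncol(object@components)
    G <- crossprod(object@components)
    if (k && max(abs(G - diag(k))) > 1e-6)
      msg <- c(msg, "components must be orthonormal")
    if (is.null(msg)) TRUE else msg
  })

#' ModelFit: per-voxel weighted-component model of the waveforms
#'
#' Least-squares fit Y = beta_1 pc_1 + ... + beta_k pc_k + eps per voxel,
#' with the predicted waveforms and (once scored) the relative RMS error
#' Rrmse = Mrmse / Drmse, where Mrmse is the RMS model prediction error
#' against the even-beat waveform and Drmse the RMS even-odd difference.
#' Rrmse < 1 means the model beats test-retest noise; its expectation under
#' a perfect model with Gaussian noise is 1/sqrt(2).
#'
#' @slot betas voxels x k matrix of component weights.
#' @slot predicted voxels x grid matrix of modeled waveforms.
#' @slot rrmse per-voxel relative RMS error (NA until scored).
#' @slot grid cycle-fraction grid.
#' @export
setClass("ModelFit",
  representation(betas = "matrix", predicted = "matrix", rrmse = "numeric",
                 grid = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@betas) != nrow(object@predicted))
      msg <- c(msg, "betas and predicted must have one row per voxel")
    if (ncol(object@predicted) != length(object@grid))
      msg <- c(msg, "predicted must live on the grid")
    if (any(object@rrmse < 0, na.rm = TRUE))
      msg <- c(msg, "rrmse must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' RoiWaveforms: region- or zone-averaged waveforms
#'
#' Voxel-mean waveform, standard error and peak-to-trough modulation
#' amplitude per region of interest (or per artery x distance-level zone).
#'
#' @slot info data.frame with one row per region/zone: identifying columns
#'   plus `nVoxels` and `amplitude` (max - min of the mean waveform, percent).
#' @slot mean regions x grid matrix of voxel-mean waveforms.
#' @slot se regions x grid matrix of per-point standard errors
#'   (SD / sqrt(nVoxels); NA where nVoxels < 2).
#' @slot grid cycle-fraction grid.
#' @export
setClass("RoiWaveforms",
  representation(info = "data.frame", mean = "matrix", se = "matrix",
                 grid = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@mean) != nrow(object@info))
      msg <- c(msg, "one waveform per info row required")
    if (!all(dim(object@mean) == dim(object@se)))
      msg <- c(msg, "mean and se must have identical dimensions")
    if (ncol(object@mean) != length(object@grid))
      msg <- c(msg, "waveforms must live on the grid")
    if (is.null(msg)) TRUE else msg
  })

#' SimConfig: synthetic-dataset configuration
#'
#' Ground-truth configuration for the synthetic PPG + fMRI generator. The
#' defaults reproduce the fast SMS study conditions: 60 bpm with 10 ms
#' beat-to-beat jitter, 220 s of 100 Hz PPG, an 8 x 8 x 40 voxel grid
#' acquired as 5 simultaneous groups of 8 slices (TR 250 ms, 50 ms per
#' group, 878 volumes), four voxel classes (artery / vein / csf / null) with
#' skewed-transient waveform templates, 1% Gaussian noise and a slow
#' linear drift.
#'
#' @slot heartRate beats per minute (mean rate).
#' @slot jitterSd beat-to-beat Gaussian jitter SD (seconds).
#' @slot lfAmp fractional amplitude of the slow (low-frequency) inter-beat-
#'   interval modulation — the autonomic drift of the heart rate that, in
#'   real recordings, sweeps the sampling comb across the cardiac cycle.
#' @slot lfFreq frequency of the slow modulation (Hz).
#' @slot duration physio recording duration (seconds).
#' @slot physioFs physio sampling rate (Hz).
#' @slot grid integer(3) image dimensions.
#' @slot timing [AcquisitionTiming-class] of the simulated run.
#' @slot classMap 3D character array over `grid` with values
#'   `"artery"`, `"vein"`, `"csf"`, `"null"`.
#' @slot templateParams named list per class: `extremumTime` (cycle
#'   fraction), `amplitude` (percent), `sign` (+1/-1), `onsetWidth`,
#'   `returnWidth` (cycle fraction).
#' @slot noiseSd Gaussian noise SD in percent-signal units.
#' @slot driftSlope linear drift in percent per volume.
#' @slot seed integer seed fixed for reproducibility.
#' @export
setClass("SimConfig",
  representation(heartRate = "numeric", jitterSd = "numeric",
                 lfAmp = "numeric", lfFreq = "numeric",
                 duration = "numeric", physioFs = "numeric", grid = "integer",
                 timing = "AcquisitionTiming", classMap = "array",
                 templateParams = "list", noiseSd = "numeric",
                 driftSlope = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@heartRate <= 0 || object@duration <= 0 || object@physioFs <= 0)
      msg <- c(msg, "rates and durations must be positive")
    if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be non-negative")
    if (object@lfAmp < 0 || object@lfAmp >= 0.5)
      msg <- c(msg, "lfAmp must lie in [0, 0.5)")
    if (object@lfFreq <= 0) msg <- c(msg, "lfFreq must be positive")
    if (length(object@grid) != 3L || any(object@grid < 1L))
      msg <- c(msg, "grid must be three positive integers")
    if (!identical(dim(object@classMap), as.integer(object@grid)))
      msg <- c(msg, "classMap must have dimensions equal to grid")
    if (!all(object@classMap %in% c("artery", "vein", "csf", "null")))
      msg <- c(msg, "classMap values must be artery/vein/csf/null")
    if (object@grid[3] != object@timing@nSlices)
      msg <- c(msg, "third grid dimension must equal nSlices")
    if (is.null(msg)) TRUE else msg
  })

#' GroundTruth: what the synthetic generator actually emitted
#'
#' @slot truePeakTimes true heartbeat peak times (seconds, fMRI clock).
#' @slot classMap 3D character array of voxel classes.
#' @slot extremumTime named numeric: true extremum cycle fraction per class.
#' @slot extremumSign named numeric: +1 (maximum) or -1 (minimum) per class.
#' @slot amplitude named numeric: template amplitude (percent) per class.
#' @slot templateParams the template parameter list used.
#' @export
setClass("GroundTruth",
  representation(truePeakTimes = "numeric", classMap = "array",
                 extremumTime = "numeric", extremumSign = "numeric",
                 amplitude = "numeric", templateParams = "list"))
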