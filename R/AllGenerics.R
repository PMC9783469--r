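#' @include AllClasses.R
NULL

#' Accessors for pulseAlign classes
#'
#' Small accessor generics: `samples()`, `samplingRate()`, `startTime()`,
#' `channel()`, `traceTimes()` and `duration()` for [PhysioTrace-class];
#' `peakTimes()`, `cycleEstimate()` and `interBeatIntervals()` for
#' [PeakSeries-class]; `sliceOffsets()` for [AcquisitionTiming-class];
#' `components()`, `singularValues()` and `spatialWeights()` for
#' [SvdModel-class] / [CanonicalComponents-class]; `betas()`, `predicted()`
#' and `rrmseValues()` for [ModelFit-class]; `r2Values()` and `r2Image()`
#' for [CardiacAlignment-class].
#'
#' @param x the object.
#' @return The corresponding slot (or derived vector/array).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setMethod("samples", "PhysioTrace", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "PhysioTrace", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setMethod("startTime", "PhysioTrace", function(x) x@startTime)

#' @rdname accessors
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))
#' @rdname accessors
#' @export
setMethod("channel", "PhysioTrace", function(x) x@channel)

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setMethod("traceTimes", "PhysioTrace", function(x)
  x@startTime + (seq_along(x@samples) - 1) / x@samplingRate)

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setMethod("duration", "PhysioTrace", function(x)
  length(x@samples) / x@samplingRate)

#' @rdname accessors
#' @export
setGeneric("peakTimes", function(x) standardGeneric("peakTimes"))
#' @rdname accessors
#' @export
setMethod("peakTimes", "PeakSeries", function(x) x@peakTimes)

#' @rdname accessors
#' @export
setGeneric("cycleEstimate", function(x) standardGeneric("cycleEstimate"))
#' @rdname accessors
#' @export
setMethod("cycleEstimate", "PeakSeries", function(x) x@cycleEstimate)
#' @rdname accessors
#' @export
setMethod("cycleEstimate", "CardiacAlignment", function(x)
  S4Vectors::metadata(x)$cycleEstimate)

#' @rdname accessors
#' @export
setGeneric("interBeatIntervals",
           function(x) standardGeneric("interBeatIntervals"))
#' @rdname accessors
#' @export
setMethod("interBeatIntervals", "PeakSeries", function(x) diff(x@peakTimes))

#' @rdname accessors
#' @export
setMethod("length", "PeakSeries", function(x) length(x@peakTimes))

#' @rdname accessors
#' @export
setGeneric("sliceOffsets", function(x) standardGeneric("sliceOffsets"))
#' @rdname accessors
#' @export
setMethod("sliceOffsets", "AcquisitionTiming", function(x) x@sliceOffsets)

#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @rdname accessors
#' @export
setMethod("components", "SvdModel", function(x) x@components)
#' @rdname accessors
#' @export
setMethod("components", "CanonicalComponents", function(x) x@components)

#' @rdname accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))
#' @rdname accessors
#' @export
setMethod("singularValues", "SvdModel", function(x) x@singularValues)

#' @rdname accessors
#' @export
setGeneric("spatialWeights", function(x) standardGeneric("spatialWeights"))
#' @rdname accessors
#' @export
setMethod("spatialWeights", "SvdModel", function(x) x@spatialWeights)

#' @rdname accessors
#' @export
setGeneric("betas", function(x) standardGeneric("betas"))
#' @rdname accessors
#' @export
setMethod("betas", "ModelFit", function(x) x@betas)

#' @rdname accessors
#' @export
setGeneric("predicted", function(x) standardGeneric("predicted"))
#' @rdname accessors
#' @export
setMethod("predicted", "ModelFit", function(x) x@predicted)

#' @rdname accessors
#' @export
setGeneric("rrmseValues", function(x) standardGeneric("rrmseValues"))
#' @rdname accessors
#' @export
setMethod("rrmseValues", "ModelFit", function(x) x@rrmse)

#' @rdname accessors
#' @export
setGeneric("r2Values", function(x) standardGeneric("r2Values"))
#' @rdname accessors
#' @export
setMethod("r2Values", "CardiacAlignment", function(x)
  SummarizedExperiment::rowData(x)$r2)
#' @rdname accessors
#' @export
setMethod("r2Values", "AlignedResponse", function(x) x@r2)

#' @rdname accessors
#' @export
setGeneric("r2Image", function(x) standardGeneric("r2Image"))
#' @rdname accessors
#' @export
setMethod("r2Image", "CardiacAlignment", function(x) {
  md <- S4Vectors::metadata(x)
  rd <- SummarizedExperiment::rowData(x)
  img <- array(NA_real_, dim = md$dim3)
  img[cbind(rd$i + 1L, rd$j + 1L, rd$k + 1L)] <- rd$r2
  img
})

setMethod("show", "PhysioTrace", function(object) {
  cat(sprintf("PhysioTrace: %s channel, %d samples at %g Hz (%.1f s), start %.3f s\n",
              object@channel, length(object@samples), object@samplingRate,
              duration(object), object@startTime))
})

setMethod("show", "PeakSeries", function(object) {
  ibi <- diff(object@peakTimes)
  cat(sprintf("PeakSeries: %d peaks, cycle estimate %.3f s (%.1f bpm), IBI range [%.3f, %.3f] s\n",
              length(object@peakTimes), object@cycleEstimate,
              60 / object@cycleEstimate, min(ibi), max(ibi)))
})

setMethod("show", "HrvReport", function(object) {
  cat(sprintf("HrvReport: %d windows of %g s, max RMSSD %.1f ms, %s at %g ms threshold\n",
              length(object@rmssd), object@windowLength, object@maxRmssd,
              if (object@passes) "PASSES" else "FAILS", object@threshold))
})

setMethod("show", "AcquisitionTiming", function(object) {
  cat(sprintf("AcquisitionTiming: TR %g s, %d slices (%d group%s of %g s), %d volumes\n",
              object@tr, object@nSlices,
              length(unique(object@sliceOffsets)),
              if (length(unique(object@sliceOffsets)) > 1) "s" else "",
              object@sliceDuration, object@nVolumes))
})

setMethod("show", "AlignedResponse", function(object) {
  cat(sprintf("AlignedResponse: %d bins over cycle fraction [%.2f, %.2f), r2 = %s\n",
              length(object@binCentersS), object@window[1], object@window[2],
              if (is.na(object@r2)) "NA (masked)" else sprintf("%.1f", object@r2)))
})

setMethod("show", "WaveformMatrix", function(object) {
  cat(sprintf("WaveformMatrix (%s beats): %d voxels x %d grid points, r2 range [%.1f, %.1f]\n",
              object@sourceParity, nrow(object@matrix), ncol(object@matrix),
              if (nrow(object@matrix)) min(object@r2) else NA,
              if (nrow(object@matrix)) max(object@r2) else NA))
})

setMethod("show", "SvdModel", function(object) {
  ve <- 100 * cumsum(object@singularValues^2) / sum(object@singularValues^2)
  cat(sprintf("SvdModel: %d components on %d grid points; in-sample variance %.1f%% (1), %.1f%% (2)\n",
              ncol(object@components), length(object@grid),
              ve[1], if (length(ve) > 1) ve[2] else NA))
})

setMethod("show", "CanonicalComponents", function(object) {
  cat(sprintf("CanonicalComponents: %d components on %d grid points (training: %s)\n",
              ncol(object@components), length(object@grid),
              paste(object@trainingSubjects, collapse = ", ")))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit: %d voxels, %d components; Rrmse < 1 in %s of scored voxels\n",
              nrow(object@betas), ncol(object@betas),
              if (all(is.na(object@rrmse))) "NA" else
                sprintf("%.1f%%", 100 * mean(object@rrmse < 1, na.rm = TRUE))))
})

setMethod("show", "RoiWaveforms", function(object) {
  cat(sprintf("RoiWaveforms: %d regions/zones on %d grid points\n",
              nrow(object@info), length(object@grid)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %g bpm (jitter %g ms), %g s physio at %g Hz; grid %s, TR %g s, %d volumes; noise %g%%, seed %d\n",
              object@heartRate, 1000 * object@jitterSd, object@duration,
              object@physioFs, paste(object@grid, collapse = "x"),
              object@timing@tr, object@timing@nVolumes, object@noiseSd,
              object@seed))
})
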