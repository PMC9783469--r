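#' @include synthetic.R
NULL

#' Read a BIDS physiological recording
#'
#' Reads `*_physio.tsv.gz` (or plain `.tsv`) with its JSON sidecar. The
#' sidecar supplies `SamplingFrequency`, `StartTime` and `Columns`; the
#' column named `cardiac` or `ppg` (case-insensitive) is returned as the PPG
#' channel. A missing `StartTime` is assumed 0 with a warning (the physio
#' clock is then taken to start with the first fMRI volume).
#'
#' @param path path to the physio `.tsv.gz` / `.tsv` file.
#' @param sidecar path to the JSON sidecar; by default derived from `path`
#'   by replacing the extension with `.json`.
#' @param column which column to extract; default auto-detects the cardiac
#'   channel.
#' @return A [PhysioTrace-class].
#' @export
readPhysio <- function(path, sidecar = NULL, column = NULL) {
  if (!file.exists(path))
    paStop(sprintf("physio file not found: %s", path), "pa_input_error")
  if (is.null(sidecar))
    sidecar <- sub("\\.tsv(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar))
    paStop(sprintf("physio sidecar not found: %s", sidecar), "pa_input_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$SamplingFrequency))
    paStop("sidecar lacks SamplingFrequency", "pa_input_error")
  startTime <- meta$StartTime
  if (is.null(startTime)) {
    warning("sidecar lacks StartTime; assuming 0 (physio starts with volume 1)")
    startTime <- 0
  }
  cols <- unlist(meta$Columns)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  dat <- read.table(con, header = FALSE, sep = "\t")
  if (!is.null(cols) && length(cols) == ncol(dat)) names(dat) <- cols
  if (is.null(column)) {
    hit <- grep("^(cardiac|ppg)$", names(dat), ignore.case = TRUE)
    column <- if (length(hit)) hit[1] else 1L
  }
  PhysioTrace(dat[[column]], samplingRate = meta$SamplingFrequency,
              startTime = startTime, channel = "ppg")
}

#' Read acquisition timing from a BIDS JSON sidecar
#'
#' Uses `RepetitionTime` and `SliceTiming` (seconds, one entry per slice).
#' The slice-acquisition window is the smallest positive gap between
#' distinct slice times (the whole TR for a single group).
#'
#' @param path path to the BOLD JSON sidecar.
#' @param nVolumes number of volumes in the matching image.
#' @return An [AcquisitionTiming-class].
#' @export
readAcquisitionTiming <- function(path, nVolumes) {
  if (!file.exists(path))
    paStop(sprintf("BOLD sidecar not found: %s", path), "pa_input_error")
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(meta$RepetitionTime) || is.null(meta$SliceTiming))
    paStop("sidecar needs RepetitionTime and SliceTiming", "pa_input_error")
  AcquisitionTiming(tr = meta$RepetitionTime,
                    sliceOffsets = as.numeric(meta$SliceTiming),
                    nVolumes = nVolumes)
}

#' Write detected peaks as TSV
#'
#' Columns: `peak_index` (0-based), `peak_time_s` (fMRI clock), `ibi_s`
#' (interval to the next peak; NA for the last).
#'
#' @param peaks a [PeakSeries-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path) {
  pt <- peakTimes(peaks)
  df <- data.frame(peak_index = seq_along(pt) - 1L, peak_time_s = pt,
                   ibi_s = c(diff(pt), NA))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an HRV report as JSON
#'
#' @param hrv an [HrvReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHrv <- function(hrv, path) {
  jsonlite::write_json(list(
    window_length_s = hrv@windowLength,
    window_start_s = hrv@windowStarts,
    rmssd_ms = hrv@rmssd,
    max_rmssd_ms = hrv@maxRmssd,
    threshold_ms = hrv@threshold,
    passes = hrv@passes), path, auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE)
  invisible(path)
}

#' Write a synthetic dataset as a miniature BIDS-like tree
#'
#' Emits `func/sim_bold.nii.gz` with a JSON sidecar (`RepetitionTime`,
#' `SliceTiming`), `func/sim_physio.tsv.gz` with its sidecar
#' (`SamplingFrequency`, `StartTime`, `Columns`), `labels.nii.gz` (integer
#' class map: 1 artery, 2 vein, 3 csf, 0 null) with `labels.tsv`, and
#' `truth.json` (true peak times and per-class template parameters).
#'
#' @param cfg a [SimConfig-class].
#' @param dir output directory (created if needed).
#' @return The list from [simulateDataset()], invisibly, with `$paths`.
#' @export
writeSimulatedDataset <- function(cfg, dir) {
  sim <- simulateDataset(cfg)
  fdir <- file.path(dir, "func")
  dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
  tm <- cfg@timing
  boldPath <- file.path(fdir, "sim_bold.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(sim$img, pixdim = c(4, 4, 4, tm@tr)),
                     boldPath)
  jsonlite::write_json(list(RepetitionTime = tm@tr,
                            SliceTiming = tm@sliceOffsets,
                            SliceAcquisitionDuration = tm@sliceDuration),
                       file.path(fdir, "sim_bold.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  physioPath <- file.path(fdir, "sim_physio.tsv.gz")
  con <- gzfile(physioPath, "wt")
  write.table(data.frame(cardiac = samples(sim$trace)), con,
              sep = "\t", row.names = FALSE, col.names = FALSE)
  close(con)
  jsonlite::write_json(list(SamplingFrequency = cfg@physioFs,
                            StartTime = startTime(sim$trace),
                            Columns = list("cardiac")),
                       file.path(fdir, "sim_physio.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  codes <- c(null = 0L, artery = 1L, vein = 2L, csf = 3L)
  lab <- array(codes[sim$truth@classMap], dim = cfg@grid)
  labPath <- file.path(dir, "labels.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(lab, pixdim = c(4, 4, 4)), labPath)
  write.table(data.frame(label = unname(codes), class = names(codes)),
              file.path(dir, "labels.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  tp <- cfg@templateParams
  jsonlite::write_json(list(
    true_peak_times_s = sim$truePeakTimes,
    heart_rate_bpm = cfg@heartRate,
    jitter_sd_s = cfg@jitterSd,
    noise_sd_percent = cfg@noiseSd,
    drift_percent_per_volume = cfg@driftSlope,
    seed = cfg@seed,
    template_params = tp), file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sim$paths <- list(bold = boldPath, boldJson = file.path(fdir, "sim_bold.json"),
                    physio = physioPath,
                    physioJson = file.path(fdir, "sim_physio.json"),
                    labels = labPath, truth = file.path(dir, "truth.json"))
  invisible(sim)
}

#' Write a 3D/4D map as NIfTI
#'
#' @param x numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param template optional NIfTI image whose geometry is copied.
#' @return `path`, invisibly.
#' @export
writeMap <- function(x, path, template = NULL) {
  img <- if (is.null(template)) RNifti::asNifti(x)
         else RNifti::asNifti(x, reference = template)
  RNifti::writeNifti(img, path)
  invisible(path)
}
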