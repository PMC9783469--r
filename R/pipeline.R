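#' @include io.R
NULL

#' Convert a cycle fraction to milliseconds
#'
#' A fraction of the heartbeat cycle expressed in time at a given heart
#' rate: `fraction * 60000 / heartRateBpm` milliseconds. For example, 20%
#' of the cycle at 60 bpm is 200 ms.
#'
#' @param fraction cycle fraction(s).
#' @param heartRateBpm heart rate in beats per minute (> 0).
#' @return Milliseconds.
#' @examples
#' cycleFractionToTime(0.2, 60)   # 200
#' cycleFractionToTime(0.5, 120)  # 250
#' @export
cycleFractionToTime <- function(fraction, heartRateBpm) {
  if (any(heartRateBpm <= 0))
    paStop("heart rate must be positive", "pa_invalid_parameter")
  fraction * 60000 / heartRateBpm
}

# fill user config over defaults, rejecting unknown fields
.pipelineConfig <- function(config) {
  defaults <- list(fmri = NULL, fmriJson = NULL, physio = NULL,
                   physioJson = NULL, labels = NULL, zones = NULL,
                   out = NULL, nDrop = 3, window = c(-0.5, 1),
                   gridSize = 128, r2Threshold = 50, cvThreshold = 70,
                   k = 2, searchWindow = c(-0.5, 0.66), hrvWindow = 20,
                   hrvThreshold = 50, seed = 1L)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      paStop(sprintf("config file not found: %s", config), "pa_config_error")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    paStop(paste("unknown config fields:", paste(bad, collapse = ", ")),
           "pa_config_error")
  cfg <- utils::modifyList(defaults, config)
  if (cfg$r2Threshold < -Inf || cfg$cvThreshold < 0 || cfg$cvThreshold > 100)
    paStop("thresholds out of range", "pa_config_error")
  if (cfg$k < 1) paStop("k must be >= 1", "pa_config_error")
  for (f in c("fmri", "physio"))
    if (is.null(cfg[[f]]))
      paStop(sprintf("config field '%s' is required", f), "pa_config_error")
  for (f in c("fmri", "physio", "labels", "zones"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      paStop(sprintf("input file for '%s' not found: %s", f, cfg[[f]]),
             "pa_input_error")
  cfg
}

#' Run the full cardiac-alignment pipeline
#'
#' Orchestrates physio peak detection, volume alignment, waveform modeling
#' and (optionally) ROI aggregation on one run, writing standard-format
#' outputs plus a machine-readable `report.json` into the output directory.
#'
#' Stages and outputs:
#' \describe{
#'   \item{physio}{[readPhysio()], [detectPeaks()], [rmssdHrv()] ->
#'     `peaks.tsv`, `hrv.json`.}
#'   \item{align}{[alignVolume()] with timing from the BOLD JSON sidecar ->
#'     `r2.nii.gz`.}
#'   \item{model}{odd/even waveforms resampled onto the cycle-fraction grid,
#'     reliability-weighted SVD of the odd half, cross-validated variance on
#'     the even half, per-voxel betas (this single-run mode uses the run's
#'     own components as the canonical set), Rrmse, extrema timing ->
#'     `t_min.nii.gz`, `t_max.nii.gz` (masked at the reliability threshold),
#'     `betas.nii.gz`, `rrmse.nii.gz`, `canonical_pcs.tsv`, `model.json`.}
#'   \item{roi}{when a label volume and zone table are given:
#'     [aggregateRoi()], [aggregateZones()], [amplitudeGradientTest()] ->
#'     `waveforms.tsv`, `roi_waveforms.tsv`, `zone_amplitudes.tsv`.}
#' }
#'
#' @param config a named list or path to a JSON file. Required: `fmri`
#'   (4D NIfTI), `physio` (BIDS physio tsv.gz). Optional: `fmriJson`,
#'   `physioJson` (sidecars; derived from the data paths by default),
#'   `labels`, `zones`, `out` (output directory; tempdir-based default),
#'   `nDrop` (3), `window` (c(-0.5, 1)), `gridSize` (128), `r2Threshold`
#'   (50), `cvThreshold` (70), `k` (2), `searchWindow` (c(-0.5, 0.66)),
#'   `hrvWindow` (20 s), `hrvThreshold` (50 ms), `seed`.
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the report (also written to
#'   `report.json`) and the intermediate objects (`peaks`, `hrv`,
#'   `alignment`, `svd`, `fit`, `timing`, `extrema`, `roi`, `zones`).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  cfg <- .pipelineConfig(config)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  outDir <- cfg$out
  if (is.null(outDir)) outDir <- file.path(tempdir(), "pulseAlign_run")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  stage <- "physio"
  result <- tryCatch({
    say("[physio] reading %s", cfg$physio)
    trace <- readPhysio(cfg$physio, sidecar = cfg$physioJson)
    peaks <- detectPeaks(trace)
    hrv <- rmssdHrv(peaks, windowLength = cfg$hrvWindow,
                    threshold = cfg$hrvThreshold)
    writePeaks(peaks, file.path(outDir, "peaks.tsv"))
    writeHrv(hrv, file.path(outDir, "hrv.json"))
    say("[physio] %d peaks, cycle %.3f s, max RMSSD %.1f ms (%s)",
        length(peaks), cycleEstimate(peaks), hrv@maxRmssd,
        if (hrv@passes) "pass" else "FAIL")

    stage <- "align"
    fmri <- RNifti::readNifti(cfg$fmri)
    fmriJson <- cfg$fmriJson
    if (is.null(fmriJson))
      fmriJson <- sub("\\.nii(\\.gz)?$", ".json", cfg$fmri)
    timing <- readAcquisitionTiming(fmriJson, nVolumes = dim(fmri)[4])
    say("[align] TR %g s, %d slices, %d volumes; window [%g, %g) cycles",
        timing@tr, timing@nSlices, timing@nVolumes,
        cfg$window[1], cfg$window[2])
    ca <- alignVolume(fmri, peaks, timing, window = cfg$window,
                      nDrop = cfg$nDrop)
    writeMap(r2Image(ca), file.path(outDir, "r2.nii.gz"))
    r2 <- r2Values(ca)

    stage <- "model"
    grid <- cycleFractionGrid(cfg$gridSize, cfg$window)
    Modd <- buildWaveformMatrix(ca, grid = grid, parity = "odd")
    Mev <- buildWaveformMatrix(ca, grid = grid, parity = "even")
    sv <- svdDecompose(Modd)
    cv <- cvVarianceExplained(Modd, Mev, k = cfg$k,
                              threshold = cfg$cvThreshold)
    say("[model] CV variance explained by %d components: %.1f%% (smallest k over %g%%: %s)",
        cfg$k, cv$percent, cfg$cvThreshold, cv$nSelected)
    pcs <- new("CanonicalComponents",
               components = sv@components[, seq_len(min(cfg$k,
                 ncol(sv@components))), drop = FALSE],
               grid = grid, trainingSubjects = "self",
               signConvention = "component value at cycle fraction 0 is negative")
    common <- intersect(Modd@voxelIds, Mev@voxelIds)
    io <- match(common, Modd@voxelIds)
    ie <- match(common, Mev@voxelIds)
    oddW <- Modd@matrix[io, , drop = FALSE] / Modd@r2[io]
    evenW <- Mev@matrix[ie, , drop = FALSE] / Mev@r2[ie]
    fit <- fitBetas(oddW, pcs)   # unit-scale odd waveforms
    fit <- rrmse(fit, even = evenW, odd = oddW)
    ext <- extremaTimes(fit, searchWindow = cfg$searchWindow)
    rd <- SummarizedExperiment::rowData(ca)
    d3 <- S4Vectors::metadata(ca)$dim3
    relSel <- Modd@r2[io] > cfg$r2Threshold
    reliable <- common[relSel]
    if (!length(reliable))
      warning("no voxels exceed the reliability threshold; timing maps are empty")
    toImg <- function(vals, ids) {
      img <- array(NA_real_, dim = d3)
      img[cbind(rd$i[ids] + 1L, rd$j[ids] + 1L, rd$k[ids] + 1L)] <- vals
      img
    }
    writeMap(toImg(ext$tMin[relSel], reliable), file.path(outDir, "t_min.nii.gz"))
    writeMap(toImg(ext$tMax[relSel], reliable), file.path(outDir, "t_max.nii.gz"))
    writeMap(toImg(fit@rrmse, common), file.path(outDir, "rrmse.nii.gz"))
    betaImg <- array(NA_real_, dim = c(d3, ncol(fit@betas)))
    for (kk in seq_len(ncol(fit@betas)))
      betaImg[, , , kk] <- toImg(fit@betas[, kk], common)
    writeMap(betaImg, file.path(outDir, "betas.nii.gz"))
    write.table(cbind(data.frame(cycle_fraction = grid),
                      setNames(as.data.frame(pcs@components),
                               paste0("pc", seq_len(ncol(pcs@components))))),
                file.path(outDir, "canonical_pcs.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(
      grid_size = cfg$gridSize, window = cfg$window,
      search_window = cfg$searchWindow, k = cfg$k,
      cv_threshold_percent = cfg$cvThreshold,
      r2_threshold = cfg$r2Threshold,
      sign_convention = pcs@signConvention,
      cv_variance_explained_percent = cv$percent,
      n_components_over_threshold = cv$nSelected),
      file.path(outDir, "model.json"), auto_unbox = TRUE, digits = NA,
      na = "null", pretty = TRUE)

    stage <- "roi"
    roiRes <- zoneRes <- gradient <- NULL
    if (!is.null(cfg$labels) && !is.null(cfg$zones)) {
      labImg <- RNifti::readNifti(cfg$labels)
      if (!identical(dim(labImg)[1:3], as.integer(d3)))
        paStop("label volume grid does not match the fMRI grid",
               "pa_geometry_error")
      zt <- readZoneTable(cfg$zones)
      labs <- unclass(labImg)[cbind(rd$i[common] + 1L,
                                    rd$j[common] + 1L,
                                    rd$k[common] + 1L)]
      W <- oddW
      roiRes <- aggregateRoi(W, labs, zt, grid = grid)
      zoneRes <- aggregateZones(W, labs, zt, grid = grid)
      gradient <- amplitudeGradientTest(zoneRes)
      say("[roi] %d regions, %d zones", nrow(roiRes@info), nrow(zoneRes@info))
      longWave <- do.call(rbind, lapply(seq_len(nrow(roiRes@info)), function(i)
        data.frame(label = roiRes@info$label[i],
                   region_name = roiRes@info$regionName[i],
                   cycle_fraction = grid, mean = roiRes@mean[i, ],
                   se = roiRes@se[i, ])))
      write.table(longWave, file.path(outDir, "roi_waveforms.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(zoneRes@info, file.path(outDir, "zone_amplitudes.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      binWave <- do.call(rbind, lapply(zt$label, function(lb) {
        sel <- which(labs == lb)
        if (!length(sel)) return(NULL)
        ids <- common[sel]
        a <- SummarizedExperiment::assays(ca)
        cd <- SummarizedExperiment::colData(ca)
        data.frame(label = lb, bin_center_s = cd$binCenterS,
                   bin_center_frac = cd$binCenterFrac,
                   even_mean = colMeans(a$evenMean[ids, , drop = FALSE]),
                   odd_mean = colMeans(a$oddMean[ids, , drop = FALSE]),
                   count_even = colSums(a$countsEven[ids, , drop = FALSE]),
                   count_odd = colSums(a$countsOdd[ids, , drop = FALSE]))
      }))
      if (!is.null(binWave))
        write.table(binWave, file.path(outDir, "waveforms.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
    }

    r2Bands <- c(`<0` = sum(r2 < 0, na.rm = TRUE),
                 `0-30` = sum(r2 >= 0 & r2 < 30, na.rm = TRUE),
                 `30-50` = sum(r2 >= 30 & r2 < 50, na.rm = TRUE),
                 `50-70` = sum(r2 >= 50 & r2 < 70, na.rm = TRUE),
                 `70-100` = sum(r2 >= 70, na.rm = TRUE),
                 masked = sum(is.na(r2)))
    rrRel <- fit@rrmse[relSel]
    report <- list(
      n_beats = length(peaks),
      mean_heart_rate_bpm = 60 / mean(interBeatIntervals(peaks)),
      cycle_estimate_s = cycleEstimate(peaks),
      max_rmssd_ms = hrv@maxRmssd,
      hrv_passes = hrv@passes,
      n_voxels = nrow(ca),
      voxels_by_r2_band = as.list(r2Bands),
      n_reliable_voxels = length(reliable),
      cv_variance_explained_percent = cv$percent,
      fraction_rrmse_below_1 = if (length(rrRel))
        mean(rrRel < 1, na.rm = TRUE) else NA,
      t_min_quantiles = if (length(reliable))
        as.list(quantile(ext$tMin[relSel], c(.25, .5, .75), na.rm = TRUE))
        else NULL,
      t_max_quantiles = if (length(reliable))
        as.list(quantile(ext$tMax[relSel], c(.25, .5, .75), na.rm = TRUE))
        else NULL,
      zone_amplitudes = if (!is.null(zoneRes))
        zoneRes@info[, c("regionName", "artery", "distanceLevel", "nVoxels",
                         "amplitude")] else NULL,
      amplitude_gradient = gradient,
      parameters = cfg[c("nDrop", "window", "gridSize", "r2Threshold",
                         "cvThreshold", "k", "searchWindow", "seed")])
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    say("[done] outputs in %s", outDir)
    list(report = report, peaks = peaks, hrv = hrv, alignment = ca,
         svd = sv, cv = cv, pcs = pcs, fit = fit, extrema = ext,
         roi = roiRes, zones = zoneRes, gradient = gradient,
         outDir = outDir)
  }, pulseAlign_error = function(e) {
    paStop(sprintf("pipeline failed at stage '%s': %s", stage,
                   conditionMessage(e)),
           c(class(e)[1], "pa_stage_failure"))
  })
  invisible(result)
}
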