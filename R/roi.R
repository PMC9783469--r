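#' @include model.R
NULL

#' Read an arterial-zone lookup table
#'
#' Reads a TSV mapping label-volume integers to region names, arterial
#' territory (ACA / MCA / PCA / other) and a distance level 1-4 (1 =
#' closest to the arterial input). A starter table with the canonical
#' closest-region examples ships in
#' `system.file("extdata", "zone_table_starter.tsv", package = "pulseAlign")`;
#' the full assignment is user-supplied.
#'
#' @param path TSV file with columns `label`, `region_name`, `artery`,
#'   `distance_level`.
#' @return A data.frame.
#' @export
readZoneTable <- function(path) {
  if (!file.exists(path))
    paStop(sprintf("zone table not found: %s", path), "pa_input_error")
  zt <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("label", "region_name", "artery", "distance_level")
  if (!all(need %in% names(zt)))
    paStop(paste("zone table must have columns:", paste(need, collapse = ", ")),
           "pa_input_error")
  if (anyDuplicated(zt$label))
    paStop("zone table labels must be unique", "pa_input_error")
  if (!all(zt$distance_level %in% 1:4))
    paStop("distance_level must be in 1..4", "pa_input_error")
  zt
}

# voxel-mean waveform, per-point SE and max-min amplitude for one group
.roiStats <- function(W) {
  n <- nrow(W)
  if (n == 0L)
    return(list(mean = NULL, se = NULL, n = 0L, amplitude = NA_real_))
  m <- colMeans(W)
  se <- if (n >= 2L) apply(W, 2, sd) / sqrt(n) else rep(NA_real_, ncol(W))
  list(mean = m, se = se, n = n,
       amplitude = if (all(is.finite(m))) max(m) - min(m) else NA_real_)
}

#' Aggregate cardiac-gated waveforms over labeled regions
#'
#' Voxel-mean waveform, standard error (SD / sqrt(n) per grid point) and
#' peak-to-trough modulation amplitude (max - min of the mean waveform, in
#' percent) per label in the zone table. Labels with no voxels are reported
#' with `nVoxels = 0` and missing statistics.
#'
#' @param waveforms voxels x grid matrix of waveforms on the cycle-fraction
#'   grid (e.g. the rows of a resampled [CardiacAlignment-class]).
#' @param labels integer vector of label values, one per waveform row (use
#'   the label volume indexed at the voxel positions).
#' @param table zone table (see [readZoneTable()]).
#' @param grid the cycle-fraction grid.
#' @return A [RoiWaveforms-class] with one row per table label.
#' @export
aggregateRoi <- function(waveforms, labels, table,
                         grid = cycleFractionGrid(ncol(waveforms))) {
  W <- as.matrix(waveforms)
  if (length(labels) != nrow(W))
    paStop("one label per waveform row required", "pa_geometry_error")
  ok <- rowSums(is.finite(W)) == ncol(W)
  res <- lapply(table$label, function(lb) .roiStats(W[ok & labels == lb, ,
                                                      drop = FALSE]))
  mn <- do.call(rbind, lapply(res, function(r)
    if (is.null(r$mean)) rep(NA_real_, ncol(W)) else r$mean))
  se <- do.call(rbind, lapply(res, function(r)
    if (is.null(r$se)) rep(NA_real_, ncol(W)) else r$se))
  info <- data.frame(label = table$label, regionName = table$region_name,
                     artery = table$artery,
                     distanceLevel = table$distance_level,
                     nVoxels = vapply(res, `[[`, 0L, "n"),
                     amplitude = vapply(res, `[[`, 0, "amplitude"))
  new("RoiWaveforms", info = info, mean = mn, se = se,
      grid = as.numeric(grid))
}

#' Aggregate waveforms into artery x distance-level zones
#'
#' Pools all voxels of the regions sharing an arterial territory and a
#' distance level (voxels are averaged directly, not region means), giving
#' the zone-mean waveform, SE and modulation amplitude per zone.
#'
#' @inheritParams aggregateRoi
#' @return A [RoiWaveforms-class] with one row per artery x level present in
#'   the table.
#' @export
aggregateZones <- function(waveforms, labels, table,
                           grid = cycleFractionGrid(ncol(waveforms))) {
  W <- as.matrix(waveforms)
  if (length(labels) != nrow(W))
    paStop("one label per waveform row required", "pa_geometry_error")
  ok <- rowSums(is.finite(W)) == ncol(W)
  zones <- unique(table[, c("artery", "distance_level")])
  zones <- zones[order(zones$artery, zones$distance_level), ]
  res <- lapply(seq_len(nrow(zones)), function(i) {
    lbs <- table$label[table$artery == zones$artery[i] &
                       table$distance_level == zones$distance_level[i]]
    .roiStats(W[ok & labels %in% lbs, , drop = FALSE])
  })
  mn <- do.call(rbind, lapply(res, function(r)
    if (is.null(r$mean)) rep(NA_real_, ncol(W)) else r$mean))
  se <- do.call(rbind, lapply(res, function(r)
    if (is.null(r$se)) rep(NA_real_, ncol(W)) else r$se))
  info <- data.frame(label = NA_integer_,
                     regionName = paste0(zones$artery, "_level",
                                         zones$distance_level),
                     artery = zones$artery,
                     distanceLevel = zones$distance_level,
                     nVoxels = vapply(res, `[[`, 0L, "n"),
                     amplitude = vapply(res, `[[`, 0, "amplitude"))
  new("RoiWaveforms", info = info, mean = mn, se = se,
      grid = as.numeric(grid))
}

#' Does modulation amplitude decrease with distance from the arterial input?
#'
#' For each arterial territory, lists the modulation amplitude by distance
#' level and reports whether the sequence is non-increasing (and strictly
#' decreasing), with the first violating level if any. Purely descriptive -
#' no inferential statistic is attached.
#'
#' @param zones a [RoiWaveforms-class] from [aggregateZones()].
#' @return A data.frame with one row per artery: `artery`, `levels`,
#'   `amplitudes` (comma-separated), `nonIncreasing`, `strictlyDecreasing`,
#'   `firstViolation` (level index, NA if none).
#' @examples
#' # amplitudes 1.0, 0.7, 0.5, 0.4 across levels 1-4 are monotone decreasing
#' @export
amplitudeGradientTest <- function(zones) {
  stopifnot(is(zones, "RoiWaveforms"))
  info <- zones@info
  out <- lapply(split(info, info$artery), function(z) {
    z <- z[order(z$distanceLevel), ]
    z <- z[!is.na(z$amplitude), ]
    if (nrow(z) < 2L)
      return(data.frame(artery = z$artery[1], levels = nrow(z),
                        amplitudes = paste(signif(z$amplitude, 4),
                                           collapse = ","),
                        nonIncreasing = NA, strictlyDecreasing = NA,
                        firstViolation = NA_integer_))
    d <- diff(z$amplitude)
    viol <- which(d > 1e-12)
    data.frame(artery = z$artery[1], levels = nrow(z),
               amplitudes = paste(signif(z$amplitude, 4), collapse = ","),
               nonIncreasing = length(viol) == 0L,
               strictlyDecreasing = all(d < -1e-12),
               firstViolation = if (length(viol))
                 z$distanceLevel[min(viol) + 1L] else NA_integer_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
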