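#' @include alignment.R
NULL

#' Standardized cycle-fraction grid
#'
#' Evenly spaced cycle-fraction points over the epoch window, default 128
#' points on \[-0.5, 1.0). Waveforms from all subjects are resampled onto
#' this common abscissa before modeling.
#'
#' @param n number of grid points (default 128).
#' @param window cycle-fraction window, default `c(-0.5, 1)`; the upper end
#'   is excluded (half-open).
#' @return Numeric vector of length `n`.
#' @export
cycleFractionGrid <- function(n = 128, window = c(-0.5, 1)) {
  seq(window[1], window[2], length.out = n + 1)[seq_len(n)]
}

#' Resample a cardiac-gated waveform onto the cycle-fraction grid
#'
#' Linear interpolation of the per-bin waveform (odd- or even-beat mean)
#' onto a standardized cycle-fraction grid. Grid points outside the covered
#' range are filled with the nearest edge value. Missing bins are dropped
#' before interpolation.
#'
#' @param resp an [AlignedResponse-class], or a numeric vector of bin values
#'   when `at` is given.
#' @param grid target cycle-fraction grid (see [cycleFractionGrid()]).
#' @param parity which half to resample, `"odd"` (default) or `"even"`.
#' @param at cycle-fraction positions of `resp` when `resp` is a plain
#'   vector.
#' @return Numeric vector on `grid`, or NULL when fewer than 2 bins are
#'   available (voxel excluded).
#' @export
resampleToCycle <- function(resp, grid = cycleFractionGrid(),
                            parity = c("odd", "even"), at = NULL) {
  parity <- match.arg(parity)
  if (is(resp, "AlignedResponse")) {
    y <- if (parity == "odd") resp@oddMean else resp@evenMean
    x <- resp@binCentersFrac
  } else {
    y <- as.numeric(resp)
    x <- at
    if (is.null(x))
      paStop("`at` is required for plain-vector input", "pa_invalid_parameter")
  }
  use <- is.finite(x) & is.finite(y)
  if (sum(use) < 2L) return(NULL)
  approx(x[use], y[use], xout = grid, rule = 2)$y
}

# deterministic component sign rule: flip each column so its value at the
# grid point nearest cycle fraction 0 is negative (blood dips at the PPG
# peak); if that value is (numerically) zero, make the largest-|.| entry
# negative instead.
.applySignRule <- function(V, grid) {
  i0 <- which.min(abs(grid))
  flip <- vapply(seq_len(ncol(V)), function(k) {
    v0 <- V[i0, k]
    if (abs(v0) > 1e-10) v0 > 0 else V[which.max(abs(V[, k])), k] > 0
  }, logical(1))
  list(V = sweep(V, 2, ifelse(flip, -1, 1), "*"), flip = flip)
}

#' Build the reliability-scaled waveform matrix
#'
#' Assembles the voxels-by-time matrix M entering the SVD: each voxel's
#' waveform is resampled onto the grid, unit-normalized, and multiplied by
#' `max(r2, 0)` so the row norm equals its reliability and the most reliable
#' responses dominate the decomposition. Voxels with undefined or
#' non-positive r2 (and voxels whose waveform cannot be resampled) are
#' pruned.
#'
#' @param responses a [CardiacAlignment-class], or a numeric matrix of
#'   already-resampled waveforms (voxels x grid).
#' @param r2 per-voxel reliability; taken from `responses` when it is a
#'   [CardiacAlignment-class].
#' @param grid target cycle-fraction grid.
#' @param parity which half the waveforms come from (`"odd"` default).
#' @return A [WaveformMatrix-class].
#' @export
buildWaveformMatrix <- function(responses, r2 = NULL,
                                grid = cycleFractionGrid(),
                                parity = c("odd", "even")) {
  parity <- match.arg(parity)
  if (is(responses, "CardiacAlignment")) {
    ca <- responses
    if (is.null(r2)) r2 <- r2Values(ca)
    a <- SummarizedExperiment::assays(ca)
    W <- if (parity == "odd") a$oddMean else a$evenMean
    at <- SummarizedExperiment::colData(ca)$binCenterFrac
    M <- matrix(NA_real_, nrow(W), length(grid))
    for (i in seq_len(nrow(W))) {
      v <- resampleToCycle(as.numeric(W[i, ]), grid = grid, at = at)
      if (!is.null(v)) M[i, ] <- v
    }
  } else {
    M <- as.matrix(responses)
    if (ncol(M) != length(grid))
      paStop("waveform matrix must have one column per grid point",
             "pa_geometry_error")
    if (is.null(r2))
      paStop("r2 is required for matrix input", "pa_invalid_parameter")
  }
  if (length(r2) != nrow(M))
    paStop("one r2 per voxel required", "pa_invalid_parameter")
  nrm <- sqrt(rowSums(M^2))
  keep <- which(is.finite(r2) & r2 > 0 & is.finite(nrm) & nrm > 0)
  if (!length(keep))
    paStop("no voxels with positive reliability", "pa_model_error")
  Mk <- M[keep, , drop = FALSE] / nrm[keep] * r2[keep]
  new("WaveformMatrix", matrix = Mk, grid = as.numeric(grid),
      r2 = as.numeric(r2[keep]), voxelIds = as.integer(keep),
      sourceParity = parity)
}

#' Singular value decomposition of the waveform matrix
#'
#' Thin SVD M = U D V' with the deterministic sign rule applied to the time
#' courses (each component's value at cycle fraction 0 is negative). At full
#' rank the reconstruction reproduces M to numerical tolerance.
#'
#' @param M a [WaveformMatrix-class], or a plain matrix plus `grid`.
#' @param grid cycle-fraction grid for plain-matrix input.
#' @return An [SvdModel-class].
#' @export
svdDecompose <- function(M, grid = NULL) {
  if (is(M, "WaveformMatrix")) {
    grid <- M@grid
    M <- M@matrix
  }
  if (is.null(grid)) grid <- cycleFractionGrid(ncol(M))
  if (nrow(M) < 2L || ncol(M) < 2L)
    paStop("need at least 2 rows and 2 columns", "pa_model_error")
  s <- svd(M)
  if (max(s$d) <= 0 || !any(s$d > 1e-12 * max(s$d)))
    paStop("matrix has rank 0", "pa_model_error")
  sr <- .applySignRule(s$v, grid)
  U <- sweep(s$u, 2, ifelse(sr$flip, -1, 1), "*")
  new("SvdModel", components = sr$V, singularValues = s$d,
      spatialWeights = U, grid = as.numeric(grid))
}

#' Cross-validated variance explained by the first k components
#'
#' Projects the held-out half (even-beat waveform matrix) onto the span of
#' the first k components of the training half (odd-beat matrix) and
#' returns the percent variance explained,
#' `100 * (1 - sum(||test - proj||^2) / sum(||test||^2))`. Also reports the
#' full curve over k and the smallest k exceeding a threshold (default 70%).
#'
#' @param train,test [WaveformMatrix-class] objects on the same grid with
#'   the same voxels (train is typically the odd half, test the even half).
#' @param k number of components to evaluate; capped at the rank of train.
#' @param threshold percent-variance threshold for component selection.
#' @return A list with `percent` (variance explained at `k`), `curve`
#'   (percent for k = 1 ... rank), and `nSelected` (smallest k with
#'   `curve > threshold`, NA if never reached).
#' @export
cvVarianceExplained <- function(train, test, k = 2, threshold = 70) {
  stopifnot(is(train, "WaveformMatrix"), is(test, "WaveformMatrix"))
  if (!isTRUE(all.equal(train@grid, test@grid)))
    paStop("train and test must share the grid", "pa_geometry_error")
  common <- intersect(train@voxelIds, test@voxelIds)
  if (!length(common))
    paStop("train and test share no voxels", "pa_model_error")
  Tr <- train@matrix[match(common, train@voxelIds), , drop = FALSE]
  Te <- test@matrix[match(common, test@voxelIds), , drop = FALSE]
  sv <- svd(Tr)
  rank <- sum(sv$d > 1e-12 * max(sv$d))
  kEff <- min(k, rank)
  ssTot <- sum(Te^2)
  res <- Te
  curve <- numeric(rank)
  for (kk in seq_len(rank)) {
    v <- sv$v[, kk]
    res <- res - (res %*% v) %*% t(v)
    curve[kk] <- 100 * (1 - sum(res^2) / ssTot)
  }
  pct <- if (kEff == 0) 0 else curve[kEff]
  sel <- which(curve > threshold)
  list(percent = pct, curve = curve,
       nSelected = if (length(sel)) min(sel) else NA_integer_)
}

#' Canonical components across subjects (leave-one-out)
#'
#' Stacks the per-subject component time courses (each unit-normalized),
#' excludes the held-out subject, and runs a second-level SVD; the first k
#' right singular vectors are the canonical components, with the sign rule
#' applied. With a single training subject the canonical components are that
#' subject's components (degenerate; a warning is issued).
#'
#' @param subjectComponents named list of grid x k component matrices, one
#'   per subject, all on the same grid.
#' @param heldOut name (or index) of the subject to exclude; NULL keeps all.
#' @param k number of canonical components (default 2).
#' @param grid the common cycle-fraction grid; defaults to
#'   `cycleFractionGrid(nrow)` of the first subject.
#' @return A [CanonicalComponents-class].
#' @export
canonicalComponents <- function(subjectComponents, heldOut = NULL, k = 2,
                                grid = NULL) {
  if (!length(subjectComponents))
    paStop("need at least one subject", "pa_config_error")
  nms <- names(subjectComponents)
  if (is.null(nms)) {
    nms <- as.character(seq_along(subjectComponents))
    names(subjectComponents) <- nms
  }
  if (!is.null(heldOut)) {
    drop <- if (is.character(heldOut)) match(heldOut, nms) else as.integer(heldOut)
    if (any(is.na(drop)))
      paStop("held-out subject not found", "pa_config_error")
    subjectComponents <- subjectComponents[-drop]
    nms <- nms[-drop]
  }
  if (!length(subjectComponents))
    paStop("no training subjects remain", "pa_config_error")
  if (length(subjectComponents) == 1L)
    warning("single training subject: canonical components are degenerate")
  G <- nrow(subjectComponents[[1]])
  if (is.null(grid)) grid <- cycleFractionGrid(G)
  S <- do.call(rbind, lapply(subjectComponents, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != G)
      paStop("subject components must share the grid", "pa_geometry_error")
    t(m) / sqrt(colSums(m^2))
  }))
  sv <- svd(S)
  kEff <- min(k, sum(sv$d > 1e-12 * max(sv$d)))
  V <- .applySignRule(sv$v[, seq_len(kEff), drop = FALSE], grid)$V
  new("CanonicalComponents", components = V, grid = as.numeric(grid),
      trainingSubjects = nms,
      signConvention = "component value at cycle fraction 0 is negative")
}

#' Fit per-voxel component weights
#'
#' Least-squares fit of Y = beta_1 pc_1 + ... + beta_k pc_k + eps per voxel.
#' With orthonormal components the betas are inner products; mild
#' non-orthonormality is handled by the normal equations.
#'
#' @param Y waveform(s) on the grid: a numeric vector or a voxels x grid
#'   matrix. Rows that are entirely missing are skipped (NA betas).
#' @param pcs a [CanonicalComponents-class] or [SvdModel-class] (its first
#'   `k` components), or a grid x k matrix.
#' @param k number of components to use when `pcs` carries more.
#' @return A [ModelFit-class] (rrmse slot NA until scored with [rrmse()]).
#' @export
fitBetas <- function(Y, pcs, k = NULL) {
  P <- if (is(pcs, "CanonicalComponents") || is(pcs, "SvdModel"))
    pcs@components else as.matrix(pcs)
  grid <- if (is(pcs, "CanonicalComponents") || is(pcs, "SvdModel"))
    pcs@grid else cycleFractionGrid(nrow(P))
  if (!is.null(k)) P <- P[, seq_len(min(k, ncol(P))), drop = FALSE]
  Ym <- if (is.null(dim(Y))) matrix(Y, nrow = 1) else as.matrix(Y)
  if (ncol(Ym) != nrow(P))
    paStop("Y must live on the components' grid", "pa_geometry_error")
  good <- rowSums(is.finite(Ym)) == ncol(Ym)
  B <- matrix(NA_real_, nrow(Ym), ncol(P))
  if (any(good)) {
    G <- crossprod(P)
    B[good, ] <- t(solve(G, t(Ym[good, , drop = FALSE] %*% P)))
  }
  pred <- B %*% t(P)
  new("ModelFit", betas = B, predicted = pred,
      rrmse = rep(NA_real_, nrow(Ym)), grid = as.numeric(grid))
}

#' Relative root mean squared error (Rrmse)
#'
#' Rrmse = Mrmse / Drmse, where Mrmse is the RMS error of the model
#' prediction against the even-beat waveform and Drmse the RMS difference
#' between the even and odd waveforms (test-retest error). Values below 1
#' mean the model predicts the held-out half better than the data predict
#' themselves; a perfect model of a signal with additive zero-mean Gaussian
#' noise has expectation 1/sqrt(2).
#'
#' @param predicted model prediction(s): vector or voxels x grid matrix
#'   (typically fitted on the odd half), or a [ModelFit-class].
#' @param even,odd the two half waveforms, same shape as `predicted`.
#' @return Numeric vector of scores (Inf when Drmse = 0 with Mrmse > 0;
#'   0 when both are 0). For [ModelFit-class] input, the fit is returned
#'   with its `rrmse` slot filled.
#' @examples
#' rrmse(c(1, 2), even = c(1, 2), odd = c(0, 0))  # 0: perfect prediction
#' @export
rrmse <- function(predicted, even, odd) {
  isFit <- is(predicted, "ModelFit")
  P <- if (isFit) predicted@predicted else predicted
  toM <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  P <- toM(P); E <- toM(even); O <- toM(odd)
  if (!all(dim(P) == dim(E)) || !all(dim(P) == dim(O)))
    paStop("predicted, even and odd must share dimensions",
           "pa_geometry_error")
  m <- sqrt(rowMeans((E - P)^2))
  d <- sqrt(rowMeans((E - O)^2))
  r <- ifelse(d > 0, m / d, ifelse(m > 0, Inf, 0))
  if (isFit) {
    predicted@rrmse <- as.numeric(r)
    predicted
  } else if (is.null(dim(predicted))) as.numeric(r) else r
}

# 3-point parabolic refinement of a grid extremum (for a minimum of y);
# returns the refined abscissa, clamped to +/- half a grid step.
.parabolicRefine <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(den) < 1e-12) return(x[i])
  step <- x[2] - x[1]
  off <- 0.5 * (y[i - 1] - y[i + 1]) / den * step
  x[i] + max(-step / 2, min(step / 2, off))
}

#' Times of the modeled waveform's extrema
#'
#' Locates the global minimum and maximum of the (modeled) waveform inside a
#' cycle-fraction search window (default -0.5 to 0.66, the display range of
#' the modeled responses), refined by 3-point parabolic interpolation around
#' the grid extremum. The window is treated as closed; at exact ties the
#' earliest time wins. A flat waveform has undefined extrema (NA, voxel
#' masked).
#'
#' @param fit a [ModelFit-class], a numeric waveform on `grid`, or a
#'   voxels x grid matrix.
#' @param grid cycle-fraction grid (taken from the fit when available).
#' @param searchWindow cycle-fraction interval, default `c(-0.5, 0.66)`.
#' @param flatTol amplitude below which a waveform counts as flat.
#' @return A data.frame with `tMin`, `tMax` (cycle fraction) and
#'   `dominantSign` (+1 if the largest-|.| extremum is the maximum, -1 if
#'   the minimum), one row per voxel.
#' @examples
#' g <- cycleFractionGrid()
#' extremaTimes(-cos(2 * pi * g), grid = g)  # minimum at 0
#' @export
extremaTimes <- function(fit, grid = NULL, searchWindow = c(-0.5, 0.66),
                         flatTol = 1e-9) {
  if (is(fit, "ModelFit")) {
    W <- fit@predicted
    grid <- fit@grid
  } else {
    W <- if (is.null(dim(fit))) matrix(fit, nrow = 1) else as.matrix(fit)
    if (is.null(grid)) grid <- cycleFractionGrid(ncol(W))
  }
  sel <- which(grid >= searchWindow[1] & grid <= searchWindow[2])
  if (length(sel) < 3L)
    paStop("search window must contain at least 3 grid points",
           "pa_invalid_parameter")
  g <- grid[sel]
  out <- data.frame(tMin = rep(NA_real_, nrow(W)), tMax = NA_real_,
                    dominantSign = NA_real_)
  for (v in seq_len(nrow(W))) {
    y <- W[v, sel]
    if (!all(is.finite(y)) || diff(range(y)) < flatTol) next
    iMin <- which.min(y)   # which.* return the earliest tie
    iMax <- which.max(y)
    out$tMin[v] <- .parabolicRefine(g, y, iMin)
    out$tMax[v] <- .parabolicRefine(g, -y, iMax)
    out$dominantSign[v] <- if (abs(y[iMax]) >= abs(y[iMin])) 1 else -1
  }
  out
}
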