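# SVD waveform model: resampling, matrix building, decomposition,
# cross-validation, canonical components, betas, Rrmse, extrema timing

test_that("cycle resampling is exact for on-grid and affine input, close for cosine", {
  g <- cycleFractionGrid(64)
  y <- rnorm(64)
  expect_equal(resampleToCycle(y, grid = g, at = g), y)

  bins <- seq(-0.45, 0.95, by = 0.05)
  ramp <- 2 * bins + 1
  out <- resampleToCycle(ramp, grid = g, at = bins)
  interior <- g >= min(bins) & g <= max(bins)
  expect_equal(out[interior], 2 * g[interior] + 1, tolerance = 1e-10)

  cosBins <- cos(2 * pi * bins)
  outC <- resampleToCycle(cosBins, grid = g, at = bins)
  expect_lt(max(abs(outC[interior] - cos(2 * pi * g[interior]))), 0.015)

  expect_null(resampleToCycle(c(NA, NA, 1), grid = g, at = bins[1:3]))
})

test_that("waveform matrix rows carry their reliability as norm, pruning the rest", {
  g <- cycleFractionGrid()
  w <- waveformTemplate("artery")(g)
  M <- rbind(w, 2 * w, w, w)
  r2 <- c(100, 50, -10, NA)
  wm <- buildWaveformMatrix(M, r2 = r2, grid = g)
  expect_equal(nrow(wm@matrix), 2L)
  expect_equal(unname(sqrt(rowSums(wm@matrix^2))), c(100, 50))
  expect_equal(wm@voxelIds, c(1L, 2L))
  # identical shapes scale to proportional rows
  expect_equal(wm@matrix[1, ] / 100, wm@matrix[2, ] / 50, tolerance = 1e-12)
  expect_error(buildWaveformMatrix(M, r2 = c(-1, -2, 0, NA), grid = g),
               class = "pa_model_error")
})

test_that("generator waveforms cluster by class template", {
  sh <- sharedSim()
  g <- cycleFractionGrid()
  wm <- buildWaveformMatrix(sh$ca, grid = g, parity = "odd")
  cls <- sh$cls[wm@voxelIds]
  keep <- wm@r2 > 70 & cls != "null"   # the best-averaged half of voxels
  # oracle: the class template centered to zero time-mean, because percent
  # modulation removes each voxel's mean over the whole acquisition
  cosSim <- vapply(which(keep), function(i) {
    tmpl <- centeredTemplate(cls[i], g)
    sum(wm@matrix[i, ] * tmpl) / sqrt(sum(wm@matrix[i, ]^2) * sum(tmpl^2))
  }, numeric(1))
  expect_gt(mean(cosSim > 0.9), 0.95)
})

test_that("SVD recovers rank-1 structure with orthonormal signed components", {
  g <- cycleFractionGrid(32)
  tc <- -abs(sin(2 * pi * g)) - 0.2          # negative at fraction 0
  A <- outer(c(3, 1, 2), tc)
  sv <- svdDecompose(A, grid = g)
  expect_gt(singularValues(sv)[1], 1)
  expect_lt(singularValues(sv)[2] / singularValues(sv)[1], 1e-12)
  cc <- components(sv)[, 1]
  expect_gt(abs(sum(cc * tc)) / sqrt(sum(tc^2)), 1 - 1e-12)  # proportional
  expect_lt(cc[which.min(abs(g))], 0)                        # sign rule
  # reconstruction at full rank
  rec <- sv@spatialWeights %*% diag(singularValues(sv)) %*% t(components(sv))
  expect_lt(max(abs(rec - A)) / max(abs(A)), 1e-8)
  expect_error(svdDecompose(matrix(0, 3, 4)), class = "pa_model_error")
  expect_error(svdDecompose(matrix(1, 1, 4)), class = "pa_model_error")
})

test_that("rank-2 components span the generating pair within 10 degrees", {
  set.seed(12)
  g <- cycleFractionGrid()
  U <- canonicalPair(g)
  B <- cbind(rnorm(300), rnorm(300, 0, 0.6))
  M <- B %*% t(U) + matrix(rnorm(300 * length(g), 0, 0.05), 300)
  sv <- svdDecompose(M, grid = g)
  V2 <- components(sv)[, 1:2]
  # principal angles between the two 2D subspaces
  ang <- acos(pmin(1, svd(crossprod(U, V2))$d)) * 180 / pi
  expect_lt(max(ang), 10)
})

test_that("cross-validated variance explained behaves and selects components", {
  h <- rank2Halves(nVox = 400, seed = 2)
  g <- cycleFractionGrid()
  r2 <- vapply(seq_len(nrow(h$even)), function(i)
    reliabilityR2(h$even[i, ], h$odd[i, ]), numeric(1))
  tr <- buildWaveformMatrix(h$odd, r2 = r2, grid = g)
  te <- buildWaveformMatrix(h$even, r2 = r2, grid = g)
  cv <- cvVarianceExplained(tr, te, k = 2)
  expect_true(all(diff(cv$curve) > -1e-9))           # monotone in k
  expect_equal(cv$nSelected, 2L)

  # test = train reaches 100 at full rank; k capped at rank
  cvSelf <- cvVarianceExplained(tr, tr, k = 999)
  expect_equal(max(cvSelf$curve), 100, tolerance = 1e-6)
  expect_equal(cvSelf$percent, 100, tolerance = 1e-6)

  # k = 0 explains nothing
  expect_equal(cvVarianceExplained(tr, te, k = 0)$percent, 0)
})

test_that("canonical components pool subjects and honor leave-one-out", {
  g <- cycleFractionGrid(64)
  U <- canonicalPair(g)
  same <- list(s1 = U, s2 = U, s3 = U)
  cc <- canonicalComponents(same, heldOut = "s3", k = 2, grid = g)
  expect_equal(cc@trainingSubjects, c("s1", "s2"))
  ang <- acos(pmin(1, svd(crossprod(U, components(cc)))$d)) * 180 / pi
  expect_lt(max(ang), 1e-6)

  # small rotations of a common pair: canonical pair within 5 degrees
  rot <- function(theta) U %*% matrix(c(cos(theta), sin(theta),
                                        -sin(theta), cos(theta)), 2)
  subs <- list(a = rot(0.05), b = rot(-0.04), c = rot(0.08), d = rot(-0.06))
  cc2 <- canonicalComponents(subs, heldOut = "d", k = 2, grid = g)
  ang2 <- acos(pmin(1, svd(crossprod(U, components(cc2)))$d)) * 180 / pi
  expect_lt(max(ang2), 5)

  expect_warning(canonicalComponents(list(s1 = U), k = 2, grid = g),
                 "single training subject")
  expect_error(canonicalComponents(same, heldOut = "nope", k = 2, grid = g),
               class = "pa_config_error")
})

test_that("beta fitting is exact in-span and calibrated under noise", {
  g <- cycleFractionGrid(64)
  U <- canonicalPair(g)
  pcs <- new("CanonicalComponents", components = U, grid = g,
             trainingSubjects = "t", signConvention = "none")
  f1 <- fitBetas(U[, 1], pcs)
  expect_equal(unname(betas(f1)[1, ]), c(1, 0), tolerance = 1e-10)

  y <- 3 * U[, 1] - 2 * U[, 2]
  f2 <- fitBetas(y, pcs)
  expect_equal(unname(betas(f2)[1, ]), c(3, -2), tolerance = 1e-10)
  expect_lt(max(abs(predicted(f2)[1, ] - y)), 1e-10)

  # Monte-Carlo: 500 voxels, known betas + noise sigma; with an orthonormal
  # design the beta sampling SD equals sigma (closed-form least squares)
  set.seed(3)
  sigma <- 0.3
  Btrue <- cbind(rnorm(500, 2, 1), rnorm(500, -1, 1))
  Y <- Btrue %*% t(U) + matrix(rnorm(500 * length(g), 0, sigma), 500)
  f3 <- fitBetas(Y, pcs)
  err <- betas(f3) - Btrue
  expect_lt(max(abs(colMeans(err))), 3 * sigma / sqrt(500))   # unbiased
  expect_lt(abs(sd(err[, 1]) - sigma) / sigma, 0.2)
  expect_lt(abs(sd(err[, 2]) - sigma) / sigma, 0.2)
})

test_that("Rrmse is 0 for perfect prediction, 1 when predicting the odd half", {
  even <- c(1.5, -2, 0.5, 1)
  odd <- c(1.2, -1.7, 0.8, 0.9)
  expect_equal(rrmse(even, even = even, odd = odd), 0)
  expect_equal(rrmse(odd, even = even, odd = odd), 1)
  expect_identical(rrmse(c(1, 1), even = c(0, 0), odd = c(0, 0)), Inf)
  expect_identical(rrmse(c(0, 0), even = c(0, 0), odd = c(0, 0)), 0)
})

test_that("a perfect model under Gaussian noise has mean Rrmse near 1/sqrt(2)", {
  set.seed(4)
  G <- 128
  n <- 10000
  truth <- matrix(rep(waveformTemplate("vein")(cycleFractionGrid(G)), n),
                  n, byrow = TRUE)
  sigma <- 0.5
  even <- truth + matrix(rnorm(n * G, 0, sigma), n)
  odd <- truth + matrix(rnorm(n * G, 0, sigma), n)
  r <- rrmse(truth, even = even, odd = odd)
  expect_gt(mean(r), 0.69)
  expect_lt(mean(r), 0.72)
})

test_that("extrema timing finds, refines and masks correctly", {
  g <- cycleFractionGrid()
  ext <- extremaTimes(-cos(2 * pi * g), grid = g)
  expect_equal(ext$tMin, 0, tolerance = 1e-6)
  expect_equal(ext$tMax, -0.5)   # tie at +/-0.5: earliest grid point wins

  art <- extremaTimes(waveformTemplate("artery")(g), grid = g)
  expect_lt(abs(art$tMin - (-0.15)), 1.5 / 128)
  expect_equal(art$dominantSign, -1)
  csf <- extremaTimes(waveformTemplate("csf")(g), grid = g)
  expect_lt(abs(csf$tMax - 0.05), 1.5 / 128)
  expect_equal(csf$dominantSign, 1)

  flat <- extremaTimes(rep(1, 128), grid = g)
  expect_true(is.na(flat$tMin) && is.na(flat$tMax))

  # parabolic refinement beats the grid for an off-grid extremum
  coarse <- cycleFractionGrid(40)
  y <- -exp(-(coarse - 0.123)^2 / (2 * 0.1^2))
  extc <- extremaTimes(y, grid = coarse)
  gridStep <- coarse[2] - coarse[1]
  expect_lt(abs(extc$tMin - 0.123), gridStep / 2)
})

test_that("the model pipeline is equivariant to positive rescaling", {
  h <- rank2Halves(nVox = 200, seed = 6)
  g <- cycleFractionGrid()
  r2 <- vapply(seq_len(nrow(h$even)), function(i)
    reliabilityR2(h$even[i, ], h$odd[i, ]), numeric(1))
  c0 <- 7.3
  run <- function(scale) {
    tr <- buildWaveformMatrix(scale * h$odd, r2 = r2, grid = g)
    sv <- svdDecompose(tr)
    pcs <- new("CanonicalComponents", components = components(sv)[, 1:2],
               grid = g, trainingSubjects = "t", signConvention = "none")
    fit <- fitBetas(scale * h$odd[tr@voxelIds, ], pcs)
    fit <- rrmse(fit, even = scale * h$even[tr@voxelIds, ],
                 odd = scale * h$odd[tr@voxelIds, ])
    list(sv = sv, fit = fit, ext = extremaTimes(fit))
  }
  a <- run(1); b <- run(c0)
  expect_equal(components(a$sv)[, 1:2], components(b$sv)[, 1:2],
               tolerance = 1e-8)
  expect_equal(betas(b$fit) / betas(a$fit),
               matrix(c0, nrow(betas(a$fit)), 2), tolerance = 1e-6)
  expect_equal(rrmseValues(a$fit), rrmseValues(b$fit), tolerance = 1e-8)
  expect_equal(a$ext$tMin, b$ext$tMin, tolerance = 1e-10)
})
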