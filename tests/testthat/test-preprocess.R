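make_cube <- function(S, h, w, axis) {
  # S: npix x B matrix, column-major pixel order
  hyperCube(array(as.vector(S), dim = c(h, w, ncol(S))), axis)
}

test_that("quality control retains clean tissue and rejects artifacts", {
  ax <- spectralAxis()
  lib <- defaultBandLibrary()
  tissue <- classSpectrum("connective", lib, ax)
  zero <- numeric(length(wavenumbers(ax)))
  sat <- tissue + 10
  S <- rbind(tissue, zero, sat, tissue)
  cube <- make_cube(S, 2, 2, ax)
  mask <- qualityFilter(cube)
  expect_identical(qcKeep(mask), matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_identical(qcReason(mask)[2, 1], "low-signal")
  expect_identical(qcReason(mask)[1, 2], "saturated")
})

test_that("quality control is monotone in amide signal below saturation", {
  ax <- spectralAxis()
  base <- classSpectrum("lumen", defaultBandLibrary(), ax)
  set.seed(4)
  noise <- matrix(rnorm(12 * length(base), 0, 0.005), 12)
  scales <- rep(c(1, 2, 4, 8), each = 3)
  S <- t(sapply(seq_along(scales), function(i) scales[i] * base + noise[i, ]))
  mask <- qualityFilter(make_cube(S, 12, 1, ax))
  keep <- qcKeep(mask)[, 1]
  expect_true(all(keep[1:3] <= keep[4:6]))
  expect_true(all(keep[4:6] <= keep[7:9]))
  # once retained, scaling up (below saturation) never loses retention
  expect_true(all(keep[7:12]))
})

test_that("regions outside the axis raise parameter errors", {
  ax <- spectralAxis(high = 1500, low = 1200, spacing = 2)
  cube <- hyperCube(array(1, dim = c(2, 2, length(wavenumbers(ax)))), ax)
  expect_error(qualityFilter(cube), "not covered")
})

test_that("van de Hulst extinction matches its closed form and limits", {
  expect_identical(vdhExtinction(0), 0)
  expect_equal(vdhExtinction(2 * pi), 2, tolerance = 1e-12)
  # 50-term Taylor series oracle at rho = 1
  kk <- 1:50
  sinSeries <- sum((-1)^(kk - 1) / factorial(2 * kk - 1))        # sin(1)
  cosSeries <- 1 + sum((-1)^kk / factorial(2 * kk))              # cos(1)
  oracle <- 2 - 4 * sinSeries + 4 * (1 - cosSeries)
  expect_equal(vdhExtinction(1), oracle, tolerance = 1e-10)
  # series branch agrees with the closed form just inside the switch radius
  r <- 0.99e-2
  closed <- 2 - (4 / r) * sin(r) + (4 / r^2) * (1 - cos(r))
  expect_equal(vdhExtinction(r), closed, tolerance = 1e-6)
  expect_equal(vdhExtinction(1e-4), (1e-4)^2 / 2, tolerance = 1e-9)
  expect_gte(vdhExtinction(1e6), 1.99)
  expect_error(vdhExtinction(-1), "domain error")
})

test_that("the Mie basis is orthonormal and spans the curve family", {
  ax <- spectralAxis()
  ref <- testReference(ax)
  expect_error(buildMieBasis(ax, ref, nGrid = 1.0), "basis error")

  # two-curve family: the single component is the normalized centered curve
  b1 <- buildMieBasis(ax, ref, dGrid = c(5, 10), nGrid = 1.3, K = 1L)
  wn <- wavenumbers(ax)
  q1 <- vdhExtinction(2 * pi * 5e-4 * 0.3 * wn)
  q2 <- vdhExtinction(2 * pi * 10e-4 * 0.3 * wn)
  cen <- q1 - (q1 + q2) / 2
  cen <- cen / sqrt(sum(cen^2))
  comp <- b1@components[, 1]
  expect_equal(abs(sum(comp * cen)), 1, tolerance = 1e-9)

  # default grids: orthonormal, and K = 6 explains >= 95% of family variance
  basis <- buildMieBasis(ax, ref)
  G <- crossprod(basis@components)
  expect_lt(max(abs(G - diag(6))), 1e-8)
  fam <- sapply(basis@nGrid, function(n) sapply(basis@dGrid, function(d)
    vdhExtinction(2 * pi * d * 1e-4 * (n - 1) * wn)))
  fam <- matrix(fam, nrow = length(wn))
  cenF <- fam - rowMeans(fam)
  sv <- svd(cenF)    # full-rank SVD oracle
  expect_gte(sum(sv$d[1:6]^2) / sum(sv$d^2), 0.95)
})

test_that("EMSC fit recovers constructed coefficients exactly", {
  ax <- spectralAxis()
  ref <- testReference(ax)
  basis <- buildMieBasis(ax, ref)
  wn <- wavenumbers(ax)

  f <- emscFit(ref, basis)
  expect_equal(f@c, 1, tolerance = 1e-8)
  expect_lt(max(abs(c(f@a, f@b, f@g))), 1e-8)
  expect_lt(f@residualRms, 1e-8)

  f2 <- emscFit(2 * ref + 0.5, basis)
  expect_equal(f2@c, 2, tolerance = 1e-8)
  expect_equal(f2@a, 0.5, tolerance = 1e-8)
  expect_lt(max(abs(c(f2@b, f2@g))), 1e-8)

  f3 <- emscFit(ref + 0.3 * basis@components[, 2], basis)
  expect_equal(f3@g[2], 0.3, tolerance = 1e-8)
  expect_lt(max(abs(f3@g[-2])), 1e-8)

  f4 <- emscFit(1.5 * ref + 0.2 - 1e-4 * wn + 0.1 * basis@components[, 5],
                basis)
  expect_equal(f4@c, 1.5, tolerance = 1e-8)
  expect_equal(f4@b, -1e-4, tolerance = 1e-10)
  expect_equal(f4@g[5], 0.1, tolerance = 1e-8)
})

test_that("EMSC fitter agrees with a brute-force normal-equations oracle", {
  ax <- spectralAxis(high = 1800, low = 1000, spacing = 8)
  wn <- wavenumbers(ax)
  set.seed(11)
  for (i in 1:100) {
    ref <- abs(rnorm(1, 1, 0.2)) *
      exp(-(wn - 1656)^2 / (2 * (runif(1, 30, 70) / 2.3548)^2)) + 0.05
    basis <- buildMieBasis(ax, ref, dGrid = runif(3, 2, 20),
                           nGrid = runif(2, 1.1, 1.5), K = 2L)
    s <- ref * rnorm(1, 1, 0.3) + rnorm(length(wn), 0, 0.05)
    f <- emscFit(s, basis)
    # normal equations on a unit-scaled design (slope column in kcm^-1)
    X <- cbind(ref, 1, wn / 1000, basis@components)
    beta <- solve(crossprod(X), crossprod(X, s))
    beta[3] <- beta[3] / 1000
    expect_equal(c(f@c, f@a, f@b, f@g), as.vector(beta), tolerance = 1e-8)
  }
})

test_that("correct-then-fit is the identity within 1e-6", {
  ax <- spectralAxis()
  ref <- testReference(ax)
  basis <- buildMieBasis(ax, ref)
  s <- applyMieDistortion(1.4 * ref + 0.1, d = 7, n = 1.3, scale = 0.15, ax)
  fit <- emscFit(s, basis)
  corr <- emscCorrect(s, fit, basis)
  refit <- emscFit(corr, basis)
  expect_equal(refit@c, 1, tolerance = 1e-6)
  expect_lt(max(abs(c(refit@a, refit@b, refit@g))), 1e-6)

  expect_equal(emscCorrect(ref, emscFit(ref, basis), basis), ref,
               tolerance = 1e-8)
  expect_equal(emscCorrect(2 * ref + 0.5, emscFit(2 * ref + 0.5, basis),
                           basis), ref, tolerance = 1e-8)
})

test_that("correction removes in-grid Mie distortion from phantom spectra", {
  ax <- spectralAxis()
  lib <- defaultBandLibrary()
  s0 <- classSpectrum("crypts", lib, ax)
  basis <- buildMieBasis(ax, testReference(ax))
  correct <- function(x) emscCorrect(x, emscFit(x, basis), basis)
  set.seed(21)
  for (i in 1:10) {
    d <- runif(1, 2, 20); n <- runif(1, 1.1, 1.5)
    dist <- applyMieDistortion(s0, d, n, scale = 0.1, ax)
    pre <- sqrt(mean((dist - s0)^2))
    post <- sqrt(mean((correct(dist) - correct(s0))^2))
    expect_lte(post, 0.1 * pre)
  }
})

test_that("a fit with tiny reference coefficient is rejected", {
  ax <- spectralAxis()
  ref <- testReference(ax)
  basis <- buildMieBasis(ax, ref)
  s <- 0.01 * ref
  expect_error(emscCorrect(s, emscFit(s, basis), basis),
               "correction rejected")
})

test_that("cube-level Mie correction: identity, passthrough and efficacy", {
  ax <- spectralAxis()
  ref <- testReference(ax)
  # uniform cube: reference is (a scaled version of) every pixel -> self-fit
  S <- matrix(rep(ref, each = 9), 9)
  cube <- make_cube(S, 3, 3, ax)
  keep <- matrix(TRUE, 3, 3); keep[2, 2] <- FALSE
  reason <- matrix("", 3, 3); reason[2, 2] <- "low-snr"
  mask <- new("QCMask", keep = keep, reason = reason)
  out <- mieCorrectCube(cube, mask)
  S1 <- matrix(cubeData(out$cube), 9, ncol(S))
  # masked-out pixel bit-identical to input
  expect_identical(S1[5, ], S[5, ])
  # retained pixels: corrected spectra all equal (uniform input stays uniform)
  expect_lt(max(apply(S1[-5, ], 2, function(col) diff(range(col)))), 1e-8)
  expect_error(
    mieCorrectCube(cube, new("QCMask", keep = matrix(FALSE, 3, 3),
                             reason = matrix("low-snr", 3, 3))),
    "empty-mask")
})

test_that("one and two correction iterations both reduce distortion", {
  spD <- phantomSpec(height = 48, width = 48, seed = 31L, mieScale = 0.1)
  spC <- phantomSpec(height = 48, width = 48, seed = 31L, mieScale = 0)
  synD <- synthesizeCube(spD); synC <- synthesizeCube(spC)
  mD <- qualityFilter(synD$cube); mC <- qualityFilter(synC$cube)
  for (iters in 1:2) {
    cD <- mieCorrectCube(synD$cube, mD, iterations = iters)
    cC <- mieCorrectCube(synC$cube, mC, iterations = iters)
    np <- 48 * 48
    B <- length(wavenumbers(spD@axis))
    raw <- rowMeans((matrix(cubeData(synD$cube), np, B) -
                     matrix(cubeData(synC$cube), np, B))^2)
    cor <- rowMeans((matrix(cubeData(cD$cube), np, B) -
                     matrix(cubeData(cC$cube), np, B))^2)
    sel <- raw > 0 & as.vector(qcKeep(cD$mask) & qcKeep(cC$mask))
    expect_lt(median(sqrt(cor[sel])) / median(sqrt(raw[sel])), 0.5)
  }
})

test_that("Savitzky-Golay second derivative is exact for low-order polynomials", {
  x <- seq(1, 50)
  expect_equal(secondDerivative(x^2, spacing = 1), rep(2, 50),
               tolerance = 1e-9)
  expect_lt(max(abs(secondDerivative(rep(3.7, 20), spacing = 1))), 1e-12)
  # cubic on a 2 cm^-1 grid: interior exact
  wn <- seq(1800, 1700, by = -2)
  y <- 2 * wn^3 - wn^2 + 5
  expect_equal(secondDerivative(y, spacing = 2)[5:47], (12 * wn - 2)[5:47],
               tolerance = 1e-6)
  expect_error(secondDerivative(rnorm(5), spacing = 1), "length error")
})

test_that("SG derivative approximates the analytic Gaussian curvature", {
  wn <- seq(1800, 948, by = -2)
  c0 <- 1400; fwhm <- 80; sg <- fwhm / (2 * sqrt(2 * log(2)))
  g <- exp(-(wn - c0)^2 / (2 * sg^2))
  d2 <- secondDerivative(g, spacing = 2)
  ana <- ((wn - c0)^2 / sg^4 - 1 / sg^2) * g
  i <- which(wn == c0)
  expect_lt(d2[i], 0)                       # negative peak at the band center
  expect_equal(d2[i], ana[i], tolerance = 0.02)
})

test_that("the SG operator is linear", {
  set.seed(8)
  s <- rnorm(60); t <- rnorm(60)
  lhs <- secondDerivative(2.5 * s - 1.25 * t, spacing = 2)
  rhs <- 2.5 * secondDerivative(s, spacing = 2) -
         1.25 * secondDerivative(t, spacing = 2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("fingerprint cropping yields the documented channel counts", {
  ax <- spectralAxis(high = 1800, low = 948, spacing = 2)
  cube <- hyperCube(array(0, dim = c(2, 2, length(wavenumbers(ax)))), ax)
  fp <- cropFingerprint(cube)
  expect_identical(dim(fp)[3], 382L)
  expect_equal(range(wavenumbers(fp)), c(998, 1760))

  one <- cropFingerprint(cube, low = 1656, high = 1656)
  expect_identical(dim(one)[3], 1L)

  ax4 <- spectralAxis(high = 1760, low = 1000, spacing = 4)
  cube4 <- hyperCube(array(0, dim = c(2, 2, length(wavenumbers(ax4)))), ax4)
  expect_identical(dim(cropFingerprint(cube4, 1000, 1760))[3], 191L)

  expect_error(cropFingerprint(cube, low = 100, high = 200),
               "parameter error")
})

test_that("spectral downsampling decimates from the highest wavenumber", {
  ax <- spectralAxis(high = 1760, low = 998, spacing = 2)
  cube <- hyperCube(array(rnorm(2 * 2 * 382), dim = c(2, 2, 382)), ax)
  expect_identical(downsampleCube(cube, 2), cube)
  d4 <- downsampleCube(cube, 4)
  expect_identical(dim(d4)[3], 191L)
  expect_equal(wavenumbers(d4)[1], 1760)
  d16 <- downsampleCube(cube, 16)
  expect_identical(dim(d16)[3], 48L)   # ceiling(382 / 8)
  expect_equal(axisSpacing(d16), 16)
  expect_equal(cubeData(d16)[1, 1, ], cubeData(cube)[1, 1, seq(1, 382, 8)])
  expect_error(downsampleCube(cube, 5), "parameter error")
})

test_that("overview image picks the nearest channel, ties to higher wavenumber", {
  ax <- spectralAxis()
  arr <- array(0, dim = c(2, 2, length(wavenumbers(ax))))
  arr[, , which(wavenumbers(ax) == 1656)] <- 3
  cube <- hyperCube(arr, ax)
  img <- overviewImage(cube, 1656)
  expect_equal(attr(img, "wavenumber"), 1656)
  expect_true(all(img == 3))
  expect_equal(attr(overviewImage(cube, 1657), "wavenumber"), 1658)
  expect_true(all(overviewImage(hyperCube(array(0, dim = dim(arr)), ax)) == 0))
  expect_error(overviewImage(cube, 900), "parameter error")
})
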