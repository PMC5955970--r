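test_that("training is deterministic and reaches high out-of-bag accuracy", {
  casc <- fixtureCascade()
  expect_gte(casc@oob[["level1"]], 0.95)
  expect_gte(casc@oob[["level2"]], 0.95)

  # same seed twice: identical predictions on a fixed probe set
  syn <- fixturePhantom()
  pre <- preprocessCube(syn$cube)
  maps1 <- classifyCube(pre$cube, casc, pre$mask)
  maps2 <- classifyCube(pre$cube, casc, pre$mask)
  expect_identical(labelCodes(maps1$level1), labelCodes(maps2$level1))
  expect_identical(labelCodes(maps1$level2), labelCodes(maps2$level2))
})

test_that("classification recovers phantom ground truth and routes subtypes", {
  casc <- fixtureCascade()
  syn <- fixturePhantom()
  pre <- preprocessCube(syn$cube)
  maps <- classifyCube(pre$cube, casc, pre$mask)
  l1 <- labelCodes(maps$level1); l2 <- labelCodes(maps$level2)

  expect_gte(tissueAccuracy(maps$level1, syn$truth, pre$mask), 0.90)
  # QC-rejected pixels are background in both maps
  expect_true(all(l1[!qcKeep(pre$mask)] == 0L))
  expect_true(all(l2[!qcKeep(pre$mask)] == 0L))
  # level-2 nonzero only where level 1 is pathological or inflammatory
  expect_true(all(l1[l2 %in% 1:3] == 1L))
  expect_true(all(l1[l2 == 4L] == 2L))
  # inflammatory pixels pass through unchanged into the level-2 map
  expect_true(all(l2[l1 == 2L] == 4L))
  expect_true(all(l2[l1 %in% 3:6] == 0L))

  # a fully masked cube yields all-zero maps
  allOff <- new("QCMask", keep = matrix(FALSE, 64, 64),
                reason = matrix("low-snr", 64, 64))
  zero <- classifyCube(pre$cube, casc, allOff)
  expect_true(all(labelCodes(zero$level1) == 0L))
  expect_true(all(labelCodes(zero$level2) == 0L))
})

test_that("axis mismatches are grid errors", {
  casc <- fixtureCascade()
  syn <- fixturePhantom()
  pre <- preprocessCube(syn$cube)
  wrong <- downsampleCube(pre$cube, 4)
  expect_error(classifyCube(wrong, casc, pre$mask), "grid error")
})

test_that("Gini importances are normalized and localize discriminant bands", {
  casc <- fixtureCascade()
  imp <- variableImportance(casc)
  expect_equal(sum(imp$level1), 1, tolerance = 1e-9)
  expect_equal(sum(imp$level2), 1, tolerance = 1e-9)

  # classes differing in exactly one band: top importances inside its FWHM
  ax <- spectralAxis(high = 1760, low = 998, spacing = 2)
  wn <- wavenumbers(ax)
  set.seed(6)
  n <- 120
  base <- 0.5 * exp(-(wn - 1300)^2 / (2 * (60 / 2.3548)^2))
  marker <- exp(-(wn - 1080)^2 / (2 * (30 / 2.3548)^2))
  X <- rbind(
    t(replicate(n, base + rnorm(length(wn), 0, 0.01))),
    t(replicate(n, base + 0.4 * marker + rnorm(length(wn), 0, 0.01))))
  mkdb <- function(X, classes, level, roster) {
    n <- nrow(X)
    new("SpectralDatabase", spectra = X,
        classes = factor(classes, levels = roster), level = level, axis = ax,
        provenance = data.frame(cube = 1L, row = seq_len(n), col = 1L))
  }
  db1 <- mkdb(X, rep(c("connective", "pathological"), each = n), 1L,
              c("connective", "pathological"))
  db2 <- mkdb(X, rep(c("tumor", "necrosis"), each = n), 2L,
              c("tumor", "necrosis"))
  cascM <- trainCascade(db1, db2, nTrees = 100L, seed = 2L)
  impM <- variableImportance(cascM)$level1
  top <- as.numeric(names(sort(impM, decreasing = TRUE)[1:5]))
  expect_true(all(abs(top - 1080) <= 30))   # within +/- FWHM of the marker
  expect_gt(max(impM) / mean(impM), 15)     # sharply localized

  # identical spectra across classes: no informative split exists, so the
  # importance distribution is flat (no wavenumber dominates)
  Xsame <- rbind(X[1:n, ], X[1:n, ])
  dbS1 <- mkdb(Xsame, rep(c("connective", "pathological"), each = n), 1L,
               c("connective", "pathological"))
  cascS <- trainCascade(dbS1, db2, nTrees = 100L, seed = 3L)
  impS <- variableImportance(cascS)$level1
  expect_lt(max(impS) / mean(impS), 5)
})

test_that("a single-class degenerate forest always predicts that class", {
  ax <- spectralAxis(high = 1760, low = 998, spacing = 2)
  wn <- wavenumbers(ax)
  set.seed(3)
  X <- t(replicate(30, exp(-(wn - 1656)^2 / 1800) + rnorm(length(wn), 0, 0.01)))
  db1 <- new("SpectralDatabase", spectra = X,
             classes = factor(rep("pathological", 30)), level = 1L, axis = ax,
             provenance = data.frame(cube = 1L, row = 1:30, col = 1L))
  db2 <- new("SpectralDatabase", spectra = X,
             classes = factor(rep("tumor", 30)), level = 2L, axis = ax,
             provenance = data.frame(cube = 1L, row = 1:30, col = 1L))
  casc <- trainCascade(db1, db2, nTrees = 1L, seed = 1L)
  probe <- hyperCube(array(as.vector(X[1:4, ]), dim = c(2, 2, length(wn))), ax)
  mask <- new("QCMask", keep = matrix(TRUE, 2, 2),
              reason = matrix("", 2, 2))
  maps <- classifyCube(probe, casc, mask)
  expect_true(all(labelCodes(maps$level1) == 1L))   # pathological everywhere
  expect_true(all(labelCodes(maps$level2) == 1L))   # tumor everywhere
})

test_that("cascades retrained on coarser grids lose little accuracy", {
  spec <- phantomSpec(height = 96, width = 96)
  accs <- sapply(c(2, 4, 8), function(ts) {
    train <- lapply(1:2, function(i) {
      sp <- spec; sp@seed <- 60L + i
      syn <- synthesizeCube(sp)
      mask <- qualityFilter(syn$cube)
      cor <- mieCorrectCube(syn$cube, mask)
      cube <- downsampleCube(cropFingerprint(cor$cube), ts)
      list(cube = cube, truth = syn$truth, mask = cor$mask)
    })
    db1 <- buildDatabase(lapply(train, `[[`, "cube"),
                         lapply(train, `[[`, "truth"),
                         lapply(train, `[[`, "mask"), 1L,
                         perClassCap = 150L, seed = 9L)
    db2 <- buildDatabase(lapply(train, `[[`, "cube"),
                         lapply(train, `[[`, "truth"),
                         lapply(train, `[[`, "mask"), 2L,
                         perClassCap = 150L, seed = 10L)
    casc <- trainCascade(db1, db2, nTrees = 150L, seed = 11L)
    syn <- synthesizeCube(phantomSpec(height = 64, width = 64, seed = 77L))
    mask <- qualityFilter(syn$cube)
    cor <- mieCorrectCube(syn$cube, mask)
    cube <- downsampleCube(cropFingerprint(cor$cube), ts)
    maps <- classifyCube(cube, casc, cor$mask)
    tissueAccuracy(maps$level1, syn$truth, cor$mask)
  })
  expect_lte(accs[1] - accs[2], 0.05)
  expect_lte(accs[1] - accs[3], 0.05)
})
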