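# Two-level random-forest cascade. The first forest discriminates healthy
# tissue types from pathological; spectra the first forest calls
# pathological are presented to the second forest, which resolves tumor,
# necrosis and inflammation. Both forests consume the identical unsmoothed
# Mie-corrected fingerprint vector. Vote aggregation is done in the package
# (majority over trees, ties broken toward the lowest class code) so that
# classification is exactly reproducible.

#' Train the two-level cascade
#'
#' Both forests use the same hyperparameters: `nTrees` trees and
#' `featuresPerSplit` candidate wavenumbers per split (clamped to the
#' feature count when the grid is shorter, e.g. after downsampling).
#' Gini (impurity) variable importance is recorded, as is out-of-bag
#' accuracy per level. Deterministic given `seed` (single-threaded).
#'
#' @param db1 level-1 [SpectralDatabase-class] (must include a
#'   `pathological` class).
#' @param db2 level-2 [SpectralDatabase-class] (roster within
#'   tumor/necrosis/inflammation).
#' @param nTrees trees per forest (default 500).
#' @param featuresPerSplit candidate features per split (default 16).
#' @param seed integer seed.
#' @return A [TrainedCascade-class].
#' @export
trainCascade <- function(db1, db2, nTrees = 500L, featuresPerSplit = 16L,
                         seed = 1L) {
  if (!"pathological" %in% levels(db1@classes))
    stop("config error: level-1 database must include a 'pathological' class")
  if (db1@level != 1L || db2@level != 2L)
    stop("config error: databases must be level 1 and level 2")
  if (!isTRUE(all.equal(wavenumbers(db1@axis), wavenumbers(db2@axis))))
    stop("grid error: the two databases must share one fingerprint axis")
  B <- ncol(db1@spectra)
  mtry <- min(as.integer(featuresPerSplit), B)
  fit <- function(db, s) {
    df <- data.frame(db@spectra)
    df$.class <- factor(as.character(db@classes))
    ranger::ranger(dependent.variable.name = ".class", data = df,
                   num.trees = as.integer(nTrees), mtry = mtry,
                   importance = "impurity", seed = s, num.threads = 1L)
  }
  rf1 <- fit(db1, as.integer(seed))
  rf2 <- fit(db2, as.integer(seed) + 1L)
  new("TrainedCascade", rf1 = rf1, rf2 = rf2, axis = db1@axis,
      roster1 = levels(db1@classes), roster2 = levels(db2@classes),
      oob = c(level1 = 1 - rf1$prediction.error,
              level2 = 1 - rf2$prediction.error),
      nTrees = as.integer(nTrees),
      featuresPerSplit = as.integer(featuresPerSplit),
      seed = as.integer(seed))
}

# majority vote over per-tree predictions with deterministic tie-breaking:
# among tied classes the lowest display code wins. preds: n x ntree matrix
# of factor-level indices; prefOrder: class names in tie-preference order.
.majorityVote <- function(preds, classLevels, prefOrder) {
  n <- nrow(preds)
  counts <- matrix(0L, n, length(classLevels))
  for (j in seq_along(classLevels))
    counts[, j] <- rowSums(preds == j)
  pref <- match(classLevels, prefOrder)      # smaller = preferred
  # order columns by preference so max.col("first") breaks ties as required
  ord <- order(pref)
  classLevels[ord][max.col(counts[, ord, drop = FALSE], ties.method = "first")]
}

# display code maps
.L1CODE <- c(pathological = 1L, inflammatory = 2L, muscleA = 3L, muscleB = 3L,
             connective = 4L, crypts = 5L, lumen = 6L, debris = 0L)
.L2CODE <- c(tumor = 1L, necrosis = 2L, inflammation = 3L)

#' Classify a preprocessed cube with a trained cascade
#'
#' QC-rejected pixels receive code 0 (background, black) in both maps. The
#' first forest assigns tissue types by majority vote over trees (ties to
#' the lowest class code); debris/blood predictions map to background and
#' the two muscle subclasses merge into `muscle`. Pixels called
#' `pathological` are re-classified by the second forest into tumor,
#' necrosis or inflammation; pixels called `inflammatory` at level 1 pass
#' through unchanged (yellow) into the level-2 map; every other tissue type
#' is background in the level-2 map.
#'
#' @param cube Mie-corrected [HyperCube-class] cropped to the cascade's
#'   fingerprint grid.
#' @param cascade a [TrainedCascade-class].
#' @param mask a [QCMask-class].
#' @return A list with `level1` and `level2` [LabelMap-class] maps.
#' @export
classifyCube <- function(cube, cascade, mask) {
  if (!isTRUE(all.equal(wavenumbers(cube), wavenumbers(cascade@axis))))
    stop("grid error: cube axis does not match the cascade's fingerprint grid")
  d <- dim(cube@data)
  keep <- as.vector(mask@keep)
  l1 <- matrix(0L, d[1L], d[2L])
  l2 <- matrix(0L, d[1L], d[2L])
  if (any(keep)) {
    S <- matrix(cube@data, d[1L] * d[2L], d[3L])[keep, , drop = FALSE]
    df <- data.frame(S)
    names(df) <- cascade@rf1$forest$independent.variable.names
    p1 <- stats::predict(cascade@rf1, data = df, predict.all = TRUE,
                         num.threads = 1L)$predictions
    lev1 <- cascade@rf1$forest$levels
    pref1 <- names(sort(.L1CODE[.L1CODE > 0]))        # by display code
    pref1 <- c(pref1, setdiff(lev1, pref1))           # debris last
    cls1 <- .majorityVote(p1, lev1, pref1)
    l1[keep] <- unname(.L1CODE[cls1])

    path <- cls1 == "pathological"
    if (any(path)) {
      df2 <- df[path, , drop = FALSE]
      names(df2) <- cascade@rf2$forest$independent.variable.names
      p2 <- stats::predict(cascade@rf2, data = df2, predict.all = TRUE,
                           num.threads = 1L)$predictions
      if (is.null(dim(p2))) p2 <- matrix(p2, ncol = cascade@nTrees)
      lev2 <- cascade@rf2$forest$levels
      pref2 <- names(sort(.L2CODE[lev2 %in% names(.L2CODE)]))
      cls2 <- .majorityVote(p2, lev2, pref2)
      sub <- which(keep)[path]
      l2[sub] <- unname(.L2CODE[cls2])
    }
    l2[which(keep)[cls1 == "inflammatory"]] <- 4L     # pass-through
  }
  list(level1 = labelMap(l1, level = 1L),
       level2 = labelMap(l2, level = 2L))
}

#' Per-wavenumber Gini variable importance
#'
#' Mean decrease in Gini impurity per wavenumber, normalized to sum to 1
#' per level.
#'
#' @param cascade a [TrainedCascade-class].
#' @return A list with numeric vectors `level1` and `level2`, named by
#'   wavenumber.
#' @export
variableImportance <- function(cascade) {
  wn <- wavenumbers(cascade@axis)
  norm <- function(v) {
    v <- pmax(v, 0)
    v <- if (sum(v) > 0) v / sum(v) else rep(1 / length(v), length(v))
    names(v) <- format(wn, trim = TRUE)
    v
  }
  list(level1 = norm(unname(cascade@rf1$variable.importance)),
       level2 = norm(unname(cascade@rf2$variable.importance)))
}
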