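# Curation of the two-level labeled spectral database from annotated,
# preprocessed cubes. Unsupervised clustering of smoothed second-derivative
# spectra is used to purge outlier (mislabeled or artifact) spectra from
# each class sample, mirroring database curation practice; the classifier
# itself is trained on the unsmoothed Mie-corrected spectra.

#' Unsupervised clustering of spectra
#'
#' K-means (Euclidean, deterministic given `seed`) or hierarchical
#' clustering with Ward linkage cut at `k`. Input spectra are expected to be
#' smoothed second-derivative spectra restricted to the clustering range.
#'
#' @param spectra numeric n x B matrix, one spectrum per row.
#' @param k number of clusters (`1 <= k <= n`).
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param seed RNG seed for k-means restarts.
#' @param nstart k-means restarts.
#' @return Integer cluster labels in `0 ... k-1`.
#' @export
clusterSpectra <- function(spectra, k, method = c("kmeans", "hierarchical"),
                           seed = 1L, nstart = 5L) {
  method <- match.arg(method)
  n <- nrow(spectra)
  if (k > n) stop("parameter error: k = ", k, " exceeds ", n, " spectra")
  if (k == 1L) return(integer(n))
  if (method == "kmeans") {
    set.seed(as.integer(seed))
    km <- stats::kmeans(spectra, centers = k, nstart = nstart,
                        iter.max = 100L)
    as.integer(km$cluster) - 1L
  } else {
    hc <- stats::hclust(stats::dist(spectra), method = "ward.D2")
    as.integer(stats::cutree(hc, k = k)) - 1L
  }
}

# truth-code -> roster mapping per level
.rosterMap <- function(level) {
  if (level == 1L)
    c(lumen = "lumen", crypts = "crypts", connective = "connective",
      muscleA = "muscleA", muscleB = "muscleB",
      inflammatory = "inflammatory", tumor = "pathological",
      necrosis = "pathological", debris = "debris")
  else
    c(tumor = "tumor", necrosis = "necrosis", inflammatory = "inflammation")
}

#' Build a labeled spectral database from annotated cubes
#'
#' For each roster class, QC-retained pixels carrying the class's
#' ground-truth code are sampled without replacement (capped at
#' `perClassCap`, stratified across source cubes). Within each class the
#' sampled spectra are clustered (k-means on smoothed second-derivative
#' spectra restricted to `clusterRange`); if the smallest cluster holds less
#' than `outlierFraction` of the class sample it is dropped as outliers.
#'
#' Level 1 covers all tissue types (tumor and necrosis merge into
#' `pathological`; the two anatomical muscle layers stay separate in the
#' roster and are merged only at render time). Level 2 covers the
#' pathological subtypes `tumor`, `necrosis` and `inflammation`.
#'
#' @param cubes list of preprocessed (QC + Mie-corrected, unsmoothed)
#'   [HyperCube-class] objects cropped to the fingerprint region.
#' @param truths list of ground-truth [LabelMap-class] maps (combined
#'   coding, see [truthPalette()]).
#' @param masks list of [QCMask-class] objects.
#' @param level 1 or 2.
#' @param perClassCap maximum spectra per class (default 2000).
#' @param outlierFraction smallest-cluster drop threshold (default 0.05).
#' @param clusterK clusters per class for the purge (default 3).
#' @param clusterRange wavenumber window for clustering (default
#'   1000-1750 cm^-1).
#' @param seed RNG seed (sampling and clustering).
#' @return A [SpectralDatabase-class].
#' @export
buildDatabase <- function(cubes, truths, masks, level, perClassCap = 2000L,
                          outlierFraction = 0.05, clusterK = 3L,
                          clusterRange = c(1000, 1750), seed = 1L) {
  level <- as.integer(level)
  stopifnot(length(cubes) == length(truths), length(cubes) == length(masks))
  axis <- cubeAxis(cubes[[1L]])
  wn <- wavenumbers(axis)
  map <- .rosterMap(level)
  roster <- unique(unname(map))
  set.seed(as.integer(seed))

  spectraList <- list(); classList <- list(); provList <- list()
  for (cls in roster) {
    codes <- .TRUTH[names(map)[map == cls]]
    perCube <- lapply(seq_along(cubes), function(i) {
      sel <- which(matrix(labelCodes(truths[[i]]) %in% codes,
                          nrow(labelCodes(truths[[i]]))) & qcKeep(masks[[i]]))
      sel
    })
    avail <- sum(lengths(perCube))
    if (avail == 0L)
      stop("coverage error: class '", cls,
           "' has no QC-retained pixels in any truth map")
    # stratified draw across cubes, proportional with round-robin remainder
    want <- min(perClassCap, avail)
    quota <- pmin(lengths(perCube),
                  ceiling(want * lengths(perCube) / avail))
    while (sum(quota) > want) {     # trim overshoot deterministically
      i <- which.max(quota)
      quota[i] <- quota[i] - 1L
    }
    picks <- lapply(seq_along(cubes), function(i) {
      if (quota[i] == 0L) return(integer(0))
      sort(sample(perCube[[i]], quota[i]))
    })
    X <- do.call(rbind, lapply(seq_along(cubes), function(i) {
      if (!length(picks[[i]])) return(NULL)
      d <- dim(cubes[[i]]@data)
      matrix(cubes[[i]]@data, d[1L] * d[2L], d[3L])[picks[[i]], , drop = FALSE]
    }))
    prov <- do.call(rbind, lapply(seq_along(cubes), function(i) {
      if (!length(picks[[i]])) return(NULL)
      h <- nrow(labelCodes(truths[[i]]))
      data.frame(cube = i, row = ((picks[[i]] - 1L) %% h) + 1L,
                 col = ((picks[[i]] - 1L) %/% h) + 1L)
    }))
    # outlier purge by clustering second-derivative spectra
    if (nrow(X) >= max(20L, 2L * clusterK)) {
      d2 <- secondDerivative(X, spacing = axisSpacing(axis))
      cidx <- wn >= clusterRange[1L] & wn <= clusterRange[2L]
      lab <- clusterSpectra(d2[, cidx, drop = FALSE], k = clusterK,
                            method = "kmeans", seed = seed)
      sizes <- table(lab)
      smallest <- names(sizes)[which.min(sizes)]
      if (min(sizes) < outlierFraction * nrow(X)) {
        keepRows <- lab != as.integer(smallest)
        X <- X[keepRows, , drop = FALSE]
        prov <- prov[keepRows, , drop = FALSE]
      }
    }
    spectraList[[cls]] <- X
    classList[[cls]] <- rep(cls, nrow(X))
    provList[[cls]] <- prov
  }
  spectra <- do.call(rbind, spectraList)
  rownames(spectra) <- NULL
  prov <- do.call(rbind, provList)
  rownames(prov) <- NULL
  new("SpectralDatabase", spectra = spectra,
      classes = factor(unlist(classList, use.names = FALSE), levels = roster),
      level = level, axis = axis, provenance = prov)
}

#' Serialize / restore a spectral database as one tabular file
#'
#' One row per spectrum: class, provenance columns (`cube`, `row`, `col`),
#' then one column per wavenumber channel.
#'
#' @param db a [SpectralDatabase-class].
#' @param path TSV file path.
#' @return Invisibly `path`; `readDatabase` returns the
#'   [SpectralDatabase-class].
#' @export
writeDatabase <- function(db, path) {
  tab <- data.frame(class = as.character(db@classes), db@provenance,
                    db@spectra, check.names = FALSE)
  names(tab)[-(1:4)] <- format(wavenumbers(db@axis), trim = TRUE)
  utils::write.table(cbind(level = db@level, tab), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDatabase
#' @param path TSV file written by `writeDatabase`.
#' @export
readDatabase <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  wn <- as.numeric(names(tab)[-(1:5)])
  new("SpectralDatabase",
      spectra = unname(as.matrix(tab[, -(1:5), drop = FALSE])),
      classes = factor(tab$class, levels = unique(tab$class)),
      level = as.integer(tab$level[1L]), axis = spectralAxis(wn),
      provenance = tab[, c("cube", "row", "col")])
}
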