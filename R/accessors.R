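#' @describeIn SpectralAxis-class wavenumber vector of an axis.
#' @export
setMethod("wavenumbers", "SpectralAxis", function(x) x@wavenumbers)

#' @describeIn HyperCube-class wavenumber vector of a cube's axis.
#' @export
setMethod("wavenumbers", "HyperCube", function(x) x@axis@wavenumbers)

#' @describeIn SpectralAxis-class grid spacing in cm^-1.
#' @export
setMethod("axisSpacing", "SpectralAxis", function(x) x@spacing)

#' @describeIn HyperCube-class grid spacing of a cube's axis.
#' @export
setMethod("axisSpacing", "HyperCube", function(x) x@axis@spacing)

#' @describeIn HyperCube-class the H x W x B absorbance array.
#' @export
setMethod("cubeData", "HyperCube", function(x) x@data)

#' @describeIn HyperCube-class pixel edge in micrometers.
#' @export
setMethod("pixelSize", "HyperCube", function(x) x@pixelSize)

#' Spectral axis of a cube
#' @param x a [HyperCube-class].
#' @return The cube's [SpectralAxis-class].
#' @export
cubeAxis <- function(x) x@axis

#' @describeIn LabelMap-class integer matrix of class codes.
#' @export
setMethod("labelCodes", "LabelMap", function(x) x@labels)

#' @describeIn LabelMap-class the palette data.frame.
#' @export
setMethod("labelPalette", "LabelMap", function(x) x@palette)

#' @describeIn LabelMap-class the roster level (0, 1 or 2).
#' @export
setMethod("labelLevel", "LabelMap", function(x) x@level)

#' Retention matrix of a QC mask
#' @param x a [QCMask-class].
#' @return Logical H x W matrix, `TRUE` where the pixel is retained.
#' @export
qcKeep <- function(x) x@keep

#' Rejection reasons of a QC mask
#' @param x a [QCMask-class].
#' @return Character H x W matrix of reasons ("" where retained).
#' @export
qcReason <- function(x) x@reason

setMethod("dim", "HyperCube", function(x) dim(x@data))
setMethod("dim", "LabelMap", function(x) dim(x@labels))

setMethod("show", "SpectralAxis", function(object) {
  wn <- object@wavenumbers
  cat(sprintf("SpectralAxis: %d channels, %.0f -> %.0f cm-1, spacing %g cm-1\n",
              length(wn), wn[1L], wn[length(wn)], object@spacing))
})

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  wn <- object@axis@wavenumbers
  cat(sprintf("HyperCube: %d x %d pixels, %d bands (%.0f -> %.0f cm-1 @ %g cm-1), pixel %g um\n",
              d[1L], d[2L], d[3L], wn[1L], wn[length(wn)],
              object@axis@spacing, object@pixelSize))
})

setMethod("show", "QCMask", function(object) {
  n <- length(object@keep)
  cat(sprintf("QCMask: %d x %d pixels, %d retained (%.1f%%)\n",
              nrow(object@keep), ncol(object@keep), sum(object@keep),
              100 * sum(object@keep) / n))
  rej <- table(object@reason[!object@keep])
  if (length(rej))
    cat("  rejected:", paste(sprintf("%s=%d", names(rej), rej), collapse = ", "),
        "\n")
})

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap (level %d): %d x %d pixels\n", object@level,
              nrow(object@labels), ncol(object@labels)))
  tab <- table(factor(object@labels, levels = object@palette$code,
                      labels = object@palette$name))
  tab <- tab[tab > 0]
  for (nm in names(tab))
    cat(sprintf("  %-26s %d\n", nm, tab[[nm]]))
})

setMethod("show", "EMSCBasis", function(object) {
  cat(sprintf("EMSCBasis: %d Mie components on %d channels; d in [%g, %g] um, n in [%g, %g]\n",
              ncol(object@components), nrow(object@components),
              min(object@dGrid), max(object@dGrid),
              min(object@nGrid), max(object@nGrid)))
})

setMethod("show", "EMSCFit", function(object) {
  cat(sprintf("EMSCFit: c=%.4g a=%.4g b=%.4g |g|=%.4g residualRms=%.4g\n",
              object@c, object@a, object@b, sqrt(sum(object@g^2)),
              object@residualRms))
})

setMethod("show", "SpectralDatabase", function(object) {
  cat(sprintf("SpectralDatabase (level %d): %d spectra x %d channels\n",
              object@level, nrow(object@spectra), ncol(object@spectra)))
  print(table(object@classes))
})

setMethod("show", "TrainedCascade", function(object) {
  cat(sprintf("TrainedCascade: %d trees, %d features/split, %d channels\n",
              object@nTrees, object@featuresPerSplit,
              length(object@axis@wavenumbers)))
  cat(sprintf("  level 1: %s (OOB acc %.3f)\n",
              paste(object@roster1, collapse = ", "), object@oob[["level1"]]))
  cat(sprintf("  level 2: %s (OOB acc %.3f)\n",
              paste(object@roster2, collapse = ", "), object@oob[["level2"]]))
})

setMethod("show", "DiagnosisResult", function(object) {
  cat(sprintf("DiagnosisResult: %s (tumor fraction %.4f, threshold %.3f; %d / %d pixels)\n",
              object@call, object@tumorFraction, object@threshold,
              object@tumorPixels, object@tissuePixels))
})
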