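#' @rdname SpectralAxis-class
#' @param x an object with a spectral axis.
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectralAxis-class
#' @export
setGeneric("axisSpacing", function(x) standardGeneric("axisSpacing"))

#' @rdname HyperCube-class
#' @param x a [HyperCube-class].
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname HyperCube-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname LabelMap-class
#' @param x a [LabelMap-class].
#' @export
setGeneric("labelCodes", function(x) standardGeneric("labelCodes"))

#' @rdname LabelMap-class
#' @export
setGeneric("labelPalette", function(x) standardGeneric("labelPalette"))

#' @rdname LabelMap-class
#' @export
setGeneric("labelLevel", function(x) standardGeneric("labelLevel"))

#' Second derivative of spectra (smoothed Savitzky-Golay)
#'
#' @param x numeric spectrum, n x B spectra matrix, or [HyperCube-class].
#' @param ... passed to methods (`spacing` for plain numeric input).
#' @export
setGeneric("secondDerivative", function(x, ...) standardGeneric("secondDerivative"))
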