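# Savitzky-Golay second derivatives, fingerprint cropping, spectral
# downsampling and single-wavenumber overview images.

# B x B Savitzky-Golay differentiation operator (window n, order p,
# derivative m), with edge rows from one-sided polynomial fits. Matches
# signal::sgolayfilt but is applied to many spectra as one matrix product.
.sgOperator <- function(B, spacing, p = 3L, n = 9L, m = 2L) {
  if (B < n) stop("length error: spectra must have at least ", n, " channels")
  Fm <- signal::sgolay(p = p, n = n, m = m, ts = spacing)
  k <- (n - 1L) %/% 2L
  D <- matrix(0, B, B)
  for (i in seq_len(k)) D[i, seq_len(n)] <- Fm[i, ]
  for (i in (k + 1L):(B - k)) D[i, (i - k):(i + k)] <- Fm[k + 1L, ]
  for (i in seq_len(k)) D[B - k + i, (B - n + 1L):B] <- Fm[k + 1L + i, ]
  D
}

#' @describeIn secondDerivative numeric spectrum; `spacing` is the grid
#'   spacing in cm^-1 (default 1). 9-point window, polynomial order 3,
#'   exact for cubics in the interior; edges use one-sided polynomial fits.
#' @param spacing grid spacing in cm^-1.
#' @export
setMethod("secondDerivative", "numeric", function(x, spacing = 1) {
  D <- .sgOperator(length(x), spacing)
  as.numeric(D %*% x)
})

#' @describeIn secondDerivative rows are spectra on a common grid.
#' @export
setMethod("secondDerivative", "matrix", function(x, spacing = 1) {
  D <- .sgOperator(ncol(x), spacing)
  x %*% t(D)
})

#' @describeIn secondDerivative per-pixel derivative of a cube (spacing
#'   taken from the cube's axis).
#' @export
setMethod("secondDerivative", "HyperCube", function(x) {
  d <- dim(x@data)
  S <- matrix(x@data, d[1L] * d[2L], d[3L])
  D <- .sgOperator(d[3L], axisSpacing(x))
  out <- x
  out@data <- array(as.vector(S %*% t(D)), dim = d)
  out
})

#' Crop a cube to the fingerprint region
#'
#' Retains exactly the channels with `low <= wn <= high`. With the default
#' 1760-998 cm^-1 window on a 2 cm^-1 axis this yields 382 channels, the
#' feature grid of the random-forest classifiers.
#'
#' @param cube a [HyperCube-class].
#' @param low,high window bounds in cm^-1.
#' @return The cropped [HyperCube-class].
#' @export
cropFingerprint <- function(cube, low = 998, high = 1760) {
  wn <- wavenumbers(cube)
  idx <- which(wn >= low & wn <= high)
  if (!length(idx))
    stop("parameter error: [", low, ", ", high,
         "] cm-1 is outside the cube's axis")
  out <- cube
  out@data <- cube@data[, , idx, drop = FALSE]
  out@axis <- spectralAxis(wn[idx])
  out
}

#' Downsample the spectral axis by decimation
#'
#' Keeps every k-th channel starting at the highest wavenumber, where
#' `k = targetSpacing / axisSpacing(cube)` must be a positive integer.
#' The channel count becomes `ceiling(B / k)`.
#'
#' @param cube a [HyperCube-class].
#' @param targetSpacing target spacing in cm^-1 (e.g. 4, 8 or 16 from a
#'   2 cm^-1 acquisition).
#' @return The decimated [HyperCube-class].
#' @export
downsampleCube <- function(cube, targetSpacing) {
  sp <- axisSpacing(cube)
  k <- targetSpacing / sp
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("parameter error: target spacing ", targetSpacing,
         " is not an integer multiple of the current spacing ", sp)
  k <- as.integer(round(k))
  if (k == 1L) return(cube)
  wn <- wavenumbers(cube)
  idx <- seq(1L, length(wn), by = k)
  out <- cube
  out@data <- cube@data[, , idx, drop = FALSE]
  out@axis <- spectralAxis(wn[idx])
  out
}

#' Single-wavenumber overview image
#'
#' Absorbance plane at the axis channel nearest the requested wavenumber
#' (the amide I band at 1656 cm^-1 by default, the standard morphology
#' overview); ties round toward the higher wavenumber. The channel actually
#' used is reported in the `"wavenumber"` attribute.
#'
#' @param cube a [HyperCube-class].
#' @param wavenumber requested wavenumber in cm^-1 (must lie within the
#'   axis range).
#' @return H x W numeric matrix with attribute `wavenumber`.
#' @export
overviewImage <- function(cube, wavenumber = 1656) {
  wn <- wavenumbers(cube)
  if (wavenumber > max(wn) || wavenumber < min(wn))
    stop("parameter error: ", wavenumber, " cm-1 is outside the axis range")
  i <- which.min(abs(wn - wavenumber))  # first minimum = higher wavenumber
  img <- cube@data[, , i]
  attr(img, "wavenumber") <- wn[i]
  img
}
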