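#' Quality-control parameters
#'
#' Retention criteria for pixel spectra: the trapezoidal integral of
#' absorbance over the amide I region must lie within
#' `[amideIntegralMin, amideIntegralMax]` (below: `low-signal`; above:
#' `saturated`, as for folds, cracks or thick debris), and the
#' signal-to-noise ratio -- maximum absorbance in the amide region divided
#' by the standard deviation of the linearly detrended signal in a
#' signal-free noise region at the high-wavenumber edge -- must be at least
#' `snrMin` (`low-snr`).
#'
#' Default thresholds are calibrated on the phantom band library so that
#' clean tissue (including the weak lumen signal) passes while empty and
#' high-baseline debris spectra fail; all are exposed here.
#'
#' @param amideRegion amide I integration window, `c(low, high)` in cm^-1.
#' @param noiseRegion signal-free window for the noise estimate, in cm^-1.
#' @param amideIntegralMin,amideIntegralMax integral bounds in
#'   absorbance * cm^-1.
#' @param snrMin minimum signal-to-noise ratio (dimensionless).
#' @return A named list of parameters.
#' @export
qcParams <- function(amideRegion = c(1600, 1700),
                     noiseRegion = c(1760, 1800),
                     amideIntegralMin = 1, amideIntegralMax = 120,
                     snrMin = 5) {
  stopifnot(amideRegion[1L] < amideRegion[2L],
            noiseRegion[1L] < noiseRegion[2L],
            amideIntegralMin < amideIntegralMax, snrMin > 0)
  list(amideRegion = amideRegion, noiseRegion = noiseRegion,
       amideIntegralMin = amideIntegralMin,
       amideIntegralMax = amideIntegralMax, snrMin = snrMin)
}

.regionIndex <- function(wn, region) {
  idx <- which(wn >= region[1L] & wn <= region[2L])
  if (length(idx) < 2L)
    stop("parameter error: region [", region[1L], ", ", region[2L],
         "] cm-1 is not covered by the spectral axis")
  idx
}

# trapezoidal integral over a descending uniform grid (positive orientation)
.trapz <- function(Y, spacing) {
  # Y: npix x k matrix over the region's channels
  k <- ncol(Y)
  spacing * (rowSums(Y) - 0.5 * (Y[, 1L] + Y[, k]))
}

#' Pixel quality control of a cube
#'
#' @param cube a [HyperCube-class].
#' @param params see [qcParams()].
#' @return A [QCMask-class]; retained iff the amide I integral lies within
#'   bounds and SNR >= `snrMin`. Deterministic.
#' @export
qualityFilter <- function(cube, params = qcParams()) {
  wn <- wavenumbers(cube)
  ia <- .regionIndex(wn, params$amideRegion)
  inoise <- .regionIndex(wn, params$noiseRegion)
  d <- dim(cube@data)
  npix <- d[1L] * d[2L]
  S <- matrix(cube@data, npix, d[3L])

  A <- S[, ia, drop = FALSE]
  integ <- .trapz(A, axisSpacing(cube))
  peak <- apply(A, 1L, max)

  # linear detrend of the noise region per pixel (shared residual maker)
  x <- wn[inoise]
  X <- cbind(1, x)
  Rm <- diag(length(x)) - X %*% solve(crossprod(X), t(X))
  Nresid <- S[, inoise, drop = FALSE] %*% t(Rm)
  noiseSd <- sqrt(rowSums(Nresid^2) / (length(x) - 2L))
  snr <- ifelse(noiseSd > 0, peak / noiseSd, Inf)

  reason <- rep("", npix)
  reason[snr < params$snrMin] <- "low-snr"
  reason[integ < params$amideIntegralMin] <- "low-signal"
  reason[integ > params$amideIntegralMax] <- "saturated"
  keep <- reason == ""
  new("QCMask", keep = matrix(keep, d[1L], d[2L]),
      reason = matrix(reason, d[1L], d[2L]))
}
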