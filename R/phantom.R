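# Synthetic QCL-IR phantoms of layered colon wall with known ground truth.
# The generator reproduces the statistical structure the classifier assumes:
# class-specific band spectra (pseudo-Voigt profiles), multiplicative
# amplitude jitter, additive linear baselines, van-de-Hulst-type resonant
# Mie distortion concentrated on tissue boundaries, and detector noise.
# One global seed expands into per-stage child seeds by fixed offsets so
# that, e.g., disabling the Mie distortion leaves every other stage's random
# stream untouched (bit-identical clean twins).

.childSeed <- function(seed, offset) as.integer((seed + offset) %% 2147483647L)

#' Phantom specification
#'
#' Parameters of a synthetic colon-wall phantom. Geometry is a layered
#' layout (lumen, crypt-bearing mucosa, thin muscularis mucosae, submucosal
#' connective tissue, muscularis propria) with optional tumor blobs (and
#' necrotic cores) invading the connective tissue, scattered inflammatory
#' cell clusters, and debris/blood deposits in the lumen.
#'
#' @slot height,width canvas size in pixels.
#' @slot axis [SpectralAxis-class] of the synthesized cube.
#' @slot tumorFractionTarget target fraction of tissue pixels carrying the
#'   tumor code (0 disables tumor and necrosis entirely).
#' @slot cryptRadius crypt disk radius in pixels.
#' @slot inflammatoryDensity target fraction of tissue pixels in
#'   inflammatory-cell clusters.
#' @slot debrisCount number of debris/blood blobs placed in the lumen.
#' @slot mieD,mieN ranges of Mie sphere diameter (micrometers) and refractive
#'   index drawn per distorted pixel.
#' @slot mieScale amplitude (absorbance) of the extinction curve added to a
#'   distorted pixel.
#' @slot mieFraction fraction of non-boundary tissue pixels distorted
#'   (tissue-boundary pixels are always distorted, emulating edge coherence).
#' @slot noiseSd standard deviation of i.i.d. Gaussian detector noise
#'   (absorbance).
#' @slot baselineOffsetMax per-pixel baseline offsets are drawn uniformly
#'   from `[0, baselineOffsetMax]` (debris pixels instead from
#'   `debrisOffsetRange`).
#' @slot baselineSlopeSd standard deviation of the per-pixel linear baseline
#'   slope (absorbance per cm^-1).
#' @slot debrisOffsetRange anomalously high baseline offset range for
#'   debris/blood pixels.
#' @slot jitterSd sigma of the per-pixel lognormal amplitude jitter.
#' @slot seed integer master seed.
#' @seealso [phantomSpec()], [synthesizeCube()], [makeGeometry()]
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer", axis = "SpectralAxis",
    tumorFractionTarget = "numeric", cryptRadius = "numeric",
    inflammatoryDensity = "numeric", debrisCount = "integer",
    mieD = "numeric", mieN = "numeric", mieScale = "numeric",
    mieFraction = "numeric", noiseSd = "numeric",
    baselineOffsetMax = "numeric", baselineSlopeSd = "numeric",
    debrisOffsetRange = "numeric", jitterSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@tumorFractionTarget < 0 || object@tumorFractionTarget > 1)
      return("tumorFractionTarget must lie in [0, 1]")
    if (object@noiseSd < 0) return("noiseSd must be non-negative")
    if (min(object@mieD) <= 0 || max(object@mieD) > 50)
      return("mieD range must lie in (0, 50] micrometers")
    if (min(object@mieN) <= 1 || max(object@mieN) >= 2)
      return("mieN range must lie in (1, 2)")
    if (object@mieFraction < 0 || object@mieFraction > 1)
      return("mieFraction must lie in [0, 1]")
    TRUE
  }
)

#' Construct a phantom specification
#'
#' Defaults give a 128 x 128 pixel phantom on the full acquisition axis
#' (1800 to 948 cm^-1 at 2 cm^-1), 10% tumor fraction, detector noise of
#' 0.01 absorbance, and Mie distortion of amplitude 0.1 on tissue boundaries
#' plus 30% of interior tissue pixels.
#'
#' @param height,width canvas size in pixels (minimum 32).
#' @param axis [SpectralAxis-class]; default 1800 to 948 cm^-1 at 2 cm^-1.
#' @param tumorFractionTarget,cryptRadius,inflammatoryDensity,debrisCount
#'   geometry parameters, see [PhantomSpec-class].
#' @param mieD,mieN,mieScale,mieFraction Mie distortion parameters.
#' @param noiseSd,baselineOffsetMax,baselineSlopeSd,debrisOffsetRange,jitterSd
#'   spectral nuisance parameters.
#' @param seed integer master seed.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(height = 128, width = 128, axis = spectralAxis(),
    tumorFractionTarget = 0.10, cryptRadius = 5,
    inflammatoryDensity = 0.02, debrisCount = 2L,
    mieD = c(2, 20), mieN = c(1.1, 1.5), mieScale = 0.1, mieFraction = 0.3,
    noiseSd = 0.01, baselineOffsetMax = 0.03, baselineSlopeSd = 1e-5,
    debrisOffsetRange = c(0.6, 1.6), jitterSd = 0.05, seed = 1L) {
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      axis = axis, tumorFractionTarget = tumorFractionTarget,
      cryptRadius = cryptRadius, inflammatoryDensity = inflammatoryDensity,
      debrisCount = as.integer(debrisCount), mieD = mieD, mieN = mieN,
      mieScale = mieScale, mieFraction = mieFraction, noiseSd = noiseSd,
      baselineOffsetMax = baselineOffsetMax, baselineSlopeSd = baselineSlopeSd,
      debrisOffsetRange = debrisOffsetRange, jitterSd = jitterSd,
      seed = as.integer(seed))
}

#' Default band library
#'
#' Pseudo-Voigt band parameters per tissue class: for each class a
#' data.frame with columns `center` (cm^-1), `fwhm` (cm^-1), `amplitude`
#' (absorbance) and `eta` (Lorentzian mixing fraction in `[0,1]`). Bands
#' are placed at the canonical protein, nucleic-acid and carbohydrate
#' features (amide I ~1656, amide II ~1546, CH deformation ~1452,
#' amide III / phosphate 1310-1240, C-O and phosphate/glycogen 1160-1030
#' cm^-1) with class-distinct amplitude patterns, so classes are linearly
#' separable at zero noise. Lumen has near-zero amplitudes; debris/blood has
#' weak amide bands (its anomalously high baseline is added at synthesis).
#'
#' @return Named list of data.frames, one per ground-truth class.
#' @export
defaultBandLibrary <- function() {
  bd <- function(center, fwhm, amplitude, eta = 0.3)
    data.frame(center = center, fwhm = fwhm, amplitude = amplitude, eta = eta)
  list(
    lumen = bd(c(1656, 1546, 1080),
               c(50, 46, 60), c(0.16, 0.08, 0.06)),
    crypts = bd(c(1656, 1546, 1452, 1396, 1240, 1160, 1080, 1030),
                c(48, 44, 34, 36, 44, 40, 50, 38),
                c(0.85, 0.48, 0.22, 0.18, 0.20, 0.16, 0.28, 0.34)),
    connective = bd(c(1656, 1546, 1452, 1338, 1310, 1240, 1204, 1080),
                    c(52, 46, 34, 30, 34, 44, 32, 50),
                    c(0.80, 0.52, 0.25, 0.18, 0.22, 0.30, 0.15, 0.16)),
    muscleA = bd(c(1656, 1546, 1452, 1396, 1310, 1240, 1080),
                 c(46, 44, 34, 36, 34, 44, 50),
                 c(0.95, 0.60, 0.30, 0.22, 0.14, 0.16, 0.14)),
    muscleB = bd(c(1656, 1546, 1452, 1396, 1240, 1080, 1030),
                 c(50, 46, 34, 36, 44, 50, 38),
                 c(0.90, 0.55, 0.26, 0.16, 0.22, 0.22, 0.12)),
    inflammatory = bd(c(1656, 1546, 1452, 1240, 1120, 1080, 1030),
                      c(46, 44, 34, 40, 36, 46, 38),
                      c(0.75, 0.50, 0.18, 0.34, 0.14, 0.40, 0.16)),
    tumor = bd(c(1656, 1546, 1452, 1396, 1240, 1160, 1120, 1080, 1030),
               c(48, 44, 34, 36, 42, 38, 36, 48, 38),
               c(0.88, 0.52, 0.20, 0.16, 0.30, 0.20, 0.18, 0.34, 0.20)),
    necrosis = bd(c(1740, 1656, 1546, 1400, 1240, 1080),
                  c(40, 56, 50, 60, 44, 50),
                  c(0.15, 0.60, 0.30, 0.25, 0.12, 0.10)),
    debris = bd(c(1656, 1546, 1452, 1240),
                c(52, 48, 36, 46), c(0.55, 0.35, 0.12, 0.08))
  )
}

#' Validate a band library against an axis
#'
#' Checks every band center lies within the axis range and every tissue
#' class (all classes except lumen and background) has a positive-amplitude
#' amide I band with center in 1600-1700 cm^-1.
#'
#' @param lib band library (see [defaultBandLibrary()]).
#' @param axis [SpectralAxis-class].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validateBandLibrary <- function(lib, axis = spectralAxis()) {
  wn <- wavenumbers(axis)
  for (cls in names(lib)) {
    b <- lib[[cls]]
    if (!nrow(b)) {
      if (cls %in% c("lumen", "background")) next
      stop("band library error: tissue class '", cls, "' has no bands")
    }
    if (any(b$center > max(wn) | b$center < min(wn)))
      stop("band library error: class '", cls, "' has band centers outside ",
           "the axis range")
    if (!cls %in% c("lumen", "background")) {
      amide <- b$center <= 1700 & b$center >= 1600
      if (!any(amide & b$amplitude > 0))
        stop("band library error: tissue class '", cls,
             "' lacks a positive amide I band in 1600-1700 cm-1")
    }
  }
  invisible(TRUE)
}

.pseudoVoigt <- function(wn, center, fwhm, amplitude, eta) {
  u <- (wn - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  amplitude * ((1 - eta) * g + eta * l)
}

#' Evaluate a class spectrum from the band library
#'
#' Sum of pseudo-Voigt profiles on the axis, optionally scaled by one draw
#' of lognormal amplitude jitter (taken from the current RNG stream).
#'
#' @param class class name (e.g. `"tumor"`) or ground-truth code.
#' @param lib band library.
#' @param axis [SpectralAxis-class].
#' @param jitterSd sigma of the lognormal multiplicative jitter; 0 disables.
#' @return Numeric absorbance spectrum of length `length(wavenumbers(axis))`.
#' @export
classSpectrum <- function(class, lib, axis = spectralAxis(), jitterSd = 0) {
  if (is.numeric(class)) class <- names(.TRUTH)[match(class, .TRUTH)]
  if (!class %in% names(lib))
    stop("band library error: class '", class, "' not in the library")
  b <- lib[[class]]
  wn <- wavenumbers(axis)
  s <- numeric(length(wn))
  for (i in seq_len(nrow(b)))
    s <- s + .pseudoVoigt(wn, b$center[i], b$fwhm[i], b$amplitude[i], b$eta[i])
  if (jitterSd > 0) s <- s * exp(stats::rnorm(1L, 0, jitterSd))
  s
}

#' Add resonant-Mie-type distortion to a spectrum
#'
#' Adds `scale * Q(rho)` with the van de Hulst anomalous-diffraction
#' extinction efficiency `Q` and phase parameter
#' `rho(wn) = 2 * pi * d * (n - 1) * wn` (`d` converted from micrometers to
#' centimeters, `wn` in cm^-1).
#'
#' @param s numeric spectrum on `axis`.
#' @param d sphere diameter in micrometers, in `(0, 50]`.
#' @param n refractive index, in `(1, 2)`.
#' @param scale distortion amplitude in absorbance units.
#' @param axis [SpectralAxis-class].
#' @return The distorted spectrum.
#' @seealso [vdhExtinction()]
#' @export
applyMieDistortion <- function(s, d, n, scale, axis = spectralAxis()) {
  if (d <= 0 || d > 50) stop("sphere diameter d must lie in (0, 50] um")
  if (n <= 1 || n >= 2) stop("refractive index n must lie in (1, 2)")
  wn <- wavenumbers(axis)
  rho <- 2 * pi * (d * 1e-4) * (n - 1) * wn
  s + scale * vdhExtinction(rho)
}

.paintDisk <- function(labels, r0, c0, radius, code, onlyOver = NULL) {
  h <- nrow(labels); w <- ncol(labels)
  rr <- max(1L, floor(r0 - radius)):min(h, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(w, ceiling(c0 + radius))
  for (ci in cc) {
    d2 <- (rr - r0)^2 + (ci - c0)^2
    sel <- rr[d2 <= radius^2]
    if (!is.null(onlyOver)) sel <- sel[labels[sel, ci] %in% onlyOver]
    labels[sel, ci] <- code
  }
  labels
}

#' Generate the ground-truth geometry of a phantom
#'
#' Deterministic given the spec's seed. Layers from the top: lumen, crypt
#' band (crypt disks in lamina-propria connective tissue), thin muscularis
#' mucosae, submucosal connective tissue, muscularis propria. Tumor blobs
#' with necrotic cores invade the connective tissue until the achieved
#' tumor-pixel fraction is within about 8% relative of the target;
#' inflammatory-cell clusters are scattered over mucosa and submucosa and
#' debris/blood blobs over the lumen.
#'
#' @param spec a [PhantomSpec-class].
#' @return A ground-truth [LabelMap-class] (level 0, combined coding; see
#'   [truthPalette()]).
#' @export
makeGeometry <- function(spec) {
  h <- spec@height; w <- spec@width
  if (h < 32L || w < 32L)
    stop("geometry error: canvas must be at least 32 x 32 pixels")
  rs <- .childSeed(spec@seed, 101L)
  labels <- matrix(.TRUTH[["connective"]], h, w)
  set.seed(rs)

  cols <- seq_len(w)
  wave <- function(amp) {
    ph <- stats::runif(2L, 0, 2 * pi)
    amp * (sin(2 * pi * cols / w * 2 + ph[1L]) +
           0.5 * sin(2 * pi * cols / w * 5 + ph[2L]))
  }
  b1 <- round(0.14 * h + wave(0.02 * h))   # lumen | mucosa
  b2 <- round(0.32 * h + wave(0.02 * h))   # mucosa | muscularis mucosae
  b3 <- round(0.38 * h + wave(0.015 * h))  # m. mucosae | submucosa
  b4 <- round(0.72 * h + wave(0.02 * h))   # submucosa | muscularis propria
  for (ci in cols) {
    labels[seq_len(max(1L, b1[ci])), ci] <- .TRUTH[["lumen"]]
    mm <- max(b1[ci] + 1L, b2[ci]):max(b2[ci], b3[ci])
    labels[mm[mm >= 1 & mm <= h], ci] <- .TRUTH[["muscleA"]]
    mp <- min(h, max(1L, b4[ci])):h
    labels[mp, ci] <- .TRUTH[["muscleB"]]
  }
  # crypt disks inside the mucosa band
  step <- max(3, round(2.4 * spec@cryptRadius))
  centers <- seq(step %/% 2, w - step %/% 2, by = step)
  for (c0 in centers) {
    c0j <- c0 + round(stats::runif(1L, -1, 1))
    r0 <- round((b1[min(max(c0, 1L), w)] + b2[min(max(c0, 1L), w)]) / 2 +
                stats::runif(1L, -0.03, 0.03) * h)
    rad <- spec@cryptRadius * stats::runif(1L, 0.8, 1.1)
    labels <- .paintDisk(labels, r0, c0j, rad, .TRUTH[["crypts"]],
                         onlyOver = .TRUTH[["connective"]])
  }
  # debris/blood in the lumen
  for (i in seq_len(spec@debrisCount)) {
    c0 <- stats::runif(1L, 3, w - 2)
    r0 <- stats::runif(1L, 2, max(3, 0.10 * h))
    labels <- .paintDisk(labels, r0, c0, stats::runif(1L, 2, 4),
                         .TRUTH[["debris"]], onlyOver = .TRUTH[["lumen"]])
  }
  # inflammatory-cell clusters over mucosa and submucosa
  tissueCodes <- .TRUTH[c("crypts", "connective", "muscleA", "muscleB")]
  nInfTarget <- round(spec@inflammatoryDensity * sum(labels %in% c(tissueCodes)))
  guard <- 0L
  while (sum(labels == .TRUTH[["inflammatory"]]) < nInfTarget &&
         guard < 10000L) {
    guard <- guard + 1L
    r0 <- stats::runif(1L, 0.15 * h, 0.95 * h)
    c0 <- stats::runif(1L, 2, w - 1)
    labels <- .paintDisk(labels, r0, c0, stats::runif(1L, 1, 2.4),
                         .TRUTH[["inflammatory"]],
                         onlyOver = c(.TRUTH[["connective"]], .TRUTH[["crypts"]]))
  }
  # tumor blobs with necrotic cores invading the connective tissue
  if (spec@tumorFractionTarget > 0) {
    tissue <- c(.TRUTH[c("crypts", "connective", "muscleA", "muscleB",
                         "inflammatory")])
    nTissue <- sum(labels %in% tissue)
    target <- round(spec@tumorFractionTarget * nTissue)
    count <- function() sum(labels == .TRUTH[["tumor"]])
    guard <- 0L
    while (count() < 0.95 * target && guard < 500L) {
      guard <- guard + 1L
      remaining <- target - count()
      rad <- min(0.16 * h, max(2.5, sqrt(remaining / pi) *
                                     stats::runif(1L, 0.55, 1.0)))
      r0 <- stats::runif(1L, 0.40 * h, 0.70 * h)
      c0 <- stats::runif(1L, rad, w - rad + 1)
      prev <- labels
      labels <- .paintDisk(labels, r0, c0, rad, .TRUTH[["tumor"]],
                           onlyOver = .TRUTH[["connective"]])
      if (rad >= 6) {
        core <- labels
        core <- .paintDisk(core, r0, c0, 0.4 * rad, .TRUTH[["necrosis"]],
                           onlyOver = .TRUTH[["tumor"]])
        labels <- core
      }
      if (count() > 1.08 * target) labels <- prev   # overshoot: retry smaller
    }
    achieved <- count() / nTissue
    if (abs(achieved - spec@tumorFractionTarget) >
        0.2 * spec@tumorFractionTarget)
      stop(sprintf(paste0("geometry error: achieved tumor fraction %.3f is ",
                          "outside 20%% of target %.3f"), achieved,
                   spec@tumorFractionTarget))
  }
  labelMap(labels, level = 0L, palette = truthPalette())
}

# pixels of a label map whose 4-neighborhood contains a different code
.boundaryPixels <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  b <- matrix(FALSE, h, w)
  b[-1, ] <- b[-1, ] | (labels[-1, ] != labels[-h, ])
  b[-h, ] <- b[-h, ] | (labels[-h, ] != labels[-1, ])
  b[, -1] <- b[, -1] | (labels[, -1] != labels[, -w])
  b[, -w] <- b[, -w] | (labels[, -w] != labels[, -1])
  b
}

#' Synthesize a phantom cube with ground truth
#'
#' Per pixel: the class spectrum (with per-pixel lognormal amplitude
#' jitter), plus a linear baseline `offset + slope * wn` (debris pixels get
#' an anomalously high offset), plus van-de-Hulst Mie distortion on all
#' tissue-boundary pixels and a random `mieFraction` of interior tissue
#' pixels, plus i.i.d. Gaussian detector noise. Fully deterministic given
#' `spec@seed`; setting `mieScale = 0` (or `noiseSd = 0`, etc.) changes only
#' that term, all other random draws being taken from independent per-stage
#' streams.
#'
#' @param spec a [PhantomSpec-class].
#' @param lib band library (default [defaultBandLibrary()]).
#' @return A list with elements `cube` ([HyperCube-class]) and `truth`
#'   (ground-truth [LabelMap-class]).
#' @export
synthesizeCube <- function(spec, lib = defaultBandLibrary()) {
  validateBandLibrary(lib, spec@axis)
  truth <- makeGeometry(spec)
  labels <- labelCodes(truth)
  h <- spec@height; w <- spec@width
  wn <- wavenumbers(spec@axis)
  B <- length(wn)
  npix <- h * w

  base <- sapply(names(.TRUTH), function(cls) {
    if (cls == "background" || !cls %in% names(lib)) numeric(B)
    else classSpectrum(cls, lib, spec@axis)
  })                                       # B x class matrix
  codeIdx <- match(as.vector(labels), .TRUTH)
  S <- t(base)[codeIdx, , drop = FALSE]    # npix x B

  set.seed(.childSeed(spec@seed, 202L))    # jitter stage
  jit <- exp(stats::rnorm(npix, 0, spec@jitterSd))
  S <- S * jit

  set.seed(.childSeed(spec@seed, 205L))    # baseline stage
  off <- stats::runif(npix, 0, spec@baselineOffsetMax)
  isDebris <- as.vector(labels) == .TRUTH[["debris"]]
  off[isDebris] <- stats::runif(sum(isDebris), spec@debrisOffsetRange[1L],
                                spec@debrisOffsetRange[2L])
  slope <- stats::rnorm(npix, 0, spec@baselineSlopeSd)
  S <- S + outer(off, rep(1, B)) + outer(slope, wn)

  set.seed(.childSeed(spec@seed, 303L))    # Mie stage
  tissueCodes <- .TRUTH[c("crypts", "connective", "muscleA", "muscleB",
                          "inflammatory", "tumor", "necrosis")]
  isTissue <- matrix(labels %in% tissueCodes, h, w)
  bnd <- .boundaryPixels(labels) & isTissue
  interior <- which(isTissue & !bnd)
  nPick <- round(spec@mieFraction * length(interior))
  picked <- if (nPick > 0) sample(interior, nPick) else integer(0)
  distorted <- sort(unique(c(which(bnd), picked)))
  if (length(distorted)) {
    dDraw <- stats::runif(length(distorted), spec@mieD[1L], spec@mieD[2L])
    nDraw <- stats::runif(length(distorted), spec@mieN[1L], spec@mieN[2L])
    if (spec@mieScale != 0) {
      coefs <- 2 * pi * (dDraw * 1e-4) * (nDraw - 1)
      rho <- outer(coefs, wn)
      S[distorted, ] <- S[distorted, ] + spec@mieScale * vdhExtinction(rho)
    }
  }

  set.seed(.childSeed(spec@seed, 404L))    # noise stage
  if (spec@noiseSd > 0)
    S <- S + matrix(stats::rnorm(npix * B, 0, spec@noiseSd), npix, B)

  cube <- hyperCube(array(as.vector(S), dim = c(h, w, B)), spec@axis)
  list(cube = cube, truth = truth)
}
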