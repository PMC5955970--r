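#' @import methods
NULL

#' Uniform wavenumber grid
#'
#' A `SpectralAxis` holds the wavenumber grid shared by spectra, hyperspectral
#' cubes, EMSC bases and trained classifiers. Wavenumbers are stored strictly
#' descending (e.g. 1800 down to 948 cm^-1), the convention in which band 1 of
#' a cube is the highest-wavenumber plane.
#'
#' @slot wavenumbers numeric vector of wavenumbers in cm^-1, strictly
#'   decreasing on a uniform grid.
#' @slot spacing positive grid spacing in cm^-1.
#'
#' @seealso [spectralAxis()]
#' @export
setClass("SpectralAxis",
  representation(wavenumbers = "numeric", spacing = "numeric"),
  validity = function(object) {
    wn <- object@wavenumbers
    if (length(wn) < 1L) return("axis must contain at least one wavenumber")
    if (!all(is.finite(wn))) return("wavenumbers must be finite")
    if (length(wn) > 1L) {
      d <- diff(wn)
      if (any(d >= 0)) return("wavenumbers must be strictly decreasing")
      if (max(abs(-d - object@spacing)) >= 1e-9)
        return("wavenumber grid is not uniform at the stated spacing")
    }
    if (object@spacing <= 0) return("spacing must be positive")
    TRUE
  }
)

#' Construct a spectral axis
#'
#' Builds a descending uniform wavenumber grid. Either pass the wavenumbers
#' directly (any order; they are sorted descending) or give `high`, `low` and
#' `spacing`.
#'
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, or `NULL`.
#' @param high,low range bounds in cm^-1 (used when `wavenumbers` is `NULL`).
#' @param spacing grid spacing in cm^-1.
#' @return A [SpectralAxis-class] object.
#' @examples
#' ax <- spectralAxis(high = 1800, low = 948, spacing = 2)
#' length(wavenumbers(ax))  # 427
#' @export
spectralAxis <- function(wavenumbers = NULL, high = 1800, low = 948,
                         spacing = 2) {
  if (is.null(wavenumbers))
    wavenumbers <- seq(high, low, by = -abs(spacing))
  wavenumbers <- sort(as.numeric(wavenumbers), decreasing = TRUE)
  sp <- if (length(wavenumbers) > 1L) wavenumbers[1L] - wavenumbers[2L]
        else abs(spacing)
  new("SpectralAxis", wavenumbers = wavenumbers, spacing = sp)
}

#' Hyperspectral absorbance cube
#'
#' An H x W x B absorbance image: every pixel carries a full infrared
#' absorbance spectrum on the cube's [SpectralAxis-class]. Band `b` of
#' `cubeData(x)` is the image plane at `wavenumbers(x)[b]`.
#'
#' @slot data numeric array, H x W x B, finite absorbance values.
#' @slot axis [SpectralAxis-class] with B entries.
#' @slot pixelSize pixel edge length in micrometers (metadata only).
#'
#' @seealso [hyperCube()], [readCube()], [writeCube()]
#' @export
setClass("HyperCube",
  representation(data = "array", axis = "SpectralAxis", pixelSize = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3-dimensional array")
    if (d[3L] != length(object@axis@wavenumbers))
      return("third data dimension must match the axis length")
    if (!all(is.finite(object@data))) return("all absorbance values must be finite")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      return("pixelSize must be a single positive number")
    TRUE
  }
)

#' Construct a hyperspectral cube
#'
#' @param data numeric H x W x B array of absorbance.
#' @param axis [SpectralAxis-class] with B entries.
#' @param pixelSize pixel edge in micrometers (default 4.25, the focal-plane
#'   array pixel pitch of the imaging system the pipeline targets).
#' @return A [HyperCube-class].
#' @export
hyperCube <- function(data, axis, pixelSize = 4.25) {
  new("HyperCube", data = data, axis = axis, pixelSize = pixelSize)
}

#' Quality-control mask
#'
#' Per-pixel retention decisions from [qualityFilter()]. `keep` is `TRUE`
#' where the spectrum passes quality control; `reason` holds one of
#' `"low-signal"`, `"saturated"`, `"low-snr"` exactly where `keep` is `FALSE`
#' and `""` elsewhere.
#'
#' @slot keep logical H x W matrix.
#' @slot reason character H x W matrix.
#' @export
setClass("QCMask",
  representation(keep = "matrix", reason = "matrix"),
  validity = function(object) {
    if (!is.logical(object@keep)) return("keep must be logical")
    if (!identical(dim(object@keep), dim(object@reason)))
      return("keep and reason must have identical dimensions")
    if (any(object@reason[object@keep] != ""))
      return("retained pixels must have empty rejection reason")
    if (any(object@reason[!object@keep] == ""))
      return("rejected pixels must carry a rejection reason")
    TRUE
  }
)

#' Per-pixel tissue label map
#'
#' Integer class codes per pixel plus the palette used for index-color
#' rendering. Code 0 is reserved for background and renders black. `level`
#' identifies the roster: 1 for tissue types (pathological, inflammatory,
#' muscle, connective, crypts, lumen), 2 for pathological subtypes (tumor,
#' necrosis, inflammation, plus the inflammatory pass-through), and 0 for
#' free-form palettes such as phantom ground truth with combined coding.
#'
#' @slot labels integer H x W matrix of class codes (>= 0).
#' @slot level integer; 0 (free-form), 1 or 2.
#' @slot palette data.frame with columns `code`, `name`, `r`, `g`, `b`.
#'
#' @seealso [labelMap()], [renderLabelMap()], [readLabelMap()]
#' @export
setClass("LabelMap",
  representation(labels = "matrix", level = "integer", palette = "data.frame"),
  validity = function(object) {
    if (!is.integer(object@labels)) return("labels must be integer")
    if (any(object@labels < 0L)) return("label codes must be non-negative")
    pal <- object@palette
    need <- c("code", "name", "r", "g", "b")
    if (!all(need %in% names(pal)))
      return("palette must have columns code, name, r, g, b")
    if (anyDuplicated(pal$code)) return("palette codes must be unique")
    used <- setdiff(unique(as.vector(object@labels)), 0L)
    if (!all(used %in% pal$code))
      return("every nonzero label code must have a palette entry")
    if (!(object@level %in% c(0L, 1L, 2L))) return("level must be 0, 1 or 2")
    if (object@level == 1L &&
        !setequal(pal$name[pal$code != 0L],
                  c("pathological", "inflammatory", "muscle", "connective",
                    "crypts", "lumen")))
      return("level-1 palette must contain exactly the six tissue-type classes")
    if (object@level == 2L &&
        !setequal(pal$name[pal$code != 0L],
                  c("tumor", "necrosis", "inflammation",
                    "inflammatory-passthrough")))
      return("level-2 palette must contain exactly the four subtype classes")
    TRUE
  }
)

#' Construct a label map
#'
#' @param labels integer H x W matrix of class codes.
#' @param level 0 (free-form palette), 1 or 2.
#' @param palette palette data.frame; defaults to [levelOnePalette()] /
#'   [levelTwoPalette()] for levels 1 and 2.
#' @return A [LabelMap-class].
#' @export
labelMap <- function(labels, level, palette = NULL) {
  if (is.null(palette)) {
    palette <- switch(as.character(level),
      "1" = levelOnePalette(),
      "2" = levelTwoPalette(),
      stop("a palette must be supplied for free-form (level 0) maps"))
  }
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels, level = as.integer(level),
      palette = palette)
}

#' EMSC scatter-correction basis
#'
#' Design components for extended multiplicative signal correction with a
#' resonant-Mie interferent subspace: a reference spectrum, implicit constant
#' and linear baseline terms, and K orthonormal principal components of a
#' family of van de Hulst extinction curves Q(rho) evaluated over a grid of
#' sphere diameters d and refractive indices n.
#'
#' @slot reference numeric reference spectrum on `axis`.
#' @slot components B x K matrix of orthonormal Mie components.
#' @slot axis [SpectralAxis-class].
#' @slot dGrid,nGrid the diameter (micrometer) and refractive-index grids the
#'   curve family was built from.
#' @seealso [buildMieBasis()], [emscFit()], [emscCorrect()]
#' @export
setClass("EMSCBasis",
  representation(reference = "numeric", components = "matrix",
                 axis = "SpectralAxis", dGrid = "numeric", nGrid = "numeric"),
  validity = function(object) {
    B <- length(object@axis@wavenumbers)
    if (length(object@reference) != B) return("reference must lie on the axis")
    if (nrow(object@components) != B) return("components must lie on the axis")
    G <- crossprod(object@components)
    if (max(abs(G - diag(ncol(object@components)))) >= 1e-8)
      return("Mie components must be orthonormal")
    TRUE
  }
)

#' Per-spectrum EMSC fit
#'
#' Ordinary least-squares decomposition of one spectrum against
#' `c * reference + a + b * wavenumber + sum_k g_k p_k`.
#'
#' @slot c multiplicative reference coefficient.
#' @slot a constant baseline offset (absorbance).
#' @slot b linear baseline slope (absorbance per cm^-1).
#' @slot g numeric vector of Mie component loadings.
#' @slot residualRms root-mean-square of the fit residual (absorbance).
#' @export
setClass("EMSCFit",
  representation(c = "numeric", a = "numeric", b = "numeric", g = "numeric",
                 residualRms = "numeric"),
  validity = function(object) {
    if (!all(is.finite(c(object@c, object@a, object@b, object@g,
                         object@residualRms))))
      return("all EMSC coefficients must be finite")
    if (object@residualRms < 0) return("residualRms must be non-negative")
    TRUE
  }
)

#' Labeled spectral database
#'
#' Curated training spectra for one classifier level: Mie-corrected,
#' unsmoothed spectra on the fingerprint axis, with class labels and pixel
#' provenance.
#'
#' @slot spectra numeric n x B matrix, one spectrum per row.
#' @slot classes factor of length n over the level's roster.
#' @slot level integer 1 or 2.
#' @slot axis [SpectralAxis-class] shared by all spectra.
#' @slot provenance data.frame with columns `cube`, `row`, `col`.
#' @seealso [buildDatabase()]
#' @export
setClass("SpectralDatabase",
  representation(spectra = "matrix", classes = "factor", level = "integer",
                 axis = "SpectralAxis", provenance = "data.frame"),
  validity = function(object) {
    if (ncol(object@spectra) != length(object@axis@wavenumbers))
      return("spectra must lie on the database axis")
    if (nrow(object@spectra) != length(object@classes))
      return("one class label per spectrum required")
    if (nrow(object@spectra) != nrow(object@provenance))
      return("one provenance row per spectrum required")
    if (!(object@level %in% c(1L, 2L))) return("level must be 1 or 2")
    if (object@level == 2L &&
        !all(levels(object@classes) %in% c("tumor", "necrosis", "inflammation")))
      return("level-2 roster must be a subset of tumor/necrosis/inflammation")
    key <- paste(object@provenance$cube, object@provenance$row,
                 object@provenance$col)
    if (anyDuplicated(key)) return("duplicate (cube, pixel) entries")
    TRUE
  }
)

#' Trained two-level random-forest cascade
#'
#' The first forest discriminates tissue types (including a pathological
#' class); pixels it calls pathological are re-classified by the second
#' forest into tumor, necrosis and inflammation.
#'
#' @slot rf1,rf2 ranger forest objects for levels 1 and 2.
#' @slot axis fingerprint [SpectralAxis-class] both forests consume.
#' @slot roster1,roster2 class rosters (factor levels) per forest.
#' @slot oob named numeric: out-of-bag accuracy per level.
#' @slot nTrees,featuresPerSplit,seed training hyperparameters.
#' @seealso [trainCascade()], [classifyCube()], [variableImportance()]
#' @export
setClass("TrainedCascade",
  representation(rf1 = "ANY", rf2 = "ANY", axis = "SpectralAxis",
                 roster1 = "character", roster2 = "character",
                 oob = "numeric", nTrees = "integer",
                 featuresPerSplit = "integer", seed = "integer"))

#' Sample-level tumor diagnosis
#'
#' @slot tumorFraction tumor-coded pixels divided by tissue pixels.
#' @slot threshold decision threshold on the fraction (default 0.02).
#' @slot call `"positive"` or `"negative"`; positive iff
#'   `tumorFraction > threshold` (strict).
#' @slot tissuePixels,tumorPixels the underlying counts.
#' @seealso [diagnoseSample()], [callSample()]
#' @export
setClass("DiagnosisResult",
  representation(tumorFraction = "numeric", threshold = "numeric",
                 call = "character", tissuePixels = "integer",
                 tumorPixels = "integer"),
  validity = function(object) {
    if (object@tumorFraction < 0 || object@tumorFraction > 1)
      return("tumorFraction must lie in [0, 1]")
    expected <- if (object@tumorFraction > object@threshold) "positive"
                else "negative"
    if (object@call != expected)
      return("call must be positive iff tumorFraction exceeds the threshold")
    TRUE
  }
)
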