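# Resonant-Mie EMSC scatter correction. The model per spectrum is
#   A_obs(wn) = c * m(wn) + a + b * wn + sum_k g_k p_k(wn) + eps
# with m a reference spectrum and p_k orthonormal principal components of a
# family of van de Hulst extinction curves. Correction inverts the nuisance
# terms: (A_obs - a - b*wn - sum g_k p_k) / c.

#' Van de Hulst extinction efficiency
#'
#' Anomalous-diffraction approximation of the extinction efficiency of a
#' sphere, `Q(rho) = 2 - (4/rho) sin(rho) + (4/rho^2)(1 - cos(rho))`, with
#' the phase parameter `rho = 2 pi d (n - 1) wn`. Evaluated by Taylor series
#' for small `rho` (where the closed form cancels catastrophically) so that
#' `Q(0) = 0` continuously; `Q -> 2` as `rho -> Inf`.
#'
#' @param rho non-negative phase parameter (vectorized).
#' @return `Q(rho)`, same shape as `rho`.
#' @export
vdhExtinction <- function(rho) {
  if (any(rho < 0)) stop("domain error: rho must be non-negative")
  q <- rho
  small <- rho < 1e-2
  q[small] <- rho[small]^2 / 2 - rho[small]^4 / 36 + rho[small]^6 / 1440
  r <- rho[!small]
  q[!small] <- 2 - (4 / r) * sin(r) + (4 / r^2) * (1 - cos(r))
  q
}

#' Build the Mie EMSC basis
#'
#' Evaluates `Q(2 pi d (n - 1) wn)` for every `(d, n)` pair of the grids,
#' mean-centers the curve family, and takes its first `K` principal
#' components (left singular vectors) as the orthonormal Mie interferent
#' subspace. Deterministic.
#'
#' @param axis [SpectralAxis-class].
#' @param reference reference spectrum on `axis` (used by [emscFit()]).
#' @param dGrid sphere diameters in micrometers (default 10 steps in 2-20).
#' @param nGrid refractive indices (default 9 steps in 1.1-1.5).
#' @param K number of components (default 6; must not exceed the family
#'   size).
#' @return An [EMSCBasis-class].
#' @export
buildMieBasis <- function(axis, reference,
                          dGrid = seq(2, 20, length.out = 10),
                          nGrid = seq(1.1, 1.5, length.out = 9), K = 6L) {
  stopifnot(length(reference) == length(wavenumbers(axis)))
  if (K > length(dGrid) * length(nGrid))
    stop("parameter error: K exceeds the curve-family size")
  wn <- wavenumbers(axis)
  ia <- which(wn >= 1600 & wn <= 1700)
  if (length(ia) > 1L) {
    sp <- axisSpacing(axis)
    integ <- sp * (sum(reference[ia]) -
                   0.5 * (reference[ia[1L]] + reference[ia[length(ia)]]))
    if (integ <= 0)
      stop("basis error: reference spectrum has non-positive amide I integral")
  }
  fam <- matrix(0, length(wn), length(dGrid) * length(nGrid))
  j <- 0L
  for (n in nGrid) for (d in dGrid) {
    j <- j + 1L
    fam[, j] <- vdhExtinction(2 * pi * (d * 1e-4) * (n - 1) * wn)
  }
  centered <- fam - rowMeans(fam)
  if (max(abs(centered)) < 1e-12 || max(abs(fam)) < 1e-12)
    stop("basis error: degenerate Mie curve family (all curves identical)")
  sv <- svd(centered, nu = K, nv = 0L)
  new("EMSCBasis", reference = as.numeric(reference),
      components = sv$u[, seq_len(K), drop = FALSE], axis = axis,
      dGrid = dGrid, nGrid = nGrid)
}

.emscDesign <- function(basis) {
  wn <- wavenumbers(basis@axis)
  cbind(reference = basis@reference, offset = 1, slope = wn,
        basis@components)
}

# least-squares fit of many spectra at once; S is B x N
.emscFitMatrix <- function(S, basis) {
  X <- .emscDesign(basis)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    nm <- c("reference", "offset", "slope",
            paste0("mie", seq_len(ncol(basis@components))))
    stop("fit error: rank-deficient EMSC design; collinear column(s): ",
         paste(nm[drop], collapse = ", "))
  }
  beta <- qr.coef(qrX, S)
  resid <- S - X %*% beta
  list(beta = beta, residualRms = sqrt(colMeans(resid^2)))
}

#' Fit the EMSC model to one spectrum
#'
#' Ordinary least squares of `s` against the design
#' `[reference, 1, wn, p_1 ... p_K]`.
#'
#' @param s numeric spectrum on the basis axis.
#' @param basis an [EMSCBasis-class].
#' @return An [EMSCFit-class].
#' @export
emscFit <- function(s, basis) {
  stopifnot(length(s) == length(wavenumbers(basis@axis)))
  f <- .emscFitMatrix(matrix(s, ncol = 1L), basis)
  K <- ncol(basis@components)
  b <- unname(f$beta[, 1L])
  new("EMSCFit", c = b[1L], a = b[2L], b = b[3L],
      g = b[3L + seq_len(K)], residualRms = unname(f$residualRms[1L]))
}

#' Correct one spectrum with a fitted EMSC model
#'
#' Returns `(s - a - b * wn - sum_k g_k p_k) / c`. Re-fitting the corrected
#' spectrum yields the identity coefficients (`c = 1`, rest 0) within 1e-6.
#'
#' @param s numeric spectrum on the basis axis.
#' @param fit an [EMSCFit-class] for `s`.
#' @param basis the [EMSCBasis-class] used for the fit.
#' @param cMin rejection guard: fits with `|c| < cMin` are refused (such
#'   degenerate pixels are routed to background by [mieCorrectCube()]).
#' @return The corrected spectrum.
#' @export
emscCorrect <- function(s, fit, basis, cMin = 0.1) {
  if (abs(fit@c) < cMin)
    stop("correction rejected: |c| = ", format(abs(fit@c)),
         " below cMin = ", cMin)
  wn <- wavenumbers(basis@axis)
  as.numeric((s - fit@a - fit@b * wn - basis@components %*% fit@g) / fit@c)
}

#' Resonant-Mie EMSC correction of a whole cube
#'
#' The reference spectrum is the mean of the QC-retained pixel spectra of
#' the cube itself, orthogonalized against the baseline and Mie components
#' before fitting: an in-cube mean is itself scatter-contaminated, and
#' without the purge the contamination would be preserved by the correction
#' (the reference term is the one component EMSC keeps). The Mie basis is
#' built once per iteration; every retained pixel is fit and corrected. With `iterations > 1` the reference
#' is recomputed from the corrected spectra and the fit repeated (one
#' iteration is the default and does not change results appreciably).
#' Rejected pixels pass through unchanged. Pixels whose fitted `|c|` falls
#' below `cMin` are not corrected and are routed to background: the
#' returned mask marks them rejected with reason `low-signal`.
#'
#' @param cube a [HyperCube-class].
#' @param mask a [QCMask-class] of matching shape.
#' @param iterations number of reference-update iterations (default 1).
#' @param cMin rejection guard on the reference coefficient.
#' @param dGrid,nGrid,K forwarded to [buildMieBasis()].
#' @return A list with elements `cube` (corrected [HyperCube-class]), `mask`
#'   (updated [QCMask-class]) and `basis` (the last [EMSCBasis-class]).
#' @export
mieCorrectCube <- function(cube, mask, iterations = 1L, cMin = 0.1,
                           dGrid = seq(2, 20, length.out = 10),
                           nGrid = seq(1.1, 1.5, length.out = 9), K = 6L) {
  d <- dim(cube@data)
  stopifnot(identical(dim(mask@keep), d[1:2]))
  keep <- as.vector(mask@keep)
  if (!any(keep)) stop("empty-mask error: no retained pixels to correct")
  npix <- d[1L] * d[2L]
  S <- t(matrix(cube@data, npix, d[3L]))        # B x npix
  reason <- as.vector(mask@reason)
  basis <- NULL
  wn <- wavenumbers(cube@axis)
  for (it in seq_len(iterations)) {
    reference <- rowMeans(S[, keep, drop = FALSE])
    basis <- buildMieBasis(cube@axis, reference, dGrid, nGrid, K)
    # purge scatter/baseline contamination from the in-cube reference
    N <- cbind(1, wn, basis@components)
    reference <- as.numeric(reference - N %*% qr.solve(N, reference))
    basis@reference <- reference
    f <- .emscFitMatrix(S[, keep, drop = FALSE], basis)
    cc <- f$beta[1L, ]
    ok <- abs(cc) >= cMin
    X <- .emscDesign(basis)
    nuisance <- X[, -1L, drop = FALSE] %*% f$beta[-1L, , drop = FALSE]
    corrected <- sweep(S[, keep, drop = FALSE] - nuisance, 2L, cc, "/")
    idx <- which(keep)
    S[, idx[ok]] <- corrected[, ok]
    if (any(!ok)) {                  # degenerate fits -> background
      reason[idx[!ok]] <- "low-signal"
      keep[idx[!ok]] <- FALSE
    }
  }
  out <- cube
  out@data <- array(as.vector(t(S)), dim = d)
  newMask <- new("QCMask", keep = matrix(keep, d[1L], d[2L]),
                 reason = matrix(reason, d[1L], d[2L]))
  list(cube = out, mask = newMask, basis = basis)
}
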