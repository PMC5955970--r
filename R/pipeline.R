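#' Preprocess a cube for classification
#'
#' Quality control, resonant-Mie EMSC correction on the full loaded axis,
#' then cropping to the fingerprint region. This is the standard front-end
#' before database curation or classification.
#'
#' @param cube a raw [HyperCube-class].
#' @param qc see [qcParams()].
#' @param iterations EMSC reference-update iterations (default 1).
#' @param low,high fingerprint window in cm^-1 (defaults 998 and 1760).
#' @param ... forwarded to [mieCorrectCube()].
#' @return A list with `cube` (corrected, fingerprint-cropped
#'   [HyperCube-class]), `mask` ([QCMask-class]) and `basis`
#'   ([EMSCBasis-class]).
#' @export
preprocessCube <- function(cube, qc = qcParams(), iterations = 1L,
                           low = 998, high = 1760, ...) {
  mask <- qualityFilter(cube, qc)
  corr <- mieCorrectCube(cube, mask, iterations = iterations, ...)
  list(cube = cropFingerprint(corr$cube, low = low, high = high),
       mask = corr$mask, basis = corr$basis)
}

#' Classify and diagnose one phantom sample end to end
#'
#' Synthesize (or accept) a cube, preprocess, classify with a trained
#' cascade and call the sample against the 2% tumor-fraction rule.
#'
#' @param cube raw [HyperCube-class].
#' @param cascade a [TrainedCascade-class].
#' @param qc see [qcParams()].
#' @param threshold tumor-fraction threshold (default 0.02).
#' @return A list with `level1`, `level2` ([LabelMap-class]), `mask` and
#'   `diagnosis` ([DiagnosisResult-class]).
#' @export
classifySample <- function(cube, cascade, qc = qcParams(), threshold = 0.02) {
  pre <- preprocessCube(cube, qc = qc)
  maps <- classifyCube(pre$cube, cascade, pre$mask)
  list(level1 = maps$level1, level2 = maps$level2, mask = pre$mask,
       diagnosis = diagnoseSample(maps$level2, maps$level1,
                                  threshold = threshold))
}

#' Train a cascade from phantom draws
#'
#' Convenience wrapper for validation studies: synthesizes `nCubes` phantom
#' cubes (seeds `seed, seed+1, ...`), preprocesses them, curates the two
#' spectral databases and trains the cascade.
#'
#' @param nCubes number of training phantoms.
#' @param spec template [PhantomSpec-class]; its seed is replaced per cube.
#' @param lib band library.
#' @param perClassCap spectra per class and database (default 2000).
#' @param nTrees,featuresPerSplit forest hyperparameters.
#' @param seed master seed.
#' @param qc see [qcParams()].
#' @return A [TrainedCascade-class].
#' @export
trainPhantomCascade <- function(nCubes = 3L, spec = phantomSpec(),
                                lib = defaultBandLibrary(),
                                perClassCap = 2000L, nTrees = 500L,
                                featuresPerSplit = 16L, seed = 1L,
                                qc = qcParams()) {
  cubes <- list(); truths <- list(); masks <- list()
  for (i in seq_len(nCubes)) {
    sp <- spec
    sp@seed <- as.integer(seed + i - 1L)
    syn <- synthesizeCube(sp, lib)
    pre <- preprocessCube(syn$cube, qc = qc)
    cubes[[i]] <- pre$cube
    truths[[i]] <- syn$truth
    masks[[i]] <- pre$mask
  }
  db1 <- buildDatabase(cubes, truths, masks, level = 1L,
                       perClassCap = perClassCap, seed = seed)
  db2 <- buildDatabase(cubes, truths, masks, level = 2L,
                       perClassCap = perClassCap, seed = seed + 1L)
  trainCascade(db1, db2, nTrees = nTrees,
               featuresPerSplit = featuresPerSplit, seed = seed)
}
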