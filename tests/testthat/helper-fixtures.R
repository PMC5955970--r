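# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code (no binary data); seeds are fixed so every run sees the
# same objects.

.fx <- new.env(parent = emptyenv())

# a small phantom with ground truth, shared across read-only tests
fixturePhantom <- function() {
  if (is.null(.fx$phantom))
    .fx$phantom <- synthesizeCube(phantomSpec(height = 64, width = 64,
                                              seed = 7L))
  .fx$phantom
}

# a cascade trained on two 96 x 96 phantoms at default noise; 500 trees /
# 16 features per split, <= 250 spectra per class
fixtureCascade <- function() {
  if (is.null(.fx$cascade))
    .fx$cascade <- trainPhantomCascade(
      nCubes = 2L, spec = phantomSpec(height = 96, width = 96),
      perClassCap = 250L, nTrees = 500L, featuresPerSplit = 16L, seed = 42L)
  .fx$cascade
}

# tissue-pixel accuracy of a predicted level-1 map against ground truth
tissueAccuracy <- function(level1, truth, mask) {
  truthToL1 <- c(`1` = 6L, `2` = 5L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 2L,
                 `7` = 1L, `8` = 1L)
  lab <- labelCodes(truth)
  sel <- lab %in% 2:8 & qcKeep(mask)   # tissue pixels that were classified
  mean(labelCodes(level1)[sel] == truthToL1[as.character(lab[sel])])
}

# a simple two-band spectrum used as an EMSC reference in tests
testReference <- function(axis = spectralAxis()) {
  wn <- wavenumbers(axis)
  0.8 * exp(-(wn - 1656)^2 / (2 * (50 / 2.3548)^2)) +
    0.5 * exp(-(wn - 1546)^2 / (2 * (45 / 2.3548)^2)) +
    0.3 * exp(-(wn - 1080)^2 / (2 * (60 / 2.3548)^2))
}
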