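# Sample-level tumor diagnosis: the fraction of tissue pixels labeled tumor
# must exceed a 2% threshold (strict) for a positive call, because isolated
# tumor-labeled pixels can also arise from spectral noise. Study-level
# metrics accumulate per-sample calls against truth.

#' Tumor-pixel fraction of a classified sample
#'
#' Tumor-coded pixels divided by tissue pixels, where tissue means level-1
#' nonzero (QC-retained, non-background): empty slide area does not dilute
#' the fraction.
#'
#' @param level2 level-2 [LabelMap-class] (tumor code 1).
#' @param level1 aligned level-1 [LabelMap-class].
#' @return The fraction in `[0, 1]`.
#' @export
tumorFraction <- function(level2, level1) {
  stopifnot(identical(dim(level2@labels), dim(level1@labels)))
  tissue <- sum(level1@labels != 0L)
  if (tissue == 0L) stop("empty-tissue error: no tissue pixels in the sample")
  sum(level2@labels == 1L) / tissue
}

#' Sample-level tumor call
#'
#' Positive iff `fraction > threshold` -- the inequality is strict, a
#' fraction exactly at the threshold is negative.
#'
#' @param fraction tumor-pixel fraction in `[0, 1]`.
#' @param threshold decision threshold (default 0.02).
#' @return `"positive"` or `"negative"`.
#' @export
callSample <- function(fraction, threshold = 0.02) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction > threshold) "positive" else "negative"
}

#' Diagnose a classified sample
#'
#' @param level2,level1 classified [LabelMap-class] maps.
#' @param threshold decision threshold on the tumor fraction (default 0.02).
#' @return A [DiagnosisResult-class].
#' @export
diagnoseSample <- function(level2, level1, threshold = 0.02) {
  fr <- tumorFraction(level2, level1)
  new("DiagnosisResult", tumorFraction = fr, threshold = threshold,
      call = callSample(fr, threshold),
      tissuePixels = sum(level1@labels != 0L),
      tumorPixels = sum(level2@labels == 1L))
}

.roundHalfUp <- function(x) floor(x + 0.5)

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each as
#' an exact fraction and as a nearest-integer percent (rounded half-up,
#' the clinical reporting convention). A metric with zero denominator is
#' reported as `NA` (undefined), not an error.
#'
#' @param tp,fn,tn,fp non-negative sample counts.
#' @return A list with `fractions` and `percents` (named numeric vectors)
#'   and the `counts`.
#' @export
confusionMetrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  frac <- c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
            specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
            ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
            npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  list(fractions = frac, percents = .roundHalfUp(100 * frac),
       counts = c(tp = tp, fn = fn, tn = tn, fp = fp))
}

#' Evaluate a study of diagnosed samples
#'
#' Accumulates true/false positives/negatives from sample calls against
#' truth (the statistics are per tissue section, not per pixel) and derives
#' the diagnostic metrics.
#'
#' @param results list of [DiagnosisResult-class] objects.
#' @param truth logical vector: is each sample tumor-bearing?
#' @param ids optional sample identifiers.
#' @return A list with `counts`, `metrics` (see [confusionMetrics()]) and
#'   `samples` (per-sample data.frame: id, tissue and tumor pixel counts,
#'   fraction, call, truth).
#' @export
evaluateStudy <- function(results, truth, ids = seq_along(results)) {
  stopifnot(length(results) >= 1L, length(results) == length(truth))
  calls <- vapply(results, function(r) r@call, character(1L))
  pos <- calls == "positive"
  counts <- c(tp = sum(pos & truth), fn = sum(!pos & truth),
              tn = sum(!pos & !truth), fp = sum(pos & !truth))
  samples <- data.frame(
    id = ids,
    tissue_pixels = vapply(results, function(r) r@tissuePixels, integer(1L)),
    tumor_pixels = vapply(results, function(r) r@tumorPixels, integer(1L)),
    tumor_fraction = vapply(results, function(r) r@tumorFraction, numeric(1L)),
    call = calls,
    truth = ifelse(truth, "tumor", "tumor-free"))
  list(counts = counts,
       metrics = confusionMetrics(counts[["tp"]], counts[["fn"]],
                                  counts[["tn"]], counts[["fp"]]),
       samples = samples)
}

#' Write a study report as CSV
#'
#' Per-sample table followed by a summary block (counts and metrics) as
#' comment lines.
#'
#' @param study result of [evaluateStudy()].
#' @param path output CSV path.
#' @return Invisibly `path`.
#' @export
writeStudyReport <- function(study, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(study$samples, con, row.names = FALSE)
  cnt <- study$counts
  pct <- study$metrics$percents
  writeLines(c(
    sprintf("# counts: TP=%d FN=%d TN=%d FP=%d",
            cnt[["tp"]], cnt[["fn"]], cnt[["tn"]], cnt[["fp"]]),
    sprintf("# sensitivity=%s%% specificity=%s%% ppv=%s%% npv=%s%%",
            pct[["sensitivity"]], pct[["specificity"]], pct[["ppv"]],
            pct[["npv"]])), con)
  invisible(path)
}
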