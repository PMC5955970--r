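#' Render a label map as an index-color PNG
#'
#' Writes an RGB PNG in which pixel (i, j) carries exactly the palette RGB
#' triple of its class code; background (code 0) renders black.
#'
#' @param map a [LabelMap-class].
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @seealso [readLabelMap()]
#' @export
renderLabelMap <- function(map, path) {
  stopifnot(is(map, "LabelMap"))
  pal <- map@palette
  idx <- match(map@labels, pal$code)
  if (anyNA(idx))
    stop("palette error: label code(s) ",
         paste(unique(map@labels[is.na(idx)]), collapse = ", "),
         " have no palette entry")
  h <- nrow(map@labels); w <- ncol(map@labels)
  img <- array(0, dim = c(h, w, 3L))
  img[, , 1L] <- pal$r[idx] / 255
  img[, , 2L] <- pal$g[idx] / 255
  img[, , 3L] <- pal$b[idx] / 255
  png::writePNG(img, path)
  invisible(path)
}

#' Read a label map from an index-color PNG or a CSV of codes
#'
#' PNG pixels are matched exactly against the palette RGB triples; a color
#' not in the palette is an error. CSV files hold one integer class code per
#' cell (no header), validated against the palette.
#'
#' @param path path to a `.png` or `.csv` file.
#' @param palette palette data.frame (see [levelOnePalette()]).
#' @param level roster level of the returned map (0, 1 or 2).
#' @return A [LabelMap-class].
#' @export
readLabelMap <- function(path, palette, level = 0L) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    codes <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(codes) <- NULL
    storage.mode(codes) <- "integer"
    bad <- setdiff(unique(as.vector(codes)), palette$code)
    if (length(bad))
      stop("palette error: unknown class code(s) ",
           paste(bad, collapse = ", "), " in ", path)
    return(labelMap(codes, level = level, palette = palette))
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  rgb <- round(img[, , 1:3] * 255)
  key <- rgb[, , 1L] * 65536 + rgb[, , 2L] * 256 + rgb[, , 3L]
  palKey <- palette$r * 65536 + palette$g * 256 + palette$b
  idx <- match(key, palKey)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])[1L]
    stop(sprintf("palette error: RGB (%d,%d,%d) in %s is not in the palette",
                 bad %/% 65536, (bad %/% 256) %% 256, bad %% 256, path))
  }
  codes <- matrix(palette$code[idx], nrow = dim(img)[1L])
  labelMap(codes, level = level, palette = palette)
}

#' Write a label map as a CSV of integer class codes
#'
#' @param map a [LabelMap-class].
#' @param path output CSV path (no header; one row per image row).
#' @return Invisibly, `path`.
#' @export
writeLabelMapCSV <- function(map, path) {
  stopifnot(is(map, "LabelMap"))
  utils::write.table(map@labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
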