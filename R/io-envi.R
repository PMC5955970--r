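# ENVI header/raster I/O. Canonical written dialect: band-sequential (BSQ),
# data type 4 (float32), byte order 0 (little-endian); BIL/BIP accepted on
# read, never written. The raster stores bands in on-disk wavelength order;
# read always normalizes the axis to descending wavenumber, permuting bands
# to match.

.enviHeaderPath <- function(path) {
  if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
}
.enviDataPath <- function(path) sub("\\.hdr$", "", path)

.parseEnviHeader <- function(hdrPath) {
  txt <- readLines(hdrPath, warn = FALSE)
  if (!length(txt) || !grepl("^ENVI", txt[1L]))
    stop("ENVI format error: missing ENVI magic line in ", hdrPath)
  body <- paste(txt[-1L], collapse = "\n")
  # join brace-delimited multi-line values
  fields <- list()
  # split on lines that look like "key = value"; values in {...} may span lines
  pat <- "(?s)([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, body, perl = TRUE)[[1]]
  if (m[1L] != -1L) {
    starts <- as.vector(m); lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      piece <- substr(body, starts[i], starts[i] + lens[i] - 1L)
      key <- tolower(trimws(sub("(?s)^([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=.*$", "\\1",
                                piece, perl = TRUE)))
      val <- trimws(sub("(?s)^[^=]*=\\s*", "", piece, perl = TRUE))
      fields[[key]] <- val
    }
  }
  fields
}

.enviNum <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) stop("ENVI format error: header field '", key, "' is missing")
  n <- suppressWarnings(as.numeric(v))
  if (is.na(n)) stop("ENVI format error: header field '", key, "' is not numeric")
  n
}

#' Read a hyperspectral cube from an ENVI header/raster pair
#'
#' Reads an ENVI cube (32-bit float; BSQ, BIL or BIP interleave; little- or
#' big-endian) whose header declares the wavelength list in cm^-1. The
#' returned cube always has a descending wavenumber axis; if the file stores
#' wavelengths ascending, the bands are permuted so that band 1 holds the
#' highest-wavenumber plane.
#'
#' @param path path to the `.hdr` file or to the raster file (the `.hdr`
#'   extension is appended to find the header).
#' @return A [HyperCube-class].
#' @seealso [writeCube()]
#' @export
readCube <- function(path) {
  hdrPath <- .enviHeaderPath(path)
  if (!file.exists(hdrPath)) stop("ENVI format error: header not found: ", hdrPath)
  datPath <- .enviDataPath(hdrPath)
  if (!file.exists(datPath)) stop("ENVI format error: raster not found: ", datPath)
  f <- .parseEnviHeader(hdrPath)
  samples <- as.integer(.enviNum(f, "samples"))
  lines   <- as.integer(.enviNum(f, "lines"))
  bands   <- as.integer(.enviNum(f, "bands"))
  dtype   <- as.integer(.enviNum(f, "data type"))
  if (dtype != 4L)
    stop("ENVI format error: field 'data type' must be 4 (float32), got ", dtype)
  byteOrder <- if (is.null(f[["byte order"]])) 0L
               else as.integer(.enviNum(f, "byte order"))
  interleave <- tolower(if (is.null(f[["interleave"]])) "bsq"
                        else f[["interleave"]])
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("ENVI format error: field 'interleave' has unsupported value '",
         interleave, "'")
  wl <- f[["wavelength"]]
  if (is.null(wl))
    stop("ENVI format error: header field 'wavelength' is missing")
  wl <- as.numeric(strsplit(gsub("[{}\n]", "", wl), ",")[[1]])
  if (any(is.na(wl)))
    stop("ENVI format error: field 'wavelength' contains non-numeric entries")
  if (length(wl) != bands)
    stop("ENVI format error: field 'wavelength' lists ", length(wl),
         " values but 'bands' declares ", bands)
  dwl <- diff(wl)
  if (length(wl) > 1L &&
      (any(dwl == 0) || max(abs(abs(dwl) - abs(dwl[1L]))) > 1e-6))
    stop("spectral axis error: non-uniform wavelength grid in ", hdrPath)

  expected <- as.numeric(samples) * lines * bands * 4
  actual <- file.info(datPath)$size
  if (actual != expected)
    stop("ENVI format error: raster size ", actual, " bytes does not match ",
         "header (", lines, " lines x ", samples, " samples x ", bands,
         " bands x 4 = ", expected, " bytes)")

  con <- file(datPath, "rb")
  on.exit(close(con))
  endian <- if (byteOrder == 0L) "little" else "big"
  raw <- readBin(con, what = "numeric", n = samples * lines * bands, size = 4L,
                 endian = endian)
  # assemble H x W x B (row-major lines within each band on disk)
  cube <- switch(interleave,
    bsq = aperm(array(raw, dim = c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(raw, dim = c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(raw, dim = c(bands, samples, lines)), c(3L, 2L, 1L)))

  if (length(wl) > 1L && wl[2L] > wl[1L]) {   # stored ascending: flip
    ord <- rev(seq_along(wl))
    wl <- wl[ord]
    cube <- cube[, , ord, drop = FALSE]
  }
  px <- if (!is.null(f[["pixel size"]]))
          as.numeric(gsub("[{}]", "", strsplit(f[["pixel size"]], ",")[[1]][1]))
        else 4.25
  hyperCube(cube, spectralAxis(wl), pixelSize = px)
}

#' Write a hyperspectral cube as an ENVI header/raster pair
#'
#' Writes the canonical dialect: BSQ interleave, float32, little-endian,
#' with the wavelength list (descending, cm^-1) and pixel size in the header.
#' [readCube()] inverts it exactly for data representable in float32.
#'
#' @param cube a [HyperCube-class].
#' @param path path of the raster file to write; the header is written to
#'   `paste0(path, ".hdr")`.
#' @return Invisibly, `path`.
#' @export
writeCube <- function(cube, path) {
  stopifnot(is(cube, "HyperCube"))
  d <- dim(cube@data)
  wl <- cube@axis@wavenumbers
  hdr <- c(
    "ENVI",
    "description = {mirtissue hyperspectral absorbance cube}",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = cm-1",
    paste0("pixel size = {", cube@pixelSize, ", ", cube@pixelSize, "}"),
    paste0("wavelength = {", paste(format(wl, trim = TRUE, digits = 12),
                                   collapse = ", "), "}"))
  tryCatch({
    writeLines(hdr, paste0(path, ".hdr"))
    con <- file(path, "wb")
    on.exit(close(con))
    # BSQ: per band, lines of samples (row-major within band)
    writeBin(as.vector(aperm(cube@data, c(2L, 1L, 3L))), con, size = 4L,
             endian = "little")
  }, error = function(e) stop("I/O error writing cube to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
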