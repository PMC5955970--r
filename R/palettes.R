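.pal <- function(code, name, r, g, b)
  data.frame(code = as.integer(code), name = name, r = as.integer(r),
             g = as.integer(g), b = as.integer(b), stringsAsFactors = FALSE)

#' Index-color palettes
#'
#' Fixed palettes for the two classifier levels and for phantom ground truth.
#' Level 1 (tissue types): red pathological, yellow infiltrating inflammatory
#' cells, white muscle, green connective tissue, cyan crypts, blue lumen,
#' black background. Level 2 (pathological subtypes): red tumor, magenta
#' necrosis, green inflammation, yellow inflammatory pass-through, black
#' background. The ground-truth palette uses combined coding: level-1 tissue
#' classes with the two anatomical muscle layers kept separate, plus distinct
#' tumor, necrosis and debris/blood codes.
#'
#' @return A data.frame with columns `code`, `name`, `r`, `g`, `b`.
#' @export
levelOnePalette <- function() rbind(
  .pal(0L, "background",   0,   0,   0),
  .pal(1L, "pathological", 255, 0,   0),
  .pal(2L, "inflammatory", 255, 255, 0),
  .pal(3L, "muscle",       255, 255, 255),
  .pal(4L, "connective",   0,   128, 0),
  .pal(5L, "crypts",       0,   255, 255),
  .pal(6L, "lumen",        0,   0,   255)
)

#' @rdname levelOnePalette
#' @export
levelTwoPalette <- function() rbind(
  .pal(0L, "background",               0,   0,   0),
  .pal(1L, "tumor",                    255, 0,   0),
  .pal(2L, "necrosis",                 255, 0,   255),
  .pal(3L, "inflammation",             0,   128, 0),
  .pal(4L, "inflammatory-passthrough", 255, 255, 0)
)

# ground-truth codes used by the phantom generator
.TRUTH <- c(background = 0L, lumen = 1L, crypts = 2L, connective = 3L,
            muscleA = 4L, muscleB = 5L, inflammatory = 6L, tumor = 7L,
            necrosis = 8L, debris = 9L)

#' Ground-truth class codes of the phantom generator
#'
#' @return Named integer vector mapping class names to the combined-coding
#'   values used in phantom ground-truth maps.
#' @export
truthCodes <- function() .TRUTH

#' @rdname levelOnePalette
#' @export
truthPalette <- function() rbind(
  .pal(0L, "background",   0,   0,   0),
  .pal(1L, "lumen",        0,   0,   255),
  .pal(2L, "crypts",       0,   255, 255),
  .pal(3L, "connective",   0,   128, 0),
  .pal(4L, "muscleA",      255, 255, 255),
  .pal(5L, "muscleB",      200, 200, 200),
  .pal(6L, "inflammatory", 255, 255, 0),
  .pal(7L, "tumor",        255, 0,   0),
  .pal(8L, "necrosis",     255, 0,   255),
  .pal(9L, "debris",       128, 0,   0)
)
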