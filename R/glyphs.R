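# Bitmap glyph faces.
#
# The deliverable ships no font binaries; instead two monospaced bitmap
# faces are defined here in source.  The same glyphs drive (a) the synthetic
# report renderer / OCR corpus generator and (b) the deterministic
# template-matching reference recognizer, which is what makes the reference
# recognizer an exact oracle on clean synthetic fixtures.

.glyph5x7 <- list(
  "0" = c("01110","10001","10011","10101","11001","10001","01110"),
  "1" = c("00100","01100","00100","00100","00100","00100","01110"),
  "2" = c("01110","10001","00001","00010","00100","01000","11111"),
  "3" = c("11111","00010","00100","00010","00001","10001","01110"),
  "4" = c("00010","00110","01010","10010","11111","00010","00010"),
  "5" = c("11111","10000","11110","00001","00001","10001","01110"),
  "6" = c("00110","01000","10000","11110","10001","10001","01110"),
  "7" = c("11111","00001","00010","00100","01000","01000","01000"),
  "8" = c("01110","10001","10001","01110","10001","10001","01110"),
  "9" = c("01110","10001","10001","01111","00001","00010","01100"),
  "." = c("00000","00000","00000","00000","00000","01100","01100"),
  "-" = c("00000","00000","00000","11111","00000","00000","00000"),
  "%" = c("11001","11010","00010","00100","01000","01011","10011"),
  "/" = c("00001","00010","00010","00100","01000","01000","10000"),
  ":" = c("00000","01100","01100","00000","01100","01100","00000"),
  " " = c("00000","00000","00000","00000","00000","00000","00000"),
  "A" = c("01110","10001","10001","11111","10001","10001","10001"),
  "B" = c("11110","10001","10001","11110","10001","10001","11110"),
  "C" = c("01110","10001","10000","10000","10000","10001","01110"),
  "D" = c("11100","10010","10001","10001","10001","10010","11100"),
  "E" = c("11111","10000","10000","11110","10000","10000","11111"),
  "F" = c("11111","10000","10000","11110","10000","10000","10000"),
  "G" = c("01110","10001","10000","10111","10001","10001","01111"),
  "H" = c("10001","10001","10001","11111","10001","10001","10001"),
  "I" = c("01110","00100","00100","00100","00100","00100","01110"),
  "J" = c("00111","00010","00010","00010","00010","10010","01100"),
  "K" = c("10001","10010","10100","11000","10100","10010","10001"),
  "L" = c("10000","10000","10000","10000","10000","10000","11111"),
  "M" = c("10001","11011","10101","10101","10001","10001","10001"),
  "N" = c("10001","10001","11001","10101","10011","10001","10001"),
  "O" = c("01110","10001","10001","10001","10001","10001","01110"),
  "P" = c("11110","10001","10001","11110","10000","10000","10000"),
  "Q" = c("01110","10001","10001","10001","10101","10010","01101"),
  "R" = c("11110","10001","10001","11110","10100","10010","10001"),
  "S" = c("01111","10000","10000","01110","00001","00001","11110"),
  "T" = c("11111","00100","00100","00100","00100","00100","00100"),
  "U" = c("10001","10001","10001","10001","10001","10001","01110"),
  "V" = c("10001","10001","10001","10001","10001","01010","00100"),
  "W" = c("10001","10001","10001","10101","10101","10101","01010"),
  "X" = c("10001","10001","01010","00100","01010","10001","10001"),
  "Y" = c("10001","10001","10001","01010","00100","00100","00100"),
  "Z" = c("11111","00001","00010","00100","01000","10000","11111")
)

#' Default recognizable character set
#'
#' Digits, decimal point, minus sign, percent, slash, colon, space and the
#' uppercase Latin letters.  Configurable wherever a charset is accepted.
#' @return Single string of the 42 default characters.
#' @export
default_charset <- function() {
  "0123456789.-%/: ABCDEFGHIJKLMNOPQRSTUVWXYZ"
}

.glyph_to_matrix <- function(rows) {
  m <- do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1L]])))
  storage.mode(m) <- "double"
  m
}

# Emboldened variant: each glyph OR-ed with a one-pixel rightward shift on a
# one-column-wider cell.  Visually heavier strokes; forces the trained
# recognizer to be style-invariant.
.embolden <- function(m) {
  out <- cbind(m, 0)
  out[, -1L] <- pmax(out[, -1L], m)
  out
}

.font_cache <- new.env(parent = emptyenv())

#' Bundled bitmap fonts
#' @return Named list of fonts; each font is a list with `name`, `height`,
#'   `cell_width` and `glyphs` (character -> 0/1 matrix).
#' @export
octreport_fonts <- function() {
  if (!is.null(.font_cache$fonts)) return(.font_cache$fonts)
  plain <- lapply(.glyph5x7, .glyph_to_matrix)
  bold <- lapply(plain, .embolden)
  fonts <- list(
    plain = list(name = "plain", height = 7L, cell_width = 5L, glyphs = plain),
    bold  = list(name = "bold",  height = 7L, cell_width = 6L, glyphs = bold)
  )
  .font_cache$fonts <- fonts
  fonts
}

# Nearest-neighbour scale of a 0/1 bitmap by (possibly fractional) factor s.
scale_bitmap <- function(m, s) {
  h <- max(1L, as.integer(round(nrow(m) * s)))
  w <- max(1L, as.integer(round(ncol(m) * s)))
  ri <- pmin(nrow(m), floor((seq_len(h) - 0.5) / s) + 1L)
  ci <- pmin(ncol(m), floor((seq_len(w) - 0.5) / s) + 1L)
  m[ri, ci, drop = FALSE]
}

#' Render a text line as an ink bitmap
#'
#' Glyphs are composed left to right with a one-unit inter-character gap and
#' the whole line is scaled by `scale` (nearest neighbour).
#'
#' @param text Characters drawn from [default_charset()].
#' @param font `"plain"` or `"bold"` (or a font object from
#'   [octreport_fonts()]).
#' @param scale Scale factor; 1 unit = 1 pixel at scale 1.
#' @return 0/1 matrix, 1 = ink.
#' @export
render_text_bitmap <- function(text, font = "plain", scale = 2) {
  if (is.character(font)) font <- octreport_fonts()[[font]]
  if (is.null(font)) stop_octreport("schema", "unknown font")
  chars <- strsplit(text, "")[[1L]]
  bad <- setdiff(chars, names(font$glyphs))
  if (length(bad)) {
    stop_octreport("charset",
                   sprintf("character(s) outside charset: %s",
                           paste(unique(bad), collapse = " ")))
  }
  gap <- matrix(0, font$height, 1L)
  pieces <- vector("list", 2L * length(chars) - 1L)
  for (i in seq_along(chars)) {
    pieces[[2L * i - 1L]] <- font$glyphs[[chars[i]]]
    if (i < length(chars)) pieces[[2L * i]] <- gap
  }
  line <- do.call(cbind, pieces)
  if (scale != 1) line <- scale_bitmap(line, scale)
  line
}
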