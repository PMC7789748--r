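#' @useDynLib octreport, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Internal image convention: a grayscale page or crop is a plain numeric
# matrix indexed [row = y, col = x] with intensities in [0, 1], background
# bright (1 = white paper) and ink dark.  Boxes are integer vectors
# c(x0, y0, x1, y1), 0-based and half-open, x rightward, y downward, so a
# box's width is x1 - x0 exactly.

#' Read a report image into a grayscale matrix
#'
#' Reads PNG directly and JPEG/BMP/TIFF through EBImage, converting colour
#' planes to luminance.  The result is a `[y, x]` matrix in `[0, 1]`.
#'
#' @param path Path to a raster image file.
#' @return Numeric matrix with intensities in `[0, 1]`.
#' @export
read_report_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_octreport("unreadable_file",
                   sprintf("cannot read report image '%s': file not found", path))
  }
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext == "png") {
      png::readPNG(path)
    } else {
      a <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores [x, y(, channel)]
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    }
  }, error = function(e) {
    stop_octreport("unreadable_file",
                   sprintf("cannot read report image '%s': %s", path,
                           conditionMessage(e)))
  })
  as_gray_matrix(img)
}

# Collapse an array read from disk to a [y, x] luminance matrix.
as_gray_matrix <- function(img) {
  if (is.matrix(img)) {
    m <- img
  } else if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc >= 3L) {
      m <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    } else {
      m <- img[, , 1L]
    }
  } else {
    stop_octreport("unreadable_file", "unsupported image array shape")
  }
  m[m < 0] <- 0
  m[m > 1] <- 1
  unname(m)
}

#' Write a grayscale matrix as a lossless PNG
#' @param image `[y, x]` numeric matrix in `[0, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}

#' Crop a rectangular region from a page
#'
#' Boxes are 0-based half-open `c(x0, y0, x1, y1)`, so the crop has exactly
#' `x1 - x0` columns and `y1 - y0` rows.  Pixels are copied; the source is
#' never modified.
#'
#' @param image `[y, x]` numeric matrix.
#' @param box Integer vector `c(x0, y0, x1, y1)`.
#' @return The cropped sub-matrix.
#' @export
crop_region <- function(image, box) {
  check_box(box)
  h <- nrow(image); w <- ncol(image)
  if (box[1L] < 0L || box[2L] < 0L || box[3L] > w || box[4L] > h) {
    stop_octreport("out_of_bounds",
                   sprintf("box (%d,%d,%d,%d) exceeds page size %dx%d",
                           box[1L], box[2L], box[3L], box[4L], w, h))
  }
  image[(box[2L] + 1L):box[4L], (box[1L] + 1L):box[3L], drop = FALSE]
}

# Paste a sub-image back at (x0, y0); used by the renderer and round-trip
# tests.  Returns a modified copy.
paste_region <- function(image, sub, x0, y0) {
  image[(y0 + 1L):(y0 + nrow(sub)), (x0 + 1L):(x0 + ncol(sub))] <- sub
  image
}

check_box <- function(box, what = "box") {
  if (!is.numeric(box) || length(box) != 4L || any(is.na(box))) {
    stop_octreport("schema", sprintf("%s must be four numbers (x0,y0,x1,y1)", what))
  }
  if (box[1L] >= box[3L] || box[2L] >= box[4L]) {
    stop_octreport("schema",
                   sprintf("%s (%s) is degenerate: requires x0 < x1 and y0 < y1",
                           what, paste(box, collapse = ",")))
  }
  invisible(TRUE)
}

# Bilinear resample to (h, w) via row/column interpolation matrices.
# Deterministic and fast enough for tens of thousands of small crops.
resize_gray <- function(img, h, w) {
  interp_mat <- function(n_out, n_in) {
    if (n_in == 1L) return(matrix(1, n_out, 1L))
    # map output pixel centers into input pixel-center coordinates
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pos <- pmin(pmax(pos, 0), n_in - 1)
    lo <- floor(pos)
    frac <- pos - lo
    hi <- pmin(lo + 1, n_in - 1)
    m <- matrix(0, n_out, n_in)
    idx <- seq_len(n_out)
    m[cbind(idx, lo + 1)] <- m[cbind(idx, lo + 1)] + (1 - frac)
    m[cbind(idx, hi + 1)] <- m[cbind(idx, hi + 1)] + frac
    m
  }
  A <- interp_mat(h, nrow(img))
  B <- interp_mat(w, ncol(img))
  A %*% img %*% t(B)
}

# Otsu threshold on a [0,1] matrix (through EBImage).
otsu_threshold <- function(img) {
  EBImage::otsu(EBImage::Image(t(img)), range = c(0, 1), levels = 256)
}

# Classed condition helpers ---------------------------------------------

stop_octreport <- function(type, msg, ...) {
  cond <- structure(
    class = c(paste0("octreport_error_", type), "octreport_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1L), ...)
  )
  stop(cond)
}

warn_octreport <- function(type, msg, ...) {
  cond <- structure(
    class = c(paste0("octreport_warning_", type), "octreport_warning",
              "warning", "condition"),
    list(message = msg, call = sys.call(-1L), ...)
  )
  warning(cond)
}
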