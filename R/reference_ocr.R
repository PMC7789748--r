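# Deterministic template-matching reference recognizer.  It shares glyph
# bitmaps with the synthetic renderer, so it is exact on clean fixtures and
# serves as the trainingless oracle for the pipeline plumbing.

# Per-font template metadata: tight glyph bounding boxes and their
# placement inside the 7-row cell.
.tmpl_cache <- new.env(parent = emptyenv())

.font_templates <- function(font_name) {
  key <- paste0("tmpl_", font_name)
  if (!is.null(.tmpl_cache[[key]])) return(.tmpl_cache[[key]])
  font <- octreport_fonts()[[font_name]]
  tmpl <- lapply(names(font$glyphs), function(ch) {
    m <- font$glyphs[[ch]]
    rs <- which(rowSums(m) > 0); cs <- which(colSums(m) > 0)
    if (!length(rs)) return(NULL)               # space has no ink
    bm <- m[rs[1L]:rs[length(rs)], cs[1L]:cs[length(cs)], drop = FALSE]
    list(char = ch, bitmap = bm,
         top = rs[1L] - 1L, h = nrow(bm), w = ncol(bm))
  })
  names(tmpl) <- names(font$glyphs)
  tmpl <- Filter(Negate(is.null), tmpl)
  .tmpl_cache[[key]] <- tmpl
  tmpl
}

# Match one segment bitmap against every template of a font; returns the
# best char and its composite score.  A near-perfect shape match (sim >=
# 0.97) outranks any merely-plausible candidate: position and height cues
# are unreliable for lines made only of low glyphs (a lone "."), while an
# exact shape is unambiguous.
.match_segment <- function(seg, seg_top_units, line_units, tmpl,
                           use_position = TRUE) {
  best_char <- NULL; best_score <- -Inf; best_sim <- 0
  exact_char <- NULL; exact_score <- -Inf; exact_sim <- 0
  seg_h <- nrow(seg); seg_w <- ncol(seg)
  # crisp nearest-neighbour upscale; the renderer's own duplication
  # pattern depends on sub-pixel position, so score the best of several
  # plausible index mappings
  nn_up_sims <- function(tm_bitmap, seg) {
    h <- nrow(seg); w <- ncol(seg)
    maps <- list(
      list(r = ceiling(seq_len(h) * nrow(tm_bitmap) / h),
           c = ceiling(seq_len(w) * ncol(tm_bitmap) / w)),
      list(r = floor((seq_len(h) - 1L) * nrow(tm_bitmap) / h) + 1L,
           c = floor((seq_len(w) - 1L) * ncol(tm_bitmap) / w) + 1L),
      list(r = pmin(nrow(tm_bitmap), floor((seq_len(h) - 0.5) * nrow(tm_bitmap) / h) + 1L),
           c = pmin(ncol(tm_bitmap), floor((seq_len(w) - 0.5) * ncol(tm_bitmap) / w) + 1L))
    )
    vapply(maps, function(mp) {
      up <- tm_bitmap[pmax(1L, mp$r), pmax(1L, mp$c), drop = FALSE]
      1 - mean(abs(seg - up))
    }, numeric(1L))
  }
  for (tm in tmpl) {
    # scale-symmetric comparison: bilinear downsample of the segment to
    # the template, and crisp nearest-neighbour upsample of the template
    # to the segment (bilinear blur can erase single-pixel strokes)
    down <- 1 - mean(abs(resize_gray(seg, tm$h, tm$w) - tm$bitmap))
    ups <- nn_up_sims(tm$bitmap, seg)
    up <- max(ups)
    sim <- max(down, up)
    sim_both <- min(down, up)
    pos_pen <- abs(seg_top_units - tm$top) / 7
    asp_pen <- abs(log((seg_w / seg_h) / (tm$w / tm$h)))
    hgt_pen <- abs(seg_h / line_units * 7 - tm$h) / 7
    score <- sim - 0.25 * min(asp_pen, 2) -
      (if (use_position) 0.3 * pos_pen + 0.25 * hgt_pen else 0)
    if (score > best_score) {
      best_score <- score; best_char <- tm$char; best_sim <- sim
    }
    if (sim_both >= 0.97) {
      sc2 <- sim - 0.25 * min(asp_pen, 2)
      if (sc2 > exact_score) {
        exact_score <- sc2; exact_char <- tm$char; exact_sim <- sim
      }
    }
  }
  if (!is.null(exact_char)) {
    return(list(char = exact_char, score = exact_score, sim = exact_sim))
  }
  list(char = best_char, score = best_score, sim = best_sim)
}

#' Deterministic reference recognizer
#'
#' Left-to-right normalized template matching against the bundled glyph
#' bitmaps.  Exact on clean renderings at any scale; raises a
#' recognition-failure error when a glyph cannot be matched within
#' tolerance (e.g., under heavy noise).  No training involved.
#'
#' @param crop `[y, x]` matrix in `[0, 1]`, dark text on bright background.
#' @param charset Characters eligible for output.
#' @param tol Minimum acceptable per-glyph shape similarity in `[0, 1]`.
#' @return A `recognition` list (`text`, `confidence`).
#' @export
reference_recognize <- function(crop, charset = default_charset(), tol = 0.8) {
  if (is.null(dim(crop)) || any(dim(crop) == 0L)) {
    stop_octreport("empty_crop", "crop has zero size")
  }
  rng <- diff(range(crop))
  if (rng < 0.2) {
    return(structure(list(text = "", confidence = 0), class = "recognition"))
  }
  thr <- otsu_threshold(crop)
  ink <- crop < thr
  if (!any(ink)) {
    return(structure(list(text = "", confidence = 0), class = "recognition"))
  }
  rows_ink <- which(rowSums(ink) > 0)
  line_top <- rows_ink[1L]; line_bot <- rows_ink[length(rows_ink)]
  ink <- ink[line_top:line_bot, , drop = FALSE]
  col_ink <- colSums(ink) > 0
  # segments: maximal runs of inked columns
  r <- rle(col_ink)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(segs) == 0L) {
    return(structure(list(text = "", confidence = 0), class = "recognition"))
  }
  line_h <- nrow(ink)
  # glyph-scale estimate: line height over the 7-row cell, but a line of
  # low glyphs only (e.g. "--") underestimates it, so widths bound it below
  seg_w_max <- max(segs$end - segs$start + 1L)
  scale_hat <- max(line_h / 7, seg_w_max / 6)
  # with no full-height glyph on the line (a lone "." or "--") the scale
  # estimate is unreliable and vertical position/height penalties mislead;
  # full-height glyphs are taller (7 units) than any glyph is wide (<= 6)
  scale_reliable <- line_h >= 1.05 * seg_w_max
  allowed <- charset_chars(charset)
  out <- character(0); sims <- numeric(0)
  prev_end <- NULL
  for (i in seq_len(nrow(segs))) {
    if (!is.null(prev_end)) {
      gap <- segs$start[i] - prev_end - 1L
      # tight-bbox gaps reach ~5 glyph units between narrow characters;
      # a true space adds a full 5-unit cell plus spacing (>= 7 units).
      # Without a reliable scale estimate gaps cannot be judged.
      if (scale_reliable && gap > 6 * scale_hat && " " %in% allowed) {
        out <- c(out, " ")
      }
    }
    sub <- ink[, segs$start[i]:segs$end[i], drop = FALSE]
    rs <- which(rowSums(sub) > 0)
    seg_top_units <- (rs[1L] - 1L) / scale_hat
    seg <- sub[rs[1L]:rs[length(rs)], , drop = FALSE] * 1
    best <- list(score = -Inf)
    for (fn in names(octreport_fonts())) {
      tmpl <- .font_templates(fn)
      tmpl <- tmpl[names(tmpl) %in% allowed]
      m <- .match_segment(seg, seg_top_units, line_h, tmpl)
      if (m$score > best$score) best <- m
    }
    if (best$sim < tol) {
      stop_octreport("recognition_failure",
                     sprintf("unmatched glyph (best '%s', similarity %.2f < %.2f)",
                             best$char, best$sim, tol))
    }
    out <- c(out, best$char)
    sims <- c(sims, best$sim)
    prev_end <- segs$end[i]
  }
  structure(list(text = paste(out, collapse = ""),
                 confidence = mean(sims)),
            class = "recognition")
}

# ---------------------------------------------------------------------------
# Parsing recognized text into typed measurements

#' Construct a measurement
#' @param name Field name.
#' @param value Numeric value (NA for the missing marker).
#' @param unit Unit string copied from the field spec.
#' @param raw_text Recognized text the value was parsed from.
#' @return A `measurement` list.
#' @export
measurement <- function(name, value, unit = "", raw_text = "") {
  structure(list(name = name, value = value, unit = unit,
                 raw_text = raw_text),
            class = "measurement")
}

#' Parse a recognition into a typed measurement
#'
#' The dash placeholder (`"--"` or `"-"`) maps to a missing value, never to
#' zero.  Any other text must match the field's pattern; a mismatch raises
#' a parse error carrying the raw text.
#'
#' @param recognition A `recognition` (or plain string).
#' @param field A [field_spec()] with `kind == "numeric"`.
#' @return A `measurement`.
#' @export
parse_value <- function(recognition, field) {
  if (field$kind != "numeric") {
    stop_octreport("schema",
                   sprintf("parse_value requires a numeric field; '%s' is %s",
                           field$name, field$kind))
  }
  raw <- if (is.character(recognition)) recognition else recognition$text
  txt <- gsub("^ +| +$", "", raw)
  if (txt %in% c("--", "-")) {
    return(measurement(field$name, NA_real_, field$unit, raw))
  }
  pattern <- if (is.null(field$pattern)) "^-?[0-9]+(\\.[0-9]+)?$" else field$pattern
  if (!grepl(pattern, txt)) {
    stop_octreport("parse_error",
                   sprintf("field '%s': text '%s' does not match pattern %s",
                           field$name, raw, pattern),
                   raw_text = raw, field = field$name)
  }
  val <- suppressWarnings(as.numeric(txt))
  if (is.na(val)) {
    stop_octreport("parse_error",
                   sprintf("field '%s': text '%s' is not numeric", field$name, raw),
                   raw_text = raw, field = field$name)
  }
  measurement(field$name, val, field$unit, raw)
}
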