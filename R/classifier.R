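# Header-based report-type classification.
#
# The mechanism is deterministic and trainingless: the binarized header
# crop is compared by normalized cross-correlation against a rendered
# template of each layout's canonical title; if no template clears the
# accept threshold, a recognizer-based text match over the header line is
# tried as a fallback.  Ties break to the lexicographically lowest type_id.

.header_cache <- new.env(parent = emptyenv())

# Ink-mask template of a layout's header, built by painting the title with
# the same placement routine the renderer uses.
.header_template <- function(layout) {
  key <- paste0(layout$type_id, "|", layout$header_title, "|",
                paste(layout$header_box, collapse = ","))
  if (!is.null(.header_cache[[key]])) return(.header_cache[[key]])
  bh <- layout$header_box[4L] - layout$header_box[2L]
  bw <- layout$header_box[3L] - layout$header_box[1L]
  canvas <- matrix(1, bh, bw)
  canvas <- paint_text_box(canvas, layout$header_title,
                           c(0L, 0L, bw, bh), font = "plain", scale = 2,
                           contrast = 1)
  tmpl <- (canvas < 0.5) * 1
  .header_cache[[key]] <- tmpl
  tmpl
}

.binarize_header <- function(crop) {
  if (diff(range(crop)) < 0.15) return(matrix(0, nrow(crop), ncol(crop)))
  thr <- otsu_threshold(crop)
  (crop < thr) * 1
}

#' Classify a report image by its header
#'
#' @param image `[y, x]` page matrix in `[0, 1]`.
#' @param catalog A `layout_catalog`.
#' @param threshold Accept threshold on the correlation score (default
#'   0.7; exposed in config as `classifier.accept_threshold`).
#' @param use_text_fallback Try a reference-recognizer text match on the
#'   header when no template clears the threshold.
#' @return A `classification` list: `type_id`, `score`, `header_text`.
#' @export
classify_report <- function(image, catalog, threshold = 0.7,
                            use_text_fallback = TRUE) {
  ids <- sort(names(catalog$layouts))          # deterministic tie-break order
  scores <- stats::setNames(rep(-1, length(ids)), ids)
  any_fits <- FALSE
  for (id in ids) {
    layout <- catalog$layouts[[id]]
    hb <- layout$header_box
    if (nrow(image) < hb[4L] || ncol(image) < hb[3L]) next
    any_fits <- TRUE
    crop <- crop_region(image, hb)
    bin <- .binarize_header(crop)
    tmpl <- .header_template(layout)
    if (stats::sd(bin) == 0 || stats::sd(tmpl) == 0) next
    sc <- suppressWarnings(stats::cor(as.numeric(bin), as.numeric(tmpl)))
    scores[id] <- if (is.na(sc)) 0 else sc
  }
  if (!any_fits) {
    stop_octreport("image_too_small",
                   "image is smaller than every layout's header region")
  }
  best_id <- ids[which.max(scores)]            # ties: first = lowest type_id
  if (scores[best_id] >= threshold) {
    return(structure(list(type_id = best_id,
                          score = unname(scores[best_id]),
                          header_text = catalog$layouts[[best_id]]$header_title),
                     class = "classification"))
  }
  if (use_text_fallback) {
    for (id in ids) {
      layout <- catalog$layouts[[id]]
      hb <- layout$header_box
      if (nrow(image) < hb[4L] || ncol(image) < hb[3L]) next
      rec <- tryCatch(
        reference_recognize(crop_region(image, hb), catalog$charset),
        octreport_error = function(e) NULL)
      if (is.null(rec)) next
      norm <- function(s) gsub(" +", " ", trimws(s))
      if (nzchar(rec$text) && norm(rec$text) == norm(layout$header_title)) {
        return(structure(list(type_id = id, score = rec$confidence,
                              header_text = rec$text),
                         class = "classification"))
      }
    }
  }
  stop_octreport("unknown_report_type",
                 sprintf("no header title matched above threshold %.2f (best %.2f)",
                         threshold, max(scores)))
}
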