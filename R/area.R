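# Area Explorer: route each configured region to its consumer.

#' Route a configured region to the correct consumer
#'
#' The crop is taken with [crop_region()] and classified by content:
#' `empty` when the ink fraction after binarization falls below `ink_eps`;
#' `tomogram` for dense dark-background grayscale content; otherwise
#' `numeric_text`.  When the detected class contradicts the field's
#' declared kind a routing warning is emitted and the detected class is
#' honored, so a shifted or corrupted report fails loudly instead of
#' feeding a tomogram to the character recognizer.
#'
#' @param page `[y, x]` page matrix.
#' @param field A [field_spec()].
#' @param ink_eps Minimum ink fraction for a non-empty region (default
#'   0.5\% of crop pixels).
#' @return A `routed_region` list: `field`, `content_class`, `crop`.
#' @export
route_region <- function(page, field, ink_eps = 0.005) {
  crop <- crop_region(page, field$box)
  cls <- .detect_content_class(crop, ink_eps)
  expected <- if (field$kind == "tomogram") "tomogram" else "numeric_text"
  if (cls != "empty" && cls != expected) {
    warn_octreport("routing",
                   sprintf("field '%s': declared %s but content looks like %s; honoring detected class",
                           field$name, field$kind, cls))
  }
  structure(list(field = field, content_class = cls, crop = crop),
            class = "routed_region")
}

.detect_content_class <- function(crop, ink_eps = 0.005) {
  rng <- diff(range(crop))
  if (rng < 0.12) return("empty")
  mean_int <- mean(crop)
  mid_frac <- mean(crop > 0.15 & crop < 0.85)
  if (mean_int < 0.55 || mid_frac > 0.35) return("tomogram")
  thr <- otsu_threshold(crop)
  ink_frac <- mean(crop < thr)
  if (ink_frac < ink_eps) return("empty")
  "numeric_text"
}
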