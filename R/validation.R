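# Validation: per-report-type accuracy tallies for the Value Reader.
#
# Only the three numeric report categories are validated; the scan-only
# layouts carry no characters to read.  A report counts as a success iff
# every non-missing ground-truth field matches the predicted raw text
# exactly (string equality); the overall column pools counts, it is never
# a mean of rates.

.validated_categories <- c(rnfl_unilateral = "rnfl", rnfl_bilateral = "rnfl",
                           macula_current = "macula_current",
                           macula_prev_current = "macula_prev_current")

#' Sample a validation set of synthetic fixtures
#'
#' Draws `n_per_type` fixtures per validated category (RNFL pools the
#' unilateral and bilateral layouts, which share one reading algorithm),
#' reproducibly by seed.
#'
#' @param fixtures List of `synthetic_report` fixtures.
#' @param n_per_type Reports per validated category (default 100, three
#'   categories, i.e. 300 reports).
#' @param seed Integer seed.
#' @return Subset of `fixtures`.
#' @export
sample_validation_set <- function(fixtures, n_per_type = 100L, seed = 1L) {
  cats <- vapply(fixtures, function(f) {
    .validated_categories[f$type_id] %||% NA_character_
  }, "")
  out <- integer(0)
  with_seed_(seed, {
    for (cat in unique(stats::na.omit(.validated_categories))) {
      idx <- which(cats == cat)
      if (length(idx) < n_per_type) {
        stop_octreport("insufficient_fixtures",
                       sprintf("category '%s' has %d fixtures; %d requested",
                               cat, length(idx), n_per_type))
      }
      out <- c(out, sample(idx, n_per_type))
    }
  })
  fixtures[out]
}

#' Score extraction output against ground truth
#'
#' @param predictions List of `extracted_record` (or lists of records as
#'   returned by [process_image()]); matched to truths by position.
#' @param truths List of sidecar-style truth lists (each with `type_id` and
#'   `truth`, as in a `synthetic_report`).
#' @return An `accuracy_report`: data frame with rows n_reports,
#'   n_success, success_rate, failure_rate and columns total plus one per
#'   validated category; per-field tallies in `attr(, "field_detail")`.
#' @export
score_extraction <- function(predictions, truths) {
  if (length(predictions) != length(truths)) {
    stop_octreport("unmatched_pair",
                   sprintf("%d predictions vs %d truths",
                           length(predictions), length(truths)))
  }
  cats <- character(length(truths))
  success <- logical(length(truths))
  field_rows <- list()
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    cat_i <- .validated_categories[tr$type_id]
    if (is.na(cat_i)) {
      stop_octreport("schema",
                     sprintf("report %d: type '%s' is not a validated category",
                             i, tr$type_id))
    }
    cats[i] <- cat_i
    pred <- predictions[[i]]
    raw <- if (inherits(pred, "extracted_record")) pred$raw else pred[[1L]]$raw
    ok <- TRUE
    for (nm in names(tr$truth)) {
      tv <- tr$truth[[nm]]
      if (is.na(tv)) next
      pv <- raw[[nm]] %||% ""
      match_i <- identical(as.character(pv), as.character(tv))
      field_rows[[length(field_rows) + 1L]] <- data.frame(
        category = cat_i, field = nm, match = match_i,
        stringsAsFactors = FALSE)
      if (!match_i) ok <- FALSE
    }
    success[i] <- ok
  }
  cat_levels <- unique(stats::na.omit(.validated_categories))
  tally <- function(mask) {
    n <- sum(mask); s <- sum(success[mask])
    c(n_reports = n, n_success = s,
      success_rate = if (n) round(100 * s / n, 2) else NA_real_,
      failure_rate = if (n) round(100 * (n - s) / n, 2) else NA_real_)
  }
  cols <- list(total = tally(rep(TRUE, length(success))))
  for (cl in cat_levels) cols[[cl]] <- tally(cats == cl)
  report <- as.data.frame(cols)
  fd <- if (length(field_rows)) do.call(rbind, field_rows) else data.frame()
  if (nrow(fd)) {
    fd <- stats::aggregate(match ~ category + field, data = fd,
                           FUN = function(x) mean(x) * 100)
    names(fd)[names(fd) == "match"] <- "field_success_rate"
  }
  structure(report, class = c("accuracy_report", "data.frame"),
            field_detail = fd)
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Value Reader accuracy\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write an accuracy report as CSV
#' @param report An `accuracy_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accuracy_csv <- function(report, path) {
  df <- cbind(statistic = rownames(report), as.data.frame(report))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
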