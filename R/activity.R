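# Longitudinal disease-activity labels.
#
# The rule: the first visit of a (patient, laterality) series is always
# not_applicable; at later visits the relative change in central macular
# thickness (CMT) against the immediately preceding visit decides —
# improvement when the change is at or below -threshold, worsening when it
# is at or above +threshold or any finding newly appears, otherwise
# stationary.  Resolution of a finding alone never counts as improvement.
# The default threshold 0.25 is the midpoint of the interval of thresholds
# consistent with all printed example labels in the source material
# (relative CMT changes of -31% labeled improvement; -13%, +8%, +1% and
# -21% labeled stationary constrain the threshold to (0.206, 0.310]).

.activity_levels <- c("not_applicable", "improvement", "worsening", "stationary")

#' Derive disease-activity labels for one patient/laterality series
#'
#' @param series Data frame with one row per visit, sorted by `visit_date`,
#'   containing `visit_date`, `central_macular_thickness` (µm; may be NA),
#'   and zero or more logical finding columns (e.g. `subretinal_fluid`,
#'   `macular_edema`).
#' @param threshold Relative CMT change threshold (default 0.25).
#' @param finding_cols Names of the logical finding columns; defaults to
#'   the intersection of the known vocabulary with `names(series)`.
#' @return Character vector of labels (one per visit, `NA` where a
#'   non-first visit lacks CMT).
#' @export
derive_activity <- function(series, threshold = 0.25, finding_cols = NULL) {
  if (is.null(finding_cols)) {
    finding_cols <- intersect(.known_findings, names(series))
  }
  dates <- as.Date(series$visit_date)
  if (anyNA(dates)) {
    stop_octreport("schema", "series visit_date must be parseable dates")
  }
  if (is.unsorted(dates, strictly = FALSE)) {
    stop_octreport("unsorted_series",
                   "series must be sorted by visit date before labeling")
  }
  n <- nrow(series)
  cmt <- suppressWarnings(as.numeric(series$central_macular_thickness))
  out <- rep(NA_character_, n)
  if (n >= 1L) out[1L] <- "not_applicable"
  if (n < 2L) return(out)
  for (k in 2L:n) {
    if (is.na(cmt[k]) || is.na(cmt[k - 1L])) {
      warn_octreport("missing_cmt",
                     sprintf("visit %s lacks central macular thickness; activity label skipped",
                             format(dates[k])))
      next
    }
    rel <- (cmt[k] - cmt[k - 1L]) / cmt[k - 1L]
    new_finding <- FALSE
    for (fc in finding_cols) {
      prev <- isTRUE(series[[fc]][k - 1L]); cur <- isTRUE(series[[fc]][k])
      if (!prev && cur) new_finding <- TRUE
    }
    out[k] <- if (rel <= -threshold) {
      "improvement"
    } else if (rel >= threshold || new_finding) {
      "worsening"
    } else {
      "stationary"
    }
  }
  out
}
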