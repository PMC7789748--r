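# Pipeline orchestration: classify -> route -> read -> classify findings,
# longitudinal assembly, and CSV / CDM-shaped / crop outputs.

.strip_eye_prefix <- function(name) sub("^(right|left)_", "", name)
.eye_of_field <- function(name) {
  if (grepl("^right_", name)) "right" else if (grepl("^left_", name)) "left" else NA_character_
}

new_extracted_record <- function(patient_id, visit_date, type_id, laterality,
                                 measurements, findings, source_path,
                                 warnings, raw, crops) {
  structure(list(patient_id = patient_id, visit_date = visit_date,
                 type_id = type_id, laterality = laterality,
                 measurements = measurements, findings = findings,
                 activity = NA_character_, source_path = source_path,
                 warnings = warnings, raw = raw, crops = crops),
            class = "extracted_record")
}

#' @export
print.extracted_record <- function(x, ...) {
  cat(sprintf("<extracted_record> %s %s %s (%s): %d measurements%s\n",
              x$patient_id, x$visit_date, x$laterality, x$type_id,
              length(x$measurements),
              if (length(x$warnings)) sprintf(", %d warnings", length(x$warnings)) else ""))
  invisible(x)
}

# Normalize an on-page date string to ISO-8601.
.normalize_date <- function(txt, format = "%Y-%m-%d") {
  d <- as.Date(txt, format = format)
  if (is.na(d)) NA_character_ else format(d, "%Y-%m-%d")
}

#' Process one report image end to end
#'
#' Runs the header classifier, routes every configured region, reads
#' numeric/text regions with the recognizer (the deterministic reference
#' recognizer when `ocr` is `NULL`), and classifies tomographic regions
#' when a finding model is supplied.  Bilateral layouts yield one record
#' per eye.  Failures in individual fields are recorded as warnings on the
#' record — never silent zeros.
#'
#' @param input Path to a raster image, or a page matrix.
#' @param catalog A `layout_catalog`.
#' @param ocr A trained `ocr_model`, or `NULL` for the reference
#'   recognizer.
#' @param finding_model Optional `finding_model` for tomogram regions.
#' @param sidecar Optional sidecar metadata list (fallback for patient id /
#'   visit date / laterality when the layout carries no such fields).
#' @return List of `extracted_record` (length 2 for bilateral layouts).
#' @export
process_image <- function(input, catalog, ocr = NULL, finding_model = NULL,
                          sidecar = NULL) {
  if (is.character(input)) {
    source_path <- input
    page <- read_report_image(input)
    sc_path <- paste0(tools::file_path_sans_ext(input), ".json")
    if (is.null(sidecar) && file.exists(sc_path)) sidecar <- read_sidecar(sc_path)
  } else {
    source_path <- NA_character_
    page <- input
  }
  cls <- classify_report(page, catalog)
  layout <- catalog$layouts[[cls$type_id]]
  warns <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, octreport_warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  raws <- list(); meas <- list(); crops <- list()
  finding_probs <- NULL
  for (field in layout$fields) {
    rr <- collect(route_region(page, field))
    if (field$kind == "tomogram" || rr$content_class == "tomogram") {
      crops[[field$name]] <- rr$crop
      if (!is.null(finding_model) && rr$content_class == "tomogram") {
        fr <- collect(tryCatch(classify_finding(rr, finding_model),
                               octreport_error = function(e) {
          warns <<- c(warns, conditionMessage(e)); NULL
        }))
        if (!is.null(fr)) {
          finding_probs <- if (is.null(finding_probs)) fr$probabilities else
            pmax(finding_probs, fr$probabilities)
        }
      }
      next
    }
    if (rr$content_class == "empty") {
      raws[[field$name]] <- ""
      if (field$kind == "numeric") {
        meas[[field$name]] <- measurement(field$name, NA_real_, field$unit, "")
      }
      warns <- c(warns, sprintf("field '%s': region is empty", field$name))
      next
    }
    rec <- tryCatch({
      if (is.null(ocr)) {
        reference_recognize(rr$crop, field$charset %||% catalog$charset)
      } else {
        recognize(ocr, rr$crop, charset = field$charset)
      }
    }, octreport_error = function(e) {
      warns <<- c(warns, sprintf("field '%s': %s", field$name,
                                 conditionMessage(e)))
      NULL
    })
    if (is.null(rec)) { raws[[field$name]] <- NA_character_; next }
    raws[[field$name]] <- rec$text
    if (field$kind == "numeric") {
      m <- tryCatch(parse_value(rec, field), octreport_error = function(e) {
        warns <<- c(warns, conditionMessage(e))
        measurement(field$name, NA_real_, field$unit, rec$text)
      })
      meas[[field$name]] <- m
    }
  }
  findings <- if (!is.null(finding_probs)) {
    structure(list(labels = finding_probs >= 0.5,
                   probabilities = finding_probs),
              class = "finding_result")
  } else NULL
  # metadata: on-page fields first, sidecar fallback
  pid <- raws[["patient_id"]] %||% sidecar$patient_id %||% NA_character_
  vdate_raw <- raws[["visit_date"]] %||% sidecar$visit_date %||% NA_character_
  vdate <- if (!is.na(vdate_raw) && nzchar(vdate_raw)) {
    .normalize_date(vdate_raw) %||% vdate_raw
  } else NA_character_
  if (is.na(vdate) && !is.null(sidecar$visit_date)) vdate <- sidecar$visit_date
  bilateral <- layout$type_id == "rnfl_bilateral"
  if (!bilateral) {
    lat <- if (!is.null(raws[["laterality"]])) {
      tolower(raws[["laterality"]])
    } else sidecar$laterality %||% NA_character_
    if (!lat %in% c("right", "left")) {
      warns <- c(warns, sprintf("unrecognized laterality '%s'", lat))
      lat <- sidecar$laterality %||% NA_character_
    }
    rec <- new_extracted_record(pid, vdate, layout$type_id, lat,
                                meas, findings, source_path, warns, raws, crops)
    return(list(rec))
  }
  # bilateral: split prefixed measurements into one record per eye
  out <- lapply(c("right", "left"), function(eye) {
    eye_meas <- list()
    for (nm in names(meas)) {
      if (identical(.eye_of_field(nm), eye)) {
        m <- meas[[nm]]
        m$name <- .strip_eye_prefix(nm)
        eye_meas[[m$name]] <- m
      }
    }
    new_extracted_record(pid, vdate, layout$type_id, eye, eye_meas, findings,
                         source_path, warns, raws, crops)
  })
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# ---------------------------------------------------------------------------
# Longitudinal assembly

#' Assign disease-activity labels across a set of records
#'
#' Groups records by (patient, laterality), orders each group by visit
#' date, and applies [derive_activity()].
#'
#' @param records List of `extracted_record`.
#' @param threshold Relative CMT change threshold (see [derive_activity()]).
#' @return The records, time-ordered within groups, with `activity` set.
#' @export
assemble_records <- function(records, threshold = 0.25) {
  keys <- vapply(records, function(r) {
    paste(r$patient_id, r$laterality, sep = "\r")
  }, "")
  out <- list()
  for (key in unique(keys)) {
    grp <- records[keys == key]
    ord <- order(vapply(grp, function(r) r$visit_date, ""))
    grp <- grp[ord]
    cmt <- vapply(grp, function(r) {
      m <- r$measurements[["central_macular_thickness"]]
      if (is.null(m)) NA_real_ else m$value
    }, numeric(1L))
    series <- data.frame(
      visit_date = vapply(grp, function(r) r$visit_date, ""),
      central_macular_thickness = cmt)
    for (fc in .known_findings) {
      series[[fc]] <- vapply(grp, function(r) {
        if (is.null(r$findings)) FALSE else isTRUE(r$findings$labels[[fc]])
      }, logical(1L))
    }
    labels <- suppressWarnings(derive_activity(series, threshold = threshold))
    for (i in seq_along(grp)) grp[[i]]$activity <- labels[i]
    out <- c(out, grp)
  }
  out
}

# ---------------------------------------------------------------------------
# CSV output

.measurement_columns <- function(catalog) {
  cols <- character(0)
  for (id in intersect(.canonical_type_ids, names(catalog$layouts))) {
    for (f in catalog$layouts[[id]]$fields) {
      if (f$kind == "numeric") cols <- c(cols, .strip_eye_prefix(f$name))
    }
  }
  unique(cols)
}

.format_findings <- function(findings) {
  if (is.null(findings)) return("")
  pretty <- c(subretinal_fluid = "Subretinal fluid",
              macular_edema = "Macular edema")
  parts <- vapply(names(findings$labels), function(nm) {
    sprintf("%s (%s)", pretty[[nm]] %||% nm,
            if (isTRUE(findings$labels[[nm]])) "+" else "-")
  }, "")
  paste(parts, collapse = "; ")
}

#' Convert records to the output table
#' @param records List of `extracted_record`.
#' @param catalog Catalog that defines the measurement column order.
#' @return Data frame, one row per record, sorted by
#'   (patient, laterality, visit date).
#' @export
records_to_table <- function(records, catalog = default_catalog()) {
  cols <- .measurement_columns(catalog)
  rows <- lapply(records, function(r) {
    row <- data.frame(patient_id = r$patient_id %||% "",
                      visit_date = r$visit_date %||% "",
                      report_type = r$type_id,
                      laterality = r$laterality %||% "",
                      stringsAsFactors = FALSE)
    for (cn in cols) {
      m <- r$measurements[[cn]]
      row[[cn]] <- if (is.null(m) || is.na(m$value)) "" else format(m$value)
    }
    row$finding <- .format_findings(r$findings)
    row$activity <- if (is.na(r$activity)) "" else r$activity
    row$warnings <- paste(r$warnings, collapse = " | ")
    row
  })
  df <- do.call(rbind, rows)
  df[order(df$patient_id, df$laterality, df$visit_date), , drop = FALSE]
}

#' Write records to a CSV file
#'
#' Stable column order (patient, visit date, report type, laterality, the
#' catalog's measurement columns, finding, activity, warnings); rows sorted
#' by (patient, laterality, visit date); missing cells empty.
#'
#' @param records List of `extracted_record` (non-empty).
#' @param path Output CSV path.
#' @param catalog Catalog defining the measurement columns.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path, catalog = default_catalog()) {
  if (!length(records)) {
    stop_octreport("schema", "no records to write")
  }
  utils::write.csv(records_to_table(records, catalog), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a records CSV back into records
#' @param path CSV written by [write_records_csv()].
#' @param catalog Catalog used when writing.
#' @return List of `extracted_record` (CSV-visible fields only).
#' @export
read_records_csv <- function(path, catalog = default_catalog()) {
  df <- utils::read.csv(path, colClasses = "character")
  cols <- .measurement_columns(catalog)
  units <- list()
  for (id in names(catalog$layouts)) {
    for (f in catalog$layouts[[id]]$fields) {
      if (f$kind == "numeric") units[[.strip_eye_prefix(f$name)]] <- f$unit
    }
  }
  lapply(seq_len(nrow(df)), function(i) {
    meas <- list()
    for (cn in cols) {
      v <- df[[cn]][i]
      if (!is.na(v) && nzchar(v)) {
        meas[[cn]] <- measurement(cn, as.numeric(v), units[[cn]] %||% "", v)
      }
    }
    findings <- if (nzchar(df$finding[i])) {
      parts <- strsplit(df$finding[i], "; ", fixed = TRUE)[[1L]]
      labs <- grepl("\\(\\+\\)", parts)
      nms <- tolower(gsub(" ", "_", sub(" \\([+-]\\)", "", parts)))
      structure(list(labels = stats::setNames(labs, nms),
                     probabilities = stats::setNames(as.numeric(labs), nms)),
                class = "finding_result")
    } else NULL
    rec <- new_extracted_record(df$patient_id[i], df$visit_date[i],
                                df$report_type[i], df$laterality[i],
                                meas, findings, NA_character_, character(0),
                                list(), list())
    rec$activity <- if (nzchar(df$activity[i])) df$activity[i] else NA_character_
    rec
  })
}

# ---------------------------------------------------------------------------
# CDM-shaped measurement rows

#' Default concept map path (editable two-column CSV with placeholder ids)
#' @return File path of the bundled concept map.
#' @export
default_concept_map_path <- function() {
  system.file("extdata", "concept_map.csv", package = "octreport",
              mustWork = TRUE)
}

#' Map records to OMOP-CDM measurement-shaped rows
#'
#' One row per non-missing measurement; every row is traceable to exactly
#' one measurement through (source file, field name).
#'
#' @param records List of `extracted_record`.
#' @param concept_map Data frame with columns `field`, `concept_id`,
#'   `unit_concept_id` (or a path to such a CSV; default the bundled map).
#' @return Data frame shaped like the CDM MEASUREMENT table.
#' @export
to_cdm_rows <- function(records, concept_map = default_concept_map_path()) {
  if (is.character(concept_map)) {
    concept_map <- utils::read.csv(concept_map, stringsAsFactors = FALSE)
  }
  used <- unique(unlist(lapply(records, function(r) names(r$measurements))))
  unmapped <- setdiff(used, concept_map$field)
  if (length(unmapped)) {
    stop_octreport("unmapped_field",
                   sprintf("concept map lacks entries for: %s",
                           paste(sort(unmapped), collapse = ", ")))
  }
  rows <- list()
  for (r in records) {
    for (m in r$measurements) {
      if (is.na(m$value)) next
      cm <- concept_map[concept_map$field == m$name, , drop = FALSE][1L, ]
      rows[[length(rows) + 1L]] <- data.frame(
        person_id = r$patient_id,
        measurement_concept_id = cm$concept_id,
        measurement_date = r$visit_date,
        value_as_number = m$value,
        unit_concept_id = cm$unit_concept_id,
        unit_source_value = m$unit,
        measurement_source_value = m$name,
        provenance_file = r$source_path %||% "",
        provenance_field = m$name,
        laterality = r$laterality,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame())
  }
  df <- do.call(rbind, rows)
  df[order(df$person_id, df$laterality, df$measurement_date,
           df$measurement_source_value), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Crop export

#' Export tomogram crops as lossless PNGs with a manifest
#'
#' Files are named `{patient}_{date}_{laterality}_{field}.png`; re-export
#' is byte-identical.
#'
#' @param records List of `extracted_record` with tomogram crops.
#' @param dir Output directory.
#' @return Manifest data frame, invisibly.
#' @export
export_crops <- function(records, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2L) != 0L) {
    stop_octreport("unwritable_dir", sprintf("cannot write to directory '%s'", dir))
  }
  rows <- list()
  for (r in records) {
    for (nm in names(r$crops)) {
      fn <- sprintf("%s_%s_%s_%s.png", r$patient_id, r$visit_date,
                    r$laterality, nm)
      write_image_png(r$crops[[nm]], file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        file = fn, patient_id = r$patient_id, visit_date = r$visit_date,
        laterality = r$laterality, field = nm,
        source_path = r$source_path %||% "", stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else data.frame()
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
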