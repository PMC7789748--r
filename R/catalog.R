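# Layout catalog: where each value or tomogram lives on each report type.

.canonical_type_ids <- c("rnfl_unilateral", "rnfl_bilateral",
                         "macula_current", "macula_prev_current",
                         "macula_scan_current", "macula_scan_prev_current")

.field_kinds <- c("numeric", "date", "text", "tomogram")

#' Construct a field specification
#'
#' @param name Field identifier, unique within a layout.
#' @param kind One of `"numeric"`, `"date"`, `"text"`, `"tomogram"`.
#' @param box Pixel rectangle `c(x0, y0, x1, y1)`, 0-based half-open.
#' @param unit Measurement unit string; must be empty unless `kind` is
#'   `"numeric"` (a unitless numeric field may also use `""`).
#' @param pattern Optional regular expression the recognized text must match.
#' @param charset Optional string of characters the recognizer may emit
#'   for this field (constrained decoding); `NULL` = unconstrained.
#' @return A `field_spec` object.
#' @export
field_spec <- function(name, kind, box, unit = "", pattern = NULL,
                       charset = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_octreport("schema", "field name must be a non-empty string")
  }
  if (!kind %in% .field_kinds) {
    stop_octreport("schema",
                   sprintf("field '%s': unknown kind '%s'", name, kind))
  }
  tryCatch(check_box(box, sprintf("field '%s' box", name)),
           octreport_error = function(e) stop(e))
  if (nzchar(unit) && kind != "numeric") {
    stop_octreport("schema",
                   sprintf("field '%s': unit only allowed for numeric fields", name))
  }
  structure(list(name = name, kind = kind, box = as.integer(box),
                 unit = unit, pattern = pattern, charset = charset),
            class = "field_spec")
}

#' Construct a report layout
#'
#' @param type_id One of the six canonical report type identifiers.
#' @param header_title Canonical title text painted in the header region.
#' @param header_box Pixel rectangle of the header region.
#' @param page_size `c(width, height)` in pixels.
#' @param fields List of [field_spec()] objects.
#' @param version_range Informational device software version span.
#' @return A `report_layout` object.
#' @export
report_layout <- function(type_id, header_title, header_box, page_size,
                          fields, version_range = "") {
  if (!type_id %in% .canonical_type_ids) {
    stop_octreport("schema", sprintf("unknown report type_id '%s'", type_id))
  }
  check_box(header_box, sprintf("layout '%s' header_box", type_id))
  if (length(page_size) != 2L || any(page_size <= 0)) {
    stop_octreport("schema", sprintf("layout '%s': bad page_size", type_id))
  }
  layout <- structure(
    list(type_id = type_id, header_title = header_title,
         header_box = as.integer(header_box),
         page_size = as.integer(page_size),
         fields = fields, version_range = version_range),
    class = "report_layout")
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  nm <- vapply(layout$fields, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop_octreport("schema",
                   sprintf("layout '%s': duplicate field name '%s'",
                           layout$type_id, nm[duplicated(nm)][1L]))
  }
  w <- layout$page_size[1L]; h <- layout$page_size[2L]
  inside <- function(box, what) {
    if (box[1L] < 0L || box[2L] < 0L || box[3L] > w || box[4L] > h) {
      stop_octreport("schema",
                     sprintf("layout '%s': %s (%s) outside page %dx%d",
                             layout$type_id, what,
                             paste(box, collapse = ","), w, h))
    }
  }
  inside(layout$header_box, "header_box")
  for (f in layout$fields) inside(f$box, sprintf("field '%s' box", f$name))
  kinds <- vapply(layout$fields, `[[`, "", "kind")
  scan_only <- grepl("^macula_scan", layout$type_id)
  if (scan_only && any(kinds != "tomogram")) {
    stop_octreport("schema",
                   sprintf("layout '%s': scan-only layouts may contain only tomogram fields",
                           layout$type_id))
  }
  if (!scan_only && !any(kinds == "numeric")) {
    stop_octreport("schema",
                   sprintf("layout '%s': must contain at least one numeric field",
                           layout$type_id))
  }
  invisible(TRUE)
}

#' Construct and validate a layout catalog
#'
#' @param layouts List of [report_layout()] objects.
#' @param charset Recognizable character set (single string).
#' @param complete If `TRUE`, require exactly the six canonical report types.
#' @return A `layout_catalog` object (layouts keyed by `type_id`).
#' @export
layout_catalog <- function(layouts, charset = default_charset(),
                           complete = FALSE) {
  ids <- vapply(layouts, `[[`, "", "type_id")
  if (anyDuplicated(ids)) {
    stop_octreport("schema",
                   sprintf("duplicate layout type_id '%s'", ids[duplicated(ids)][1L]))
  }
  names(layouts) <- ids
  titles <- vapply(layouts, `[[`, "", "header_title")
  if (anyDuplicated(titles)) {
    stop_octreport("duplicate_title",
                   sprintf("header titles must be pairwise distinct; '%s' repeats",
                           titles[duplicated(titles)][1L]))
  }
  if (complete && !setequal(ids, .canonical_type_ids)) {
    stop_octreport("schema",
                   sprintf("complete catalog requires the six canonical types; got: %s",
                           paste(sort(ids), collapse = ", ")))
  }
  structure(list(layouts = layouts, charset = charset),
            class = "layout_catalog")
}

#' @export
print.layout_catalog <- function(x, ...) {
  cat(sprintf("<layout_catalog> %d layouts, charset of %d characters\n",
              length(x$layouts), nchar(x$charset)))
  for (l in x$layouts) {
    cat(sprintf("  %-26s '%s' (%d fields, page %dx%d)\n", l$type_id,
                l$header_title, length(l$fields),
                l$page_size[1L], l$page_size[2L]))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Serialization (YAML)

#' Load a layout catalog from a YAML/JSON config file
#'
#' Invalid entries are rejected with an error naming the offending layout or
#' field; nothing is silently repaired.
#'
#' @param path Config file path.
#' @param complete Require the six canonical report types (default `TRUE`,
#'   matching a full device catalog; pass `FALSE` for partial user catalogs).
#' @return A validated `layout_catalog`.
#' @export
load_catalog <- function(path, complete = TRUE) {
  if (!file.exists(path)) {
    stop_octreport("missing_file", sprintf("catalog file '%s' not found", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$layouts)) {
    stop_octreport("schema", "catalog file has no 'layouts' entry")
  }
  layouts <- lapply(raw$layouts, function(l) {
    fields <- lapply(l$fields, function(f) {
      field_spec(name = f$name, kind = f$kind, box = unlist(f$box),
                 unit = if (is.null(f$unit)) "" else f$unit,
                 pattern = f$pattern, charset = f$charset)
    })
    report_layout(type_id = l$type_id, header_title = l$header_title,
                  header_box = unlist(l$header_box),
                  page_size = unlist(l$page_size), fields = fields,
                  version_range = if (is.null(l$version_range)) "" else l$version_range)
  })
  charset <- if (is.null(raw$charset)) default_charset() else raw$charset
  layout_catalog(layouts, charset = charset, complete = complete)
}

#' Save a layout catalog to a YAML config file
#' @param catalog A `layout_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_catalog <- function(catalog, path) {
  as_plain <- list(
    charset = catalog$charset,
    layouts = unname(lapply(catalog$layouts, function(l) {
      list(type_id = l$type_id,
           header_title = l$header_title,
           header_box = as.integer(l$header_box),
           page_size = as.integer(l$page_size),
           version_range = l$version_range,
           fields = lapply(l$fields, function(f) {
             out <- list(name = f$name, kind = f$kind,
                         box = as.integer(f$box), unit = f$unit)
             if (!is.null(f$pattern)) out$pattern <- f$pattern
             if (!is.null(f$charset)) out$charset <- f$charset
             out
           }))
    }))
  )
  yaml::write_yaml(as_plain, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Bundled default catalog (coordinates are those of the package's own
# synthetic renderer; real-device coordinates are user-supplied config).

.pat_numeric <- "^-?[0-9]+(\\.[0-9]+)?$"
.pat_date <- "^[0-9]{4}-[0-9]{2}-[0-9]{2}$"
.pat_id <- "^[0-9]{4,12}$"
.pat_lat <- "^(RIGHT|LEFT)$"

.meta_fields <- function(with_laterality = TRUE) {
  out <- list(
    field_spec("patient_id", "text", c(90L, 52L, 206L, 78L),
               pattern = .pat_id, charset = "0123456789"),
    field_spec("visit_date", "date", c(300L, 52L, 432L, 78L),
               pattern = .pat_date, charset = "0123456789-")
  )
  if (with_laterality) {
    out <- c(out, list(
      field_spec("laterality", "text", c(520L, 52L, 624L, 78L),
                 pattern = .pat_lat, charset = "RIGHTLEF")))
  }
  out
}

.num_field <- function(name, x0, y0, unit) {
  field_spec(name, "numeric", c(x0, y0, x0 + 110L, y0 + 26L), unit = unit,
             pattern = .pat_numeric, charset = "0123456789.-")
}

#' The bundled default layout catalog
#'
#' Six report layouts on a 640 x 480 page: unilateral and bilateral retinal
#' nerve fiber layer (RNFL) thickness; unilateral macula thickness/volume
#' (current only, and previous + current); and the two scan-only macula
#' layouts that carry tomographic panels without numeric values.  Header
#' titles are descriptive stand-ins; coordinates are defined by the
#' package's synthetic renderer.
#'
#' @return A complete `layout_catalog`.
#' @export
default_catalog <- function() {
  um <- "µm"; mm3 <- "mm³"
  tomo_full <- c(60L, 240L, 580L, 420L)
  layouts <- list(
    report_layout(
      "rnfl_unilateral", "RNFL ANALYSIS SINGLE EXAM",
      header_box = c(12L, 10L, 470L, 40L), page_size = c(640L, 480L),
      fields = c(.meta_fields(), list(
        .num_field("global_rnfl_thickness", 150L, 120L, um),
        .num_field("superior_rnfl_thickness", 150L, 160L, um),
        .num_field("inferior_rnfl_thickness", 150L, 200L, um))),
      version_range = "1.7.0.0-1.10.4.0"),
    report_layout(
      "rnfl_bilateral", "RNFL ANALYSIS OU REPORT",
      header_box = c(12L, 10L, 470L, 40L), page_size = c(640L, 480L),
      fields = c(.meta_fields(with_laterality = FALSE), list(
        .num_field("right_global_rnfl_thickness", 150L, 120L, um),
        .num_field("right_superior_rnfl_thickness", 150L, 160L, um),
        .num_field("right_inferior_rnfl_thickness", 150L, 200L, um),
        .num_field("left_global_rnfl_thickness", 400L, 120L, um),
        .num_field("left_superior_rnfl_thickness", 400L, 160L, um),
        .num_field("left_inferior_rnfl_thickness", 400L, 200L, um))),
      version_range = "1.7.0.0-1.10.4.0"),
    report_layout(
      "macula_current", "MACULAR THICKNESS SINGLE EXAM",
      header_box = c(12L, 10L, 470L, 40L), page_size = c(640L, 480L),
      fields = c(.meta_fields(), list(
        .num_field("total_macular_volume", 150L, 120L, mm3),
        .num_field("central_macular_thickness", 150L, 160L, um),
        field_spec("macula_scan", "tomogram", tomo_full))),
      version_range = "1.7.0.0-1.10.4.0"),
    report_layout(
      "macula_prev_current", "MACULAR THICKNESS CHANGE REPORT",
      header_box = c(12L, 10L, 470L, 40L), page_size = c(640L, 480L),
      fields = c(.meta_fields(), list(
        .num_field("prev_total_macular_volume", 150L, 120L, mm3),
        .num_field("prev_central_macular_thickness", 150L, 160L, um),
        .num_field("total_macular_volume", 400L, 120L, mm3),
        .num_field("central_macular_thickness", 400L, 160L, um),
        field_spec("macula_scan", "tomogram", tomo_full))),
      version_range = "1.7.0.0-1.10.4.0"),
    report_layout(
      "macula_scan_current", "MACULA SCAN SINGLE EXAM",
      header_box = c(12L, 10L, 470L, 40L), page_size = c(640L, 480L),
      fields = list(
        field_spec("horizontal_scan", "tomogram", c(60L, 80L, 580L, 250L)),
        field_spec("vertical_scan", "tomogram", c(60L, 270L, 580L, 440L))),
      version_range = "1.7.0.0-1.10.4.0"),
    report_layout(
      "macula_scan_prev_current", "MACULA SCAN CHANGE REPORT",
      header_box = c(12L, 10L, 470L, 40L), page_size = c(640L, 480L),
      fields = list(
        field_spec("prev_horizontal_scan", "tomogram", c(40L, 80L, 300L, 250L)),
        field_spec("horizontal_scan", "tomogram", c(340L, 80L, 600L, 250L)),
        field_spec("prev_vertical_scan", "tomogram", c(40L, 270L, 300L, 440L)),
        field_spec("vertical_scan", "tomogram", c(340L, 270L, 600L, 440L))),
      version_range = "1.7.0.0-1.10.4.0")
  )
  layout_catalog(layouts, complete = TRUE)
}

# Convenience: path of the bundled YAML copy of default_catalog().
default_catalog_path <- function() {
  system.file("extdata", "default_catalog.yaml", package = "octreport",
              mustWork = TRUE)
}

# Non-tomogram fields of a layout, i.e. the fields a ground-truth sidecar
# must cover.
layout_value_fields <- function(layout) {
  Filter(function(f) f$kind != "tomogram", layout$fields)
}

layout_tomogram_fields <- function(layout) {
  Filter(function(f) f$kind == "tomogram", layout$fields)
}
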