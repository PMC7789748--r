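# Synthetic fixtures: OCR text-image corpora, full mock report pages with
# ground-truth sidecars, and tomogram phantoms.  This is the package's only
# data source; every test oracle is built from it.

#' Describe a text rendering style
#'
#' @param font `"plain"` or `"bold"`.
#' @param scale Glyph scale factor (1 unit = 1 px at scale 1).
#' @param contrast Ink darkness in `(0, 1]`; 1 = black on white.
#' @param noise_sd Additive Gaussian pixel noise standard deviation.
#' @param bg_level Background intensity (1 = white).
#' @param texture Amplitude of a smooth background texture (0 = none).
#' @param margin Background margin in pixels around the rendered line.
#' @return A `synth_style` list.
#' @export
synth_style <- function(font = "plain", scale = 2, contrast = 0.9,
                        noise_sd = 0.02, bg_level = 1, texture = 0,
                        margin = 4L) {
  structure(list(font = font, scale = scale, contrast = contrast,
                 noise_sd = noise_sd, bg_level = bg_level,
                 texture = texture, margin = as.integer(margin)),
            class = "synth_style")
}

#' A clean, noise-free rendering style
#' @param scale Glyph scale factor.
#' @return A `synth_style` with zero noise and full contrast.
#' @export
clean_style <- function(scale = 2) {
  synth_style(font = "plain", scale = scale, contrast = 1, noise_sd = 0,
              bg_level = 1, texture = 0, margin = 4L)
}

# Run expr with a deterministic RNG state, restoring the caller's state.
# `seed` is forced before the state is saved: a lazily evaluated seed
# expression may itself draw from the caller's stream.
with_seed_ <- function(seed, expr) {
  force(seed)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Paint a text line inside a field box: left-aligned 4 px from the box's
# left edge, vertically centered, shrunk to fit if necessary.  Shared by
# the report renderer and the header-template builder, so classifier
# templates align with rendered pages by construction.
paint_text_box <- function(img, text, box, font, scale, contrast) {
  mask <- render_text_bitmap(text, font = font, scale = scale)
  bh <- box[4L] - box[2L]; bw <- box[3L] - box[1L]
  if (nrow(mask) > bh - 4L || ncol(mask) > bw - 4L) {
    s <- min((bh - 4L) / nrow(mask), (bw - 4L) / ncol(mask))
    mask <- scale_bitmap(mask, s)
  }
  y0 <- box[2L] + max(2L, (bh - nrow(mask)) %/% 2L)
  x0 <- box[1L] + 4L
  yy <- y0 + seq_len(nrow(mask)); xx <- x0 + seq_len(ncol(mask))
  img[yy, xx] <- img[yy, xx] - contrast * mask
  img
}

# Paint an ink bitmap onto a background canvas; returns the image matrix.
# With `canvas_w` the canvas is widened and the line left-aligned `x_off`
# pixels in, emulating the geometry of a report field box (text flush left,
# background to the right).
.paint_line <- function(mask, style, canvas_w = NULL, x_off = NULL) {
  h <- nrow(mask) + 2L * style$margin
  w <- if (is.null(canvas_w)) ncol(mask) + 2L * style$margin else
    max(canvas_w, ncol(mask) + 2L * style$margin)
  if (is.null(x_off)) x_off <- style$margin
  img <- matrix(style$bg_level, h, w)
  if (style$texture > 0) {
    xs <- seq_len(w); ys <- seq_len(h)
    phase <- stats::runif(4L, 0, 2 * pi)
    tex <- style$texture * (outer(sin(ys / 9 + phase[1L]), cos(xs / 13 + phase[2L])) +
                            outer(cos(ys / 5 + phase[3L]), sin(xs / 7 + phase[4L]))) / 2
    img <- img - abs(tex)
  }
  yy <- style$margin + seq_len(nrow(mask))
  xx <- x_off + seq_len(ncol(mask))
  img[yy, xx] <- img[yy, xx] - style$contrast * mask
  if (style$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, style$noise_sd), h, w)
  }
  pmin(pmax(img, 0), 1)
}

#' Render one synthetic text image
#'
#' Deterministic given `(label, style, seed)`.  Labels are limited to 50
#' characters and must be drawn from the charset; empty labels are rejected
#' (a missing value on a report is the `"--"` placeholder, not an empty
#' image).
#'
#' @param label Character string to render.
#' @param style A [synth_style()].
#' @param seed Integer seed for the noise draw.
#' @param charset Allowed characters.
#' @return A `text_sample` list with `image`, `label`, `style`.
#' @export
synth_text_image <- function(label, style = synth_style(), seed = 1L,
                             charset = default_charset()) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop_octreport("empty_label", "label must be a non-empty string")
  }
  if (nchar(label) > 50L) {
    stop_octreport("overlength_label",
                   sprintf("label has %d characters; the recognizer is limited to 50",
                           nchar(label)))
  }
  allowed <- strsplit(charset, "")[[1L]]
  chars <- strsplit(label, "")[[1L]]
  if (!all(chars %in% allowed)) {
    stop_octreport("charset",
                   sprintf("label contains character(s) outside charset: %s",
                           paste(setdiff(chars, allowed), collapse = " ")))
  }
  img <- with_seed_(seed, {
    mask <- render_text_bitmap(label, font = style$font, scale = style$scale)
    .paint_line(mask, style)
  })
  structure(list(image = img, label = label, style = style),
            class = "text_sample")
}

# ---------------------------------------------------------------------------
# OCR corpus

#' Specify an OCR training corpus
#'
#' The default desk-scale corpus holds 50,000 samples split 0.92 / 0.08 into
#' training and validation; `n_total` is a knob, so a full-scale corpus
#' remains producible.
#'
#' @param n_total Total number of samples (>= 2).
#' @param train_fraction Training fraction in (0, 1); default 0.92.
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @param charset Characters labels may use.
#' @param max_len Maximum label length (<= 50).
#' @param label_kinds Probability weights over label generators
#'   (`integer`, `decimal`, `date`, `id`, `word`, `mixed`).
#' @param scale_range,contrast_range,noise_range Style ranges sampled per
#'   sample.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_total = 50000L, train_fraction = 0.92, seed = 1L,
                        charset = default_charset(), max_len = 12L,
                        label_kinds = c(integer = 0.26, decimal = 0.22,
                                        date = 0.14, id = 0.18, word = 0.10,
                                        mixed = 0.10),
                        scale_range = c(1.5, 3), contrast_range = c(0.55, 1),
                        noise_range = c(0, 0.12)) {
  if (!is.numeric(n_total) || n_total < 2) {
    stop_octreport("schema", "corpus n_total must be at least 2")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_octreport("schema", "train_fraction must lie strictly between 0 and 1")
  }
  if (max_len > 50L) stop_octreport("schema", "max_len may not exceed 50")
  structure(list(n_total = as.integer(n_total),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 charset = charset, max_len = as.integer(max_len),
                 label_kinds = label_kinds, scale_range = scale_range,
                 contrast_range = contrast_range, noise_range = noise_range),
            class = "corpus_spec")
}

# One random label per the spec's generator mix.  Covers the content that
# appears on report pages: integers (thicknesses), decimals (volumes),
# ISO dates, uppercase words (laterality etc.), and mixed alphanumerics.
.random_label <- function(spec) {
  kind <- sample(names(spec$label_kinds), 1L, prob = spec$label_kinds)
  digits <- function(n) paste(sample(0:9, n, replace = TRUE), collapse = "")
  label <- switch(kind,
    integer = digits(sample(1:4, 1L)),
    decimal = paste0(if (stats::runif(1) < 0.1) "-" else "",
                     digits(sample(1:2, 1L)), ".", digits(sample(1:2, 1L))),
    date = sprintf("%04d-%02d-%02d", sample(2006:2019, 1L),
                   sample(1:12, 1L), sample(1:28, 1L)),
    id = digits(sample(6:min(10L, spec$max_len), 1L,
                       prob = c(1, 1, 3, 1, 1)[seq_len(min(10L, spec$max_len) - 5L)])),
    word = paste(sample(LETTERS, sample(3:min(8L, spec$max_len), 1L),
                        replace = TRUE), collapse = ""),
    mixed = {
      pool <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ-/.:%", "")[[1L]]
      n <- sample(2:spec$max_len, 1L)
      paste(sample(pool, n, replace = TRUE), collapse = "")
    })
  list(label = label, kind = kind)
}

.random_style <- function(spec) {
  synth_style(
    font = sample(c("plain", "bold"), 1L),
    scale = stats::runif(1L, spec$scale_range[1L], spec$scale_range[2L]),
    contrast = stats::runif(1L, spec$contrast_range[1L], spec$contrast_range[2L]),
    noise_sd = stats::runif(1L, spec$noise_range[1L], spec$noise_range[2L]),
    bg_level = stats::runif(1L, 0.85, 1),
    texture = if (stats::runif(1L) < 0.3) stats::runif(1L, 0, 0.08) else 0,
    margin = sample(2:7, 1L))
}

#' Generate an OCR training/validation corpus
#'
#' Images are rendered, preprocessed to the recognizer's input geometry and
#' packed as 8-bit rasters.  `|train| = round(n_total * train_fraction)`;
#' the remainder is validation.  Byte-identical for identical specs.
#'
#' @param spec A [corpus_spec()].
#' @param progress Print a dot every 5000 samples.
#' @return List with `train` and `val`, each a `corpus_set` carrying
#'   `images` (raw matrix, one row per sample, 32*128 bytes), `labels`, and
#'   a `manifest` data frame (label, split, font, scale, noise_sd).
#' @export
generate_corpus <- function(spec, progress = FALSE) {
  n <- spec$n_total
  n_train <- as.integer(round(n * spec$train_fraction))
  n_val <- n - n_train
  geom <- ocr_input_geometry()
  npx <- geom$h * geom$w
  images <- matrix(as.raw(0L), nrow = n, ncol = npx)
  labels <- character(n); kinds <- character(n)
  fonts <- character(n); scales <- numeric(n); noises <- numeric(n)
  with_seed_(spec$seed, {
    for (i in seq_len(n)) {
      rl <- .random_label(spec)
      lbl <- rl$label
      kinds[i] <- rl$kind
      sty <- .random_style(spec)
      mask <- render_text_bitmap(lbl, font = sty$font, scale = sty$scale)
      # canvas geometry mirrors a report field box: text flush left with
      # background to the right, box aspect like the configured field boxes
      aspect <- stats::runif(1L, 3.2, 6.5)
      h <- nrow(mask) + 2L * sty$margin
      img <- .paint_line(mask, sty, canvas_w = round(h * aspect), x_off = 4L)
      pp <- preprocess_crop(img)
      images[i, ] <- as.raw(pmin(pmax(round(pp * 255), 0), 255))
      labels[i] <- lbl
      fonts[i] <- sty$font; scales[i] <- sty$scale; noises[i] <- sty$noise_sd
      if (progress && i %% 5000L == 0L) cat(".")
    }
  })
  split <- rep(c("train", "val"), c(n_train, n_val))
  manifest <- data.frame(label = labels, kind = kinds, split = split,
                         font = fonts, scale = scales, noise_sd = noises,
                         stringsAsFactors = FALSE)
  set_of <- function(idx, nm) {
    structure(list(images = images[idx, , drop = FALSE],
                   labels = labels[idx],
                   manifest = manifest[idx, , drop = FALSE],
                   geometry = geom, charset = spec$charset),
              class = "corpus_set")
  }
  list(train = set_of(seq_len(n_train)),
       val = set_of(if (n_val > 0L) n_train + seq_len(n_val) else integer(0)))
}

#' Write a corpus to disk as PNGs plus a manifest CSV
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  geom <- corpus$train$geometry
  for (split in c("train", "val")) {
    set <- corpus[[split]]
    for (i in seq_along(set$labels)) {
      fn <- sprintf("%s_%06d.png", split, i)
      img <- matrix(as.integer(set$images[i, ]) / 255, geom$h, geom$w)
      write_image_png(img, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        path = fn, label = set$labels[i], split = split,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Tomogram phantoms

.known_findings <- c("subretinal_fluid", "macular_edema")

#' Render a tomogram phantom
#'
#' Layered bright horizontal bands on a dark background mimic retinal
#' strata (inner retinal complex above, a bright retinal pigment epithelium
#' band below) with speckle noise.  `subretinal_fluid` carves a dark
#' hypo-intense blob beneath the top band, just above the lower band;
#' `macular_edema` adds round hypo-reflective cysts inside the inner band
#' and a dome-shaped elevation.  Deterministic given `seed`.
#'
#' @param finding_flags Named logical vector over
#'   `c("subretinal_fluid", "macular_edema")` (missing names default FALSE).
#' @param seed Integer seed.
#' @param width,height Output size in pixels.
#' @return `[y, x]` matrix in `[0, 1]`.
#' @export
render_tomogram_phantom <- function(finding_flags = c(subretinal_fluid = FALSE,
                                                      macular_edema = FALSE),
                                    seed = 1L, width = 260L, height = 140L) {
  bad <- setdiff(names(finding_flags), .known_findings)
  if (length(bad)) {
    stop_octreport("unknown_finding",
                   sprintf("unknown finding name(s): %s", paste(bad, collapse = ", ")))
  }
  flags <- stats::setNames(rep(FALSE, length(.known_findings)), .known_findings)
  flags[names(finding_flags)] <- as.logical(finding_flags)
  with_seed_(seed, {
    w <- as.integer(width); h <- as.integer(height)
    img <- matrix(0.05, h, w)
    xs <- seq_len(w)
    und <- function(amp) amp * sin(xs / stats::runif(1, 25, 60) +
                                   stats::runif(1, 0, 2 * pi))
    # top (inner retina) band and bottom (RPE) band centers per column
    top_c <- h * 0.30 + und(h * 0.04)
    bot_c <- h * 0.72 + und(h * 0.02)
    dome <- if (flags["macular_edema"]) {
      -h * 0.08 * exp(-((xs - w / 2)^2) / (2 * (w / 6)^2))
    } else 0
    top_c <- top_c + dome
    ys <- seq_len(h)
    add_band <- function(img, centers, half, peak) {
      d <- outer(ys, centers, function(y, c) abs(y - c))
      img + peak * exp(-(d / half)^2)
    }
    img <- add_band(img, top_c, h * 0.05, 0.55)
    img <- add_band(img, top_c + h * 0.12, h * 0.03, 0.30)
    img <- add_band(img, bot_c, h * 0.035, 0.85)
    # medium-reflective tissue between the inner complex and the RPE band;
    # hypo-intense findings are carved out of this, as on real B-scans
    tissue <- outer(ys, seq_len(w), function(y, x) {
      as.numeric(y > top_c[x] & y < bot_c[x])
    })
    img <- pmax(img, 0.38 * tissue)
    if (flags["subretinal_fluid"]) {
      # dark blob beneath the top band, sitting on the RPE band
      cx <- w / 2 + stats::runif(1, -w / 10, w / 10)
      cy <- (mean(top_c) + mean(bot_c)) / 2 + h * 0.06
      rx <- w * stats::runif(1, 0.12, 0.18); ry <- h * stats::runif(1, 0.10, 0.14)
      d2 <- outer(ys, xs, function(y, x) ((x - cx) / rx)^2 + ((y - cy) / ry)^2)
      img[d2 <= 1] <- 0.02
    }
    if (flags["macular_edema"]) {
      for (k in 1:3) {
        cx <- w * stats::runif(1, 0.3, 0.7)
        cy <- mean(top_c) + h * stats::runif(1, -0.03, 0.05)
        r <- h * stats::runif(1, 0.03, 0.05)
        d2 <- outer(ys, xs, function(y, x) ((x - cx)^2 + (y - cy)^2) / r^2)
        img[d2 <= 1] <- 0.04
      }
    }
    # multiplicative speckle plus additive noise
    img <- img * (1 + matrix(stats::rnorm(h * w, 0, 0.18), h, w))
    img <- img + matrix(stats::rnorm(h * w, 0, 0.02), h, w)
    pmin(pmax(img, 0), 1)
  })
}

# ---------------------------------------------------------------------------
# Full mock report pages

# Static page furniture labels (not inside any field box).
.furniture <- list(
  list(text = "PATIENT ID:", x = 14L, y = 56L),
  list(text = "DATE:", x = 230L, y = 56L),
  list(text = "EYE:", x = 470L, y = 56L)
)

#' Render a synthetic report page with a ground-truth sidecar
#'
#' Each non-tomogram truth value is painted inside its field box (missing
#' optional values as the `"--"` placeholder); the header title is painted
#' in the header box; tomogram fields are filled with
#' [render_tomogram_phantom()] driven by `finding_flags`.
#'
#' @param truth Named list/character vector: field name -> string value for
#'   every non-tomogram field of the layout (values may be `NA` for the
#'   dash placeholder).
#' @param layout A `report_layout`.
#' @param style A [synth_style()] controlling text rendering on the page.
#' @param seed Integer seed (noise, phantom details).
#' @param patient_id,visit_date,laterality Metadata for the sidecar; for
#'   layouts that carry the matching text fields these must equal the truth
#'   entries.
#' @param finding_flags Named logical vector of phantom findings.
#' @return A `synthetic_report` list: `image`, `truth`, `type_id`,
#'   `patient_id`, `visit_date`, `laterality`, `finding_flags`.
#' @export
render_report <- function(truth, layout, style = synth_style(), seed = 1L,
                          patient_id = NULL, visit_date = NULL,
                          laterality = NULL,
                          finding_flags = c(subretinal_fluid = FALSE,
                                            macular_edema = FALSE)) {
  truth <- as.list(truth)
  value_fields <- layout_value_fields(layout)
  want <- vapply(value_fields, `[[`, "", "name")
  have <- names(truth)
  if (!setequal(want, have)) {
    stop_octreport("truth_mismatch",
                   sprintf("truth fields do not match layout '%s': missing [%s], extra [%s]",
                           layout$type_id,
                           paste(setdiff(want, have), collapse = ", "),
                           paste(setdiff(have, want), collapse = ", ")))
  }
  if (is.null(patient_id)) patient_id <- truth[["patient_id"]]
  if (is.null(visit_date)) visit_date <- truth[["visit_date"]]
  if (is.null(laterality)) {
    laterality <- if (!is.null(truth[["laterality"]])) {
      tolower(truth[["laterality"]])
    } else "right"
  }
  page <- with_seed_(seed, {
    w <- layout$page_size[1L]; h <- layout$page_size[2L]
    img <- matrix(style$bg_level, h, w)
    if (style$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, style$noise_sd), h, w)
    }
    paint_text_in_box <- function(img, text, box) {
      paint_text_box(img, text, box, font = style$font, scale = style$scale,
                     contrast = style$contrast)
    }
    img <- paint_text_in_box(img, layout$header_title, layout$header_box)
    if (!grepl("^macula_scan", layout$type_id)) {
      for (f in .furniture) {
        mask <- render_text_bitmap(f$text, font = style$font, scale = 1)
        yy <- f$y + seq_len(nrow(mask)); xx <- f$x + seq_len(ncol(mask))
        img[yy, xx] <- img[yy, xx] - style$contrast * mask
      }
    }
    for (f in value_fields) {
      v <- truth[[f$name]]
      v <- if (is.null(v) || is.na(v) || !nzchar(v)) "--" else as.character(v)
      img <- paint_text_in_box(img, v, f$box)
    }
    for (f in layout_tomogram_fields(layout)) {
      ph <- render_tomogram_phantom(
        finding_flags, seed = seed + utf8ToInt(substr(f$name, 1L, 1L)),
        width = f$box[3L] - f$box[1L], height = f$box[4L] - f$box[2L])
      img <- paste_region(img, ph, f$box[1L], f$box[2L])
    }
    pmin(pmax(img, 0), 1)
  })
  truth_chr <- lapply(truth, function(v) {
    if (is.null(v) || is.na(v)) NA_character_ else as.character(v)
  })
  structure(list(image = page, truth = truth_chr, type_id = layout$type_id,
                 patient_id = patient_id, visit_date = visit_date,
                 laterality = laterality,
                 finding_flags = finding_flags),
            class = "synthetic_report")
}

#' Draw a random synthetic report of a given type
#'
#' Values are drawn from clinically plausible ranges: central macular
#' thickness 170-550 µm, total macular volume 7-12 mm³, RNFL thicknesses
#' 40-140 µm; patient ids are 8 digits and visit dates span 2006-2019.
#'
#' @param type_id One of the six canonical type ids.
#' @param seed Integer seed.
#' @param catalog Layout catalog (default bundled catalog).
#' @param style Page rendering style (default near-clean, as device-rendered
#'   report pages are).
#' @return A `synthetic_report`.
#' @export
random_report <- function(type_id, seed = 1L, catalog = default_catalog(),
                          style = synth_style(noise_sd = 0.015)) {
  layout <- catalog$layouts[[type_id]]
  if (is.null(layout)) {
    stop_octreport("schema", sprintf("no layout '%s' in catalog", type_id))
  }
  with_seed_(seed, {
    pid <- paste(sample(0:9, 8L, replace = TRUE), collapse = "")
    date <- sprintf("%04d-%02d-%02d", sample(2006:2019, 1L),
                    sample(1:12, 1L), sample(1:28, 1L))
    lat <- sample(c("right", "left"), 1L)
    flags <- c(subretinal_fluid = stats::runif(1L) < 0.35,
               macular_edema = stats::runif(1L) < 0.25)
    rint <- function(lo, hi) as.character(sample(lo:hi, 1L))
    rvol <- function() sprintf("%.2f", stats::runif(1L, 7, 12))
    truth <- list()
    for (f in layout_value_fields(layout)) {
      truth[[f$name]] <- switch(
        f$name,
        patient_id = pid,
        visit_date = date,
        laterality = toupper(lat),
        total_macular_volume = rvol(),
        prev_total_macular_volume = rvol(),
        central_macular_thickness = rint(170L, 550L),
        prev_central_macular_thickness = rint(170L, 550L),
        rint(40L, 140L))  # RNFL thicknesses
    }
    inner_seed <- sample.int(.Machine$integer.max, 1L)
    render_report(truth, layout, style = style, seed = inner_seed,
                  patient_id = pid, visit_date = date, laterality = lat,
                  finding_flags = flags)
  })
}

#' Write a synthetic report image and its JSON sidecar
#' @param report A `synthetic_report`.
#' @param dir Output directory.
#' @param basename File basename (without extension).
#' @return Named list with `image` and `sidecar` paths.
#' @export
write_synthetic_report <- function(report, dir, basename) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(basename, ".png"))
  sc_path <- file.path(dir, paste0(basename, ".json"))
  write_image_png(report$image, img_path)
  jsonlite::write_json(
    list(type_id = report$type_id, patient_id = report$patient_id,
         visit_date = report$visit_date, laterality = report$laterality,
         truth = report$truth,
         finding_flags = as.list(report$finding_flags)),
    sc_path, auto_unbox = TRUE, null = "null", na = "null")
  list(image = img_path, sidecar = sc_path)
}

#' Read a ground-truth sidecar written by [write_synthetic_report()]
#' @param path Sidecar JSON path.
#' @return List mirroring the sidecar contents.
#' @export
read_sidecar <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = FALSE)
  sc$truth <- lapply(sc$truth, function(v) if (is.null(v)) NA_character_ else v)
  sc$finding_flags <- unlist(sc$finding_flags)
  sc
}
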