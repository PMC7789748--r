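# Synthetic fixtures: text images, corpora, report pages, phantoms.

test_that("synth_text_image validates labels and is deterministic", {
  s1 <- synth_text_image("364", clean_style(), seed = 1L)
  s2 <- synth_text_image("364", clean_style(), seed = 1L)
  expect_identical(s1$image, s2$image)
  s3 <- synth_text_image("364", synth_style(noise_sd = 0.05), seed = 2L)
  expect_false(identical(s1$image, s3$image))
  expect_error(synth_text_image("", clean_style()),
               class = "octreport_error_empty_label")
  expect_error(synth_text_image(strrep("7", 51L), clean_style()),
               class = "octreport_error_overlength_label")
  expect_error(synth_text_image("abc", clean_style()),
               class = "octreport_error_charset")
})

test_that("reference recognizer reads clean synthetic text exactly", {
  expect_identical(reference_recognize(
    synth_text_image("364", clean_style(), seed = 1L)$image)$text, "364")
  # 1000 random labels over fonts and scales, zero noise
  set.seed(31L)
  chars <- setdiff(strsplit(default_charset(), "")[[1L]], " ")
  n_ok <- 0L
  for (i in 1:1000) {
    lbl <- paste(sample(chars, sample(1:10, 1L), replace = TRUE), collapse = "")
    st <- synth_style(font = sample(c("plain", "bold"), 1L),
                      scale = runif(1L, 1.5, 3), contrast = 1, noise_sd = 0)
    got <- reference_recognize(synth_text_image(lbl, st, seed = i)$image)$text
    n_ok <- n_ok + (got == lbl)
  }
  expect_identical(n_ok, 1000L)
})

test_that("corpus split arithmetic is exact and generation deterministic", {
  spec <- corpus_spec(n_total = 1000L, train_fraction = 0.92, seed = 3L,
                      scale_range = c(1.5, 2.5))
  corpus <- generate_corpus(spec)
  expect_identical(nrow(corpus$train$images), 920L)
  expect_identical(nrow(corpus$val$images), 80L)
  corpus2 <- generate_corpus(spec)
  expect_identical(corpus$train$images, corpus2$train$images)
  expect_identical(corpus$val$labels, corpus2$val$labels)
  expect_error(corpus_spec(n_total = 1L), class = "octreport_error_schema")
  expect_error(corpus_spec(train_fraction = 1), class = "octreport_error_schema")
})

test_that("digit-restricted corpus yields only digit labels", {
  spec <- corpus_spec(n_total = 100L, seed = 5L,
                      label_kinds = c(integer = 1))
  corpus <- generate_corpus(spec)
  labels <- c(corpus$train$labels, corpus$val$labels)
  expect_length(labels, 100L)
  expect_true(all(grepl("^[0-9]+$", labels)))
})

test_that("rendered reports agree with their sidecar truth under the reference reader", {
  catalog <- test_catalog()
  for (tid in c("rnfl_unilateral", "macula_current")) {
    rp <- random_report(tid, seed = 77L)
    layout <- catalog$layouts[[tid]]
    expect_identical(dim(rp$image),
                     c(layout$page_size[2L], layout$page_size[1L]))
    for (f in octreport:::layout_value_fields(layout)) {
      crop <- crop_region(rp$image, f$box)
      expect_identical(reference_recognize(crop, catalog$charset)$text,
                       rp$truth[[f$name]],
                       label = sprintf("%s/%s", tid, f$name))
    }
  }
})

test_that("missing optional values render as the dash placeholder", {
  catalog <- test_catalog()
  layout <- catalog$layouts[["macula_current"]]
  truth <- list(patient_id = "00112233", visit_date = "2015-03-02",
                laterality = "LEFT", total_macular_volume = NA,
                central_macular_thickness = "301")
  rp <- render_report(truth, layout, style = clean_style(), seed = 2L)
  crop <- crop_region(rp$image,
                      Filter(function(f) f$name == "total_macular_volume",
                             layout$fields)[[1L]]$box)
  expect_identical(reference_recognize(crop, catalog$charset)$text, "--")
})

test_that("render_report rejects truth/layout mismatches", {
  layout <- test_catalog()$layouts[["macula_current"]]
  expect_error(render_report(list(bogus = "1"), layout),
               class = "octreport_error_truth_mismatch")
})

test_that("tomogram phantoms are deterministic with a fluid blob only when flagged", {
  ph0 <- render_tomogram_phantom(c(subretinal_fluid = FALSE), seed = 4L)
  ph0b <- render_tomogram_phantom(c(subretinal_fluid = FALSE), seed = 4L)
  expect_identical(ph0, ph0b)
  ph1 <- render_tomogram_phantom(c(subretinal_fluid = TRUE), seed = 4L)
  expect_false(identical(ph0, ph1))
  # connected hypo-intense region below the top band, between the strata
  mid <- function(img) img[round(nrow(img) * 0.42):round(nrow(img) * 0.62), ]
  dark1 <- EBImage::bwlabel(EBImage::Image(t(mid(ph1) < 0.05)))
  sizes1 <- tabulate(EBImage::imageData(dark1))
  expect_true(any(sizes1 >= 150), label = "fluid blob present when flagged")
  dark0 <- EBImage::bwlabel(EBImage::Image(t(mid(ph0) < 0.05)))
  sizes0 <- tabulate(EBImage::imageData(dark0))
  expect_true(max(sizes1, 0) > 3 * max(sizes0, 1),
              label = "blob much larger than background speckle")
  expect_error(render_tomogram_phantom(c(drusen = TRUE)),
               class = "octreport_error_unknown_finding")
})

test_that("report writing produces a readable PNG + JSON sidecar pair", {
  dir <- withr::local_tempdir()
  rp <- random_report("macula_current", seed = 12L)
  paths <- write_synthetic_report(rp, dir, "r1")
  img <- read_report_image(paths$image)
  expect_equal(dim(img), dim(rp$image))
  expect_lt(max(abs(img - rp$image)), 1 / 254)   # 8-bit quantization only
  sc <- read_sidecar(paths$sidecar)
  expect_identical(sc$type_id, rp$type_id)
  expect_identical(sc$truth$central_macular_thickness,
                   rp$truth$central_macular_thickness)
})
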