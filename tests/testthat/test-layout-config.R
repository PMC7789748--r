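# Layout catalog: construction, validation, serialization, cropping.

test_that("bundled catalog has six layouts with distinct titles and in-page boxes", {
  catalog <- test_catalog()
  expect_length(catalog$layouts, 6L)
  titles <- vapply(catalog$layouts, `[[`, "", "header_title")
  expect_false(anyDuplicated(titles) > 0L)
  for (l in catalog$layouts) {
    w <- l$page_size[1L]; h <- l$page_size[2L]
    for (f in l$fields) {
      expect_true(f$box[1L] >= 0L && f$box[2L] >= 0L &&
                  f$box[3L] <= w && f$box[4L] <= h,
                  label = sprintf("%s/%s inside page", l$type_id, f$name))
    }
    kinds <- vapply(l$fields, `[[`, "", "kind")
    if (grepl("^macula_scan", l$type_id)) {
      expect_true(all(kinds == "tomogram"), label = l$type_id)
    } else {
      expect_true(any(kinds == "numeric"), label = l$type_id)
    }
  }
})

test_that("bundled YAML catalog loads and matches the in-code catalog", {
  loaded <- load_catalog(system.file("extdata", "default_catalog.yaml",
                                     package = "octreport"))
  strip <- function(cl) lapply(cl$layouts, function(l) {
    l$fields <- lapply(l$fields, function(f) f[c("name", "kind", "box", "unit")])
    l[c("type_id", "header_title", "header_box", "page_size")]
  })
  expect_identical(strip(loaded), strip(test_catalog()))
})

test_that("invalid catalogs are rejected with errors naming the offender", {
  expect_error(field_spec("bad", "numeric", c(50, 50, 40, 60)),
               "bad", class = "octreport_error_schema")
  expect_error(load_catalog(tempfile("nofile")),
               class = "octreport_error_missing_file")
  l1 <- report_layout("macula_scan_current", "TITLE X",
                      c(0L, 0L, 100L, 20L), c(200L, 200L),
                      list(field_spec("s", "tomogram", c(0L, 30L, 100L, 100L))))
  l2 <- report_layout("macula_scan_prev_current", "TITLE X",
                      c(0L, 0L, 100L, 20L), c(200L, 200L),
                      list(field_spec("s", "tomogram", c(0L, 30L, 100L, 100L))))
  expect_error(layout_catalog(list(l1, l2)),
               class = "octreport_error_duplicate_title")
  # field outside page names the field
  expect_error(
    report_layout("macula_scan_current", "T", c(0L, 0L, 50L, 10L),
                  c(100L, 100L),
                  list(field_spec("huge", "tomogram", c(0L, 20L, 150L, 90L)))),
    "huge", class = "octreport_error_schema")
  # non-tomogram field on a scan-only layout
  expect_error(
    report_layout("macula_scan_current", "T", c(0L, 0L, 50L, 10L),
                  c(100L, 100L),
                  list(field_spec("v", "numeric", c(0L, 20L, 80L, 40L)))),
    class = "octreport_error_schema")
})

test_that("catalog serialization round-trips", {
  catalog <- test_catalog()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_catalog(catalog, path)
  again <- load_catalog(path)
  expect_identical(again$charset, catalog$charset)
  expect_identical(names(again$layouts), names(catalog$layouts))
  for (id in names(catalog$layouts)) {
    a <- catalog$layouts[[id]]; b <- again$layouts[[id]]
    expect_identical(a[c("type_id", "header_title", "header_box",
                         "page_size", "version_range")],
                     b[c("type_id", "header_title", "header_box",
                         "page_size", "version_range")])
    expect_identical(lapply(a$fields, unclass), lapply(b$fields, unclass))
  }
})

test_that("crop_region copies pixels exactly and round-trips via paste", {
  set.seed(7)
  img <- matrix(runif(100), 10L, 10L)
  q <- crop_region(img, c(0L, 0L, 5L, 5L))
  expect_identical(dim(q), c(5L, 5L))
  expect_identical(q, img[1:5, 1:5])
  expect_identical(crop_region(img, c(0L, 0L, 10L, 10L)), img)
  # lossless re-embedding
  box <- c(2L, 3L, 7L, 9L)
  sub <- crop_region(img, box)
  expect_identical(dim(sub), c(6L, 5L))
  back <- octreport:::paste_region(img, sub, box[1L], box[2L])
  expect_identical(back, img)
  # errors
  expect_error(crop_region(img, c(0L, 0L, 11L, 5L)),
               class = "octreport_error_out_of_bounds")
  expect_error(crop_region(img, c(5L, 5L, 5L, 9L)),
               class = "octreport_error_schema")
})
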