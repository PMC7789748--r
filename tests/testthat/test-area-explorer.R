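# Region routing: numeric text vs tomogram vs empty.

test_that("rendered text, blank and phantom crops route to the right class", {
  catalog <- test_catalog()
  layout <- catalog$layouts[["macula_current"]]
  rp <- random_report("macula_current", seed = 41L)
  cmt_field <- Filter(function(f) f$name == "central_macular_thickness",
                      layout$fields)[[1L]]
  rr <- route_region(rp$image, cmt_field)
  expect_identical(rr$content_class, "numeric_text")
  expect_identical(rr$crop, crop_region(rp$image, cmt_field$box))
  tomo_field <- Filter(function(f) f$kind == "tomogram", layout$fields)[[1L]]
  expect_identical(route_region(rp$image, tomo_field)$content_class, "tomogram")
  # all-white region
  blank_page <- matrix(1, 480L, 640L)
  expect_identical(route_region(blank_page, cmt_field)$content_class, "empty")
})

test_that("a declared/detected mismatch warns but honors the detected class", {
  layout <- test_catalog()$layouts[["macula_current"]]
  rp <- random_report("macula_current", seed = 43L)
  tomo_field <- Filter(function(f) f$kind == "tomogram", layout$fields)[[1L]]
  lying_field <- field_spec("not_really_text", "numeric", tomo_field$box,
                            unit = "µm")
  expect_warning(rr <- route_region(rp$image, lying_field),
                 class = "octreport_warning_routing")
  expect_identical(rr$content_class, "tomogram")
})

test_that("detected class agrees with the declared kind on 200+ fixture regions", {
  catalog <- test_catalog()
  n <- 0L; agree <- 0L
  for (tid in names(catalog$layouts)) {
    for (i in 1:7) {
      rp <- random_report(tid, seed = 600L + i * 17L + nchar(tid))
      for (f in catalog$layouts[[tid]]$fields) {
        rr <- suppressWarnings(route_region(rp$image, f))
        n <- n + 1L
        expected <- if (f$kind == "tomogram") "tomogram" else "numeric_text"
        agree <- agree + (rr$content_class == expected)
      }
    }
  }
  expect_gte(n, 200L)
  expect_identical(agree, n)
})
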