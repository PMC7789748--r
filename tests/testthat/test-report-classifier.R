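# Header-based report-type classification.

test_that("all six rendered report types classify correctly", {
  catalog <- test_catalog()
  for (tid in names(catalog$layouts)) {
    rp <- random_report(tid, seed = 11L)
    cls <- classify_report(rp$image, catalog)
    expect_identical(cls$type_id, tid)
    expect_gte(cls$score, 0.7)
  }
})

test_that("a blank page raises the unknown-report-type error", {
  blank <- matrix(1, 480L, 640L)
  expect_error(classify_report(blank, test_catalog()),
               class = "octreport_error_unknown_report_type")
})

test_that("classification is invariant to +/-20% brightness scaling", {
  catalog <- test_catalog()
  rp <- random_report("rnfl_bilateral", seed = 21L)
  for (fac in c(0.8, 1.2)) {
    img <- pmin(pmax(rp$image * fac, 0), 1)
    expect_identical(classify_report(img, catalog)$type_id, "rnfl_bilateral")
  }
})

test_that("catalog order does not change the chosen type", {
  catalog <- test_catalog()
  rp <- random_report("macula_prev_current", seed = 31L)
  for (perm_seed in 1:3) {
    set.seed(perm_seed)
    shuffled <- catalog
    shuffled$layouts <- catalog$layouts[sample(names(catalog$layouts))]
    expect_identical(classify_report(rp$image, shuffled)$type_id,
                     "macula_prev_current")
  }
})

test_that("an undersized image raises a dedicated error", {
  expect_error(classify_report(matrix(1, 20L, 20L), test_catalog()),
               class = "octreport_error_image_too_small")
})
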