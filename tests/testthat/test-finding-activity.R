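# Finding classification on phantoms and longitudinal activity labels.

test_that("baseline finding classifier separates held-out phantoms", {
  model <- baseline_finding_model()
  set.seed(77L)
  correct <- 0L; n <- 0L
  for (i in 1:30) {
    flags <- c(subretinal_fluid = runif(1L) < 0.5,
               macular_edema = runif(1L) < 0.5)
    ph <- render_tomogram_phantom(flags, seed = 90000L + i)
    fr <- classify_finding(ph, model)
    for (v in names(flags)) {
      n <- n + 1L
      correct <- correct + (fr$labels[[v]] == flags[[v]])
    }
    expect_true(all(fr$probabilities >= 0 & fr$probabilities <= 1))
    expect_identical(unname(fr$labels), unname(fr$probabilities >= 0.5))
  }
  expect_gte(correct / n, 0.95)
})

test_that("non-tomogram input is refused", {
  model <- baseline_finding_model()
  txt <- synth_text_image("251", clean_style(), seed = 1L)$image
  expect_error(classify_finding(txt, model),
               class = "octreport_error_not_tomogram")
})

test_that("activity labels reproduce the published worked example", {
  visits <- worked_example_visits()
  labels <- derive_activity(visits)
  expect_identical(labels, visits$activity)
})

test_that("activity rule is Markov in the previous visit", {
  visits <- worked_example_visits()
  full <- derive_activity(visits)
  for (k in 2:nrow(visits)) {
    truncated <- derive_activity(visits[(k - 1L):k, , drop = FALSE])
    expect_identical(truncated[2L], full[k], label = sprintf("visit %d", k))
  }
})

test_that("activity edge cases: single visit, infinite threshold, new finding", {
  one <- worked_example_visits()[1L, , drop = FALSE]
  expect_identical(derive_activity(one), "not_applicable")
  visits <- worked_example_visits()
  inf_lab <- derive_activity(visits, threshold = Inf)
  expect_identical(inf_lab[-1L], rep("stationary", nrow(visits) - 1L))
  # a finding appearing anew forces worsening even with stable CMT
  s <- data.frame(visit_date = c("2020-01-01", "2020-02-01"),
                  central_macular_thickness = c(300, 305),
                  subretinal_fluid = c(FALSE, TRUE))
  expect_identical(derive_activity(s)[2L], "worsening")
  # resolution alone stays stationary
  s2 <- data.frame(visit_date = c("2020-01-01", "2020-02-01"),
                   central_macular_thickness = c(300, 295),
                   subretinal_fluid = c(TRUE, FALSE))
  expect_identical(derive_activity(s2)[2L], "stationary")
})

test_that("unsorted series error and missing-CMT warning", {
  bad <- data.frame(visit_date = c("2020-02-01", "2020-01-01"),
                    central_macular_thickness = c(300, 310))
  expect_error(derive_activity(bad), class = "octreport_error_unsorted_series")
  holes <- data.frame(visit_date = c("2020-01-01", "2020-02-01", "2020-03-01"),
                      central_macular_thickness = c(300, NA, 250))
  warns <- capture_warnings(lab <- derive_activity(holes))
  expect_length(warns, 2L)   # visit 2 lacks CMT; visit 3 lacks a baseline
  expect_match(warns[1L], "activity label skipped")
  expect_identical(lab[1L], "not_applicable")
  expect_true(is.na(lab[2L]))
  expect_true(is.na(lab[3L]))
})
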