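# Accuracy scoring and validation-set sampling.

fake_pair <- function(type_id, truth, raw = truth) {
  truth_l <- as.list(truth)
  pred <- structure(list(raw = as.list(raw)), class = "extracted_record")
  list(pred = pred, truth = list(type_id = type_id, truth = truth_l))
}

test_that("one failure in 300 reports gives the published overall rate", {
  preds <- list(); truths <- list()
  types <- rep(c("rnfl_unilateral", "macula_current", "macula_prev_current"),
               each = 100L)
  for (i in seq_along(types)) {
    truth <- c(v = as.character(i))
    raw <- if (i == 150L) c(v = "999999") else truth   # one macula failure
    fp <- fake_pair(types[i], truth, raw)
    preds[[i]] <- fp$pred; truths[[i]] <- fp$truth
  }
  rep <- score_extraction(preds, truths)
  expect_identical(rep["n_reports", "total"], 300)
  expect_identical(rep["success_rate", "total"], 99.67)
  expect_identical(rep["failure_rate", "total"], 0.33)
  expect_identical(rep["success_rate", "rnfl"], 100)
  expect_identical(rep["success_rate", "macula_current"], 99)
  expect_identical(rep["failure_rate", "macula_current"], 1)
})

test_that("success and failure rates sum to 100 and overall pools counts", {
  set.seed(12L)
  preds <- list(); truths <- list()
  types <- sample(rep(c("rnfl_unilateral", "rnfl_bilateral", "macula_current",
                        "macula_prev_current"), times = c(20, 15, 30, 25)))
  for (i in seq_along(types)) {
    truth <- c(a = as.character(i), b = sprintf("%.2f", runif(1) * 10))
    raw <- truth
    if (runif(1) < 0.2) raw["b"] <- "mangled"
    fp <- fake_pair(types[i], truth, raw)
    preds[[i]] <- fp$pred; truths[[i]] <- fp$truth
  }
  rep <- score_extraction(preds, truths)
  for (cl in colnames(rep)) {
    expect_equal(rep["success_rate", cl] + rep["failure_rate", cl], 100)
    expect_lte(rep["n_success", cl], rep["n_reports", cl])
  }
  expect_identical(rep["n_reports", "total"],
                   sum(unlist(rep["n_reports", -1L])))
  expect_identical(rep["n_success", "total"],
                   sum(unlist(rep["n_success", -1L])))
  # scoring is idempotent and order-symmetric
  perm <- sample(seq_along(preds))
  rep2 <- score_extraction(preds[perm], truths[perm])
  expect_identical(rep["success_rate", "total"], rep2["success_rate", "total"])
})

test_that("identical predictions score 100% everywhere", {
  preds <- list(); truths <- list()
  for (i in 1:30) {
    fp <- fake_pair(c("rnfl_unilateral", "macula_current",
                      "macula_prev_current")[(i %% 3L) + 1L],
                    c(x = as.character(i)))
    preds[[i]] <- fp$pred; truths[[i]] <- fp$truth
  }
  rep <- score_extraction(preds, truths)
  expect_true(all(unlist(rep["success_rate", ]) == 100))
})

test_that("validation-set sampling is seeded, exact and guards sizes", {
  fixtures <- make_fixture_set(
    c("rnfl_unilateral", "rnfl_bilateral", "macula_current",
      "macula_prev_current"), n_per_type = 6L)
  sub <- sample_validation_set(fixtures, n_per_type = 6L, seed = 2L)
  expect_length(sub, 18L)
  cats <- table(vapply(sub, function(f)
    octreport:::.validated_categories[f$type_id], ""))
  expect_true(all(cats == 6L))
  sub2 <- sample_validation_set(fixtures, n_per_type = 6L, seed = 2L)
  expect_identical(vapply(sub, `[[`, "", "patient_id"),
                   vapply(sub2, `[[`, "", "patient_id"))
  expect_error(sample_validation_set(fixtures, n_per_type = 100L, seed = 1L),
               class = "octreport_error_insufficient_fixtures")
})

test_that("mismatched prediction/truth counts are refused", {
  fp <- fake_pair("macula_current", c(v = "1"))
  expect_error(score_extraction(list(fp$pred), list()),
               class = "octreport_error_unmatched_pair")
})
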