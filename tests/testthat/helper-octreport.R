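# Shared fixtures.  Heavy objects (the desk-scale trained recognizer, the
# baseline finding model) are built once per test session and reused.

.helper_cache <- new.env(parent = emptyenv())

test_catalog <- function() {
  if (is.null(.helper_cache$catalog)) .helper_cache$catalog <- default_catalog()
  .helper_cache$catalog
}

# Desk-scale recognizer: 50,000-sample corpus, reduced iteration count.
desk_ocr_model <- function() {
  if (is.null(.helper_cache$model)) {
    corpus <- generate_corpus(corpus_spec(n_total = 50000L, seed = 20260901L))
    .helper_cache$model <- ocr_train(
      corpus, ocr_model_config(),
      train_config(iterations = 4500L, seed = 106L, eval_every = 250L,
                   val_subset = 600L))
    .helper_cache$corpus <- corpus
  }
  .helper_cache$model
}

desk_corpus <- function() {
  desk_ocr_model()
  .helper_cache$corpus
}

baseline_finding_model <- function() {
  if (is.null(.helper_cache$finding)) {
    .helper_cache$finding <- train_finding_classifier(n_phantoms = 240L,
                                                      seed = 42L)
  }
  .helper_cache$finding
}

# The published worked example: one neovascular AMD patient, right eye,
# six printed visits (total macular volume mm3, central macular thickness
# um, subretinal fluid status, expected activity label).
worked_example_visits <- function() {
  data.frame(
    visit_date = c("2013-07-17", "2013-08-27", "2013-10-10",
                   "2016-06-02", "2016-08-19", "2019-08-29"),
    total_macular_volume = c("9.08", "8.21", "8.16", "8.34", "8.29", "8.05"),
    central_macular_thickness = c("364", "251", "218", "236", "238", "189"),
    subretinal_fluid = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    activity = c("not_applicable", "improvement", "stationary",
                 "stationary", "stationary", "stationary"),
    stringsAsFactors = FALSE)
}

render_worked_example_report <- function(visit_row, seed = 1L) {
  layout <- test_catalog()$layouts[["macula_current"]]
  truth <- list(patient_id = "12349876",
                visit_date = visit_row$visit_date,
                laterality = "RIGHT",
                total_macular_volume = visit_row$total_macular_volume,
                central_macular_thickness = visit_row$central_macular_thickness)
  render_report(truth, layout, style = synth_style(noise_sd = 0.015),
                seed = seed,
                finding_flags = c(subretinal_fluid = visit_row$subretinal_fluid,
                                  macular_edema = FALSE))
}

# n random fixtures per type over the given type ids, deterministic.
make_fixture_set <- function(type_ids, n_per_type, seed0 = 500L) {
  out <- list()
  for (ti in seq_along(type_ids)) {
    for (i in seq_len(n_per_type)) {
      out[[length(out) + 1L]] <- random_report(
        type_ids[ti], seed = seed0 + ti * 1000L + i)
    }
  }
  out
}

sidecar_of <- function(report) {
  list(type_id = report$type_id, patient_id = report$patient_id,
       visit_date = report$visit_date, laterality = report$laterality,
       truth = report$truth, finding_flags = report$finding_flags)
}
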