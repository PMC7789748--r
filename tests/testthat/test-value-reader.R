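# Value Reader: recognizer training mechanics, decoding contracts, parsing.

tiny_cfg <- function() {
  list(input_h = 16L, input_w = 32L, conv1 = 2L, conv2 = 3L,
       enc_hidden = 4L, dec_hidden = 5L, emb_dim = 3L, att_dim = 4L,
       loc_channels = 3L, loc_kernel = 3L, charset_size = 5L, max_len = 6L)
}

test_that("analytic gradients match numerical differentiation", {
  cfg <- tiny_cfg()
  params <- ocr_init_params(structure(cfg, class = "ocr_model_config"),
                            seed = 3L)
  set.seed(1L)
  B <- 2L
  X <- matrix(runif(B * cfg$input_h * cfg$input_w), nrow = B)
  targets <- matrix(-1L, 4L, B)
  targets[, 1L] <- c(0L, 3L, 5L, -1L)
  targets[, 2L] <- c(2L, 2L, 1L, 5L)
  lens <- c(3L, 4L)
  res <- .ocr_loss_grad_cpp(params, cfg, X, targets, lens)
  expect_gt(res$loss, 0)
  eps <- 1e-5
  for (nm in c("conv1_W", "conv3b_W", "encf_Wh", "encb_Wx", "emb",
               "att_We", "att_v", "att_Wl", "att_K", "dec_Wx", "out_W")) {
    p <- params[[nm]]
    idx <- sample(length(p), min(4L, length(p)))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- p[i] + eps
      pm <- params; pm[[nm]][i] <- p[i] - eps
      num <- (.ocr_loss_grad_cpp(pp, cfg, X, targets, lens)$loss -
              .ocr_loss_grad_cpp(pm, cfg, X, targets, lens)$loss) / (2 * eps)
      ana <- res$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-3,
                label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training on a tiny corpus reduces the loss and records curves", {
  corpus <- generate_corpus(corpus_spec(n_total = 500L, seed = 8L,
                                        label_kinds = c(integer = 1),
                                        noise_range = c(0, 0.05)))
  model <- ocr_train(corpus,
                     ocr_model_config(conv1 = 3L, conv2 = 6L,
                                      enc_hidden = 12L, dec_hidden = 16L,
                                      emb_dim = 8L, att_dim = 12L),
                     train_config(iterations = 200L, seed = 4L,
                                  eval_every = 50L, val_subset = 40L))
  curves <- model$curves
  expect_identical(nrow(curves), 4L)
  expect_lt(curves$loss[nrow(curves)], curves$loss[1L])
  # best-checkpoint envelope of validation accuracy is non-decreasing
  env <- cummax(curves$val_accuracy)
  expect_true(all(diff(env) >= 0))
})

test_that("invalid training configurations are rejected", {
  expect_error(train_config(batch_size = 0L), class = "octreport_error_schema")
  expect_error(train_config(iterations = 0L), class = "octreport_error_schema")
  empty <- list(train = list(labels = character(0)),
                val = list(labels = character(0)))
  expect_error(ocr_train(empty), class = "octreport_error_empty_corpus")
})

test_that("decoding never emits more than 50 characters", {
  cfg0 <- ocr_model_config(conv1 = 2L, conv2 = 3L, enc_hidden = 4L,
                           dec_hidden = 5L, emb_dim = 3L, att_dim = 4L)
  model <- structure(list(params = ocr_init_params(cfg0, seed = 9L),
                          config = cfg0), class = "ocr_model")
  set.seed(2L)
  for (i in 1:5) {
    crop <- matrix(runif(64L * 400L), 64L, 400L)   # adversarial wide noise
    rec <- recognize(model, crop)
    expect_lte(nchar(rec$text), 50L)
  }
  expect_error(ocr_model_config(max_len = 51L), class = "octreport_error_schema")
})

test_that("recognition of a blank crop yields an empty, low-confidence result", {
  cfg0 <- ocr_model_config(conv1 = 2L, conv2 = 3L, enc_hidden = 4L,
                           dec_hidden = 5L, emb_dim = 3L, att_dim = 4L)
  model <- structure(list(params = ocr_init_params(cfg0, seed = 10L),
                          config = cfg0), class = "ocr_model")
  rec <- recognize(model, matrix(1, 30L, 120L))
  if (rec$text == "") expect_identical(rec$confidence, 0)
  expect_error(recognize(model, matrix(numeric(0), 0L, 0L)),
               class = "octreport_error_empty_crop")
})

test_that("reference recognizer matches printed example values and rejects noise", {
  expect_identical(reference_recognize(
    synth_text_image("9.08", clean_style(), seed = 1L)$image)$text, "9.08")
  expect_identical(reference_recognize(
    synth_text_image("189", clean_style(), seed = 1L)$image)$text, "189")
  heavy <- synth_text_image("123", synth_style(contrast = 0.5,
                                               noise_sd = 0.35), seed = 1L)
  expect_error(reference_recognize(heavy$image),
               class = "octreport_error_recognition_failure")
})

test_that("parse_value types values, honors placeholders and patterns", {
  field <- field_spec("central_macular_thickness", "numeric",
                      c(0L, 0L, 10L, 10L), unit = "µm",
                      pattern = "^-?[0-9]+(\\.[0-9]+)?$")
  m <- parse_value(structure(list(text = "364", confidence = 1),
                             class = "recognition"), field)
  expect_identical(m$value, 364)
  expect_identical(m$unit, "µm")
  miss <- parse_value("--", field)
  expect_true(is.na(miss$value))
  err <- tryCatch(parse_value("3..6", field), octreport_error_parse_error = identity)
  expect_s3_class(err, "octreport_error_parse_error")
  expect_identical(err$raw_text, "3..6")
})

test_that("formatted values round-trip through rendering and parsing", {
  field <- field_spec("v", "numeric", c(0L, 0L, 10L, 10L), unit = "µm")
  set.seed(5L)
  vals <- c(sprintf("%d", sample(1:999, 10L)),
            sprintf("%.2f", runif(10L, 0, 20)))
  for (v in vals) {
    img <- synth_text_image(v, clean_style(), seed = 3L)$image
    rec <- reference_recognize(img)
    m <- parse_value(rec, field)
    expect_identical(m$value, as.numeric(v), label = v)
    expect_identical(m$raw_text, v)
  }
})
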