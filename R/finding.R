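# Pathologic-finding classification on tomogram crops.
#
# The bundled baseline is deliberately small: a fixed, seeded random bank
# of 3x3 convolution filters with ReLU and coarse average pooling feeds a
# per-finding logistic regression trained on phantom renders.  It exists
# to make the pipeline end-to-end testable; any stronger model can be
# plugged in through the same `finding_model` interface (an object with a
# `predict_findings` method returning per-finding probabilities).

.finding_geom <- list(h = 24L, w = 48L, n_filters = 4L, pool = 6L)

# Convolutional feature map for one crop: a box-filter (smoothing) channel
# capturing regional reflectivity plus a small random 3x3 bank capturing
# texture, each average-pooled into block means and flattened.
.finding_features <- function(crop, filters) {
  g <- .finding_geom
  img <- resize_gray(crop, g$h, g$w)
  ph <- g$h %/% g$pool; pw <- g$w %/% g$pool
  pool_of <- function(m) {
    sapply(seq_len(pw), function(j) {
      sapply(seq_len(ph), function(i) {
        mean(m[((i - 1L) * g$pool + 1L):(i * g$pool),
               ((j - 1L) * g$pool + 1L):(j * g$pool)])
      })
    })
  }
  feats <- as.numeric(pool_of(img))          # box-convolution channel
  for (k in seq_len(dim(filters)[3L])) {
    f <- filters[, , k]
    conv <- matrix(0, g$h, g$w)
    for (dy in -1:1) for (dx in -1:1) {
      shifted <- matrix(0, g$h, g$w)
      ys <- max(1, 1 + dy):min(g$h, g$h + dy)
      xs <- max(1, 1 + dx):min(g$w, g$w + dx)
      shifted[ys - dy, xs - dx] <- img[ys, xs]
      conv <- conv + f[dy + 2L, dx + 2L] * shifted
    }
    conv <- pmax(conv, 0)
    feats <- c(feats, as.numeric(pool_of(conv)))
  }
  feats
}

#' Train the baseline finding classifier on tomogram phantoms
#'
#' Per-finding ridge-regularized logistic regressions over the pooled
#' convolutional features (regularization keeps the fit stable with more
#' features than phantoms).
#'
#' @param n_phantoms Number of phantom training images.
#' @param seed Integer seed (filters, phantom draws).
#' @param vocabulary Finding names to model.
#' @return A `finding_model` list.
#' @export
train_finding_classifier <- function(n_phantoms = 240L, seed = 1L,
                                     vocabulary = c("subretinal_fluid",
                                                    "macular_edema")) {
  bad <- setdiff(vocabulary, .known_findings)
  if (length(bad)) {
    stop_octreport("unknown_finding",
                   sprintf("no phantom generator for finding(s): %s",
                           paste(bad, collapse = ", ")))
  }
  with_seed_(seed, {
    g <- .finding_geom
    filters <- array(stats::rnorm(3 * 3 * g$n_filters, 0, 1), c(3L, 3L, g$n_filters))
    flags <- matrix(stats::runif(n_phantoms * length(vocabulary)) < 0.5,
                    n_phantoms, length(vocabulary),
                    dimnames = list(NULL, vocabulary))
    feats <- t(vapply(seq_len(n_phantoms), function(i) {
      ph <- render_tomogram_phantom(flags[i, ], seed = sample.int(1e6, 1L))
      .finding_features(ph, filters)
    }, numeric((g$n_filters + 1L) * (g$h %/% g$pool) * (g$w %/% g$pool))))
    mu <- colMeans(feats)
    sdv <- pmax(apply(feats, 2L, stats::sd), 1e-8)
    fs <- sweep(sweep(feats, 2L, mu), 2L, sdv, "/")
    coefs <- lapply(vocabulary, function(v) {
      fit <- glmnet::glmnet(fs, as.integer(flags[, v]), family = "binomial",
                            alpha = 0, lambda = 0.05, standardize = FALSE)
      as.numeric(stats::coef(fit, s = 0.05))
    })
    names(coefs) <- vocabulary
    structure(list(filters = filters, coefs = coefs, mu = mu, sd = sdv,
                   vocabulary = vocabulary),
              class = "finding_model")
  })
}

#' Classify pathologic findings on a tomogram crop
#'
#' A finding is reported present when its probability reaches 0.5.
#' Deterministic at inference.
#'
#' @param crop A tomogram crop (matrix) or a `routed_region`.
#' @param model A `finding_model` from [train_finding_classifier()].
#' @return A `finding_result`: `labels` (named logical) and
#'   `probabilities` (named numeric in `[0, 1]`).
#' @export
classify_finding <- function(crop, model) {
  if (inherits(crop, "routed_region")) {
    if (crop$content_class != "tomogram") {
      stop_octreport("not_tomogram",
                     sprintf("region '%s' routed as %s, not a tomogram",
                             crop$field$name, crop$content_class))
    }
    crop <- crop$crop
  } else {
    if (.detect_content_class(crop) != "tomogram") {
      stop_octreport("not_tomogram",
                     "input does not look like a tomographic image")
    }
  }
  feats <- (.finding_features(crop, model$filters) - model$mu) / model$sd
  probs <- vapply(model$vocabulary, function(v) {
    cf <- model$coefs[[v]]
    eta <- cf[1L] + sum(cf[-1L] * feats)
    1 / (1 + exp(-eta))
  }, numeric(1L))
  structure(list(labels = probs >= 0.5, probabilities = probs),
            class = "finding_result")
}
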