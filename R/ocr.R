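# Trainable Value Reader: R surface over the compiled recognizer.

# Fixed recognizer input geometry: grayscale crops resized to height 32,
# aspect-preserving width, right-padded with background (or squeezed) to
# width 128.
ocr_input_geometry <- function() list(h = 32L, w = 128L)

#' Recognizer architecture configuration
#'
#' @param charset Characters the decoder may emit.
#' @param conv1,conv2 Channel counts of the two convolution stages (a
#'   residual block runs at `conv2` width).
#' @param enc_hidden Hidden units per direction of the bidirectional LSTM.
#' @param dec_hidden Hidden units of the attention decoder LSTM.
#' @param emb_dim Character embedding dimension.
#' @param att_dim Attention energy dimension.
#' @param loc_channels,loc_kernel Channels and kernel width of the
#'   location-aware attention convolution (the previous alignment is
#'   convolved and fed to the attention scorer, which suppresses the
#'   repeat/skip failure mode of content-only attention on long runs of
#'   identical characters).
#' @param max_len Decoding cap; at most 50 characters are ever emitted.
#' @return An `ocr_model_config` list.
#' @export
ocr_model_config <- function(charset = default_charset(), conv1 = 6L,
                             conv2 = 12L, enc_hidden = 32L, dec_hidden = 64L,
                             emb_dim = 24L, att_dim = 48L, loc_channels = 8L,
                             loc_kernel = 7L, max_len = 50L) {
  if (max_len > 50L) {
    stop_octreport("schema", "max_len may not exceed 50 characters")
  }
  geom <- ocr_input_geometry()
  structure(list(input_h = geom$h, input_w = geom$w,
                 conv1 = as.integer(conv1), conv2 = as.integer(conv2),
                 enc_hidden = as.integer(enc_hidden),
                 dec_hidden = as.integer(dec_hidden),
                 emb_dim = as.integer(emb_dim), att_dim = as.integer(att_dim),
                 loc_channels = as.integer(loc_channels),
                 loc_kernel = as.integer(loc_kernel),
                 charset = charset, charset_size = nchar(charset),
                 max_len = as.integer(max_len)),
            class = "ocr_model_config")
}

#' Training configuration for the recognizer
#'
#' Defaults follow the recognizer's training recipe — batch size 32 and
#' AdaDelta with learning rate 1 and decay rate 0.95 — at desk-scale
#' iteration count; the full-scale 160,000-iteration setting remains
#' selectable.
#'
#' @param batch_size Samples per iteration (>= 1).
#' @param iterations Number of training iterations (>= 1).
#' @param lr AdaDelta learning rate.
#' @param rho AdaDelta decay rate.
#' @param seed Integer seed governing initialization and batch sampling.
#' @param eval_every Iterations between validation evaluations.
#' @param val_subset Maximum validation samples per evaluation.
#' @param clip Global gradient-norm clip.
#' @param verbose Print the learning curve while training.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32L, iterations = 6000L, lr = 1,
                         rho = 0.95, seed = 1L, eval_every = 250L,
                         val_subset = 1500L, clip = 5, verbose = FALSE) {
  if (!is.numeric(batch_size) || batch_size < 1) {
    stop_octreport("schema", "batch_size must be at least 1")
  }
  if (!is.numeric(iterations) || iterations < 1) {
    stop_octreport("schema", "iterations must be at least 1")
  }
  structure(list(batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations), lr = lr, rho = rho,
                 seed = as.integer(seed), eval_every = as.integer(eval_every),
                 val_subset = as.integer(val_subset), clip = clip,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Preprocess a crop to the recognizer input geometry
#'
#' Resize to height 32 preserving aspect; wider results are squeezed to
#' width 128, narrower ones right-padded with the background intensity.
#'
#' @param crop `[y, x]` matrix in `[0, 1]`.
#' @return 32 x 128 matrix in `[0, 1]`.
#' @export
preprocess_crop <- function(crop) {
  if (is.null(dim(crop)) || any(dim(crop) == 0L)) {
    stop_octreport("empty_crop", "crop has zero size")
  }
  geom <- ocr_input_geometry()
  w_new <- max(1L, round(ncol(crop) * geom$h / nrow(crop)))
  if (w_new >= geom$w) {
    out <- resize_gray(crop, geom$h, geom$w)
  } else {
    body <- resize_gray(crop, geom$h, w_new)
    bg <- stats::median(crop[1L, ])            # top edge is background
    out <- matrix(bg, geom$h, geom$w)
    out[, seq_len(w_new)] <- body
  }
  pmin(pmax(out, 0), 1)
}

# charset <-> 0-based class index
charset_chars <- function(charset) strsplit(charset, "")[[1L]]

encode_labels <- function(labels, charset, max_len) {
  chars <- charset_chars(charset)
  K <- length(chars)
  enc <- matrix(-1L, nrow = max_len + 1L, ncol = length(labels))
  lens <- integer(length(labels))
  for (i in seq_along(labels)) {
    idx <- match(strsplit(labels[i], "")[[1L]], chars) - 1L
    if (anyNA(idx)) {
      stop_octreport("charset",
                     sprintf("label '%s' uses characters outside the charset",
                             labels[i]))
    }
    if (length(idx) > max_len) {
      stop_octreport("overlength_label",
                     sprintf("label '%s' exceeds max_len %d", labels[i], max_len))
    }
    enc[seq_along(idx), i] <- idx
    enc[length(idx) + 1L, i] <- K           # EOS
    lens[i] <- length(idx) + 1L
  }
  list(targets = enc, lens = lens)
}

decode_tokens <- function(tokens, charset) {
  chars <- charset_chars(charset)
  apply(tokens, 2L, function(col) {
    col <- col[col >= 0L]
    paste(chars[col + 1L], collapse = "")
  })
}

#' Initialize recognizer parameters
#' @param config An [ocr_model_config()].
#' @param seed Integer seed.
#' @return Named list of parameter matrices.
#' @export
ocr_init_params <- function(config, seed = 1L) {
  with_seed_(seed, {
    he_conv <- function(rows, cols, fan_in) {
      matrix(stats::rnorm(rows * cols, 0, sqrt(2 / fan_in)), rows, cols)
    }
    glorot <- function(rows, cols) {
      r <- sqrt(6 / (rows + cols))
      matrix(stats::runif(rows * cols, -r, r), rows, cols)
    }
    lstm_init <- function(hidden, input) {
      Wx <- glorot(4L * hidden, input)
      Wh <- glorot(4L * hidden, hidden)
      b <- matrix(0, 4L * hidden, 1L)
      b[(hidden + 1L):(2L * hidden), 1L] <- 1   # forget-gate bias
      list(Wx = Wx, Wh = Wh, b = b)
    }
    C1 <- config$conv1; C2 <- config$conv2
    He <- config$enc_hidden; Hd <- config$dec_hidden
    E <- config$emb_dim; A <- config$att_dim; K <- config$charset_size
    D <- C2 * (config$input_h %/% 4L)
    ef <- lstm_init(He, D); eb <- lstm_init(He, D)
    dc <- lstm_init(Hd, E + 2L * He)
    list(
      conv1_W = he_conv(C1, 9L, 9), conv1_b = matrix(0, C1, 1L),
      conv2_W = he_conv(C2, 9L * C1, 9 * C1), conv2_b = matrix(0, C2, 1L),
      conv3a_W = he_conv(C2, 9L * C2, 9 * C2), conv3a_b = matrix(0, C2, 1L),
      conv3b_W = he_conv(C2, 9L * C2, 9 * C2) * 0.1, conv3b_b = matrix(0, C2, 1L),
      encf_Wx = ef$Wx, encf_Wh = ef$Wh, encf_b = ef$b,
      encb_Wx = eb$Wx, encb_Wh = eb$Wh, encb_b = eb$b,
      emb = glorot(K + 1L, E),
      att_We = glorot(A, 2L * He), att_Wd = glorot(A, Hd),
      att_b = matrix(0, A, 1L), att_v = glorot(A, 1L),
      att_Wl = glorot(A, config$loc_channels),
      att_K = glorot(config$loc_channels, config$loc_kernel),
      dec_Wx = dc$Wx, dec_Wh = dc$Wh, dec_b = dc$b,
      out_W = glorot(K + 1L, Hd + 2L * He), out_b = matrix(0, K + 1L, 1L)
    )
  })
}

.cfg_for_cpp <- function(config) {
  config[c("input_h", "input_w", "conv1", "conv2", "enc_hidden", "dec_hidden",
           "emb_dim", "att_dim", "loc_channels", "loc_kernel",
           "charset_size", "max_len")]
}

#' Train the Value Reader recognizer
#'
#' Teacher-forced cross-entropy training with AdaDelta; the checkpoint with
#' the best validation sequence accuracy is returned together with the
#' learning-curve series (iteration, loss, validation accuracy).  The
#' validation subset used for checkpoint selection is the lowest-noise
#' stratum of the validation split: report pages are crisp device renders,
#' so model selection is aligned with that deployment distribution (a
#' random subset is used when the corpus carries no noise annotations).
#'
#' @param corpus Result of [generate_corpus()] (non-empty `train` and `val`).
#' @param model_config An [ocr_model_config()]; its charset must cover the
#'   corpus labels.
#' @param config A [train_config()].
#' @return An `ocr_model`: `params`, `config`, `curves`,
#'   `best_val_accuracy`.
#' @export
ocr_train <- function(corpus, model_config = ocr_model_config(),
                      config = train_config()) {
  if (length(corpus$train$labels) == 0L || length(corpus$val$labels) == 0L) {
    stop_octreport("empty_corpus", "train and validation sets must be non-empty")
  }
  max_lab <- max(nchar(c(corpus$train$labels, corpus$val$labels)))
  tr <- encode_labels(corpus$train$labels, model_config$charset, max_lab)
  va <- encode_labels(corpus$val$labels, model_config$charset, max_lab)
  params <- ocr_init_params(model_config, seed = config$seed)
  val_idx <- integer(0)
  noise <- corpus$val$manifest$noise_sd
  if (!is.null(noise)) {
    # checkpoint-selection subset: low-noise samples of the structured
    # label kinds that occur on report fields (numbers, dates, ids, words)
    kind <- corpus$val$manifest$kind
    eligible <- if (is.null(kind)) seq_along(noise) else which(kind != "mixed")
    take <- min(length(eligible), config$val_subset)
    val_idx <- as.integer(eligible[order(noise[eligible])][seq_len(take)] - 1L)
  }
  fit <- .ocr_train_cpp(params, .cfg_for_cpp(model_config),
                        corpus$train$images, tr$targets, tr$lens,
                        corpus$val$images, va$targets, va$lens,
                        config$iterations, config$batch_size, config$seed,
                        config$eval_every, config$val_subset, config$lr,
                        config$rho, config$clip, config$verbose, val_idx)
  structure(list(params = fit$params, config = model_config,
                 train_config = config, curves = fit$curves,
                 best_val_accuracy = fit$best_val_accuracy),
            class = "ocr_model")
}

#' @export
print.ocr_model <- function(x, ...) {
  cat(sprintf("<ocr_model> charset %d chars, best val accuracy %.4f (%d iterations)\n",
              x$config$charset_size, x$best_val_accuracy,
              x$train_config$iterations))
  invisible(x)
}

#' Recognize text in a cropped region
#'
#' Greedy attention decoding until end-of-sequence, capped at 50
#' characters; deterministic given the model weights.  Confidence is the
#' geometric mean of per-character probabilities (0 for an empty readout).
#'
#' @param model A trained `ocr_model`.
#' @param crop `[y, x]` matrix in `[0, 1]` (or a list of such crops).
#' @param charset Optional string restricting the characters the decoder
#'   may emit (constrained decoding, e.g. digits only for a numeric
#'   field); `NULL` leaves decoding unconstrained.
#' @return A `recognition` list (`text`, `confidence`), or a list of them
#'   when `crop` is a list.
#' @export
recognize <- function(model, crop, charset = NULL) {
  crops <- if (is.list(crop)) crop else list(crop)
  pp <- lapply(crops, preprocess_crop)
  X <- do.call(rbind, lapply(pp, function(m) as.numeric(m)))
  allowed <- if (is.null(charset)) integer(0) else {
    idx <- match(unique(strsplit(charset, "")[[1L]]),
                 charset_chars(model$config$charset)) - 1L
    idx <- idx[!is.na(idx)]
    if (!length(idx)) {
      stop_octreport("charset", "constraint charset shares no characters with the model charset")
    }
    as.integer(idx)
  }
  res <- .ocr_predict_cpp(model$params, .cfg_for_cpp(model$config), X,
                          model$config$max_len, allowed)
  texts <- decode_tokens(res$tokens, model$config$charset)
  out <- lapply(seq_along(texts), function(i) {
    n <- res$lens[i]
    conf <- if (n == 0L) 0 else exp(mean(log(pmax(res$probs[seq_len(n), i], 1e-12))))
    structure(list(text = texts[i], confidence = conf), class = "recognition")
  })
  if (is.list(crop)) out else out[[1L]]
}

#' Save / load a trained recognizer
#' @param model An `ocr_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_ocr_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ocr_model
#' @export
load_ocr_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ocr_model")) {
    stop_octreport("schema", sprintf("'%s' is not an ocr_model checkpoint", path))
  }
  m
}

#' Write learning curves as CSV (iteration, loss, val_accuracy)
#' @param model An `ocr_model`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_learning_curves <- function(model, path) {
  utils::write.csv(model$curves, path, row.names = FALSE)
  invisible(path)
}
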