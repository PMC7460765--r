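# User-facing neural translator API: build, train, translate, save/load.

#' Training configuration for the neural translators
#'
#' Defaults follow the training protocol this package reproduces: batch
#' size 64, 100 epochs, latent dimensionality 256 for both the encoding
#' and decoding space, with 20% of the corpus held out for validation.
#'
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training data.
#' @param latent_dim Width of the embeddings, recurrent states and
#'   convolution channels.
#' @param seed Integer seed driving parameter initialization and epoch
#'   shuffling.
#' @param validation_fraction Fraction of the training corpus monitored
#'   as a validation set during training (0 disables monitoring).
#' @param learning_rate Adam step size.
#' @param clip_norm Global gradient-norm clip.
#' @param verbose Emit a message per epoch.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, epochs = 100L,
                         latent_dim = 256L, seed = 1L,
                         validation_fraction = 0.2,
                         learning_rate = 0.002, clip_norm = 5,
                         verbose = FALSE) {
  stopifnot(batch_size >= 1, epochs >= 0, latent_dim >= 1,
            validation_fraction >= 0, validation_fraction < 1,
            learning_rate > 0, clip_norm > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 latent_dim = as.integer(latent_dim),
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 learning_rate = learning_rate, clip_norm = clip_norm,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

new_translation_model <- function(architecture, vocab, config, params) {
  structure(list(architecture = architecture, vocab = vocab,
                 config = config, params = params,
                 max_source_len = NULL, max_target_len = NULL,
                 history = empty_history(), epochs_trained = 0L),
            class = "translation_model")
}

empty_history <- function() {
  tibble::tibble(epoch = integer(0), loss = numeric(0),
                 accuracy = numeric(0), val_loss = numeric(0),
                 val_accuracy = numeric(0))
}

#' @export
print.translation_model <- function(x, ...) {
  cat(sprintf(
    "<translation_model> %s, latent_dim=%d, %s (%d epochs trained)\n",
    x$architecture, x$config$latent_dim,
    if (x$epochs_trained > 0) "trained" else "untrained",
    x$epochs_trained))
  invisible(x)
}

#' Build an LSTM encoder-decoder translator
#'
#' The encoder turns the input character sequence into two state vectors
#' of width `latent_dim`; the decoder, initialized with those states, is
#' trained by teacher forcing to emit the target sequence offset by one
#' timestep.  Initial parameters are a deterministic function of the
#' configuration seed.
#'
#' @param vocab A `char_vocabulary`.
#' @param config A [train_config()].
#' @return An untrained `translation_model`.
#' @export
build_lstm_translator <- function(vocab, config = train_config()) {
  params <- withr::with_seed(config$seed, {
    lstm_init_params(vocab_size(vocab, "source"),
                     vocab_size(vocab, "target"),
                     config$latent_dim, config$latent_dim)
  })
  new_translation_model("LSTM", vocab, config, params)
}

#' Build a convolutional translator with attention
#'
#' Three one-dimensional convolution layers encode the source sequence;
#' three causal one-dimensional convolution layers process the offset
#' target sequence; scaled dot-product attention combines the two
#' streams; two further causal convolution layers and a softmax head
#' emit the per-step character distribution.
#'
#' @inheritParams build_lstm_translator
#' @return An untrained `translation_model`.
#' @export
build_cnn_translator <- function(vocab, config = train_config()) {
  params <- withr::with_seed(config$seed, {
    cnn_init_params(vocab_size(vocab, "source"),
                    vocab_size(vocab, "target"),
                    config$latent_dim, config$latent_dim)
  })
  new_translation_model("CNN", vocab, config, params)
}

model_loss_fn <- function(architecture) {
  switch(architecture, LSTM = lstm_loss_and_grads,
         CNN = cnn_loss_and_grads,
         stop("unknown architecture: ", architecture, call. = FALSE))
}

# assert the teacher-forcing shift on a batch before it reaches a model
check_teacher_forcing <- function(batch, vocab) {
  sp <- vocab_special(vocab, "target")
  Tn <- ncol(batch$decoder_input)
  shifted <- batch$decoder_input[, -1L, drop = FALSE]
  ref <- batch$decoder_target[, -Tn, drop = FALSE]
  live <- shifted != sp$pad
  if (!all(shifted[live] == ref[live]) ||
      !all(batch$decoder_input[, 1L] == sp$sos)) {
    stop("encoded batch violates the teacher-forcing offset invariant",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Train a neural translator
#'
#' Teacher-forced minibatch training with Adam and per-step
#' cross-entropy, pad positions masked.  Shuffling and initialization
#' are governed by the configuration seed; with `epochs = 0` the model
#' is returned untouched with an empty history.  All corpus characters
#' must be covered by the model's vocabulary (checked up front).
#'
#' @param model An untrained or previously trained `translation_model`.
#' @param corpus A `parallel_corpus` of training pairs.
#' @param config Optional [train_config()] overriding the model's.
#' @return The trained `translation_model`, with per-epoch `history`.
#' @export
train <- function(model, corpus, config = NULL) {
  if (!is.null(config)) model$config <- config
  cfg <- model$config
  full <- encode_batch(corpus, model$vocab)   # OOV check happens here
  model$max_source_len <- ncol(full$encoder_input)
  model$max_target_len <- ncol(full$decoder_input) - 1L
  if (cfg$epochs == 0L) {
    model$history <- empty_history()
    return(model)
  }
  n <- nrow(corpus)
  loss_fn <- model_loss_fn(model$architecture)
  hdim <- cfg$latent_dim
  withr::with_seed(cfg$seed + 1L, {
    n_val <- floor(n * cfg$validation_fraction)
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    state <- adam_state()
    hist <- vector("list", cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      losses <- c()
      accs <- c()
      wts <- c()
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        batch <- slice_batch(full, idx)
        check_teacher_forcing(batch, model$vocab)
        res <- loss_fn(model$params, batch, model$vocab, hdim)
        grads <- clip_gradients(res$grads, cfg$clip_norm)
        model$params <- adam_update(model$params, grads, state,
                                    cfg$learning_rate)
        losses <- c(losses, res$loss)
        accs <- c(accs, res$accuracy)
        wts <- c(wts, length(idx))
      }
      val_loss <- NA_real_
      val_acc <- NA_real_
      if (n_val > 0) {
        vres <- loss_fn(model$params, slice_batch(full, val_idx),
                        model$vocab, hdim, compute_grads = FALSE)
        val_loss <- vres$loss
        val_acc <- vres$accuracy
      }
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch + model$epochs_trained,
        loss = stats::weighted.mean(losses, wts),
        accuracy = stats::weighted.mean(accs, wts),
        val_loss = val_loss, val_accuracy = val_acc)
      if (cfg$verbose) {
        message(sprintf(
          "epoch %d/%d  loss %.4f  acc %.4f  val_acc %.4f",
          epoch, cfg$epochs, hist[[epoch]]$loss, hist[[epoch]]$accuracy,
          val_acc))
      }
    }
    model$history <- rbind(model$history, do.call(rbind, hist))
    model$epochs_trained <- model$epochs_trained + cfg$epochs
  })
  model
}

slice_batch <- function(full, idx) {
  list(encoder_input = full$encoder_input[idx, , drop = FALSE],
       decoder_input = full$decoder_input[idx, , drop = FALSE],
       decoder_target = full$decoder_target[idx, , drop = FALSE])
}

default_max_output_len <- function(model) {
  if (!is.null(model$max_target_len)) model$max_target_len + 10L else 40L
}

#' Translate names with a neural translator
#'
#' Greedy decoding: starting from the start symbol, the most probable
#' character is emitted at each step until the end symbol or the length
#' bound.  Inputs containing characters outside the source vocabulary
#' never raise an error; they yield unsuccessful results tagged
#' `oov_character`, which is what caps a neural translator's success
#' rate below 100% only when unseen characters occur.
#'
#' @param model A `translation_model` (untrained models produce
#'   arbitrary but well-formed output).
#' @param names Character vector of input names.
#' @param max_output_len Decoding step bound; defaults to the longest
#'   training target plus 10.
#' @return A `translation_results` tibble, one row per input.
#' @export
translate_batch <- function(model, names, max_output_len = NULL) {
  if (is.null(max_output_len)) max_output_len <- default_max_output_len(model)
  names <- normalize_name(names)
  n <- length(names)
  output <- rep(NA_character_, n)
  reason <- rep("oov_character", n)
  known <- c(model$vocab$source_chars)
  in_vocab <- vapply(strsplit(names, "", fixed = TRUE),
                     function(ch) all(ch %in% known), logical(1))
  if (any(in_vocab)) {
    idx <- which(in_vocab)
    pairs <- tibble::tibble(source = names[idx], target = "x")
    # dummy targets: only the encoder input is used for decoding
    pairs$target <- strrep(model$vocab$target_chars[1], 1L)
    enc <- encode_batch(pairs, model$vocab)
    decode <- switch(model$architecture, LSTM = lstm_greedy_decode,
                     CNN = cnn_greedy_decode)
    out_mat <- decode(model$params, enc$encoder_input, model$vocab,
                      model$config$latent_dim, max_output_len)
    output[idx] <- decode_indices(out_mat, model$vocab, "target")
    reason[idx] <- "none"
  }
  translation_results(names, output, in_vocab, reason)
}

#' @rdname translate_batch
#' @param name A single input name.
#' @export
translate <- function(model, name, max_output_len = NULL) {
  translate_batch(model, name, max_output_len = max_output_len)
}

#' Save a neural translator checkpoint
#'
#' Writes a checkpoint directory: vocabulary and configuration as JSON,
#' the architecture tag, training history as CSV, and the parameter
#' arrays.  [load_translator()] restores a model whose predictions are
#' identical to the saved one.
#'
#' @param model A `translation_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_translator <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vocabulary(model$vocab, file.path(dir, "vocabulary.json"))
  jsonlite::write_json(
    c(unclass(model$config),
      list(architecture = model$architecture,
           max_source_len = model$max_source_len,
           max_target_len = model$max_target_len,
           epochs_trained = model$epochs_trained)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' Load a neural translator checkpoint
#' @param dir Directory written by [save_translator()].
#' @return A `translation_model`.
#' @export
load_translator <- function(dir) {
  cfgj <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  vocab <- read_vocabulary(file.path(dir, "vocabulary.json"))
  config <- train_config(batch_size = cfgj$batch_size,
                         epochs = cfgj$epochs,
                         latent_dim = cfgj$latent_dim, seed = cfgj$seed,
                         validation_fraction = cfgj$validation_fraction,
                         learning_rate = cfgj$learning_rate,
                         clip_norm = cfgj$clip_norm,
                         verbose = cfgj$verbose)
  model <- new_translation_model(cfgj$architecture, vocab, config,
                                 readRDS(file.path(dir, "params.rds")))
  if (!is.null(cfgj$max_source_len)) {
    model$max_source_len <- cfgj$max_source_len
    model$max_target_len <- cfgj$max_target_len
  }
  model$epochs_trained <- cfgj$epochs_trained
  hist_path <- file.path(dir, "history.csv")
  if (file.exists(hist_path)) {
    h <- utils::read.csv(hist_path)
    if (nrow(h) > 0) model$history <- tibble::as_tibble(h)
  }
  model
}
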