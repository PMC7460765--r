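# Neural translator mechanisms: seeded builds, architecture shape,
# causality, analytic gradients, training loop behavior, greedy
# decoding and checkpointing.

small_vocab <- function() build_vocabulary(tiny_corpus())

test_that("builds are deterministic in the seed and sized by latent_dim", {
  v <- small_vocab()
  cfg <- train_config(latent_dim = 16L, seed = 7L)
  m1 <- build_lstm_translator(v, cfg)
  m2 <- build_lstm_translator(v, cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_lstm_translator(v, train_config(latent_dim = 16L, seed = 8L))
  expect_false(identical(m1$params, m3$params))
  # encoder emits two state vectors of width latent_dim
  expect_equal(dim(m1$params$enc_U), c(16L, 64L))
  batch <- encode_batch(tiny_corpus(), v)
  enc <- chemnmt:::lstm_run(batch$encoder_input, m1$params$Es,
                            m1$params$enc_W, m1$params$enc_U,
                            m1$params$enc_b,
                            chemnmt:::vocab_special(v, "source")$pad,
                            matrix(0, 3, 16), matrix(0, 3, 16))
  expect_equal(dim(enc$h), c(3L, 16L))
  expect_equal(dim(enc$c), c(3L, 16L))
  c1 <- build_cnn_translator(v, cfg)
  c2 <- build_cnn_translator(v, cfg)
  expect_identical(c1$params, c2$params)
  expect_error(train_config(latent_dim = 0), "latent_dim")
})

test_that("the convolutional model has 3 + 3 + 2 convolution layers", {
  v <- small_vocab()
  m <- build_cnn_translator(v, train_config(latent_dim = 8L))
  layers <- chemnmt:::cnn_layer_names()
  expect_equal(layers, c("enc1", "enc2", "enc3", "dec1", "dec2", "dec3",
                         "out1", "out2"))
  for (nm in layers) {
    expect_true(all(paste0(nm, c("_W1", "_W2", "_W3", "_b")) %in%
                      names(m$params)))
  }
})

test_that("untrained models emit well-formed per-step distributions", {
  v <- small_vocab()
  batch <- encode_batch(tiny_corpus(), v)
  for (arch in c("LSTM", "CNN")) {
    cfg <- train_config(latent_dim = 12L, seed = 2L)
    m <- if (arch == "LSTM") build_lstm_translator(v, cfg)
         else build_cnn_translator(v, cfg)
    logits <- if (arch == "LSTM") {
      hp <- m$params
      h0 <- matrix(0, 3, 12)
      enc <- chemnmt:::lstm_run(batch$encoder_input, hp$Es, hp$enc_W,
                                hp$enc_U, hp$enc_b,
                                chemnmt:::vocab_special(v, "source")$pad,
                                h0, h0)
      dec <- chemnmt:::lstm_run(batch$decoder_input, hp$Et, hp$dec_W,
                                hp$dec_U, hp$dec_b,
                                chemnmt:::vocab_special(v, "target")$pad,
                                enc$h, enc$c)
      sweep(do.call(rbind, dec$hs) %*% hp$Wo, 2, hp$bo, "+")
    } else {
      chemnmt:::cnn_forward(m$params, batch$encoder_input,
                            batch$decoder_input, v, 12L)$logits
    }
    p <- chemnmt:::row_softmax(logits)
    expect_equal(ncol(p), length(v$target_all))
    expect_true(all(abs(rowSums(p) - 1) < 1e-5))
  }
})

test_that("target-side convolutions are causal under perturbation", {
  v <- small_vocab()
  m <- build_cnn_translator(v, train_config(latent_dim = 10L, seed = 5L))
  batch <- encode_batch(tiny_corpus(), v)
  base <- chemnmt:::cnn_forward(m$params, batch$encoder_input,
                                batch$decoder_input, v, 10L)$logits
  B <- nrow(batch$decoder_input)
  Tu <- ncol(batch$decoder_input)
  withr::with_seed(3, {
    for (t0 in 2:Tu) {
      pert <- batch$decoder_input
      pert[, t0] <- sample(length(v$target_all), B, replace = TRUE)
      out <- chemnmt:::cnn_forward(m$params, batch$encoder_input, pert,
                                   v, 10L)$logits
      # rows of steps strictly before t0 are untouched
      before <- seq_len((t0 - 1L) * B)
      expect_lt(max(abs(out[before, ] - base[before, ])), 1e-6)
    }
  })
})

test_that("analytic gradients match numerical differentiation", {
  co <- parallel_corpus(c("ab", "ba", "aab"), c("xy", "yx", "xxy"))
  v <- build_vocabulary(co)
  batch <- encode_batch(co, v)
  for (arch in c("LSTM", "CNN")) {
    cfg <- train_config(latent_dim = 5L, seed = 3L)
    m <- if (arch == "LSTM") build_lstm_translator(v, cfg)
         else build_cnn_translator(v, cfg)
    fn <- chemnmt:::model_loss_fn(arch)
    res <- fn(m$params, batch, v, 5L)
    withr::with_seed(9, {
      for (nm in names(m$params)) {
        for (rep in 1:3) {
          i <- sample(length(m$params[[nm]]), 1)
          eps <- 1e-5
          p1 <- m$params
          p1[[nm]][i] <- p1[[nm]][i] + eps
          p2 <- m$params
          p2[[nm]][i] <- p2[[nm]][i] - eps
          num <- (fn(p1, batch, v, 5L, compute_grads = FALSE)$loss -
                    fn(p2, batch, v, 5L, compute_grads = FALSE)$loss) /
            (2 * eps)
          ana <- res$grads[[nm]][i]
          if (abs(num) + abs(ana) > 1e-10) {
            expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4)
          }
        }
      }
    })
  }
})

test_that("training with zero epochs is a no-op with empty history", {
  v <- small_vocab()
  m <- build_lstm_translator(v, train_config(latent_dim = 8L,
                                             epochs = 0L))
  trained <- train(m, tiny_corpus())
  expect_identical(trained$params, m$params)
  expect_equal(nrow(trained$history), 0L)
})

test_that("training reduces loss and records a per-epoch history", {
  co <- generate_corpus(default_grammar(), 12, seed = 19)
  v <- build_vocabulary(co)
  cfg <- train_config(batch_size = 12L, epochs = 40L, latent_dim = 24L,
                      seed = 1L, validation_fraction = 0.25,
                      learning_rate = 0.01)
  m <- train(build_lstm_translator(v, cfg), co)
  expect_equal(nrow(m$history), 40L)
  expect_lt(tail(m$history$loss, 1), head(m$history$loss, 1) / 2)
  expect_false(anyNA(m$history$val_loss))
  # training twice from the same seed is identical
  m2 <- train(build_lstm_translator(v, cfg), co)
  expect_identical(m$params, m2$params)
})

test_that("training refuses corpora outside the model vocabulary", {
  v <- small_vocab()
  m <- build_lstm_translator(v, train_config(latent_dim = 8L))
  expect_error(train(m, parallel_corpus("benzene", "苯")),
               "out-of-vocabulary")
})

test_that("teacher-forcing violations are caught before training", {
  v <- small_vocab()
  batch <- encode_batch(tiny_corpus(), v)
  expect_true(chemnmt:::check_teacher_forcing(batch, v))
  broken <- batch
  broken$decoder_input[1, 1] <- 1L  # not the start symbol
  expect_error(chemnmt:::check_teacher_forcing(broken, v),
               "teacher-forcing")
})

test_that("greedy decoding terminates, is bounded and flags OOV inputs", {
  v <- small_vocab()
  for (arch in c("LSTM", "CNN")) {
    cfg <- train_config(latent_dim = 8L, seed = 4L)
    m <- if (arch == "LSTM") build_lstm_translator(v, cfg)
         else build_cnn_translator(v, cfg)
    res <- translate_batch(m, c("methanol", "hexane"),
                           max_output_len = 5L)
    expect_true(all(res$succeeded))          # untrained but well-formed
    expect_true(all(nchar(res$output) <= 5))
    oov <- translate(m, "benzene")           # 'z' unseen
    expect_false(oov$succeeded)
    expect_equal(oov$failure_reason, "oov_character")
    expect_true(is.na(oov$output))
  }
})

test_that("checkpoints restore prediction-identical models", {
  co <- generate_corpus(default_grammar(), 10, seed = 3)
  v <- build_vocabulary(co)
  cfg <- train_config(batch_size = 10L, epochs = 15L, latent_dim = 16L,
                      seed = 2L, validation_fraction = 0,
                      learning_rate = 0.01)
  for (arch in c("LSTM", "CNN")) {
    m <- if (arch == "LSTM") build_lstm_translator(v, cfg)
         else build_cnn_translator(v, cfg)
    m <- train(m, co)
    dir <- withr::local_tempdir()
    save_translator(m, dir)
    m2 <- load_translator(dir)
    expect_identical(m2$params, m$params)
    expect_identical(translate_batch(m2, co$source),
                     translate_batch(m, co$source))
    expect_equal(m2$max_target_len, m$max_target_len)
  }
})
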