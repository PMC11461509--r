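test_that("training configuration enforces its invariants", {
  expect_error(pk_train_config(epochs = 0), class = "pkner_config")
  expect_error(pk_train_config(dropout = 1), class = "pkner_config")
  expect_error(pk_train_config(max_sequence_length = 4), class = "pkner_config")
  cfg <- pk_train_config()
  expect_equal(cfg$epochs, 20L)
  expect_equal(cfg$batch_size, 16L)
  expect_equal(cfg$learning_rate, 3e-5)
  expect_equal(cfg$weight_decay, 0.05)
  expect_equal(cfg$dropout, 0.1)
  expect_equal(cfg$max_sequence_length, 256L)
})

test_that("the linear tagger memorises a small consistent training set", {
  train <- small_train_corpus(n = 80, seed = 501)
  model <- quiet_train(train, config = pk_train_config(epochs = 15, seed = 1))
  ev <- evaluate_corpus(train, predict(model, train))
  expect_equal(ev$strict$f1, 100)
})

test_that("same-seed training is bit-reproducible, different seeds differ", {
  train <- small_train_corpus(n = 60, seed = 502)
  held <- small_test_corpus(n = 40, seed = 503)
  m1 <- quiet_train(train, config = pk_train_config(epochs = 5, seed = 9))
  m2 <- quiet_train(train, config = pk_train_config(epochs = 5, seed = 9))
  expect_identical(m1$W, m2$W)
  p1 <- predict(m1, held); p2 <- predict(m2, held)
  expect_identical(lapply(p1$sentences, `[[`, "spans"),
                   lapply(p2$sentences, `[[`, "spans"))
})

test_that("development-set selection records a full history and picks the argmax", {
  train <- small_train_corpus(n = 80, seed = 504)
  dev <- small_train_corpus(n = 40, seed = 505)
  model <- quiet_train(train, dev, config = pk_train_config(epochs = 6, seed = 2))
  expect_length(model$dev_history, 6L)
  expect_false(anyNA(model$dev_history))
  expect_equal(model$best_epoch, which.max(model$dev_history))
  expect_equal(model$dev_f1, max(model$dev_history))
  expect_gte(model$dev_history[model$best_epoch], model$dev_history[1])
  # without a dev corpus the final epoch is kept and a message says so
  expect_message(m2 <- suppressWarnings(
    train_tagger(train, config = pk_train_config(epochs = 3, seed = 2))
  ), "final epoch")
  expect_equal(m2$best_epoch, 3L)
  expect_true(all(is.na(m2$dev_history)))
})

test_that("a corpus without entity mentions trains with a degenerate-data warning", {
  blank <- generate_corpus(generator_config(n_sentences = 20, prevalence = 0, seed = 1))
  expect_warning(
    suppressMessages(train_tagger(blank, config = pk_train_config(epochs = 2, seed = 1))),
    "zero entity mentions"
  )
})

test_that("decoding never emits BIO-invalid sequences", {
  train <- small_train_corpus(n = 80, seed = 506)
  model <- quiet_train(train, config = pk_train_config(epochs = 3, seed = 4))
  held <- small_test_corpus(n = 150, seed = 507)
  expect_true(all_predictions_bio_valid(model, held))
  # also under an adversarial encoder that loves I- labels
  enc <- encoder_tagger(function(toks) {
    matrix(rep(c(0, 0, 5), each = length(toks)), nrow = length(toks))
  })
  for (txt in c("one two three", "CL was 5")) {
    tk <- pk_tokenize(txt)
    tags <- spans_to_bio(tk, predict(enc, txt), policy = "snap")
    expect_true(is_bio_valid(tags))
  }
})

test_that("the C++ decoder matches the reference R decoder", {
  set.seed(31)
  labels <- c("O", "B-PK", "I-PK")
  masks <- pkner:::transition_masks(labels)
  for (rep in 1:25) {
    T <- sample(1:12, 1)
    n_feat <- 30L
    W <- matrix(rnorm(n_feat * 3), n_feat, 3)
    ids <- sample(0:n_feat, T * 4L, replace = TRUE)
    ptr <- 4L * (0:T)
    S <- pkner:::cpp_scores(W, as.integer(ids), as.integer(ptr))
    got <- labels[pkner:::cpp_decode(W, as.integer(ids), as.integer(ptr),
                                     masks$allowed, masks$start_ok)]
    want <- pkner:::decode_greedy_scores(S, labels, masks)
    expect_identical(got, want)
  }
})

test_that("empty input predicts no spans", {
  train <- small_train_corpus(n = 40, seed = 508)
  model <- quiet_train(train, config = pk_train_config(epochs = 2, seed = 1))
  expect_equal(nrow(predict(model, "")), 0L)
  expect_equal(uncertainty(model, ""), 0)
})

test_that("long sentences are chunked and re-joined without splitting entities", {
  # deterministic encoder: B/I scores keyed on the entity's surface tokens
  labels <- c("O", "B-PK", "I-PK")
  enc <- encoder_tagger(function(toks) {
    S <- matrix(0, length(toks), 3)
    S[, 1] <- 1
    S[toks == "total", ] <- c(0, 5, 0)[col(S)[toks == "total", , drop = FALSE]]
    S[toks %in% c("body", "clearance"), 1] <- -5
    S[toks %in% c("body", "clearance"), 3] <- 5
    S
  }, config = pk_train_config(max_sequence_length = 16))
  filler <- rep("alpha", 30)
  for (pos in c(14, 15, 16)) {  # entity straddles the 16-token chunk cut
    toks <- filler
    toks <- append(toks, c("total", "body", "clearance"), after = pos)
    text <- paste(toks, collapse = " ")
    sp <- predict(enc, text)
    expect_equal(nrow(sp), 1L)
    expect_equal(substring(text, sp$start + 1, sp$end), "total body clearance")
  }
})

test_that("linear-backend chunked prediction equals unchunked on long input", {
  train <- small_train_corpus(n = 60, seed = 509)
  m_short <- quiet_train(train, config = pk_train_config(epochs = 3, seed = 5,
                                                         max_sequence_length = 16))
  m_full <- m_short
  m_full$config$max_sequence_length <- 1024L
  long_text <- paste(rep("Blood samples were collected over 24 h and", 40), collapse = " ")
  expect_identical(predict(m_short, long_text), predict(m_full, long_text))
})

test_that("uncertainty is the mean softmax margin complement", {
  # one-hot-confident scorer: uncertainty ~ 0
  sharp <- encoder_tagger(function(toks) {
    S <- matrix(0, length(toks), 3); S[, 1] <- 1000; S
  })
  expect_lt(uncertainty(sharp, "a b c d"), 1e-6)
  # uniform scores over three labels: uncertainty exactly 1
  flat <- encoder_tagger(function(toks) matrix(1, length(toks), 3))
  expect_equal(uncertainty(flat, "a b c d"), 1)
  # bounded in [0, 1] across random score matrices
  set.seed(77)
  for (rep in 1:2000) {
    S <- matrix(rnorm(3 * sample(1:8, 1), sd = 3), ncol = 3)
    u <- pkner:::uncertainty_from_scores(S)
    expect_gte(u, 0); expect_lte(u, 1)
  }
  # and on real model scores over generated text
  train <- small_train_corpus(n = 40, seed = 510)
  model <- quiet_train(train, config = pk_train_config(epochs = 2, seed = 1))
  u <- uncertainty(model, small_test_corpus(n = 60, seed = 511))
  expect_true(all(u >= 0 & u <= 1))
})

test_that("model archives round-trip and reject corrupt or foreign files", {
  train <- small_train_corpus(n = 50, seed = 512)
  model <- quiet_train(train, config = pk_train_config(epochs = 3, seed = 8))
  path <- withr::local_tempfile(fileext = ".pkn")
  save_tagger(model, path)
  back <- load_tagger(path)
  held <- small_test_corpus(n = 40, seed = 513)
  expect_identical(lapply(predict(back, held)$sentences, `[[`, "spans"),
                   lapply(predict(model, held)$sentences, `[[`, "spans"))
  # provenance survives
  expect_identical(back$config, model$config)
  expect_identical(back$best_epoch, model$best_epoch)
  # truncated archive -> integrity error, not silent misprediction
  raw_bytes <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw_bytes[1:40], path)
  expect_error(load_tagger(path), class = "pkner_integrity")
  # RDS that is not a tagger archive
  saveRDS(list(a = 1), path)
  expect_error(load_tagger(path), class = "pkner_integrity")
})

test_that("the encoder contract validates scorer output dimensions", {
  bad <- encoder_tagger(function(toks) matrix(0, 2, 2))
  expect_error(predict(bad, "one two three"), class = "pkner_encoder")
  expect_error(encoder_tagger("not a function"))
  # coefficients only exist for the linear backend
  enc <- encoder_tagger(function(toks) matrix(0, length(toks), 3))
  expect_error(coef(enc), class = "pkner_config")
})
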