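#' Training configuration for the sequence tagger
#'
#' The defaults carry the transformer fine-tuning recipe used for PK NER:
#' 20 epochs, batch size 16, learning rate 3e-5, linear weight decay 0.05,
#' dropout 0.1, maximum sequence length 256 tokens, with the model state
#' selected by entity-level strict F1 on the development set at the end of
#' each epoch. The linear (averaged-perceptron) backend consumes `epochs`,
#' `max_sequence_length` and `seed` and records the rest as provenance for
#' encoder backends; `learning_rate`, `weight_decay`, `dropout` and
#' `batch_size` parameterise an encoder plugged in via [encoder_tagger()].
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size for encoder backends.
#' @param learning_rate optimiser step size for encoder backends.
#' @param weight_decay linear weight-decay coefficient.
#' @param dropout dropout probability in `[0, 1)`.
#' @param max_sequence_length token cap per decoded chunk (>= 8). Longer
#'   sentences are split and re-joined at prediction time.
#' @param seed integer seed; linear-backend training is deterministic given
#'   the seed.
#' @return an object of class `pk_train_config`.
#' @export
pk_train_config <- function(epochs = 20L, batch_size = 16L, learning_rate = 3e-5,
                            weight_decay = 0.05, dropout = 0.1,
                            max_sequence_length = 256L, seed = 1L) {
  if (epochs < 1L) stop_pkner("epochs must be >= 1", class = "pkner_config")
  if (dropout < 0 || dropout >= 1) stop_pkner("dropout must lie in [0, 1)", class = "pkner_config")
  if (max_sequence_length < 8L) {
    stop_pkner("max_sequence_length must be >= 8", class = "pkner_config")
  }
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, weight_decay = weight_decay,
    dropout = dropout, max_sequence_length = as.integer(max_sequence_length),
    selection_metric = "strict_f1_dev", seed = as.integer(seed)
  ), class = "pk_train_config")
}

bio_alphabet <- function(entity_labels) {
  entity_labels <- sort(unique(entity_labels))
  c("O", as.vector(rbind(paste0("B-", entity_labels), paste0("I-", entity_labels))))
}

# allowed[prev, cur] and start_ok[cur]: I-X only after B-X/I-X, never at start.
transition_masks <- function(labels) {
  L <- length(labels)
  allowed <- matrix(TRUE, L, L)
  start_ok <- rep(TRUE, L)
  info <- lapply(labels, parse_bio_tag)
  for (cur in seq_len(L)) {
    if (info[[cur]]$prefix == "I") {
      start_ok[cur] <- FALSE
      for (prev in seq_len(L)) {
        ok <- info[[prev]]$prefix %in% c("B", "I") &&
          identical(info[[prev]]$label, info[[cur]]$label)
        allowed[prev, cur] <- ok
      }
    }
  }
  list(allowed = allowed, start_ok = start_ok)
}

entity_labels_of <- function(corpus) {
  labs <- unlist(lapply(corpus$sentences, function(s) s$spans$label))
  unique(labs)
}

#' Train a BIO sequence tagger
#'
#' The reference backend is a structured averaged perceptron over windowed
#' lexical/shape features with transition-constrained greedy decoding:
#' CPU-only, seconds to train at desk scale, and deterministic given
#' `config$seed`. After every epoch the model is evaluated on the development
#' corpus (entity-level strict F1) and the state of the best epoch is kept;
#' without a development corpus the final epoch is kept (a message says so).
#'
#' @param train_corpus a [pk_corpus()] with gold spans; must be non-empty.
#' @param dev_corpus optional development [pk_corpus()] for model selection.
#' @param config a [pk_train_config()].
#' @param lexicon character vector of lowercased in-domain tokens for the
#'   lexicon feature; defaults to the [default_inventory()] token inventory.
#' @param vocab optional fixed feature vocabulary (character); defaults to
#'   the features observed in `train_corpus`. Supplying a larger vocabulary
#'   (e.g. covering an unlabelled pool) lets later retrainings share feature
#'   ids.
#' @return an object of class `pk_tagger` with, among others, the selected
#'   weights, the label alphabet, the per-epoch development F1 history and
#'   training provenance (config, seed, best epoch).
#' @seealso [predict.pk_tagger()], [uncertainty()], [save_tagger()]
#' @export
train_tagger <- function(train_corpus, dev_corpus = NULL, config = pk_train_config(),
                         lexicon = NULL, vocab = NULL) {
  stopifnot(inherits(train_corpus, "pk_corpus"))
  if (length(train_corpus) == 0L) {
    stop_pkner("training corpus is empty", class = "pkner_config")
  }
  lexicon <- lexicon %||% inventory_lexicon()
  ents <- entity_labels_of(train_corpus)
  if (!length(ents)) {
    warning("training corpus contains zero entity mentions; the tagger will be degenerate",
            call. = FALSE)
    ents <- "PK"
  }
  labels <- bio_alphabet(ents)
  ftr <- featurize_corpus(train_corpus, lexicon)
  vocab <- vocab %||% unique(unlist(ftr$flat, use.names = FALSE))
  train_data <- list(
    ids = features_to_ids(ftr$flat, vocab),
    ptr = ftr$ptr,
    gold = lapply(ftr$tags, function(tg) match(tg, labels))
  )
  if (anyNA(unlist(train_data$gold, use.names = FALSE))) {
    stop_pkner("training tags outside the label alphabet", class = "pkner_validation")
  }
  dev <- NULL
  if (!is.null(dev_corpus) && length(dev_corpus) > 0L) {
    dftr <- featurize_corpus(dev_corpus, lexicon)
    dev <- list(ids = features_to_ids(dftr$flat, vocab), ptr = dftr$ptr,
                tokens = dftr$tokens, corpus = dev_corpus)
  }
  train_core(train_data, labels, vocab, lexicon, config, dev)
}

# Epoch loop over pre-featurised data; shared by train_tagger() and the
# active-learning loop (which caches feature ids across retrainings).
train_core <- function(train_data, labels, vocab, lexicon, config, dev = NULL) {
  masks <- transition_masks(labels)
  L <- length(labels); n_feat <- length(vocab); n_sent <- length(train_data$ids)
  W <- matrix(0, n_feat, L); Wa <- matrix(0, n_feat, L)
  tcount <- 1.0
  history <- numeric(config$epochs)
  best_f1 <- -Inf; best_W <- NULL; best_epoch <- NA_integer_
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n_sent)
      tcount <- cpp_train_epoch(W, Wa, tcount, train_data$ids, train_data$ptr,
                                train_data$gold, ord, masks$allowed, masks$start_ok)
      W_avg <- W - Wa / tcount
      if (!is.null(dev)) {
        f1 <- dev_strict_f1(W_avg, dev, labels, masks, config$max_sequence_length)
        history[ep] <- f1
        if (f1 > best_f1) { best_f1 <- f1; best_W <- W_avg; best_epoch <- ep }
      } else {
        history[ep] <- NA_real_
        best_W <- W_avg; best_epoch <- ep
      }
    }
  })
  if (is.null(dev)) {
    message("no development corpus supplied; keeping the final epoch")
  }
  structure(list(
    backend = "linear", labels = labels, vocab = vocab, W = best_W,
    lexicon = lexicon, config = config, dev_history = history,
    best_epoch = best_epoch, dev_f1 = if (is.null(dev)) NA_real_ else best_f1,
    n_train = n_sent, version = 1L
  ), class = "pk_tagger")
}

dev_strict_f1 <- function(W, dev, labels, masks, maxlen) {
  counts <- vector("list", length(dev$ids))
  for (i in seq_along(dev$ids)) {
    tags <- decode_tags_linear(W, dev$ids[[i]], dev$ptr[[i]], labels, masks, maxlen)
    pred <- bio_to_spans(dev$tokens[[i]], tags)
    counts[[i]] <- align_spans(dev$corpus$sentences[[i]]$spans, pred)
  }
  score_counts(sum_match_counts(counts), "strict")$f1
}

# Transition-constrained greedy decode with long-sentence chunking: chunks of
# at most `maxlen` tokens are decoded independently; when a cut would land
# inside a predicted entity, it is shifted to the nearest preceding
# O-predicted token within 10 tokens, and predictions are re-joined.
decode_tags_linear <- function(W, ids, ptr, labels, masks, maxlen) {
  T <- length(ptr) - 1L
  if (T == 0L) return(character())
  if (T <= maxlen) {
    dec <- cpp_decode(W, ids, ptr, masks$allowed, masks$start_ok)
    return(labels[dec])
  }
  out <- integer()
  pos <- 1L
  o_idx <- which(labels == "O")
  while (pos <= T) {
    end <- min(pos + maxlen - 1L, T)
    sl <- slice_ids(ids, ptr, pos, end)
    dec <- cpp_decode(W, sl$ids, sl$ptr, masks$allowed, masks$start_ok)
    if (end < T) {
      len <- length(dec)
      window <- which(dec == o_idx & seq_along(dec) > len - 10L)
      if (length(window) && max(window) < len) {
        keep <- max(window)
        dec <- dec[seq_len(keep)]
        end <- pos + keep - 1L
      }
    }
    out <- c(out, dec)
    pos <- end + 1L
  }
  labels[out]
}

slice_ids <- function(ids, ptr, from, to) {
  lo <- ptr[from] + 1L; hi <- ptr[to + 1L]
  list(ids = ids[lo:hi], ptr = ptr[from:(to + 1L)] - ptr[from])
}

# Greedy constrained decode of an explicit score matrix (encoder backend);
# mirrors the C++ decoder and is cross-checked against it in the tests.
decode_greedy_scores <- function(S, labels, masks) {
  T <- nrow(S)
  out <- integer(T)
  prev <- 0L
  for (t in seq_len(T)) {
    ok <- if (prev == 0L) masks$start_ok else masks$allowed[prev, ]
    sc <- S[t, ]
    sc[!ok] <- -Inf
    out[t] <- which.max(sc)
    prev <- out[t]
  }
  labels[out]
}

#' Predict entity spans for new sentences
#'
#' Sentences longer than `max_sequence_length` tokens are split at token
#' boundaries, decoded per chunk, and re-joined before spans are formed; a
#' chunk cut that would split a predicted entity is shifted to the nearest
#' preceding O-predicted token within 10 tokens. Decoding forbids invalid
#' BIO transitions, so predictions are always BIO-valid.
#'
#' @param object a `pk_tagger`.
#' @param newdata a [pk_corpus()], a [pk_sentence()], or a character vector
#'   of sentence texts.
#' @param ... unused.
#' @return for a corpus, a predicted `pk_corpus` (same ids/texts); for a
#'   single sentence or string, a span table; for a character vector, a list
#'   of span tables.
#' @export
predict.pk_tagger <- function(object, newdata, ...) {
  if (inherits(newdata, "pk_corpus")) {
    preds <- predict_texts(object, vapply(newdata$sentences, `[[`, character(1), "text"))
    sentences <- Map(function(s, sp) {
      pk_sentence(s$id, s$text, sp, section = s$section, doc_id = s$doc_id)
    }, newdata$sentences, preds)
    return(pk_corpus(unname(sentences), split = newdata$split))
  }
  if (inherits(newdata, "pk_sentence")) return(predict_texts(object, newdata$text)[[1]])
  stopifnot(is.character(newdata))
  out <- predict_texts(object, newdata)
  if (length(newdata) == 1L) out[[1]] else out
}

predict_texts <- function(model, texts) {
  masks <- transition_masks(model$labels)
  maxlen <- model$config$max_sequence_length
  lapply(texts, function(text) {
    tk <- pk_tokenize(text)
    if (nrow(tk) == 0L) return(empty_spans())
    tags <- if (model$backend == "linear") {
      flat <- featurize_tokens(tk$text, model$lexicon)
      ids <- features_to_ids(list(flat), model$vocab)[[1]]
      decode_tags_linear(model$W, ids, .N_FEATS * (0:nrow(tk)), model$labels,
                         masks, maxlen)
    } else {
      decode_tags_encoder(model, tk, masks, maxlen)
    }
    bio_to_spans(tk, tags)
  })
}

decode_tags_encoder <- function(model, tokens, masks, maxlen) {
  S <- encoder_scores(model, tokens$text)
  T <- nrow(S)
  if (T <= maxlen) return(decode_greedy_scores(S, model$labels, masks))
  out <- character()
  pos <- 1L
  while (pos <= T) {
    end <- min(pos + maxlen - 1L, T)
    dec <- decode_greedy_scores(S[pos:end, , drop = FALSE], model$labels, masks)
    if (end < T) {
      len <- length(dec)
      window <- which(dec == "O" & seq_along(dec) > len - 10L)
      if (length(window) && max(window) < len) {
        keep <- max(window)
        dec <- dec[seq_len(keep)]
        end <- pos + keep - 1L
      }
    }
    out <- c(out, dec)
    pos <- end + 1L
  }
  out
}

encoder_scores <- function(model, toks) {
  S <- model$scorer(toks)
  if (!is.matrix(S) || nrow(S) != length(toks) || ncol(S) != length(model$labels)) {
    stop_pkner("encoder scorer must return a %d x %d score matrix",
               length(toks), length(model$labels), class = "pkner_encoder")
  }
  S
}

#' Wrap a pluggable encoder as a tagger
#'
#' The encoder contract: a function taking a character vector of tokens and
#' returning a numeric matrix of unnormalised per-token label scores
#' (`n_tokens x n_labels`, columns in the order of the model's BIO label
#' alphabet). Decoding, chunking, uncertainty and evaluation then behave
#' exactly as for the linear backend, so a transformer token-classification
#' head can be dropped in without touching any other module. For sub-word
#' encoders the convention is that the first piece of each token carries the
#' label and continuation pieces are masked from the loss; the scorer must
#' return one row per whole token.
#'
#' @param scorer the scoring function.
#' @param entity_labels entity classes (default `"PK"`).
#' @param config a [pk_train_config()]; its optimisation fields document the
#'   fine-tuning recipe for the encoder.
#' @return an object of class `pk_tagger` with `backend = "encoder"`.
#' @export
encoder_tagger <- function(scorer, entity_labels = "PK", config = pk_train_config()) {
  stopifnot(is.function(scorer))
  structure(list(
    backend = "encoder", labels = bio_alphabet(entity_labels), scorer = scorer,
    config = config, dev_history = numeric(), best_epoch = NA_integer_,
    version = 1L
  ), class = "pk_tagger")
}

#' Sentence-level model uncertainty
#'
#' The margin measure used for uncertainty sampling: per token, the model's
#' raw label scores are softmax-normalised and the margin between the best
#' and second-best label probability is computed; sentence uncertainty is
#' the mean of `1 - margin` over tokens. A sentence scored one-hot at every
#' token has uncertainty 0; uniform scores give 1. Empty sentences score 0.
#'
#' @param model a `pk_tagger`.
#' @param x a [pk_corpus()], [pk_sentence()], or character vector of texts.
#' @return numeric vector of uncertainties in `[0, 1]`.
#' @export
uncertainty <- function(model, x) {
  stopifnot(inherits(model, "pk_tagger"))
  texts <- if (inherits(x, "pk_corpus")) {
    vapply(x$sentences, `[[`, character(1), "text")
  } else if (inherits(x, "pk_sentence")) {
    x$text
  } else {
    as.character(x)
  }
  if (model$backend == "linear") {
    flats <- lapply(texts, function(tx) featurize_tokens(pk_tokenize(tx)$text, model$lexicon))
    ids <- features_to_ids(flats, model$vocab)
    ptr <- lapply(flats, function(f) .N_FEATS * (0:(length(f) %/% .N_FEATS)))
    as.numeric(cpp_uncertainty(model$W, ids, ptr))
  } else {
    vapply(texts, function(tx) {
      toks <- pk_tokenize(tx)$text
      if (!length(toks)) return(0)
      uncertainty_from_scores(encoder_scores(model, toks))
    }, numeric(1), USE.NAMES = FALSE)
  }
}

uncertainty_from_scores <- function(S) {
  margins <- apply(S, 1L, function(row) {
    p <- exp(row - max(row))
    p <- p / sum(p)
    srt <- sort(p, decreasing = TRUE)
    srt[1] - if (length(srt) > 1L) srt[2] else 0
  })
  mean(1 - margins)
}

#' Save / load a tagger
#'
#' Single-file archive with a versioned header; loading a file written by an
#' incompatible version, or a truncated/corrupt file, raises an explicit
#' error instead of silently mispredicting. Training provenance (config,
#' seed, development history) survives the round-trip, and
#' `predict(load_tagger(save_tagger(m, p)))` equals `predict(m)`.
#'
#' @param model a `pk_tagger`.
#' @param path file path.
#' @return `save_tagger` returns `path` invisibly; `load_tagger` the model.
#' @export
save_tagger <- function(model, path) {
  stopifnot(inherits(model, "pk_tagger"))
  saveRDS(list(format = "pkner_tagger", format_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop_pkner("cannot read tagger archive '%s': %s", path, conditionMessage(e),
               class = "pkner_integrity")
  })
  if (!is.list(obj) || !identical(obj$format, "pkner_tagger")) {
    stop_pkner("'%s' is not a pkner tagger archive", path, class = "pkner_integrity")
  }
  if (!identical(obj$format_version, 1L)) {
    stop_pkner("tagger archive version %s is not supported", obj$format_version,
               class = "pkner_integrity")
  }
  obj$model
}

#' @export
print.pk_tagger <- function(x, ...) {
  cat(sprintf("<pk_tagger backend=%s> labels: %s\n", x$backend,
              paste(x$labels, collapse = " ")))
  if (x$backend == "linear") {
    cat(sprintf("  %d features, trained on %d sentences, seed %d\n",
                length(x$vocab), x$n_train, x$config$seed))
    if (!is.na(x$dev_f1)) {
      cat(sprintf("  selected epoch %d/%d (dev strict F1 = %.2f)\n",
                  x$best_epoch, x$config$epochs, x$dev_f1))
    }
  }
  invisible(x)
}

#' @export
summary.pk_tagger <- function(object, ...) {
  print(object)
  if (length(object$dev_history) && !all(is.na(object$dev_history))) {
    cat("  dev strict F1 by epoch:\n")
    cat("   ", paste(sprintf("%.1f", object$dev_history), collapse = " "), "\n")
  }
  invisible(object)
}

#' @export
coef.pk_tagger <- function(object, ...) {
  if (object$backend != "linear") {
    stop_pkner("coefficients are only defined for the linear backend", class = "pkner_config")
  }
  W <- object$W
  dimnames(W) <- list(object$vocab, object$labels)
  W
}
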