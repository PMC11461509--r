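#' Configuration for the active-learning loop
#'
#' @param budget total number of sentences to label.
#' @param update_every sentences annotated between model updates (default 10,
#'   the cadence of model-in-the-loop span annotation).
#' @param selection `"uncertainty"` (stochastic preference for uncertain
#'   sentences, sampling without replacement with probability proportional to
#'   squared [uncertainty()] -- the exploration-preserving behaviour of
#'   production model-in-the-loop samplers), `"uncertainty_topk"`
#'   (deterministic: strictly the most uncertain sentences; prone to starving
#'   rare negative context classes, see the methods vignette), or
#'   `"random"`.
#' @param seed integer seed; the whole loop is reproducible from it.
#' @param initial_set optional pre-labelled [pk_corpus()] used to train the
#'   first in-loop model (the heuristic-bootstrap stage; see
#'   [bootstrap_initial_set()]). With no initial set and uncertainty
#'   selection, the first batch is drawn at random (an untrained model ranks
#'   every sentence equally).
#' @param train_epochs epochs for each in-loop (re)training. The in-loop
#'   model is fully retrained on the labelled set after every update, which
#'   keeps the simulation deterministic.
#' @return an object of class `pk_al_config`.
#' @export
al_config <- function(budget, update_every = 10L,
                      selection = c("uncertainty", "uncertainty_topk", "random"),
                      seed = 1L, initial_set = NULL, train_epochs = 5L) {
  selection <- match.arg(selection)
  if (update_every < 1L) stop_pkner("update_every must be >= 1", class = "pkner_config")
  if (budget < update_every) {
    stop_pkner("budget (%d) must be >= update_every (%d)", budget, update_every,
               class = "pkner_config")
  }
  structure(list(
    budget = as.integer(budget), update_every = as.integer(update_every),
    selection = selection, seed = as.integer(seed), initial_set = initial_set,
    train_epochs = as.integer(train_epochs)
  ), class = "pk_al_config")
}

#' Simulated annotator with binary review plus correction round
#'
#' Emulates the two-phase annotation protocol of model-in-the-loop span
#' labelling: in phase 1 each proposed span receives a binary accept/reject
#' decision by exact match against the hidden gold annotation; in phase 2 a
#' correction round replaces the result with the full gold annotation
#' (adding missed spans and fixing boundaries). Bookkeeping records how many
#' proposals were accepted, how many were boundary corrections (rejected
#' proposals overlapping a gold span), and how many gold spans were added.
#'
#' @param sentence a gold-annotated [pk_sentence()] (the hidden reference).
#' @param proposed a span table of model proposals ([pk_spans()]).
#' @return list with `sentence` (gold-annotated), `n_proposed`,
#'   `n_accepted`, `n_rejected`, `n_boundary_corrections`, `n_added`.
#' @export
simulated_annotator <- function(sentence, proposed = pk_spans()) {
  gold <- sentence$spans
  proposed <- as_span_df(proposed)
  accepted <- logical(nrow(proposed))
  overlaps_gold <- logical(nrow(proposed))
  for (j in seq_len(nrow(proposed))) {
    accepted[j] <- any(gold$start == proposed$start[j] & gold$end == proposed$end[j] &
                         gold$label == proposed$label[j])
    overlaps_gold[j] <- any(gold$start < proposed$end[j] & gold$end > proposed$start[j])
  }
  matched_gold <- rep(FALSE, nrow(gold))
  for (i in seq_len(nrow(gold))) {
    matched_gold[i] <- any(accepted & proposed$start == gold$start[i] &
                             proposed$end == gold$end[i] & proposed$label == gold$label[i])
  }
  list(
    sentence = sentence,
    n_proposed = nrow(proposed),
    n_accepted = sum(accepted),
    n_rejected = sum(!accepted),
    n_boundary_corrections = sum(!accepted & overlaps_gold),
    n_added = sum(!matched_gold)
  )
}

#' Heuristic-bootstrap initial training set
#'
#' Models the bootstrap stage of corpus construction: the rule-based matcher
#' is applied to the candidate pool, sentences with at least one rule match
#' are sampled, and their machine labels are passed through the simulated
#' annotator (binary review + correction). The fraction of sampled sentences
#' that retain at least one mention after correction is reported -- with a
#' perfect-recall reviewer this equals the rule matcher's sentence-level
#' precision on the sample.
#'
#' @param pool a gold-annotated [pk_corpus()].
#' @param n number of rule-matched sentences to sample (default 300).
#' @param ruleset a [pk_ruleset()].
#' @param seed integer seed.
#' @return list with `corpus` (the corrected initial set), `retention_pct`
#'   (percent of sentences with mentions after correction) and
#'   `annotation_log`.
#' @export
bootstrap_initial_set <- function(pool, n = 300L, ruleset = default_pk_ruleset(),
                                  seed = 1L) {
  matcher <- compile_rules(ruleset)
  pred <- match_rules(matcher, pool)
  has_match <- vapply(pred$sentences, function(s) nrow(s$spans) > 0L, logical(1))
  cand <- which(has_match)
  if (!length(cand)) stop_pkner("no rule-matched sentences in pool", class = "pkner_config")
  take <- with_seed(seed, sample(cand, min(n, length(cand))))
  take <- sort(take)
  reviews <- lapply(take, function(i) {
    simulated_annotator(pool$sentences[[i]], pred$sentences[[i]]$spans)
  })
  corpus <- pk_corpus(lapply(reviews, `[[`, "sentence"), split = "train")
  retained <- vapply(reviews, function(r) nrow(r$sentence$spans) > 0L, logical(1))
  list(
    corpus = corpus,
    retention_pct = round2(100 * mean(retained)),
    annotation_log = data.frame(
      n_proposed = vapply(reviews, `[[`, integer(1), "n_proposed"),
      n_accepted = vapply(reviews, `[[`, integer(1), "n_accepted"),
      n_added = vapply(reviews, `[[`, integer(1), "n_added")
    )
  )
}

#' Run the model-in-the-loop active-learning simulation
#'
#' Loop: rank the remaining pool by model uncertainty (or sample at random),
#' take `update_every` sentences, annotate them via [simulated_annotator()]
#' (proposals come from the current model), move them to the labelled set,
#' retrain the model from scratch on the labelled set, and append a history
#' row; stop when `budget` sentences are labelled. Fully reproducible from
#' `config$seed`.
#'
#' @param pool a gold-annotated [pk_corpus()]; the gold spans are hidden
#'   from selection (only [simulated_annotator()] sees them).
#' @param dev optional [pk_corpus()]; when given, entity-level strict dev F1
#'   is recorded in the history after every update.
#' @param config an [al_config()].
#' @return an object of class `pk_al_state` with fields `labelled`, `pool`
#'   (remaining), `model`, `history` (data.frame: step, pool_size,
#'   labelled_size, dev_f1), and `annotation` (accept/correction totals).
#' @export
run_al <- function(pool, dev = NULL, config) {
  stopifnot(inherits(pool, "pk_corpus"), inherits(config, "pk_al_config"))
  if (config$budget > length(pool)) {
    stop_pkner("budget (%d) exceeds pool size (%d)", config$budget, length(pool),
               class = "pkner_config")
  }
  lexicon <- inventory_lexicon()
  # Featurise the whole pool (and any initial set) once; every in-loop
  # retraining reuses these cached feature ids and the fixed vocabulary.
  ftr <- featurize_corpus(pool, lexicon)
  initial <- config$initial_set
  has_initial <- !is.null(initial) && length(initial) > 0L
  iftr <- if (has_initial) featurize_corpus(initial, lexicon)
  vocab <- unique(c(unlist(ftr$flat, use.names = FALSE),
                    if (has_initial) unlist(iftr$flat, use.names = FALSE)))
  pool_ids <- features_to_ids(ftr$flat, vocab)
  ents <- unique(c(entity_labels_of(pool), if (has_initial) entity_labels_of(initial)))
  if (!length(ents)) ents <- "PK"
  labels <- bio_alphabet(ents)
  pool_gold <- lapply(ftr$tags, match, labels)
  tcfg_base <- pk_train_config(epochs = config$train_epochs,
                               max_sequence_length = 256L, seed = config$seed)
  i_ids <- list(); i_ptr <- list(); i_gold <- list()
  if (has_initial) {
    i_ids <- features_to_ids(iftr$flat, vocab)
    i_ptr <- iftr$ptr
    i_gold <- lapply(iftr$tags, match, labels)
  }
  retrain <- function(idx) {
    suppressMessages(train_core(
      list(ids = c(i_ids, pool_ids[idx]), ptr = c(i_ptr, ftr$ptr[idx]),
           gold = c(i_gold, pool_gold[idx])),
      labels, vocab, lexicon, tcfg_base
    ))
  }
  remaining <- seq_len(length(pool))
  labelled_idx <- integer()
  model <- NULL
  if (has_initial) {
    model <- retrain(integer())
  }
  history <- list()
  n_accepted <- 0L; n_proposed <- 0L; n_boundary <- 0L; n_added <- 0L
  step <- 0L
  with_seed(config$seed, {
    while (length(labelled_idx) < config$budget) {
      step <- step + 1L
      n_take <- min(config$update_every, config$budget - length(labelled_idx))
      pick <- if (config$selection == "random" || is.null(model)) {
        remaining[sample.int(length(remaining), n_take)]
      } else {
        u <- cpp_uncertainty(model$W, pool_ids[remaining], ftr$ptr[remaining])
        if (config$selection == "uncertainty_topk") {
          # deterministic: strictly the most uncertain sentences
          remaining[order(-u)[seq_len(n_take)]]
        } else {
          # stochastic uncertainty preference (probability ~ u^2), the
          # behaviour of production model-in-the-loop samplers: favours
          # uncertain sentences while keeping exploration, so confidently
          # mis-handled context classes still enter the labelled set
          remaining[sample.int(length(remaining), n_take, prob = (u + 1e-6)^2)]
        }
      }
      for (i in pick) {
        proposals <- if (is.null(model)) {
          pk_spans()
        } else {
          predict(model, pool$sentences[[i]])
        }
        rev <- simulated_annotator(pool$sentences[[i]], proposals)
        n_proposed <- n_proposed + rev$n_proposed
        n_accepted <- n_accepted + rev$n_accepted
        n_boundary <- n_boundary + rev$n_boundary_corrections
        n_added <- n_added + rev$n_added
      }
      labelled_idx <- c(labelled_idx, pick)
      remaining <- setdiff(remaining, pick)
      model <- retrain(sort(labelled_idx))
      dev_f1 <- if (is.null(dev)) NA_real_ else evaluate_corpus(dev, predict(model, dev))$strict$f1
      history[[step]] <- data.frame(
        step = step, pool_size = length(remaining),
        labelled_size = length(labelled_idx), dev_f1 = dev_f1
      )
    }
  })
  labelled_corpus <- pool[sort(labelled_idx)]
  labelled_corpus$split <- "train"
  structure(list(
    labelled = labelled_corpus,
    pool = pool[sort(remaining)],
    model = model,
    history = do.call(rbind, history),
    annotation = list(n_proposed = n_proposed, n_accepted = n_accepted,
                      n_boundary_corrections = n_boundary, n_added = n_added)
  ), class = "pk_al_state")
}

#' @export
print.pk_al_state <- function(x, ...) {
  cat(sprintf("<pk_al_state> %d labelled, %d in pool, %d updates\n",
              length(x$labelled), length(x$pool), nrow(x$history)))
  st <- corpus_stats(x$labelled)
  cat(sprintf("  labelled-set entity prevalence: %.2f%%\n", st$pct_with_mentions))
  invisible(x)
}

#' Configuration of the AL-vs-random comparison experiment
#'
#' @param n_labelled sentences labelled per arm (default 500).
#' @param runs replicate count (default 10).
#' @param seeds one seed per run (distinct); defaults to `seq_len(runs)`.
#' @param train_epochs epochs for the per-arm final taggers (default 5).
#' @param update_every in-loop update cadence for the AL arm (default 10).
#' @return an object of class `pk_al_experiment_config`.
#' @export
al_experiment_config <- function(n_labelled = 500L, runs = 10L, seeds = NULL,
                                 train_epochs = 5L, update_every = 10L) {
  if (runs < 1L) stop_pkner("runs must be >= 1", class = "pkner_config")
  seeds <- seeds %||% seq_len(runs)
  if (length(seeds) != runs || anyDuplicated(seeds)) {
    stop_pkner("`seeds` must supply one distinct seed per run", class = "pkner_config")
  }
  structure(list(
    n_labelled = as.integer(n_labelled), runs = as.integer(runs),
    seeds = as.integer(seeds), train_epochs = as.integer(train_epochs),
    update_every = as.integer(update_every)
  ), class = "pk_al_experiment_config")
}

train_and_eval_arm <- function(labelled, test, epochs, seed) {
  cfg <- pk_train_config(epochs = epochs, seed = seed)
  model <- suppressMessages(train_tagger(labelled, config = cfg))
  ev <- evaluate_corpus(test, predict(model, test))
  list(eval = ev, prevalence = corpus_stats(labelled)$pct_with_mentions)
}

#' Active-learning versus random-sampling experiment
#'
#' The machine twin of the sampling-strategy comparison. Per run a fresh
#' candidate pool is generated and two annotation strategies are simulated:
#' the selective arm reproduces the two-stage corpus-construction protocol
#' (`bootstrap_n` rule-matched sentences corrected by the simulated
#' annotator, then the uncertainty-driven loop of [run_al()] seeded with
#' them), and `n_labelled` sentences are drawn at random from everything the
#' protocol labelled; the random arm draws `n_labelled` sentences directly
#' from the pool. A fresh tagger is trained on each arm's labelled set (same
#' seed and epochs in both arms) and scored -- strict and partial
#' precision/recall/F1 -- on a shared held-out synthetic test set. Returns
#' per-run scores, labelled-set entity prevalences, and per-arm medians.
#' Everything is reproducible from `(generator seed, experiment seeds)`.
#'
#' @param gen_config a [generator_config()] describing the pool (its
#'   `n_sentences` is the pool size per run; its seed is combined with each
#'   run's seed).
#' @param experiment an [al_experiment_config()].
#' @param test_n,dev_n sizes of the shared held-out test set and of the dev
#'   set used for in-loop history (dev is not used for model selection here;
#'   the per-arm taggers keep their final epoch, and are trained with the
#'   same seed in both arms).
#' @param bootstrap_n size of the heuristic-bootstrap stage feeding the
#'   selective arm (default 300 rule-matched sentences); set to 0 for a
#'   cold-start loop.
#' @return an object of class `pk_al_experiment`: `scores` (long data.frame
#'   with run, arm, scheme, metric, value), `prevalence` (per run and arm),
#'   and `medians`.
#' @export
compare_al_vs_random <- function(gen_config = generator_config(n_sentences = 5000L),
                                 experiment = al_experiment_config(),
                                 test_n = 1000L, dev_n = 0L, bootstrap_n = 300L) {
  test <- generate_corpus(modify_gen_config(gen_config,
                                            n_sentences = test_n,
                                            seed = derive_seed(gen_config$seed, 9999L)))
  test$split <- "test"
  dev <- if (dev_n > 0L) {
    generate_corpus(modify_gen_config(gen_config, n_sentences = dev_n,
                                      seed = derive_seed(gen_config$seed, 8888L)))
  }
  scores <- list(); prevalence <- list()
  for (r in seq_len(experiment$runs)) {
    run_seed <- experiment$seeds[r]
    pool <- generate_corpus(modify_gen_config(gen_config,
                                              seed = derive_seed(gen_config$seed, run_seed)))
    initial <- NULL
    al_pool <- pool
    if (bootstrap_n > 0L) {
      boot <- bootstrap_initial_set(pool, n = bootstrap_n,
                                    seed = derive_seed(run_seed, 23L))
      initial <- boot$corpus
      al_pool <- pool[!corpus_ids(pool) %in% corpus_ids(initial)]
    }
    al_state <- run_al(al_pool, dev = dev,
                       al_config(budget = experiment$n_labelled,
                                 update_every = experiment$update_every,
                                 selection = "uncertainty", seed = run_seed,
                                 train_epochs = experiment$train_epochs,
                                 initial_set = initial))
    collected <- if (is.null(initial)) {
      al_state$labelled
    } else {
      bind_corpora(initial, al_state$labelled, split = "train")
    }
    al_idx <- with_seed(derive_seed(run_seed, 29L),
                        sort(sample.int(length(collected), experiment$n_labelled)))
    al_labelled <- collected[al_idx]
    al_labelled$split <- "train"
    rand_idx <- with_seed(derive_seed(run_seed, 17L),
                          sort(sample.int(length(pool), experiment$n_labelled)))
    rand_labelled <- pool[rand_idx]
    rand_labelled$split <- "train"
    arms <- list(
      al = train_and_eval_arm(al_labelled, test, experiment$train_epochs, run_seed),
      random = train_and_eval_arm(rand_labelled, test, experiment$train_epochs, run_seed)
    )
    for (arm in names(arms)) {
      ev <- arms[[arm]]$eval
      for (scheme in c("strict", "partial")) {
        for (metric in c("precision", "recall", "f1")) {
          scores[[length(scores) + 1L]] <- data.frame(
            run = r, arm = arm, scheme = scheme, metric = metric,
            value = ev[[scheme]][[metric]]
          )
        }
      }
      prevalence[[length(prevalence) + 1L]] <- data.frame(
        run = r, arm = arm, pct_with_mentions = arms[[arm]]$prevalence
      )
    }
  }
  scores <- do.call(rbind, scores)
  prevalence <- do.call(rbind, prevalence)
  med <- stats::aggregate(value ~ arm + scheme + metric, data = scores, FUN = median)
  structure(list(scores = scores, prevalence = prevalence, medians = med,
                 runs = experiment$runs),
            class = "pk_al_experiment")
}

modify_gen_config <- function(cfg, ...) {
  upd <- list(...)
  for (nm in names(upd)) cfg[[nm]] <- upd[[nm]]
  generator_config(
    n_sentences = cfg$n_sentences, prevalence = cfg$prevalence,
    ambiguity_rate = cfg$ambiguity_rate, distractor_rate = cfg$distractor_rate,
    pct_full_text = cfg$pct_full_text, seed = cfg$seed, vocabulary = cfg$vocabulary
  )
}

#' @export
print.pk_al_experiment <- function(x, ...) {
  med <- x$medians
  get_med <- function(arm, scheme, metric) {
    med$value[med$arm == arm & med$scheme == scheme & med$metric == metric]
  }
  cat(sprintf("AL-vs-random sampling experiment (%d runs)\n", x$runs))
  for (scheme in c("strict", "partial")) {
    cat(sprintf("  %s median F1: AL = %.2f, random = %.2f (gain %+.2f)\n",
                scheme, get_med("al", scheme, "f1"), get_med("random", scheme, "f1"),
                get_med("al", scheme, "f1") - get_med("random", scheme, "f1")))
  }
  prev <- stats::aggregate(pct_with_mentions ~ arm, data = x$prevalence, FUN = median)
  cat(sprintf("  median labelled-set prevalence: AL = %.2f%%, random = %.2f%%\n",
              prev$pct_with_mentions[prev$arm == "al"],
              prev$pct_with_mentions[prev$arm == "random"]))
  invisible(x)
}
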