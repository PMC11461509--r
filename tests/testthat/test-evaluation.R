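test_that("alignment assigns MUC-style categories on worked examples", {
  id <- align_spans(pk_spans(c(0, 20), c(9, 25)), pk_spans(c(0, 20), c(9, 25)))
  expect_equal(unclass(id)[c("COR", "INC", "PAR", "MIS", "SPU")],
               list(COR = 2L, INC = 0L, PAR = 0L, MIS = 0L, SPU = 0L))
  cnt <- align_spans(pk_spans(c(0, 20), c(9, 25)), pk_spans(c(0, 21, 30), c(9, 25, 33)))
  expect_equal(cnt$COR, 1L); expect_equal(cnt$PAR, 1L)
  expect_equal(cnt$SPU, 1L); expect_equal(cnt$MIS, 0L)
  only_spu <- align_spans(pk_spans(), pk_spans(0, 3))
  expect_equal(only_spu$SPU, 1L)
  expect_equal(only_spu$COR + only_spu$INC + only_spu$PAR + only_spu$MIS, 0L)
  expect_error(align_spans(pk_spans(c(0, 3), c(5, 8)), pk_spans()),
               class = "pkner_validation")
})

test_that("exact boundaries with the wrong label count as INC, not COR", {
  cnt <- align_spans(pk_spans(0, 9, "PK"), pk_spans(0, 9, "PD"))
  expect_equal(cnt$INC, 1L)
  expect_equal(cnt$COR, 0L)
  expect_equal(score_counts(cnt, "strict")$precision, 0)
  # partial gives no credit to INC either
  expect_equal(score_counts(cnt, "partial")$precision, 0)
})

test_that("scores reproduce the hand-derived precision/recall/F1", {
  cnt <- align_spans(pk_spans(c(0, 20), c(9, 25)), pk_spans(c(0, 21, 30), c(9, 25, 33)))
  s <- score_counts(cnt, "strict")
  expect_equal(c(s$precision, s$recall, s$f1), c(33.33, 50.00, 40.00))
  p <- score_counts(cnt, "partial")
  expect_equal(c(p$precision, p$recall, p$f1), c(50.00, 75.00, 60.00))
  perfect <- score_counts(align_spans(pk_spans(0, 5), pk_spans(0, 5)), "strict")
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(100, 100, 100))
  zero <- score_counts(align_spans(pk_spans(), pk_spans()), "strict")
  expect_equal(c(zero$precision, zero$recall, zero$f1), c(0, 0, 0))
  expect_true(zero$empty_input)
  neg <- align_spans(pk_spans(0, 5), pk_spans(0, 5))
  neg$COR <- -1L
  expect_error(score_counts(neg, "strict"), class = "pkner_validation")
})

test_that("count conservation and partial>=strict hold on random instances", {
  set.seed(42)
  for (rep in 1:300) {
    gold <- random_span_list()
    pred <- random_span_list()
    cnt <- align_spans(gold, pred)
    expect_equal(cnt$COR + cnt$INC + cnt$PAR + cnt$MIS, nrow(gold))
    expect_equal(cnt$COR + cnt$INC + cnt$PAR + cnt$SPU, nrow(pred))
    expect_gte(score_counts(cnt, "partial")$f1, score_counts(cnt, "strict")$f1)
  }
})

test_that("greedy alignment agrees with the brute-force matching oracle", {
  set.seed(99)
  for (rep in 1:300) {
    gold <- random_span_list()
    pred <- random_span_list()
    got <- align_spans(gold, pred)
    want <- oracle_align(gold, pred)
    expect_equal(unclass(got)[c("COR", "INC", "PAR", "MIS", "SPU")], want,
                 info = sprintf("rep %d", rep))
  }
})

test_that("corpus evaluation micro-averages and aligns by sentence id", {
  gold <- generate_corpus(generator_config(n_sentences = 60, prevalence = 0.6, seed = 3))
  expect_equal(evaluate_corpus(gold, gold)$strict$f1, 100)
  # shift every multi-character span one character right (single-character
  # spans are dropped): no exact boundary survives, overlaps do
  shifted <- gold
  shifted$sentences <- lapply(gold$sentences, function(s) {
    sp <- s$spans[s$spans$end - s$spans$start >= 2L, , drop = FALSE]
    if (nrow(sp)) sp$start <- sp$start + 1L
    pk_sentence(s$id, s$text, sp, section = s$section, doc_id = s$doc_id)
  })
  ev <- evaluate_corpus(gold, shifted)
  expect_equal(ev$strict$f1, 0)
  expect_gt(ev$partial$f1, 0)
  # empty predictions: zero recall, flagged zero precision
  empty_pred <- gold
  empty_pred$sentences <- lapply(gold$sentences, function(s) {
    pk_sentence(s$id, s$text, pk_spans(), section = s$section, doc_id = s$doc_id)
  })
  ev0 <- evaluate_corpus(gold, empty_pred)
  expect_equal(ev0$strict$recall, 0)
  expect_true(ev0$strict$empty_input)
  # id mismatch is an alignment error listing the missing id
  bad <- empty_pred
  bad$sentences[[1]]$id <- "rogue"
  expect_error(evaluate_corpus(gold, bad), "rogue", class = "pkner_alignment")
})

test_that("summing counts then scoring equals scoring the pooled corpus", {
  gold <- generate_corpus(generator_config(n_sentences = 80, prevalence = 0.5, seed = 19))
  matcher <- compile_rules(default_pk_ruleset())
  pred <- match_rules(matcher, gold)
  per_sentence <- lapply(seq_along(gold$sentences), function(i) {
    align_spans(gold$sentences[[i]]$spans, pred$sentences[[i]]$spans)
  })
  pooled <- sum_match_counts(per_sentence)
  ev <- evaluate_corpus(gold, pred)
  expect_identical(unclass(ev$counts), unclass(pooled))
  expect_equal(ev$strict, score_counts(pooled, "strict"))
})

test_that("pairwise IAA is symmetric with a diagonal of 100", {
  gold <- generate_corpus(generator_config(n_sentences = 50, prevalence = 0.5, seed = 23))
  matcher <- compile_rules(default_pk_ruleset())
  ann <- list(alice = gold, bob = match_rules(matcher, gold), carol = gold)
  iaa <- pairwise_iaa(ann)
  expect_equal(diag(iaa$f1), c(alice = 100, bob = 100, carol = 100))
  expect_equal(iaa$f1, t(iaa$f1))
  expect_equal(iaa$f1["alice", "carol"], 100)
  # F1 symmetry holds when computed in both directions explicitly
  expect_equal(evaluate_corpus(ann$alice, ann$bob)$strict$f1,
               evaluate_corpus(ann$bob, ann$alice)$strict$f1)
  # mean excludes the diagonal
  up <- iaa$f1[upper.tri(iaa$f1)]
  expect_equal(iaa$mean_pairwise, round(mean(up), 2))
  # annotator with no spans on a span-bearing sentence scores 0 against it
  one <- pk_corpus(list(pk_sentence("s", "CL was 5", pk_spans(0, 2))))
  none <- pk_corpus(list(pk_sentence("s", "CL was 5")))
  expect_equal(pairwise_iaa(list(a = one, b = none))$f1["a", "b"], 0)
  expect_error(pairwise_iaa(list(a = one)), class = "pkner_validation")
  other <- pk_corpus(list(pk_sentence("zzz", "CL was 5")))
  expect_error(pairwise_iaa(list(a = one, b = other)), class = "pkner_alignment")
})
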