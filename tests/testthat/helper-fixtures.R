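# Hand-built miniature corpus used across the I/O and statistics tests.
tiny_corpus <- function() {
  pk_corpus(list(
    pk_sentence("s1", "CL was 5 L/h", pk_spans(0, 2), section = "abstract",
                doc_id = "doc-1"),
    pk_sentence("s2", "The clearance and half-life were reduced",
                pk_spans(c(4, 18), c(13, 27)), section = "full_text"),
    pk_sentence("s3", "No adverse events were reported", section = "full_text")
  ), split = "test")
}

# Small generated corpora shared by several tagger / AL tests; memoised per
# test file via the testthat helper environment.
small_train_corpus <- function(n = 120L, seed = 401L) {
  generate_corpus(generator_config(n_sentences = n, prevalence = 0.6425, seed = seed))
}

small_test_corpus <- function(n = 200L, seed = 402L) {
  generate_corpus(generator_config(n_sentences = n, prevalence = 0.164, seed = seed))
}

quiet_train <- function(...) suppressWarnings(suppressMessages(train_tagger(...)))

all_predictions_bio_valid <- function(model, corpus) {
  all(vapply(corpus$sentences, function(s) {
    tk <- pk_tokenize(s$text)
    tags <- spans_to_bio(tk, predict(model, s), policy = "snap")
    is_bio_valid(tags)
  }, logical(1)))
}
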