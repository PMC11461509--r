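test_that("tokenizer keeps PK acronyms, numbers and unit strings intact", {
  expect_equal(pk_tokenize("AUC0-24 was 4.2 mg·h/L")$text,
               c("AUC0-24", "was", "4.2", "mg·h/L"))
  expect_equal(pk_tokenize("t1/2")$text, "t1/2")
  expect_equal(nrow(pk_tokenize("")), 0L)
  expect_equal(pk_tokenize("(F)")$text, c("(", "F", ")"))
  expect_equal(pk_tokenize("AUC0-∞")$text, "AUC0-∞")
})

test_that("tokenizer offsets are 0-based half-open and lossless on non-whitespace", {
  for (seed in 1:3) {
    corp <- generate_corpus(generator_config(n_sentences = 40, seed = seed))
    for (s in corp$sentences) {
      tk <- pk_tokenize(s$text)
      expect_equal(tk$text, substring(s$text, tk$start + 1L, tk$end))
      expect_equal(paste(tk$text, collapse = ""), gsub("\\s", "", s$text))
      expect_true(all(tk$start[-1L] >= tk$end[-nrow(tk)]))
    }
  }
})

test_that("sentence validation rejects malformed, unsorted and nested spans", {
  expect_error(pk_sentence("x", "short", pk_spans(0, 99)), class = "pkner_validation")
  expect_error(pk_sentence("x", "abcdef", pk_spans(3, 3)), class = "pkner_validation")
  expect_error(pk_sentence("x", "abcdef", pk_spans(c(4, 0), c(6, 2))),
               class = "pkner_validation")
  expect_error(pk_sentence("x", "abcdef", pk_spans(c(0, 2), c(4, 6))),
               class = "pkner_validation")
  expect_error(pk_corpus(list(pk_sentence("a", "x y"), pk_sentence("a", "y z"))),
               class = "pkner_validation")
})

test_that("JSON-Lines reader handles minimal and Prodigy-style records", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"text":"CL was 5 L/h","spans":[{"start":0,"end":2,"label":"PK"}]}',
    '{"id":"abc","text":"No spans here","spans":[],"section":"abstract"}'
  ), path)
  corp <- read_corpus(path, "jsonl")
  expect_length(corp, 2L)
  expect_equal(corp$sentences[[1]]$spans$end, 2L)
  expect_equal(span_text(corp$sentences[[1]]), "CL")
  expect_true(corp$sentences[[1]]$section_imputed)  # no section field
  expect_equal(corp$sentences[[2]]$id, "abc")
  expect_equal(corp$sentences[[2]]$section, "abstract")
})

test_that("reader reports malformed input with line number or sentence id", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"text":"ok","spans":[]}', "{not json"), path)
  expect_error(read_corpus(path, "jsonl"), "line 2", class = "pkner_format")
  writeLines('{"id":"bad1","text":"abc","spans":[{"start":0,"end":9,"label":"PK"}]}', path)
  expect_error(read_corpus(path, "jsonl"), "bad1", class = "pkner_validation")
  writeLines('{"id":"bad2","text":"abcdef","spans":[{"start":3,"end":3,"label":"PK"}]}', path)
  expect_error(read_corpus(path, "jsonl"), "bad2", class = "pkner_validation")
})

test_that("empty files and empty corpora round-trip", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  file.create(path)
  expect_length(read_corpus(path, "jsonl"), 0L)
  write_corpus(pk_corpus(), path, "jsonl")
  expect_length(read_corpus(path, "jsonl"), 0L)
})

test_that("JSON-Lines round-trip is the identity on valid corpora", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  for (seed in c(11, 12)) {
    corp <- generate_corpus(generator_config(n_sentences = 50, seed = seed))
    write_corpus(corp, path, "jsonl")
    back <- read_corpus(path, "jsonl", split = corp$split)
    expect_equal(length(back), length(corp))
    for (i in seq_along(corp$sentences)) {
      a <- corp$sentences[[i]]; b <- back$sentences[[i]]
      expect_identical(b$id, a$id)
      expect_identical(b$text, a$text)
      expect_identical(b$spans, a$spans)
      expect_identical(b$section, a$section)
      expect_identical(b$doc_id, a$doc_id)
    }
  }
  # a sentence with zero spans is written as an empty span list, not omitted
  write_corpus(tiny_corpus(), path, "jsonl")
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_match(lines[3], '"spans":\\[\\]')
})

test_that("CoNLL export round-trips tokens and tags (offsets re-derived)", {
  path <- withr::local_tempfile(fileext = ".conll")
  corp <- generate_corpus(generator_config(n_sentences = 30, seed = 5))
  write_corpus(corp, path, "conll")
  back <- read_corpus(path, "conll")
  expect_length(back, length(corp))
  for (i in seq_along(corp$sentences)) {
    orig <- tag_sentence(corp$sentences[[i]])
    got <- tag_sentence(back$sentences[[i]])
    expect_identical(got$tokens$text, orig$tokens$text)
    expect_identical(got$tags, orig$tags)
  }
  lines <- readLines(path)
  expect_match(lines[1], "^[^\t]+\t[^\t]+$")
})

test_that("spans_to_bio projects spans onto tokens under both policies", {
  tk <- pk_tokenize("The clearance was high")
  expect_equal(spans_to_bio(tk, pk_spans(4, 13)), c("O", "B-PK", "O", "O"))
  expect_equal(spans_to_bio(tk, pk_spans()), rep("O", 4))
  tk2 <- pk_tokenize("The total body clearance was reduced")
  expect_equal(spans_to_bio(tk2, pk_spans(4, 24)),
               c("O", "B-PK", "I-PK", "I-PK", "O", "O"))
  # boundary inside a token: snap expands with a warning, strict errors
  expect_warning(tags <- spans_to_bio(tk, pk_spans(4, 9), policy = "snap"),
                 "snapped")
  expect_equal(tags, c("O", "B-PK", "O", "O"))
  expect_error(spans_to_bio(tk, pk_spans(4, 9), policy = "strict"),
               class = "pkner_misalignment")
})

test_that("bio_to_spans forms maximal runs and repairs dangling I-", {
  tk <- pk_tokenize("a bb ccc dddd")
  expect_equal(bio_to_spans(tk, c("O", "B-PK", "I-PK", "O")), pk_spans(2, 8))
  expect_equal(bio_to_spans(tk, c("O", "I-PK", "I-PK", "O")), pk_spans(2, 8))
  expect_equal(bio_to_spans(tk, c("B-PK", "B-PK", "O", "B-PD")),
               pk_spans(c(0, 2, 9), c(1, 4, 13), c("PK", "PK", "PD")))
  expect_error(bio_to_spans(tk, c("O", "Q-PK", "O", "O")), class = "pkner_validation")
  expect_error(bio_to_spans(tk, c("O", "O")), class = "pkner_validation")
})

test_that("BIO encode/decode round-trips token-aligned spans", {
  corp <- generate_corpus(generator_config(n_sentences = 200, seed = 31))
  for (s in corp$sentences) {
    tk <- pk_tokenize(s$text)
    tags <- spans_to_bio(tk, s$spans, policy = "snap")
    expect_true(is_bio_valid(tags))
    expect_identical(bio_to_spans(tk, tags), s$spans)
  }
})

test_that("corpus statistics match hand counts and flag degenerate input", {
  st <- corpus_stats(pk_corpus(list(
    pk_sentence("a", "CL was 5", pk_spans(c(0, 7), c(2, 8)), section = "full_text"),
    pk_sentence("b", "nothing here", section = "abstract")
  )))
  expect_equal(st$n_sentences, 2L)
  expect_equal(st$n_mentions, 2L)
  expect_equal(st$pct_with_mentions, 50)
  expect_equal(st$pct_full_text, 50)
  empty <- corpus_stats(pk_corpus())
  expect_true(empty$undefined_pct)
  expect_equal(empty$n_sentences, 0L)
  # sentences without a section field are imputed and flagged
  noseq <- pk_corpus(list(pk_sentence("c", "abc")))
  expect_equal(corpus_stats(noseq)$n_section_imputed, 1L)
})

test_that("reported percentages agree with raw counts to 0.01", {
  for (seed in c(7, 8)) {
    corp <- generate_corpus(generator_config(n_sentences = 300, seed = seed))
    st <- corpus_stats(corp)
    with_m <- sum(vapply(corp$sentences, function(s) nrow(s$spans) > 0, logical(1)))
    ft <- sum(vapply(corp$sentences, function(s) s$section == "full_text", logical(1)))
    expect_equal(st$pct_with_mentions, 100 * with_m / 300, tolerance = 0.01)
    expect_equal(st$pct_full_text, 100 * ft / 300, tolerance = 0.01)
  }
})
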