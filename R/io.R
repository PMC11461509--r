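#' Read a sentence corpus from disk
#'
#' Two dialects are supported. `"jsonl"` is the native format: one JSON object
#' per line with keys `text`, `spans` (a list of `{start, end, label}` records
#' with 0-based half-open offsets), and optionally `id`, `section`, `doc_id`
#' -- the shape used by Prodigy-style span-annotation releases. Records
#' without an `id` get one generated from the line number; records without a
#' `section` default to `"full_text"` and are flagged. `"conll"` reads
#' TOKEN<TAB>TAG lines with blank-line sentence separators; sentence text and
#' offsets are re-derived by joining tokens with single spaces.
#'
#' Malformed spans (e.g. `end` beyond the text length, overlapping spans) are
#' rejected with the offending sentence id; lines that fail to parse raise a
#' format error naming the line number.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"conll"`.
#' @param split split label to attach to the corpus.
#' @return a [pk_corpus()].
#' @export
read_corpus <- function(path, format = c("jsonl", "conll"), split = "unsplit") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_pkner("no such file: %s", path, class = "pkner_io")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (format == "jsonl") read_jsonl_lines(lines, split) else read_conll_lines(lines, split)
}

read_jsonl_lines <- function(lines, split) {
  keep <- nzchar(trimws(lines))
  sentences <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) {
        stop_pkner("line %d: not valid JSON (%s)", i, conditionMessage(e),
                   class = "pkner_format")
      }
    )
    if (is.null(rec$text)) {
      stop_pkner("line %d: record has no `text` field", i, class = "pkner_format")
    }
    id <- rec$id %||% sprintf("line-%06d", i)
    sent <- tryCatch(
      pk_sentence(
        id = id, text = rec$text,
        spans = as_span_df(rec$spans %||% list()),
        section = rec$section, doc_id = rec$doc_id
      ),
      error = function(e) {
        stop_pkner("sentence '%s': %s", id, conditionMessage(e), class = "pkner_validation")
      }
    )
    j <- j + 1L
    sentences[[j]] <- sent
  }
  pk_corpus(sentences[seq_len(j)], split = split)
}

read_conll_lines <- function(lines, split) {
  sentences <- list()
  tok <- character(); tag <- character()
  flush <- function() {
    if (!length(tok)) return(invisible())
    text <- paste(tok, collapse = " ")
    tokens <- pk_tokenize(text)
    if (nrow(tokens) != length(tok) || !all(tokens$text == tok)) {
      stop_pkner("CoNLL sentence %d: tokens are not reproducible from joined text",
                 length(sentences) + 1L, class = "pkner_format")
    }
    spans <- bio_to_spans(tokens, tag)
    sentences[[length(sentences) + 1L]] <<-
      pk_sentence(sprintf("conll-%06d", length(sentences) + 1L), text, spans)
    tok <<- character(); tag <<- character()
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) { flush(); next }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop_pkner("line %d: expected TOKEN<TAB>TAG", i, class = "pkner_format")
    }
    tok <- c(tok, parts[1]); tag <- c(tag, parts[2])
  }
  flush()
  pk_corpus(sentences, split = split)
}

#' Write a sentence corpus to disk
#'
#' JSON-Lines output round-trips exactly through [read_corpus()] (ids, texts,
#' spans, sections); sentences with no spans are written with an empty span
#' list, never omitted. CoNLL output preserves tokens and BIO tags but loses
#' original character offsets (they are re-derived on read by joining tokens
#' with single spaces).
#'
#' @param corpus a [pk_corpus()].
#' @param path output file path.
#' @param format `"jsonl"` or `"conll"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "conll")) {
  format <- match.arg(format)
  validate_corpus(corpus)
  lines <- if (format == "jsonl") {
    vapply(corpus$sentences, sentence_to_json, character(1))
  } else {
    unlist(lapply(corpus$sentences, sentence_to_conll), use.names = FALSE)
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop_pkner("cannot open '%s' for writing", path, class = "pkner_io")
  })
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

sentence_to_json <- function(s) {
  spans <- if (nrow(s$spans)) {
    lapply(seq_len(nrow(s$spans)), function(i) {
      list(start = s$spans$start[i], end = s$spans$end[i], label = s$spans$label[i])
    })
  } else {
    list()
  }
  rec <- list(id = s$id, text = s$text, spans = spans, section = s$section)
  if (!is.null(s$doc_id)) rec$doc_id <- s$doc_id
  enc2utf8(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)))
}

sentence_to_conll <- function(s) {
  ts <- tag_sentence(s)
  c(paste(ts$tokens$text, ts$tags, sep = "\t"), "")
}
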