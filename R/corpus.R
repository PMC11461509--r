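#' Construct an entity span table
#'
#' Spans use 0-based half-open character offsets into the owning sentence, the
#' convention of most span-annotated corpus releases: a span `[start, end)`
#' covers `substr(text, start + 1, end)`.
#'
#' @param start,end integer vectors of character offsets (0-based, half-open).
#' @param label entity class, recycled; defaults to `"PK"`.
#' @return a `data.frame` with columns `start`, `end`, `label`.
#' @examples
#' pk_spans(0, 2)                       # "CL" in "CL was 5 L/h"
#' @export
pk_spans <- function(start = integer(), end = integer(), label = "PK") {
  if (length(start) != length(end)) {
    stop_pkner("`start` and `end` must have equal length", class = "pkner_validation")
  }
  data.frame(
    start = as.integer(start),
    end = as.integer(end),
    label = if (length(start)) rep_len(as.character(label), length(start)) else character(),
    stringsAsFactors = FALSE
  )
}

empty_spans <- function() pk_spans()

#' Construct a sentence with entity spans
#'
#' @param id stable sentence identifier, unique within a corpus.
#' @param text sentence text.
#' @param spans a span table as returned by [pk_spans()] (may be empty).
#' @param section `"abstract"` or `"full_text"`. When missing it defaults to
#'   `"full_text"` and the sentence is flagged (`section_imputed`), which
#'   [corpus_stats()] reports.
#' @param doc_id optional source document identifier.
#' @return an object of class `pk_sentence`.
#' @export
pk_sentence <- function(id, text, spans = pk_spans(), section = NULL, doc_id = NULL) {
  imputed <- is.null(section)
  s <- structure(
    list(
      id = as.character(id),
      text = as.character(text),
      spans = as_span_df(spans),
      section = if (imputed) "full_text" else as.character(section),
      doc_id = if (is.null(doc_id) || is.na(doc_id)) NULL else as.character(doc_id),
      section_imputed = imputed
    ),
    class = "pk_sentence"
  )
  validate_sentence(s)
  s
}

as_span_df <- function(spans) {
  if (is.null(spans) || (is.list(spans) && length(spans) == 0L && !is.data.frame(spans))) {
    return(empty_spans())
  }
  if (is.data.frame(spans)) {
    if (nrow(spans) == 0L) return(empty_spans())
    if (!all(c("start", "end") %in% names(spans))) {
      stop_pkner("span table needs `start` and `end` columns", class = "pkner_validation")
    }
    lab <- if ("label" %in% names(spans)) as.character(spans$label) else rep("PK", nrow(spans))
    return(pk_spans(spans$start, spans$end, lab))
  }
  # list of per-span records (as parsed from JSON)
  starts <- vapply(spans, function(s) as.integer(s$start), integer(1))
  ends <- vapply(spans, function(s) as.integer(s$end), integer(1))
  labs <- vapply(spans, function(s) as.character(s$label %||% "PK"), character(1))
  pk_spans(starts, ends, labs)
}

validate_sentence <- function(s) {
  if (!is_string(s$id) || !nzchar(s$id)) {
    stop_pkner("sentence has a missing or empty id", class = "pkner_validation")
  }
  if (!is_string(s$text)) {
    stop_pkner("sentence '%s': text must be a single string", s$id, class = "pkner_validation")
  }
  if (!s$section %in% c("abstract", "full_text")) {
    stop_pkner("sentence '%s': section must be 'abstract' or 'full_text'", s$id,
               class = "pkner_validation")
  }
  sp <- s$spans
  n <- nchar(s$text)
  if (nrow(sp)) {
    bad <- sp$start < 0L | sp$end <= sp$start | sp$end > n
    if (any(bad)) {
      stop_pkner("sentence '%s': span [%d, %d) violates 0 <= start < end <= %d",
                 s$id, sp$start[which(bad)[1]], sp$end[which(bad)[1]], n,
                 class = "pkner_validation")
    }
    if (is.unsorted(sp$start, strictly = FALSE)) {
      stop_pkner("sentence '%s': spans must be sorted by start", s$id,
                 class = "pkner_validation")
    }
    if (nrow(sp) > 1L && any(sp$start[-1L] < sp$end[-nrow(sp)])) {
      stop_pkner("sentence '%s': spans overlap (flat annotation required)", s$id,
                 class = "pkner_validation")
    }
  }
  invisible(s)
}

#' Surface forms of a sentence's spans
#' @param sentence a [pk_sentence()].
#' @return character vector of covered text slices.
#' @export
span_text <- function(sentence) {
  sp <- sentence$spans
  if (!nrow(sp)) return(character())
  vapply(seq_len(nrow(sp)),
         function(i) slice_text(sentence$text, sp$start[i], sp$end[i]),
         character(1))
}

#' Construct a corpus of sentences
#'
#' @param sentences list of [pk_sentence()] objects.
#' @param split one of `"train"`, `"dev"`, `"test"`, `"pool"`, `"unsplit"`.
#' @return an object of class `pk_corpus`.
#' @export
pk_corpus <- function(sentences = list(), split = "unsplit") {
  split <- match.arg(split, c("train", "dev", "test", "pool", "unsplit"))
  corp <- structure(list(sentences = sentences, split = split), class = "pk_corpus")
  validate_corpus(corp)
  corp
}

validate_corpus <- function(corpus) {
  for (s in corpus$sentences) validate_sentence(s)
  ids <- corpus_ids(corpus)
  if (anyDuplicated(ids)) {
    stop_pkner("duplicate sentence id '%s' in corpus", ids[duplicated(ids)][1],
               class = "pkner_validation")
  }
  invisible(corpus)
}

corpus_ids <- function(corpus) {
  vapply(corpus$sentences, `[[`, character(1), "id")
}

#' @export
length.pk_corpus <- function(x) length(x$sentences)

#' @export
`[.pk_corpus` <- function(x, i) {
  pk_corpus(x$sentences[i], split = x$split)
}

#' @export
print.pk_sentence <- function(x, ...) {
  cat(sprintf("<pk_sentence %s> [%s]\n  %s\n", x$id, x$section, x$text))
  if (nrow(x$spans)) {
    surf <- span_text(x)
    for (i in seq_len(nrow(x$spans))) {
      cat(sprintf("  span [%d,%d) %s: \"%s\"\n",
                  x$spans$start[i], x$spans$end[i], x$spans$label[i], surf[i]))
    }
  }
  invisible(x)
}

#' @export
print.pk_corpus <- function(x, ...) {
  n <- length(x)
  nm <- sum(vapply(x$sentences, function(s) nrow(s$spans), integer(1)))
  cat(sprintf("<pk_corpus> %d sentences, %d entity mentions, split = %s\n",
              n, nm, x$split))
  invisible(x)
}

#' Concatenate corpora
#' @param ... `pk_corpus` objects.
#' @param split split label of the result.
#' @return a `pk_corpus`.
#' @export
bind_corpora <- function(..., split = "unsplit") {
  pk_corpus(unlist(lapply(list(...), `[[`, "sentences"), recursive = FALSE),
            split = split)
}
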