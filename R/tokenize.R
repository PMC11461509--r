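# Word characters: ASCII alphanumerics plus the infinity sign (AUC0-∞ is a
# single token in PK prose). Glue characters join two word runs into one token
# so that "AUC0-24", "t1/2", "4.2" and "mg·h/L" survive tokenisation intact.
.token_regex <- "[[:alnum:]∞]+(?:[-/.·][[:alnum:]∞]+)*|[^[:space:]]"

#' Deterministic regex tokenizer
#'
#' Splits a sentence into tokens with 0-based half-open character offsets.
#' A token is either a run of alphanumeric characters (optionally glued by
#' internal `-`, `/`, `.` or the middle dot, so that PK acronyms such as
#' `AUC0-24`, `t1/2` and unit strings like `mg·h/L` stay whole), or a single
#' non-whitespace character. Whitespace is the only text not covered by a
#' token, hence tokenisation is lossless on non-whitespace characters.
#'
#' @param text a single sentence string.
#' @return a `data.frame` with columns `text`, `start`, `end` (0-based,
#'   half-open), sorted and non-overlapping; zero rows for empty input.
#' @examples
#' pk_tokenize("AUC0-24 was 4.2 mg·h/L")$text
#' @export
pk_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr(.token_regex, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(text = substring(text, start + 1L, end), start = start, end = end,
             stringsAsFactors = FALSE)
}

bio_label <- function(prefix, label) paste0(prefix, "-", label)

#' Project character-offset spans onto token BIO labels
#'
#' The first token covered by a span receives `B-<label>`, subsequent covered
#' tokens `I-<label>`, all others `O`. Under `policy = "snap"` (the default) a
#' token counts as covered when it overlaps the span by at least one
#' character, so spans whose boundaries fall inside a token are expanded to
#' the covering tokens (with a warning). Under `policy = "strict"` only tokens
#' fully inside the span are covered and a span boundary strictly inside a
#' token is a misalignment error.
#'
#' @param tokens token table from [pk_tokenize()].
#' @param spans span table from [pk_spans()].
#' @param policy `"snap"` or `"strict"`.
#' @return character vector of BIO tags, one per token.
#' @export
spans_to_bio <- function(tokens, spans, policy = c("snap", "strict")) {
  policy <- match.arg(policy)
  tags <- rep("O", nrow(tokens))
  spans <- as_span_df(spans)
  if (!nrow(spans)) return(tags)
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    boundary_inside <- any(tokens$start < s & s < tokens$end) ||
      any(tokens$start < e & e < tokens$end)
    if (policy == "strict") {
      if (boundary_inside) {
        stop_pkner("span [%d, %d) boundary falls inside a token", s, e,
                   class = "pkner_misalignment")
      }
      covered <- which(tokens$start >= s & tokens$end <= e)
    } else {
      if (boundary_inside) {
        warning(sprintf("span [%d, %d) snapped to covering token boundaries", s, e),
                call. = FALSE)
      }
      covered <- which(tokens$start < e & tokens$end > s)
    }
    if (!length(covered)) next
    tags[covered[1]] <- bio_label("B", spans$label[i])
    if (length(covered) > 1L) {
      tags[covered[-1]] <- bio_label("I", spans$label[i])
    }
  }
  tags
}

parse_bio_tag <- function(tag) {
  if (tag == "O") return(list(prefix = "O", label = NA_character_))
  if (!grepl("^[BI]-.+$", tag)) {
    stop_pkner("unknown BIO tag '%s'", tag, class = "pkner_validation")
  }
  list(prefix = substr(tag, 1, 1), label = substring(tag, 3))
}

#' Recover character-offset spans from token BIO labels
#'
#' Maximal `B-`/`I-` runs of one label become spans from the first token's
#' start to the last token's end. A dangling `I-X` (at sentence start, after
#' `O`, or after a different label) is repaired to `B-X`, i.e. it opens a new
#' span -- the standard conservative BIO repair.
#'
#' @param tokens token table from [pk_tokenize()].
#' @param tags character vector of BIO tags, one per token.
#' @return a span table ([pk_spans()]), sorted and non-overlapping.
#' @export
bio_to_spans <- function(tokens, tags) {
  if (length(tags) != nrow(tokens)) {
    stop_pkner("length(tags) == %d but %d tokens given", length(tags), nrow(tokens),
               class = "pkner_validation")
  }
  starts <- integer(); ends <- integer(); labels <- character()
  open <- FALSE; cur_label <- NA_character_; cur_start <- NA_integer_; cur_end <- NA_integer_
  close_span <- function() {
    if (open) {
      starts[[length(starts) + 1L]] <<- cur_start
      ends[[length(ends) + 1L]] <<- cur_end
      labels[[length(labels) + 1L]] <<- cur_label
    }
    open <<- FALSE
  }
  for (i in seq_along(tags)) {
    p <- parse_bio_tag(tags[i])
    if (p$prefix == "O") {
      close_span()
    } else if (p$prefix == "B" || !open || !identical(p$label, cur_label)) {
      # B- always opens; a dangling I- is repaired to B- and opens too
      close_span()
      open <- TRUE
      cur_label <- p$label
      cur_start <- tokens$start[i]
      cur_end <- tokens$end[i]
    } else {
      cur_end <- tokens$end[i]
    }
  }
  close_span()
  pk_spans(starts, ends, labels)
}

#' Check BIO validity of a tag sequence
#' @param tags character vector of BIO tags.
#' @return `TRUE` when no `I-X` follows `O`, start-of-sentence, or a
#'   different-label tag.
#' @export
is_bio_valid <- function(tags) {
  prev <- "O"
  for (tag in tags) {
    p <- parse_bio_tag(tag)
    if (p$prefix == "I") {
      pp <- parse_bio_tag(prev)
      if (pp$prefix == "O" || !identical(pp$label, p$label)) return(FALSE)
    }
    prev <- tag
  }
  TRUE
}

#' Tag a sentence's tokens with its gold spans
#' @param sentence a [pk_sentence()].
#' @param policy see [spans_to_bio()].
#' @return list with `sentence`, `tokens`, `tags` (a tagged-sentence record).
#' @export
tag_sentence <- function(sentence, policy = "snap") {
  tokens <- pk_tokenize(sentence$text)
  list(sentence = sentence, tokens = tokens,
       tags = spans_to_bio(tokens, sentence$spans, policy = policy))
}
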