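#' Load a token-pattern ruleset from its JSON schema file
#'
#' A ruleset is data, not code: one record per rule with an `id`, a `label`,
#' a `case_sensitive` flag, a token `pattern` (each element matching one
#' token by exact `form` or regular expression `re`, optionally skippable via
#' `opt`), and an optional lexical `context` gate (`required` / `forbidden`
#' neighbour terms within `window` tokens of the match).
#'
#' @param path path to a ruleset JSON file.
#' @return an object of class `pk_ruleset`.
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) stop_pkner("no such ruleset file: %s", path, class = "pkner_io")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- lapply(raw$rules, function(r) {
    list(
      id = r$id,
      label = r$label %||% "PK",
      case_sensitive = isTRUE(r$case_sensitive),
      pattern = lapply(r$pattern, function(el) {
        list(form = el$form %||% NULL, re = el$re %||% NULL, opt = isTRUE(el$opt))
      }),
      context = if (!is.null(r$context)) {
        list(
          required = as.character(unlist(r$context$required %||% list())),
          forbidden = as.character(unlist(r$context$forbidden %||% list())),
          window = as.integer(r$context$window %||% 5L)
        )
      } else {
        NULL
      }
    )
  })
  pk_ruleset(rules, version = raw$version %||% "unversioned")
}

#' Construct a ruleset
#' @param rules list of rule records (see [load_ruleset()] for the schema).
#' @param version version string.
#' @return an object of class `pk_ruleset`.
#' @export
pk_ruleset <- function(rules, version = "unversioned") {
  for (r in rules) {
    if (!is_string(r$id)) stop_pkner("every rule needs a string id", class = "pkner_validation")
    if (!length(r$pattern)) {
      stop_pkner("rule '%s': pattern must be non-empty", r$id, class = "pkner_validation")
    }
    if (!is.null(r$context) && r$context$window < 0L) {
      stop_pkner("rule '%s': context window must be >= 0", r$id, class = "pkner_validation")
    }
  }
  structure(list(rules = rules, version = version), class = "pk_ruleset")
}

#' The shipped PK ruleset
#'
#' Covers the long parameter names of [default_inventory()] with optional
#' modifier tokens (e.g. optional `total`/`body`/`apparent`/`oral` before
#' `clearance`), subscripted/range acronym patterns (`AUC0-24`, `AUC0-∞` via
#' a token regex), case-sensitive acronym rules, and a context-gated rule for
#' the ambiguous acronym `F` (fires only near bioavailability/dose/percent
#' vocabulary). PD terms such as AUEC and MTD are deliberately not covered.
#' The rule table ships as a reviewable JSON file under
#' `system.file("extdata", "pk_rules_v1.json", package = "pkner")`.
#'
#' @return an object of class `pk_ruleset`.
#' @export
default_pk_ruleset <- function() {
  load_ruleset(system.file("extdata", "pk_rules_v1.json", package = "pkner"))
}

#' @export
print.pk_ruleset <- function(x, ...) {
  cat(sprintf("<pk_ruleset v%s> %d rules: %s\n", x$version, length(x$rules),
              paste(vapply(x$rules, `[[`, character(1), "id"), collapse = ", ")))
  invisible(x)
}

#' Compile a ruleset into a matcher
#'
#' Validates rule ids (must be unique) and regular expressions; a broken
#' regex raises a compilation error naming the rule id.
#'
#' @param ruleset a [pk_ruleset()].
#' @return an object of class `pk_matcher`.
#' @export
compile_rules <- function(ruleset) {
  stopifnot(inherits(ruleset, "pk_ruleset"))
  ids <- vapply(ruleset$rules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop_pkner("duplicate rule id '%s'", ids[duplicated(ids)][1], class = "pkner_compile")
  }
  for (r in ruleset$rules) {
    for (el in r$pattern) {
      if (is.null(el$form) && is.null(el$re)) {
        stop_pkner("rule '%s': pattern element needs `form` or `re`", r$id,
                   class = "pkner_compile")
      }
      if (!is.null(el$re)) {
        ok <- tryCatch({ grepl(el$re, "x", perl = TRUE); TRUE },
                       error = function(e) FALSE, warning = function(w) FALSE)
        if (!ok) {
          stop_pkner("rule '%s': invalid regular expression '%s'", r$id, el$re,
                     class = "pkner_compile")
        }
      }
    }
  }
  structure(list(rules = ruleset$rules, version = ruleset$version), class = "pk_matcher")
}

# Longest number of tokens consumed by pattern elements ei.. starting at
# token position pos, or -1 when the pattern cannot match. Optional elements
# branch (skip vs consume) and the longer completion wins.
pattern_match_len <- function(pattern, ei, toks, toks_lower, pos, case_sensitive) {
  if (ei > length(pattern)) return(0L)
  el <- pattern[[ei]]
  best <- -1L
  if (isTRUE(el$opt)) {
    r <- pattern_match_len(pattern, ei + 1L, toks, toks_lower, pos, case_sensitive)
    if (r >= 0L) best <- r
  }
  if (pos <= length(toks)) {
    tok <- if (case_sensitive) toks[pos] else toks_lower[pos]
    hit <- if (!is.null(el$form)) {
      target <- if (case_sensitive) el$form else tolower(el$form)
      identical(tok, target)
    } else {
      grepl(el$re, toks[pos], perl = TRUE, ignore.case = !case_sensitive)
    }
    if (hit) {
      r <- pattern_match_len(pattern, ei + 1L, toks, toks_lower, pos + 1L, case_sensitive)
      if (r >= 0L && 1L + r > best) best <- 1L + r
    }
  }
  best
}

context_ok <- function(ctx, toks_lower, s, e) {
  if (is.null(ctx)) return(TRUE)
  n <- length(toks_lower)
  lo <- max(1L, s - ctx$window); hi <- min(n, e + ctx$window)
  idx <- setdiff(seq.int(lo, hi), seq.int(s, e))
  neigh <- toks_lower[idx]
  if (length(ctx$required) && !any(neigh %in% tolower(ctx$required))) return(FALSE)
  if (length(ctx$forbidden) && any(neigh %in% tolower(ctx$forbidden))) return(FALSE)
  TRUE
}

#' Apply a compiled matcher to text
#'
#' All rules are applied to the tokenised sentence; overlapping candidate
#' matches are resolved deterministically to the longest span (ties broken by
#' leftmost start, then by rule order in the ruleset). Context-gated rules
#' fire only when their lexical window constraint holds.
#'
#' @param matcher a [compile_rules()] result.
#' @param x a [pk_sentence()], a [pk_corpus()], or a character string.
#' @return for a sentence or string, a span table ([pk_spans()]); for a
#'   corpus, a predicted corpus with the same sentence ids and texts.
#' @examples
#' m <- compile_rules(default_pk_ruleset())
#' match_rules(m, "The total body clearance was reduced")
#' @export
match_rules <- function(matcher, x) {
  stopifnot(inherits(matcher, "pk_matcher"))
  if (inherits(x, "pk_corpus")) {
    sentences <- lapply(x$sentences, function(s) {
      pk_sentence(s$id, s$text, match_rules(matcher, s$text),
                  section = s$section, doc_id = s$doc_id)
    })
    return(pk_corpus(sentences, split = x$split))
  }
  text <- if (inherits(x, "pk_sentence")) x$text else x
  stopifnot(is_string(text))
  tokens <- pk_tokenize(text)
  n <- nrow(tokens)
  if (n == 0L) return(empty_spans())
  toks <- tokens$text
  toks_lower <- tolower(toks)
  cand <- list()
  for (ri in seq_along(matcher$rules)) {
    r <- matcher$rules[[ri]]
    for (s in seq_len(n)) {
      len <- pattern_match_len(r$pattern, 1L, toks, toks_lower, s, r$case_sensitive)
      if (len > 0L) {
        e <- s + len - 1L
        if (!context_ok(r$context, toks_lower, s, e)) next
        cand[[length(cand) + 1L]] <- list(
          cs = tokens$start[s], ce = tokens$end[e], label = r$label, rule = ri
        )
      }
    }
  }
  if (!length(cand)) return(empty_spans())
  cs <- vapply(cand, `[[`, integer(1), "cs")
  ce <- vapply(cand, `[[`, integer(1), "ce")
  ord <- order(-(ce - cs), cs, vapply(cand, `[[`, integer(1), "rule"))
  keep_s <- integer(); keep_e <- integer(); keep_l <- character()
  for (k in ord) {
    if (any(cs[k] < keep_e & ce[k] > keep_s)) next
    keep_s <- c(keep_s, cs[k]); keep_e <- c(keep_e, ce[k])
    keep_l <- c(keep_l, cand[[k]]$label)
  }
  o <- order(keep_s)
  pk_spans(keep_s[o], keep_e[o], keep_l[o])
}
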