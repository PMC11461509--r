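#' Corpus statistics
#'
#' Sentence and entity-mention counts of a corpus in the layout of standard
#' NER corpus reports: number of sentences, total entity mentions, percentage
#' of sentences containing at least one mention, and percentage of sentences
#' drawn from full text (vs abstracts). Percentages are reported to two
#' decimals. An empty corpus yields zero counts with `undefined_pct = TRUE`
#' rather than a division failure.
#'
#' @param corpus a [pk_corpus()].
#' @return an object of class `pk_corpus_stats` with fields `n_sentences`,
#'   `n_mentions`, `pct_with_mentions`, `pct_full_text`, `undefined_pct`,
#'   and `n_section_imputed` (sentences whose section was defaulted at load).
#' @export
corpus_stats <- function(corpus) {
  validate_corpus(corpus)
  n <- length(corpus)
  mentions <- vapply(corpus$sentences, function(s) nrow(s$spans), integer(1))
  full_text <- vapply(corpus$sentences, function(s) s$section == "full_text", logical(1))
  imputed <- vapply(corpus$sentences, function(s) isTRUE(s$section_imputed), logical(1))
  structure(
    list(
      split = corpus$split,
      n_sentences = n,
      n_mentions = sum(mentions),
      pct_with_mentions = if (n) round2(100 * mean(mentions > 0L)) else 0,
      pct_full_text = if (n) round2(100 * mean(full_text)) else 0,
      undefined_pct = n == 0L,
      n_section_imputed = sum(imputed)
    ),
    class = "pk_corpus_stats"
  )
}

#' @export
print.pk_corpus_stats <- function(x, ...) {
  cat(sprintf("Corpus statistics (split = %s)\n", x$split))
  cat(sprintf("  sentences:               %d\n", x$n_sentences))
  cat(sprintf("  entity mentions:         %d\n", x$n_mentions))
  if (x$undefined_pct) {
    cat("  percentages undefined (empty corpus)\n")
  } else {
    cat(sprintf("  sentences with mentions: %.2f%%\n", x$pct_with_mentions))
    cat(sprintf("  full-text sentences:     %.2f%%\n", x$pct_full_text))
  }
  if (x$n_section_imputed > 0L) {
    cat(sprintf("  note: %d sentence(s) had no section field (imputed full_text)\n",
                x$n_section_imputed))
  }
  invisible(x)
}
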