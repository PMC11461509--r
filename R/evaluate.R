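#' Align gold and predicted spans into MUC-style match categories
#'
#' Each gold span is matched to at most one prediction and vice versa, in
#' span order, with exact-boundary matches claimed before partial overlaps:
#' exact boundaries and equal label count as COR; exact boundaries with a
#' different label as INC; an overlap of at least one character as PAR;
#' leftover gold spans are MIS (missed) and leftover predictions SPU
#' (spurious). The counts always satisfy `COR + INC + PAR + MIS = n_gold`
#' and `COR + INC + PAR + SPU = n_pred`.
#'
#' @param gold,pred span tables ([pk_spans()]); each must be sorted and
#'   non-overlapping.
#' @return an object of class `pk_match_counts` with fields `COR`, `INC`,
#'   `PAR`, `MIS`, `SPU`.
#' @export
align_spans <- function(gold, pred) {
  gold <- check_eval_spans(gold, "gold")
  pred <- check_eval_spans(pred, "pred")
  ng <- nrow(gold); np <- nrow(pred)
  gold_m <- rep(FALSE, ng); pred_m <- rep(FALSE, np)
  COR <- 0L; INC <- 0L; PAR <- 0L
  # pass 1: exact boundary matches
  for (i in seq_len(ng)) {
    j <- which(!pred_m & pred$start == gold$start[i] & pred$end == gold$end[i])
    if (length(j)) {
      j <- j[1]
      gold_m[i] <- TRUE; pred_m[j] <- TRUE
      if (identical(pred$label[j], gold$label[i])) COR <- COR + 1L else INC <- INC + 1L
    }
  }
  # pass 2: partial overlaps (>= 1 character), greedy in span order
  for (i in seq_len(ng)) {
    if (gold_m[i]) next
    j <- which(!pred_m & pred$start < gold$end[i] & pred$end > gold$start[i])
    if (length(j)) {
      gold_m[i] <- TRUE; pred_m[j[1]] <- TRUE
      PAR <- PAR + 1L
    }
  }
  new_match_counts(COR, INC, PAR, MIS = sum(!gold_m), SPU = sum(!pred_m))
}

check_eval_spans <- function(spans, what) {
  spans <- as_span_df(spans)
  if (nrow(spans) > 1L) {
    o <- order(spans$start, spans$end)
    spans <- spans[o, , drop = FALSE]
    if (any(spans$start[-1L] < spans$end[-nrow(spans)])) {
      stop_pkner("%s spans overlap within one list", what, class = "pkner_validation")
    }
  }
  spans
}

new_match_counts <- function(COR, INC, PAR, MIS, SPU) {
  counts <- list(COR = as.integer(COR), INC = as.integer(INC), PAR = as.integer(PAR),
                 MIS = as.integer(MIS), SPU = as.integer(SPU))
  structure(counts, class = "pk_match_counts")
}

#' Combine match counts
#' @param ... `pk_match_counts` objects.
#' @return their field-wise sum, a `pk_match_counts`.
#' @export
sum_match_counts <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && is.list(cs[[1]]) && !inherits(cs[[1]], "pk_match_counts")) {
    cs <- cs[[1]]
  }
  tot <- Reduce(function(a, b) Map(`+`, a, b), lapply(cs, unclass))
  new_match_counts(tot$COR, tot$INC, tot$PAR, tot$MIS, tot$SPU)
}

#' @export
print.pk_match_counts <- function(x, ...) {
  cat(sprintf("COR=%d INC=%d PAR=%d MIS=%d SPU=%d\n", x$COR, x$INC, x$PAR, x$MIS, x$SPU))
  invisible(x)
}

#' Entity-level precision, recall and F1 from match counts
#'
#' Strict matching credits only exact-boundary, correct-label matches:
#' `P = COR / (COR + INC + PAR + SPU)` and `R = COR / (COR + INC + PAR + MIS)`
#' (the denominators are the numbers of predicted and gold entities). Partial
#' matching gives half credit to partial overlaps, replacing `COR` with
#' `COR + 0.5 * PAR` in both numerators. F1 is the harmonic mean. Values are
#' percentages rounded to two decimals; a zero denominator yields 0 with
#' `empty_input = TRUE` rather than a failure.
#'
#' @param counts a [align_spans()] result.
#' @param scheme `"strict"` or `"partial"`.
#' @return list with `precision`, `recall`, `f1` (percent) and `empty_input`.
#' @export
score_counts <- function(counts, scheme = c("strict", "partial")) {
  scheme <- match.arg(scheme)
  vals <- unlist(counts[c("COR", "INC", "PAR", "MIS", "SPU")])
  if (any(vals < 0)) stop_pkner("negative match counts", class = "pkner_validation")
  n_pred <- counts$COR + counts$INC + counts$PAR + counts$SPU
  n_gold <- counts$COR + counts$INC + counts$PAR + counts$MIS
  num <- if (scheme == "strict") counts$COR else counts$COR + 0.5 * counts$PAR
  p <- if (n_pred > 0) 100 * num / n_pred else 0
  r <- if (n_gold > 0) 100 * num / n_gold else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = round2(p), recall = round2(r), f1 = round2(f1),
       empty_input = n_pred == 0L || n_gold == 0L)
}

#' Evaluate a predicted corpus against gold annotations
#'
#' Counts are summed over sentences before scoring (micro-average), the
#' convention of entity-level NER evaluation.
#'
#' @param gold,pred [pk_corpus()] objects over the same sentence ids.
#' @return an object of class `pk_eval` with `strict` and `partial`
#'   precision/recall/F1 blocks, the pooled `counts`, and `n_sentences`.
#' @export
evaluate_corpus <- function(gold, pred) {
  gid <- corpus_ids(gold); pid <- corpus_ids(pred)
  missing_ids <- c(setdiff(gid, pid), setdiff(pid, gid))
  if (length(missing_ids)) {
    stop_pkner("gold/pred sentence ids do not align; missing: %s",
               paste(head(missing_ids, 5), collapse = ", "), class = "pkner_alignment")
  }
  pred_by_id <- setNames(pred$sentences, pid)
  counts <- sum_match_counts(lapply(gold$sentences, function(g) {
    align_spans(g$spans, pred_by_id[[g$id]]$spans)
  }))
  structure(list(
    strict = score_counts(counts, "strict"),
    partial = score_counts(counts, "partial"),
    counts = counts,
    n_sentences = length(gold)
  ), class = "pk_eval")
}

#' @export
print.pk_eval <- function(x, ...) {
  cat(sprintf("Entity-level evaluation over %d sentences\n", x$n_sentences))
  cat(sprintf("  counts:  COR=%d INC=%d PAR=%d MIS=%d SPU=%d\n",
              x$counts$COR, x$counts$INC, x$counts$PAR, x$counts$MIS, x$counts$SPU))
  cat(sprintf("  strict:  P=%6.2f R=%6.2f F1=%6.2f\n",
              x$strict$precision, x$strict$recall, x$strict$f1))
  cat(sprintf("  partial: P=%6.2f R=%6.2f F1=%6.2f\n",
              x$partial$precision, x$partial$recall, x$partial$f1))
  invisible(x)
}

#' Pairwise-F1 inter-annotator agreement
#'
#' Agreement between annotators is measured as entity-level strict F1,
#' treating one annotator's spans as ground truth and the other's as system
#' predictions. Because swapping gold and prediction exchanges precision and
#' recall, F1 is symmetric and the matrix needs only its upper triangle
#' computed. The mean pairwise F1 excludes the diagonal (which is 100 by
#' construction).
#'
#' @param annotations named list of [pk_corpus()] objects (one per
#'   annotator) over identical sentence id sets; at least two annotators.
#' @return an object of class `pk_iaa`: fields `f1` (symmetric matrix, %)
#'   and `mean_pairwise`.
#' @export
pairwise_iaa <- function(annotations) {
  k <- length(annotations)
  if (k < 2L) stop_pkner("need at least two annotators", class = "pkner_validation")
  ids <- lapply(annotations, corpus_ids)
  for (i in seq_len(k)) {
    if (!setequal(ids[[i]], ids[[1]])) {
      stop_pkner("annotator %d covers a different sentence set", i,
                 class = "pkner_alignment")
    }
  }
  nms <- names(annotations) %||% paste0("annotator", seq_len(k))
  m <- diag(100, k)
  dimnames(m) <- list(nms, nms)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      f1 <- evaluate_corpus(annotations[[i]], annotations[[j]])$strict$f1
      m[i, j] <- f1; m[j, i] <- f1
    }
  }
  structure(list(f1 = m, mean_pairwise = round2(mean(m[upper.tri(m)]))),
            class = "pk_iaa")
}

#' @export
print.pk_iaa <- function(x, ...) {
  cat("Pairwise strict-F1 inter-annotator agreement (%)\n")
  print(round(x$f1, 2))
  cat(sprintf("Mean pairwise F1: %.2f\n", x$mean_pairwise))
  invisible(x)
}
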