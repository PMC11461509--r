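# Brute-force matching oracle for entity-level evaluation, independent of the
# implementation in align_spans(): enumerate every injective gold<->pred
# matching in which matched pairs overlap by at least one character, and keep
# the matching that maximises (number of exact-boundary pairs, then total
# matched pairs) lexicographically.
oracle_align <- function(gold, pred) {
  ng <- nrow(gold); np <- nrow(pred)
  best_score <- c(-1L, -1L)
  best_assign <- rep(NA_integer_, ng)
  assign <- rep(NA_integer_, ng)
  used <- rep(FALSE, np)
  rec <- function(i, n_exact, n_match) {
    if (i > ng) {
      if (n_exact > best_score[1] ||
          (n_exact == best_score[1] && n_match > best_score[2])) {
        best_score <<- c(n_exact, n_match)
        best_assign <<- assign
      }
      return(invisible())
    }
    rec(i + 1L, n_exact, n_match)      # leave gold i unmatched
    for (j in seq_len(np)) {
      if (used[j]) next
      if (pred$start[j] < gold$end[i] && pred$end[j] > gold$start[i]) {
        ex <- pred$start[j] == gold$start[i] && pred$end[j] == gold$end[i]
        used[j] <<- TRUE; assign[i] <<- j
        rec(i + 1L, n_exact + ex, n_match + 1L)
        used[j] <<- FALSE; assign[i] <<- NA_integer_
      }
    }
  }
  rec(1L, 0L, 0L)
  COR <- 0L; INC <- 0L; PAR <- 0L
  for (i in seq_len(ng)) {
    j <- best_assign[i]
    if (is.na(j)) next
    if (pred$start[j] == gold$start[i] && pred$end[j] == gold$end[i]) {
      if (identical(pred$label[j], gold$label[i])) COR <- COR + 1L else INC <- INC + 1L
    } else {
      PAR <- PAR + 1L
    }
  }
  matched <- sum(!is.na(best_assign))
  list(COR = COR, INC = INC, PAR = PAR, MIS = ng - matched, SPU = np - matched)
}

# Precision/recall/F1 written out independently from the package's
# score_counts(): numerator COR (strict) or COR + PAR/2 (partial) over the
# number of predicted / gold entities.
oracle_score <- function(cnt, scheme) {
  n_pred <- cnt$COR + cnt$INC + cnt$PAR + cnt$SPU
  n_gold <- cnt$COR + cnt$INC + cnt$PAR + cnt$MIS
  num <- if (scheme == "strict") cnt$COR else cnt$COR + cnt$PAR / 2
  p <- if (n_pred > 0) 100 * num / n_pred else 0
  r <- if (n_gold > 0) 100 * num / n_gold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = round(p, 2), recall = round(r, 2), f1 = round(f, 2))
}

# Random sorted non-overlapping span list on [0, space); labels mostly "PK"
# with an occasional second class so the incorrect-label path is exercised.
random_span_list <- function(max_spans = 6L, space = 40L) {
  k <- sample(0:max_spans, 1L)
  if (k == 0L) return(pk_spans())
  pts <- sort(sample(0:space, 2L * k))
  pk_spans(pts[seq(1L, 2L * k, by = 2L)], pts[seq(2L, 2L * k, by = 2L)],
           sample(c("PK", "PD"), k, replace = TRUE, prob = c(0.85, 0.15)))
}
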