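#' Configuration for the synthetic PK-sentence generator
#'
#' The generator emulates the statistical structure of a span-annotated PK
#' sentence corpus: a single `"PK"` entity class; an entity prevalence of
#' 16.4% under random sampling of the PK literature versus about 64% in
#' selectively sampled training data (the two regimes are selected via
#' `prevalence`); long multi-token mentions with complementary modifiers;
#' context-dependent acronyms ("F"); and pharmacodynamic distractors (AUEC,
#' MTD) in non-entity sentences.
#'
#' @param n_sentences number of sentences to generate.
#' @param prevalence fraction of sentences containing at least one PK span.
#'   Default 0.164, the random-sampling regime.
#' @param ambiguity_rate fraction of entity sentences that use the
#'   context-dependent acronym "F" (with its long form); the same fraction of
#'   plain filler sentences mentions "F" as a test statistic. Default 0.2.
#' @param distractor_rate fraction of non-entity sentences containing a PD
#'   distractor term. Default 0.3.
#' @param pct_full_text fraction of sentences tagged as full text (the
#'   remainder are abstracts). Default 0.508, matching randomly sampled
#'   evaluation splits.
#' @param seed integer seed; generation is deterministic given the seed.
#' @param vocabulary a [default_inventory()]-shaped surface-form inventory.
#' @return an object of class `pk_generator_config`.
#' @export
generator_config <- function(n_sentences = 1000L,
                             prevalence = 0.164,
                             ambiguity_rate = 0.2,
                             distractor_rate = 0.3,
                             pct_full_text = 0.508,
                             seed = 1L,
                             vocabulary = default_inventory()) {
  rates <- c(prevalence = prevalence, ambiguity_rate = ambiguity_rate,
             distractor_rate = distractor_rate, pct_full_text = pct_full_text)
  if (any(rates < 0 | rates > 1)) {
    stop_pkner("rate '%s' must lie in [0, 1]", names(rates)[which(rates < 0 | rates > 1)][1],
               class = "pkner_config")
  }
  if (n_sentences < 0) {
    stop_pkner("n_sentences must be >= 0", class = "pkner_config")
  }
  validate_inventory(vocabulary)
  structure(list(
    n_sentences = as.integer(n_sentences), prevalence = prevalence,
    ambiguity_rate = ambiguity_rate, distractor_rate = distractor_rate,
    pct_full_text = pct_full_text, seed = as.integer(seed),
    vocabulary = vocabulary
  ), class = "pk_generator_config")
}

.gen_drugs <- c("midazolam", "caffeine", "rifampicin", "metformin", "warfarin",
                "ibuprofen", "digoxin", "artemether", "tacrolimus", "voriconazole")
.gen_units <- c("L/h", "mL/min", "L", "mg·h/L", "ng/mL", "h", "1/h")
.gen_groups <- c("healthy volunteers", "fasted subjects", "paediatric patients",
                 "renally impaired patients", "elderly participants")

gen_val <- function(lo = 0.5, hi = 50) formatC(round(runif(1, lo, hi), 1), format = "f", digits = 1)
gen_int <- function(lo, hi) as.character(sample(seq.int(lo, hi), 1))
cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substring(x, 2))

# A sentence is assembled from segments; `ent` segments receive gold spans
# covering exactly the inserted surface form.
seg_lit <- function(text) list(text = text, ent = FALSE)
seg_ent <- function(text, label = "PK") list(text = text, ent = TRUE, label = label)

assemble_sentence <- function(id, segments, section, doc_id) {
  text <- ""
  starts <- integer(); ends <- integer(); labels <- character()
  for (sg in segments) {
    if (isTRUE(sg$ent)) {
      starts <- c(starts, nchar(text))
      ends <- c(ends, nchar(text) + nchar(sg$text))
      labels <- c(labels, sg$label)
    }
    text <- paste0(text, sg$text)
  }
  pk_sentence(id, text, pk_spans(starts, ends, labels), section = section, doc_id = doc_id)
}

sample_forms <- function(inv, k) {
  pool <- c(inv$long_forms, inv$acronyms)
  forms <- pool[sample.int(length(pool), k)]
  # AUC acronyms carry a variable integration window in real prose
  vapply(forms, function(f) {
    if (grepl("^AUC0-", f)) {
      paste0("AUC0-", sample(c("6", "8", "12", "24", "48", "72", "t", "tau", "∞"), 1))
    } else {
      f
    }
  }, character(1), USE.NAMES = FALSE)
}

entity_segments <- function(inv) {
  k <- sample.int(3L, 1L, prob = c(0.6, 0.3, 0.1))
  drug <- sample(.gen_drugs, 1)
  forms <- sample_forms(inv, k)
  if (k == 1L) {
    tno <- sample.int(3L, 1L)
    if (tno == 1L) {
      list(seg_lit("The "), seg_ent(forms[1]),
           seg_lit(sprintf(" of %s was %s %s in %s.", drug, gen_val(),
                           sample(.gen_units, 1), sample(.gen_groups, 1))))
    } else if (tno == 2L) {
      list(seg_lit("Mean "), seg_ent(forms[1]),
           seg_lit(sprintf(" was %s %s after a single oral dose.", gen_val(),
                           sample(.gen_units, 1))))
    } else {
      list(seg_lit("After repeated dosing, the "), seg_ent(forms[1]),
           seg_lit(sprintf(" of %s increased from %s to %s %s.", drug, gen_val(),
                           gen_val(), sample(.gen_units, 1))))
    }
  } else if (k == 2L) {
    list(seg_lit(""), seg_ent(cap1(forms[1])), seg_lit(" and "), seg_ent(forms[2]),
         seg_lit(sprintf(" of %s were %s %s and %s %s, respectively.", drug,
                         gen_val(), sample(.gen_units, 1), gen_val(),
                         sample(.gen_units, 1))))
  } else {
    list(seg_lit("Estimates of "), seg_ent(forms[1]), seg_lit(", "),
         seg_ent(forms[2]), seg_lit(" and "), seg_ent(forms[3]),
         seg_lit(" were obtained by noncompartmental analysis."))
  }
}

# Entity sentence exercising the context-dependent acronym "F": the long
# bioavailability form and "F" both receive gold spans, with dose/percent
# context nearby so the shipped context rule can fire.
ambiguous_entity_segments <- function(inv) {
  pct <- gen_int(10, 95)
  drug <- sample(.gen_drugs, 1)
  tno <- sample.int(3L, 1L)
  if (tno == 1L) {
    list(seg_lit("The "), seg_ent("absolute bioavailability"), seg_lit(" ("),
         seg_ent("F"), seg_lit(sprintf(") of %s was %s%%.", drug, pct)))
  } else if (tno == 2L) {
    list(seg_lit(""), seg_ent("Oral bioavailability"), seg_lit(" ("), seg_ent("F"),
         seg_lit(sprintf(") was %s%% after administration of %s.", pct, drug)))
  } else {
    list(seg_lit("The "), seg_ent("bioavailability"), seg_lit(" ("), seg_ent("F"),
         seg_lit(sprintf(") averaged %s%% in the fed state.", pct)))
  }
}

distractor_segments <- function(inv) {
  dis <- sample(inv$distractors, 1)
  tno <- sample.int(3L, 1L)
  if (tno == 1L) {
    list(seg_lit(sprintf("The %s was %s %s in the dose-escalation study.",
                         dis, gen_val(), sample(c("ng/mL", "mg"), 1))))
  } else if (tno == 2L) {
    list(seg_lit(sprintf("%s values did not differ significantly between groups.",
                         cap1(dis))))
  } else {
    list(seg_lit(sprintf("The %s of %s was reached at the highest dose level.",
                         dis, sample(.gen_drugs, 1))))
  }
}

# Non-entity filler; a slice of it mentions "F" as a test statistic, the
# negative context class for the acronym gate.
filler_segments <- function(use_f_statistic) {
  if (use_f_statistic) {
    v <- gen_val(1, 20)
    switch(sample.int(6L, 1L),
      list(seg_lit(sprintf("The F statistic was %s for the ANOVA model.", v))),
      list(seg_lit(sprintf("A one-way ANOVA gave F = %s with p < 0.05.", v))),
      list(seg_lit(sprintf("Analysis of variance yielded an F value of %s.", v))),
      list(seg_lit(sprintf("The F test indicated no significant difference (F = %s).", v))),
      list(seg_lit(sprintf("F ratios ranged from %s to %s across subgroups.", v,
                           gen_val(1, 20)))),
      list(seg_lit("Between-group differences were assessed with an F test."))
    )
  } else {
    tno <- sample.int(5L, 1L)
    switch(tno,
      list(seg_lit(sprintf("Blood samples were collected at %s time points over %s h.",
                           gen_int(4, 16), gen_int(12, 96)))),
      list(seg_lit(sprintf("Patients received %s mg of %s twice daily for %s days.",
                           gen_int(5, 400), sample(.gen_drugs, 1), gen_int(3, 28)))),
      list(seg_lit("Plasma concentrations were determined by a validated LC-MS/MS assay.")),
      list(seg_lit(sprintf("The study enrolled %s healthy subjects aged %s to %s years.",
                           gen_int(8, 60), gen_int(18, 30), gen_int(45, 75)))),
      list(seg_lit("No serious adverse events were reported during the trial."))
    )
  }
}

#' Generate a synthetic PK corpus with gold spans
#'
#' Template-based, fully deterministic for a fixed seed. Entity sentences
#' embed 1--3 PK surface forms (gold spans cover them exactly); a configurable
#' fraction uses the ambiguous acronym "F" in a bioavailability context.
#' Non-entity sentences are either methods-style filler (some mentioning "F"
#' as a test statistic) or PD-distractor sentences (AUEC, MTD, ...), which
#' never receive spans. Realised prevalence is binomial around
#' `config$prevalence`.
#'
#' @param config a [generator_config()].
#' @return a [pk_corpus()] with split `"pool"`.
#' @examples
#' corp <- generate_corpus(generator_config(n_sentences = 50, seed = 7))
#' corpus_stats(corp)
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "pk_generator_config"))
  inv <- config$vocabulary
  with_seed(config$seed, {
    sentences <- vector("list", config$n_sentences)
    for (i in seq_len(config$n_sentences)) {
      is_entity <- runif(1) < config$prevalence
      section <- if (runif(1) < config$pct_full_text) "full_text" else "abstract"
      segs <- if (is_entity) {
        if (runif(1) < config$ambiguity_rate) {
          ambiguous_entity_segments(inv)
        } else {
          entity_segments(inv)
        }
      } else if (runif(1) < config$distractor_rate) {
        distractor_segments(inv)
      } else {
        # statistical-test mentions of "F" are an occasional feature of
        # methods prose, far rarer than PK mentions of F
        filler_segments(use_f_statistic = runif(1) < 0.15 * config$ambiguity_rate)
      }
      sentences[[i]] <- assemble_sentence(
        sprintf("syn-%06d", i), segs, section,
        doc_id = sprintf("doc-%04d", (i - 1L) %/% 8L + 1L)
      )
    }
    pk_corpus(sentences, split = "pool")
  })
}

#' Partition a corpus into train/dev/test splits
#'
#' @param corpus a [pk_corpus()].
#' @param fractions numeric vector of three fractions summing to 1.
#' @param seed integer seed for the permutation.
#' @return named list of three `pk_corpus` objects (`train`, `dev`, `test`);
#'   disjoint, exhaustive, reproducible per seed.
#' @export
make_splits <- function(corpus, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop_pkner("`fractions` must be three numbers summing to 1", class = "pkner_config")
  }
  n <- length(corpus)
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  perm <- with_seed(seed, sample.int(n))
  grp <- factor(rep.int(seq_along(sizes), times = sizes), levels = 1:3)
  idx <- split(perm, grp)
  names(idx) <- c("train", "dev", "test")
  out <- lapply(names(idx), function(nm) {
    sub <- corpus[sort(idx[[nm]])]
    sub$split <- nm
    sub
  })
  names(out) <- names(idx)
  out
}
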