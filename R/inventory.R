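#' Default inventory of PK surface forms and distractors
#'
#' The surface forms a PK named-entity recogniser has to deal with fall into
#' three groups: long multi-token parameter names that carry complementary
#' modifiers ("total body clearance", "apparent volume of distribution"),
#' compact acronyms ("CL/F", "AUC0-24", "t1/2"), and context-dependent
#' acronyms -- above all "F" for bioavailability, which outside a dosing or
#' bioavailability context is usually a test statistic. Alongside these sit
#' pharmacodynamic (PD) distractors such as AUEC (area under the effect
#' curve) and MTD (maximum tolerated dose) that look like PK parameters but
#' are out of class.
#'
#' @return an object of class `pk_inventory` with fields `long_forms`,
#'   `acronyms`, `ambiguous_acronyms` and `distractors`. Distractors are
#'   disjoint from the PK surface forms.
#' @export
default_inventory <- function() {
  inv <- structure(list(
    long_forms = c(
      "clearance",
      "total clearance",
      "total body clearance",
      "apparent clearance",
      "apparent oral clearance",
      "oral clearance",
      "systemic clearance",
      "renal clearance",
      "hepatic clearance",
      "intrinsic clearance",
      "volume of distribution",
      "apparent volume of distribution",
      "steady-state volume of distribution",
      "half-life",
      "elimination half-life",
      "terminal half-life",
      "absorption half-life",
      "area under the curve",
      "area under the concentration-time curve",
      "elimination rate constant",
      "absorption rate constant",
      "bioavailability",
      "absolute bioavailability",
      "oral bioavailability",
      "mean residence time",
      "time to peak concentration",
      "peak plasma concentration",
      "maximum plasma concentration",
      "trough concentration",
      "lag time",
      "accumulation ratio",
      long_tail_forms()
    ),
    acronyms = c(
      "CL", "CL/F", "CLr", "AUC", "AUC0-24", "AUC0-t", "AUC0-∞",
      "Cmax", "Tmax", "Cmin", "Ctrough", "t1/2", "Vd", "Vss", "Vz/F",
      "ke", "ka", "MRT"
    ),
    ambiguous_acronyms = c("F"),
    distractors = c(
      "AUEC", "MTD", "Emax", "EC50", "ED50",
      "maximum tolerated dose", "area under the effect curve"
    )
  ), class = "pk_inventory")
  validate_inventory(inv)
  inv
}

# Combinatorial long tail of parameter mentions: study-level qualifiers
# composed with parameter heads, emulating the open-ended surface variety of
# PK prose ("dose-normalized trough concentration", "apparent mean residence
# time", ...). Real mention variety far exceeds what a few hundred randomly
# sampled sentences can cover, which is what makes selective sampling of
# informative sentences pay off.
long_tail_forms <- function() {
  heads <- c(
    "mean residence time", "trough concentration", "lag time",
    "accumulation ratio", "time to peak concentration",
    "peak plasma concentration", "maximum plasma concentration",
    "fraction unbound", "unbound fraction", "mean absorption time",
    "absorption lag time", "first-pass extraction ratio",
    "fraction absorbed", "partition coefficient"
  )
  modifiers <- c("apparent", "mean", "median", "steady-state",
                 "dose-normalized", "weight-normalized", "baseline-adjusted")
  combos <- unlist(lapply(heads, function(h) {
    first <- pk_tokenize(h)$text[1]
    ok <- modifiers[modifiers != first]
    paste(ok, h)
  }))
  unique(combos)
}

validate_inventory <- function(inv) {
  pk_forms <- c(inv$long_forms, inv$acronyms, inv$ambiguous_acronyms)
  if (!length(pk_forms)) {
    stop_pkner("inventory has no PK surface forms", class = "pkner_config")
  }
  clash <- intersect(tolower(inv$distractors), tolower(pk_forms))
  if (length(clash)) {
    stop_pkner("distractor '%s' collides with a PK surface form", clash[1],
               class = "pkner_config")
  }
  invisible(inv)
}

#' @export
print.pk_inventory <- function(x, ...) {
  cat(sprintf("<pk_inventory> %d long forms, %d acronyms, %d ambiguous, %d distractors\n",
              length(x$long_forms), length(x$acronyms),
              length(x$ambiguous_acronyms), length(x$distractors)))
  invisible(x)
}

# Lowercased token inventory of all PK surface forms; used as the tagger's
# lexicon feature and for sanity checks.
inventory_lexicon <- function(inv = default_inventory()) {
  forms <- c(inv$long_forms, inv$acronyms, inv$ambiguous_acronyms)
  unique(tolower(unlist(lapply(forms, function(f) pk_tokenize(f)$text))))
}
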