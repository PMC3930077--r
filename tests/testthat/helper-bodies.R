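# Fixture builders: bodies of evidence shaped like the worked headache-
# persistence examples, plus small constructors used across the suite.

options(prognograde.log_level = "error")

# risk-of-bias profile with `n_mod` moderate domains, the rest low
rob_mod <- function(n_mod) {
  do.call(rob_profile, as.list(c(rep("moderate", n_mod), rep("low", 6 - n_mod))))
}

# uniform profile at one level across all six domains
.rob_all <- function(level) do.call(rob_profile, as.list(rep(level, 6)))

mk_study <- function(id, or = NULL, lo = NA, hi = NA, n = 300L, phase = 1L,
                     rob = rob_profile("low", "low", "low", "low", "low", "low"),
                     events = NA, vars = NA, adjusted = TRUE,
                     uni_vote = NA_character_, mv_vote = NA_character_, ...) {
  effects <- if (is.null(or)) list() else
    list(effect_estimate("OR", or, lo, hi, adjusted = adjusted))
  study_record(id, phase, "prospective_cohort", n, rob,
               n_events = events, n_prognostic_variables = vars,
               effects = effects, uni_vote = uni_vote, mv_vote = mv_vote, ...)
}

# Three small studies at moderate risk of bias, same-direction precise
# estimates, one significant: limitations and publication bias downgrade,
# nothing else; grades to '+'.
body_headache_intensity <- function() {
  body_of_evidence("headache intensity", "headache persistence", list(
    mk_study("hi-1", 1.40, 1.10, 1.80, n = 180L, rob = rob_mod(4),
             adjusted = FALSE, uni_vote = "positive"),
    mk_study("hi-2", 1.20, 0.90, 1.60, n = 178L, rob = rob_mod(4),
             adjusted = FALSE, uni_vote = "null"),
    mk_study("hi-3", 1.15, 0.85, 1.55, n = 178L, rob = rob_mod(4),
             adjusted = FALSE, uni_vote = "null")))
}

# One significant risk estimate plus two studies reporting no association
# without any usable interval: inconsistency downgrades on top of
# limitations and publication bias.
body_age <- function() {
  body_of_evidence("age", "headache persistence", list(
    mk_study("age-1", 1.88, 1.65, 2.15, n = 289L, rob = rob_mod(4),
             adjusted = FALSE, uni_vote = "positive"),
    mk_study("age-2", n = 289L, rob = rob_mod(4), uni_vote = "null"),
    mk_study("age-3", n = 289L, rob = rob_mod(4), uni_vote = "null")))
}

# Single study, no effect estimate reported, events-per-variable inputs
# known: single-study inconsistency, unclear imprecision, indirect
# population; floors at '+'.
body_menstruation <- function() {
  body_of_evidence("menstruation", "migraine persistence", list(
    mk_study("wang", n = 449L, rob = rob_mod(4), events = 134L, vars = 14L,
             uni_vote = "null", indirect_population = TRUE)))
}

# Four moderate-risk studies, three with same-direction moderate effects:
# publication-bias exemption (k = 4) plus the effect-size upgrade; '+++'.
body_sex <- function() {
  body_of_evidence("sex", "headache persistence", list(
    mk_study("sex-1", 2.6, 1.30, 5.20, n = 818L, rob = rob_mod(4),
             uni_vote = "positive", mv_vote = "positive"),
    mk_study("sex-2", 2.7, 0.95, 7.70, n = 818L, rob = rob_mod(4),
             uni_vote = "null", mv_vote = "null"),
    mk_study("sex-3", 2.9, 0.98, 8.60, n = 818L, rob = rob_mod(4),
             uni_vote = "null", mv_vote = "null"),
    mk_study("sex-4", 1.2, 0.80, 1.80, n = 818L, rob = rob_mod(4),
             mv_vote = "null")))
}

# The six narrative summary-of-findings rows as flag patterns, in table
# order, with the printed overall grades.
published_rows <- function() {
  list(
    list(name = "Headache intensity", n = 536L, k = 3L, plus = "+",
         flags = c(study_limitations = "serious", inconsistency = "no_concern",
                   indirectness = "no_concern", imprecision = "no_concern",
                   publication_bias = "serious", effect_size = "absent",
                   dose_response = "absent")),
    list(name = "Age", n = 867L, k = 3L, plus = "+",
         flags = c(study_limitations = "serious", inconsistency = "serious",
                   indirectness = "no_concern", imprecision = "no_concern",
                   publication_bias = "serious", effect_size = "absent",
                   dose_response = "absent")),
    list(name = "Type of headache diagnosis", n = 249L, k = 3L, plus = "+",
         flags = c(study_limitations = "serious", inconsistency = "no_concern",
                   indirectness = "serious", imprecision = "no_concern",
                   publication_bias = "serious", effect_size = "present",
                   dose_response = "absent")),
    list(name = "Menstruation", n = 449L, k = 1L, plus = "+",
         flags = c(study_limitations = "serious", inconsistency = "serious",
                   indirectness = "serious", imprecision = "unclear",
                   publication_bias = "serious", effect_size = "absent",
                   dose_response = "absent")),
    list(name = "Sex", n = 3272L, k = 4L, plus = "+++",
         flags = c(study_limitations = "serious", inconsistency = "no_concern",
                   indirectness = "no_concern", imprecision = "no_concern",
                   publication_bias = "no_concern", effect_size = "present",
                   dose_response = "absent")),
    list(name = "Family history of pain", n = 654L, k = 2L, plus = "+",
         flags = c(study_limitations = "no_concern", inconsistency = "serious",
                   indirectness = "serious", imprecision = "no_concern",
                   publication_bias = "serious", effect_size = "present",
                   dose_response = "absent")))
}

# stub narrative bodies matching the six rows' participant/study counts
published_stub_bodies <- function() {
  rows <- published_rows()
  lapply(rows, function(r) {
    per <- r$n %/% r$k
    sizes <- rep(per, r$k)
    sizes[r$k] <- r$n - per * (r$k - 1L)
    studies <- lapply(seq_len(r$k), function(i)
      mk_study(sprintf("%s-%d", gsub(" ", "_", tolower(r$name)), i),
               n = sizes[i], rob = rob_mod(4), uni_vote = "null"))
    body_of_evidence(r$name, "headache persistence", studies)
  })
}
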