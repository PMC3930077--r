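test_that("the starting level follows the majority phase with a conservative tie-break", {
  mk <- function(phases) body_of_evidence("f", "o", lapply(seq_along(phases),
    function(i) mk_study(paste0("s", i), phase = phases[i])))
  expect_equal(starting_level(mk(c(1, 1, 1)))$level, 3L)
  expect_equal(starting_level(mk(c(3, 3)))$level, 4L)
  expect_equal(starting_level(mk(c(2, 2, 3)))$level, 4L)
  # tie between phase-1 and phase-2 studies resolves to moderate
  expect_equal(starting_level(mk(c(1, 1, 2, 2)))$level, 3L)
})

test_that("study limitations aggregate QUIPS domain ratings across studies", {
  # three studies each with 4/6 domains at moderate risk: serious
  b <- body_of_evidence("f", "o", lapply(1:3, function(i)
    mk_study(paste0("s", i), rob = rob_mod(4))))
  a <- assess_study_limitations(b)
  expect_equal(a$rating, "serious")
  expect_equal(a$level_delta, -1L)

  # all studies at low risk everywhere: no concern
  b2 <- body_of_evidence("f", "o", lapply(1:3, function(i) mk_study(paste0("s", i))))
  expect_equal(assess_study_limitations(b2)$rating, "no_concern")

  # all studies high on every domain: very serious, two levels
  b3 <- body_of_evidence("f", "o", lapply(1:3, function(i)
    mk_study(paste0("s", i), rob = .rob_all("high"))))
  a3 <- assess_study_limitations(b3)
  expect_equal(a3$rating, "very_serious")
  expect_equal(a3$level_delta, -2L)

  # minority at moderate risk does not drag the body down
  b4 <- body_of_evidence("f", "o", list(
    mk_study("s1", rob = rob_mod(4)), mk_study("s2"), mk_study("s3")))
  expect_equal(assess_study_limitations(b4)$rating, "no_concern")
})

test_that("a single-study body always downgrades for inconsistency", {
  b <- body_of_evidence("f", "o", list(mk_study("only", 1.5, 1.1, 2.0)))
  a <- assess_inconsistency(b)
  expect_equal(a$rating, "serious")
  expect_match(a$rationale, "not well established")
})

test_that("narrative inconsistency requires varying directions with minimal or unavailable overlap", {
  # one significant risk estimate, two null reports without intervals: serious
  a <- assess_inconsistency(body_age())
  expect_equal(a$rating, "serious")
  expect_match(a$rationale, "unavailable")

  # same direction, overlapping intervals: no concern
  expect_equal(assess_inconsistency(body_headache_intensity())$rating, "no_concern")

  # identical estimates across five studies: no concern
  b <- body_of_evidence("f", "o", lapply(1:5, function(i)
    mk_study(paste0("s", i), 1.6, 1.2, 2.1)))
  expect_equal(assess_inconsistency(b)$rating, "no_concern")

  # opposite directions with disjoint intervals: very serious
  b2 <- body_of_evidence("f", "o", list(
    mk_study("s1", 2.5, 2.0, 3.1), mk_study("s2", 0.4, 0.3, 0.55)))
  a2 <- assess_inconsistency(b2)
  expect_equal(a2$rating, "very_serious")
  expect_equal(a2$level_delta, -2L)
})

test_that("meta-analytic inconsistency needs two concurrent statistical signals", {
  mk_meta <- function(thetas, ses, cm = NULL) {
    studies <- Map(function(th, se, i)
      mk_study(paste0("s", i), exp(th), exp(th - qnorm(0.975) * se),
               exp(th + qnorm(0.975) * se), n = 1000L),
      thetas, ses, seq_along(thetas))
    body_of_evidence("f", "o", studies, synthesis_mode = "meta_analysis",
                     clinical_meaningfulness_of_differences = cm)
  }
  # strong heterogeneity: p tiny and I^2 large
  b <- mk_meta(c(-1.2, 1.0, 1.4, -0.9), rep(0.1, 4))
  expect_equal(assess_inconsistency(b)$rating %in% c("serious", "very_serious"), TRUE)
  # homogeneous: no concern
  b2 <- mk_meta(c(0.50, 0.52, 0.48, 0.51), rep(0.2, 4))
  expect_equal(assess_inconsistency(b2)$rating, "no_concern")
  # reviewer judges the differences not clinically meaningful: gate closes
  b3 <- mk_meta(c(-1.2, 1.0, 1.4, -0.9), rep(0.1, 4), cm = FALSE)
  expect_equal(assess_inconsistency(b3)$rating, "no_concern")
})

test_that("the I^2 trigger fires at the substantial-heterogeneity boundary", {
  b <- body_of_evidence("f", "o", list(
    mk_study("s1", 1.5, 1.2, 1.9), mk_study("s2", 1.6, 1.3, 2.0),
    mk_study("s3", 1.4, 1.1, 1.8)), synthesis_mode = "meta_analysis")
  mk_pooled <- function(i2) pooled_result(0.4, 0.1, 0.2, 0.6, Q = 20, df = 2,
                                          p_heterogeneity = 0.001,
                                          i_squared = i2, tau_squared = 0.1,
                                          k = 3)
  expect_equal(assess_inconsistency(b, pooled = mk_pooled(49.9))$rating, "no_concern")
  expect_equal(assess_inconsistency(b, pooled = mk_pooled(50.0))$rating, "serious")
})

test_that("indirectness downgrades on a majority of flagged studies, doubly on two dimensions", {
  # all three studies recruited from specialty clinics
  b <- body_of_evidence("f", "o", lapply(1:3, function(i)
    mk_study(paste0("s", i), indirect_population = TRUE)))
  a <- assess_indirectness(b)
  expect_equal(a$rating, "serious")
  expect_match(a$rationale, "population")

  b2 <- body_of_evidence("f", "o", lapply(1:3, function(i) mk_study(paste0("s", i))))
  expect_equal(assess_indirectness(b2)$rating, "no_concern")

  b3 <- body_of_evidence("f", "o", lapply(1:3, function(i)
    mk_study(paste0("s", i), indirect_population = TRUE, indirect_outcome = TRUE)))
  a3 <- assess_indirectness(b3)
  expect_equal(a3$rating, "very_serious")
  expect_equal(a3$level_delta, -2L)
})

test_that("sample-size adequacy follows the events-per-variable and endpoint-case rules", {
  th <- grade_thresholds()
  wang <- mk_study("wang", n = 449L, events = 134L, vars = 14L)
  # 134 events against 14 candidate variables misses the 10-per-variable rule
  expect_false(study_sample_adequate(wang, th))
  expect_true(study_sample_adequate(mk_study("s", events = 140L, vars = 14L), th))
  # continuous outcomes fall back to the 100-endpoint-case rule
  cont <- study_record("c", 1L, "prospective_cohort", 500L, rob_mod(0),
                       n_events = 100L, outcome_type = "continuous")
  expect_true(study_sample_adequate(cont, th))
  cont$n_events <- 99L
  expect_false(study_sample_adequate(cont, th))
  # author-provided justification short-circuits the rules of thumb
  just <- mk_study("j", events = 5L, vars = 14L, sample_size_justified = TRUE)
  expect_true(study_sample_adequate(just, th))
  # nothing reported: not judgeable
  expect_true(is.na(study_sample_adequate(mk_study("n"), th)))
})

test_that("imprecision is unclear when no study reports an estimate to judge", {
  a <- assess_imprecision(body_menstruation())
  expect_equal(a$rating, "unclear")
  expect_equal(a$level_delta, 0L)
  # the events-per-variable discrepancy is surfaced, not silently dropped
  expect_match(paste(a$notes, collapse = " "), "events-per-variable")
})

test_that("precise studies block the imprecision downgrade regardless of study count", {
  # two small precise studies: no downgrade even though k and n are small
  b <- body_of_evidence("f", "o", list(
    mk_study("s1", 1.9, 1.4, 2.4, n = 80L), mk_study("s2", 1.8, 1.3, 2.3, n = 70L)))
  expect_equal(assess_imprecision(b)$rating, "no_concern")

  # few, small, imprecise studies: serious
  b2 <- body_of_evidence("f", "o", list(
    mk_study("s1", 1.2, 0.3, 4.8, n = 60L, events = 10L, vars = 5L),
    mk_study("s2", 0.9, 0.2, 4.1, n = 55L, events = 9L, vars = 5L)))
  a2 <- assess_imprecision(b2)
  expect_equal(a2$rating, "serious")
  expect_equal(a2$level_delta, -1L)
})

test_that("publication bias is the default and is waived only with enough studies", {
  mk_k <- function(k) body_of_evidence("f", "o", lapply(seq_len(k), function(i)
    mk_study(paste0("s", i), 1.4, 1.1, 1.8)))
  a4 <- assess_publication_bias(mk_k(4))
  expect_equal(a4$rating, "no_concern")
  # all-phase-1 exemption records the no-double-downgrade rationale
  expect_match(a4$rationale, "no double-downgrade with phase")
  expect_equal(assess_publication_bias(mk_k(3))$rating, "serious")
  expect_equal(assess_publication_bias(mk_k(1))$rating, "serious")
})

test_that("effect magnitudes follow the published rules of thumb with reciprocal symmetry", {
  expect_equal(classify_effect_magnitude(effect_estimate("OR", 6.2)), "large")
  expect_equal(classify_effect_magnitude(effect_estimate("OR", 2.08)), "small")
  expect_equal(classify_effect_magnitude(effect_estimate("OR", 3.0)), "moderate")
  # protective effects classify by their reciprocal
  expect_equal(classify_effect_magnitude(effect_estimate("OR", 0.2)), "large")
  expect_equal(classify_effect_magnitude(effect_estimate("SMD", 0.8)), "large")
  expect_equal(classify_effect_magnitude(effect_estimate("SMD", -0.5)), "moderate")
  expect_equal(classify_effect_magnitude(effect_estimate("SMD", 0.49)), "small")
  # symmetry property over a grid of ratio values
  for (x in c(0.1, 0.24, 0.4, 0.9, 1.7, 2.5, 4.25, 6.2, 9.9)) {
    expect_identical(classify_effect_magnitude(effect_estimate("OR", x)),
                     classify_effect_magnitude(effect_estimate("OR", 1 / x)),
                     label = paste("OR", x))
  }
})

test_that("the effect-size upgrade needs a moderate-or-large pooled or majority effect", {
  # pooled OR of 3 is moderate: upgrade
  b <- body_of_evidence("f", "o", list(
    mk_study("s1", 3.1, 2.2, 4.4), mk_study("s2", 2.9, 2.1, 4.0)),
    synthesis_mode = "meta_analysis")
  a <- assess_effect_size_upgrade(b)
  expect_equal(a$rating, "present")
  expect_equal(a$level_delta, 1L)

  # near-null effects everywhere: absent
  b2 <- body_of_evidence("f", "o", list(
    mk_study("s1", 1.02, 0.9, 1.2), mk_study("s2", 0.98, 0.85, 1.1)))
  expect_equal(assess_effect_size_upgrade(b2)$rating, "absent")

  # one large and one small effect: absent by default, present under override
  studies <- list(mk_study("monastero", 6.2, 2.5, 15.4, adjusted = FALSE),
                  mk_study("ozge", 2.08, 1.2, 3.6, adjusted = FALSE))
  b3 <- body_of_evidence("family history", "migraine persistence", studies)
  expect_equal(assess_effect_size_upgrade(b3)$rating, "absent")
  b4 <- body_of_evidence("family history", "migraine persistence", studies,
    overrides = list(effect_size = list(
      rating = "present",
      justification = "collectively these effect sizes are large enough to warrant upgrading")))
  a4 <- assess_effect_size_upgrade(b4)
  expect_equal(a4$rating, "present")
  expect_true(a4$overridden)
  expect_match(a4$rationale, "override")
})

test_that("the dose-response upgrade needs consistent within-study gradients", {
  lv <- function(pts) Map(function(d, p) list(dose = d, effect = effect_estimate("OR", p)),
                          c(1, 3, 5), pts)
  # no exposure data anywhere: not applicable
  b0 <- body_of_evidence("f", "o", list(mk_study("s1"), mk_study("s2")))
  a0 <- assess_dose_response(b0)
  expect_equal(a0$rating, "not_applicable")
  expect_equal(a0$level_delta, 0L)

  # a single study with the monotone 1.2 / 1.7 / 2.1 series: present
  b1 <- body_of_evidence("f", "o", list(
    mk_study("anda", exposure_levels = lv(c(1.2, 1.7, 2.1)))))
  expect_equal(assess_dose_response(b1)$rating, "present")

  # two studies with opposite monotone directions: absent
  b2 <- body_of_evidence("f", "o", list(
    mk_study("s1", exposure_levels = lv(c(1.2, 1.7, 2.1))),
    mk_study("s2", exposure_levels = lv(c(2.1, 1.7, 1.2)))))
  expect_equal(assess_dose_response(b2)$rating, "absent")
})

test_that("every assessor is deterministic and order-insensitive over studies", {
  b <- body_sex()
  b_rev <- body_of_evidence(b$factor_name, b$outcome_name, rev(b$studies),
                            synthesis_mode = b$synthesis_mode)
  assessors <- list(assess_study_limitations, assess_inconsistency,
                    assess_indirectness, assess_imprecision,
                    assess_publication_bias, assess_effect_size_upgrade,
                    assess_dose_response)
  for (f in assessors) {
    a1 <- f(b); a2 <- f(b); a3 <- f(b_rev)
    expect_identical(a1$rating, a2$rating)
    expect_identical(a1$level_delta, a2$level_delta)
    expect_identical(a1$rating, a3$rating)
  }
})

test_that("overrides take precedence over every computed rating", {
  base <- body_sex()
  for (f in c("study_limitations", "inconsistency", "indirectness",
              "imprecision", "publication_bias")) {
    ov <- list(list(rating = "very_serious", justification = "panel judgment"))
    names(ov) <- f
    b <- body_of_evidence(base$factor_name, base$outcome_name, base$studies,
                          overrides = ov)
    a <- switch(f,
                study_limitations = assess_study_limitations(b),
                inconsistency = assess_inconsistency(b),
                indirectness = assess_indirectness(b),
                imprecision = assess_imprecision(b),
                publication_bias = assess_publication_bias(b))
    expect_equal(a$rating, "very_serious")
    expect_true(a$overridden)
    expect_equal(a$level_delta, -2L)
    expect_true(nzchar(a$rationale))
  }
})
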