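## One rule-based assessor per GRADE factor. Each returns a factor_assessment
## carrying the rating, the level adjustment it implies, and a
## machine-generated rationale; each honours a reviewer override (with
## mandatory justification) recorded on the body.

.DOWN_RATINGS <- c("no_concern", "serious", "very_serious", "unclear", "not_applicable")
.UP_RATINGS <- c("absent", "present", "not_applicable")

#' Level adjustments implied by factor ratings
#'
#' Serious concerns subtract one level and very serious concerns two; a
#' present upgrade factor adds one. How far each factor should move the grade
#' is deliberately left open in the framework, so the magnitudes are
#' configurable; these defaults follow the intervention-GRADE convention.
#'
#' @param serious,very_serious,upgrade Level deltas.
#' @return Named list of deltas.
#' @export
grade_deltas <- function(serious = -1L, very_serious = -2L, upgrade = 1L) {
  stopifnot(serious <= 0, very_serious <= serious, upgrade >= 0)
  list(serious = as.integer(serious), very_serious = as.integer(very_serious),
       upgrade = as.integer(upgrade))
}

.delta_for <- function(rating, deltas = grade_deltas()) {
  switch(rating,
         serious = deltas$serious,
         very_serious = deltas$very_serious,
         present = deltas$upgrade,
         0L)
}

#' Construct a factor assessment
#'
#' One GRADE factor's rating with its implied level adjustment and rationale.
#' Downgrade factors rate `no_concern` / `serious` / `very_serious` /
#' `unclear` / `not_applicable` (delta <= 0; unclear and not-applicable carry
#' zero delta but are surfaced in the ledger and footnotes); upgrade factors
#' rate `absent` / `present` / `not_applicable` (delta >= 0).
#'
#' @param factor Factor identifier; one of `phase`, `study_limitations`,
#'   `inconsistency`, `indirectness`, `imprecision`, `publication_bias`,
#'   `effect_size`, `dose_response`.
#' @param rating Rating string from the factor's vocabulary.
#' @param rationale Human-readable justification (required for any rating
#'   that moves the grade; rendered as a table footnote).
#' @param deltas A [grade_deltas()] policy.
#' @param overridden Was this assessment supplied by reviewer override?
#' @param notes Optional extra notes (e.g. rule-discrepancy warnings).
#' @return An object of class `factor_assessment`.
#' @export
factor_assessment <- function(factor, rating, rationale = "",
                              deltas = grade_deltas(), overridden = FALSE,
                              notes = character()) {
  factor <- .chk_enum(factor, c("phase", .ALL_FACTORS), "factor")
  vocab <- if (factor %in% .UPGRADE_FACTORS) .UP_RATINGS else .DOWN_RATINGS
  rating <- .chk_enum(rating, vocab, paste0("rating for ", factor))
  delta <- .delta_for(rating, deltas)
  if (rating %in% c("serious", "very_serious") && !nzchar(trimws(rationale)))
    stop("a downgrade for ", factor, " requires a justification (footnote)",
         call. = FALSE)
  structure(list(factor = factor, rating = rating, level_delta = delta,
                 rationale = rationale, overridden = isTRUE(overridden),
                 notes = notes),
            class = "factor_assessment")
}

#' @export
print.factor_assessment <- function(x, ...) {
  cat(sprintf("%-18s %-13s (delta %+d)%s  %s\n", x$factor, x$rating,
              x$level_delta, if (x$overridden) " [override]" else "", x$rationale))
  invisible(x)
}

## Apply a reviewer override, if one is recorded on the body for this factor.
.with_override <- function(body, factor, default_fn, deltas) {
  ov <- body$overrides[[factor]]
  if (is.null(ov)) return(default_fn())
  j <- ov$justification
  if (is.null(j) || !nzchar(trimws(j)))
    stop("override for ", factor, " requires a nonempty justification", call. = FALSE)
  factor_assessment(factor, ov$rating, rationale = paste0("reviewer override: ", j),
                    deltas = deltas, overridden = TRUE)
}

#' Starting quality level from the phase of investigation
#'
#' A body whose studies are mostly phase 2 (confirmatory) or phase 3
#' (explanatory, model-driven) starts at level 4 (high); a body dominated by
#' phase 1 hypothesis-generating studies — particularly vulnerable to
#' false-positive findings — starts at level 3 (moderate). Majority is by
#' study count; a tie resolves to the lower (conservative) starting point.
#'
#' @param body A [body_of_evidence()].
#' @return `list(level = 3L or 4L, rationale =)`.
#' @export
starting_level <- function(body) {
  phases <- vapply(body$studies, `[[`, integer(1), "phase")
  n_confirm <- sum(phases >= 2)
  if (n_confirm * 2 > length(phases)) {
    list(level = 4L,
         rationale = sprintf("%d of %d studies are phase 2/3 (confirmatory or explanatory): start high",
                             n_confirm, length(phases)))
  } else {
    list(level = 3L,
         rationale = sprintf("%d of %d studies are phase 1 (hypothesis-generating): start moderate",
                             length(phases) - n_confirm, length(phases)))
  }
}

## Per-study risk-of-bias class: "high" when almost all (>= 5 of 6) domains
## are high risk; "low" when a strict majority of domains are low risk;
## otherwise "moderate" (unclear pools with moderate; an even 3-3 split is
## not mostly-low and counts as moderate).
.study_rob_class <- function(rob, rob_majority = 0.5) {
  r <- unclass(rob)
  n_high <- sum(r == "high")
  n_low <- sum(r == "low")
  if (n_high >= 5) "high"
  else if (n_low / 6 > rob_majority) "low"
  else "moderate"
}

#' Assess study limitations (risk of bias)
#'
#' Classifies the body from the QUIPS domain profiles: no serious limitations
#' when most studies are at low risk of bias for most domains; serious
#' limitations when most evidence comes from studies at moderate or unclear
#' risk for most domains; very serious limitations when most information is
#' from studies at high risk for almost all (five or more of six) domains.
#' "Most" is a strict majority by study count (participant-weighted with
#' `weight_by = "participants"`).
#'
#' @param body A [body_of_evidence()].
#' @param thresholds A [grade_thresholds()].
#' @param deltas A [grade_deltas()] policy.
#' @param weight_by `"count"` or `"participants"`.
#' @return A [factor_assessment()] for `study_limitations`.
#' @export
assess_study_limitations <- function(body, thresholds = grade_thresholds(),
                                     deltas = grade_deltas(),
                                     weight_by = c("count", "participants")) {
  weight_by <- match.arg(weight_by)
  .with_override(body, "study_limitations", deltas = deltas, default_fn = function() {
    cls <- vapply(body$studies, function(s)
      .study_rob_class(s$rob, thresholds$rob_majority), character(1))
    w <- if (weight_by == "participants")
      vapply(body$studies, `[[`, integer(1), "n_participants") else NULL
    maj <- thresholds$rob_majority
    k <- length(cls)
    if (.is_majority(cls == "high", maj, w)) {
      factor_assessment("study_limitations", "very_serious", deltas = deltas,
                        rationale = sprintf("most of %d studies are at high risk of bias for almost all QUIPS domains", k))
    } else if (.is_majority(cls != "low", maj, w)) {
      factor_assessment("study_limitations", "serious", deltas = deltas,
                        rationale = sprintf("most of %d studies are at moderate or unclear risk of bias for most QUIPS domains", k))
    } else {
      factor_assessment("study_limitations", "no_concern", deltas = deltas,
                        rationale = "most studies are at low risk of bias for most QUIPS domains")
    }
  })
}

#' Statistical inconsistency signals
#'
#' The three meta-analytic warning signs for inconsistency: (1) point
#' estimates straddle the line of no effect with minimal pairwise CI overlap,
#' (2) the heterogeneity test rejects (p < 0.05), (3) I-squared is
#' substantial. Exposed separately so the trigger logic can be inspected and
#' scanned.
#'
#' @param pooled A [pooled_result()] (or `NULL`; then signals 2-3 are
#'   `FALSE`).
#' @param effects List of [log_effect()] objects (or `NULL`; then signal 1 is
#'   `FALSE`).
#' @param thresholds A [grade_thresholds()].
#' @return Named logical vector `c(straddle_min_overlap, het_p, i2)`.
#' @export
inconsistency_signals <- function(pooled, effects, thresholds = grade_thresholds()) {
  s1 <- FALSE
  if (!is.null(effects) && length(effects) >= 2) {
    dirs <- effect_direction_split(effects)
    ov <- ci_overlap_profile(effects)
    s1 <- dirs$straddles_null &&
      ov$min_pairwise_overlap_fraction < thresholds$overlap_minimal
  }
  s2 <- !is.null(pooled) && is.finite(pooled$p_heterogeneity) &&
    pooled$p_heterogeneity < 0.05
  s3 <- !is.null(pooled) && is.finite(pooled$i_squared) &&
    pooled$i_squared >= thresholds$i2_substantial
  c(straddle_min_overlap = s1, het_p = s2, i2 = s3)
}

## Direction classes observed across studies, from point estimates where
## available and from extracted significance votes where not.
.narrative_directions <- function(body) {
  classes <- character(0)
  for (s in body$studies) {
    e <- preferred_effect(s)
    if (!is.null(e) && !is.na(e$point)) {
      th <- if (e$measure %in% .RATIO_MEASURES) log(e$point) else e$point
      classes <- c(classes, if (th > 0) "risk" else if (th < 0) "protective" else "null")
    } else {
      v <- if (!is.na(s$mv_vote)) s$mv_vote else s$uni_vote
      if (!is.na(v))
        classes <- c(classes,
                     switch(v, positive = "risk", negative = "protective", null = "null"))
    }
  }
  classes
}

#' Assess inconsistency
#'
#' Unexplained heterogeneity or variability in results across studies. A
#' single-study body is always downgraded: inconsistency cannot be assessed
#' and a lone study signals that the literature is not well established. In
#' meta-analysis mode the body is downgraded when at least two of the three
#' statistical signals ([inconsistency_signals()]) fire — provided the
#' reviewer has not judged the between-study differences clinically
#' meaningless (the judgment gates the downgrade only when it is supplied).
#' In narrative mode the body is downgraded when effect directions vary
#' across studies and confidence intervals show minimal overlap or are
#' unavailable. Very serious inconsistency is reserved for directions
#' straddling the null with disjoint intervals.
#'
#' @param body A [body_of_evidence()].
#' @param pooled Optional [pooled_result()]; defaults to `body$pooled`.
#' @param thresholds A [grade_thresholds()].
#' @param deltas A [grade_deltas()] policy.
#' @return A [factor_assessment()] for `inconsistency`.
#' @export
assess_inconsistency <- function(body, pooled = body$pooled,
                                 thresholds = grade_thresholds(),
                                 deltas = grade_deltas()) {
  .with_override(body, "inconsistency", deltas = deltas, default_fn = function() {
    k <- length(body$studies)
    if (k == 1) {
      return(factor_assessment("inconsistency", "serious", deltas = deltas,
        rationale = "single study: literature not well established in this area"))
    }
    effects <- list()
    for (s in body$studies) {
      e <- preferred_effect(s)
      if (!is.null(e) && !is.na(e$point) && !is.na(e$ci_low) && !is.na(e$ci_high))
        effects[[length(effects) + 1]] <- to_log_effect(e, s$study_id)
    }
    cm <- body$clinical_meaningfulness_of_differences
    gate_open <- is.null(cm) || isTRUE(cm)

    ## escalation condition: once a downgrade triggers, directions straddling
    ## the null together with disjoint intervals make it very serious
    escalate <- FALSE
    if (length(effects) >= 2) {
      dirs <- effect_direction_split(effects)
      ov <- ci_overlap_profile(effects)
      escalate <- dirs$straddles_null && ov$any_disjoint
    }
    escalated <- function(why) {
      if (escalate) {
        factor_assessment("inconsistency", "very_serious", deltas = deltas,
          rationale = paste0(why,
            "; effect directions straddle the line of no effect with disjoint confidence intervals"))
      } else {
        factor_assessment("inconsistency", "serious", deltas = deltas,
                          rationale = why)
      }
    }

    if (identical(body$synthesis_mode, "meta_analysis")) {
      sig <- inconsistency_signals(pooled,
                                   if (length(effects) >= 2) effects else NULL,
                                   thresholds)
      if (gate_open && sum(sig) >= 2) {
        lab <- c("direction straddles null with minimal CI overlap",
                 "heterogeneity test p < 0.05",
                 sprintf("I^2 >= %g%%", thresholds$i2_substantial))
        return(escalated(paste0("clinically meaningful heterogeneity: ",
                                paste(lab[sig], collapse = "; "))))
      }
      return(factor_assessment("inconsistency", "no_concern", deltas = deltas,
        rationale = "heterogeneity diagnostics below the downgrade triggers"))
    }

    ## narrative mode
    classes <- .narrative_directions(body)
    varies <- length(unique(classes)) > 1
    cis_unavailable <- length(effects) < 2
    overlap_min <- !cis_unavailable &&
      ci_overlap_profile(effects)$min_pairwise_overlap_fraction < thresholds$overlap_minimal
    if (gate_open && varies && (overlap_min || cis_unavailable)) {
      why <- if (cis_unavailable)
        "effect directions vary across studies and confidence intervals are unavailable to judge overlap"
      else
        "effect directions vary across studies with minimal confidence-interval overlap"
      return(escalated(why))
    }
    factor_assessment("inconsistency", "no_concern", deltas = deltas,
                      rationale = "results are consistent in direction or intervals overlap substantially")
  })
}

#' Assess indirectness
#'
#' The body is downgraded when a majority of studies fail to represent the
#' review question on any of the three dimensions — participant population,
#' prognostic factor operationalization, or outcome. When a majority of
#' studies is flagged on two or more dimensions the concern is very serious.
#'
#' @inheritParams assess_study_limitations
#' @return A [factor_assessment()] for `indirectness`.
#' @export
assess_indirectness <- function(body, thresholds = grade_thresholds(),
                                deltas = grade_deltas()) {
  .with_override(body, "indirectness", deltas = deltas, default_fn = function() {
    maj <- thresholds$rob_majority
    flags <- sapply(c("indirect_population", "indirect_factor", "indirect_outcome"),
                    function(f) vapply(body$studies, `[[`, logical(1), f))
    flags <- matrix(flags, nrow = length(body$studies),
                    dimnames = list(NULL, c("population", "factor", "outcome")))
    dim_major <- apply(flags, 2, .is_majority, threshold = maj)
    any_flag_major <- .is_majority(apply(flags, 1, any), maj)
    if (sum(dim_major) >= 2) {
      factor_assessment("indirectness", "very_serious", deltas = deltas,
        rationale = paste0("a majority of studies is indirect on multiple dimensions: ",
                           paste(names(dim_major)[dim_major], collapse = ", ")))
    } else if (any_flag_major) {
      triggered <- colnames(flags)[colSums(flags) > 0]
      factor_assessment("indirectness", "serious", deltas = deltas,
        rationale = paste0("a majority of studies does not fully represent the review question (",
                           paste(triggered, collapse = ", "), ")"))
    } else {
      factor_assessment("indirectness", "no_concern", deltas = deltas,
        rationale = "studies represent the review population, factor and outcome directly")
    }
  })
}

#' Is a study's sample size adequate?
#'
#' Adequate when the authors justified the sample size; otherwise, for
#' dichotomous outcomes with known events and candidate-variable counts, when
#' there are at least 10 outcome events per candidate prognostic variable;
#' for continuous outcomes — or when the events-per-variable inputs are
#' unavailable — when at least 100 cases reached the endpoint.
#'
#' @param study A [study_record()].
#' @param thresholds A [grade_thresholds()].
#' @return `TRUE`, `FALSE`, or `NA` when nothing reported permits a judgment.
#' @export
study_sample_adequate <- function(study, thresholds = grade_thresholds()) {
  if (isTRUE(study$sample_size_justified)) return(TRUE)
  epv_known <- study$outcome_type == "dichotomous" &&
    !is.na(study$n_events) && !is.na(study$n_prognostic_variables)
  if (epv_known)
    return(study$n_events >= thresholds$events_per_variable * study$n_prognostic_variables)
  if (!is.na(study$n_events))
    return(study$n_events >= thresholds$continuous_endpoint_cases)
  NA
}

#' Is a study's estimate precise?
#'
#' Precise when a confidence interval is reported and it does not both
#' include the null and extend beyond the moderate-effect threshold on both
#' the risk and the protective side (i.e. it does not simultaneously admit
#' "no effect", "appreciable risk" and "appreciable protection").
#'
#' @param study A [study_record()].
#' @param thresholds A [grade_thresholds()].
#' @return `TRUE`, `FALSE`, or `NA` when no confidence interval is reported.
#' @export
study_precise <- function(study, thresholds = grade_thresholds()) {
  e <- preferred_effect(study)
  if (is.null(e) || is.na(e$ci_low) || is.na(e$ci_high)) return(NA)
  if (e$measure %in% .RATIO_MEASURES) {
    null_v <- 1; mod <- thresholds$or_moderate
    spans_null <- e$ci_low <= null_v && e$ci_high >= null_v
    both_appreciable <- e$ci_low <= 1 / mod && e$ci_high >= mod
  } else {
    mod <- thresholds$smd_moderate
    spans_null <- e$ci_low <= 0 && e$ci_high >= 0
    both_appreciable <- e$ci_low <= -mod && e$ci_high >= mod
  }
  !(spans_null && both_appreciable)
}

#' Assess imprecision
#'
#' In meta-analysis mode the pooled estimate is imprecise when its
#' confidence interval spans the null and reaches into both the appreciable
#' risk and appreciable protection regions, or when the total sample falls
#' below a reviewer-supplied required size. In narrative mode each study is
#' judged by sample-size adequacy ([study_sample_adequate()]) and interval
#' precision ([study_precise()]); the body is downgraded only when most
#' studies are imprecise AND there are few studies AND few participants
#' overall — if the majority of studies is precise, the body is never
#' downgraded, regardless of how many studies there are. When no study
#' reports enough to judge, the level of imprecision is `unclear`: no
#' downgrade, but flagged in the ledger and footnotes.
#'
#' @param body A [body_of_evidence()].
#' @param pooled Optional [pooled_result()]; defaults to `body$pooled`.
#' @param thresholds A [grade_thresholds()].
#' @param deltas A [grade_deltas()] policy.
#' @param required_meta_n Optional reviewer-supplied required sample size for
#'   the meta-analysis (from a heterogeneity-aware sample-size estimate).
#' @param min_total_participants Floor under which the across-study sample
#'   counts as small in narrative mode.
#' @return A [factor_assessment()] for `imprecision`.
#' @export
assess_imprecision <- function(body, pooled = body$pooled,
                               thresholds = grade_thresholds(),
                               deltas = grade_deltas(),
                               required_meta_n = NULL,
                               min_total_participants = 400) {
  .with_override(body, "imprecision", deltas = deltas, default_fn = function() {
    k <- length(body$studies)
    precise <- vapply(body$studies, study_precise, logical(1), thresholds = thresholds)
    adequate <- vapply(body$studies, study_sample_adequate, logical(1),
                       thresholds = thresholds)
    notes <- character()
    epv_fail <- vapply(body$studies, function(s)
      s$outcome_type == "dichotomous" && !is.na(s$n_events) &&
        !is.na(s$n_prognostic_variables) && !s$sample_size_justified &&
        s$n_events < thresholds$events_per_variable * s$n_prognostic_variables,
      logical(1))
    if (any(epv_fail))
      notes <- c(notes, sprintf(
        "events-per-variable rule of thumb (%g per variable) not met by: %s",
        thresholds$events_per_variable,
        paste(vapply(body$studies[epv_fail], `[[`, character(1), "study_id"),
              collapse = ", ")))

    if (all(is.na(precise))) {
      return(factor_assessment("imprecision", "unclear", deltas = deltas,
        rationale = "no study reports an effect size or confidence interval to judge precision",
        notes = notes))
    }

    if (identical(body$synthesis_mode, "meta_analysis")) {
      if (!is.null(required_meta_n) && !is.null(pooled) &&
          !is.na(pooled$total_n) && pooled$total_n < required_meta_n) {
        return(factor_assessment("imprecision", "serious", deltas = deltas,
          rationale = sprintf("meta-analysis sample (%d) below the required size (%g)",
                              pooled$total_n, required_meta_n),
          notes = notes))
      }
      if (!is.null(pooled)) {
        pe <- if (pooled$measure %in% .RATIO_MEASURES)
          effect_estimate(pooled$measure, exp(pooled$theta_hat),
                          exp(pooled$ci_low), exp(pooled$ci_high),
                          adjusted = TRUE)
        else
          effect_estimate("SMD", pooled$theta_hat, pooled$ci_low, pooled$ci_high,
                          adjusted = TRUE)
        stub <- study_record("pooled", 1L, "prospective_cohort", 1L,
                             .rob_uniform("low"), effects = list(pe))
        if (isFALSE(study_precise(stub, thresholds))) {
          return(factor_assessment("imprecision", "serious", deltas = deltas,
            rationale = "pooled confidence interval spans no effect and both appreciable risk and protection",
            notes = notes))
        }
      }
      return(factor_assessment("imprecision", "no_concern", deltas = deltas,
        rationale = "pooled estimate sufficiently precise", notes = notes))
    }

    ## narrative mode: a study is imprecise when its sample is not adequate
    ## and its interval is not demonstrably precise
    imprecise <- (!adequate | is.na(adequate)) & (is.na(precise) | !precise)
    imprecise[is.na(imprecise)] <- TRUE
    if (.is_majority(!is.na(precise) & precise, thresholds$rob_majority)) {
      return(factor_assessment("imprecision", "no_concern", deltas = deltas,
        rationale = "the majority of studies report precise estimates", notes = notes))
    }
    total_n <- sum(vapply(body$studies, `[[`, integer(1), "n_participants"))
    if (.is_majority(imprecise, thresholds$rob_majority) &&
        k <= thresholds$few_studies && total_n < min_total_participants) {
      return(factor_assessment("imprecision", "serious", deltas = deltas,
        rationale = sprintf("most of %d studies are imprecise with only %d participants across studies",
                            k, total_n),
        notes = notes))
    }
    factor_assessment("imprecision", "no_concern", deltas = deltas,
      rationale = "within- and across-study precision above the downgrade triggers",
      notes = notes)
  })
}

#' Assess publication bias
#'
#' Prognosis research lacks a study register and null associations often go
#' unreported, so the prudent default is to assume serious publication bias
#' until there is evidence to the contrary. The default downgrade is waived
#' when the factor has been investigated by an adequate number of cohort
#' studies; when that repetition consists purely of phase 1 studies the
#' rationale records that the phase penalty is not applied a second time
#' here.
#'
#' @inheritParams assess_study_limitations
#' @return A [factor_assessment()] for `publication_bias`.
#' @export
assess_publication_bias <- function(body, thresholds = grade_thresholds(),
                                    deltas = grade_deltas()) {
  .with_override(body, "publication_bias", deltas = deltas, default_fn = function() {
    k <- length(body$studies)
    if (k >= thresholds$min_studies_no_pub_bias) {
      phases <- vapply(body$studies, `[[`, integer(1), "phase")
      note <- if (all(phases == 1))
        "; repetition is purely phase 1, already penalized at the starting level (no double-downgrade with phase)"
      else ""
      factor_assessment("publication_bias", "no_concern", deltas = deltas,
        rationale = sprintf("factor repetitively investigated (%d studies >= %d): default downgrade waived%s",
                            k, thresholds$min_studies_no_pub_bias, note))
    } else {
      factor_assessment("publication_bias", "serious", deltas = deltas,
        rationale = sprintf("default position: prognosis research assumed seriously affected by publication bias (%d studies < %d)",
                            k, thresholds$min_studies_no_pub_bias))
    }
  })
}

#' Classify the magnitude of an effect
#'
#' Ratio measures are judged by `m = max(point, 1/point)` so that protective
#' effects are classified by their reciprocal: large from `or_large`
#' (default 4.25 or greater), moderate from `or_moderate` (default around
#' 2.5), otherwise small. SMDs are judged by absolute value against the
#' `smd_*` thresholds (0.5 / 0.8). All boundaries inclusive.
#'
#' @param e An [effect_estimate()] with a point estimate.
#' @param thresholds A [grade_thresholds()].
#' @return `"small"`, `"moderate"` or `"large"`.
#' @examples
#' classify_effect_magnitude(effect_estimate("OR", 6.2))
#' @export
classify_effect_magnitude <- function(e, thresholds = grade_thresholds()) {
  stopifnot(inherits(e, "effect_estimate"))
  if (is.na(e$point)) stop("point estimate required", call. = FALSE)
  if (e$measure %in% .RATIO_MEASURES) {
    if (e$point <= 0) stop("ratio measure must be positive", call. = FALSE)
    m <- max(e$point, 1 / e$point)
    lo <- thresholds$or_moderate; hi <- thresholds$or_large
  } else {
    m <- abs(e$point)
    lo <- thresholds$smd_moderate; hi <- thresholds$smd_large
  }
  if (m >= hi) "large" else if (m >= lo) "moderate" else "small"
}

#' Assess the moderate-or-large effect size upgrade
#'
#' In meta-analysis mode the body is upgraded when the pooled effect is
#' moderate or large. In narrative mode it is upgraded when a strict
#' majority of studies reports same-direction effects classified moderate or
#' large. Since the magnitude rules of thumb are arbitrary guidelines, a
#' reviewer override (with justification) is supported for judgment calls.
#'
#' @param body A [body_of_evidence()].
#' @param pooled Optional [pooled_result()]; defaults to `body$pooled`.
#' @param thresholds A [grade_thresholds()].
#' @param deltas A [grade_deltas()] policy.
#' @return A [factor_assessment()] for `effect_size`.
#' @export
assess_effect_size_upgrade <- function(body, pooled = body$pooled,
                                       thresholds = grade_thresholds(),
                                       deltas = grade_deltas()) {
  .with_override(body, "effect_size", deltas = deltas, default_fn = function() {
    if (identical(body$synthesis_mode, "meta_analysis") && !is.null(pooled)) {
      pt <- if (pooled$measure %in% .RATIO_MEASURES) exp(pooled$theta_hat)
            else pooled$theta_hat
      mag <- classify_effect_magnitude(effect_estimate(pooled$measure, pt), thresholds)
      if (mag %in% c("moderate", "large")) {
        return(factor_assessment("effect_size", "present", deltas = deltas,
          rationale = sprintf("pooled effect is %s (%s = %.2f)", mag, pooled$measure, pt)))
      }
      return(factor_assessment("effect_size", "absent", deltas = deltas,
        rationale = "pooled effect is small"))
    }
    ## narrative: strict majority with same-direction moderate/large effects
    dirs <- character(); mags <- character()
    for (s in body$studies) {
      e <- preferred_effect(s)
      if (is.null(e) || is.na(e$point)) { dirs <- c(dirs, NA); mags <- c(mags, NA); next }
      th <- if (e$measure %in% .RATIO_MEASURES) log(e$point) else e$point
      dirs <- c(dirs, if (th > 0) "risk" else if (th < 0) "protective" else "null")
      mags <- c(mags, classify_effect_magnitude(e, thresholds))
    }
    big <- !is.na(mags) & mags %in% c("moderate", "large")
    for (d in c("risk", "protective")) {
      if (.is_majority(big & !is.na(dirs) & dirs == d, thresholds$rob_majority)) {
        return(factor_assessment("effect_size", "present", deltas = deltas,
          rationale = sprintf("most studies report moderate or large same-direction (%s) effects", d)))
      }
    }
    factor_assessment("effect_size", "absent", deltas = deltas,
      rationale = "no majority of moderate or large same-direction effects")
  })
}

#' Assess the exposure-response gradient upgrade
#'
#' Upgraded when every study that reports exposure-level series shows a
#' strictly monotone gradient ([detect_gradient()]) and the directions agree
#' across those studies. Not applicable when no study reports exposure
#' levels.
#'
#' @inheritParams assess_study_limitations
#' @return A [factor_assessment()] for `dose_response`.
#' @export
assess_dose_response <- function(body, thresholds = grade_thresholds(),
                                 deltas = grade_deltas()) {
  .with_override(body, "dose_response", deltas = deltas, default_fn = function() {
    results <- list()
    for (s in body$studies) {
      if (is.null(s$exposure_levels)) next
      doses <- vapply(s$exposure_levels, function(l) as.numeric(l$dose), numeric(1))
      pts <- vapply(s$exposure_levels, function(l) as.numeric(l$effect$point), numeric(1))
      results[[s$study_id]] <- detect_gradient(doses, pts)
    }
    results <- Filter(function(r) isTRUE(r$applicable), results)
    if (length(results) == 0) {
      return(factor_assessment("dose_response", "not_applicable", deltas = deltas,
        rationale = "no study reports effect estimates at multiple exposure levels"))
    }
    all_grad <- all(vapply(results, `[[`, logical(1), "gradient"))
    dirs <- unique(vapply(results, `[[`, character(1), "direction"))
    if (all_grad && length(dirs) == 1) {
      factor_assessment("dose_response", "present", deltas = deltas,
        rationale = sprintf("consistent %s exposure-response gradient in every reporting study (%d)",
                            dirs, length(results)))
    } else {
      factor_assessment("dose_response", "absent", deltas = deltas,
        rationale = "exposure-response gradients absent or inconsistent across studies")
    }
  })
}
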