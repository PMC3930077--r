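## Domain model for bodies of prognostic evidence: one prognostic factor
## crossed with one outcome, carried by a set of primary cohort studies.

.MEASURES <- c("OR", "RR", "HR", "SMD")
.RATIO_MEASURES <- c("OR", "RR", "HR")
.QUIPS_DOMAINS <- c("study_participation", "study_attrition",
                    "prognostic_factor_measurement", "outcome_measurement",
                    "confounding", "analysis")
.ROB_LEVELS <- c("low", "moderate", "high", "unclear")
.DESIGNS <- c("prospective_cohort", "retrospective_cohort")
.OUTCOME_TYPES <- c("dichotomous", "continuous")
.VOTES <- c("positive", "null", "negative")
.DOWNGRADE_FACTORS <- c("study_limitations", "inconsistency", "indirectness",
                        "imprecision", "publication_bias")
.UPGRADE_FACTORS <- c("effect_size", "dose_response")
.ALL_FACTORS <- c(.DOWNGRADE_FACTORS, .UPGRADE_FACTORS)

.chk_enum <- function(x, allowed, what) {
  if (length(x) != 1 || is.na(x) || !(x %in% allowed))
    stop(what, " must be one of: ", paste(allowed, collapse = ", "), call. = FALSE)
  x
}

.scalar_num <- function(x, what, allow_na = TRUE) {
  if (is.null(x) || length(x) == 0) x <- NA_real_
  if (length(x) != 1) stop(what, " must be a single number", call. = FALSE)
  x <- as.numeric(x)
  if (!allow_na && is.na(x)) stop(what, " must not be missing", call. = FALSE)
  x
}

#' Construct an effect estimate
#'
#' A point estimate on a named measure scale (odds ratio, risk ratio, hazard
#' ratio, or standardized mean difference) with its confidence interval.
#' Missing values are represented as `NA`, never as zero: a study that reports
#' a point estimate without a confidence interval is a real and common case in
#' prognosis research, and downstream rules treat it distinctly.
#'
#' Constructors validate types and enumerations only; relational invariants
#' (bound ordering, positivity of ratio measures) are reported by
#' [validate_body()] so that malformed extracted data can be loaded, audited
#' and listed rather than silently rejected.
#'
#' @param measure One of `"OR"`, `"RR"`, `"HR"`, `"SMD"`.
#' @param point Point estimate on the measure's natural scale.
#' @param ci_low,ci_high Confidence-interval bounds (`NA` if not reported).
#' @param ci_level Confidence level in (0, 1); defaults to 0.95 when the
#'   source study does not state one.
#' @param adjusted `TRUE` for a multivariate (covariate-adjusted) estimate,
#'   `FALSE` for univariate.
#' @param n_covariates Number of co-variables in the model that produced this
#'   estimate.
#' @return An object of class `effect_estimate`.
#' @examples
#' effect_estimate("OR", 1.88, 1.65, 2.15)
#' @export
effect_estimate <- function(measure, point, ci_low = NA_real_, ci_high = NA_real_,
                            ci_level = 0.95, adjusted = FALSE, n_covariates = 0L) {
  measure <- .chk_enum(as.character(measure), .MEASURES, "measure")
  ci_level <- .scalar_num(ci_level, "ci_level", allow_na = FALSE)
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)", call. = FALSE)
  n_covariates <- as.integer(n_covariates)
  if (is.na(n_covariates) || n_covariates < 0)
    stop("n_covariates must be a nonnegative integer", call. = FALSE)
  e <- list(measure = measure,
            point = .scalar_num(point, "point"),
            ci_low = .scalar_num(ci_low, "ci_low"),
            ci_high = .scalar_num(ci_high, "ci_high"),
            ci_level = ci_level,
            adjusted = isTRUE(adjusted),
            n_covariates = n_covariates)
  class(e) <- "effect_estimate"
  e
}

#' Construct a QUIPS risk-of-bias profile
#'
#' One rating per QUIPS domain: study participation, study attrition,
#' prognostic factor measurement, outcome measurement, confounding
#' (measurement and account), and statistical analysis. Each domain is rated
#' `"low"`, `"moderate"`, `"high"`, or `"unclear"`; during aggregation an
#' unclear rating is pooled with moderate.
#'
#' @param study_participation,study_attrition,prognostic_factor_measurement,outcome_measurement,confounding,analysis
#'   Domain ratings.
#' @return An object of class `rob_profile`: a named character vector over
#'   the six domains.
#' @examples
#' rob_profile("low", "moderate", "low", "low", "high", "unclear")
#' @export
rob_profile <- function(study_participation, study_attrition,
                        prognostic_factor_measurement, outcome_measurement,
                        confounding, analysis) {
  ratings <- c(study_participation = study_participation,
               study_attrition = study_attrition,
               prognostic_factor_measurement = prognostic_factor_measurement,
               outcome_measurement = outcome_measurement,
               confounding = confounding,
               analysis = analysis)
  for (d in .QUIPS_DOMAINS) .chk_enum(unname(ratings[[d]]), .ROB_LEVELS, paste0("rob ", d))
  structure(ratings, class = "rob_profile")
}

## convenience: a uniform profile for tests and the generator
.rob_uniform <- function(level) do.call(rob_profile, as.list(rep(level, 6)))

#' Construct a primary-study record
#'
#' One row of extracted evidence: the study's phase of investigation (1 =
#' hypothesis-generating association finding, 2 = confirmatory testing of an
#' independent association, 3 = explanatory, driven by a conceptual model),
#' design, sample size, outcome events, the number of candidate prognostic
#' variables in the analysis, effect estimates (possibly none — estimates are
#' frequently unreported), a six-domain risk-of-bias profile, indirectness
#' flags, optional exposure-level/effect pairs, and optional reported
#' significance votes (extracted, never recomputed).
#'
#' @param study_id Unique study label.
#' @param phase Phase of investigation: 1, 2 or 3.
#' @param design `"prospective_cohort"` or `"retrospective_cohort"`.
#' @param n_participants Number of participants (positive integer).
#' @param rob A [rob_profile()].
#' @param n_events Outcome events (dichotomous outcomes); `NA` if not
#'   reported.
#' @param n_prognostic_variables Candidate prognostic variables in the
#'   analysis; `NA` if not reported.
#' @param outcome_type `"dichotomous"` or `"continuous"`.
#' @param sample_size_justified Did the authors justify their sample size?
#' @param effects List of [effect_estimate()] objects (possibly empty).
#' @param indirect_population,indirect_factor,indirect_outcome Indirectness
#'   flags: does the study sample / factor operationalization / outcome fail
#'   to represent the review question?
#' @param exposure_levels Optional list of `list(dose =, effect =)` pairs with
#'   strictly increasing doses, for exposure-response assessment.
#' @param uni_vote,mv_vote Optional reported significance of the univariate /
#'   multivariate analysis: `"positive"`, `"null"`, `"negative"`, or `NA` when
#'   not reported.
#' @return An object of class `study_record`.
#' @export
study_record <- function(study_id, phase, design, n_participants, rob,
                         n_events = NA_integer_,
                         n_prognostic_variables = NA_integer_,
                         outcome_type = "dichotomous",
                         sample_size_justified = FALSE,
                         effects = list(),
                         indirect_population = FALSE,
                         indirect_factor = FALSE,
                         indirect_outcome = FALSE,
                         exposure_levels = NULL,
                         uni_vote = NA_character_,
                         mv_vote = NA_character_) {
  if (!is.character(study_id) || length(study_id) != 1 || !nzchar(study_id))
    stop("study_id must be a nonempty string", call. = FALSE)
  phase <- as.integer(phase)
  if (is.na(phase) || !(phase %in% 1:3)) stop("phase must be 1, 2 or 3", call. = FALSE)
  design <- .chk_enum(design, .DESIGNS, "design")
  outcome_type <- .chk_enum(outcome_type, .OUTCOME_TYPES, "outcome_type")
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants <= 0)
    stop("n_participants must be a positive integer", call. = FALSE)
  if (!is.list(effects) || (length(effects) > 0 &&
      !all(vapply(effects, inherits, logical(1), "effect_estimate"))))
    stop("effects must be a list of effect_estimate objects", call. = FALSE)
  if (!inherits(rob, "rob_profile")) stop("rob must be a rob_profile", call. = FALSE)
  for (v in list(uni_vote, mv_vote)) {
    if (!is.na(v)) .chk_enum(v, .VOTES, "vote")
  }
  if (!is.null(exposure_levels)) {
    ok <- is.list(exposure_levels) && length(exposure_levels) > 0 &&
      all(vapply(exposure_levels, function(l)
        is.list(l) && all(c("dose", "effect") %in% names(l)) &&
          inherits(l$effect, "effect_estimate"), logical(1)))
    if (!ok) stop("exposure_levels must be a list of list(dose =, effect =) pairs",
                  call. = FALSE)
  }
  s <- list(study_id = study_id, phase = phase, design = design,
            n_participants = n_participants,
            n_events = suppressWarnings(as.integer(n_events)),
            n_prognostic_variables = suppressWarnings(as.integer(n_prognostic_variables)),
            outcome_type = outcome_type,
            sample_size_justified = isTRUE(sample_size_justified),
            effects = effects, rob = rob,
            indirect_population = isTRUE(indirect_population),
            indirect_factor = isTRUE(indirect_factor),
            indirect_outcome = isTRUE(indirect_outcome),
            exposure_levels = exposure_levels,
            uni_vote = as.character(uni_vote), mv_vote = as.character(mv_vote))
  class(s) <- "study_record"
  s
}

#' Construct a body of evidence
#'
#' All included studies addressing one prognostic factor for one outcome,
#' together with the synthesis mode and any reviewer overrides. In
#' meta-analysis mode a pooled result is required; if not supplied it is
#' computed from the studies' preferred estimates with [pool_body()]
#' (DerSimonian-Laird random effects).
#'
#' @param factor_name Name of the prognostic factor.
#' @param outcome_name Name of the outcome.
#' @param studies Nonempty list of [study_record()] objects.
#' @param synthesis_mode `"meta_analysis"` or `"narrative"`.
#' @param pooled Optional [pooled_result()]; auto-computed in meta-analysis
#'   mode when `NULL` and at least two studies carry usable estimates.
#' @param clinical_meaningfulness_of_differences Optional reviewer judgment:
#'   are the observed between-study differences clinically meaningful? Gates
#'   the inconsistency downgrade when supplied.
#' @param overrides Named list mapping a GRADE factor identifier to
#'   `list(rating =, justification =)`; the justification must be nonempty.
#' @return An object of class `body_of_evidence`.
#' @export
body_of_evidence <- function(factor_name, outcome_name, studies,
                             synthesis_mode = c("narrative", "meta_analysis"),
                             pooled = NULL,
                             clinical_meaningfulness_of_differences = NULL,
                             overrides = list()) {
  synthesis_mode <- match.arg(synthesis_mode)
  if (!is.list(studies) || length(studies) == 0 ||
      !all(vapply(studies, inherits, logical(1), "study_record")))
    stop("nonempty list of StudyRecord required", call. = FALSE)
  if (length(overrides) > 0) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named list keyed by factor identifier", call. = FALSE)
    bad <- setdiff(names(overrides), .ALL_FACTORS)
    if (length(bad) > 0)
      stop("unknown override factor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  body <- list(factor_name = as.character(factor_name),
               outcome_name = as.character(outcome_name),
               studies = studies,
               synthesis_mode = synthesis_mode,
               pooled = pooled,
               clinical_meaningfulness_of_differences =
                 if (is.null(clinical_meaningfulness_of_differences)) NULL
                 else isTRUE(clinical_meaningfulness_of_differences),
               overrides = overrides)
  class(body) <- "body_of_evidence"
  if (synthesis_mode == "meta_analysis" && is.null(pooled)) {
    body$pooled <- tryCatch(pool_body(body), error = function(e) {
      stop("meta_analysis mode requires a pooled result and none could be computed: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  body
}

#' The study's preferred effect estimate
#'
#' The multivariate (adjusted) estimate is preferred wherever a single
#' estimate is needed; when only a univariate estimate is available it is used
#' with a logged warning, since unadjusted prognostic associations may be
#' confounded.
#'
#' @param study A [study_record()].
#' @return An `effect_estimate`, or `NULL` when the study reports none.
#' @export
preferred_effect <- function(study) {
  if (length(study$effects) == 0) return(NULL)
  adj <- Filter(function(e) isTRUE(e$adjusted), study$effects)
  if (length(adj) > 0) return(adj[[1]])
  .log("warn", sprintf("study %s: no multivariate estimate; falling back to univariate",
                       study$study_id))
  study$effects[[1]]
}

#' Validate a body of evidence
#'
#' Checks every relational invariant of the domain model and returns findings
#' rather than raising errors, so that extracted data can be audited in bulk.
#' A well-formed body yields a zero-row data frame. The check is idempotent,
#' order-insensitive over studies, and never mutates its input.
#'
#' Checked invariants: confidence bounds ordered around the point estimate;
#' ratio measures strictly positive; events not exceeding participants;
#' strictly increasing exposure doses; ci_level in (0, 1); override
#' justifications nonempty; a pooled result present in meta-analysis mode.
#'
#' @param body A [body_of_evidence()].
#' @return A data frame with columns `study_id`, `field`, `message`; one row
#'   per violated invariant.
#' @export
validate_body <- function(body) {
  findings <- list()
  add <- function(study_id, field, message) {
    findings[[length(findings) + 1]] <<-
      data.frame(study_id = study_id, field = field, message = message,
                 stringsAsFactors = FALSE)
  }
  if (!inherits(body, "body_of_evidence")) {
    add("<body>", "class", "not a body_of_evidence")
    return(do.call(rbind, findings))
  }
  for (s in body$studies) {
    sid <- s$study_id
    if (!is.na(s$n_events) && s$n_events > s$n_participants)
      add(sid, "n_events", "n_events exceeds n_participants")
    if (!is.na(s$n_events) && s$n_events < 0)
      add(sid, "n_events", "n_events must be nonnegative")
    k_e <- 0
    for (e in s$effects) {
      k_e <- k_e + 1
      fld <- sprintf("effects[%d]", k_e)
      if (e$measure %in% .RATIO_MEASURES) {
        vals <- c(e$point, e$ci_low, e$ci_high)
        if (any(!is.na(vals) & vals <= 0))
          add(sid, fld, "ratio measure must be positive")
      }
      if (!is.na(e$point) && !is.na(e$ci_low) && e$ci_low > e$point)
        add(sid, fld, "ci_low exceeds point")
      if (!is.na(e$point) && !is.na(e$ci_high) && e$ci_high < e$point)
        add(sid, fld, "ci_high below point")
      if (is.na(e$ci_low) != is.na(e$ci_high))
        add(sid, fld, "confidence interval must have both bounds or neither")
    }
    if (!is.null(s$exposure_levels)) {
      doses <- vapply(s$exposure_levels, function(l) as.numeric(l$dose), numeric(1))
      if (length(doses) > 1 && any(diff(doses) <= 0))
        add(sid, "exposure_levels", "dose values must be strictly increasing")
    }
  }
  if (length(body$overrides) > 0) {
    for (f in names(body$overrides)) {
      ov <- body$overrides[[f]]
      j <- ov$justification
      if (is.null(j) || !is.character(j) || !nzchar(trimws(j)))
        add("<body>", paste0("overrides.", f), "override requires a nonempty justification")
    }
  }
  if (identical(body$synthesis_mode, "meta_analysis") && is.null(body$pooled))
    add("<body>", "pooled", "meta_analysis mode requires a pooled result")
  if (length(findings) == 0)
    return(data.frame(study_id = character(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' @export
print.body_of_evidence <- function(x, ...) {
  cat(sprintf("Body of evidence: %s -> %s\n", x$factor_name, x$outcome_name))
  cat(sprintf("  %d studies, %d participants, %s synthesis\n",
              length(x$studies),
              sum(vapply(x$studies, `[[`, integer(1), "n_participants")),
              x$synthesis_mode))
  if (!is.null(x$pooled))
    cat(sprintf("  pooled: theta_hat = %.4f, I^2 = %.1f%%\n",
                x$pooled$theta_hat, x$pooled$i_squared))
  invisible(x)
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("Study %s: phase %d %s, n = %d, %d effect estimate(s)\n",
              x$study_id, x$phase, x$design, x$n_participants, length(x$effects)))
  invisible(x)
}
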