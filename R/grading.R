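## The grading engine: combine the phase-based starting level with every
## factor assessment into a final quality grade, keeping a complete ledger.

#' The four-level quality scale
#'
#' @return A data frame with one row per level: numeric level (1 = very low
#'   ... 4 = high), label, plus notation, and the standard definition of the
#'   confidence each level expresses.
#' @export
grade_scale <- function() {
  data.frame(
    level = 1:4,
    label = c("very_low", "low", "moderate", "high"),
    notation = c("+", "++", "+++", "++++"),
    definition = c(
      "We have very little confidence in the effect estimate: the true effect is likely to be substantially different from the estimate of effect",
      "Our confidence in the effect estimate is limited: the true effect may be substantially different from the estimate of the effect",
      "We are moderately confident in the effect estimate: the true effect is likely to be close to the estimate of the effect, but there is a possibility that it is substantially different",
      "We are very confident that the true effect lies close to that of the estimate of the effect"),
    stringsAsFactors = FALSE)
}

.clamp <- function(x, lo = 1L, hi = 4L) max(lo, min(hi, x))

.quality_grade <- function(starting_level, ledger) {
  deltas <- vapply(ledger, `[[`, integer(1), "level_delta")
  level <- .clamp(starting_level + sum(deltas))
  footnotes <- character()
  marks <- character()
  for (a in ledger) {
    needs_note <- a$rating %in% c("serious", "very_serious", "unclear") ||
      a$overridden || length(a$notes) > 0
    if (!needs_note) next
    m <- letters[length(footnotes) + 1L]
    txt <- sprintf("%s. %s (%s): %s", m, gsub("_", " ", a$factor),
                   a$rating, a$rationale)
    if (length(a$notes) > 0)
      txt <- paste0(txt, " [", paste(a$notes, collapse = "; "), "]")
    footnotes <- c(footnotes, txt)
    marks[a$factor] <- m
  }
  structure(list(level = level,
                 plus_notation = strrep("+", level),
                 label = grade_scale()$label[level],
                 starting_level = as.integer(starting_level),
                 ledger = ledger,
                 footnotes = footnotes,
                 footnote_marks = marks),
            class = "quality_grade")
}

#' Grade a body of evidence
#'
#' Runs the full adapted-GRADE pipeline: validates the body, determines the
#' starting level from the phase of investigation, runs every factor
#' assessor in the fixed order study limitations, inconsistency,
#' indirectness, imprecision, publication bias, moderate-or-large effect
#' size, exposure-response gradient, and combines the results as
#' `level = clamp(start + sum(deltas), 1, 4)`. The returned grade carries
#' the complete ordered ledger of assessments and the footnotes justifying
#' every downgrade, unclear rating, and override. Deterministic and
#' order-insensitive over studies.
#'
#' @param body A [body_of_evidence()]; must validate cleanly.
#' @param thresholds A [grade_thresholds()].
#' @param deltas A [grade_deltas()] policy.
#' @param required_meta_n,min_total_participants Passed to
#'   [assess_imprecision()].
#' @param weight_by Majority weighting, passed to
#'   [assess_study_limitations()].
#' @return An object of class `quality_grade`.
#' @examples
#' b <- generate_body(scenario_suite()[["phase2-clean"]]$spec)
#' grade(b)
#' @export
grade <- function(body, thresholds = grade_thresholds(),
                  deltas = grade_deltas(),
                  required_meta_n = NULL, min_total_participants = 400,
                  weight_by = c("count", "participants")) {
  weight_by <- match.arg(weight_by)
  findings <- validate_body(body)
  if (nrow(findings) > 0) {
    stop("body does not validate; findings:\n",
         paste(sprintf("  %s / %s: %s", findings$study_id, findings$field,
                       findings$message), collapse = "\n"),
         call. = FALSE)
  }
  start <- starting_level(body)
  pooled <- body$pooled
  ledger <- list(
    factor_assessment("phase",
                      if (start$level == 4L) "no_concern" else "serious",
                      rationale = start$rationale, deltas = grade_deltas(0L, 0L, 0L)),
    assess_study_limitations(body, thresholds, deltas, weight_by),
    assess_inconsistency(body, pooled, thresholds, deltas),
    assess_indirectness(body, thresholds, deltas),
    assess_imprecision(body, pooled, thresholds, deltas,
                       required_meta_n, min_total_participants),
    assess_publication_bias(body, thresholds, deltas),
    assess_effect_size_upgrade(body, pooled, thresholds, deltas),
    assess_dose_response(body, thresholds, deltas))
  ## the phase entry is informational: its effect is the starting level, not a delta
  ledger[[1]]$level_delta <- 0L
  .quality_grade(start$level, ledger[-1]) -> qg
  qg$ledger <- ledger
  qg$phase_start <- start
  qg
}

#' Grade directly from factor ratings
#'
#' Bypasses the assessors: applies the grading arithmetic to a starting
#' level and a complete map of factor ratings. Useful for auditing a grade,
#' for replaying a published summary-of-findings row, and as the oracle
#' entry point for the engine's arithmetic.
#'
#' @param start Starting level, 3 (phase 1 evidence) or 4 (phase 2/3).
#' @param flags Named character vector or list covering all seven adjustable
#'   factors (`study_limitations`, `inconsistency`, `indirectness`,
#'   `imprecision`, `publication_bias`, `effect_size`, `dose_response`),
#'   each mapped to a rating from that factor's vocabulary.
#' @param deltas A [grade_deltas()] policy.
#' @return A `quality_grade`.
#' @examples
#' grade_from_flags(3, c(study_limitations = "serious", inconsistency = "no_concern",
#'                       indirectness = "no_concern", imprecision = "no_concern",
#'                       publication_bias = "no_concern", effect_size = "present",
#'                       dose_response = "absent"))
#' @export
grade_from_flags <- function(start, flags, deltas = grade_deltas()) {
  start <- as.integer(start)
  if (is.na(start) || !(start %in% 3:4))
    stop("start must be 3 (phase 1) or 4 (phase 2/3)", call. = FALSE)
  flags <- as.list(flags)
  unknown <- setdiff(names(flags), .ALL_FACTORS)
  if (length(unknown) > 0)
    stop("unknown factor key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(.ALL_FACTORS, names(flags))
  if (length(missing) > 0)
    stop("flags must cover all seven factors; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ledger <- lapply(.ALL_FACTORS, function(f)
    factor_assessment(f, flags[[f]], rationale = "supplied rating",
                      deltas = deltas))
  .quality_grade(start, ledger)
}

#' @export
print.quality_grade <- function(x, ...) {
  cat(sprintf("Quality of evidence: %s (%s, level %d of 4; started at %d)\n",
              x$plus_notation, gsub("_", " ", x$label), x$level, x$starting_level))
  for (a in x$ledger) print(a)
  if (length(x$footnotes) > 0) {
    cat("Footnotes:\n")
    for (f in x$footnotes) cat(" ", f, "\n")
  }
  invisible(x)
}
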