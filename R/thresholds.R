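#' Default grading thresholds
#'
#' Bundles every numeric rule of thumb the factor assessors consume. The
#' defaults encode the published guidance for prognostic evidence: an odds
#' ratio around 2.5 counts as a moderate effect and 4.25 or greater as large;
#' a standardized mean difference around 0.5 is moderate and 0.8 or larger is
#' large; heterogeneity is substantial from I-squared = 50%; a multivariable
#' model of a dichotomous outcome is adequately powered from 10 outcome events
#' per candidate prognostic variable, or 100 cases reaching the endpoint for
#' continuous (or indeterminable) outcomes; a prognostic factor investigated
#' by at least 4 cohort studies is exempt from the default publication-bias
#' downgrade; 3 or fewer studies count as "few" for across-study imprecision;
#' pairwise confidence-interval overlap below 10% of the shorter interval
#' counts as "minimal overlap"; and "most" studies/domains means a strict
#' majority (fraction strictly greater than 0.5).
#'
#' All boundaries are inclusive: an OR of exactly 4.25 is large, I-squared of
#' exactly 50 is substantial, exactly 10 events per variable is adequate.
#'
#' @param or_moderate Odds/risk/hazard-ratio threshold for a moderate effect.
#' @param or_large Ratio threshold for a large effect.
#' @param smd_moderate Standardized-mean-difference threshold for a moderate
#'   effect.
#' @param smd_large SMD threshold for a large effect.
#' @param i2_substantial I-squared percentage from which heterogeneity is
#'   substantial.
#' @param events_per_variable Minimum outcome events per candidate prognostic
#'   variable for an adequately powered dichotomous-outcome analysis.
#' @param continuous_endpoint_cases Minimum cases reaching the endpoint for an
#'   adequately powered continuous-outcome (or indeterminable) analysis.
#' @param min_studies_no_pub_bias Number of studies from which the default
#'   publication-bias downgrade is waived.
#' @param few_studies At most this many studies counts as "few" when judging
#'   across-study imprecision in a narrative synthesis.
#' @param overlap_minimal Pairwise CI overlap fraction below which overlap is
#'   "minimal".
#' @param rob_majority Fraction above which a share of studies or domains is a
#'   majority (strict inequality).
#' @return An object of class `grade_thresholds`: a named list of the eleven
#'   thresholds.
#' @examples
#' th <- grade_thresholds()
#' th$or_large
#' @export
grade_thresholds <- function(or_moderate = 2.5,
                             or_large = 4.25,
                             smd_moderate = 0.5,
                             smd_large = 0.8,
                             i2_substantial = 50,
                             events_per_variable = 10,
                             continuous_endpoint_cases = 100,
                             min_studies_no_pub_bias = 4,
                             few_studies = 3,
                             overlap_minimal = 0.10,
                             rob_majority = 0.5) {
  th <- list(
    or_moderate = as.numeric(or_moderate),
    or_large = as.numeric(or_large),
    smd_moderate = as.numeric(smd_moderate),
    smd_large = as.numeric(smd_large),
    i2_substantial = as.numeric(i2_substantial),
    events_per_variable = as.numeric(events_per_variable),
    continuous_endpoint_cases = as.numeric(continuous_endpoint_cases),
    min_studies_no_pub_bias = as.integer(min_studies_no_pub_bias),
    few_studies = as.integer(few_studies),
    overlap_minimal = as.numeric(overlap_minimal),
    rob_majority = as.numeric(rob_majority)
  )
  if (th$or_large < th$or_moderate)
    stop("or_large must be >= or_moderate", call. = FALSE)
  if (th$smd_large < th$smd_moderate)
    stop("smd_large must be >= smd_moderate", call. = FALSE)
  num <- unlist(th[c("or_moderate", "or_large", "smd_moderate", "smd_large",
                     "events_per_variable", "continuous_endpoint_cases")])
  if (any(num <= 0)) stop("effect and adequacy thresholds must be strictly positive",
                          call. = FALSE)
  if (th$overlap_minimal < 0 || th$overlap_minimal > 1)
    stop("overlap_minimal must lie in [0, 1]", call. = FALSE)
  class(th) <- "grade_thresholds"
  th
}

#' Read grading thresholds from a configuration file
#'
#' Accepts the same JSON/YAML dialect used for body-of-evidence documents.
#' Keys absent from the file keep their documented defaults; unknown keys are
#' rejected.
#'
#' @param path Path to a JSON or YAML file whose top level is a mapping of
#'   threshold names to numbers.
#' @return A `grade_thresholds` object.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("thresholds file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- names(formals(grade_thresholds))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown threshold key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(grade_thresholds, raw)
}

#' @export
print.grade_thresholds <- function(x, ...) {
  cat("Grading thresholds (", length(unclass(x)), " settings):\n", sep = "")
  nm <- names(x)
  for (k in nm) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}

## strict-majority helper shared by the assessors; weights default to study count
.is_majority <- function(flags, threshold = 0.5, weights = NULL) {
  flags <- as.logical(flags)
  if (is.null(weights)) weights <- rep(1, length(flags))
  if (length(flags) == 0) return(FALSE)
  sum(weights[flags]) / sum(weights) > threshold
}
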