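## Inverse-variance meta-analysis support: log-scale conversion, fixed- and
## random-effects pooling, Cochran's Q / I-squared heterogeneity diagnostics,
## interval-overlap and direction profiles, exposure-gradient detection.
##
## Ratio measures (OR/RR/HR, null value 1) are pooled on the log scale; SMDs
## (null value 0) pool on their own scale. Mixing measures within one body is
## an error, never a silent conversion.

.z_for <- function(ci_level) stats::qnorm(1 - (1 - ci_level) / 2)

#' Construct a log-scale effect
#'
#' The standard inverse-variance representation: a point estimate `theta` on
#' the log scale for ratio measures (raw scale for SMD) and its standard
#' error.
#'
#' @param theta Point estimate on the analysis scale.
#' @param se Standard error, strictly positive.
#' @param study_id Label of the contributing study.
#' @return An object of class `log_effect`.
#' @export
log_effect <- function(theta, se, study_id = "") {
  theta <- as.numeric(theta); se <- as.numeric(se)
  if (is.na(se) || se <= 0) stop("se must be strictly positive", call. = FALSE)
  structure(list(theta = theta, se = se, study_id = as.character(study_id)),
            class = "log_effect")
}

#' Convert an effect estimate to the analysis scale
#'
#' For OR/RR/HR: `theta = ln(point)` and the standard error is recovered from
#' the confidence interval as `(ln(ci_high) - ln(ci_low)) / (2 z)`, where `z`
#' is the standard-normal quantile for the estimate's confidence level
#' (1.959964 at 95%). For SMD the identity scale is used with the analogous
#' width-based standard error.
#'
#' @param e An [effect_estimate()] with both confidence bounds.
#' @param study_id Study label carried into the result.
#' @return A [log_effect()].
#' @export
to_log_effect <- function(e, study_id = "") {
  stopifnot(inherits(e, "effect_estimate"))
  if (is.na(e$ci_low) || is.na(e$ci_high) || is.na(e$point))
    stop("cannot derive precision: study '", study_id,
         "' lacks a point estimate or confidence bounds", call. = FALSE)
  z <- .z_for(e$ci_level)
  if (e$measure %in% .RATIO_MEASURES) {
    if (e$point <= 0 || e$ci_low <= 0 || e$ci_high <= 0)
      stop("ratio measure must be positive (study '", study_id, "')", call. = FALSE)
    log_effect(log(e$point), (log(e$ci_high) - log(e$ci_low)) / (2 * z), study_id)
  } else {
    log_effect(e$point, (e$ci_high - e$ci_low) / (2 * z), study_id)
  }
}

#' Construct a pooled meta-analysis result
#'
#' Container for a pooled estimate with its heterogeneity diagnostics.
#' Usually produced by [pool_fixed()], [pool_random()] or [pool_body()];
#' exposed so results computed elsewhere can be attached to a body.
#'
#' @param theta_hat Pooled estimate on the analysis scale.
#' @param se_hat Its standard error.
#' @param ci_low,ci_high Confidence bounds on the analysis scale.
#' @param Q Cochran's Q statistic.
#' @param df Degrees of freedom, `k - 1`.
#' @param p_heterogeneity P value of the chi-square heterogeneity test.
#' @param i_squared I-squared percentage in `[0, 100)`.
#' @param tau_squared Between-study variance estimate.
#' @param k Number of pooled studies.
#' @param total_n Total participants behind the pooled estimate (`NA` when
#'   unknown).
#' @param measure Measure scale of the underlying estimates.
#' @param method `"fixed"` or `"random"`.
#' @return An object of class `pooled_result`.
#' @export
pooled_result <- function(theta_hat, se_hat, ci_low, ci_high, Q, df,
                          p_heterogeneity, i_squared, tau_squared, k,
                          total_n = NA_integer_, measure = "OR",
                          method = "random") {
  structure(list(theta_hat = theta_hat, se_hat = se_hat,
                 ci_low = ci_low, ci_high = ci_high,
                 Q = Q, df = as.integer(df),
                 p_heterogeneity = p_heterogeneity,
                 i_squared = i_squared, tau_squared = tau_squared,
                 k = as.integer(k), total_n = total_n,
                 measure = measure, method = method),
            class = "pooled_result")
}

.pool_core <- function(thetas, ses, tau2, k, ci_level, total_n, measure, method) {
  w <- 1 / (ses^2 + tau2)
  theta_hat <- sum(w * thetas) / sum(w)
  se_hat <- sqrt(1 / sum(w))
  ## Q and I^2 are always reported from the fixed-effect weights
  w0 <- 1 / ses^2
  th0 <- sum(w0 * thetas) / sum(w0)
  Q <- sum(w0 * (thetas - th0)^2)
  df <- k - 1L
  p_het <- stats::pchisq(Q, df = df, lower.tail = FALSE)
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  z <- .z_for(ci_level)
  pooled_result(theta_hat = theta_hat, se_hat = se_hat,
                ci_low = theta_hat - z * se_hat, ci_high = theta_hat + z * se_hat,
                Q = Q, df = df, p_heterogeneity = p_het, i_squared = i2,
                tau_squared = tau2, k = k, total_n = total_n,
                measure = measure, method = method)
}

.as_theta_se <- function(effects) {
  if (!is.list(effects) || length(effects) < 2 ||
      !all(vapply(effects, inherits, logical(1), "log_effect")))
    stop("inconsistency not assessable: pooling requires at least 2 effects",
         call. = FALSE)
  list(thetas = vapply(effects, `[[`, numeric(1), "theta"),
       ses = vapply(effects, `[[`, numeric(1), "se"))
}

#' Fixed-effect inverse-variance pooling
#'
#' Weights each effect by the reciprocal of its sampling variance and reports
#' Cochran's Q (weighted sum of squared deviations from the pooled estimate),
#' its chi-square p value at `k - 1` degrees of freedom, and I-squared,
#' `max(0, (Q - df)/Q) * 100`.
#'
#' @param effects List of at least two [log_effect()] objects.
#' @param ci_level Confidence level of the reported pooled interval.
#' @param total_n Total participants, echoed into the result.
#' @param measure Measure label, echoed into the result.
#' @return A [pooled_result()] with `method = "fixed"` and
#'   `tau_squared = 0`.
#' @export
pool_fixed <- function(effects, ci_level = 0.95, total_n = NA_integer_,
                       measure = "OR") {
  x <- .as_theta_se(effects)
  .pool_core(x$thetas, x$ses, tau2 = 0, k = length(effects),
             ci_level = ci_level, total_n = total_n, measure = measure,
             method = "fixed")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Estimates the between-study variance by the method of moments,
#' `tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effect
#' weights `w`, then pools with weights `1 / (se^2 + tau^2)`. With
#' homogeneous inputs (`Q <= df`) the estimator floors at zero and the result
#' equals the fixed-effect pooling.
#'
#' @inheritParams pool_fixed
#' @return A [pooled_result()] with `method = "random"`.
#' @export
pool_random <- function(effects, ci_level = 0.95, total_n = NA_integer_,
                        measure = "OR") {
  x <- .as_theta_se(effects)
  k <- length(effects)
  w <- 1 / x$ses^2
  th0 <- sum(w * x$thetas) / sum(w)
  Q <- sum(w * (x$thetas - th0)^2)
  df <- k - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  .pool_core(x$thetas, x$ses, tau2 = tau2, k = k, ci_level = ci_level,
             total_n = total_n, measure = measure, method = "random")
}

#' Pool a body of evidence
#'
#' Extracts each study's preferred estimate (multivariate first, univariate
#' fallback), requires a single common measure scale, converts to the
#' analysis scale and pools. Studies without both confidence bounds are
#' skipped with a logged warning.
#'
#' @param body A [body_of_evidence()].
#' @param method `"random"` (default) or `"fixed"`.
#' @param ci_level Confidence level for the pooled interval.
#' @return A [pooled_result()].
#' @export
pool_body <- function(body, method = c("random", "fixed"), ci_level = 0.95) {
  method <- match.arg(method)
  effects <- list(); measures <- character(); n_used <- 0L
  for (s in body$studies) {
    e <- preferred_effect(s)
    if (is.null(e)) next
    if (is.na(e$ci_low) || is.na(e$ci_high) || is.na(e$point)) {
      .log("warn", sprintf("study %s: estimate lacks confidence bounds; excluded from pooling",
                           s$study_id))
      next
    }
    measures <- c(measures, e$measure)
    effects[[length(effects) + 1]] <- to_log_effect(e, s$study_id)
    n_used <- n_used + s$n_participants
  }
  mm <- unique(ifelse(measures %in% .RATIO_MEASURES, "ratio", "SMD"))
  if (length(mm) > 1)
    stop("cannot pool mixed measure scales (ratio and SMD) within one body",
         call. = FALSE)
  f <- if (method == "random") pool_random else pool_fixed
  f(effects, ci_level = ci_level, total_n = n_used,
    measure = if (length(measures) > 0) measures[[1]] else "OR")
}

#' Pairwise confidence-interval overlap profile
#'
#' For every pair of effects, the overlap fraction is the length of the
#' interval intersection divided by the length of the shorter interval
#' (intervals taken on the analysis scale, `theta +/- z se`). Reports the
#' minimum over all pairs and whether any pair is disjoint. Degenerate
#' zero-width pairs count as fully overlapping when equal, disjoint
#' otherwise.
#'
#' @param effects List of at least two [log_effect()] objects.
#' @param ci_level Confidence level used to materialize the intervals.
#' @return `list(min_pairwise_overlap_fraction =, any_disjoint =)`.
#' @export
ci_overlap_profile <- function(effects, ci_level = 0.95) {
  x <- .as_theta_se(effects)
  z <- .z_for(ci_level)
  lo <- x$thetas - z * x$ses
  hi <- x$thetas + z * x$ses
  k <- length(lo)
  min_frac <- 1; disjoint <- FALSE
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      inter <- min(hi[i], hi[j]) - max(lo[i], lo[j])
      shorter <- min(hi[i] - lo[i], hi[j] - lo[j])
      frac <- if (inter <= 0) 0 else if (shorter <= 0) 1 else min(1, inter / shorter)
      if (inter < 0) disjoint <- TRUE
      if (inter == 0 && shorter > 0) disjoint <- TRUE
      min_frac <- min(min_frac, frac)
    }
  }
  list(min_pairwise_overlap_fraction = min_frac, any_disjoint = disjoint)
}

#' Classify effect directions relative to the line of no effect
#'
#' On the analysis scale the null is zero for every measure (1 on the ratio
#' scale maps to 0 under the log transform). Counts point estimates on the
#' risk side (`theta > 0`), exactly null, and the protective side, and flags
#' whether the set straddles the null (at least one estimate on each side).
#'
#' @param effects List of at least one [log_effect()].
#' @return `list(n_risk =, n_null_or_unknown =, n_protective =,
#'   straddles_null =)`.
#' @export
effect_direction_split <- function(effects) {
  if (length(effects) < 1) stop("at least one effect required", call. = FALSE)
  thetas <- vapply(effects, `[[`, numeric(1), "theta")
  n_risk <- sum(thetas > 0)
  n_prot <- sum(thetas < 0)
  list(n_risk = n_risk,
       n_null_or_unknown = sum(thetas == 0 | is.na(thetas)),
       n_protective = n_prot,
       straddles_null = n_risk > 0 && n_prot > 0)
}

#' Detect an exposure-response gradient
#'
#' A gradient is present when effect sizes are strictly monotone across at
#' least three strictly increasing exposure doses — elevated levels of the
#' prognostic factor consistently producing a larger (or consistently
#' smaller, for protective factors) effect.
#'
#' @param doses Strictly increasing dose values (length >= 3 for an
#'   assessable gradient).
#' @param points Effect point estimates at each dose, natural scale.
#' @param tol Tolerance: consecutive steps must exceed `tol` in absolute
#'   value to count as monotone movement (default 0, i.e. strict
#'   monotonicity; ties break the gradient).
#' @return `list(gradient =, direction = "increasing"|"decreasing"|"none",
#'   applicable =)`. With fewer than three levels the gradient is not
#'   assessable and `applicable` is `FALSE`.
#' @examples
#' detect_gradient(c(1, 3, 5), c(1.2, 1.7, 2.1))
#' @export
detect_gradient <- function(doses, points, tol = 0) {
  doses <- as.numeric(doses); points <- as.numeric(points)
  if (length(doses) != length(points))
    stop("doses and points must have equal length", call. = FALSE)
  if (length(doses) < 3)
    return(list(gradient = FALSE, direction = "none", applicable = FALSE))
  if (any(diff(doses) <= 0))
    stop("dose values must be strictly increasing", call. = FALSE)
  d <- diff(points)
  if (all(d > tol))
    list(gradient = TRUE, direction = "increasing", applicable = TRUE)
  else if (all(d < -tol))
    list(gradient = TRUE, direction = "decreasing", applicable = TRUE)
  else
    list(gradient = FALSE, direction = "none", applicable = TRUE)
}

#' Odds ratio from a 2x2 table
#'
#' `OR = (a d) / (b c)` with the Woolf confidence interval
#' `exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero a
#' +0.5 continuity correction is added to every cell. A row or column that is
#' entirely zero leaves the odds ratio undefined and raises an error.
#'
#' Cell layout: `a` = exposed with event, `b` = exposed without event,
#' `c` = unexposed with event, `d` = unexposed without event.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @param ci_level Confidence level of the interval.
#' @param adjusted,n_covariates Passed through to [effect_estimate()].
#' @return An [effect_estimate()] on the OR scale.
#' @export
odds_ratio_from_counts <- function(a, b, c, d, ci_level = 0.95,
                                   adjusted = FALSE, n_covariates = 0L) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("all cells must be nonnegative", call. = FALSE)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("undefined odds ratio: a row or column of the 2x2 table is zero",
         call. = FALSE)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]])
  se <- sqrt(sum(1 / cells))
  z <- .z_for(ci_level)
  effect_estimate("OR", or,
                  ci_low = exp(log(or) - z * se),
                  ci_high = exp(log(or) + z * se),
                  ci_level = ci_level, adjusted = adjusted,
                  n_covariates = n_covariates)
}

#' @export
print.pooled_result <- function(x, ...) {
  scale_lab <- if (x$measure %in% .RATIO_MEASURES) "log scale" else "SMD scale"
  cat(sprintf("Pooled result (%s effects, %s): theta_hat = %.4f (SE %.4f), CI [%.4f, %.4f]\n",
              x$method, scale_lab, x$theta_hat, x$se_hat, x$ci_low, x$ci_high))
  cat(sprintf("  k = %d, Q = %.3f (df = %d, p = %.4g), I^2 = %.1f%%, tau^2 = %.4f\n",
              x$k, x$Q, x$df, x$p_heterogeneity, x$i_squared, x$tau_squared))
  invisible(x)
}
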