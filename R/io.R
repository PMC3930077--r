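## Readers and writers for body-of-evidence documents. JSON is the canonical
## lossless dialect (YAML carries the same tree); the per-study CSV is a flat
## alternative restricted to one univariate and one multivariate estimate per
## study. Reading always validates: a document either loads completely and
## cleanly or not at all.

.BODY_KEYS <- c("factor_name", "outcome_name", "synthesis_mode", "studies",
                "pooled", "clinical_meaningfulness_of_differences", "overrides")
.STUDY_KEYS <- c("study_id", "phase", "design", "n_participants", "n_events",
                 "n_prognostic_variables", "outcome_type",
                 "sample_size_justified", "effects", "rob",
                 "indirect_population", "indirect_factor", "indirect_outcome",
                 "exposure_levels", "uni_vote", "mv_vote")
.EFFECT_KEYS <- c("measure", "point", "ci_low", "ci_high", "ci_level",
                  "adjusted", "n_covariates")
.POOLED_KEYS <- c("theta_hat", "se_hat", "ci_low", "ci_high", "Q", "df",
                  "p_heterogeneity", "i_squared", "tau_squared", "k",
                  "total_n", "measure", "method")

.na_or <- function(x, na) if (is.null(x)) na else x

.reject_unknown <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0)
    stop("unknown key(s) at ", where, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
}

.effect_to_list <- function(e) {
  list(measure = e$measure, point = e$point, ci_low = e$ci_low,
       ci_high = e$ci_high, ci_level = e$ci_level, adjusted = e$adjusted,
       n_covariates = e$n_covariates)
}

.effect_from_list <- function(x, where) {
  .reject_unknown(x, .EFFECT_KEYS, where)
  effect_estimate(x$measure,
                  .na_or(x$point, NA_real_),
                  .na_or(x$ci_low, NA_real_),
                  .na_or(x$ci_high, NA_real_),
                  .na_or(x$ci_level, 0.95),
                  .na_or(x$adjusted, FALSE),
                  .na_or(x$n_covariates, 0L))
}

.body_to_list <- function(body) {
  studies <- lapply(body$studies, function(s) {
    out <- list(
      study_id = s$study_id, phase = s$phase, design = s$design,
      n_participants = s$n_participants, n_events = s$n_events,
      n_prognostic_variables = s$n_prognostic_variables,
      outcome_type = s$outcome_type,
      sample_size_justified = s$sample_size_justified,
      effects = lapply(s$effects, .effect_to_list),
      rob = as.list(unclass(s$rob)),
      indirect_population = s$indirect_population,
      indirect_factor = s$indirect_factor,
      indirect_outcome = s$indirect_outcome,
      uni_vote = s$uni_vote, mv_vote = s$mv_vote)
    if (!is.null(s$exposure_levels))
      out$exposure_levels <- lapply(s$exposure_levels, function(l)
        list(dose = as.numeric(l$dose), effect = .effect_to_list(l$effect)))
    out
  })
  out <- list(factor_name = body$factor_name, outcome_name = body$outcome_name,
              synthesis_mode = body$synthesis_mode, studies = studies)
  if (!is.null(body$pooled)) {
    p <- body$pooled
    out$pooled <- p[.POOLED_KEYS]
  }
  if (!is.null(body$clinical_meaningfulness_of_differences))
    out$clinical_meaningfulness_of_differences <-
      body$clinical_meaningfulness_of_differences
  if (length(body$overrides) > 0)
    out$overrides <- lapply(body$overrides, function(ov)
      list(rating = ov$rating, justification = ov$justification))
  out
}

.body_from_list <- function(x, source = "<document>") {
  .reject_unknown(x, .BODY_KEYS, paste0(source, " (body)"))
  if (is.null(x$studies) || length(x$studies) == 0)
    stop("nonempty list of StudyRecord required (", source, ")", call. = FALSE)
  studies <- lapply(x$studies, function(s) {
    sid <- .na_or(s$study_id, "<unnamed>")
    .reject_unknown(s, .STUDY_KEYS, paste0(source, " study ", sid))
    .reject_unknown(s$rob, .QUIPS_DOMAINS, paste0(source, " study ", sid, " rob"))
    if (length(s$rob) != 6)
      stop("study ", sid, ": rob must rate exactly six QUIPS domains",
           call. = FALSE)
    effects <- lapply(seq_along(s$effects), function(i)
      .effect_from_list(s$effects[[i]],
                        sprintf("%s study %s effects[%d]", source, sid, i)))
    exposure <- NULL
    if (!is.null(s$exposure_levels)) {
      exposure <- lapply(seq_along(s$exposure_levels), function(i) {
        l <- s$exposure_levels[[i]]
        .reject_unknown(l, c("dose", "effect"),
                        sprintf("%s study %s exposure_levels[%d]", source, sid, i))
        list(dose = as.numeric(l$dose),
             effect = .effect_from_list(l$effect,
               sprintf("%s study %s exposure_levels[%d].effect", source, sid, i)))
      })
    }
    study_record(
      study_id = sid, phase = s$phase, design = s$design,
      n_participants = s$n_participants, rob = do.call(rob_profile, s$rob),
      n_events = .na_or(s$n_events, NA_integer_),
      n_prognostic_variables = .na_or(s$n_prognostic_variables, NA_integer_),
      outcome_type = .na_or(s$outcome_type, "dichotomous"),
      sample_size_justified = .na_or(s$sample_size_justified, FALSE),
      effects = effects,
      indirect_population = .na_or(s$indirect_population, FALSE),
      indirect_factor = .na_or(s$indirect_factor, FALSE),
      indirect_outcome = .na_or(s$indirect_outcome, FALSE),
      exposure_levels = exposure,
      uni_vote = .na_or(s$uni_vote, NA_character_),
      mv_vote = .na_or(s$mv_vote, NA_character_))
  })
  pooled <- NULL
  if (!is.null(x$pooled)) {
    .reject_unknown(x$pooled, .POOLED_KEYS, paste0(source, " pooled"))
    pooled <- do.call(pooled_result, x$pooled)
  }
  overrides <- list()
  if (!is.null(x$overrides)) {
    overrides <- lapply(x$overrides, function(ov) {
      .reject_unknown(ov, c("rating", "justification"), paste0(source, " override"))
      list(rating = ov$rating, justification = ov$justification)
    })
  }
  body_of_evidence(x$factor_name, x$outcome_name, studies,
                   synthesis_mode = x$synthesis_mode, pooled = pooled,
                   clinical_meaningfulness_of_differences =
                     x$clinical_meaningfulness_of_differences,
                   overrides = overrides)
}

#' Write a body-of-evidence document
#'
#' JSON (canonical: reading it back and re-writing reproduces the file
#' byte-for-byte), YAML, or the flat per-study CSV schema. The CSV dialect
#' carries at most one univariate and one multivariate estimate per study
#' and cannot express overrides or a stored pooled result; lossy writes are
#' logged.
#'
#' @param body A [body_of_evidence()].
#' @param path Output path; the extension selects the dialect unless
#'   `format` is given.
#' @param format `"json"`, `"yaml"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_body <- function(body, path, format = c("auto", "json", "yaml", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", yaml = , yml = "yaml", csv = "csv",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  if (format == "csv") return(.write_body_csv(body, path))
  x <- .body_to_list(body)
  txt <- if (format == "json") {
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                  na = "null", null = "null", pretty = 2))
  } else {
    yaml::as.yaml(x, precision = 15)
  }
  con <- file(path, open = "wb")
  writeBin(charToRaw(paste0(txt, "\n")), con)
  close(con)
  invisible(path)
}

#' Read a body-of-evidence document
#'
#' Parses, rejects unknown keys with diagnostics naming the study and field,
#' builds the domain objects, and runs [validate_body()]; any finding aborts
#' the load (a document never partial-loads).
#'
#' @param path Input path.
#' @param format `"json"`, `"yaml"` or `"csv"`; inferred from the extension
#'   by default.
#' @return A validated [body_of_evidence()].
#' @export
read_body <- function(path, format = c("auto", "json", "yaml", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", yaml = , yml = "yaml", csv = "csv",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  body <- if (format == "csv") {
    .read_body_csv(path)
  } else {
    x <- if (format == "json") {
      jsonlite::fromJSON(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
    .body_from_list(x, source = basename(path))
  }
  findings <- validate_body(body)
  if (nrow(findings) > 0) {
    stop("document ", basename(path), " failed validation:\n",
         paste(sprintf("  %s / %s: %s", findings$study_id, findings$field,
                       findings$message), collapse = "\n"),
         call. = FALSE)
  }
  .log("info", sprintf("read %s (%s, md5 %s): %d studies",
                       basename(path), format, .digest_file(path),
                       length(body$studies)))
  body
}

.CSV_COLS <- c("factor_name", "outcome_name", "synthesis_mode", "study_id",
               "phase", "design", "n_participants", "n_events",
               "n_prognostic_variables", "outcome_type",
               "sample_size_justified",
               paste0("rob_", .QUIPS_DOMAINS),
               "indirect_population", "indirect_factor", "indirect_outcome",
               "uni_vote", "mv_vote",
               "uni_measure", "uni_point", "uni_ci_low", "uni_ci_high",
               "uni_ci_level",
               "mv_measure", "mv_point", "mv_ci_low", "mv_ci_high",
               "mv_ci_level", "mv_n_covariates", "exposure_levels")

.encode_exposure <- function(levels) {
  if (is.null(levels)) return("")
  paste(vapply(levels, function(l)
    paste(l$dose, l$effect$measure, l$effect$point, l$effect$ci_low,
          l$effect$ci_high, sep = ":"), character(1)), collapse = ";")
}

.decode_exposure <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  lapply(strsplit(s, ";", fixed = TRUE)[[1]], function(item) {
    p <- strsplit(item, ":", fixed = TRUE)[[1]]
    if (length(p) != 5) stop("malformed exposure_levels entry: ", item,
                             call. = FALSE)
    list(dose = as.numeric(p[1]),
         effect = effect_estimate(p[2], suppressWarnings(as.numeric(p[3])),
                                  suppressWarnings(as.numeric(p[4])),
                                  suppressWarnings(as.numeric(p[5]))))
  })
}

.write_body_csv <- function(body, path) {
  if (length(body$overrides) > 0 || !is.null(body$clinical_meaningfulness_of_differences))
    .log("warn", "CSV dialect cannot carry overrides or the clinical-meaningfulness judgment; dropped")
  rows <- lapply(body$studies, function(s) {
    uni <- Filter(function(e) !e$adjusted, s$effects)
    mv <- Filter(function(e) e$adjusted, s$effects)
    if (length(uni) > 1 || length(mv) > 1)
      .log("warn", sprintf("study %s: CSV keeps only the first estimate of each analysis type",
                           s$study_id))
    uni <- if (length(uni) > 0) uni[[1]] else NULL
    mv <- if (length(mv) > 0) mv[[1]] else NULL
    g <- function(e, f) if (is.null(e)) NA else e[[f]]
    data.frame(
      factor_name = body$factor_name, outcome_name = body$outcome_name,
      synthesis_mode = body$synthesis_mode,
      study_id = s$study_id, phase = s$phase, design = s$design,
      n_participants = s$n_participants, n_events = s$n_events,
      n_prognostic_variables = s$n_prognostic_variables,
      outcome_type = s$outcome_type,
      sample_size_justified = s$sample_size_justified,
      rob_study_participation = s$rob[["study_participation"]],
      rob_study_attrition = s$rob[["study_attrition"]],
      rob_prognostic_factor_measurement = s$rob[["prognostic_factor_measurement"]],
      rob_outcome_measurement = s$rob[["outcome_measurement"]],
      rob_confounding = s$rob[["confounding"]],
      rob_analysis = s$rob[["analysis"]],
      indirect_population = s$indirect_population,
      indirect_factor = s$indirect_factor,
      indirect_outcome = s$indirect_outcome,
      uni_vote = s$uni_vote, mv_vote = s$mv_vote,
      uni_measure = g(uni, "measure"), uni_point = g(uni, "point"),
      uni_ci_low = g(uni, "ci_low"), uni_ci_high = g(uni, "ci_high"),
      uni_ci_level = g(uni, "ci_level"),
      mv_measure = g(mv, "measure"), mv_point = g(mv, "point"),
      mv_ci_low = g(mv, "ci_low"), mv_ci_high = g(mv, "ci_high"),
      mv_ci_level = g(mv, "ci_level"), mv_n_covariates = g(mv, "n_covariates"),
      exposure_levels = .encode_exposure(s$exposure_levels),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df[, .CSV_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

.read_body_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  .reject_unknown(df, .CSV_COLS, basename(path))
  missing <- setdiff(.CSV_COLS, names(df))
  if (length(missing) > 0)
    stop("CSV ", basename(path), " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  as_bool <- function(x) !is.na(x) & toupper(x) %in% c("TRUE", "1", "YES")
  as_num <- function(x) suppressWarnings(as.numeric(x))
  studies <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    effects <- list()
    if (!is.na(r$uni_measure))
      effects[[length(effects) + 1]] <-
        effect_estimate(r$uni_measure, as_num(r$uni_point),
                        as_num(r$uni_ci_low), as_num(r$uni_ci_high),
                        .na_or2(as_num(r$uni_ci_level), 0.95), adjusted = FALSE)
    if (!is.na(r$mv_measure))
      effects[[length(effects) + 1]] <-
        effect_estimate(r$mv_measure, as_num(r$mv_point),
                        as_num(r$mv_ci_low), as_num(r$mv_ci_high),
                        .na_or2(as_num(r$mv_ci_level), 0.95), adjusted = TRUE,
                        n_covariates = .na_or2(as.integer(as_num(r$mv_n_covariates)), 0L))
    study_record(
      study_id = r$study_id, phase = as.integer(r$phase), design = r$design,
      n_participants = as.integer(as_num(r$n_participants)),
      rob = rob_profile(r$rob_study_participation, r$rob_study_attrition,
                        r$rob_prognostic_factor_measurement,
                        r$rob_outcome_measurement, r$rob_confounding,
                        r$rob_analysis),
      n_events = as.integer(as_num(r$n_events)),
      n_prognostic_variables = as.integer(as_num(r$n_prognostic_variables)),
      outcome_type = r$outcome_type,
      sample_size_justified = as_bool(r$sample_size_justified),
      effects = effects,
      indirect_population = as_bool(r$indirect_population),
      indirect_factor = as_bool(r$indirect_factor),
      indirect_outcome = as_bool(r$indirect_outcome),
      exposure_levels = .decode_exposure(r$exposure_levels),
      uni_vote = .na_or2(r$uni_vote, NA_character_),
      mv_vote = .na_or2(r$mv_vote, NA_character_))
  })
  if (length(unique(df$factor_name)) != 1 ||
      length(unique(df$outcome_name)) != 1 ||
      length(unique(df$synthesis_mode)) != 1)
    stop("CSV ", basename(path),
         ": all rows must share factor_name, outcome_name and synthesis_mode",
         call. = FALSE)
  body_of_evidence(df$factor_name[1], df$outcome_name[1], studies,
                   synthesis_mode = df$synthesis_mode[1])
}

.na_or2 <- function(x, default) if (length(x) == 0 || is.na(x)) default else x
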