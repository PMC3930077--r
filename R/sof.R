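## Summary-of-findings tables: a pure view over bodies and their grades.
## Two layouts (meta-analysis, with the pooled estimate column; narrative,
## with univariate/multivariate significance-vote columns), two formats
## (Markdown with glyphs, CSV with an ASCII fallback vocabulary).

.GLYPHS <- list(
  unicode = c(ok = "✓", down = "✕", down2 = "✕✕",
              unclear = "Unclear", na = "NA"),
  ascii = c(ok = "ok", down = "down", down2 = "down2",
            unclear = "unclear", na = "na"))

.glyph_for <- function(assessment, vocab) {
  if (assessment$factor %in% .UPGRADE_FACTORS) {
    if (assessment$rating == "present") vocab[["ok"]] else vocab[["down"]]
  } else {
    switch(assessment$rating,
           no_concern = vocab[["ok"]],
           serious = vocab[["down"]],
           very_serious = vocab[["down2"]],
           unclear = vocab[["unclear"]],
           not_applicable = vocab[["na"]])
  }
}

.mark_seq <- function(i) {
  # a..z, then aa, ab, ...
  if (i <= 26) letters[i]
  else paste0(letters[(i - 1) %/% 26], letters[(i - 1) %% 26 + 1])
}

.modal_phase <- function(body) {
  phases <- vapply(body$studies, `[[`, integer(1), "phase")
  tab <- table(phases)
  as.integer(names(tab)[which.max(tab)])   # ties resolve to the lower phase
}

.vote_counts <- function(body, which = c("uni_vote", "mv_vote")) {
  which <- match.arg(which)
  v <- vapply(body$studies, `[[`, character(1), which)
  if (all(is.na(v))) return(c(pos = NA_integer_, null = NA_integer_, neg = NA_integer_))
  c(pos = sum(v == "positive", na.rm = TRUE),
    null = sum(v == "null", na.rm = TRUE),
    neg = sum(v == "negative", na.rm = TRUE))
}

.format_pooled <- function(pooled) {
  if (is.null(pooled)) return("")
  if (pooled$measure %in% .RATIO_MEASURES) {
    sprintf("%s %.2f (%.2f to %.2f)", pooled$measure, exp(pooled$theta_hat),
            exp(pooled$ci_low), exp(pooled$ci_high))
  } else {
    sprintf("SMD %.2f (%.2f to %.2f)", pooled$theta_hat, pooled$ci_low,
            pooled$ci_high)
  }
}

.sof_factor_order <- c("study_limitations", "inconsistency", "indirectness",
                       "imprecision", "publication_bias", "effect_size",
                       "dose_response")

#' Write a summary-of-findings table
#'
#' Renders one row per graded body of evidence. Every cell is reconstructed
#' from the quality grade's ledger: downgrade factors render a check mark
#' when of no concern, a cross when serious (a double cross when very
#' serious), the literal word "Unclear" when unclear, "NA" when not
#' applicable; upgrade factors render a check mark when present and a cross
#' otherwise. Each downgrade, unclear rating or override carries a footnote
#' marker linking to its machine-generated rationale below the table. CSV
#' output uses an ASCII glyph vocabulary (`ok`/`down`/`down2`/`unclear`/`na`)
#' and RFC 4180 quoting, and is byte-stable across runs.
#'
#' @param bodies List of [body_of_evidence()] objects (possibly empty; then
#'   a header-only document is produced).
#' @param grades List of `quality_grade` objects, one per body.
#' @param layout `"narrative"` (significance-vote columns) or `"meta"`
#'   (pooled-estimate column). Every body's synthesis mode must match the
#'   layout.
#' @param format `"markdown"` or `"csv"`.
#' @param path Optional output file; the document string is returned either
#'   way.
#' @return The document, invisibly when `path` is given.
#' @export
write_sof <- function(bodies, grades, layout = c("narrative", "meta"),
                      format = c("markdown", "csv"), path = NULL) {
  layout <- match.arg(layout)
  format <- match.arg(format)
  if (length(bodies) != length(grades))
    stop("one grade per body required", call. = FALSE)
  want_mode <- if (layout == "meta") "meta_analysis" else "narrative"
  for (b in bodies) {
    if (!identical(b$synthesis_mode, want_mode))
      stop("layout/synthesis-mode mismatch: body '", b$factor_name,
           "' has mode '", b$synthesis_mode, "' but layout is '", layout, "'",
           call. = FALSE)
  }
  vocab <- if (format == "csv") .GLYPHS$ascii else .GLYPHS$unicode

  base_cols <- c("Prognostic factor", "Number of participants",
                 "Number of studies", "Number of cohorts")
  mid_cols <- if (layout == "meta") {
    "Estimated effect size (95% CI)"
  } else {
    c("Univariate +", "Univariate 0", "Univariate -",
      "Multivariate +", "Multivariate 0", "Multivariate -")
  }
  grade_cols <- c("Phase", "Study limitations", "Inconsistency", "Indirectness",
                  "Imprecision", "Publication bias", "Moderate/large effect size",
                  "Dose effect", "Overall quality")
  header <- c(base_cols, mid_cols, grade_cols)

  rows <- list()
  footnotes <- character()
  n_marks <- 0L
  for (i in seq_along(bodies)) {
    b <- bodies[[i]]; g <- grades[[i]]
    by_factor <- stats::setNames(
      g$ledger[match(.sof_factor_order,
                     vapply(g$ledger, `[[`, character(1), "factor"))],
      .sof_factor_order)
    if (any(vapply(by_factor, is.null, logical(1))))
      stop("grade ledger for '", b$factor_name,
           "' does not cover every GRADE factor", call. = FALSE)
    cells <- character()
    for (f in .sof_factor_order) {
      a <- by_factor[[f]]
      glyph <- .glyph_for(a, vocab)
      needs_note <- a$rating %in% c("serious", "very_serious", "unclear") ||
        a$overridden || length(a$notes) > 0
      if (needs_note) {
        n_marks <- n_marks + 1L
        m <- .mark_seq(n_marks)
        txt <- sprintf("%s. %s - %s (%s): %s", m, b$factor_name,
                       gsub("_", " ", a$factor), a$rating, a$rationale)
        if (length(a$notes) > 0)
          txt <- paste0(txt, " [", paste(a$notes, collapse = "; "), "]")
        footnotes <- c(footnotes, txt)
        glyph <- if (format == "csv") sprintf("%s[%s]", glyph, m)
                 else sprintf("%s^%s^", glyph, m)
      }
      cells <- c(cells, glyph)
    }
    n_part <- sum(vapply(b$studies, `[[`, integer(1), "n_participants"))
    k <- length(b$studies)
    mid <- if (layout == "meta") {
      .format_pooled(b$pooled)
    } else {
      uv <- .vote_counts(b, "uni_vote"); mv <- .vote_counts(b, "mv_vote")
      fmt <- function(x) ifelse(is.na(x), "", as.character(x))
      c(fmt(uv), fmt(mv))
    }
    rows[[i]] <- c(b$factor_name, format(n_part, big.mark = ",", trim = TRUE),
                   as.character(k), as.character(k), mid,
                   as.character(.modal_phase(b)), cells, g$plus_notation)
  }

  doc <- if (format == "markdown") {
    .render_markdown(header, rows, footnotes)
  } else {
    .render_csv(header, rows, footnotes)
  }
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    writeBin(charToRaw(doc), con)
    close(con)
    return(invisible(doc))
  }
  doc
}

.render_markdown <- function(header, rows, footnotes) {
  line <- function(cells) paste0("| ", paste(cells, collapse = " | "), " |")
  out <- c(line(header),
           line(rep("---", length(header))),
           vapply(rows, line, character(1)))
  if (length(footnotes) > 0) out <- c(out, "", footnotes)
  paste0(paste(out, collapse = "\n"), "\n")
}

.csv_field <- function(x) {
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

.render_csv <- function(header, rows, footnotes) {
  line <- function(cells) paste(.csv_field(cells), collapse = ",")
  out <- c(line(header), vapply(rows, line, character(1)))
  if (length(footnotes) > 0)
    out <- c(out, vapply(footnotes, function(f) line(c("footnote", f)),
                         character(1), USE.NAMES = FALSE))
  paste0(paste(out, collapse = "\r\n"), "\r\n")
}
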