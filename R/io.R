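# CSV readers/writers and JSON/markdown report generation.

parse_flag <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t", "yes")] <- TRUE
  out[v %in% c("0", "false", "f", "no")] <- FALSE
  out
}

#' Read per-study source-indicator records
#'
#' Expects a UTF-8 CSV with header `study_id, source_a, source_b,
#' source_c`; indicator cells may be `0/1` or `true/false`
#' (case-insensitive). Validation errors name the offending data row.
#'
#' @param path CSV path.
#' @return A validated records data frame accepted by
#'   [build_capture_table()].
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("study_id", "source_a", "source_b", "source_c")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("no records")
  for (col in c("source_a", "source_b", "source_c")) {
    val <- parse_flag(df[[col]])
    bad <- which(is.na(val))
    if (length(bad))
      stop(sprintf("non-boolean value %s in column %s, row %d",
                   dQuote(df[[col]][bad[1]]), col, bad[1]))
    df[[col]] <- val
  }
  dup <- which(duplicated(df$study_id))
  if (length(dup))
    stop(sprintf("duplicate study_id %s at row %d",
                 dQuote(df$study_id[dup[1]]), dup[1]))
  none <- which(!(df$source_a | df$source_b | df$source_c))
  if (length(none))
    stop(sprintf("record %s (row %d) captured by no source",
                 dQuote(df$study_id[none[1]]), none[1]))
  df
}

#' Read per-study effect data
#'
#' Accepts either an `effect, se` schema or an `events, total` schema
#' (converted via [transform_proportion()]); a file carrying both is
#' refused as ambiguous.
#'
#' @param path CSV path.
#' @param scale Transform scale for events/total input.
#' @return An `effect_studies` data frame.
#' @export
read_effects_csv <- function(path, scale = c("raw", "logit", "ft")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"study_id" %in% names(df)) stop("missing column: study_id")
  has_es <- all(c("effect", "se") %in% names(df))
  has_et <- all(c("events", "total") %in% names(df))
  if (has_es && has_et)
    stop("ambiguous schema: both effect/se and events/total present")
  if (!has_es && !has_et)
    stop("need either effect/se or events/total columns")
  if (has_es) {
    bad <- which(!is.finite(df$effect) | !is.finite(df$se) | df$se <= 0)
    if (length(bad))
      stop(sprintf("invalid effect/se at row %d", bad[1]))
    return(effect_studies(df$study_id, df$effect, df$se))
  }
  es <- t(vapply(seq_len(nrow(df)), function(i) {
    tryCatch(transform_proportion(df$events[i], df$total[i], scale),
             error = function(e)
               stop(sprintf("row %d: %s", i, conditionMessage(e)),
                    call. = FALSE))
  }, numeric(2)))
  effect_studies(df$study_id, es[, 1], es[, 2])
}

#' Write per-study effect data
#'
#' @param studies An `effect_studies` data frame.
#' @param path Output CSV path.
#' @export
write_effects_csv <- function(studies, path) {
  write.csv(studies[, c("study_id", "effect", "se")], path,
            row.names = FALSE)
  invisible(path)
}

#' Write a capture table as a 7-row cell CSV
#'
#' One row per cell with a `pattern` column (`100` ... `111`) and the
#' cell count; the inverse of [read_capture_csv()].
#'
#' @param table A `capture_table`.
#' @param path Output CSV path.
#' @export
write_capture_csv <- function(table, path) {
  stopifnot(inherits(table, "capture_table"))
  write.csv(data.frame(pattern = CELL_PATTERNS,
                       count = unname(table$cells)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a 7-row cell CSV back into a capture table
#'
#' @param path CSV with `pattern` and `count` columns.
#' @return A `capture_table`.
#' @export
read_capture_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(pattern = "character"))
  if (!all(c("pattern", "count") %in% names(df)))
    stop("need pattern and count columns")
  if (!setequal(df$pattern, CELL_PATTERNS))
    stop("patterns must be exactly ", paste(CELL_PATTERNS, collapse = ", "))
  cnt <- setNames(df$count, df$pattern)[CELL_PATTERNS]
  capture_table(cnt[1], cnt[2], cnt[3], cnt[4], cnt[5], cnt[6], cnt[7])
}

#' Assemble an analysis report
#'
#' @param table Optional `capture_table` analyzed.
#' @param fits Optional `crc_fit_list`.
#' @param selected Optional selected `crc_fit`.
#' @param completeness Optional `crc_completeness` table.
#' @param bias Optional named list of `bias_test` results.
#' @param trimfill Optional `trim_fill_result`.
#' @param pooled Optional `meta_result`.
#' @param seed,config Provenance fields echoed into the report.
#' @return A `crc_report` list; see [write_report()].
#' @export
crc_report <- function(table = NULL, fits = NULL, selected = NULL,
                       completeness = NULL, bias = NULL, trimfill = NULL,
                       pooled = NULL, seed = NULL, config = NULL) {
  rep <- list(provenance = list(
    package = "crcbias",
    version = as.character(utils::packageVersion("crcbias")),
    seed = seed, config = config))
  if (!is.null(table)) {
    rep$input <- list(n_obs = table$n_obs,
                      cells = as.list(table$cells),
                      margins = as.list(table$margins),
                      sources = table$sources)
  }
  if (!is.null(fits)) rep$models <- crc_fit_table(fits)
  if (!is.null(selected)) {
    rep$selected <- list(model = selected$model$label,
                         g2 = selected$g2, df = selected$df,
                         p = selected$p, x_hat = selected$x_hat,
                         n_est = selected$n_est,
                         ci_x = as.list(selected$ci_x),
                         aic = selected$aic, bic = selected$bic)
  }
  if (!is.null(completeness)) rep$completeness <- as.data.frame(completeness)
  if (!is.null(pooled)) {
    rep$pooled <- list(k = pooled$k, est_fixed = pooled$est_fixed,
                       est_random = pooled$est_random, q = pooled$q,
                       df = pooled$df, p_q = pooled$p_q, i2 = pooled$i2,
                       tau2 = pooled$tau2)
  }
  if (!is.null(bias)) {
    rep$bias <- lapply(bias, function(b) {
      out <- list(method = b$method, statistic = b$statistic, p = b$p)
      if (!is.null(b$se)) out$se <- b$se
      out
    })
  }
  if (!is.null(trimfill)) {
    rep$trimfill <- list(
      k0 = trimfill$k0, side = trimfill$side,
      estimator = trimfill$estimator,
      filled = if (trimfill$k0 > 0)
        as.data.frame(trimfill$filled) else list(),
      pooled_original = trimfill$pooled_original$est,
      pooled_adjusted = trimfill$pooled_adjusted$est)
  }
  structure(rep, class = "crc_report")
}

fmt_inf <- function(x, digits = 0) {
  ifelse(is.finite(x),
         formatC(x, format = "f", digits = digits), "Inf")
}

report_markdown <- function(report) {
  lines <- c("# Capture-recapture publication-bias report", "")
  if (!is.null(report$input)) {
    lines <- c(lines,
               sprintf("Observed studies: %d (margins %s)",
                       report$input$n_obs,
                       paste(sprintf("%s=%d", report$input$sources,
                                     unlist(report$input$margins)),
                             collapse = ", ")),
               "")
  }
  if (!is.null(report$models)) {
    m <- report$models
    lines <- c(lines, "## Log-linear models", "",
               "| Model | df | G2 | P | N_est | X | AIC | BIC |",
               "|---|---|---|---|---|---|---|---|",
               sprintf("| %s | %d | %.2f | %.4f | %s | %s | %.2f | %.2f |",
                       m$model, m$df, m$g2, m$p, fmt_inf(m$n_est),
                       fmt_inf(m$x_hat), m$aic, m$bic),
               "")
  }
  if (!is.null(report$selected)) {
    lines <- c(lines, sprintf(
      "Selected model: %s (X = %s missing studies, N = %s)",
      report$selected$model,
      fmt_inf(round_half_up(report$selected$x_hat)),
      fmt_inf(round_half_up(report$selected$n_est))), "")
  }
  if (!is.null(report$completeness)) {
    cm <- report$completeness
    lines <- c(lines, "## Source completeness", "",
               "| Source | Observed | Estimated | Completeness (%) | Lower | Upper |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %d | %d | %.1f | %.1f | %.1f |",
                       cm$source, cm$observed, cm$estimated,
                       cm$completeness, cm$ci_lower, cm$ci_upper),
               "")
  }
  if (!is.null(report$bias)) {
    lines <- c(lines, "## Bias tests", "",
               vapply(report$bias, function(b)
                 sprintf("- %s: statistic %.4f, p = %.4f",
                         b$method, b$statistic, b$p), character(1)),
               "")
  }
  if (!is.null(report$trimfill)) {
    tf <- report$trimfill
    lines <- c(lines, "## Trim-and-fill", "",
               sprintf("- %d imputed studies (%s, %s side)", tf$k0,
                       tf$estimator, tf$side),
               sprintf("- Pooled original %.4f, adjusted %.4f",
                       tf$pooled_original, tf$pooled_adjusted),
               "")
  }
  paste(lines, collapse = "\n")
}

#' Write a report as JSON or markdown
#'
#' JSON output is deterministic for identical inputs (stable key order,
#' full numeric precision); markdown renders the model and completeness
#' tables at display precision.
#'
#' @param report A `crc_report`.
#' @param path Output path.
#' @param format `"json"` or `"markdown"`.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else {
    writeLines(report_markdown(report), path)
  }
  invisible(path)
}
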