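#' Record schema for survey CSV files
#'
#' @param mediators named character vector: mediator column -> type
#'   (`"binary"`, `"count"`, `"ordinal"`).
#' @param covariates named character vector: covariate column -> type
#'   (`"numeric"`, `"binary"`).
#' @param n_rounds maximum survey round (default 8).
#' @return list of class `crt_record_schema`.
#' @export
record_schema <- function(mediators = character(), covariates = character(),
                          n_rounds = 8L) {
  structure(list(
    required = c("block_id", "cluster_id", "compound_id", "child_id",
                 "round", "date", "arm", "diarrhea"),
    mediators = mediators, covariates = covariates,
    n_rounds = as.integer(n_rounds)
  ), class = "crt_record_schema")
}

#' Load and validate survey records from CSV
#'
#' Reads a long-format records file (one row per child-by-round), validates
#' identifiers, arm coding, round range and the outcome, and reports every
#' violation with its row number. Empty fields are preserved as missing.
#'
#' @param path CSV path.
#' @param schema a [record_schema()].
#' @return validated data.frame.
#' @export
load_records <- function(path, schema = record_schema()) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  stopifnot(inherits(schema, "crt_record_schema"))
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  missing_cols <- setdiff(schema$required, names(rec))
  if (length(missing_cols)) {
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  probs <- character(0)
  dates <- as.Date(rec$date, format = "%Y-%m-%d")
  bad <- which(!is.na(rec$date) & is.na(dates))
  if (length(bad)) {
    probs <- c(probs, sprintf("unparseable date in row(s): %s",
                              paste(utils::head(bad, 5), collapse = ", ")))
  }
  rec$date <- dates
  bad <- which(!is.na(rec$arm) & !rec$arm %in% c(0, 1))
  if (length(bad)) {
    probs <- c(probs, sprintf("arm not in {0,1} in row(s): %s",
                              paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(!is.na(rec$diarrhea) & !rec$diarrhea %in% c(0, 1))
  if (length(bad)) {
    probs <- c(probs, sprintf("diarrhea not in {0,1,missing} in row(s): %s",
                              paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(!is.na(rec$round) &
               (rec$round < 1 | rec$round > schema$n_rounds))
  if (length(bad)) {
    probs <- c(probs, sprintf("round outside 1..%d in row(s): %s",
                              schema$n_rounds,
                              paste(utils::head(bad, 5), collapse = ", ")))
  }
  for (id in c("block_id", "cluster_id", "compound_id", "child_id")) {
    bad <- which(is.na(rec[[id]]) | rec[[id]] == "")
    if (length(bad)) {
      probs <- c(probs, sprintf("empty %s in row(s): %s", id,
                                paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  for (m in names(schema$mediators)) {
    if (!m %in% names(rec)) {
      probs <- c(probs, sprintf("declared mediator column '%s' absent", m))
      next
    }
    if (schema$mediators[[m]] == "binary") {
      bad <- which(!is.na(rec[[m]]) & !rec[[m]] %in% c(0, 1))
      if (length(bad)) {
        probs <- c(probs, sprintf("binary mediator '%s' outside {0,1} in row(s): %s",
                                  m, paste(utils::head(bad, 5), collapse = ", ")))
      }
    }
    if (schema$mediators[[m]] %in% c("count", "ordinal")) {
      bad <- which(!is.na(rec[[m]]) & (rec[[m]] < 0 | rec[[m]] != floor(rec[[m]])))
      if (length(bad)) {
        probs <- c(probs, sprintf("mediator '%s' has non-integer/negative level in row(s): %s",
                                  m, paste(utils::head(bad, 5), collapse = ", ")))
      }
    }
  }
  if (length(probs)) stopf("record validation failed:\n  %s",
                           paste(probs, collapse = "\n  "))
  rec
}

#' Write survey records as CSV
#'
#' ISO-8601 dates, missing values as empty fields; deterministic given the
#' input, and re-parsed bit-exactly by [load_records()].
#'
#' @param records data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  if ("date" %in% names(out)) out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize synthetic-trial truth to JSON
#' @param truth a `crt_synth_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "crt_synth_truth"))
  payload <- list(oracle_mc_n = truth$oracle_mc_n, truth = truth$table,
                  seed = truth$config$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Crude prevalence/count ratio from printed arm percentages
#'
#' The worked-example calculator: the ratio of two printed arm prevalences,
#' rounded to 2 decimals as effect estimates are reported.
#'
#' @param p_treated treated-arm percentage (e.g. 10.0).
#' @param p_control control-arm percentage (> 0).
#' @return ratio rounded to 2 decimals.
#' @examples
#' crude_ratio(10.0, 14.8)  # 0.68
#' crude_ratio(97.1, 76.1)  # 1.28
#' @export
crude_ratio <- function(p_treated, p_control) {
  if (any(p_control == 0)) stopf("control prevalence is 0; ratio undefined")
  round(p_treated / p_control, 2)
}

#' Render the step-one screening table
#'
#' Emits the arm-summary / effect-estimate table (the published step-one
#' layout): per mediator, `n (%)` or `median (range)` per arm and the
#' ratio-scale estimate with CI, footnoted with the estimate type implied by
#' the model family (prevalence ratio, count ratio, or odds ratio).
#'
#' @param screen a `crt_screen_report` (or rbind of two seasons).
#' @param path optional CSV output path.
#' @return data.frame (written to `path` when given).
#' @export
render_table1 <- function(screen, path = NULL) {
  cols <- c("mediator", "category", "season", "sanitation_summary",
            "control_summary", "estimate", "ci_low", "ci_high", "p",
            "family", "retained")
  tab <- as.data.frame(screen)[, intersect(cols, names(screen)), drop = FALSE]
  tab$estimate_type <- vapply(tab$family, function(f) {
    if (is.na(f)) return(NA_character_)
    switch(f, "binomial-log" = "prevalence ratio",
           "modified-poisson" = "prevalence ratio",
           "poisson" = "count ratio",
           "ordinal-logit" = "odds ratio (proportional odds)",
           NA_character_)
  }, "")
  tab$estimate <- round(tab$estimate, 2)
  tab$ci_low <- round(tab$ci_low, 2)
  tab$ci_high <- round(tab$ci_high, 2)
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE, na = "")
  tab
}

#' Render the mediation-effect table (figure analog)
#'
#' Tabular equivalent of the ACME/ADE forest figure: per mediator and season,
#' ACME, ADE and total effect as prevalence differences in percentage points
#' with CIs, ordered from largest to smallest `|ACME|` within season.
#'
#' @param analysis a `crt_analysis` from [run_full_analysis()] (or its
#'   `table`).
#' @param path optional CSV output path.
#' @param percentage report effects in percentage points (default TRUE).
#' @return data.frame.
#' @export
render_mediation_figure_table <- function(analysis, path = NULL,
                                          percentage = TRUE) {
  tab <- if (inherits(analysis, "crt_analysis")) analysis$table else analysis
  if (is.null(tab) || !nrow(tab)) {
    return(data.frame(mediator = character(), season = character()))
  }
  eff_cols <- c("acme", "acme_ci_low", "acme_ci_high",
                "ade", "ade_ci_low", "ade_ci_high",
                "total", "total_ci_low", "total_ci_high")
  out <- tab
  scale <- if (percentage) 100 else 1
  for (cc in eff_cols) out[[cc]] <- round(out[[cc]] * scale, 3)
  out <- do.call(rbind, lapply(split(out, out$season), function(d) {
    d[order(-abs(d$acme)), ]
  }))
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE, na = "")
  out
}

#' Arm summaries recomputed from raw records
#'
#' @param records data.frame with `arm` and `season`.
#' @param variables columns to summarise.
#' @return data.frame: variable, season, arm, n, n_pos, pct (binary) or
#'   median/min/max.
#' @export
arm_summaries <- function(records, variables) {
  grid <- expand.grid(variable = variables,
                      season = unique(records$season), arm = c(0, 1),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$variable[i]
    x <- records[[v]][records$season == grid$season[i] &
                        records$arm == grid$arm[i]]
    x <- x[!is.na(x)]
    binary <- all(x %in% c(0, 1))
    data.frame(variable = v, season = grid$season[i], arm = grid$arm[i],
               n = length(x),
               n_pos = if (binary) sum(x == 1) else NA_integer_,
               pct = if (binary) 100 * mean(x == 1) else NA_real_,
               median = stats::median(x), min = suppressWarnings(min(x)),
               max = suppressWarnings(max(x)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize mediation results to tidy CSV and JSON
#'
#' One row per mediator, season and estimand — the interchange format for
#' downstream reporting.
#'
#' @param analysis a `crt_analysis`.
#' @param csv_path,json_path optional output paths.
#' @return tidy data.frame.
#' @export
write_mediation_results <- function(analysis, csv_path = NULL,
                                    json_path = NULL) {
  tab <- if (inherits(analysis, "crt_analysis")) analysis$table else analysis
  if (is.null(tab) || !nrow(tab)) return(invisible(NULL))
  long <- do.call(rbind, lapply(c("acme", "ade", "total"), function(e) {
    data.frame(mediator = tab$mediator, season = tab$season,
               estimand = toupper(e), method = tab$method, n = tab$n,
               estimate = tab[[e]],
               ci_low = tab[[paste0(e, "_ci_low")]],
               ci_high = tab[[paste0(e, "_ci_high")]],
               p = tab[[paste0(e, "_p")]], stringsAsFactors = FALSE)
  }))
  long <- long[order(long$season, long$mediator, long$estimand), ]
  rownames(long) <- NULL
  if (!is.null(csv_path)) utils::write.csv(long, csv_path, row.names = FALSE,
                                           na = "")
  if (!is.null(json_path)) {
    jsonlite::write_json(long, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  long
}
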