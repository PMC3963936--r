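# CSV schemas (comma separator, header required, '.' decimal, UTF-8) and the
# end-to-end pipeline.

validate_table <- function(df, need_cols, what, path = NULL) {
  src <- if (is.null(path)) what else sprintf("%s ('%s')", what, path)
  if (!is.data.frame(df)) stop(sprintf("%s is not a table", src), call. = FALSE)
  missing <- setdiff(need_cols, names(df))
  if (length(missing))
    stop(sprintf("schema error in %s: missing column(s) %s", src,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L)
    stop(sprintf("schema error in %s: no data rows", src), call. = FALSE)
  num_cols <- setdiff(need_cols, c("animal_id", "sample_id", "group"))
  for (cn in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad))
      stop(sprintf("schema error in %s: non-numeric value in column '%s' at data row %d",
                   src, cn, bad[1]), call. = FALSE)
    df[[cn]] <- as.numeric(df[[cn]])
  }
  df
}

validate_tac_table <- function(df, path = NULL) {
  validate_table(df, c("animal_id", "time_h", "activity_MBq", "injected_MBq"),
                 "time-activity table", path)
}

#' Read pipeline input tables
#'
#' Schema-checked CSV readers.  Expected columns:
#' * `read_tac_csv()`: `animal_id,time_h,activity_MBq,injected_MBq`
#' * `read_stunning_csv()`: `animal_id,initial_dose_Gy,baseline_uptake,rechallenge_uptake,day`
#'   (`percent_change` is recomputed on read)
#' * `read_qpcr_csv()`: `sample_id,group,ct_target,ct_reference`
#'
#' Violations raise errors naming the offending column and data row.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_tac_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_tac_table(df, path)
}

#' @rdname read_tac_csv
#' @export
read_stunning_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- validate_table(df, c("animal_id", "initial_dose_Gy", "baseline_uptake",
                             "rechallenge_uptake", "day"),
                       "stunning table", path)
  df$percent_change <- percent_change(df$baseline_uptake, df$rechallenge_uptake)
  df
}

#' @rdname read_tac_csv
#' @export
read_qpcr_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, c("sample_id", "group", "ct_target", "ct_reference"),
                 "qPCR table", path)
}

#' Write a table as CSV
#'
#' Fixed dialect: comma separator, header, no row names, '.' decimal.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param s_value Thyroid self S-value in Gy/Bq/s (default 4.55e-10), or the
#'   string `"simulate"` to compute it by Monte Carlo on the default phantom.
#' @param t_end_h Cumulated-activity endpoint (hours, default 24).
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed; stage sub-seeds are derived deterministically.
#' @param svalue_histories Histories per electron line when simulating the
#'   S-value (default 1e5).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(s_value = 4.55e-10, t_end_h = 24, alpha = 0.05,
                            seed = 20140324, svalue_histories = 1e5) {
  if (is.numeric(s_value)) {
    if (s_value <= 0) stop("s_value must be > 0", call. = FALSE)
  } else if (!identical(s_value, "simulate")) {
    stop('s_value must be a positive number or "simulate"', call. = FALSE)
  }
  stopifnot_scalar(t_end_h, "t_end_h", positive = TRUE)
  structure(list(s_value = s_value, t_end_h = t_end_h, alpha = alpha,
                 seed = seed, svalue_histories = svalue_histories),
            class = "pipeline_config")
}

#' Run the full dosimetry and stunning pipeline
#'
#' Fits every animal's time-activity curve, computes cumulated activities
#' and MIRD absorbed doses, calibrates peak activity against dose, and (when
#' a stunning table is supplied) scans for the stunning dose threshold.
#' When `config$s_value == "simulate"` the S-value is first computed by
#' Monte Carlo on the default 5.4 mg phantom with the packaged Tc-99m
#' spectrum.
#'
#' @param config A [pipeline_config()].
#' @param tac_table Validated time-activity table (see [read_tac_csv()]).
#' @param stunning_table Optional stunning table (see [read_stunning_csv()]).
#' @param recovery Optional list with `records` and `day0_values` for
#'   [recovery_profile()].
#' @return An object of class `pipeline_report`: list with `doses`,
#'   `dose_by_group` (per injected activity), `calibration`, `threshold`,
#'   `recovery`, `s_value` and `meta` (seed, config echo, package version).
#' @export
run_pipeline <- function(config = pipeline_config(), tac_table,
                         stunning_table = NULL, recovery = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  tac_table <- validate_tac_table(tac_table)

  sval_result <- NULL
  s_value <- config$s_value
  if (identical(s_value, "simulate")) {
    phantom <- build_phantom()
    spectrum <- tc99m_spectrum()
    sval_result <- self_svalue(phantom, spectrum, n = config$svalue_histories,
                               seed = derive_seed(config$seed, 1))
    s_value <- sval_result$s_value
  }

  doses <- tac_to_doses(tac_table, s_value = s_value, t_end_h = config$t_end_h)
  by_grp <- split(doses$dose_Gy, doses$injected_MBq)
  dose_by_group <- data.frame(
    injected_MBq = as.numeric(names(by_grp)),
    n = vapply(by_grp, length, integer(1)),
    mean_dose_Gy = vapply(by_grp, mean, numeric(1)),
    sd_dose_Gy = vapply(by_grp, function(x) if (length(x) > 1) sd(x) else NA_real_,
                        numeric(1)),
    row.names = NULL)

  calibration <- if (nrow(doses) >= 3 && length(unique(doses$peak_activity_MBq)) >= 2)
    calibrate_peak_to_dose(doses) else NULL

  threshold <- if (!is.null(stunning_table)) {
    st <- validate_table(stunning_table,
                         c("animal_id", "initial_dose_Gy", "baseline_uptake",
                           "rechallenge_uptake", "day"), "stunning table")
    st$percent_change <- percent_change(st$baseline_uptake, st$rechallenge_uptake)
    threshold_scan(st, alpha = config$alpha)
  } else NULL

  recov <- if (!is.null(recovery))
    recovery_profile(recovery$records, recovery$day0_values, alpha = config$alpha)
  else NULL

  structure(list(
    doses = doses,
    dose_by_group = dose_by_group,
    calibration = calibration,
    threshold = threshold,
    recovery = recov,
    s_value = s_value,
    s_value_result = sval_result,
    meta = list(seed = config$seed,
                t_end_h = config$t_end_h,
                alpha = config$alpha,
                s_value_mode = if (is.null(sval_result)) "fixed" else "simulate",
                package_version = as.character(packageVersion("stunmird")))
  ), class = "pipeline_report")
}

#' Serialize a pipeline report to JSON
#'
#' Fixed key order and 12 significant digits, so identical inputs and seed
#' give byte-identical output.
#'
#' @param report A [run_pipeline()] result.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  x <- list(
    meta = report$meta,
    s_value = report$s_value,
    dose_by_group = report$dose_by_group,
    calibration = report$calibration,
    threshold = if (!is.null(report$threshold))
      report$threshold[c("threshold_Gy", "p_value", "significant",
                         "mean_below", "mean_above", "n_below", "n_above",
                         "alpha", "note")] else NULL,
    recovery = if (!is.null(report$recovery))
      list(per_day = report$recovery$per_day, anova_p = report$recovery$anova_p)
    else NULL
  )
  js <- jsonlite::toJSON(x, digits = 12, auto_unbox = TRUE, dataframe = "columns",
                         na = "null", null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  S-value: %.4e Gy/Bq/s (%s)\n", x$s_value, x$meta$s_value_mode))
  cat("  dose by group:\n")
  print(x$dose_by_group, row.names = FALSE)
  if (!is.null(x$calibration))
    cat(sprintf("  peak->dose calibration: slope %.3f Gy/MBq, intercept %.3f Gy, R2 %.4f\n",
                x$calibration$slope_Gy_per_MBq, x$calibration$intercept_Gy,
                x$calibration$r_squared))
  if (!is.null(x$threshold)) print(x$threshold)
  if (!is.null(x$recovery)) print(x$recovery)
  invisible(x)
}
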