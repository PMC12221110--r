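# CSV and JSON interchange. Calibration CSV dialect: two named columns
# `temp_c,do2i_per_m2`, header required, UTF-8, '.' decimal separator;
# '#'-prefixed lines are provenance comments. Profile CSV: columns
# `time_min,temp_c`, header required.

# Read, tolerate comment lines, and report the 1-based file line number of
# the first malformed record.
read_two_column_csv <- function(path, col1, col2, what) {
  lines <- tryCatch(readLines(path, encoding = "UTF-8", warn = FALSE),
                    error = function(e) {
                      parse_error(sprintf("cannot read %s file '%s': %s",
                                          what, path, conditionMessage(e)))
                    })
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) == 0L) {
    parse_error(sprintf("%s file '%s' is empty", what, path))
  }
  header <- strsplit(trimws(lines[lineno[1]]), ",")[[1]]
  header <- trimws(header)
  i1 <- match(col1, header)
  i2 <- match(col2, header)
  if (is.na(i1) || is.na(i2)) {
    parse_error(sprintf(
      "%s file '%s', line %d: header must contain columns '%s' and '%s' (got '%s')",
      what, path, lineno[1], col1, col2, paste(header, collapse = ",")))
  }
  body <- lineno[-1]
  if (length(body) == 0L) {
    parse_error(sprintf("%s file '%s' has a header but no data rows",
                        what, path))
  }
  v1 <- numeric(length(body))
  v2 <- numeric(length(body))
  for (k in seq_along(body)) {
    fields <- trimws(strsplit(lines[body[k]], ",")[[1]])
    if (length(fields) < max(i1, i2)) {
      parse_error(sprintf("%s file '%s', line %d: expected %d fields, got %d",
                          what, path, body[k], length(header),
                          length(fields)))
    }
    a <- suppressWarnings(as.numeric(fields[i1]))
    b <- suppressWarnings(as.numeric(fields[i2]))
    if (is.na(a) || is.na(b)) {
      parse_error(sprintf("%s file '%s', line %d: non-numeric value",
                          what, path, body[k]))
    }
    v1[k] <- a
    v2[k] <- b
  }
  list(v1 = v1, v2 = v2)
}

#' Read a calibration dataset from CSV
#'
#' Expects a header row with columns `temp_c` and `do2i_per_m2` (any order,
#' extra columns ignored); `#`-prefixed lines are treated as provenance
#' comments. Malformed input raises a parse error naming the offending line.
#'
#' @param path path to the CSV file.
#' @param provenance provenance tag for the resulting dataset.
#' @return A [calibration_dataset()].
#' @export
read_calibration_csv <- function(path, provenance = "user") {
  cols <- read_two_column_csv(path, "temp_c", "do2i_per_m2", "calibration")
  calibration_dataset(cols$v1, cols$v2, provenance = provenance)
}

#' Write a calibration dataset to CSV
#'
#' Emits the `temp_c,do2i_per_m2` dialect. For synthetic datasets the
#' generating spec (grid, model, noise, seed) is embedded as `#`-prefixed
#' comment header lines, so a file documents its own provenance. Output is
#' byte-deterministic for a given dataset.
#'
#' @param data a [calibration_dataset()].
#' @param path output path, or `""` for standard output.
#' @return `invisible(path)`.
#' @export
write_calibration_csv <- function(data, path) {
  if (!inherits(data, "tado2i_dataset")) {
    parameter_error("`data` must be a calibration_dataset()")
  }
  lines <- character(0)
  spec <- attr(data, "spec")
  if (!is.null(spec)) {
    lines <- c(
      "# synthetic calibration dataset",
      sprintf("# generator_model: %s", spec$generator_model),
      sprintf("# temp_grid: %g to %g by %g", spec$temp_start, spec$temp_stop,
              spec$temp_step),
      sprintf("# noise_sd: %g", spec$noise_sd),
      sprintf("# blend_weight: %g", spec$blend_weight),
      sprintf("# seed: %d", spec$seed)
    )
  } else {
    lines <- sprintf("# provenance: %s", attr(data, "provenance") %||% "user")
  }
  lines <- c(lines, "temp_c,do2i_per_m2",
             paste(format_csv_number(data$temp_c),
                   format_csv_number(data$do2i_per_m2), sep = ","))
  writeLines(lines, if (identical(path, "")) stdout() else path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read a temperature profile from CSV
#'
#' Expects a header row with columns `time_min` and `temp_c`. Malformed
#' input raises a parse error naming the offending line.
#'
#' @param path path to the CSV file.
#' @return A [temperature_profile()].
#' @export
read_profile_csv <- function(path) {
  cols <- read_two_column_csv(path, "time_min", "temp_c", "profile")
  temperature_profile(cols$v1, cols$v2)
}

#' Write a trajectory or comparison table
#'
#' Fixed column order `time_min,temp_c,linear_do2i,q10_do2i,tado2i_per_m2,
#' tado2i_total` (the comparison table omits `time_min`). CSV or JSON.
#'
#' @param x a `tado2i_trajectory` or comparison-table data frame.
#' @param path output path, or `""` for standard output.
#' @param format `"csv"` or `"json"`.
#' @param digits display rounding applied to the value columns (default 1);
#'   `NULL` for full precision.
#' @return `invisible(path)`.
#' @export
write_trajectory <- function(x, path = "", format = c("csv", "json"),
                             digits = 1L) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  value_cols <- setdiff(names(df), c("time_min", "temp_c"))
  for (cc in value_cols) df[[cc]] <- round_display(df[[cc]], digits)
  con <- if (identical(path, "")) stdout() else path
  if (format == "csv") {
    header <- paste(names(df), collapse = ",")
    rows <- apply(df, 1, function(r) paste(format_csv_number(as.numeric(r)),
                                           collapse = ","))
    writeLines(c(header, rows), con)
  } else {
    writeLines(jsonlite::toJSON(df, dataframe = "rows", digits = NA,
                                pretty = TRUE), con)
  }
  invisible(path)
}

#' Write a calibration fit report as JSON
#'
#' Serializes coefficients, goodness of fit, sample size, and (when
#' present) bootstrap interval metadata: confidence level, per-coefficient
#' bounds, seed and resample count.
#'
#' @param fit a `tado2i_fit` (optionally from [calibrate()], with CIs).
#' @param path output path, or `""` for standard output.
#' @return `invisible(path)`.
#' @export
write_fit_json <- function(fit, path = "") {
  if (!inherits(fit, "tado2i_fit")) {
    parameter_error("`fit` must be a tado2i_fit")
  }
  out <- list(
    coefficients = list(a = fit$coeffs$a, b = fit$coeffs$b, c = fit$coeffs$c),
    r_squared = fit$r_squared,
    see = fit$see,
    n = fit$n
  )
  if (!is.null(fit$ci)) {
    out$ci <- list(
      confidence = fit$ci_confidence,
      a = list(lower = fit$ci["a", "lower"], upper = fit$ci["a", "upper"]),
      b = list(lower = fit$ci["b", "lower"], upper = fit$ci["b", "upper"]),
      c = list(lower = fit$ci["c", "lower"], upper = fit$ci["c", "upper"])
    )
    out$n_resamples <- fit$n_resamples
    out$seed <- fit$seed
    out$redraws <- fit$redraws
  }
  txt <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(txt, if (identical(path, "")) stdout() else path)
  invisible(path)
}
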