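# Per-patient glucometric metrics over a fixed analysis window. All range
# metrics are absolute cumulative times divided by total monitored time; each
# historic reading stands for one nominal cadence interval (15 min for the
# intermittently scanned sensors this targets), so no interpolation or
# gap-filling is performed.

RANGE_LEVELS <- c("TBR2", "TBR1", "TIR", "TAR1", "TAR2")

#' Restrict a reading series to the analysis window
#'
#' Keeps the last `window_days` days of readings, anchored at the latest
#' timestamp in the series (inclusive at the early boundary). Monitored time
#' is the number of retained historic readings times the nominal cadence;
#' scan events never contribute monitored time unless `count_scans` is set.
#'
#' @param series A [reading_series()].
#' @param window_days Window length in days (default 14).
#' @param cadence_min Nominal historic cadence in minutes (default 15).
#' @param count_scans Whether scan rows also count toward monitored time and
#'   range times (default `FALSE`).
#' @return An `analysis_window`: list with the restricted `series`,
#'   `window_days`, `window_end`, `cadence_min`, `count_scans` and
#'   `monitored_time` (minutes).
#' @export
select_window <- function(series, window_days = 14, cadence_min = 15,
                          count_scans = FALSE) {
  if (nrow(series) == 0) {
    stop("cannot select a window from an empty series")
  }
  window_end <- max(series$timestamp)
  cutoff <- window_end - window_days * 86400
  keep <- series$timestamp >= cutoff
  df <- series[keep, , drop = FALSE]
  rownames(df) <- NULL
  n_time <- sum(df$kind == "historic") +
    if (count_scans) sum(df$kind == "scan") else 0L
  structure(list(
    series = df,
    window_days = window_days,
    window_end = window_end,
    cadence_min = cadence_min,
    count_scans = count_scans,
    monitored_time = n_time * cadence_min
  ), class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> %g days ending %s: %d readings, %g min monitored\n",
              x$window_days, format(x$window_end), nrow(x$series),
              x$monitored_time))
  invisible(x)
}

#' Assign glucose values to consensus ranges
#'
#' The five clinical ranges partition the positive axis: TBR2 (0, 54), TBR1
#' \[54, 70), TIR \[70, 180\], TAR1 (180, 250\], TAR2 (250, Inf). The target
#' range is closed at both ends, so 70 and 180 mg/dL count as in range.
#'
#' @param value Numeric glucose values, mg/dL; must be positive.
#' @return Factor with levels `TBR2, TBR1, TIR, TAR1, TAR2`.
#' @export
#' @examples
#' assign_range(c(53.9, 54, 70, 180, 250, 251))
assign_range <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("glucose values must be finite and > 0")
  }
  lab <- ifelse(value < 54, "TBR2",
         ifelse(value < 70, "TBR1",
         ifelse(value <= 180, "TIR",
         ifelse(value <= 250, "TAR1", "TAR2"))))
  factor(lab, levels = RANGE_LEVELS)
}

#' Absolute cumulative time per range
#'
#' Each historic reading contributes one cadence interval to the range of its
#' value; the five times always sum to the monitored time.
#'
#' @param window An `analysis_window` with at least one historic reading.
#' @return A `range_times` list: `t_tbr2`, `t_tbr1`, `t_tir`, `t_tar1`,
#'   `t_tar2`, `t_total`, all in minutes.
#' @export
compute_range_times <- function(window) {
  df <- window$series
  use <- df$kind == "historic" | (window$count_scans & df$kind == "scan")
  if (!any(df$kind == "historic")) {
    stop("no historic readings in window")
  }
  tab <- table(assign_range(df$value[use])) * window$cadence_min
  structure(list(
    t_tbr2 = unname(tab[["TBR2"]]),
    t_tbr1 = unname(tab[["TBR1"]]),
    t_tir = unname(tab[["TIR"]]),
    t_tar1 = unname(tab[["TAR1"]]),
    t_tar2 = unname(tab[["TAR2"]]),
    t_total = window$monitored_time
  ), class = "range_times")
}

#' Range times as percentages of monitored time
#'
#' @param rt A `range_times` with positive total.
#' @return Named numeric vector `tbr2_pct, tbr1_pct, tir_pct, tar1_pct,
#'   tar2_pct` summing to 100.
#' @export
compute_range_percentages <- function(rt) {
  if (rt$t_total <= 0) {
    stop("total monitored time must be > 0")
  }
  c(tbr2_pct = 100 * rt$t_tbr2 / rt$t_total,
    tbr1_pct = 100 * rt$t_tbr1 / rt$t_total,
    tir_pct = 100 * rt$t_tir / rt$t_total,
    tar1_pct = 100 * rt$t_tar1 / rt$t_total,
    tar2_pct = 100 * rt$t_tar2 / rt$t_total)
}

#' Mean, SD and coefficient of variation of historic glucose
#'
#' Uses historic readings only (scan values would double-count and are biased
#' toward moments the patient chose to look). SD uses the sample (n-1)
#' denominator; CV is 100 * SD / mean.
#'
#' @param window An `analysis_window` with at least two historic readings.
#' @return Named vector `mean_glucose, sd_glucose, cv_pct`.
#' @export
compute_summary_glucose <- function(window) {
  v <- window$series$value[window$series$kind == "historic"]
  if (length(v) < 2) {
    stop("need at least 2 historic readings for mean/SD/CV")
  }
  m <- mean(v)
  s <- stats::sd(v)
  c(mean_glucose = m, sd_glucose = s, cv_pct = 100 * s / m)
}

#' Glucose management indicator
#'
#' Estimated HbA1c-equivalent from mean sensor glucose via the standard
#' linear regression GMI(%) = 3.31 + 0.02392 x mean glucose (mg/dL).
#'
#' @param mean_glucose Mean glucose in mg/dL, > 0.
#' @return GMI in percent.
#' @export
#' @examples
#' compute_gmi(154) # ~6.99
compute_gmi <- function(mean_glucose) {
  if (any(!is.finite(mean_glucose)) || any(mean_glucose <= 0)) {
    stop("mean glucose must be finite and > 0")
  }
  3.31 + 0.02392 * mean_glucose
}

#' Mean daily scan frequency
#'
#' @param window An `analysis_window`.
#' @return Scans per day (0 when no scans; never an error).
#' @export
compute_scan_rate <- function(window) {
  sum(window$series$kind == "scan") / window$window_days
}

#' Sensor usage percentage
#'
#' Fraction of expected historic readings actually present, where the
#' expectation is `window_days * 1440 / cadence_min` (96/day at the 15-min
#' cadence). Capped at 100.
#'
#' @param window An `analysis_window`.
#' @return Usage in percent, in \[0, 100\].
#' @export
compute_sensor_usage <- function(window) {
  expected <- window$window_days * 1440 / window$cadence_min
  min(100, 100 * sum(window$series$kind == "historic") / expected)
}

#' Full per-patient metric vector
#'
#' Composes the range, summary, GMI, scan-rate and usage computations into
#' the metric vector the classifiers consume.
#'
#' @param window An `analysis_window`.
#' @param patient Patient identifier used in error messages.
#' @return A `glycemic_metrics` list with fields `tir_pct`, `tar1_pct`,
#'   `tar2_pct`, `tbr1_pct`, `tbr2_pct`, `mean_glucose`, `sd_glucose`,
#'   `cv_pct`, `gmi_pct`, `mean_daily_scans`, `sensor_usage_pct`.
#' @export
compute_patient_metrics <- function(window, patient = "?") {
  res <- tryCatch({
    pct <- compute_range_percentages(compute_range_times(window))
    sg <- compute_summary_glucose(window)
    c(as.list(pct), as.list(sg),
      list(gmi_pct = compute_gmi(sg[["mean_glucose"]]),
           mean_daily_scans = compute_scan_rate(window),
           sensor_usage_pct = compute_sensor_usage(window)))
  }, error = function(e) {
    stop("patient ", patient, ": ", conditionMessage(e), call. = FALSE)
  })
  structure(res, class = "glycemic_metrics")
}

#' @export
print.glycemic_metrics <- function(x, ...) {
  cat(sprintf("<glycemic_metrics> TIR %.1f%% | TAR %.1f/%.1f | TBR %.1f/%.1f | CV %.1f%% | GMI %.2f%%\n",
              x$tir_pct, x$tar1_pct, x$tar2_pct, x$tbr1_pct, x$tbr2_pct,
              x$cv_pct, x$gmi_pct))
  invisible(x)
}

#' Metric table for a whole cohort
#'
#' Applies [select_window()] and [compute_patient_metrics()] to every patient
#' with a data file. Patients whose series cannot support the metrics (for
#' example fewer than two historic readings) get a row of `NA` metrics and an
#' entry in the `failures` attribute instead of aborting the cohort.
#'
#' @param cohort A `cgm_cohort`.
#' @param window_days,cadence_min,count_scans Passed to [select_window()].
#' @return data.frame with `patient_id` plus the metric columns; attribute
#'   `failures` is a named character vector of per-patient error messages.
#' @export
cohort_metrics <- function(cohort, window_days = 14, cadence_min = 15,
                           count_scans = FALSE) {
  ids <- names(cohort$patients)
  cols <- c("tbr2_pct", "tbr1_pct", "tir_pct", "tar1_pct", "tar2_pct",
            "mean_glucose", "sd_glucose", "cv_pct", "gmi_pct",
            "mean_daily_scans", "sensor_usage_pct")
  out <- as.data.frame(matrix(NA_real_, nrow = length(ids),
                              ncol = length(cols),
                              dimnames = list(NULL, cols)))
  out <- cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE), out)
  failures <- character()
  for (i in seq_along(ids)) {
    m <- tryCatch({
      w <- select_window(cohort$patients[[ids[i]]], window_days = window_days,
                         cadence_min = cadence_min, count_scans = count_scans)
      compute_patient_metrics(w, patient = ids[i])
    }, error = function(e) conditionMessage(e))
    if (is.character(m)) {
      failures[ids[i]] <- m
      # usage is still well defined for a sparse series
      w <- tryCatch(select_window(cohort$patients[[ids[i]]],
                                  window_days = window_days,
                                  cadence_min = cadence_min,
                                  count_scans = count_scans),
                    error = function(e) NULL)
      if (!is.null(w)) {
        out$sensor_usage_pct[i] <- compute_sensor_usage(w)
        out$mean_daily_scans[i] <- compute_scan_rate(w)
      }
    } else {
      out[i, cols] <- unlist(m)[cols]
    }
  }
  attr(out, "failures") <- failures
  out
}
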