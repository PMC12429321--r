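# Automatic data-quality exclusions applied before any classification:
# missing essential demographics, implausible glucose entries, empty series,
# and insufficient sensor usage. Filtering never raises on bad data; it
# excludes and logs.

EXCLUSION_REASONS <- c("missing_essential_field", "empty_series",
                       "erroneous_entries", "low_sensor_usage")

#' Validate one patient record
#'
#' Checks the essential manifest fields (age, hospital_id), the
#' device-plausible glucose span, and that any historic readings survived
#' parsing.
#'
#' @param meta One-row data.frame (or list) with `age` and `hospital_id`.
#' @param series The patient's [reading_series()], or `NULL`.
#' @param plausible_range Device-plausible glucose span in mg/dL.
#' @return data.frame of issues with columns `reason` and `detail` (zero rows
#'   for a clean record).
#' @export
validate_record <- function(meta, series, plausible_range = c(40, 500)) {
  issues <- list()
  if (is.null(meta$age) || is.na(suppressWarnings(as.numeric(meta$age))) ||
      as.numeric(meta$age) < 0) {
    issues[[length(issues) + 1]] <- c("missing_essential_field",
                                      "age absent or non-numeric")
  }
  if (is.null(meta$hospital_id) || is.na(meta$hospital_id) ||
      !nzchar(as.character(meta$hospital_id))) {
    issues[[length(issues) + 1]] <- c("missing_essential_field",
                                      "hospital_id absent")
  }
  n_hist <- if (is.null(series)) 0L else sum(series$kind == "historic")
  if (n_hist == 0) {
    issues[[length(issues) + 1]] <- c("empty_series",
                                      "no historic readings survived parsing")
  } else {
    bad <- series$value < plausible_range[1] | series$value > plausible_range[2]
    if (any(bad)) {
      issues[[length(issues) + 1]] <-
        c("erroneous_entries",
          sprintf("%d reading(s) outside [%g, %g] mg/dL", sum(bad),
                  plausible_range[1], plausible_range[2]))
    }
  }
  if (length(issues) == 0) {
    return(data.frame(reason = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(reason = vapply(issues, `[`, "", 1),
             detail = vapply(issues, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Apply the automatic quality filter
#'
#' A patient is excluded iff sensor usage is strictly below the threshold
#' (the gate is printed as "< 70%", so exactly 70% is kept) or
#' [validate_record()] reports any issue. Inclusion is all-or-nothing per
#' patient; the exclusion log is exhaustive and ordered by patient id, one
#' record per excluded patient with the highest-priority reason and all
#' details.
#'
#' @param cohort A `cgm_cohort`.
#' @param metrics Metric table from [cohort_metrics()] (for
#'   `sensor_usage_pct`).
#' @param min_usage_pct Usage threshold in percent (default 70).
#' @param plausible_range Device-plausible glucose span in mg/dL.
#' @return List with `included` (a `cgm_cohort`) and `exclusions`
#'   (data.frame `patient_id, reason, detail`).
#' @export
apply_quality_filter <- function(cohort, metrics, min_usage_pct = 70,
                                 plausible_range = c(40, 500)) {
  ids <- sort(names(cohort$patients))
  recs <- list()
  for (pid in ids) {
    meta <- cohort$manifest[cohort$manifest$patient_id == pid, , drop = FALSE]
    iss <- validate_record(if (nrow(meta)) meta[1, ] else list(),
                           cohort$patients[[pid]], plausible_range)
    usage <- metrics$sensor_usage_pct[metrics$patient_id == pid]
    if (length(usage) == 1 && !is.na(usage) && usage < min_usage_pct) {
      iss <- rbind(iss, data.frame(
        reason = "low_sensor_usage",
        detail = sprintf("sensor usage %.2f%% < %g%%", usage, min_usage_pct),
        stringsAsFactors = FALSE))
    }
    if (nrow(iss) > 0) {
      iss$reason <- factor(iss$reason, levels = EXCLUSION_REASONS)
      iss <- iss[order(iss$reason), , drop = FALSE]
      recs[[pid]] <- data.frame(
        patient_id = pid,
        reason = as.character(iss$reason[1]),
        detail = paste(iss$detail, collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  exclusions <- if (length(recs)) do.call(rbind, recs) else
    data.frame(patient_id = character(), reason = character(),
               detail = character(), stringsAsFactors = FALSE)
  rownames(exclusions) <- NULL
  included <- subset_cohort(cohort, setdiff(ids, exclusions$patient_id))
  list(included = included, exclusions = exclusions)
}

#' Write the exclusion log
#'
#' @param exclusions data.frame from [apply_quality_filter()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusions_csv <- function(exclusions, path) {
  utils::write.csv(exclusions, path, row.names = FALSE)
  invisible(path)
}
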