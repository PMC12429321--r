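# Reading and writing: sensor CSV exports, cohort manifests, classification
# output. The sensor dialect is pinned to the common LibreView export layout:
# one metadata line, then a header containing "Device Timestamp" and
# "Record Type", historic rows of Record Type 0 and scan rows of Record Type 1.

LIBREVIEW_TS_COL <- "Device Timestamp"
LIBREVIEW_TYPE_COL <- "Record Type"
LIBREVIEW_HISTORIC_COL <- "Historic Glucose mg/dL"
LIBREVIEW_SCAN_COL <- "Scan Glucose mg/dL"
GENERIC_COLS <- c("patient_id", "timestamp", "value", "kind")

#' Construct a reading series
#'
#' A reading series is one patient's time-ordered glucose readings: a
#' data.frame with columns `timestamp` (POSIXct, minute resolution), `value`
#' (glucose, mg/dL) and `kind` (`"historic"` for the sensor's fixed-cadence
#' log, `"scan"` for user scan events). Rows are sorted by timestamp and
#' historic timestamps are unique.
#'
#' @param patient_id Opaque pseudo-identifier.
#' @param timestamp POSIXct vector.
#' @param value Numeric glucose values, mg/dL; must be finite and positive.
#' @param kind Character vector, `"historic"` or `"scan"`.
#' @return An object of class `reading_series` (a data.frame with a
#'   `patient_id` attribute).
#' @export
reading_series <- function(patient_id, timestamp, value, kind) {
  stopifnot(length(timestamp) == length(value), length(value) == length(kind))
  if (!inherits(timestamp, "POSIXct")) {
    stop("timestamp must be POSIXct")
  }
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("glucose values must be finite and > 0")
  }
  if (!all(kind %in% c("historic", "scan"))) {
    stop("kind must be 'historic' or 'scan'")
  }
  df <- data.frame(timestamp = timestamp, value = as.numeric(value),
                   kind = kind, stringsAsFactors = FALSE)
  df <- df[order(df$timestamp, df$kind), , drop = FALSE]
  rownames(df) <- NULL
  hist_ts <- df$timestamp[df$kind == "historic"]
  if (anyDuplicated(hist_ts)) {
    stop("duplicate historic timestamps; deduplicate before construction")
  }
  structure(df, patient_id = as.character(patient_id),
            class = c("reading_series", "data.frame"))
}

#' @export
print.reading_series <- function(x, ...) {
  cat(sprintf("<reading_series> patient %s: %d readings (%d historic, %d scan)\n",
              attr(x, "patient_id"), nrow(x),
              sum(x$kind == "historic"), sum(x$kind == "scan")))
  if (nrow(x) > 0) {
    cat(sprintf("  span %s .. %s\n", format(min(x$timestamp)),
                format(max(x$timestamp))))
  }
  invisible(x)
}

#' Patient identifier of a reading series
#' @param series A `reading_series`.
#' @return Character scalar.
#' @export
patient_id <- function(series) attr(series, "patient_id")

#' Detect the format of a CGM data file
#'
#' Inspects the first two lines of a file and tags it as `"libreview_csv"`
#' (metadata line, then a header containing the "Device Timestamp" and
#' "Record Type" columns), `"generic_long_csv"` (first line is exactly the
#' header \{patient_id, timestamp, value, kind\}), or `"unknown"`.
#'
#' @param path Path to an existing readable file.
#' @return One of `"libreview_csv"`, `"generic_long_csv"`, `"unknown"`.
#' @export
detect_format <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read file: ", path)
  }
  lines <- tryCatch(readLines(path, n = 2L, warn = FALSE),
                    error = function(e) stop("cannot read file: ", path))
  if (length(lines) >= 1) {
    first <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
    first <- gsub('^"|"$', "", trimws(first))
    if (length(first) == 4 && setequal(first, GENERIC_COLS)) {
      return("generic_long_csv")
    }
  }
  if (length(lines) >= 2 &&
      grepl(LIBREVIEW_TS_COL, lines[[2]], fixed = TRUE) &&
      grepl(LIBREVIEW_TYPE_COL, lines[[2]], fixed = TRUE)) {
    return("libreview_csv")
  }
  "unknown"
}

#' Parse a CGM export into a reading series
#'
#' For the LibreView dialect, historic rows (Record Type 0) are read from the
#' historic-glucose column and scan rows (Record Type 1) from the scan-glucose
#' column; rows of any other record type (device events, notes, carbs or
#' insulin entries) are skipped and counted. Rows with an unparseable
#' timestamp or non-numeric glucose are dropped and counted. Duplicate
#' historic timestamps collapse to the last occurrence in file order, with a
#' warning.
#'
#' @param path Path to the file.
#' @param dialect Format tag from [detect_format()]; auto-detected when
#'   missing. Must not be `"unknown"`.
#' @param timestamp_format `strptime` pattern for the timestamp column.
#' @param patient_id Identifier to attach (LibreView exports carry none); for
#'   the generic dialect defaults to the file's `patient_id` column.
#' @return A [reading_series()] with attributes `n_skipped` (other record
#'   types), `n_bad_rows` (parse failures) and `n_duplicates` (collapsed
#'   historic duplicates).
#' @export
parse_cgm_csv <- function(path, dialect = detect_format(path),
                          timestamp_format = "%Y-%m-%d %H:%M",
                          patient_id = NULL) {
  if (identical(dialect, "unknown")) {
    stop("unknown file format: ", path)
  }
  if (dialect == "libreview_csv") {
    raw <- utils::read.csv(path, skip = 1, check.names = FALSE,
                           colClasses = "character")
    needed <- c(LIBREVIEW_TS_COL, LIBREVIEW_TYPE_COL)
    if (!all(needed %in% names(raw))) {
      stop("file lacks LibreView columns: ", path)
    }
    type <- suppressWarnings(as.integer(raw[[LIBREVIEW_TYPE_COL]]))
    keep <- !is.na(type) & type %in% c(0L, 1L)
    n_skipped <- sum(!keep)
    raw <- raw[keep, , drop = FALSE]
    type <- type[keep]
    value <- ifelse(type == 0L,
                    raw[[LIBREVIEW_HISTORIC_COL]] %||% NA_character_,
                    raw[[LIBREVIEW_SCAN_COL]] %||% NA_character_)
    ts_chr <- raw[[LIBREVIEW_TS_COL]]
    kind <- ifelse(type == 0L, "historic", "scan")
    if (is.null(patient_id)) {
      patient_id <- tools::file_path_sans_ext(basename(path))
    }
  } else {
    raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    if (!all(GENERIC_COLS %in% names(raw))) {
      stop("file lacks generic long columns: ", path)
    }
    n_skipped <- 0L
    ts_chr <- raw$timestamp
    value <- raw$value
    kind <- raw$kind
    if (is.null(patient_id)) {
      ids <- unique(raw$patient_id)
      patient_id <- if (length(ids)) ids[[1]] else
        tools::file_path_sans_ext(basename(path))
    }
  }

  ts <- as.POSIXct(ts_chr, format = timestamp_format, tz = "UTC")
  val <- suppressWarnings(as.numeric(value))
  ok <- !is.na(ts) & !is.na(val) & is.finite(val) & val > 0 &
    kind %in% c("historic", "scan")
  n_bad <- sum(!ok)
  ts <- ts[ok]; val <- val[ok]; kind <- kind[ok]
  if (length(val) == 0) {
    stop("no valid readings in ", path,
         " (", n_bad, " unparseable rows dropped)")
  }

  # keep-last dedup of historic timestamps, in file order
  n_dup <- 0L
  is_hist <- kind == "historic"
  if (any(is_hist)) {
    dup <- is_hist & duplicated(ifelse(is_hist, as.numeric(ts), NA),
                                fromLast = TRUE) & !is.na(ts)
    dup[!is_hist] <- FALSE
    n_dup <- sum(dup)
    if (n_dup > 0) {
      warning(sprintf("%s: %d duplicate historic timestamp(s) collapsed to last occurrence",
                      patient_id, n_dup))
      ts <- ts[!dup]; val <- val[!dup]; kind <- kind[!dup]
    }
  }

  out <- reading_series(patient_id, ts, val, kind)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_bad_rows") <- n_bad
  attr(out, "n_duplicates") <- n_dup
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reading series as generic long CSV
#'
#' The generic long dialect (`patient_id,timestamp,value,kind`) round-trips
#' through [parse_cgm_csv()] without loss.
#'
#' @param series A `reading_series`.
#' @param path Output file path.
#' @param timestamp_format `strptime` pattern used to render timestamps.
#' @return `path`, invisibly.
#' @export
write_reading_series <- function(series, path,
                                 timestamp_format = "%Y-%m-%d %H:%M") {
  df <- data.frame(
    patient_id = patient_id(series),
    timestamp = format(series$timestamp, timestamp_format, tz = "UTC"),
    value = series$value,
    kind = series$kind,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a cohort from a data directory and manifest
#'
#' The manifest is a CSV with header `patient_id,age,hospital_id` (device
#' exports carry no demographics, so these travel separately). Each patient's
#' readings are expected at `<data_dir>/<patient_id>.csv` in either supported
#' dialect. Patients listed in the manifest whose file is absent are recorded
#' in the `missing` log, not silently dropped.
#'
#' @param data_dir Directory of per-patient CSV files.
#' @param manifest_path Path to the manifest CSV.
#' @param timestamp_format `strptime` pattern for the data files.
#' @return A `cgm_cohort`: list with `patients` (named list of
#'   `reading_series`), `manifest` (data.frame), and `missing` (character
#'   vector of patient ids without a data file).
#' @export
load_cohort <- function(data_dir, manifest_path,
                        timestamp_format = "%Y-%m-%d %H:%M") {
  manifest <- utils::read.csv(manifest_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  if (!all(c("patient_id", "age", "hospital_id") %in% names(manifest))) {
    stop("manifest must have columns patient_id, age, hospital_id")
  }
  if (nrow(manifest) == 0) {
    stop("manifest is empty: ", manifest_path)
  }
  manifest$patient_id <- as.character(manifest$patient_id)
  manifest$hospital_id <- as.character(manifest$hospital_id)
  manifest$age <- suppressWarnings(as.numeric(manifest$age))
  if (anyDuplicated(manifest$patient_id)) {
    stop("duplicate patient_id in manifest: ",
         paste(unique(manifest$patient_id[duplicated(manifest$patient_id)]),
               collapse = ", "))
  }
  patients <- list()
  missing <- character()
  for (pid in manifest$patient_id) {
    f <- file.path(data_dir, paste0(pid, ".csv"))
    if (!file.exists(f)) {
      missing <- c(missing, pid)
      next
    }
    patients[[pid]] <- parse_cgm_csv(f, timestamp_format = timestamp_format,
                                     patient_id = pid)
  }
  structure(list(patients = patients, manifest = manifest, missing = missing),
            class = "cgm_cohort")
}

#' @export
print.cgm_cohort <- function(x, ...) {
  cc <- center_counts(x)
  cat(sprintf("<cgm_cohort> %d patients with data, %d missing files, %d centres\n",
              length(x$patients), length(x$missing), length(cc)))
  invisible(x)
}

#' Patients per centre
#'
#' Tally of patients with data files per `hospital_id`. Always sums to the
#' number of loaded reading series.
#'
#' @param cohort A `cgm_cohort`.
#' @return Named integer vector, one entry per hospital.
#' @export
center_counts <- function(cohort) {
  m <- cohort$manifest
  m <- m[m$patient_id %in% names(cohort$patients), , drop = FALSE]
  tab <- table(m$hospital_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Restrict a cohort to a set of patients
#'
#' @param cohort A `cgm_cohort`.
#' @param ids Patient identifiers to keep.
#' @return A `cgm_cohort` containing only those patients.
#' @export
subset_cohort <- function(cohort, ids) {
  structure(list(
    patients = cohort$patients[names(cohort$patients) %in% ids],
    manifest = cohort$manifest[cohort$manifest$patient_id %in% ids, ,
                               drop = FALSE],
    missing = intersect(cohort$missing, ids)
  ), class = "cgm_cohort")
}

#' Write the per-patient classification CSV
#'
#' One row per included patient joining demographics, the metric vector and
#' the three classifications. Numeric fields are rendered with two decimal
#' places; a patient without a Glycemic Risk Index carries the literal string
#' `"not_allowed"` in `gri_zone` and `NA` in `gri_score`.
#'
#' @param cohort The included `cgm_cohort`.
#' @param metrics Metric table from [cohort_metrics()].
#' @param classifications Classification table from [classify_cohort()].
#' @param out_path Output CSV path.
#' @return `out_path`, invisibly.
#' @export
write_classification_csv <- function(cohort, metrics, classifications,
                                     out_path) {
  ids <- names(cohort$patients)
  if (!all(ids %in% metrics$patient_id) ||
      !all(ids %in% classifications$patient_id)) {
    stop("results missing for included patient(s): ",
         paste(setdiff(ids, intersect(metrics$patient_id,
                                      classifications$patient_id)),
               collapse = ", "))
  }
  cols <- c("patient_id", "age", "hospital_id", "tir_pct", "tar1_pct",
            "tar2_pct", "tbr1_pct", "tbr2_pct", "cv_pct", "gmi_pct",
            "mean_daily_scans", "sensor_usage_pct", "attd_all_met",
            "attd_level1_met", "andiacare_category", "gri_score", "gri_zone")
  if (length(ids) == 0) {
    writeLines(paste(cols, collapse = ","), out_path)
    return(invisible(out_path))
  }
  m <- cohort$manifest[match(ids, cohort$manifest$patient_id), , drop = FALSE]
  mt <- metrics[match(ids, metrics$patient_id), , drop = FALSE]
  cl <- classifications[match(ids, classifications$patient_id), , drop = FALSE]
  num2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  out <- data.frame(
    patient_id = ids,
    age = num2(m$age),
    hospital_id = m$hospital_id,
    tir_pct = num2(mt$tir_pct),
    tar1_pct = num2(mt$tar1_pct),
    tar2_pct = num2(mt$tar2_pct),
    tbr1_pct = num2(mt$tbr1_pct),
    tbr2_pct = num2(mt$tbr2_pct),
    cv_pct = num2(mt$cv_pct),
    gmi_pct = num2(mt$gmi_pct),
    mean_daily_scans = num2(mt$mean_daily_scans),
    sensor_usage_pct = num2(mt$sensor_usage_pct),
    attd_all_met = cl$attd_all_met,
    attd_level1_met = cl$attd_level1_met,
    andiacare_category = cl$andiacare_category,
    gri_score = num2(cl$gri_score),
    gri_zone = cl$gri_zone,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, out_path, row.names = FALSE, quote = FALSE)
  invisible(out_path)
}
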