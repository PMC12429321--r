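# Cohort report assembly: the classifier cross-tab (agreement between the
# four-colour triage and the GRI zones), per-patient stacked range rows, the
# centre and achievement tables, and a self-contained sortable HTML report.
# Plot aesthetics are non-contractual; the data files written alongside are
# the tested surface.

GRI_ZONE_LEVELS <- c("A", "B", "C", "D", "E", "not_allowed")
ANDIACARE_LEVELS <- c("green", "yellow", "orange", "red", "unclassifiable")

#' Cross-tabulate the two classifiers
#'
#' Counts patients per (triage category, GRI zone) pair -- the flows of a
#' Sankey-style agreement diagram. Patients without the GRI inputs fall in
#' the `not_allowed` column but keep their triage category.
#'
#' @param classifications Table from [classify_cohort()].
#' @return data.frame `andiacare_category, gri_zone, n` covering every
#'   observed pair; counts sum to the number of classified patients.
#' @export
build_crosstab <- function(classifications) {
  a <- factor(classifications$andiacare_category, levels = ANDIACARE_LEVELS)
  z <- factor(classifications$gri_zone, levels = GRI_ZONE_LEVELS)
  tab <- as.data.frame(table(andiacare_category = a, gri_zone = z),
                       responseName = "n", stringsAsFactors = FALSE)
  tab <- tab[tab$n > 0, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Per-patient stacked range rows
#'
#' The five range percentages of every patient, ordered by TIR ascending
#' (ties broken by patient id) -- the data behind a stacked range bar plot.
#'
#' @param metrics Metric table from [cohort_metrics()].
#' @return data.frame `patient_id, tbr2_pct, tbr1_pct, tir_pct, tar1_pct,
#'   tar2_pct`; each row sums to 100.
#' @export
stacked_range_rows <- function(metrics) {
  cols <- c("patient_id", "tbr2_pct", "tbr1_pct", "tir_pct", "tar1_pct",
            "tar2_pct")
  df <- metrics[!is.na(metrics$tir_pct), cols, drop = FALSE]
  df <- df[order(df$tir_pct, df$patient_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assemble the report bundle
#'
#' Computes every table the report embeds: centre counts with size classes,
#' the achievement and descriptive tables by age band, the stacked range
#' rows, the classifier cross-tab, the full metric table, a configuration
#' echo and the exclusion log.
#'
#' @param cohort The included `cgm_cohort`.
#' @param metrics Metric table from [cohort_metrics()].
#' @param classifications Table from [classify_cohort()].
#' @param exclusions Exclusion log from [apply_quality_filter()].
#' @param config Configuration list.
#' @return A `report_bundle` list.
#' @export
build_report_bundle <- function(cohort, metrics, classifications,
                                exclusions = NULL,
                                config = default_config()) {
  frame <- analysis_frame(cohort, metrics, classifications)
  cc <- center_counts(cohort)
  centers <- data.frame(hospital_id = names(cc), n_patients = as.integer(cc),
                        stringsAsFactors = FALSE)
  centers$size_class <- as.character(assign_center_size(centers$n_patients))
  if (is.null(exclusions)) {
    exclusions <- data.frame(patient_id = character(), reason = character(),
                             detail = character(), stringsAsFactors = FALSE)
  }
  structure(list(
    frame = frame,
    centers = centers,
    achievement = achievement_table(frame),
    descriptives = descriptive_table(frame),
    stacked_ranges = stacked_range_rows(metrics),
    crosstab = build_crosstab(classifications),
    exclusions = exclusions,
    config = config
  ), class = "report_bundle")
}

REQUIRED_BUNDLE_TABLES <- c("frame", "centers", "achievement",
                            "descriptives", "stacked_ranges", "crosstab",
                            "exclusions", "config")

check_bundle <- function(bundle) {
  missing <- REQUIRED_BUNDLE_TABLES[vapply(REQUIRED_BUNDLE_TABLES,
                                           function(nm) is.null(bundle[[nm]]),
                                           TRUE)]
  if (length(missing)) {
    stop("report bundle is missing table(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Export the bundle as machine-readable JSON
#'
#' A schema-versioned mirror of every report table, round-trippable through
#' [jsonlite::read_json()].
#'
#' @param bundle A `report_bundle`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
export_summary_json <- function(bundle, path) {
  check_bundle(bundle)
  payload <- list(
    schema_version = "1.0",
    config = bundle$config,
    centers = bundle$centers,
    achievement = bundle$achievement,
    descriptives = bundle$descriptives,
    stacked_ranges = bundle$stacked_ranges,
    crosstab = bundle$crosstab,
    exclusions = bundle$exclusions,
    n_included = nrow(bundle$frame)
  )
  jsonlite::write_json(payload, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null",
                       factor = "string")
  invisible(path)
}

html_table <- function(df, id) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  fmt <- function(col) {
    if (is.numeric(col)) ifelse(is.na(col), "", sprintf("%.2f", col))
    else esc(ifelse(is.na(col), "", as.character(col)))
  }
  head <- paste0("<tr>", paste0("<th onclick=\"sortTable('", id, "',",
                                seq_along(df) - 1, ")\">", esc(names(df)),
                                "</th>", collapse = ""), "</tr>")
  cells <- vapply(seq_len(nrow(df)), function(i) {
    paste0("<tr>", paste0("<td>",
                          vapply(df, function(c) fmt(c)[i], ""),
                          "</td>", collapse = ""), "</tr>")
  }, "")
  paste0("<table id=\"", id, "\">", head, paste(cells, collapse = ""),
         "</table>")
}

#' Render the cohort HTML report
#'
#' Writes a single self-contained HTML file with client-side sortable
#' tables (centres by size class, target achievement, descriptives, stacked
#' ranges, the classifier cross-tab and the full per-patient metric table),
#' and emits the data behind every table as CSV plus a JSON mirror under
#' `out_dir/tables`. Rendering is deterministic: the same bundle yields
#' byte-identical data files.
#'
#' @param bundle A complete `report_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return Path of the HTML file, invisibly.
#' @export
render_report <- function(bundle, out_dir) {
  check_bundle(bundle)
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE,
             recursive = TRUE)
  tabs <- list(centers = bundle$centers, achievement = bundle$achievement,
               descriptives = bundle$descriptives,
               stacked_ranges = bundle$stacked_ranges,
               crosstab = bundle$crosstab, exclusions = bundle$exclusions,
               metrics = bundle$frame)
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]],
                     file.path(out_dir, "tables", paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  export_summary_json(bundle, file.path(out_dir, "summary.json"))

  js <- paste(
    "function sortTable(id, col) {",
    " var t = document.getElementById(id);",
    " var rows = Array.from(t.rows).slice(1);",
    " var asc = t.getAttribute('data-asc') !== 'true';",
    " rows.sort(function(a, b) {",
    "  var x = a.cells[col].innerText, y = b.cells[col].innerText;",
    "  var nx = parseFloat(x), ny = parseFloat(y);",
    "  if (!isNaN(nx) && !isNaN(ny)) return asc ? nx - ny : ny - nx;",
    "  return asc ? x.localeCompare(y) : y.localeCompare(x);",
    " });",
    " rows.forEach(function(r) { t.appendChild(r); });",
    " t.setAttribute('data-asc', asc);",
    "}", sep = "\n")
  css <- paste(
    "body { font-family: sans-serif; margin: 2em; }",
    "table { border-collapse: collapse; margin-bottom: 2em; }",
    "th, td { border: 1px solid #999; padding: 4px 8px; }",
    "th { background: #eee; cursor: pointer; }", sep = "\n")
  sections <- c(
    "<h1>CGM cohort report</h1>",
    sprintf("<p>%d patients included; %d excluded by the quality filter.</p>",
            nrow(bundle$frame), nrow(bundle$exclusions)),
    "<h2>Centres</h2>", html_table(bundle$centers, "centers"),
    "<h2>Target achievement by age band</h2>",
    html_table(bundle$achievement, "achievement"),
    "<h2>Descriptive statistics</h2>",
    html_table(bundle$descriptives, "descriptives"),
    "<h2>Per-patient glycemic ranges (ordered by TIR)</h2>",
    html_table(bundle$stacked_ranges, "stacked"),
    "<h2>Classifier agreement (triage vs GRI zone)</h2>",
    html_table(bundle$crosstab, "crosstab"),
    "<h2>Exclusions</h2>", html_table(bundle$exclusions, "exclusions"),
    "<h2>All metrics</h2>", html_table(bundle$frame, "metrics")
  )
  html <- paste0("<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
                 "<title>CGM cohort report</title><style>", css,
                 "</style><script>", js, "</script></head><body>",
                 paste(sections, collapse = "\n"), "</body></html>")
  out <- file.path(out_dir, "report.html")
  writeLines(html, out)
  invisible(out)
}
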