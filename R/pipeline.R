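#' Run the full cohort pipeline
#'
#' Loads a cohort (format detection and parsing), computes the per-patient
#' metric vectors over the analysis window, applies the automatic quality
#' filter, classifies every included patient (ATTD targets, four-colour
#' triage, GRI), and writes the classification CSV, the exclusion log, the
#' report tables, a JSON summary and the HTML report.
#'
#' @param data_dir Directory of per-patient CGM CSV files.
#' @param manifest_path Path to the manifest CSV
#'   (`patient_id,age,hospital_id`).
#' @param out_dir Output directory.
#' @param config Configuration list, see [default_config()] /
#'   [read_config()].
#' @param report Whether to render the HTML report (default `TRUE`).
#' @return Invisibly, a list with `cohort`, `metrics`, `included`,
#'   `exclusions`, `classifications`, `bundle` and the output paths.
#' @export
run_pipeline <- function(data_dir, manifest_path, out_dir,
                         config = default_config(), report = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- load_cohort(data_dir, manifest_path,
                        timestamp_format = config$io$timestamp_format)
  metrics <- cohort_metrics(cohort,
                            window_days = config$window$days,
                            cadence_min = config$window$cadence_min,
                            count_scans = config$io$count_scans_in_monitored)
  filt <- apply_quality_filter(cohort, metrics,
                               min_usage_pct = config$quality$min_usage_pct,
                               plausible_range = config$quality$plausible_range)
  included <- filt$included
  metrics_in <- metrics[metrics$patient_id %in% names(included$patients), ,
                        drop = FALSE]
  classifications <- classify_cohort(included, metrics_in, config)

  paths <- list(
    classifications = file.path(out_dir, "classifications.csv"),
    exclusions = file.path(out_dir, "exclusions.csv")
  )
  write_classification_csv(included, metrics_in, classifications,
                           paths$classifications)
  write_exclusions_csv(filt$exclusions, paths$exclusions)

  bundle <- build_report_bundle(included, metrics_in, classifications,
                                filt$exclusions, config)
  if (report) {
    paths$report <- render_report(bundle, out_dir)
    paths$summary <- file.path(out_dir, "summary.json")
  }
  invisible(list(cohort = cohort, metrics = metrics, included = included,
                 exclusions = filt$exclusions,
                 classifications = classifications, bundle = bundle,
                 paths = paths))
}
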