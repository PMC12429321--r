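#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()] and, piecewise,
#' by the lower-level functions. Every tunable threshold of the platform lives
#' here so that a single YAML file can override it reproducibly.
#'
#' Sections:
#' \describe{
#'   \item{io}{`timestamp_format` (default ISO-8601 `"%Y-%m-%d %H:%M"`; the
#'     documented alternative for day-first exports is `"%d-%m-%Y %H:%M"`) and
#'     `count_scans_in_monitored` (whether scan rows contribute monitored
#'     time; default `FALSE`).}
#'   \item{window}{`days` of the analysis window (14) and the nominal historic
#'     cadence `cadence_min` (15 minutes).}
#'   \item{quality}{`min_usage_pct` sensor-usage gate (70; strictly-below is
#'     excluded) and the device-plausible glucose span `plausible_range`
#'     (40--500 mg/dL).}
#'   \item{gri}{Glycemic Risk Index weights and score cap.}
#'   \item{stats}{significance level `alpha` (0.05) and p-value adjustment
#'     method (`"BH"`).}
#' }
#'
#' @return A nested named list.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$window$days
default_config <- function() {
  list(
    io = list(
      timestamp_format = "%Y-%m-%d %H:%M",
      count_scans_in_monitored = FALSE
    ),
    window = list(days = 14, cadence_min = 15),
    quality = list(min_usage_pct = 70, plausible_range = c(40, 500)),
    attd = as.list(attd_targets()),
    gri = list(
      weights = c(vlow = 3.0, low = 2.4, vhigh = 1.6, high = 0.8),
      cap = 100
    ),
    stats = list(alpha = 0.05, p_adjust = "BH")
  )
}

#' Read a configuration file
#'
#' Reads a YAML configuration file and merges it over [default_config()], so a
#' file only needs to state the values it changes.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return The merged configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) {
    return(cfg)
  }
  if (!file.exists(path)) {
    stop("config file not found: ", path)
  }
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}
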