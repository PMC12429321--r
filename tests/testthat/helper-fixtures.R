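# Fixtures are built in code at test time; nothing binary ships with the
# package.

T0 <- as.POSIXct("2022-10-01 00:00", tz = "UTC")

# A reading series on the nominal 15-min grid.
toy_series <- function(values, kinds = rep("historic", length(values)),
                       patient = "T1", start = T0, step_min = 15) {
  reading_series(patient,
                 start + (seq_along(values) - 1) * step_min * 60,
                 values, kinds)
}

# Hand-written LibreView-dialect CSV text (independent of the package's own
# writer).
libreview_text <- function(rows) {
  c("Glucose data,hand-made fixture,,,,",
    "Device,Serial Number,Device Timestamp,Record Type,Historic Glucose mg/dL,Scan Glucose mg/dL",
    rows)
}

write_fixture <- function(lines, dir = withr::local_tempdir(),
                          name = "fixture.csv") {
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

# A tiny on-disk cohort in the generic long dialect plus manifest.
make_disk_cohort <- function(dir, series_list, manifest) {
  for (s in series_list) {
    write_reading_series(s, file.path(dir, paste0(patient_id(s), ".csv")))
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  mp
}

# Random plausible trace values for property tests.
random_trace_values <- function(n, seed) {
  set.seed(seed)
  pmin(500, pmax(41, round(exp(rnorm(n, log(150), 0.4)))))
}

metrics_row <- function(tir = 70, tar1 = 10, tar2 = 5, tbr1 = 10, tbr2 = 5,
                        ...) {
  c(list(tir_pct = tir, tar1_pct = tar1, tar2_pct = tar2, tbr1_pct = tbr1,
         tbr2_pct = tbr2), list(...))
}
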