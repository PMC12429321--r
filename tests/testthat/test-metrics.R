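test_that("select_window keeps the last 14 days and measures monitored time", {
  # 20 days of readings: only the last 14 are retained
  n <- 20 * 96
  s <- toy_series(rep(120, n))
  w <- select_window(s)
  expect_equal(w$window_end, max(s$timestamp))
  expect_true(all(w$series$timestamp >= w$window_end - 14 * 86400))
  expect_equal(nrow(w$series), 14 * 96 + 1) # early boundary is inclusive

  # exactly 14 days span: everything retained
  s14 <- toy_series(rep(120, 14 * 96))
  expect_equal(nrow(select_window(s14)$series), 14 * 96)

  # monitored time is historic count x cadence
  s96 <- toy_series(rep(120, 96))
  expect_equal(select_window(s96)$monitored_time, 1440)

  # idempotence: windowing twice equals once
  w1 <- select_window(s)
  w2 <- select_window(structure(w1$series, patient_id = "T1",
                                class = c("reading_series", "data.frame")))
  expect_equal(w2$series$value, w1$series$value)
  expect_equal(w2$monitored_time, w1$monitored_time)

  expect_error(select_window(toy_series(numeric(0))), "empty")
})

test_that("assign_range partitions the positive axis with the stated bounds", {
  expect_equal(as.character(assign_range(c(70, 180))), c("TIR", "TIR"))
  expect_equal(as.character(assign_range(c(54, 53.9))), c("TBR1", "TBR2"))
  expect_equal(as.character(assign_range(c(250, 251))), c("TAR1", "TAR2"))
  expect_error(assign_range(0), "> 0")
  expect_error(assign_range(-5), "> 0")

  # brute force on a 0.1-mg/dL grid: each value lands in exactly one range,
  # checked against independently-written interval membership
  g <- seq(0.1, 500, by = 0.1)
  got <- assign_range(g)
  member <- cbind(g < 54,
                  g >= 54 & g < 70,
                  g >= 70 & g <= 180,
                  g > 180 & g <= 250,
                  g > 250)
  expect_true(all(rowSums(member) == 1))
  oracle <- c("TBR2", "TBR1", "TIR", "TAR1", "TAR2")[
    apply(member, 1, which)]
  expect_equal(as.character(got), oracle)
})

test_that("range times and percentages follow equal-interval attribution", {
  s <- toy_series(c(100, 200, 260, 60))
  w <- select_window(s)
  rt <- compute_range_times(w)
  expect_equal(rt$t_tir, 15)
  expect_equal(rt$t_tar1, 15)
  expect_equal(rt$t_tar2, 15)
  expect_equal(rt$t_tbr1, 15)
  expect_equal(rt$t_tbr2, 0)
  expect_equal(rt$t_total, 60)
  pct <- compute_range_percentages(rt)
  expect_equal(unname(pct), c(0, 25, 25, 25, 25))
  expect_equal(sum(pct), 100)

  # scans contribute no time
  s2 <- toy_series(c(100, 200, 300), c("historic", "historic", "scan"))
  rt2 <- compute_range_times(select_window(s2))
  expect_equal(rt2$t_total, 30)
  expect_equal(rt2$t_tar2, 0)

  # all in range / single reading
  expect_equal(compute_range_times(select_window(
    toy_series(c(100, 120, 140))))$t_tir, 45)
  rt1 <- compute_range_times(select_window(toy_series(300)))
  expect_equal(rt1$t_tar2, 15)
  expect_equal(rt1$t_tir + rt1$t_tbr1 + rt1$t_tbr2 + rt1$t_tar1, 0)

  rt0 <- rt
  rt0$t_total <- 0
  expect_error(compute_range_percentages(rt0), "> 0")
  expect_error(compute_range_times(select_window(
    toy_series(c(100, 200), c("scan", "scan")))), "historic")
})

test_that("summary glucose uses historic readings and the sample SD", {
  const <- compute_summary_glucose(select_window(toy_series(rep(120, 10))))
  expect_equal(unname(const), c(120, 0, 0))

  two <- compute_summary_glucose(select_window(toy_series(c(100, 140))))
  expect_equal(two[["mean_glucose"]], 120)
  expect_equal(two[["sd_glucose"]], sqrt(sum((c(100, 140) - 120)^2) / 1))
  expect_equal(two[["cv_pct"]], 100 * two[["sd_glucose"]] / 120,
               tolerance = 1e-12)
  expect_equal(two[["cv_pct"]], 23.5702, tolerance = 1e-4)

  # scans do not enter the mean
  mix <- toy_series(c(100, 140, 400), c("historic", "historic", "scan"))
  expect_equal(compute_summary_glucose(select_window(mix))[["mean_glucose"]],
               120)
  expect_error(compute_summary_glucose(select_window(toy_series(100))),
               "at least 2")
})

test_that("GMI follows the standard regression and is increasing", {
  expect_equal(compute_gmi(154), 3.31 + 0.02392 * 154)
  expect_equal(compute_gmi(154), 6.99368)
  expect_error(compute_gmi(0), "> 0")
  m <- seq(60, 350, by = 5)
  expect_true(all(diff(compute_gmi(m)) > 0))
})

test_that("scan rate and sensor usage follow their counting definitions", {
  s <- toy_series(c(rep(120, 96), rep(130, 28)),
                  c(rep("historic", 96), rep("scan", 28)))
  w <- select_window(s)
  expect_equal(compute_scan_rate(w), 2)
  expect_equal(compute_scan_rate(select_window(toy_series(rep(120, 5)))), 0)

  usage <- function(n_hist) {
    vals <- rep(120, n_hist)
    w <- select_window(toy_series(vals))
    compute_sensor_usage(w)
  }
  expect_equal(usage(672), 50)
  expect_equal(usage(941), 100 * 941 / 1344)
  expect_gt(usage(941), 70)
  expect_equal(usage(1344), 100)
  # more readings than expected (overlapping sensors) caps at 100
  expect_equal(usage(1400), 100)
})

test_that("compute_patient_metrics composes the full vector", {
  s <- toy_series(c(100, 200, 260, 60))
  m <- compute_patient_metrics(select_window(s), patient = "toy")
  expect_s3_class(m, "glycemic_metrics")
  expect_equal(m$tir_pct, 25)
  expect_equal(m$tar1_pct, 25)
  expect_equal(m$tar2_pct, 25)
  expect_equal(m$tbr1_pct, 25)
  expect_equal(m$tbr2_pct, 0)
  expect_equal(m$cv_pct, 100 * m$sd_glucose / m$mean_glucose)
  expect_equal(m$gmi_pct, compute_gmi(m$mean_glucose))

  all_in <- compute_patient_metrics(select_window(toy_series(c(100, 150))))
  expect_equal(all_in$tir_pct, 100)
  expect_equal(all_in$tar1_pct + all_in$tbr1_pct + all_in$tbr2_pct +
                 all_in$tar2_pct, 0)

  expect_error(compute_patient_metrics(select_window(toy_series(100)),
                                       patient = "P9"), "P9")
})

test_that("range percentages conserve and respond monotonically to shifts", {
  for (seed in 1:20) {
    v <- random_trace_values(50 + seed, seed)
    w <- select_window(toy_series(v))
    pct <- compute_range_percentages(compute_range_times(w))
    expect_equal(sum(pct), 100, tolerance = 1e-9)
    # shifting the whole trace up never lowers TAR2 nor raises TBR2
    up <- compute_range_percentages(compute_range_times(
      select_window(toy_series(pmin(v + 40, 600)))))
    expect_gte(up[["tar2_pct"]], pct[["tar2_pct"]])
    expect_lte(up[["tbr2_pct"]], pct[["tbr2_pct"]])
  }
})
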