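test_that("ATTD compliance uses strict printed inequalities", {
  m <- metrics_row(tir = 70, tar1 = 10, tar2 = 1, tbr1 = 2, tbr2 = 0.5,
                   cv_pct = 30, mean_glucose = 140, sd_glucose = 20)
  a <- check_attd_targets(m)
  expect_false(a$meets_tir) # exactly 70 fails "> 70%"
  expect_true(a$meets_tar1)
  expect_false(a$all_met)

  ok <- metrics_row(tir = 75, tar1 = 20, tar2 = 4, tbr1 = 3, tbr2 = 0.5,
                    cv_pct = 30, mean_glucose = 140, sd_glucose = 20)
  aok <- check_attd_targets(ok)
  expect_true(aok$all_met)
  expect_true(aok$level1_met)
  expect_true(aok$meets_cv)
  expect_true(aok$meets_mean_sd)

  lvl1 <- metrics_row(tir = 72, tar1 = 24, tar2 = 6, tbr1 = 3.9, tbr2 = 0.5)
  al <- check_attd_targets(lvl1)
  expect_true(al$level1_met)
  expect_false(al$all_met)

  # boundary values of the remaining targets are also strict
  expect_false(check_attd_targets(metrics_row(tar2 = 5))$meets_tar2)
  expect_false(check_attd_targets(metrics_row(tbr1 = 4))$meets_tbr1)
  expect_false(check_attd_targets(metrics_row(tbr2 = 1))$meets_tbr2)
  expect_false(check_attd_targets(
    metrics_row(cv_pct = 36))$meets_cv)
  expect_false(check_attd_targets(
    metrics_row(mean_glucose = 154, sd_glucose = 20))$meets_mean_sd)
})

test_that("triage categories resolve severity-max with severe-ward gaps", {
  cl <- function(tir, tbr1, tar1) {
    classify_andiacare(list(tir_pct = tir, tbr1_pct = tbr1, tar1_pct = tar1))
  }
  expect_equal(cl(75, 2, 20), "green")
  expect_equal(cl(20, 0, 70), "red")
  expect_equal(cl(80, 15, 5), "orange")  # TBR1 triggers despite green TIR
  expect_equal(cl(80, 4.0, 10), "yellow") # gap at TBR1 = 4 goes severe-ward
  expect_equal(cl(40, 0, 20), "orange")   # gap at TIR = 40
  expect_equal(cl(80, 20, 5), "red")      # gap at TBR1 = 20
  expect_equal(cl(60, 2, 10), "yellow")
  expect_equal(cl(30, 2, 10), "orange")
  expect_equal(cl(80, 2, 75), "red")      # TAR1 >= 75 is red
  expect_error(cl(NA, 2, 10), "unclassifiable")
})

test_that("triage is exhaustive and monotone on the constrained grid", {
  # independent vectorised re-derivation of the band rules
  oracle <- function(tir, tbr1, tar1) {
    ifelse(tir < 25 | tbr1 >= 20 | tar1 >= 75, "red",
    ifelse(tir <= 40 | tbr1 >= 11 | tar1 >= 50, "orange",
    ifelse(tir <= 70 | tbr1 >= 4 | tar1 >= 25, "yellow", "green")))
  }
  g <- seq(0, 100, by = 0.5)
  grid <- expand.grid(tir = g, tbr1 = g)
  # brute-force sweep: every triple with tar1 chosen so the mass is feasible
  grid <- grid[grid$tir + grid$tbr1 <= 100, ]
  grid$tar1 <- 100 - grid$tir - grid$tbr1
  lab <- oracle(grid$tir, grid$tbr1, grid$tar1)
  expect_true(all(lab %in% c("green", "yellow", "orange", "red")))

  set.seed(99)
  idx <- sample(nrow(grid), 4000)
  got <- vapply(idx, function(i) {
    classify_andiacare(list(tir_pct = grid$tir[i], tbr1_pct = grid$tbr1[i],
                            tar1_pct = grid$tar1[i]))
  }, "")
  expect_equal(got, lab[idx])

  # moving mass from TIR to TAR1 (TBR1 fixed) never reduces severity
  set.seed(7)
  for (rep in 1:50) {
    tbr1 <- runif(1, 0, 15)
    tir0 <- runif(1, 50, 100 - tbr1)
    tirs <- seq(tir0, 0, length.out = 12)
    sev <- andiacare_severity(vapply(tirs, function(t) {
      classify_andiacare(list(tir_pct = t, tbr1_pct = tbr1,
                              tar1_pct = 100 - tbr1 - t))
    }, ""))
    expect_true(all(diff(sev) >= 0))
  }
})

test_that("GRI combines the printed weights, caps at 100 and stays bounded", {
  expect_equal(compute_gri(metrics_row(tbr2 = 0, tbr1 = 0, tar2 = 0,
                                       tar1 = 0)), 0)
  expect_equal(compute_gri(metrics_row(tbr2 = 100, tbr1 = 0, tar2 = 0,
                                       tar1 = 0)), 100)
  expect_equal(compute_gri(metrics_row(tbr2 = 1, tbr1 = 5, tar2 = 10,
                                       tar1 = 30)), 55)
  expect_true(is.na(compute_gri(list(tbr2_pct = 1, tbr1_pct = NA,
                                     tar2_pct = 0, tar1_pct = 0))))

  set.seed(3)
  for (i in 1:100) {
    p <- diff(sort(c(0, runif(4), 1))) * 100 # five shares summing to 100
    sc <- compute_gri(list(tbr2_pct = p[1], tbr1_pct = p[2],
                           tar2_pct = p[3], tar1_pct = p[4]))
    expect_gte(sc, 0)
    expect_lte(sc, 100)
    expect_identical(sc == 0, all(p[1:4] == 0))
  }
})

test_that("GRI zones are half-open readings of the printed bands", {
  expect_equal(assign_gri_zone(0), "A")
  expect_equal(assign_gri_zone(20), "A")
  expect_equal(assign_gri_zone(20.5), "B")
  expect_equal(assign_gri_zone(40), "B")
  expect_equal(assign_gri_zone(55), "C")
  expect_equal(assign_gri_zone(80), "D")
  expect_equal(assign_gri_zone(80.5), "E")
  expect_equal(assign_gri_zone(100), "E")
  expect_equal(assign_gri_zone(NA_real_), "not_allowed")
  expect_error(assign_gri_zone(101), "\\[0, 100\\]")
  expect_error(assign_gri_zone(-1), "\\[0, 100\\]")
})

test_that("classify_cohort completes every patient and flags missing GRI", {
  dir <- withr::local_tempdir()
  manifest <- data.frame(patient_id = c("A", "B", "C"), age = c(5, 9, 14),
                         hospital_id = "H1")
  mp <- make_disk_cohort(dir, list(
    toy_series(random_trace_values(96, 11), patient = "A"),
    toy_series(random_trace_values(96, 12), patient = "B"),
    toy_series(random_trace_values(96, 13), patient = "C")), manifest)
  ch <- load_cohort(dir, mp)
  met <- cohort_metrics(ch, window_days = 1)
  cls <- classify_cohort(ch, met)
  expect_equal(nrow(cls), 3)
  expect_true(all(cls$gri_zone %in% c("A", "B", "C", "D", "E")))

  # a patient with tar2 missing keeps the triage category, GRI not allowed
  met$tar2_pct[met$patient_id == "B"] <- NA
  cls2 <- classify_cohort(ch, met)
  b <- cls2[cls2$patient_id == "B", ]
  expect_identical(b$gri_zone, "not_allowed")
  expect_true(is.na(b$gri_score))
  expect_true(b$andiacare_category %in% c("green", "yellow", "orange", "red"))

  empty <- subset_cohort(ch, character())
  expect_equal(nrow(classify_cohort(empty, met)), 0)
})
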