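test_that("detect_format recognises the two dialects and degenerate files", {
  dir <- withr::local_tempdir()
  lv <- write_fixture(libreview_text(
    "FreeStyle Libre 2,SN1,2022-10-01 00:00,0,120,"), dir, "lv.csv")
  expect_identical(detect_format(lv), "libreview_csv")

  gl <- write_fixture(c("patient_id,timestamp,value,kind",
                        "P1,2022-10-01 00:00,120,historic"), dir, "gl.csv")
  expect_identical(detect_format(gl), "generic_long_csv")

  empty <- write_fixture(character(), dir, "empty.csv")
  expect_identical(detect_format(empty), "unknown")
  other <- write_fixture(c("a,b", "1,2"), dir, "other.csv")
  expect_identical(detect_format(other), "unknown")
  expect_error(detect_format(file.path(dir, "nope.csv")), "nope.csv")
})

test_that("parse_cgm_csv maps record types, skips non-glucose rows and dedups", {
  dir <- withr::local_tempdir()
  p <- write_fixture(libreview_text(c(
    "FreeStyle Libre 2,SN1,2022-10-01 00:00,0,100,",
    "FreeStyle Libre 2,SN1,2022-10-01 00:15,0,110,",
    "FreeStyle Libre 2,SN1,2022-10-01 00:30,0,120,",
    "FreeStyle Libre 2,SN1,2022-10-01 00:20,1,,140")), dir, "p1.csv")
  s <- parse_cgm_csv(p)
  expect_s3_class(s, "reading_series")
  expect_equal(nrow(s), 4)
  expect_equal(sum(s$kind == "historic"), 3)
  expect_equal(sum(s$kind == "scan"), 1)
  expect_equal(s$value[s$kind == "scan"], 140)
  expect_false(is.unsorted(s$timestamp))

  # duplicate historic timestamps keep the last occurrence, with a warning
  pd <- write_fixture(libreview_text(c(
    "FreeStyle Libre 2,SN1,2022-10-01 00:00,0,100,",
    "FreeStyle Libre 2,SN1,2022-10-01 00:00,0,105,")), dir, "pd.csv")
  expect_warning(sd <- parse_cgm_csv(pd), "duplicate")
  expect_equal(nrow(sd), 1)
  expect_equal(sd$value, 105)
  expect_equal(attr(sd, "n_duplicates"), 1L)

  # record type 6 (non-glucose event) is skipped, not an error
  p6 <- write_fixture(libreview_text(c(
    "FreeStyle Libre 2,SN1,2022-10-01 00:00,0,100,",
    "FreeStyle Libre 2,SN1,2022-10-01 00:05,6,,")), dir, "p6.csv")
  s6 <- parse_cgm_csv(p6)
  expect_equal(nrow(s6), 1)
  expect_equal(attr(s6, "n_skipped"), 1L)

  # bad rows are dropped and counted; all-bad is an error
  pb <- write_fixture(libreview_text(c(
    "FreeStyle Libre 2,SN1,not-a-date,0,100,",
    "FreeStyle Libre 2,SN1,2022-10-01 00:15,0,abc,",
    "FreeStyle Libre 2,SN1,2022-10-01 00:30,0,120,")), dir, "pb.csv")
  sb <- parse_cgm_csv(pb)
  expect_equal(nrow(sb), 1)
  expect_equal(attr(sb, "n_bad_rows"), 2L)
  pall <- write_fixture(libreview_text(
    "FreeStyle Libre 2,SN1,not-a-date,0,100,"), dir, "pall.csv")
  expect_error(parse_cgm_csv(pall), "no valid readings")
})

test_that("generic long CSV round-trips and parsing is order-independent", {
  dir <- withr::local_tempdir()
  set.seed(42)
  s <- toy_series(c(100, 150, 200, 60, 300),
                  c("historic", "historic", "scan", "historic", "historic"),
                  patient = "RT")
  f <- file.path(dir, "RT.csv")
  write_reading_series(s, f)
  s2 <- parse_cgm_csv(f)
  expect_equal(patient_id(s2), "RT")
  expect_equal(s2$timestamp, s$timestamp)
  expect_equal(s2$value, s$value)
  expect_equal(s2$kind, s$kind)

  # shuffle the data rows of the file; the parsed series is unchanged
  lines <- readLines(f)
  shuffled <- c(lines[1], sample(lines[-1]))
  f2 <- write_fixture(shuffled, dir, "RT2.csv")
  s3 <- parse_cgm_csv(f2)
  expect_equal(s3$timestamp, s2$timestamp)
  expect_equal(s3$value, s2$value)
})

test_that("load_cohort counts centres, logs missing files and validates", {
  dir <- withr::local_tempdir()
  manifest <- data.frame(patient_id = c("A", "B", "C"), age = c(5, 9, 14),
                         hospital_id = c("H1", "H1", "H2"))
  mp <- make_disk_cohort(dir, list(
    toy_series(rep(120, 8), patient = "A"),
    toy_series(rep(150, 8), patient = "B"),
    toy_series(rep(200, 8), patient = "C")), manifest)
  ch <- load_cohort(dir, mp)
  expect_equal(length(ch$patients), 3)
  expect_equal(center_counts(ch), c(H1 = 2L, H2 = 1L))
  expect_length(ch$missing, 0)

  # manifest of 2 with one file on disk
  dir2 <- withr::local_tempdir()
  m2 <- data.frame(patient_id = c("A", "Z"), age = c(5, 9),
                   hospital_id = c("H1", "H1"))
  mp2 <- make_disk_cohort(dir2, list(toy_series(rep(120, 8), patient = "A")),
                          m2)
  ch2 <- load_cohort(dir2, mp2)
  expect_equal(length(ch2$patients), 1)
  expect_equal(ch2$missing, "Z")
  expect_equal(sum(center_counts(ch2)), 1L)

  # duplicate / empty manifests are validation errors
  dup <- data.frame(patient_id = c("A", "A"), age = c(5, 6),
                    hospital_id = c("H1", "H1"))
  dp <- file.path(dir2, "dup.csv")
  utils::write.csv(dup, dp, row.names = FALSE)
  expect_error(load_cohort(dir2, dp), "duplicate patient_id")
  ep <- file.path(dir2, "emptym.csv")
  utils::write.csv(dup[0, ], ep, row.names = FALSE)
  expect_error(load_cohort(dir2, ep), "empty")
})

test_that("classification CSV holds one formatted row per patient", {
  dir <- withr::local_tempdir()
  manifest <- data.frame(patient_id = c("A", "B"), age = c(5.5, 14),
                         hospital_id = c("H1", "H2"))
  mp <- make_disk_cohort(dir, list(
    toy_series(random_trace_values(96, 1), patient = "A"),
    toy_series(random_trace_values(96, 2), patient = "B")), manifest)
  ch <- load_cohort(dir, mp)
  met <- cohort_metrics(ch, window_days = 1)
  cls <- classify_cohort(ch, met)
  out <- file.path(dir, "cls.csv")
  write_classification_csv(ch, met, cls, out)
  lines <- readLines(out)
  expect_length(lines, 3)
  got <- utils::read.csv(out)
  expect_identical(names(got)[1:3], c("patient_id", "age", "hospital_id"))
  expect_match(lines[2], "\\d+\\.\\d{2}") # two-decimal rendering

  # a patient without GRI inputs carries the literal not_allowed
  met_na <- met
  met_na$tar2_pct[1] <- NA
  cls_na <- classify_cohort(ch, met_na)
  write_classification_csv(ch, met_na, cls_na, out)
  got <- utils::read.csv(out)
  expect_identical(got$gri_zone[got$patient_id == "A"], "not_allowed")

  # empty included set yields a header-only file
  empty <- subset_cohort(ch, character())
  write_classification_csv(empty, met, cls, out)
  expect_length(readLines(out), 1)

  # missing result is a consistency error
  expect_error(write_classification_csv(ch, met[1, , drop = FALSE], cls, out),
               "missing")
})
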