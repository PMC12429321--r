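# Cohort stratification (age bands, centre-size classes) and the descriptive,
# achievement, comparative and correlation statistics. Normality decides
# between parametric and rank-based procedures; p values are
# Benjamini-Hochberg adjusted within each emitted table (family).

AGE_BAND_LEVELS <- c("band_4_6", "band_6_12", "band_12_plus", "out_of_band")

#' Assign pediatric age bands
#'
#' Half-open low-inclusive bands so every age maps to exactly one: \[4, 6),
#' \[6, 12), \[12, 18\]. Ages below 4 or above 18 are `out_of_band`; they are
#' excluded from band tables but kept in cohort totals.
#'
#' @param age Numeric ages in years (fractional allowed), >= 0.
#' @return Factor with levels `band_4_6, band_6_12, band_12_plus,
#'   out_of_band`.
#' @export
assign_age_band <- function(age) {
  if (any(age < 0, na.rm = TRUE)) {
    stop("age must be >= 0")
  }
  lab <- rep("out_of_band", length(age))
  lab[!is.na(age) & age >= 4 & age < 6] <- "band_4_6"
  lab[!is.na(age) & age >= 6 & age < 12] <- "band_6_12"
  lab[!is.na(age) & age >= 12 & age <= 18] <- "band_12_plus"
  factor(lab, levels = AGE_BAND_LEVELS)
}

#' Classify centre size
#'
#' SWEET-style size classes: small < 50 patients, medium 50--150 (both ends
#' inclusive), large > 150.
#'
#' @param n_patients Non-negative patient counts.
#' @return Factor with levels `small, medium, large`.
#' @export
assign_center_size <- function(n_patients) {
  if (any(n_patients < 0, na.rm = TRUE)) {
    stop("patient counts must be >= 0")
  }
  lab <- ifelse(n_patients > 150, "large",
         ifelse(n_patients >= 50, "medium", "small"))
  factor(lab, levels = c("small", "medium", "large"))
}

#' Descriptive statistics of one variable
#'
#' Mean, extremes, quartiles (linear interpolation between order statistics,
#' i.e. [stats::quantile()] type 7), sample SD, count and missing count.
#' Missing entries are counted, never silently dropped.
#'
#' @param values Numeric vector, possibly with `NA`s.
#' @return One-row data.frame `mean, minimum, maximum, q1, q2, q3, sd, n,
#'   n_missing`; all statistics `NA` when no complete values exist.
#' @export
describe <- function(values) {
  n_missing <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) == 0) {
    return(data.frame(mean = NA_real_, minimum = NA_real_, maximum = NA_real_,
                      q1 = NA_real_, q2 = NA_real_, q3 = NA_real_,
                      sd = NA_real_, n = 0L, n_missing = n_missing))
  }
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(mean = mean(v), minimum = min(v), maximum = max(v),
             q1 = q[1], q2 = q[2], q3 = q[3],
             sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
             n = length(v), n_missing = n_missing)
}

#' Assemble the per-patient analysis frame
#'
#' Joins demographics (with derived age band), metrics and classifications
#' into the flat table the statistical functions consume.
#'
#' @param cohort The included `cgm_cohort`.
#' @param metrics Metric table from [cohort_metrics()].
#' @param classifications Table from [classify_cohort()].
#' @return data.frame keyed by `patient_id`.
#' @export
analysis_frame <- function(cohort, metrics, classifications) {
  ids <- names(cohort$patients)
  m <- cohort$manifest[match(ids, cohort$manifest$patient_id), , drop = FALSE]
  df <- data.frame(patient_id = ids, age = m$age,
                   hospital_id = m$hospital_id, stringsAsFactors = FALSE)
  df$age_band <- assign_age_band(df$age)
  df <- merge(df, metrics, by = "patient_id", sort = TRUE)
  merge(df, classifications, by = "patient_id", sort = TRUE)
}

#' Target-achievement table by age band
#'
#' For each age band (and a TOTAL row over all included patients) the count
#' and percentage of patients meeting each of the five range targets.
#' Percentages are `NA` for empty bands.
#'
#' @param frame Analysis frame from [analysis_frame()].
#' @return data.frame with one row per band plus `TOTAL`.
#' @export
achievement_table <- function(frame) {
  flag_cols <- c(meets_tar2 = "tar2", meets_tar1 = "tar1", meets_tir = "tir",
                 meets_tbr1 = "tbr1", meets_tbr2 = "tbr2")
  one_row <- function(sub, label) {
    out <- data.frame(band = label, n = nrow(sub), stringsAsFactors = FALSE)
    for (fc in names(flag_cols)) {
      nm <- flag_cols[[fc]]
      cnt <- sum(sub[[fc]], na.rm = TRUE)
      out[[paste0("n_meet_", nm)]] <- cnt
      out[[paste0("pct_meet_", nm)]] <-
        if (nrow(sub) > 0) 100 * cnt / nrow(sub) else NA_real_
    }
    out
  }
  bands <- c("band_4_6", "band_6_12", "band_12_plus")
  rows <- lapply(bands, function(b) {
    one_row(frame[frame$age_band == b, , drop = FALSE], b)
  })
  rows[[length(rows) + 1]] <- one_row(frame, "TOTAL")
  do.call(rbind, rows)
}

#' Choose a two-sample test by normality
#'
#' Both samples are screened with the Shapiro-Wilk test at `alpha`; the
#' parametric t test is used only when neither rejects normality, otherwise
#' the rank-based Wilcoxon test. (Shapiro-Wilk accepts at most 5000 values;
#' larger samples are screened on a deterministic 5000-value thinning.)
#'
#' @param values_a,values_b Numeric samples, each of size >= 3.
#' @param alpha Normality screening level (default 0.05).
#' @return `"t_test"` or `"wilcoxon"`.
#' @export
choose_test <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("both samples must have at least 3 values")
  }
  if (is_normalish(values_a, alpha) && is_normalish(values_b, alpha)) {
    "t_test"
  } else {
    "wilcoxon"
  }
}

is_normalish <- function(v, alpha) {
  v <- v[!is.na(v)]
  if (length(v) > 5000) {
    v <- v[seq(1, length(v), length.out = 5000)]
  }
  if (stats::sd(v) == 0) {
    return(FALSE) # degenerate: rank test is the safe default
  }
  stats::shapiro.test(v)$p.value >= alpha
}

#' Pairwise group comparisons of one variable
#'
#' Two-sided unpaired tests between every pair of groups, the method chosen
#' per pair by [choose_test()]. All pairwise p values of the emitted table
#' form one Benjamini-Hochberg family.
#'
#' @param frame Analysis frame (or any data.frame).
#' @param field Name of the numeric column to compare.
#' @param group Name of the grouping column.
#' @param alpha Normality screening level.
#' @param min_n Minimum group size (default 3); smaller groups are dropped
#'   with a message.
#' @return data.frame with one row per group pair: `field, group_a, group_b,
#'   method, statistic, p_raw, p_adjusted`.
#' @export
compare_groups <- function(frame, field, group, alpha = 0.05, min_n = 3) {
  g <- frame[[group]]
  if (is.factor(g)) g <- droplevels(g)
  split_vals <- split(frame[[field]], g)
  split_vals <- lapply(split_vals, function(v) v[!is.na(v)])
  sizes <- vapply(split_vals, length, 0L)
  if (any(sizes < min_n)) {
    message("dropping group(s) with fewer than ", min_n, " values: ",
            paste(names(sizes)[sizes < min_n], collapse = ", "))
    split_vals <- split_vals[sizes >= min_n]
  }
  if (length(split_vals) < 2) {
    stop("need at least two groups with >= ", min_n, " values")
  }
  pairs <- utils::combn(names(split_vals), 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    a <- split_vals[[p[1]]]
    b <- split_vals[[p[2]]]
    method <- choose_test(a, b, alpha)
    res <- if (method == "t_test") {
      stats::t.test(a, b)
    } else {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    }
    data.frame(field = field, group_a = p[1], group_b = p[2],
               method = method, statistic = unname(res$statistic),
               p_raw = res$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Correlation between two variables
#'
#' Pearson when both variables pass the Shapiro-Wilk screen, Spearman
#' otherwise; complete pairs only.
#'
#' @param frame data.frame containing the two columns.
#' @param field_x,field_y Column names.
#' @param alpha Normality screening level.
#' @return One-row data.frame `field_x, field_y, method, coefficient,
#'   statistic, p_raw, p_adjusted` (`p_adjusted` equals `p_raw` for a single
#'   test; use [correlation_table()] for a BH family).
#' @export
correlate <- function(frame, field_x, field_y, alpha = 0.05) {
  x <- frame[[field_x]]
  y <- frame[[field_y]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop("need at least 3 complete pairs")
  }
  method <- if (is_normalish(x, alpha) && is_normalish(y, alpha)) {
    "pearson"
  } else {
    "spearman"
  }
  res <- suppressWarnings(stats::cor.test(x, y, method = method))
  data.frame(field_x = field_x, field_y = field_y, method = method,
             coefficient = unname(res$estimate),
             statistic = unname(res$statistic), p_raw = res$p.value,
             p_adjusted = res$p.value, stringsAsFactors = FALSE)
}

#' Correlation family over several field pairs
#'
#' Runs [correlate()] for every pair of the given fields and
#' Benjamini-Hochberg adjusts the whole family together.
#'
#' @param frame data.frame of variables.
#' @param fields Column names to correlate pairwise.
#' @param alpha Normality screening level.
#' @return data.frame, one row per pair.
#' @export
correlation_table <- function(frame, fields, alpha = 0.05) {
  pairs <- utils::combn(fields, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    tryCatch(correlate(frame, p[1], p[2], alpha), error = function(e) NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no correlatable pair among fields")
  }
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Chi-square association between two categoricals
#'
#' Plain (uncorrected) chi-square test of independence on the contingency
#' table of observed levels.
#'
#' @param frame data.frame containing the two columns.
#' @param cat_a,cat_b Column names of categorical variables; each must show
#'   at least 2 observed levels.
#' @return List with `table` (contingency counts) and `test` (one-row
#'   data.frame `statistic, df, p_raw, p_adjusted`).
#' @export
crosstab_categorical <- function(frame, cat_a, cat_b) {
  a <- factor(frame[[cat_a]])
  b <- factor(frame[[cat_b]])
  ok <- !is.na(a) & !is.na(b)
  tab <- table(droplevels(a[ok]), droplevels(b[ok]))
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("both categorical variables need at least 2 observed levels")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab,
       test = data.frame(statistic = unname(res$statistic),
                         df = unname(res$parameter),
                         p_raw = res$p.value, p_adjusted = res$p.value))
}

#' Descriptive table of the analyzed fields by age band
#'
#' [describe()] applied to each analyzed field within each age band and over
#' the whole frame.
#'
#' @param frame Analysis frame.
#' @param fields Numeric columns to summarize.
#' @return data.frame with `band` and `field` keys plus the descriptive
#'   columns.
#' @export
descriptive_table <- function(frame,
                              fields = c("tir_pct", "tar1_pct", "tar2_pct",
                                         "tbr1_pct", "tbr2_pct",
                                         "mean_daily_scans", "age")) {
  groups <- c("band_4_6", "band_6_12", "band_12_plus", "TOTAL")
  rows <- list()
  for (g in groups) {
    sub <- if (g == "TOTAL") frame else
      frame[frame$age_band == g, , drop = FALSE]
    for (f in fields) {
      d <- describe(sub[[f]])
      rows[[length(rows) + 1]] <- cbind(
        data.frame(band = g, field = f, stringsAsFactors = FALSE), d)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
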