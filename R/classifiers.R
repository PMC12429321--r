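# The three classification systems: the ATTD-2019 seven-target compliance
# check, the four-colour triage algorithm, and the Glycemic Risk Index (GRI)
# with its five zones.

#' ATTD-2019 pediatric consensus targets
#'
#' The seven cut-offs for glucometric control: TIR > 70%, TAR1 < 25%,
#' TAR2 < 5%, TBR1 < 4%, TBR2 < 1%, CV < 36%, and the composite
#' mean glucose < 154 mg/dL with SD < 29 mg/dL.
#'
#' @return Named numeric vector of the cut-offs.
#' @export
attd_targets <- function() {
  c(tir_min = 70, tar1_max = 25, tar2_max = 5, tbr1_max = 4, tbr2_max = 1,
    cv_max = 36, mean_glucose_max = 154, sd_max = 29)
}

#' Check compliance with the ATTD targets
#'
#' All inequalities are strict, read literally from the consensus wording:
#' a patient at TIR = 70.0% exactly does not meet the "> 70%" target.
#' `all_met` aggregates the five range targets; `level1_met` aggregates the
#' level-1 triple (TIR, TBR1, TAR1).
#'
#' @param m A `glycemic_metrics` (or any list/row with the metric fields).
#' @param targets Cut-offs, by default [attd_targets()].
#' @return An `attd_compliance` list of logical flags: `meets_tir`,
#'   `meets_tar1`, `meets_tar2`, `meets_tbr1`, `meets_tbr2`, `meets_cv`,
#'   `meets_mean_sd`, `all_met`, `level1_met`. Flags are `NA` when the
#'   underlying metric is missing.
#' @export
check_attd_targets <- function(m, targets = attd_targets()) {
  g <- function(f) {
    v <- m[[f]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v[[1]])
  }
  flags <- list(
    meets_tir = g("tir_pct") > targets[["tir_min"]],
    meets_tar1 = g("tar1_pct") < targets[["tar1_max"]],
    meets_tar2 = g("tar2_pct") < targets[["tar2_max"]],
    meets_tbr1 = g("tbr1_pct") < targets[["tbr1_max"]],
    meets_tbr2 = g("tbr2_pct") < targets[["tbr2_max"]],
    meets_cv = g("cv_pct") < targets[["cv_max"]],
    meets_mean_sd = g("mean_glucose") < targets[["mean_glucose_max"]] &
      g("sd_glucose") < targets[["sd_max"]]
  )
  flags$all_met <- flags$meets_tir & flags$meets_tar1 & flags$meets_tar2 &
    flags$meets_tbr1 & flags$meets_tbr2
  flags$level1_met <- flags$meets_tir & flags$meets_tar1 & flags$meets_tbr1
  structure(flags, class = "attd_compliance")
}

#' Four-colour triage thresholds
#'
#' The published band rules are ORs over TIR, TBR1 and TAR1 and can conflict
#' across variables, so classification is severity-max: red, then orange,
#' then yellow, is tested in turn and the most severe band triggered wins.
#' The printed rules leave TIR = 40 and TBR1 = 4 and 20 unassigned; those
#' boundaries resolve to the more severe adjacent band (clinically
#' conservative), which this constant table makes auditable.
#'
#' @return Nested list of band trigger thresholds.
#' @export
andiacare_thresholds <- function() {
  list(
    # red triggered when: tir < 25 | tbr1 >= 20 | tar1 >= 75; the orange and
    # yellow TIR triggers are inclusive (<=) so the printed gap at TIR = 40
    # lands in orange
    red = list(tir_lt = 25, tbr1_ge = 20, tar1_ge = 75),
    orange = list(tir_le = 40, tbr1_ge = 11, tar1_ge = 50),
    yellow = list(tir_le = 70, tbr1_ge = 4, tar1_ge = 25)
  )
}

#' Classify a patient with the four-colour triage algorithm
#'
#' Green means all three level-1 targets are met (TIR > 70%, TBR1 < 4%,
#' TAR1 < 25%); yellow, orange and red mark progressively worse deviation in
#' any one of the three variables, resolved severity-max (see
#' [andiacare_thresholds()]).
#'
#' @param m A `glycemic_metrics` (or any list/row with `tir_pct`, `tbr1_pct`,
#'   `tar1_pct`).
#' @param thresholds Band thresholds, by default [andiacare_thresholds()].
#' @return One of `"green"`, `"yellow"`, `"orange"`, `"red"`.
#' @export
#' @examples
#' classify_andiacare(list(tir_pct = 75, tbr1_pct = 2, tar1_pct = 20))
classify_andiacare <- function(m, thresholds = andiacare_thresholds()) {
  tir <- m$tir_pct
  tbr1 <- m$tbr1_pct
  tar1 <- m$tar1_pct
  if (length(c(tir, tbr1, tar1)) != 3 || any(is.na(c(tir, tbr1, tar1)))) {
    stop("unclassifiable: tir_pct, tbr1_pct and tar1_pct are all required")
  }
  th <- thresholds
  if (tir < th$red$tir_lt || tbr1 >= th$red$tbr1_ge ||
      tar1 >= th$red$tar1_ge) {
    return("red")
  }
  if (tir <= th$orange$tir_le || tbr1 >= th$orange$tbr1_ge ||
      tar1 >= th$orange$tar1_ge) {
    return("orange")
  }
  if (tir <= th$yellow$tir_le || tbr1 >= th$yellow$tbr1_ge ||
      tar1 >= th$yellow$tar1_ge) {
    return("yellow")
  }
  "green"
}

#' Severity rank of triage categories
#'
#' @param category Character vector of categories.
#' @return Integer rank: green 0 < yellow 1 < orange 2 < red 3.
#' @export
andiacare_severity <- function(category) {
  match(category, c("green", "yellow", "orange", "red")) - 1L
}

#' Glycemic Risk Index score
#'
#' GRI = 3.0 x %time < 54 + 2.4 x %time 54--70 + 1.6 x %time > 250 +
#' 0.8 x %time 180--250, capped at 100. Zero marks optimal control, 100 the
#' poorest. The hypo- and hyperglycemia components reuse the same TBR/TAR
#' quantities computed by the metrics module.
#'
#' @param m A `glycemic_metrics` (or list/row with `tbr2_pct`, `tbr1_pct`,
#'   `tar2_pct`, `tar1_pct`).
#' @param weights The four component weights.
#' @param cap Maximum score (100).
#' @return Numeric score in \[0, 100\], or `NA` when any component is
#'   missing (the "not allowed" marker).
#' @export
#' @examples
#' compute_gri(list(tbr2_pct = 1, tbr1_pct = 5, tar2_pct = 10, tar1_pct = 30))
compute_gri <- function(m, weights = c(vlow = 3.0, low = 2.4, vhigh = 1.6,
                                       high = 0.8), cap = 100) {
  comp <- c(m$tbr2_pct, m$tbr1_pct, m$tar2_pct, m$tar1_pct)
  if (length(comp) < 4 || any(is.na(comp))) {
    return(NA_real_)
  }
  min(cap, weights[["vlow"]] * comp[1] + weights[["low"]] * comp[2] +
        weights[["vhigh"]] * comp[3] + weights[["high"]] * comp[4])
}

#' Zone of a GRI score
#'
#' The published integer bands (A 0--20, B 21--40, C 41--60, D 61--80,
#' E 81--100) are read as half-open real intervals so every continuous score
#' is zoned: A \[0, 20\], B (20, 40\], C (40, 60\], D (60, 80\], E (80, 100\].
#' A missing score maps to `"not_allowed"`.
#'
#' @param score Numeric GRI score in \[0, 100\], or `NA`.
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"not_allowed"`.
#' @export
assign_gri_zone <- function(score) {
  if (is.na(score)) {
    return("not_allowed")
  }
  if (score < 0 || score > 100) {
    stop("GRI score must lie in [0, 100], got ", score)
  }
  if (score <= 20) "A"
  else if (score <= 40) "B"
  else if (score <= 60) "C"
  else if (score <= 80) "D"
  else "E"
}

#' Classify every patient in a cohort
#'
#' Applies the ATTD check, the four-colour triage and the GRI to each row of
#' the metric table. Patients lacking any GRI component keep their triage
#' category and are tagged `gri_zone = "not_allowed"`; patients the triage
#' algorithm cannot classify are tagged `"unclassifiable"` and listed in the
#' `failures` attribute.
#'
#' @param cohort The included `cgm_cohort` (quality filter already applied).
#' @param metrics Metric table from [cohort_metrics()].
#' @param config Configuration list (for thresholds and weights).
#' @return data.frame with `patient_id`, the seven `meets_*` flags,
#'   `attd_all_met`, `attd_level1_met`, `andiacare_category`, `gri_score`,
#'   `gri_zone`.
#' @export
classify_cohort <- function(cohort, metrics, config = default_config()) {
  ids <- names(cohort$patients)
  rows <- vector("list", length(ids))
  failures <- character()
  targets <- unlist(config$attd)
  for (i in seq_along(ids)) {
    m <- as.list(metrics[metrics$patient_id == ids[i], , drop = FALSE])
    att <- check_attd_targets(m, targets)
    cat_ <- tryCatch(classify_andiacare(m), error = function(e) {
      failures[ids[i]] <<- conditionMessage(e)
      "unclassifiable"
    })
    score <- compute_gri(m, weights = config$gri$weights, cap = config$gri$cap)
    rows[[i]] <- data.frame(
      patient_id = ids[i],
      meets_tir = att$meets_tir, meets_tar1 = att$meets_tar1,
      meets_tar2 = att$meets_tar2, meets_tbr1 = att$meets_tbr1,
      meets_tbr2 = att$meets_tbr2, meets_cv = att$meets_cv,
      meets_mean_sd = att$meets_mean_sd,
      attd_all_met = att$all_met, attd_level1_met = att$level1_met,
      andiacare_category = cat_,
      gri_score = score,
      gri_zone = assign_gri_zone(score),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    patient_id = character(), meets_tir = logical(), meets_tar1 = logical(),
    meets_tar2 = logical(), meets_tbr1 = logical(), meets_tbr2 = logical(),
    meets_cv = logical(), meets_mean_sd = logical(),
    attd_all_met = logical(), attd_level1_met = logical(),
    andiacare_category = character(), gri_score = numeric(),
    gri_zone = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
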