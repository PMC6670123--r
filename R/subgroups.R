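#' Dichotomization rule for the diabetic cohort
#'
#' A clinical cutoff splitting the diabetic eyes into a low and a high arm,
#' e.g. age at 55 years or HbA1c at 7%.
#'
#' @param variable cohort column name.
#' @param cutoff finite cutoff value; rows with `value < cutoff` form the
#'   low arm, `value >= cutoff` the high arm (exact ties go high — the
#'   published labels are the disjoint "<" / ">", so tie handling is this
#'   package's stated convention).
#' @param unit optional unit string used in labels.
#' @return A list of class `subgroup_rule` with `label_low`/`label_high`.
#' @export
subgroup_rule <- function(variable, cutoff, unit = "") {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  structure(list(variable = variable, cutoff = cutoff, unit = unit,
                 label_low = sprintf("%s < %g%s", variable, cutoff, unit),
                 label_high = sprintf("%s > %g%s", variable, cutoff, unit)),
            class = "subgroup_rule")
}

#' The default clinical cutoffs of the risk-factor analysis
#'
#' Age 55 y; BMI 25 kg/m2; duration of diabetes 5 y; HbA1c 7%; SBP 140 and
#' DBP 90 mmHg; TG 1.7, TC 5.2, HDL-C 1.96 and LDL-C 3.1 mmol/L; BUN 8.2
#' mmol/L; creatinine 70 umol/L.
#'
#' @return A named list of [subgroup_rule()]s.
#' @export
default_subgroup_rules <- function() {
  list(age = subgroup_rule("age", 55, "y"),
       bmi = subgroup_rule("bmi", 25, " kg/m2"),
       duration = subgroup_rule("duration", 5, "y"),
       hba1c = subgroup_rule("hba1c", 7, "%"),
       sbp = subgroup_rule("sbp", 140, " mmHg"),
       dbp = subgroup_rule("dbp", 90, " mmHg"),
       tg = subgroup_rule("tg", 1.7, " mmol/L"),
       tc = subgroup_rule("tc", 5.2, " mmol/L"),
       hdl_c = subgroup_rule("hdl_c", 1.96, " mmol/L"),
       ldl_c = subgroup_rule("ldl_c", 3.1, " mmol/L"),
       bun = subgroup_rule("bun", 8.2, " mmol/L"),
       creatinine = subgroup_rule("creatinine", 70, " umol/L"))
}

#' Composition percentages of a subgroup arm
#'
#' The NDR/MDR makeup of one arm, as percentages of the arm total rounded
#' to one decimal — the bookkeeping printed next to each cutoff row of a
#' risk-factor table.
#'
#' @param n_ndr,n_mdr counts of NDR and MDR eyes in the arm.
#' @return Named vector `c(ndr_pct, mdr_pct)`, `NA` for an empty arm.
#' @export
subgroup_composition <- function(n_ndr, n_mdr) {
  tot <- n_ndr + n_mdr
  if (tot == 0) return(c(ndr_pct = NA_real_, mdr_pct = NA_real_))
  c(ndr_pct = round(100 * n_ndr / tot, 1),
    mdr_pct = round(100 * n_mdr / tot, 1))
}

#' Split the diabetic cohort at a clinical cutoff
#'
#' Control rows pass through unchanged as the comparison arm; diabetic rows
#' (NDR + MDR) with a non-missing value of the rule's variable are assigned
#' to the low (`< cutoff`) or high (`>= cutoff`) arm. Rows with a missing
#' value are excluded from both arms and counted.
#'
#' @param cohort a cohort `data.frame` with a `group` column
#'   (control/ndr/mdr).
#' @param rule a [subgroup_rule()].
#' @return A list of class `dichotomy`: `low`, `high`, `control`
#'   (data.frames), `composition` (per-arm NDR/MDR counts and
#'   percentages), `n_missing`.
#' @export
dichotomize <- function(cohort, rule) {
  stopifnot(is.data.frame(cohort), inherits(rule, "subgroup_rule"))
  if (!rule$variable %in% names(cohort))
    stop("variable '", rule$variable, "' is not in the cohort table")
  diab <- cohort[cohort$group != "control", , drop = FALSE]
  v <- diab[[rule$variable]]
  n_missing <- sum(is.na(v))
  if (n_missing > 0)
    message(n_missing, " diabetic rows with missing '", rule$variable,
            "' excluded from both arms")
  low <- diab[!is.na(v) & v < rule$cutoff, , drop = FALSE]
  high <- diab[!is.na(v) & v >= rule$cutoff, , drop = FALSE]
  comp <- function(arm) {
    n_ndr <- sum(arm$group == "ndr"); n_mdr <- sum(arm$group == "mdr")
    c(ndr_n = n_ndr, mdr_n = n_mdr, subgroup_composition(n_ndr, n_mdr))
  }
  composition <- rbind(low = comp(low), high = comp(high))
  structure(list(low = low, high = high,
                 control = cohort[cohort$group == "control", , drop = FALSE],
                 composition = as.data.frame(composition),
                 n_missing = n_missing, rule = rule),
            class = "dichotomy")
}

sig_flag <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "c" else if (p < 0.01) "b"
  else if (p < 0.05) "a" else ""
}

#' Risk-factor subgroup report
#'
#' For each rule and each capillary layer: the low and high arms are each
#' compared against the control group, and against each other, by one-way
#' ANOVA on the raw densities. Arm-vs-control significance is flagged
#' a/b/c for p < 0.05 / 0.01 / 0.001; no multiple-testing correction is
#' applied. An arm with fewer than 2 usable rows is reported as not
#' testable (`NA` p).
#'
#' @param cohort a cohort `data.frame`.
#' @param rules a list of [subgroup_rule()]s
#'   (default [default_subgroup_rules()]).
#' @param layers names of the density columns to analyze.
#' @return A `data.frame`, one row per rule x layer, with arm sizes,
#'   compositions, arm means/SDs, and the three p-values with flags.
#' @export
subgroup_analysis <- function(cohort, rules = default_subgroup_rules(),
                              layers = c("rcd_srcl", "rcd_drcl")) {
  stopifnot(is.data.frame(cohort))
  missing_layers <- setdiff(layers, names(cohort))
  if (length(missing_layers))
    stop("cohort lacks density columns: ",
         paste(missing_layers, collapse = ", "))
  rows <- list()
  for (rule in rules) {
    d <- dichotomize(cohort, rule)
    for (layer in layers) {
      ctrl <- d$control[[layer]]; lo <- d$low[[layer]]; hi <- d$high[[layer]]
      lo <- lo[!is.na(lo)]; hi <- hi[!is.na(hi)]
      p2 <- function(x, y)
        if (length(x) < 2 || length(y) < 2) NA_real_
        else one_way_anova(list(x, y))$p_value
      p_lo_ctrl <- p2(lo, ctrl)
      p_hi_ctrl <- p2(hi, ctrl)
      p_arms <- p2(lo, hi)
      rows[[length(rows) + 1]] <- data.frame(
        variable = rule$variable, cutoff = rule$cutoff, layer = layer,
        n_low = length(lo), n_high = length(hi),
        low_ndr_pct = d$composition["low", "ndr_pct"],
        low_mdr_pct = d$composition["low", "mdr_pct"],
        high_ndr_pct = d$composition["high", "ndr_pct"],
        high_mdr_pct = d$composition["high", "mdr_pct"],
        low_mean = if (length(lo)) mean(lo) else NA_real_,
        low_sd = if (length(lo) > 1) stats::sd(lo) else NA_real_,
        high_mean = if (length(hi)) mean(hi) else NA_real_,
        high_sd = if (length(hi) > 1) stats::sd(hi) else NA_real_,
        p_low_vs_control = p_lo_ctrl,
        flag_low = sig_flag(p_lo_ctrl),
        p_high_vs_control = p_hi_ctrl,
        flag_high = sig_flag(p_hi_ctrl),
        p_low_vs_high = p_arms,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame())
  do.call(rbind, rows)
}
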