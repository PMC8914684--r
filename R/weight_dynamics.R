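#' Classify a BMI value into its WHO category
#'
#' The four categories partition the positive axis with half-open
#' intervals: underweight `[0, 18.5)`, normal `[18.5, 25)`, overweight
#' `[25, 30)`, obese `[30, Inf)`. The half-open convention closes the gaps
#' left by the printed ranges (24.9--25.0, 29.9--30.0).
#'
#' @param bmi_kg_m2 BMI in kg/m^2 (positive scalar).
#' @return One of `"underweight"`, `"normal"`, `"overweight"`, `"obese"`.
#' @export
#' @examples
#' classify_bmi(22)
#' classify_bmi(30) # boundary belongs upward
classify_bmi <- function(bmi_kg_m2) {
  .assert_positive(bmi_kg_m2, "bmi_kg_m2")
  pol <- .gwg_policy_table
  idx <- which(bmi_kg_m2 >= pol$bmi_lo & bmi_kg_m2 < pol$bmi_hi)
  pol$category[idx]
}

.category_row <- function(category) {
  category <- match.arg(category, .bmi_categories)
  .gwg_policy_table[.gwg_policy_table$category == category, , drop = FALSE]
}

#' IOM average total gestational weight gain
#'
#' Midpoint of the IOM recommended total-gain range for a BMI category.
#'
#' @param category BMI category label (see [classify_bmi()]).
#' @return Average total gain in kg.
#' @export
#' @examples
#' iom_average_gwg("underweight") # 15.455
iom_average_gwg <- function(category) {
  row <- .category_row(category)
  (row$total_lo_kg + row$total_hi_kg) / 2
}

#' Predict cumulative gestational weight gain
#'
#' Piecewise accumulation scheme reproducing both published anchors: the
#' category's central weekly rate holds during trimesters 2--3 (weeks
#' 12--40), and the remainder of the IOM average total
#' (`avg_total - 28 * weekly_rate`) is accrued linearly over weeks 0--12,
#' so the curve is continuous, starts at zero and ends at the IOM average
#' total at week 40.
#'
#' @inheritParams iom_average_gwg
#' @param gestational_week Gestational age in weeks; values outside
#'   `[0, 40]` are clamped with a warning.
#' @return Cumulative gain in kg.
#' @export
#' @examples
#' predict_weight_gain("underweight", 24)
predict_weight_gain <- function(category, gestational_week) {
  row <- .category_row(category)
  .assert_number(gestational_week, "gestational_week")
  wk <- .clamp_warn(gestational_week, 0, 40, "gestational_week")
  avg <- iom_average_gwg(category)
  first_tri <- avg - 28 * row$weekly_kg
  if (wk <= 12) first_tri * wk / 12 else first_tri + row$weekly_kg * (wk - 12)
}

#' Rule-of-three transfer of a retention value
#'
#' Proportional scaling `huang_retention * iom_gwg / huang_gwg`: transfers a
#' cohort's six-month postpartum retention onto the IOM average gain level
#' of the same BMI category.
#'
#' @param huang_retention_kg Source-cohort six-month retention (kg).
#' @param iom_gwg_kg IOM average total gain for the category (kg).
#' @param huang_gwg_kg Source-cohort average total gain (kg); must be
#'   non-zero.
#' @return Transferred retention in kg.
#' @export
#' @examples
#' retention_rule_of_three(3.32, 15.455, 14.36)
retention_rule_of_three <- function(huang_retention_kg, iom_gwg_kg,
                                    huang_gwg_kg) {
  .assert_number(huang_retention_kg, "huang_retention_kg")
  .assert_number(iom_gwg_kg, "iom_gwg_kg")
  .assert_number(huang_gwg_kg, "huang_gwg_kg")
  if (huang_gwg_kg == 0) .stopf("`huang_gwg_kg` must be non-zero")
  huang_retention_kg * iom_gwg_kg / huang_gwg_kg
}

#' Postpartum weight retention curve
#'
#' Quadratic retention-vs-week curves per BMI category, anchored at week 0
#' to half the IOM average total gain and fitted over weeks 0--24. Weeks
#' outside that fitting domain are clamped with a warning.
#'
#' @inheritParams iom_average_gwg
#' @param postpartum_week Weeks since delivery.
#' @return Retention (current minus pre-pregnancy weight) in kg; can be
#'   negative late postpartum for the obese category.
#' @export
#' @examples
#' predict_retention("normal", 0) # 6.8175, half of 13.635
predict_retention <- function(category, postpartum_week) {
  category <- match.arg(category, .bmi_categories)
  .assert_number(postpartum_week, "postpartum_week")
  wk <- .clamp_warn(postpartum_week, 0, 24, "postpartum_week")
  cv <- .retention_curve_table[.retention_curve_table$category == category, ]
  cv$a * wk^2 + cv$b * wk + cv$c
}

#' Predict postpartum weight
#'
#' Pre-pregnancy weight plus the category retention curve.
#'
#' @inheritParams predict_retention
#' @param pre_pregnancy_weight_kg Pre-pregnancy weight (kg).
#' @return Predicted maternal weight in kg.
#' @export
#' @examples
#' predict_postpartum_weight(60, "normal", 0)
predict_postpartum_weight <- function(pre_pregnancy_weight_kg, category,
                                      postpartum_week) {
  .assert_positive(pre_pregnancy_weight_kg, "pre_pregnancy_weight_kg")
  pre_pregnancy_weight_kg + predict_retention(category, postpartum_week)
}

#' Retention curve coefficients
#'
#' The quadratic coefficients `(a, b, c)` of the per-category postpartum
#' retention curves `retention = a*week^2 + b*week + c`.
#'
#' @return A data frame with columns `category`, `a`, `b`, `c`.
#' @export
retention_curves <- function() .retention_curve_table
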