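#' Body mass index
#'
#' @param weight_kg Body weight in kilograms.
#' @param height_cm Standing height in centimetres.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(60, 165)
bmi <- function(weight_kg, height_cm) {
  .assert_positive(weight_kg, "weight_kg")
  .assert_positive(height_cm, "height_cm")
  weight_kg / (height_cm / 100)^2
}

#' Pregnancy covariate profile
#'
#' Bundles the covariates of the pregnant-circumference regression. When
#' `weight_gain_kg` is `NULL` it is predicted from the pre-pregnancy BMI
#' category via [predict_weight_gain()] at prediction time.
#'
#' @param pre_pregnancy_weight_kg Pre-pregnancy weight (kg).
#' @param height_cm Height (cm).
#' @param gestational_week Gestational age in weeks (0--42; values beyond
#'   40 are clamped with a warning when used for weight-gain prediction).
#' @param age_years Age in years; defaults to 30 when unknown.
#' @param gravida Number of pregnancies including the current one (>= 1).
#' @param weight_gain_kg Weight gained so far this pregnancy (kg), or `NULL`
#'   to predict it from the BMI category.
#' @return An object of class `pregnancy_profile`.
#' @export
#' @examples
#' pregnancy_profile(60, 160, gestational_week = 24)
pregnancy_profile <- function(pre_pregnancy_weight_kg, height_cm,
                              gestational_week, age_years = 30, gravida = 1,
                              weight_gain_kg = NULL) {
  .assert_positive(pre_pregnancy_weight_kg, "pre_pregnancy_weight_kg")
  .assert_positive(height_cm, "height_cm")
  .assert_number(gestational_week, "gestational_week")
  if (gestational_week < 0 || gestational_week > 42)
    .stopf("`gestational_week` must be in [0, 42], got %g", gestational_week)
  .assert_positive(age_years, "age_years")
  .assert_number(gravida, "gravida")
  if (gravida < 1) .stopf("`gravida` must be >= 1")
  if (!is.null(weight_gain_kg)) .assert_number(weight_gain_kg, "weight_gain_kg")
  structure(list(age_years = age_years,
                 pre_pregnancy_weight_kg = pre_pregnancy_weight_kg,
                 height_cm = height_cm, gravida = gravida,
                 gestational_week = gestational_week,
                 weight_gain_kg = weight_gain_kg),
            class = "pregnancy_profile")
}

#' Postpartum covariate profile
#'
#' Bundles the covariates of the postpartum-circumference regression. When
#' `postpartum_weight_kg` is `NULL` it is predicted as pre-pregnancy weight
#' plus the BMI-category retention curve via [predict_postpartum_weight()].
#'
#' @inheritParams pregnancy_profile
#' @param postpartum_week Weeks since delivery (0--24; clamped with a
#'   warning beyond).
#' @param baby_weight_kg Birth weight of the baby (kg); defaults to 3.
#' @param postpartum_weight_kg Current maternal weight (kg), or `NULL` to
#'   predict it.
#' @return An object of class `postpartum_profile`.
#' @export
#' @examples
#' postpartum_profile(60, 160, postpartum_week = 12)
postpartum_profile <- function(pre_pregnancy_weight_kg, height_cm,
                               postpartum_week, age_years = 30, gravida = 1,
                               baby_weight_kg = 3,
                               postpartum_weight_kg = NULL) {
  .assert_positive(pre_pregnancy_weight_kg, "pre_pregnancy_weight_kg")
  .assert_positive(height_cm, "height_cm")
  .assert_number(postpartum_week, "postpartum_week")
  postpartum_week <- .clamp_warn(postpartum_week, 0, 24, "postpartum_week")
  .assert_positive(age_years, "age_years")
  .assert_positive(baby_weight_kg, "baby_weight_kg")
  if (gravida < 1) .stopf("`gravida` must be >= 1")
  if (!is.null(postpartum_weight_kg))
    .assert_positive(postpartum_weight_kg, "postpartum_weight_kg")
  structure(list(age_years = age_years,
                 pre_pregnancy_weight_kg = pre_pregnancy_weight_kg,
                 height_cm = height_cm, gravida = gravida,
                 baby_weight_kg = baby_weight_kg,
                 postpartum_week = postpartum_week,
                 postpartum_weight_kg = postpartum_weight_kg),
            class = "postpartum_profile")
}

#' Body measurement set
#'
#' The lingua franca between the statistical and the mesh side: five
#' circumferences plus inseam (crotch-to-floor leg length) and height, all
#' in centimetres.
#'
#' @param chest_cm,waist_cm,hip_cm,upper_arm_cm,thigh_cm Circumferences (cm).
#' @param inseam_cm Leg length from crotch to floor (cm); must be below
#'   `height_cm`.
#' @param height_cm Standing height (cm).
#' @return A named numeric vector of class `body_measurements`.
#' @export
body_measurements <- function(chest_cm, waist_cm, hip_cm, upper_arm_cm,
                              thigh_cm, inseam_cm, height_cm) {
  m <- c(chest_cm = chest_cm, waist_cm = waist_cm, hip_cm = hip_cm,
         upper_arm_cm = upper_arm_cm, thigh_cm = thigh_cm,
         inseam_cm = inseam_cm, height_cm = height_cm)
  if (any(!is.finite(m)) || any(m <= 0))
    .stopf("all body measurements must be strictly positive (got: %s)",
           paste(sprintf("%s=%.3f", names(m), m), collapse = ", "))
  if (inseam_cm >= height_cm)
    .stopf("inseam (%.1f cm) must be smaller than height (%.1f cm)",
           inseam_cm, height_cm)
  structure(m, class = "body_measurements")
}

#' @export
print.body_measurements <- function(x, ...) {
  cat("Body measurements (cm):\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Regression coefficients for circumference prediction
#'
#' A coefficient matrix (one row per response: chest, waist, hip, upper_arm,
#' thigh; one column per covariate plus an intercept) in a fixed, documented
#' covariate order. The built-in published values are returned by
#' `regression_coefficients("pregnant")` / `"postpartum"`; alternative
#' values can be loaded with [read_coefficients_csv()].
#'
#' @param mode `"pregnant"` or `"postpartum"`.
#' @param table Optional coefficient matrix replacing the built-in one; must
#'   have the same dimnames.
#' @return An object of class `regression_coefficients`.
#' @export
#' @examples
#' regression_coefficients("pregnant")
regression_coefficients <- function(mode, table = NULL) {
  mode <- .match_mode(mode)
  builtin <- if (mode == "pregnant") .pregnant_coef_table else .postpartum_coef_table
  if (is.null(table)) {
    table <- builtin
  } else {
    table <- as.matrix(table)
    if (!identical(dim(table), dim(builtin)))
      .stopf("coefficient table for mode '%s' must be %d x %d", mode,
             nrow(builtin), ncol(builtin))
    if (is.null(dimnames(table))) dimnames(table) <- dimnames(builtin)
    if (!identical(rownames(table), rownames(builtin)) ||
        !identical(colnames(table), colnames(builtin)))
      .stopf("coefficient table dimnames must match the documented order (%s)",
             paste(colnames(builtin), collapse = ", "))
  }
  structure(list(mode = mode, table = table),
            class = "regression_coefficients")
}

#' @export
print.regression_coefficients <- function(x, ...) {
  cat(sprintf("Circumference regression coefficients (%s mode):\n", x$mode))
  print(x$table)
  invisible(x)
}

#' Write / read a coefficient table as CSV
#'
#' The CSV has a `response` column followed by the covariates in the
#' documented order and a final `intercept` column, one row per response.
#' A written table re-read with [read_coefficients_csv()] reproduces
#' predictions bit-identically.
#'
#' @param coeffs A `regression_coefficients` object.
#' @param path File path.
#' @return `write_coefficients_csv()` returns `path` invisibly;
#'   `read_coefficients_csv()` returns a `regression_coefficients` object.
#' @export
write_coefficients_csv <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "regression_coefficients"))
  df <- data.frame(response = rownames(coeffs$table), coeffs$table,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficients_csv
#' @param mode `"pregnant"` or `"postpartum"`, declaring which covariate
#'   layout the file must follow.
#' @export
read_coefficients_csv <- function(path, mode) {
  mode <- .match_mode(mode)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"response" %in% names(df)) .stopf("coefficient CSV needs a 'response' column")
  tab <- as.matrix(df[, setdiff(names(df), "response"), drop = FALSE])
  rownames(tab) <- df$response
  builtin <- if (mode == "pregnant") .pregnant_coef_table else .postpartum_coef_table
  tab <- tab[rownames(builtin), colnames(builtin), drop = FALSE]
  regression_coefficients(mode, tab)
}

#' Non-pregnant baseline measurements
#'
#' Chest, waist, hip, and inseam of a non-pregnant woman as fixed linear
#' functions of weight and height. These baselines anchor the morph space:
#' base blend weights are always computed from them at the pre-pregnancy
#' weight, and the inseam during pregnancy/postpartum is taken from here
#' (leg length is measured once and treated as static).
#'
#' @inheritParams bmi
#' @param .validate Set to `FALSE` to skip the positivity checks (used in
#'   analytic tests of the linear forms only).
#' @return Named numeric vector with `chest_cm`, `waist_cm`, `hip_cm`,
#'   `inseam_cm`.
#' @export
#' @examples
#' baseline_measurements(60, 165)
baseline_measurements <- function(weight_kg, height_cm, .validate = TRUE) {
  if (.validate) {
    .assert_positive(weight_kg, "weight_kg")
    .assert_positive(height_cm, "height_cm")
  }
  v <- .baseline_coef[, "weight"] * weight_kg +
       .baseline_coef[, "height"] * height_cm +
       .baseline_coef[, "intercept"]
  stats::setNames(v, c("chest_cm", "waist_cm", "hip_cm", "inseam_cm"))
}

# evaluate one regression row over a named covariate vector
.predict_responses <- function(coeffs, covariates) {
  tab <- coeffs$table
  x <- c(covariates[colnames(tab)[-ncol(tab)]], 1)
  drop(tab %*% x)
}

#' Predict body measurements of a pregnant woman
#'
#' Evaluates the published fixed-coefficient multiple linear regression for
#' chest, waist, hip, upper-arm and thigh circumference from the profile
#' covariates. If the profile does not carry a weight gain, it is predicted
#' from the pre-pregnancy BMI category first. Inseam comes from the
#' non-pregnant baseline at pre-pregnancy weight; height is passed through.
#'
#' @param profile A [pregnancy_profile()].
#' @param coeffs A `regression_coefficients` object with mode `"pregnant"`
#'   (default: the built-in published values).
#' @return A [body_measurements()] vector.
#' @export
#' @examples
#' p <- pregnancy_profile(60, 160, gestational_week = 24, weight_gain_kg = 8)
#' predict_pregnant_measurements(p)
predict_pregnant_measurements <- function(profile,
                                          coeffs = regression_coefficients("pregnant")) {
  stopifnot(inherits(profile, "pregnancy_profile"))
  if (!inherits(coeffs, "regression_coefficients") || coeffs$mode != "pregnant")
    .stopf("`coeffs` must be regression_coefficients with mode 'pregnant'")
  wg <- profile$weight_gain_kg
  if (is.null(wg)) {
    cat_ <- classify_bmi(bmi(profile$pre_pregnancy_weight_kg, profile$height_cm))
    wg <- predict_weight_gain(cat_, profile$gestational_week)
  }
  covs <- c(age_years = profile$age_years,
            pre_pregnancy_weight_kg = profile$pre_pregnancy_weight_kg,
            height_cm = profile$height_cm,
            gravida = profile$gravida,
            gestational_week = profile$gestational_week,
            weight_gain_kg = wg)
  girths <- .predict_responses(coeffs, covs)
  if (any(girths <= 0))
    .stopf("regression predicted non-positive girth (%s); inputs are outside the model's plausible range",
           paste(sprintf("%s=%.2f", names(girths), girths), collapse = ", "))
  base <- baseline_measurements(profile$pre_pregnancy_weight_kg, profile$height_cm)
  body_measurements(girths[["chest"]], girths[["waist"]], girths[["hip"]],
                    girths[["upper_arm"]], girths[["thigh"]],
                    base[["inseam_cm"]], profile$height_cm)
}

#' Predict body measurements of a postpartum woman
#'
#' As [predict_pregnant_measurements()], with the postpartum regression. A
#' missing postpartum weight is predicted as pre-pregnancy weight plus the
#' BMI-category retention curve.
#'
#' @param profile A [postpartum_profile()].
#' @param coeffs A `regression_coefficients` object with mode
#'   `"postpartum"` (default: the built-in published values).
#' @return A [body_measurements()] vector.
#' @export
#' @examples
#' p <- postpartum_profile(60, 160, postpartum_week = 12, postpartum_weight_kg = 65)
#' predict_postpartum_measurements(p)
predict_postpartum_measurements <- function(profile,
                                            coeffs = regression_coefficients("postpartum")) {
  stopifnot(inherits(profile, "postpartum_profile"))
  if (!inherits(coeffs, "regression_coefficients") || coeffs$mode != "postpartum")
    .stopf("`coeffs` must be regression_coefficients with mode 'postpartum'")
  wppt <- profile$postpartum_weight_kg
  if (is.null(wppt)) {
    cat_ <- classify_bmi(bmi(profile$pre_pregnancy_weight_kg, profile$height_cm))
    wppt <- predict_postpartum_weight(profile$pre_pregnancy_weight_kg, cat_,
                                      profile$postpartum_week)
  }
  covs <- c(age_years = profile$age_years,
            pre_pregnancy_weight_kg = profile$pre_pregnancy_weight_kg,
            height_cm = profile$height_cm,
            gravida = profile$gravida,
            baby_weight_kg = profile$baby_weight_kg,
            postpartum_week = profile$postpartum_week,
            postpartum_weight_kg = wppt)
  girths <- .predict_responses(coeffs, covs)
  if (any(girths <= 0))
    .stopf("regression predicted non-positive girth (%s); inputs are outside the model's plausible range",
           paste(sprintf("%s=%.2f", names(girths), girths), collapse = ", "))
  base <- baseline_measurements(profile$pre_pregnancy_weight_kg, profile$height_cm)
  body_measurements(girths[["chest"]], girths[["waist"]], girths[["hip"]],
                    girths[["upper_arm"]], girths[["thigh"]],
                    base[["inseam_cm"]], profile$height_cm)
}
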