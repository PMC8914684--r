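# Synthetic longitudinal cohort generator.
#
# Emulates the covariate structure of the source cohorts (truncated-normal
# age / pre-pregnancy weight / height with the printed range, mean and SD;
# gravida 1 or 2) and generates responses from the fixed regression
# coefficients plus i.i.d. Gaussian measurement noise, so every
# statistical stage is testable without any external data.

.pregnant_covariate_defaults <- data.frame(
  variable = c("age_years", "pre_pregnancy_weight_kg", "height_cm"),
  mean = c(29.64, 54.07, 157.58),
  sd = c(5.24, 11.30, 5.97),
  lo = c(18, 38, 104),
  hi = c(43.5, 102, 174),
  stringsAsFactors = FALSE)

.postpartum_covariate_defaults <- data.frame(
  variable = c("age_years", "pre_pregnancy_weight_kg", "height_cm",
               "baby_weight_kg"),
  mean = c(29.05, 56.35, 156.85, 2.97),
  sd = c(5.17, 12.10, 5.99, 0.42),
  lo = c(17.1, 38, 142, 2.1),
  hi = c(45.25, 95, 173, 4.02),
  stringsAsFactors = FALSE)

# per-visit retention probabilities reproducing the published visit counts
# (pregnant: 94, 98, 91, 82, 79, 78, 65 of 98; postpartum: 81, 76, 73, 72,
# 72, 70, 59 of 83)
.default_visit_retention <- function(mode) {
  if (mode == "pregnant") c(94, 98, 91, 82, 79, 78, 65) / 98
  else c(81, 76, 73, 72, 72, 70, 59) / 83
}

#' Cohort generation specification
#'
#' @param mode `"pregnant"` or `"postpartum"`.
#' @param n_subjects Number of women.
#' @param visit_weeks Measurement visit weeks (default: every 4 weeks,
#'   gestational 12--36 or postpartum 0--24, as in the source protocol).
#' @param covariates Data frame with columns `variable`, `mean`, `sd`,
#'   `lo`, `hi` describing the truncated-normal subject covariates;
#'   defaults to the published cohort descriptives.
#' @param gravida_p2 Probability of gravida 2 (vs 1).
#' @param noise_sd_cm SD of the i.i.d. measurement noise on each girth
#'   (default 1 cm, putting ~95% of repeat measurements within the +/-2 cm
#'   interrater spread the protocol reports).
#' @param gain_jitter_sd_kg SD of the subject-level offset around the
#'   category weight-gain / retention curve.
#' @param visit_retention Per-visit retention probabilities (same length
#'   as `visit_weeks`), `NULL` for complete follow-up, or `"published"` for
#'   probabilities reproducing the published visit counts.
#' @param seed Mandatory integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(mode, n_subjects = 98,
                        visit_weeks = NULL, covariates = NULL,
                        gravida_p2 = NULL, noise_sd_cm = 1,
                        gain_jitter_sd_kg = 2, visit_retention = NULL,
                        seed) {
  mode <- .match_mode(mode)
  if (missing(seed)) .stopf("`seed` is mandatory for cohort generation")
  if (is.null(visit_weeks))
    visit_weeks <- if (mode == "pregnant") seq(12, 36, 4) else seq(0, 24, 4)
  if (is.null(covariates))
    covariates <- if (mode == "pregnant") .pregnant_covariate_defaults
                  else .postpartum_covariate_defaults
  if (is.null(gravida_p2)) gravida_p2 <- if (mode == "pregnant") 0.39 else 0.41
  if (identical(visit_retention, "published")) {
    ret <- .default_visit_retention(mode)
    if (length(ret) != length(visit_weeks))
      .stopf("'published' visit retention is defined for the default 7-visit schedule")
    visit_retention <- ret
  }
  if (!is.null(visit_retention) &&
      (length(visit_retention) != length(visit_weeks) ||
       any(visit_retention < 0 | visit_retention > 1)))
    .stopf("`visit_retention` must be probabilities, one per visit week")
  if (any(covariates$sd <= 0) || any(covariates$lo >= covariates$hi))
    .stopf("invalid covariate distribution parameters")
  structure(list(mode = mode, n_subjects = as.integer(n_subjects),
                 visit_weeks = visit_weeks, covariates = covariates,
                 gravida_p2 = gravida_p2, noise_sd_cm = noise_sd_cm,
                 gain_jitter_sd_kg = gain_jitter_sd_kg,
                 visit_retention = visit_retention, seed = as.integer(seed)),
            class = "cohort_spec")
}

# truncated normal by inverse-CDF (exact, vectorised)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# location parameter making the *truncated* mean equal the target (with
# asymmetric bounds the truncated mean drifts off the location parameter)
.truncnorm_location <- function(target_mean, sd, lo, hi) {
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  stats::uniroot(function(mu) tmean(mu) - target_mean,
                 c(target_mean - 3 * sd, target_mean + 3 * sd))$root
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws subject covariates once per woman from truncated normals, walks
#' each retained visit, sets the time-varying weight covariate (weight
#' gain during pregnancy, or postpartum weight) from the BMI-category
#' curves plus a subject-level jitter, and generates the five girth
#' responses from the regression coefficients plus i.i.d. Gaussian noise.
#' Fully deterministic given the spec's seed; the caller's RNG state is
#' left untouched.
#'
#' @param spec A [cohort_spec()].
#' @param coeffs Optional [regression_coefficients()] used for the
#'   responses (default: the built-in published values for `spec$mode`).
#' @return A data frame with one row per retained visit: `subject_id`,
#'   the mode's covariate columns, and `chest_cm`, `waist_cm`, `hip_cm`,
#'   `upper_arm_cm`, `thigh_cm`, `inseam_cm`.
#' @export
#' @examples
#' head(generate_cohort(cohort_spec("pregnant", n_subjects = 5, seed = 7)))
generate_cohort <- function(spec, coeffs = regression_coefficients(spec$mode)) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (coeffs$mode != spec$mode)
    .stopf("coefficient mode '%s' does not match cohort mode '%s'",
           coeffs$mode, spec$mode)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  n <- spec$n_subjects
  cv <- spec$covariates
  subj <- data.frame(subject_id = seq_len(n))
  for (i in seq_len(nrow(cv))) {
    mu <- .truncnorm_location(cv$mean[i], cv$sd[i], cv$lo[i], cv$hi[i])
    subj[[cv$variable[i]]] <- .rtruncnorm(n, mu, cv$sd[i], cv$lo[i], cv$hi[i])
  }
  subj$gravida <- 1L + stats::rbinom(n, 1L, spec$gravida_p2)
  subj$gain_jitter <- stats::rnorm(n, 0, spec$gain_jitter_sd_kg)
  subj$category <- vapply(seq_len(n), function(i)
    classify_bmi(bmi(subj$pre_pregnancy_weight_kg[i], subj$height_cm[i])), "")

  rows <- vector("list", length(spec$visit_weeks))
  for (vi in seq_along(spec$visit_weeks)) {
    wk <- spec$visit_weeks[vi]
    keep <- if (is.null(spec$visit_retention)) rep(TRUE, n)
            else stats::runif(n) < spec$visit_retention[vi]
    if (!any(keep)) next
    d <- subj[keep, , drop = FALSE]
    if (spec$mode == "pregnant") {
      d$gestational_week <- wk
      d$weight_gain_kg <- vapply(d$category, function(ct)
        predict_weight_gain(ct, wk), 0) + d$gain_jitter
    } else {
      d$postpartum_week <- wk
      d$postpartum_weight_kg <- d$pre_pregnancy_weight_kg +
        vapply(d$category, function(ct) predict_retention(ct, wk), 0) +
        d$gain_jitter
    }
    rows[[vi]] <- d
  }
  out <- do.call(rbind, rows)
  covs <- if (spec$mode == "pregnant") .pregnant_covariates else .postpartum_covariates
  X <- cbind(as.matrix(out[covs]), intercept = 1)
  mu <- X %*% t(coeffs$table)
  noise <- matrix(stats::rnorm(length(mu), 0, spec$noise_sd_cm), nrow = nrow(mu))
  girths <- mu + noise
  colnames(girths) <- paste0(.responses, "_cm")
  out$inseam_cm <- .baseline_coef["inseam", "weight"] * out$pre_pregnancy_weight_kg +
    .baseline_coef["inseam", "height"] * out$height_cm +
    .baseline_coef["inseam", "intercept"] +
    stats::rnorm(nrow(out), 0, spec$noise_sd_cm)
  out <- cbind(out[c("subject_id", covs)], girths, inseam_cm = out$inseam_cm)
  rownames(out) <- NULL
  out
}
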