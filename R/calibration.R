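# Calibration and agreement machinery: re-fitting the measurement
# regressions from cohort records, re-deriving the Alp correction tensor
# against an avatar set, and the method-agreement statistics used to
# compare measurement routes.

#' Re-fit the circumference regressions from cohort records
#'
#' Ordinary least squares per response, with the covariates in the
#' documented order of the prediction equations. A noise-free cohort
#' generated from a coefficient table recovers it to numerical precision.
#'
#' @param records Data frame with the mode's covariate columns (see
#'   [generate_cohort()] for the schema) and response columns `chest_cm`,
#'   `waist_cm`, `hip_cm`, `upper_arm_cm`, `thigh_cm`.
#' @param mode `"pregnant"` or `"postpartum"`.
#' @return A [regression_coefficients()] object.
#' @export
fit_measurement_regression <- function(records, mode) {
  mode <- .match_mode(mode)
  covs <- if (mode == "pregnant") .pregnant_covariates else .postpartum_covariates
  resp <- paste0(.responses, "_cm")
  miss <- setdiff(c(covs, resp), names(records))
  if (length(miss))
    .stopf("records are missing columns: %s", paste(miss, collapse = ", "))
  X <- cbind(as.matrix(records[covs]), intercept = 1)
  if (nrow(X) < ncol(X) + 1L)
    .stopf("singular design: %d records cannot identify %d coefficients",
           nrow(X), ncol(X))
  if (qr(X)$rank < ncol(X))
    .stopf("singular design: covariate matrix is rank deficient")
  fit <- stats::lm.fit(X, as.matrix(records[resp]))
  tab <- t(fit$coefficients)
  rownames(tab) <- .responses
  colnames(tab) <- c(covs, "intercept")
  regression_coefficients(mode, tab)
}

#' Least-squares quadratic fit
#'
#' Fits `y = a*x^2 + b*x + c`; with exactly three distinct x values this
#' interpolates.
#'
#' @param xs,ys Numeric vectors of equal length, at least three distinct
#'   `xs`.
#' @return Named numeric `c(a, b, c)`.
#' @export
#' @examples
#' polyfit_quadratic(0:4, (0:4)^2) # c(1, 0, 0)
polyfit_quadratic <- function(xs, ys) {
  if (length(xs) != length(ys)) .stopf("`xs` and `ys` must have equal length")
  if (length(unique(xs)) < 3L)
    .stopf("quadratic fit needs at least 3 distinct x values")
  co <- stats::lm.fit(cbind(xs^2, xs, 1), ys)$coefficients
  stats::setNames(co, c("a", "b", "c"))
}

#' Calibration grid
#'
#' The (BMI x week) design over which [calibrate_alp()] solves for
#' per-cell corrections. Defaults span the four BMI categories and the
#' tensor fitting domain of the mode (gestational weeks 12--36, postpartum
#' 0--24), for a reference subject of fixed height, age and gravida.
#'
#' @param mode `"pregnant"` or `"postpartum"`.
#' @param bmi BMI values (>= 3 distinct values needed for the BMI
#'   quadratics).
#' @param weeks Week values (>= 3 distinct).
#' @param height_cm,age_years,gravida,baby_weight_kg Reference-subject
#'   covariates held fixed over the grid.
#' @return A list of class `calibration_grid`.
#' @export
calibration_grid <- function(mode,
                             bmi = c(17, 22, 27.5, 32),
                             weeks = if (mode == "pregnant") c(12, 20, 28, 36)
                                     else c(0, 8, 16, 24),
                             height_cm = 158, age_years = 30, gravida = 1,
                             baby_weight_kg = 3) {
  mode <- .match_mode(mode)
  if (length(unique(bmi)) < 3L || length(unique(weeks)) < 3L)
    .stopf("calibration grid needs >= 3 distinct BMI and week values")
  structure(list(mode = mode, bmi = sort(unique(bmi)),
                 weeks = sort(unique(weeks)), height_cm = height_cm,
                 age_years = age_years, gravida = gravida,
                 baby_weight_kg = baby_weight_kg),
            class = "calibration_grid")
}

# statistical targets (chest/waist/hip/inseam/height) for one grid cell
.cell_targets <- function(grid, bmi_val, week) {
  h <- grid$height_cm
  wpp <- bmi_val * (h / 100)^2
  if (grid$mode == "pregnant") {
    prof <- pregnancy_profile(wpp, h, gestational_week = week,
                              age_years = grid$age_years, gravida = grid$gravida)
    m <- suppressWarnings(predict_pregnant_measurements(prof))
  } else {
    prof <- postpartum_profile(wpp, h, postpartum_week = week,
                               age_years = grid$age_years, gravida = grid$gravida,
                               baby_weight_kg = grid$baby_weight_kg)
    m <- suppressWarnings(predict_postpartum_measurements(prof))
  }
  m[c("chest_cm", "waist_cm", "hip_cm", "inseam_cm", "height_cm")]
}

# the five mesh quantities entering the calibration objective
.measure_calibration_targets <- function(mesh, config) {
  h <- max(mesh$vertices[, 2])
  crotch <- .crotch_height(mesh, config)
  hip_lo <- max(config$hip_band[1] * h, crotch + 0.2)
  c(chest_cm = .band_girth(mesh, config$chest_band * h, TRUE, config, refine_tol = 0.15),
    waist_cm = .band_girth(mesh, config$waist_band * h, FALSE, config, refine_tol = 0.15),
    hip_cm = .band_girth(mesh, c(hip_lo, config$hip_band[2] * h), TRUE, config,
                         refine_tol = 0.15),
    inseam_cm = crotch, height_cm = h)
}

# residual vector (measured - target) for a correction vector
.cell_residual <- function(alp, k0x, mode, avatars, target, config) {
  k <- stats::setNames(unname(k0x) + alp, paste0("k", 0:5))
  if (mode == "postpartum") k[["k0"]] <- 0
  w <- suppressWarnings(new_morph_weights(k, mode))
  mesh <- blend(avatars, w)
  .measure_calibration_targets(mesh, config) - target
}

# damped Gauss-Newton with box projection; deterministic start at 0, with
# damping-reset restarts (the girth landscape has hull/argmax kinks that
# can inflate the damping mid-run)
.solve_cell_gn <- function(k0x, mode, avatars, target, config, bounds,
                           max_iter = 15, tol = 1e-5) {
  sol <- .gn_run(numeric(6), k0x, mode, avatars, target, config, bounds,
                 max_iter, tol)
  restarts <- 0L
  while (sol$rmse > 0.02 && restarts < 3L) {
    nxt <- .gn_run(sol$alp, k0x, mode, avatars, target, config, bounds,
                   max_iter, tol)
    restarts <- restarts + 1L
    if (nxt$rmse >= sol$rmse * 0.999) { sol <- if (nxt$rmse < sol$rmse) nxt else sol; break }
    sol <- nxt
  }
  sol
}

.gn_run <- function(alp, k0x, mode, avatars, target, config, bounds,
                    max_iter = 15, tol = 1e-5) {
  free <- if (mode == "pregnant") 1:6 else 2:6   # indices into alp0..alp5
  r <- .cell_residual(alp, k0x, mode, avatars, target, config)
  lambda <- 1e-4
  for (it in seq_len(max_iter)) {
    # forward-difference Jacobian on the free coordinates; the step is kept
    # well above the girth-search discretization so derivatives stay clean
    hstep <- 0.02
    J <- matrix(0, length(r), length(free))
    for (j in seq_along(free)) {
      ap <- alp; ap[free[j]] <- ap[free[j]] + hstep
      J[, j] <- (.cell_residual(ap, k0x, mode, avatars, target, config) - r) / hstep
    }
    step <- tryCatch(
      solve(crossprod(J) + lambda * diag(length(free)), -crossprod(J, r)),
      error = function(e) NULL)
    if (is.null(step)) break
    cand <- alp
    cand[free] <- pmin(pmax(alp[free] + step, bounds[1]), bounds[2])
    rc <- .cell_residual(cand, k0x, mode, avatars, target, config)
    if (sum(rc^2) < sum(r^2)) {
      moved <- max(abs(cand - alp))
      alp <- cand; r <- rc
      lambda <- max(lambda / 4, 1e-8)
      if (moved < tol || sqrt(mean(r^2)) < 5e-3) break
    } else {
      lambda <- lambda * 8
      if (lambda > 1e3) break
    }
  }
  list(alp = alp, residual = r, rmse = sqrt(mean(r^2)))
}

# bounded cyclic coordinate descent (golden-section per coordinate)
.solve_cell_cd <- function(k0x, mode, avatars, target, config, bounds,
                           max_sweeps = 6, tol = 1e-4) {
  free <- if (mode == "pregnant") c(5, 6, 2, 3, 4, 1) else c(5, 6, 2, 3, 4)
  alp <- numeric(6)
  sse <- function(a) sum(.cell_residual(a, k0x, mode, avatars, target, config)^2)
  for (sweep in seq_len(max_sweeps)) {
    moved <- 0
    for (j in free) {
      f1 <- function(v) { a <- alp; a[j] <- v; sse(a) }
      opt <- stats::optimize(f1, bounds, tol = max(tol / 2, 1e-5))
      moved <- max(moved, abs(opt$minimum - alp[j]))
      alp[j] <- opt$minimum
    }
    if (moved < tol) break
  }
  r <- .cell_residual(alp, k0x, mode, avatars, target, config)
  list(alp = alp, residual = r, rmse = sqrt(mean(r^2)))
}

#' Calibrate the Alp correction tensor against an avatar set
#'
#' Re-derives the morph-correction tensor for a given avatar set: for
#' every (BMI, week) grid cell it solves a small bounded nonlinear
#' least-squares problem for the corrections `alp0..alp5` that make the
#' mesh-measured chest, waist, hip, inseam and height of the blended body
#' match the statistical targets; the per-cell corrections are then
#' condensed into the tensor by quadratic fits, first in BMI per week,
#' then in week per tensor row. Upper arm and thigh are not part of the
#' objective (no dedicated morph target drives them).
#'
#' Cells whose inner solve leaves a root-mean-square residual above
#' `cell_rmse_tol` are flagged with a warning and excluded from the
#' polynomial stage.
#'
#' @param avatars An `avatar_set`.
#' @param grid A [calibration_grid()].
#' @param targets Optional numeric matrix of explicit targets (one row per
#'   grid cell in `expand.grid(bmi, weeks)` order; columns `chest_cm`,
#'   `waist_cm`, `hip_cm`, `inseam_cm`, `height_cm`). Default: targets
#'   computed from the measurement regressions.
#' @param method Inner solver: `"gauss_newton"` (damped, box-projected;
#'   default) or `"coordinate"` (cyclic bounded coordinate descent).
#' @param bounds Box bounds per correction.
#' @param cell_rmse_tol RMS residual (cm) above which a cell is flagged.
#' @param config [measure_config()] used for the mesh measurements.
#' @return An [alp_calibration()] whose attribute `cells` holds the
#'   per-cell corrections and residuals.
#' @export
calibrate_alp <- function(avatars, grid, targets = NULL,
                          method = c("gauss_newton", "coordinate"),
                          bounds = c(-1, 1), cell_rmse_tol = 1,
                          config = measure_config(n_scan = 7)) {
  stopifnot(inherits(avatars, "avatar_set"), inherits(grid, "calibration_grid"))
  method <- match.arg(method)
  mode <- grid$mode
  cells <- expand.grid(bmi = grid$bmi, week = grid$weeks,
                       KEEP.OUT.ATTRS = FALSE)
  if (!is.null(targets)) {
    targets <- as.matrix(targets)
    if (nrow(targets) != nrow(cells) || ncol(targets) != 5L)
      .stopf("`targets` must be %d x 5", nrow(cells))
    colnames(targets) <- c("chest_cm", "waist_cm", "hip_cm", "inseam_cm",
                           "height_cm")
  }
  solver <- if (method == "gauss_newton") .solve_cell_gn else .solve_cell_cd
  res <- matrix(NA_real_, nrow(cells), 6,
                dimnames = list(NULL, paste0("alp", 0:5)))
  rmse <- numeric(nrow(cells))
  wpp_of <- function(b) b * (grid$height_cm / 100)^2
  for (i in seq_len(nrow(cells))) {
    b <- cells$bmi[i]; wk <- cells$week[i]
    tgt <- if (is.null(targets)) .cell_targets(grid, b, wk) else targets[i, ]
    base <- baseline_measurements(wpp_of(b), grid$height_cm)
    k0x <- base_weights(c(base, height_cm = grid$height_cm))
    sol <- solver(k0x, mode, avatars, tgt, config, bounds)
    res[i, ] <- sol$alp
    rmse[i] <- sol$rmse
  }
  ok <- rmse <= cell_rmse_tol
  if (!all(ok))
    .warnf("%d of %d calibration cells left RMS residual > %.2f cm and were excluded from the polynomial stage",
           sum(!ok), length(ok), cell_rmse_tol)
  if (sum(ok) < 9L)
    .stopf("too few converged cells (%d) to fit the tensor polynomials", sum(ok))
  xs <- if (mode == "pregnant") 0:5 else 1:5
  # stage 1: per week, quadratic in BMI -> AlpXY(week) samples
  wks <- sort(unique(cells$week[ok]))
  slot_samples <- array(NA_real_, c(length(xs), 3, length(wks)))
  for (wi in seq_along(wks)) {
    sel <- ok & cells$week == wks[wi]
    for (xi in seq_along(xs)) {
      co <- polyfit_quadratic(cells$bmi[sel], res[sel, paste0("alp", xs[xi])])
      slot_samples[xi, , wi] <- co   # (a, b, c) = (AlpX1, AlpX2, AlpX3)
    }
  }
  # stage 2: per (X, Y) row, quadratic in week -> (A, B, C)
  tensor <- matrix(NA_real_, length(xs) * 3, 3,
                   dimnames = list(paste0("Alp", rep(xs, each = 3), rep(1:3, length(xs))),
                                   c("A", "B", "C")))
  for (xi in seq_along(xs)) for (Y in 1:3) {
    co <- polyfit_quadratic(wks, slot_samples[xi, Y, ])
    tensor[paste0("Alp", xs[xi], Y), ] <- c(A = co[["c"]], B = co[["b"]], C = co[["a"]])
  }
  out <- alp_calibration(mode, tensor)
  attr(out, "cells") <- cbind(cells, res, rmse = rmse, converged = ok)
  out
}

#' Agreement statistics between two measurement series
#'
#' Per-series mean and SD (n-1 denominator), normal-approximation 95%
#' confidence intervals (`mean +/- 1.96*SD/sqrt(n)`), the relative error
#' `|mean1 - mean2| / mean_ref * 100` and the Pearson correlation of the
#' paired values. The published comparisons normalise inconsistently
#' (sometimes by the first series, sometimes by the second), so the
#' denominator is an explicit argument defaulting to the first.
#'
#' @param x,y Paired numeric vectors (same length, >= 2).
#' @param reference `"first"` or `"second"`: which mean is the
#'   relative-error denominator.
#' @return A list of class `agreement_summary`.
#' @export
#' @examples
#' agreement_stats(c(94, 95, 96), c(94.5, 95.2, 95.8))
agreement_stats <- function(x, y, reference = c("first", "second")) {
  reference <- match.arg(reference)
  if (length(x) != length(y) || length(x) < 2L)
    .stopf("`x` and `y` must be paired vectors of length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .stopf("correlation undefined: a series has zero variance")
  out <- agreement_from_moments(mean(x), stats::sd(x), mean(y), stats::sd(y),
                                length(x), reference)
  out$correlation <- stats::cor(x, y)
  out
}

#' @rdname agreement_stats
#' @param mean1,sd1,mean2,sd2 Printed summary moments of the two series.
#' @param n Number of paired observations.
#' @export
agreement_from_moments <- function(mean1, sd1, mean2, sd2, n,
                                   reference = c("first", "second")) {
  reference <- match.arg(reference)
  half1 <- 1.96 * sd1 / sqrt(n); half2 <- 1.96 * sd2 / sqrt(n)
  ref_mean <- if (reference == "first") mean1 else mean2
  structure(list(
    n = n,
    mean = c(mean1, mean2), sd = c(sd1, sd2),
    ci_lower = c(mean1 - half1, mean2 - half2),
    ci_upper = c(mean1 + half1, mean2 + half2),
    relative_error_pct = abs(mean1 - mean2) / ref_mean * 100,
    reference = reference, correlation = NA_real_),
    class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("agreement (n = %d, relative-error reference: %s series)\n",
              x$n, x$reference))
  tab <- rbind(mean = x$mean, sd = x$sd, `L CI` = x$ci_lower,
               `U CI` = x$ci_upper)
  colnames(tab) <- c("series 1", "series 2")
  print(round(tab, 2))
  cat(sprintf("relative error: %.3f%%", x$relative_error_pct))
  if (!is.na(x$correlation)) cat(sprintf("; correlation: %.3f", x$correlation))
  cat("\n")
  invisible(x)
}
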