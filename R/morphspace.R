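# Morph space: measurements -> blend weights -> mesh.
#
# Each blend weight K couples one measurement to one morph target through a
# fixed affine rescaling between the thin avatar's value and the target
# avatar's maximum (the base weight K0X), plus a BMI- and week-dependent
# polynomial correction AlpX from the calibration tensor. The output mesh
# is the per-vertex affine combination of the seven avatars, the thin
# avatar taking coefficient 1 - sum(K).

#' Alp correction calibration tensor
#'
#' The three-level polynomial tensor driving the week- and BMI-dependent
#' morph corrections: row `AlpXY` holds the week-quadratic coefficients
#' `(A, B, C)` of slot `Y` (`AlpXY(week) = C*week^2 + B*week + A`), and the
#' three slots of weight `X` form the BMI quadratic
#' `AlpX(bmi) = AlpX1*bmi^2 + AlpX2*bmi + AlpX3`. The built-in pregnant
#' tensor has 18 rows (`Alp01`..`Alp53`, including the belly weight
#' `X = 0`), the postpartum one 15 (`Alp11`..`Alp53`).
#'
#' Note the built-in tensors are the published constants, fitted against
#' the original (proprietary) avatar meshes; against the bundled synthetic
#' avatars they preserve the published formula structure but not magnitude
#' fidelity, which [calibrate_alp()] restores.
#'
#' @param mode `"pregnant"` or `"postpartum"`.
#' @param tensor Optional replacement matrix with the same dimnames as the
#'   built-in tensor of that mode.
#' @return An object of class `alp_calibration`.
#' @export
#' @examples
#' alp_calibration("pregnant")
alp_calibration <- function(mode, tensor = NULL) {
  mode <- .match_mode(mode)
  builtin <- if (mode == "pregnant") .pregnant_alp_tensor else .postpartum_alp_tensor
  if (is.null(tensor)) {
    tensor <- builtin
  } else {
    tensor <- as.matrix(tensor)
    if (!identical(dim(tensor), dim(builtin)))
      .stopf("%s tensor must be %d x 3 (rows %s..%s)", mode, nrow(builtin),
             rownames(builtin)[1], rownames(builtin)[nrow(builtin)])
    if (is.null(dimnames(tensor))) dimnames(tensor) <- dimnames(builtin)
    tensor <- tensor[rownames(builtin), c("A", "B", "C"), drop = FALSE]
  }
  structure(list(mode = mode, tensor = tensor), class = "alp_calibration")
}

#' @export
print.alp_calibration <- function(x, ...) {
  cat(sprintf("alp_calibration (%s mode), %d rows:\n", x$mode, nrow(x$tensor)))
  print(signif(x$tensor, 4))
  invisible(x)
}

#' Write / read an Alp tensor as JSON
#'
#' Serialized as `{"mode": ..., "rows": {"Alp01": {"A": ..., "B": ...,
#' "C": ...}, ...}}` with explicit row labels.
#'
#' @param cal An [alp_calibration()].
#' @param path File path.
#' @return `write_alp_json()` returns `path` invisibly; `read_alp_json()`
#'   an `alp_calibration`.
#' @export
write_alp_json <- function(cal, path) {
  stopifnot(inherits(cal, "alp_calibration"))
  rows <- lapply(seq_len(nrow(cal$tensor)), function(i) as.list(cal$tensor[i, ]))
  names(rows) <- rownames(cal$tensor)
  jsonlite::write_json(list(mode = cal$mode, rows = rows), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_alp_json
#' @export
read_alp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tensor <- do.call(rbind, lapply(obj$rows, function(r) unlist(r)[c("A", "B", "C")]))
  rownames(tensor) <- names(obj$rows)
  alp_calibration(obj$mode, tensor)
}

#' Base blend weights from body measurements
#'
#' The affine rescalings of chest, waist, hip, height and inseam onto the
#' morph-target axes. The belly weight `k00` is identically zero: all
#' pregnancy belly shape is carried by the Alp correction. The
#' measurements fed here are the *non-pregnant baseline* girths at
#' pre-pregnancy weight (see [baseline_measurements()]); all pregnancy and
#' postpartum change enters through the corrections.
#'
#' @param measurements A [body_measurements()] vector, or any named numeric
#'   vector with `chest_cm`, `waist_cm`, `hip_cm`, `height_cm`,
#'   `inseam_cm`.
#' @return Named numeric vector `k00`..`k05`.
#' @export
#' @examples
#' b <- baseline_measurements(60, 165)
#' base_weights(c(b, height_cm = 165))
base_weights <- function(measurements) {
  m <- unclass(measurements)
  need <- c("chest_cm", "waist_cm", "hip_cm", "height_cm", "inseam_cm")
  if (!all(need %in% names(m)))
    .stopf("`measurements` must provide %s", paste(need, collapse = ", "))
  a <- .base_weight_anchors
  c(k00 = 0,
    k01 = (m[["chest_cm"]] - a$chest[["lo"]]) / (a$chest[["hi"]] - a$chest[["lo"]]),
    k02 = (m[["waist_cm"]] - a$waist[["lo"]]) / (a$waist[["hi"]] - a$waist[["lo"]]),
    k03 = (m[["hip_cm"]] - a$hip[["lo"]]) / (a$hip[["hi"]] - a$hip[["lo"]]),
    k04 = a$height[["gain"]] * (m[["height_cm"]] - a$height[["lo"]]) /
      (a$height[["hi"]] - a$height[["lo"]]),
    k05 = (m[["inseam_cm"]] - a$inseam[["ref"]]) /
      (a$inseam[["hi"]] - a$inseam[["lo"]]))
}

#' Alp corrections at a BMI and week
#'
#' Evaluates the calibration tensor: each `AlpXY` as a quadratic in the
#' week, then each `AlpX` as a quadratic in BMI. Weeks are clamped to the
#' tensor's fitting domain (12--40 gestational, 0--24 postpartum) before
#' polynomial evaluation; in pregnant mode below 12 weeks the belly
#' correction `alp0` is then scaled by `week/12` (using the raw week), so
#' the belly grows in smoothly from zero at conception. In postpartum mode
#' `alp0` is identically zero.
#'
#' @param cal An [alp_calibration()].
#' @param bmi_kg_m2 Pre-pregnancy BMI (kg/m^2).
#' @param week Gestational or postpartum week (>= 0).
#' @return Named numeric vector `alp0`..`alp5`.
#' @export
#' @examples
#' alp_corrections(alp_calibration("pregnant"), 22, 24)
alp_corrections <- function(cal, bmi_kg_m2, week) {
  stopifnot(inherits(cal, "alp_calibration"))
  .assert_positive(bmi_kg_m2, "bmi_kg_m2")
  .assert_number(week, "week")
  if (week < 0) .stopf("`week` must be >= 0")
  wk_poly <- if (cal$mode == "pregnant") min(max(week, 12), 40) else min(week, 24)
  tens <- cal$tensor
  alp <- stats::setNames(numeric(6), paste0("alp", 0:5))
  xs <- if (cal$mode == "pregnant") 0:5 else 1:5
  for (X in xs) {
    slot <- function(Y) {
      r <- tens[paste0("Alp", X, Y), ]
      r[["C"]] * wk_poly^2 + r[["B"]] * wk_poly + r[["A"]]
    }
    alp[[paste0("alp", X)]] <- slot(1) * bmi_kg_m2^2 + slot(2) * bmi_kg_m2 + slot(3)
  }
  if (cal$mode == "pregnant" && week < 12)
    alp[["alp0"]] <- alp[["alp0"]] * week / 12
  alp
}

#' Morph weight set
#'
#' Combines base weights and Alp corrections component-wise into the blend
#' weights `k0` (pregnant belly), `k1` (chest), `k2` (waist), `k3` (hip),
#' `k4` (height), `k5` (legs). In postpartum mode `k0` is forced to zero.
#' Weights outside a sanity band (each K in `[-0.5, 1.5]`, thin-avatar
#' coefficient `>= -0.5`) trigger warnings, never clamping.
#'
#' @inheritParams alp_corrections
#' @param measurements Non-pregnant baseline measurements (see
#'   [base_weights()]).
#' @param mode `"pregnant"` or `"postpartum"`; must match `cal`.
#' @param sanity_band Numeric `c(lo, hi)` band for the warnings.
#' @return An object of class `morph_weights`: numeric `k0`..`k5` plus a
#'   `mode` attribute.
#' @export
morph_weights <- function(measurements, bmi_kg_m2, week,
                          cal = alp_calibration(mode), mode = cal$mode,
                          sanity_band = c(-0.5, 1.5)) {
  mode <- .match_mode(mode)
  if (cal$mode != mode)
    .stopf("calibration mode '%s' does not match requested mode '%s'", cal$mode, mode)
  k0x <- base_weights(measurements)
  alp <- alp_corrections(cal, bmi_kg_m2, week)
  k <- stats::setNames(unname(k0x + alp), paste0("k", 0:5))
  if (mode == "postpartum") k[["k0"]] <- 0
  new_morph_weights(k, mode, sanity_band = sanity_band)
}

#' @rdname morph_weights
#' @param k Named numeric vector `k0`..`k5` (missing entries default 0).
#' @export
new_morph_weights <- function(k, mode, sanity_band = c(-0.5, 1.5)) {
  mode <- .match_mode(mode)
  full <- stats::setNames(numeric(6), paste0("k", 0:5))
  full[names(k)] <- k
  if (mode == "postpartum" && full[["k0"]] != 0)
    .stopf("postpartum morph weights have no belly component (k0 must be 0)")
  base_coef <- 1 - sum(full[.applicable_k(mode)])
  if (any(full < sanity_band[1]) || any(full > sanity_band[2]) ||
      base_coef < sanity_band[1])
    .warnf("morph weights outside the sanity band [%g, %g] (K: %s; base coefficient %.3f); blending proceeds unclamped",
           sanity_band[1], sanity_band[2],
           paste(sprintf("%.3f", full), collapse = ", "), base_coef)
  structure(full, mode = mode, class = "morph_weights")
}

.applicable_k <- function(mode)
  if (mode == "pregnant") paste0("k", 0:5) else paste0("k", 1:5)

#' @export
print.morph_weights <- function(x, ...) {
  cat(sprintf("morph_weights (%s): %s\n  thin-avatar coefficient: %.3f\n",
              attr(x, "mode"),
              paste(sprintf("%s=%.3f", names(unclass(x)), x), collapse = " "),
              1 - sum(x[.applicable_k(attr(x, "mode"))])))
  invisible(x)
}

#' Blend the avatar set into a body mesh
#'
#' Per-vertex affine combination of the seven topology-identical avatars:
#' the thin avatar takes coefficient `1 - sum(K)` over the applicable
#' weights, the pregnant-thin avatar takes `k0` (pregnant mode only), and
#' the big-breast / big-waist / big-hip / tall / long-legs avatars take
#' `k1`..`k5`.
#'
#' @param avatars An `avatar_set` (see [generate_synthetic_avatars()]).
#' @param weights A `morph_weights` object.
#' @return A [mesh3()] with the shared topology.
#' @export
#' @examples
#' \donttest{
#' av <- generate_synthetic_avatars()
#' w <- new_morph_weights(c(k1 = 0.3), "postpartum")
#' m <- blend(av, w)
#' }
blend <- function(avatars, weights) {
  stopifnot(inherits(avatars, "avatar_set"), inherits(weights, "morph_weights"))
  nv <- vapply(avatars, function(m) nrow(m$vertices), 1L)
  if (length(unique(nv)) != 1L)
    .stopf("avatars do not share topology (vertex counts: %s)",
           paste(nv, collapse = ", "))
  mode <- attr(weights, "mode")
  k <- unclass(weights)
  coef <- c(thin = 1 - sum(k[.applicable_k(mode)]),
            pregnant_thin = if (mode == "pregnant") k[["k0"]] else 0,
            big_breast = k[["k1"]], big_waist = k[["k2"]],
            big_hip = k[["k3"]], tall = k[["k4"]], long_legs = k[["k5"]])
  V <- matrix(0, nrow = nv[1], ncol = 3)
  for (nm in names(coef))
    if (coef[[nm]] != 0) V <- V + coef[[nm]] * avatars[[nm]]$vertices
  mesh3(V, avatars$thin$faces)
}

#' Synthesize a body mesh from a covariate profile
#'
#' End-to-end convenience: computes the non-pregnant baseline at
#' pre-pregnancy weight, the base weights, the Alp corrections at the
#' profile's pre-pregnancy BMI and week, and blends the avatar set.
#'
#' @param profile A [pregnancy_profile()] or [postpartum_profile()].
#' @param avatars An `avatar_set`.
#' @param cal An [alp_calibration()] of the matching mode; defaults to the
#'   built-in published tensor.
#' @return A [mesh3()].
#' @export
synthesize_body <- function(profile, avatars, cal = NULL) {
  if (inherits(profile, "pregnancy_profile")) {
    mode <- "pregnant"; week <- profile$gestational_week
  } else if (inherits(profile, "postpartum_profile")) {
    mode <- "postpartum"; week <- profile$postpartum_week
  } else .stopf("`profile` must be a pregnancy_profile or postpartum_profile")
  if (is.null(cal)) cal <- alp_calibration(mode)
  base <- baseline_measurements(profile$pre_pregnancy_weight_kg, profile$height_cm)
  meas <- c(base, height_cm = profile$height_cm)
  w <- morph_weights(meas,
                     bmi(profile$pre_pregnancy_weight_kg, profile$height_cm),
                     week, cal, mode)
  blend(avatars, w)
}
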