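# Mesh measurement by horizontal cross-sectioning.
#
# Girths are read the way a tape measure reads them: the convex-hull
# perimeter of the slice loop (a tape bridges concavities such as the
# inter-breast notch); the raw polygon perimeter is available as an
# alternative. Landmark heights are fractions of total height; the bands
# are a package convention, chosen to bracket the anatomical levels of the
# bundled avatars, and are exposed in `measure_config()`.

#' Measurement configuration
#'
#' @param chest_band,waist_band,hip_band Landmark search bands as fractions
#'   of body height. Chest and hip take the maximal torso girth in their
#'   band, waist the minimal.
#' @param arm_height_frac Height (fraction of body height) at which the
#'   upper-arm girth is read.
#' @param thigh_below_crotch_cm Distance below the crotch (cm) at which the
#'   thigh girth is read.
#' @param n_scan Coarse scan points per band before local refinement.
#' @param method `"hull"` (convex-hull perimeter, tape-measure semantics,
#'   default) or `"polygon"` (raw loop perimeter).
#' @param torso_max_cx Maximal |centroid x| (cm) for a loop to count as the
#'   torso; `arm_min_cx` the minimal |centroid x| for an arm loop.
#' @return A list of class `measure_config`.
#' @export
measure_config <- function(chest_band = c(0.67, 0.78),
                           waist_band = c(0.565, 0.635),
                           hip_band = c(0.45, 0.535),
                           arm_height_frac = 0.75,
                           thigh_below_crotch_cm = 5,
                           n_scan = 9,
                           method = c("hull", "polygon"),
                           torso_max_cx = 12, arm_min_cx = 18) {
  structure(list(chest_band = chest_band, waist_band = waist_band,
                 hip_band = hip_band, arm_height_frac = arm_height_frac,
                 thigh_below_crotch_cm = thigh_below_crotch_cm,
                 n_scan = n_scan, method = match.arg(method),
                 torso_max_cx = torso_max_cx, arm_min_cx = arm_min_cx),
            class = "measure_config")
}

.polygon_area_centroid <- function(xy) {
  x <- xy[, 1]; z <- xy[, 2]
  x2 <- c(x[-1], x[1]); z2 <- c(z[-1], z[1])
  cr <- x * z2 - x2 * z
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) {
    list(area = 0, centroid = c(mean(x), mean(z)))
  } else {
    list(area = abs(a),
         centroid = c(sum((x + x2) * cr), sum((z + z2) * cr)) / (6 * a))
  }
}

.hull_perimeter <- function(xy) {
  h <- grDevices::chull(xy)
  hx <- xy[h, 1]; hz <- xy[h, 2]
  sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hz, hz[1]))^2))
}

.polygon_perimeter <- function(xy) {
  sum(sqrt(diff(c(xy[, 1], xy[1, 1]))^2 + diff(c(xy[, 2], xy[1, 2]))^2))
}

#' Horizontal cross-section of a mesh
#'
#' Intersects the plane `y = const` with the mesh and assembles the
#' triangle-plane segments into closed loops using shared-edge
#' connectivity (exact; no coordinate snapping needed). Vertices lying
#' numerically on the plane are nudged by a tolerance.
#'
#' @param mesh A [mesh3()].
#' @param y Plane height (cm); must intersect the mesh.
#' @return An object of class `cross_section`: the plane height and a list
#'   of loops, each with ordered planar `points` (x, z), `area`,
#'   `centroid`, `perimeter` and `hull_perimeter`.
#' @export
slice_mesh <- function(mesh, y) {
  stopifnot(inherits(mesh, "mesh3"))
  V <- mesh$vertices; F <- mesh$faces
  d <- V[, 2] - y
  z0 <- abs(d) < 1e-9
  if (any(z0)) d[z0] <- 1e-9
  pos <- d > 0
  p1 <- pos[F[, 1]]; p2 <- pos[F[, 2]]; p3 <- pos[F[, 3]]
  crossing <- (p1 | p2 | p3) & !(p1 & p2 & p3)
  if (!any(crossing))
    .stopf("empty section: plane y = %.2f does not intersect the mesh (y range %.2f..%.2f)",
           y, min(V[, 2]), max(V[, 2]))
  Fc <- F[crossing, , drop = FALSE]
  nf <- nrow(Fc)
  # the two sign-changing edges per face, as canonical edge keys
  ea <- cbind(Fc[, 1], Fc[, 2], Fc[, 3])
  eb <- cbind(Fc[, 2], Fc[, 3], Fc[, 1])
  chg <- pos[ea] != pos[eb]           # nf x 3 logical, two TRUE per row
  dim(chg) <- c(nf, 3L)
  nv <- nrow(V)
  keys <- pmin(ea, eb) * (nv + 1) + pmax(ea, eb)
  dim(keys) <- c(nf, 3L)
  face_keys <- matrix(t(keys)[t(chg)], ncol = 2L, byrow = TRUE)
  # intersection point per unique edge
  uk <- unique(as.vector(face_keys))
  ia <- floor(uk / (nv + 1)); ib <- uk - ia * (nv + 1)
  t_ <- d[ia] / (d[ia] - d[ib])
  px <- V[ia, 1] + t_ * (V[ib, 1] - V[ia, 1])
  pz <- V[ia, 3] + t_ * (V[ib, 3] - V[ia, 3])
  names(px) <- names(pz) <- as.character(uk)
  # adjacency: which faces carry each edge key
  kf <- data.frame(key = as.vector(face_keys), face = rep(seq_len(nf), 2L))
  key2faces <- split(kf$face, kf$key)
  loops <- list()
  visited <- logical(nf)
  for (start in seq_len(nf)) {
    if (visited[start]) next
    pts_keys <- numeric(0)
    f <- start; enter <- face_keys[start, 1L]
    repeat {
      visited[f] <- TRUE
      pts_keys <- c(pts_keys, enter)
      exit_ <- if (face_keys[f, 1L] == enter) face_keys[f, 2L] else face_keys[f, 1L]
      adj <- key2faces[[as.character(exit_)]]
      nxt <- adj[adj != f]
      if (length(nxt) == 0L || visited[nxt[1L]]) break
      f <- nxt[1L]; enter <- exit_
    }
    if (length(pts_keys) >= 3L) {
      ks <- as.character(pts_keys)
      xy <- cbind(x = px[ks], z = pz[ks])
      rownames(xy) <- NULL
      ac <- .polygon_area_centroid(xy)
      loops[[length(loops) + 1L]] <-
        list(points = xy, area = ac$area, centroid = ac$centroid,
             perimeter = .polygon_perimeter(xy),
             hull_perimeter = .hull_perimeter(xy))
    }
  }
  structure(list(y = y, loops = loops), class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("cross_section at y = %.2f cm: %d loop(s)\n", x$y, length(x$loops)))
  for (l in x$loops)
    cat(sprintf("  centroid (%.1f, %.1f), area %.1f, hull perimeter %.2f\n",
                l$centroid[1], l$centroid[2], l$area, l$hull_perimeter))
  invisible(x)
}

#' Girth of a body region in a cross-section
#'
#' Selects the region's loop and returns its perimeter under the
#' configured semantics. The torso is the largest-area loop (its centroid
#' must sit near the mid-sagittal plane); arms are the lateral loops; legs
#' are the near-midline loops below the crotch, split by the sign of x.
#'
#' @param section A [slice_mesh()] result.
#' @param region One of `"torso"`, `"left_arm"`, `"right_arm"`,
#'   `"left_leg"`, `"right_leg"`.
#' @param config A [measure_config()].
#' @return Girth in cm.
#' @export
girth <- function(section, region = c("torso", "left_arm", "right_arm",
                                      "left_leg", "right_leg"),
                  config = measure_config()) {
  stopifnot(inherits(section, "cross_section"))
  region <- match.arg(region)
  loops <- section$loops
  if (!length(loops)) .stopf("region '%s' not found: empty section", region)
  cx <- vapply(loops, function(l) l$centroid[1], 0)
  areas <- vapply(loops, function(l) l$area, 0)
  per <- function(l) if (config$method == "hull") l$hull_perimeter else l$perimeter
  pick <- switch(region,
    torso = {
      i <- which.max(areas)
      if (abs(cx[i]) > config$torso_max_cx)
        .stopf("region 'torso' not found at y = %.2f: largest loop is lateral (centroid x = %.1f)",
               section$y, cx[i])
      i
    },
    left_arm = , right_arm = {
      sgn <- if (region == "left_arm") -1 else 1
      cand <- which(sgn * cx >= config$arm_min_cx)
      if (!length(cand))
        .stopf("region '%s' not found at y = %.2f (no loop with centroid %sx >= %.1f)",
               region, section$y, if (sgn < 0) "-" else "+", config$arm_min_cx)
      cand[which.max(areas[cand])]
    },
    left_leg = , right_leg = {
      sgn <- if (region == "left_leg") -1 else 1
      cand <- which(sgn * cx > 0 & abs(cx) < config$arm_min_cx)
      if (!length(cand))
        .stopf("region '%s' not found at y = %.2f", region, section$y)
      cand[which.max(areas[cand])]
    })
  per(loops[[pick]])
}

# torso girth at height y, NA_real_ if the torso loop is absent
.torso_girth <- function(mesh, y, config) {
  sec <- try(slice_mesh(mesh, y), silent = TRUE)
  if (inherits(sec, "try-error")) return(NA_real_)
  g <- try(girth(sec, "torso", config), silent = TRUE)
  if (inherits(g, "try-error")) NA_real_ else g
}

# count near-midline loops (legs/torso; lateral arm loops excluded)
.midline_loop_count <- function(mesh, y, config) {
  sec <- try(slice_mesh(mesh, y), silent = TRUE)
  if (inherits(sec, "try-error")) return(0L)
  cx <- vapply(sec$loops, function(l) l$centroid[1], 0)
  sum(abs(cx) < config$arm_min_cx)
}

# crotch height: lowest y where the midline section is a single torso loop
.crotch_height <- function(mesh, config, tol = 0.02) {
  h <- max(mesh$vertices[, 2])
  lo <- 0.15 * h; hi <- 0.62 * h
  if (.midline_loop_count(mesh, lo, config) < 2L)
    .stopf("landmark failure: expected two leg loops at y = %.2f", lo)
  if (.midline_loop_count(mesh, hi, config) != 1L)
    .stopf("landmark failure: expected a single torso loop at y = %.2f (crotch above the search band)", hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.midline_loop_count(mesh, mid, config) >= 2L) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# band extremum of the torso girth: coarse scan, then local refinement of
# *every* scanned local extremum (the girth profile can carry several
# competing local maxima; refining only the scanned argmax would make the
# band extremum jump discontinuously when the leader changes)
.band_girth <- function(mesh, band_cm, maximize, config, refine_tol = 0.1) {
  ys <- seq(band_cm[1], band_cm[2], length.out = config$n_scan)
  gs <- vapply(ys, function(y) .torso_girth(mesh, y, config), 0)
  if (all(is.na(gs)))
    .stopf("landmark failure: no torso loop anywhere in band %.1f..%.1f cm",
           band_cm[1], band_cm[2])
  sgn <- if (maximize) 1 else -1
  v <- sgn * gs
  v[is.na(v)] <- -Inf
  n <- length(v)
  is_local <- v >= c(-Inf, v[-n]) & v >= c(v[-1], -Inf)
  f <- function(y) {
    g <- .torso_girth(mesh, y, config)
    if (is.na(g)) if (maximize) -Inf else Inf else g
  }
  best <- max(v)
  for (i in which(is_local)) {
    lo <- ys[max(1L, i - 1L)]; hi <- ys[min(n, i + 1L)]
    opt <- stats::optimize(f, c(lo, hi), maximum = maximize, tol = refine_tol)
    best <- max(best, sgn * opt$objective)
  }
  sgn * best
}

.measure_one <- function(mesh, dim, config = measure_config()) {
  h <- max(mesh$vertices[, 2])
  switch(dim,
    height_cm = h,
    inseam_cm = .crotch_height(mesh, config),
    chest_cm = .band_girth(mesh, config$chest_band * h, TRUE, config),
    waist_cm = .band_girth(mesh, config$waist_band * h, FALSE, config),
    hip_cm = {
      crotch <- .crotch_height(mesh, config)
      lo <- max(config$hip_band[1] * h, crotch + 0.2)
      hi <- config$hip_band[2] * h
      if (lo >= hi)
        .stopf("landmark failure: hip band [%.2f, %.2f] x height lies below the crotch (%.1f cm)",
               config$hip_band[1], config$hip_band[2], crotch)
      .band_girth(mesh, c(lo, hi), TRUE, config)
    },
    .stopf("unknown dimension '%s'", dim))
}

#' Measure a humanoid mesh
#'
#' Computes the full measurement set of a mesh in the package coordinate
#' convention (cm, Y-up, feet at `y = 0`): height as the maximal y; inseam
#' as the crotch height (the lowest level where the single torso loop
#' splits into two leg loops, found by bisection); chest/waist/hip as the
#' band extrema of the torso girth (maximal, minimal, maximal
#' respectively); upper arm as the arm girth at a fixed height fraction;
#' thigh as the leg girth slightly below the crotch (left/right averaged
#' for the paired limbs).
#'
#' @param mesh A [mesh3()].
#' @param config A [measure_config()].
#' @return A [body_measurements()] vector.
#' @export
#' @examples
#' \donttest{
#' av <- generate_synthetic_avatars()
#' measure_all(av$thin)
#' }
measure_all <- function(mesh, config = measure_config()) {
  stopifnot(inherits(mesh, "mesh3"))
  h <- max(mesh$vertices[, 2])
  crotch <- .crotch_height(mesh, config)
  chest <- .band_girth(mesh, config$chest_band * h, TRUE, config)
  waist <- .band_girth(mesh, config$waist_band * h, FALSE, config)
  hip_lo <- max(config$hip_band[1] * h, crotch + 0.2)
  if (hip_lo >= config$hip_band[2] * h)
    .stopf("landmark failure: hip band [%.2f, %.2f] x height lies below the crotch (%.1f cm)",
           config$hip_band[1], config$hip_band[2], crotch)
  hip <- .band_girth(mesh, c(hip_lo, config$hip_band[2] * h), TRUE, config)
  arm_sec <- slice_mesh(mesh, config$arm_height_frac * h)
  arm <- mean(c(girth(arm_sec, "left_arm", config),
                girth(arm_sec, "right_arm", config)))
  thigh_sec <- slice_mesh(mesh, crotch - config$thigh_below_crotch_cm)
  thigh <- mean(c(girth(thigh_sec, "left_leg", config),
                  girth(thigh_sec, "right_leg", config)))
  body_measurements(chest, waist, hip, arm, thigh, crotch, h)
}
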