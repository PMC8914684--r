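# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# the bundled avatar set at default resolution (anchors verified once here)
test_avatars <- function() {
  if (is.null(.fixture_env$avatars))
    .fixture_env$avatars <- generate_synthetic_avatars()
  .fixture_env$avatars
}

# a simple independent cylinder mesh (own construction, not the package loft)
make_cylinder <- function(radius, height, n_theta = 64, n_rings = 8,
                          center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  ys <- seq(0, height, length.out = n_rings)
  verts <- do.call(rbind, lapply(ys, function(y)
    cbind(center[1] + radius * cos(th), y, center[2] + radius * sin(th))))
  faces <- NULL
  for (k in seq_len(n_rings - 1)) {
    b <- (k - 1) * n_theta
    j <- seq_len(n_theta); jn <- c(j[-1], 1)
    faces <- rbind(faces,
                   cbind(b + j, b + jn, b + n_theta + j),
                   cbind(b + jn, b + n_theta + jn, b + n_theta + j))
  }
  nv <- nrow(verts)
  verts <- rbind(verts, c(center[1], 0, center[2]),
                 c(center[1], height, center[2]))
  j <- seq_len(n_theta); jn <- c(j[-1], 1)
  faces <- rbind(faces, cbind(jn, j, nv + 1),
                 cbind((n_rings - 1) * n_theta + j,
                       (n_rings - 1) * n_theta + jn, nv + 2))
  mesh3(verts, faces)
}

# an extruded arbitrary planar polygon (closed prism)
make_prism <- function(xy, height) {
  n <- nrow(xy)
  verts <- rbind(cbind(xy[, 1], 0, xy[, 2]), cbind(xy[, 1], height, xy[, 2]))
  j <- seq_len(n); jn <- c(j[-1], 1)
  faces <- rbind(cbind(j, jn, n + j), cbind(jn, n + jn, n + j))
  nv <- nrow(verts)
  verts <- rbind(verts, c(mean(xy[, 1]), 0, mean(xy[, 2])),
                 c(mean(xy[, 1]), height, mean(xy[, 2])))
  faces <- rbind(faces, cbind(jn, j, nv + 1), cbind(n + j, n + jn, nv + 2))
  mesh3(verts, faces)
}
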