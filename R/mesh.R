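#' Triangle mesh
#'
#' A minimal triangle-mesh container: an `N x 3` vertex matrix (cm, Y-up,
#' feet plane at `y = 0`, bilateral symmetry about `x = 0` for the bundled
#' avatars) and an `M x 3` integer face matrix of 1-based vertex indices.
#'
#' @param vertices Numeric `N x 3` matrix of vertex coordinates.
#' @param faces Integer `M x 3` matrix of 1-based vertex indices.
#' @return An object of class `mesh3`.
#' @export
mesh3 <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (ncol(vertices) != 3L) .stopf("`vertices` must have 3 columns")
  if (ncol(faces) != 3L) .stopf("`faces` must have 3 columns (triangles)")
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    .stopf("face indices out of range [1, %d]", nrow(vertices))
  if (nrow(faces) && any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
                         faces[, 1] == faces[, 3]))
    .stopf("degenerate faces (repeated vertex index) are not allowed")
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "mesh3")
}

#' @export
print.mesh3 <- function(x, ...) {
  cat(sprintf("mesh3: %d vertices, %d triangles, height %.1f cm\n",
              nrow(x$vertices), nrow(x$faces),
              diff(range(x$vertices[, "y"]))))
  invisible(x)
}

#' Read a Wavefront OBJ file
#'
#' Parses `v` and `f` records; quad faces are triangulated fan-wise;
#' texture/normal references (`f v/vt/vn`) are accepted and stripped;
#' negative (relative) and zero indices are rejected. Malformed records
#' raise an error naming the offending line.
#'
#' @param path Path to an OBJ file.
#' @return A [mesh3()].
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vs <- list(); fs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- tok[1]
    if (key == "v") {
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (length(tok) < 4 || any(is.na(xyz)))
        .stopf("OBJ parse error at line %d: bad vertex record '%s'", i, ln)
      vs[[length(vs) + 1L]] <- xyz
    } else if (key == "f") {
      ref <- tok[-1]
      if (length(ref) < 3)
        .stopf("OBJ parse error at line %d: face with <3 vertices", i)
      idx <- suppressWarnings(as.integer(vapply(
        strsplit(ref, "/", fixed = TRUE), `[[`, "", 1L)))
      if (any(is.na(idx)))
        .stopf("OBJ parse error at line %d: bad face record '%s'", i, ln)
      if (any(idx < 1))
        .stopf("OBJ parse error at line %d: indices must be positive 1-based (got %s)",
               i, paste(idx, collapse = " "))
      if (length(idx) > 4)
        .stopf("OBJ parse error at line %d: only triangles and quads supported", i)
      if (length(idx) == 3) {
        fs[[length(fs) + 1L]] <- idx
      } else {
        fs[[length(fs) + 1L]] <- idx[c(1, 2, 3)]
        fs[[length(fs) + 1L]] <- idx[c(1, 3, 4)]
      }
    }
    # other records (vn, vt, o, g, usemtl, ...) are ignored
  }
  if (!length(vs)) .stopf("OBJ file '%s' contains no vertices", path)
  mesh3(do.call(rbind, vs), do.call(rbind, fs))
}

#' Write a mesh as Wavefront OBJ
#'
#' Writes plain `v`/`f` records (no materials) with six decimal places;
#' `read_obj(write_obj(mesh))` reproduces vertices to 1e-6 and the face
#' list exactly.
#'
#' @param mesh A [mesh3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh3"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}
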