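# Shared fixtures, all generated in code.

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = 1
  )
  triangle_mesh(v, f, name = "unit_cube")
}

cube_missing_facet <- function() {
  m <- unit_cube_mesh()
  m$faces <- m$faces[-1L, , drop = FALSE]
  m
}

cube_flipped_facet <- function() {
  m <- unit_cube_mesh()
  m$faces[1L, ] <- m$faces[1L, c(1L, 3L, 2L)]
  m
}

rotate_mesh <- function(mesh, angle, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  rot <- diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
  mesh$vertices <- mesh$vertices %*% t(rot)
  mesh
}

# Independent mesh oracle: python trimesh on a full-precision OBJ export.
trimesh_area_volume <- function(mesh) {
  obj <- tempfile(fileext = ".obj")
  on.exit(unlink(obj))
  write_mesh(mesh, obj, format = "obj")
  py <- tempfile(fileext = ".py")
  on.exit(unlink(py), add = TRUE)
  writeLines(c(
    "import sys, json, trimesh",
    "m = trimesh.load(sys.argv[1], process=False)",
    "print(json.dumps({'area': float(m.area), 'volume': float(abs(m.volume))}))"
  ), py)
  out <- system2("python", c(py, obj), stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(out[length(out)])
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
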