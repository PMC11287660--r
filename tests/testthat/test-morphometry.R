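test_that("surface area matches analytic values", {
  expect_equal(surface_area(unit_cube_mesh()), 6)
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)))
  expect_equal(surface_area(tri), 0.5)
  expect_rel(surface_area(make_icosphere(5, 4)), 4 * pi * 25, 0.002)
})

test_that("surface area is invariant to rigid motion and winding", {
  cube <- unit_cube_mesh()
  rot <- rotate_mesh(cube, 0.7, c(1, 2, 3))
  rot$vertices <- sweep(rot$vertices, 2, c(10, -4, 2), "+")
  expect_equal(surface_area(rot), 6)
  flipped <- cube
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  expect_equal(surface_area(flipped), 6)
})

test_that("biovolume matches closed forms and is translation invariant", {
  cube <- unit_cube_mesh()
  expect_equal(biovolume(cube), 1)
  far <- cube
  far$vertices <- far$vertices + 1000
  expect_equal(biovolume(far), 1)
  cap <- make_revolution(shape_capsule(2, 10), n_theta = 256, n_z = 128)
  expect_rel(biovolume(cap), pi * 4 * 10 + 4 / 3 * pi * 8, 0.005)
})

test_that("biovolume errors on open meshes and names the boundary edges", {
  expect_error(biovolume(cube_missing_facet()), "3 boundary edge")
})

test_that("biovolume of a globally inverted mesh is still positive", {
  inv <- unit_cube_mesh()
  inv$faces <- inv$faces[, c(1, 3, 2)]
  expect_equal(biovolume(inv), 1)
})

test_that("inconsistent winding errors unless fix_orientation repairs it", {
  bad <- cube_flipped_facet()
  expect_error(biovolume(bad), "orient")
  expect_equal(biovolume(bad, fix_orientation = TRUE), 1)
  ico <- make_icosphere(2, 2)
  bad_ico <- ico
  flip <- seq(1, nrow(ico$faces), by = 3)
  bad_ico$faces[flip, ] <- bad_ico$faces[flip, c(1, 3, 2)]
  expect_equal(biovolume(bad_ico, fix_orientation = TRUE), biovolume(ico))
})

test_that("equivalent diameters follow the defining formulas", {
  # sphere self-consistency: d = 10
  eq <- equivalent_diameters(100 * pi, 500 / 3 * pi)
  expect_equal(eq$d_esa, 10)
  expect_equal(eq$d_esv, 10)
  expect_error(equivalent_diameters(-1, 2), "positive")
  expect_error(equivalent_diameters(1, 0), "positive")
})

test_that("principal extents recover box dimensions under rotation", {
  # axis-aligned box with the Halamphora model footprint
  box <- unit_cube_mesh()
  box$vertices <- sweep(box$vertices, 2, c(16.27, 3.94, 3.24), "*")
  ext <- principal_extents(box)
  expect_equal(unlist(ext), c(length = 16.27, width = 3.94, depth = 3.24))
  rot <- rotate_mesh(box, pi / 6)
  ext_rot <- principal_extents(rot)
  expect_equal(unlist(ext_rot), unlist(ext), tolerance = 1e-6)
  sph <- principal_extents(make_icosphere(5, 3))
  expect_equal(unlist(sph), c(length = 10, width = 10, depth = 10),
               tolerance = 0.01)
})

test_that("aabb extents measure the as-stored orientation", {
  box <- unit_cube_mesh()
  box$vertices <- sweep(box$vertices, 2, c(2, 5, 3), "*")
  expect_equal(unlist(principal_extents(box, method = "aabb")),
               c(length = 5, width = 3, depth = 2))
})

test_that("degenerate vertex clouds are rejected", {
  flat <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                        rbind(c(1, 2, 3), c(2, 4, 3)))
  expect_error(principal_extents(flat), "degenerate")
})

test_that("watertightness QC distinguishes closed, holed and mis-wound meshes", {
  qc <- check_watertight(unit_cube_mesh())
  expect_identical(unname(unlist(qc)),
                   c(TRUE, TRUE, 0L), ignore_attr = TRUE)
  holed <- check_watertight(cube_missing_facet())
  expect_false(holed$watertight)
  expect_true(holed$consistently_oriented)
  expect_identical(holed$boundary_edges, 3L)
  flipped <- check_watertight(cube_flipped_facet())
  expect_true(flipped$watertight)
  expect_false(flipped$consistently_oriented)
  expect_identical(flipped$boundary_edges, 0L)
})

test_that("scaling multiplies SA by s^2 and V by s^3", {
  for (mesh in list(unit_cube_mesh(), make_icosphere(3, 2))) {
    s <- 3.7
    sa <- surface_area(mesh)
    vol <- biovolume(mesh)
    scaled <- scale_mesh(mesh, s)
    expect_equal(surface_area(scaled), sa * s^2)
    expect_equal(biovolume(scaled), vol * s^3)
  }
})

test_that("d_esa >= d_esv on watertight fixtures (isoperimetric inequality)", {
  fixtures <- list(
    unit_cube_mesh(),
    make_icosphere(5, 3),
    make_revolution(shape_capsule(2, 10), 64, 48),
    plankton_preset("p-micans-like", 64, 48),
    plankton_preset("halamphora-like", 64, 48)
  )
  for (mesh in fixtures) {
    eq <- equivalent_diameters(surface_area(mesh), biovolume(mesh))
    expect_gt(eq$d_esa, eq$d_esv)
  }
  # equality approached from above by refining icospheres
  gaps <- vapply(1:4, function(s) {
    m <- make_icosphere(5, s)
    eq <- equivalent_diameters(surface_area(m), biovolume(m))
    eq$d_esa - eq$d_esv
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("mesh_morphometry assembles a coherent one-row report", {
  rep <- mesh_morphometry(make_icosphere(5, 3))
  expect_s3_class(rep, "morphometry_report")
  expect_identical(nrow(rep), 1L)
  expect_equal(rep$d_esa, sqrt(rep$surface_area / pi))
  expect_equal(rep$sa_to_v, rep$surface_area / rep$biovolume)
  expect_true(rep$watertight && rep$consistently_oriented)
  # open mesh: volume-derived columns NA, no error
  open_rep <- mesh_morphometry(cube_missing_facet())
  expect_true(is.na(open_rep$biovolume))
  expect_true(is.na(open_rep$d_esv))
  expect_identical(open_rep$boundary_edges, 3L)
  # tidy/glance
  td <- tidy(rep)
  expect_identical(td$quantity[1:2], c("surface_area", "biovolume"))
  expect_false(inherits(glance(rep), "morphometry_report"))
})
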