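test_that("binary STL round-trips a cube with vertex merging", {
  cube <- unit_cube_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, path, format = "stl-binary")
  expect_identical(file.size(path), 84 + 12 * 50)  # header + 12 facet records
  m <- read_mesh(path)
  expect_identical(m$source_format, "stl-binary")
  expect_identical(nrow(m$vertices), 8L)   # facet soup merged back to 8
  expect_identical(nrow(m$faces), 12L)
  expect_equal(surface_area(m), 6)
  expect_equal(biovolume(m), 1)
})

test_that("two successive binary STL write/read cycles are byte-stable", {
  mesh <- make_icosphere(2.5, 2)
  p1 <- withr::local_tempfile(fileext = ".stl")
  p2 <- withr::local_tempfile(fileext = ".stl")
  p3 <- withr::local_tempfile(fileext = ".stl")
  write_mesh(mesh, p1, format = "stl-binary")
  write_mesh(read_mesh(p1), p2, format = "stl-binary")
  write_mesh(read_mesh(p2), p3, format = "stl-binary")
  expect_identical(readBin(p2, "raw", file.size(p2)),
                   readBin(p3, "raw", file.size(p3)))
})

test_that("ASCII STL round-trips vertices and faces", {
  cube <- unit_cube_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, path, format = "stl-ascii")
  m <- read_mesh(path)
  expect_identical(m$source_format, "stl-ascii")
  expect_equal(m$vertices[m$faces[1, ], ], cube$vertices[cube$faces[1, ], ])
  expect_identical(nrow(m$faces), 12L)
  expect_equal(sort(as.vector(m$vertices)), sort(as.vector(cube$vertices)))
})

test_that("OBJ writes cube as 8 v-lines + 12 f-lines and round-trips exactly", {
  cube <- unit_cube_mesh()
  path <- withr::local_tempfile(fileext = ".obj")
  write_mesh(cube, path, format = "obj")
  lines <- readLines(path)
  expect_identical(sum(grepl("^v ", lines)), 8L)
  expect_identical(sum(grepl("^f ", lines)), 12L)
  m <- read_mesh(path)
  expect_identical(m$vertices, cube$vertices)
  expect_identical(m$faces, cube$faces)
})

test_that("OBJ quad faces are fan-triangulated around the first vertex", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3 4"), path)
  m <- read_mesh(path)
  expect_identical(nrow(m$faces), 2L)
  expect_identical(m$faces, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
})

test_that("OBJ parser ignores texture/normal indices and negative indices work", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0",
               "vt 0 0", "vn 0 0 1",
               "f 1/1/1 2/1/1 3/1/1",
               "f -3 -2 -1"), path)
  m <- read_mesh(path)
  expect_identical(m$faces, rbind(c(1L, 2L, 3L), c(1L, 2L, 3L)))
})

test_that("vertex merging never changes the facet count", {
  for (mesh in list(unit_cube_mesh(), make_icosphere(1, 2),
                    make_revolution(shape_capsule(1, 4), 16, 8))) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_mesh(mesh, path, format = "stl-binary")
    expect_identical(nrow(read_mesh(path)$faces), nrow(mesh$faces))
  }
})

test_that("malformed and degenerate inputs are rejected with diagnostics", {
  expect_error(read_mesh(withr::local_tempfile()), "not found")
  expect_error(write_mesh(triangle_mesh(diag(3), matrix(integer(0), 0, 3)),
                          tempfile(fileext = ".stl")), "empty")
  expect_error(triangle_mesh(rbind(c(0, 0, NaN)), rbind(c(1, 1, 1))),
               "non-finite")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 4))), "out of range")
  # degenerate face: rejected by default, droppable on request
  expect_error(triangle_mesh(diag(3), rbind(c(1, 1, 2))), "degenerate")
  m <- triangle_mesh(diag(3), rbind(c(1, 1, 2), c(1, 2, 3)),
                     drop_degenerate = TRUE)
  expect_identical(nrow(m$faces), 1L)
  # truncated binary STL
  path <- withr::local_tempfile(fileext = ".stl")
  con <- file(path, "wb")
  writeBin(raw(80), con)
  writeBin(5L, con, size = 4, endian = "little")
  writeBin(raw(20), con)
  close(con)
  expect_error(read_mesh(path), "STL|detect")
})

test_that("format auto-detection distinguishes the three formats", {
  cube <- unit_cube_mesh()
  for (fmt in c("stl-binary", "stl-ascii", "obj")) {
    ext <- if (fmt == "obj") ".obj" else ".stl"
    path <- withr::local_tempfile(fileext = ext)
    write_mesh(cube, path, format = fmt)
    expect_identical(read_mesh(path)$source_format, fmt)
  }
})
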