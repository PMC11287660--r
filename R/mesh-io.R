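#' Triangle mesh container
#'
#' An indexed triangle mesh: an `n x 3` numeric matrix of vertex coordinates
#' (micrometres by convention throughout the package) and an `m x 3` integer
#' matrix of 1-based vertex indices per face, counter-clockwise when viewed
#' from outside (outward normal). STL and OBJ carry no unit metadata; all
#' morphometric quantities inherit whatever unit the coordinates are in, so a
#' model exported in metres must be rescaled with [scale_mesh()] first.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param name free-text model name.
#' @param source_format one of `"stl-binary"`, `"stl-ascii"`, `"obj"`,
#'   `"generated"`.
#' @param drop_degenerate if `TRUE`, faces repeating a vertex index are
#'   dropped; if `FALSE` such faces raise an error.
#' @return An object of class `triangle_mesh`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
#' m <- triangle_mesh(v, f, name = "tetrahedron")
#' m
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh",
                          source_format = "generated",
                          drop_degenerate = FALSE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  if (!all(is.finite(vertices))) {
    stop("non-finite vertex coordinate at row ",
         which(!apply(is.finite(vertices), 1L, all))[1L])
  }
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices)) {
      stop("face index out of range [1, ", nrow(vertices), "]")
    }
    degen <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
      faces[, 1L] == faces[, 3L]
    if (any(degen)) {
      if (drop_degenerate) {
        faces <- faces[!degen, , drop = FALSE]
      } else {
        stop(sum(degen), " degenerate face(s) repeating a vertex index; ",
             "use drop_degenerate = TRUE to drop them")
      }
    }
  }
  structure(
    list(vertices = vertices, faces = faces, name = as.character(name)[1L],
         source_format = source_format),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %s: %d vertices, %d faces (%s)\n",
              x$name, nrow(x$vertices), nrow(x$faces), x$source_format))
  invisible(x)
}

#' Uniformly scale mesh coordinates
#'
#' @param mesh a [triangle_mesh()].
#' @param factor scale factor applied to all coordinates (e.g. `1e6` to go
#'   from metres to micrometres).
#' @return The scaled `triangle_mesh`.
#' @export
scale_mesh <- function(mesh, factor) {
  stopifnot(inherits(mesh, "triangle_mesh"), is.finite(factor), factor > 0)
  mesh$vertices <- mesh$vertices * factor
  mesh
}

# Merge exactly-equal vertex coordinates into one indexed vertex. Exact
# float equality by design: deterministic topology, no tolerance weld.
merge_vertices <- function(vertices, faces) {
  key <- paste(vertices[, 1L], vertices[, 2L], vertices[, 3L], sep = "|")
  first <- !duplicated(key)
  new_id <- match(key, key[first])
  list(vertices = vertices[first, , drop = FALSE],
       faces = matrix(new_id[faces], ncol = 3L))
}

#' Read a triangle mesh from STL or OBJ
#'
#' Auto-detects the format: binary STL when the 80-byte header plus the
#' declared 32-bit triangle count is consistent with the file size, ASCII STL
#' when the file starts with `solid` and contains `facet` records, otherwise
#' Wavefront OBJ. STL facet soups are indexed by merging vertices that agree
#' exactly in all three coordinates; OBJ faces with more than three vertices
#' are fan-triangulated around their first vertex. OBJ texture/normal
#' references (`v/vt/vn`) and materials are ignored; only geometry is read.
#'
#' @param path path to an `.stl` or `.obj` file.
#' @param drop_degenerate drop faces repeating a vertex index instead of
#'   erroring.
#' @return A [triangle_mesh()].
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, drop_degenerate = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- detect_mesh_format(path)
  switch(fmt,
    "stl-binary" = read_stl_binary(path, drop_degenerate),
    "stl-ascii"  = read_stl_ascii(path, drop_degenerate),
    "obj"        = read_obj(path, drop_degenerate)
  )
}

detect_mesh_format <- function(path) {
  size <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", n = min(84L, size))
  if (length(head_raw) >= 84L) {
    n_tri <- readBin(head_raw[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(n_tri) && n_tri >= 0 && size == 84 + 50 * as.numeric(n_tri)) {
      return("stl-binary")
    }
  }
  lead <- rawToChar(head_raw[head_raw != as.raw(0L)][seq_len(min(40L, size))])
  if (grepl("^\\s*solid", lead)) return("stl-ascii")
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") return("obj")
  txt <- tryCatch(readLines(path, n = 50L, warn = FALSE),
                  error = function(e) character(0))
  if (any(grepl("^v\\s", txt)) || any(grepl("^f\\s", txt))) return("obj")
  stop("cannot detect mesh format of ", path,
       " (not binary STL, ASCII STL, or OBJ)")
}

read_stl_binary <- function(path, drop_degenerate) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80L)
  n_tri <- readBin(con, "integer", size = 4L, endian = "little")
  if (is.na(n_tri) || n_tri < 0L) stop("malformed binary STL header (byte 81)")
  # 12 floats per facet (normal + 3 vertices) + 2-byte attribute count
  rec <- readBin(con, "raw", n = 50L * n_tri)
  if (length(rec) != 50L * n_tri) {
    stop("binary STL truncated at byte ", 84L + length(rec))
  }
  rec <- matrix(rec, nrow = 50L)
  floats <- readBin(as.vector(rec[1:48, ]), "double", size = 4L,
                    n = 12L * n_tri, endian = "little")
  floats <- matrix(floats, nrow = 12L)          # cols = facets
  verts <- t(matrix(floats[4:12, ], nrow = 3L)) # 3 verts per facet, rowwise
  if (!all(is.finite(verts))) stop("non-finite coordinate in binary STL")
  faces <- matrix(seq_len(3L * n_tri), ncol = 3L, byrow = TRUE)
  mg <- merge_vertices(verts, faces)
  triangle_mesh(mg$vertices, mg$faces,
                name = sub("\\s+$", "", rawToChar(header[header != as.raw(0)])),
                source_format = "stl-binary", drop_degenerate = drop_degenerate)
}

read_stl_ascii <- function(path, drop_degenerate) {
  lines <- readLines(path, warn = FALSE)
  vtx_idx <- grep("^\\s*vertex\\s", lines)
  if (length(vtx_idx) == 0L || length(vtx_idx) %% 3L != 0L) {
    stop("malformed ASCII STL: ", length(vtx_idx),
         " vertex lines (not a multiple of 3)")
  }
  coords <- t(vapply(strsplit(trimws(lines[vtx_idx]), "\\s+"), function(p) {
    v <- suppressWarnings(as.numeric(p[2:4]))
    v
  }, numeric(3L)))
  bad <- which(!stats::complete.cases(coords))
  if (length(bad)) {
    stop("malformed vertex line ", vtx_idx[bad[1L]], " in ", path)
  }
  name <- sub("^\\s*solid\\s*", "", lines[grep("^\\s*solid", lines)[1L]])
  faces <- matrix(seq_len(nrow(coords)), ncol = 3L, byrow = TRUE)
  mg <- merge_vertices(coords, faces)
  triangle_mesh(mg$vertices, mg$faces, name = trimws(name),
                source_format = "stl-ascii", drop_degenerate = drop_degenerate)
}

read_obj <- function(path, drop_degenerate) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  verts <- t(vapply(strsplit(trimws(vl), "\\s+"), function(p) {
    suppressWarnings(as.numeric(p[2:4]))
  }, numeric(3L)))
  if (nrow(verts) == 0L) stop("OBJ has no vertex records: ", path)
  bad <- which(!stats::complete.cases(verts))
  if (length(bad)) stop("malformed OBJ vertex line (v #", bad[1L], ")")
  fl <- grep("^f\\s", lines, value = TRUE)
  face_list <- lapply(seq_along(fl), function(i) {
    toks <- strsplit(trimws(fl[i]), "\\s+")[[1L]][-1L]
    idx <- suppressWarnings(as.integer(sub("/.*$", "", toks)))
    if (anyNA(idx) || length(idx) < 3L) {
      stop("malformed OBJ face line (f #", i, ")")
    }
    idx[idx < 0L] <- nrow(verts) + 1L + idx[idx < 0L]  # negative = relative
    # fan triangulation around the first vertex
    if (length(idx) == 3L) matrix(idx, 1L, 3L)
    else cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  })
  faces <- do.call(rbind, face_list)
  if (is.null(faces)) faces <- matrix(integer(0), 0L, 3L)
  triangle_mesh(verts, faces, name = basename(path), source_format = "obj",
                drop_degenerate = drop_degenerate)
}

#' Write a triangle mesh to STL or OBJ
#'
#' Binary STL is written with the canonical layout: 80-byte header, 32-bit
#' little-endian triangle count, then one 50-byte record per facet (12
#' little-endian 32-bit floats: normal then three vertices, plus a zero
#' attribute byte count), so a 12-face mesh produces exactly 684 bytes.
#' Reading the file back reproduces the faces and vertices up to 32-bit float
#' rounding; OBJ round-trips exactly at the default 17 significant digits.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format `"stl-binary"`, `"stl-ascii"` or `"obj"`; defaults from the
#'   file extension (`.obj` or `.stl`, the latter binary).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path,
                       format = c("auto", "stl-binary", "stl-ascii", "obj")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "obj") "obj" else "stl-binary"
  }
  if (nrow(mesh$faces) == 0L) stop("refusing to write an empty mesh")
  switch(format,
    "stl-binary" = write_stl_binary(mesh, path),
    "stl-ascii"  = write_stl_ascii(mesh, path),
    "obj"        = write_obj(mesh, path)
  )
  invisible(path)
}

face_corners <- function(mesh) {
  f <- mesh$faces
  list(v0 = mesh$vertices[f[, 1L], , drop = FALSE],
       v1 = mesh$vertices[f[, 2L], , drop = FALSE],
       v2 = mesh$vertices[f[, 3L], , drop = FALSE])
}

cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

face_normals <- function(mesh) {
  co <- face_corners(mesh)
  n <- cross3(co$v1 - co$v0, co$v2 - co$v0)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", substr(mesh$name, 1L, 79L)))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4L, endian = "little")
  co <- face_corners(mesh)
  nrm <- face_normals(mesh)
  block <- cbind(nrm, co$v0, co$v1, co$v2)   # 12 floats per facet
  zero2 <- as.raw(c(0L, 0L))
  for (i in seq_len(nrow(block))) {
    writeBin(block[i, ], con, size = 4L, endian = "little")
    writeBin(zero2, con)
  }
}

write_stl_ascii <- function(mesh, path) {
  co <- face_corners(mesh)
  nrm <- face_normals(mesh)
  fmt_v <- function(v) sprintf("      vertex %.9g %.9g %.9g",
                               v[, 1L], v[, 2L], v[, 3L])
  out <- c(
    paste0("solid ", mesh$name),
    as.vector(rbind(
      sprintf("  facet normal %.9g %.9g %.9g",
              nrm[, 1L], nrm[, 2L], nrm[, 3L]),
      "    outer loop",
      fmt_v(co$v0), fmt_v(co$v1), fmt_v(co$v2),
      "    endloop",
      "  endfacet")),
    paste0("endsolid ", mesh$name)
  )
  writeLines(out, path)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  out <- c(
    paste0("# ", mesh$name),
    sprintf("v %.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]),
    sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L])
  )
  writeLines(out, path)
}
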