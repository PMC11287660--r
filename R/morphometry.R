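#' Total surface area of a triangle mesh
#'
#' Sum over faces of half the cross-product magnitude,
#' \eqn{\frac{1}{2}\lVert (v_1-v_0)\times(v_2-v_0)\rVert}. Independent of
#' vertex ordering and rigid motion; degenerate faces contribute zero.
#'
#' @param mesh a [triangle_mesh()] with coordinates in micrometres.
#' @return Surface area in square micrometres.
#' @examples
#' surface_area(make_icosphere(5, 4))  # ~ 4 * pi * 25
#' @export
surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  co <- face_corners(mesh)
  sum(sqrt(rowSums(cross3(co$v1 - co$v0, co$v2 - co$v0)^2))) / 2
}

#' Enclosed volume (biovolume) of a watertight mesh
#'
#' Signed-tetrahedron sum from the divergence theorem,
#' \eqn{\lvert\sum_f v_0\cdot(v_1\times v_2)\rvert / 6}, which is
#' translation-invariant for closed meshes. The absolute value is taken at
#' the end so a globally inverted mesh (inward normals, common in STL files
#' found in the wild) still yields a positive volume. The mesh must be
#' watertight; if face windings are inconsistent the per-face signs disagree
#' and the sum is meaningless, so this errors unless `fix_orientation = TRUE`
#' repairs the winding first.
#'
#' @param mesh a [triangle_mesh()] with coordinates in micrometres.
#' @param fix_orientation repair inconsistent face windings (by flood-filling
#'   a consistent orientation across edge-adjacent faces) before integrating.
#' @return Enclosed volume in cubic micrometres.
#' @examples
#' biovolume(make_icosphere(5, 4))  # ~ (4/3) * pi * 125
#' @export
biovolume <- function(mesh, fix_orientation = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  qc <- check_watertight(mesh)
  if (!qc$watertight) {
    stop("mesh is not watertight: ", qc$boundary_edges,
         " boundary edge(s); volume is undefined")
  }
  if (!qc$consistently_oriented) {
    if (!fix_orientation) {
      stop("mesh has inconsistently oriented faces; ",
           "rerun with fix_orientation = TRUE")
    }
    mesh <- orient_faces(mesh)
  }
  co <- face_corners(mesh)
  abs(sum(rowSums(co$v0 * cross3(co$v1, co$v2)))) / 6
}

#' Spherical equivalent diameters
#'
#' The diameter of the sphere with the same surface area,
#' \eqn{d_{ESA} = \sqrt{SA/\pi}}, and of the sphere with the same volume,
#' \eqn{d_{ESV} = (6V/\pi)^{1/3}}. By the isoperimetric inequality
#' \eqn{d_{ESA} \ge d_{ESV}}, with equality only for a perfect sphere; the
#' gap between the two is a simple shape-elongation signal.
#'
#' @param surface_area surface area in square micrometres (> 0).
#' @param biovolume volume in cubic micrometres (> 0).
#' @return A tibble with columns `d_esa` and `d_esv` (micrometres).
#' @examples
#' equivalent_diameters(2341.26, 8714.20)  # P. micans-scale model
#' @export
equivalent_diameters <- function(surface_area, biovolume) {
  if (any(surface_area <= 0) || any(biovolume <= 0)) {
    stop("surface_area and biovolume must be positive")
  }
  tibble::tibble(d_esa = sqrt(surface_area / pi),
                 d_esv = (6 * biovolume / pi)^(1 / 3))
}

# Covariance of the uniform measure on the mesh surface: exact per-triangle
# second moments, area-weighted. Robust to non-uniform tessellation (a
# refined patch does not drag the axes the way lumped vertex weights would).
surface_covariance <- function(mesh) {
  co <- face_corners(mesh)
  fa <- sqrt(rowSums(cross3(co$v1 - co$v0, co$v2 - co$v0)^2)) / 2
  a_tot <- sum(fa)
  s <- co$v0 + co$v1 + co$v2
  ctr <- colSums(fa * s / 3) / a_tot
  m2 <- matrix(0, 3L, 3L)
  # E[x x^T] over a triangle = (sum v_i v_i^T + s s^T) / 12
  for (v in list(co$v0, co$v1, co$v2)) m2 <- m2 + crossprod(v * sqrt(fa))
  m2 <- (m2 + crossprod(s * sqrt(fa))) / 12 / a_tot
  list(center = ctr, cov = m2 - tcrossprod(ctr), area = a_tot)
}

#' Principal extents of a mesh (length, width, depth)
#'
#' Extents of the mesh along the three orthogonal principal axes of the
#' surface covariance (the covariance of the uniform measure on the
#' triangulated surface, computed from exact per-triangle moments), sorted
#' descending so length >= width >= depth. Rotation-invariant and robust to
#' non-uniform tessellation. `method = "aabb"` instead returns the
#' axis-aligned bounding-box extents of the mesh as stored, for comparison
#' with tools that measure the as-exported orientation.
#'
#' @param mesh a [triangle_mesh()].
#' @param method `"principal"` (default) or `"aabb"`.
#' @return A tibble with columns `length`, `width`, `depth` (micrometres).
#' @export
principal_extents <- function(mesh, method = c("principal", "aabb")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  method <- match.arg(method)
  v <- mesh$vertices
  if (method == "aabb") {
    ext <- sort(apply(v, 2L, function(x) diff(range(x))), decreasing = TRUE)
  } else {
    if (nrow(v) < 4L) stop("need at least 4 vertices")
    sc <- surface_covariance(mesh)
    eg <- eigen(sc$cov, symmetric = TRUE)
    if (eg$values[3L] / max(eg$values[1L], .Machine$double.eps) < 1e-12) {
      stop("degenerate (flat or collinear) vertex cloud")
    }
    d <- sweep(v, 2L, sc$center)
    proj <- d %*% eg$vectors
    ext <- apply(proj, 2L, function(x) diff(range(x)))
    # deterministic ordering: by extent, ties by axis-vector lexicographic order
    ord <- order(-ext, apply(eg$vectors, 2L, paste, collapse = ","))
    ext <- ext[ord]
  }
  tibble::tibble(length = ext[1L], width = ext[2L], depth = ext[3L])
}

# Directed edge table: one row per face half-edge (3m rows), columns a, b.
directed_edges <- function(faces) {
  rbind(cbind(faces[, 1L], faces[, 2L]),
        cbind(faces[, 2L], faces[, 3L]),
        cbind(faces[, 3L], faces[, 1L]))
}

#' Watertightness and orientation check
#'
#' A mesh is watertight (closed 2-manifold, hence sliceable for 3D printing
#' and valid for volume integration) when every undirected edge is shared by
#' exactly two faces; it is consistently oriented when each such edge is
#' traversed once in each direction by its two faces. Boundary edges are
#' undirected edges used by exactly one face.
#'
#' @param mesh a [triangle_mesh()].
#' @return A tibble with logical columns `watertight`,
#'   `consistently_oriented` and integer `boundary_edges`.
#' @examples
#' check_watertight(make_icosphere(2, 1))
#' @export
check_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  de <- directed_edges(mesh$faces)
  lo <- pmin(de[, 1L], de[, 2L])
  hi <- pmax(de[, 1L], de[, 2L])
  und_key <- paste(lo, hi)
  und_n <- table(und_key)
  watertight <- length(und_n) > 0L && all(und_n == 2L)
  boundary <- sum(und_n == 1L)
  # consistent orientation: no directed edge repeated, and every 2-shared
  # undirected edge is covered once per direction
  dir_key <- paste(de[, 1L], de[, 2L])
  oriented <- !anyDuplicated(dir_key) && all(und_n[und_n == 2L] == 2L)
  tibble::tibble(watertight = watertight,
                 consistently_oriented = as.logical(oriented),
                 boundary_edges = as.integer(boundary))
}

# Flood-fill a consistent winding over edge-adjacent faces, then flip the
# whole mesh if the signed volume came out negative.
orient_faces <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  und <- cbind(pmin(directed_edges(f)[, 1L], directed_edges(f)[, 2L]),
               pmax(directed_edges(f)[, 1L], directed_edges(f)[, 2L]))
  key <- paste(und[, 1L], und[, 2L])
  face_of <- rep(seq_len(m), 3L)
  adj <- split(face_of, key)
  neighbours <- vector("list", m)
  for (pair in adj) {
    if (length(pair) == 2L) {
      neighbours[[pair[1L]]] <- c(neighbours[[pair[1L]]], pair[2L])
      neighbours[[pair[2L]]] <- c(neighbours[[pair[2L]]], pair[1L])
    }
  }
  dir_edges_of <- function(tri) {
    rbind(tri[c(1L, 2L)], tri[c(2L, 3L)], tri[c(3L, 1L)])
  }
  visited <- rep(FALSE, m)
  for (seed in seq_len(m)) {
    if (visited[seed]) next
    visited[seed] <- TRUE
    queue <- seed
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      ei <- dir_edges_of(f[i, ])
      for (j in neighbours[[i]]) {
        if (visited[j]) next
        ej <- dir_edges_of(f[j, ])
        # consistent neighbours traverse the shared edge in opposite directions
        same_dir <- any(paste(ei[, 1L], ei[, 2L]) %in%
                          paste(ej[, 1L], ej[, 2L]))
        if (same_dir) f[j, ] <- f[j, c(1L, 3L, 2L)]
        visited[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  mesh$faces <- f
  mesh
}

#' Full morphometric report for a mesh
#'
#' One-stop summary of the quantities used to characterise phytoplankton
#' cell size and morphology: surface area, biovolume, principal extents,
#' spherical equivalent diameters, surface-to-volume ratio and the
#' watertightness/orientation QC flags. Returns a one-row tibble so reports
#' for many models stack with `dplyr::bind_rows()`.
#'
#' @param mesh a [triangle_mesh()] with coordinates in micrometres.
#' @param fix_orientation passed to [biovolume()].
#' @param extents_method passed to [principal_extents()].
#' @return A one-row tibble of class `morphometry_report` with columns
#'   `name`, `n_vertices`, `n_faces`, `surface_area` (um^2), `biovolume`
#'   (um^3), `length`, `width`, `depth`, `d_esa`, `d_esv` (um), `sa_to_v`
#'   (1/um), `watertight`, `consistently_oriented`, `boundary_edges`.
#'   Non-watertight meshes get `NA` for volume-derived columns.
#' @examples
#' mesh_morphometry(make_icosphere(5, 3))
#' @export
mesh_morphometry <- function(mesh, fix_orientation = FALSE,
                             extents_method = "principal") {
  stopifnot(inherits(mesh, "triangle_mesh"))
  qc <- check_watertight(mesh)
  sa <- surface_area(mesh)
  vol <- if (qc$watertight && (qc$consistently_oriented || fix_orientation)) {
    biovolume(mesh, fix_orientation = fix_orientation)
  } else {
    NA_real_
  }
  ext <- principal_extents(mesh, method = extents_method)
  eq <- if (is.na(vol)) {
    tibble::tibble(d_esa = sqrt(sa / pi), d_esv = NA_real_)
  } else {
    equivalent_diameters(sa, vol)
  }
  out <- tibble::tibble(
    name = mesh$name,
    n_vertices = nrow(mesh$vertices),
    n_faces = nrow(mesh$faces),
    surface_area = sa,
    biovolume = vol,
    length = ext$length, width = ext$width, depth = ext$depth,
    d_esa = eq$d_esa, d_esv = eq$d_esv,
    sa_to_v = sa / vol,
    watertight = qc$watertight,
    consistently_oriented = qc$consistently_oriented,
    boundary_edges = qc$boundary_edges
  )
  class(out) <- c("morphometry_report", class(out))
  out
}
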