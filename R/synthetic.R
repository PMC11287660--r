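# Evaluate fn with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Icosphere mesh
#'
#' Recursively subdivided icosahedron with every vertex projected onto the
#' sphere of the requested radius: `20 * 4^subdivisions` faces, watertight
#' and consistently oriented. The workhorse fixture: its surface area and
#' volume converge monotonically from below to \eqn{4\pi r^2} and
#' \eqn{\frac{4}{3}\pi r^3} as subdivision increases.
#'
#' @param radius sphere radius in micrometres.
#' @param subdivisions subdivision level, 0 (icosahedron) to 7.
#' @return A [triangle_mesh()].
#' @examples
#' make_icosphere(5, 0)  # 12 vertices, 20 faces
#' @export
make_icosphere <- function(radius, subdivisions = 3L) {
  stopifnot(radius > 0, subdivisions >= 0L, subdivisions <= 7L)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  normalize <- function(m) m * (radius / sqrt(rowSums(m^2)))
  v <- normalize(v)
  for (lev in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_id <- new.env(hash = TRUE)
    mid_list <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_id[[key]]
      if (is.null(id)) {
        id <- nv + length(mid_list) + 1L
        mid_list[[length(mid_list) + 1L]] <<- (v[i, ] + v[j, ]) / 2
        edge_id[[key]] <- id
      }
      id
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; c_ <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[(4L * k - 3L):(4L * k), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, normalize(do.call(rbind, mid_list)))
    f <- newf
  }
  triangle_mesh(v, f, name = sprintf("icosphere_r%g_s%d", radius, subdivisions))
}

# Radius profile r(z) on [0, L] for a solid of revolution about z.
revolution_profile <- function(shape) {
  d <- shape$dims
  switch(shape$kind,
    sphere = list(L = 2 * d$r,
                  r = function(z) sqrt(pmax(0, d$r^2 - (z - d$r)^2))),
    prolate_spheroid = ,
    oblate_spheroid = list(
      L = 2 * d$c,
      r = function(z) d$a * sqrt(pmax(0, 1 - ((z - d$c) / d$c)^2))),
    capsule = list(
      L = d$h + 2 * d$r,
      r = function(z) {
        out <- rep(d$r, length(z))
        lo <- z < d$r
        hi <- z > d$r + d$h
        out[lo] <- sqrt(pmax(0, d$r^2 - (d$r - z[lo])^2))
        out[hi] <- sqrt(pmax(0, d$r^2 - (z[hi] - d$r - d$h)^2))
        out
      }),
    drop_of_revolution = list(L = d$length, r = d$profile),
    stop("shape kind ", shape$kind, " is not a solid of revolution")
  )
}

#' Surface-of-revolution mesh
#'
#' Tessellates a solid of revolution (sphere, spheroid, capsule or
#' [drop_profile()]) about the z axis: `n_z` rings of `n_theta` vertices with
#' triangle-fan caps at the poles, so the result is always watertight and
#' consistently oriented. z samples cluster near the poles (cosine spacing)
#' so curvature there is resolved and morphometry converges to the
#' [shape_surface_area()] / [shape_volume()] closed forms as resolution
#' grows. Optional vertex jitter along the surface normal emulates
#' biological variability while staying watertight.
#'
#' @param shape a `geometric_shape` that is a solid of revolution.
#' @param n_theta vertices per ring (>= 8).
#' @param n_z number of z levels including poles (>= 4).
#' @param jitter relative jitter amplitude (fraction of the local radius,
#'   <= 0.01 recommended); 0 disables.
#' @param seed RNG seed for the jitter.
#' @return A [triangle_mesh()].
#' @examples
#' m <- make_revolution(shape_capsule(2, 10), n_theta = 64, n_z = 48)
#' biovolume(m)  # ~ pi * 4 * 10 + (4/3) * pi * 8
#' @export
make_revolution <- function(shape, n_theta = 128L, n_z = 96L,
                            jitter = 0, seed = 0L) {
  stopifnot(inherits(shape, "geometric_shape"), n_theta >= 8L, n_z >= 4L)
  pr <- revolution_profile(shape)
  z <- pr$L / 2 * (1 - cos(pi * seq(0, 1, length.out = n_z)))
  r <- pr$r(z)
  inner <- which(r > 0 & z > 0 & z < pr$L)
  theta <- 2 * pi * seq(0L, n_theta - 1L) / n_theta
  rings <- length(inner)
  v <- matrix(0, rings * n_theta + 2L, 3L)
  for (i in seq_len(rings)) {
    idx <- (i - 1L) * n_theta + seq_len(n_theta)
    v[idx, ] <- cbind(r[inner[i]] * cos(theta), r[inner[i]] * sin(theta),
                      z[inner[i]])
  }
  south <- rings * n_theta + 1L   # z = 0 pole
  north <- rings * n_theta + 2L   # z = L pole
  v[south, ] <- c(0, 0, 0)
  v[north, ] <- c(0, 0, pr$L)
  ring_idx <- function(i) (i - 1L) * n_theta + seq_len(n_theta)
  nxt <- c(seq_len(n_theta)[-1L], 1L)
  faces <- vector("list", rings + 1L)
  # south fan: outward normal points to -z, so wind clockwise seen from +z
  faces[[1L]] <- cbind(south, ring_idx(1L)[nxt], ring_idx(1L))
  for (i in seq_len(rings - 1L)) {
    a <- ring_idx(i); b <- ring_idx(i + 1L)
    faces[[i + 1L]] <- rbind(cbind(a, a[nxt], b[nxt]), cbind(a, b[nxt], b))
  }
  faces[[rings + 1L]] <- cbind(north, ring_idx(rings), ring_idx(rings)[nxt])
  mesh <- triangle_mesh(v, do.call(rbind, faces),
                        name = paste0(shape$kind, "_revolution"))
  if (jitter > 0) {
    mesh <- with_local_seed(seed, function() {
      nrm <- vertex_normals(mesh)
      amp <- stats::runif(nrow(mesh$vertices), -jitter, jitter) *
        max(shape_extent(shape)) / 2
      mesh$vertices <- mesh$vertices + nrm * amp
      mesh
    })
  }
  mesh
}

shape_extent <- function(shape) {
  pr <- try(revolution_profile(shape), silent = TRUE)
  if (inherits(pr, "try-error")) return(unlist(shape$dims))
  c(pr$L, 2 * max(pr$r(seq(0, pr$L, length.out = 257L))))
}

# Area-weighted vertex normals (mean of incident face normals).
vertex_normals <- function(mesh) {
  co <- face_corners(mesh)
  fn <- cross3(co$v1 - co$v0, co$v2 - co$v0)  # area-weighted
  n <- matrix(0, nrow(mesh$vertices), 3L)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- tapply(fn[, k], mesh$faces[, j], sum)
      idx <- as.integer(names(acc))
      n[idx, k] <- n[idx, k] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Plankton-like preset meshes
#'
#' Ready-made watertight surrogates at the scale of the two study organisms:
#' `"p-micans-like"` is a pyriform drop of revolution 40 um long and 25 um
#' wide (a Prorocentrum micans-scale dinoflagellate), `"halamphora-like"` a
#' prolate spheroid 16.27 um long and 3.94 um wide (an elongated
#' Halamphora-scale diatom).
#'
#' @param preset preset name.
#' @param n_theta,n_z tessellation resolution, passed to [make_revolution()].
#' @return A [triangle_mesh()].
#' @export
plankton_preset <- function(preset = c("p-micans-like", "halamphora-like"),
                            n_theta = 128L, n_z = 96L) {
  preset <- match.arg(preset)
  shape <- switch(preset,
    "p-micans-like" = drop_profile(length = 40, max_width = 25,
                                   shoulder = 0.5),
    "halamphora-like" = shape_prolate_spheroid(a = 1.97, c = 8.135)
  )
  mesh <- make_revolution(shape, n_theta = n_theta, n_z = n_z)
  mesh$name <- preset
  mesh
}

#' Synthetic SEM / render image pair
#'
#' Renders a shaded ellipse on a dark background as the "reference"
#' (SEM-like) image, then derives a "distorted" (render-like) partner by a
#' known monotone brightness transform plus optional Gaussian noise, clipped
#' to the bit depth. The true foreground mask is returned so masking and
#' histogram-matching accuracy can be scored against ground truth.
#' Deterministic for a given seed.
#'
#' @param width,height image size in pixels.
#' @param transform `"identity"` or `"gamma"` (with exponent `gamma`), the
#'   brightness map applied to the reference.
#' @param gamma gamma exponent when `transform = "gamma"`.
#' @param noise_sd Gaussian noise standard deviation in gray levels, added
#'   to the distorted image.
#' @param seed RNG seed.
#' @param bit_depth 8 or 16.
#' @return A list with [gray_image()] elements `reference` and `distorted`
#'   and a logical matrix `true_mask`.
#' @examples
#' pair <- make_image_pair(64, 48, transform = "gamma", gamma = 0.5)
#' @export
make_image_pair <- function(width = 256L, height = 192L,
                            transform = c("identity", "gamma"), gamma = 0.5,
                            noise_sd = 0, seed = 0L, bit_depth = 8L) {
  transform <- match.arg(transform)
  stopifnot(width >= 16L, height >= 16L, bit_depth %in% c(8L, 16L))
  maxv <- 2^bit_depth - 1
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  ax <- 0.35 * width; ay <- 0.30 * height
  rr <- sqrt(((xs - cx) / ax)^2 + ((ys - cy) / ay)^2)
  mask <- rr <= 1
  bg <- 0.08 * maxv
  # dome shading: bright at the centre, darker toward the rim
  fg <- (0.45 + 0.35 * sqrt(pmax(0, 1 - rr^2))) * maxv
  ref <- matrix(bg, height, width)
  ref[mask] <- fg[mask]
  ref <- round(ref)
  dist <- switch(transform,
    identity = ref,
    gamma = maxv * (ref / maxv)^gamma
  )
  if (noise_sd > 0) {
    dist <- with_local_seed(seed, function() {
      dist + stats::rnorm(length(dist), sd = noise_sd)
    })
  }
  dist <- matrix(pmin(maxv, pmax(0, round(dist))), height, width)
  list(reference = gray_image(ref, bit_depth),
       distorted = gray_image(dist, bit_depth),
       true_mask = mask)
}
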