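#' Closed-form geometric shape proxies
#'
#' Simple solids of the kind classically used to approximate phytoplankton
#' cell surface area and biovolume from length/width/depth measurements,
#' before realistic mesh models were available. All dimensions in
#' micrometres.
#'
#' @param r,a,b,c,h semi-axes / radius / height in micrometres. Spheroids
#'   take equatorial semi-axis `a` and polar semi-axis `c`; a prolate
#'   spheroid requires `c > a`, an oblate one `c < a`.
#' @return An object of class `geometric_shape`.
#' @name geometric_shape
#' @examples
#' shape_surface_area(shape_sphere(5))           # 100 * pi
#' shape_volume(shape_capsule(r = 2, h = 10))    # 159.174
NULL

new_shape <- function(kind, dims) {
  if (any(!is.finite(unlist(dims))) || any(unlist(dims) <= 0)) {
    stop("all shape dimensions must be positive and finite")
  }
  structure(list(kind = kind, dims = dims), class = "geometric_shape")
}

#' @rdname geometric_shape
#' @export
shape_sphere <- function(r) new_shape("sphere", list(r = r))

#' @rdname geometric_shape
#' @export
shape_prolate_spheroid <- function(a, c) {
  if (c <= a) stop("prolate spheroid requires polar semi-axis c > a")
  new_shape("prolate_spheroid", list(a = a, c = c))
}

#' @rdname geometric_shape
#' @export
shape_oblate_spheroid <- function(a, c) {
  if (c >= a) stop("oblate spheroid requires polar semi-axis c < a")
  new_shape("oblate_spheroid", list(a = a, c = c))
}

#' @rdname geometric_shape
#' @export
shape_ellipsoid <- function(a, b, c) {
  new_shape("general_ellipsoid", list(a = a, b = b, c = c))
}

#' @rdname geometric_shape
#' @export
shape_capsule <- function(r, h) new_shape("capsule", list(r = r, h = h))

#' @rdname geometric_shape
#' @export
shape_cylinder <- function(r, h) new_shape("cylinder", list(r = r, h = h))

#' @export
print.geometric_shape <- function(x, ...) {
  cat(sprintf("<geometric_shape> %s (%s um)\n", x$kind,
              paste(names(x$dims), unlist(x$dims), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Pyriform drop of revolution
#'
#' A smooth solid of revolution emulating a pear/drop-shaped (pyriform)
#' dinoflagellate cell: rounded at the anterior end, widest at
#' `shoulder * length` from the anterior, tapering smoothly to a point
#' posteriorly. The radius profile is a quarter-ellipse from the anterior
#' pole to the shoulder joined C1-continuously to a cosine taper
#' \eqn{r(z) = (W/2)\cos(\pi t/2)}, \eqn{t = (z - z_0)/(L - z_0)}, chosen so
#' the posterior slope is finite (a true point, not a second rounded cap).
#'
#' @param length total length L in micrometres.
#' @param max_width maximum diameter W in micrometres.
#' @param shoulder position of the widest point as a fraction of length,
#'   strictly between 0 and 1.
#' @return A `geometric_shape` of kind `drop_of_revolution` whose
#'   `dims$profile` is the radius function r(z) on `[0, length]`.
#' @examples
#' d <- drop_profile(40, 25, 0.5)  # P. micans-scale drop
#' shape_volume(d)
#' @export
drop_profile <- function(length, max_width, shoulder = 0.5) {
  if (shoulder <= 0 || shoulder >= 1) stop("shoulder must be in (0, 1)")
  if (length <= 0 || max_width <= 0) stop("dimensions must be positive")
  z0 <- shoulder * length
  w2 <- max_width / 2
  profile <- function(z) {
    r <- numeric(base::length(z))
    ant <- z >= 0 & z <= z0
    post <- z > z0 & z <= length
    r[ant] <- w2 * sqrt(pmax(0, 1 - ((z0 - z[ant]) / z0)^2))
    r[post] <- w2 * cos(pi / 2 * (z[post] - z0) / (length - z0))
    r
  }
  s <- new_shape("drop_of_revolution",
                 list(length = length, max_width = max_width,
                      shoulder = shoulder))
  s$dims$profile <- profile
  s
}

#' Surface area of a geometric shape
#'
#' Closed forms: sphere \eqn{4\pi r^2}; prolate spheroid
#' \eqn{2\pi a^2(1 + \frac{c}{ae}\arcsin e)} with
#' \eqn{e=\sqrt{1-a^2/c^2}}; oblate spheroid
#' \eqn{2\pi a^2 + \frac{\pi c^2}{e}\ln\frac{1+e}{1-e}} with
#' \eqn{e=\sqrt{1-c^2/a^2}}; general ellipsoid by the Thomsen approximation
#' \eqn{4\pi\left(\frac{a^pb^p + a^pc^p + b^pc^p}{3}\right)^{1/p}},
#' \eqn{p = 1.6075} (relative error below 1.1 percent); capsule
#' \eqn{2\pi rh + 4\pi r^2}; cylinder \eqn{2\pi r(r+h)}; drop of revolution
#' by quadrature of \eqn{2\pi\int r\sqrt{1+r'^2}\,dz}.
#'
#' @param shape a `geometric_shape`.
#' @return Surface area in square micrometres.
#' @export
shape_surface_area <- function(shape) {
  stopifnot(inherits(shape, "geometric_shape"))
  d <- shape$dims
  switch(shape$kind,
    sphere = 4 * pi * d$r^2,
    prolate_spheroid = {
      e <- sqrt(1 - d$a^2 / d$c^2)
      2 * pi * d$a^2 * (1 + (d$c / (d$a * e)) * asin(e))
    },
    oblate_spheroid = {
      e <- sqrt(1 - d$c^2 / d$a^2)
      2 * pi * d$a^2 + (pi * d$c^2 / e) * log((1 + e) / (1 - e))
    },
    general_ellipsoid = {
      p <- 1.6075
      4 * pi * ((d$a^p * d$b^p + d$a^p * d$c^p + d$b^p * d$c^p) / 3)^(1 / p)
    },
    capsule = 2 * pi * d$r * d$h + 4 * pi * d$r^2,
    cylinder = 2 * pi * d$r * (d$r + d$h),
    drop_of_revolution = {
      r <- d$profile
      eps <- d$length * 1e-7
      drdz <- function(z) (r(pmin(z + eps, d$length)) - r(pmax(z - eps, 0))) /
        (pmin(z + eps, d$length) - pmax(z - eps, 0))
      f <- function(z) 2 * pi * r(z) * sqrt(1 + drdz(z)^2)
      stats::integrate(f, 0, d$length, subdivisions = 500L,
                       rel.tol = 1e-8)$value
    },
    stop("unknown shape kind: ", shape$kind)
  )
}

#' Volume of a geometric shape
#'
#' Closed forms: sphere \eqn{\frac{4}{3}\pi r^3}; spheroids and ellipsoids
#' \eqn{\frac{4}{3}\pi abc}; capsule \eqn{\pi r^2h + \frac{4}{3}\pi r^3};
#' cylinder \eqn{\pi r^2 h}; drop of revolution by quadrature of
#' \eqn{\pi\int r(z)^2\,dz}.
#'
#' @param shape a `geometric_shape`.
#' @return Volume in cubic micrometres.
#' @export
shape_volume <- function(shape) {
  stopifnot(inherits(shape, "geometric_shape"))
  d <- shape$dims
  switch(shape$kind,
    sphere = 4 / 3 * pi * d$r^3,
    prolate_spheroid = 4 / 3 * pi * d$a^2 * d$c,
    oblate_spheroid = 4 / 3 * pi * d$a^2 * d$c,
    general_ellipsoid = 4 / 3 * pi * d$a * d$b * d$c,
    capsule = pi * d$r^2 * d$h + 4 / 3 * pi * d$r^3,
    cylinder = pi * d$r^2 * d$h,
    drop_of_revolution = stats::integrate(
      function(z) pi * d$profile(z)^2, 0, d$length,
      subdivisions = 500L, rel.tol = 1e-10)$value,
    stop("unknown shape kind: ", shape$kind)
  )
}
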