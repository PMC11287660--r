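#' Scattering configuration
#'
#' Optical parameters for the homogeneous-sphere (Lorenz-Mie) baselines.
#' Defaults follow the values commonly used for phytoplankton: a vacuum
#' wavelength of 0.532 um (green laser) and a relative refractive index of
#' 1.05 + 0.01i. The index is taken as relative to the surrounding medium
#' exactly as given; set `medium_index` to divide the wavelength for
#' in-water wavenumbers.
#'
#' @param diameter sphere diameter in micrometres.
#' @param wavelength wavelength in micrometres.
#' @param refractive_index complex relative refractive index, `Im >= 0`.
#' @param n_angles number of scattering angles, equally spaced on
#'   `[0, 180]` degrees inclusive.
#' @param medium_index real index of the surrounding medium; the effective
#'   wavelength is `wavelength / medium_index`.
#' @return An object of class `scattering_config`.
#' @export
scattering_config <- function(diameter, wavelength = 0.532,
                              refractive_index = complex(real = 1.05,
                                                         imaginary = 0.01),
                              n_angles = 181L, medium_index = 1) {
  stopifnot(diameter > 0, wavelength > 0, n_angles >= 2L, medium_index >= 1)
  refractive_index <- as.complex(refractive_index)
  if (Im(refractive_index) < 0) {
    stop("imaginary part of the refractive index must be >= 0 (absorption)")
  }
  structure(list(diameter = diameter, wavelength = wavelength,
                 refractive_index = refractive_index,
                 n_angles = as.integer(n_angles),
                 medium_index = medium_index),
            class = "scattering_config")
}

#' Lorenz-Mie scattering coefficients
#'
#' The partial-wave coefficients a_n, b_n for a homogeneous sphere of size
#' parameter \eqn{x = \pi d/\lambda} and relative index m, computed from
#' Riccati-Bessel functions with the logarithmic derivative obtained by
#' downward recurrence (stable for absorbing indices). The series is
#' truncated at the Wiscombe criterion
#' \eqn{N = \lceil x + 4x^{1/3} + 2\rceil}.
#'
#' @param x size parameter (> 0).
#' @param m complex relative refractive index.
#' @param n_max_cap guard on the series length; exceeding it errors rather
#'   than silently truncating.
#' @return A list with complex vectors `a`, `b` of length N and the
#'   efficiencies `q_sca`, `q_ext` (dimensionless).
#' @examples
#' mie_coefficients(1, 1.05 + 0.01i)$q_ext
#' @export
mie_coefficients <- function(x, m, n_max_cap = 20000L) {
  stopifnot(x > 0)
  m <- as.complex(m)
  n_stop <- ceiling(x + 4 * x^(1 / 3) + 2)
  if (n_stop > n_max_cap) {
    stop("size parameter x = ", x, " needs ", n_stop,
         " terms; raise n_max_cap (currently ", n_max_cap, ")")
  }
  mx <- m * x
  n_d <- max(n_stop, ceiling(Mod(mx))) + 16L
  # logarithmic derivative D_n(mx) by downward recurrence
  d <- complex(n_d + 1L)       # d[k] holds D_{k-1}
  for (n in n_d:1L) {
    d[n] <- n / mx - 1 / (d[n + 1L] + n / mx)
  }
  n <- seq_len(n_stop)
  # Riccati-Bessel psi_n = x j_n(x), chi_n = -x y_n(x), upward recurrence
  psi <- numeric(n_stop + 2L)  # psi[k] = psi_{k-2}: psi_{-1}, psi_0, ...
  chi <- numeric(n_stop + 2L)
  psi[1L] <- cos(x); psi[2L] <- sin(x)
  chi[1L] <- -sin(x); chi[2L] <- cos(x)
  for (k in seq_len(n_stop)) {
    psi[k + 2L] <- (2 * k - 1) / x * psi[k + 1L] - psi[k]
    chi[k + 2L] <- (2 * k - 1) / x * chi[k + 1L] - chi[k]
  }
  psi_n <- psi[n + 2L]; psi_nm1 <- psi[n + 1L]
  xi_n <- complex(real = psi_n, imaginary = -chi[n + 2L])
  xi_nm1 <- complex(real = psi_nm1, imaginary = -chi[n + 1L])
  dn <- d[n + 1L]
  fa <- dn / m + n / x
  fb <- dn * m + n / x
  a <- (fa * psi_n - psi_nm1) / (fa * xi_n - xi_nm1)
  b <- (fb * psi_n - psi_nm1) / (fb * xi_n - xi_nm1)
  two_n1 <- 2 * n + 1
  list(a = a, b = b,
       q_sca = 2 / x^2 * sum(two_n1 * (Mod(a)^2 + Mod(b)^2)),
       q_ext = 2 / x^2 * sum(two_n1 * Re(a + b)),
       n_terms = n_stop)
}

# Angular functions pi_n(mu), tau_n(mu) for all n up to n_max at one mu.
mie_pi_tau <- function(mu, n_max) {
  p <- numeric(n_max)
  t <- numeric(n_max)
  p[1L] <- 1
  t[1L] <- mu
  if (n_max >= 2L) {
    p[2L] <- 3 * mu
    t[2L] <- 2 * mu * p[2L] - 3 * p[1L]
    for (n in 3:n_max) {
      p[n] <- ((2 * n - 1) * mu * p[n - 1L] - n * p[n - 2L]) / (n - 1)
      t[n] <- n * mu * p[n] - (n + 1) * p[n - 1L]
    }
  }
  list(pi_n = p, tau_n = t)
}

#' Angular differential scattering cross sections of a sphere
#'
#' Computes the scattering amplitudes S1 (perpendicular) and S2 (parallel)
#' on the configured angle grid and from them the differential scattering
#' cross sections \eqn{|S_2|^2/k^2} (HH, parallel polarisation — the
#' primary output), \eqn{|S_1|^2/k^2} (VV) and their unpolarised mean,
#' with \eqn{k = 2\pi/\lambda}; plus the total scattering cross section
#' from the partial-wave series and the backscattering cross section, the
#' unpolarised DSCS integrated over the backward hemisphere
#' (\eqn{\theta \in [90^\circ, 180^\circ]}) with solid-angle weighting by
#' the trapezoid rule on the angle grid.
#'
#' @param config a [scattering_config()].
#' @return A tibble of class `scattering_spectrum` with columns `angle`
#'   (degrees), `dscs_hh`, `dscs_vv`, `dscs_unpol` (um^2/sr), and
#'   attributes `q_sca`, `q_ext`, `c_sca`, `c_ext`, `c_bb` (um^2) and
#'   `config`.
#' @examples
#' sp <- angular_dscs(scattering_config(diameter = 25.53))
#' attr(sp, "c_bb") / attr(sp, "c_sca")
#' @export
angular_dscs <- function(config) {
  stopifnot(inherits(config, "scattering_config"))
  lambda <- config$wavelength / config$medium_index
  x <- pi * config$diameter / lambda
  k <- 2 * pi / lambda
  co <- mie_coefficients(x, config$refractive_index)
  n <- seq_len(co$n_terms)
  wt <- (2 * n + 1) / (n * (n + 1))
  angles <- seq(0, 180, length.out = config$n_angles)
  mu <- cos(angles * pi / 180)
  s1 <- complex(length(mu))
  s2 <- complex(length(mu))
  # pi_n/tau_n recurrence vectorised over the angle grid
  pi_prev <- numeric(length(mu))   # pi_0
  pi_cur <- rep(1, length(mu))     # pi_1
  for (n in seq_len(co$n_terms)) {
    tau_n <- n * mu * pi_cur - (n + 1) * pi_prev
    s1 <- s1 + wt[n] * (co$a[n] * pi_cur + co$b[n] * tau_n)
    s2 <- s2 + wt[n] * (co$a[n] * tau_n + co$b[n] * pi_cur)
    pi_next <- ((2 * n + 1) * mu * pi_cur - (n + 1) * pi_prev) / n
    pi_prev <- pi_cur
    pi_cur <- pi_next
  }
  dscs_hh <- Mod(s2)^2 / k^2
  dscs_vv <- Mod(s1)^2 / k^2
  dscs_unpol <- (dscs_hh + dscs_vv) / 2
  geom <- pi * (config$diameter / 2)^2
  c_sca <- co$q_sca * geom
  back <- angles >= 90
  th <- angles[back] * pi / 180
  integrand <- dscs_unpol[back] * 2 * pi * sin(th)
  c_bb <- sum(diff(th) * (utils::head(integrand, -1) +
                            utils::tail(integrand, -1)) / 2)
  out <- tibble::tibble(angle = angles, dscs_hh = dscs_hh,
                        dscs_vv = dscs_vv, dscs_unpol = dscs_unpol)
  attr(out, "q_sca") <- co$q_sca
  attr(out, "q_ext") <- co$q_ext
  attr(out, "c_sca") <- c_sca
  attr(out, "c_ext") <- co$q_ext * geom
  attr(out, "c_bb") <- c_bb
  attr(out, "config") <- config
  class(out) <- c("scattering_spectrum", class(out))
  out
}

#' Equivalent-sphere scattering baselines for a measured mesh
#'
#' Runs [angular_dscs()] at the two spherical-equivalent diameters of a
#' morphometry report — the sphere with the same surface area (`d_esa`) and
#' the sphere with the same biovolume (`d_esv`) — giving the two
#' homogeneous-sphere baselines against which shape effects on scattering
#' are judged.
#'
#' @param report a [mesh_morphometry()] report (or any list/tibble with
#'   `d_esa` and `d_esv` in micrometres).
#' @param config a [scattering_config()]; its `diameter` is overridden.
#' @return A list with `spectrum_esa` and `spectrum_esv`, both
#'   `scattering_spectrum` tibbles.
#' @export
equivalent_sphere_spectra <- function(report,
                                      config = scattering_config(diameter = 1)) {
  stopifnot(is.finite(report$d_esa), is.finite(report$d_esv),
            report$d_esa > 0, report$d_esv > 0)
  cfg_esa <- config; cfg_esa$diameter <- as.numeric(report$d_esa)
  cfg_esv <- config; cfg_esv$diameter <- as.numeric(report$d_esv)
  list(spectrum_esa = angular_dscs(cfg_esa),
       spectrum_esv = angular_dscs(cfg_esv))
}
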