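#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a morphometry report into long form
#'
#' @param x a [mesh_morphometry()] report.
#' @param ... unused.
#' @return A tibble with columns `name`, `quantity`, `value`, `unit`.
#' @export
tidy.morphometry_report <- function(x, ...) {
  units <- c(surface_area = "um^2", biovolume = "um^3", length = "um",
             width = "um", depth = "um", d_esa = "um", d_esv = "um",
             sa_to_v = "1/um")
  tibble::tibble(
    name = rep(x$name, length(units)),
    quantity = names(units),
    value = as.numeric(unlist(x[1L, names(units)])),
    unit = unname(units)
  )
}

#' One-row summary of a morphometry report
#'
#' @param x a [mesh_morphometry()] report.
#' @param ... unused.
#' @return The report as a plain one-row tibble.
#' @export
glance.morphometry_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "morphometry_report")
  out
}

#' Tidy an image comparison into per-pixel records
#'
#' @param x a `comparison_result` from [compare_pair()] or
#'   [relative_difference()].
#' @param ... unused.
#' @return A tibble with one row per defined in-mask pixel: `row`, `col`,
#'   `reldiff`.
#' @export
tidy.comparison_result <- function(x, ...) {
  idx <- which(!is.na(x$reldiff), arr.ind = TRUE)
  tibble::tibble(row = idx[, 1L], col = idx[, 2L],
                 reldiff = x$reldiff[idx])
}

#' One-row summary of an image comparison
#'
#' @param x a `comparison_result`.
#' @param ... unused.
#' @return A one-row tibble: `mean_reldiff`, `median_reldiff`, `n_defined`,
#'   `excluded_zero_pixels`, `mask_fraction`.
#' @export
glance.comparison_result <- function(x, ...) {
  tibble::tibble(mean_reldiff = x$mean_reldiff,
                 median_reldiff = x$median_reldiff,
                 n_defined = x$n_defined,
                 excluded_zero_pixels = x$excluded_zero_pixels,
                 mask_fraction = mean(x$mask))
}

#' Tidy a scattering spectrum
#'
#' @param x a `scattering_spectrum` from [angular_dscs()].
#' @param ... unused.
#' @return The angle-resolved tibble with the spectrum class dropped.
#' @export
tidy.scattering_spectrum <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "scattering_spectrum")
  attr(out, "q_sca") <- attr(out, "q_ext") <- NULL
  attr(out, "c_sca") <- attr(out, "c_ext") <- NULL
  attr(out, "c_bb") <- attr(out, "config") <- NULL
  out
}

#' One-row summary of a scattering spectrum
#'
#' @param x a `scattering_spectrum`.
#' @param ... unused.
#' @return A one-row tibble: `diameter`, `wavelength`, `m_re`, `m_im`,
#'   `q_sca`, `q_ext`, `c_sca`, `c_ext`, `c_bb` and the backscattering
#'   ratio `b_ratio = c_bb / c_sca`.
#' @export
glance.scattering_spectrum <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    diameter = cfg$diameter, wavelength = cfg$wavelength,
    m_re = Re(cfg$refractive_index), m_im = Im(cfg$refractive_index),
    q_sca = attr(x, "q_sca"), q_ext = attr(x, "q_ext"),
    c_sca = attr(x, "c_sca"), c_ext = attr(x, "c_ext"),
    c_bb = attr(x, "c_bb"),
    b_ratio = attr(x, "c_bb") / attr(x, "c_sca")
  )
}

#' Plot a scattering spectrum
#'
#' Log-scale differential scattering cross section against scattering
#' angle, in the layout conventional for phase-function comparisons.
#'
#' @param object a `scattering_spectrum`.
#' @param polarisation which DSCS column(s) to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.scattering_spectrum <- function(object,
                                         polarisation = c("hh", "vv",
                                                          "unpol"),
                                         ...) {
  polarisation <- match.arg(polarisation, several.ok = TRUE)
  cols <- paste0("dscs_", polarisation)
  df <- tidy.scattering_spectrum(object)
  long <- do.call(rbind, lapply(cols, function(cl) {
    data.frame(angle = df$angle, dscs = df[[cl]],
               polarisation = toupper(sub("dscs_", "", cl)))
  }))
  cfg <- attr(object, "config")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$angle, y = .data$dscs,
                                     colour = .data$polarisation)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "scattering angle (degrees)",
      y = expression("DSCS (" * mu * m^2 * sr^-1 * ")"),
      title = sprintf("Sphere d = %.2f um, lambda = %.3f um",
                      cfg$diameter, cfg$wavelength)
    )
}

#' Plot a relative-difference map
#'
#' @param object a `comparison_result`.
#' @param ... unused.
#' @return A ggplot object (raster of the in-mask relative differences).
#' @export
autoplot.comparison_result <- function(object, ...) {
  df <- tidy.comparison_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$reldiff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "relative\ndifference")
}

#' @export
plot.scattering_spectrum <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.comparison_result <- function(x, ...) print(autoplot(x, ...))

#' @importFrom ggplot2 .data
#' @importFrom tibble tibble
NULL
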