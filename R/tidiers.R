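# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a fitted plaque scenario
#'
#' @param x A `plaque_fit` from [run_scenario()].
#' @param ... Unused.
#' @return The nodal cylindrical stress field as a tibble.
#' @export
tidy.plaque_fit <- function(x, ...) {
  tibble::as_tibble(x$stress)
}

#' @rdname tidy.plaque_fit
#' @export
glance.plaque_fit <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario$name,
    n_crystals = length(x$scenario$crystals),
    pressure_kpa = x$scenario$pressure,
    n_elements = nrow(x$mesh$elements),
    pcs_kpa = x$pcs$pcs,
    pcs_r_mm = x$pcs$r,
    pcs_theta_deg = x$pcs$theta,
    residual = x$solution$residual
  )
}

#' Tidy a sweep result
#'
#' @param x A `capstress_sweep`.
#' @param ... Unused.
#' @return The per-step sweep table.
#' @export
tidy.capstress_sweep <- function(x, ...) {
  x$data
}

#' @rdname tidy.capstress_sweep
#' @export
glance.capstress_sweep <- function(x, ...) {
  switch(x$kind,
    expansion = tibble::tibble(
      kind = x$kind, slope_kpa_per_um = x$slope, intercept_kpa = x$intercept,
      max_residual = x$max_residual, argmax_constant = x$argmax_constant
    ),
    pressure = tibble::tibble(
      kind = x$kind, d_um = x$d_um, slope_kpa_per_kpa = x$slope,
      all_collocated = all(x$data$collocated)
    ),
    sensitivity = tibble::tibble(
      kind = x$kind, max_deviation_pct = x$max_deviation_pct
    )
  )
}

#' Plot a sweep
#'
#' @param object A `capstress_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.capstress_sweep <- function(object, ...) {
  d <- object$data
  if (object$kind == "expansion") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$d_um, y = .data$pcs_kpa)) +
      ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                           linetype = 2, colour = "grey50") +
      ggplot2::geom_point() +
      ggplot2::labs(x = "crystal expansion d (µm)", y = "PCS (kPa)")
  } else if (object$kind == "pressure") {
    dd <- tidyr::pivot_longer(d[, c("P_kpa", "pcs_kpa", "baseline_kpa")],
                              -"P_kpa", names_to = "series",
                              values_to = "pcs")
    ggplot2::ggplot(dd, ggplot2::aes(x = .data$P_kpa, y = .data$pcs,
                                     colour = .data$series)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "luminal pressure (kPa)", y = "PCS (kPa)")
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$factor),
                                    y = .data$deviation_pct)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~scenario) +
      ggplot2::labs(x = "crystal modulus factor", y = "|PCS deviation| (%)")
  }
}

#' Map the circumferential stress field
#'
#' @param object A `plaque_fit`.
#' @param component Stress component column to map (default `sigma_tt`).
#' @param ... Unused.
#' @return A ggplot of the nodal stress component.
#' @export
autoplot.plaque_fit <- function(object, component = "sigma_tt", ...) {
  d <- tibble::as_tibble(object$stress)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data[[component]])) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = paste0(component,
                                                              " (kPa)"))
}

#' Display a B-scan
#'
#' @param object A `bscan` (or `sim_bscan`).
#' @param ... Unused.
#' @return A ggplot raster of log-intensity.
#' @export
autoplot.bscan <- function(object, ...) {
  img <- object$intensity
  d <- tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    value = log1p(as.vector(img))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "A-line", y = "depth (px)", fill = "log intensity")
}

#' @rdname autoplot.bscan
#' @export
autoplot.sim_bscan <- function(object, ...) {
  autoplot(object$scan, ...)
}
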