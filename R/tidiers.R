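# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @method tidy vgm_model
#' @rdname tidiers
#' @param x A fitted object.
#' @param ... Unused.
tidy.vgm_model <- function(x, ...) {
  pars <- if (x$family == "linear") {
    tibble::tibble(term = c("nugget", "slope"), estimate = c(x$nugget, x$slope))
  } else if (x$family == "matern_stein") {
    tibble::tibble(term = c("nugget", "psill", "range", "kappa"),
                   estimate = c(x$nugget, x$psill, x$range, x$kappa))
  } else {
    tibble::tibble(term = c("nugget", "psill", "range"),
                   estimate = c(x$nugget, x$psill, x$range))
  }
  dplyr::mutate(pars, family = x$family, .before = 1)
}

#' Tidy and glance methods for fitted geostatistical objects
#'
#' `tidy()` returns per-parameter rows; `glance()` one row of fit
#' diagnostics.
#'
#' @name tidiers
NULL

#' @export
#' @method glance vgm_model
#' @rdname tidiers
glance.vgm_model <- function(x, ...) {
  tibble::tibble(family = x$family, rss = x$rss, aic = x$aic,
                 converged = isTRUE(x$converged))
}

#' @export
#' @method tidy lmc_model
#' @rdname tidiers
tidy.lmc_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$structures), function(k) {
    s <- x$structures[[k]]
    tibble::tibble(
      structure = k, family = s$family,
      range = s$range %||% NA_real_,
      b11 = x$B[[k]][1, 1], b12 = x$B[[k]][1, 2], b22 = x$B[[k]][2, 2]
    )
  })
}

#' @export
#' @method glance lmc_model
#' @rdname tidiers
glance.lmc_model <- function(x, ...) {
  tibble::tibble(
    n_structures = length(x$structures),
    rss = attr(x, "rss") %||% NA_real_,
    psd_binding = isTRUE(attr(x, "psd_binding"))
  )
}

#' @export
#' @method tidy cv_report
#' @rdname tidiers
tidy.cv_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
#' @method glance cv_report
#' @rdname tidiers
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    n = nrow(x),
    rmse = attr(x, "rmse"),
    msdr = attr(x, "msdr")
  )
}

#' @export
#' @method tidy trend_model
#' @rdname tidiers
tidy.trend_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients_raw),
                 estimate = unname(x$coefficients_raw))
}

#' Plot an empirical variogram, optionally with fitted models
#'
#' @param object An `empirical_variogram`.
#' @param models Optional `vgm_model` or list of them, drawn as curves.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot empirical_variogram
autoplot.empirical_variogram <- function(object, models = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lag / 1000, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$np), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4, name = "pairs") +
    ggplot2::labs(x = "lag (km)",
                  y = expression(gamma(h) ~ "(‰²)")) +
    ggplot2::theme_minimal()
  if (!is.null(models)) {
    if (inherits(models, "vgm_model")) models <- list(models)
    hs <- seq(1, max(df$lag), length.out = 200)
    curves <- purrr::map_dfr(models, function(m) {
      tibble::tibble(lag = hs, gamma = model_gamma(m, hs), family = m$family)
    })
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$lag / 1000, y = .data$gamma, colour = .data$family)
    )
  }
  p
}

#' Plot a raster surface
#'
#' @param object An `iso_raster`.
#' @param ... Unused.
#' @return A ggplot of the cell values.
#' @export
#' @method autoplot iso_raster
autoplot.iso_raster <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[is.finite(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "easting (km)", y = "northing (km)") +
    ggplot2::theme_minimal()
}

#' Plot an isoscape: prediction surface and CI width
#'
#' @param object An `isoscape`.
#' @param layer `"prediction"`, `"variance"`, `"ci_width"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot isoscape
autoplot.isoscape <- function(object, layer = c("prediction", "variance", "ci_width"), ...) {
  layer <- match.arg(layer)
  r <- switch(layer,
    prediction = object$prediction,
    variance = object$variance,
    ci_width = iso_raster(object$ci_high$values - object$ci_low$values,
                          object$prediction$x0, object$prediction$y0,
                          object$prediction$cell, object$prediction$nodata)
  )
  autoplot.iso_raster(r) +
    ggplot2::labs(fill = layer,
                  title = sprintf("%s %s %s", object$method,
                                  object$variable %||% "", layer))
}

#' Plot observed against cross-validation predictions
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot with the 1:1 line.
#' @export
#' @method autoplot cv_report
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      title = sprintf("LOOCV %s: RMSE %.3g, MSDR %.3g", attr(object, "method"),
                      attr(object, "rmse"), attr(object, "msdr")),
      x = "observed (‰)", y = "predicted (‰)"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
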