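#' Build an isoscape with 95% confidence surfaces
#'
#' Runs [predict_grid()] with the chosen kriging method over the masked
#' grid and derives the Gaussian 95% confidence bounds
#' `prediction +/- 1.96 * sqrt(variance)` cell-wise.
#'
#' @inheritParams predict_grid
#' @param mask An `iso_raster`; `NA` cells are excluded from prediction.
#' @param variable,year Optional labels carried in the result.
#' @return Object of class `isoscape`: rasters `prediction`, `variance`,
#'   `ci_low`, `ci_high`, plus `method`, `variable`, `year` labels.
#' @export
build_isoscape <- function(sites, values, model_or_lmc,
                           method = c("KriO", "KriL", "KriQ", "CoK"),
                           mask, values_covariate = NULL, covariate_grid = NULL,
                           variable = NA_character_, year = NA_character_) {
  method <- match.arg(method)
  stopifnot(inherits(mask, "iso_raster"))
  idx <- raster_cell_index(mask, sites$x, sites$y)
  outside <- is.na(idx$row)
  if (any(outside)) {
    warning(sprintf("%d site(s) fall outside the mask extent.", sum(outside)))
  }
  pg <- predict_grid(sites, values, model_or_lmc, method = method, grid = mask,
                     values_covariate = values_covariate,
                     covariate_grid = covariate_grid)
  sdv <- sqrt(pg$variance$values)
  ci_low <- pg$prediction$values - 1.96 * sdv
  ci_high <- pg$prediction$values + 1.96 * sdv
  structure(
    list(
      prediction = pg$prediction,
      variance = pg$variance,
      ci_low = iso_raster(ci_low, mask$x0, mask$y0, mask$cell, mask$nodata),
      ci_high = iso_raster(ci_high, mask$x0, mask$y0, mask$cell, mask$nodata),
      method = method, variable = variable, year = year
    ),
    class = "isoscape"
  )
}

#' @export
print.isoscape <- function(x, ...) {
  s <- summarize_isoscape(x)
  cat(sprintf(
    "<isoscape> %s %s %s: prediction [%.4g, %.4g], CI width [%.4g, %.4g], %d cells\n",
    x$method, x$variable %||% "", x$year %||% "",
    s$prediction_min, s$prediction_max, s$ci_width_min, s$ci_width_max, s$n_cells
  ))
  invisible(x)
}

#' Summary statistics of an isoscape
#'
#' Nodata-aware extrema and quartiles of the prediction and the confidence
#' interval width (`ci_high - ci_low`, equal to `3.92 * sqrt(variance)`);
#' half-widths are reported too so either reading of a "CI range" figure
#' can be compared.
#'
#' @param iso An `isoscape`.
#' @return One-row tibble of summary statistics.
#' @export
summarize_isoscape <- function(iso) {
  stopifnot(inherits(iso, "isoscape"))
  p <- iso$prediction$values
  valid <- is.finite(p)
  if (!any(valid)) stop_isokrig("Isoscape has no valid cells.", "empty_summary")
  w <- iso$ci_high$values - iso$ci_low$values
  pv <- p[valid]; wv <- w[valid]
  qs <- stats::quantile(pv, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(
    method = iso$method, variable = iso$variable, year = iso$year,
    n_cells = sum(valid),
    area_km2 = sum(valid) * iso$prediction$cell^2 / 1e6,
    prediction_min = min(pv), prediction_max = max(pv),
    prediction_q25 = qs[1], prediction_median = qs[2], prediction_q75 = qs[3],
    ci_width_min = min(wv), ci_width_max = max(wv),
    ci_halfwidth_min = min(wv) / 2, ci_halfwidth_max = max(wv) / 2
  )
}

#' Write the four isoscape rasters as ESRI ASCII grids
#'
#' @param iso An `isoscape`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Character vector of the four file paths, invisibly.
#' @export
write_isoscape <- function(iso, dir, stem = "isoscape") {
  stopifnot(inherits(iso, "isoscape"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(stem, "_", c("prediction", "variance", "ci_low", "ci_high"), ".asc"))
  write_ascii_raster(iso$prediction, paths[1])
  write_ascii_raster(iso$variance, paths[2])
  write_ascii_raster(iso$ci_low, paths[3])
  write_ascii_raster(iso$ci_high, paths[4])
  invisible(paths)
}

#' Rasterize a polygon mask for isoscape prediction
#'
#' Builds a grid covering the polygon's bounding box at `resolution`;
#' cells whose centre falls inside the polygon get value 1, others `NA`.
#'
#' @param polygon Data frame of vertices (`x`, `y`).
#' @param resolution Cell size in metres (default 250 for display-quality
#'   surfaces; coarser for quick runs).
#' @return An `iso_raster` mask.
#' @export
polygon_mask <- function(polygon, resolution = 250) {
  check_site_table(polygon)
  x0 <- min(polygon$x); y0 <- min(polygon$y)
  nc <- ceiling((max(polygon$x) - x0) / resolution)
  nr <- ceiling((max(polygon$y) - y0) / resolution)
  cx <- x0 + (rep(seq_len(nc), each = nr) - 0.5) * resolution
  cy <- y0 + (nr - rep(seq_len(nr), nc) + 0.5) * resolution
  inside <- points_in_polygon(cx, cy, polygon$x, polygon$y)
  m <- matrix(ifelse(inside, 1, NA_real_), nr, nc)
  iso_raster(m, x0, y0, resolution)
}
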