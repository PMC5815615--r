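#' Canopy cover from a canopy-height model
#'
#' Reclassifies the CHM to a binary raster (cells strictly above
#' `height_threshold` become 1, cells at or below it become 0), sums the
#' binary values over a circular neighbourhood of radius `radius` (cells
#' whose centre lies within the radius), divides by `denominator` — kept at
#' the conventional plot-area constant 1256.4 for a 20 m radius — and
#' multiplies by 100. The result is clipped to `[0, 100]`.
#'
#' A true circular cell mask is used for the neighbourhood (some GIS
#' neighbourhood operators approximate the circle with a square window;
#' values can differ slightly near the rim). Cells outside the raster
#' contribute zero; nodata CHM cells count as no canopy but stay nodata in
#' the output.
#'
#' @param chm An `iso_raster` of canopy heights (m); cell size nominally
#'   1 m — for other cell sizes the denominator is rescaled by
#'   `cell^2` so the output remains a percentage of the plot area.
#' @param height_threshold Height (m) above which a cell counts as canopy
#'   (default 2; equality counts as no canopy).
#' @param radius Neighbourhood radius in metres (default 20).
#' @param denominator Plot-area constant (default 1256.4, the area of a
#'   20 m-radius circular plot used by the field procedure).
#' @return An `iso_raster` of canopy cover percentages.
#' @export
canopy_cover_from_chm <- function(chm, height_threshold = 2, radius = 20,
                                  denominator = 1256.4) {
  stopifnot(inherits(chm, "iso_raster"))
  if (radius <= chm$cell) stop_isokrig("radius must exceed the cell size.", "parameter_error")
  # only rescale the default plot-area constant when the radius changes
  denom <- if (radius != 20 && denominator == 1256.4) pi * radius^2 else denominator
  bin <- (chm$values > height_threshold) * 1
  bin[is.na(bin)] <- 0
  nr <- nrow(bin); nc <- ncol(bin)
  k <- floor(radius / chm$cell)
  counts <- matrix(0, nr, nc)
  for (di in -k:k) {
    for (dj in -k:k) {
      if ((di^2 + dj^2) * chm$cell^2 > radius^2) next
      src_r <- seq_len(nr) + di
      src_c <- seq_len(nc) + dj
      ok_r <- src_r >= 1 & src_r <= nr
      ok_c <- src_c >= 1 & src_c <= nc
      counts[which(ok_r), which(ok_c)] <-
        counts[which(ok_r), which(ok_c), drop = FALSE] +
        bin[src_r[ok_r], src_c[ok_c], drop = FALSE]
    }
  }
  cover <- pmin(pmax(100 * counts * chm$cell^2 / denom, 0), 100)
  cover <- matrix(cover, nr, nc)
  cover[is.na(chm$values)] <- NA_real_
  iso_raster(cover, chm$x0, chm$y0, chm$cell, chm$nodata)
}

#' Standardize a covariate to zero mean and unit (sample) SD
#'
#' `(v - mean) / sd` with the sample (n-1) standard deviation. The mean and
#' SD are attached so the transform inverts exactly with
#' [unstandardize()].
#'
#' @param values Numeric vector.
#' @return Numeric vector with attributes `center` and `scale`.
#' @examples
#' standardize(c(1, 2, 3)) # -1, 0, 1
#' @export
standardize <- function(values) {
  values <- as.numeric(values)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop_isokrig("Covariate has zero variance; cannot standardize.", "zero_variance")
  }
  m <- mean(values)
  out <- (values - m) / s
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

#' Invert a standardization
#'
#' @param values Output of [standardize()] (or any numeric vector, with
#'   `center`/`scale` supplied explicitly).
#' @param center,scale Mean and SD used in the forward transform; default
#'   to the attributes left by [standardize()].
#' @return Numeric vector on the original scale.
#' @export
unstandardize <- function(values, center = attr(values, "center"),
                          scale = attr(values, "scale")) {
  if (is.null(center) || is.null(scale)) {
    stop_isokrig("center/scale metadata missing.", "parameter_error")
  }
  as.numeric(values) * scale + center
}
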