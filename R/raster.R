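#' Create a grid raster
#'
#' Lightweight in-memory raster used for DEM / canopy-height / isoscape grids.
#' Values are stored as a matrix whose first row is the *northernmost* row
#' (the ESRI ASCII grid convention); missing cells are `NA`.
#'
#' @param values Numeric matrix, first row = top (north) row.
#' @param x0,y0 Coordinates of the lower-left corner of the grid, in metres.
#' @param cell Cell size in metres (square cells).
#' @param nodata Sentinel written to file for missing cells (default -9999).
#' @return An object of class `iso_raster`.
#' @examples
#' r <- iso_raster(matrix(1:4, 2, 2), x0 = 0, y0 = 0, cell = 10)
#' @export
iso_raster <- function(values, x0, y0, cell, nodata = -9999) {
  stopifnot(is.matrix(values), cell > 0, is.finite(x0), is.finite(y0))
  structure(
    list(values = values, x0 = x0, y0 = y0, cell = cell, nodata = nodata),
    class = "iso_raster"
  )
}

#' @export
print.iso_raster <- function(x, ...) {
  cat(sprintf(
    "<iso_raster> %d rows x %d cols, cell %g m, origin (%g, %g), %d NA cells\n",
    nrow(x$values), ncol(x$values), x$cell, x$x0, x$y0, sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.iso_raster <- function(x) dim(x$values)

#' Convert a raster to a tibble of cell centres
#'
#' @param x An `iso_raster`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `value` (one row per cell,
#'   `NA` cells included).
#' @export
#' @method as_tibble iso_raster
as_tibble.iso_raster <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), nc)
  cx <- x$x0 + (col - 0.5) * x$cell
  cy <- x$y0 + (nr - row + 0.5) * x$cell
  vals <- as.vector(x$values)
  tibble::tibble(x = cx, y = cy, value = vals)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @return An `iso_raster`. Cells equal to the file's NODATA value become `NA`.
#' @export
read_ascii_raster <- function(path) {
  if (!file.exists(path)) stop_isokrig(paste0("File not found: ", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", trimws(lines[i]))) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) < 2) stop_isokrig("Malformed raster header line.", "format_error")
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr))) {
    stop_isokrig("Raster header missing ncols/nrows/cellsize.", "format_error")
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  nodata <- hdr$nodata_value %||% -9999
  body <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  if (length(body) == 0L) stop_isokrig("Raster file has a header but no data rows.", "format_error")
  vals <- as.numeric(unlist(strsplit(trimws(paste(body, collapse = " ")), "\\s+")))
  if (length(vals) != nr * nc) {
    stop_isokrig(
      sprintf("Raster body has %d values; header promises %d.", length(vals), nr * nc),
      "format_error"
    )
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  iso_raster(m, x0 = x0, y0 = y0, cell = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with full double precision (`%.17g`) so that a
#' write/read round trip is bit-exact.
#'
#' @param raster An `iso_raster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_raster <- function(raster, path) {
  stopifnot(inherits(raster, "iso_raster"))
  m <- raster$values
  m[is.na(m)] <- raster$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.17g", raster$x0),
    sprintf("yllcorner %.17g", raster$y0),
    sprintf("cellsize %.17g", raster$cell),
    sprintf("NODATA_value %.17g", raster$nodata)
  )
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Locate the grid cell containing each point
#'
#' Cell membership uses half-open intervals `[edge, edge + cell)`: a point on
#' a shared edge belongs to the lower-index (west / south) cell.
#'
#' @return Data frame with matrix row/col indices (`NA` if outside the grid).
#' @noRd
raster_cell_index <- function(raster, x, y) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  col <- floor((x - raster$x0) / raster$cell) + 1
  row_from_bottom <- floor((y - raster$y0) / raster$cell) + 1
  row <- nr - row_from_bottom + 1
  bad <- col < 1 | col > nc | row < 1 | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' Nearest-cell rule: each point receives the value of the cell containing it.
#' Points on cell boundaries are assigned by the half-open convention
#' (boundary belongs to the lower-index cell).
#'
#' @param raster An `iso_raster`.
#' @param sites Data frame with columns `x`, `y` (projected metres).
#' @return `sites` with an added `value` column (tibble).
#' @export
extract_raster_at_points <- function(raster, sites) {
  stopifnot(inherits(raster, "iso_raster"))
  check_site_table(sites)
  idx <- raster_cell_index(raster, sites$x, sites$y)
  if (anyNA(idx$row)) {
    off <- which(is.na(idx$row))
    stop_isokrig(
      paste0(
        "Site(s) outside raster extent: ",
        paste(utils::head(off, 10), collapse = ", ")
      ),
      "extent_error"
    )
  }
  vals <- raster$values[cbind(idx$row, idx$col)]
  if (anyNA(vals)) {
    warning(sprintf("%d site(s) fall on nodata cells; value set to NA.", sum(is.na(vals))))
  }
  out <- tibble::as_tibble(sites)
  out$value <- vals
  out
}
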