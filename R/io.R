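#' Read a per-site isotope table from CSV
#'
#' Reads the study's site table: one row per sampling site with projected
#' coordinates (metres, e.g. UTM 32N), altitude, optional covariates and
#' per-year isotope columns (permil vs VSMOW). Column names in the file are
#' mapped onto the canonical names via `schema`.
#'
#' Rows sharing identical `(x, y)` coordinates after mapping are averaged
#' (numeric columns) with a warning, so duplicated field records collapse to
#' one site.
#'
#' @param path CSV file with a header row.
#' @param schema Named character vector mapping canonical names to file
#'   column names, e.g. `c(site_id = "ID", x = "East", y = "North")`.
#'   Defaults to the identity mapping for whatever columns are present.
#' @return A tibble with at least `site_id`, `x`, `y`.
#' @export
read_site_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_isokrig(paste0("File not found: ", path), "io_error")
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop_isokrig("Site table is empty or unreadable.", "schema_error")
  )
  if (nrow(raw) == 0L || ncol(raw) == 0L) {
    stop_isokrig("Site table is empty.", "schema_error")
  }
  if (!is.null(schema)) {
    missing <- setdiff(unname(schema), names(raw))
    if (length(missing)) {
      stop_isokrig(
        paste0("Mapped column(s) absent from file: ", paste(missing, collapse = ", ")),
        "schema_error"
      )
    }
    for (canon in names(schema)) {
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  check_site_table(raw, c("x", "y"))
  num_cols <- setdiff(names(raw), "site_id")
  for (cl in num_cols) {
    v <- raw[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad)) {
        stop_isokrig(
          sprintf("Non-numeric value in column '%s' at row %d.", cl, bad[1]),
          "parse_error"
        )
      }
      raw[[cl]] <- conv
    }
  }
  if (!all(is.finite(raw$x)) || !all(is.finite(raw$y))) {
    stop_isokrig("Non-finite coordinates in site table.", "parse_error")
  }
  if (!"site_id" %in% names(raw)) raw$site_id <- as.character(seq_len(nrow(raw)))
  key <- paste(raw$x, raw$y, sep = "_")
  if (anyDuplicated(key)) {
    warning(sprintf(
      "%d duplicated coordinate(s); duplicate rows averaged.",
      sum(duplicated(key))
    ))
    first <- !duplicated(key)
    agg <- raw[first, , drop = FALSE]
    for (cl in num_cols) {
      agg[[cl]] <- tapply(raw[[cl]], key, mean, na.rm = TRUE)[key[first]]
    }
    raw <- agg
  }
  dup_id <- duplicated(raw$site_id)
  if (any(dup_id)) {
    raw$site_id <- make.unique(as.character(raw$site_id))
  }
  tibble::as_tibble(raw)[, c("site_id", setdiff(names(raw), "site_id"))]
}

#' Write a site table to CSV
#'
#' Numeric columns are written with 15 significant digits so a write/read
#' cycle is lossless to better than 12 significant digits.
#'
#' @param sites Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  out <- as.data.frame(sites)
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) out[[cl]] <- formatC(out[[cl]], digits = 15, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-point normalization of an isotope measurement
#'
#' Maps a measured delta value onto the reference scale through the affine
#' (linear) calibration fixed by two certified standards, e.g. USGS lignin
#' standards at -154.4 and -44 permil for delta-2H.
#'
#' @param measured_std_a,measured_std_b Measured delta values of the two
#'   standards (permil).
#' @param ref_a,ref_b Certified reference values of the same standards.
#' @param sample Measured delta value(s) of the sample(s).
#' @return Normalized delta value(s), permil.
#' @examples
#' two_point_normalization(-154.4, -44, -154.4, -44, -100) # identity: -100
#' @export
two_point_normalization <- function(measured_std_a, measured_std_b,
                                    ref_a, ref_b, sample) {
  if (isTRUE(all.equal(measured_std_a, measured_std_b))) {
    stop_isokrig("Measured standards are equal: calibration line is degenerate.",
                 "degenerate_calibration")
  }
  slope <- (ref_b - ref_a) / (measured_std_b - measured_std_a)
  ref_a + slope * (sample - measured_std_a)
}
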