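#' Construct a tree-ring width series
#'
#' @param widths Positive ring widths (mm, typically measured to 0.01 mm).
#' @param start_year Calendar year of the first ring.
#' @return Tibble with columns `year`, `width`.
#' @export
ring_series <- function(widths, start_year) {
  widths <- as.numeric(widths)
  if (length(widths) < 2) stop_isokrig("Ring series needs length >= 2.", "input_error")
  if (any(!is.finite(widths)) || any(widths <= 0)) {
    stop_isokrig("Ring widths must be positive and finite.", "input_error")
  }
  tibble::tibble(year = start_year + seq_along(widths) - 1L, width = widths)
}

as_ring_series <- function(x) {
  if (is.data.frame(x)) {
    check_site_table(x, c("year", "width"))
    return(x)
  }
  ring_series(x, start_year = 1L)
}

overlap_widths <- function(a, b) {
  a <- as_ring_series(a); b <- as_ring_series(b)
  years <- intersect(a$year, b$year)
  list(
    years = sort(years),
    wa = a$width[match(sort(years), a$year)],
    wb = b$width[match(sort(years), b$year)]
  )
}

#' Gleichlaeufigkeit (sign-agreement) between two ring series
#'
#' The percentage agreement in the signs of first differences over the
#' overlapping years: each year-to-year step scores 1 when both series move
#' in the same direction (or both are flat), 1/2 when exactly one is flat,
#' and 0 when they move oppositely — the Eckstein-Bauch convention.
#' Computed on raw widths, no detrending.
#'
#' @param a,b Ring series (tibbles from [ring_series()], or numeric width
#'   vectors interpreted as starting in year 1).
#' @return Percentage in `[0, 100]`.
#' @examples
#' gleichlaeufigkeit(c(1, 2, 3, 4), c(2, 3, 4, 5)) # 100
#' @export
gleichlaeufigkeit <- function(a, b) {
  ov <- overlap_widths(a, b)
  if (length(ov$years) < 3) {
    stop_isokrig("Series overlap must be at least 3 years.", "insufficient_overlap")
  }
  ga <- sign(diff(ov$wa))
  gb <- sign(diff(ov$wb))
  scores <- 1 - abs(ga - gb) / 2
  100 * mean(scores)
}

#' Cross-dating t-value between two ring series
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` where `r` is the Pearson
#' correlation of the overlapping ring widths and `n` the overlap length.
#' Perfect correlation returns an infinite sentinel of the matching sign.
#'
#' @inheritParams gleichlaeufigkeit
#' @return The t statistic (dimensionless; `Inf`/`-Inf` at `r = +/-1`).
#' @export
tvalue <- function(a, b) {
  ov <- overlap_widths(a, b)
  n <- length(ov$years)
  if (n < 4) stop_isokrig("Series overlap must be at least 4 years.", "insufficient_overlap")
  if (stats::sd(ov$wa) == 0 || stats::sd(ov$wb) == 0) {
    stop_isokrig("Zero-variance series: correlation undefined.", "undefined_correlation")
  }
  r <- stats::cor(ov$wa, ov$wb)
  if (abs(r) >= 1 - 1e-12) return(sign(r) * Inf)
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

#' Cross-dating report of candidate series against a reference chronology
#'
#' @param series List of ring series.
#' @param reference Reference ring series.
#' @param glk_threshold Series with Gleichlaeufigkeit below this percentage
#'   are flagged (default 60).
#' @return Tibble with `series`, `overlap`, `glk`, `t`, `flagged`.
#' @export
crossdate_report <- function(series, reference, glk_threshold = 60) {
  if (length(series) == 0) {
    return(tibble::tibble(series = character(), overlap = integer(),
                          glk = numeric(), t = numeric(), flagged = logical()))
  }
  nm <- names(series) %||% as.character(seq_along(series))
  nm[nm == ""] <- as.character(which(nm == ""))
  purrr::map2_dfr(series, nm, function(s, id) {
    ov <- overlap_widths(s, reference)
    tibble::tibble(
      series = id,
      overlap = length(ov$years),
      glk = gleichlaeufigkeit(s, reference),
      t = tvalue(s, reference)
    )
  }) |>
    dplyr::mutate(flagged = .data$glk < glk_threshold)
}

#' Read a two-column (year, width) ring-series CSV
#'
#' @param path CSV with columns `year` and `width`.
#' @return A ring-series tibble.
#' @export
read_ring_series <- function(path) {
  d <- utils::read.csv(path)
  check_site_table(d, c("year", "width"))
  ring_series(d$width, start_year = d$year[1])
}
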