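# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Ray-casting point-in-polygon test (even-odd rule)
#'
#' Points exactly on an edge may fall on either side; callers sampling
#' continuous coordinates never hit edges with probability one.
#' @noRd
points_in_polygon <- function(x, y, poly_x, poly_y) {
  n <- length(poly_x)
  stopifnot(n >= 3, length(poly_y) == n)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Signed area of a polygon (shoelace formula)
#' @noRd
polygon_area <- function(poly_x, poly_y) {
  n <- length(poly_x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(poly_x[j] * poly_y - poly_x * poly_y[j])) / 2
}

#' Pairwise Euclidean distance matrix from coordinate vectors
#' @noRd
dist_matrix <- function(x, y) {
  as.matrix(stats::dist(cbind(x, y)))
}

#' Distances from each of n points to a single target
#' @noRd
dist_to_point <- function(x, y, x0, y0) {
  sqrt((x - x0)^2 + (y - y0)^2)
}

stop_isokrig <- function(msg, class) {
  rlang::abort(msg, class = paste0("isokrig_", class))
}

check_site_table <- function(sites, cols = c("x", "y")) {
  if (!is.data.frame(sites)) {
    stop_isokrig("`sites` must be a data frame.", "type_error")
  }
  missing <- setdiff(cols, names(sites))
  if (length(missing)) {
    stop_isokrig(
      paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
      "schema_error"
    )
  }
  invisible(sites)
}
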