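#' Fisher-style optimal interval classification
#'
#' Partitions a set of values into at most `k` contiguous classes on the
#' sorted values, minimising the total within-class sum of squared deviations
#' (Fisher's optimal partitioning, a.k.a. Fisher-Jenks natural breaks). The
#' exact optimum is found by dynamic programming over the distinct values,
#' weighted by their multiplicities; DP ties break toward the earliest split.
#'
#' If fewer than `k` distinct values are present, each distinct value becomes
#' its own class (the partition saturates and the SSD is zero).
#'
#' @param values numeric vector of finite observations (e.g. all finite cells
#'   of a raster).
#' @param k maximum number of classes (`>= 1`); the study design uses 5.
#' @return An object of class `fisher_breaks`: list with `k` (classes
#'   actually used), `boundaries` (ascending `k - 1` upper class bounds,
#'   equal to the maximum value of each lower class), and `within_class_ssd`.
#' @examples
#' fisher_breaks(c(1, 2, 3, 10, 11, 12, 100), k = 3)
#' @export
fisher_breaks <- function(values, k = 5L) {
  values <- as.numeric(values)
  if (length(values) == 0L) abort("`values` must be non-empty.")
  if (anyNA(values) || any(!is.finite(values))) {
    abort("`values` must be finite (drop nodata cells before classifying).")
  }
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be >= 1.")
  tab <- table_distinct(values)
  k_eff <- min(k, length(tab$x))
  dp <- .fisher_partition_dp(tab$x, tab$w, k_eff)
  boundaries <- tab$x[dp$last_index][-k_eff]
  structure(
    list(k = k_eff, boundaries = as.numeric(boundaries),
         within_class_ssd = dp$ssd),
    class = "fisher_breaks"
  )
}

table_distinct <- function(values) {
  x <- sort(unique(values))
  w <- as.numeric(tabulate(match(values, x), nbins = length(x)))
  list(x = x, w = w)
}

#' @export
print.fisher_breaks <- function(x, ...) {
  cat(sprintf("<fisher_breaks> %d classes, within-class SSD = %g\n",
              x$k, x$within_class_ssd))
  if (length(x$boundaries)) {
    cat("  upper bounds:", paste(signif(x$boundaries, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify a raster with Fisher-style breaks
#'
#' Assigns class labels `1..k` using right-closed intervals: a value less than
#' or equal to the first boundary gets label 1, a value exactly on a boundary
#' falls in the lower class, and values above the last boundary get label
#' `k`. Missing cells stay missing.
#'
#' @param grid a [raster_grid()].
#' @param breaks a [fisher_breaks()] object.
#' @return A `classified_raster`: list with integer `labels` matrix, `k`, and
#'   the `breaks` used.
#' @export
classify_raster <- function(grid, breaks) {
  stopifnot(inherits(grid, "raster_grid"), inherits(breaks, "fisher_breaks"))
  v <- grid$values
  lab <- matrix(1L, nrow(v), ncol(v))
  for (b in breaks$boundaries) lab <- lab + (v > b)
  lab[is.na(v)] <- NA_integer_
  structure(
    list(labels = lab, k = breaks$k, breaks = breaks,
         origin = grid$origin, cell_size = grid$cell_size),
    class = "classified_raster"
  )
}

#' @export
print.classified_raster <- function(x, ...) {
  cat(sprintf("<classified_raster> %d x %d cells, k = %d classes\n",
              nrow(x$labels), ncol(x$labels), x$k))
  invisible(x)
}
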