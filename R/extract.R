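#' Extract per-plot raster values
#'
#' Looks up the raster value under each plot. Point plots take the value of
#' the cell containing the point. Polygon plots (a `geometry` list-column of
#' two-column vertex matrices) take all cells whose centre lies inside the
#' polygon and reduce them with `reducer`: `"mean"` averages the non-missing
#' cell values, `"center"` takes the value of the cell containing the polygon
#' centroid.
#'
#' @param plots data frame with a `plot_id` column plus either `x`/`y` point
#'   coordinates or a `geometry` list-column of polygon vertex matrices
#'   (closed or open rings).
#' @param grid a [raster_grid()].
#' @param reducer polygon reduction rule, `"mean"` (default) or `"center"`.
#' @return A tibble `plot_id`, `value` in input order.
#' @export
extract_plot_values <- function(plots, grid, reducer = c("mean", "center")) {
  reducer <- match.arg(reducer)
  stopifnot(inherits(grid, "raster_grid"))
  plots <- tibble::as_tibble(plots)
  if (!"plot_id" %in% names(plots)) abort("`plots` needs a `plot_id` column.")
  has_geom <- "geometry" %in% names(plots)
  if (!has_geom && !all(c("x", "y") %in% names(plots))) {
    abort("`plots` needs `x`/`y` columns or a `geometry` list-column.")
  }
  value <- purrr::map_dbl(seq_len(nrow(plots)), function(i) {
    if (has_geom && !is.null(plots$geometry[[i]])) {
      extract_polygon(grid, plots$geometry[[i]], reducer,
                      id = plots$plot_id[i])
    } else {
      extract_point(grid, plots$x[i], plots$y[i], id = plots$plot_id[i])
    }
  })
  tibble::tibble(plot_id = plots$plot_id, value = value)
}

extract_point <- function(grid, x, y, id = "?") {
  rc <- world_to_cell(grid, x, y)
  if (is.na(rc$row)) {
    abort(sprintf("plot '%s' at (%g, %g) lies outside the raster extent.",
                  id, x, y))
  }
  grid$values[rc$row, rc$col]
}

extract_polygon <- function(grid, ring, reducer, id = "?") {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L || nrow(ring) < 3L || !all(is.finite(ring))) {
    abort(sprintf("plot '%s': polygon must be >= 3 finite (x, y) vertices.", id))
  }
  # drop an explicit closing vertex
  if (all(ring[1L, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  if (reducer == "center") {
    ctr <- polygon_centroid(ring)
    return(extract_point(grid, ctr[1], ctr[2], id = id))
  }
  # candidate cells: bounding box, then centre-containment test
  rc_lo <- world_to_cell_clamped(grid, min(ring[, 1]), max(ring[, 2]))
  rc_hi <- world_to_cell_clamped(grid, max(ring[, 1]), min(ring[, 2]))
  rows <- seq(rc_lo$row, rc_hi$row); cols <- seq(rc_lo$col, rc_hi$col)
  rr <- rep(rows, times = length(cols)); cc <- rep(cols, each = length(rows))
  ctrs <- cell_center(grid, rr, cc)
  inside <- mgcv::in.out(rbind(ring, ring[1L, ]), cbind(ctrs$x, ctrs$y))
  if (!any(inside)) {
    abort(sprintf("plot '%s': polygon covers no cell centre of the raster.", id))
  }
  vals <- grid$values[cbind(rr[inside], cc[inside])]
  if (all(is.na(vals))) {
    abort(sprintf("plot '%s': all intersected cells are nodata.", id))
  }
  mean(vals, na.rm = TRUE)
}

world_to_cell_clamped <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1
  row <- floor((grid$origin[2] - y) / grid$cell_size) + 1
  list(row = max(1L, min(nrow(grid$values), as.integer(row))),
       col = max(1L, min(ncol(grid$values), as.integer(col))))
}

# area-weighted centroid of a simple polygon (shoelace); falls back to the
# vertex mean for degenerate (zero-area) rings
polygon_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr) / (6 * a), sum((y + ys) * cr) / (6 * a))
}
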