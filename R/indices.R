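#' Normalized difference vegetation index
#'
#' Cellwise `(nir - red) / (nir + red)` on two co-registered reflectance
#' grids. Cells where the denominator is zero, or where either input is
#' missing, are nodata.
#'
#' @param nir,red co-registered [raster_grid()]s of near-infrared and red
#'   reflectance.
#' @return A [raster_grid()] with values in `[-1, 1]` where defined.
#' @export
ndvi <- function(nir, red) {
  normalized_difference(nir, red, what = "ndvi inputs")
}

#' Red-blue normalized difference vegetation index
#'
#' Cellwise `(red - blue) / (red + blue)`; conventions as in [ndvi()].
#'
#' @param red,blue co-registered [raster_grid()]s.
#' @return A [raster_grid()].
#' @export
rbvi <- function(red, blue) {
  normalized_difference(red, blue, what = "rbvi inputs")
}

normalized_difference <- function(a, b, what) {
  check_coregistered(a, b, what)
  den <- a$values + b$values
  out <- (a$values - b$values) / den
  out[!is.na(den) & den == 0] <- NA_real_
  raster_grid(out, origin = a$origin, cell_size = a$cell_size,
              nodata = a$nodata, crs = a$crs)
}

#' Topographic position index
#'
#' Each cell's elevation minus the mean elevation of the surrounding square
#' window of side `2 * window_radius + 1`, excluding the centre cell. Positive
#' on ridges, negative in valleys, zero on planes and linear ramps (interior).
#' At grid edges the window is truncated to the available cells; missing
#' neighbours are excluded from the mean.
#'
#' @param dem a [raster_grid()] digital elevation model.
#' @param window_radius window half-width in cells (`>= 1`); a "surrounding of
#'   N pixels" in the sense of a square window of side N corresponds to
#'   `window_radius = (N - 1) / 2`.
#' @return A [raster_grid()] of TPI values; cells whose window holds no
#'   non-missing neighbour are nodata.
#' @export
tpi <- function(dem, window_radius = 1L) {
  stopifnot(inherits(dem, "raster_grid"))
  r <- as.integer(window_radius)
  if (r < 1L) abort("`window_radius` must be >= 1.")
  v <- dem$values
  if (2L * r + 1L > min(dim(v))) {
    abort(sprintf("window (side %d) is larger than the grid (%d x %d).",
                  2L * r + 1L, nrow(v), ncol(v)))
  }
  filled <- v; filled[is.na(v)] <- 0
  wsum <- window_sum(filled, r)
  wcnt <- window_sum(matrix(as.double(!is.na(v)), nrow(v), ncol(v)), r)
  nb_sum <- wsum - ifelse(is.na(v), 0, v)
  nb_cnt <- wcnt - as.double(!is.na(v))
  out <- v - nb_sum / nb_cnt
  out[nb_cnt == 0] <- NA_real_
  raster_grid(out, origin = dem$origin, cell_size = dem$cell_size,
              nodata = dem$nodata, crs = dem$crs)
}

# moving square-window sum via summed-area table, window truncated at edges
window_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  sat <- matrix(0, nr + 1L, nc + 1L)
  sat[-1L, -1L] <- m
  sat <- apply(sat, 2L, cumsum)
  sat <- t(apply(sat, 1L, cumsum))
  i0 <- pmax(seq_len(nr) - r, 1L); i1 <- pmin(seq_len(nr) + r, nr)
  j0 <- pmax(seq_len(nc) - r, 1L); j1 <- pmin(seq_len(nc) + r, nc)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    out[, j] <- sat[cbind(i1 + 1L, j1[j] + 1L)] - sat[cbind(i0, j1[j] + 1L)] -
      sat[cbind(i1 + 1L, j0[j])] + sat[cbind(i0, j0[j])]
  }
  out
}

# local 3x3 standard deviation (population of available cells, sample sd);
# used by the heterogeneity-driven simulation regime
local_sd3 <- function(grid) {
  v <- grid$values
  ok <- !is.na(v)
  f <- v; f[!ok] <- 0
  s1 <- window_sum(f, 1L)
  s2 <- window_sum(f * f, 1L)
  n <- window_sum(matrix(as.double(ok), nrow(v), ncol(v)), 1L)
  out <- sqrt(pmax(s2 - s1^2 / n, 0) / pmax(n - 1, 1))
  out[n < 2 | !ok] <- NA_real_
  raster_grid(out, origin = grid$origin, cell_size = grid$cell_size,
              nodata = grid$nodata, crs = grid$crs)
}
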