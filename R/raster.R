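#' Construct a georeferenced raster grid
#'
#' A `raster_grid` is a light container for a single-band gridded surface: a
#' numeric matrix (row 1 = northernmost row) with square cells, the world
#' coordinate of the grid's top-left outer corner, the cell size in metres,
#' a nodata sentinel used on disk, and an opaque CRS tag. Missing cells are
#' held as `NA` in memory.
#'
#' Cell/world convention: cell `(r, c)` covers the half-open square
#' `[x0 + (c-1)s, x0 + c s) x (y0 - r s, y0 - (r-1) s]`; a point lying exactly
#' on a shared edge belongs to the cell with the larger row/column index.
#'
#' @param values numeric matrix; `NA` marks missing cells.
#' @param origin numeric length-2, world `(x, y)` of the top-left outer corner.
#' @param cell_size positive cell edge length in metres (cells are square).
#' @param nodata sentinel written to disk for `NA` cells.
#' @param crs opaque coordinate-reference identifier carried along unchanged.
#' @return A `raster_grid` object.
#' @examples
#' g <- raster_grid(matrix(1:12, 3, 4), origin = c(0, 90), cell_size = 30)
#' dim(g$values)
#' @export
raster_grid <- function(values, origin = c(0, nrow(values) * cell_size),
                        cell_size = 1, nodata = -9999, crs = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    abort("`cell_size` must be a single positive number (square cells).")
  }
  if (length(origin) != 2L || !all(is.finite(origin))) {
    abort("`origin` must be two finite world coordinates (x, y).")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    abort("raster values must be finite or NA (nodata).")
  }
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), nodata = nodata, crs = crs),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, %g m cell size\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  origin (top-left corner): (%g, %g)\n", x$origin[1], x$origin[2]))
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  values: [%g, %g], %d NA cells\n",
                min(fin), max(fin), sum(is.na(v))))
  } else {
    cat("  values: all NA\n")
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Tabulate a raster as cell-centre coordinates plus values
#'
#' @param x a [raster_grid()].
#' @param ... unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @importFrom tibble as_tibble
#' @method as_tibble raster_grid
#' @export
as_tibble.raster_grid <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  cc <- cell_center(x, rep(seq_len(nr), times = nc), rep(seq_len(nc), each = nr))
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = cc$x, y = cc$y,
    value = as.vector(x$values)
  )
}

#' World coordinates of cell centres
#'
#' @param grid a [raster_grid()].
#' @param row,col cell indices (vectorised).
#' @return list with numeric `x` and `y`.
#' @export
cell_center <- function(grid, row, col) {
  list(x = grid$origin[1] + (col - 0.5) * grid$cell_size,
       y = grid$origin[2] - (row - 0.5) * grid$cell_size)
}

#' Cell indices containing world points
#'
#' Points on a shared cell edge map to the cell with the larger index; points
#' outside the extent get `NA` indices.
#'
#' @param grid a [raster_grid()].
#' @param x,y world coordinates (vectorised).
#' @return list with integer `row` and `col` (`NA` outside the extent).
#' @export
world_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  row <- floor((grid$origin[2] - y) / grid$cell_size) + 1L
  bad <- row < 1L | row > nrow(grid$values) | col < 1L | col > ncol(grid$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Reads the plain-text `.asc` raster format: a six-line header
#' (`ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`,
#' `cellsize`, `NODATA_value`) followed by rows of cell values, north first.
#' Files declaring rectangular cells (`dx`/`dy` headers) are rejected: the
#' toolkit works on square cells only.
#'
#' @param path file to read.
#' @param crs optional CRS tag to attach (the format itself carries none).
#' @return A [raster_grid()]; sentinel cells become `NA`.
#' @export
read_ascii_raster <- function(path, crs = "") {
  if (!file.exists(path)) abort(paste0("no such raster file: ", path))
  lines <- readLines(path, n = 12L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  if (any(c("dx", "dy") %in% names(hdr))) {
    abort("raster declares rectangular cells (dx/dy); only square cells are supported.")
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort(paste0("not an ESRI ASCII grid (missing header): ", path))
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc) {
    abort(sprintf("expected %d cell values, found %d in %s", nr * nc,
                  length(vals), path))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  # llcorner/llcenter -> top-left outer corner
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  raster_grid(m, origin = c(xll, yll + nr * cs), cell_size = cs,
              nodata = nodata, crs = crs)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with 17 significant digits so that write/read round-trips
#' are lossless for doubles; `NA` cells are written as the grid's nodata
#' sentinel.
#'
#' @param grid a [raster_grid()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_ascii_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  yll <- grid$origin[2] - nr * grid$cell_size
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", grid$origin[1]),
    sprintf("yllcorner %.17g", yll),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", grid$nodata)
  )
  v[is.na(v)] <- grid$nodata
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# internal: check two grids share dimension, origin, cell size
check_coregistered <- function(a, b, what = "grids") {
  if (!identical(dim(a$values), dim(b$values)) ||
      any(abs(a$origin - b$origin) > 1e-9) ||
      abs(a$cell_size - b$cell_size) > 1e-12) {
    abort(paste0(what, " are not co-registered (dimension, origin and cell size must match)."))
  }
  invisible(TRUE)
}
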