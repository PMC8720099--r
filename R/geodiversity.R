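#' Class counts in a plot's 3x3 pixel neighbourhood
#'
#' Extracts the central pixel of a plot plus all adjacent pixels - nine
#' pixels for an interior, nodata-free centre - from a classified raster and
#' tabulates the frequency of each class. Each class plays the role of a
#' "species" whose abundance is its pixel frequency. Off-grid and missing
#' cells are dropped and the result is flagged as truncated; `strict = TRUE`
#' turns truncation into an error.
#'
#' @param classified a [classify_raster()] result.
#' @param row,col cell index of the plot's central pixel.
#' @param strict error instead of truncating edge/nodata neighbourhoods.
#' @return A `neighborhood_counts` object: named integer `counts` (one entry
#'   per class present), `total` cells used, and a `truncated` flag.
#' @export
neighborhood_counts <- function(classified, row, col, strict = FALSE) {
  stopifnot(inherits(classified, "classified_raster"))
  lab <- classified$labels
  nr <- nrow(lab); nc <- ncol(lab)
  if (row < 1L || row > nr || col < 1L || col > nc) {
    abort(sprintf("centre cell (%d, %d) is outside the %d x %d grid.",
                  row, col, nr, nc))
  }
  rows <- max(1L, row - 1L):min(nr, row + 1L)
  cols <- max(1L, col - 1L):min(nc, col + 1L)
  block <- lab[rows, cols]
  vals <- block[!is.na(block)]
  truncated <- length(vals) < 9L
  if (length(vals) == 0L) {
    abort(sprintf("all cells in the neighbourhood of (%d, %d) are nodata.",
                  row, col))
  }
  if (strict && truncated) {
    abort(sprintf("truncated neighbourhood at (%d, %d) in strict mode.",
                  row, col))
  }
  cnt <- table(vals)
  structure(
    list(counts = setNames(as.integer(cnt), names(cnt)),
         total = length(vals), truncated = truncated),
    class = "neighborhood_counts"
  )
}

#' @export
print.neighborhood_counts <- function(x, ...) {
  cat(sprintf("<neighborhood_counts> %d cells%s: ", x$total,
              if (x$truncated) " (truncated)" else ""))
  cat(paste0(names(x$counts), ":", x$counts, collapse = "  "), "\n")
  invisible(x)
}

#' Shannon entropy of counts or proportions
#'
#' `H = -sum(p_i * log(p_i))` with `p_i = x_i / sum(x)`; zero entries
#' contribute nothing. This is the diversity measure applied both to class
#' frequencies in a plot neighbourhood (geodiversity) and to species
#' abundances (plug-in taxon diversity).
#'
#' @param x non-negative counts or proportions (a numeric vector or a
#'   [neighborhood_counts()] object).
#' @param base logarithm base; natural log (nats) by default, the ecology
#'   convention.
#' @return Entropy in units of `log(base)`.
#' @examples
#' shannon_entropy(c(3, 3, 3))  # log(3)
#' @export
shannon_entropy <- function(x, base = exp(1)) {
  if (inherits(x, "neighborhood_counts")) x <- x$counts
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x) || any(x < 0)) {
    abort("`x` must be non-negative counts or proportions.")
  }
  s <- sum(x)
  if (s <= 0) abort("`x` must contain at least one positive entry.")
  p <- x[x > 0] / s
  -sum(p * log(p)) / log(base)
}

#' Compound geodiversity index
#'
#' Sums the per-variable neighbourhood Shannon diversities into the single
#' compound index `G = sum(H_j)`, treating each classified environmental
#' variable like a taxon in a multi-taxon summed-diversity analysis.
#'
#' @param per_variable_h numeric vector of per-variable entropies (nats).
#' @return The compound index `G` in nats.
#' @export
compound_geodiversity <- function(per_variable_h) {
  per_variable_h <- as.numeric(per_variable_h)
  if (length(per_variable_h) == 0L) abort("need at least one per-variable entropy.")
  if (anyNA(per_variable_h)) abort("per-variable entropies must not be NA.")
  sum(per_variable_h)
}

#' Geodiversity index at plots
#'
#' The full compound-index construction: each environmental raster is
#' classified into (at most) `k` classes with Fisher-style optimal intervals
#' computed over all its finite cells, the 3x3 pixel neighbourhood around the
#' cell containing each plot (polygon plots use their centroid) is extracted,
#' class frequencies give a per-variable Shannon diversity, and the compound
#' index is the sum over variables.
#'
#' @param grids named list of [raster_grid()]s (the selected environmental
#'   variables; three in the study design).
#' @param plots data frame with `plot_id` and `x`/`y` (or a `geometry`
#'   list-column; centroids are used).
#' @param k classes per variable (default 5).
#' @param strict error on truncated neighbourhoods instead of renormalising
#'   over the available cells.
#' @return A tibble with `plot_id`, one `H_<variable>` column per raster,
#'   `compound_g`, and a `truncated` flag (TRUE if any variable's
#'   neighbourhood was truncated).
#' @export
geodiversity_at_plots <- function(grids, plots, k = 5L, strict = FALSE) {
  if (!is.list(grids) || length(grids) == 0L || is.null(names(grids)) ||
      any(names(grids) == "")) {
    abort("`grids` must be a non-empty named list of raster_grid objects.")
  }
  plots <- tibble::as_tibble(plots)
  pts <- plot_points(plots)
  per_var <- purrr::imap(grids, function(g, nm) {
    stopifnot(inherits(g, "raster_grid"))
    br <- fisher_breaks(g$values[is.finite(g$values)], k = k)
    cls <- classify_raster(g, br)
    purrr::map(seq_len(nrow(pts)), function(i) {
      rc <- world_to_cell(cls_as_grid(cls), pts$x[i], pts$y[i])
      if (is.na(rc$row)) {
        abort(sprintf("plot '%s' lies outside raster '%s'.", pts$plot_id[i], nm))
      }
      nb <- neighborhood_counts(cls, rc$row, rc$col, strict = strict)
      list(h = shannon_entropy(nb), truncated = nb$truncated)
    })
  })
  out <- tibble::tibble(plot_id = pts$plot_id)
  for (nm in names(per_var)) {
    out[[paste0("H_", nm)]] <- purrr::map_dbl(per_var[[nm]], "h")
  }
  out$compound_g <- rowSums(as.matrix(out[paste0("H_", names(per_var))]))
  out$truncated <- purrr::reduce(
    purrr::map(per_var, ~ purrr::map_lgl(.x, "truncated")), `|`
  )
  out
}

# classified_raster shares geometry fields with raster_grid; adapter for
# world_to_cell
cls_as_grid <- function(cls) {
  structure(list(values = cls$labels, origin = cls$origin,
                 cell_size = cls$cell_size, nodata = NA, crs = ""),
            class = "raster_grid")
}

# point coordinates per plot (polygon centroid when a geometry is present)
plot_points <- function(plots) {
  if ("geometry" %in% names(plots)) {
    xy <- purrr::map(seq_len(nrow(plots)), function(i) {
      g <- plots$geometry[[i]]
      if (is.null(g)) c(plots$x[i], plots$y[i]) else polygon_centroid(as.matrix(g))
    })
    tibble::tibble(plot_id = plots$plot_id,
                   x = purrr::map_dbl(xy, 1), y = purrr::map_dbl(xy, 2))
  } else {
    if (!all(c("x", "y") %in% names(plots))) {
      abort("`plots` needs `x`/`y` columns or a `geometry` list-column.")
    }
    tibble::tibble(plot_id = plots$plot_id, x = plots$x, y = plots$y)
  }
}
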