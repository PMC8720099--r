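#' Three-set variance partitioning of a GAM's explained deviance
#'
#' Decomposes the explained deviance of the full three-predictor GAM into
#' seven components by inclusion-exclusion over the seven subset models
#' (three single-predictor, three two-predictor, one full): the pure
#' fractions explained exclusively by the climate, habitat and soil
#' predictors, the three pairwise-shared fractions, and the triple-shared
#' fraction. With `D(S)` the explained deviance of the GAM on subset `S` and
#' groups A = climate, B = habitat, C = soil:
#'
#' * `pure_climate  = D(ABC) - D(BC)` (likewise for habitat and soil),
#' * `shared_climate_habitat = D(AC) + D(BC) - D(C) - D(ABC)` (cyclically),
#' * `shared_all = D(ABC) - (sum of the other six)`.
#'
#' Components therefore sum to `D(ABC)` exactly. Shared fractions can be
#' negative: a negative value means the deviance explained by the predictors
#' jointly is less than the sum of their separate contributions (e.g.
#' suppression); negative values are reported as-is, never truncated.
#'
#' For comparability, every subset model is fitted with its smoothing
#' parameters frozen at the values estimated in the full three-predictor
#' model (`freeze = "sp"`, the default); `freeze = "none"` re-estimates
#' smoothing per subset instead.
#'
#' @param data data frame with the response and three predictor columns.
#' @param response response column name.
#' @param climate,habitat,soil names of the three predictor columns.
#' @param k basis functions per smooth (default 4).
#' @param freeze `"sp"` (freeze subset smoothing parameters at the full
#'   model's values) or `"none"`.
#' @return A `geodiv_vp` object: `components` (named length-7 numeric),
#'   `subset_deviance` (named length-7, `D(S)` per subset), `full_deviance`,
#'   `groups`, and the full fit under `fit_full`.
#' @export
variance_partition <- function(data, response, climate, habitat, soil,
                               k = 4L, freeze = c("sp", "none")) {
  freeze <- match.arg(freeze)
  preds <- c(climate = climate, habitat = habitat, soil = soil)
  if (anyDuplicated(unname(preds))) {
    warn("predictor columns are not distinct; shared fractions absorb everything.")
  }
  full <- fit_gam(data, response, unname(preds), k = k)
  sp_full <- setNames(full$sp, unname(preds))
  subfit <- function(vars) {
    sp <- if (freeze == "sp") unname(sp_full[vars]) else NULL
    fit_gam(data, response, vars, k = k, sp = sp)$explained_deviance
  }
  A <- preds[["climate"]]; B <- preds[["habitat"]]; C <- preds[["soil"]]
  D <- c(A   = subfit(A),          B  = subfit(B),         C = subfit(C),
         AB  = subfit(c(A, B)),    AC = subfit(c(A, C)),
         BC  = subfit(c(B, C)),    ABC = full$explained_deviance)
  a <- D[["ABC"]] - D[["BC"]]
  b <- D[["ABC"]] - D[["AC"]]
  c_ <- D[["ABC"]] - D[["AB"]]
  d <- D[["AC"]] + D[["BC"]] - D[["C"]] - D[["ABC"]]
  e <- D[["AB"]] + D[["AC"]] - D[["A"]] - D[["ABC"]]
  f <- D[["AB"]] + D[["BC"]] - D[["B"]] - D[["ABC"]]
  g <- D[["ABC"]] - (a + b + c_ + d + e + f)
  structure(
    list(components = c(pure_climate = a, pure_habitat = b, pure_soil = c_,
                        shared_climate_habitat = d, shared_habitat_soil = e,
                        shared_climate_soil = f, shared_all = g),
         subset_deviance = D, full_deviance = D[["ABC"]],
         groups = preds, fit_full = full),
    class = "geodiv_vp"
  )
}

#' @export
print.geodiv_vp <- function(x, ...) {
  cat(sprintf("<geodiv_vp> full explained deviance %.3f (climate = %s, habitat = %s, soil = %s)\n",
              x$full_deviance, x$groups[["climate"]], x$groups[["habitat"]],
              x$groups[["soil"]]))
  print(round(x$components, 4))
  invisible(x)
}

#' @describeIn variance_partition components as a tibble
#'   (`component`, `fraction`).
#' @param x a `geodiv_vp` object.
#' @param ... unused.
#' @method tidy geodiv_vp
#' @export
tidy.geodiv_vp <- function(x, ...) {
  tibble::tibble(component = names(x$components),
                 fraction = unname(x$components))
}

#' @describeIn variance_partition one-row summary (full deviance, pure and
#'   shared totals).
#' @method glance geodiv_vp
#' @export
glance.geodiv_vp <- function(x, ...) {
  cmp <- x$components
  tibble::tibble(full_deviance = x$full_deviance,
                 pure_total = sum(cmp[startsWith(names(cmp), "pure")]),
                 shared_total = sum(cmp[startsWith(names(cmp), "shared")]))
}
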