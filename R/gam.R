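#' Fit an additive model with limited-flexibility smooths
#'
#' Fits a Gaussian identity-link GAM with one penalized cubic-regression-
#' spline smooth per predictor. Each smooth gets a 4-function basis, so its
#' effective degrees of freedom can vary between 1 (exactly linear; the
#' penalty null space) and 3, with smoothing chosen by generalized
#' cross-validation - linear relationships are recovered as linear fits.
#'
#' @param data data frame holding response and predictor columns.
#' @param response name of the response column.
#' @param predictors character vector of 1-3 predictor column names.
#' @param k basis functions per smooth (default 4, i.e. max edf 3).
#' @param sp optional fixed smoothing parameters (one per predictor), e.g.
#'   frozen from a richer model for comparability of nested fits.
#' @return A `geodiv_gam` object wrapping the `mgcv` fit with its summary:
#'   per-term edf, intercept, explained deviance (`1 - RSS/RSS_null` for the
#'   Gaussian family), adjusted R-squared, AIC, GCV score, `n`.
#' @examples
#' d <- data.frame(x = 1:40, y = 2 * (1:40))
#' fit <- fit_gam(d, "y", "x")
#' glance(fit)
#' @export
fit_gam <- function(data, response, predictors, k = 4L, sp = NULL) {
  data <- as.data.frame(data)
  if (!response %in% names(data)) abort(sprintf("response '%s' not in data.", response))
  missing_p <- setdiff(predictors, names(data))
  if (length(missing_p)) {
    abort(paste0("predictors not in data: ", paste(missing_p, collapse = ", ")))
  }
  if (length(predictors) < 1L || length(predictors) > 3L) {
    abort("supply between one and three predictors.")
  }
  cols <- data[c(response, predictors)]
  if (any(!vapply(cols, is.numeric, TRUE)) || anyNA(cols) ||
      any(!vapply(cols, function(x) all(is.finite(x)), TRUE))) {
    abort("response and predictors must be finite numeric columns.")
  }
  n <- nrow(data)
  basis_size <- 1L + (k - 1L) * length(predictors)
  if (n <= basis_size) {
    abort(sprintf("n = %d is too small for %d predictor smooth(s) (need n > %d).",
                  n, length(predictors), basis_size))
  }
  rhs <- paste(sprintf("s(%s, bs = \"cr\", k = %d)", predictors, k),
               collapse = " + ")
  fml <- as.formula(paste(response, "~", rhs))
  fit <- mgcv::gam(fml, data = data, family = stats::gaussian(),
                   method = "GCV.Cp", sp = sp)
  sm <- summary(fit)
  structure(
    list(model = fit, response = response, predictors = predictors,
         intercept = unname(coef(fit)[1]),
         edf = setNames(as.numeric(sm$edf), predictors),
         edf_total = sum(fit$edf),
         explained_deviance = as.numeric(sm$dev.expl),
         adj_r2 = as.numeric(sm$r.sq),
         aic = AIC(fit), gcv = as.numeric(fit$gcv.ubre),
         sp = fit$sp, n = n),
    class = "geodiv_gam"
  )
}

#' Explained deviance of a fitted model
#'
#' For the Gaussian family this is `1 - RSS / RSS_null`, the share of the
#' null deviance removed by the model (the GAM analogue of R-squared).
#'
#' @param fit a [fit_gam()] result.
#' @return Fraction of deviance explained.
#' @export
explained_deviance <- function(fit) {
  stopifnot(inherits(fit, "geodiv_gam"))
  fit$explained_deviance
}

#' @export
print.geodiv_gam <- function(x, ...) {
  cat(sprintf("<geodiv_gam> %s ~ %s\n", x$response,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  n = %d, expl. deviance = %.3f, adj R2 = %.3f, AIC = %.2f\n",
              x$n, x$explained_deviance, x$adj_r2, x$aic))
  cat("  edf:", paste(sprintf("%s %.2f", names(x$edf), x$edf), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn fit_gam per-term smooth summary (term, edf, F, p-value).
#' @param x a `geodiv_gam` object.
#' @param ... unused.
#' @method tidy geodiv_gam
#' @export
tidy.geodiv_gam <- function(x, ...) {
  sm <- summary(x$model)
  tibble::tibble(term = x$predictors,
                 edf = as.numeric(sm$edf),
                 ref_df = as.numeric(sm$s.table[, "Ref.df"]),
                 statistic = as.numeric(sm$s.table[, "F"]),
                 p.value = as.numeric(sm$s.table[, "p-value"]))
}

#' @describeIn fit_gam one-row model-level summary.
#' @method glance geodiv_gam
#' @export
glance.geodiv_gam <- function(x, ...) {
  tibble::tibble(nobs = x$n, intercept = x$intercept,
                 edf_total = x$edf_total, adj_r2 = x$adj_r2,
                 deviance_explained = x$explained_deviance,
                 aic = x$aic, gcv = x$gcv)
}

#' Flag collinear predictor pairs
#'
#' Reports every unordered pair of candidate predictors whose absolute
#' Pearson correlation exceeds the threshold; the study rule replaces a
#' predictor combination whenever any pair has `|r| > 0.6`. Zero-variance
#' candidates are reported with a warning and excluded from pairing.
#'
#' @param data data frame of candidate predictor columns.
#' @param vars columns to screen (default: all numeric columns).
#' @param threshold absolute correlation cutoff (default 0.6).
#' @return A tibble `var1`, `var2`, `r` (possibly empty), ordered by
#'   decreasing `|r|`.
#' @export
collinearity_screen <- function(data, vars = NULL, threshold = 0.6) {
  data <- as.data.frame(data)
  if (is.null(vars)) vars <- names(data)[vapply(data, is.numeric, TRUE)]
  if (length(vars) < 2L) abort("need at least two candidate predictors.")
  if (nrow(data) < 3L) abort("need n >= 3 observations.")
  sds <- vapply(data[vars], sd, 0)
  if (any(sds == 0)) {
    warn(paste0("zero-variance candidates excluded: ",
                paste(vars[sds == 0], collapse = ", ")))
    vars <- vars[sds > 0]
  }
  if (length(vars) < 2L) return(tibble::tibble(var1 = character(),
                                               var2 = character(), r = numeric()))
  cm <- cor(data[vars])
  pairs <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  out <- tibble::tibble(var1 = vars[pairs[, 1]], var2 = vars[pairs[, 2]],
                        r = cm[pairs])
  dplyr::arrange(out, dplyr::desc(abs(.data$r)))
}

#' Choose among predictor variants by AIC
#'
#' Fits a univariate GAM of the response on each variant (e.g. the mean,
#' maximum and standard deviation statistics of one climate variable) and
#' returns the name of the variant whose model has the smallest AIC. Exact
#' AIC ties (within `1e-9`) break deterministically toward the first variant
#' name in alphabetical order.
#'
#' @param data data frame with the response and all variant columns.
#' @param response response column name.
#' @param variants character vector of candidate column names.
#' @return The chosen variant name, with the AIC table as attribute `"aic"`.
#' @export
select_by_aic <- function(data, response, variants) {
  if (length(variants) < 1L) abort("need at least one variant.")
  if (length(variants) == 1L) return(variants)
  fits <- purrr::map(variants, function(v) {
    tryCatch(fit_gam(data, response, v), error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) abort("all variant fits failed.")
  aic <- vapply(fits[ok], function(f) f$aic, 0)
  names(aic) <- variants[ok]
  best <- aic[order(aic, names(aic))]       # tie -> name order
  chosen <- names(best)[abs(best - best[1]) < 1e-9][1]
  structure(chosen, aic = aic)
}

#' Bidirectional stepwise multiple linear regression
#'
#' AIC-guided forward/backward selection from the intercept-only model over
#' the candidate terms - the procedure used to build spatial soil-variable
#' prediction models.
#'
#' @param data data frame with response and candidates.
#' @param response response column name.
#' @param candidates character vector of candidate predictor columns.
#' @return A `stepwise_fit`: list with `terms` (selected, possibly empty),
#'   `coefficients`, `adj_r2`, `model` (the `lm`), `response`.
#' @export
stepwise_linear <- function(data, response, candidates) {
  data <- as.data.frame(data)[c(response, candidates)]
  if (anyNA(data)) abort("stepwise selection needs complete cases.")
  if (nrow(data) <= length(candidates) + 1L) {
    abort("need n > number of candidates + 1.")
  }
  null_fml <- as.formula(paste(response, "~ 1"))
  full_fml <- as.formula(paste(response, "~", paste(candidates, collapse = " + ")))
  base <- lm(null_fml, data = data)
  sel <- step(base, scope = list(lower = null_fml, upper = full_fml),
              direction = "both", trace = 0)
  terms <- setdiff(attr(stats::terms(sel), "term.labels"), "1")
  structure(
    list(terms = terms, coefficients = coef(sel),
         adj_r2 = summary(sel)$adj.r.squared, model = sel,
         response = response),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> %s ~ %s (adj R2 = %.3f)\n", x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$adj_r2))
  invisible(x)
}

#' @describeIn stepwise_linear one-row summary of a stepwise fit.
#' @param x a `stepwise_fit`.
#' @param ... unused.
#' @method glance stepwise_fit
#' @export
glance.stepwise_fit <- function(x, ...) {
  tibble::tibble(response = x$response, n_terms = length(x$terms),
                 terms = paste(x$terms, collapse = " + "),
                 adj_r2 = x$adj_r2, aic = AIC(x$model))
}

#' Retain models above an adjusted-R-squared floor
#'
#' The soil-modelling retention rule: only prediction models explaining more
#' than the threshold share of variance (default 45%) are kept for spatial
#' prediction.
#'
#' @param fits a list of [stepwise_linear()] fits or a data frame with an
#'   `adj_r2` column.
#' @param min_adj_r2 retention threshold (strictly greater than).
#' @return The retained subset, same shape as the input.
#' @export
filter_soil_models <- function(fits, min_adj_r2 = 0.45) {
  if (is.data.frame(fits)) {
    if (!"adj_r2" %in% names(fits)) abort("data frame needs an `adj_r2` column.")
    return(dplyr::filter(tibble::as_tibble(fits), .data$adj_r2 > min_adj_r2))
  }
  keep <- vapply(fits, function(f) f$adj_r2 > min_adj_r2, TRUE)
  fits[keep]
}
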