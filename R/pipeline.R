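#' Run the geodiversity-versus-environment comparison on a landscape
#'
#' Orchestrates the full analysis for each response (taxon diversity and/or
#' ecosystem function) of a landscape bundle:
#'
#' 1. extract every candidate predictor at the plots;
#' 2. choose the climate statistic by AIC of univariate GAMs
#'    ([select_by_aic()]); habitat and soil candidates come from
#'    configuration (their field choice is knowledge-guided, not automatable);
#' 3. apply the collinearity rule: if any pair of the chosen triple has
#'    `|r| > 0.6`, switch to the best-AIC non-collinear combination of
#'    candidates;
#' 4. standardize taxon diversity to complete coverage
#'    ([diversity_by_plot()]);
#' 5. fit the environment model (three-predictor GAM) and the geodiversity
#'    model (univariate GAM on the compound index built from the *same*
#'    three rasters, [geodiversity_at_plots()]);
#' 6. variance-partition the environment model
#'    ([variance_partition()]).
#'
#' The same selected triple feeds both model families by construction. A
#' failure in one response is logged and recorded; other responses continue.
#'
#' @param bundle a [generate_landscape()] result (or an equivalently shaped
#'   list built from files).
#' @param responses which responses to analyse: `"diversity"`,
#'   `"function"`, or both (default).
#' @param climate_candidates,habitat_candidates,soil_candidates raster names
#'   considered per group; the climate set is compared by AIC, the first
#'   habitat/soil candidate is used unless the collinearity rule forces a
#'   swap.
#' @param k classes for the geodiversity index (default 5).
#' @param scale diversity scale, `"hill"` (default) or `"entropy"`.
#' @param r_threshold collinearity cutoff (default 0.6).
#' @return A `study_result`: tibble with one row per response (`response`,
#'   selected predictor names, `env_deviance`, `geodiv_deviance`,
#'   `env_adj_r2`, `geodiv_adj_r2`, `error`) carrying list-columns
#'   `env_fit`, `geodiv_fit`, `vp`; attributes hold the per-plot analysis
#'   table and the diversity-function Pearson correlation.
#' @export
run_study <- function(bundle,
                      responses = c("diversity", "function"),
                      climate_candidates = c("temp_mean", "temp_max", "temp_sd",
                                             "humidity"),
                      habitat_candidates = c("ndvi", "tpi"),
                      soil_candidates = c("phosphorus", "ph", "organic_depth"),
                      k = 5L, scale = c("hill", "entropy"),
                      r_threshold = 0.6) {
  scale <- match.arg(scale)
  responses <- match.arg(responses, several.ok = TRUE)
  all_cand <- c(climate_candidates, habitat_candidates, soil_candidates)
  missing_r <- setdiff(all_cand, names(bundle$rasters))
  if (length(missing_r)) {
    abort(paste0("bundle lacks candidate rasters: ",
                 paste(missing_r, collapse = ", ")))
  }

  # per-plot predictor table
  pred <- bundle$plots["plot_id"]
  for (nm in all_cand) {
    pred[[nm]] <- extract_plot_values(bundle$plots, bundle$rasters[[nm]])$value
  }

  div <- diversity_by_plot(bundle$community, scale = scale)
  resp_tbl <- dplyr::left_join(pred, div[c("plot_id", "diversity")], by = "plot_id")
  resp_tbl <- dplyr::left_join(resp_tbl,
                               dplyr::rename(bundle$functions,
                                             func_value = "value"),
                               by = "plot_id")

  rows <- purrr::map(responses, function(resp) {
    ycol <- if (resp == "diversity") "diversity" else "func_value"
    tryCatch(
      analyse_response(bundle, resp_tbl, resp, ycol, climate_candidates,
                       habitat_candidates, soil_candidates, k, r_threshold),
      error = function(e) {
        message(sprintf("[run_study] response '%s' failed: %s", resp,
                        conditionMessage(e)))
        tibble::tibble(response = resp, climate = NA_character_,
                       habitat = NA_character_, soil = NA_character_,
                       env_deviance = NA_real_, geodiv_deviance = NA_real_,
                       env_adj_r2 = NA_real_, geodiv_adj_r2 = NA_real_,
                       env_fit = list(NULL), geodiv_fit = list(NULL),
                       vp = list(NULL), error = conditionMessage(e))
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "plot_table") <- resp_tbl
  attr(out, "diversity_function_r") <- tryCatch(
    suppressWarnings(cor(resp_tbl$diversity, resp_tbl$func_value,
                         use = "complete.obs")),
    error = function(e) NA_real_)
  class(out) <- c("study_result", class(out))
  out
}

analyse_response <- function(bundle, resp_tbl, resp, ycol, climate_candidates,
                             habitat_candidates, soil_candidates, k,
                             r_threshold) {
  d <- as.data.frame(resp_tbl[!is.na(resp_tbl[[ycol]]), ])
  triple <- select_triple(d, ycol, climate_candidates, habitat_candidates,
                          soil_candidates, r_threshold)
  env_fit <- fit_gam(d, ycol, unname(triple))
  geo <- geodiversity_at_plots(bundle$rasters[unname(triple)],
                               bundle$plots[bundle$plots$plot_id %in% d$plot_id, ],
                               k = k)
  d <- dplyr::left_join(d, geo[c("plot_id", "compound_g")], by = "plot_id")
  geo_fit <- fit_gam(d, ycol, "compound_g")
  vp <- variance_partition(d, ycol, climate = triple[["climate"]],
                           habitat = triple[["habitat"]],
                           soil = triple[["soil"]])
  tibble::tibble(response = resp,
                 climate = triple[["climate"]], habitat = triple[["habitat"]],
                 soil = triple[["soil"]],
                 env_deviance = env_fit$explained_deviance,
                 geodiv_deviance = geo_fit$explained_deviance,
                 env_adj_r2 = env_fit$adj_r2, geodiv_adj_r2 = geo_fit$adj_r2,
                 env_fit = list(env_fit), geodiv_fit = list(geo_fit),
                 vp = list(vp), error = NA_character_)
}

# climate slot by AIC among its statistics; habitat/soil default to the first
# configured candidate; if the triple violates the collinearity rule, walk
# the AIC-ranked candidate combinations and take the best non-collinear one
select_triple <- function(d, ycol, climate_candidates, habitat_candidates,
                          soil_candidates, r_threshold) {
  clim <- as.character(select_by_aic(d, ycol, climate_candidates))
  triple <- c(climate = clim, habitat = habitat_candidates[1],
              soil = soil_candidates[1])
  if (nrow(screen_triple(d, triple, r_threshold)) == 0L) return(triple)
  aic_of <- function(v) tryCatch(fit_gam(d, ycol, v)$aic, error = function(e) Inf)
  aics <- vapply(unique(c(climate_candidates, habitat_candidates,
                          soil_candidates)), aic_of, 0)
  combos <- expand.grid(climate = climate_candidates,
                        habitat = habitat_candidates,
                        soil = soil_candidates, stringsAsFactors = FALSE)
  combos$score <- aics[combos$climate] + aics[combos$habitat] + aics[combos$soil]
  combos <- combos[order(combos$score, combos$climate, combos$habitat,
                         combos$soil), ]
  for (i in seq_len(nrow(combos))) {
    cand <- c(climate = combos$climate[i], habitat = combos$habitat[i],
              soil = combos$soil[i])
    if (nrow(screen_triple(d, cand, r_threshold)) == 0L) return(cand)
  }
  warn("every candidate triple is collinear; keeping the default triple.")
  triple
}

screen_triple <- function(d, triple, r_threshold) {
  collinearity_screen(d, vars = unname(triple), threshold = r_threshold)
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  print(tidy(x))
  r <- attr(x, "diversity_function_r")
  if (!is.null(r) && is.finite(r)) {
    cat(sprintf("diversity-function Pearson r = %.2f\n", r))
  }
  invisible(x)
}

#' @describeIn run_study per-response summary without list-columns.
#' @param x a `study_result`.
#' @param ... unused.
#' @method tidy study_result
#' @export
tidy.study_result <- function(x, ...) {
  tibble::as_tibble(x)[c("response", "climate", "habitat", "soil",
                         "env_deviance", "geodiv_deviance", "env_adj_r2",
                         "geodiv_adj_r2", "error")]
}

#' Write the comparison report to disk
#'
#' Emits `comparison.csv` (per-response model table mirroring the
#' environment-versus-geodiversity summary), `varpart.csv` (seven fractions
#' per response), `report.json` (everything, machine-readable) and
#' `run_log.txt` (stage log with a configuration fingerprint).
#'
#' @param result a [run_study()] result.
#' @param dir output directory (created if needed).
#' @param config optional [scenario_config()] to fingerprint in the log.
#' @return Invisibly, the paths written.
#' @export
emit_report <- function(result, dir, config = NULL) {
  stopifnot(inherits(result, "study_result"))
  if (nrow(result) == 0L) abort("empty result; nothing to report.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comparison <- tidy(result)
  model_rows <- purrr::map(seq_len(nrow(result)), function(i) {
    ef <- result$env_fit[[i]]; gf <- result$geodiv_fit[[i]]
    if (is.null(ef)) return(NULL)
    dplyr::bind_rows(
      dplyr::mutate(glance(ef), response = result$response[i], model = "environment"),
      dplyr::mutate(glance(gf), response = result$response[i], model = "geodiversity")
    )
  })
  models <- dplyr::bind_rows(model_rows)
  vparts <- dplyr::bind_rows(purrr::map(seq_len(nrow(result)), function(i) {
    v <- result$vp[[i]]
    if (is.null(v)) return(NULL)
    dplyr::mutate(tidy(v), response = result$response[i])
  }))
  paths <- c(comparison = file.path(dir, "comparison.csv"),
             models = file.path(dir, "models.csv"),
             varpart = file.path(dir, "varpart.csv"),
             json = file.path(dir, "report.json"),
             log = file.path(dir, "run_log.txt"))
  utils::write.csv(comparison, paths[["comparison"]], row.names = FALSE)
  utils::write.csv(models, paths[["models"]], row.names = FALSE)
  utils::write.csv(vparts, paths[["varpart"]], row.names = FALSE)
  jsonlite::write_json(
    list(comparison = comparison, models = models, varpart = vparts,
         diversity_function_r = attr(result, "diversity_function_r")),
    paths[["json"]], auto_unbox = TRUE, digits = NA, na = "null")
  fp <- if (is.null(config)) "none" else rlang::hash(unclass(config))
  writeLines(c(
    sprintf("config_fingerprint: %s", fp),
    sprintf("seed: %s", if (is.null(config)) "none" else config$seed),
    sprintf("responses: %s", paste(result$response, collapse = ", ")),
    sprintf("stages: extract, select, diversity, env_gam, geodiv_gam, varpart, report")
  ), paths[["log"]])
  invisible(paths)
}
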