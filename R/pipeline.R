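#' Run the discovery/validation analysis for one region
#'
#' End-to-end driver over a cohort: aggregate spine traits per case, merge
#' with covariates, drop cases with missing required scores, split the
#' remainder into discovery and validation halves, select memory-associated
#' spine traits on the discovery half by cross-validated LASSO, and compare
#' the nested linear models on the validation half by LOOCV MSE (optionally
#' with bootstrap MSE intervals).
#'
#' @param cohort a \code{\link{generate_cohort}} result, or a list with
#'   \code{spines}, \code{segments}, \code{cases} tables in the same
#'   schemas.
#' @param region region label to analyse.
#' @param split_seed seed for the discovery/validation split.
#' @param lasso_cfg a \code{\link{lasso_config}}.
#' @param specs nested model list; defaults to
#'   \code{\link{default_model_specs}}.
#' @param bootstrap_B bootstrap replicates for the per-model MSE interval
#'   (0 skips the bootstrap).
#' @param bootstrap_level interval coverage.
#' @param aggregation spine-trait averaging convention; see
#'   \code{\link{aggregate_features}}.
#' @return List: features, analysis (filtered merged table), discovery,
#'   validation, lasso (lasso_result), trait_ranking, models
#'   (\code{\link{compare_models}} output), bootstrap (named list of
#'   intervals or NULL), n_removed.
#' @export
run_region_analysis <- function(cohort, region, split_seed = 111,
                                lasso_cfg = lasso_config(),
                                specs = default_model_specs(),
                                bootstrap_B = 0, bootstrap_level = 0.90,
                                aggregation = "pooled") {
  traits <- c("mean_density", "mean_length", "mean_head_diameter",
              "mean_volume")
  feats <- aggregate_features(cohort$spines, cohort$segments,
                              aggregation = aggregation)
  at <- analysis_table(feats, cohort$cases, region)
  at <- filter_complete_cases(at)
  n_removed <- length(attr(at, "removed_cases"))
  halves <- split_discovery_validation(at, seed = split_seed)
  disc <- halves$discovery
  X <- as.matrix(disc[, traits, with = FALSE])
  y <- disc$episodic_memory
  las <- select_lambda(X, y, lasso_cfg)
  ranking <- rank_traits(las)
  models <- compare_models(halves$validation, specs)
  boot <- NULL
  if (bootstrap_B > 0) {
    boot <- lapply(models$reports, function(r)
      bootstrap_mse_ci(halves$validation, r$spec, B = bootstrap_B,
                       level = bootstrap_level,
                       seed = substream_seed(split_seed, 7,
                                             nchar(r$spec$name))))
    names(boot) <- names(models$reports)
  }
  list(region = region, features = feats, analysis = at,
       discovery = disc, validation = halves$validation,
       lasso = las, trait_ranking = ranking, models = models,
       bootstrap = boot, n_removed = n_removed)
}
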