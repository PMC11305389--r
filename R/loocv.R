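#' Nested model specification
#'
#' @param name short model label.
#' @param predictors character vector of analysis-table column names; the
#'   pseudo-predictor \code{"1"} denotes the intercept-only model.
#' @return List of class \code{"model_spec"}.
#' @export
model_spec <- function(name, predictors) {
  if (!length(predictors)) stop("model must have at least one predictor")
  structure(list(name = name, predictors = unique(predictors)),
            class = "model_spec")
}

#' Default nested model set
#'
#' The comparison set used for validation: the full model (age, sex,
#' pathology scores, and the region's four spine traits), the full model
#' without age, pathology + sex + head diameter, pathology + sex,
#' pathology + head diameter, and pathology + sex + length.
#'
#' @param include_apoe4 add apoe4 to the full models (optional covariate;
#'   requires an \code{apoe4} column).
#' @return List of \code{\link{model_spec}} objects.
#' @export
default_model_specs <- function(include_apoe4 = FALSE) {
  path <- c("np_score", "nft_burden")
  traits <- c("mean_density", "mean_length", "mean_head_diameter",
              "mean_volume")
  full <- c("age", "sex", path, traits)
  if (include_apoe4) full <- c(full, "apoe4")
  list(
    model_spec("full", full),
    model_spec("full_minus_age", setdiff(full, "age")),
    model_spec("pathology_sex_head_diameter",
               c(path, "sex", "mean_head_diameter")),
    model_spec("pathology_sex", c(path, "sex")),
    model_spec("pathology_head_diameter", c(path, "mean_head_diameter")),
    model_spec("pathology_sex_length", c(path, "sex", "mean_length"))
  )
}

#' Leave-one-out cross-validation of a linear model
#'
#' Fits ordinary least squares with each row held out in turn and evaluates
#' the held-out squared prediction error, via the hat-matrix identity
#' e_(-i) = e_i / (1 - h_ii) (algebraically equal to n explicit refits).
#' Reports the LOOCV MSE, an R-squared on the pooled out-of-fold predictions
#' (1 - SSE_pred/SST about the observed mean), and the Pearson correlation
#' between observed and predicted values.
#'
#' @param table analysis table (one row per case).
#' @param spec a \code{\link{model_spec}}.
#' @param response response column name.
#' @return Object of class \code{"model_report"}: spec, n_used, loocv_mse,
#'   r_squared, pearson, predictions (case_id/observed/predicted).
#' @export
loocv_evaluate <- function(table, spec, response = "episodic_memory") {
  stopifnot(inherits(spec, "model_spec"))
  dt <- data.table::as.data.table(table)
  preds <- setdiff(spec$predictors, "1")
  miss <- setdiff(c(preds, response), names(dt))
  if (length(miss))
    stop("model '", spec$name, "' needs absent column(s): ",
         paste(miss, collapse = ", "))
  use <- stats::complete.cases(dt[, c(preds, response), with = FALSE])
  dt <- dt[use]
  n <- nrow(dt)
  p <- length(preds)
  if (n < p + 2)
    stop("model '", spec$name, "' has too few complete cases (", n, ")")
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (p) X <- cbind(X, as.matrix(dt[, preds, with = FALSE]))
  y <- dt[[response]]
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("singular design for model '", spec$name, "'")
  h <- rowSums(qr.Q(qx)^2)
  if (any(1 - h < 1e-10))
    stop("a leave-one-out fold is singular for model '", spec$name, "'")
  res <- y - X %*% qr.coef(qx, y)
  e_loo <- drop(res) / (1 - h)
  pred <- y - e_loo
  sst <- sum((y - mean(y))^2)
  structure(list(
    spec = spec,
    n_used = n,
    loocv_mse = mean(e_loo^2),
    r_squared = 1 - sum(e_loo^2) / sst,
    pearson = stats::cor(y, pred),
    predictions = data.table::data.table(
      case_id = if ("case_id" %in% names(dt)) dt$case_id else seq_len(n),
      observed = y, predicted = pred)), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model %-28s n=%d  MSE-CV=%.4f  R2=%.4f  r=%.4f\n",
              x$spec$name, x$n_used, x$loocv_mse, x$r_squared, x$pearson))
  invisible(x)
}

#' Compare nested models by LOOCV mean squared error
#'
#' Evaluates each candidate model on the same table and ranks them by
#' ascending LOOCV MSE (the smallest-MSE model best predicts the response).
#' Models with singular designs are reported and skipped.
#'
#' @param table analysis table.
#' @param specs list of \code{\link{model_spec}}s; defaults to
#'   \code{\link{default_model_specs}}.
#' @param response response column name.
#' @return List with \code{reports} (named, in ranked order) and
#'   \code{comparison} (data.table: model, n_used, loocv_mse, r_squared,
#'   pearson, rank).
#' @export
compare_models <- function(table, specs = default_model_specs(),
                           response = "episodic_memory") {
  if (length(specs) < 2) stop("need at least 2 model specs to compare")
  reports <- list()
  for (s in specs) {
    rep_s <- tryCatch(loocv_evaluate(table, s, response),
                      error = function(e) {
                        message("skipping model '", s$name, "': ",
                                conditionMessage(e))
                        NULL
                      })
    if (!is.null(rep_s)) reports[[length(reports) + 1]] <- rep_s
  }
  if (!length(reports)) stop("all candidate models failed")
  cmp <- data.table::rbindlist(lapply(reports, function(r)
    list(model = r$spec$name, n_used = r$n_used, loocv_mse = r$loocv_mse,
         r_squared = r$r_squared, pearson = r$pearson)))
  ord <- order(cmp$loocv_mse)
  cmp <- cmp[ord]
  cmp[, "rank" := seq_len(nrow(cmp))]
  reports <- reports[ord]
  names(reports) <- cmp$model
  list(reports = reports, comparison = cmp[])
}

#' Bootstrap percentile interval for the LOOCV MSE
#'
#' Case-level resampling with replacement: each replicate redraws whole
#' cases, recomputes the full LOOCV MSE on the resampled table, and the
#' interval is the percentile interval of the replicate MSEs at the
#' requested coverage (level 0 degenerates to the median replicate).
#' Replicates with singular designs are redrawn and counted.
#'
#' @param table analysis table.
#' @param spec a \code{\link{model_spec}}.
#' @param B number of bootstrap replicates (>= 100 recommended).
#' @param level interval coverage in [0, 1); default 0.90.
#' @param seed integer seed.
#' @param response response column name.
#' @return List: lower, upper, level, B, replicates (MSE vector),
#'   n_redrawn.
#' @export
bootstrap_mse_ci <- function(table, spec, B = 1000, level = 0.90,
                             seed = 1, response = "episodic_memory") {
  dt <- data.table::as.data.table(table)
  use <- stats::complete.cases(dt[, c(setdiff(spec$predictors, "1"),
                                      response), with = FALSE])
  dt <- dt[use]
  n <- nrow(dt)
  mses <- numeric(B)
  redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      for (try in 1:100) {
        idx <- sample(n, replace = TRUE)
        r <- tryCatch(loocv_evaluate(dt[idx], spec, response),
                      error = function(e) NULL)
        if (!is.null(r)) break
        redrawn <- redrawn + 1L
      }
      if (is.null(r)) stop("bootstrap replicate repeatedly singular")
      mses[b] <- r$loocv_mse
    }
  })
  if (level <= 0) {
    med <- stats::median(mses)
    ci <- c(med, med)
  } else {
    a <- (1 - level) / 2
    ci <- unname(stats::quantile(mses, c(a, 1 - a)))
  }
  list(lower = ci[1], upper = ci[2], level = level, B = B,
       replicates = mses, n_redrawn = redrawn)
}
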