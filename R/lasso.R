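# L1-penalized least squares by cyclic coordinate descent with covariance
# updates and warm starts along a decreasing lambda path.  Objective:
#   (1/(2n)) * sum_i (y_i - b0 - x_i' b)^2 + lambda * sum_j |b_j|
# with the intercept unpenalized.  Predictors are standardized internally
# (population SD) by default and coefficients reported on the original
# scale.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Internal path fit on precomputed moments.  C = X'X/n, b = X'y/n for the
# centered (and possibly scaled) design; returns p x nlambda matrix.
# The sweep kernel is compiled (src/cd_path.cpp).
cd_path <- function(C, b, lambda, tol = 1e-7, max_sweeps = 1e5) {
  cd_path_cpp(C, b, lambda, tol, as.integer(max_sweeps))
}

#' Configuration for cross-validated penalty selection
#'
#' @param n_lambda number of penalty values on the log-spaced grid.
#' @param cv_folds folds per cross-validation.
#' @param cv_repeats number of re-shuffled cross-validation repeats; the
#'   selected penalty is the (lower) median of the per-repeat minimizers.
#' @param lambda_min_ratio smallest grid value as a fraction of the
#'   full-shrinkage bound lambda_max.
#' @param standardize standardize predictors to unit (population) SD before
#'   penalization.
#' @param rule "min" picks the penalty minimizing mean CV MSE; "1se" the
#'   largest penalty within one standard error of that minimum.
#' @param seed integer seed for fold shuffling.
#' @return List of class \code{"lasso_config"}.
#' @export
lasso_config <- function(n_lambda = 100, cv_folds = 10, cv_repeats = 1000,
                         lambda_min_ratio = 1e-4, standardize = TRUE,
                         rule = c("min", "1se"), seed = 1) {
  rule <- match.arg(rule)
  stopifnot(n_lambda >= 2, cv_folds >= 2, cv_repeats >= 1,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(n_lambda = n_lambda, cv_folds = cv_folds,
                 cv_repeats = cv_repeats,
                 lambda_min_ratio = lambda_min_ratio,
                 standardize = standardize, rule = rule, seed = seed),
            class = "lasso_config")
}

# Center/scale bookkeeping shared by lasso_path and select_lambda.
lasso_moments <- function(X, y, standardize) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in predictors or response")
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  sx <- sqrt(colMeans(Xc^2))
  const <- sx == 0
  if (any(const)) {
    warning("dropping constant predictor column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    sx[const] <- 1  # coefficient pinned to zero below
  }
  if (standardize) Xc <- sweep(Xc, 2, sx, "/")
  ym <- mean(y)
  yc <- y - ym
  list(Xc = Xc, yc = yc, xm = xm, ym = ym,
       sx = if (standardize) sx else rep(1, ncol(X)),
       const = const, n = n,
       C = crossprod(Xc) / n, b = drop(crossprod(Xc, yc)) / n)
}

#' Penalty grid from the full-shrinkage bound
#'
#' Log-spaced grid of \code{n_lambda} values from lambda_max (the smallest
#' penalty at which every coefficient is exactly zero) down to
#' lambda_max * lambda_min_ratio.
#'
#' @param X predictor matrix; @param y response.
#' @param n_lambda grid size; @param lambda_min_ratio lower end as a
#'   fraction of lambda_max; @param standardize as in
#'   \code{\link{lasso_path}}.
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(X, y, n_lambda = 100, lambda_min_ratio = 1e-4,
                        standardize = TRUE) {
  mo <- lasso_moments(X, y, standardize)
  lmax <- max(abs(mo$b))
  if (lmax == 0) lmax <- 1e-3  # response orthogonal to all predictors
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' LASSO coefficient path
#'
#' Fits the L1-penalized least-squares path over a decreasing penalty grid
#' by cyclic coordinate descent with warm starts.  At \code{lambda = 0} the
#' fit coincides with ordinary least squares; at or above the
#' full-shrinkage bound all penalized coefficients are exactly zero.
#'
#' @param X numeric predictor matrix (n x p), no missing values.
#' @param y numeric response vector.
#' @param lambda decreasing penalty vector; defaults to
#'   \code{\link{lambda_grid}}.
#' @param standardize standardize predictors internally (coefficients are
#'   always returned on the original scale).
#' @param tol convergence tolerance on the maximum coefficient change per
#'   sweep (standardized scale).
#' @return List with \code{lambda}, \code{beta} (p x nlambda, original
#'   scale), \code{beta_std} (standardized scale), \code{intercept}
#'   (per-lambda), and the standardization constants.
#' @export
lasso_path <- function(X, y, lambda = NULL, standardize = TRUE,
                       tol = 1e-7) {
  X <- as.matrix(X)
  if (is.null(lambda))
    lambda <- lambda_grid(X, y, standardize = standardize)
  if (is.unsorted(rev(lambda)))
    lambda <- sort(lambda, decreasing = TRUE)
  mo <- lasso_moments(X, y, standardize)
  bs <- cd_path(mo$C, mo$b, lambda, tol = tol)
  bs[mo$const, ] <- 0
  beta <- bs / mo$sx
  intercept <- mo$ym - drop(crossprod(beta, mo$xm))
  rownames(beta) <- rownames(bs) <- colnames(X)
  list(lambda = lambda, beta = beta, beta_std = bs, intercept = intercept,
       x_center = mo$xm, x_scale = mo$sx, y_center = mo$ym)
}

#' Select the penalty by repeated K-fold cross-validation
#'
#' For each repeat, fold membership is reshuffled, the path is refit on each
#' training fold, and the penalty minimizing the mean held-out MSE is
#' recorded; the selected penalty is the (lower) median of the per-repeat
#' minimizers, and the final coefficients come from refitting the path on
#' all rows at that penalty.
#'
#' @param X predictor matrix (n x p); @param y response.
#' @param config a \code{\link{lasso_config}}.
#' @return Object of class \code{"lasso_result"}: lambda_grid,
#'   lambda_repeats (per-repeat minimizers), selected_lambda, coefficients
#'   (original scale, named), coefficients_std, intercept, cv_mse (grid
#'   curve averaged over folds and repeats), config.
#' @export
select_lambda <- function(X, y, config = lasso_config()) {
  stopifnot(inherits(config, "lasso_config"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < config$cv_folds) stop("need n >= cv_folds")
  grid <- lambda_grid(X, y, config$n_lambda, config$lambda_min_ratio,
                      config$standardize)
  K <- config$cv_folds
  lam_sel <- numeric(config$cv_repeats)
  curve_sum <- numeric(length(grid))
  with_seed(config$seed, {
    for (rep_i in seq_len(config$cv_repeats)) {
      folds <- sample(rep_len(seq_len(K), n))
      if (min(tabulate(folds, K)) < 2)
        stop("a cross-validation fold has fewer than 2 observations")
      fold_mse <- matrix(0, K, length(grid))
      for (k in seq_len(K)) {
        tr <- folds != k
        fit <- lasso_path(X[tr, , drop = FALSE], y[tr], lambda = grid,
                          standardize = config$standardize)
        pred <- X[!tr, , drop = FALSE] %*% fit$beta
        pred <- sweep(pred, 2, fit$intercept, "+")
        fold_mse[k, ] <- colMeans((y[!tr] - pred)^2)
      }
      curve <- colMeans(fold_mse)
      curve_sum <- curve_sum + curve
      if (config$rule == "min") {
        lam_sel[rep_i] <- grid[which.min(curve)]
      } else {
        se <- apply(fold_mse, 2, stats::sd) / sqrt(K)
        i0 <- which.min(curve)
        ok <- which(curve <= curve[i0] + se[i0])
        lam_sel[rep_i] <- grid[min(ok)]  # grid is decreasing: largest lambda
      }
    }
  })
  selected <- lower_median(lam_sel)
  sub <- grid[grid >= selected]
  fit <- lasso_path(X, y, lambda = sub, standardize = config$standardize)
  j <- length(sub)
  structure(list(
    lambda_grid = grid,
    lambda_repeats = lam_sel,
    selected_lambda = selected,
    coefficients = stats::setNames(fit$beta[, j], colnames(X)),
    coefficients_std = stats::setNames(fit$beta_std[, j], colnames(X)),
    intercept = fit$intercept[j],
    cv_mse = curve_sum / config$cv_repeats,
    config = config), class = "lasso_result")
}

#' Rank traits by shrunken association strength
#'
#' Orders predictors by the magnitude of their standardized LASSO
#' coefficients at the selected penalty; exact zeros are reported as not
#' selected.  An all-zero fit is flagged as the null model.
#'
#' @param result a \code{\link{select_lambda}} result.
#' @return data.table with trait, coefficient (original scale),
#'   std_coefficient, selected flag, ordered by |std_coefficient|
#'   descending; attribute \code{null_model} is TRUE when nothing was
#'   selected.
#' @export
rank_traits <- function(result) {
  stopifnot(inherits(result, "lasso_result"))
  dt <- data.table::data.table(
    trait = names(result$coefficients),
    coefficient = as.numeric(result$coefficients),
    std_coefficient = as.numeric(result$coefficients_std))
  dt <- dt[order(-abs(dt$std_coefficient))]
  dt[, "selected" := dt$std_coefficient != 0]
  data.table::setattr(dt, "null_model", !any(dt$selected))
  dt[]
}
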