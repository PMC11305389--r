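test_that("the unpenalized limit matches ordinary least squares", {
  set.seed(31)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- 0.5 + X %*% c(1, -0.5, 0, 0.25) + rnorm(n, 0, 0.3)
  fit <- lasso_path(X, y, lambda = c(0.1, 0), tol = 1e-10)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$beta[, 2]), unname(ols[-1]), tolerance = 1e-8)
  expect_equal(unname(fit$intercept[2]), unname(ols[1]), tolerance = 1e-8)
})

test_that("all coefficients are exactly zero at and above lambda_max", {
  set.seed(32)
  X <- matrix(rnorm(200), 50, 4)
  y <- rnorm(50)
  grid <- lambda_grid(X, y, n_lambda = 5)
  lmax <- grid[1]
  fit <- lasso_path(X, y, lambda = c(2 * lmax, lmax))
  expect_identical(unname(fit$beta), matrix(0, 4, 2))
  # fractionally below lambda_max something enters
  fit2 <- lasso_path(X, y, lambda = lmax * 0.9)
  expect_gt(max(abs(fit2$beta)), 0)
})

test_that("orthonormal designs reduce to closed-form soft-thresholding", {
  set.seed(33)
  n <- 64
  M <- scale(matrix(rnorm(n * 4), n, 4), scale = FALSE)
  Q <- qr.Q(qr(M)) * sqrt(n)  # centered columns with X'X/n = I
  y <- rnorm(n)
  yc <- y - mean(y)
  b <- drop(crossprod(Q, yc)) / n
  st <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (lam in c(0.02, 0.1, 0.3)) {
    fit <- lasso_path(Q, y, lambda = lam, standardize = FALSE, tol = 1e-10)
    expect_equal(unname(drop(fit$beta)), st(b, lam), tolerance = 1e-6)
  }
})

test_that("KKT conditions hold along the computed path", {
  set.seed(34)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4)
  X[, 2] <- X[, 1] * 0.8 + X[, 2] * 0.6  # correlated pair
  y <- X %*% c(1, 0.5, 0, -0.3) + rnorm(n, 0, 0.5)
  fit <- lasso_path(X, y, tol = 1e-9)
  mo_x <- scale(X, scale = sqrt(colMeans(scale(X, scale = FALSE)^2)))
  yc <- y - mean(y)
  for (l in seq(1, length(fit$lambda), by = 17)) {
    lam <- fit$lambda[l]
    bstd <- fit$beta_std[, l]
    r <- yc - mo_x %*% bstd
    grad <- drop(crossprod(mo_x, r)) / n
    active <- bstd != 0
    expect_true(all(abs(grad[!active]) <= lam + 1e-6))
    if (any(active))
      expect_equal(grad[active], lam * sign(bstd[active]),
                   tolerance = 1e-5)
  }
  # L1 norm is non-increasing in lambda from lambda_max downward
  l1 <- colSums(abs(fit$beta_std))
  expect_true(all(diff(l1) >= -1e-8))
})

test_that("lasso path agrees with glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  set.seed(35)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- drop(X %*% c(0.9, 0, -0.4, 0.1) + rnorm(n, 0, 0.4))
  grid <- lambda_grid(X, y, n_lambda = 30, lambda_min_ratio = 0.01)
  fit <- lasso_path(X, y, lambda = grid, tol = 1e-10)
  gn <- glmnet::glmnet(X, y, lambda = grid, standardize = TRUE,
                       thresh = 1e-14)
  expect_equal(unname(as.matrix(gn$beta)), unname(fit$beta),
               tolerance = 1e-4)
  expect_equal(unname(gn$a0), unname(fit$intercept), tolerance = 1e-4)
})

test_that("a single repeat reduces to plain K-fold CV-min selection", {
  tab <- toy_regression_table(n = 40)
  X <- as.matrix(tab[, c("x1", "x2", "x3"), with = FALSE])
  y <- tab$episodic_memory
  cfg <- lasso_config(cv_repeats = 1, cv_folds = 5, n_lambda = 40, seed = 8)
  r <- select_lambda(X, y, cfg)
  expect_length(r$lambda_repeats, 1)
  expect_equal(r$selected_lambda, r$lambda_repeats[1])
  expect_equal(r$selected_lambda, r$lambda_grid[which.min(r$cv_mse)])
  refit <- lasso_path(X, y, lambda = r$lambda_grid[r$lambda_grid >=
                                                     r$selected_lambda])
  expect_equal(unname(r$coefficients),
               unname(refit$beta[, ncol(refit$beta)]))
  # determinism
  r2 <- select_lambda(X, y, cfg)
  expect_identical(r$selected_lambda, r2$selected_lambda)
  expect_identical(r$coefficients, r2$coefficients)
})

test_that("a dominant noiseless signal is ranked first across seeds", {
  hits <- logical(50)
  for (s in 1:50) {
    set.seed(400 + s)
    n <- 50
    hd <- rnorm(n)
    X <- cbind(density = rnorm(n), length = rnorm(n), head_diameter = hd,
               volume = rnorm(n))
    y <- 2 * hd
    r <- select_lambda(X, y, lasso_config(cv_repeats = 3, cv_folds = 5,
                                          n_lambda = 50, seed = s))
    rk <- rank_traits(r)
    hits[s] <- rk$trait[1] == "head_diameter"
  }
  expect_true(all(hits))
})

test_that("trait ranking orders by standardized magnitude and flags nulls", {
  r <- structure(list(
    coefficients = c(density = 0, length = 0, head_diameter = 0.4,
                     volume = 0.1),
    coefficients_std = c(density = 0, length = 0, head_diameter = 0.3,
                         volume = 0.15)), class = "lasso_result")
  rk <- rank_traits(r)
  expect_equal(rk$trait[1:2], c("head_diameter", "volume"))
  expect_equal(rk$selected, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(attr(rk, "null_model"))
  r0 <- structure(list(coefficients = c(a = 0, b = 0),
                       coefficients_std = c(a = 0, b = 0)),
                  class = "lasso_result")
  expect_true(attr(rank_traits(r0), "null_model"))
})

test_that("constant predictors are dropped with a warning, not an error", {
  set.seed(36)
  X <- cbind(a = rnorm(30), b = rep(1, 30))
  y <- rnorm(30)
  expect_warning(fit <- lasso_path(X, y, lambda = 0.05), "constant")
  expect_equal(unname(fit$beta["b", ]), 0)
})

test_that("null-trait cohorts rarely admit spine traits (sparse selection)", {
  # traits carry no memory signal here; CV-min keeps selection sparse and
  # the 1-SE rule shrinks everything to zero in the majority of replicates
  n_rep <- 30
  nsel_min <- integer(n_rep)
  allzero_1se <- logical(n_rep)
  for (s in 1:n_rep) {
    set.seed(500 + s)
    n <- 63
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, c("density", "length",
                                        "head_diameter", "volume")))
    y <- rnorm(n)
    rmin <- select_lambda(X, y, lasso_config(cv_repeats = 10,
                                             n_lambda = 50, seed = 600 + s))
    nsel_min[s] <- sum(rmin$coefficients != 0)
    r1se <- select_lambda(X, y, lasso_config(cv_repeats = 10,
                                             n_lambda = 50, rule = "1se",
                                             seed = 600 + s))
    allzero_1se[s] <- all(r1se$coefficients == 0)
  }
  expect_lt(mean(nsel_min), 1.5)
  expect_gt(mean(allzero_1se), 0.5)
})
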