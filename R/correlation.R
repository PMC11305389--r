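# Spearman correlation screen with Storey q-value FDR control.

# All n! permutations of 1..n as an (n! x n) index matrix; n <= 9 keeps this
# within a few MB.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, m * n, n)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * m + 1L):(k * m)
    out[rows, 1L] <- n - k + 1L
    rest <- sub
    rest[rest >= (n - k + 1L)] <- rest[rest >= (n - k + 1L)] + 1L
    out[rows, -1L] <- rest
  }
  out
}

#' Spearman rank correlation with tie-aware p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties),
#' computed on pairwise-complete observations.  The p-value comes from the
#' t approximation with n - 2 degrees of freedom, or from exact enumeration
#' of all rank permutations for small samples (n <= 9 by default under
#' \code{method = "auto"}).
#'
#' @param x,y numeric vectors of equal length.
#' @param method "auto" (exact below \code{exact_max_n + 1}, otherwise t),
#'   "t", or "exact".
#' @param exact_max_n largest n for which "auto" enumerates permutations.
#' @return List: rho, p_value, n_pairs, method, constant (TRUE when either
#'   vector is constant after deletion, leaving rho undefined).
#' @export
spearman_cor <- function(x, y, method = c("auto", "t", "exact"),
                         exact_max_n = 9) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n_pairs = n,
                method = "none", constant = TRUE))
  rho <- stats::cor(rx, ry)
  use_exact <- method == "exact" || (method == "auto" && n <= exact_max_n)
  if (use_exact) {
    if (n > 9) stop("exact permutation p-value limited to n <= 9")
    P <- all_permutations(n)
    ryp <- matrix(ry[P], nrow(P), n)
    rhos <- (ryp %*% rx / n - mean(rx) * mean(ry)) /
      (stats::sd(rx) * stats::sd(ry) * (n - 1) / n)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    meth <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), n - 2)
    }
    meth <- "t"
  }
  list(rho = rho, p_value = p, n_pairs = n, method = meth,
       constant = FALSE)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 and converts p-values to q-values by
#' the step-up minimum q_(i) = min over p_(j) >= p_(i) of
#' pi0 * m * p_(j) / rank(j).  With pi0 fixed at 1 this reproduces
#' Benjamini-Hochberg adjusted p-values exactly.  pi0 is estimated by
#' Storey's smoother over lambda in (0.05, ..., 0.95) for m >= 20; shorter
#' lists fall back to the fixed lambda = 0.5 estimate, floored at 1/m, and
#' to 1 when that is degenerate.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param pi0 optional fixed null proportion (overrides estimation).
#' @param lambda tuning grid for the smoother estimate.
#' @return Numeric q-values in the order of \code{p}, with attribute
#'   \code{pi0}.
#' @export
storey_qvalues <- function(p, pi0 = NULL,
                           lambda = seq(0.05, 0.95, by = 0.05)) {
  if (!length(p)) stop("empty p-value list")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0, 1] with no missing values")
  m <- length(p)
  if (is.null(pi0)) {
    if (m >= 20) {
      pl <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pl, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
    } else {
      pi0 <- mean(p > 0.5) / 0.5
    }
    if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
    pi0 <- min(pi0, 1)
    pi0 <- max(pi0, 1 / m)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must be in (0, 1]")
  }
  ord <- order(p)
  q <- pi0 * m * p[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Feature-by-score Spearman correlation grid with FDR control
#'
#' Computes Spearman correlations between every spine-feature column and
#' every cognition/pathology score column over shared cases (pairwise
#' deletion), then applies Storey q-values across all testable cells of the
#' grid.  Cells are flagged at each requested FDR level and annotated with
#' the heatmap convention: "*" for q below the lenient level (with p < 0.05)
#' and "**" for q below the stringent level.
#'
#' @param features per-case feature table (must contain case_id).
#' @param scores per-case score table (must contain case_id).
#' @param feature_cols,score_cols column names to correlate.
#' @param fdr_levels two FDR levels, lenient first (default 0.1 and 0.05).
#' @param min_pairs minimum complete pairs for a testable cell.
#' @param ... passed to \code{\link{spearman_cor}}.
#' @return data.table with one row per (feature, score) cell: rho, n_pairs,
#'   p_value, q_value, sig flags and annotation; attribute \code{pi0}.
#' @export
correlation_matrix <- function(features, scores, feature_cols, score_cols,
                               fdr_levels = c(0.1, 0.05), min_pairs = 4,
                               ...) {
  ft <- data.table::as.data.table(features)
  sc <- data.table::as.data.table(scores)
  tab <- merge(ft, sc, by = "case_id")
  if (!nrow(tab)) stop("no overlapping cases between features and scores")
  miss <- setdiff(c(feature_cols, score_cols), names(tab))
  if (length(miss))
    stop("columns absent from merged table: ", paste(miss, collapse = ", "))
  fdr_levels <- sort(fdr_levels, decreasing = TRUE)
  cells <- data.table::CJ(feature = feature_cols, score = score_cols,
                          sorted = FALSE)
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    xf <- tab[[cells$feature[i]]]
    ys <- tab[[cells$score[i]]]
    npair <- sum(stats::complete.cases(xf, ys))
    if (npair < min_pairs) {
      res[[i]] <- list(rho = NA_real_, p_value = NA_real_, n_pairs = npair,
                       constant = NA)
    } else {
      s <- spearman_cor(xf, ys, ...)
      res[[i]] <- list(rho = s$rho, p_value = s$p_value,
                       n_pairs = s$n_pairs, constant = s$constant)
    }
  }
  cells[, "rho" := vapply(res, `[[`, numeric(1), "rho")]
  cells[, "p_value" := vapply(res, `[[`, numeric(1), "p_value")]
  cells[, "n_pairs" := vapply(res, function(r) as.integer(r$n_pairs),
                              integer(1))]
  testable <- !is.na(cells$p_value)
  qv <- rep(NA_real_, nrow(cells))
  pi0 <- NA_real_
  if (any(testable)) {
    qq <- storey_qvalues(cells$p_value[testable])
    qv[testable] <- qq
    pi0 <- attr(qq, "pi0")
  }
  cells[, "q_value" := qv]
  lenient <- fdr_levels[1]; stringent <- fdr_levels[2]
  cells[, "sig_lenient" := !is.na(qv) & qv < lenient]
  cells[, "sig_stringent" := !is.na(qv) & qv < stringent]
  ann <- rep("", nrow(cells))
  ann[cells$sig_lenient & cells$p_value < 0.05] <- "*"
  ann[cells$sig_stringent & cells$p_value < 0.05] <- "**"
  cells[, "annotation" := ann]
  data.table::setattr(cells, "pi0", pi0)
  data.table::setattr(cells, "fdr_levels", fdr_levels)
  cells[]
}

#' Reshape a correlation grid into a heatmap matrix
#'
#' @param cells output of \code{\link{correlation_matrix}}.
#' @param value which cell value to spread ("rho", "q_value", "p_value" or
#'   "annotation").
#' @return Matrix with features as rows and scores as columns.
#' @export
correlation_heatmap_matrix <- function(cells, value = "rho") {
  w <- data.table::dcast(data.table::as.data.table(cells),
                         feature ~ score, value.var = value)
  m <- as.matrix(w[, -1])
  rownames(m) <- w$feature
  m
}
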