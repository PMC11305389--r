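test_that("spearman rho is invariant to monotone transforms and flips sign", {
  x <- c(-2, -1, 0.5, 1, 2.5, 4)
  s <- spearman_cor(x, x^3, method = "t")
  expect_equal(s$rho, 1.0)
  s2 <- spearman_cor(x, -x, method = "t")
  expect_equal(s2$rho, -1.0)
  expect_equal(s2$p_value, 0)
})

test_that("tied data match an independent mid-rank Pearson oracle", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    x <- sample(1:5, n, replace = TRUE) + rnorm(n, 0, 1e-6 * (i %% 2))
    y <- sample(1:4, n, replace = TRUE) + 0.3 * x
    # oracle: mid-ranks built from sort order, Pearson by moment formula
    midrank <- function(v) {
      o <- order(v); r <- numeric(n); i1 <- 1
      while (i1 <= n) {
        i2 <- i1
        while (i2 < n && v[o[i2 + 1]] == v[o[i1]]) i2 <- i2 + 1
        r[o[i1:i2]] <- mean(i1:i2)
        i1 <- i2 + 1
      }
      r
    }
    rx <- midrank(x); ry <- midrank(y)
    num <- sum((rx - mean(rx)) * (ry - mean(ry)))
    den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    s <- spearman_cor(x, y, method = "t")
    expect_equal(s$rho, num / den, tolerance = 1e-12)
    expect_equal(s$rho,
                 suppressWarnings(cor.test(x, y,
                                           method = "spearman")$estimate),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("t-approximation p-values match cor.test's asymptotic path", {
  set.seed(62)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  s <- spearman_cor(x, y, method = "t")
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(s$p_value, ct$p.value, tolerance = 1e-12)
  expect_equal(s$method, "t")
})

test_that("exact permutation p-values match cor.test's exact distribution", {
  set.seed(63)
  for (n in c(6, 7)) {
    x <- rnorm(n); y <- rnorm(n)  # continuous: no ties
    s <- spearman_cor(x, y)
    expect_equal(s$method, "exact")
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(s$p_value, ct$p.value, tolerance = 1e-10)
  }
  # with ties cor.test cannot do exact; ours still enumerates
  xt <- c(1, 1, 2, 3, 4, 5)
  yt <- c(2, 1, 1, 3, 5, 4)
  st <- spearman_cor(xt, yt)
  expect_equal(st$method, "exact")
  expect_true(st$p_value > 0 && st$p_value <= 1)
})

test_that("pairwise deletion and degenerate vectors are handled", {
  x <- c(1, 2, NA, 4, 5, 6)
  y <- c(2, 1, 3, NA, 5, 7)
  s <- spearman_cor(x, y)
  expect_equal(s$n_pairs, 4)
  expect_error(spearman_cor(1:3, c(1, 2, 3)), "at least 4")
  sc <- spearman_cor(c(1, 1, 1, 1, 1), c(1, 2, 3, 4, 5))
  expect_true(sc$constant)
  expect_true(is.na(sc$rho))
})

test_that("storey q-values reduce to BH at pi0 = 1 and saturate correctly", {
  expect_equal(storey_qvalues(0.37, pi0 = 1), 0.37, ignore_attr = TRUE)
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(as.numeric(storey_qvalues(p4, pi0 = 1)),
               p.adjust(p4, "BH"))
  set.seed(64)
  for (i in 1:10) {
    p <- runif(sample(5:60, 1))^sample(1:3, 1)
    expect_equal(as.numeric(storey_qvalues(p, pi0 = 1)),
                 p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_equal(as.numeric(storey_qvalues(rep(1, 8))), rep(1, 8))
  expect_error(storey_qvalues(numeric(0)), "empty")
  expect_error(storey_qvalues(c(0.1, 1.2)), "0, 1")
})

test_that("q-values are monotone in p and bounded by 1", {
  set.seed(65)
  for (i in 1:10) {
    p <- runif(40)^2
    q <- storey_qvalues(p)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q <= 1 & q >= 0))
    pi0 <- attr(q, "pi0")
    expect_true(pi0 > 0 && pi0 <= 1)
    # estimated-pi0 q-values never exceed the BH (pi0 = 1) values
    expect_true(all(q <= as.numeric(storey_qvalues(p, pi0 = 1)) + 1e-12))
  }
})

test_that("correlation grid flags the generated head-diameter association", {
  co <- small_ba37_cohort()
  f <- aggregate_features(co$spines, co$segments)
  feats <- c("mean_density", "mean_length", "mean_head_diameter",
             "mean_volume", paste0(spine_classes(), "_head_diameter"),
             paste0(spine_classes(), "_density"))
  scores <- c("episodic_memory", "np_score", "nft_burden", "age")
  grid <- correlation_matrix(f[f$region == "BA37"], co$cases, feats, scores)
  cell <- grid[grid$feature == "mean_head_diameter" &
                 grid$score == "episodic_memory"]
  expect_gt(cell$rho, 0)
  expect_true(cell$sig_stringent)
  expect_equal(cell$annotation, "**")
  expect_true(all(grid$n_pairs <= nrow(co$cases)))

  # permuting case order leaves the grid unchanged
  set.seed(66)
  perm <- sample(nrow(co$cases))
  grid2 <- correlation_matrix(f[f$region == "BA37"][sample(128)],
                              co$cases[perm], feats, scores)
  expect_equal(as.data.frame(grid), as.data.frame(grid2))

  # role swap: feeding a pair both ways gives the mirrored cell
  gswap <- correlation_matrix(co$cases, f[f$region == "BA37"],
                              "np_score", "mean_head_diameter")
  cell2 <- grid[grid$feature == "mean_head_diameter" &
                  grid$score == "np_score"]
  expect_equal(gswap$rho[1], cell2$rho)

  m <- correlation_heatmap_matrix(grid)
  expect_equal(dim(m), c(length(feats), length(scores)))
  expect_equal(m["mean_head_diameter", "episodic_memory"], cell$rho)

  bad <- data.table::data.table(case_id = 900:905, s = rnorm(6))
  expect_error(correlation_matrix(f, bad, "mean_density", "s"),
               "no overlapping cases")
})
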