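test_that("paired t with gate matches the formula-level computation", {
  set.seed(201)
  x <- round(rnorm(10, 10, 2), 2)
  y <- round(rnorm(10, 9, 2), 2)
  res <- paired_t_gate(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$statistic, t_manual, tolerance = 1e-10)
  expect_equal(res$df, 9)
  expect_equal(res$cohen_d, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(res$hedges_g / res$cohen_d, 1 - 3 / (4 * 9 - 1))
  # degenerate: identical pairs
  z <- paired_t_gate(x, x)
  expect_equal(z$statistic, 0)
  expect_equal(z$p, 1)
  expect_match(z$flags, "zero-variance")
})

test_that("the Shapiro gate attaches a Wilcoxon sensitivity result", {
  set.seed(202)
  x <- rexp(20)^3          # heavily skewed differences
  y <- rep(0, 20)
  res <- paired_t_gate(x, y)
  expect_false(is.null(res$sensitivity))
  expect_lt(res$sensitivity$shapiro_p, 0.05)
  expect_true(is.finite(res$sensitivity$p))
  # normal differences leave the sensitivity slot empty
  set.seed(203)
  res2 <- paired_t_gate(rnorm(30), rnorm(30))
  expect_null(res2$sensitivity)
})

test_that("Welch t matches the Welch-Satterthwaite formulas and effect sizes", {
  set.seed(204)
  a <- rnorm(12, 10, 2)
  b <- rnorm(9, 8, 4)
  res <- welch_t(a, b)
  se <- sqrt(var(a) / 12 + var(b) / 9)
  expect_equal(res$statistic, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  df_w <- se^4 / ((var(a) / 12)^2 / 11 + (var(b) / 9)^2 / 8)
  expect_equal(res$df, df_w, tolerance = 1e-10)
  expect_equal(res$ci95,
               (mean(a) - mean(b)) + c(-1, 1) * qt(0.975, df_w) * se,
               tolerance = 1e-10)
  sd_pool <- sqrt((11 * var(a) + 8 * var(b)) / 19)
  expect_equal(res$cohen_d, res$mean_diff / sd_pool)
  expect_equal(res$hedges_g / res$cohen_d, 1 - 3 / (4 * 19 - 1))
  expect_equal(res$d_av, res$mean_diff / ((sd(a) + sd(b)) / 2))
  # identical groups
  z <- welch_t(a, a)
  expect_equal(z$statistic, 0)
  expect_equal(z$mean_diff, 0)
  expect_equal(z$cohen_d, 0)
})

test_that("d_av divides the mean difference by the average SD", {
  # groups engineered to sds 2 and 4 with mean difference 3
  a <- c(-2, 0, 2) / 2 * 2 + 3   # sd 2, mean 3
  b <- c(-4, 0, 4)               # sd 4, mean 0
  expect_equal(sd(a), 2)
  expect_equal(sd(b), 4)
  expect_equal(welch_t(a, b)$d_av, 1.0)
})

test_that("the exact Hedges correction brackets the approximation", {
  for (df in c(5, 10, 20, 50)) {
    approx <- hedges_correction(df)
    exact <- hedges_correction(df, exact = TRUE)
    expect_equal(approx, exact, tolerance = 5e-3)
    expect_true(exact < 1 && approx < 1)
  }
})

test_that("Kruskal-Wallis matches the brute-force rank formula", {
  g0 <- list(rep(3, 5), rep(3, 4), rep(3, 6))
  expect_equal(kruskal_wallis(g0)$H, 0)
  g1 <- list(1:5, 6:10, 11:15)  # three non-overlapping groups of 5
  expect_equal(kruskal_wallis(g1)$H, kw_oracle(g1), tolerance = 1e-9)
  set.seed(205)
  for (i in 1:40) {
    k <- sample(2:4, 1)
    g <- lapply(seq_len(k), function(j) sample(1:8, sample(3:12, 1),
                                               replace = TRUE))
    expect_equal(kruskal_wallis(g)$H, kw_oracle(g), tolerance = 1e-9)
  }
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("two-group Kruskal-Wallis is the squared standardized Mann-Whitney", {
  set.seed(206)
  a <- rnorm(10); b <- rnorm(8)
  h <- kruskal_wallis(list(a, b))$H
  u <- mann_whitney(a, b)$U
  na <- 10; nb <- 8
  z <- (u - na * nb / 2) / sqrt(na * nb * (na + nb + 1) / 12)
  expect_equal(h, z^2, tolerance = 1e-10)
})

test_that("Spearman matches rank correlation with average ranks for ties", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  set.seed(207)
  for (i in 1:30) {
    x <- sample(1:6, 10, replace = TRUE)  # tie-rich
    y <- sample(1:6, 10, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_cor(x, y)$rho, spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_match(spearman_cor(rep(1, 5), 1:5)$flags, "constant")
})

test_that("Mann-Whitney U matches the pair-count oracle with rank-biserial", {
  a <- c(10, 11, 12); b <- c(1, 2, 3, 4)
  res <- mann_whitney(a, b)
  expect_equal(res$U, 12)              # complete dominance: U = n_a * n_b
  expect_equal(abs(res$rank_biserial), 1)
  # interleaved equal samples are symmetric
  res2 <- mann_whitney(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_equal(abs(res2$rank_biserial), 0.25)
  res3 <- mann_whitney(1:4, 1:4)
  expect_equal(res3$rank_biserial, 0)
  set.seed(208)
  for (i in 1:40) {
    a <- sample(1:10, sample(2:12, 1), replace = TRUE)
    b <- sample(1:10, sample(2:12, 1), replace = TRUE)
    res <- mann_whitney(a, b)
    expect_equal(res$U, u_oracle(a, b))
    expect_equal(res$rank_biserial, 1 - 2 * u_oracle(a, b) /
                   (length(a) * length(b)))
    expect_true(res$p >= 0 && res$p <= 1)
  }
})
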