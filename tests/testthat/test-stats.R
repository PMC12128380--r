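test_that("Mann-Whitney U counts exceeding pairs", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  # pairs (1,2) (1,4) (3,2) (3,4): one a > b
  expect_equal(mann_whitney_u(c(1, 3), c(2, 4))$statistic, 1)
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.9)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney exact p matches an exhaustive label-assignment oracle", {
  a <- c(1.2, 3.4, 5.1, 2.2, 0.7)
  b <- c(2.9, 6.3, 4.4, 7.0, 8.1)
  res <- mann_whitney_u(a, b)
  pooled <- c(a, b)
  u_stat <- function(ia) {
    aa <- pooled[ia]; bb <- pooled[-ia]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  obs <- u_stat(1:5)
  groups <- utils::combn(10, 5)
  us <- apply(groups, 2, u_stat)
  mu <- length(a) * length(b) / 2
  p_oracle <- mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("Kruskal-Wallis H matches hand rank computation and edge cases", {
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  # ranks 1..6: H = 12/(6*7) * sum n (rbar - 3.5)^2 = 32/7
  res <- kruskal_wallis(g)
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(res$df, 2L)

  ties <- kruskal_wallis(list(a = rep(1, 3), b = rep(1, 3)))
  expect_equal(ties$statistic, 0)
  expect_equal(ties$p_value, 1)
  expect_error(kruskal_wallis(list(a = 1:3)), ">= 2 groups")
})

test_that("two-group Kruskal-Wallis agrees asymptotically with Mann-Whitney", {
  set.seed(21)
  a <- rnorm(60); b <- rnorm(60, 0.4)
  p_kw <- kruskal_wallis(list(a = a, b = b))$p_value
  p_mw <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                       correct = FALSE))$p.value
  expect_equal(p_kw, p_mw, tolerance = 0.01)
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(31)
  for (i in 1:20) {
    g <- list(a = runif(sample(3:10, 1)), b = runif(sample(3:10, 1)),
              c = runif(sample(3:10, 1)))
    h1 <- kruskal_wallis(g)$statistic
    h2 <- kruskal_wallis(lapply(g, function(x) exp(3 * x) - 1))$statistic
    h3 <- kruskal_wallis(lapply(g, function(x) x^3 + 2 * x))$statistic
    expect_equal(h1, h2, tolerance = 1e-12)
    expect_equal(h1, h3, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis p matches a permutation oracle on a small input", {
  set.seed(41)
  g <- list(a = c(0.1, 0.9, 0.4), b = c(1.2, 0.8, 2.0), c = c(2.5, 1.9, 0.3))
  obs <- kruskal_wallis(g)$statistic
  pooled <- unlist(g)
  perm <- replicate(4000, {
    p <- sample(pooled)
    kruskal_wallis(list(a = p[1:3], b = p[4:6], c = p[7:9]))$statistic
  })
  p_oracle <- mean(perm >= obs - 1e-12)
  # at n = 3 per group the chi-square reference undershoots the exact
  # permutation p; allow the documented approximation gap
  expect_lt(abs(kruskal_wallis(g)$p_value - p_oracle), 0.1)
})

test_that("type-I error of MWU and KW at alpha 0.05 is calibrated under the null", {
  set.seed(1234)
  n_sim <- 10000
  rej_mw <- rej_kw <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    x <- rnorm(63)
    rej_mw[i] <- mann_whitney_u(x[1:21], x[22:42])$p_value < 0.05
    rej_kw[i] <- kruskal_wallis(list(x[1:21], x[22:42], x[43:63]))$p_value < 0.05
  }
  expect_gt(mean(rej_mw), 0.03); expect_lt(mean(rej_mw), 0.07)
  expect_gt(mean(rej_kw), 0.03); expect_lt(mean(rej_kw), 0.07)
})

test_that("Dunn's z statistics and adjustment behave as documented", {
  set.seed(51)
  g <- list(lo = rnorm(20, 0), mid = rnorm(20, 0.2), hi = rnorm(20, 5))
  res <- dunn_posthoc(g)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
  expect_true(all(res$p_adjusted <= 1))
  # widely separated pair is significant after Bonferroni
  sep <- res[res$group1 == "lo" & res$group2 == "hi", ]
  expect_lt(sep$p_adjusted, 0.001)
  raw <- dunn_posthoc(g, adjust = "none")
  expect_equal(raw$p_value, res$p_value)
  expect_equal(raw$p_adjusted, raw$p_value)
  expect_equal(res$p_adjusted, pmin(res$p_value * 3, 1))
  expect_warning(dunn_posthoc(list(a = 1, b = c(1, 2, 3))), "singleton")
})

test_that("Dunn family-wise error under the null is controlled near alpha", {
  set.seed(61)
  fwe <- replicate(800, {
    g <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50))
    any(dunn_posthoc(g)$p_adjusted < 0.05)
  })
  expect_lt(mean(fwe), 0.07)  # <= 0.05 within Monte-Carlo tolerance
})

test_that("Spearman matches hand values and equals Pearson on ranks", {
  expect_equal(spearman_corr(1:3, 3:1)$rho, -1)
  expect_equal(spearman_corr(1:4, c(1, 3, 2, 4))$rho, 0.8)
  expect_error(spearman_corr(rep(1, 5), 1:5), "zero variance")
  set.seed(71)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    x <- sample(1:12, n, replace = TRUE)  # ties
    y <- rnorm(n)
    if (sd(x) == 0) next
    expect_equal(spearman_corr(x, y)$rho,
                 cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("Spearman p matches an exhaustive permutation oracle at n = 7", {
  x <- c(3.1, 0.2, 5.5, 2.2, 4.4, 1.0, 6.6)
  y <- c(0.4, 1.1, 3.3, 5.5, 2.0, 4.1, 6.0)
  obs <- abs(cor(rank(x), rank(y)))
  perms <- all_perms(7)
  rhos <- apply(perms, 1, function(p) abs(cor(rank(x), rank(y[p]))))
  p_oracle <- mean(rhos >= obs - 1e-12)
  expect_equal(spearman_corr(x, y)$p_value, p_oracle, tolerance = 1e-9)
})

test_that("linear fit recovers exact and perturbed relationships", {
  exact <- suppressWarnings(linear_fit(1:5, 2 * (1:5) + 1))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r, 1)
  expect_equal(exact$r_squared, exact$r^2, tolerance = 1e-12)

  y <- -(1:5); y[3] <- y[3] + 0.1
  fit <- linear_fit(1:5, y)
  expect_true(fit$ci95_slope[1] <= -1 && -1 <= fit$ci95_slope[2])
  expect_lt(fit$r, 0)

  expect_error(linear_fit(1:2, 1:2), "n >= 3")
  expect_error(linear_fit(rep(2, 5), 1:5), "degenerate")
})

test_that("concordance R^2 is squared Pearson correlation", {
  x <- runif(50)
  expect_equal(concordance_r2(x, x), 1)
  expect_equal(concordance_r2(x, 2 * x + 3), 1)
  set.seed(81)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(concordance_r2(a, b), 0.02)
  expect_error(concordance_r2(rep(1, 5), 1:5), "zero variance")
})
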