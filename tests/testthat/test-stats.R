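test_that("Welch ANOVA reproduces the hand-computed two-group case", {
  res <- welch_anova(list(a = c(1, 2, 3), b = c(2, 3, 4)))
  expect_equal(res$w_statistic, 1.5)       # (-1.2247...)^2
  expect_equal(res$df_num, 1)
  expect_equal(res$df_den, 4)
  same <- welch_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$w_statistic, 0)
  shifted <- welch_anova(list(a = c(1, 2, 3) + 10, b = c(2, 3, 4) + 10))
  expect_equal(shifted$w_statistic, res$w_statistic)
  expect_equal(shifted$p_value, res$p_value)
})

test_that("Welch ANOVA with k = 2 equals the squared Welch t statistic", {
  set.seed(51)
  for (i in 1:10) {
    a <- rnorm(sample(4:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(4:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    w <- welch_anova(list(a = a, b = b))
    tt <- t.test(a, b)   # Welch by default
    expect_equal(w$w_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(w$df_den, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate zero-variance groups are handled explicitly", {
  eq <- welch_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(eq$w_statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_warning(res <- welch_anova(list(a = c(2, 2), b = c(3, 3))), "degenerate")
  expect_true(res$degenerate)
})

test_that("SMM tail probabilities agree with a Monte-Carlo oracle", {
  m <- 3; df <- 30
  q95 <- qsmm(0.95, m, df)
  set.seed(52)
  nmc <- 1e6
  z <- matrix(abs(rnorm(nmc * m)), ncol = m)
  s <- sqrt(rchisq(nmc, df) / df)
  mc_q <- unname(quantile(pmax(z[, 1], z[, 2], z[, 3]) / s, 0.95))
  expect_equal(q95, mc_q, tolerance = 0.01)
  expect_equal(psmm(mc_q, m, df), 0.95, tolerance = 0.005)
  # df = Inf closed form
  expect_equal(psmm(2, 3, Inf), (2 * pnorm(2) - 1)^3, tolerance = 1e-10)
})

test_that("Dunnett T3 reduces to the Welch t-test for one comparison", {
  set.seed(53)
  a <- rnorm(8); b <- rnorm(8, 1)
  d <- dunnett_t3(list(a = a, b = b))
  tt <- t.test(a, b)
  expect_equal(nrow(d), 1L)
  expect_equal(d$p_unadjusted, tt$p.value, tolerance = 1e-10)
  expect_equal(d$p_adjusted, tt$p.value, tolerance = 1e-4)
})

test_that("T3 adjusted p-values exceed unadjusted ones and respect references", {
  set.seed(54)
  g <- list(a = rnorm(8), b = rnorm(8, 0.8), c = rnorm(8, 1.6, 2))
  d <- dunnett_t3(g)
  expect_equal(nrow(d), 3L)
  expect_true(all(d$p_adjusted >= d$p_unadjusted - 1e-12))
  ref <- dunnett_t3(g, reference = "a")
  expect_equal(nrow(ref), 2L)
  expect_true(all(grepl("- a$", ref$pair)))
  # adjustment grows with the number of comparisons for the shared pair
  shared <- d[d$pair == "a - b", "p_adjusted"]
  expect_gte(shared, ref[ref$pair == "b - a", "p_adjusted"] - 1e-9)
})

test_that("weighted ANOVA reduces to ordinary ANOVA under equal weights", {
  set.seed(55)
  v <- rnorm(15); lab <- rep(c("x", "y", "z"), each = 5)
  wa <- weighted_one_way_anova(v, lab, rep(2, 15))
  ref <- summary(aov(v ~ factor(lab)))[[1]]
  expect_equal(wa$f_statistic, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(wa$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_error(weighted_one_way_anova(v, lab, rep(-1, 15)), "positive")
})

test_that("doubling a weight is equivalent to duplicating the observation", {
  set.seed(56)
  v <- rnorm(10); lab <- rep(c("x", "y"), each = 5)
  w <- rep(1, 10); w[3] <- 2
  weighted <- weighted_one_way_anova(v, lab, w)
  dup <- weighted_one_way_anova(c(v, v[3]), c(lab, lab[3]), rep(1, 11))
  # identical group means and sums of squares; F differs only through the
  # residual-df convention (n rows vs n+1 rows), so align the dfs
  expect_equal(weighted$emmeans$emmean, dup$emmeans$emmean, tolerance = 1e-12)
  ss <- function(x) {
    a <- anova(x$model); c(a[["Sum Sq"]][1], a[["Sum Sq"]][2])
  }
  expect_equal(ss(weighted), ss(dup), tolerance = 1e-12)
  f_aligned <- (ss(weighted)[1] / weighted$df_num) / (ss(weighted)[2] / dup$df_den)
  expect_equal(f_aligned, dup$f_statistic, tolerance = 1e-12)
})

test_that("two-group weighted ANOVA equals the squared pooled-weighted t", {
  set.seed(57)
  v <- rnorm(12); lab <- rep(c("x", "y"), each = 6); w <- runif(12, 0.5, 3)
  wa <- weighted_one_way_anova(v, lab, w)
  # independent construction of the pooled-weighted t statistic
  wx <- w[lab == "x"]; wy <- w[lab == "y"]
  vx <- v[lab == "x"]; vy <- v[lab == "y"]
  mx <- sum(wx * vx) / sum(wx); my <- sum(wy * vy) / sum(wy)
  sse <- sum(wx * (vx - mx)^2) + sum(wy * (vy - my)^2)
  s2 <- sse / (length(v) - 2)
  tstat <- (mx - my) / sqrt(s2 * (1 / sum(wx) + 1 / sum(wy)))
  expect_equal(wa$f_statistic, tstat^2, tolerance = 1e-10)
})

test_that("Pearson analysis matches the closed-form t and the reported n = 45 case", {
  x <- 1:10
  expect_equal(pearson(x, x + 0)$r, 1)
  set.seed(58)
  # construct data with exactly r = 0.36 at n = 45
  z1 <- rnorm(45); z2 <- rnorm(45)
  z2 <- residuals(lm(z2 ~ z1))
  z1s <- scale(z1)[, 1]; z2s <- scale(z2)[, 1]
  y <- 0.36 * z1s + sqrt(1 - 0.36^2) * z2s
  res <- pearson(z1s, y)
  expect_equal(res$r, 0.36, tolerance = 1e-10)
  expect_equal(res$r_squared, 0.1296, tolerance = 1e-10)
  expect_lt(abs(res$p_value - 0.0148), 5e-4)
  flipped <- pearson(z1s, -y)
  expect_equal(flipped$r, -res$r)
  expect_equal(flipped$p_value, res$p_value)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
})
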