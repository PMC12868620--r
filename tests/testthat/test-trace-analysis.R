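test_that("baseline subtraction centres the pre-exposure samples and is idempotent", {
  t <- seq(0, 60, by = 3)
  tr <- fluorescence_trace(t, rep(7, length(t)), exposure_time = 10)
  expect_equal(subtract_baseline(tr)$values, rep(0, length(t)))

  tr2 <- fluorescence_trace(t, 3.2 + seq_along(t), exposure_time = 10)
  out <- subtract_baseline(tr2)
  expect_equal(out$values, tr2$values - mean(tr2$values[t < 10]))
  expect_lt(abs(mean(out$values[t < 10])), 1e-12)
  expect_equal(subtract_baseline(out)$values, out$values)
})

test_that("trace construction rejects malformed series", {
  expect_error(fluorescence_trace(c(0, 3, 3, 6), 1:4, 10), "increasing")
  expect_error(fluorescence_trace(seq(0, 30, 3), rep(1, 11), 2), "before")
  expect_error(fluorescence_trace(seq(0, 30, 3), rep(1, 11), 29), "after")
})

test_that("noiseless uptake fits recover (A, tau) over a grid of ground truths", {
  fit <- fit_uptake(make_model_trace(a = 100, tau = 130, baseline = 7))
  expect_equal(unname(coef(fit)), c(100, 130), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1)

  grid <- expand.grid(a = c(2, 20, 100, 600, 3000),
                      tau = c(3, 10, 40, 130, 400))
  for (i in seq_len(nrow(grid))) {
    fit <- fit_uptake(make_model_trace(a = grid$a[i], tau = grid$tau[i]))
    expect_equal(fit$amplitude, grid$a[i], tolerance = 1e-6)
    expect_equal(fit$tau_reseal, grid$tau[i], tolerance = 1e-6)
  }
})

test_that("uptake fit never loses to a dense grid search over tau", {
  set.seed(31)
  for (i in 1:10) {
    tr <- make_model_trace(a = runif(1, 10, 200), tau = runif(1, 5, 500))
    tr$values <- tr$values + rnorm(length(tr$values), 0, 3)
    fit <- fit_uptake(tr)
    expect_lte(rss_of_uptake_fit(fit), grid_search_rss(tr) * (1 + 1e-6))
  }
})

test_that("degenerate traces are flagged rather than mis-fit", {
  t <- seq(0, 180, by = 3)
  flat <- fluorescence_trace(t, rep(5, length(t)), exposure_time = 10)
  fit <- fit_uptake(flat)
  expect_true(fit$converged)
  expect_equal(fit$amplitude, 0)
  expect_false(fit$tau_identifiable)

  falling <- fluorescence_trace(t, ifelse(t >= 10, -0.5 * (t - 10), 0), 10)
  expect_false(fit_uptake(falling)$converged)
})

test_that("group-mean fitting averages amplitudes but preserves a shared tau", {
  tr <- make_model_trace(a = 100, tau = 90)
  same <- fit_group_mean(list(tr, tr))
  expect_equal(coef(same$mean_fit), coef(same$fits[[1]]))

  two <- fit_group_mean(list(make_model_trace(a = 60, tau = 90),
                             make_model_trace(a = 140, tau = 90)))
  expect_equal(two$mean_fit$tau_reseal, 90, tolerance = 1e-6)
  expect_equal(two$mean_fit$amplitude, 100, tolerance = 1e-6)

  other_t0 <- make_model_trace(a = 100, tau = 90, t0 = 13)
  expect_error(fit_group_mean(list(tr, other_t0)), "exposure")
})

test_that("AUC matches rectangles, triangles, the closed form, and is additive", {
  t <- seq(0, 180, by = 3)
  const <- fluorescence_trace(t, ifelse(t >= 0, 5, 5), exposure_time = 10)
  expect_equal(trace_auc(const, 0, 180, baseline_subtract = FALSE), 900)

  t2 <- seq(0, 10, by = 0.5)
  ramp <- fluorescence_trace(t2, t2, exposure_time = 2)
  expect_equal(trace_auc(ramp, 0, 10, baseline_subtract = FALSE), 50)

  tr <- make_model_trace(a = 100, tau = 130, t0 = 9,
                         times = seq(0, 180, by = 3))
  got <- trace_auc(tr, 9, 180, baseline_subtract = FALSE)
  closed <- 100 * (171 - 130 * (1 - exp(-171 / 130)))
  expect_equal(got, closed, tolerance = 1e-3)

  split_sum <- trace_auc(tr, 9, 90, baseline_subtract = FALSE) +
    trace_auc(tr, 90, 180, baseline_subtract = FALSE)
  expect_equal(split_sum, got)
  expect_error(trace_auc(tr, 100, 100), "strictly less")
})

test_that("AUC and fold change are invariant to a common pre-exposure baseline", {
  tr0 <- make_model_trace(a = 80, tau = 100, baseline = 0)
  tr7 <- make_model_trace(a = 80, tau = 100, baseline = 7)
  expect_equal(trace_auc(tr0), trace_auc(tr7))
  expect_equal(final_uptake(tr0, 180), final_uptake(tr7, 180))
})

test_that("fold change is 1 for identical groups and scales with the numerator", {
  a <- list(make_model_trace(a = 100), make_model_trace(a = 100))
  expect_equal(group_fold_change(a, a, 180)$fold_change, 1)
  b <- lapply(a, function(tr) { tr$values <- tr$values * 2; tr })
  expect_equal(group_fold_change(b, a, 180)$fold_change, 2)
  zero <- list(fluorescence_trace(seq(0, 180, 3), rep(1, 61), 10))
  expect_warning(res <- group_fold_change(a, zero, 180), "undefined")
  expect_false(res$defined)
})

test_that("percent area change reads 42% for a 1.42-fold expansion", {
  t <- seq(0, 630, by = 10)
  area <- ifelse(t >= 30, 1.42e5, 1.0e5)
  tr <- fluorescence_trace(t, area, exposure_time = 30, kind = "area")
  expect_equal(percent_area_change(tr, 630), 42)
  flat <- fluorescence_trace(t, rep(1e5, length(t)), 30, kind = "area")
  expect_equal(percent_area_change(flat), 0)
  up <- make_model_trace()
  expect_error(percent_area_change(up), "area")
})
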