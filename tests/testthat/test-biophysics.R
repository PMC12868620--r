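test_that("steady-state Schwan field matches direct arithmetic and scales linearly", {
  expect_equal(steady_state_schwan_field(0.2, um(10)), 2 / 3 * 0.2 / 10e-6)
  expect_equal(steady_state_schwan_field(0.2, um(10)), 13333.3333, tolerance = 1e-6)
  expect_equal(steady_state_schwan_field(0.2, um(15)), 8888.8889, tolerance = 1e-6)
  expect_equal(steady_state_schwan_field(0.4, um(10)),
               2 * steady_state_schwan_field(0.2, um(10)))
  expect_error(steady_state_schwan_field(0, um(10)), "positive")
  expect_error(steady_state_schwan_field(0.2, -1), "positive")
})

test_that("charging factor has the right limits and the 300 ns / 2 us value", {
  expect_equal(charging_factor(0, 2e-6), 0)
  expect_equal(charging_factor(200e-6, 2e-6), 1, tolerance = 1e-12)
  # frozen: 1 - exp(-0.15) evaluated independently
  expect_equal(charging_factor(300e-9, 2e-6), 0.139292, tolerance = 1e-6)
  tt <- seq(0, 10e-6, length.out = 50)
  expect_true(all(diff(charging_factor(tt, 2e-6)) > 0))
  expect_error(charging_factor(-1e-9, 2e-6), "non-negative")
})

test_that("threshold field follows 1/R scaling at any pulse duration", {
  # frozen: 8888.8889 / 0.1392920 by independent arithmetic
  expect_equal(threshold_field(um(15), 300e-9), 63814.77, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:20) {
    r1 <- runif(1, 4e-6, 25e-6); r2 <- runif(1, 4e-6, 25e-6)
    t <- runif(1, 50e-9, 5e-6)
    expect_equal(threshold_field(r1, t) / threshold_field(r2, t), r2 / r1)
  }
  expect_error(threshold_field(um(10), 0), "positive")
})

test_that("threshold field decreases with duration and reaches steady state by 14 tau", {
  durs <- c(100e-9, 300e-9, 1e-6, 5e-6, 30e-6)
  e <- threshold_field(um(10), durs)
  expect_true(all(diff(e) < 0))
  e_ss <- steady_state_schwan_field(0.2, um(10))
  expect_lt(abs(threshold_field(um(10), 14 * 2e-6) - e_ss) / e_ss, 1e-3)
})

test_that("threshold curve keeps the 20 vs 30 um ratio fixed across durations", {
  tc <- threshold_curve(c(20, 30), c(100e-9, 300e-9, 1e-6))
  expect_equal(nrow(tc), 6L)
  for (d in unique(tc$pulse_duration_s)) {
    sub <- tc[tc$pulse_duration_s == d, ]
    expect_equal(sub$e_threshold_v_per_m[sub$diameter_um == 20] /
                   sub$e_threshold_v_per_m[sub$diameter_um == 30], 1.5)
  }
  one <- threshold_curve(25, 300e-9)
  expect_equal(one$e_threshold_v_per_m, threshold_field(um(12.5), 300e-9))
  expect_equal(one$e_threshold_kv_per_cm, one$e_threshold_v_per_m / 1e5)
  doubled <- threshold_curve(c(20, 30), 300e-9,
                             params = threshold_params(dv_threshold = 0.4))
  expect_equal(doubled$e_threshold_v_per_m,
               2 * threshold_curve(c(20, 30), 300e-9)$e_threshold_v_per_m)
  expect_error(threshold_curve(numeric(0), 300e-9), "non-empty")
})

test_that("two-wire field matches the line-charge closed form at the midpoint", {
  g <- electrode_geometry()   # 0.25 mm radius, 1.5 mm spacing, 1 V
  s <- sqrt(0.75e-3^2 - 0.25e-3^2)
  expect_equal(two_wire_field_profile(g, 0, 0), 1 / (s * acosh(3)),
               tolerance = 1e-12)
  expect_equal(two_wire_field_profile(g, 0, 0), 802.28, tolerance = 1e-4)
})

test_that("two-wire field equals the numerical gradient of the potential", {
  g <- electrode_geometry(applied_voltage = 1000)
  set.seed(21)
  pts <- 0L; checked <- 0L
  while (checked < 100L) {
    x <- runif(1, -2.5e-3, 2.5e-3); y <- runif(1, -2.5e-3, 2.5e-3)
    if (sqrt((x - 0.75e-3)^2 + y^2) < 0.3e-3 ||
        sqrt((x + 0.75e-3)^2 + y^2) < 0.3e-3) next
    checked <- checked + 1L
    e_num <- field_by_gradient(g, x, y)
    e_ana <- two_wire_field_profile(g, x, y)
    expect_equal(e_ana, e_num, tolerance = 1e-9)
  }
})

test_that("two-wire field is reflection-symmetric, decaying, and linear in voltage", {
  g <- electrode_geometry()
  ys <- seq(0.1e-3, 3e-3, length.out = 25)
  along <- two_wire_field_profile(g, rep(0, 25), ys)
  expect_true(all(diff(along) < 0))
  expect_equal(two_wire_field_profile(g, 0.3e-3, 0.4e-3),
               two_wire_field_profile(g, -0.3e-3, 0.4e-3))
  g2 <- electrode_geometry(applied_voltage = 2)
  expect_equal(two_wire_field_profile(g2, 0.1e-3, 0.2e-3),
               2 * two_wire_field_profile(g, 0.1e-3, 0.2e-3))
  expect_error(two_wire_field_profile(g, 0.75e-3, 0), "inside")
})

test_that("subROI fields decay away from the gap and converge under grid refinement", {
  g <- electrode_geometry()
  sub <- assign_subroi_fields(g, roi_spec())
  expect_equal(sub$subroi_index, 1:3)
  expect_true(all(diff(sub$e_mean) < 0))
  expect_true(all(sub$e_min <= sub$e_mean & sub$e_mean <= sub$e_max))
  fine <- assign_subroi_fields(g, roi_spec(), grid_n = 41)
  expect_true(all(abs(fine$e_mean - sub$e_mean) / sub$e_mean < 0.01))
  g2 <- electrode_geometry(applied_voltage = 2)
  expect_equal(assign_subroi_fields(g2, roi_spec())$e_mean, 2 * sub$e_mean)
  wide <- roi_spec(roi_width = 2e-3)
  expect_error(assign_subroi_fields(g, wide), "overlaps")
})

test_that("permeabilized fraction behaves as a population threshold rule", {
  expect_equal(permeabilized_fraction(um(c(10, 15)), 0, 300e-9), 0)
  expect_equal(permeabilized_fraction(um(c(1e5, 2e5)), 1e3, 300e-9), 1)
  e1 <- threshold_field(um(10), 300e-9)
  e2 <- threshold_field(um(15), 300e-9)
  expect_equal(permeabilized_fraction(um(c(10, 15)), (e1 + e2) / 2, 300e-9), 0.5)
  fields <- seq(0, 2 * e1, length.out = 30)
  fr <- vapply(fields, permeabilized_fraction, numeric(1),
               radii = um(c(8, 10, 12, 15, 20)), pulse_duration = 300e-9)
  expect_true(all(diff(fr) >= 0))
})
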