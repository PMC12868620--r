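test_that("generators are deterministic under a fixed seed and leave the RNG alone", {
  g <- uptake_group_defaults()[1, ]
  a <- generate_uptake_traces(g, 3, seed = 7)
  b <- generate_uptake_traces(g, 3, seed = 7)
  expect_identical(a, b)
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_uptake_traces(g, 2, seed = 7))
  expect_identical(rnorm(1), before)
  expect_error(generate_uptake_traces(g, 0), "positive")
})

test_that("zero-noise uptake traces invert the fitting model exactly", {
  cfg <- generator_config(trace_noise_sd = 0, replicate_cv = 0)
  g <- uptake_group_defaults()
  row <- g[g$cell_line == "T24" & g$ca_mM == 0, ]
  df <- generate_uptake_traces(row, 2, config = cfg, seed = 1)
  fits <- lapply(traces_from_table(df), fit_uptake)
  for (f in fits) {
    expect_equal(f$tau_reseal, 130, tolerance = 1e-6)
    expect_equal(f$r_squared, 1)
  }
  # the model value 170 s after exposure equals the configured uptake level
  expect_equal(final_uptake(traces_from_table(df)[[1]], 180),
               row$uptake180_au, tolerance = 1e-8)
})

test_that("noisy defaults recover the printed cancer-line time constants", {
  g <- uptake_group_defaults()
  for (case in list(list(line = "T24", ca = 0, tau = 130),
                    list(line = "T24", ca = 2, tau = 84),
                    list(line = "UM-UC-3", ca = 0, tau = 115))) {
    df <- generate_uptake_traces(g[g$cell_line == case$line & g$ca_mM == case$ca, ],
                                 20, seed = 42)
    taus <- vapply(lapply(traces_from_table(df), fit_uptake),
                   `[[`, numeric(1), "tau_reseal")
    expect_lt(abs(mean(taus) - case$tau) / case$tau, 0.10)
  }
})

test_that("T24 vs SV-HUC-1 uptake at 5 mM Ca reproduces the 6.1-fold difference", {
  g <- uptake_group_defaults()
  t24 <- traces_from_table(generate_uptake_traces(
    g[g$cell_line == "T24" & g$ca_mM == 5, ], 20, seed = 42))
  sv <- traces_from_table(generate_uptake_traces(
    g[g$cell_line == "SV-HUC-1" & g$ca_mM == 5, ], 20, seed = 43))
  fc <- group_fold_change(t24, sv, 180)$fold_change
  expect_lt(abs(fc - 6.1) / 6.1, 0.15)
})

test_that("noiseless spheroid swelling hits the group targets exactly", {
  cfg <- generator_config(swelling_cv = 0, swelling_noise_sd = 0,
                          trace_noise_sd = 0)
  d <- generate_spheroid_dataset(5, config = cfg, seed = 1)
  sw <- traces_from_table(d$swelling)
  targets <- spheroid_group_defaults()
  for (tr in sw) {
    want <- targets$final_percent[targets$type == tr$meta$cell_line]
    expect_equal(percent_area_change(tr), want, tolerance = 1e-6)
  }
})

test_that("noiseless spheroid fluorescence is perfectly correlated with cell size", {
  d <- generate_spheroid_dataset(12, target_r = 0, seed = 2)
  expect_equal(pearson(d$spheroids$mean_cell_area_um2,
                       d$spheroids$final_fluor_au)$r, 1, tolerance = 1e-9)
  expect_error(generate_spheroid_dataset(12, target_r = 1), "unattainable")
  expect_error(generate_spheroid_dataset(2), "at least 3")
})

test_that("morphometry generator inverts the form-factor relation", {
  circles <- generate_morphometry("monolayer", ff_cv = 0,
                                  defaults = within(morphometry_defaults(), {
                                    monolayer$mean_ff <- 1
                                  }), seed = 3)
  expect_equal(circles$perimeter_um, 2 * sqrt(pi * circles$area_um2),
               tolerance = 1e-12)
  m <- generate_morphometry("monolayer", seed = 3)
  expect_equal(form_factor(m$area_um2, m$perimeter_um), m$form_factor,
               tolerance = 1e-12)
})

test_that("monolayer defaults give the 1.8-fold cancer/normal area ratio", {
  m <- generate_morphometry("monolayer", seed = 42)
  s <- summarize_rois(m)
  ratio <- mean(s$area_um2[s$cell_line %in% c("T24", "UM-UC-3")]) /
    mean(s$area_um2[s$cell_line %in% c("SV-HUC-1", "HBLAK")])
  expect_lt(abs(ratio - 1.8) / 1.8, 0.10)
  expect_equal(length(unique(s$roi_id)), 4 * 18)
})

test_that("TMA defaults recover the printed class means within 5%", {
  tm <- generate_morphometry("tma", seed = 42)
  expect_equal(sum(tm$weights$n_cores), 47 + 66 + 56)
  cm <- tissue_group_means(tm$records, tm$weights)$class_means
  expect_lt(abs(cm$mean_area_um2[cm$tissue_class == "normal"] - 90.7) / 90.7, 0.05)
  expect_lt(abs(cm$mean_area_um2[cm$tissue_class == "primary_tumor"] - 111.8) / 111.8, 0.05)
  expect_lt(abs(cm$mean_area_um2[cm$tissue_class == "lymph_node_met"] - 111.8) / 111.8, 0.05)
})

test_that("noiseless force maps invert the full mechanics chain", {
  fm <- generate_force_maps("RT4", n_spheroids = 2, noiseless = TRUE, seed = 1)
  defs <- stiffness_group_defaults()
  rt4 <- defs[defs$group == "RT4", ]
  an <- analyze_force_maps(fm$curves, fm$metadata)
  expect_equal(an$decay_fit$plateau_fraction, rt4$plateau_fraction,
               tolerance = 1e-6)
  expect_equal(an$decay_fit$tau_decay, rt4$tau_decay_min, tolerance = 1e-4)
  # every fitted modulus equals the generator truth
  t0 <- an$map_moduli$modulus_pa[an$map_moduli$timepoint_min == 0]
  expect_equal(t0, rep(rt4$baseline_pa, 2), tolerance = 1e-6)
  expect_error(generate_force_maps("NOPE"), "unknown")
})

test_that("stiffness defaults encode the solved decay constants and baselines", {
  defs <- stiffness_group_defaults()
  rt4 <- defs[defs$group == "RT4", ]
  expect_equal(rt4$plateau_fraction, 0.40)
  expect_equal(rt4$tau_decay_min, 4 / log(6), tolerance = 1e-12)
  # SV-HUC-1 parameters reproduce its two reported losses
  sv <- defs[defs$group == "SV-HUC-1", ]
  y <- function(t) sv$plateau_fraction + (1 - sv$plateau_fraction) * exp(-t / sv$tau_decay_min)
  expect_equal(100 * (1 - y(4)), 26, tolerance = 1e-6)
  expect_equal(100 * (1 - y(10)), 29, tolerance = 1e-6)
  # baselines recover the printed 10-min moduli
  expect_equal(rt4$baseline_pa * (0.4 + 0.6 * exp(-10 / rt4$tau_decay_min)),
               401.8, tolerance = 1e-10)
  expect_equal(sv$baseline_pa * y(10), 1218.5, tolerance = 1e-6)
})
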