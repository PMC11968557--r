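test_that("the generator reproduces the replicate plan and is deterministic", {
  cfg <- sim_config(n_genes = 20, scenario = "late", seed = 11)
  sim <- simulate_timecourse(cfg)
  md <- sim$metadata
  expect_equal(length(unique(md$time_hpf)), 10L)
  per_tp <- table(md$time_hpf, md$concentration_level)
  expect_true(all(per_tp[, "control"] == 2L))
  expect_true(all(per_tp[, c("C_medium", "C_high")] == 1L))
  expect_equal(nrow(sim$expression), 20L)
  expect_setequal(colnames(sim$expression), md$sample_id)

  sim2 <- simulate_timecourse(cfg)
  expect_identical(unclass(sim$expression), unclass(sim2$expression))
  expect_identical(sim$truth, sim2$truth)

  early <- simulate_timecourse(sim_config(n_genes = 5, scenario = "early",
                                          seed = 2))
  expect_equal(length(unique(early$metadata$time_hpf)), 6L)
  expect_setequal(levels(droplevels(factor(early$metadata$concentration_level))),
                  c("control", "C_low", "C_medium"))
})

test_that("null-only mixes leave treatment and control exchangeable", {
  cfg <- sim_config(n_genes = 200, scenario = "late",
                    treatment_levels = "C_medium",
                    pattern_mix = c(null = 1, impulse = 0, sustained = 0),
                    noise_sd = 0.3, seed = 12)
  sim <- simulate_timecourse(cfg)
  md <- sim$metadata
  v <- unclass(sim$expression)
  diff_per_gene <- rowMeans(v[, md$concentration_level == "C_medium"]) -
    rowMeans(v[, md$concentration_level == "control"])
  expect_lt(abs(mean(diff_per_gene)), 0.05)
  expect_true(all(sim$truth$magnitude == 0))
})

test_that("sustained effects materialise at the configured magnitude", {
  cfg <- sim_config(n_genes = 30, scenario = "late",
                    treatment_levels = "C_medium",
                    pattern_mix = c(null = 0, impulse = 0, sustained = 1),
                    magnitude = 1, noise_sd = 1e-6, seed = 13)
  sim <- simulate_timecourse(cfg)
  md <- sim$metadata
  v <- unclass(sim$expression)
  # well after onset the treatment-minus-control difference reaches the
  # (signed) configured magnitude
  late_t <- md$time_hpf >= 90
  trt <- v[, late_t & md$concentration_level == "C_medium", drop = FALSE]
  ctl <- v[, late_t & md$concentration_level == "control", drop = FALSE]
  gap <- rowMeans(trt) - rowMeans(ctl)
  far <- sim$truth$onset_hpf < 60
  expect_equal(unname(abs(gap[far])), rep(1, sum(far)), tolerance = 0.1)
  sgn <- ifelse(sim$truth$direction == "up", 1, -1)
  expect_true(all(sign(gap[far]) == sgn[far]))
})

test_that("negative-binomial counts honour library sizes and the log-CPM path", {
  cfg <- sim_config(n_genes = 300, scenario = "late",
                    treatment_levels = "C_medium",
                    count_mode = "negative_binomial", dispersion = 1e-8,
                    library_size_range = c(1e8, 2e8), seed = 14)
  sim <- simulate_counts(cfg)
  expect_identical(scale_tag(sim$expression), "counts")
  cs <- colSums(unclass(sim$expression))
  # Poisson-scale check; 4-sigma margin so 50 simultaneous samples pass
  expect_true(all(abs(cs - sim$library_sizes) <= 4 * sqrt(sim$library_sizes)))

  # near-Poisson with large libraries: log-CPM recovers the log2 signal up
  # to the per-sample normalisation constant
  lc <- log_cpm_transform(sim$expression)
  resid <- unclass(lc) - sim$signal
  centred <- sweep(resid, 2L, colMeans(resid))
  expect_lt(sqrt(mean(centred^2)), 0.05)

  sim_b <- simulate_counts(cfg)
  expect_identical(unclass(sim$expression), unclass(sim_b$expression))
  expect_error(sim_config(count_mode = "negative_binomial",
                          dispersion = 0), "dispersion")
})

test_that("labelled calibration scores separate strong effects completely", {
  lab <- simulate_labeled_scores(n_per_scenario = 8, magnitude = 2,
                                 noise_sd = 0.2,
                                 pattern_mix = c(null = 0.5, impulse = 0,
                                                 sustained = 0.5),
                                 n_sim = 300, seed = 15)
  expect_equal(nrow(lab), 16L)
  expect_setequal(unique(lab$scenario), c("early", "late"))
  expect_true(all(c("de", "not_de") %in% lab$label))
  cal <- calibrate_cutoff(lab$score, lab$label)
  expect_equal(cal$min_cost, 0)
})

test_that("mean effect size grows with the simulated magnitude", {
  mean_abs <- vapply(c(0.5, 1, 2), function(mag) {
    cfg <- sim_config(n_genes = 12, scenario = "late",
                      treatment_levels = "C_medium",
                      pattern_mix = c(null = 0, impulse = 0, sustained = 1),
                      magnitude = mag, noise_sd = 0.3, seed = 16)
    sim <- simulate_timecourse(cfg)
    fits <- fit_timecourse(sim$expression, sim$metadata)
    sc <- vapply(names(fits$fits), function(g) {
      b <- difference_band(fits$fits[[g]], "C_medium", n_sim = 300,
                           seed = derive_seed(16, g))
      effect_score(b)$auci95_per_hour
    }, numeric(1))
    mean(abs(sc))
  }, numeric(1))
  expect_true(all(diff(mean_abs) > 0))
})

test_that("invalid pattern mixes are rejected", {
  expect_error(sim_config(pattern_mix = c(null = 0.5, impulse = 0.2,
                                          sustained = 0.2)), "summing to 1")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(time_points = c(24, 24, 48)), "increasing")
})
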