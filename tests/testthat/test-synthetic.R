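test_that("generation is bit-reproducible from the spec seed", {
  sp <- sim_spec(n_subjects_per_group = 3, n_voxels = 10, n_timepoints = 60,
                 run_lengths = c(30, 30), voxel_timescale_s = 10, seed = 5)
  g1 <- generate_bold_groups(sp)
  g2 <- generate_bold_groups(sp)
  expect_identical(g1$group_a$data, g2$group_a$data)
  expect_identical(g1$group_b$data, g2$group_b$data)
  expect_identical(g1$truth, g2$truth)
})

test_that("zero amplitudes give pure noise with ISC near zero", {
  sp <- sim_spec(n_subjects_per_group = 5, n_voxels = 50, n_timepoints = 200,
                 run_lengths = c(100, 100), voxel_timescale_s = 0,
                 shared_amplitude = 0, seed = 2)
  g <- generate_bold_groups(sp)
  expect_false(any(g$truth$shared_voxel_mask))
  m <- isc_across(g$group_a, g$group_b)
  expect_lt(abs(mean(m$mean_r)), 0.02)
  expect_lt(max(abs(m$mean_r)), 4 / sqrt(200))
})

test_that("the noiseless limit drives pairwise correlations to one", {
  sp <- sim_spec(n_subjects_per_group = 3, n_voxels = 4, n_timepoints = 100,
                 run_lengths = 100, voxel_timescale_s = 20,
                 shared_amplitude = 1e4, noise_ar1 = 0, seed = 3)
  g <- generate_bold_groups(sp)
  m <- isc_across(g$group_a, g$group_b)
  expect_true(all(m$mean_r > 0.999))
})

test_that("shared-voxel ISC matches the closed-form signal-plus-noise value", {
  ## amplitude a with unit-variance noise: r = a^2 / (a^2 + 1) = 0.5 at a = 1
  sp <- sim_spec(n_subjects_per_group = 5, n_voxels = 40, n_timepoints = 300,
                 run_lengths = c(150, 150), voxel_timescale_s = 20,
                 shared_amplitude = 1, noise_ar1 = 0, seed = 7)
  g <- generate_bold_groups(sp)
  ## brute-force correlation of the returned arrays, all cross pairs
  rs <- c()
  for (v in 1:40) for (i in 1:5) for (j in 1:5)
    rs <- c(rs, cor(g$group_a$data[[i]][v, ], g$group_b$data[[j]][v, ]))
  expect_equal(mean(rs), 0.5, tolerance = 0.05)
})

test_that("swapping the groups leaves across-condition statistics unchanged", {
  sp <- sim_spec(n_subjects_per_group = 4, n_voxels = 12, n_timepoints = 120,
                 run_lengths = c(60, 60), voxel_timescale_s = 16, seed = 9)
  g <- generate_bold_groups(sp)
  ab <- isc_across(g$group_a, g$group_b)
  ba <- isc_across(g$group_b, g$group_a)
  expect_equal(ab$mean_r, ba$mean_r, tolerance = 1e-14)
  expect_equal(ab$t_stat, ba$t_stat, tolerance = 1e-12)
})

test_that("design-length mismatches are rejected", {
  sp <- sim_spec(n_subjects_per_group = 3, n_voxels = 5, n_timepoints = 50,
                 run_lengths = 50, voxel_timescale_s = 0,
                 model_amplitude = 1, seed = 1)
  expect_error(generate_bold_groups(sp, designs = matrix(rnorm(40 * 2), 40, 2)),
               "40 rows")
})

test_that("feature models have the declared collinearity structure", {
  sp <- sim_spec(n_subjects_per_group = 3, n_voxels = 5, n_timepoints = 2000,
                 run_lengths = c(1000, 1000), voxel_timescale_s = 0, seed = 3)
  ## collinearity 0: model columns uncorrelated with editing
  fm0 <- generate_feature_models(sp, collinearity = 0)
  expect_lt(max(abs(cor(fm0$low_auditory$matrix, fm0$editing$matrix))), 0.25)
  ## collinearity 0.5: R^2 of each column on editing ~ 0.25, by direct regression
  fm <- generate_feature_models(sp, collinearity = 0.5)
  r2 <- apply(fm$high_semantic$matrix, 2, function(y)
    summary(lm(y ~ fm$editing$matrix))$r.squared)
  expect_equal(mean(r2), 0.25, tolerance = 0.08)
  ## all columns standardized
  expect_equal(unname(apply(fm$low_visual$matrix, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_error(generate_feature_models(sp, collinearity = 1), "collinearity")
})

test_that("near-total collinearity leaves almost no orthogonalized variance", {
  sp <- sim_spec(n_subjects_per_group = 3, n_voxels = 5, n_timepoints = 300,
                 run_lengths = 300, voxel_timescale_s = 0, seed = 4)
  fm <- generate_feature_models(sp, collinearity = 0.999)
  om <- orthogonalize(fm$low_auditory, fm$editing)
  expect_lt(mean(apply(om$matrix, 2, var)), 0.01)
})

test_that("stimulus streams plant the ground-truth events and respect Nyquist", {
  st <- generate_stimulus_streams(60, 25, data.frame(onset_s = 10, duration_s = 20,
                                                     period_s = 4), seed = 11)
  expect_length(st$stream_a$values, 1500)
  tt <- (seq_len(1500) - 1) / 25
  on <- tt >= 10 & tt < 30
  ## shared oscillation raises the in-event cross-correlation
  expect_gt(cor(st$stream_a$values[on], st$stream_b$values[on]), 0.2)
  expect_lt(abs(cor(st$stream_a$values[!on], st$stream_b$values[!on])), 0.1)
  ## no events: independent noise
  st0 <- generate_stimulus_streams(20, 25, NULL, seed = 12)
  expect_lt(abs(cor(st0$stream_a$values, st0$stream_b$values)), 0.1)
  ## noiseless single event: identical streams
  st1 <- generate_stimulus_streams(20, 25,
                                   data.frame(onset_s = 0, duration_s = 20, period_s = 5),
                                   seed = 13, noise_sd = 0)
  expect_equal(st1$stream_a$values, st1$stream_b$values, tolerance = 1e-12)
  expect_error(generate_stimulus_streams(20, 25,
                                         data.frame(onset_s = 0, duration_s = 10, period_s = 0.05),
                                         seed = 1), "Nyquist")
  expect_error(generate_stimulus_streams(20, 25,
                                         data.frame(onset_s = 15, duration_s = 10, period_s = 2),
                                         seed = 1), "within")
})

test_that("downstream p-values are uniform under the null generator", {
  ## exchangeability: no shared signal -> surrogate p-values ~ U(0,1)
  sp <- sim_spec(n_subjects_per_group = 4, n_voxels = 500, n_timepoints = 120,
                 run_lengths = c(60, 60), voxel_timescale_s = 0,
                 shared_amplitude = 0, seed = 21)
  g <- generate_bold_groups(sp)
  m <- isc_across(g$group_a, g$group_b)
  nd <- null_distribution(isc_stat_across, list(g$group_a, g$group_b),
                          surrogate_spec(n_permutations = 99, seed = 22))
  p <- iscor:::.p_from_null(m$t_stat, nd$per_voxel_stats, gpd = TRUE)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
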