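test_that("window_average: identity, constants, hand arithmetic, affine commutation", {
  expect_equal(window_average(c(1, 2, 3, 4), 2), c(1.5, 2.5, 3.5))
  x <- rnorm(20)
  expect_equal(window_average(x, 1), x)
  expect_equal(window_average(rep(2.5, 10), 4), rep(2.5, 7))
  expect_error(window_average(x, 21), "exceeds")
  ## commutes with affine transforms
  expect_equal(window_average(3 * x + 1, 5), 3 * window_average(x, 5) + 1,
               tolerance = 1e-12)
})

test_that("the smallest-width row of a TRW profile is exactly the classical ISC map", {
  sp <- sim_spec(n_subjects_per_group = 4, n_voxels = 15, n_timepoints = 150,
                 run_lengths = c(75, 75), voxel_timescale_s = 20, seed = 61)
  g <- generate_bold_groups(sp)
  pr <- trw_profile(g$group_a, widths_s = seq(2, 60, 2))
  expect_identical(pr$isc_by_width[1, ], isc_within(g$group_a)$mean_r)
  ## across-condition variant too
  pr2 <- trw_profile(g$group_a, g$group_b, widths_s = c(2, 10, 20))
  expect_identical(pr2$isc_by_width[1, ], isc_across(g$group_a, g$group_b)$mean_r)
})

test_that("trw_peak: argmax with smallest-width ties, oracle agreement, transform invariance", {
  widths <- seq(2, 20, 2)
  mk <- function(m) structure(list(widths_s = widths, isc_by_width = m),
                              class = "trw_profile")
  inc <- matrix(seq(0.1, 1, length.out = 10), 10, 1)
  expect_equal(trw_peak(mk(inc)), 20)
  flat <- matrix(0.3, 10, 1)
  expect_equal(trw_peak(mk(flat)), 2)
  allna <- matrix(NA_real_, 10, 1)
  expect_true(is.na(trw_peak(mk(allna))))
  set.seed(3)
  m <- matrix(rnorm(10 * 25), 10, 25)
  got <- trw_peak(mk(m))
  want <- sapply(1:25, function(v) {     # linear-scan oracle
    best <- 1
    for (i in 2:10) if (m[i, v] > m[best, v]) best <- i
    widths[best]
  })
  expect_equal(got, want)
  ## invariant under a strictly monotone transform of all rows
  expect_equal(trw_peak(mk(exp(2 * m))), got)
})

test_that("trw_significance uses each voxel's tuning and degenerates correctly", {
  sp <- sim_spec(n_subjects_per_group = 4, n_voxels = 10, n_timepoints = 120,
                 run_lengths = c(60, 60), voxel_timescale_s = 20, seed = 71)
  g <- generate_bold_groups(sp)
  pr <- trw_profile(g$group_a, widths_s = seq(2, 40, 2))
  sig <- trw_significance(pr, g$group_a, spec = surrogate_spec(n_permutations = 40, seed = 72),
                          min_cluster = 1)
  expect_length(sig$p, 10)
  expect_true(all(sig$p > 0 & sig$p <= 1))
  ## shared voxels should dominate the significant set
  expect_gt(mean(sig$significant_mask), 0.5)
  sig1 <- trw_significance(pr, g$group_a, spec = surrogate_spec(n_permutations = 1, seed = 73),
                           min_cluster = 1)
  expect_true(all(sig1$p %in% c(0.5, 1)))
})

test_that("map_similarity: identical, reversed and null-referenced maps", {
  set.seed(9)
  map_a <- sample(seq(2, 240, 2), 40, replace = TRUE)
  nulls <- matrix(sample(seq(2, 240, 2), 40 * 50, replace = TRUE), 50, 40)
  same <- map_similarity(map_a, map_a, rep(TRUE, 40), nulls)
  expect_equal(same$rho, 1)
  expect_lte(same$p, 2 / 51 + 1e-12)
  rev_b <- max(map_a) + min(map_a) - map_a
  expect_equal(map_similarity(map_a, rev_b, rep(TRUE, 40), nulls)$rho, -1)
  expect_gte(same$p, 1 / 51)
  expect_error(map_similarity(map_a, map_a, 1:5, nulls), "at least 10")
  expect_error(map_similarity(rep(4, 40), map_a, rep(TRUE, 40), nulls), "constant")
})

test_that("planted chronotopic structure is recovered across synthetic conditions", {
  ## the same timescale topography in two independent datasets gives rho > 0
  ts <- rep(c(10, 30, 60), each = 8)
  mk <- function(seed) generate_bold_groups(
    sim_spec(n_subjects_per_group = 5, n_voxels = 24, n_timepoints = 400,
             run_lengths = c(200, 200), voxel_timescale_s = ts,
             shared_amplitude = 1.5, seed = seed))
  g1 <- mk(81); g2 <- mk(82)
  w <- seq(2, 100, 2)
  p1 <- trw_profile(g1$group_a, g1$group_b, widths_s = w)
  p2 <- trw_profile(g2$group_a, g2$group_b, widths_s = w)
  nulls <- trw_null_maps(g1$group_a, g1$group_b, widths_s = w, n_maps = 40,
                         spec = surrogate_spec(seed = 83))
  sim <- map_similarity(p1$peak_width_s, p2$peak_width_s, rep(TRUE, 24), nulls)
  expect_gt(sim$rho, 0.3)
  expect_lte(sim$p, 0.05)
})
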