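test_that("pairwise_r matches hand computation and handles degenerate input", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  ## textbook covariance over product of standard deviations, by hand
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pairwise_r(x, y), r_hand, tolerance = 1e-15)
  expect_equal(pairwise_r(x, x), 1, tolerance = 1e-14)
  expect_equal(pairwise_r(x, -x), -1, tolerance = 1e-14)
  expect_error(pairwise_r(x, rep(2, 4)), "second series has zero variance")
  expect_error(pairwise_r(rep(0, 4), x), "first series has zero variance")
  expect_error(pairwise_r(1:4, 1:5), "lengths differ")
  expect_error(pairwise_r(c(1, 2), c(3, 4)), "at least 3")
})

test_that("isc_within reproduces the brute-force oracle and trivial cases", {
  ## three identical subjects: mean r is 1 everywhere
  set.seed(11)
  m <- matrix(rnorm(5 * 40), 5, 40)
  g_id <- bold_group(list(m, m, m), 2, 40)
  expect_equal(isc_within(g_id)$mean_r, rep(1, 5), tolerance = 1e-12)
  expect_equal(isc_within(make_group(10, 2, 30))$n_pairs, 45L)

  g <- make_group(5, 10, 50, run_lengths = c(20, 30), seed = 42)
  got <- isc_within(g)
  want <- oracle_isc_within(g)
  expect_equal(got$mean_r, want$mean_r, tolerance = 1e-12)
  expect_equal(got$t_stat, want$t_stat, tolerance = 1e-12)
})

test_that("isc_across counts cross pairs only, is symmetric, and matches the oracle", {
  ga <- make_group(10, 3, 40, seed = 1)
  gb <- make_group(10, 3, 40, seed = 2)
  expect_equal(isc_across(ga, gb)$n_pairs, 100L)
  ga9 <- make_group(9, 3, 40, seed = 3)
  gb9 <- make_group(9, 3, 40, seed = 4)
  expect_equal(isc_across(ga9, gb9)$n_pairs, 81L)

  a <- make_group(4, 8, 50, run_lengths = c(25, 25), seed = 5)
  b <- make_group(5, 8, 50, run_lengths = c(25, 25), seed = 6)
  expect_equal(isc_across(a, b)$mean_r, isc_across(b, a)$mean_r, tolerance = 1e-14)
  expect_equal(isc_across(a, b)$mean_r, oracle_isc_across(a, b), tolerance = 1e-12)

  ## group correlated with itself: mean of the full N x N matrix incl. diagonal
  full <- sapply(seq_len(n_voxels(a)), function(v) {
    rs <- outer(seq_along(a$data), seq_along(a$data), Vectorize(function(i, j)
      cor(oracle_demean(a$data[[i]][v, ], a$run_lengths),
          oracle_demean(a$data[[j]][v, ], a$run_lengths))))
    mean(rs)
  })
  expect_equal(isc_across(a, a)$mean_r, full, tolerance = 1e-12)

  expect_error(isc_across(a, make_group(3, 8, 40, seed = 7)), "shapes differ")
})

test_that("mean_r is invariant to per-subject affine rescaling and bounded by the pair max", {
  g <- make_group(4, 6, 60, run_lengths = c(30, 30), seed = 8)
  g2 <- g
  g2$data[[2]] <- 3.7 * g2$data[[2]] + 11
  g2$data[[4]] <- 0.2 * g2$data[[4]] - 5
  expect_equal(isc_within(g)$mean_r, isc_within(g2)$mean_r, tolerance = 1e-12)

  got <- isc_within(g, keep_pairs = TRUE)
  expect_true(all(abs(got$mean_r) <= apply(abs(got$pair_r), 2, max) + 1e-14))
})

test_that("conjunction is the voxelwise AND of significance masks", {
  mk <- function(mask) structure(list(significant_mask = mask), class = "isc_map")
  allt <- mk(rep(TRUE, 8)); allf <- mk(rep(FALSE, 8))
  expect_equal(conjunction(list(allt, allf)), rep(FALSE, 8))
  m <- mk(c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(conjunction(list(m, m)), m$significant_mask)
  set.seed(2)
  m1 <- mk(runif(30) > 0.5); m2 <- mk(runif(30) > 0.5)
  got <- conjunction(list(m1, m2))
  want_idx <- intersect(which(m1$significant_mask), which(m2$significant_mask))
  expect_equal(which(got), want_idx)
  expect_error(conjunction(list(mk(rep(TRUE, 3)), mk(rep(TRUE, 4)))), "voxel count")
})

test_that("roi_pair_matrix composes ROI averaging with pairwise correlation", {
  g <- make_group(4, 12, 48, run_lengths = c(24, 24), seed = 9)
  roi <- c(2, 5, 7)
  res <- roi_pair_matrix(list(g), roi, spec = surrogate_spec(n_permutations = 30, seed = 1))
  expect_equal(unname(diag(res$r)), rep(1, 4))
  expect_equal(res$r, t(res$r))
  ## independent composition: ROI-mean series then pairwise_r
  for (i in 1:3) for (j in (i + 1):4) {
    si <- oracle_demean(colMeans(g$data[[i]][roi, ]), g$run_lengths)
    sj <- oracle_demean(colMeans(g$data[[j]][roi, ]), g$run_lengths)
    expect_equal(res$r[i, j], pairwise_r(si, sj), tolerance = 1e-12)
  }
  ## duplicated subject: off-diagonal unit correlation
  gd <- bold_group(list(g$data[[1]], g$data[[1]]), 2, c(24, 24))
  rd <- roi_pair_matrix(list(gd), roi, spec = surrogate_spec(n_permutations = 20, seed = 2))
  expect_equal(rd$r[1, 2], 1, tolerance = 1e-12)
  expect_error(roi_pair_matrix(list(g), integer(0)), "empty")
})

test_that("compare_groups: rank-sum statistic, Bonferroni and power", {
  same <- compare_groups(1:20 / 20, 1:20 / 20, n_regions = 6)
  expect_equal(same$mean_diff_r, 0)
  expect_gt(same$p_raw, 0.9)

  sep <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$W, 1 + 2 + 3)  # complete separation: lowest three ranks
  expect_equal(sep$p_bonferroni, min(1, sep$p_raw * 1))

  bonf <- compare_groups(rnorm(30), rnorm(30, 2), n_regions = 6)
  expect_equal(bonf$p_bonferroni, min(1, bonf$p_raw * 6))

  ## shifted normal samples, n = 100 / 81: rejection in > 99% of replicates
  set.seed(101)
  rej <- mean(replicate(200, {
    compare_groups(rnorm(100, 1), rnorm(81))$p_raw < 0.05
  }))
  expect_gt(rej, 0.99)
})
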