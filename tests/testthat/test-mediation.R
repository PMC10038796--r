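sim_models <- function(seed = 3, nt = 1500, runs = c(750, 750)) {
  sp <- sim_spec(n_subjects_per_group = 3, n_voxels = 5, n_timepoints = nt,
                 run_lengths = runs, voxel_timescale_s = 0, seed = seed)
  generate_feature_models(sp, collinearity = 0.5)
}

test_that("orthogonalize removes editing variance, is idempotent, leaves orthogonal input alone", {
  fm <- sim_models()
  om <- orthogonalize(fm$low_auditory, fm$editing)
  expect_lt(max(abs(cor(om$matrix, fm$editing$matrix))), 1e-10)
  ## residual variance ~ 1 - 0.5^2 of the (unit) original column variance
  expect_equal(mean(apply(om$matrix, 2, var)), 0.75, tolerance = 0.08)
  ## idempotence
  om2 <- orthogonalize(om, fm$editing)
  expect_equal(om2$matrix, om$matrix, tolerance = 1e-10)
  ## a column already orthogonal to editing: unchanged up to mean removal
  set.seed(8)
  q <- qr.resid(qr(cbind(1, fm$editing$matrix)), rnorm(nrow(fm$editing$matrix)))
  solo <- feature_model("solo", "high_semantic", fm$editing$times_s,
                        cbind(q), fm$editing$native_rate_hz)
  os <- orthogonalize(solo, fm$editing)
  expect_equal(as.numeric(os$matrix), q - mean(q), tolerance = 1e-10)
  ## a column inside the editing span: residual ~ 0
  span <- feature_model("span", "high_semantic", fm$editing$times_s,
                        cbind(fm$editing$matrix %*% c(1, -2, 0.5)),
                        fm$editing$native_rate_hz)
  expect_lt(max(abs(orthogonalize(span, fm$editing)$matrix)), 1e-10)
})

test_that("rank-deficient editing matrices are pruned with a warning", {
  fm <- sim_models()
  E <- fm$editing
  E$matrix <- cbind(E$matrix, E$matrix[, 1] * 2)
  expect_warning(om <- orthogonalize(fm$low_visual, E), "rank-deficient")
  om0 <- orthogonalize(fm$low_visual, fm$editing)
  expect_equal(om$matrix, om0$matrix, tolerance = 1e-10)
})

test_that("build_design convolves, bins and normalizes as the brute-force oracle says", {
  nt <- 100; tr <- 2
  times <- seq(0.02, by = 0.04, length.out = nt * tr * 25)  # native 25 Hz
  ## unit impulse at t = 0
  imp <- numeric(length(times)); imp[1] <- 1
  m <- feature_model("imp", "low_auditory", times, cbind(imp), 25)
  D <- build_design(m, tr, nt, run_lengths = nt)
  h <- iscor:::hrf_double_gamma(seq(0, 32, by = 0.04)); h <- h / sum(h)
  want <- numeric(nt)
  for (k in seq_len(nt)) {
    bin <- times >= (k - 1) * tr & times < k * tr
    hh <- c(h, rep(0, length(times)))[seq_along(times)]
    want[k] <- mean(hh[bin])
  }
  want <- (want - mean(want)) / sd(want)
  expect_equal(unname(D[, 1]), want, tolerance = 1e-8)
  ## all-zero feature column stays all-zero (z-score guard)
  mz <- feature_model("z", "low_auditory", times, cbind(0 * imp), 25)
  expect_true(all(build_design(mz, tr, nt, nt)[, 1] == 0))
  ## boxcar of 20 s equals direct numerical convolution, TR-binned
  box <- as.numeric(times >= 10 & times < 30)
  mb <- feature_model("box", "low_visual", times, cbind(box), 25)
  Db <- build_design(mb, tr, nt, nt)
  conv_full <- numeric(length(box))
  for (i in seq_along(box)) {
    jmax <- min(i, length(h))
    conv_full[i] <- sum(h[1:jmax] * box[i - (1:jmax) + 1])
  }
  wantb <- sapply(seq_len(nt), function(k)
    mean(conv_full[times >= (k - 1) * tr & times < k * tr]))
  wantb <- (wantb - mean(wantb)) / sd(wantb)
  expect_equal(unname(Db[, 1]), wantb, tolerance = 1e-6)
  expect_error(build_design(mb, tr, 5 * nt, 5 * nt), "spans")
})

test_that("residualize_bold produces design-orthogonal residuals (normal equations)", {
  g <- make_group(3, 6, 80, run_lengths = c(40, 40), seed = 12)
  set.seed(13)
  X <- matrix(rnorm(80 * 3), 80, 3)
  rg <- residualize_bold(g, X)
  for (s in 1:3) {
    R <- rg$data[[s]]
    expect_lt(max(abs(R %*% X)), 1e-8)
    expect_lt(max(abs(rowSums(R))), 1e-8)   # intercept removed too
    ## normal-equations oracle for one voxel
    y <- g$data[[s]][4, ]
    XX <- cbind(1, X)
    beta <- solve(t(XX) %*% XX, t(XX) %*% y)
    expect_equal(R[4, ], as.numeric(y - XX %*% beta), tolerance = 1e-10)
  }
  ## intercept-only design: mean-centring
  rg0 <- residualize_bold(g, matrix(1, 80, 1))
  expect_equal(rg0$data[[1]], g$data[[1]] - rowMeans(g$data[[1]]), tolerance = 1e-12)
  ## voxel series inside the design span: residual ~ 0
  g2 <- g
  g2$data[[1]][2, ] <- as.numeric(X %*% c(2, -1, 3)) + 5
  expect_lt(max(abs(residualize_bold(g2, X)$data[[1]][2, ])), 1e-9)
  expect_error(residualize_bold(g, cbind(X, X[, 1])), "rank-deficient")
})

test_that("mediated_isc: no design, full containment, and planted half-variance", {
  ## intercept-only designs: drop ~ 0
  sp <- sim_spec(n_subjects_per_group = 4, n_voxels = 20, n_timepoints = 200,
                 run_lengths = c(100, 100),
                 voxel_timescale_s = rep(c(10, 20, 40, 60), 5), seed = 31)
  g <- generate_bold_groups(sp)
  r0 <- mediated_isc(g$group_a, g$group_b)
  expect_lt(max(abs(r0$drop)), 1e-10)
  expect_equal(r0$drop, r0$isc_original - r0$isc_mediated, tolerance = 1e-14)

  ## latent fully inside the design span: mediated ~ 0, drop ~ original.
  ## run intercepts let the span cover the per-run-demeaned latent the
  ## emitted data actually contain
  X <- t(g$truth$latents)                 # timepoints x voxels latent designs
  X <- cbind(X[, 1:3], iscor:::.run_intercepts(c(100, 100)))
  attr(X, "run_intercepts") <- TRUE
  rf <- mediated_isc(subset_voxels(g$group_a, 1:3),
                     subset_voxels(g$group_b, 1:3), X, X)
  expect_lt(max(abs(rf$isc_mediated)), 2 / sqrt(200))
  expect_lt(max(abs(rf$drop - rf$isc_original)), 2 / sqrt(200))

  ## half of the shared variance model-driven: in the weak-correlation
  ## regime (shared variance << noise) drop / original ~ 0.5
  spm <- sim_spec(n_subjects_per_group = 5, n_voxels = 30, n_timepoints = 600,
                  run_lengths = c(300, 300), voxel_timescale_s = 24,
                  shared_amplitude = 0.25, model_amplitude = 0.25, seed = 32)
  set.seed(33)
  D <- matrix(rnorm(600 * 3), 600, 3)
  gm <- generate_bold_groups(spm, designs = D)
  rm_ <- mediated_isc(gm$group_a, gm$group_b, D, D)
  ratio <- mean(rm_$drop) / mean(rm_$isc_original)
  expect_equal(ratio, 0.5, tolerance = 0.1)
})

test_that("drop is invariant to invertible recombination of design columns", {
  g <- make_group(3, 8, 60, run_lengths = c(30, 30), seed = 41)
  set.seed(42)
  X <- matrix(rnorm(60 * 3), 60, 3)
  A <- matrix(c(2, 0, 1, -1, 3, 0, 0.5, 0, 1), 3, 3)
  r1 <- mediated_isc(g, make_group(3, 8, 60, run_lengths = c(30, 30), seed = 43), X, X)
  r2 <- mediated_isc(g, make_group(3, 8, 60, run_lengths = c(30, 30), seed = 43),
                     X %*% A, X %*% A)
  expect_equal(r1$drop, r2$drop, tolerance = 1e-10)
})

test_that("compare_model_drops: degenerate, full-positive and exact enumeration", {
  ## identical inputs: all differences zero, voxels untestable
  d <- matrix(rnorm(6 * 4), 6, 4)
  same <- compare_model_drops(d, d, n_permutations = 100, seed = 1)
  expect_true(all(same$untestable))

  ## all positive differences over 6 pairs: W = 21
  lo <- matrix(2, 6, 2); hi <- matrix(1, 6, 2)
  allpos <- compare_model_drops(lo + matrix(runif(12), 6) * 0.1, hi,
                                n_permutations = 64, seed = 2)
  expect_equal(unname(allpos$W), c(21, 21))

  ## n = 8 pairs: permutation p equals the exhaustive 2^8 oracle
  set.seed(5)
  dl <- matrix(rnorm(8 * 3), 8, 3)
  dh <- matrix(rnorm(8 * 3), 8, 3)
  got <- compare_model_drops(dl, dh, n_permutations = 256, seed = 3)
  expect_true(got$exact)
  for (v in 1:3)
    expect_equal(got$p[v], oracle_signrank_p(dl[, v] - dh[, v]), tolerance = 1 / 256)
})

test_that("drop_significance finds a planted mediated block and nothing under the null", {
  sp <- sim_spec(n_subjects_per_group = 4, n_voxels = 27, n_timepoints = 240,
                 run_lengths = c(120, 120), voxel_timescale_s = 0,
                 shared_amplitude = 0, model_amplitude = 0, seed = 51)
  g <- generate_bold_groups(sp)
  ## plant a model-driven shared component in the first 9 voxels
  set.seed(52)
  X <- matrix(rnorm(240 * 2), 240, 2)
  comp <- as.numeric(scale(X %*% c(1, -1)))
  for (s in 1:4) {
    g$group_a$data[[s]][1:9, ] <- g$group_a$data[[s]][1:9, ] + rep(comp, each = 9)
    g$group_b$data[[s]][1:9, ] <- g$group_b$data[[s]][1:9, ] + rep(comp, each = 9)
  }
  res <- mediated_isc(g$group_a, g$group_b, X, X)
  sig <- drop_significance(res, g$group_a, g$group_b, X, X,
                           surrogate_spec(n_permutations = 60, seed = 53),
                           min_cluster = 5)
  expect_true(all(which(sig$significant_mask) %in% 1:9))
  expect_gt(sum(sig$significant_mask), 0)
  ## single permutation: counting estimator gives p in {0.5, 1}
  sig1 <- drop_significance(res, g$group_a, g$group_b, X, X,
                            surrogate_spec(n_permutations = 1, seed = 54),
                            min_cluster = 1)
  expect_true(all(sig1$p_drop %in% c(0.5, 1)))
})
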