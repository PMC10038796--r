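#' Stimulus feature model
#'
#' A time-by-feature descriptor matrix at its native sampling rate, tagged
#' by level: low-level auditory (spectral, envelope), low-level visual
#' (Gabor filters, motion energy), high-level semantic (categories, word
#' embeddings) or editing (cuts, scene transitions, dialogue/music
#' presence). Editing models are nuisance descriptors that the other models
#' are orthogonalized against before use.
#'
#' @param name label.
#' @param level one of `"low_auditory"`, `"low_visual"`, `"high_semantic"`,
#'   `"editing"`.
#' @param times_s strictly increasing sample times in seconds.
#' @param matrix numeric timepoint x feature matrix, rows matching
#'   `times_s`.
#' @param native_rate_hz nominal sampling rate.
#' @return a `feature_model`.
#' @export
feature_model <- function(name, level, times_s, matrix, native_rate_hz) {
  level <- match.arg(level, c("low_auditory", "low_visual", "high_semantic", "editing"))
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(times_s))
    .stopf("model '%s': %d rows but %d sample times", name, nrow(matrix), length(times_s))
  if (any(diff(times_s) <= 0)) .stopf("model '%s': times must be strictly increasing", name)
  if (!is.numeric(native_rate_hz) || native_rate_hz <= 0)
    .stopf("native_rate_hz must be positive")
  structure(list(name = name, level = level, times_s = as.numeric(times_s),
                 matrix = matrix, native_rate_hz = native_rate_hz),
            class = "feature_model")
}

#' @export
print.feature_model <- function(x, ...) {
  cat(sprintf("<feature_model> '%s' (%s): %d samples x %d features @ %g Hz\n",
              x$name, x$level, nrow(x$matrix), ncol(x$matrix), x$native_rate_hz))
  invisible(x)
}

#' Resample a feature model onto a new time grid
#'
#' Linear interpolation of every column; constant extrapolation at the
#' edges.
#'
#' @param model a [feature_model()].
#' @param times_new new sample times (seconds).
#' @return a `feature_model` on the new grid.
#' @export
resample_model <- function(model, times_new) {
  m <- apply(model$matrix, 2L, function(col)
    stats::approx(model$times_s, col, xout = times_new, rule = 2)$y)
  feature_model(model$name, model$level, times_new, m,
                1 / stats::median(diff(times_new)))
}

#' Orthogonalize a feature model against editing descriptors
#'
#' Replaces every column of `model` by the residuals of its least-squares
#' regression on an intercept plus all editing columns, removing the
#' variance that editing events (cuts, transitions, dialogue) inject into
#' both low- and high-level descriptors. Residual columns are uncorrelated
#' with every editing column. Rank-deficient editing matrices have their
#' dependent columns dropped with a warning.
#'
#' @param model a [feature_model()].
#' @param editing a [feature_model()] of level `"editing"`; resampled to
#'   the model's grid if needed.
#' @return the orthogonalized `feature_model`.
#' @export
orthogonalize <- function(model, editing) {
  if (!identical(editing$level, "editing"))
    .stopf("second argument must be an editing-level model, got '%s'", editing$level)
  if (!isTRUE(all.equal(editing$times_s, model$times_s)))
    editing <- resample_model(editing, model$times_s)
  E <- editing$matrix
  qe <- qr(cbind(1, E))
  if (qe$rank < ncol(E) + 1L) {
    keep <- qe$pivot[seq_len(qe$rank)]
    keep <- setdiff(keep, 1L) - 1L
    .warnf("editing matrix is rank-deficient; dropping %d dependent column(s)",
           ncol(E) - length(keep))
    E <- E[, keep, drop = FALSE]
    qe <- qr(cbind(1, E))
  }
  res <- qr.resid(qe, model$matrix)
  out <- model
  out$matrix <- res
  out
}

## Canonical double-gamma haemodynamic response (peak 5 s, undershoot 15 s,
## peak-to-undershoot ratio 6), unit TR-sum normalization applied by the
## caller.
hrf_double_gamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
       stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

#' Build a BOLD-space design matrix from a feature model
#'
#' Convolves each feature column with the canonical double-gamma
#' haemodynamic response at the model's native rate, averages within TR
#' bins, z-scores per run, and appends per-run intercept columns. HRF
#' convolution can be disabled to regress features at lag zero.
#'
#' @param model a [feature_model()] whose time span covers the scan.
#' @param tr_seconds TR of the target scan.
#' @param n_timepoints scan length in TRs.
#' @param run_lengths run structure of the scan.
#' @param hrf convolve with the haemodynamic response (default `TRUE`).
#' @return a timepoint x column design matrix with attribute
#'   `"run_intercepts"` marking the appended intercept block.
#' @export
build_design <- function(model, tr_seconds, n_timepoints, run_lengths,
                         hrf = TRUE) {
  scan_dur <- n_timepoints * tr_seconds
  if (max(model$times_s) < scan_dur - tr_seconds)
    .stopf("model spans %.1f s but the scan lasts %.1f s",
           max(model$times_s), scan_dur)
  dt <- 1 / model$native_rate_hz
  X <- model$matrix
  if (hrf) {
    h <- hrf_double_gamma(seq(0, 32, by = dt))
    h <- h / sum(h)
    X <- apply(X, 2L, function(col)
      stats::convolve(col, rev(h), type = "open")[seq_along(col)])
  }
  ## average native samples within each TR bin
  bin <- pmin(floor(model$times_s / tr_seconds) + 1L, n_timepoints)
  keep <- model$times_s < scan_dur
  D <- apply(as.matrix(X[keep, , drop = FALSE]), 2L, function(col)
    as.numeric(tapply(col, bin[keep], mean)[as.character(seq_len(n_timepoints))]))
  D[is.na(D)] <- 0
  ## z-score per run
  at <- 0L
  for (L in run_lengths) {
    idx <- at + seq_len(L)
    D[idx, ] <- apply(D[idx, , drop = FALSE], 2L, function(col) {
      s <- stats::sd(col)
      if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
    at <- at + L
  }
  out <- cbind(D, .run_intercepts(run_lengths))
  attr(out, "run_intercepts") <- TRUE
  out
}

#' Remove a design's contribution from every subject's data
#'
#' Per subject and voxel, replaces the series by the residuals of its
#' least-squares regression on the design (an intercept is added unless the
#' design already carries run intercepts).
#'
#' @param group a [bold_group()].
#' @param design timepoint x column numeric matrix (e.g. from
#'   [build_design()]), rows matching the group's timepoints.
#' @return a `bold_group` of residual series.
#' @export
residualize_bold <- function(group, design) {
  design <- as.matrix(design)
  if (nrow(design) != n_timepoints(group))
    .stopf("design has %d rows but the group has %d timepoints",
           nrow(design), n_timepoints(group))
  if (qr(design)$rank < ncol(design))
    .stopf("design matrix is rank-deficient (%d columns, rank %d)",
           ncol(design), qr(design)$rank)
  X <- if (isTRUE(attr(design, "run_intercepts"))) design else cbind(1, design)
  qx <- qr(X)
  group$data <- lapply(group$data, function(m) t(qr.resid(qx, t(m))))
  group
}

#' Model-mediated intersubject correlation
#'
#' The mediation contrast at the heart of the approach: ISC is computed on
#' the raw groups and again after the feature design has been regressed out
#' of every subject, and the per-voxel "drop" (original minus mediated ISC)
#' quantifies how much synchronization that model carries. Designs may
#' differ between groups (cross-modal assignment: visual features removed
#' from listeners, acoustic features from viewers).
#'
#' @param group_a,group_b [bold_group()]s as in [isc_across()].
#' @param design_a,design_b designs for each group; `NULL` means intercept
#'   only (no mediation).
#' @return a `mediation_result`: `isc_original`, `isc_mediated`, `drop`
#'   (per-voxel), the two `isc_map`s, and the residualized groups' pair
#'   matrices are recomputable via the stored designs.
#' @export
mediated_isc <- function(group_a, group_b, design_a = NULL, design_b = NULL) {
  orig <- isc_across(group_a, group_b, keep_pairs = TRUE)
  ra <- if (is.null(design_a)) residualize_bold(group_a, matrix(1, n_timepoints(group_a), 1L))
        else residualize_bold(group_a, design_a)
  rb <- if (is.null(design_b)) residualize_bold(group_b, matrix(1, n_timepoints(group_b), 1L))
        else residualize_bold(group_b, design_b)
  med <- isc_across(ra, rb, keep_pairs = TRUE)
  structure(list(isc_original = orig$mean_r, isc_mediated = med$mean_r,
                 drop = orig$mean_r - med$mean_r,
                 map_original = orig, map_mediated = med,
                 p_drop = NULL, fwe_threshold = NULL,
                 significant_mask = NULL,
                 geometry = group_a$geometry),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %d voxels; mean drop %.4f (original %.4f -> mediated %.4f)\n",
              length(x$drop), mean(x$drop, na.rm = TRUE),
              mean(x$isc_original, na.rm = TRUE), mean(x$isc_mediated, na.rm = TRUE)))
  invisible(x)
}

## drop statistic of surrogate groups under fixed designs
.drop_stat_fn <- function(design_a, design_b) {
  function(groups) {
    res <- mediated_isc(groups[[1L]], groups[[2L]], design_a, design_b)
    res$drop
  }
}

#' Permutation significance of the mediation drop
#'
#' Surrogates both groups, recomputes the drop per permutation, and fills
#' one-tailed tail-approximated p-values, the max-drop FWE threshold and the
#' cluster-filtered significance mask.
#'
#' @param result a `mediation_result` from [mediated_isc()] on the same
#'   inputs.
#' @param group_a,group_b the raw groups.
#' @param design_a,design_b the designs used for the observed result.
#' @param spec a [surrogate_spec()].
#' @param alpha familywise error level.
#' @param min_cluster minimum cluster extent (applied when geometry is
#'   available).
#' @param connectivity cluster connectivity.
#' @return the `mediation_result` with `p_drop`, `fwe_threshold`,
#'   `significant_mask` set (plus `null` holding the permutation
#'   distribution).
#' @export
drop_significance <- function(result, group_a, group_b,
                              design_a = NULL, design_b = NULL,
                              spec = surrogate_spec(),
                              alpha = 0.05, min_cluster = 20L,
                              connectivity = 18L) {
  null <- null_distribution(.drop_stat_fn(design_a, design_b),
                            list(group_a, group_b), spec)
  result$p_drop <- .p_from_null(result$drop, null$per_voxel_stats)
  result$fwe_threshold <- fwe_threshold(null, alpha)
  supra <- is.finite(result$drop) & result$drop >= result$fwe_threshold
  if (!is.null(result$geometry) && min_cluster > 1L) {
    d <- result$drop
    d[!supra] <- -Inf
    result$significant_mask <- cluster_filter(d, result$fwe_threshold,
                                              min_size = min_cluster,
                                              connectivity = connectivity,
                                              geometry = result$geometry)
  } else {
    result$significant_mask <- supra
  }
  result$null <- null
  result
}

#' Per-pair decomposition of the mediation drop
#'
#' For the signed-rank contrast of two models the drop is needed at the
#' level of individual subject pairs: `r_pair(raw) - r_pair(residualized)`
#' for every cross pair, the natural pairwise decomposition of the
#' map-level drop.
#'
#' @inheritParams mediated_isc
#' @return a pair x voxel matrix of per-pair drops.
#' @export
pairwise_drops <- function(group_a, group_b, design_a = NULL, design_b = NULL) {
  res <- mediated_isc(group_a, group_b, design_a, design_b)
  res$map_original$pair_r - res$map_mediated$pair_r
}

#' Voxelwise signed-rank contrast of two models' mediation drops
#'
#' Compares, voxel by voxel, the per-pair drop of one model against
#' another's with a two-sided Wilcoxon signed-rank statistic
#' (`W` = sum of ranks of positive differences, midranks for ties, zero
#' differences dropped). The null is built by randomly sign-flipping each
#' pair's difference (the flip pattern shared across voxels so the spatial
#' maximum is meaningful); familywise thresholds are the 95th percentile of
#' the max-W and the 5th percentile of the min-W distributions, giving
#' separate masks for the two directions. With few enough pairs the
#' sign-flip null is enumerated exhaustively.
#'
#' @param drop_pairs_low,drop_pairs_high pair x voxel matrices from
#'   [pairwise_drops()], identical dimensions.
#' @param n_permutations sign-flip draws (exhaustive enumeration is used
#'   when `2^n_pairs <= n_permutations`).
#' @param seed RNG seed for the flip patterns.
#' @param min_nonzero voxels with fewer non-zero differences are flagged
#'   untestable (default 5).
#' @return a list: `W` (per voxel), `p` (two-sided per voxel),
#'   `fwe_threshold_high`/`fwe_threshold_low` (max-W / min-W thresholds),
#'   `mask_low_gt_high`, `mask_high_gt_low`, `untestable`, `exact`.
#' @export
compare_model_drops <- function(drop_pairs_low, drop_pairs_high,
                                n_permutations = 1000L, seed = NULL,
                                min_nonzero = 5L) {
  if (!identical(dim(drop_pairs_low), dim(drop_pairs_high)))
    .stopf("drop matrices must have identical pair and voxel dimensions")
  d <- drop_pairs_low - drop_pairs_high
  np <- nrow(d); nv <- ncol(d)
  w_of <- function(dv) {
    dv <- dv[dv != 0]
    if (!length(dv)) return(NA_real_)
    r <- rank(abs(dv))
    sum(r[dv > 0])
  }
  W <- apply(d, 2L, w_of)
  nz <- colSums(d != 0)
  untestable <- nz < min_nonzero
  exact <- 2^np <= n_permutations
  flips <- if (exact) {
    m <- as.matrix(expand.grid(rep(list(c(1, -1)), np)))
    t(m)
  } else {
    .with_seed(seed, matrix(sample(c(1, -1), np * n_permutations, replace = TRUE),
                            nrow = np))
  }
  nperm <- ncol(flips)
  Wnull <- matrix(NA_real_, nperm, nv)
  for (k in seq_len(nperm))
    Wnull[k, ] <- apply(d * flips[, k], 2L, w_of)
  p <- vapply(seq_len(nv), function(v) {
    if (untestable[v] || !is.finite(W[v])) return(NA_real_)
    nullv <- Wnull[, v]
    if (exact) {
      pg <- sum(nullv >= W[v]) / nperm
      pl <- sum(nullv <= W[v]) / nperm
    } else {
      pg <- (1 + sum(nullv >= W[v])) / (nperm + 1)
      pl <- (1 + sum(nullv <= W[v])) / (nperm + 1)
    }
    min(1, 2 * min(pg, pl))
  }, 0)
  ok <- !untestable
  if (any(ok)) {
    max_w <- apply(Wnull[, ok, drop = FALSE], 1L, max, na.rm = TRUE)
    min_w <- apply(Wnull[, ok, drop = FALSE], 1L, min, na.rm = TRUE)
    thr_hi <- stats::quantile(max_w, 0.95, names = FALSE)
    thr_lo <- stats::quantile(min_w, 0.05, names = FALSE)
  } else {
    thr_hi <- NA_real_; thr_lo <- NA_real_
  }
  list(W = W, p = p,
       fwe_threshold_high = thr_hi, fwe_threshold_low = thr_lo,
       mask_low_gt_high = ok & is.finite(W) & !is.na(thr_hi) & W >= thr_hi,
       mask_high_gt_low = ok & is.finite(W) & !is.na(thr_lo) & W <= thr_lo,
       untestable = untestable, exact = exact)
}
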