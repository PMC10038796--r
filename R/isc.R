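#' Pearson correlation of two time series
#'
#' The elementary ISC operation: the product-moment correlation of two
#' equal-length series. Unlike [stats::cor()] it refuses zero-variance input
#' with an error naming the offending series, the failure mode that marks a
#' voxel invalid further up the stack.
#'
#' @param x,y numeric vectors of equal length (at least 3), finite values.
#' @return the correlation coefficient, in `[-1, 1]`.
#' @export
pairwise_r <- function(x, y) {
  if (length(x) != length(y)) .stopf("series lengths differ: %d vs %d", length(x), length(y))
  if (length(x) < 3L) .stopf("need at least 3 timepoints, got %d", length(x))
  if (!all(is.finite(x)) || !all(is.finite(y))) .stopf("series contain non-finite values")
  x <- x - mean(x); y <- y - mean(y)
  sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
  if (sx == 0) .stopf("undefined correlation: first series has zero variance")
  if (sy == 0) .stopf("undefined correlation: second series has zero variance")
  max(-1, min(1, sum(x * y) / (sx * sy)))
}

## Pair-by-voxel correlation matrix from unit-norm subject representations.
## `zb = NULL` gives all unordered within-group pairs; otherwise all cross
## pairs (one subject from each group).
.pair_r_matrix <- function(za, zb = NULL) {
  nv <- nrow(za[[1L]])
  if (is.null(zb)) {
    idx <- utils::combn(length(za), 2L)
    out <- matrix(NA_real_, ncol(idx), nv)
    for (k in seq_len(ncol(idx)))
      out[k, ] <- rowSums(za[[idx[1L, k]]] * za[[idx[2L, k]]])
  } else {
    out <- matrix(NA_real_, length(za) * length(zb), nv)
    k <- 0L
    for (j in seq_along(zb)) for (i in seq_along(za)) {
      k <- k + 1L
      out[k, ] <- rowSums(za[[i]] * zb[[j]])
    }
  }
  out
}

## Fold a pair x voxel correlation matrix into an isc_map.
.isc_map_from_pairs <- function(pair_r, keep_pairs = FALSE) {
  n_pairs <- nrow(pair_r)
  valid <- colSums(!is.finite(pair_r)) == 0L
  mean_r <- colMeans(pair_r)
  mean_r[!valid] <- NA_real_
  if (n_pairs > 1L) {
    sd_r <- apply(pair_r, 2L, stats::sd)
    t_stat <- mean_r / (sd_r / sqrt(n_pairs))
  } else {
    t_stat <- rep(NA_real_, ncol(pair_r))
  }
  t_stat[!valid] <- NA_real_
  out <- structure(list(mean_r = mean_r, t_stat = t_stat, n_pairs = n_pairs,
                        valid = valid, p = NULL, fwe_threshold = NULL,
                        significant_mask = NULL),
                   class = "isc_map")
  if (keep_pairs) out$pair_r <- pair_r
  out
}

#' Within-condition intersubject correlation map
#'
#' Per voxel, the mean Pearson correlation over all N(N-1)/2 unordered
#' subject pairs, computed on run-concatenated series after per-run mean
#' removal, together with the pair t-statistic (mean r divided by the
#' standard error of the pair correlations). Voxels where any pair
#' correlation is undefined (zero variance) are marked invalid (`NA`).
#'
#' @param group a [bold_group()] with at least 3 subjects.
#' @param keep_pairs retain the full pair x voxel correlation matrix in the
#'   result (needed by region-level group comparisons).
#' @return an `isc_map` with `mean_r`, `t_stat`, `n_pairs`, `valid`;
#'   significance fields are unset until permutation inference is run.
#' @export
isc_within <- function(group, keep_pairs = FALSE) {
  if (n_subjects(group) < 3L)
    .stopf("within-condition ISC needs at least 3 subjects, got %d", n_subjects(group))
  map <- .isc_map_from_pairs(.pair_r_matrix(.prep_group(group)), keep_pairs)
  map$geometry <- group$geometry
  map
}

#' Across-condition intersubject correlation map
#'
#' ISC restricted to cross pairs: every subject of one condition paired with
#' every subject of the other (N_A x N_B pairs, no within-condition pairs),
#' measuring stimulus-locked synchronization that survives a change of
#' sensory modality. Symmetric in its two arguments.
#'
#' @param group_a,group_b [bold_group()]s with equal voxel and timepoint
#'   counts and equal TR.
#' @inheritParams isc_within
#' @return an `isc_map`; see [isc_within()].
#' @export
isc_across <- function(group_a, group_b, keep_pairs = FALSE) {
  if (n_voxels(group_a) != n_voxels(group_b) ||
      n_timepoints(group_a) != n_timepoints(group_b))
    .stopf("group shapes differ: %d x %d vs %d x %d (voxels x timepoints)",
           n_voxels(group_a), n_timepoints(group_a),
           n_voxels(group_b), n_timepoints(group_b))
  if (group_a$tr_seconds != group_b$tr_seconds)
    .stopf("TR differs between groups: %g vs %g", group_a$tr_seconds, group_b$tr_seconds)
  map <- .isc_map_from_pairs(
    .pair_r_matrix(.prep_group(group_a), .prep_group(group_b)), keep_pairs)
  map$geometry <- group_a$geometry
  map
}

#' @export
print.isc_map <- function(x, ...) {
  cat(sprintf("<isc_map> %d voxels, %d pairs; mean r range [%.3f, %.3f]\n",
              length(x$mean_r), x$n_pairs,
              min(x$mean_r, na.rm = TRUE), max(x$mean_r, na.rm = TRUE)))
  if (!is.null(x$fwe_threshold))
    cat(sprintf("  FWE threshold %.3f; %d voxels significant\n",
                x$fwe_threshold, sum(x$significant_mask)))
  invisible(x)
}

#' Conjunction of thresholded ISC maps
#'
#' Voxelwise logical AND of the significance masks of independently
#' thresholded maps, identifying voxels significant in every contributing
#' analysis.
#'
#' @param maps a list of `isc_map`s sharing a voxel grid, each with
#'   `significant_mask` set.
#' @return a logical per-voxel mask.
#' @export
conjunction <- function(maps) {
  if (!length(maps)) .stopf("need at least one map")
  masks <- lapply(maps, function(m) {
    if (is.null(m$significant_mask))
      .stopf("every map must carry a significance mask; run threshold_map() first")
    m$significant_mask
  })
  nv <- vapply(masks, length, 1L)
  if (any(nv != nv[1L])) .stopf("maps disagree on voxel count: %s", paste(nv, collapse = "/"))
  Reduce(`&`, masks)
}

#' Region-of-interest pair correlation matrix
#'
#' Averages the series over a voxel mask for every subject of every supplied
#' group, then fills the full symmetric subject x subject correlation matrix
#' (unit diagonal). Each pair is flagged significant when its one-tailed
#' surrogate p-value falls below `pair_threshold_p`, mirroring matrix
#' figures in which non-significant pairings are blanked.
#'
#' @param groups a list of [bold_group()]s with a common voxel grid and TR.
#' @param roi_mask logical or integer voxel index, non-empty.
#' @param pair_threshold_p per-pair one-tailed significance level.
#' @param spec a [surrogate_spec()] controlling the per-pair null.
#' @return a list with `r` (subject x subject matrix), `p`, `significant`
#'   and the per-subject labels.
#' @export
roi_pair_matrix <- function(groups, roi_mask, pair_threshold_p = 0.05,
                            spec = surrogate_spec(n_permutations = 200)) {
  if (inherits(groups, "bold_group")) groups <- list(groups)
  if (is.logical(roi_mask)) roi_mask <- which(roi_mask)
  if (!length(roi_mask)) .stopf("ROI mask is empty")
  run_lengths <- groups[[1L]]$run_lengths
  series <- list(); labels <- character(0)
  for (g in groups) {
    pg <- lapply(g$data, function(m)
      colMeans(m[roi_mask, , drop = FALSE]))
    series <- c(series, pg)
    labels <- c(labels, paste(g$condition, g$subject_ids, sep = ":"))
  }
  n <- length(series)
  prep <- function(x) {
    z <- .row_unitize(.demean_runs(matrix(x, nrow = 1L), run_lengths))
    as.numeric(z)
  }
  zs <- lapply(series, prep)
  r <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    r[i, j] <- r[j, i] <- sum(zs[[i]] * zs[[j]])
  ## per-pair null: correlations of independently chunk-shuffled surrogates
  nperm <- spec$n_permutations
  null_r <- array(NA_real_, c(nperm, n, n))
  .with_seed(spec$seed, {
    for (k in seq_len(nperm)) {
      zsur <- lapply(series, function(x)
        prep(surrogate_series(x, run_lengths, spec)))
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        null_r[k, i, j] <- sum(zsur[[i]] * zsur[[j]])
    }
  })
  p <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    p[i, j] <- p[j, i] <- (1 + sum(null_r[, i, j] >= r[i, j])) / (nperm + 1)
  dimnames(r) <- dimnames(p) <- list(labels, labels)
  list(r = r, p = p, significant = !is.na(p) & p < pair_threshold_p,
       labels = labels)
}

#' Spherical region of interest from a centre coordinate
#'
#' Selects the voxels whose world-space centres lie within `radius_mm` of a
#' given coordinate, using the affine of the mask geometry.
#'
#' @param geometry a geometry list (as carried by [bold_group()]s read from
#'   NIfTI) with `dim`, `mask_idx` and `affine` (4 x 4 voxel-to-world).
#' @param centre_mm length-3 world coordinate of the sphere centre.
#' @param radius_mm sphere radius in millimetres (default 6).
#' @return integer indices into the group's voxel dimension.
#' @export
roi_sphere <- function(geometry, centre_mm, radius_mm = 6) {
  if (is.null(geometry$affine)) .stopf("geometry carries no affine")
  ijk <- arrayInd(geometry$mask_idx, geometry$dim) - 1L  # 0-based voxel coords
  xyz <- t(geometry$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
  d2 <- rowSums(sweep(xyz, 2L, centre_mm)^2)
  which(d2 <= radius_mm^2)
}

#' Region-level comparison of pair ISC between two groups
#'
#' Two-sided Wilcoxon rank-sum test on the per-pair ISC values of two
#' analyses (e.g. typically-developed vs sensory-deprived across-condition
#' pairs within one region), with Bonferroni correction over the number of
#' regions examined. The reported `W` is the sum of (mid)ranks of the first
#' sample in the pooled ranking.
#'
#' @param pair_r_a,pair_r_b numeric vectors of per-pair ISC values.
#' @param n_regions number of regions across which to Bonferroni-correct.
#' @param region optional region label carried through to the result.
#' @return a `group_comparison` list: `region`, `W`, `p_raw`, `p_bonferroni`,
#'   `n_pairs_a`, `n_pairs_b`, `mean_diff_r`, `se_diff`.
#' @export
compare_groups <- function(pair_r_a, pair_r_b, n_regions = 1L,
                           region = NA_character_) {
  if (!length(pair_r_a) || !length(pair_r_b)) .stopf("both samples must be non-empty")
  if (!.is_count(n_regions)) .stopf("`n_regions` must be a positive integer")
  ranks <- rank(c(pair_r_a, pair_r_b))
  W <- sum(ranks[seq_along(pair_r_a)])
  p_raw <- stats::wilcox.test(pair_r_a, pair_r_b, alternative = "two.sided",
                              exact = FALSE, correct = TRUE)$p.value
  se <- sqrt(stats::var(pair_r_a) / length(pair_r_a) +
             stats::var(pair_r_b) / length(pair_r_b))
  structure(list(region = region, W = W, p_raw = p_raw,
                 p_bonferroni = min(1, p_raw * n_regions),
                 n_pairs_a = length(pair_r_a), n_pairs_b = length(pair_r_b),
                 mean_diff_r = mean(pair_r_a) - mean(pair_r_b),
                 se_diff = se),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: W = %.0f, p_bonf = %.3g, r diff = %.3f (SE %.3f), n = %d/%d\n",
              x$region, x$W, x$p_bonferroni, x$mean_diff_r, x$se_diff,
              x$n_pairs_a, x$n_pairs_b))
  invisible(x)
}
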