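#' Rectangular sliding-window average
#'
#' Moving average of consecutive timepoints with stride one and full
#' windows only: the output has `length(ts) - width_tr + 1` points. This is
#' the temporal filter behind the temporal-receptive-window (TRW) analysis.
#'
#' @param ts numeric series.
#' @param width_tr window width in timepoints, between 1 and the series
#'   length.
#' @return the averaged series.
#' @export
window_average <- function(ts, width_tr) {
  if (!.is_count(width_tr)) .stopf("`width_tr` must be a positive integer")
  if (width_tr > length(ts))
    .stopf("window of %d timepoints exceeds series length %d", width_tr, length(ts))
  as.numeric(.row_movavg(matrix(ts, nrow = 1L), as.integer(width_tr)))
}

## mean pair correlation of smoothed, per-run-demeaned groups at one width
.isc_at_width <- function(dm_a, dm_b, w) {
  za <- lapply(dm_a, function(m) .row_unitize(.row_movavg(m, w)))
  zb <- if (is.null(dm_b)) NULL else lapply(dm_b, function(m) .row_unitize(.row_movavg(m, w)))
  colMeans(.pair_r_matrix(za, zb))
}

#' Temporal-receptive-window profile
#'
#' Computes ISC (within one group, or across two) after smoothing every
#' subject's series with rectangular sliding windows of increasing width,
#' and extracts per voxel the width of maximal synchronization — the TRW.
#' The row at the smallest width (one TR) is exactly the classical ISC map.
#'
#' @param group_a a [bold_group()].
#' @param group_b optional second group for across-condition profiles.
#' @param widths_s window widths in seconds, each a multiple of the TR
#'   (default 2 to 240 s in steps of 2 s, clipped to the series length).
#' @return a `trw_profile`: `widths_s`, `isc_by_width` (width x voxel),
#'   `peak_width_s`, significance fields unset.
#' @export
trw_profile <- function(group_a, group_b = NULL,
                        widths_s = seq(2, 240, by = 2)) {
  tr <- group_a$tr_seconds
  if (!is.null(group_b)) {
    if (n_voxels(group_a) != n_voxels(group_b) ||
        n_timepoints(group_a) != n_timepoints(group_b) ||
        group_a$tr_seconds != group_b$tr_seconds)
      .stopf("groups must share shape and TR")
  }
  wtr <- widths_s / tr
  if (any(abs(wtr - round(wtr)) > 1e-8))
    .stopf("every width must be a multiple of the TR (%g s)", tr)
  wtr <- as.integer(round(wtr))
  nt <- n_timepoints(group_a)
  usable <- nt - wtr + 1L >= 3L
  if (!all(usable)) {
    .warnf("skipping %d width(s) leaving fewer than 3 smoothed timepoints",
           sum(!usable))
    widths_s <- widths_s[usable]; wtr <- wtr[usable]
  }
  dm_a <- lapply(group_a$data, .demean_runs, run_lengths = group_a$run_lengths)
  dm_b <- if (is.null(group_b)) NULL
          else lapply(group_b$data, .demean_runs, run_lengths = group_b$run_lengths)
  prof <- matrix(NA_real_, length(wtr), n_voxels(group_a))
  for (i in seq_along(wtr))
    prof[i, ] <- .isc_at_width(dm_a, dm_b, wtr[i])
  out <- structure(list(widths_s = widths_s, isc_by_width = prof,
                        peak_width_s = NULL, p = NULL,
                        fwe_threshold = NULL, significant_mask = NULL,
                        tr_seconds = tr, geometry = group_a$geometry),
                   class = "trw_profile")
  out$peak_width_s <- trw_peak(out)
  out
}

#' Peak-width (chronotopic) map of a TRW profile
#'
#' Per voxel, the window width at which ISC is maximal; ties break toward
#' the smallest width (the most conservative temporal-integration claim).
#' Voxels whose whole profile is non-finite come back `NA`.
#'
#' @param profile a `trw_profile` with `isc_by_width` filled.
#' @return a per-voxel numeric vector of peak widths in seconds.
#' @export
trw_peak <- function(profile) {
  apply(profile$isc_by_width, 2L, function(col) {
    if (!any(is.finite(col))) return(NA_real_)
    col[!is.finite(col)] <- -Inf
    profile$widths_s[which.max(col)]
  })
}

#' @export
print.trw_profile <- function(x, ...) {
  cat(sprintf("<trw_profile> %d widths (%g-%g s) x %d voxels; median peak %g s\n",
              length(x$widths_s), min(x$widths_s), max(x$widths_s),
              ncol(x$isc_by_width), stats::median(x$peak_width_s, na.rm = TRUE)))
  invisible(x)
}

#' Voxel-tuned permutation significance of TRW peaks
#'
#' For each permutation every subject is surrogated and, for every voxel,
#' ISC is re-evaluated at that voxel's *observed* peak width (its specific
#' temporal tuning). One-tailed tail-approximated p-values, max-statistic
#' FWE threshold and cluster filtering as elsewhere.
#'
#' @param profile a `trw_profile`.
#' @param group_a,group_b the groups the profile came from.
#' @param spec a [surrogate_spec()].
#' @param alpha familywise error level.
#' @param min_cluster,connectivity cluster-extent settings.
#' @return the profile with `p`, `fwe_threshold`, `significant_mask` set.
#' @export
trw_significance <- function(profile, group_a, group_b = NULL,
                             spec = surrogate_spec(), alpha = 0.05,
                             min_cluster = 20L, connectivity = 18L) {
  tr <- profile$tr_seconds
  peak_tr <- as.integer(round(profile$peak_width_s / tr))
  widths <- sort(unique(peak_tr[is.finite(peak_tr)]))
  obs <- vapply(seq_along(peak_tr), function(v) {
    i <- match(peak_tr[v] * tr, profile$widths_s)
    if (is.na(i)) NA_real_ else profile$isc_by_width[i, v]
  }, 0)
  nperm <- spec$n_permutations
  nv <- length(peak_tr)
  null_m <- matrix(NA_real_, nperm, nv)
  .with_seed(spec$seed, {
    for (k in seq_len(nperm)) {
      sa <- surrogate_group(group_a, spec)
      sb <- if (is.null(group_b)) NULL else surrogate_group(group_b, spec)
      dm_a <- lapply(sa$data, .demean_runs, run_lengths = group_a$run_lengths)
      dm_b <- if (is.null(sb)) NULL
              else lapply(sb$data, .demean_runs, run_lengths = group_b$run_lengths)
      for (w in widths) {
        vox <- which(peak_tr == w)
        r_all <- .isc_at_width(lapply(dm_a, function(m) m[vox, , drop = FALSE]),
                               if (is.null(dm_b)) NULL
                               else lapply(dm_b, function(m) m[vox, , drop = FALSE]),
                               w)
        null_m[k, vox] <- r_all
      }
    }
  })
  profile$p <- .p_from_null(obs, null_m)
  profile$fwe_threshold <- fwe_threshold(apply(null_m, 1L, max, na.rm = TRUE), alpha)
  supra <- is.finite(obs) & obs >= profile$fwe_threshold
  if (!is.null(profile$geometry) && min_cluster > 1L) {
    o <- obs; o[!supra] <- -Inf
    profile$significant_mask <- cluster_filter(o, profile$fwe_threshold,
                                               min_size = min_cluster,
                                               connectivity = connectivity,
                                               geometry = profile$geometry)
  } else {
    profile$significant_mask <- supra
  }
  profile
}

#' Null TRW peak maps from surrogate data
#'
#' Recomputes the full TRW profile and its peak map on surrogate copies of
#' the groups, yielding null chronotopic maps with the spatial smoothness of
#' the originals — the reference set for [map_similarity()] (the study uses
#' 200 of them).
#'
#' @inheritParams trw_significance
#' @param widths_s widths passed to [trw_profile()].
#' @param n_maps number of null maps.
#' @return an `n_maps` x voxel matrix of peak widths (seconds).
#' @export
trw_null_maps <- function(group_a, group_b = NULL,
                          widths_s = seq(2, 240, by = 2), n_maps = 200L,
                          spec = surrogate_spec()) {
  out <- matrix(NA_real_, n_maps, n_voxels(group_a))
  .with_seed(spec$seed, {
    for (k in seq_len(n_maps)) {
      sa <- surrogate_group(group_a, spec)
      sb <- if (is.null(group_b)) NULL else surrogate_group(group_b, spec)
      out[k, ] <- suppressWarnings(trw_profile(sa, sb, widths_s))$peak_width_s
    }
  })
  out
}

#' Spatial similarity of two chronotopic maps
#'
#' Spearman rank correlation of two peak-width maps over a voxel mask, with
#' a two-sided p-value against null maps built from surrogate data:
#' `p = (1 + #[|rho_null| >= |rho|]) / (n_null + 1)`.
#'
#' @param map_a,map_b per-voxel peak-width vectors.
#' @param mask logical or integer voxel subset (at least 10 voxels).
#' @param null_maps_a matrix of null peak maps for the first condition
#'   (rows = maps), e.g. from [trw_null_maps()].
#' @return a `map_similarity`: `rho`, `p`, `n_null_maps`, `voxel_mask`.
#' @export
map_similarity <- function(map_a, map_b, mask, null_maps_a) {
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) < 10L) .stopf("need at least 10 masked voxels, got %d", length(mask))
  if (is.null(dim(null_maps_a)) || nrow(null_maps_a) < 1L)
    .stopf("need at least one null map")
  a <- map_a[mask]; b <- map_b[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    .stopf("constant map within mask: ranks undefined")
  rho <- stats::cor(a, b, method = "spearman")
  rho_null <- apply(null_maps_a[, mask, drop = FALSE], 1L, function(nm) {
    if (stats::sd(nm) == 0) return(0)
    stats::cor(nm, b, method = "spearman")
  })
  p <- (1 + sum(abs(rho_null) >= abs(rho))) / (length(rho_null) + 1)
  structure(list(rho = rho, p = p, n_null_maps = nrow(null_maps_a),
                 voxel_mask = mask),
            class = "map_similarity")
}

#' @export
print.map_similarity <- function(x, ...) {
  cat(sprintf("<map_similarity> rho = %.3f, p = %.4g (%d null maps, %d voxels)\n",
              x$rho, x$p, x$n_null_maps, length(x$voxel_mask)))
  invisible(x)
}

#' TRW synchronization-profile matrix plot
#'
#' Image of the width x voxel ISC matrix with voxels ordered by peak width
#' and each voxel's profile scaled to a maximum of one — the standard way of
#' displaying a chronotopic gradient.
#'
#' @param profile a `trw_profile`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the voxel ordering used.
#' @export
plot_trw_matrix <- function(profile, ...) {
  ord <- order(profile$peak_width_s)
  m <- profile$isc_by_width[, ord, drop = FALSE]
  mx <- apply(m, 2L, max, na.rm = TRUE)
  mx[mx <= 0 | !is.finite(mx)] <- 1
  m <- sweep(m, 2L, mx, `/`)
  graphics::image(x = profile$widths_s, y = seq_len(ncol(m)), z = m,
                  xlab = "window width (s)", ylab = "voxel (sorted by peak)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(ord)
}
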