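#' Familywise-error threshold from a max-statistic null
#'
#' The empirical `(1 - alpha)` quantile (linear interpolation) of the
#' per-permutation maximum statistic over voxels: thresholding the observed
#' map at this value controls the probability of any false-positive voxel
#' at level `alpha`.
#'
#' @param null a [null_distribution()] (or a numeric vector of max
#'   statistics).
#' @param alpha familywise error level in (0, 1).
#' @return the threshold (scalar).
#' @export
fwe_threshold <- function(null, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    .stopf("`alpha` must lie strictly between 0 and 1")
  mx <- if (inherits(null, "null_distribution")) null$max_stat else null
  stats::quantile(mx, 1 - alpha, names = FALSE, type = 7)
}

## Neighbourhood offsets for 6 (face), 18 (face+edge) or 26 (face+edge+
## corner) connectivity on a 3-D grid.
.conn_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    .stopf("unknown connectivity %s; use 6, 18 or 26", connectivity)
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  d <- rowSums(abs(g))
  keep <- d > 0 & d <= switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  g[keep, , drop = FALSE]
}

## Label connected components of a logical 3-D array by breadth-first
## search. Returns an integer array (0 = background).
.label_components <- function(mask_arr, connectivity = 18L) {
  dm <- dim(mask_arr)
  off <- .conn_offsets(connectivity)
  labels <- array(0L, dm)
  lab <- 0L
  todo <- which(mask_arr)
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- arrayInd(queue, dm)
      queue <- integer(0)
      for (o in seq_len(nrow(off))) {
        nb <- cur + matrix(off[o, ], nrow(cur), 3L, byrow = TRUE)
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
              nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
              nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
        if (!any(ok)) next
        lin <- nb[ok, 1L] + dm[1L] * (nb[ok, 2L] - 1L) + dm[1L] * dm[2L] * (nb[ok, 3L] - 1L)
        new <- lin[mask_arr[lin] & labels[lin] == 0L]
        if (length(new)) {
          labels[new] <- lab
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  labels
}

#' Cluster-extent filtering of a thresholded statistic volume
#'
#' Groups supra-threshold voxels into connected components on the 3-D grid
#' and removes components smaller than `min_size` voxels (the study
#' convention is a minimum cluster size of 20), returning the surviving
#' voxel mask.
#'
#' @param stat per-voxel statistic: either a 3-D array, or a vector
#'   accompanied by `geometry` (a list with `dim` and `mask_idx` as carried
#'   by [bold_group()]).
#' @param threshold voxels with `stat >= threshold` enter clustering.
#' @param min_size minimum surviving component size in voxels.
#' @param connectivity 6, 18 (default) or 26.
#' @param geometry grid geometry when `stat` is a vector.
#' @return a logical mask of the same form as `stat` (array in, array out;
#'   vector in, vector out).
#' @export
cluster_filter <- function(stat, threshold, min_size = 20L, connectivity = 18L,
                           geometry = NULL) {
  vec_in <- is.null(dim(stat)) || length(dim(stat)) != 3L
  if (vec_in) {
    if (is.null(geometry))
      .stopf("vector input needs `geometry` (grid dim + mask indices)")
    arr <- array(FALSE, geometry$dim)
    supra_vec <- is.finite(stat) & stat >= threshold
    arr[geometry$mask_idx] <- supra_vec
  } else {
    arr <- is.finite(stat) & stat >= threshold
  }
  labels <- .label_components(arr, connectivity)
  sizes <- tabulate(labels)
  keep <- labels > 0L & sizes[pmax(labels, 1L)] >= min_size
  if (vec_in) as.vector(keep[geometry$mask_idx]) else keep
}

#' Threshold an ISC map with FWE control and cluster filtering
#'
#' Fills the inference fields of an `isc_map`: per-voxel tail-approximated
#' permutation p-values, the max-statistic FWE threshold at `alpha`, and the
#' significance mask after cluster-extent filtering (when the map carries
#' volumetric geometry).
#'
#' @param map an `isc_map` from [isc_within()] or [isc_across()].
#' @param null a [null_distribution()] of the same statistic on the same
#'   voxels.
#' @param alpha familywise error level.
#' @param min_cluster minimum cluster extent in voxels (applied only when
#'   geometry is available).
#' @param connectivity cluster connectivity (6/18/26).
#' @param statistic which observed field the null refers to: `"t"` or
#'   `"mean_r"`.
#' @return the map with `p`, `fwe_threshold`, `significant_mask` set.
#' @export
threshold_map <- function(map, null, alpha = 0.05, min_cluster = 20L,
                          connectivity = 18L, statistic = c("t", "mean_r")) {
  statistic <- match.arg(statistic)
  obs <- if (statistic == "t") map$t_stat else map$mean_r
  map$p <- .p_from_null(obs, null$per_voxel_stats)
  map$fwe_threshold <- fwe_threshold(null, alpha)
  supra <- is.finite(obs) & obs >= map$fwe_threshold
  if (!is.null(map$geometry) && min_cluster > 1L) {
    obs_cl <- obs
    obs_cl[!supra] <- -Inf
    map$significant_mask <- cluster_filter(obs_cl, map$fwe_threshold,
                                           min_size = min_cluster,
                                           connectivity = connectivity,
                                           geometry = map$geometry)
  } else {
    map$significant_mask <- supra
  }
  map
}
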