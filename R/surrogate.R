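#' Surrogate-generation settings
#'
#' Parameters of the chunk-shuffling surrogate scheme used by every
#' permutation test in the package: each run is spliced into
#' `chunks_per_run` contiguous chunks, the chunks of all runs are pooled and
#' globally re-arranged, and each chunk is independently time-reversed with
#' probability 1/2. With the study's 6 runs and the default 3 chunks per run
#' this is the 18-chunk scheme; surrogates preserve each series' value
#' multiset (hence mean and variance) exactly while destroying
#' stimulus-locked temporal alignment.
#'
#' @param chunks_per_run chunks each run is spliced into (default 3).
#' @param allow_time_reversal reverse chunks with probability 1/2 (default
#'   `TRUE`).
#' @param n_permutations number of surrogate datasets drawn (default 1000).
#' @param seed integer seed making the whole permutation schedule
#'   reproducible; `NULL` uses the current RNG stream.
#' @return a `surrogate_spec` list.
#' @export
surrogate_spec <- function(chunks_per_run = 3L, allow_time_reversal = TRUE,
                           n_permutations = 1000L, seed = NULL) {
  if (!.is_count(chunks_per_run)) .stopf("`chunks_per_run` must be a positive integer")
  if (!.is_count(n_permutations)) .stopf("`n_permutations` must be a positive integer")
  structure(list(chunks_per_run = as.integer(chunks_per_run),
                 allow_time_reversal = isTRUE(allow_time_reversal),
                 n_permutations = as.integer(n_permutations),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "surrogate_spec")
}

## Chunk boundaries: each run contributes `chunks_per_run` contiguous chunks,
## remainder timepoints going to the run's last chunk.
.chunk_bounds <- function(run_lengths, chunks_per_run) {
  starts <- integer(0); lens <- integer(0)
  at <- 0L
  for (L in run_lengths) {
    if (L < chunks_per_run)
      .stopf("run of length %d is shorter than %d chunks", L, chunks_per_run)
    base <- L %/% chunks_per_run
    l <- rep(base, chunks_per_run)
    l[chunks_per_run] <- L - base * (chunks_per_run - 1L)
    starts <- c(starts, at + cumsum(c(0L, l[-chunks_per_run])) + 1L)
    lens <- c(lens, l)
    at <- at + L
  }
  list(start = starts, len = lens)
}

#' Chunk-shuffled surrogate of one time series
#'
#' Draws one surrogate under the scheme described in [surrogate_spec()],
#' using the current RNG stream (seed externally for reproducibility).
#'
#' @param ts numeric series.
#' @param run_lengths per-run timepoint counts summing to `length(ts)`.
#' @param spec a [surrogate_spec()].
#' @return a series of the same length with the same value multiset.
#' @export
surrogate_series <- function(ts, run_lengths, spec = surrogate_spec()) {
  if (sum(run_lengths) != length(ts))
    .stopf("run lengths sum to %d but series has %d points", sum(run_lengths), length(ts))
  b <- .chunk_bounds(run_lengths, spec$chunks_per_run)
  nc <- length(b$start)
  ord <- sample.int(nc)
  rev_bit <- spec$allow_time_reversal & (stats::runif(nc) < 0.5)
  idx <- sequence(b$len[ord],
                  from = ifelse(rev_bit, b$start[ord] + b$len[ord] - 1L, b$start[ord]),
                  by = ifelse(rev_bit, -1L, 1L))
  ts[idx]
}

## Independent surrogate of every row of a voxel x time matrix, drawn with a
## single vectorized pass: per row a random chunk order and reversal
## pattern, assembled via one sequence() call.
.surrogate_matrix <- function(mat, bounds, allow_reversal) {
  nv <- nrow(mat); nt <- ncol(mat); nc <- length(bounds$start)
  ordflat <- order(rep(seq_len(nv), each = nc), stats::runif(nv * nc))
  chunk_seq <- ordflat - rep((seq_len(nv) - 1L) * nc, each = nc)
  rev_bit <- if (allow_reversal) stats::runif(nv * nc) < 0.5 else rep(FALSE, nv * nc)
  lens <- bounds$len[chunk_seq]
  from <- ifelse(rev_bit, bounds$start[chunk_seq] + lens - 1L, bounds$start[chunk_seq])
  col_idx <- sequence(lens, from = from, by = ifelse(rev_bit, -1L, 1L))
  matrix(mat[cbind(rep(seq_len(nv), each = nt), col_idx)],
         nrow = nv, byrow = TRUE)
}

#' Surrogate copy of a whole group
#'
#' Replaces every voxel series of every subject by an independent
#' chunk-shuffled surrogate (uses the current RNG stream).
#'
#' @param group a [bold_group()].
#' @param spec a [surrogate_spec()].
#' @return a `bold_group` of identical shape.
#' @export
surrogate_group <- function(group, spec = surrogate_spec()) {
  bounds <- .chunk_bounds(group$run_lengths, spec$chunks_per_run)
  group$data <- lapply(group$data, .surrogate_matrix, bounds = bounds,
                       allow_reversal = spec$allow_time_reversal)
  group
}

#' Permutation null distribution of a voxelwise statistic
#'
#' Repeatedly replaces every subject's every voxel series by an independent
#' surrogate, re-evaluates the statistic, and records both the per-voxel
#' null values and the per-permutation maximum over voxels (the basis of
#' familywise-error control).
#'
#' @param stat_fn function mapping a list of [bold_group()]s to a per-voxel
#'   numeric statistic (e.g. [isc_stat_across()]).
#' @param groups a list of [bold_group()]s passed to `stat_fn`.
#' @param spec a [surrogate_spec()]; its `seed` fixes the whole schedule.
#' @return a `null_distribution`: `per_voxel_stats` (permutation x voxel
#'   matrix), `max_stat`, `spec`.
#' @export
null_distribution <- function(stat_fn, groups, spec = surrogate_spec()) {
  if (inherits(groups, "bold_group")) groups <- list(groups)
  nperm <- spec$n_permutations
  .with_seed(spec$seed, {
    first <- TRUE
    stats_m <- NULL
    for (k in seq_len(nperm)) {
      sur <- lapply(groups, surrogate_group, spec = spec)
      s <- tryCatch(stat_fn(sur),
                    error = function(e) .stopf("stat_fn failed at permutation %d: %s",
                                               k, conditionMessage(e)))
      if (first) { stats_m <- matrix(NA_real_, nperm, length(s)); first <- FALSE }
      stats_m[k, ] <- s
    }
    structure(list(per_voxel_stats = stats_m,
                   max_stat = apply(stats_m, 1L, max, na.rm = TRUE),
                   spec = spec),
              class = "null_distribution")
  })
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d permutations x %d voxels; max-stat 95th pct %.3f\n",
              nrow(x$per_voxel_stats), ncol(x$per_voxel_stats),
              stats::quantile(x$max_stat, 0.95)))
  invisible(x)
}

#' Built-in voxelwise statistics for permutation nulls
#'
#' `isc_stat_across` returns the across-condition pair t-statistic for a
#' list of two groups; `isc_stat_within` the within-condition one for a
#' single group; `isc_stat_mean_r` the plain mean pair correlation.
#'
#' @param groups a list of [bold_group()]s (two for across, one for within).
#' @return a per-voxel numeric vector.
#' @export
isc_stat_across <- function(groups) isc_across(groups[[1L]], groups[[2L]])$t_stat

#' @rdname isc_stat_across
#' @export
isc_stat_within <- function(groups) isc_within(groups[[1L]])$t_stat

#' @rdname isc_stat_across
#' @export
isc_stat_mean_r <- function(groups) {
  if (length(groups) == 1L) isc_within(groups[[1L]])$mean_r
  else isc_across(groups[[1L]], groups[[2L]])$mean_r
}
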