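## Internal helpers shared across modules.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards. `seed = NULL` uses the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

## Remove the per-run mean from every row of a voxel x time matrix.
.demean_runs <- function(mat, run_lengths) {
  stopifnot(sum(run_lengths) == ncol(mat))
  at <- 0L
  for (len in run_lengths) {
    idx <- at + seq_len(len)
    mat[, idx] <- mat[, idx] - rowMeans(mat[, idx, drop = FALSE])
    at <- at + len
  }
  mat
}

## Centre each row and scale it to unit Euclidean norm, so that the Pearson
## correlation of two rows is the plain dot product. Rows with zero variance
## come back as NaN (propagated downstream as invalid voxels).
.row_unitize <- function(mat) {
  mat <- mat - rowMeans(mat)
  nrm <- sqrt(rowSums(mat^2))
  nrm[nrm == 0] <- NaN
  mat / nrm
}

## Moving average over `w` consecutive columns, full windows only:
## output has ncol(mat) - w + 1 columns.
.row_movavg <- function(mat, w) {
  if (w == 1L) return(mat)
  n <- ncol(mat)
  cs <- mat
  for (j in 2:n) cs[, j] <- cs[, j] + cs[, j - 1L]  # row-wise cumulative sum
  out <- cs[, w:n, drop = FALSE]
  if (w < n) out[, -1L] <- out[, -1L] - cs[, 1:(n - w), drop = FALSE]
  out / w
}

## Smallest grid box holding n voxels, used when a dataset has no volumetric
## geometry of its own.
.default_grid <- function(n) {
  k <- ceiling(n^(1 / 3))
  d2 <- ceiling(n / k^2)
  c(k, k, max(d2, 1L))
}
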