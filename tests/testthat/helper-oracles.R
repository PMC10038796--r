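## Independent brute-force reference implementations used as oracles.
## These deliberately avoid the package's vectorized code paths.

## per-run demeaning, one voxel series, loop form
oracle_demean <- function(x, run_lengths) {
  out <- numeric(0)
  at <- 0
  for (L in run_lengths) {
    seg <- x[(at + 1):(at + L)]
    out <- c(out, seg - mean(seg))
    at <- at + L
  }
  out
}

## naive within-group ISC: double loop over subject pairs, stats::cor
oracle_isc_within <- function(group) {
  n <- length(group$data)
  nv <- nrow(group$data[[1]])
  mean_r <- t_stat <- numeric(nv)
  n_pairs <- n * (n - 1) / 2
  for (v in seq_len(nv)) {
    rs <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      xi <- oracle_demean(group$data[[i]][v, ], group$run_lengths)
      xj <- oracle_demean(group$data[[j]][v, ], group$run_lengths)
      rs <- c(rs, stats::cor(xi, xj))
    }
    mean_r[v] <- mean(rs)
    t_stat[v] <- mean(rs) / (stats::sd(rs) / sqrt(n_pairs))
  }
  list(mean_r = mean_r, t_stat = t_stat, n_pairs = n_pairs)
}

## naive across-group ISC
oracle_isc_across <- function(ga, gb) {
  na <- length(ga$data); nb <- length(gb$data)
  nv <- nrow(ga$data[[1]])
  mean_r <- numeric(nv)
  for (v in seq_len(nv)) {
    rs <- c()
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      xi <- oracle_demean(ga$data[[i]][v, ], ga$run_lengths)
      xj <- oracle_demean(gb$data[[j]][v, ], gb$run_lengths)
      rs <- c(rs, stats::cor(xi, xj))
    }
    mean_r[v] <- mean(rs)
  }
  mean_r
}

## every surrogate reachable from one run split into 3 chunks of a length-6
## series: all chunk orders x all reversal patterns
oracle_surrogate_set <- function(ts) {
  stopifnot(length(ts) == 6)
  chunks <- list(ts[1:2], ts[3:4], ts[5:6])
  orders <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  out <- list()
  for (o in orders) for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
    bs <- c(b1, b2, b3)
    parts <- lapply(seq_len(3), function(k) {
      ch <- chunks[[o[k]]]
      if (bs[k]) rev(ch) else ch
    })
    out[[length(out) + 1]] <- unlist(parts)
  }
  unique(lapply(out, as.numeric))
}

## connected-component labelling by iterative label propagation to a
## fixpoint (very different from the package's BFS)
oracle_label <- function(arr, connectivity) {
  dm <- dim(arr)
  lab <- array(0, dm)
  lab[arr] <- seq_len(sum(arr))
  reach <- function(d) sum(abs(d)) > 0 &&
    sum(abs(d)) <= switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  repeat {
    changed <- FALSE
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
      if (!arr[i, j, k]) next
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (!reach(c(di, dj, dk))) next
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] || kk < 1 || kk > dm[3]) next
        if (arr[ii, jj, kk] && lab[ii, jj, kk] < lab[i, j, k]) {
          lab[i, j, k] <- lab[ii, jj, kk]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

## exact two-sided sign-flip p of the signed-rank W, by full enumeration
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  Ws <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    dd <- d * ifelse(bits == 1, -1, 1)
    Ws[m + 1] <- sum(rank(abs(dd))[dd > 0])
  }
  pg <- mean(Ws >= W_obs)
  pl <- mean(Ws <= W_obs)
  min(1, 2 * min(pg, pl))
}

## tiny random group builder used across test files
make_group <- function(n_sub, n_vox, n_tp, run_lengths = n_tp, seed = 1,
                       tr = 2) {
  set.seed(seed)
  data <- lapply(seq_len(n_sub), function(s)
    matrix(rnorm(n_vox * n_tp), n_vox, n_tp))
  bold_group(data, tr, run_lengths)
}
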