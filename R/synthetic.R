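#' Simulation settings for synthetic multi-subject BOLD data
#'
#' Describes a two-group synthetic dataset emulating the statistical
#' structure of a naturalistic-stimulus ISC study: groups of ~10 subjects,
#' voxelwise series of ~1600 timepoints at TR = 2 s split into 6 runs,
#' condition-shared latent signals band-limited at known timescales, optional
#' stimulus-feature-driven components, and autocorrelated subject noise. The
#' defaults mirror those study conditions; tests typically pass smaller
#' explicit values.
#'
#' @param n_subjects_per_group subjects in each of the two groups.
#' @param n_voxels number of voxels.
#' @param n_timepoints timepoints per subject (default 1614).
#' @param tr_seconds repetition time (default 2).
#' @param run_lengths per-run timepoint counts summing to `n_timepoints`
#'   (default 6 equal runs).
#' @param voxel_timescale_s per-voxel timescale in seconds: 0 means no
#'   shared latent; positive values (at least `tr_seconds`) plant a
#'   band-limited latent whose ISC-versus-window profile peaks at that
#'   width. A scalar is recycled. `NULL` assigns timescales
#'   10/20/40/60/120 s to the first 40% of voxels and 0 elsewhere.
#' @param shared_amplitude amplitude of the shared latent relative to the
#'   unit-variance noise innovations (default 1).
#' @param model_amplitude amplitude of the stimulus-feature-driven component
#'   (default 0; requires feature designs at generation time).
#' @param noise_ar1 lag-one autoregressive coefficient of the subject noise
#'   in `[0, 1)` (default 0.3, a typical BOLD autocorrelation).
#' @param seed integer seed; the generated dataset is a pure function of the
#'   spec including this seed.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_subjects_per_group = 10L, n_voxels = 125L,
                     n_timepoints = 1614L, tr_seconds = 2,
                     run_lengths = NULL, voxel_timescale_s = NULL,
                     shared_amplitude = 1, model_amplitude = 0,
                     noise_ar1 = 0.3, seed = 1L) {
  if (is.null(run_lengths)) {
    nr <- 6L
    base <- n_timepoints %/% nr
    run_lengths <- rep(base, nr)
    run_lengths[nr] <- n_timepoints - base * (nr - 1L)
  }
  run_lengths <- as.integer(run_lengths)
  if (sum(run_lengths) != n_timepoints)
    .stopf("run_lengths sum to %d, expected n_timepoints = %d",
           sum(run_lengths), n_timepoints)
  if (is.null(voxel_timescale_s)) {
    voxel_timescale_s <- rep(0, n_voxels)
    ns <- floor(0.4 * n_voxels)
    if (ns > 0)
      voxel_timescale_s[seq_len(ns)] <- rep(c(10, 20, 40, 60, 120), length.out = ns)
  }
  if (length(voxel_timescale_s) == 1L)
    voxel_timescale_s <- rep(voxel_timescale_s, n_voxels)
  if (length(voxel_timescale_s) != n_voxels)
    .stopf("voxel_timescale_s must have length 1 or n_voxels")
  bad <- voxel_timescale_s != 0 & voxel_timescale_s < tr_seconds
  if (any(bad))
    .stopf("timescales must be 0 or >= TR (%g s); offenders: %s", tr_seconds,
           paste(utils::head(unique(voxel_timescale_s[bad])), collapse = ", "))
  if (noise_ar1 < 0 || noise_ar1 >= 1) .stopf("noise_ar1 must lie in [0, 1)")
  if (shared_amplitude < 0 || model_amplitude < 0)
    .stopf("amplitudes must be non-negative")
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_voxels = as.integer(n_voxels),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, run_lengths = run_lengths,
                 voxel_timescale_s = voxel_timescale_s,
                 shared_amplitude = shared_amplitude,
                 model_amplitude = model_amplitude,
                 noise_ar1 = noise_ar1, seed = as.integer(seed)),
            class = "sim_spec")
}

## --- timescale -> latent period calibration ------------------------------
##
## The planted latent is a random-phase sinusoid. Its period is chosen so
## that the EXPECTED ISC-versus-window profile peaks at the declared
## timescale, accounting for (i) the discrete moving-average gain on a
## sinusoid, (ii) the autocovariance of AR(1) noise after smoothing, and
## (iii) the finite-sample downward bias of the sample variance of smoothed
## noise when the window approaches the series length.

## Mean sample variance (per window width) of the moving-averaged series,
## mirroring the analysis pipeline exactly: per-run mean removal, then a
## full-window moving average, then variance about the smoothed mean.
.smoothed_sample_var <- function(mat, run_lengths, l_grid) {
  mat <- .demean_runs(mat, run_lengths)
  vapply(l_grid, function(L) {
    sm <- .row_movavg(mat, L)
    mean(apply(sm, 1L, stats::var))
  }, 0)
}

## Expected noise variance curve: small fixed-seed Monte-Carlo over the
## generator's own run-structured AR(1) noise (deterministic, cached).
.noise_var_curve <- function(run_lengths, ar1, l_grid, nsim = 200L) {
  .with_seed(771L, {
    noise <- .ar1_noise_matrix(nsim, run_lengths, ar1)
    .smoothed_sample_var(noise, run_lengths, l_grid)
  })
}

## Per-phase signal variance curves (phase x width) for a standardized
## sinusoid of period P.
.signal_var_curves <- function(period_s, n_timepoints, tr_seconds, run_lengths,
                               l_grid, n_phase = 16L) {
  tt <- (seq_len(n_timepoints) - 1L) * tr_seconds
  ph <- (seq_len(n_phase) - 1L) / n_phase * 2 * pi
  sig <- t(vapply(ph, function(p) .standardize(cos(2 * pi * tt / period_s + p)),
                  numeric(n_timepoints)))
  sig <- .demean_runs(sig, run_lengths)
  out <- matrix(NA_real_, n_phase, length(l_grid))
  for (i in seq_along(l_grid)) {
    sm <- .row_movavg(sig, l_grid[i])
    out[, i] <- apply(sm, 1L, stats::var)
  }
  out
}

.timescale_cache <- new.env(parent = emptyenv())

## Invert the expected ISC-versus-window profile: find the latent period P
## such that rho(L) = a^2 * signal_var(L; P) / noise_var(L) peaks at the
## declared timescale. The profile is computed on the same smoothing and
## demeaning pipeline the TRW analysis uses, so run structure and
## finite-sample effects are accounted for.
.timescale_period <- function(w_s, n_timepoints, tr_seconds, run_lengths, ar1) {
  key <- paste(w_s, n_timepoints, tr_seconds, paste(run_lengths, collapse = ","),
               ar1, sep = "|")
  hit <- .timescale_cache[[key]]
  if (!is.null(hit)) return(hit)
  l_max <- max(min(n_timepoints - 3L, max(120L, ceiling(2.5 * w_s / tr_seconds))), 2L)
  l_grid <- seq_len(l_max)
  nv_key <- paste("noise", paste(run_lengths, collapse = ","), ar1, l_max, sep = "|")
  noise_var <- .timescale_cache[[nv_key]]
  if (is.null(noise_var)) {
    noise_var <- .noise_var_curve(run_lengths, ar1, l_grid)
    .timescale_cache[[nv_key]] <- noise_var
  }
  ## the realized latent of a voxel has a single phase, so the calibration
  ## target is the median over phases of the per-phase profile argmax
  peak_for <- function(P) {
    sv <- .signal_var_curves(P, n_timepoints, tr_seconds, run_lengths, l_grid)
    peaks <- apply(sweep(sv, 2L, noise_var, `/`), 1L, which.max)
    stats::median(l_grid[peaks]) * tr_seconds
  }
  ## peak width grows with the period: bisect on P
  lo <- w_s / 0.30; hi <- w_s / 0.55
  if (peak_for(hi) > w_s) {
    period <- hi
  } else if (peak_for(lo) < w_s) {
    period <- lo
  } else {
    for (it in seq_len(18L)) {
      mid <- (lo + hi) / 2
      if (peak_for(mid) > w_s) lo <- mid else hi <- mid
      if (lo - hi < tr_seconds / 4) break
    }
    period <- (lo + hi) / 2
  }
  .timescale_cache[[key]] <- period
  period
}

## AR(1) noise with unit innovation variance, re-initialized (stationary
## start) at each run boundary. Returns a voxel x timepoint matrix; the
## recursion runs columnwise so all voxels advance together.
.ar1_noise_matrix <- function(n_voxels, run_lengths, phi) {
  nt <- sum(run_lengths)
  out <- matrix(0, n_voxels, nt)
  at <- 0L
  for (L in run_lengths) {
    e <- matrix(stats::rnorm(n_voxels * L), n_voxels, L)
    e[, 1L] <- e[, 1L] / sqrt(1 - phi^2)
    if (phi != 0 && L > 1L)
      for (t in 2:L) e[, t] <- phi * e[, t - 1L] + e[, t]
    out[, at + seq_len(L)] <- e
    at <- at + L
  }
  out
}

.standardize <- function(x) (x - mean(x)) / stats::sd(x)

#' Generate two synthetic BOLD groups with known ground truth
#'
#' Builds a pair of subject groups emulating an across-condition ISC setting:
#' voxels with a positive timescale receive one latent series embedded in
#' every subject of both groups with weight `shared_amplitude`; feature
#' designs, when supplied with a positive `model_amplitude`, add a
#' stimulus-driven component with per-voxel weights; each subject gets
#' independent AR(1) noise with unit innovation variance (re-initialized per
#' run). Series are emitted already "preprocessed": per-run mean removed.
#'
#' The latent of a voxel with declared timescale `w` is a random-phase
#' sinusoid whose period is calibrated (see the methods vignette) so that
#' the expected ISC-versus-window profile of the temporal-receptive-window
#' analysis peaks at width `w`.
#'
#' @param spec a [sim_spec()].
#' @param designs optional stimulus drive: a numeric timepoint x feature
#'   matrix on the TR grid, or a list of [feature_model()]s (resampled to
#'   the TR grid; editing-level models are ignored as drivers).
#' @return a list with `group_a`, `group_b` ([bold_group()]s of identical
#'   shape) and `truth` (a `ground_truth`: `shared_voxel_mask`,
#'   `voxel_timescale_s`, `model_weights`, `latents`, `grid_dim`).
#' @export
generate_bold_groups <- function(spec, designs = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  nv <- spec$n_voxels; nt <- spec$n_timepoints; tr <- spec$tr_seconds
  D <- NULL
  if (!is.null(designs) && spec$model_amplitude > 0) {
    D <- .designs_to_matrix(designs, nt, tr)
    if (nrow(D) != nt)
      .stopf("design has %d rows but the scan has %d timepoints", nrow(D), nt)
  }
  .with_seed(spec$seed, {
    tt <- (seq_len(nt) - 1L) * tr
    latents <- matrix(0, nv, nt)
    w <- spec$voxel_timescale_s
    for (v in which(w > 0)) {
      P <- .timescale_period(w[v], nt, tr, spec$run_lengths, spec$noise_ar1)
      latents[v, ] <- .standardize(cos(2 * pi * tt / P + stats::runif(1, 0, 2 * pi)))
    }
    model_weights <- matrix(0, nv, if (is.null(D)) 0L else ncol(D))
    model_comp <- matrix(0, nv, nt)
    if (!is.null(D)) {
      Ds <- scale(D)
      for (v in seq_len(nv)) {
        beta <- stats::rnorm(ncol(D)) / sqrt(ncol(D))
        comp <- as.numeric(Ds %*% beta)
        s <- stats::sd(comp)
        if (s > 0) {
          model_weights[v, ] <- beta / s
          model_comp[v, ] <- comp / s
        }
      }
    }
    shared <- spec$shared_amplitude * latents +
              spec$model_amplitude * model_comp
    make_group <- function(condition, population) {
      data <- lapply(seq_len(spec$n_subjects_per_group), function(s) {
        noise <- .ar1_noise_matrix(nv, spec$run_lengths, spec$noise_ar1)
        .demean_runs(shared + noise, spec$run_lengths)
      })
      bold_group(data, tr, spec$run_lengths,
                 condition = condition, population = population,
                 geometry = list(dim = .default_grid(nv),
                                 mask_idx = seq_len(nv)))
    }
    group_a <- make_group("A", "sim")
    group_b <- make_group("V", "sim")
    truth <- structure(list(
      shared_voxel_mask = w > 0 | rowSums(abs(model_weights)) > 0,
      voxel_timescale_s = w,
      model_weights = model_weights,
      latents = latents,
      grid_dim = .default_grid(nv)),
      class = "ground_truth")
    list(group_a = group_a, group_b = group_b, truth = truth)
  })
}

## Coerce a design argument (matrix or list of feature models) to one
## timepoint x feature matrix on the TR grid.
.designs_to_matrix <- function(designs, n_timepoints, tr_seconds) {
  if (is.matrix(designs)) return(designs)
  if (inherits(designs, "feature_model")) designs <- list(designs)
  mats <- lapply(designs, function(fm) {
    if (!inherits(fm, "feature_model")) .stopf("designs must be feature models or a matrix")
    if (identical(fm$level, "editing")) return(NULL)
    grid <- (seq_len(n_timepoints) - 0.5) * tr_seconds
    resample_model(fm, grid)$matrix
  })
  mats <- Filter(Negate(is.null), mats)
  if (!length(mats)) .stopf("no non-editing feature models supplied")
  do.call(cbind, mats)
}

#' Generate synthetic stimulus feature models
#'
#' Builds a hierarchy of feature models on the scan's TR grid with a known
#' collinearity structure: `editing` columns are independent boxcar trains
#' (scene cuts, dialogue on/off and the like); every low- and high-level
#' column is a mixture `collinearity * (standardized editing blend) +
#' sqrt(1 - collinearity^2) * unique smooth component`, so the squared
#' multiple correlation of a model column on the editing set is
#' `collinearity^2` in expectation. All columns are standardized.
#'
#' @param spec a [sim_spec()] (supplies grid, TR and the seed offset).
#' @param n_low columns in each of the two low-level models (auditory,
#'   visual).
#' @param n_high columns in the high-level semantic model.
#' @param n_editing editing descriptor columns.
#' @param collinearity in `[0, 1)`: correlation of model columns with their
#'   editing blend.
#' @return a list of [feature_model()]s: `low_auditory`, `low_visual`,
#'   `high_semantic`, `editing`.
#' @export
generate_feature_models <- function(spec, n_low = 3L, n_high = 3L,
                                    n_editing = 3L, collinearity = 0.3) {
  stopifnot(inherits(spec, "sim_spec"))
  if (collinearity < 0 || collinearity >= 1)
    .stopf("collinearity must lie in [0, 1)")
  if (n_low < 1L || n_high < 1L || n_editing < 1L)
    .stopf("feature counts must be at least 1")
  nt <- spec$n_timepoints; tr <- spec$tr_seconds
  .with_seed(spec$seed + 1L, {
    times <- (seq_len(nt) - 0.5) * tr
    boxcar <- function() {
      x <- numeric(nt)
      t_at <- 0
      while (t_at < nt * tr) {
        gap <- stats::rexp(1, rate = 1 / 30)       # mean 30 s between events
        dur <- stats::runif(1, 4, 20)              # 4-20 s events
        on <- times >= t_at + gap & times < t_at + gap + dur
        x[on] <- 1
        t_at <- t_at + gap + dur
      }
      if (stats::sd(x) == 0) x[seq_len(max(2, nt %/% 10))] <- 1
      .standardize(x)
    }
    smooth_unique <- function() {
      w <- max(1L, round(10 / tr))                 # ~10 s lowpass
      x <- as.numeric(.row_movavg(matrix(stats::rnorm(nt + w - 1L), 1L), w))
      .standardize(x)
    }
    editing <- vapply(seq_len(n_editing), function(i) boxcar(), numeric(nt))
    model_cols <- function(k) {
      vapply(seq_len(k), function(i) {
        wts <- stats::rnorm(n_editing)
        blend <- .standardize(as.numeric(editing %*% wts))
        .standardize(collinearity * blend +
                     sqrt(1 - collinearity^2) * smooth_unique())
      }, numeric(nt))
    }
    fm <- function(name, level, m) feature_model(name, level, times, m, 1 / tr)
    list(low_auditory = fm("low_auditory", "low_auditory", model_cols(n_low)),
         low_visual = fm("low_visual", "low_visual", model_cols(n_low)),
         high_semantic = fm("high_semantic", "high_semantic", model_cols(n_high)),
         editing = fm("editing", "editing", editing))
  })
}

#' Generate a pair of stimulus descriptor streams with planted coherent events
#'
#' Two independent noise streams that share, inside each event interval, a
#' common band-limited oscillation at the event's period — the ground truth
#' for wavelet-coherence event recovery.
#'
#' @param duration_s total stream duration in seconds.
#' @param fs_hz sampling rate (the study's movie descriptors run at 25 Hz).
#' @param events a data frame (or list of 3-vectors) with columns
#'   `onset_s`, `duration_s`, `period_s`; events must fit in the stream and
#'   respect the Nyquist limit `period_s >= 2/fs_hz`.
#' @param seed integer seed.
#' @param noise_sd standard deviation of the independent noise (default 1).
#' @param event_amplitude amplitude of the common oscillation (default 1;
#'   within a wavelet band this is far above the in-band noise floor, so
#'   in-event coherence is high while limiting temporal bleed of the
#'   detected event beyond its true interval).
#' @return a list with `stream_a`, `stream_b` ([descriptor_stream()]s) and
#'   `events` (the ground-truth table).
#' @export
generate_stimulus_streams <- function(duration_s, fs_hz = 25, events,
                                      seed = 1L, noise_sd = 1,
                                      event_amplitude = 1) {
  if (is.list(events) && !is.data.frame(events))
    events <- as.data.frame(do.call(rbind, lapply(events, function(e)
      stats::setNames(as.list(e), c("onset_s", "duration_s", "period_s")))))
  if (is.null(events)) events <- data.frame(onset_s = numeric(0),
                                            duration_s = numeric(0),
                                            period_s = numeric(0))
  n <- round(duration_s * fs_hz)
  tt <- (seq_len(n) - 1L) / fs_hz
  if (nrow(events)) {
    if (any(events$period_s < 2 / fs_hz))
      .stopf("event periods below the Nyquist limit 2/fs = %g s", 2 / fs_hz)
    if (any(events$onset_s < 0 | events$onset_s + events$duration_s > duration_s))
      .stopf("events must lie within [0, %g] s", duration_s)
  }
  .with_seed(seed, {
    a <- stats::rnorm(n, sd = noise_sd)
    b <- stats::rnorm(n, sd = noise_sd)
    for (e in seq_len(nrow(events))) {
      on <- tt >= events$onset_s[e] & tt < events$onset_s[e] + events$duration_s[e]
      osc <- event_amplitude *
        sin(2 * pi * tt[on] / events$period_s[e] + stats::runif(1, 0, 2 * pi))
      a[on] <- a[on] + osc
      b[on] <- b[on] + osc
    }
    list(stream_a = descriptor_stream(a, fs_hz, "stream_a"),
         stream_b = descriptor_stream(b, fs_hz, "stream_b"),
         events = events)
  })
}
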