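#' Stimulus descriptor stream
#'
#' A single stimulus descriptor sampled at a fixed rate (the study's movie
#' descriptors run at 25 Hz, the frame rate).
#'
#' @param values finite numeric sequence.
#' @param fs_hz sampling rate in Hz.
#' @param name label.
#' @return a `descriptor_stream`.
#' @export
descriptor_stream <- function(values, fs_hz, name = "stream") {
  if (!is.numeric(fs_hz) || fs_hz <= 0) .stopf("`fs_hz` must be positive")
  if (!all(is.finite(values))) .stopf("stream '%s' contains non-finite values", name)
  if (length(values) < 2) .stopf("stream '%s' is too short", name)
  structure(list(fs_hz = fs_hz, values = as.numeric(values), name = name),
            class = "descriptor_stream")
}

#' @export
print.descriptor_stream <- function(x, ...) {
  cat(sprintf("<descriptor_stream> '%s': %d samples @ %g Hz (%.1f s)\n",
              x$name, length(x$values), x$fs_hz, length(x$values) / x$fs_hz))
  invisible(x)
}

#' Default period grid for wavelet analysis
#'
#' Log-spaced periods, 12 voices per octave, from `4/fs` to a quarter of
#' the stream duration.
#'
#' @param stream a [descriptor_stream()].
#' @param voices_per_octave grid density (default 12).
#' @return increasing periods in seconds.
#' @export
default_periods <- function(stream, voices_per_octave = 12L) {
  pmin <- 4 / stream$fs_hz
  pmax <- length(stream$values) / stream$fs_hz / 4
  n_oct <- log2(pmax / pmin)
  pmin * 2^(seq(0, n_oct, by = 1 / voices_per_octave))
}

## Morlet scale for a given Fourier period (omega0 = 6 by default):
## period = scale * 4*pi / (omega0 + sqrt(2 + omega0^2)).
.morlet_scale <- function(period_s, omega0) {
  period_s * (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
}

#' Continuous Morlet wavelet transform
#'
#' Analytic Morlet transform (centre frequency `omega0 = 6`) of a stream at
#' the requested Fourier periods, computed in the frequency domain with
#' zero padding to the next power of two.
#'
#' @param stream a [descriptor_stream()].
#' @param periods_s requested Fourier periods, each at least the Nyquist
#'   period `2/fs` and at most half the stream duration.
#' @param omega0 Morlet centre frequency (default 6).
#' @return a period x time complex coefficient matrix with attributes
#'   `periods_s`, `times_s`, `scales_s`.
#' @export
cwt_morlet <- function(stream, periods_s = default_periods(stream), omega0 = 6) {
  x <- stream$values
  n <- length(x); dt <- 1 / stream$fs_hz
  dur <- n * dt
  bad <- periods_s < 2 * dt - 1e-12 | periods_s > dur / 2 + 1e-12
  if (any(bad))
    .stopf("periods out of range [2/fs, duration/2] = [%g, %g] s: %s",
           2 * dt, dur / 2, paste(signif(periods_s[bad], 4), collapse = ", "))
  npad <- 2^ceiling(log2(n))
  xf <- stats::fft(c(x - mean(x), rep(0, npad - n)))
  omega <- 2 * pi * c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) / (npad * dt)
  scales <- .morlet_scale(periods_s, omega0)
  W <- matrix(NA_complex_, length(periods_s), n)
  for (i in seq_along(scales)) {
    s <- scales[i]
    psi <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
      exp(-((s * omega - omega0)^2) / 2) * (omega > 0)
    w <- stats::fft(xf * psi, inverse = TRUE) / npad
    W[i, ] <- w[seq_len(n)]
  }
  structure(W, periods_s = periods_s, times_s = (seq_len(n) - 1L) * dt,
            scales_s = scales)
}

## Gaussian smoothing in time with width proportional to scale, applied
## rowwise in the frequency domain.
.smooth_time <- function(M, scales_s, dt) {
  n <- ncol(M)
  npad <- 2^ceiling(log2(n))
  omega <- 2 * pi * c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) / (npad * dt)
  out <- M
  for (i in seq_len(nrow(M))) {
    filt <- exp(-0.5 * (scales_s[i] * omega)^2)
    row <- c(M[i, ], rep(0, npad - n))
    sm <- stats::fft(stats::fft(row) * filt, inverse = TRUE) / npad
    out[i, ] <- sm[seq_len(n)]
  }
  out
}

## Boxcar smoothing across scales spanning `octaves` (default 0.6).
.smooth_scale <- function(M, periods_s, octaves = 0.6) {
  dv <- mean(diff(log2(periods_s)))
  half <- max(0L, floor(octaves / dv / 2))
  if (half == 0L) return(M)
  np <- nrow(M)
  out <- M
  for (i in seq_len(np)) {
    lo <- max(1L, i - half); hi <- min(np, i + half)
    out[i, ] <- colMeans(M[lo:hi, , drop = FALSE])
  }
  out
}

#' Wavelet coherence of two descriptor streams
#'
#' Magnitude-squared coherence in the time-period plane: the smoothed
#' cross-spectrum of the two Morlet transforms normalized by the product of
#' the smoothed auto-spectra. Smoothing is Gaussian in time with width
#' equal to the scale and a 0.6-octave boxcar across scales. The cone of
#' influence marks cells closer to a series edge than the e-folding
#' distance `sqrt(2) * scale`.
#'
#' @param a,b [descriptor_stream()]s with equal rate and length.
#' @param periods_s analysis periods (default: both streams' default grid).
#' @param omega0 Morlet centre frequency.
#' @return a `coherence_result`: `periods_s`, `times_s`, `coherence`
#'   (period x time, in `[0, 1]`), `cone_of_influence` (`TRUE` = edge
#'   contaminated), `events` unset.
#' @export
wavelet_coherence <- function(a, b, periods_s = default_periods(a), omega0 = 6) {
  if (a$fs_hz != b$fs_hz) .stopf("streams have different rates: %g vs %g Hz", a$fs_hz, b$fs_hz)
  if (length(a$values) != length(b$values))
    .stopf("stream lengths differ: %d vs %d", length(a$values), length(b$values))
  dt <- 1 / a$fs_hz
  Wa <- cwt_morlet(a, periods_s, omega0)
  Wb <- cwt_morlet(b, periods_s, omega0)
  scales <- attr(Wa, "scales_s")
  sinv <- 1 / scales
  Sab <- .smooth_scale(.smooth_time(sinv * (Wa * Conj(Wb)), scales, dt), periods_s)
  Saa <- Re(.smooth_scale(.smooth_time(sinv * (abs(Wa)^2), scales, dt), periods_s))
  Sbb <- Re(.smooth_scale(.smooth_time(sinv * (abs(Wb)^2), scales, dt), periods_s))
  coh <- abs(Sab)^2 / (Saa * Sbb)
  coh <- pmin(pmax(Re(coh), 0), 1)
  times <- attr(Wa, "times_s")
  dur <- length(a$values) * dt
  edge_dist <- pmin(times, dur - dt - times)
  coi <- outer(sqrt(2) * scales, edge_dist, `>`)
  structure(list(periods_s = periods_s, times_s = times, coherence = coh,
                 cone_of_influence = coi, event_mask = NULL, events = NULL,
                 fs_hz = a$fs_hz),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> %d periods (%.2f-%.1f s) x %d timepoints; mean coherence %.2f\n",
              length(x$periods_s), min(x$periods_s), max(x$periods_s),
              length(x$times_s), mean(x$coherence[!x$cone_of_influence])))
  if (!is.null(x$events))
    cat(sprintf("  %d coherent event(s)\n", nrow(x$events)))
  invisible(x)
}

#' Segment highly coherent events
#'
#' Thresholds the coherence plane outside the cone of influence, groups the
#' surviving cells into 8-connected components in the period x time plane,
#' and summarizes each component by onset (earliest time), duration (time
#' extent) and a coherence-weighted mean period. An oscillatory event must
#' outlast itself: components whose time extent is shorter than
#' `min_cycles` of their own period are discarded. The default of 3 cycles
#' exceeds the e-folding footprint of the combined wavelet-and-smoothing
#' kernel (about 2.7 periods), so kernel-sized noise blobs are suppressed
#' while genuine events, whose detected extent includes the same kernel
#' spread, pass.
#'
#' @param result a `coherence_result`.
#' @param threshold coherence threshold in (0, 1): either a fixed value
#'   (default 0.9) or one calibrated on surrogate pairs via
#'   [coherence_null_threshold()].
#' @param min_cells discard components smaller than this many cells
#'   (speckle suppression, default 5).
#' @param min_cycles minimum event duration in units of its period
#'   (default 3).
#' @return the result with `event_mask` and `events` (a data frame with
#'   `onset_s`, `duration_s`, `period_s`, `n_cells`, ordered by onset) set.
#' @export
coherent_events <- function(result, threshold = 0.9, min_cells = 5L,
                            min_cycles = 3) {
  if (threshold <= 0 || threshold >= 1) .stopf("`threshold` must lie in (0, 1)")
  mask <- result$coherence >= threshold & !result$cone_of_influence
  dm <- dim(mask)
  labels3 <- .label_components(array(mask, c(dm, 1L)), connectivity = 18L)
  labels <- matrix(labels3, dm[1L], dm[2L])
  n_lab <- max(labels)
  evs <- list()
  dt <- 1 / result$fs_hz
  for (l in seq_len(n_lab)) {
    cells <- which(labels == l, arr.ind = TRUE)
    if (nrow(cells) < min_cells) next
    t_on <- min(result$times_s[cells[, 2L]])
    t_off <- max(result$times_s[cells[, 2L]]) + dt
    wts <- result$coherence[cells]
    per <- sum(result$periods_s[cells[, 1L]] * wts) / sum(wts)
    if (t_off - t_on < min_cycles * per) next
    evs[[length(evs) + 1L]] <- data.frame(onset_s = t_on,
                                          duration_s = t_off - t_on,
                                          period_s = per,
                                          n_cells = nrow(cells))
  }
  events <- if (length(evs)) do.call(rbind, evs)
            else data.frame(onset_s = numeric(0), duration_s = numeric(0),
                            period_s = numeric(0), n_cells = integer(0))
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  result$event_mask <- mask
  result$events <- events
  result
}

## Phase-randomized surrogate: same amplitude spectrum, uniformly random
## phases (conjugate-symmetric), destroying any cross-stream alignment.
.phase_randomize <- function(x) {
  n <- length(x)
  xf <- stats::fft(x)
  half <- 2:ceiling(n / 2)
  ph <- stats::runif(length(half), 0, 2 * pi)
  xf[half] <- abs(xf[half]) * exp(1i * ph)
  xf[n + 2L - half] <- Conj(xf[half])
  Re(stats::fft(xf, inverse = TRUE) / n)
}

#' Surrogate-calibrated coherence threshold
#'
#' Estimates a null level of the coherence plane from phase-randomized
#' copies of both streams. The default is a pointwise cluster-forming
#' threshold — the `1 - alpha` quantile of all null coherence cells outside
#' the cone of influence, pooled across surrogate pairs — intended to be
#' combined with the extent rules of [coherent_events()] (minimum cells,
#' minimum cycles), in direct analogy to cluster-forming plus
#' cluster-extent thresholding of statistical maps. `type = "max"` instead
#' returns the `1 - alpha` quantile of the per-surrogate maximum coherence,
#' a familywise detection threshold; it is far stricter and can exceed the
#' plateau of genuine moderate-amplitude events.
#'
#' @param a,b [descriptor_stream()]s.
#' @param periods_s analysis periods.
#' @param n_surrogates surrogate pairs to draw (default 9).
#' @param alpha tail level (default 0.001 per cell for the pointwise type;
#'   use e.g. 0.05 with `type = "max"`).
#' @param type `"pointwise"` (default) or `"max"`.
#' @param seed RNG seed.
#' @return a threshold in (0, 1).
#' @export
coherence_null_threshold <- function(a, b, periods_s = default_periods(a),
                                     n_surrogates = 9L, alpha = 0.001,
                                     type = c("pointwise", "max"),
                                     seed = NULL) {
  type <- match.arg(type)
  .with_seed(seed, {
    vals <- lapply(seq_len(n_surrogates), function(k) {
      sa <- descriptor_stream(.phase_randomize(a$values), a$fs_hz, "surrogate_a")
      sb <- descriptor_stream(.phase_randomize(b$values), b$fs_hz, "surrogate_b")
      w <- wavelet_coherence(sa, sb, periods_s)
      cells <- w$coherence[!w$cone_of_influence]
      if (type == "max") max(cells) else cells
    })
    stats::quantile(unlist(vals), 1 - alpha, names = FALSE)
  })
}
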