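#' Construct a force trace
#'
#' One limb's continuous push-phase force record for one set: equally spaced
#' samples at `sampling_interval_s` (times are derived, starting at 0).
#'
#' @param subject_id,limb,set_index Identifiers (set_index 1-based).
#' @param forces_N Numeric vector of force samples (N), finite.
#' @param body_mass_kg Subject body mass (kg), positive.
#' @param sampling_interval_s Sample spacing Delta-t (s), positive.
#' @param times_s Optional explicit sample times; must be increasing and
#'   equally spaced at `sampling_interval_s` within tolerance.
#' @return A `force_trace` object.
#' @export
force_trace <- function(subject_id, limb, set_index, forces_N, body_mass_kg,
                        sampling_interval_s, times_s = NULL) {
  forces_N <- as.numeric(forces_N)
  if (!all(is.finite(forces_N))) stop_input("forces must be finite")
  if (body_mass_kg <= 0) stop_input("body_mass_kg must be positive")
  if (sampling_interval_s <= 0) stop_input("sampling_interval_s must be positive")
  if (is.null(times_s)) {
    times_s <- (seq_along(forces_N) - 1) * sampling_interval_s
  } else {
    if (length(times_s) != length(forces_N))
      stop_input("times and forces must have equal length")
    d <- diff(times_s)
    if (any(d <= 0)) stop_input("sample times must be increasing")
    if (any(abs(d - sampling_interval_s) > 1e-6 * sampling_interval_s))
      stop_input("sample times must be equally spaced at sampling_interval_s")
  }
  structure(list(subject_id = subject_id, limb = limb,
                 set_index = as.integer(set_index),
                 times_s = times_s, forces_N = forces_N,
                 body_mass_kg = body_mass_kg,
                 sampling_interval_s = sampling_interval_s),
            class = "force_trace")
}

#' Low-pass filter specification
#'
#' Defaults to the preprocessing used for load-cell bench-press signals: a
#' fourth-order Butterworth low-pass at 20 Hz on 50 Hz data, applied in zero
#' phase (forward-backward), which squares the magnitude response but leaves
#' the time-to-peak unbiased.
#'
#' @param order Filter order (analog prototype order; the zero-phase
#'   application doubles the effective order).
#' @param cutoff_hz -3 dB cutoff (single-pass), must be below Nyquist.
#' @param sampling_hz Sampling rate.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 20, sampling_hz = 50) {
  if (order < 1) stop_config("filter order must be >= 1")
  if (cutoff_hz <= 0 || cutoff_hz >= sampling_hz / 2)
    stop_config("cutoff_hz must lie in (0, sampling_hz/2); got %g with Nyquist %g",
                cutoff_hz, sampling_hz / 2)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 sampling_hz = sampling_hz),
            class = "filter_spec")
}

# polynomial coefficients (descending powers, leading 1) from roots
poly_from_roots <- function(r) {
  coefs <- 1
  for (root in r) coefs <- c(coefs, 0) - c(0, coefs * root)
  coefs
}

#' Digital Butterworth low-pass coefficients
#'
#' Bilinear transform of the analog Butterworth prototype with frequency
#' prewarping, so the digital magnitude response is exactly the analog
#' response evaluated at `tan(pi f / fs) / tan(pi fc / fs)`:
#' `|H(f)|^2 = 1 / (1 + (tan(pi f/fs)/tan(pi fc/fs))^(2 order))`.
#'
#' @param spec A [filter_spec()].
#' @return List with numerator `b` and denominator `a` (a\[1\] = 1).
#' @export
butter_lowpass <- function(spec = filter_spec()) {
  n <- spec$order
  fs <- spec$sampling_hz
  k <- seq_len(n)
  # analog prototype poles on the unit circle, left half-plane
  p <- complex(modulus = 1, argument = pi * (2 * k + n - 1) / (2 * n))
  warped <- 2 * fs * tan(pi * spec$cutoff_hz / fs)
  p <- p * warped
  pz <- (2 * fs + p) / (2 * fs - p) # bilinear transform
  a <- Re(poly_from_roots(pz))
  b <- choose(n, 0:n) # n zeros at z = -1
  b <- b * sum(a) / sum(b) # unit DC gain
  list(b = b, a = a / a[1])
}

# Single-pass IIR filter using the C-level recursions in stats::filter.
# Initial conditions assume the signal sat at `init_value` forever before
# its first sample (steady state), so a constant input passes through
# exactly -- the same device as scipy's lfilter_zi.
iir_filter <- function(b, a, x, init_value = x[1]) {
  nb <- length(b)
  v <- stats::filter(c(rep(init_value, nb - 1), x), b,
                     method = "convolution", sides = 1)
  v <- as.numeric(v)[(nb - 1) + seq_along(x)]
  if (length(a) > 1) {
    y0 <- init_value * sum(b) / sum(a)
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive",
                                  init = rep(y0, length(a) - 1)))
  }
  v
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Filters forward, reverses, filters again, reverses. Edge transients are
#' suppressed by odd-reflection padding of one warm-up length
#' (`3 * (length(a) - 1)` samples) at each end; traces must be longer than
#' the pad.
#'
#' @param b,a Filter coefficients as from [butter_lowpass()].
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  padlen <- 3 * (max(length(a), length(b)) - 1)
  n <- length(x)
  if (n <= padlen)
    stop_input("trace has %d samples; zero-phase filtering needs more than %d",
               n, padlen)
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  y <- iir_filter(b, a, c(pre, x, post))
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Low-pass filter a force trace
#'
#' @param trace A [force_trace()].
#' @param spec A [filter_spec()].
#' @return The trace with filtered `forces_N` (same length; DC preserved).
#' @export
lowpass <- function(trace, spec = filter_spec()) {
  ba <- butter_lowpass(spec)
  trace$forces_N <- filtfilt(ba$b, ba$a, trace$forces_N)
  trace
}

#' Repetition segmentation thresholds
#'
#' Onset/offset detection is relative to the trace maximum (so it survives
#' inter-subject strength differences) with hysteresis: onset at the first
#' of `k` consecutive samples above `alpha * max`, offset at the first of
#' `k` consecutive samples below `beta * max` after the onset.
#'
#' @param alpha Onset threshold fraction of trace max (default 0.15).
#' @param beta Offset threshold fraction (default 0.10, must be < alpha).
#' @param k Consecutive samples required (default 3).
#' @param min_duration_s Segments shorter than this are discarded.
#' @return A `seg_params` object.
#' @export
seg_params <- function(alpha = 0.15, beta = 0.10, k = 3, min_duration_s = 0.3) {
  if (beta >= alpha) stop_config("offset fraction beta must be below onset alpha")
  if (k < 1) stop_config("k must be >= 1")
  structure(list(alpha = alpha, beta = beta, k = as.integer(k),
                 min_duration_s = min_duration_s),
            class = "seg_params")
}

# start indices i such that cond[i..i+k-1] are all TRUE
runs_of <- function(cond, k) {
  n <- length(cond)
  if (n < k) return(integer(0))
  cs <- cumsum(cond)
  which((cs[k:n] - c(0, cs)[1:(n - k + 1)]) == k)
}

#' Segment a trace into repetitions
#'
#' Scans the (filtered) trace with hysteresis thresholds; returns ordered,
#' disjoint half-open sample windows. An all-zero or flat-low trace yields
#' zero repetitions (not an error). Thresholds are relative to the trace
#' maximum, so segmentation is invariant to uniform force scaling.
#'
#' @param trace A [force_trace()] (filter first; see [lowpass()]).
#' @param params A [seg_params()].
#' @return data.frame with columns `rep_index`, `start_sample`, `end_sample`
#'   (1-based, half-open `[start, end)`), `t_start`; the per-repetition
#'   force windows are in attribute `"rep_forces"` (list of numeric vectors).
#' @export
segment_reps <- function(trace, params = seg_params()) {
  f <- trace$forces_N
  dt <- trace$sampling_interval_s
  M <- max(f)
  empty <- data.frame(rep_index = integer(0), start_sample = integer(0),
                      end_sample = integer(0), t_start = numeric(0))
  attr(empty, "rep_forces") <- list()
  if (M <= 0) return(empty)
  th_on <- params$alpha * M
  th_off <- params$beta * M
  k <- params$k
  on_starts <- runs_of(f > th_on, k)
  off_starts <- runs_of(f < th_off, k)
  n <- length(f)
  pos <- 1
  wins <- list()
  repeat {
    onset <- on_starts[on_starts >= pos][1]
    if (is.na(onset)) break
    offset <- off_starts[off_starts > onset][1]
    end <- if (is.na(offset)) n + 1L else offset
    if ((end - onset) * dt >= params$min_duration_s)
      wins[[length(wins) + 1]] <- c(onset, end)
    if (is.na(offset)) break
    pos <- offset + k
  }
  if (!length(wins)) return(empty)
  w <- do.call(rbind, wins)
  out <- data.frame(rep_index = seq_len(nrow(w)),
                    start_sample = as.integer(w[, 1]),
                    end_sample = as.integer(w[, 2]),
                    t_start = trace$times_s[w[, 1]])
  attr(out, "rep_forces") <- lapply(seq_len(nrow(w)),
                                    function(i) f[w[i, 1]:(w[i, 2] - 1)])
  out
}

#' Normalize force by body mass
#'
#' Allometric scaling `F / m^exponent` with the conventional exponent 0.67
#' capturing the sub-linear strength-to-size relationship; `exponent = 1`
#' gives plain per-mass normalization.
#'
#' @param force_N Force value(s), N.
#' @param body_mass_kg Body mass, kg (> 0).
#' @param exponent Allometric exponent (default 0.67).
#' @return Normalized force, elementwise `force_N / body_mass_kg^exponent`.
#' @export
normalize_force <- function(force_N, body_mass_kg, exponent = 0.67) {
  if (!is.numeric(body_mass_kg) || length(body_mass_kg) != 1 ||
      is.na(body_mass_kg) || body_mass_kg <= 0)
    stop_input("body_mass_kg must be a single positive number")
  force_N / body_mass_kg^exponent
}
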