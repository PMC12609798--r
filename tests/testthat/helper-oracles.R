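# Definition-level oracles, coded independently of the package internals
# (explicit loops, no shared helpers), used to pin the feature formulas and
# evaluation metrics.

oracle_primary <- function(f, dt) {
  n <- length(f)
  m <- sum(f) / n
  css2 <- 0; css3 <- 0; css4 <- 0
  for (x in f) {
    css2 <- css2 + (x - m)^2
    css3 <- css3 + (x - m)^3
    css4 <- css4 + (x - m)^4
  }
  sig_pop <- sqrt(css2 / n)
  peak_i <- 1
  for (i in seq_len(n)) if (f[i] > f[peak_i]) peak_i <- i
  max_step <- -Inf
  for (i in 2:n) if (f[i] - f[i - 1] > max_step) max_step <- f[i] - f[i - 1]
  c(peak_force = f[peak_i],
    mean_force = m,
    rms = sqrt(sum(f^2) / n),
    variance = css2 / (n - 1),
    sd = sqrt(css2 / (n - 1)),
    skewness = if (sig_pop > 0) (css3 / n) / sig_pop^3 else NA_real_,
    kurtosis = if (sig_pop > 0) (css4 / n) / sig_pop^4 else NA_real_,
    work = sum(f) * dt,
    ttp_s = (peak_i - 1) * dt,
    rfd = max_step / dt)
}

# Analytic squared-magnitude response of the digital Butterworth low-pass
# obtained by bilinear transform with prewarping (exact for that design).
butter_mag2 <- function(f_hz, cutoff_hz, sampling_hz, order) {
  ratio <- tan(pi * f_hz / sampling_hz) / tan(pi * cutoff_hz / sampling_hz)
  1 / (1 + ratio^(2 * order))
}

# Amplitude of the sinusoidal component at freq_hz via least squares.
sine_amplitude <- function(x, freq_hz, sampling_hz) {
  t <- (seq_along(x) - 1) / sampling_hz
  X <- cbind(1, sin(2 * pi * freq_hz * t), cos(2 * pi * freq_hz * t))
  cf <- qr.coef(qr(X), x)
  sqrt(cf[2]^2 + cf[3]^2)
}

oracle_metrics <- function(pred, true) {
  n <- length(pred)
  mt <- sum(true) / n
  ss_tot <- sum((true - mt)^2)
  ss_res <- sum((pred - true)^2)
  mp <- sum(pred) / n
  r <- sum((pred - mp) * (true - mt)) /
    sqrt(sum((pred - mp)^2) * sum((true - mt)^2))
  list(r2 = 1 - ss_res / ss_tot,
       mae = sum(abs(pred - true)) / n,
       rmse = sqrt(ss_res / n),
       pearson_r = r)
}

# A profile with every stochastic ingredient controllable; fields default
# to round numbers so closed forms are easy to state in tests.
test_profile <- function(fatigue_rate = 0.05, noise_sd_frac = 0,
                         limb_asymmetry = 0.1, rep_duration_s = 2,
                         rpe_intercept = 4, rpe_fatigue_gain = 20,
                         label_noise_sd = 0, rpe_link = "linear",
                         variability_gain = 0.05, plateau_frac = 0.8,
                         base_peak_force_N = 350, body_mass_kg = 74.4) {
  structure(list(subject_id = "T001", body_mass_kg = body_mass_kg,
                 base_peak_force_N = base_peak_force_N,
                 fatigue_rate = fatigue_rate,
                 variability_gain = variability_gain,
                 noise_sd_frac = noise_sd_frac,
                 plateau_frac = plateau_frac,
                 rpe_intercept = rpe_intercept,
                 rpe_fatigue_gain = rpe_fatigue_gain,
                 limb_asymmetry = limb_asymmetry,
                 rep_duration_s = rep_duration_s,
                 rpe_link = rpe_link, label_noise_sd = label_noise_sd,
                 gap_noise_sd = 0.5),
            class = "subject_profile")
}

make_trace <- function(forces, dt = 0.02, mass = 74.4) {
  force_trace("TS", "L", 1, forces, mass, dt)
}

PRIMARY_FEATURES_FOR_TEST <- c("peak_force", "mean_force", "rms", "variance",
                               "sd", "skewness", "kurtosis", "work", "ttp_s",
                               "rfd")

# Names of the engineered relative-change columns (for ablation).
relative_columns <- function(table) {
  grep("_(delta|ratio)_(base|prev)$|^delta_times_ratio$", names(table),
       value = TRUE)
}
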