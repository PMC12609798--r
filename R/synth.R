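#' Population-level parameters for the synthetic cohort generator
#'
#' Means and SDs of the subject-level profile fields, plus the latent
#' fatigue to RPE link. Defaults emulate the cohort this analysis targets:
#' trained adult men (body mass 74.4 +/- 11.58 kg) pressing a 7RM load on an
#' isokinetic machine for 7 sets of 8 repetitions, with per-set mechanical
#' work declining as fatigue accumulates and OMNI-RES (0-10) ratings rising
#' across sets. Fields drawn outside their physical bounds are clipped
#' (bounds documented per field).
#'
#' @param coupling `"realistic"` (default) or `"strong"`. The strong preset
#'   shrinks the between-subject SD of the RPE intercept (0.3 vs 0.8) and
#'   gain (2 vs 3) so that labels are dominated by fatigue progression; it is
#'   the stated world for the signal-recovery acceptance property.
#' @param rpe_link Latent fatigue to RPE link: `"linear"`
#'   (intercept + gain * latent), `"quadratic"` (intercept + gain *
#'   latent^2 / 0.3, endpoint-matched at latent = 0.3 but convex), or
#'   `"threshold"` (intercept + gain * 0.3 * logistic((latent - 0.15) /
#'   0.03), a steep saturating link; exertion jumps once fatigue crosses
#'   ~15% work loss). Over the fatigue range the protocol induces the
#'   quadratic link is close to linear in the extracted features; the
#'   threshold link is the genuinely nonlinear cohort.
#' @param label_noise_sd SD (RPE units) of the Gaussian noise added to the
#'   latent RPE before rounding; default 0.5 reproduces a +/-1 disagreement
#'   band without modeling psychophysics.
#' @param ... named overrides; each profile field takes `c(mean, sd)`.
#'
#' @return A list of class `population_params`.
#' @export
population_params <- function(coupling = c("realistic", "strong"),
                              rpe_link = c("linear", "quadratic", "threshold"),
                              label_noise_sd = 0.5, ...) {
  coupling <- match.arg(coupling)
  rpe_link <- match.arg(rpe_link)
  pop <- list(
    body_mass_kg      = c(74.4, 11.58), # clipped to >= 40
    base_peak_force_N = c(350, 70),     # per-limb push force, clipped >= 50
    fatigue_rate      = c(0.05, 0.02),  # fractional work decline per set, [0.005, 0.2]
    variability_gain  = c(0.05, 0.02),  # noise-SD growth per set, >= 0
    noise_sd_frac     = c(0.03, 0.01),  # force noise SD / base peak, >= 0
    plateau_frac      = c(0.80, 0.05),  # post-peak plateau level, [0.6, 0.9]
    rpe_intercept     = c(4, 0.8),      # RPE after set 1, clipped [0, 10]
    rpe_fatigue_gain  = c(20, 3),       # RPE units per unit latent fatigue, >= 0
    limb_asymmetry    = c(0.10, 0.05)   # right-limb force deficit, [0, 0.3]
  )
  if (coupling == "strong") {
    pop$rpe_intercept <- c(4, 0.3)
    pop$rpe_fatigue_gain <- c(20, 2)
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(pop))
      stop_config("unknown population parameter '%s'", nm)
    v <- dots[[nm]]
    if (!is.numeric(v) || length(v) != 2 || anyNA(v) || v[2] < 0)
      stop_config("population parameter '%s' must be c(mean, sd) with sd >= 0", nm)
    pop[[nm]] <- v
  }
  for (nm in c("body_mass_kg", "base_peak_force_N"))
    if (pop[[nm]][1] <= 0)
      stop_config("population mean of '%s' must be positive", nm)
  pop$label_noise_sd <- label_noise_sd
  pop$rpe_link <- rpe_link
  pop$gap_noise_sd <- 0.5 # N; inter-rep gap force is small positive noise
  structure(pop, class = "population_params")
}

#' Protocol configuration for a simulated session
#'
#' Mirrors the acquisition protocol: 7 sets of 8 repetitions per limb,
#' force sampled every 20 ms (50 Hz), repetitions lasting 1-4 s (isokinetic,
#' so each subject's repetition duration is constant across sets).
#'
#' @param n_sets Number of sets (>= 2; inter-set relative features need a
#'   baseline and at least one later set).
#' @param reps_per_set Repetitions per set (>= 1).
#' @param sampling_interval_s Sample spacing Delta-t in seconds.
#' @param rep_duration_s Length-2 range (s) from which each subject's fixed
#'   repetition duration is drawn.
#' @param inter_rep_gap_s Low-force gap between repetitions, seconds.
#' @param seed Integer seed for cohort generation.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(n_sets = 7, reps_per_set = 8,
                            sampling_interval_s = 0.02,
                            rep_duration_s = c(1, 4),
                            inter_rep_gap_s = 0.5, seed = 1L) {
  if (n_sets < 2) stop_config("n_sets must be >= 2 (relative features need a baseline set)")
  if (reps_per_set < 1) stop_config("reps_per_set must be >= 1")
  if (sampling_interval_s <= 0) stop_config("sampling_interval_s must be positive")
  if (length(rep_duration_s) != 2 || any(rep_duration_s <= 0) ||
      rep_duration_s[1] > rep_duration_s[2])
    stop_config("rep_duration_s must be an increasing positive range")
  structure(list(n_sets = as.integer(n_sets),
                 reps_per_set = as.integer(reps_per_set),
                 sampling_interval_s = sampling_interval_s,
                 rep_duration_s = rep_duration_s,
                 inter_rep_gap_s = inter_rep_gap_s,
                 seed = as.integer(seed)),
            class = "protocol_config")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw one subject profile from the current RNG stream.
draw_subject <- function(pop, subject_id, protocol) {
  g <- function(nm) rnorm(1, pop[[nm]][1], pop[[nm]][2])
  structure(list(
    subject_id        = subject_id,
    body_mass_kg      = max(g("body_mass_kg"), 40),
    base_peak_force_N = max(g("base_peak_force_N"), 50),
    fatigue_rate      = clip(g("fatigue_rate"), 0.005, 0.2),
    variability_gain  = max(g("variability_gain"), 0),
    noise_sd_frac     = max(g("noise_sd_frac"), 0),
    plateau_frac      = clip(g("plateau_frac"), 0.6, 0.9),
    rpe_intercept     = clip(g("rpe_intercept"), 0, 10),
    rpe_fatigue_gain  = max(g("rpe_fatigue_gain"), 0),
    limb_asymmetry    = clip(g("limb_asymmetry"), 0, 0.3),
    rep_duration_s    = runif(1, protocol$rep_duration_s[1], protocol$rep_duration_s[2]),
    rpe_link          = pop$rpe_link,
    label_noise_sd    = pop$label_noise_sd,
    gap_noise_sd      = pop$gap_noise_sd
  ), class = "subject_profile")
}

#' Generate one subject profile
#'
#' Deterministic for a given seed: the profile is drawn from the population
#' distributions after `set.seed(seed)`. Out-of-bound draws are clipped.
#'
#' @param seed Integer seed.
#' @param population A [population_params()] object.
#' @param protocol A [protocol_config()] (supplies the repetition-duration
#'   range; isokinetic movement fixes each subject's duration across sets).
#' @param subject_id Label for the subject.
#' @return A `subject_profile` list.
#' @export
generate_subject <- function(seed, population = population_params(),
                             protocol = protocol_config(),
                             subject_id = sprintf("S%03d", seed)) {
  set.seed(seed)
  draw_subject(population, subject_id, protocol)
}

# Deterministic (noise-free) single-repetition shape, unit peak.
# Fast linear rise to the peak over the first ~2% of samples, exponential
# settle onto a plateau, brief terminal drop. Peak force in the first 1-2%
# of the range of motion is the empirical signature this emulates.
rep_shape <- function(n, plateau) {
  n_rise <- max(2, ceiling(0.02 * n))
  i <- seq_len(n)
  s <- numeric(n)
  s[1:n_rise] <- (1:n_rise) / n_rise
  post <- (n_rise + 1):n
  tau <- max(0.08 * n, 1)
  s[post] <- plateau + (1 - plateau) * exp(-(post - n_rise) / tau)
  n_drop <- ceiling(0.04 * n)
  tail_idx <- (n - n_drop + 1):n
  s[tail_idx] <- s[tail_idx] * seq(1, 0.4, length.out = n_drop)
  list(shape = s, n_rise = n_rise)
}

rep_sample_count <- function(profile, protocol) {
  max(round(profile$rep_duration_s / protocol$sampling_interval_s), 10)
}

limb_amplitude <- function(profile, limb) {
  profile$base_peak_force_N * (1 - profile$limb_asymmetry * (limb == "R"))
}

#' Generate the force samples of a single repetition
#'
#' Amplitude scales as `(1 - fatigue_rate)^(set_index - 1)` so expected
#' per-repetition work follows the same geometric decay; additive Gaussian
#' noise SD grows as `1 + variability_gain * (set_index - 1)`. Consumes the
#' global RNG stream. Samples are non-negative and the maximum always falls
#' in the first 5% of the repetition: post-rise samples are capped at 97% of
#' the rise peak, so the early-peak constraint holds for any noise level.
#'
#' @param profile A `subject_profile`.
#' @param set_index,rep_index 1-based indices (`rep_index` only validates).
#' @param protocol A [protocol_config()].
#' @param limb `"L"` or `"R"` (right limb force scaled by 1 - limb_asymmetry).
#' @return Numeric vector of force samples (N) with attribute `true_work`,
#'   the noise-free work (N s) of the repetition.
#' @export
generate_rep_trace <- function(profile, set_index, rep_index,
                               protocol = protocol_config(), limb = "L") {
  if (set_index < 1 || rep_index < 1)
    stop_input("set_index and rep_index must be >= 1")
  n <- rep_sample_count(profile, protocol)
  sh <- rep_shape(n, profile$plateau_frac)
  amp0 <- limb_amplitude(profile, limb)
  amp <- amp0 * (1 - profile$fatigue_rate)^(set_index - 1)
  f <- amp * sh$shape
  noise_sd <- amp0 * profile$noise_sd_frac *
    (1 + profile$variability_gain * (set_index - 1))
  if (noise_sd > 0) f <- f + rnorm(n, 0, noise_sd)
  # enforce the early-peak construction constraint
  rise_max <- max(f[1:sh$n_rise])
  post <- (sh$n_rise + 1):n
  f[post] <- pmin(f[post], 0.97 * rise_max)
  f <- pmax(f, 0)
  attr(f, "true_work") <- amp * sum(sh$shape) * protocol$sampling_interval_s
  f
}

# latent fatigue of a set: 1 - E[work(set)] / E[work(1)]
latent_fatigue <- function(fatigue_rate, set_index) {
  1 - (1 - fatigue_rate)^(set_index - 1)
}

rpe_latent_value <- function(profile, latent) {
  g <- switch(profile$rpe_link,
    quadratic = latent^2 / 0.3,
    # steep logistic in latent fatigue: exertion stays near baseline until
    # fatigue crosses ~0.15, then rises sharply -- a feature-target map a
    # linear model cannot capture over the observed fatigue range
    threshold = 0.3 / (1 + exp(-(latent - 0.15) / 0.03)),
    latent)
  profile$rpe_intercept + profile$rpe_fatigue_gain * g
}

#' Generate a full session (both limbs, all sets) for one subject
#'
#' Each set's trace is the concatenation of its repetitions separated by
#' short low-force gaps (small positive noise, never exact zero), so the
#' segmentation stage has real work to do. RPE labels are
#' `clip(round(latent RPE + noise), 0, 10)` where the latent RPE is a
#' monotone function of the set's latent fatigue. Ground truth (repetition
#' windows, noise-free work, latent fatigue) is retained for oracle tests.
#'
#' @param profile A `subject_profile`.
#' @param protocol A [protocol_config()].
#' @return A `session_data` list: `traces` (list of `force_trace`), `labels`
#'   (data.frame subject_id, limb, set_index, rpe), `ground_truth`.
#' @export
generate_session <- function(profile, protocol = protocol_config()) {
  if (protocol$n_sets < 2)
    stop_config("n_sets must be >= 2 (relative features need a baseline set)")
  dt <- protocol$sampling_interval_s
  n_gap <- max(round(protocol$inter_rep_gap_s / dt), 2)
  traces <- list()
  gt <- list()
  labels <- NULL
  for (limb in c("L", "R")) {
    for (s in seq_len(protocol$n_sets)) {
      forces <- abs(rnorm(n_gap, 0, profile$gap_noise_sd))
      windows <- matrix(0, protocol$reps_per_set, 2)
      true_work <- numeric(protocol$reps_per_set)
      for (r in seq_len(protocol$reps_per_set)) {
        rep_f <- generate_rep_trace(profile, s, r, protocol, limb)
        windows[r, ] <- c(length(forces) + 1, length(forces) + 1 + length(rep_f))
        true_work[r] <- attr(rep_f, "true_work")
        forces <- c(forces, as.numeric(rep_f),
                    abs(rnorm(n_gap, 0, profile$gap_noise_sd)))
      }
      tr <- force_trace(subject_id = profile$subject_id, limb = limb,
                        set_index = s, forces_N = forces,
                        body_mass_kg = profile$body_mass_kg,
                        sampling_interval_s = dt)
      key <- paste(limb, s, sep = ".")
      traces[[key]] <- tr
      lat <- latent_fatigue(profile$fatigue_rate, s)
      noise <- if (profile$label_noise_sd > 0) rnorm(1, 0, profile$label_noise_sd) else 0
      rpe <- clip(round(rpe_latent_value(profile, lat) + noise), 0, 10)
      labels <- rbind(labels, data.frame(subject_id = profile$subject_id,
                                         limb = limb, set_index = s,
                                         rpe = as.integer(rpe)))
      gt[[key]] <- list(rep_windows = windows, true_rep_work = true_work,
                        true_set_work = sum(true_work),
                        latent_fatigue = lat,
                        rpe_latent = rpe_latent_value(profile, lat))
    }
  }
  structure(list(profile = profile, traces = traces, labels = labels,
                 ground_truth = gt),
            class = "session_data")
}

#' Generate a seeded synthetic cohort
#'
#' Draws `n_subjects` profiles and simulates a full session for each; both
#' limbs of a subject share one profile (the right limb's force is scaled by
#' `1 - limb_asymmetry`), which induces the within-subject limb correlation
#' that subject-grouped cross-validation exists to guard against.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param protocol A [protocol_config()] (its `seed` drives everything).
#' @param population A [population_params()].
#' @return A `repforce_cohort`: `sessions` (list of `session_data`) and
#'   `manifest` (seed and all generator parameters).
#' @export
generate_cohort <- function(n_subjects, protocol = protocol_config(),
                            population = population_params()) {
  if (n_subjects < 2) stop_config("n_subjects must be >= 2")
  set.seed(protocol$seed)
  sessions <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    prof <- draw_subject(population, sprintf("S%03d", i), protocol)
    sessions[[i]] <- generate_session(prof, protocol)
  }
  names(sessions) <- vapply(sessions, function(s) s$profile$subject_id, "")
  manifest <- list(generator = "repforce-synth", version = "0.1.0",
                   seed = protocol$seed, n_subjects = n_subjects,
                   protocol = unclass(protocol),
                   population = unclass(population))
  structure(list(sessions = sessions, manifest = manifest),
            class = "repforce_cohort")
}

#' Flatten a cohort's traces into one list
#' @param cohort A `repforce_cohort`.
#' @return List of `force_trace` objects.
#' @export
cohort_traces <- function(cohort) {
  unlist(lapply(cohort$sessions, function(s) s$traces), recursive = FALSE,
         use.names = FALSE)
}

#' Collect a cohort's RPE labels
#' @param cohort A `repforce_cohort`.
#' @return data.frame with subject_id, limb, set_index, rpe.
#' @export
cohort_labels <- function(cohort) {
  do.call(rbind, c(lapply(cohort$sessions, function(s) s$labels),
                   make.row.names = FALSE))
}

#' Export a cohort as plain-text files
#'
#' Writes `samples.csv` (subject_id, limb, set_index, rep_index, time_s,
#' force_N; rep_index is the ground-truth repetition, NA in inter-rep gaps),
#' `labels.csv`, `subjects.csv` (body mass and profile summary) and
#' `manifest.json`. Output is byte-identical for the same seed.
#'
#' @param cohort A `repforce_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$sessions, function(sess) {
    do.call(rbind, lapply(names(sess$traces), function(key) {
      tr <- sess$traces[[key]]
      gt <- sess$ground_truth[[key]]
      rep_idx <- rep(NA_integer_, length(tr$forces_N))
      for (r in seq_len(nrow(gt$rep_windows)))
        rep_idx[gt$rep_windows[r, 1]:(gt$rep_windows[r, 2] - 1)] <- r
      data.frame(subject_id = tr$subject_id, limb = tr$limb,
                 set_index = tr$set_index, rep_index = rep_idx,
                 time_s = tr$times_s, force_N = tr$forces_N)
    }))
  })
  write.csv(do.call(rbind, c(rows, make.row.names = FALSE)),
            file.path(dir, "samples.csv"), row.names = FALSE)
  write.csv(cohort_labels(cohort), file.path(dir, "labels.csv"),
            row.names = FALSE)
  subj <- do.call(rbind, lapply(cohort$sessions, function(s) {
    p <- s$profile
    data.frame(subject_id = p$subject_id, body_mass_kg = p$body_mass_kg,
               base_peak_force_N = p$base_peak_force_N,
               fatigue_rate = p$fatigue_rate,
               rep_duration_s = p$rep_duration_s,
               limb_asymmetry = p$limb_asymmetry)
  }))
  write.csv(subj, file.path(dir, "subjects.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an exported cohort's traces and labels
#'
#' Reconstructs `force_trace` objects from `samples.csv` plus the body mass
#' in `subjects.csv`; ground truth is not reloaded (it exists for tests).
#'
#' @param dir Directory written by [write_cohort()].
#' @return List with `traces`, `labels` and `manifest`.
#' @export
read_cohort <- function(dir) {
  samples <- read.csv(file.path(dir, "samples.csv"),
                      colClasses = c(subject_id = "character", limb = "character"))
  labels <- read.csv(file.path(dir, "labels.csv"),
                     colClasses = c(subject_id = "character", limb = "character"))
  subjects <- read.csv(file.path(dir, "subjects.csv"),
                       colClasses = c(subject_id = "character"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  mass <- setNames(subjects$body_mass_kg, subjects$subject_id)
  dt <- manifest$protocol$sampling_interval_s
  keys <- unique(samples[c("subject_id", "limb", "set_index")])
  traces <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- samples$subject_id == k$subject_id & samples$limb == k$limb &
      samples$set_index == k$set_index
    force_trace(subject_id = k$subject_id, limb = k$limb,
                set_index = k$set_index, forces_N = samples$force_N[sel],
                body_mass_kg = unname(mass[k$subject_id]),
                sampling_interval_s = dt)
  })
  list(traces = traces, labels = labels, manifest = manifest)
}
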