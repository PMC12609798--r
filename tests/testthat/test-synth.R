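test_that("subject generation is seeded, bounded, and degenerates correctly", {
  p1 <- generate_subject(1)
  p2 <- generate_subject(1)
  expect_identical(p1, p2)
  expect_false(identical(p1, generate_subject(2)))

  # zero population SD -> every subject is the mean profile
  pop0 <- population_params(body_mass_kg = c(74.4, 0),
                            base_peak_force_N = c(350, 0),
                            fatigue_rate = c(0.05, 0),
                            variability_gain = c(0.05, 0),
                            noise_sd_frac = c(0.03, 0),
                            plateau_frac = c(0.8, 0),
                            rpe_intercept = c(4, 0),
                            rpe_fatigue_gain = c(20, 0),
                            limb_asymmetry = c(0.1, 0))
  q1 <- generate_subject(10, pop0, protocol_config(rep_duration_s = c(2, 2)))
  q2 <- generate_subject(99, pop0, protocol_config(rep_duration_s = c(2, 2)))
  q2$subject_id <- q1$subject_id
  expect_equal(q1, q2)
  expect_equal(q1$body_mass_kg, 74.4)

  expect_error(population_params(body_mass_kg = c(74.4, -1)),
               class = "repforce_config_error")
  expect_error(population_params(nonsense = c(1, 1)),
               class = "repforce_config_error")
})

test_that("cohort body mass matches the configured population mean (Monte Carlo)", {
  masses <- vapply(1:1000, function(s) generate_subject(s)$body_mass_kg,
                   numeric(1))
  se <- 11.58 / sqrt(1000)
  expect_lt(abs(mean(masses) - 74.4), 3 * se)
})

test_that("repetition traces obey the generator's decay law and shape constraints", {
  # no fatigue, no noise -> identical trace for every set
  p <- test_profile(fatigue_rate = 0, noise_sd_frac = 0)
  t1 <- generate_rep_trace(p, 1, 1)
  t7 <- generate_rep_trace(p, 7, 1)
  expect_equal(as.numeric(t1), as.numeric(t7))

  # closed-form work decay: work(set 7) / work(set 1) = 0.95^6
  p <- test_profile(fatigue_rate = 0.05, noise_sd_frac = 0)
  w1 <- sum(generate_rep_trace(p, 1, 1)) * 0.02
  w7 <- sum(generate_rep_trace(p, 7, 1)) * 0.02
  expect_equal(w7 / w1, 0.95^6, tolerance = 1e-12)

  # early peak and non-negativity hold for any noise level
  set.seed(42)
  for (i in 1:20) {
    pn <- test_profile(noise_sd_frac = runif(1, 0, 0.2),
                       rep_duration_s = runif(1, 1, 4))
    f <- generate_rep_trace(pn, sample(1:7, 1), 1)
    expect_true(all(f >= 0))
    expect_lt(which.max(f), 0.05 * length(f))
  }

  expect_error(generate_rep_trace(p, 0, 1), class = "repforce_input_error")
})

test_that("session labels follow the latent-fatigue link and stay on the 0-10 scale", {
  # zero gain, zero label noise -> constant labels round(intercept)
  set.seed(1)
  p <- test_profile(rpe_fatigue_gain = 0, rpe_intercept = 3.4)
  sess <- generate_session(p, protocol_config())
  expect_true(all(sess$labels$rpe == 3L))

  # strong coupling, no label noise -> labels non-decreasing in set index
  set.seed(2)
  p <- test_profile(rpe_fatigue_gain = 25, rpe_intercept = 3)
  sess <- generate_session(p)
  for (lb in split(sess$labels, sess$labels$limb))
    expect_true(all(diff(lb$rpe[order(lb$set_index)]) >= 0))

  # clipping: an absurd gain cannot leave the OMNI-RES range
  set.seed(3)
  p <- test_profile(rpe_fatigue_gain = 200, label_noise_sd = 2)
  sess <- generate_session(p)
  expect_true(all(sess$labels$rpe >= 0 & sess$labels$rpe <= 10))
  expect_true(is.integer(sess$labels$rpe))

  bad <- protocol_config()
  bad$n_sets <- 1L
  expect_error(generate_session(test_profile(), bad),
               class = "repforce_config_error")
})

test_that("ground-truth per-set work declines strictly and limbs are asymmetric as configured", {
  set.seed(4)
  sess <- generate_session(test_profile(noise_sd_frac = 0.05))
  for (limb in c("L", "R")) {
    works <- vapply(1:7, function(s)
      sess$ground_truth[[paste(limb, s, sep = ".")]]$true_set_work, numeric(1))
    expect_true(all(diff(works) < 0)) # noise-free ground truth, fatigue_rate > 0
  }

  # limb_asymmetry = 0, noise = 0 -> left and right reps identical
  p0 <- test_profile(limb_asymmetry = 0, noise_sd_frac = 0)
  expect_equal(as.numeric(generate_rep_trace(p0, 3, 1, limb = "L")),
               as.numeric(generate_rep_trace(p0, 3, 1, limb = "R")))
})

test_that("cohorts are reproducible, exported byte-identically, and limb-correlated", {
  proto <- protocol_config(n_sets = 3, reps_per_set = 4, seed = 77)
  c1 <- generate_cohort(3, proto)
  c2 <- generate_cohort(3, proto)
  expect_equal(length(cohort_traces(c1)), 3 * 2 * 3)
  expect_identical(c1$manifest$seed, 77L)

  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in c("samples.csv", "labels.csv", "subjects.csv", "manifest.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))

  back <- read_cohort(d1)
  expect_equal(length(back$traces), 18)
  expect_equal(back$traces[[1]]$forces_N, cohort_traces(c1)[[1]]$forces_N)

  # upward label shift and positive left/right work correlation at scale
  c3 <- generate_cohort(25, protocol_config(seed = 5))
  lab <- cohort_labels(c3)
  expect_gt(mean(lab$rpe[lab$set_index == 7]), mean(lab$rpe[lab$set_index == 1]))
  wl <- vapply(c3$sessions, function(s) s$ground_truth[["L.1"]]$true_set_work, numeric(1))
  wr <- vapply(c3$sessions, function(s) s$ground_truth[["R.1"]]$true_set_work, numeric(1))
  expect_gt(cor(wl, wr), 0)

  expect_error(generate_cohort(1), class = "repforce_config_error")
})
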