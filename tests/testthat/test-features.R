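test_that("primary features have the stated closed forms on simple inputs", {
  p <- primary_features(rep(10, 50), 0.02)
  expect_equal(unname(p[c("peak_force", "mean_force", "rms", "variance",
                          "work", "ttp_s", "rfd")]),
               c(10, 10, 10, 0, 10, 0, 0))
  expect_true(is.na(p["skewness"]) && is.na(p["kurtosis"]))

  p <- primary_features(c(0, 1, 3), 0.02)
  expect_equal(unname(p["rfd"]), (3 - 1) / 0.02)
  expect_equal(unname(p["ttp_s"]), 2 * 0.02)
  expect_equal(unname(p["work"]), 4 * 0.02)

  expect_error(primary_features(5, 0.02), class = "repforce_input_error")
  expect_error(primary_features(1:5, 0), class = "repforce_input_error")
})

test_that("primary features match the definition-level oracle on random reps", {
  set.seed(101)
  for (i in 1:50) {
    f <- runif(200, 0, 400)
    got <- primary_features(f, 0.02)
    want <- oracle_primary(f, 0.02)
    expect_equal(got, want, tolerance = 1e-9)
    # moment identity ties the RMS definition to the N-1 variance divisor
    n <- length(f)
    expect_equal(got[["rms"]]^2,
                 got[["mean_force"]]^2 + got[["variance"]] * (n - 1) / n,
                 tolerance = 1e-9)
  }
})

test_that("feature transforms behave under affine force maps (property)", {
  set.seed(7)
  f <- runif(150, 10, 300)
  base <- primary_features(f, 0.02)
  scaled <- primary_features(3.5 * f, 0.02)
  expect_equal(scaled[["work"]], 3.5 * base[["work"]], tolerance = 1e-9)
  shifted <- primary_features(2 * f + 40, 0.02)
  expect_equal(shifted[["skewness"]], base[["skewness"]], tolerance = 1e-9)
  expect_equal(shifted[["kurtosis"]], base[["kurtosis"]], tolerance = 1e-9)
  neg <- primary_features(-f, 0.02)
  expect_equal(neg[["skewness"]], -base[["skewness"]], tolerance = 1e-9)
})

test_that("set aggregation uses mean/max/sum as designated", {
  set.seed(8)
  r1 <- primary_features(runif(100, 0, 100), 0.02)
  expect_equal(aggregate_set(list(r1)), r1)

  r2 <- primary_features(runif(100, 0, 100), 0.02)
  agg <- aggregate_set(list(r1, r2))
  expect_equal(agg[["work"]], r1[["work"]] + r2[["work"]])
  expect_equal(agg[["peak_force"]], max(r1[["peak_force"]], r2[["peak_force"]]))
  expect_equal(agg[["mean_force"]], mean(c(r1[["mean_force"]], r2[["mean_force"]])))

  same <- aggregate_set(replicate(8, r1, simplify = FALSE))
  expect_equal(same[["mean_force"]], r1[["mean_force"]])

  expect_error(aggregate_set(list()), class = "repforce_input_error")
})

test_that("relative features implement the baseline and previous-set forms", {
  r <- relative_features(c(8, 10))
  expect_equal(unname(unlist(r[2, -1])), c(2, 1.25, 2, 1.25))
  expect_equal(unname(unlist(r[1, c("delta_base", "ratio_base")])), c(0, 1))
  expect_true(is.na(r$delta_prev[1]) && is.na(r$ratio_prev[1]))

  r <- relative_features(c(4, 2, 1))
  expect_equal(r$ratio_base[3], 0.25)
  expect_equal(r$ratio_prev[3], 0.5)

  # zero baseline: ratios undefined, not infinite
  r <- relative_features(c(0, 3))
  expect_true(is.na(r$ratio_base[2]))
  expect_equal(r$ratio_base[1], 1)

  expect_error(relative_features(5), class = "repforce_input_error")
})

test_that("composite features combine work, SD, peak and RMS", {
  p <- c(peak_force = 10, mean_force = 5, rms = 8, variance = 4, sd = 2,
         skewness = 0, kurtosis = 3, work = 30, ttp_s = 0.1, rfd = 100)
  comp <- composite_features(p, data.frame(delta_base = -3, ratio_base = 0.9))
  expect_equal(unname(comp), c(30 / 2, 80, -2.7))

  p["sd"] <- 0
  comp <- composite_features(p, data.frame(delta_base = 0, ratio_base = 1))
  expect_true(is.na(comp[["work_over_sd"]]))
  expect_equal(comp[["delta_times_ratio"]], 0) # set-1 baseline: 0 x 1
})

test_that("the learning table has one deterministic row per (subject, limb, set)", {
  coh <- generate_cohort(3, protocol_config(n_sets = 4, reps_per_set = 3,
                                            seed = 31))
  tab <- build_table(coh)
  expect_equal(nrow(tab), 3 * 2 * 4)
  expect_true(all(c("set_index", "rpe", "work", "work_ratio_base",
                    "delta_times_ratio", "log1p_work") %in% names(tab)))

  # set-1 rows: baseline relatives are exactly (0, 1), prev relatives missing
  s1 <- tab[tab$set_index == 1, ]
  for (f in c("peak_force", "work", "rms")) {
    expect_true(all(s1[[paste0(f, "_delta_base")]] == 0))
    expect_true(all(s1[[paste0(f, "_ratio_base")]] == 1))
    expect_true(all(is.na(s1[[paste0(f, "_delta_prev")]])))
  }

  expect_equal(tab$log1p_work, log1p(tab$work))

  # determinism
  expect_identical(tab, build_table(coh))

  # missing label -> row skipped with a warning
  labs <- cohort_labels(coh)
  expect_warning(tab2 <- build_table(cohort_traces(coh), labs[-1, ]),
                 "skipped")
  expect_equal(nrow(tab2), nrow(tab) - 1)

  # exp-term family is opt-in
  tab3 <- build_table(coh, exp_terms = TRUE)
  expect_true("exp_ratio_work" %in% names(tab3))
  expect_equal(tab3$exp_ratio_work, exp(tab3$work_ratio_base))
})

test_that("fatiguing cohorts show declining work but no time-to-peak trend", {
  coh <- generate_cohort(4, protocol_config(seed = 55),
                         population_params(noise_sd_frac = c(0, 0)))
  tab <- build_table(coh)
  for (g in split(tab, paste(tab$subject_id, tab$limb))) {
    g <- g[order(g$set_index), ]
    expect_true(all(diff(g$work) < 0))
    expect_true(all(g$work_delta_base[-1] < 0))
  }
  # ttp is pinned to the (fixed-position) early peak: no set-index trend
  fit <- stats::lm(ttp_s ~ set_index, data = tab)
  pval <- summary(fit)$coefficients["set_index", 4]
  expect_gt(pval, 0.05)
})
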