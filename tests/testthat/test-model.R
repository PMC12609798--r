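test_that("cleaning drops non-numeric, constant and gappy columns; medians impute", {
  tab <- data.frame(subject_id = c("a", "a", "b", "b"), limb = "L",
                    set_index = c(1, 2, 1, 2), rpe = c(2L, 4L, 3L, 5L),
                    good = c(1, 2, 3, 4), flat = 5,
                    words = letters[1:4],
                    gappy = c(1, NA, NA, NA),
                    holey = c(1, NA, 3, 5))
  fm <- clean_features(tab)
  expect_setequal(names(fm$X), c("set_index", "good", "holey"))
  expect_equal(unname(fm$dropped[c("flat", "words", "gappy")]),
               c("constant", "non-numeric", "excess missing"))

  pp <- fit_preproc(fm$X, fm$labels, select = FALSE)
  X <- apply_preproc(pp, fm$X)
  expect_equal(unname(X[2, "holey"]), 3) # median of 1, 3, 5

  expect_error(clean_features(tab[0, ]), class = "repforce_input_error")
  expect_error(clean_features(data.frame(subject_id = "a", rpe = 1L,
                                         w = "x")),
               class = "repforce_input_error")
})

test_that("correlation screening keeps |r| >= threshold and falls back when empty", {
  set.seed(41)
  y <- rnorm(1000)
  X <- data.frame(same = y, indep = rnorm(1000), noisy = y + rnorm(1000, 0, 3))
  keep <- select_features(X, y)
  expect_equal(keep[1], "same")
  expect_false("indep" %in% keep)
  expect_equal(abs(cor(X$indep, y)) >= 0.5, "indep" %in% keep)

  expect_setequal(select_features(X, y, threshold = 0), names(X))

  # affine invariance of the screen
  X2 <- X; X2$same <- -3 * X2$same + 7
  expect_setequal(select_features(X2, y), keep)

  Xw <- data.frame(a = rnorm(100), b = rnorm(100))
  yw <- rnorm(100)
  expect_warning(kw <- select_features(Xw, yw, threshold = 0.99,
                                       fallback_k = 1), "falling back")
  expect_length(kw, 1)
})

test_that("all three regressors reproduce a constant target and are seeded", {
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(4, 20)
  for (kind in c("rf", "histgbr", "ridge")) {
    fit <- fit_model(X, y, model_spec(kind, n_estimators = 30, max_iter = 30))
    expect_equal(unname(predict(fit, X)), y, tolerance = 1e-9,
                 label = kind)
  }

  yv <- rnorm(20)
  f1 <- fit_model(X, yv, model_spec("rf", n_estimators = 30, seed = 5))
  f2 <- fit_model(X, yv, model_spec("rf", n_estimators = 30, seed = 5))
  expect_identical(predict(f1, X), predict(f2, X))
  f3 <- fit_model(X, yv, model_spec("rf", n_estimators = 30, seed = 6))
  expect_false(identical(predict(f1, X), predict(f3, X)))

  expect_error(fit_model(X[1, , drop = FALSE], 1, model_spec("ridge")),
               class = "repforce_input_error")
})

test_that("ridge with vanishing penalty recovers an exact linear map", {
  set.seed(13)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(2 + X %*% c(1.5, -2, 0.5))
  fit <- fit_model(X, y, model_spec("ridge", alpha = 1e-10))
  expect_equal(unname(predict(fit, X)), y, tolerance = 1e-6)
})

test_that("tree ensembles have near-interpolation training capacity", {
  set.seed(14)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(5 * X[, 1] - 2 * X[, 2])
  rf <- fit_model(X, y, model_spec("rf", n_estimators = 300))
  expect_lt(mean(abs(predict(rf, X) - y)), 0.25 * sd(y))
  gb <- fit_model(X, y, model_spec("histgbr", min_leaf = 1))
  expect_lt(mean(abs(predict(gb, X) - y)), 0.05 * sd(y))
})

test_that("cut-points are class-median midpoints with monotone pooling", {
  pred <- c(2.0, 2.1, 2.2, 2.8, 2.9, 3.0)
  lab <- c(2, 2, 2, 3, 3, 3)
  cp <- optimize_cutpoints(pred, lab)
  expect_equal(cp$thresholds, 2.5)
  expect_equal(cp$classes, c(2, 3))

  # monotone medians 1, 2, 4 -> thresholds 1.5, 3
  cp <- optimize_cutpoints(c(0.9, 1.0, 1.1, 1.9, 2.0, 2.1, 3.9, 4.0, 4.1),
                           rep(3:5, each = 3))
  expect_equal(cp$thresholds, c(1.5, 3.0))

  # medians 3.0, 2.8, 4.0 violate ordering: PAV pools classes 2 and 3
  pred <- c(2.9, 3.0, 3.1, 2.7, 2.8, 2.9, 3.9, 4.0, 4.1)
  lab <- rep(2:4, each = 3)
  cp <- optimize_cutpoints(pred, lab)
  expect_true(all(diff(cp$thresholds) > 0))
  # every training class median maps to a label at most 1 away
  for (cl in 2:4) {
    m <- median(pred[lab == cl])
    expect_lte(abs(discretize(m, cp) - cl), 1)
  }
  # brute force: no increasing pair of median midpoints misclassifies less
  meds <- vapply(2:4, function(cl) median(pred[lab == cl]), numeric(1))
  cands <- unique(as.numeric(outer(meds, meds, "+") / 2))
  best <- Inf
  for (t1 in cands) for (t2 in cands[cands > t1]) {
    guess <- vapply(pred, function(p) c(2, 3, 4)[1 + sum(c(t1, t2) < p)],
                    numeric(1))
    best <- min(best, sum(guess != lab))
  }
  expect_equal(sum(discretize(pred, cp) != lab), best)

  expect_error(optimize_cutpoints(rnorm(5), rep(3, 5)),
               class = "repforce_input_error")
})

test_that("threshold monotonicity holds for random prediction/label sets (property)", {
  set.seed(15)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    lab <- sample(0:10, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    pred <- rnorm(n, lab * runif(1, -1, 1), runif(1, 0.1, 3))
    cp <- optimize_cutpoints(pred, lab)
    expect_length(cp$thresholds, length(cp$classes) - 1)
    expect_true(all(diff(cp$thresholds) > 0))
  }
})

test_that("discretization uses strictly-below counting with ties to the lower class", {
  cp <- structure(list(classes = c(2, 5, 6), thresholds = c(3.5, 5.5)),
                  class = "cutpoints")
  expect_equal(discretize(c(-10, 3.4), cp), c(2L, 2L))
  expect_equal(discretize(3.5, cp), 2L) # exact tie -> lower class
  expect_equal(discretize(c(3.6, 5.5, 5.6, 99), cp), c(5L, 5L, 6L, 6L))

  # monotone medians map back to their own class
  pred <- c(1.0, 2.0, 4.0)
  cp <- optimize_cutpoints(c(0.9, 1.1, 1.9, 2.1, 3.9, 4.1),
                           rep(c(3, 4, 5), each = 2))
  expect_equal(discretize(pred, cp), c(3L, 4L, 5L))
})

test_that("cut-point discretization does not hurt training MAE versus rounding", {
  set.seed(16)
  # biased continuous predictions with monotone class medians
  lab <- sample(2:9, 200, replace = TRUE)
  pred <- lab * 0.8 + 1.7 + rnorm(200, 0, 0.3)
  cp <- optimize_cutpoints(pred, lab)
  expect_lte(mean(abs(discretize(pred, cp) - lab)),
             mean(abs(round(pred) - lab)))
})
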