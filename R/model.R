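#' Clean a feature table into a modeling matrix
#'
#' Drops non-numeric columns, constant columns, and columns whose
#' missingness exceeds `missing_cap`; remaining `NA`s are left in place so
#' that imputation statistics can be computed on training rows only inside
#' cross-validation (see [fit_preproc()]). Identifier and label columns are
#' carried alongside, never as features.
#'
#' @param table A [build_table()] data.frame (needs `subject_id` and `rpe`).
#' @param missing_cap Maximum tolerated fraction of missing values per
#'   column (default 0.3).
#' @param drop Extra column names to exclude from the feature set.
#' @return List of class `feature_matrix`: `X` (numeric data.frame with
#'   NAs), `labels`, `groups`, `dropped` (named reasons).
#' @export
clean_features <- function(table, missing_cap = 0.3, drop = character(0)) {
  if (!nrow(table)) stop_input("empty feature table")
  reserved <- c("subject_id", "limb", "set_index_id", "rpe", "n_reps", drop)
  cand <- setdiff(names(table), reserved)
  dropped <- character(0)
  keep <- character(0)
  for (nm in cand) {
    col <- table[[nm]]
    if (!is.numeric(col)) { dropped[nm] <- "non-numeric"; next }
    if (mean(is.na(col)) > missing_cap) { dropped[nm] <- "excess missing"; next }
    u <- unique(col[!is.na(col)])
    if (length(u) <= 1) { dropped[nm] <- "constant"; next }
    keep <- c(keep, nm)
  }
  if (!length(keep)) stop_input("no usable numeric feature columns after cleaning")
  structure(list(X = table[keep], labels = as.numeric(table$rpe),
                 groups = table$subject_id, dropped = dropped),
            class = "feature_matrix")
}

#' Screen features by absolute Pearson correlation with the label
#'
#' Retains columns with `|r| >= threshold` against the RPE labels, sorted by
#' `|r|` descending; columns with undefined correlation (zero variance after
#' imputation) are excluded. If nothing passes, falls back to the top
#' `fallback_k` columns by `|r|` with a warning.
#'
#' @param X Complete (imputed) numeric data.frame or matrix.
#' @param y Numeric label vector.
#' @param threshold Absolute-correlation cut (default 0.5).
#' @param fallback_k Columns kept when nothing passes (default 10).
#' @return Character vector of retained column names.
#' @export
select_features <- function(X, y, threshold = 0.5, fallback_k = 10) {
  r <- suppressWarnings(vapply(as.data.frame(X), function(col) cor(col, y),
                               numeric(1)))
  r <- r[is.finite(r)]
  if (!length(r)) stop_input("no feature has a defined correlation with the labels")
  r <- r[order(-abs(r))]
  keep <- names(r)[abs(r) >= threshold]
  if (!length(keep)) {
    warning(sprintf(
      "no feature reached |r| >= %g; falling back to the top %d by |r|",
      threshold, fallback_k))
    keep <- names(r)[seq_len(min(fallback_k, length(r)))]
  }
  keep
}

#' Fit fold-local preprocessing: imputation medians, selection, scaling
#'
#' Computes column medians, imputes, drops columns that became constant,
#' screens by [select_features()] and records standardization statistics --
#' all from the rows given (a training fold), so no label or distributional
#' information leaks out of the fold. Apply with [apply_preproc()].
#'
#' @param X Numeric data.frame with NAs (a [clean_features()] `X` subset).
#' @param y Labels for the same rows.
#' @param threshold,fallback_k See [select_features()].
#' @param select If `FALSE`, skip correlation screening (keep all columns).
#' @return List of class `repforce_preproc`.
#' @export
fit_preproc <- function(X, y, threshold = 0.5, fallback_k = 10, select = TRUE) {
  med <- vapply(X, function(col) median(col, na.rm = TRUE), numeric(1))
  med[is.na(med)] <- 0
  Xi <- impute_with(X, med)
  usable <- names(Xi)[vapply(Xi, function(col) length(unique(col)) > 1, TRUE)]
  Xi <- Xi[usable]
  cols <- if (select) select_features(Xi, y, threshold, fallback_k) else usable
  ctr <- colMeans(Xi[cols])
  scl <- vapply(Xi[cols], sd, numeric(1))
  scl[scl == 0] <- 1
  structure(list(medians = med, columns = cols, center = ctr, scale = scl),
            class = "repforce_preproc")
}

impute_with <- function(X, medians) {
  for (nm in names(X)) {
    col <- X[[nm]]
    col[is.na(col)] <- medians[[nm]]
    X[[nm]] <- col
  }
  X
}

#' Apply fitted preprocessing to new rows
#'
#' @param pp A [fit_preproc()] object.
#' @param X Numeric data.frame with the training columns present.
#' @param standardize If `TRUE`, center/scale with the training statistics
#'   (used for the ridge path; tree models are scale-invariant).
#' @return Numeric matrix with the selected columns.
#' @export
apply_preproc <- function(pp, X, standardize = FALSE) {
  X <- impute_with(X[names(pp$medians)], pp$medians)[pp$columns]
  M <- as.matrix(X)
  if (standardize)
    M <- sweep(sweep(M, 2, pp$center), 2, pp$scale, "/")
  M
}

#' Model specification
#'
#' Hyperparameter defaults follow the reference configuration: random
#' forest with 400 bootstrap-aggregated trees; gradient boosting with
#' maximum depth 6, 800 iterations, learning rate 0.04; ridge with
#' penalty `alpha = 1.0` on standardized features.
#'
#' @param kind `"rf"`, `"histgbr"` or `"ridge"`.
#' @param n_estimators Random-forest tree count.
#' @param mtry Features tried per split (`NULL` = all, the scikit-learn
#'   regression default).
#' @param max_depth Tree depth cap for boosting (and optionally RF).
#' @param max_iter Boosting iterations.
#' @param learning_rate Boosting shrinkage.
#' @param min_leaf Minimum samples per leaf (RF 1, boosting 20 by default).
#' @param alpha Ridge L2 penalty.
#' @param seed Integer seed; fitting is reproducible under a fixed seed.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(kind = c("rf", "histgbr", "ridge"), n_estimators = 400,
                       mtry = NULL, max_depth = 6, max_iter = 800,
                       learning_rate = 0.04, min_leaf = NULL, alpha = 1.0,
                       seed = 0L) {
  kind <- match.arg(kind)
  if (is.null(min_leaf)) min_leaf <- if (kind == "histgbr") 20L else 1L
  structure(list(kind = kind, n_estimators = as.integer(n_estimators),
                 mtry = mtry, max_depth = as.integer(max_depth),
                 max_iter = as.integer(max_iter),
                 learning_rate = learning_rate,
                 min_leaf = as.integer(min_leaf), alpha = alpha,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit a regressor
#'
#' Dispatches on `spec$kind`. The ridge path standardizes internally
#' (training center/scale, unpenalized intercept) and solves
#' `(X'X + alpha I) w = X'y` in closed form; tree ensembles are fitted by
#' the compiled CART routines, seeded through R's RNG.
#'
#' @param X Numeric matrix (rows = set records, columns = features).
#' @param y Numeric labels.
#' @param spec A [model_spec()].
#' @return A `repforce_model` with a [predict][predict.repforce_model]
#'   method.
#' @export
fit_model <- function(X, y, spec = model_spec()) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_input("need at least 2 rows to fit")
  if (anyNA(X)) stop_input("X must be imputed before fitting")
  set.seed(spec$seed)
  fit <- switch(spec$kind,
    rf = {
      mtry <- if (is.null(spec$mtry)) ncol(X) else min(spec$mtry, ncol(X))
      trees <- .rf_fit_cpp(X, y, spec$n_estimators, mtry, 30L,
                           spec$min_leaf, TRUE)
      list(trees = trees, n_trees = spec$n_estimators)
    },
    histgbr = .gbr_fit_cpp(X, y, spec$max_iter, spec$learning_rate,
                           spec$max_depth, spec$min_leaf),
    ridge = {
      ctr <- colMeans(X)
      scl <- apply(X, 2, sd)
      scl[scl == 0] <- 1
      Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
      p <- ncol(Xs)
      w <- solve(crossprod(Xs) + diag(spec$alpha, p), crossprod(Xs, y - mean(y)))
      list(center = ctr, scale = scl, coef = drop(w), intercept = mean(y))
    })
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 columns = colnames(X)),
            class = "repforce_model")
}

#' Predict continuous RPE estimates
#'
#' @param object A [fit_model()] result.
#' @param newdata Numeric matrix/data.frame with the training columns.
#' @param ... Unused.
#' @return Numeric vector of continuous predictions.
#' @export
predict.repforce_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$columns) && !is.null(colnames(X)))
    X <- X[, object$columns, drop = FALSE]
  switch(object$kind,
    rf = .ensemble_predict_cpp(object$fit$trees, X,
                               1 / object$fit$n_trees, 0),
    histgbr = .ensemble_predict_cpp(object$fit$trees, X,
                                    object$spec$learning_rate,
                                    object$fit$f0),
    ridge = {
      Xs <- sweep(sweep(X, 2, object$fit$center), 2, object$fit$scale, "/")
      drop(object$fit$intercept + Xs %*% object$fit$coef)
    })
}

# Pool-adjacent-violators: weighted isotonic (non-decreasing) fit.
# Returns the fitted values and the pooled blocks (index vectors).
pav <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  v <- values; w <- weights; idx <- as.list(seq_len(n))
  i <- 1
  while (i < length(v)) {
    if (v[i] > v[i + 1] + 1e-15) {
      tw <- w[i] + w[i + 1]
      v[i] <- (v[i] * w[i] + v[i + 1] * w[i + 1]) / tw
      w[i] <- tw
      idx[[i]] <- c(idx[[i]], idx[[i + 1]])
      v <- v[-(i + 1)]; w <- w[-(i + 1)]; idx <- idx[-(i + 1)]
      if (i > 1) i <- i - 1
    } else i <- i + 1
  }
  fitted <- numeric(n)
  for (b in seq_along(v)) fitted[idx[[b]]] <- v[b]
  list(fitted = fitted, blocks = idx)
}

#' Median-based ordinal cut-point optimization
#'
#' For each adjacent pair of label classes present in the data, the
#' threshold is the midpoint between the classes' prediction medians,
#' constrained to maintain monotone ordering: if the raw medians violate the
#' label ordering, adjacent classes are pooled by weighted
#' pool-adjacent-violators (weights = class counts) before midpoints are
#' taken. Classes pooled into one block share a fitted median, so their
#' internal boundaries are degenerate; they are collapsed toward the block
#' edges so that the block's prediction region maps to its most frequent
#' class (ties to the lower class), which minimizes training
#' misclassification among median-midpoint rules. The returned thresholds
#' are always strictly increasing (degenerate boundaries are separated by an
#' epsilon of 1e-8 of the prediction range).
#'
#' @param predictions Continuous model outputs (training predictions).
#' @param labels Integer class labels aligned with `predictions`.
#' @return List of class `cutpoints`: `classes` (sorted distinct labels) and
#'   `thresholds` (strictly increasing, length `length(classes) - 1`).
#' @export
optimize_cutpoints <- function(predictions, labels) {
  ok <- !is.na(predictions) & !is.na(labels)
  predictions <- predictions[ok]; labels <- labels[ok]
  classes <- sort(unique(labels))
  K <- length(classes)
  if (K < 2)
    stop_input("cut-point optimization needs >= 2 distinct labels; bypass discretization")
  med_raw <- vapply(classes, function(cl) median(predictions[labels == cl]),
                    numeric(1))
  cnt <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  iso <- pav(med_raw, cnt)
  med <- iso$fitted
  eps <- 1e-8 * max(diff(range(predictions)), 1)

  thr <- numeric(K - 1)
  for (b in seq_along(iso$blocks)) {
    ix <- iso$blocks[[b]] # class positions in this block
    lo <- ix[1]; hi <- ix[length(ix)]
    # block region edges: midpoints to the neighbouring blocks
    L <- if (lo == 1) min(predictions) - 1 else (med[lo - 1] + med[lo]) / 2
    U <- if (hi == K) max(predictions) + 1 else (med[hi] + med[hi + 1]) / 2
    if (hi < K) thr[hi] <- U
    if (length(ix) > 1) {
      m <- ix[which.max(cnt[ix])] # majority class, ties to the lower
      for (k in ix[ix < m]) thr[k] <- L + (k - lo + 1) * eps
      for (k in ix[ix >= m & ix < hi]) thr[k] <- U - (hi - k) * eps
    }
  }
  for (j in seq_along(thr)[-1]) # safety: strict increase
    if (thr[j] <= thr[j - 1]) thr[j] <- thr[j - 1] + eps
  structure(list(classes = classes, thresholds = thr), class = "cutpoints")
}

#' Discretize continuous predictions to ordinal labels
#'
#' `label = classes[1 + #(thresholds strictly below pred)]`; a prediction
#' exactly on a threshold goes to the lower class.
#'
#' @param pred Numeric predictions.
#' @param cp A [optimize_cutpoints()] object.
#' @return Integer labels drawn from `cp$classes`.
#' @export
discretize <- function(pred, cp) {
  k <- vapply(pred, function(p) sum(cp$thresholds < p), integer(1))
  as.integer(cp$classes[1 + k])
}
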