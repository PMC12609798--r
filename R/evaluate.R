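#' Cross-validation scheme
#'
#' `"kfold5"` is plain row-wise K-fold; `"groupkfold"` keeps all rows of a
#' subject (both limbs, all sets) in the same fold, preventing information
#' leakage between contralateral limbs and repeated sets of one person.
#'
#' @param kind `"kfold5"` or `"groupkfold"`.
#' @param n_folds Number of folds (default 5).
#' @param seed Shuffle seed for fold assignment.
#' @return List of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("groupkfold", "kfold5"), n_folds = 5,
                      seed = 0L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Assign rows to cross-validation folds
#'
#' Plain K-fold shuffles rows and deals them out so test sizes differ by at
#' most one. Group K-fold shuffles the distinct groups, then assigns each
#' (largest first) to the currently smallest fold, balancing row counts
#' while never splitting a group.
#'
#' @param scheme A [cv_scheme()].
#' @param n Number of rows.
#' @param groups Group key per row (required for `"groupkfold"`).
#' @return Integer fold id (1..n_folds) per row.
#' @export
make_folds <- function(scheme, n, groups = NULL) {
  set.seed(scheme$seed)
  k <- scheme$n_folds
  if (scheme$kind == "kfold5") {
    return(rep_len(seq_len(k), n)[order(sample.int(n))])
  }
  if (is.null(groups)) stop_input("groupkfold needs a group key per row")
  gs <- table(groups)
  if (length(gs) < k)
    stop_input("groupkfold needs at least as many groups (%d) as folds (%d)",
               length(gs), k)
  ord <- sample(length(gs)) # random tie-breaking
  gs <- gs[ord][order(-gs[ord])]
  load <- numeric(k)
  fold_of <- integer(length(gs))
  names(fold_of) <- names(gs)
  for (i in seq_along(gs)) {
    f <- which.min(load)
    fold_of[i] <- f
    load[f] <- load[f] + gs[i]
  }
  unname(fold_of[as.character(groups)])
}

#' Out-of-fold cross-validated predictions
#'
#' For each fold: preprocessing (median imputation, correlation screening,
#' standardization statistics) is fitted on the training rows only (set
#' `leak_free = FALSE` to reproduce the single-pass variant that computes
#' them on all rows), the model is fitted on the training rows, cut-points
#' are optimized on the model's own training predictions, and the held-out
#' rows are predicted once each, continuously and discretized.
#'
#' @param table A [build_table()] data.frame.
#' @param spec A [model_spec()].
#' @param scheme A [cv_scheme()].
#' @param threshold,fallback_k,missing_cap Screening / cleaning settings.
#' @param select Apply correlation screening (default `TRUE`).
#' @param leak_free Fit preprocessing inside each training fold (default).
#' @param drop Extra feature columns to exclude (e.g. the engineered
#'   relative features, for ablation).
#' @return data.frame with `row`, `fold`, `subject_id`, `rpe`, `pred`
#'   (continuous) and `pred_disc` (discretized).
#' @export
cross_validate <- function(table, spec = model_spec(),
                           scheme = cv_scheme(), threshold = 0.5,
                           fallback_k = 10, missing_cap = 0.3,
                           select = TRUE, leak_free = TRUE,
                           drop = character(0)) {
  fm <- clean_features(table, missing_cap = missing_cap, drop = drop)
  folds <- make_folds(scheme, nrow(fm$X), fm$groups)
  pred <- numeric(nrow(fm$X))
  pred_disc <- integer(nrow(fm$X))
  pp_all <- if (!leak_free)
    suppressWarnings(fit_preproc(fm$X, fm$labels, threshold, fallback_k, select))
  for (f in seq_len(scheme$n_folds)) {
    tr <- folds != f
    te <- !tr
    if (!any(te)) next
    pp <- if (leak_free)
      suppressWarnings(fit_preproc(fm$X[tr, , drop = FALSE], fm$labels[tr],
                                   threshold, fallback_k, select))
    else pp_all
    standardize <- spec$kind == "ridge"
    Xtr <- apply_preproc(pp, fm$X[tr, , drop = FALSE], standardize)
    Xte <- apply_preproc(pp, fm$X[te, , drop = FALSE], standardize)
    fit <- fit_model(Xtr, fm$labels[tr], spec)
    ptr <- predict(fit, Xtr)
    pte <- predict(fit, Xte)
    cp <- optimize_cutpoints(ptr, as.integer(fm$labels[tr]))
    pred[te] <- pte
    pred_disc[te] <- discretize(pte, cp)
  }
  data.frame(row = seq_len(nrow(fm$X)), fold = folds,
             subject_id = fm$groups, rpe = as.integer(fm$labels),
             pred = pred, pred_disc = pred_disc)
}

#' Continuous regression metrics
#'
#' `R^2 = 1 - SS_res / SS_tot`, mean absolute error, root mean square
#' error, and Pearson's r. With a constant truth, `r2` and `pearson_r` are
#' undefined and returned as `NA` (never silently 0).
#'
#' @param pred,true Aligned numeric vectors (>= 2 values).
#' @return Named list `r2, mae, rmse, pearson_r`.
#' @export
continuous_metrics <- function(pred, true) {
  if (length(pred) != length(true)) stop_input("pred and true must align")
  if (length(pred) < 2) stop_input("need at least 2 pairs")
  ss_tot <- sum((true - mean(true))^2)
  err <- pred - true
  list(r2 = if (ss_tot == 0) NA_real_ else 1 - sum(err^2) / ss_tot,
       mae = mean(abs(err)),
       rmse = sqrt(mean(err^2)),
       pearson_r = if (ss_tot == 0 || sd(pred) == 0) NA_real_
                   else cor(pred, true))
}

#' Tolerance accuracies, confusion matrix and error buckets
#'
#' Tolerance accuracy is the fraction of predictions with
#' `|pred - true| <= tol` (inclusive), computed on the continuous
#' predictions; exact accuracy and the confusion matrix use the discretized
#' predictions; error buckets count continuous absolute errors in
#' `[0, 1]`, `(1, 2]` and `(2, Inf)`.
#'
#' @param pred Continuous predictions.
#' @param true Integer labels.
#' @param pred_disc Discretized predictions (default `round(pred)`).
#' @param tolerances Inclusive tolerance bands (default 0.5 and 1.0).
#' @return List with `acc_within` (named by tolerance), `exact_accuracy`,
#'   `confusion` (table over the union label range), `error_buckets`.
#' @export
tolerance_metrics <- function(pred, true, pred_disc = round(pred),
                              tolerances = c(0.5, 1.0)) {
  err <- abs(pred - true)
  acc <- vapply(tolerances, function(tol) mean(err <= tol), numeric(1))
  names(acc) <- sprintf("within_%.1f", tolerances)
  lev <- seq(min(true, pred_disc), max(true, pred_disc))
  confusion <- table(true = factor(true, levels = lev),
                     predicted = factor(pred_disc, levels = lev))
  buckets <- c(le_1 = sum(err <= 1), in_1_2 = sum(err > 1 & err <= 2),
               gt_2 = sum(err > 2))
  list(acc_within = acc,
       exact_accuracy = mean(pred_disc == true),
       confusion = confusion,
       error_buckets = buckets)
}

#' Bland-Altman limits of agreement
#'
#' Differences are `pred - true`; the limits are `mean +/- 1.96 sd` with
#' the sample (N-1) SD. The per-group variant repeats the computation within
#' each subject; groups with fewer than 2 pairs are flagged with `NA`s.
#'
#' @param pred,true Aligned numeric vectors (>= 2 pairs).
#' @param groups Optional group key for per-subject limits.
#' @return List `mean_diff, sd_diff, loa_low, loa_high`, plus `per_group`
#'   (data.frame) when `groups` is given.
#' @export
bland_altman <- function(pred, true, groups = NULL) {
  if (length(pred) != length(true)) stop_input("pred and true must align")
  if (length(pred) < 2) stop_input("need at least 2 pairs")
  d <- pred - true
  out <- list(mean_diff = mean(d), sd_diff = sd(d))
  out$loa_low <- out$mean_diff - 1.96 * out$sd_diff
  out$loa_high <- out$mean_diff + 1.96 * out$sd_diff
  if (!is.null(groups)) {
    per <- lapply(split(d, groups), function(dg) {
      if (length(dg) < 2)
        return(data.frame(n = length(dg), mean_diff = NA_real_,
                          sd_diff = NA_real_, loa_low = NA_real_,
                          loa_high = NA_real_))
      m <- mean(dg); s <- sd(dg)
      data.frame(n = length(dg), mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
    })
    out$per_group <- cbind(group = names(per),
                           do.call(rbind, c(per, make.row.names = FALSE)))
  }
  out
}

#' Full evaluation report from out-of-fold predictions
#'
#' @param oof A [cross_validate()] result.
#' @return List of class `eval_report`: continuous metrics, tolerance
#'   accuracies, exact accuracy, confusion, error buckets, Bland-Altman
#'   (overall and per subject), and a per-fold breakdown of the continuous
#'   metrics.
#' @export
evaluate_predictions <- function(oof) {
  cm <- continuous_metrics(oof$pred, oof$rpe)
  tm <- tolerance_metrics(oof$pred, oof$rpe, oof$pred_disc)
  ba <- bland_altman(oof$pred, oof$rpe, oof$subject_id)
  per_fold <- do.call(rbind, lapply(split(oof, oof$fold), function(d) {
    f <- continuous_metrics(d$pred, d$rpe)
    data.frame(fold = d$fold[1], n = nrow(d), r2 = f$r2, mae = f$mae,
               rmse = f$rmse, pearson_r = f$pearson_r)
  }))
  structure(c(cm, tm, list(bland_altman = ba, per_fold = per_fold,
                           n = nrow(oof))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Out-of-fold evaluation (n = %d)\n", x$n))
  cat(sprintf("  R^2 %.3f | MAE %.3f | RMSE %.3f | Pearson r %.3f\n",
              x$r2, x$mae, x$rmse, x$pearson_r))
  cat(sprintf("  within +/-0.5: %.3f | within +/-1: %.3f | exact: %.3f\n",
              x$acc_within[["within_0.5"]], x$acc_within[["within_1.0"]],
              x$exact_accuracy))
  cat(sprintf("  Bland-Altman: mean %.3f, LoA [%.3f, %.3f]\n",
              x$bland_altman$mean_diff, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  invisible(x)
}

#' Compare regressors on identical folds
#'
#' Cross-validates each specification with the same fold assignment and
#' ranks the reports by out-of-fold R^2.
#'
#' @param table A [build_table()] data.frame.
#' @param specs Named list of [model_spec()]s (>= 2).
#' @param scheme A [cv_scheme()].
#' @param ... Passed to [cross_validate()].
#' @return List of class `model_comparison`: `reports` (per spec), `oof`
#'   (per spec), and `ranking` (data.frame sorted by R^2 descending).
#' @export
compare_models <- function(table, specs, scheme = cv_scheme(), ...) {
  if (length(specs) < 2) stop_input("compare_models needs >= 2 specs")
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$kind, "")
  oof <- lapply(specs, function(sp) cross_validate(table, sp, scheme, ...))
  reports <- lapply(oof, evaluate_predictions)
  ranking <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, r2 = r$r2, mae = r$mae, rmse = r$rmse,
               pearson_r = r$pearson_r,
               within_0.5 = r$acc_within[["within_0.5"]],
               within_1.0 = r$acc_within[["within_1.0"]])
  }))
  ranking <- ranking[order(-ranking$r2), ]
  rownames(ranking) <- NULL
  structure(list(reports = reports, oof = oof, ranking = ranking),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (out-of-fold)\n")
  print(x$ranking, digits = 3)
  invisible(x)
}
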