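# Names of the per-repetition primary descriptors, in export order.
PRIMARY_FEATURES <- c("peak_force", "mean_force", "rms", "variance", "sd",
                      "skewness", "kurtosis", "work", "ttp_s", "rfd")

# Non-negative magnitude/energy features that get log1p companions.
LOG_FEATURES <- c("peak_force", "mean_force", "rms", "variance", "sd", "work")

#' Primary biomechanical features of one repetition
#'
#' Computes the standard force-time descriptors of a single push:
#' peak force, mean force, RMS, variance and SD (sample, N-1 divisor),
#' skewness and kurtosis (population 1/N central moments over the population
#' SD; kurtosis is raw, not excess), work (`sum(f_i) * dt`, N s -- the
#' impulse, which under isokinetic constant velocity is proportional to
#' mechanical work), time to peak (time of the first maximum relative to
#' repetition onset) and rate of force development (maximum single-step
#' `diff(f) / dt`, N/s).
#'
#' A constant signal has zero SD, so skewness and kurtosis are undefined and
#' returned as `NA` for downstream imputation.
#'
#' @param rep Numeric vector: the repetition's force samples (>= 2).
#' @param dt Sampling interval in seconds (> 0).
#' @return Named numeric vector with elements
#'   `peak_force, mean_force, rms, variance, sd, skewness, kurtosis, work,
#'   ttp_s, rfd`.
#' @export
primary_features <- function(rep, dt) {
  rep <- as.numeric(rep)
  n <- length(rep)
  if (n < 2) stop_input("a repetition needs at least 2 samples")
  if (dt <= 0) stop_input("dt must be positive")
  m <- mean(rep)
  v <- sum((rep - m)^2) / (n - 1)
  s <- sqrt(v)
  sig_pop <- sqrt(sum((rep - m)^2) / n)
  if (sig_pop > 0) {
    skew <- sum((rep - m)^3) / n / sig_pop^3
    kurt <- sum((rep - m)^4) / n / sig_pop^4
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  c(peak_force = max(rep),
    mean_force = m,
    rms = sqrt(mean(rep^2)),
    variance = v,
    sd = s,
    skewness = skew,
    kurtosis = kurt,
    work = sum(rep) * dt,
    ttp_s = (which.max(rep) - 1) * dt,
    rfd = max(diff(rep)) / dt)
}

#' Aggregate repetition-level features to the set level
#'
#' Unweighted mean of each descriptor across a set's repetitions, except
#' `peak_force` (maximum across reps) and `work` (sum across reps, the set's
#' cumulative output). `NA` descriptors (e.g. moments of a constant rep) are
#' dropped from the mean; a set whose reps are all `NA` for a descriptor
#' stays `NA`.
#'
#' @param reps List of [primary_features()] vectors (>= 1) or a matrix with
#'   one row per repetition.
#' @return Named numeric vector on the same scale as [primary_features()].
#' @export
aggregate_set <- function(reps) {
  if (is.list(reps)) {
    if (!length(reps)) stop_input("cannot aggregate an empty set")
    reps <- do.call(rbind, reps)
  }
  if (is.null(dim(reps))) reps <- matrix(reps, 1, dimnames = list(NULL, names(reps)))
  if (nrow(reps) < 1) stop_input("cannot aggregate an empty set")
  out <- apply(reps, 2, function(col) {
    if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE)
  })
  out["peak_force"] <- max(reps[, "peak_force"])
  out["work"] <- sum(reps[, "work"])
  out
}

#' Inter-set relative features of one descriptor
#'
#' Baseline-referenced (set 1 as the individual's reference) and
#' previous-set-referenced differences and ratios:
#' `delta_base(s) = f(s) - f(1)`, `ratio_base(s) = f(s) / f(1)`,
#' `delta_prev(s) = f(s) - f(s-1)`, `ratio_prev(s) = f(s) / f(s-1)`.
#' At s = 1 the baseline pair is identically (0, 1) and the previous-set
#' pair is missing (no predecessor). Ratios with zero denominator are `NA`.
#'
#' @param set_values Numeric vector, the descriptor's value for sets 1..S
#'   (S >= 2).
#' @return data.frame with columns `set_index, delta_base, ratio_base,
#'   delta_prev, ratio_prev`.
#' @export
relative_features <- function(set_values) {
  S <- length(set_values)
  if (S < 2) stop_input("relative features need at least 2 sets")
  f1 <- set_values[1]
  prev <- c(NA_real_, set_values[-S])
  ratio0 <- function(num, den) {
    out <- num / den
    out[rep_len(!is.na(den) & den == 0, length(out))] <- NA_real_
    out
  }
  out <- data.frame(
    set_index = seq_len(S),
    delta_base = set_values - f1,
    ratio_base = ratio0(set_values, f1),
    delta_prev = set_values - prev,
    ratio_prev = ratio0(set_values, prev))
  # s = 1 is its own reference by definition, even if f(1) is 0 or NA
  out$delta_base[1] <- 0
  out$ratio_base[1] <- 1
  out$delta_prev[1] <- NA_real_
  out$ratio_prev[1] <- NA_real_
  out
}

#' Composite (interaction) features
#'
#' `work_over_sd` (workload adjusted for stability; `NA` when SD is 0),
#' `peak_times_rms` (compound intensity x sustained-energy indicator), and
#' `delta_times_ratio` = `delta_base * ratio_base` of a designated base
#' descriptor (work by default -- the headline fatigue-sensitive feature),
#' integrating absolute deviation and proportional change; it is identically
#' 0 x 1 = 0 at set 1.
#'
#' @param p Named vector from [primary_features()] / [aggregate_set()].
#' @param rel One row of [relative_features()] for the designated base
#'   descriptor (needs `delta_base` and `ratio_base`).
#' @return Named numeric vector `work_over_sd, peak_times_rms,
#'   delta_times_ratio`.
#' @export
composite_features <- function(p, rel) {
  wos <- if (!is.na(p[["sd"]]) && p[["sd"]] == 0) NA_real_ else p[["work"]] / p[["sd"]]
  c(work_over_sd = wos,
    peak_times_rms = p[["peak_force"]] * p[["rms"]],
    delta_times_ratio = rel$delta_base * rel$ratio_base)
}

# Filter + segment + normalize one trace and return its set-level primary
# feature vector (plus the recovered rep count).
trace_set_features <- function(trace, filter = filter_spec(),
                               seg = seg_params(),
                               normalization = c("allometric", "per_mass", "raw"),
                               exponent = 0.67) {
  normalization <- match.arg(normalization)
  filtered <- lowpass(trace, filter)
  segs <- segment_reps(filtered, seg)
  rep_forces <- attr(segs, "rep_forces")
  if (!length(rep_forces))
    return(list(features = setNames(rep(NA_real_, length(PRIMARY_FEATURES)),
                                    PRIMARY_FEATURES),
                n_reps = 0L, segments = segs))
  rep_forces <- switch(normalization,
    allometric = lapply(rep_forces, normalize_force, trace$body_mass_kg, exponent),
    per_mass = lapply(rep_forces, normalize_force, trace$body_mass_kg, 1),
    raw = rep_forces)
  feats <- lapply(rep_forces, primary_features, dt = trace$sampling_interval_s)
  list(features = aggregate_set(feats), n_reps = nrow(segs), segments = segs)
}

#' Assemble the set-level learning table
#'
#' Runs preprocessing and feature extraction over a cohort's traces and
#' builds one row per (subject, limb, set): the ten primary descriptors,
#' their four inter-set relative companions each, the three composite
#' features, `log(1 + x)` companions for the non-negative magnitude/energy
#' descriptors, the numeric set index, and the RPE label. Traces without a
#' label are skipped with a warning. Column order is deterministic.
#'
#' @param traces List of [force_trace()] objects (or a `repforce_cohort`).
#' @param labels data.frame with subject_id, limb, set_index, rpe; defaults
#'   to the cohort's own labels when `traces` is a cohort.
#' @param filter,seg,normalization,exponent Passed to the preprocessing
#'   stage (see [filter_spec()], [seg_params()], [normalize_force()]).
#' @param base_feature Descriptor feeding `delta_times_ratio` (default
#'   `"work"`).
#' @param exp_terms If `TRUE`, add `exp_ratio_<f> = exp(f(s)/f(1))` columns
#'   for the magnitude features (disabled by default).
#' @return data.frame of class `set_feature_table`.
#' @export
build_table <- function(traces, labels = NULL, filter = filter_spec(),
                        seg = seg_params(),
                        normalization = c("allometric", "per_mass", "raw"),
                        exponent = 0.67, base_feature = "work",
                        exp_terms = FALSE) {
  normalization <- match.arg(normalization)
  if (inherits(traces, "repforce_cohort")) {
    if (is.null(labels)) labels <- cohort_labels(traces)
    traces <- cohort_traces(traces)
  }
  if (is.null(labels)) stop_input("labels are required")
  if (!base_feature %in% PRIMARY_FEATURES)
    stop_config("base_feature must be one of: %s",
                paste(PRIMARY_FEATURES, collapse = ", "))

  per_set <- do.call(rbind, lapply(traces, function(tr) {
    fs <- trace_set_features(tr, filter, seg, normalization, exponent)
    cbind(data.frame(subject_id = tr$subject_id, limb = tr$limb,
                     set_index = tr$set_index, n_reps = fs$n_reps),
          as.data.frame(as.list(fs$features)))
  }))

  groups <- split(per_set, paste(per_set$subject_id, per_set$limb, sep = "\r"))
  rows <- lapply(groups, function(g) {
    g <- g[order(g$set_index), , drop = FALSE]
    rel_all <- lapply(PRIMARY_FEATURES, function(f) {
      r <- relative_features(g[[f]])
      names(r)[-1] <- paste0(f, "_", names(r)[-1])
      r[-1]
    })
    rel <- do.call(cbind, rel_all)
    base_rel <- data.frame(
      delta_base = rel[[paste0(base_feature, "_delta_base")]],
      ratio_base = rel[[paste0(base_feature, "_ratio_base")]])
    comp <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      p <- setNames(as.numeric(g[i, PRIMARY_FEATURES]), PRIMARY_FEATURES)
      as.data.frame(as.list(composite_features(p, base_rel[i, ])))
    }))
    logs <- as.data.frame(lapply(g[LOG_FEATURES], log1p))
    names(logs) <- paste0("log1p_", LOG_FEATURES)
    out <- cbind(g[c("subject_id", "limb", "set_index", "n_reps")],
                 g[PRIMARY_FEATURES], rel, comp, logs)
    if (exp_terms) {
      ex <- as.data.frame(lapply(LOG_FEATURES, function(f)
        exp(rel[[paste0(f, "_ratio_base")]])))
      names(ex) <- paste0("exp_ratio_", LOG_FEATURES)
      out <- cbind(out, ex)
    }
    out
  })
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  tab <- tab[order(tab$subject_id, tab$limb, tab$set_index), , drop = FALSE]

  key <- function(d) paste(d$subject_id, d$limb, d$set_index, sep = "\r")
  idx <- match(key(tab), key(labels))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))
    warning(sprintf("%d set(s) without an RPE label were skipped", length(miss)))
    tab <- tab[-miss, , drop = FALSE]
    idx <- idx[-miss]
  }
  tab$rpe <- as.integer(labels$rpe[idx])
  rownames(tab) <- NULL
  class(tab) <- c("set_feature_table", "data.frame")
  tab
}

#' Write a feature table with a JSON schema sidecar
#'
#' @param table A [build_table()] result.
#' @param path CSV path; the sidecar is written to `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  describe <- function(nm) {
    if (nm %in% PRIMARY_FEATURES) return("set-level primary descriptor")
    if (grepl("_delta_base$", nm)) return("difference from set-1 baseline")
    if (grepl("_ratio_base$", nm)) return("ratio to set-1 baseline")
    if (grepl("_delta_prev$", nm)) return("difference from previous set")
    if (grepl("_ratio_prev$", nm)) return("ratio to previous set")
    if (grepl("^log1p_", nm)) return("log(1 + x) transform")
    if (grepl("^exp_ratio_", nm)) return("exp of baseline ratio")
    switch(nm,
           work_over_sd = "work / SD composite",
           peak_times_rms = "peak x RMS composite",
           delta_times_ratio = "delta_base x ratio_base composite",
           set_index = "1-based set number (numeric feature)",
           rpe = "OMNI-RES 0-10 end-of-set label",
           "identifier")
  }
  schema <- lapply(names(table), function(nm)
    list(column = nm, description = describe(nm)))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
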