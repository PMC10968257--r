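#' Sliding-window segmentation of a longitudinal series
#'
#' Cuts one eye's follow-up into overlapping segments of 4-8 years so that
#' long-term gradual progression is represented by many short-term episodes.
#' For each window length `L` a segment starts at offsets 0, `stride`,
#' `2 * stride`, ... while the offset plus `L` fits in the follow-up span.
#' A segment keeps the visits whose time relative to its start lies in
#' \[0, L\]. Segments with fewer than `min_visits` visits, or too few visits
#' to be classified at even the largest truncation time, are dropped.
#'
#' @param eye_df Cohort rows of a single eye (any order; sorted internally).
#' @param windows Window lengths in years.
#' @param stride Start-offset spacing in years.
#' @param truncations Truncation grid (years into the segment) used
#'   downstream by [classify_at_time()].
#' @param min_visits Minimum visits in the full window for a ground-truth
#'   label (OLS slope with estimable residual variance).
#' @param threshold Progression criterion for the ground-truth label
#'   (dB/year; strict inequality).
#' @return List of segments; each has `eye_id`, `window_length`, `start`
#'   (absolute date), `rel_times`, `rows` (row indices into `eye_df` after
#'   date-sorting is applied; the sorted frame is attached as attribute
#'   `data`), `label` (logical ground truth), `truncations`.
#' @export
segment_series <- function(eye_df, windows = 4:8, stride = 1,
                           truncations = seq(1, 3, by = 0.5),
                           min_visits = 4L, threshold = -0.5) {
  stopifnot(stride > 0, nrow(eye_df) >= 1)
  eye_df <- eye_df[order(eye_df$test_date), , drop = FALSE]
  t0 <- eye_df$test_date[1]
  rel <- eye_df$test_date - t0
  span <- max(rel)
  segs <- list()
  for (L in windows) {
    if (L > span + 1e-9) next
    starts <- seq(0, span - L + 1e-9, by = stride)
    for (s in starts) {
      in_win <- which(rel >= s - 1e-9 & rel <= s + L + 1e-9)
      if (length(in_win) < min_visits) next
      rt <- rel[in_win] - s
      # must be classifiable at at least one truncation point
      if (max(vapply(truncations, function(tt) sum(rt <= tt + 1e-9),
                     numeric(1))) < 2) next
      lab <- label_segment(rt, eye_df$md[in_win], threshold)
      segs[[length(segs) + 1L]] <- list(
        eye_id = eye_df$eye_id[1], window_length = L, start = t0 + s,
        rel_times = rt, rows = in_win, label = lab,
        truncations = truncations)
    }
  }
  attr(segs, "data") <- eye_df
  segs
}

#' Ground-truth progression label of a segment
#'
#' Progressing iff the OLS slope of MD over the full window is strictly
#' worse than the threshold. Fused segments always inherit the label of
#' their measured twin; labels are never recomputed from fused data.
#'
#' @param rel_times Visit times within the segment (years).
#' @param md MD values (dB).
#' @param threshold dB/year, default -0.5.
#' @return Logical.
#' @export
label_segment <- function(rel_times, md, threshold = -0.5) {
  if (length(rel_times) < 2) stop("insufficient visits to label")
  ols_slope(rel_times, md)$slope < threshold
}

#' Classify progression from a truncated segment
#'
#' Uses only visits within `t` years of the segment start. Methods `vf` and
#' `fused` fit an OLS slope to the (measured or fused) MD values; `blr`
#' combines the MD slope with the structural prior via [blr_classify()]. At
#' least two visits must fall inside the truncation; otherwise `NA` is
#' returned and the segment is excluded from the counts at that time.
#'
#' @param rel_times Visit times within the segment (years).
#' @param md MD values aligned with `rel_times` (measured for `vf`/`blr`,
#'   fused for `fused`).
#' @param t Truncation time (years).
#' @param method One of `"vf"`, `"fused"`, `"blr"`.
#' @param mrnflt Mean RNFL thickness values (needed for `blr`).
#' @param threshold dB/year.
#' @param kappa,se_kappa Structure-to-function conversion for `blr`.
#' @return Logical prediction, or `NA` if unclassifiable at `t`.
#' @export
classify_at_time <- function(rel_times, md, t, method = c("vf", "fused", "blr"),
                             mrnflt = NULL, threshold = -0.5,
                             kappa = NULL, se_kappa = 0) {
  method <- match.arg(method)
  keep <- rel_times <= t + 1e-9
  if (sum(keep & is.finite(md)) < 2) return(NA)
  if (method %in% c("vf", "fused")) {
    return(ols_slope(rel_times[keep], md[keep])$slope < threshold)
  }
  if (is.null(kappa)) stop("blr classification needs kappa")
  blr_classify(rel_times, md, mrnflt, truncate_at = t,
               threshold = threshold, kappa = kappa,
               se_kappa = se_kappa)$progressing
}

#' Confusion-matrix metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP) and F1 = 2TP/(2TP+FP+FN).
#' A zero denominator yields `NaN` together with an `undefined` flag, never a
#' silent 0; undefined values contribute nothing to aggregation.
#'
#' @param predictions,labels Logical vectors of equal length (NA predictions
#'   are dropped pairwise).
#' @return List with `tp`, `tn`, `fp`, `fn`, `sensitivity`, `specificity`,
#'   `f1`, `n`, `undefined` (character vector of metric names with zero
#'   denominators).
#' @export
confusion_metrics <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  keep <- !is.na(predictions) & !is.na(labels)
  p <- as.logical(predictions[keep]); l <- as.logical(labels[keep])
  if (!length(p)) stop("no classified cases")
  counts_to_metrics(tp = sum(p & l), tn = sum(!p & !l),
                    fp = sum(p & !l), fn = sum(!p & l))
}

counts_to_metrics <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  f1 <- ratio(2 * tp, 2 * tp + fp + fn)
  undef <- c("sensitivity", "specificity", "f1")[is.nan(c(sens, spec, f1))]
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sensitivity = sens, specificity = spec, f1 = f1,
       n = tp + tn + fp + fn, undefined = undef)
}

#' Mean and 95% confidence interval of aggregated metrics
#'
#' Aggregates the per-window (and per-fold) metric values obtained at one
#' truncation time: mean, standard error of the mean, and the normal 95%
#' interval mean +/- 1.96 SEM.
#'
#' @param values Numeric vector (NaN/NA values are dropped); at least two
#'   finite values required.
#' @return List with `mean`, `sem`, `lower`, `upper`, `n`.
#' @export
aggregate_ci <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("need at least two values to aggregate")
  m <- mean(v); sem <- sd(v) / sqrt(length(v))
  list(mean = m, sem = sem, lower = m - 1.96 * sem, upper = m + 1.96 * sem,
       n = length(v))
}

#' Exact Wilcoxon signed-rank test with midranks
#'
#' Two-sided paired signed-rank test. Zero differences are discarded; tied
#' absolute differences receive midranks. For n <= 25 the p-value comes from
#' the exact permutation distribution of the positive-rank sum (computed by
#' dynamic programming over the 2^n sign assignments, so ties are handled
#' exactly); for larger n a normal approximation with the usual tie
#' correction is used.
#'
#' @param x,y Paired samples (equal length; pairs with NA dropped).
#' @return List with `statistic` (positive-rank sum), `p_value`, `n`
#'   (nonzero differences), `exact` (logical), `degenerate` (TRUE when all
#'   differences are zero; then no p-value is emitted).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                exact = NA, degenerate = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    # doubled midranks are integers; DP over achievable doubled rank sums
    m <- as.integer(round(2 * r))
    total <- sum(m)
    counts <- numeric(total + 1L)
    counts[1] <- 1
    for (mi in m) {
      shifted <- c(numeric(mi), counts[seq_len(total + 1L - mi)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  list(statistic = w, p_value = p, n = n, exact = exact, degenerate = FALSE)
}

#' Paired comparison of two metric series
#'
#' Wilcoxon signed-rank comparison of two methods' metric values paired by
#' (window length, fold, truncation time). Requires at least five nonzero
#' differences; identical series are flagged as degenerate and no p-value is
#' emitted.
#'
#' @param a,b Paired numeric vectors.
#' @return See [wilcoxon_signed_rank()].
#' @export
compare_methods <- function(a, b) {
  res <- wilcoxon_signed_rank(a, b)
  if (!res$degenerate && res$n < 5) {
    res$p_value <- NA_real_
    res$note <- "fewer than 5 nonzero differences"
  }
  res
}

# ---- cohort-level evaluation --------------------------------------------

#' Progression-detection report for one cohort
#'
#' Runs the full evaluation pipeline on a (validation) cohort: segments each
#' eye's series, labels segments from the measured fields, classifies each
#' segment at every truncation time with each method, and tabulates the
#' confusion counts. The `fused` cohort (from [fuse_cohort()]) supplies MD
#' values for the `fused` method; its segments inherit the measured labels.
#'
#' @param measured Reliability-filtered measured cohort.
#' @param fused Optional fused cohort (same rows as `measured`).
#' @param blr Logical: also run the Bayesian linear-regression baseline.
#' @param threshold Progression criterion (dB/year).
#' @param windows,stride,truncations Segmentation parameters, see
#'   [segment_series()].
#' @param kappa,se_kappa Conversion coefficient for the BLR prior; defaults
#'   to [estimate_kappa()] on `measured` (pass the training-set estimate when
#'   evaluating a held-out fold).
#' @return data.frame with one row per (method, window, time): confusion
#'   counts, sensitivity, specificity, F1 and `n` segments evaluated.
#' @export
evaluate_progression <- function(measured, fused = NULL, blr = FALSE,
                                 threshold = -0.5, windows = 4:8, stride = 1,
                                 truncations = seq(1, 3, by = 0.5),
                                 kappa = NULL, se_kappa = 0) {
  if (blr && is.null(kappa)) {
    k <- estimate_kappa(measured)
    kappa <- k$kappa; se_kappa <- k$se_kappa
  }
  methods <- c("vf", if (!is.null(fused)) "fused", if (blr) "blr")
  if (!is.null(fused)) {
    key_m <- paste(measured$eye_id, round(measured$test_date, 6))
    key_f <- paste(fused$eye_id, round(fused$test_date, 6))
    fused_md <- fused$md[match(key_m, key_f)]
    if (anyNA(fused_md)) stop("fused cohort does not cover the measured rows")
  }
  mrnflt_all <- if (blr) cohort_mrnflt(measured) else NULL

  acc <- list()
  tally <- function(method, L, t, pred, lab) {
    key <- paste(method, L, t, sep = "|")
    cur <- acc[[key]] %||% c(tp = 0, tn = 0, fp = 0, fn = 0)
    if (pred & lab) cur["tp"] <- cur["tp"] + 1
    if (!pred & !lab) cur["tn"] <- cur["tn"] + 1
    if (pred & !lab) cur["fp"] <- cur["fp"] + 1
    if (!pred & lab) cur["fn"] <- cur["fn"] + 1
    acc[[key]] <<- cur
  }

  row_index <- seq_len(nrow(measured))
  for (e in unique(measured$eye_id)) {
    sel <- which(measured$eye_id == e)
    eye_df <- measured[sel, , drop = FALSE]
    segs <- segment_series(eye_df, windows, stride, truncations,
                           threshold = threshold)
    sorted <- attr(segs, "data")
    orig <- sel[order(measured$test_date[sel])]
    for (seg in segs) {
      rows_global <- orig[seg$rows]
      md_meas <- sorted$md[seg$rows]
      for (t in truncations) {
        for (method in methods) {
          md_use <- switch(method,
                           vf = md_meas, blr = md_meas,
                           fused = fused_md[rows_global])
          pred <- classify_at_time(
            seg$rel_times, md_use, t, method,
            mrnflt = if (method == "blr") mrnflt_all[rows_global],
            threshold = threshold, kappa = kappa, se_kappa = se_kappa)
          if (!is.na(pred)) tally(method, seg$window_length, t, pred,
                                  seg$label)
        }
      }
    }
  }

  out <- lapply(names(acc), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    cnt <- acc[[key]]
    m <- counts_to_metrics(cnt["tp"], cnt["tn"], cnt["fp"], cnt["fn"])
    data.frame(method = parts[1], window = as.numeric(parts[2]),
               time = as.numeric(parts[3]),
               tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               f1 = m$f1, n = m$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$method, out$window, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-validated fusion benchmark
#'
#' The end-to-end experiment: eye-grouped severity-stratified k-fold
#' cross-validation in which each fold trains the fusion model on the
#' training eyes, fuses the held-out eyes, estimates the structural
#' conversion coefficient on the training visits, and evaluates progression
#' detection on the held-out eyes with the measured (`vf`), AE-fused
#' (`fused`) and Bayesian (`blr`) data.
#'
#' @param cohort Reliability-filtered cohort.
#' @param config An [aedf_config()].
#' @param k Number of folds.
#' @param spec A [normalization_spec()].
#' @param threshold,windows,stride,truncations See [evaluate_progression()].
#' @param blr Include the BLR baseline.
#' @return List with `report` (the per-fold tidy report, extra column
#'   `fold`), `models`, `folds`.
#' @export
evaluate_fusion <- function(cohort, config = aedf_config(), k = 5L,
                            spec = normalization_spec(), threshold = -0.5,
                            windows = 4:8, stride = 1,
                            truncations = seq(1, 3, by = 0.5), blr = TRUE) {
  folds <- make_cv_folds(cohort, k, seed = config$seed)
  reports <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    val_eyes <- names(folds)[folds == f]
    val <- cohort[cohort$eye_id %in% val_eyes, , drop = FALSE]
    train <- cohort[!cohort$eye_id %in% val_eyes, , drop = FALSE]
    fit <- aedf(train, val, config, spec)
    models[[f]] <- fit
    kap <- estimate_kappa(train)
    fused_val <- fuse_cohort(fit, val)
    rep_f <- evaluate_progression(val, fused = fused_val, blr = blr,
                                  threshold = threshold, windows = windows,
                                  stride = stride, truncations = truncations,
                                  kappa = kap$kappa, se_kappa = kap$se_kappa)
    rep_f$fold <- f
    reports[[f]] <- rep_f
  }
  list(report = do.call(rbind, reports), models = models, folds = folds)
}

#' Aggregate a detection report over windows (and folds)
#'
#' @param report Output of [evaluate_progression()] or the `report` element
#'   of [evaluate_fusion()].
#' @param metric One of `"sensitivity"`, `"specificity"`, `"f1"`.
#' @return data.frame with one row per (method, time): mean, sem, lower,
#'   upper, n over the (window x fold) values.
#' @export
aggregate_report <- function(report, metric = "f1") {
  stopifnot(metric %in% c("sensitivity", "specificity", "f1"))
  keys <- unique(report[c("method", "time")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- report$method == keys$method[i] & report$time == keys$time[i]
    ci <- aggregate_ci(report[[metric]][sel])
    data.frame(method = keys$method[i], time = keys$time[i],
               mean = ci$mean, sem = ci$sem, lower = ci$lower,
               upper = ci$upper, n = ci$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$method, out$time), , drop = FALSE]
}
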