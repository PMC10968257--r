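#' Severity band of a baseline mean deviation
#'
#' Common mild / moderate / severe convention: MD of -6 dB or better is
#' mild, between -6 and -12 moderate, worse than -12 severe.
#'
#' @param md Numeric MD values (dB).
#' @return Factor with levels `mild`, `moderate`, `severe`.
#' @export
severity_band <- function(md) {
  cut(md, breaks = c(-Inf, -12, -6, Inf),
      labels = c("severe", "moderate", "mild"), right = FALSE)
}

#' Eye-grouped, severity-stratified cross-validation folds
#'
#' Folds partition eyes, never visits, so no eye contributes data to both
#' training and validation of any fold. Within each severity band (from the
#' first visit's MD) eyes are shuffled and dealt round-robin to folds, which
#' keeps per-fold band counts within one eye of exact proportionality.
#'
#' @param cohort Cohort data.frame.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Named integer vector: fold assignment (1..k) per eye id.
#' @export
make_cv_folds <- function(cohort, k = 10L, seed = 1L) {
  eyes <- unique(as.character(cohort$eye_id))
  if (length(eyes) < k) stop("fewer eyes than folds")
  base_md <- vapply(eyes, function(e) {
    rows <- cohort[cohort$eye_id == e, ]
    rows$md[which.min(rows$test_date)]
  }, numeric(1))
  band <- severity_band(base_md)
  folds <- integer(length(eyes))
  names(folds) <- eyes
  rng <- local({ set.seed(seed); function(n) sample.int(n) })
  offset <- 0L
  for (b in levels(band)) {
    idx <- which(band == b)
    if (!length(idx)) next
    idx <- idx[rng(length(idx))]
    folds[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  folds
}

#' Cross-validated training of the fusion model
#'
#' Trains one model per fold (validation = the fold's eyes, training = the
#' rest) and reports denormalized validation reconstruction errors: pointwise
#' mean absolute error of the reconstructed field (dB) and RNFL profile (um),
#' and of the encoding against the measured field (dB).
#'
#' @param cohort Reliability-filtered cohort data.frame.
#' @param config An [aedf_config()].
#' @param k Number of folds.
#' @param spec A [normalization_spec()].
#' @return List with `folds` (eye assignment), `models` (per-fold `aedf`
#'   fits) and `metrics` (data.frame: fold, n_val_eyes, mae_vf_db,
#'   mae_rnfl_um, mae_enc_db).
#' @export
crossvalidate_aedf <- function(cohort, config = aedf_config(), k = 10L,
                               spec = normalization_spec()) {
  folds <- make_cv_folds(cohort, k, seed = config$seed)
  models <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    val_eyes <- names(folds)[folds == f]
    val <- cohort[cohort$eye_id %in% val_eyes, , drop = FALSE]
    train <- cohort[!cohort$eye_id %in% val_eyes, , drop = FALSE]
    fit <- aedf(train, val, config, spec)
    models[[f]] <- fit
    rows[[f]] <- cbind(fold = f, n_val_eyes = length(val_eyes),
                       as.data.frame(as.list(aedf_mae(fit, val))))
  }
  list(folds = folds, models = models,
       metrics = do.call(rbind, rows))
}

# denormalized validation MAEs for one fitted model
aedf_mae <- function(fit, val) {
  d <- cohort_design(val, fit$spec, fit$config$include_rnfl,
                     fit$config$include_age)
  z <- encode_fusion(fit, d$x)
  xp <- decode_fusion(fit, z)
  raw_x <- denormalize_fusion(d$x, fit$spec, fit$layout)
  raw_xp <- denormalize_fusion(xp, fit$spec, fit$layout)
  raw_z <- denormalize_fusion(z, fit$spec, c(dls = 52L))
  out <- c(mae_vf_db = mean(abs(raw_xp[, 1:52] - raw_x[, 1:52])),
           mae_rnfl_um = NA_real_,
           mae_enc_db = mean(abs(raw_z - raw_x[, 1:52])))
  if (isTRUE(fit$config$include_rnfl)) {
    out["mae_rnfl_um"] <- mean(abs(raw_xp[, 53:308] - raw_x[, 53:308]))
  }
  out
}

#' Grid search over the encoding-loss weight
#'
#' Evaluates each candidate `lambda` with an evaluation function that returns
#' the aggregate F1 score for progression detection at the two-year point
#' (by default [evaluate_fusion()] run at that lambda), and returns the
#' maximizer. Ties break towards the smaller lambda (preferring
#' reconstruction fidelity).
#'
#' @param cohort Reliability-filtered cohort data.frame.
#' @param lambdas Numeric grid within \[0, 1\].
#' @param eval_fn Function `(cohort, lambda, ...) -> scalar F1`; replaceable
#'   for testing or custom pipelines.
#' @param ... Passed to `eval_fn`.
#' @return List with `lambda_star` and `table` (data.frame lambda, f1).
#' @export
grid_search_lambda <- function(cohort, lambdas = seq(0, 1, by = 0.1),
                               eval_fn = eval_lambda_f1, ...) {
  if (!length(lambdas)) stop("empty lambda grid")
  stopifnot(all(lambdas >= 0 & lambdas <= 1))
  lambdas <- sort(lambdas)
  f1 <- vapply(lambdas, function(l) eval_fn(cohort, l, ...), numeric(1))
  tab <- data.frame(lambda = lambdas, f1 = f1)
  list(lambda_star = lambdas[which.max(f1)], table = tab)
}

# default grid-search objective: cross-validated fused F1 at the 2-year point
eval_lambda_f1 <- function(cohort, lambda, k = 3L, config = aedf_config(),
                           ...) {
  config$lambda <- lambda
  res <- evaluate_fusion(cohort, config = config, k = k, ...)
  agg <- aggregate_report(res$report, metric = "f1")
  agg$mean[agg$method == "fused" & abs(agg$time - 2) < 1e-9]
}
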