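#' Configuration of the autoencoder data-fusion model
#'
#' The encoder maps the normalized input (field, RNFL profile, age) through
#' two hidden layers to a 52-dimensional encoding interpreted on the 24-2
#' grid (the AE-fused field); the decoder mirrors it. Hidden layers use GELU
#' activations with layer normalization. Defaults: encoder
#' 309-256-128-52 and decoder 52-128-256-309 (a smooth dimension taper,
#' small enough to train on a CPU in minutes), Adam with learning rate 1e-3,
#' batch size 64, at most 500 epochs with early stopping (patience 25) on the
#' validation total loss.
#'
#' @param hidden Integer vector: the two hidden-layer widths.
#' @param lambda Mixing weight of the encoding loss, in \[0, 1\].
#' @param dz Encoding width; 52 keeps the fused data interpretable as a
#'   24-2 field.
#' @param lr,batch_size,epochs,patience Optimizer hyperparameters.
#' @param val_fraction Fraction of eyes held out for validation when no
#'   explicit validation cohort is given.
#' @param include_rnfl,include_age Input-ablation flags.
#' @param seed Integer seed controlling initialization and batch order.
#' @return An object of class `aedf_config`.
#' @export
aedf_config <- function(hidden = c(256L, 128L), lambda = 0.6, dz = 52L,
                        lr = 1e-3, batch_size = 64L, epochs = 500L,
                        patience = 25L, val_fraction = 0.2,
                        include_rnfl = TRUE, include_age = TRUE, seed = 1L) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]")
  }
  stopifnot(length(hidden) == 2, all(hidden >= 1), dz >= 1,
            lr > 0, batch_size >= 1, epochs >= 1, patience >= 1)
  structure(list(hidden = as.integer(hidden), lambda = lambda,
                 dz = as.integer(dz), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_fraction = val_fraction,
                 include_rnfl = isTRUE(include_rnfl),
                 include_age = isTRUE(include_age),
                 seed = as.integer(seed)),
            class = "aedf_config")
}

#' Fit the autoencoder data-fusion model
#'
#' Trains encoder and decoder jointly by minibatch Adam to minimize the
#' convex combination `(1 - lambda) * Lrec + lambda * Lenc` of reconstruction
#' and encoding losses (see [reconstruction_loss()]). Training and validation
#' sets are disjoint by eye: either pass `val_cohort` explicitly or a
#' fraction of eyes (stratified by disease severity) is held out. Early
#' stopping monitors the validation total loss and the returned model carries
#' the best-epoch parameters.
#'
#' @param cohort Training cohort data.frame ([cohort_columns()] schema),
#'   already reliability-filtered.
#' @param val_cohort Optional validation cohort; its eyes must not appear in
#'   `cohort`.
#' @param config An [aedf_config()].
#' @param spec The [normalization_spec()] applied to all channels.
#' @return An object of class `aedf` with the trained `encoder`, `decoder`,
#'   `spec`, `config`, per-epoch `trace` (train/validation Lrec, Lenc, L) and
#'   `best_epoch`.
#' @export
#' @seealso [predict.aedf()], [fuse_cohort()], [crossvalidate_aedf()]
aedf <- function(cohort, val_cohort = NULL, config = aedf_config(),
                 spec = normalization_spec()) {
  stopifnot(inherits(config, "aedf_config"))
  if (nrow(cohort) == 0) stop("empty training set")
  if (is.null(val_cohort)) {
    folds <- make_cv_folds(cohort, k = max(2L, round(1 / config$val_fraction)),
                           seed = config$seed)
    hold <- names(folds)[folds == 1L]
    val_cohort <- cohort[cohort$eye_id %in% hold, , drop = FALSE]
    cohort <- cohort[!cohort$eye_id %in% hold, , drop = FALSE]
  }
  if (length(intersect(unique(cohort$eye_id), unique(val_cohort$eye_id)))) {
    stop("train and validation sets share eyes")
  }

  tr <- cohort_design(cohort, spec, config$include_rnfl, config$include_age)
  va <- cohort_design(val_cohort, spec, config$include_rnfl, config$include_age)
  dx <- ncol(tr$x)

  set.seed(config$seed)
  enc <- nn_init(c(dx, config$hidden, config$dz))
  dec <- nn_init(c(config$dz, rev(config$hidden), dx))
  st_enc <- adam_init(enc)
  st_dec <- adam_init(dec)

  lambda <- config$lambda
  n <- nrow(tr$x)
  step <- 0L
  best <- list(val = Inf, epoch = 0L, enc = enc, dec = dec)
  wait <- 0L
  trace <- vector("list", config$epochs)

  eval_losses <- function(enc, dec, d) {
    Z <- nn_forward(enc, d$x)$out
    Xp <- nn_forward(dec, Z)$out
    lrec <- reconstruction_loss(Xp, d$x)
    lenc <- encoding_loss(Z[, 1:52, drop = FALSE], d$v)
    c(rec = lrec, enc = lenc, total = total_loss(lrec, lenc, lambda))
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      X <- tr$x[idx, , drop = FALSE]
      V <- tr$v[idx, , drop = FALSE]
      nb <- length(idx)

      fe <- nn_forward(enc, X)
      Z <- fe$out
      fd <- nn_forward(dec, Z)
      Xp <- fd$out

      dXp <- 2 * (1 - lambda) * (Xp - X) / nb
      bd <- nn_backward(dec, fd$caches, dXp)
      dZ <- bd$dX
      dZ[, 1:52] <- dZ[, 1:52] + 2 * lambda * (Z[, 1:52] - V) / nb
      be <- nn_backward(enc, fe$caches, dZ)

      step <- step + 1L
      up <- adam_step(dec, bd$grads, st_dec, step, lr = config$lr)
      dec <- up$layers; st_dec <- up$state
      up <- adam_step(enc, be$grads, st_enc, step, lr = config$lr)
      enc <- up$layers; st_enc <- up$state
    }

    ltr <- eval_losses(enc, dec, tr)
    lva <- eval_losses(enc, dec, va)
    if (!all(is.finite(c(ltr, lva)))) {
      stop("non-finite loss at epoch ", epoch,
           " (training diverged; lower the learning rate)")
    }
    trace[[epoch]] <- c(epoch = epoch, train = ltr, val = lva)

    if (lva[["total"]] < best$val - 1e-9) {
      best <- list(val = lva[["total"]], epoch = epoch, enc = enc, dec = dec)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  trace <- as.data.frame(do.call(rbind, trace[!vapply(trace, is.null,
                                                      logical(1))]))
  names(trace) <- c("epoch", "train_rec", "train_enc", "train_total",
                    "val_rec", "val_enc", "val_total")
  structure(list(encoder = best$enc, decoder = best$dec, spec = spec,
                 config = config, layout = tr$layout, dx = dx,
                 trace = trace, best_epoch = best$epoch,
                 best_val_loss = best$val,
                 train_eyes = unique(tr$eye_id),
                 val_eyes = unique(va$eye_id),
                 train_cohort = cohort),
            class = "aedf")
}

#' Encode / decode normalized fusion vectors
#'
#' The raw forward passes of a fitted model: `encode_fusion` maps a
#' normalized input batch to 52-dimensional encodings (the AE-fused fields,
#' still in normalized units; denormalize with the `dls` channel bounds);
#' `decode_fusion` maps encodings back to reconstructed inputs. Both are
#' deterministic.
#'
#' @param model A fitted [aedf()] model.
#' @param x Normalized input matrix (samples in rows) or vector of width
#'   `model$dx`.
#' @return `encode_fusion`: n x 52 matrix; `decode_fusion`: n x dx matrix.
#' @export
encode_fusion <- function(model, x) {
  stopifnot(inherits(model, "aedf"))
  x <- as_batch(x)
  if (ncol(x) != model$dx) stop("input width does not match the model")
  nn_forward(model$encoder, x)$out
}

#' @rdname encode_fusion
#' @param z Encoding matrix (n x 52) or vector.
#' @export
decode_fusion <- function(model, z) {
  stopifnot(inherits(model, "aedf"))
  z <- as_batch(z)
  if (ncol(z) != model$config$dz) stop("encoding width does not match the model")
  nn_forward(model$decoder, z)$out
}

#' Predictions from a fitted fusion model
#'
#' @param object A fitted [aedf()] model.
#' @param newdata Cohort data.frame.
#' @param type `"fused"` returns the AE-fused fields denormalized to dB
#'   (n x 52 matrix); `"reconstruction"` returns the denormalized
#'   reconstructed input (n x dx matrix); `"encoding"` returns the raw
#'   normalized encodings.
#' @param ... Unused.
#' @return A matrix, one row per cohort row.
#' @export
predict.aedf <- function(object, newdata,
                         type = c("fused", "reconstruction", "encoding"),
                         ...) {
  type <- match.arg(type)
  d <- cohort_design(newdata, object$spec, object$config$include_rnfl,
                     object$config$include_age)
  z <- encode_fusion(object, d$x)
  if (type == "encoding") return(z)
  if (type == "fused") {
    return(denormalize_fusion(z, object$spec, c(dls = 52L)))
  }
  xp <- decode_fusion(object, z)
  denormalize_fusion(xp, object$spec, object$layout)
}

#' Replace measured fields by AE-fused fields in a cohort
#'
#' Writes the denormalized encodings into the `dls_*` columns and recomputes
#' the `md` column from the fused field (mean total deviation against the
#' same normative values as the measured field, so fused and measured MD
#' share units and progression threshold). All other columns pass through.
#'
#' @param model A fitted [aedf()] model.
#' @param cohort Cohort data.frame.
#' @return Cohort data.frame with fused fields.
#' @export
fuse_cohort <- function(model, cohort) {
  z <- predict(model, cohort, type = "fused")
  out <- cohort
  out[dls_cols()] <- as.data.frame(pmin(pmax(z, -5), 50))
  out$md <- vapply(seq_len(nrow(out)), function(i) {
    compute_md(as.numeric(out[i, dls_cols()]), normative_dls(out$age[i]))
  }, numeric(1))
  out
}

#' @export
print.aedf <- function(x, ...) {
  cfg <- x$config
  cat("Autoencoder data-fusion model\n")
  cat(sprintf("  input dx = %d (%s), encoding dz = %d\n", x$dx,
              paste(names(x$layout), collapse = "+"), cfg$dz))
  cat(sprintf("  encoder %s | decoder mirrored\n",
              paste(c(x$dx, cfg$hidden, cfg$dz), collapse = "-")))
  cat(sprintf("  lambda = %.2f; trained %d epochs (best %d), val loss %.5f\n",
              cfg$lambda, nrow(x$trace), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
summary.aedf <- function(object, ...) {
  tr <- object$trace
  last <- tr[nrow(tr), ]
  best <- tr[tr$epoch == object$best_epoch, ]
  out <- list(config = object$config,
              epochs_run = nrow(tr), best_epoch = object$best_epoch,
              best = best, last = last,
              n_train_eyes = length(object$train_eyes),
              n_val_eyes = length(object$val_eyes))
  class(out) <- "summary.aedf"
  out
}

#' @export
print.summary.aedf <- function(x, ...) {
  cat(sprintf(
    "AEDF fit: lambda %.2f, %d train / %d validation eyes, %d epochs\n",
    x$config$lambda, x$n_train_eyes, x$n_val_eyes, x$epochs_run))
  cat(sprintf("Best epoch %d: val Lrec %.5f, val Lenc %.5f, val total %.5f\n",
              x$best_epoch, x$best$val_rec, x$best$val_enc, x$best$val_total))
  invisible(x)
}

#' @export
coef.aedf <- function(object, ...) {
  list(encoder = object$encoder, decoder = object$decoder)
}

#' Reconstruction residuals on the training cohort
#'
#' @param object A fitted [aedf()] model.
#' @param newdata Optional cohort; defaults to the training cohort.
#' @param ... Unused.
#' @return n x dx matrix of denormalized residuals (input minus
#'   reconstruction).
#' @export
residuals.aedf <- function(object, newdata = object$train_cohort, ...) {
  d <- cohort_design(newdata, object$spec, object$config$include_rnfl,
                     object$config$include_age)
  xp <- predict(object, newdata, type = "reconstruction")
  x_raw <- denormalize_fusion(d$x, object$spec, object$layout)
  x_raw - xp
}

#' Training-trace plot
#'
#' @param x A fitted [aedf()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.aedf <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(tr$epoch, cbind(tr$train_total, tr$val_total),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "total loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
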