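#' Autoencoder loss terms
#'
#' Both losses use one convention, documented because it sets the effective
#' scale of the mixing weight `lambda`: the squared Euclidean norm of the
#' per-sample error vector (sum over coordinates), averaged over the N
#' samples of the batch. `reconstruction_loss` compares the decoder output to
#' the model input over all coordinates; `encoding_loss` compares the
#' 52-dimensional encoding to the measured (normalized) visual field.
#'
#' @param xprime,x Reconstructed and input batches: matrices with samples in
#'   rows (a vector is treated as one sample). Shapes must match.
#' @return Scalar loss.
#' @export
#' @examples
#' reconstruction_loss(matrix(0.1, 1, 309) + 0, matrix(0, 1, 309))  # 3.09
reconstruction_loss <- function(xprime, x) {
  sum_sq_mse(xprime, x)
}

#' @rdname reconstruction_loss
#' @param z,v Encoding and measured-field batches, 52 columns each.
#' @export
encoding_loss <- function(z, v) {
  z <- as_batch(z); v <- as_batch(v)
  if (ncol(z) != 52 || ncol(v) != 52) {
    stop("encoding_loss expects 52-column batches")
  }
  sum_sq_mse(z, v)
}

#' @rdname reconstruction_loss
#' @param lrec,lenc Scalar loss values.
#' @param lambda Mixing weight in \[0, 1\]: 0 trains a pure autoencoder, 1
#'   reduces training to regressing the encoding onto the measured field.
#' @export
total_loss <- function(lrec, lenc, lambda) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]")
  }
  (1 - lambda) * lrec + lambda * lenc
}

as_batch <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1)
}

sum_sq_mse <- function(a, b) {
  a <- as_batch(a); b <- as_batch(b)
  if (!all(dim(a) == dim(b))) stop("shape mismatch between batches")
  d <- a - b
  sum(d * d) / nrow(a)
}
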