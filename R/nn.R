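# Minimal multilayer-perceptron machinery for the autoencoder.
#
# Internal matrix code: a stack of blocks, each Linear -> LayerNorm -> GELU,
# followed by a final Linear readout. Gradients are derived analytically and
# verified against finite differences in the test suite. All randomness goes
# through R's RNG so training is reproducible from a seed.

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

# sizes: c(d_in, h1, ..., d_out). Hidden layers get LN + GELU; readout linear.
nn_init <- function(sizes) {
  L <- length(sizes) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    d_in <- sizes[l]; d_out <- sizes[l + 1]
    sdW <- sqrt(2 / (d_in + d_out))
    layers[[l]] <- list(
      W = matrix(rnorm(d_in * d_out, 0, sdW), d_in, d_out),
      b = rep(0, d_out)
    )
    if (l < L) {
      layers[[l]]$g <- rep(1, d_out)   # layer-norm gain
      layers[[l]]$bn <- rep(0, d_out)  # layer-norm bias
    }
  }
  layers
}

.ln_eps <- 1e-5

# forward pass; returns output and per-layer caches for backprop
nn_forward <- function(layers, X) {
  L <- length(layers)
  caches <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    ly <- layers[[l]]
    Z <- A %*% ly$W
    Z <- sweep(Z, 2, ly$b, "+")
    if (l < L) {
      mu <- rowMeans(Z)
      Zc <- Z - mu
      va <- rowMeans(Zc * Zc)
      inv <- 1 / sqrt(va + .ln_eps)
      Xhat <- Zc * inv
      S <- sweep(Xhat, 2, ly$g, "*")
      S <- sweep(S, 2, ly$bn, "+")
      Anext <- gelu(S)
      caches[[l]] <- list(A = A, Xhat = Xhat, inv = inv, S = S)
      A <- Anext
    } else {
      caches[[l]] <- list(A = A)
      A <- Z
    }
  }
  list(out = A, caches = caches)
}

# backward pass; dOut is the gradient wrt the network output.
# Returns list(grads = per-layer list(W, b, g, bn), dX = gradient wrt input).
nn_backward <- function(layers, caches, dOut) {
  L <- length(layers)
  grads <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    ly <- layers[[l]]; ca <- caches[[l]]
    if (l < L) {
      dS <- dA * gelu_grad(ca$S)
      dg <- colSums(dS * ca$Xhat)
      dbn <- colSums(dS)
      dXhat <- sweep(dS, 2, ly$g, "*")
      m1 <- rowMeans(dXhat)
      m2 <- rowMeans(dXhat * ca$Xhat)
      dZ <- (dXhat - m1 - ca$Xhat * m2) * ca$inv
    } else {
      dZ <- dA
      dg <- NULL; dbn <- NULL
    }
    gW <- crossprod(ca$A, dZ)
    gb <- colSums(dZ)
    dA <- dZ %*% t(ly$W)
    grads[[l]] <- list(W = gW, b = gb, g = dg, bn = dbn)
  }
  list(grads = grads, dX = dA)
}

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    lapply(ly, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(layers, grads, state, t, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    for (nm in names(layers[[l]])) {
      gr <- grads[[l]][[nm]]
      if (is.null(gr)) next
      st <- state[[l]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * gr
      st$v <- beta2 * st$v + (1 - beta2) * gr * gr
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[l]][[nm]] <- layers[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}
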