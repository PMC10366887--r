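# Layer primitives with explicit forward/backward passes. Tensors are
# [H, W, C, N] arrays; convolutions run through compiled im2col + GEMM
# kernels. Only what the encoder-decoder needs is implemented.

# ---- batch normalization ----------------------------------------------------

bn_fw <- function(x, gamma, beta, rmean, rvar, train, momentum = 0.1,
                  eps = 1e-5) {
  d <- dim(x)
  n_per <- d[1] * d[2] * d[4]
  if (train) {
    mu <- channel_dot(x, NULL) / n_per
    v <- pmax(channel_dot(x, x) / n_per - mu^2, 0)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean
    v <- rvar
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- channel_affine(x, istd, -mu * istd)
  y <- channel_affine(xhat, gamma, beta)
  list(
    y = y, cache = list(xhat = xhat, istd = istd, gamma = gamma, d = d,
                        train = train),
    rmean = rmean, rvar = rvar
  )
}

bn_bw <- function(dy, cache) {
  d <- cache$d
  n_per <- d[1] * d[2] * d[4]
  dgamma <- channel_dot(dy, cache$xhat)
  dbeta <- channel_dot(dy, NULL)
  dxhat <- channel_affine(dy, cache$gamma, numeric(d[3]))
  if (!cache$train) {
    dx <- channel_affine(dxhat, cache$istd, numeric(d[3]))
    return(list(dx = dx, dgamma = dgamma, dbeta = dbeta))
  }
  s1 <- channel_dot(dxhat, NULL)
  s2 <- channel_dot(dxhat, cache$xhat)
  corr <- channel_affine(cache$xhat, s2 / n_per, s1 / n_per)
  dx <- channel_affine(dxhat - corr, cache$istd, numeric(d[3]))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations ------------------------------------------------------------

relu_fw <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

#' Tanhshrink activation
#'
#' `tanhshrink(x) = x - tanh(x)`: near zero for small inputs, asymptotically
#' linear, and odd. Used as the output activation of the transform-domain
#' network to reduce bias at large positive and negative values.
#'
#' @param x numeric vector or array.
#' @return Same shape as `x`.
#' @export
tanhshrink <- function(x) x - tanh(x)

tanhshrink_bw <- function(dy, x) dy * tanh(x)^2

# ---- channel concatenation --------------------------------------------------

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2], da[4] == db[4])
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

split_channels <- function(dy, c1) {
  d <- dim(dy)
  list(
    a = dy[, , seq_len(c1), , drop = FALSE],
    b = dy[, , (c1 + 1):d[3], , drop = FALSE]
  )
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
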