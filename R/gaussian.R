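# Separable Gaussian blurs as explicit banded matrices with mirror boundary
# handling (reflection about the edge voxel). Building the 1D operator as a
# matrix keeps the blur exactly linear with an exact adjoint (the transpose),
# which the training loss needs for analytic gradients.

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Truncated, normalized 1D Gaussian tap weights for an odd kernel size.
gauss_taps <- function(size, fwhm) {
  stopifnot(size %% 2 == 1)
  r <- (size - 1) / 2
  k <- stats::dnorm(-r:r, sd = fwhm_to_sigma(fwhm))
  k / sum(k)
}

# n x n matrix applying the kernel along one axis, mirror boundary.
# The kernel is clipped to the axis (radius at most n - 1) and renormalized.
blur_matrix <- function(n, size, fwhm) {
  key <- sprintf("%d_%d_%g", n, size, fwhm)
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- min((size - 1) / 2, n - 1)
  k <- gauss_taps(2 * r + 1, fwhm)
  B <- matrix(0, n, n)
  for (off in -r:r) {
    j <- seq_len(n) + off
    j <- ifelse(j < 1, 2 - j, j)
    j <- ifelse(j > n, 2 * n - j, j)
    B[cbind(seq_len(n), j)] <- B[cbind(seq_len(n), j)] + k[off + r + 1]
  }
  .blur_cache[[key]] <- B
  B
}

.blur_cache <- new.env(parent = emptyenv())

# 3D separable blur of a Z x Y x X array (or one component of a 4D stack).
blur3d <- function(v, size, fwhm) {
  d <- dim(v)
  m <- blur_matrix(d[1], size, fwhm) %*% matrix(v, d[1], d[2] * d[3])
  v1 <- aperm(array(m, d), c(2, 1, 3))
  m <- blur_matrix(d[2], size, fwhm) %*% matrix(v1, d[2], d[1] * d[3])
  v2 <- aperm(array(m, c(d[2], d[1], d[3])), c(3, 2, 1))  # now X, Z, Y
  m <- blur_matrix(d[3], size, fwhm) %*% matrix(v2, d[3], d[1] * d[2])
  aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
}

# 2D separable blur of an H x W matrix (adjoint = blur2d with transposed
# operators; both operators are symmetric only away from edges, so the
# adjoint flag matters for exact gradients).
blur2d <- function(s, size, fwhm, adjoint = FALSE) {
  d <- dim(s)
  By <- blur_matrix(d[1], size, fwhm)
  Bx <- blur_matrix(d[2], size, fwhm)
  if (adjoint) t(By) %*% s %*% Bx else By %*% s %*% t(Bx)
}
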