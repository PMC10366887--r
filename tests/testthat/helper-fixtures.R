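# Shared fixtures and independent oracles, all generated in code.

# A small random spectral volume: smooth spatial structure plus optional
# white noise, so SVD components are non-degenerate.
make_test_volume <- function(seed = 1, d = c(8L, 16L, 16L, 4L), noise = 0.01) {
  withr::with_seed(seed, {
    z <- seq_len(d[1]); y <- seq_len(d[2]); x <- seq_len(d[3])
    base <- outer(outer(sin(z / 2), cos(y / 3)), sin(x / 4) + 1.5)
    arr <- array(0, d)
    for (e in seq_len(d[4])) {
      arr[, , , e] <- 0.2 + 0.1 * e / d[4] * (base + 2) +
        stats::rnorm(prod(d[1:3]), 0, noise)
    }
    spectral_volume(arr, energies = seq_len(d[4]) * 10 + 15)
  })
}

small_phantom <- function(shape = c(12L, 24L, 24L),
                          materials = c("I", "Gd")) {
  vial_phantom_template(shape, materials = materials)
}

# Brute-force multi-energy NLM: plain quadruple loop, mirror padding via
# index arithmetic, written independently of the compiled implementation.
nlm_oracle <- function(stack, out_z, search_r, patch_r, h, sigma) {
  d <- dim(stack)
  Z <- d[1]; Y <- d[2]; X <- d[3]; E <- d[4]
  mir <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  pn <- (2 * patch_r + 1)^3
  patch <- function(z, y, x, e) {
    v <- numeric(pn)
    k <- 1
    for (dx in -patch_r:patch_r)
      for (dy in -patch_r:patch_r)
        for (dz in -patch_r:patch_r) {
          v[k] <- stack[mir(z + dz, Z), mir(y + dy, Y), mir(x + dx, X), e]
          k <- k + 1
        }
    v
  }
  out <- array(0, c(Y, X, E))
  for (x in seq_len(X)) {
    for (y in seq_len(Y)) {
      p0 <- lapply(seq_len(E), function(e) patch(out_z, y, x, e))
      wsum <- 0
      acc <- numeric(E)
      for (xj in max(1, x - search_r):min(X, x + search_r))
        for (yj in max(1, y - search_r):min(Y, y + search_r))
          for (zj in max(1, out_z - search_r):min(Z, out_z + search_r)) {
            expo <- 0
            for (e in seq_len(E)) {
              de <- sum((p0[[e]] - patch(zj, yj, xj, e))^2)
              expo <- expo + de / (2 * h^2 * sigma[e]^2 * pn)
            }
            w <- exp(-expo)
            wsum <- wsum + w
            for (e in seq_len(E)) acc[e] <- acc[e] + w * stack[zj, yj, xj, e]
          }
      out[y, x, ] <- acc / wsum
    }
  }
  out
}

# Exhaustive-subset non-negative least squares: minimize ||c M - x|| over all
# material subsets whose unconstrained solution is feasible (c >= 0), the
# empty subset included. This is the global NNLS optimum for small m.
nnls_subset_oracle <- function(x, M) {
  m <- nrow(M)
  best <- rep(0, m)
  best_r <- sum(x^2)
  for (size in seq_len(m)) {
    for (sub in utils::combn(m, size, simplify = FALSE)) {
      Ms <- M[sub, , drop = FALSE]
      cs <- tryCatch(
        solve(Ms %*% t(Ms), Ms %*% x),
        error = function(e) NULL
      )
      if (is.null(cs) || any(cs < 0)) next
      r <- sum((x - t(Ms) %*% cs)^2)
      if (r < best_r - 1e-12) {
        best_r <- r
        best <- rep(0, m)
        best[sub] <- cs
      }
    }
  }
  best
}

# Finite-difference gradient of a scalar function at x (central differences).
num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
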