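make_toy_state <- function(E = 4, d = c(1L, 2L, 2L, 4L), seed = 21) {
  withr::with_seed(seed, {
    v <- qr.Q(qr(matrix(rnorm(E * E), E, E)))  # orthonormal
    structure(list(
      variances = runif(E, 0.5, 2),
      d = sort(runif(E, 0.5, 3), decreasing = TRUE),
      v = v,
      lowpass = array(rnorm(prod(d), 0, 0.1), d),
      scales = runif(E, 0.5, 1.5),
      dim = d, blur_size = 19L, blur_fwhm = 5,
      energies = seq_len(E), voxel_size = 1
    ), class = "u_transform_state")
  })
}

toy_M <- function() {
  M <- build_sensitivity_matrix(c("water", "I", "Gd", "Ta"))
  M
}

test_that("sensitivity rescaling multiplies rows by vial concentrations", {
  M <- toy_M()
  ones <- setNames(rep(1, 4), M$materials)
  expect_equal(rescale_sensitivity(M, ones)$mat, M$mat)

  conc <- setNames(c(1, 5, 10, 2), M$materials)
  Mr <- rescale_sensitivity(M, conc)
  expect_equal(Mr$mat["I", ], 5 * M$mat["I", ])
  expect_equal(Mr$mat["water", ], M$mat["water", ])

  # decomposition with the rescaled matrix divides each map by its
  # concentration: C X(Mr)^-1 = C(X)M^-1 / conc
  vol <- make_test_volume(22, c(2L, 4L, 4L, 4L))
  C0 <- unclass(decompose(vol, M))
  Cr <- unclass(decompose(vol, Mr))
  for (i in 1:4) {
    expect_equal(Cr[, , , i], C0[, , , i] / conc[i], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }

  expect_error(rescale_sensitivity(M, conc[1:3]), "missing|every material")
})

test_that("mse loss matches a brute-force sum", {
  a <- array(c(1, 2, 3), c(1, 1, 3, 1))
  b <- array(c(2, 2, 5), c(1, 1, 3, 1))
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(a + 0.5, a), 0.25)
  expect_equal(mse_loss(a, b), ((1 - 2)^2 + 0 + (3 - 5)^2) / 3)
})

test_that("the four-term loss equals a hand computation on a toy slice", {
  E <- 4
  st <- make_toy_state()
  cfg <- loss_config(toy_M())
  dU <- c(2L, 2L, E, 1L)
  U_pred <- withr::with_seed(23, array(rnorm(prod(dU), 0, 0.3), dU))
  U_label <- withr::with_seed(24, array(rnorm(prod(dU), 0, 0.3), dU))

  got <- unetu_loss(U_pred, U_label, st, slices = 1L, cfg = cfg)

  # independent scalar computation ------------------------------------------
  invert <- function(U) {
    up <- matrix(0, 4, E)   # voxels x components, voxel order (y, x)
    for (k in seq_len(E)) {
      up[, k] <- as.vector(U[, , k, 1]) * st$scales[k] +
        as.vector(st$lowpass[1, , , k])
    }
    A <- up %*% diag(st$d) %*% t(st$v)
    A %*% diag(st$variances)
  }
  Xp <- invert(U_pred)
  Xl <- invert(U_label)
  t1 <- sum((Xp - Xl)^2) / length(Xp)
  t2 <- sum((U_pred - U_label)^2) / length(U_pred)
  Mr <- diag(c(1, 10, 10, 10)) %*% toy_M()$mat  # default vial concentrations
  Cd <- (Xp - Xl) %*% solve(Mr)
  t3 <- sum(Cd^2) / length(Cd)
  # mirror-boundary Gaussian blur on a 2x2 slice, computed from first
  # principles (kernel clipped to radius 1)
  sig <- 5 / (2 * sqrt(2 * log(2)))
  k <- dnorm(-1:1, sd = sig); k <- k / sum(k)
  B <- matrix(0, 2, 2)
  for (i in 1:2) for (off in -1:1) {
    j <- i + off
    if (j < 1) j <- 2 - j
    if (j > 2) j <- 4 - j
    B[i, j] <- B[i, j] + k[off + 2]
  }
  t4 <- 0
  for (e in seq_len(E)) {
    Dslice <- matrix(Xp[, e] - Xl[, e], 2, 2)
    t4 <- t4 + sum((B %*% Dslice %*% t(B))^2)
  }
  t4 <- t4 / (4 * E)
  expected <- t1 + 15 * t2 + 0.2 * t3 + t4

  expect_equal(as.numeric(got), expected, tolerance = 1e-7)
  terms <- attr(got, "terms")
  expect_equal(unname(terms), c(t1, t2, t3, t4), tolerance = 1e-7)
  # the weighted term sum reproduces the scalar
  expect_equal(as.numeric(got),
               terms[["recon"]] + 15 * terms[["transform"]] +
                 0.2 * terms[["decomposition"]] + terms[["blur"]],
               tolerance = 1e-9)
})

test_that("the loss vanishes iff prediction equals label", {
  st <- make_toy_state(d = c(2L, 4L, 4L, 4L), seed = 31)
  cfg <- loss_config(toy_M())
  U <- withr::with_seed(32, array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2)))
  same <- unetu_loss(U, U, st, slices = c(1L, 2L), cfg = cfg)
  expect_equal(as.numeric(same), 0)
  other <- U + 0.01
  expect_gt(as.numeric(unetu_loss(U, other, st, slices = c(1L, 2L), cfg = cfg)), 0)
})

test_that("zero weights reduce the loss to its reconstruction terms", {
  st <- make_toy_state(d = c(1L, 4L, 4L, 4L), seed = 41)
  cfg0 <- loss_config(toy_M(), lambda1 = 0, lambda2 = 0)
  U_pred <- withr::with_seed(42, array(rnorm(4 * 4 * 4), c(4, 4, 4, 1)))
  U_label <- withr::with_seed(43, array(rnorm(4 * 4 * 4), c(4, 4, 4, 1)))
  l <- unetu_loss(U_pred, U_label, st, slices = 1L, cfg = cfg0)
  terms <- attr(l, "terms")
  expect_equal(as.numeric(l), terms[["recon"]] + terms[["blur"]])
})

test_that("analytic loss gradients match finite differences", {
  st <- make_toy_state(d = c(2L, 4L, 4L, 4L), seed = 51)
  cfg <- loss_config(toy_M())
  dU <- c(4L, 4L, 4L, 2L)
  U_pred <- withr::with_seed(52, array(rnorm(prod(dU), 0, 0.3), dU))
  U_label <- withr::with_seed(53, array(rnorm(prod(dU), 0, 0.3), dU))
  signs <- withr::with_seed(54, matrix(sample(c(-1, 1), 4 * 2, TRUE), 4, 2))

  r <- unetu_loss(U_pred, U_label, st, slices = c(2L, 1L), cfg = cfg,
                  signs = signs, grad = TRUE)
  f <- function(U) as.numeric(unetu_loss(U, U_label, st, slices = c(2L, 1L),
                                         cfg = cfg, signs = signs))
  withr::with_seed(55, {
    for (i in sample.int(length(U_pred), 12)) {
      eps <- 1e-6
      up <- U_pred; up[i] <- up[i] + eps
      um <- U_pred; um[i] <- um[i] - eps
      fd <- (f(up) - f(um)) / (2 * eps)
      expect_equal(r$grad[i], fd, tolerance = 1e-3)
    }
  })
})
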