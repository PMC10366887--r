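test_that("decompose exactly inverts compose for square invertible M", {
  M <- build_sensitivity_matrix(c("water", "I", "Gd", "Ta"))
  spec <- small_phantom(c(6L, 20L, 20L), materials = c("I", "Gd", "Ta"))
  ph <- compose_phantom(spec, M)
  C <- decompose(ph$volume, M)
  denom <- max(abs(unclass(ph$maps)))
  expect_lt(max(abs(unclass(C) - unclass(ph$maps))) / denom, 1e-10)
})

test_that("decompose handles identity, zero, and overdetermined systems", {
  Mi <- sensitivity_matrix(diag(3), materials = c("a", "b", "c"))
  vol <- make_test_volume(2, c(3L, 6L, 6L, 3L))
  C <- decompose(vol, Mi)
  expect_equal(unclass(C), unclass(vol), ignore_attr = TRUE)

  zero <- spectral_volume(array(0, c(2, 4, 4, 3)))
  expect_true(all(decompose(zero, Mi) == 0))

  # overdetermined: 2 materials, 3 energies, least squares recovers exactly
  # on noiseless data
  M2 <- build_sensitivity_matrix(c("water", "I"), c(25, 34, 51))
  maps <- material_maps(array(runif(2 * 4 * 4 * 2), c(2, 4, 4, 2)),
                        c("water", "I"))
  X <- compose(maps, M2)
  expect_equal(unclass(decompose(X, M2)), unclass(maps), tolerance = 1e-10,
               ignore_attr = TRUE)

  # rank-deficient matrix is rejected
  Mr <- sensitivity_matrix(rbind(c(1, 2, 3), c(2, 4, 6)), c("a", "b"))
  expect_error(decompose(X, Mr), "rank-deficient")
})

test_that("non-negative decomposition matches the exhaustive subset oracle", {
  M <- build_sensitivity_matrix(c("water", "I", "Gd", "Ta"))
  set.seed(31)
  n <- 400
  # random voxels, many of which violate non-negativity when unconstrained
  Ctrue <- cbind(runif(n, 0, 1), matrix(runif(3 * n, -2, 8), n, 3))
  X <- Ctrue %*% M$mat + matrix(rnorm(n * 4, 0, 0.02), n, 4)
  vol <- spectral_volume(array(X, c(n, 1, 1, 4)))

  C <- decompose_nonneg(vol, M)
  expect_true(all(C >= 0))

  Cm <- matrix(unclass(C), n, 4)
  for (i in seq_len(n)) {
    expect_equal(Cm[i, ], nnls_subset_oracle(X[i, ], M$mat),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }

  # voxels already feasible are untouched
  Cun <- matrix(unclass(decompose(vol, M)), n, 4)
  ok <- rowSums(Cun < 0) == 0
  expect_true(any(ok))
  expect_equal(Cm[ok, ], Cun[ok, ], tolerance = 1e-12)
})

test_that("non-negative decomposition agrees with an independent NNLS solver", {
  skip_if_not_installed("pracma")
  M <- build_sensitivity_matrix(c("water", "I", "Gd"), c(25, 34, 51))
  set.seed(7)
  X <- matrix(rnorm(50 * 3, 0.1, 0.2), 50, 3)
  vol <- spectral_volume(array(X, c(50, 1, 1, 3)))
  C <- matrix(unclass(decompose_nonneg(vol, M)), 50, 3)
  for (i in 1:50) {
    ref <- pracma::lsqnonneg(t(M$mat), X[i, ])$x
    expect_equal(C[i, ], ref, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("sensitivity calibration recovers the true matrix from vials", {
  M <- build_sensitivity_matrix(c("water", "I", "Gd"), c(25, 34, 51))
  shp <- c(10L, 32L, 32L)
  spec <- phantom_spec(shp, objects = list(
    list(shape = "cylinder", center = c(5.5, 10, 10), radii = c(4, 3, 3),
         material = "I", concentration = 8),
    list(shape = "cylinder", center = c(5.5, 22, 22), radii = c(4, 3, 3),
         material = "Gd", concentration = 12)
  ))
  ph <- compose_phantom(spec, M)
  rois <- list(
    roi_spec(c(10, 10), 2.5, c(3, 8), material = "I", concentration = 8),
    roi_spec(c(22, 22), 2.5, c(3, 8), material = "Gd", concentration = 12)
  )
  water_roi <- roi_spec(c(10, 22), 3, c(3, 8))

  fit <- fit_sensitivity(ph$volume, rois, water_roi)
  expect_equal(fit$materials, c("water", "I", "Gd"))
  rel <- max(abs(fit$mat - M$mat[fit$materials, ]) / M$mat[fit$materials, ])
  expect_lt(rel, 1e-8)

  # single vial at concentration c with attenuation a above water: slope a/c
  vol <- ph$volume
  one <- fit_sensitivity(vol, rois[1], water_roi)
  expect_equal(
    one$mat["I", ],
    (unetu:::roi_stats(vol, rois[[1]])$mean -
       unetu:::roi_stats(vol, water_roi)$mean) / 8,
    ignore_attr = TRUE
  )
})

test_that("noisy calibration stays within three standard errors", {
  M <- build_sensitivity_matrix(c("water", "I"), c(25, 34))
  shp <- c(8L, 24L, 24L)
  spec <- phantom_spec(shp, objects = list(
    list(shape = "cylinder", center = c(4.5, 8, 8), radii = c(3.5, 4, 4),
         material = "I", concentration = 10)
  ))
  ph <- compose_phantom(spec, M)
  rois <- list(roi_spec(c(8, 8), 3, c(2, 7), material = "I", concentration = 10))
  water_roi <- roi_spec(c(16, 16), 4, c(2, 7))
  sd_n <- 0.01
  n_roi <- length(unetu:::roi_indices(shp, rois[[1]]))
  # slope = (mean_vial - mean_water)/c: se = sd * sqrt(1/n1 + 1/n2) / c
  n_w <- length(unetu:::roi_indices(shp, water_roi))
  se <- sd_n * sqrt(1 / n_roi + 1 / n_w) / 10
  ests <- sapply(1:50, function(s) {
    noisy <- add_noise(ph$volume, noise_spec(c(sd_n, sd_n), seed = s))
    fit_sensitivity(noisy, rois, water_roi)$mat["I", ]
  })
  err <- rowMeans(ests) - M$mat["I", ]
  expect_true(all(abs(err) < 3 * se / sqrt(50)))
})

test_that("calibration is invariant to ROI voxel ordering and validates input", {
  M <- build_sensitivity_matrix(c("water", "I"), c(25, 34))
  ph <- compose_phantom(phantom_spec(c(4L, 12L, 12L)), M)
  expect_error(
    fit_sensitivity(ph$volume,
                    list(roi_spec(c(6, 6), 2, c(1, 4), "I", 0)),
                    roi_spec(c(6, 6), 2, c(1, 4))),
    "all-zero"
  )
  expect_error(unetu:::roi_stats(ph$volume, roi_spec(c(2, 2), 4, c(1, 4))),
               "outside")
})

test_that("colorized composites blend maps additively with clipping", {
  maps <- material_maps(array(0, c(1, 4, 4, 2)), c("I", "Gd"))
  cols <- c(I = "red", Gd = "green")
  img <- colorize_maps(maps, cols)
  expect_true(all(img == 0))

  m2 <- unclass(maps)
  m2[1, , , 1] <- 5
  img2 <- colorize_maps(material_maps(m2, c("I", "Gd")), cols)
  expect_equal(img2[, , 1], matrix(1, 4, 4))
  expect_true(all(img2[, , 2:3] == 0))

  # overlapping maps: per-pixel additive blend, clipped at 1
  m3 <- unclass(maps)
  m3[1, 1, 1, 1] <- 1; m3[1, 1, 1, 2] <- 1
  img3 <- colorize_maps(material_maps(m3, c("I", "Gd")), cols,
                        max_conc = c(I = 2, Gd = 2))
  expect_equal(img3[1, 1, ], c(0.5, 0.5, 0), ignore_attr = TRUE)
})
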