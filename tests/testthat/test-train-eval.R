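test_that("plateau scheduler halves after exactly 10 flat epochs", {
  cfg <- train_config()
  s <- unetu:::sched_init(2e-4, cfg)
  lrs <- numeric(11)
  halved_at <- integer(0)
  vals <- c(1, rep(1, 10))  # one improvement, then flat for exactly 10
  for (i in seq_along(vals)) {
    up <- unetu:::sched_update(s, vals[i])
    s <- up$state
    lrs[i] <- s$lr
    if (up$halved) halved_at <- c(halved_at, i)
  }
  expect_identical(halved_at, 11L)
  expect_equal(lrs[10], 2e-4)
  expect_equal(lrs[11], 1e-4)
})

test_that("early stopping fires after exactly 20 flat epochs", {
  cfg <- train_config()
  s <- unetu:::sched_init(2e-4, cfg)
  stopped_at <- NA
  for (i in 1:40) {
    up <- unetu:::sched_update(s, if (i == 1) 1 else 1)
    s <- up$state
    if (up$stop) { stopped_at <- i; break }
  }
  expect_identical(stopped_at, 21L)
  # two halvings happened on the way (after epochs 11 and 21)
  expect_equal(s$lr, 2e-4 / 4)
})

test_that("improvements reset both scheduler counters", {
  cfg <- train_config()
  s <- unetu:::sched_init(1e-3, cfg)
  vals <- c(1, rep(1, 9), 0.9, rep(0.9, 9), 0.8)  # improves at 11 and 21
  any_halved <- FALSE
  any_stop <- FALSE
  for (v in vals) {
    up <- unetu:::sched_update(s, v)
    s <- up$state
    any_halved <- any_halved || up$halved
    any_stop <- any_stop || up$stop
  }
  expect_false(any_halved)
  expect_false(any_stop)
  expect_equal(s$lr, 1e-3)
})

test_that("splits hold out one whole volume and shuffle deterministically", {
  vols <- lapply(1:10, function(i) list(noisy = array(0, c(5, 4, 4, 2))))
  sp <- make_splits(vols, seed = 3)
  expect_equal(sort(unique(sp$train$vol)), 1:9)
  expect_equal(unique(sp$val$vol), 10L)
  expect_equal(nrow(sp$train), 45)
  expect_equal(nrow(sp$val), 5)
  expect_identical(make_splits(vols, seed = 3), sp)
  expect_false(identical(make_splits(vols, seed = 4)$train, sp$train))
  # no slice in both splits
  key <- function(df) paste(df$vol, df$z)
  expect_length(intersect(key(sp$train), key(sp$val)), 0)
})

test_that("flip augmentation applies identically to input and label", {
  x <- array(1:8, c(2, 2, 2))
  y <- x + 100
  a <- augment_flip(x, y, TRUE, TRUE)
  expect_equal(a$x, x[2:1, 2:1, ])
  expect_equal(a$y, y[2:1, 2:1, ])
  # double flip = identity
  b <- augment_flip(a$x, a$y, TRUE, TRUE)
  expect_equal(b$x, x)
  expect_equal(b$y, y)
})

test_that("augmentation draws flips at the configured frequency", {
  vol <- array(0, c(2, 2, 2, 1))
  vol[1, , , 1] <- matrix(c(1, 2, 3, 4), 2, 2)
  vol[2, , , 1] <- matrix(c(1, 2, 3, 4), 2, 2)
  payload <- list(list(noisy = vol, clean = vol))
  n <- 10000L
  items <- data.frame(vol = 1L, z = rep(1L, n))
  cfg <- train_config(seed = 5)
  batch <- withr::with_seed(6, unetu:::make_batch(payload, items, cfg, "mse",
                                                  augmented = TRUE))
  ref <- vol[1, , , 1]
  counts <- c(fy = 0, fx = 0)
  for (i in seq_len(n)) {
    s <- batch$x[, , 1, i]
    if (!isTRUE(all.equal(s[, 1], ref[, 1])) &&
        isTRUE(all.equal(s, ref[2:1, ]))) counts["fy"] <- counts["fy"] + 1
    if (isTRUE(all.equal(s, ref[, 2:1]))) counts["fx"] <- counts["fx"] + 1
    if (isTRUE(all.equal(s, ref[2:1, 2:1]))) {
      counts <- counts + 1
    }
  }
  expect_true(all(abs(counts / n - 0.5) < 0.02))
})

test_that("sign-flip augmentation draws at the configured frequency", {
  st <- structure(list(dim = c(1L, 4L, 4L, 2L)), class = "u_transform_state")
  payload <- list(list(
    U_in = array(0, c(1, 4, 4, 2)), U_label = array(0, c(1, 4, 4, 2)),
    state = st
  ))
  n <- 5000L
  items <- data.frame(vol = 1L, z = rep(1L, n))
  cfg <- train_config(seed = 7)
  batch <- withr::with_seed(8, unetu:::make_batch(payload, items, cfg, "unetu",
                                                  augmented = TRUE))
  frac <- rowMeans(batch$signs == -1)
  expect_true(all(abs(frac - 0.5) < 0.02))
})

test_that("a short training run reduces the loss and returns curves", {
  M <- build_sensitivity_matrix(c("water", "I"), c(25, 34))
  vols <- lapply(1:2, function(i) {
    ph <- compose_phantom(small_phantom(c(4L, 16L, 16L), materials = "I"), M)
    noisy <- add_noise(ph$volume, noise_spec(c(0.03, 0.04), seed = i))
    list(noisy = unclass(noisy), clean = unclass(ph$volume))
  })
  net <- build_unet(net_config(levels = 2, base = 4, in_ch = 2, out_ch = 2,
                               residual = TRUE), seed = 9)
  cfg <- train_config(max_epochs = 4, batch_size = 4, lr = 1e-3, seed = 10)
  fit <- train(net, vols, cfg, loss = "mse")
  expect_s3_class(fit$curves, "data.frame")
  expect_equal(fit$epochs, 4)
  expect_lt(tail(fit$curves$train_loss, 1), fit$curves$train_loss[1])
})

test_that("transform-domain training runs end to end on a tiny set", {
  M <- build_sensitivity_matrix(c("water", "I"), c(25, 34))
  vols <- lapply(1:2, function(i) {
    ph <- compose_phantom(small_phantom(c(4L, 16L, 16L), materials = "I"), M)
    noisy <- add_noise(ph$volume, noise_spec(c(0.03, 0.04), seed = 20 + i))
    ft <- forward_transform(noisy)
    list(U_in = ft$U, U_label = project_label(ph$volume, ft$state),
         state = ft$state)
  })
  net <- build_unet(net_config(levels = 2, base = 4, in_ch = 2, out_ch = 2,
                               activation = "tanhshrink"), seed = 11)
  cfg <- train_config(max_epochs = 3, batch_size = 4, lr = 1e-3, seed = 12)
  fit <- train(net, vols, cfg, loss = "unetu", loss_cfg = loss_config(M))
  expect_equal(fit$epochs, 3)
  expect_true(all(is.finite(fit$curves$val_loss)))
})

test_that("HU conversion anchors at water", {
  w <- c(0.4, 0.3)
  vol <- spectral_volume(array(rep(c(0.4, 0.3), each = 8), c(2, 2, 2, 2)))
  hu <- attenuation_to_hu(vol, w)
  expect_true(all(abs(hu) < 1e-12))
  zero <- spectral_volume(array(0, c(2, 2, 2, 2)))
  expect_true(all(attenuation_to_hu(zero, w) == -1000))
  dbl <- spectral_volume(array(rep(c(0.8, 0.6), each = 8), c(2, 2, 2, 2)))
  expect_true(all(attenuation_to_hu(dbl, w) == 1000))
})

test_that("ROI bias and noise match a hand computation", {
  d <- c(2L, 4L, 4L, 1L)
  ref <- array(0.32, d)
  den <- array(0.32, d)
  # perturb the ROI voxels of the denoised copy with known values
  roi <- roi_spec(c(2.5, 2.5), 1.6, c(1, 2))
  idx <- unetu:::roi_indices(d[1:3], roi)
  vals <- seq(0.30, 0.34, length.out = length(idx))
  den[idx] <- vals
  r <- roi_bias_noise(spectral_volume(den), spectral_volume(ref), roi,
                      water_mu = 0.32)
  expect_equal(r$bias, abs(mean(vals) - 0.32) / 0.32 * 1000)
  expect_equal(r$noise, sd(vals) / 0.32 * 1000)

  same <- roi_bias_noise(spectral_volume(ref), spectral_volume(ref), roi, 0.32)
  expect_equal(same$bias, 0)
  expect_equal(same$noise, 0)
})

test_that("volume RMSE in HU matches brute-force computation", {
  w <- 0.25
  a <- spectral_volume(array(c(0.25, 0.26, 0.24, 0.25), c(1, 2, 2, 1)))
  b <- spectral_volume(array(0.25, c(1, 2, 2, 1)))
  expect_equal(rmse_hu(a, a, w), 0)
  hu_err <- 1000 * c(0, 0.01, -0.01, 0) / w
  expect_equal(rmse_hu(a, b, w), sqrt(mean(hu_err^2)))
  # constant offset: RMSE equals the offset in HU
  off <- spectral_volume(unclass(b) + 0.025)
  expect_equal(rmse_hu(off, b, w), 100)
})

test_that("per-material map RMSE is computed per map", {
  m1 <- material_maps(array(0, c(1, 2, 2, 2)), c("water", "I"))
  m2 <- unclass(m1)
  m2[, , , 2] <- 0.5
  r <- rmse_maps(material_maps(m2, c("water", "I")), m1)
  expect_equal(r, c(water = 0, I = 0.5))
})

test_that("SSIM and PSNR behave like fidelity metrics", {
  img <- withr::with_seed(71, matrix(runif(64 * 64), 64, 64))
  expect_equal(ssim_psnr(img, img), c(ssim = 1, psnr = Inf))

  noisy <- img + withr::with_seed(72, matrix(rnorm(64 * 64, 0, 0.1), 64, 64))
  r <- ssim_psnr(noisy, img)
  expect_lt(r[["ssim"]], 1)
  expect_gt(r[["ssim"]], 0)
  # SSIM is symmetric in its arguments (given the same data range)
  rng <- diff(range(img))
  expect_equal(ssim_psnr(noisy, img, rng)[["ssim"]],
               ssim_psnr(img, noisy, rng)[["ssim"]], tolerance = 1e-12)

  # PSNR hand computation on a 2x2 toy
  a <- matrix(c(0, 1, 0.5, 0.25), 2, 2)
  b <- matrix(c(0, 1, 0.25, 0.25), 2, 2)
  mse <- mean((a - b)^2)
  expect_equal(ssim_psnr(a, b)[["psnr"]], 10 * log10(1 / mse))

  # more noise, lower both metrics
  worse <- img + withr::with_seed(73, matrix(rnorm(64 * 64, 0, 0.3), 64, 64))
  r2 <- ssim_psnr(worse, img)
  expect_lt(r2[["ssim"]], r[["ssim"]])
  expect_lt(r2[["psnr"]], r[["psnr"]])
})
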