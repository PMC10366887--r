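#' Training protocol and evaluation metrics
#'
#' Supervised training of the denoising networks: one whole volume held out
#' for validation, slices shuffled, random horizontal/vertical flips (and,
#' for the transform-domain network, random sign flips of singular-vector
#' components), Adam optimization, a plateau scheduler that halves the
#' learning rate after 10 epochs without a new validation-loss minimum, and
#' early stopping after 20; the best-validation parameters are restored.
#' Evaluation covers water-ROI bias/noise in Hounsfield units, RMSE against
#' a reference reconstruction, and SSIM/PSNR on slices.
#'
#' @name train_eval
NULL

#' Training configuration
#'
#' Defaults follow the training protocol for the full-scale networks; reduce
#' `max_epochs` for desk-scale CPU runs.
#'
#' @param max_epochs maximum training epochs (default 2000).
#' @param batch_size slices per optimization step (default 8).
#' @param lr initial Adam learning rate (default 2e-4).
#' @param plateau_patience epochs without a new validation minimum before the
#'   learning rate is halved (default 10).
#' @param plateau_factor multiplicative factor at each halving (default 0.5).
#' @param early_stop_patience epochs without a new validation minimum before
#'   training stops (default 20).
#' @param flip_prob probability of each of the horizontal/vertical flips.
#' @param sign_flip_prob probability of flipping each singular-vector
#'   component (transform-domain training only).
#' @param seed RNG seed controlling shuffling, augmentation and
#'   initialization.
#' @return A `train_config` object.
#' @export
train_config <- function(max_epochs = 2000L, batch_size = 8L, lr = 2e-4,
                         plateau_patience = 10L, plateau_factor = 0.5,
                         early_stop_patience = 20L, flip_prob = 0.5,
                         sign_flip_prob = 0.5, seed = 1L) {
  stopifnot(
    plateau_patience > 0, early_stop_patience > 0,
    early_stop_patience >= plateau_patience, lr > 0, batch_size >= 1
  )
  structure(list(
    max_epochs = as.integer(max_epochs), batch_size = as.integer(batch_size),
    lr = lr, plateau_patience = as.integer(plateau_patience),
    plateau_factor = plateau_factor,
    early_stop_patience = as.integer(early_stop_patience),
    flip_prob = flip_prob, sign_flip_prob = sign_flip_prob,
    seed = as.integer(seed)
  ), class = "train_config")
}

# ---- scheduler / early stopping --------------------------------------------
# "fails to decrease" = no new strict running minimum; plateau and stop
# counters run concurrently; the plateau counter resets after each halving.

sched_init <- function(lr, cfg) {
  list(
    lr = lr, best = Inf, plateau = 0L, since_best = 0L,
    plateau_patience = cfg$plateau_patience, factor = cfg$plateau_factor,
    stop_patience = cfg$early_stop_patience
  )
}

sched_update <- function(s, val_loss) {
  halved <- FALSE
  if (val_loss < s$best) {
    s$best <- val_loss
    s$plateau <- 0L
    s$since_best <- 0L
    improved <- TRUE
  } else {
    s$plateau <- s$plateau + 1L
    s$since_best <- s$since_best + 1L
    improved <- FALSE
    if (s$plateau >= s$plateau_patience) {
      s$lr <- s$lr * s$factor
      s$plateau <- 0L
      halved <- TRUE
    }
  }
  list(state = s, improved = improved, halved = halved,
       stop = s$since_best >= s$stop_patience)
}

#' Split paired volumes into training and validation slice sets
#'
#' Holds out one whole volume for validation and shuffles the remaining
#' slices deterministically.
#'
#' @param volumes list of paired volumes (any per-volume payload).
#' @param val_index which volume to hold out (default: the last).
#' @param seed shuffle seed.
#' @return List with `train` and `val` data frames of `(vol, z)` slice
#'   indices, and `val_index`.
#' @export
make_splits <- function(volumes, val_index = length(volumes), seed = 1L) {
  stopifnot(length(volumes) >= 2, val_index >= 1, val_index <= length(volumes))
  nz <- vapply(volumes, function(v) dim(v$noisy %||% v[[1]])[1], 0)
  items <- do.call(rbind, lapply(seq_along(volumes), function(i) {
    data.frame(vol = i, z = seq_len(nz[i]))
  }))
  train <- items[items$vol != val_index, ]
  val <- items[items$vol == val_index, ]
  with_local_seed(seed, {
    train <- train[sample.int(nrow(train)), ]
    val <- val[sample.int(nrow(val)), ]
  })
  rownames(train) <- NULL
  rownames(val) <- NULL
  list(train = train, val = val, val_index = val_index)
}

#' Flip augmentation for a paired slice
#'
#' Applies the same horizontal/vertical flips to input and label slice.
#'
#' @param x,y `Y x X x E` arrays (input and label).
#' @param flip_y,flip_x logical: flip along each in-plane axis.
#' @return List with flipped `x` and `y`.
#' @export
augment_flip <- function(x, y, flip_y, flip_x) {
  if (flip_y) {
    x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
    y <- y[rev(seq_len(dim(y)[1])), , , drop = FALSE]
  }
  if (flip_x) {
    x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
    y <- y[, rev(seq_len(dim(y)[2])), , drop = FALSE]
  }
  list(x = x, y = y)
}

# extract slice z of a [Z, Y, X, E] array as [Y, X, E]
get_slice <- function(vol, z) {
  d <- dim(vol)
  array(unclass(vol)[z, , , , drop = FALSE], d[2:4])
}

#' Train a denoising network
#'
#' Runs the full protocol on a prepared dataset. Two modes:
#' \describe{
#'   \item{`loss = "mse"`}{reconstruction-domain training (the residual
#'     baseline network): volumes provide `noisy` and `clean` spectral
#'     volumes, the loss is plain MSE.}
#'   \item{`loss = "unetu"`}{transform-domain training: volumes provide
#'     `U_in`, `U_label` and `state` (from [forward_transform()] /
#'     [project_label()]), the loss is the four-term [unetu_loss()] and sign
#'     flips augment the data.}
#' }
#'
#' @param net a `unet` from [build_unet()].
#' @param volumes list of per-volume payloads (see above).
#' @param cfg a [train_config()].
#' @param loss `"mse"` or `"unetu"`.
#' @param loss_cfg a [loss_config()] (required for `"unetu"`).
#' @param val_index validation volume (default: last).
#' @param verbose print a line per epoch.
#' @return List with `net` (best-validation parameters), `curves` (data frame
#'   of per-epoch training/validation loss and learning rate), and `epochs`
#'   actually run.
#' @export
train <- function(net, volumes, cfg, loss = c("unetu", "mse"),
                  loss_cfg = NULL, val_index = length(volumes),
                  verbose = FALSE) {
  loss <- match.arg(loss)
  if (loss == "unetu" && is.null(loss_cfg)) stop("unetu loss needs a loss_config")
  splits <- make_splits(volumes, val_index, seed = cfg$seed)
  if (nrow(splits$train) == 0 || nrow(splits$val) == 0) stop("empty split")
  opt <- adam_init(net$params)
  sch <- sched_init(cfg$lr, cfg)
  curves <- data.frame()
  best_params <- net$params
  best_running <- net$running
  with_local_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(nrow(splits$train))
      tr_loss <- 0
      nb <- 0
      for (grp in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        batch <- make_batch(volumes, splits$train[grp, ], cfg, loss,
                            augmented = TRUE)
        fw <- unet_fw(net, batch$x, train = TRUE)
        net <- fw$net
        lb <- batch_loss(fw$y, batch, loss, loss_cfg, grad = TRUE)
        if (!is.finite(lb$loss)) {
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        }
        bw <- unet_bw(net, fw$caches, lb$grad)
        st <- adam_step(net$params, bw$grads, opt, sch$lr)
        net$params <- st$params
        opt <- st$state
        tr_loss <- tr_loss + lb$loss
        nb <- nb + 1
      }
      tr_loss <- tr_loss / nb
      val_loss <- evaluate_loss(net, volumes, splits$val, cfg, loss, loss_cfg)
      if (!is.finite(val_loss)) {
        stop(sprintf("non-finite validation loss at epoch %d", epoch))
      }
      up <- sched_update(sch, val_loss)
      sch <- up$state
      if (up$improved) {
        best_params <- net$params
        best_running <- net$running
      }
      curves <- rbind(curves, data.frame(
        epoch = epoch, train_loss = tr_loss, val_loss = val_loss, lr = sch$lr
      ))
      if (verbose) {
        message(sprintf("epoch %3d  train %.5g  val %.5g  lr %.3g",
                        epoch, tr_loss, val_loss, sch$lr))
      }
      if (up$stop) break
    }
  })
  net$params <- best_params
  net$running <- best_running
  list(net = net, curves = curves, epochs = nrow(curves))
}

# Assemble a [Y, X, E, B] input/label batch (with augmentation when training).
make_batch <- function(volumes, items, cfg, loss, augmented) {
  B <- nrow(items)
  v1 <- volumes[[items$vol[1]]]
  din <- if (loss == "unetu") dim(v1$U_in) else dim(v1$noisy)
  x <- array(0, c(din[2], din[3], din[4], B))
  y <- x
  signs <- matrix(1, din[4], B)
  states <- vector("list", B)
  for (i in seq_len(B)) {
    v <- volumes[[items$vol[i]]]
    z <- items$z[i]
    if (loss == "unetu") {
      xi <- get_slice(v$U_in, z)
      yi <- get_slice(v$U_label, z)
      states[[i]] <- v$state
    } else {
      xi <- get_slice(v$noisy, z)
      yi <- get_slice(v$clean, z)
    }
    if (augmented) {
      fl <- stats::runif(2) < cfg$flip_prob
      a <- augment_flip(xi, yi, fl[1], fl[2])
      xi <- a$x
      yi <- a$y
      if (loss == "unetu") {
        s <- ifelse(stats::runif(din[4]) < cfg$sign_flip_prob, -1, 1)
        signs[, i] <- s
        xi <- sweep(xi, 3, s, "*")
        yi <- sweep(yi, 3, s, "*")
      }
    }
    x[, , , i] <- xi
    y[, , , i] <- yi
  }
  list(x = x, y = y, signs = signs, states = states, slices = items$z)
}

batch_loss <- function(pred, batch, loss, loss_cfg, grad = FALSE) {
  if (loss == "mse") {
    l <- mse_loss(pred, batch$y)
    if (!grad) return(list(loss = l))
    return(list(loss = l, grad = 2 * (pred - batch$y) / length(pred)))
  }
  r <- unetu_loss(pred, batch$y, batch$states, batch$slices, loss_cfg,
                  signs = batch$signs, grad = grad)
  if (!grad) list(loss = as.numeric(r)) else r
}

evaluate_loss <- function(net, volumes, items, cfg, loss, loss_cfg) {
  total <- 0
  n <- 0
  for (grp in split(seq_len(nrow(items)),
                    ceiling(seq_len(nrow(items)) / cfg$batch_size))) {
    batch <- make_batch(volumes, items[grp, ], cfg, loss, augmented = FALSE)
    y <- unet_fw(net, batch$x, train = FALSE)$y
    total <- total + batch_loss(y, batch, loss, loss_cfg)$loss * length(grp)
    n <- n + length(grp)
  }
  total / n
}

# ---- metrics ----------------------------------------------------------------

#' Convert attenuation to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / mu_water` per energy, anchored at the
#' calibrated water attenuation for that energy.
#'
#' @param volume a [spectral_volume()] (or any `Z x Y x X x E` array).
#' @param water_mu per-energy water attenuation (cm^-1), e.g. the water row
#'   of a [sensitivity_matrix()].
#' @return Array of HU values, same shape.
#' @export
attenuation_to_hu <- function(volume, water_mu) {
  d <- dim(volume)
  stopifnot(length(water_mu) == d[4])
  out <- unclass(volume)
  for (e in seq_len(d[4])) {
    out[, , , e] <- 1000 * (out[, , , e] - water_mu[e]) / water_mu[e]
  }
  out
}

#' Water-ROI bias and noise in HU
#'
#' Bias: absolute difference between the ROI mean of the denoised volume and
#' of the reference (noisy) volume, per energy, in HU. Noise: the ROI
#' standard deviation of the denoised volume, per energy, in HU.
#'
#' @param denoised,reference [spectral_volume()]s on the same grid.
#' @param roi an [roi_spec()] inside a water vial.
#' @param water_mu per-energy water attenuation (cm^-1) anchoring the HU
#'   scale.
#' @return List with numeric vectors `bias` and `noise` (HU per energy).
#' @export
roi_bias_noise <- function(denoised, reference, roi, water_mu) {
  sd_ <- roi_stats(denoised, roi)
  sr <- roi_stats(reference, roi)
  list(
    bias = abs(sd_$mean - sr$mean) / water_mu * 1000,
    noise = sd_$sd / water_mu * 1000
  )
}

#' Volume RMSE in Hounsfield units
#'
#' Root mean square error between a volume and a reference, computed on the
#' HU scale per energy and averaged over energies.
#'
#' @inheritParams roi_bias_noise
#' @param volume the volume under test.
#' @return Scalar RMSE in HU.
#' @export
rmse_hu <- function(volume, reference, water_mu) {
  d <- dim(volume)
  per_e <- vapply(seq_len(d[4]), function(e) {
    dhu <- 1000 * (unclass(volume)[, , , e] - unclass(reference)[, , , e]) /
      water_mu[e]
    sqrt(mean(dhu^2))
  }, numeric(1))
  mean(per_e)
}

#' Per-material RMSE of decomposed maps
#'
#' @param maps,reference [material_maps()] on the same grid and materials.
#' @return Named numeric vector (g/mL for water, mg/mL otherwise).
#' @export
rmse_maps <- function(maps, reference) {
  d <- dim(maps)
  stats::setNames(vapply(seq_len(d[4]), function(i) {
    sqrt(mean((unclass(maps)[, , , i] - unclass(reference)[, , , i])^2))
  }, numeric(1)), attr(maps, "materials"))
}

#' SSIM and PSNR of a slice against a reference
#'
#' Structural similarity with an 11x11 Gaussian window (sigma 1.5,
#' k1 = 0.01, k2 = 0.03) and peak signal-to-noise ratio
#' `10 log10(range^2 / MSE)`. Identical images yield SSIM 1 and PSNR `Inf`.
#'
#' @param slice,reference 2D numeric matrices.
#' @param data_range intensity range spanned by the data; defaults to
#'   `max - min` of the reference.
#' @return Named numeric vector `c(ssim, psnr)`.
#' @export
ssim_psnr <- function(slice, reference, data_range = NULL) {
  stopifnot(identical(dim(slice), dim(reference)))
  if (identical(as.numeric(slice), as.numeric(reference))) {
    return(c(ssim = 1, psnr = Inf))
  }
  if (is.null(data_range)) data_range <- diff(range(reference))
  data_range <- max(data_range, .Machine$double.eps)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  win_fwhm <- 1.5 * 2 * sqrt(2 * log(2))
  g <- function(m) blur2d(m, 11L, win_fwhm)
  mu1 <- g(slice); mu2 <- g(reference)
  s11 <- g(slice^2) - mu1^2
  s22 <- g(reference^2) - mu2^2
  s12 <- g(slice * reference) - mu1 * mu2
  ssim_map <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
  mse <- mean((slice - reference)^2)
  c(ssim = mean(ssim_map), psnr = 10 * log10(data_range^2 / mse))
}
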