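#' Encoder-decoder (U-net) construction
#'
#' A 2D U-net with configurable depth: per level, `nconv` 3x3 convolutions
#' each followed by batch normalization and ReLU; 2x2 max pooling between
#' encoder levels; 2x2 transposed convolutions and skip-connection
#' concatenation in the decoder; a final 1x1 projection to the output
#' channels. Options: a residual input-to-output connection (the
#' reconstruction-domain baseline network) and a Tanhshrink output activation
#' (the transform-domain network).
#'
#' @name denoise_nets
NULL

#' Network configuration
#'
#' @param levels number of resolution levels (default 4).
#' @param nconv convolutions per level (default 2).
#' @param in_ch,out_ch input/output channel counts (default 4, matching four
#'   energy thresholds).
#' @param base filter count at the first level, doubling per level
#'   (default 64; reduce for desk-scale CPU work).
#' @param residual add the input to the output (identity shortcut).
#' @param activation output activation, `"identity"` or `"tanhshrink"`.
#' @param batchnorm include batch normalization after every convolution.
#' @return A `net_config` object.
#' @export
net_config <- function(levels = 4L, nconv = 2L, in_ch = 4L, out_ch = 4L,
                       base = 64L, residual = FALSE,
                       activation = c("identity", "tanhshrink"),
                       batchnorm = TRUE) {
  activation <- match.arg(activation)
  stopifnot(levels >= 1, nconv >= 1, in_ch >= 1, out_ch >= 1, base >= 1)
  if (residual && in_ch != out_ch) stop("residual connection needs in_ch == out_ch")
  structure(list(
    levels = as.integer(levels), nconv = as.integer(nconv),
    in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
    base = as.integer(base), residual = residual, activation = activation,
    batchnorm = batchnorm
  ), class = "net_config")
}

level_channels <- function(cfg) cfg$base * 2^(seq_len(cfg$levels) - 1)

#' Build a U-net with freshly initialized parameters
#'
#' Convolution weights use He initialization; batch-norm scale/shift start at
#' 1/0. Initialization is deterministic for a given seed.
#'
#' @param cfg a [net_config()].
#' @param seed integer seed for the initialization draw.
#' @return A `unet` object: `list(cfg, params, running)`.
#' @export
build_unet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  ch <- level_channels(cfg)
  params <- list()
  running <- list()
  add_conv <- function(name, k, cin, cout) {
    params[[paste0(name, "_w")]] <<-
      array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
            c(k, k, cin, cout))
    params[[paste0(name, "_b")]] <<- numeric(cout)
    if (cfg$batchnorm && !grepl("^(final|up)", name)) {
      params[[paste0(name, "_g")]] <<- rep(1, cout)
      params[[paste0(name, "_beta")]] <<- numeric(cout)
      running[[paste0(name, "_mean")]] <<- numeric(cout)
      running[[paste0(name, "_var")]] <<- rep(1, cout)
    }
  }
  with_local_seed(seed, {
    for (l in seq_len(cfg$levels - 1)) {
      cin <- if (l == 1) cfg$in_ch else ch[l - 1]
      for (j in seq_len(cfg$nconv)) {
        add_conv(sprintf("enc%d_c%d", l, j), 3,
                 if (j == 1) cin else ch[l], ch[l])
      }
    }
    cin <- if (cfg$levels == 1) cfg$in_ch else ch[cfg$levels - 1]
    for (j in seq_len(cfg$nconv)) {
      add_conv(sprintf("bot_c%d", j), 3,
               if (j == 1) cin else ch[cfg$levels], ch[cfg$levels])
    }
    for (l in rev(seq_len(cfg$levels - 1))) {
      up_cin <- if (l == cfg$levels - 1) ch[cfg$levels] else ch[l + 1]
      params[[sprintf("up%d_w", l)]] <-
        array(stats::rnorm(2 * 2 * up_cin * ch[l], 0, sqrt(2 / (4 * up_cin))),
              c(2, 2, up_cin, ch[l]))
      params[[sprintf("up%d_b", l)]] <- numeric(ch[l])
      for (j in seq_len(cfg$nconv)) {
        add_conv(sprintf("dec%d_c%d", l, j), 3,
                 if (j == 1) 2 * ch[l] else ch[l], ch[l])
      }
    }
    add_conv("final", 1, ch[1], cfg$out_ch)
    # residual nets start as the identity: zero head, shortcut carries the
    # input through, and the branch learns the correction
    if (cfg$residual) params$final_w[] <- 0
  })
  structure(list(cfg = cfg, params = params, running = running),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  cat(sprintf(
    "<unet> %d levels, %d conv/level, %d -> %d channels, base %d, %s%s%d parameters\n",
    x$cfg$levels, x$cfg$nconv, x$cfg$in_ch, x$cfg$out_ch, x$cfg$base,
    if (x$cfg$residual) "residual, " else "",
    if (x$cfg$activation == "tanhshrink") "tanhshrink, " else "",
    count_params(x)
  ))
  invisible(x)
}

#' Total trainable parameter count
#' @param net a `unet`.
#' @return Integer scalar.
#' @export
count_params <- function(net) sum(vapply(net$params, length, 0L))

# one conv(+bn)+relu sub-block
cbr_fw <- function(x, net, name, train) {
  p <- net$params
  cv <- conv2d_fw(x, p[[paste0(name, "_w")]], p[[paste0(name, "_b")]])
  cache <- list(x = x, conv = cv)
  h <- cv
  if (net$cfg$batchnorm) {
    bn <- bn_fw(cv, p[[paste0(name, "_g")]], p[[paste0(name, "_beta")]],
                net$running[[paste0(name, "_mean")]],
                net$running[[paste0(name, "_var")]], train)
    net$running[[paste0(name, "_mean")]] <- bn$rmean
    net$running[[paste0(name, "_var")]] <- bn$rvar
    cache$bn <- bn$cache
    h <- bn$y
  }
  r <- relu_fw(h)
  cache$mask <- r$mask
  list(y = r$y, cache = cache, net = net)
}

cbr_bw <- function(dy, net, name, cache, grads) {
  dy <- dy * cache$mask
  if (net$cfg$batchnorm) {
    bb <- bn_bw(dy, cache$bn)
    grads[[paste0(name, "_g")]] <- bb$dgamma
    grads[[paste0(name, "_beta")]] <- bb$dbeta
    dy <- bb$dx
  }
  cb <- conv2d_bw(cache$x, net$params[[paste0(name, "_w")]], dy)
  grads[[paste0(name, "_w")]] <- cb$dw
  grads[[paste0(name, "_b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

stack_fw <- function(x, net, prefix, train) {
  caches <- list()
  h <- x
  for (j in seq_len(net$cfg$nconv)) {
    r <- cbr_fw(h, net, sprintf("%s_c%d", prefix, j), train)
    net <- r$net
    caches[[j]] <- r$cache
    h <- r$y
  }
  list(y = h, caches = caches, net = net)
}

stack_bw <- function(dy, net, prefix, caches, grads) {
  for (j in rev(seq_len(net$cfg$nconv))) {
    r <- cbr_bw(dy, net, sprintf("%s_c%d", prefix, j), caches[[j]], grads)
    grads <- r$grads
    dy <- r$dx
  }
  list(dx = dy, grads = grads)
}

# Full forward pass. Returns the output, the caches needed for backward, and
# the net (whose batch-norm running statistics advance when train = TRUE).
unet_fw <- function(net, x, train = FALSE) {
  cfg <- net$cfg
  d <- dim(x)
  div <- 2^(cfg$levels - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop(sprintf("spatial size must be divisible by %d", div))
  }
  caches <- list(x = x)
  skips <- list()
  h <- x
  for (l in seq_len(cfg$levels - 1)) {
    r <- stack_fw(h, net, sprintf("enc%d", l), train)
    net <- r$net
    skips[[l]] <- r$y
    caches[[sprintf("enc%d", l)]] <- r$caches
    mp <- maxpool2_fw(r$y)
    caches[[sprintf("pool%d", l)]] <- list(argmax = mp$argmax, xdim = dim(r$y))
    h <- mp$y
  }
  r <- stack_fw(h, net, "bot", train)
  net <- r$net
  caches$bot <- r$caches
  h <- r$y
  for (l in rev(seq_len(cfg$levels - 1))) {
    caches[[sprintf("upin%d", l)]] <- h
    up <- upconv2_fw(h, net$params[[sprintf("up%d_w", l)]],
                     net$params[[sprintf("up%d_b", l)]])
    hc <- concat_channels(skips[[l]], up)
    r <- stack_fw(hc, net, sprintf("dec%d", l), train)
    net <- r$net
    caches[[sprintf("dec%d", l)]] <- r$caches
    h <- r$y
  }
  caches$final_x <- h
  y <- conv2d_fw(h, net$params$final_w, net$params$final_b)
  if (cfg$residual) y <- y + x
  if (cfg$activation == "tanhshrink") {
    caches$pre_act <- y
    y <- tanhshrink(y)
  }
  list(y = y, caches = caches, net = net)
}

# Full backward pass: gradient of a scalar loss with respect to every
# parameter, given dL/dy. Must follow a unet_fw call with train = TRUE.
unet_bw <- function(net, caches, dy) {
  cfg <- net$cfg
  grads <- list()
  if (cfg$activation == "tanhshrink") {
    dy <- tanhshrink_bw(dy, caches$pre_act)
  }
  dres <- if (cfg$residual) dy else NULL
  cb <- conv2d_bw(caches$final_x, net$params$final_w, dy)
  grads$final_w <- cb$dw
  grads$final_b <- cb$db
  dh <- cb$dx
  dskips <- list()
  for (l in seq_len(cfg$levels - 1)) {
    r <- stack_bw(dh, net, sprintf("dec%d", l), caches[[sprintf("dec%d", l)]],
                  grads)
    grads <- r$grads
    ch_skip <- dim(caches[[sprintf("dec%d", l)]][[1]]$x)[3] / 2
    sp <- split_channels(r$dx, ch_skip)
    dskips[[l]] <- sp$a
    ub <- upconv2_bw(caches[[sprintf("upin%d", l)]],
                     net$params[[sprintf("up%d_w", l)]], sp$b)
    grads[[sprintf("up%d_w", l)]] <- ub$dw
    grads[[sprintf("up%d_b", l)]] <- ub$db
    dh <- ub$dx
  }
  r <- stack_bw(dh, net, "bot", caches$bot, grads)
  grads <- r$grads
  dh <- r$dx
  for (l in rev(seq_len(cfg$levels - 1))) {
    pl <- caches[[sprintf("pool%d", l)]]
    dpool <- maxpool2_bw(dh, pl$argmax, pl$xdim)
    dsum <- dpool + dskips[[l]]
    r <- stack_bw(dsum, net, sprintf("enc%d", l), caches[[sprintf("enc%d", l)]],
                  grads)
    grads <- r$grads
    dh <- r$dx
  }
  if (!is.null(dres)) dh <- dh + dres
  list(dx = dh, grads = grads)
}

#' Slice-by-slice network inference over a volume
#'
#' Runs the network on every axial slice of a spectral volume (or of
#' transform-domain component images), batching slices and using fixed
#' (running) batch-norm statistics, so inference is deterministic. If the
#' in-plane size is not divisible by `2^(levels-1)`, the slices are
#' symmetrically zero-padded and the output cropped back.
#'
#' @param net a trained `unet`.
#' @param volume `Z x Y x X x E` array ([spectral_volume()] or `u_images`).
#' @param batch_size slices per forward pass.
#' @return An array of the same shape, class and metadata as the input.
#' @export
predict_volume <- function(net, volume, batch_size = 8L) {
  d <- dim(volume)
  if (d[4] != net$cfg$in_ch) stop("channel count does not match the network")
  div <- 2^(net$cfg$levels - 1)
  py <- (div - d[2] %% div) %% div
  px <- (div - d[3] %% div) %% div
  lo_y <- floor(py / 2); lo_x <- floor(px / 2)
  out <- unclass(volume)
  idx <- seq_len(d[1])
  for (grp in split(idx, ceiling(idx / batch_size))) {
    B <- length(grp)
    x <- array(0, c(d[2] + py, d[3] + px, d[4], B))
    for (i in seq_len(B)) {
      x[lo_y + seq_len(d[2]), lo_x + seq_len(d[3]), , i] <-
        aperm(unclass(volume)[grp[i], , , , drop = FALSE], c(2, 3, 4, 1))
    }
    y <- unet_fw(net, x, train = FALSE)$y
    for (i in seq_len(B)) {
      out[grp[i], , , ] <- y[lo_y + seq_len(d[2]), lo_x + seq_len(d[3]), , i]
    }
  }
  attributes(out) <- attributes(volume)
  out
}
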