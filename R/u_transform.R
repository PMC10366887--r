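#' The invertible spectral "U transform"
#'
#' Network input preprocessing for spectral denoising: each energy channel is
#' divided by its estimated noise variance, the energy dimension is
#' decorrelated by a singular value decomposition, each left-singular-vector
#' image is high-pass filtered by subtracting a 3D-Gaussian-blurred copy of
#' itself (kernel 37^3 voxels, FWHM 10 voxels by default), and each component
#' is normalized by its absolute 99.95th-percentile intensity. All steps are
#' affine for a fixed state, so the transform can be inverted exactly — for
#' the full volume or for individual axial slices.
#'
#' @name u_transform
NULL

#' Estimate per-energy noise variance from image gradients
#'
#' For each energy channel, takes the central axial slice, pools first-order
#' finite differences along both in-plane axes, and estimates the noise
#' standard deviation robustly as `1.4826 * MAD / sqrt(2)` (the difference of
#' two i.i.d. variables has twice their variance). Returns the variances,
#' floored at machine epsilon.
#'
#' @param volume a [spectral_volume()] with in-plane extent of at least 2.
#' @return Numeric vector of per-energy noise variances (cm^-2).
#' @export
estimate_noise_variance <- function(volume) {
  d <- dim(volume)
  if (d[2] < 2 || d[3] < 2) stop("in-plane extent must be at least 2 voxels")
  zc <- (d[1] + 1) %/% 2
  vapply(seq_len(d[4]), function(e) {
    s <- unclass(volume)[zc, , , e]
    g <- c(diff(s), t(diff(t(s))))
    sigma <- stats::mad(g) / sqrt(2)
    max(sigma^2, .Machine$double.eps)
  }, numeric(1))
}

#' Forward U transform
#'
#' @param volume a [spectral_volume()].
#' @param blur_size odd 3D high-pass kernel edge length in voxels.
#' @param blur_fwhm Gaussian FWHM in voxels.
#' @param percentile normalization percentile of the absolute component
#'   intensities.
#' @return A list with `U` (component images, `Z x Y x X x E`, class
#'   `u_images`) and `state` (a `u_transform_state` holding everything needed
#'   for exact inversion: noise variances, singular values, right singular
#'   vectors, low-pass volumes and percentile scales).
#' @export
forward_transform <- function(volume, blur_size = 37L, blur_fwhm = 10,
                              percentile = 0.9995) {
  d <- dim(volume)
  if (!all(is.finite(volume))) stop("non-finite values in input volume")
  E <- d[4]
  nvox <- prod(d[1:3])
  vars <- estimate_noise_variance(volume)
  A <- unclass(volume)
  dim(A) <- c(nvox, E)
  A <- sweep(A, 2, vars, "/")
  sv <- svd(A)
  # deterministic sign convention: largest-magnitude entry of each right
  # singular vector is positive (the augmentation flips signs deliberately)
  for (k in seq_len(E)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  comp <- array(sv$u, c(d[1:3], E))
  lowpass <- array(0, dim(comp))
  scales <- numeric(E)
  U <- comp
  for (k in seq_len(E)) {
    lowpass[, , , k] <- blur3d(comp[, , , k], blur_size, blur_fwhm)
    hp <- comp[, , , k] - lowpass[, , , k]
    scales[k] <- max(stats::quantile(abs(hp), percentile, names = FALSE),
                     .Machine$double.eps)
    U[, , , k] <- hp / scales[k]
  }
  state <- structure(list(
    variances = vars, d = sv$d, v = sv$v, lowpass = lowpass, scales = scales,
    dim = d, blur_size = blur_size, blur_fwhm = blur_fwhm,
    energies = vol_energies(volume), voxel_size = vol_voxel_size(volume)
  ), class = "u_transform_state")
  list(U = structure(U, class = c("u_images", "array")), state = state)
}

#' @export
print.u_transform_state <- function(x, ...) {
  cat(sprintf(
    "<u_transform_state> grid %s, %d components, singular values %s\n",
    paste(x$dim[1:3], collapse = "x"), x$dim[4],
    paste(signif(x$d, 4), collapse = ", ")
  ))
  invisible(x)
}

#' Invert the U transform
#'
#' Exact inverse of [forward_transform()] for the stored state, optionally
#' restricted to a subset of axial slices: each component is rescaled by its
#' percentile scale, its stored low-pass content is added back, the slices are
#' mapped through `S V^T`, and each energy is multiplied by its noise
#' variance. The low-frequency content added back is the input volume's own,
#' so a network operating in the transform domain only has to predict
#' high-frequency structure.
#'
#' @param U `u_images` (or any `Z' x Y x X x E` array of component slices).
#' @param state the `u_transform_state` from [forward_transform()].
#' @param slices integer axial slice indices into the original volume that
#'   `U` represents (default: all slices).
#' @param signs optional `+/-1` vector per component: inverts sign-flipped
#'   components (see [sign_flip()]) without materializing a flipped state.
#' @return A [spectral_volume()] over the requested slices.
#' @export
inverse_transform <- function(U, state, slices = NULL, signs = NULL) {
  stopifnot(inherits(state, "u_transform_state"))
  d <- state$dim
  if (is.null(slices)) slices <- seq_len(d[1])
  if (any(slices < 1) || any(slices > d[1])) stop("slice index outside grid")
  du <- dim(U)
  if (!identical(du, c(length(slices), d[2], d[3], d[4]))) {
    stop("U grid does not match state/slices")
  }
  if (is.null(signs)) signs <- rep(1, d[4])
  ns <- length(slices)
  up <- unclass(U)
  for (k in seq_len(d[4])) {
    # for a sign-flipped component, flipping both U and the stored low-pass /
    # right singular vector cancels, leaving s_k on the U term only
    up[, , , k] <- signs[k] * up[, , , k] * state$scales[k] +
      c(state$lowpass[slices, , , k])
  }
  dim(up) <- c(ns * d[2] * d[3], d[4])
  A <- up %*% (state$d * t(state$v))
  A <- sweep(A, 2, state$variances, "*")
  spectral_volume(array(A, c(ns, d[2], d[3], d[4])),
    energies = state$energies, voxel_size = state$voxel_size
  )
}

#' Flip the sign of selected transform components
#'
#' Data augmentation for transform-domain training: multiplies selected left
#' and right singular vectors by -1. The flip is applied consistently to the
#' component images, their stored low-pass volumes, and the matching columns
#' of the right-singular-vector matrix, so inversion of the flipped pair
#' reproduces the same spectral volume.
#'
#' @param U `u_images` from [forward_transform()].
#' @param state matching `u_transform_state`.
#' @param mask logical vector, one entry per component; `TRUE` flips.
#' @return A list with flipped `U` and `state`.
#' @export
sign_flip <- function(U, state, mask) {
  stopifnot(length(mask) == state$dim[4])
  s <- ifelse(mask, -1, 1)
  up <- unclass(U)
  for (k in which(mask)) {
    up[, , , k] <- -up[, , , k]
    state$lowpass[, , , k] <- -state$lowpass[, , , k]
    state$v[, k] <- -state$v[, k]
  }
  list(U = structure(up, class = c("u_images", "array")), state = state)
}

#' Project a clean label volume into an input's transform domain
#'
#' Maps a label volume through the *input's* transform state: divides each
#' energy by the input's noise variance, right-multiplies by `V S^-1`,
#' high-pass filters each component by subtracting the label image's own
#' Gaussian blur, and divides by the input's percentile scales. By
#' self-consistency, projecting the input itself reproduces its own `U`.
#'
#' @param X_label a [spectral_volume()] on the same grid as the input.
#' @param state the input's `u_transform_state`.
#' @return `u_images` for the label.
#' @export
project_label <- function(X_label, state) {
  d <- state$dim
  if (!identical(dim(unclass(X_label)), d)) stop("label grid does not match state")
  if (any(state$d <= 0)) stop("degenerate transform state: singular value <= 0")
  nvox <- prod(d[1:3])
  A <- unclass(X_label)
  dim(A) <- c(nvox, d[4])
  A <- sweep(A, 2, state$variances, "/")
  Um <- A %*% sweep(state$v, 2, state$d, "/")
  comp <- array(Um, c(d[1:3], d[4]))
  for (k in seq_len(d[4])) {
    hp <- comp[, , , k] - blur3d(comp[, , , k], state$blur_size, state$blur_fwhm)
    comp[, , , k] <- hp / state$scales[k]
  }
  structure(comp, class = c("u_images", "array"))
}
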