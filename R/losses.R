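#' Training losses
#'
#' The baseline network trains with plain mean squared error in the
#' reconstruction domain. The transform-domain network trains with a
#' four-term loss: reconstruction MSE, transform-domain MSE (weight
#' `lambda1`), material-decomposition MSE through the rescaled sensitivity
#' matrix (weight `lambda2`), and MSE of Gaussian-blurred reconstructions.
#' Every term is normalized by its own entry count. Because all operations
#' linking the transform domain to the other domains are affine, the loss has
#' an exact analytic gradient with respect to the transform-domain
#' prediction.
#'
#' @name losses
NULL

#' Loss configuration
#'
#' @param M a [sensitivity_matrix()]; it is rescaled internally via
#'   [rescale_sensitivity()] so each decomposed map is of order 1 at its
#'   calibration concentration.
#' @param lambda1 weight of the transform-domain term (default 15).
#' @param lambda2 weight of the decomposition term (default 0.2).
#' @param blur_size odd 2D kernel edge for the blurred-reconstruction term.
#' @param blur_fwhm its Gaussian FWHM in voxels.
#' @param blur_weight weight of the blurred-reconstruction term (default 1;
#'   set all three optional weights to 0 for a reconstruction-MSE-only loss).
#' @return A `loss_config` object.
#' @export
loss_config <- function(M, lambda1 = 15, lambda2 = 0.2, blur_size = 19L,
                        blur_fwhm = 5, blur_weight = 1) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, blur_weight >= 0, blur_size %% 2 == 1)
  Mr <- rescale_sensitivity(M)
  structure(list(
    M = M, M_rescaled = Mr, Minv = right_inverse(Mr$mat),
    lambda1 = lambda1, lambda2 = lambda2, blur_weight = blur_weight,
    blur_size = as.integer(blur_size), blur_fwhm = blur_fwhm
  ), class = "loss_config")
}

#' Rescale a sensitivity matrix by calibration concentrations
#'
#' Multiplies each material row by its calibration vial concentration so that
#' decomposed maps are of order 1 at calibration concentration, putting all
#' materials on a similar intensity scale inside the loss.
#'
#' @param M a [sensitivity_matrix()].
#' @param vial_concentrations named concentrations; defaults to those stored
#'   in `M`.
#' @return A rescaled [sensitivity_matrix()].
#' @export
rescale_sensitivity <- function(M, vial_concentrations = NULL) {
  if (is.null(vial_concentrations)) vial_concentrations <- M$vial_concentrations
  if (is.null(vial_concentrations)) {
    stop("no vial concentrations available for rescaling")
  }
  conc <- vial_concentrations[M$materials]
  if (anyNA(conc)) stop("missing concentration for some material")
  sensitivity_matrix(unclass(M$mat) * as.numeric(conc),
    materials = M$materials, energies = M$energies,
    vial_concentrations = stats::setNames(rep(1, length(conc)), M$materials)
  )
}

#' Mean squared error
#'
#' `(1/N) * sum((pred - label)^2)` over all entries.
#'
#' @param pred,label numeric arrays of identical shape.
#' @return Non-negative scalar.
#' @export
mse_loss <- function(pred, label) {
  stopifnot(identical(dim(pred), dim(label)))
  mean((unclass(pred) - unclass(label))^2)
}

#' Four-term transform-domain loss
#'
#' Evaluates, for a batch of axial transform-domain slices, the sum of
#' reconstruction MSE, `lambda1` times transform-domain MSE, `lambda2` times
#' decomposition MSE (plain matrix inversion with the rescaled sensitivity
#' matrix, no non-negativity constraint), and blurred-reconstruction MSE.
#' Predictions and labels are mapped to the reconstruction domain by the
#' exact per-slice inverse of the stored transform state.
#'
#' @param U_pred,U_label arrays `Y x X x E x B` of transform-domain slices.
#' @param state a single `u_transform_state`, or a list of one state per
#'   batch sample when samples come from different volumes.
#' @param slices integer vector, length B: the axial slice index of each
#'   sample within its state's volume.
#' @param cfg a [loss_config()].
#' @param signs optional `E x B` matrix of `+/-1` sign-flip factors applied
#'   during augmentation.
#' @param grad if `TRUE`, also return the analytic gradient of the loss with
#'   respect to `U_pred`.
#' @return The scalar loss with attribute `terms` (named, unweighted); if
#'   `grad = TRUE`, a list `list(loss, terms, grad)`.
#' @export
unetu_loss <- function(U_pred, U_label, state, slices, cfg, signs = NULL,
                       grad = FALSE) {
  d <- dim(U_pred)
  stopifnot(identical(d, dim(U_label)), length(slices) == d[4])
  E <- d[3]; B <- d[4]
  per_sample <- is.list(state) && !inherits(state, "u_transform_state")
  if (is.null(signs)) signs <- matrix(1, E, B)
  npix <- d[1] * d[2]
  Ntot <- npix * E * B

  t_u <- mean((U_pred - U_label)^2)
  t_recon <- 0; t_dec <- 0; t_blur <- 0
  gX <- if (grad) array(0, d) else NULL

  Xp_all <- array(0, d); Xl_all <- array(0, d)
  for (b in seq_len(B)) {
    st <- if (per_sample) state[[b]] else state
    if (any(slices[b] < 1) || slices[b] > st$dim[1]) stop("slice outside state grid")
    Xp_all[, , , b] <- ut_invert_slice(U_pred[, , , b, drop = FALSE], st,
                                       slices[b], signs[, b])
    Xl_all[, , , b] <- ut_invert_slice(U_label[, , , b, drop = FALSE], st,
                                       slices[b], signs[, b])
  }
  Dx <- Xp_all - Xl_all
  t_recon <- mean(Dx^2)

  # decomposition term: voxelwise C = X %*% Mr^-1 (rescaled M, unconstrained)
  Dm <- matrix(0, npix * B, E)
  for (b in seq_len(B)) {
    Dm[(b - 1) * npix + seq_len(npix), ] <- matrix(Dx[, , , b], npix, E)
  }
  Cd <- Dm %*% cfg$Minv
  t_dec <- mean(Cd^2)

  # blur term: 2D Gaussian per energy channel of each slice
  Bl <- array(0, c(d[1], d[2], E, B))
  for (b in seq_len(B)) {
    for (e in seq_len(E)) {
      Bl[, , e, b] <- blur2d(Dx[, , e, b], cfg$blur_size, cfg$blur_fwhm)
    }
  }
  t_blur <- mean(Bl^2)

  bw_ <- cfg$blur_weight %||% 1
  loss <- t_recon + cfg$lambda1 * t_u + cfg$lambda2 * t_dec + bw_ * t_blur
  terms <- c(recon = t_recon, transform = t_u, decomposition = t_dec,
             blur = t_blur)
  if (!grad) return(structure(loss, terms = terms))

  # dL/dX, accumulated over the three reconstruction-domain terms
  gX <- (2 / Ntot) * Dx
  gdec <- (2 / (npix * B * nrow(cfg$M_rescaled$mat))) * Cd %*% t(cfg$Minv)
  for (b in seq_len(B)) {
    gX[, , , b] <- gX[, , , b] + cfg$lambda2 *
      array(gdec[(b - 1) * npix + seq_len(npix), ], c(d[1], d[2], E))
  }
  for (b in seq_len(B)) {
    for (e in seq_len(E)) {
      gX[, , e, b] <- gX[, , e, b] +
        bw_ * (2 / Ntot) * blur2d(Bl[, , e, b], cfg$blur_size, cfg$blur_fwhm,
                                  adjoint = TRUE)
    }
  }
  # chain through the affine inverse transform, per sample
  gU <- (cfg$lambda1 * 2 / Ntot) * (U_pred - U_label)
  for (b in seq_len(B)) {
    st <- if (per_sample) state[[b]] else state
    K <- st$d * t(st$v)  # E x E, A = U' K
    gA <- matrix(gX[, , , b], npix, E)
    gA <- sweep(gA, 2, st$variances, "*")
    gUp <- gA %*% t(K)
    gU[, , , b] <- gU[, , , b] +
      array(sweep(gUp, 2, signs[, b] * st$scales, "*"), c(d[1], d[2], E))
  }
  list(loss = loss, terms = terms, grad = gU)
}

# Invert one transform-domain slice [Y, X, E, 1] to the reconstruction
# domain [Y, X, E]; mirror of inverse_transform() specialized for the loss.
ut_invert_slice <- function(Uslc, st, z, signs) {
  dy <- dim(Uslc)[1]; dx <- dim(Uslc)[2]; E <- dim(Uslc)[3]
  up <- array(0, c(dy, dx, E))
  for (k in seq_len(E)) {
    up[, , k] <- signs[k] * Uslc[, , k, 1] * st$scales[k] +
      st$lowpass[z, , , k]
  }
  A <- matrix(up, dy * dx, E) %*% (st$d * t(st$v))
  A <- sweep(A, 2, st$variances, "*")
  array(A, c(dy, dx, E))
}
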