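#' Image-domain K-edge material decomposition
#'
#' Every voxel's spectral attenuation is modelled as a linear combination of
#' basis-material sensitivities, `x = c %*% M`, with water and K-edge contrast
#' agents as the basis. Decomposition inverts this system voxel by voxel;
#' non-negativity is enforced by active-set least squares restricted to the
#' subspace of non-violating materials.
#'
#' @name spectral_materials
NULL

#' Forward spectral composition
#'
#' Computes the clean spectral volume `X` from concentration maps `C` and a
#' sensitivity matrix `M`: for every voxel, `X(e) = sum_i C_i * M_i(e)`.
#' Exact and linear in `C`.
#'
#' @param C a [material_maps()] whose materials all appear in `M`.
#' @param M a [sensitivity_matrix()].
#' @return A [spectral_volume()].
#' @export
compose <- function(C, M) {
  stopifnot(inherits(M, "sensitivity_matrix"))
  mats <- attr(C, "materials")
  if (is.null(mats)) mats <- M$materials
  if (!all(mats %in% M$materials)) stop("unknown material in maps")
  d <- dim(C)
  nvox <- prod(d[1:3])
  Cm <- unclass(C)
  dim(Cm) <- c(nvox, d[4])
  X <- Cm %*% M$mat[mats, , drop = FALSE]
  spectral_volume(array(X, c(d[1:3], ncol(M$mat))),
    energies = M$energies, voxel_size = vol_voxel_size(C)
  )
}

#' Unconstrained material decomposition by matrix inversion
#'
#' Solves `C = X %*% M^-1` voxel by voxel: the exact inverse when `M` is
#' square, the minimum-norm least-squares solution (Moore-Penrose
#' pseudo-inverse) when there are more energies than materials. Outputs may be
#' negative; see [decompose_nonneg()] for the constrained variant.
#'
#' @param X a [spectral_volume()].
#' @param M a [sensitivity_matrix()] with full row rank and no more materials
#'   than energies.
#' @return A [material_maps()] in calibration units.
#' @export
decompose <- function(X, M) {
  stopifnot(inherits(M, "sensitivity_matrix"))
  Minv <- right_inverse(M$mat)
  d <- dim(X)
  if (d[4] != ncol(M$mat)) stop("energy count mismatch between volume and M")
  nvox <- prod(d[1:3])
  Xm <- unclass(X)
  dim(Xm) <- c(nvox, d[4])
  C <- Xm %*% Minv
  material_maps(array(C, c(d[1:3], nrow(M$mat))),
    materials = M$materials, voxel_size = vol_voxel_size(X)
  )
}

# M is materials x energies with m <= E; returns the E x m matrix M^+ such
# that X %*% M^+ is the (minimum-norm) least-squares solution of c M = x.
right_inverse <- function(mat) {
  m <- nrow(mat)
  if (ncol(mat) < m) stop("more materials than energies: system underdetermined")
  g <- mat %*% t(mat)
  if (rcond(g) < 1e-12) stop("rank-deficient sensitivity matrix")
  t(mat) %*% solve(g)
}

#' Non-negative material decomposition
#'
#' Like [decompose()], but negative concentrations are prevented by
#' projecting each violating voxel onto the subspace spanned by a subset of
#' the basis materials: the active-set least-squares (Lawson-Hanson) solution
#' of `min ||c M - x||` subject to `c >= 0`. Voxels whose unconstrained
#' solution is already non-negative are returned unchanged.
#'
#' @inheritParams decompose
#' @param tol active-set tolerance on concentrations.
#' @return A [material_maps()] with all entries `>= 0`.
#' @export
decompose_nonneg <- function(X, M, tol = 1e-10) {
  C <- decompose(X, M)
  d <- dim(C)
  nvox <- prod(d[1:3])
  Cm <- unclass(C)
  dim(Cm) <- c(nvox, d[4])
  bad <- which(rowSums(Cm < -tol) > 0)
  if (length(bad)) {
    Xm <- unclass(X)
    dim(Xm) <- c(nvox, dim(X)[4])
    Cm[bad, ] <- nnls_rows_cpp(Xm[bad, , drop = FALSE], M$mat, tol)
  }
  Cm[Cm < 0] <- 0
  material_maps(array(Cm, d),
    materials = M$materials,
    voxel_size = vol_voxel_size(X)
  )
}

#' Calibrate a sensitivity matrix from vial ROIs
#'
#' For each material, fits the slope through the origin of mean ROI
#' attenuation above water versus known vial concentration, per energy.
#' Vials are assumed to be aqueous solutions, so the water background
#' attenuation (from the dedicated water ROI) is subtracted before fitting.
#' The water row is the mean water-ROI attenuation per energy, per 1 g/mL.
#'
#' @param volume a [spectral_volume()].
#' @param rois list of [roi_spec()]s, each tagged with `material` and
#'   `concentration`; one or more per material.
#' @param water_roi an [roi_spec()] inside a pure-water region.
#' @return A [sensitivity_matrix()] with water first, then the contrast
#'   materials in order of first appearance; calibration vial concentrations
#'   attached.
#' @export
fit_sensitivity <- function(volume, rois, water_roi) {
  w <- roi_stats(volume, water_roi)$mean
  mats <- unique(vapply(rois, function(r) r$material, ""))
  if (any(!nzchar(mats)) || any(is.na(mats))) stop("every ROI needs a material")
  E <- dim(volume)[4]
  rows <- matrix(NA_real_, length(mats) + 1, E)
  rows[1, ] <- w
  vialc <- stats::setNames(rep(1, length(mats) + 1), c("water", mats))
  for (i in seq_along(mats)) {
    sel <- Filter(function(r) r$material == mats[i], rois)
    conc <- vapply(sel, function(r) r$concentration, 0)
    if (all(conc == 0)) stop("all-zero concentrations for material ", mats[i])
    att <- t(vapply(sel, function(r) roi_stats(volume, r)$mean - w, numeric(E)))
    # least squares through the origin, per energy
    rows[i + 1, ] <- colSums(att * conc) / sum(conc^2)
    vialc[mats[i]] <- max(conc)
  }
  sensitivity_matrix(rows,
    materials = c("water", mats), energies = vol_energies(volume),
    vial_concentrations = vialc
  )
}

#' Colorize material maps into an RGB composite
#'
#' Assigns each material map a color, scales it by a per-material display
#' maximum (the map's own maximum by default), and blends additively with
#' clipping to `[0, 1]` — the usual composite rendering of K-edge
#' decompositions.
#'
#' @param C a [material_maps()].
#' @param colors named character vector of colors (any form
#'   [grDevices::col2rgb()] accepts), one per material.
#' @param slice axial slice index to render.
#' @param max_conc optional named per-material display maxima.
#' @return A `Y x X x 3` array of RGB values in `[0, 1]`.
#' @export
colorize_maps <- function(C, colors, slice = 1L,
                          max_conc = NULL) {
  mats <- attr(C, "materials")
  stopifnot(all(mats %in% names(colors)))
  d <- dim(C)
  rgb_img <- array(0, c(d[2], d[3], 3))
  for (i in seq_along(mats)) {
    map <- unclass(C)[slice, , , i]
    mx <- if (!is.null(max_conc)) max_conc[[mats[i]]] else max(map)
    if (is.null(mx) || mx <= 0) mx <- 1
    w <- pmin(pmax(map / mx, 0), 1)
    col <- grDevices::col2rgb(colors[[mats[i]]]) / 255
    for (ch in 1:3) rgb_img[, , ch] <- rgb_img[, , ch] + w * col[ch]
  }
  pmin(rgb_img, 1)
}
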