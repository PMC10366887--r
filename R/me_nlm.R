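#' Multi-energy non-local means filtering
#'
#' A non-data-driven denoising baseline: every voxel of the output slice is a
#' weighted average of voxels in a cubic search window, with weights derived
#' from patch similarity summed over all energy channels (joint weighting, so
#' every energy is filtered with the same weights). Filtering strength is
#' normalized per energy by a noise standard deviation measured in a
#' homogeneous (water) region. The filter is applied to stacks of adjacent
#' axial slices, taking one designated slice as the output each time.
#'
#' @name me_nlm
NULL

#' NLM parameters
#'
#' @param search_edge cubic search window edge in voxels (odd, default 11).
#' @param patch_edge cubic patch edge in voxels (odd, default 3).
#' @param h filtering strength (default 1.2).
#' @param sigma per-energy noise standard deviation (cm^-1), e.g. from
#'   [noise_std_from_roi()].
#' @param stack_depth number of adjacent axial slices passed per call
#'   (default 31).
#' @param out_index 1-based index of the slice whose filtered version is
#'   returned (default 16, the stack center).
#' @return An `nlm_params` object.
#' @export
nlm_params <- function(search_edge = 11L, patch_edge = 3L, h = 1.2, sigma,
                       stack_depth = 31L, out_index = 16L) {
  stopifnot(
    search_edge %% 2 == 1, patch_edge %% 2 == 1, h > 0,
    all(sigma > 0), out_index >= 1, out_index <= stack_depth
  )
  structure(list(
    search_edge = as.integer(search_edge), patch_edge = as.integer(patch_edge),
    h = h, sigma = as.numeric(sigma), stack_depth = as.integer(stack_depth),
    out_index = as.integer(out_index)
  ), class = "nlm_params")
}

#' Per-energy noise standard deviation from a homogeneous ROI
#'
#' @param volume a [spectral_volume()].
#' @param water_roi an [roi_spec()] inside a homogeneous (water) region.
#' @return Numeric vector of per-energy sample standard deviations, floored
#'   at machine epsilon.
#' @export
noise_std_from_roi <- function(volume, water_roi) {
  pmax(roi_stats(volume, water_roi)$sd, .Machine$double.eps)
}

#' Filter one slice from a multi-energy slice stack
#'
#' For each voxel of the designated output slice, averages search-window
#' voxels with weights `exp(-sum_e d_e / (2 h^2 sigma_e^2 |P|))`, `d_e` being
#' the squared Euclidean distance between cubic patches at energy `e` and
#' `|P|` the patch voxel count; the weights are normalized to sum to one and
#' shared across energies. Patches near borders read from a mirror-padded
#' copy; the search window is clipped to the stack.
#'
#' @param stack `Z x Y x X x E` array, `Z` equal to `params$stack_depth`.
#' @param params an [nlm_params()] whose `sigma` has one entry per energy.
#' @return `Y x X x E` array: the filtered output slice at all energies.
#' @export
me_nlm_stack <- function(stack, params) {
  stopifnot(inherits(params, "nlm_params"))
  d <- dim(stack)
  if (length(d) != 4) stop("stack must be Z x Y x X x E")
  if (d[1] != params$stack_depth) stop("stack depth does not match params")
  if (length(params$sigma) != d[4]) stop("one sigma per energy required")
  menlm_stack_cpp(
    unclass(stack), params$out_index,
    (params$search_edge - 1L) %/% 2L, (params$patch_edge - 1L) %/% 2L,
    params$h, params$sigma
  )
}

#' Filter a whole volume by sliding the slice stack
#'
#' Slides the stack through the volume so that every axial slice is once the
#' designated output slice; slices past the volume ends are supplied by
#' mirror reflection in z.
#'
#' @param volume a [spectral_volume()].
#' @param params an [nlm_params()].
#' @return The filtered [spectral_volume()], same grid as the input.
#' @export
me_nlm_volume <- function(volume, params) {
  d <- dim(volume)
  before <- params$out_index - 1L
  after <- params$stack_depth - params$out_index
  zidx <- function(i) {  # mirror about the edge slices
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > d[1], 2 * d[1] - i, i)
  }
  out <- unclass(volume)
  for (z in seq_len(d[1])) {
    sel <- zidx(seq(z - before, z + after))
    stack <- unclass(volume)[sel, , , , drop = FALSE]
    out[z, , , ] <- me_nlm_stack(stack, params)
  }
  attributes(out) <- attributes(volume)
  out
}
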