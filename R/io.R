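#' NIfTI input/output for spectral volumes
#'
#' Volumes are exchanged as 4D NIfTI files with energy as the fourth
#' dimension (file axis order X, Y, Z, E; the in-memory layout is
#' `Z x Y x X x E`). Energy-threshold labels travel in a JSON sidecar next to
#' the image file to avoid NIfTI header-extension dialects.
#'
#' @name cli_io
NULL

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Write a spectral volume to a 4D NIfTI file
#'
#' @param volume a [spectral_volume()].
#' @param path output path (`.nii` or `.nii.gz`); a `.json` sidecar with the
#'   energy labels and voxel size is written next to it.
#' @return The path, invisibly.
#' @export
write_spectral_volume <- function(volume, path) {
  arr <- aperm(unclass(volume), c(3, 2, 1, 4))
  vox <- vol_voxel_size(volume)
  img <- RNifti::asNifti(arr, pixdim = c(vox, vox, vox, 1))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(energies_kev = vol_energies(volume), voxel_size_mm = vox),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a spectral volume from NIfTI
#'
#' Accepts one 4D file (fourth dimension = energy) or a character vector of
#' per-energy 3D files on identical grids. Energy labels come from the JSON
#' sidecar of the (first) file; without one, positional labels are used with
#' a warning.
#'
#' @param path one 4D NIfTI path, or a vector of 3D NIfTI paths.
#' @return A [spectral_volume()].
#' @export
read_spectral_volume <- function(path) {
  imgs <- lapply(path, function(p) as.array(RNifti::readNifti(p)))
  nd <- vapply(imgs, function(a) length(dim(a)), 0L)
  if (length(imgs) == 1 && nd[1] == 4) {
    arr <- imgs[[1]]
  } else {
    if (any(nd != 3)) stop("expected one 4D file or several 3D files")
    if (length(unique(lapply(imgs, dim))) != 1) stop("mismatched grids")
    arr <- array(unlist(imgs), c(dim(imgs[[1]]), length(imgs)))
  }
  vox <- tryCatch(RNifti::pixdim(RNifti::readNifti(path[1]))[1],
                  error = function(e) 1)
  scs <- sidecar_path(path)
  if (all(file.exists(scs))) {
    metas <- lapply(scs, jsonlite::read_json, simplifyVector = TRUE)
    energies <- unlist(lapply(metas, `[[`, "energies_kev"))
    vox <- metas[[1]]$voxel_size_mm %||% vox
  } else {
    warning("no energy sidecar found; using positional labels")
    energies <- seq_len(dim(arr)[4])
  }
  if (length(energies) != dim(arr)[4]) energies <- seq_len(dim(arr)[4])
  spectral_volume(aperm(arr, c(3, 2, 1, 4)), energies = energies,
                  voxel_size = vox)
}

#' Write/read a sensitivity matrix as JSON
#'
#' @param M a [sensitivity_matrix()].
#' @param path JSON file path.
#' @return `write_sensitivity`: the path, invisibly. `read_sensitivity`: a
#'   [sensitivity_matrix()].
#' @export
write_sensitivity <- function(M, path) {
  jsonlite::write_json(list(
    materials = M$materials, energies = M$energies,
    matrix = unname(unclass(M$mat)),
    vial_concentrations = as.list(M$vial_concentrations)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sensitivity
#' @export
read_sensitivity <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vc <- unlist(j$vial_concentrations)
  sensitivity_matrix(j$matrix,
    materials = j$materials, energies = j$energies,
    vial_concentrations = if (length(vc)) vc else NULL
  )
}

#' Save / load a transform state
#'
#' The state holds per-energy variances, singular values and vectors,
#' low-pass volumes and scales; it is serialized as a single RDS container.
#'
#' @param state a `u_transform_state`.
#' @param path file path (`.rds`).
#' @return `write_transform_state`: the path invisibly;
#'   `read_transform_state`: the state.
#' @export
write_transform_state <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname write_transform_state
#' @export
read_transform_state <- function(path) {
  st <- readRDS(path)
  stopifnot(inherits(st, "u_transform_state"))
  st
}
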