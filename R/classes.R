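#' Spectral CT volume
#'
#' A 4D array of linear attenuation coefficients (cm^-1) with dimensions
#' `Z x Y x X x E`: axial slices along the first axis, photon-counting
#' energy-threshold channels along the last. Voxel indices are 1-based.
#'
#' @param data 4D numeric array, `Z x Y x X x E`.
#' @param energies numeric vector of energy-threshold labels (keV), one per
#'   channel. Defaults to positional labels `1:E`.
#' @param voxel_size isotropic voxel size in mm.
#' @return A `spectral_volume` object (the array with metadata attributes).
#' @export
spectral_volume <- function(data, energies = NULL, voxel_size = 0.125) {
  data <- as_num_array(data, 4L, "data")
  E <- dim(data)[4]
  if (is.null(energies)) energies <- seq_len(E)
  if (length(energies) != E) {
    stop("length(energies) must equal the number of energy channels")
  }
  structure(data,
    energies = as.numeric(energies),
    voxel_size = as.numeric(voxel_size),
    class = c("spectral_volume", "array")
  )
}

#' Per-material concentration maps
#'
#' A 4D array `Z x Y x X x M` holding one concentration volume per basis
#' material. Units follow the calibration convention: g/mL for water,
#' mg/mL for every other material.
#'
#' @param data 4D numeric array, `Z x Y x X x M`.
#' @param materials character vector of material names, one per map.
#' @param voxel_size isotropic voxel size in mm.
#' @return A `material_maps` object.
#' @export
material_maps <- function(data, materials, voxel_size = 0.125) {
  data <- as_num_array(data, 4L, "data")
  if (length(materials) != dim(data)[4]) {
    stop("length(materials) must equal the number of maps")
  }
  structure(data,
    materials = as.character(materials),
    voxel_size = as.numeric(voxel_size),
    class = c("material_maps", "array")
  )
}

#' Material sensitivity matrix
#'
#' Attenuation per unit concentration for each basis material at each energy
#' threshold: a materials-by-energies matrix `M` such that a voxel's spectral
#' attenuation row-vector is `x = c %*% M` for concentration row-vector `c`.
#'
#' @param mat numeric matrix, materials in rows, energies in columns.
#' @param materials character vector of unique material names (row labels).
#' @param energies numeric energy-threshold labels in keV (column labels).
#' @param vial_concentrations optional named numeric vector giving the
#'   calibration vial concentration for each material (g/mL for water,
#'   mg/mL otherwise), used to rescale the matrix inside the training loss.
#' @return A `sensitivity_matrix` object.
#' @export
sensitivity_matrix <- function(mat, materials = rownames(mat),
                               energies = NULL, vial_concentrations = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (is.null(materials)) stop("material names are required")
  materials <- as.character(materials)
  if (anyDuplicated(materials)) stop("duplicate material names")
  if (length(materials) != nrow(mat)) stop("one name per row required")
  if (!all(is.finite(mat))) stop("sensitivity matrix must be finite")
  if (is.null(energies)) energies <- seq_len(ncol(mat))
  if (length(energies) != ncol(mat)) stop("one energy label per column required")
  if (!is.null(vial_concentrations)) {
    vial_concentrations <- vial_concentrations[materials]
    if (anyNA(vial_concentrations)) {
      stop("vial_concentrations must name every material")
    }
  }
  dimnames(mat) <- list(materials, as.character(energies))
  structure(list(
    mat = mat, materials = materials, energies = as.numeric(energies),
    vial_concentrations = vial_concentrations
  ), class = "sensitivity_matrix")
}

#' Cylindrical region of interest
#'
#' An in-plane disc swept over a contiguous axial slice range, optionally
#' tagged with the material and known concentration of a calibration vial.
#'
#' @param center length-2 numeric `(y, x)` voxel center of the disc (1-based).
#' @param radius in-plane radius in voxels.
#' @param slices length-2 integer `(first, last)` axial slice range.
#' @param material optional material name of the vial.
#' @param concentration optional known concentration (g/mL for water,
#'   mg/mL otherwise).
#' @return An `roi_spec` object.
#' @export
roi_spec <- function(center, radius, slices, material = NULL,
                     concentration = NULL) {
  stopifnot(length(center) == 2, length(slices) == 2, radius > 0)
  structure(list(
    center = as.numeric(center), radius = as.numeric(radius),
    slices = as.integer(slices), material = material,
    concentration = concentration
  ), class = "roi_spec")
}

#' @export
print.spectral_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<spectral_volume> %d x %d x %d voxels, %d energies (%s keV), %.3g mm voxels\n",
    d[1], d[2], d[3], d[4], paste(attr(x, "energies"), collapse = ", "),
    attr(x, "voxel_size")
  ))
  invisible(x)
}

#' @export
print.material_maps <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<material_maps> %d x %d x %d voxels, materials: %s\n",
    d[1], d[2], d[3], paste(attr(x, "materials"), collapse = ", ")
  ))
  invisible(x)
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_matrix> %d materials x %d energies (cm^-1 per unit concentration)\n",
    nrow(x$mat), ncol(x$mat)
  ))
  print(round(x$mat, 5))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

as_num_array <- function(x, ndim, what) {
  x <- unclass(x)
  if (is.null(dim(x)) || length(dim(x)) != ndim) {
    stop(sprintf("%s must be a %dD array", what, ndim))
  }
  storage.mode(x) <- "double"
  attributes(x) <- list(dim = dim(x))
  x
}

vol_energies <- function(x) {
  e <- attr(x, "energies")
  if (is.null(e)) seq_len(dim(x)[4]) else e
}

vol_voxel_size <- function(x) {
  v <- attr(x, "voxel_size")
  if (is.null(v)) 1 else v
}

# Linear indices (into a Z x Y x X grid) of the voxels covered by an ROI.
# Membership is by voxel center.
roi_indices <- function(dims, roi) {
  zs <- roi$slices[1]:roi$slices[2]
  if (any(zs < 1) || any(zs > dims[1])) stop("ROI slice range outside volume")
  yy <- seq_len(dims[2])
  xx <- seq_len(dims[3])
  disc <- outer((yy - roi$center[1])^2, (xx - roi$center[2])^2, "+") <=
    roi$radius^2
  if (roi$center[1] - roi$radius < 0.5 || roi$center[1] + roi$radius > dims[2] + 0.5 ||
      roi$center[2] - roi$radius < 0.5 || roi$center[2] + roi$radius > dims[3] + 0.5) {
    stop("ROI disc outside volume")
  }
  inplane <- which(disc)  # indices into Y x X plane
  if (length(inplane) * length(zs) < 8) stop("ROI must cover at least 8 voxels")
  zy <- dims[1] * dims[2]
  idx <- outer(zs, (inplane - 1) * dims[1], "+")
  as.integer(idx)
}

# Mean/sd of an ROI per energy channel.
roi_stats <- function(volume, roi) {
  d <- dim(volume)
  idx <- roi_indices(d[1:3], roi)
  nvox <- prod(d[1:3])
  vals <- sapply(seq_len(d[4]), function(e) {
    v <- volume[(e - 1) * nvox + idx]
    c(mean(v), stats::sd(v))
  })
  list(mean = vals[1, ], sd = vals[2, ], n = length(idx))
}
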