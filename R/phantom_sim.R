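#' Synthetic spectral phantoms
#'
#' Builds plausible material sensitivity curves and voxelized phantoms so the
#' denoising pipeline can be exercised end to end without scanner data. The
#' phantoms emulate the paired volumes used for network training: a clean
#' spectral composition (standing in for a low-noise iterative reconstruction)
#' and a noisy copy (standing in for weighted filtered backprojection).
#'
#' @name phantom_sim
NULL

# K-edge energies (keV) of the contrast materials commonly separated with
# photon-counting thresholds, plus Compton/photoelectric-like baselines.
.kedge_tbl <- c(I = 33.2, Ba = 37.4, Gd = 50.2, Ta = 67.4, Au = 80.7, Bi = 90.5)

#' Synthesize a plausible sensitivity matrix
#'
#' Generates a materials-by-energies sensitivity matrix with K-edge-like
#' signatures so that energy bins are spectrally distinguishable. Water gets a
#' smoothly decaying attenuation curve (cm^-1 per g/mL); known contrast
#' materials get a decaying baseline plus a step that switches on at their
#' K-edge (cm^-1 per mg/mL); unrecognized names get a deterministic
#' pseudo-random decaying curve derived from the name, so results are
#' reproducible without a lookup table.
#'
#' @param materials character vector of material names (unique; >= 1).
#' @param energies numeric energy-threshold labels in keV; at least as many
#'   energies as materials.
#' @param vial_concentrations optional named calibration concentrations; by
#'   default 1 g/mL for water and 10 mg/mL for everything else.
#' @return A [sensitivity_matrix()].
#' @examples
#' build_sensitivity_matrix(c("water", "I", "Gd", "Ta"), c(25, 34, 51, 68))
#' @export
build_sensitivity_matrix <- function(materials,
                                     energies = default_energies(length(materials)),
                                     vial_concentrations = NULL) {
  materials <- as.character(materials)
  if (length(materials) < 1) stop("at least one material required")
  if (anyDuplicated(materials)) stop("duplicate material names")
  if (length(energies) < length(materials)) {
    stop("need at least as many energies as materials for an invertible system")
  }
  E <- as.numeric(energies)
  rows <- t(vapply(materials, material_curve, numeric(length(E)), energies = E))
  if (any(rows <= 0)) stop("internal error: non-positive sensitivity entry")
  if (is.null(vial_concentrations)) {
    vial_concentrations <- stats::setNames(
      ifelse(tolower(materials) %in% c("water", "h2o"), 1, 10), materials
    )
  }
  sensitivity_matrix(rows,
    materials = materials, energies = E,
    vial_concentrations = vial_concentrations
  )
}

default_energies <- function(n) {
  full <- c(25, 34, 51, 68, 81, 91)
  if (n > length(full)) stop("too many materials for the default energy grid")
  full[seq_len(max(n, 1))]
}

material_curve <- function(name, energies) {
  lname <- tolower(name)
  if (lname %in% c("water", "h2o")) {
    return(0.17 + 150 * energies^-2)                     # cm^-1 per g/mL
  }
  if (lname %in% c("ca", "calcium")) {
    return(0.0012 * (energies / 30)^-2.6 + 2e-4)         # cm^-1 per mg/mL
  }
  key <- names(.kedge_tbl)[match(lname, tolower(names(.kedge_tbl)))]
  if (!is.na(key)) {
    k <- .kedge_tbl[[key]]
    base <- 0.004 * (energies / 30)^-2.5
    jump <- ifelse(energies >= k, 0.028 * (energies / k)^-2.5, 0)
    return(base + jump + 5e-4)
  }
  # deterministic pseudo-curve from the name for unknown materials
  h <- sum(utf8ToInt(lname) * seq_along(utf8ToInt(lname)))
  a <- 0.002 + (h %% 97) / 97 * 0.02
  p <- 1.5 + (h %% 13) / 13 * 1.5
  a * (energies / 30)^-p + 5e-4
}

#' Phantom specification
#'
#' Describes a voxelized phantom: grid shape, voxel size, a background
#' material, and a list of objects (cylinders or ellipsoids) with material and
#' concentration. Vials are treated as aqueous solutions: the background water
#' density also fills object voxels unless an object itself sets water.
#'
#' @param shape integer length-3 grid shape `(Z, Y, X)`.
#' @param voxel_size isotropic voxel size in mm.
#' @param objects list of objects; each is a list with fields `shape`
#'   (`"cylinder"` or `"ellipsoid"`), `center` `(z, y, x)`, `radii`
#'   `(rz, ry, rx)` (a cylinder spans `|z - cz| <= rz` with an in-plane
#'   ellipse), `material`, and `concentration` (g/mL for water, mg/mL
#'   otherwise).
#' @param background list with `material` and `concentration` filling the
#'   whole grid (default water at 1 g/mL).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape, voxel_size = 0.125, objects = list(),
                         background = list(material = "water", concentration = 1)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  for (ob in objects) {
    stopifnot(
      ob$shape %in% c("cylinder", "ellipsoid"),
      length(ob$center) == 3, length(ob$radii) == 3,
      ob$concentration >= 0, all(ob$radii > 0)
    )
    if (any(ob$center < 1) || any(ob$center > shape)) {
      stop("object center outside the grid")
    }
  }
  structure(list(
    shape = shape, voxel_size = voxel_size,
    objects = objects, background = background
  ), class = "phantom_spec")
}

object_mask <- function(shape, ob) {
  z <- seq_len(shape[1]); y <- seq_len(shape[2]); x <- seq_len(shape[3])
  dz <- (z - ob$center[1]) / ob$radii[1]
  dy <- (y - ob$center[2]) / ob$radii[2]
  dx <- (x - ob$center[3]) / ob$radii[3]
  inplane <- outer(dy^2, dx^2, "+")
  if (ob$shape == "cylinder") {
    m <- outer(abs(dz) <= 1, as.vector(inplane <= 1), "&")
  } else {
    m <- outer(dz^2, as.vector(inplane), "+") <= 1
  }
  dim(m) <- shape
  m
}

#' Compose a phantom into material maps and a clean spectral volume
#'
#' Rasterizes the phantom (voxel-center membership, no partial volume) into
#' ground-truth concentration maps `C`, then forms the clean spectral volume
#' by the linear forward model `X = C %*% M` voxel by voxel.
#'
#' @param spec a [phantom_spec()].
#' @param M a [sensitivity_matrix()] containing every material used in `spec`.
#' @return A list with `maps` (a [material_maps()]) and `volume`
#'   (a [spectral_volume()]).
#' @export
compose_phantom <- function(spec, M) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(M, "sensitivity_matrix"))
  mats <- M$materials
  used <- c(spec$background$material, vapply(spec$objects, `[[`, "", "material"))
  if (!all(used %in% mats)) {
    stop("unknown material(s) in phantom: ", paste(setdiff(used, mats), collapse = ", "))
  }
  shp <- spec$shape
  C <- array(0, c(shp, length(mats)))
  C[, , , match(spec$background$material, mats)] <- spec$background$concentration
  for (ob in spec$objects) {
    m <- object_mask(shp, ob)
    k <- match(ob$material, mats)
    page <- C[, , , k]
    page[m] <- ob$concentration
    C[, , , k] <- page
  }
  maps <- material_maps(C, mats, voxel_size = spec$voxel_size)
  vol <- compose(maps, M)
  attr(vol, "voxel_size") <- spec$voxel_size
  list(maps = maps, volume = vol)
}

#' Per-energy noise specification
#'
#' @param std numeric vector of per-energy noise standard deviations (cm^-1).
#' @param seed integer RNG seed.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(std, seed = 1L) {
  std <- as.numeric(std)
  if (any(std < 0)) stop("noise std must be non-negative")
  structure(list(std = std, seed = as.integer(seed)), class = "noise_spec")
}

#' Default per-energy noise levels
#'
#' Photon starvation makes high-threshold bins noisier; the default emulates
#' water-vial noise rising from roughly 80 to 260 HU across four thresholds.
#' A dose-reduction series (undersampling by a factor `f`) is emulated by
#' scaling the standard deviations by `sqrt(f)`.
#'
#' @param n_energies number of energy bins.
#' @param dose_factor undersampling factor (1 = full dose).
#' @return Numeric vector of per-energy noise standard deviations (cm^-1).
#' @export
default_noise_std <- function(n_energies = 4L, dose_factor = 1) {
  base <- c(0.02, 0.03, 0.045, 0.065, 0.08, 0.095)[seq_len(n_energies)]
  base * sqrt(dose_factor)
}

#' Add reproducible Gaussian noise to a spectral volume
#'
#' Adds zero-mean i.i.d. Gaussian noise, independent per voxel and per energy,
#' with a per-energy standard deviation. The generator state is isolated:
#' the same `noise_spec` seed always yields the same volume and the caller's
#' RNG stream is untouched.
#'
#' @param clean a [spectral_volume()].
#' @param noise a [noise_spec()] whose `std` has one entry per energy.
#' @return A noisy [spectral_volume()] on the same grid.
#' @export
add_noise <- function(clean, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  d <- dim(clean)
  if (length(noise$std) != d[4]) stop("noise std length must match energies")
  nvox <- prod(d[1:3])
  out <- unclass(clean)
  with_local_seed(noise$seed, {
    for (e in seq_len(d[4])) {
      out[(e - 1) * nvox + seq_len(nvox)] <-
        out[(e - 1) * nvox + seq_len(nvox)] + stats::rnorm(nvox, 0, noise$std[e])
    }
  })
  spectral_volume(array(out, d),
    energies = vol_energies(clean),
    voxel_size = vol_voxel_size(clean)
  )
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default vial phantom template
#'
#' A water cylinder ("body") containing one vial per contrast material plus a
#' calcium inclusion, mimicking calibration phantoms of known concentrations.
#' Desk-scale by default: 48 slices of 64 x 64 voxels.
#'
#' @param shape grid shape `(Z, Y, X)`.
#' @param materials materials to place as vials (water is the background and
#'   gets a dedicated water-only vial region implicitly through the
#'   background).
#' @param concentrations named concentrations for the vials; defaults to the
#'   calibration concentrations of [build_sensitivity_matrix()].
#' @return A [phantom_spec()].
#' @export
vial_phantom_template <- function(shape = c(48L, 64L, 64L),
                                  materials = c("I", "Gd", "Ta"),
                                  concentrations = NULL) {
  if (is.null(concentrations)) {
    concentrations <- stats::setNames(rep(10, length(materials)), materials)
  }
  cy <- (shape[2] + 1) / 2
  cx <- (shape[3] + 1) / 2
  body_r <- min(shape[2:3]) * 0.42
  zmid <- (shape[1] + 1) / 2
  n <- length(materials)
  ang <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
  objects <- list(list(
    shape = "cylinder", center = c(zmid, cy, cx),
    radii = c(shape[1] / 2, body_r, body_r),
    material = "water", concentration = 1
  ))
  vr <- max(2.5, body_r * 0.18)
  for (i in seq_len(n)) {
    objects[[i + 1]] <- list(
      shape = "cylinder",
      center = c(zmid, cy + 0.55 * body_r * sin(ang[i]), cx + 0.55 * body_r * cos(ang[i])),
      radii = c(shape[1] * 0.4, vr, vr),
      material = materials[i],
      concentration = unname(concentrations[materials[i]])
    )
  }
  phantom_spec(shape,
    objects = objects,
    background = list(material = "water", concentration = 1)
  )
}

# Deterministically jitter vial placement and concentrations of a template.
vary_phantom <- function(template, seed) {
  spec <- template
  with_local_seed(seed, {
    for (i in seq_along(spec$objects)) {
      ob <- spec$objects[[i]]
      if (i > 1) {  # keep the body fixed, move the vials
        jit <- c(0, stats::runif(2, -2, 2))
        ob$center <- pmin(pmax(ob$center + jit, 1), spec$shape)
        ob$concentration <- ob$concentration * stats::runif(1, 0.6, 1.4)
      }
      spec$objects[[i]] <- ob
    }
  })
  spec
}

#' Write a paired clean/noisy synthetic dataset to disk
#'
#' Generates `n_volumes` phantoms from a template (vial placement and
#' concentrations jittered per volume, deterministically from the seed),
#' composes clean volumes, adds per-energy noise, and writes paired NIfTI
#' files plus a JSON manifest from which the whole dataset can be regenerated
#' bit for bit.
#'
#' @param n_volumes number of paired volumes (>= 2: at least one for training
#'   and one for validation).
#' @param template a [phantom_spec()] used as the layout template.
#' @param M a [sensitivity_matrix()].
#' @param noise a [noise_spec()]; its seed is the master seed.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
make_paired_dataset <- function(n_volumes, template, M, noise, out_dir) {
  if (n_volumes < 2) stop("need at least 2 volumes (train + validation)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output path not writable: ", out_dir)
  seeds <- with_local_seed(noise$seed, sample.int(.Machine$integer.max - 1, 2 * n_volumes))
  entries <- vector("list", n_volumes)
  for (i in seq_len(n_volumes)) {
    spec_i <- vary_phantom(template, seeds[2 * i - 1])
    ph <- compose_phantom(spec_i, M)
    noisy <- add_noise(ph$volume, noise_spec(noise$std, seeds[2 * i]))
    clean_path <- file.path(out_dir, sprintf("vol%02d_clean.nii.gz", i))
    noisy_path <- file.path(out_dir, sprintf("vol%02d_noisy.nii.gz", i))
    write_spectral_volume(ph$volume, clean_path)
    write_spectral_volume(noisy, noisy_path)
    entries[[i]] <- list(
      clean = basename(clean_path), noisy = basename(noisy_path),
      spec_seed = seeds[2 * i - 1], noise_seed = seeds[2 * i],
      concentrations = lapply(spec_i$objects, function(ob) {
        list(material = ob$material, concentration = ob$concentration)
      })
    )
  }
  manifest <- list(
    n_volumes = n_volumes,
    master_seed = noise$seed,
    noise_std = noise$std,
    energies = M$energies,
    materials = M$materials,
    sensitivity = unname(unclass(M$mat)),
    template = unclass(template),
    volumes = entries
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Regenerate the volumes described by a dataset manifest
#'
#' @param manifest manifest list or path to `manifest.json`.
#' @param index which volume to regenerate.
#' @return A list with `clean` and `noisy` [spectral_volume()]s.
#' @export
regenerate_pair <- function(manifest, index) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  tmpl <- manifest$template
  template <- phantom_spec(tmpl$shape,
    voxel_size = tmpl$voxel_size,
    objects = manifest_objects(tmpl$objects),
    background = as.list(tmpl$background)
  )
  M <- sensitivity_matrix(
    matrix(unlist(manifest$sensitivity),
      nrow = length(manifest$materials), byrow = is.list(manifest$sensitivity)
    ),
    materials = manifest$materials, energies = manifest$energies
  )
  v <- manifest$volumes
  entry <- if (is.data.frame(v)) lapply(v, `[[`, index) else v[[index]]
  spec_i <- vary_phantom(template, entry$spec_seed)
  ph <- compose_phantom(spec_i, M)
  noisy <- add_noise(ph$volume, noise_spec(manifest$noise_std, entry$noise_seed))
  list(clean = ph$volume, noisy = noisy, maps = ph$maps)
}

manifest_objects <- function(objects) {
  if (is.data.frame(objects)) {
    lapply(seq_len(nrow(objects)), function(i) {
      list(
        shape = objects$shape[i], center = unlist(objects$center[i]),
        radii = unlist(objects$radii[i]), material = objects$material[i],
        concentration = objects$concentration[i]
      )
    })
  } else {
    lapply(objects, function(ob) {
      ob$center <- unlist(ob$center); ob$radii <- unlist(ob$radii); ob
    })
  }
}
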