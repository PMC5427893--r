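#' Configuration for the MR phantom generator
#'
#' Builds a bimodal-intensity T2-like volume: an ellipsoidal brain over
#' background, a hyperintense spherical-cap lesion seated at the cortical
#' surface occupying a requested fraction of the brain, and a hypointense
#' hemorrhage core inside the lesion. Companion magnitude/phase volumes model
#' a susceptibility acquisition: the hemorrhage carries negative phase.
#'
#' Volumes are arrays indexed `[row, col, slice]`.
#'
#' @param shape_voxels `c(rows, cols, slices)`.
#' @param voxel_size_mm voxel edge lengths, `c(row, col, slice)` in mm.
#' @param brain_mean,lesion_mean,hemorrhage_mean,background_mean T2 intensity
#'   means (pairwise distinct where the compartment is present).
#' @param noise_sd additive Gaussian noise s.d.; 0 gives exact compartment
#'   means. Phase noise scales as `noise_sd / brain_mean`.
#' @param lesion_fraction_of_brain target lesion volume as a fraction of
#'   brain voxels (realized within discretization error).
#' @param hemorrhage_fraction_of_brain target hemorrhage fraction (0 = none);
#'   the hemorrhage is carved inside the lesion.
#' @param hemorrhage_phase_rad phase assigned to hemorrhage voxels (negative).
#' @param rng_seed integer seed.
#' @return An `mr_phantom_config` object.
#' @export
mr_phantom_config <- function(shape_voxels = c(96L, 96L, 24L),
                              voxel_size_mm = c(0.128, 0.128, 0.5),
                              brain_mean = 100,
                              lesion_mean = 180,
                              hemorrhage_mean = 40,
                              background_mean = 10,
                              noise_sd = 3,
                              lesion_fraction_of_brain = 0.04,
                              hemorrhage_fraction_of_brain = 0.005,
                              hemorrhage_phase_rad = -2,
                              rng_seed = 1L) {
  if (length(shape_voxels) != 3L || any(shape_voxels < 8))
    stop_config("shape_voxels must be c(rows, cols, slices), each >= 8")
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(lesion_fraction_of_brain, "lesion_fraction_of_brain", 0, 1)
  check_number(hemorrhage_fraction_of_brain, "hemorrhage_fraction_of_brain",
               0, 1)
  if (hemorrhage_phase_rad >= 0 || hemorrhage_phase_rad < -pi)
    stop_config("hemorrhage_phase_rad must lie in [-pi, 0)")
  means <- c(brain_mean, lesion_mean, background_mean)
  if (hemorrhage_fraction_of_brain > 0) means <- c(means, hemorrhage_mean)
  if (anyDuplicated(means))
    stop_config("compartment intensity means must be pairwise distinct")
  structure(list(shape_voxels = as.integer(shape_voxels),
                 voxel_size_mm = voxel_size_mm,
                 brain_mean = brain_mean, lesion_mean = lesion_mean,
                 hemorrhage_mean = hemorrhage_mean,
                 background_mean = background_mean, noise_sd = noise_sd,
                 lesion_fraction_of_brain = lesion_fraction_of_brain,
                 hemorrhage_fraction_of_brain = hemorrhage_fraction_of_brain,
                 hemorrhage_phase_rad = hemorrhage_phase_rad,
                 rng_seed = as.integer(rng_seed)),
            class = "mr_phantom_config")
}

#' Generate an MR phantom with ground-truth masks
#'
#' @param config an [mr_phantom_config()].
#' @return An `mr_phantom` list: `t2`, `magnitude`, `phase` (arrays
#'   `[row, col, slice]`), `masks` (logical arrays `brain`, `lesion`,
#'   `hemorrhage`), the realized fractions, and the configuration.
#' @export
generate_mr_phantom <- function(config) {
  if (!inherits(config, "mr_phantom_config"))
    stop_config("config must be an mr_phantom_config")
  dm <- config$shape_voxels
  nr <- dm[1L]; nc <- dm[2L]; ns <- dm[3L]
  ctr <- (dm + 1) / 2
  semi <- dm * 0.42
  rg <- (seq_len(nr) - ctr[1]) / semi[1]
  cg <- (seq_len(nc) - ctr[2]) / semi[2]
  sg <- (seq_len(ns) - ctr[3]) / semi[3]
  e2 <- outer(outer(rg^2, cg^2, `+`), sg^2, `+`)
  brain <- e2 <= 1
  n_brain <- sum(brain)

  grow_sphere <- function(center, target_n, within) {
    if (target_n > sum(within))
      stop_config("requested fraction cannot be realized in this geometry")
    d2 <- outer(outer((seq_len(nr) - center[1])^2,
                      (seq_len(nc) - center[2])^2, `+`),
                (seq_len(ns) - center[3])^2, `+`)
    dvals <- sort(d2[within])[target_n]
    within & d2 <= dvals
  }

  lesion <- array(FALSE, dm)
  if (config$lesion_fraction_of_brain > 0) {
    # cap seated at the cortical (top-row) surface of the brain
    surf <- c(ctr[1] - semi[1], ctr[2], ctr[3])
    lesion <- grow_sphere(surf, round(config$lesion_fraction_of_brain * n_brain),
                          brain)
  }
  hem <- array(FALSE, dm)
  if (config$hemorrhage_fraction_of_brain > 0) {
    if (!any(lesion))
      stop_config("hemorrhage requires a non-empty lesion")
    les_idx <- which(lesion, arr.ind = TRUE)
    les_ctr <- colMeans(les_idx)
    hem <- grow_sphere(les_ctr,
                       round(config$hemorrhage_fraction_of_brain * n_brain),
                       lesion)
  }

  t2 <- array(config$background_mean, dm)
  t2[brain] <- config$brain_mean
  t2[lesion] <- config$lesion_mean
  t2[hem] <- config$hemorrhage_mean

  magnitude <- array(config$background_mean / 2, dm)
  magnitude[brain] <- config$brain_mean
  magnitude[lesion] <- config$brain_mean * 1.1
  magnitude[hem] <- config$brain_mean * 0.6

  phase <- array(0, dm)
  phase[hem] <- config$hemorrhage_phase_rad

  if (config$noise_sd > 0) {
    with_seed(config$rng_seed, {
      t2 <- t2 + array(rnorm(length(t2), 0, config$noise_sd), dm)
      magnitude <- pmax(magnitude +
                          array(rnorm(length(t2), 0, config$noise_sd), dm), 0)
      phase <- phase + array(rnorm(length(t2), 0,
                                   config$noise_sd / config$brain_mean), dm)
    })
    phase <- pmin(pmax(phase, -pi), pi)
  }

  structure(list(t2 = t2, magnitude = magnitude, phase = phase,
                 masks = list(brain = brain, lesion = lesion,
                              hemorrhage = hem),
                 realized_lesion_fraction = sum(lesion) / n_brain,
                 realized_hemorrhage_fraction = sum(hem) / n_brain,
                 config = config),
            class = "mr_phantom")
}

#' @export
print.mr_phantom <- function(x, ...) {
  cat(sprintf(paste0("<mr_phantom> %s voxels; brain %d vox; lesion %.2f%%; ",
                     "hemorrhage %.3f%% of brain\n"),
              paste(x$config$shape_voxels, collapse = "x"),
              sum(x$masks$brain), 100 * x$realized_lesion_fraction,
              100 * x$realized_hemorrhage_fraction))
  invisible(x)
}

#' Write a volume as NIfTI-1
#' @param volume numeric array `[row, col, slice]`.
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxel_size_mm voxel edges in mm.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path, voxel_size_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#' @param path NIfTI file path.
#' @return Numeric array with a `voxel_size_mm` attribute.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)
  out
}
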