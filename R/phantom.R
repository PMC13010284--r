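#' Specification of a synthetic brain-tumor phantom
#'
#' Describes the geometry, tissue intensities, noise and inter-institution
#' gain variability of a synthetic subject: an ellipsoidal brain with a
#' posterior-inferior cerebellar reference region and a concentric
#' spherical tumor (gadolinium-enhancing core, non-enhancing tumor rim,
#' peritumoral edema shell). A latent tumor-cell-density map decays
#' linearly from its peak at the tumor center to zero at the outer rim
#' boundary and drives both the methionine-uptake (PET) signal and graded
#' components of the T2 and post-gadolinium T1 signals, so the MRI carries
#' the density information the downstream image translator must learn.
#'
#' The default density-to-uptake line gives tumor-to-normal ratio
#' `T/N = 1 + (suv_per_cell / brain SUV) * density`, i.e. a slope of
#' 5.8e-5 T/N per cell/mm2 at the default baseline uptake of 1.5 SUV —
#' the magnitude reported for methionine uptake versus glioblastoma cell
#' density in image-guided sampling studies.
#'
#' @param grid_shape integer length-3, voxel counts per axis
#' @param voxel_size_mm numeric length-3 (or scalar), voxel edge in mm
#' @param tissue_means named list of per-class mean intensities; each entry
#'   is a named vector `c(t1, t2, t1gd, pet)` in arbitrary MRI units and SUV.
#'   Classes: `background`, `brain`, `edema`, `tumor` (the non-enhancing rim;
#'   the enhancing core adds a density-graded enhancement on top).
#' @param noise_sd named vector `c(t1w, t2w, t1gd, pet)` of additive Gaussian
#'   noise SDs (MRI units / SUV); noisy intensities are clipped at zero
#' @param gain_range length-2 positive interval; each subject draws one
#'   global multiplicative gain per MRI modality from it (emulates arbitrary
#'   per-institution intensity scales; PET is in SUV and takes no gain)
#' @param tumor_geometry list: `center_mm` (NULL = default location in the
#'   right-anterior-superior brain), `core_radius_mm`, `rim_thickness_mm`,
#'   `edema_thickness_mm`
#' @param density_params list: `peak_density` (cells/mm2 at the tumor
#'   center), `suv_per_cell` (SUV increase per cell/mm2),
#'   `t2_density_gain` and `enhancement_gain` (peak graded T2 / enhancement
#'   amplitudes in MRI units)
#' @param geometry_jitter fraction by which radii and the tumor center are
#'   jittered across subjects of a cohort
#' @param n_sampling_points number of simulated tissue-sampling coordinates
#'   per subject (uniform in the tumor sphere, with analytic true density)
#' @param seed integer seed; identical spec + seed gives identical output
#' @return an object of class `phantom_spec`
#' @seealso [generate_subject()], [generate_cohort()]
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 64),
                         voxel_size_mm = c(2, 2, 2),
                         tissue_means = list(
                           background = c(t1 = 0,   t2 = 0,   t1gd = 0,   pet = 0),
                           brain      = c(t1 = 100, t2 = 100, t1gd = 100, pet = 1.5),
                           edema      = c(t1 = 85,  t2 = 160, t1gd = 85,  pet = 1.5),
                           tumor      = c(t1 = 90,  t2 = 160, t1gd = 90,  pet = 1.5)),
                         noise_sd = c(t1w = 2, t2w = 2, t1gd = 2, pet = 0.05),
                         gain_range = c(0.5, 2),
                         tumor_geometry = list(center_mm = NULL,
                                               core_radius_mm = 12,
                                               rim_thickness_mm = 8,
                                               edema_thickness_mm = 10),
                         density_params = list(peak_density = 30000,
                                               suv_per_cell = 8.7e-5,
                                               t2_density_gain = 40,
                                               enhancement_gain = 80),
                         geometry_jitter = 0.15,
                         n_sampling_points = 16,
                         seed = 1L) {
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_mm = as.numeric(voxel_size_mm),
               tissue_means = tissue_means, noise_sd = noise_sd,
               gain_range = as.numeric(gain_range),
               tumor_geometry = tumor_geometry,
               density_params = density_params,
               geometry_jitter = geometry_jitter,
               n_sampling_points = as.integer(n_sampling_points),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

# brain/cerebellum geometry derived from the field of view
phantom_anatomy <- function(spec) {
  fov <- spec$grid_shape * spec$voxel_size_mm
  center <- fov / 2
  brain_semi <- c(0.40, 0.44, 0.40) * fov
  cereb_center <- center + c(0, -0.55 * brain_semi[2], -0.55 * brain_semi[3])
  cereb_semi <- pmin(c(24, 18, 14), 0.35 * brain_semi)
  list(fov = fov, brain_center = center, brain_semi = brain_semi,
       cereb_center = cereb_center, cereb_semi = cereb_semi)
}

tumor_center_default <- function(anat) {
  anat$brain_center + c(0.35, 0.25, 0.15) * anat$brain_semi
}

validate_phantom_spec <- function(spec) {
  g <- spec$tumor_geometry
  if (any(c(g$core_radius_mm, g$rim_thickness_mm, g$edema_thickness_mm) <= 0))
    stop("tumor radii/thicknesses must be strictly positive")
  if (length(spec$gain_range) != 2L || any(spec$gain_range <= 0) ||
      diff(spec$gain_range) < 0)
    stop("gain_range must be a positive non-decreasing interval")
  if (any(spec$noise_sd < 0)) stop("noise_sd must be non-negative")
  if (spec$density_params$peak_density < 0) stop("peak_density must be >= 0")
  anat <- phantom_anatomy(spec)
  ctr <- spec$tumor_geometry$center_mm
  if (is.null(ctr)) ctr <- tumor_center_default(anat)
  check_tumor_in_brain(ctr, g$core_radius_mm + g$rim_thickness_mm, anat)
  invisible(spec)
}

# conservative containment: scaled center distance + r / (shortest semi-axis)
check_tumor_in_brain <- function(center, radius, anat) {
  f <- sqrt(sum(((center - anat$brain_center) / anat$brain_semi)^2))
  if (f + radius / min(anat$brain_semi) > 1)
    stop("tumor does not fit inside the brain; adjust tumor_geometry")
  invisible(TRUE)
}

ellipsoid_mask <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

#' Generate one synthetic subject
#'
#' Builds co-registered T1-weighted, T2-weighted, gadolinium-enhanced
#' T1-weighted and PET (SUV) volumes plus brain, cerebellum, tumor and
#' enhancing-core masks, the latent cell-density volume and simulated
#' tissue-sampling points. The forward model is affine in density:
#' `PET = baseline + suv_per_cell * density + noise`; T1Gd adds a
#' density-graded enhancement restricted to the enhancing core; T2 is
#' elevated in edema and tumor with a density-graded component. Each MRI
#' modality is scaled by a subject-level gain drawn from `gain_range`.
#'
#' @param spec a [phantom_spec()]
#' @param subject_index positive integer; combined with `spec$seed` it fixes
#'   the subject's RNG stream, geometry jitter, gains and noise
#' @return a `subject_volume_set`: list of volumes, masks, `cell_density`,
#'   `sampling_points` (tibble `x, y, z, true_density`), `gains`,
#'   `subject_id`, `voxel_size_mm`
#' @export
generate_subject <- function(spec, subject_index = 1L) {
  validate_phantom_spec(spec)
  sseed <- (spec$seed + 7919 * as.integer(subject_index)) %% 2147483647L
  set.seed(sseed)
  anat <- phantom_anatomy(spec)
  g <- spec$tumor_geometry
  jit <- spec$geometry_jitter

  ctr <- g$center_mm
  if (is.null(ctr)) ctr <- tumor_center_default(anat)
  # per-subject geometry jitter (subject_index 0 reserved: no jitter)
  if (jit > 0 && subject_index > 0) {
    ctr <- ctr + runif(3, -1, 1) * jit * g$core_radius_mm
    scale <- runif(3, 1 - jit, 1 + jit)
  } else scale <- c(1, 1, 1)
  core_r <- g$core_radius_mm * scale[1]
  rim_t <- g$rim_thickness_mm * scale[2]
  edema_t <- g$edema_thickness_mm * scale[3]
  r_out <- core_r + rim_t
  check_tumor_in_brain(ctr, r_out, anat)

  co <- coord_arrays(spec$grid_shape, spec$voxel_size_mm)
  brain <- ellipsoid_mask(co, anat$brain_center, anat$brain_semi)
  cereb <- ellipsoid_mask(co, anat$cereb_center, anat$cereb_semi) & brain
  r <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2)
  tumor <- (r <= r_out) & brain
  enhancing <- (r <= core_r) & brain
  edema <- (r > r_out) & (r <= r_out + edema_t) & brain & !cereb
  cereb <- cereb & !tumor  # reference region must stay tumor-free

  dp <- spec$density_params
  density <- dp$peak_density * pmax(1 - r / r_out, 0)
  density[!tumor] <- 0
  dfrac <- if (dp$peak_density > 0) density / dp$peak_density else density * 0

  tm <- spec$tissue_means
  pick <- function(field) {
    v <- array(tm$background[[field]], dim = spec$grid_shape)
    v[brain] <- tm$brain[[field]]
    v[edema] <- tm$edema[[field]]
    v[tumor] <- tm$tumor[[field]]
    v
  }
  t1 <- pick("t1")
  t2 <- pick("t2") + dp$t2_density_gain * dfrac
  t1gd <- pick("t1gd") + dp$enhancement_gain * dfrac * enhancing
  pet <- pick("pet") + dp$suv_per_cell * density

  nv <- prod(spec$grid_shape)
  ns <- spec$noise_sd
  gains <- runif(3, spec$gain_range[1], spec$gain_range[2])
  names(gains) <- c("t1w", "t2w", "t1gd")
  noisy <- function(clean, sd, gain = 1) {
    x <- clean
    if (sd > 0) x <- x + rnorm(nv, 0, sd)
    pmax(gain * x, 0)
  }
  vs <- spec$voxel_size_mm
  vol <- function(x) as_volume(x, vs)

  # tissue-sampling coordinates: uniform in the tumor sphere, analytic density
  npts <- spec$n_sampling_points
  if (npts > 0) {
    u <- matrix(rnorm(3 * npts), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- r_out * runif(npts)^(1 / 3)
    pos <- sweep(u * rad, 2, ctr, "+")
    pts <- tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          true_density = dp$peak_density *
                            pmax(0, 1 - rad / r_out))
  } else {
    pts <- tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          true_density = numeric(0))
  }

  subject <- list(
    subject_id = sprintf("sub-%d-%03d", spec$seed, as.integer(subject_index)),
    t1w = vol(noisy(t1, ns[["t1w"]], gains[["t1w"]])),
    t2w = vol(noisy(t2, ns[["t2w"]], gains[["t2w"]])),
    t1gd = vol(noisy(t1gd, ns[["t1gd"]], gains[["t1gd"]])),
    pet_suv = vol(noisy(pet, ns[["pet"]])),
    brain_mask = vol(brain * 1),
    cerebellum_mask = vol(cereb * 1),
    enhancing_mask = vol(enhancing * 1),
    tumor_mask = vol(tumor * 1),
    edema_mask = vol(edema * 1),
    cell_density = vol(density),
    sampling_points = pts,
    gains = gains,
    voxel_size_mm = vs,
    tumor_center_mm = ctr,
    tumor_radii_mm = c(core = core_r, rim = rim_t, edema = edema_t),
    seed = sseed
  )
  class(subject) <- "subject_volume_set"
  subject
}

#' Generate a cohort of synthetic subjects
#'
#' Subjects differ in geometry jitter, per-modality gains and noise
#' realisations; the whole cohort is a deterministic function of
#' `spec` and `seed`.
#'
#' @param spec a [phantom_spec()]
#' @param n_subjects number of subjects (>= 1)
#' @param seed cohort seed; replaces `spec$seed` so two cohorts with
#'   distinct seeds have disjoint subject ids
#' @return list of `subject_volume_set`
#' @export
generate_cohort <- function(spec, n_subjects, seed = spec$seed) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  spec$seed <- as.integer(seed)
  lapply(seq_len(n_subjects), function(i) generate_subject(spec, i))
}

#' @export
print.subject_volume_set <- function(x, ...) {
  cat(sprintf("<subject_volume_set> %s: grid %s @ %s mm, %d sampling points\n",
              x$subject_id, paste(dim(x$t1w), collapse = "x"),
              paste(signif(x$voxel_size_mm, 3), collapse = "x"),
              nrow(x$sampling_points)))
  invisible(x)
}
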