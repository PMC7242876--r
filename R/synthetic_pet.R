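# Synthetic PET phantoms: a hot interscapular region with known %ID/g and
# hand-style sparse contours traced from the true geometry.

#' Generate a PET phantom with a hot ellipsoidal region and sparse contours
#'
#' A hot ellipsoid (activated brown fat) at concentration `c_hot` over a low
#' background `c_bg`, with Gaussian (default) or Poisson-like noise. Axial
#' contours are traced from the true ellipsoid every `contour_every` slices
#' as 64-vertex polygons in mm, emulating the manual ROI workflow. The true
#' %ID/g is computed from the noiseless concentration over the true mask.
#'
#' @param dims grid (x, y, z), default `c(64, 64, 64)`.
#' @param spacing_mm isotropic voxel size (default 0.4 mm).
#' @param radii_vox ellipsoid semi-axes in voxels (default `c(10, 8, 12)`).
#' @param c_hot hot-region activity concentration (activity/mL).
#' @param c_bg background concentration.
#' @param injected_dose injected activity (same units).
#' @param noise `"gaussian"` or `"poisson"`; Gaussian uses `noise_sd`,
#'   Poisson scales counts by `poisson_scale` per voxel.
#' @param noise_sd Gaussian noise SD (default `0.02 * c_hot`).
#' @param poisson_scale expected counts per unit concentration for the
#'   Poisson model (default 200).
#' @param contour_every trace a contour every this many slices (default 3).
#' @param n_vertices vertices per contour polygon (default 64).
#' @param seed integer seed.
#' @return list with `volume` (PET [voxel_volume()]), `contours`
#'   ([contour_set()]), `true_mask` ([binary_mask()]),
#'   `true_percent_id_per_g`, `injected_dose`, `params`.
#' @export
make_pet_phantom <- function(dims = c(64, 64, 64), spacing_mm = 0.4,
                             radii_vox = c(10, 8, 12), c_hot = 2.0,
                             c_bg = 0.1, injected_dose = 10,
                             noise = c("gaussian", "poisson"),
                             noise_sd = 0.02 * c_hot, poisson_scale = 200,
                             contour_every = 3L, n_vertices = 64L,
                             seed = 1L) {
  noise <- match.arg(noise)
  dims <- as.integer(dims)
  stopifnot(injected_dose > 0)
  center <- (dims + 1) / 2
  if (any(radii_vox + 2 > dims / 2))
    stop("hot ellipsoid does not fit inside the grid")
  truth <- ellipsoid_mask(dims, center, radii_vox)
  sp <- rep(spacing_mm, 3)

  # contour slices spanning the ellipsoid, every `contour_every` slices,
  # keeping only slices where the section is at least 2 voxels in radius
  z_lo <- ceiling(center[3] - radii_vox[3])
  z_hi <- floor(center[3] + radii_vox[3])
  zall <- z_lo:z_hi
  fall <- 1 - ((zall - center[3]) / radii_vox[3])^2
  visible <- zall[fall > 0 & min(radii_vox[1:2]) * sqrt(pmax(fall, 0)) >= 1]
  # every `contour_every` slices, plus the first and last visible slice
  # (an annotator always contours the extremes of the structure)
  zs <- sort(unique(c(seq(min(visible), max(visible), by = contour_every),
                      max(visible))))
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  contours <- list()
  for (z in zs) {
    f <- 1 - ((z - center[3]) / radii_vox[3])^2
    if (f <= 0) next
    rx <- radii_vox[1] * sqrt(f)
    ry <- radii_vox[2] * sqrt(f)
    if (min(rx, ry) < 1) next
    vx <- center[1] + rx * cos(theta)
    vy <- center[2] + ry * sin(theta)
    contours[[length(contours) + 1L]] <-
      list(slice = as.integer(z),
           vertices = cbind((vx - 0.5) * sp[1], (vy - 0.5) * sp[2]))
  }

  with_seed(seed, {
    vals <- array(c_bg, dims)
    vals[truth] <- c_hot
    true_pct <- 100 * mean(vals[truth]) / injected_dose
    if (noise == "gaussian") {
      if (noise_sd > 0) vals <- vals + stats::rnorm(length(vals), 0, noise_sd)
    } else {
      vals <- stats::rpois(length(vals), vals * poisson_scale) / poisson_scale
      dim(vals) <- dims
    }
    list(volume = voxel_volume(vals, sp, "PET_ACTIVITY"),
         contours = contour_set(contours, sp),
         true_mask = binary_mask(truth, "ROI"),
         true_percent_id_per_g = true_pct,
         injected_dose = injected_dose,
         params = list(dims = dims, spacing_mm = spacing_mm,
                       radii_vox = radii_vox, c_hot = c_hot, c_bg = c_bg,
                       injected_dose = injected_dose, noise = noise,
                       noise_sd = noise_sd, contour_every = contour_every,
                       seed = seed))
  })
}

#' Generate a paired PET / gamma-count cohort from shared ground truth
#'
#' Each subject gets one true uptake value; the PET measurement runs the
#' full image pipeline (phantom, contour interpolation, ROI mean) and the
#' gamma count is derived from the same truth with small weighing/counting
#' noise. Used to exercise the PET-vs-gamma agreement regression.
#'
#' @param n_subjects number of animals (default 9).
#' @param uptake_range range of true %ID/g across subjects.
#' @param injected_dose injected activity per subject.
#' @param gamma_cv coefficient of variation of the gamma measurement
#'   (default 0.02).
#' @param dims,spacing_mm phantom grid passed to [make_pet_phantom()].
#' @param seed integer seed.
#' @return data.frame: subject, true_percent_id_per_g, pet_percent_id_per_g,
#'   gamma_percent_id_per_g, tissue_weight_g.
#' @export
make_pet_gamma_cohort <- function(n_subjects = 9, uptake_range = c(5, 30),
                                  injected_dose = 10, gamma_cv = 0.02,
                                  dims = c(48, 48, 48), spacing_mm = 0.4,
                                  seed = 1L) {
  with_seed(seed, {
    true_u <- sort(stats::runif(n_subjects, uptake_range[1], uptake_range[2]))
    weights <- stats::runif(n_subjects, 0.08, 0.15)
    sub_seeds <- sample.int(1e6, n_subjects)
    pet <- numeric(n_subjects)
    gamma <- numeric(n_subjects)
    for (i in seq_len(n_subjects)) {
      c_hot <- true_u[i] * injected_dose / 100
      ph <- make_pet_phantom(dims = dims, spacing_mm = spacing_mm,
                             radii_vox = c(9, 8, 11), c_hot = c_hot,
                             c_bg = 0.02 * c_hot, injected_dose = injected_dose,
                             noise_sd = 0.02 * c_hot, seed = sub_seeds[i])
      roi <- interpolate_roi(ph$contours, dim(ph$volume$data))
      pet[i] <- compute_pet_uptake(ph$volume, roi, injected_dose)$percent_id_per_g
      counts_inj <- 1e6
      counts <- true_u[i] / 100 * counts_inj * weights[i] *
        (1 + stats::rnorm(1, 0, gamma_cv))
      gamma[i] <- gamma_uptake(counts, counts_inj, weights[i])
    }
    data.frame(subject = seq_len(n_subjects),
               true_percent_id_per_g = true_u,
               pet_percent_id_per_g = pet,
               gamma_percent_id_per_g = gamma,
               tissue_weight_g = weights)
  })
}
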