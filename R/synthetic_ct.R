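# Synthetic whole-body CT phantoms with voxel-exact ground truth.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All generators go through this, which makes
# every phantom a pure function of (parameters, seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Logical ellipsoid mask on a voxel grid (voxel-center sampling).
ellipsoid_mask <- function(dims, center, radii) {
  x <- ((seq_len(dims[1]) - center[1]) / radii[1])^2
  y <- ((seq_len(dims[2]) - center[2]) / radii[2])^2
  z <- ((seq_len(dims[3]) - center[3]) / radii[3])^2
  m <- outer(outer(x, y, `+`), z, `+`) <= 1
  dim(m) <- dims
  m
}

# Deterministically trim `excess` voxels from a mask, farthest-first from
# `center` (ties by linear index), keeping the retained part compact.
trim_mask <- function(mask, dims, center, excess) {
  if (excess <= 0L) return(mask)
  w <- which(mask)
  z <- (w - 1L) %/% (dims[1] * dims[2]) + 1L
  rem <- (w - 1L) %% (dims[1] * dims[2])
  y <- rem %/% dims[1] + 1L
  x <- rem %% dims[1] + 1L
  d2 <- (x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2
  drop <- w[order(-d2, -w)][seq_len(excess)]
  mask[drop] <- FALSE
  mask
}

#' Generate a whole-body CT phantom with known fat fraction
#'
#' Emulates a rodent whole-body micro-CT: an ellipsoidal soft-tissue body
#' (around +60 HU) in an air background (-1000 HU), two lung cavities
#' (-900 HU), and fat compartments (around -100 HU) laid down as a
#' subcutaneous shell beneath a soft-tissue skin layer plus interior blobs
#' until an exact target fraction of the air-excluded body volume is
#' reached. Fat is kept clear of air interfaces (skin depth and a margin
#' around the lungs) the way subcutaneous and gonadal depots are, so the
#' recorded truth is a property of the geometry, not of interface voxels.
#' Optionally the noiseless volume is blurred to emulate the scanner's
#' partial-volume effect before Gaussian noise is added.
#'
#' @param dims grid size (x, y, z), default `c(96, 96, 128)`.
#' @param spacing_mm isotropic voxel size in mm (default 0.2).
#' @param fat_fraction target true fat fraction of the air-excluded body
#'   volume, in (0, 0.6); 0 generates a fat-free phantom.
#' @param noise_sd_hu standard deviation of additive Gaussian noise (HU),
#'   default 20.
#' @param lungs logical; include the two lung cavities.
#' @param blurred_interfaces logical; blur the noiseless phantom with a
#'   1-voxel kernel so air/tissue interface voxels take intermediate values
#'   (the partial-volume stressor).
#' @param skin_vox thickness (Chebyshev voxels) of the fat-free soft-tissue
#'   rind between the body surface and the subcutaneous fat shell; must
#'   exceed the air dilation used by the partial-volume correction.
#' @param hu named list overriding tissue intensities
#'   (`body`, `fat`, `lung`, `background`).
#' @param seed integer seed; identical parameters + seed give identical
#'   phantoms.
#' @return list with `volume` (a [voxel_volume()]), ground-truth masks
#'   `body`, `fat`, `lung` ([binary_mask()]), `true_percent_fat`, and
#'   `params`.
#' @export
make_ct_phantom <- function(dims = c(96, 96, 128), spacing_mm = 0.2,
                            fat_fraction = 0.30, noise_sd_hu = 20,
                            lungs = TRUE, blurred_interfaces = FALSE,
                            skin_vox = 4L,
                            hu = list(body = 60, fat = -100, lung = -900,
                                      background = -1000),
                            seed = 1L) {
  if (fat_fraction < 0 || fat_fraction >= 0.6)
    stop("fat_fraction must lie in [0, 0.6)")
  dims <- as.integer(dims)
  with_seed(seed, {
    center <- (dims + 1) / 2
    radii <- c(0.40 * dims[1], 0.40 * dims[2], 0.46 * dims[3])
    body <- ellipsoid_mask(dims, center, radii)

    lung <- array(FALSE, dims)
    if (lungs) {
      zc <- center[3] + 0.55 * radii[3]
      lr <- c(0.16 * dims[1], 0.16 * dims[2], 0.10 * dims[3])
      lung <- ellipsoid_mask(dims, c(center[1] - 0.18 * dims[1], center[2], zc), lr) |
        ellipsoid_mask(dims, c(center[1] + 0.18 * dims[1], center[2], zc), lr)
      lung <- lung & erode_mask(body, 3L)
    }

    denom <- sum(body) - sum(lung)
    target <- as.integer(round(fat_fraction * denom))
    fat <- array(FALSE, dims)

    if (target > 0L) {
      lung_margin <- if (any(lung)) dilate_mask(lung, 7L) else lung
      # Subcutaneous shell beneath the skin rind. The shell band is at least
      # three voxels thick (real depots are sheets of ~0.5 mm and up, never
      # one voxel); small targets take a contiguous angular wedge of the
      # full-thickness band rather than a thin whole-body layer.
      eroded <- body
      for (k in seq_len(skin_vox)) eroded <- erode_mask(eroded, 1L, se = "box")
      base_layers <- 3L
      deeper <- eroded
      for (k in seq_len(base_layers)) deeper <- erode_mask(deeper, 1L, se = "box")
      zone <- eroded & !deeper & !lung_margin
      if (sum(zone) > target) {
        w <- which(zone)
        rem <- (w - 1L) %% (dims[1] * dims[2])
        y <- rem %/% dims[1] + 1L
        x <- rem %% dims[1] + 1L
        ang <- atan2(y - center[2], x - center[1])
        keep <- w[order(ang, w)][seq_len(target)]
        zone[] <- FALSE
        zone[keep] <- TRUE
      }
      fat <- zone
      # deepen the shell layer by layer for larger targets
      extra <- 0L
      while (sum(fat) < target && extra < 5L) {
        inner <- erode_mask(deeper, 1L, se = "box")
        layer <- deeper & !inner & !lung_margin
        need <- target - sum(fat)
        if (sum(layer) > need) {
          w <- which(layer)
          rem <- (w - 1L) %% (dims[1] * dims[2])
          y <- rem %/% dims[1] + 1L
          x <- rem %% dims[1] + 1L
          ang <- atan2(y - center[2], x - center[1])
          keep <- w[order(ang, w)][seq_len(need)]
          layer[] <- FALSE
          layer[keep] <- TRUE
        }
        fat <- fat | layer
        deeper <- inner
        extra <- extra + 1L
      }
      # interior blobs emulating visceral depot lobes (radius 1.2-2.2 mm at
      # the default 0.2 mm spacing)
      allowed <- deeper & !lung_margin
      attempts <- 0L
      while (sum(fat) < target) {
        attempts <- attempts + 1L
        free <- which(allowed & !fat)
        need <- target - sum(fat)
        if (length(free) < need)
          stop("requested fat fraction is unattainable for this geometry")
        if (attempts > 60L) {
          # dense phantom: finish with one compact central depot
          z <- (free - 1L) %/% (dims[1] * dims[2]) + 1L
          rem <- (free - 1L) %% (dims[1] * dims[2])
          y <- rem %/% dims[1] + 1L
          x <- rem %% dims[1] + 1L
          d2 <- (x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2
          fat[free[order(d2, free)][seq_len(need)]] <- TRUE
          break
        }
        c0 <- free[sample.int(length(free), 1L)]
        z0 <- (c0 - 1L) %/% (dims[1] * dims[2]) + 1L
        rem <- (c0 - 1L) %% (dims[1] * dims[2])
        bc <- c(rem %% dims[1] + 1L, rem %/% dims[1] + 1L, z0)
        r <- stats::runif(1, 6, 11)
        blob <- ellipsoid_mask(dims, bc, rep(r, 3)) & allowed & !fat
        excess <- sum(fat) + sum(blob) - target
        if (excess > 0L) blob <- trim_mask(blob, dims, bc, excess)
        fat <- fat | blob
      }
    }

    vals <- array(hu$background, dims)
    vals[body] <- hu$body
    vals[fat] <- hu$fat
    vals[lung] <- hu$lung
    if (blurred_interfaces) vals <- gaussian_blur(vals, 0.5)
    if (noise_sd_hu > 0)
      vals <- vals + stats::rnorm(length(vals), 0, noise_sd_hu)

    list(volume = voxel_volume(vals, rep(spacing_mm, 3), "CT_HU"),
         body = binary_mask(body, "BODY"),
         fat = binary_mask(fat, "FAT_FINAL"),
         lung = binary_mask(lung, "LUNG"),
         true_percent_fat = 100 * sum(fat) / denom,
         params = list(dims = dims, spacing_mm = spacing_mm,
                       fat_fraction = fat_fraction,
                       noise_sd_hu = noise_sd_hu, lungs = lungs,
                       blurred_interfaces = blurred_interfaces,
                       skin_vox = skin_vox, seed = seed))
  })
}
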