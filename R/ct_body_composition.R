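# Automated lean/fat measurement on whole-body micro-CT.
#
# The pipeline mirrors the standard small-animal workflow: normalize to the
# Hounsfield scale, Gaussian-smooth (sigma = 0.1 mm), threshold at -700 HU
# and keep the largest connected object as the body; then take candidate fat
# as body voxels in [-250, 50] HU, and correct the partial-volume effect at
# air/tissue interfaces by masking out candidate voxels within a 3-voxel
# dilation of air regions (6 voxels around the lung, the largest air region
# inside the body) before final speckle/hole cleanup.

adp_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "adipophen_error")))
}

#' Normalize raw CT intensities to the Hounsfield scale
#'
#' Applies the affine rescale `HU = slope * raw + intercept` and tags the
#' result as a CT volume.
#'
#' @param raw numeric 3-D array of raw scanner values.
#' @param slope rescale slope (must be nonzero).
#' @param intercept rescale intercept.
#' @param spacing voxel spacing in mm, length 3.
#' @return a [voxel_volume()] with modality `"CT_HU"`.
#' @export
normalize_to_hounsfield <- function(raw, slope, intercept, spacing = c(1, 1, 1)) {
  if (!is.finite(slope) || slope == 0)
    adp_error("rescale slope must be nonzero", "invalid_calibration")
  voxel_volume(slope * raw + intercept, spacing, "CT_HU")
}

#' Gaussian-smooth a volume with a physical sigma
#'
#' The physical sigma (mm) is converted per axis into voxel units via the
#' volume spacing, so anisotropic grids are smoothed isotropically in
#' physical space.
#'
#' @param volume a [voxel_volume()].
#' @param sigma_mm physical standard deviation in mm; 0 returns the input.
#' @return a [voxel_volume()].
#' @export
smooth_volume <- function(volume, sigma_mm = 0.1) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  if (sigma_mm == 0) return(volume)
  out <- gaussian_blur(volume$data, sigma_mm / volume$spacing)
  voxel_volume(out, volume$spacing, volume$modality)
}

#' Segment the mouse body from a whole-body CT volume
#'
#' Gaussian smoothing (physical sigma), a binary threshold that removes
#' background voxels below `background_hu`, and retention of the single
#' largest connected component (26-connectivity).
#'
#' @param volume a CT [voxel_volume()].
#' @param sigma_mm smoothing sigma in mm applied before thresholding; pass 0
#'   if the volume has already been smoothed.
#' @param background_hu voxels with smoothed intensity `>= background_hu`
#'   are body candidates (default -700 HU).
#' @return a [binary_mask()] with role `"BODY"`.
#' @export
segment_body <- function(volume, sigma_mm = 0.1, background_hu = -700) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (volume$modality != "CT_HU") stop("segment_body expects a CT_HU volume")
  vs <- smooth_volume(volume, sigma_mm)
  th <- vs$data >= background_hu
  if (!any(th))
    adp_error("no voxels above the background threshold: no body found",
              "no_body_found")
  binary_mask(largest_component(th, 26L), "BODY")
}

#' Segment fat within the body with partial-volume correction
#'
#' Candidate fat is every body voxel whose intensity lies in the closed
#' interval `fat_range_hu`. To correct the partial-volume effect at
#' air/tissue interfaces, air regions (strictly below `air_below_hu`, small
#' speckles removed) are dilated by `air_dilation_px` voxels — the lung,
#' defined as the largest air component strictly interior to the body, by an
#' additional `lung_extra_dilation_px` — and candidate voxels inside the
#' dilated zones are excluded. The remaining mask is cleaned of speckles by
#' a one-voxel morphological opening followed by removal of components
#' smaller than `min_object_voxels`, and enclosed holes are filled (within
#' the candidate set, so the result always stays inside it).
#'
#' @param volume the (smoothed) CT [voxel_volume()] used for thresholding.
#' @param body a `"BODY"` [binary_mask()] from [segment_body()].
#' @param fat_range_hu closed HU interval for fat, default `c(-250, 50)`.
#' @param air_below_hu air is strictly below this HU value (default -250).
#' @param air_dilation_px dilation (voxels) applied to all air regions.
#' @param lung_extra_dilation_px additional dilation for the lung region.
#' @param min_object_voxels minimum component size kept in the air and final
#'   fat masks (default 27 = one 3x3x3 structuring element volume).
#' @param pv_correction logical; disable to skip the air-dilation exclusion
#'   (used to demonstrate the size of the partial-volume artifact).
#' @param speckle_opening logical; apply the one-voxel opening during final
#'   cleanup (on by default; set `FALSE` for pure size-based filtering).
#' @param fill_fat_holes logical; fill enclosed cavities of the final fat
#'   mask (restricted to candidate voxels outside the exclusion zone).
#' @param dilate_2d logical; if `TRUE` the air/lung dilations are applied
#'   slice-wise in-plane instead of in 3-D.
#' @return list with [binary_mask()] elements `fat` (`FAT_FINAL`),
#'   `candidate` (`FAT_CANDIDATE`), `air` (`AIR`), `lung` (`LUNG`) and the
#'   logical `excluded` partial-volume zone.
#' @export
segment_fat <- function(volume, body,
                        fat_range_hu = c(-250, 50),
                        air_below_hu = -250,
                        air_dilation_px = 3L,
                        lung_extra_dilation_px = 3L,
                        min_object_voxels = 27L,
                        pv_correction = TRUE,
                        speckle_opening = TRUE,
                        fill_fat_holes = TRUE,
                        dilate_2d = FALSE) {
  stopifnot(inherits(volume, "voxel_volume"))
  bodym <- mask_data(body)
  if (!any(bodym)) stop("body mask is empty")
  hu <- volume$data
  d <- dim(hu)
  axes <- if (dilate_2d) 1:2 else 1:3

  cand <- bodym & hu >= fat_range_hu[1] & hu <= fat_range_hu[2]

  air <- hu < air_below_hu
  air <- remove_small_components(air, min_object_voxels, 26L)

  # Lung: largest air component strictly interior to the body, i.e. enclosed
  # by it. Air cavities are below the body threshold, so "inside" is judged
  # against the hole-filled body: a lung component lies entirely within the
  # filled body, strictly off its boundary. Ties: lowest centroid z, y, x.
  body_filled <- fill_holes(bodym)
  interior <- erode_mask(body_filled, 1L)
  lung <- array(FALSE, d)
  air_lab <- label_components(air, 26L)
  n_air <- attr(air_lab, "n_components")
  if (n_air > 0L) {
    inside <- rep(TRUE, n_air)
    out_labels <- unique(air_lab[air & !interior])
    inside[out_labels[out_labels > 0L]] <- FALSE
    cand_labels <- which(inside)
    if (length(cand_labels) > 0L) {
      sizes <- component_sizes(air_lab)[cand_labels]
      best <- cand_labels[sizes == max(sizes)]
      if (length(best) > 1L) {
        cent <- vapply(best, function(l) {
          w <- which(air_lab == l)
          z <- (w - 1L) %/% (d[1] * d[2]) + 1L
          rem <- (w - 1L) %% (d[1] * d[2])
          y <- rem %/% d[1] + 1L
          x <- rem %% d[1] + 1L
          c(mean(z), mean(y), mean(x))
        }, numeric(3))
        ord <- order(cent[1, ], cent[2, ], cent[3, ])
        best <- best[ord[1]]
      }
      lung <- array(air_lab == best[1], d)
    }
  }
  if (!any(lung))
    warning("no air component strictly inside the body: lung mask is empty")

  excluded <- array(FALSE, d)
  if (pv_correction && any(air)) {
    excluded <- dilate_mask(air, air_dilation_px, axes)
    if (any(lung)) {
      excluded <- excluded |
        dilate_mask(lung, air_dilation_px + lung_extra_dilation_px, axes)
    }
  }

  fat <- cand & !excluded
  # speckle policy: one opening by the 3x3x3 box (the same structuring
  # element whose volume, 27 voxels, is the size cutoff below)
  if (speckle_opening) fat <- open_mask(fat, 1L, se = "box")
  fat <- remove_small_components(fat, min_object_voxels, 26L)
  if (fill_fat_holes && any(fat)) {
    # fill enclosed cavities, but stay inside the candidate set and outside
    # the partial-volume exclusion zone so FAT_FINAL <= FAT_CANDIDATE holds
    fat <- fat | (fill_holes(fat) & cand & !excluded)
  }

  list(fat = binary_mask(fat, "FAT_FINAL"),
       candidate = binary_mask(cand, "FAT_CANDIDATE"),
       air = binary_mask(air, "AIR"),
       lung = binary_mask(lung, "LUNG"),
       excluded = excluded)
}

#' Percentage fat of the air-excluded body volume
#'
#' `percent_fat = 100 * |fat| / |body \\ air|`: the denominator is the whole
#' body volume excluding air.
#'
#' @param fat `FAT_FINAL` [binary_mask()].
#' @param body `BODY` [binary_mask()].
#' @param air `AIR` [binary_mask()].
#' @param spacing voxel spacing (mm, length 3) used to report voxel volume.
#' @return object of class `fat_fraction_result` with fields `fat_voxels`,
#'   `body_voxels_excl_air`, `percent_fat` and `voxel_volume_mm3`.
#' @export
compute_fat_fraction <- function(fat, body, air, spacing = c(1, 1, 1)) {
  f <- mask_data(fat); b <- mask_data(body); a <- mask_data(air)
  stopifnot(identical(dim(f), dim(b)), identical(dim(f), dim(a)))
  denom <- sum(b & !a)
  if (denom == 0L)
    adp_error("body excluding air is empty: fat fraction undefined",
              "undefined_fraction")
  nf <- sum(f)
  structure(list(fat_voxels = nf,
                 body_voxels_excl_air = denom,
                 percent_fat = 100 * nf / denom,
                 voxel_volume_mm3 = prod(as.numeric(spacing))),
            class = "fat_fraction_result")
}

#' @export
print.fat_fraction_result <- function(x, ...) {
  cat(sprintf("<fat_fraction_result> %.2f%% fat (%d / %d voxels, voxel %.4g mm^3)\n",
              x$percent_fat, x$fat_voxels, x$body_voxels_excl_air,
              x$voxel_volume_mm3))
  invisible(x)
}

#' @export
as.data.frame.fat_fraction_result <- function(x, row.names = NULL,
                                              optional = FALSE, ...,
                                              subject_id = NA_character_) {
  data.frame(subject_id = subject_id,
             fat_voxels = x$fat_voxels,
             body_voxels_excl_air = x$body_voxels_excl_air,
             percent_fat = x$percent_fat,
             voxel_volume_mm3 = x$voxel_volume_mm3,
             stringsAsFactors = FALSE)
}

#' Whole-body CT fat quantification pipeline
#'
#' Convenience wrapper: smooth once, segment the body (or accept a
#' user-supplied pre-mask), segment fat with partial-volume correction, and
#' compute the fat fraction.
#'
#' The smoothed volume is used for body extraction only: thresholding fat on
#' a smoothed image systematically grows the fat mask into lean tissue at
#' every fat/lean interface (the upper window bound of 50 HU lies far on the
#' lean side of the blurred transition between -100 and +60 HU), so the fat
#' and air thresholds are applied to the original intensities by default.
#' Set `threshold_smoothed = TRUE` to threshold the smoothed volume instead.
#'
#' @param volume a CT [voxel_volume()] on the Hounsfield scale.
#' @param sigma_mm Gaussian smoothing sigma in mm (default 0.1), used for
#'   the body segmentation.
#' @param background_hu body threshold (default -700 HU).
#' @param body_mask optional precomputed `BODY` [binary_mask()] (e.g. a
#'   manual contour); when given, body segmentation is skipped.
#' @param threshold_smoothed logical; apply the fat/air thresholds to the
#'   smoothed rather than the original volume.
#' @param ... further arguments passed to [segment_fat()].
#' @return list with `body`, `fat`, `candidate`, `air`, `lung`, `excluded`
#'   masks, the smoothed volume `smoothed`, and `result`
#'   (a `fat_fraction_result`).
#' @export
ct_fat_pipeline <- function(volume, sigma_mm = 0.1, background_hu = -700,
                            body_mask = NULL, threshold_smoothed = FALSE, ...) {
  vs <- smooth_volume(volume, sigma_mm)
  body <- if (is.null(body_mask)) {
    segment_body(vs, sigma_mm = 0, background_hu = background_hu)
  } else {
    body_mask
  }
  seg <- segment_fat(if (threshold_smoothed) vs else volume, body, ...)
  res <- compute_fat_fraction(seg$fat, body, seg$air, volume$spacing)
  c(list(body = body, smoothed = vs, result = res), seg)
}
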