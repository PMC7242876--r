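# Brown-fat FDG uptake: sparse contour interpolation, %ID/g, gamma counts,
# and PET-vs-gamma agreement.

#' Sparse axial contour set
#'
#' Planar polygons traced on a subset of axial slices (the standard manual
#' ROI workflow: contours every few slices, the full volume reconstructed by
#' interpolation). Vertices are in physical mm within the slice plane
#' (x, y); slice indices are 1-based along the volume's third axis.
#'
#' @param contours list of lists with elements `slice` (integer) and
#'   `vertices` (n x 2 matrix, mm).
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @return object of class `contour_set`.
#' @export
contour_set <- function(contours, spacing) {
  if (length(contours) < 2L)
    adp_error("at least two contours are required for interpolation",
              "single_contour")
  slices <- vapply(contours, function(ct) as.integer(ct$slice), integer(1))
  if (any(duplicated(slices)))
    stop("contour slice indices must be unique")
  contours <- contours[order(slices)]
  contours <- lapply(contours, function(ct) {
    ct$slice <- as.integer(ct$slice)
    ct
  })
  for (ct in contours) {
    v <- ct$vertices
    if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 3L)
      adp_error("each contour needs >= 3 (x, y) vertices", "invalid_contour")
    if (!polygon_is_simple(v))
      adp_error("contour polygon is self-intersecting", "invalid_contour")
  }
  structure(list(contours = contours, spacing = as.numeric(spacing)),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  sl <- vapply(x$contours, `[[`, integer(1), "slice")
  cat(sprintf("<contour_set> %d contours on slices %s\n", length(sl),
              paste(sl, collapse = ", ")))
  invisible(x)
}

# Simple-polygon test: no two non-adjacent edges intersect.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent around the loop
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Rasterize one contour polygon (vertices in mm) onto a slice grid.
rasterize_contour <- function(vertices, nx, ny, spacing) {
  # voxel i has center (i - 0.5) * spacing
  vx <- vertices[, 1] / spacing[1] + 0.5
  vy <- vertices[, 2] / spacing[2] + 0.5
  rasterize_polygon(vx, vy, nx, ny)
}

#' Interpolate sparse axial contours into a 3-D ROI mask
#'
#' Shape-based interpolation: each contour is rasterized on its own slice
#' (even-odd fill at voxel centers); for slices between two contours the
#' per-slice signed Euclidean distance maps are linearly interpolated along
#' the slice axis and thresholded at zero. Contour slices themselves
#' reproduce their rasterization exactly; slices outside the first/last
#' contour are empty.
#'
#' @param contours a [contour_set()].
#' @param target_shape integer (nx, ny, nz) of the target grid.
#' @return a [binary_mask()] with role `"ROI"`.
#' @export
interpolate_roi <- function(contours, target_shape) {
  stopifnot(inherits(contours, "contour_set"))
  d <- as.integer(target_shape)
  sp <- contours$spacing
  slices <- vapply(contours$contours, `[[`, integer(1), "slice")
  if (any(slices < 1L) || any(slices > d[3]))
    stop("contour slice indices outside the target grid")
  rast <- lapply(contours$contours, function(ct)
    rasterize_contour(ct$vertices, d[1], d[2], sp))
  if (any(!vapply(rast, any, logical(1))))
    adp_error("a contour rasterizes to an empty slice", "invalid_contour")
  out <- array(FALSE, d)
  for (i in seq_along(slices)) out[, , slices[i]] <- rast[[i]]
  for (i in seq_len(length(slices) - 1L)) {
    z0 <- slices[i]; z1 <- slices[i + 1L]
    if (z1 - z0 < 2L) next
    s0 <- signed_distance_2d(rast[[i]])
    s1 <- signed_distance_2d(rast[[i + 1L]])
    for (z in (z0 + 1L):(z1 - 1L)) {
      t <- (z - z0) / (z1 - z0)
      out[, , z] <- ((1 - t) * s0 + t * s1) > 0
    }
  }
  binary_mask(out, "ROI")
}

#' Mean tracer uptake in an ROI as percent injected dose per gram
#'
#' `%ID/g = 100 * mean activity concentration / (injected dose * density)`;
#' with the default tissue density of 1 g/mL the ROI mass equals its volume.
#'
#' @param pet a `PET_ACTIVITY` [voxel_volume()] (activity per mL).
#' @param roi an `ROI` [binary_mask()] (or logical array).
#' @param injected_dose injected activity, same activity units as the
#'   volume; must be positive.
#' @param tissue_density_g_per_ml tissue density (default 1.0).
#' @return object of class `uptake_result` with `mean_intensity`,
#'   `injected_dose`, `percent_id_per_g`, `mask_voxels`, `mask_volume_ml`,
#'   `mask_weight_g`.
#' @export
compute_pet_uptake <- function(pet, roi, injected_dose,
                               tissue_density_g_per_ml = 1.0) {
  stopifnot(inherits(pet, "voxel_volume"))
  if (pet$modality != "PET_ACTIVITY")
    stop("compute_pet_uptake expects a PET_ACTIVITY volume")
  m <- mask_data(roi)
  stopifnot(identical(dim(m), dim(pet$data)))
  if (!any(m)) adp_error("empty ROI", "empty_roi")
  if (!is.finite(injected_dose) || injected_dose <= 0)
    stop("injected_dose must be positive")
  conc <- mean(pet$data[m])
  vol_ml <- sum(m) * prod(pet$spacing) / 1000  # mm^3 -> mL
  structure(list(mean_intensity = conc,
                 injected_dose = injected_dose,
                 percent_id_per_g = 100 * conc /
                   (injected_dose * tissue_density_g_per_ml),
                 mask_voxels = sum(m),
                 mask_volume_ml = vol_ml,
                 mask_weight_g = vol_ml * tissue_density_g_per_ml),
            class = "uptake_result")
}

#' @export
print.uptake_result <- function(x, ...) {
  cat(sprintf("<uptake_result> %.4g %%ID/g (mean intensity %.4g, dose %.4g, %d voxels)\n",
              x$percent_id_per_g, x$mean_intensity, x$injected_dose,
              x$mask_voxels))
  invisible(x)
}

#' Gamma-count uptake as percent injected dose per gram
#'
#' `%ID/g = 100 * counts / (injected_counts * tissue_weight_g)`, the
#' scintillation-counter analogue of PET uptake, normalized to tissue
#' weight. Vectorized over records.
#'
#' @param counts decay-corrected tissue counts (>= 0).
#' @param injected_counts counts equivalent of the injected dose (> 0).
#' @param tissue_weight_g excised tissue weight in g (> 0).
#' @return numeric vector of %ID/g.
#' @export
gamma_uptake <- function(counts, injected_counts, tissue_weight_g) {
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(injected_counts <= 0)) stop("injected_counts must be > 0")
  if (any(tissue_weight_g <= 0)) stop("tissue_weight_g must be > 0")
  100 * counts / (injected_counts * tissue_weight_g)
}

#' Gamma-count uptake for a records table
#'
#' @param records data.frame with columns `tissue`, `counts`,
#'   `injected_counts`, `tissue_weight_g` (and optionally `subject`).
#' @return the input data.frame with a `percent_id_per_g` column appended.
#' @export
gamma_uptake_table <- function(records) {
  need <- c("tissue", "counts", "injected_counts", "tissue_weight_g")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  records$percent_id_per_g <- gamma_uptake(records$counts,
                                           records$injected_counts,
                                           records$tissue_weight_g)
  records
}

#' Agreement regression between PET and gamma-count uptake
#'
#' Ordinary least squares of gamma-count %ID/g on PET %ID/g, with the
#' Pearson correlation and the two-sided p-value for the slope. This is the
#' standard cross-validation of image-derived uptake against excised-tissue
#' counting.
#'
#' @param pet_vals,gamma_vals paired %ID/g values, equal length >= 3.
#' @return list with `slope`, `intercept`, `r`, `r_squared`, `p_value`, `n`.
#' @export
correlate_pet_gamma <- function(pet_vals, gamma_vals) {
  if (length(pet_vals) != length(gamma_vals) || length(pet_vals) < 3L)
    stop("need paired vectors of equal length >= 3")
  if (stats::var(pet_vals) == 0)
    adp_error("zero variance in the PET values: regression is degenerate",
              "degenerate_regression")
  fit <- stats::lm(gamma_vals ~ pet_vals)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(pet_vals, gamma_vals),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(pet_vals))
}
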