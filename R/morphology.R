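#' @useDynLib adipophen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Label connected components of a binary array
#'
#' Flood-fill connected-component labeling of a 2-D or 3-D logical array.
#' Labels are assigned in column-major first-encounter order, so the result
#' is deterministic for a given input. The package convention pairs
#' 26-connectivity for objects with 6-connectivity for background/holes
#' (8/4 in two dimensions), the standard complementary pairing that avoids
#' topological paradoxes.
#'
#' @param mask logical array (2-D or 3-D).
#' @param connectivity 6, 18 or 26 for 3-D input; 4 or 8 for 2-D input.
#' @return integer array of the same shape; 0 = background, 1..k = components.
#'   The number of components is attached as attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("`mask` must be a 2-D or 3-D array")
  conn <- as.integer(connectivity)
  if (length(d) == 2L) {
    conn <- switch(as.character(conn), "4" = 6L, "8" = 26L,
                   "6" = 6L, "26" = 26L,
                   stop("2-D connectivity must be 4 or 8"))
    dim3 <- c(d, 1L)
  } else {
    dim3 <- d
  }
  lab <- .label_cc_cpp(as.logical(mask), as.integer(dim3), conn)
  nc <- attr(lab, "n_components")
  dim(lab) <- d
  attr(lab, "n_components") <- nc
  lab
}

#' Sizes of labeled components
#' @param labels integer array from [label_components()].
#' @return integer vector of voxel counts, indexed by label.
#' @export
component_sizes <- function(labels) {
  nc <- attr(labels, "n_components")
  if (is.null(nc)) nc <- max(labels, 0L)
  tabulate(labels, nbins = nc)
}

#' Keep only the largest connected component
#'
#' Ties are broken in favor of the component first encountered in
#' column-major order, which is deterministic.
#'
#' @inheritParams label_components
#' @return logical array with only the largest component retained.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  sizes <- component_sizes(lab)
  if (length(sizes) == 0L) return(array(FALSE, dim(mask)))
  keep <- which.max(sizes)  # first maximum -> deterministic tie-break
  out <- lab == keep
  dim(out) <- dim(mask)
  out
}

#' Remove connected components smaller than a voxel-count cutoff
#' @inheritParams label_components
#' @param min_voxels components with fewer voxels than this are removed.
#' @return logical array.
#' @export
remove_small_components <- function(mask, min_voxels, connectivity = 26L) {
  if (min_voxels <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- component_sizes(lab)
  keep <- which(sizes >= min_voxels)
  out <- array(lab %in% keep & mask, dim(mask))
  out
}

# Shift an array by `by` voxels along `axis`, filling vacated cells with `fill`.
shift_array <- function(arr, axis, by, fill) {
  d <- dim(arr)
  n <- d[axis]
  if (abs(by) >= n) return(array(fill, d))
  src <- seq_len(n) - by
  pad <- src < 1L | src > n
  src[pad] <- 1L
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- src
  out <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  idx[[axis]] <- which(pad)
  if (any(pad)) out <- do.call(`[<-`, c(list(out), idx, list(value = fill)))
  dim(out) <- d
  out
}

#' Binary dilation with a 1-voxel cross structuring element
#'
#' One iteration grows the mask by one voxel along every axis direction
#' (6-connected cross in 3-D, 4-connected in 2-D); `iterations` iterations
#' grow it by that many voxels. Dilation is performed in voxel space,
#' irrespective of physical spacing.
#'
#' @param mask logical array.
#' @param iterations number of 1-voxel growth steps.
#' @param axes axes along which to dilate (default all; use 1:2 for
#'   slice-wise 2-D dilation of a 3-D mask).
#' @param se structuring element: `"cross"` (6-connected in 3-D) or `"box"`
#'   (full 3x3x3 / 26-connected, applied separably per axis).
#' @return logical array.
#' @export
dilate_mask <- function(mask, iterations = 1L, axes = seq_along(dim(mask)),
                        se = c("cross", "box")) {
  se <- match.arg(se)
  out <- mask
  for (i in seq_len(iterations)) {
    if (se == "cross") {
      acc <- out
      for (ax in axes) {
        acc <- acc | shift_array(out, ax, 1L, FALSE) | shift_array(out, ax, -1L, FALSE)
      }
      out <- acc
    } else {
      for (ax in axes) {
        out <- out | shift_array(out, ax, 1L, FALSE) | shift_array(out, ax, -1L, FALSE)
      }
    }
  }
  out
}

#' Binary erosion with a 1-voxel cross structuring element
#'
#' The complement of [dilate_mask()]: voxels survive only if all their
#' axis neighbors are set. Voxels outside the grid count as background,
#' so the mask erodes at the grid boundary.
#'
#' @inheritParams dilate_mask
#' @return logical array.
#' @export
erode_mask <- function(mask, iterations = 1L, axes = seq_along(dim(mask)),
                       se = c("cross", "box")) {
  se <- match.arg(se)
  out <- mask
  for (i in seq_len(iterations)) {
    if (se == "cross") {
      acc <- out
      for (ax in axes) {
        acc <- acc & shift_array(out, ax, 1L, FALSE) & shift_array(out, ax, -1L, FALSE)
      }
      out <- acc
    } else {
      for (ax in axes) {
        out <- out & shift_array(out, ax, 1L, FALSE) & shift_array(out, ax, -1L, FALSE)
      }
    }
  }
  out
}

#' Morphological opening (erosion then dilation)
#'
#' Removes structures thinner than roughly `2 * iterations + 1` voxels while
#' leaving compact regions intact; the result is always a subset of the
#' input mask. The box structuring element additionally strips partially
#' occupied voxel layers riding on flat surfaces (classic threshold-noise
#' fuzz), which the cross element reconstructs and therefore keeps.
#'
#' @inheritParams dilate_mask
#' @export
open_mask <- function(mask, iterations = 1L, axes = seq_along(dim(mask)),
                      se = c("cross", "box")) {
  se <- match.arg(se)
  dilate_mask(erode_mask(mask, iterations, axes, se), iterations, axes, se) & mask
}

#' Fill enclosed cavities of a binary mask
#'
#' Background components (6-connected in 3-D, 4-connected in 2-D) that do not
#' touch the grid boundary are considered holes and are added to the mask.
#'
#' @param mask logical array.
#' @return logical array with holes filled.
#' @export
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  lab <- label_components(bg, if (length(d) == 2L) 4L else 6L)
  nc <- attr(lab, "n_components")
  if (nc == 0L) return(mask)
  touching <- logical(nc)
  for (ax in seq_along(d)) {
    idx <- rep(list(quote(expr = )), length(d))
    for (side in c(1L, d[ax])) {
      idx[[ax]] <- side
      face <- do.call(`[`, c(list(lab), idx, list(drop = TRUE)))
      touching[unique(face[face > 0L])] <- TRUE
    }
  }
  hole_labels <- which(!touching)
  if (length(hole_labels) == 0L) return(mask)
  out <- mask | array(lab %in% hole_labels, d)
  out
}

#' Separable Gaussian smoothing of a 2-D or 3-D array
#'
#' Convolves with a sampled Gaussian kernel (radius `ceiling(3 * sigma)`)
#' independently along each axis; boundary handling is replicate (clamp).
#' Sigma is given per axis in voxel units; pass 0 to skip an axis.
#'
#' @param arr numeric array.
#' @param sigma_vox numeric vector of per-axis standard deviations (voxels),
#'   recycled to the number of axes.
#' @return numeric array of the same shape.
#' @export
gaussian_blur <- function(arr, sigma_vox) {
  d <- dim(arr)
  sigma_vox <- rep_len(sigma_vox, length(d))
  out <- arr
  for (ax in seq_along(d)) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, d)
    for (j in seq(-r, r)) {
      acc <- acc + k[j + r + 1L] * shift_clamp(out, ax, j)
    }
    out <- acc
  }
  out
}

# Shift with replicate (clamp) boundary, used by gaussian_blur.
shift_clamp <- function(arr, axis, by) {
  d <- dim(arr)
  n <- d[axis]
  src <- pmin(pmax(seq_len(n) - by, 1L), n)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- src
  out <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  dim(out) <- d
  out
}

#' Signed Euclidean distance map of a 2-D binary mask
#'
#' Positive inside the mask, negative outside, measured in pixels to the
#' nearest pixel of the opposite phase. Used by shape-based contour
#' interpolation.
#'
#' @param mask logical matrix.
#' @return numeric matrix.
#' @export
signed_distance_2d <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  inside <- EBImage::distmap(m, metric = "euclidean")
  outside <- EBImage::distmap(1 - m, metric = "euclidean")
  as.matrix(inside) - as.matrix(outside)
}
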