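# Adipocyte morphometry and stain %-area scoring on 2-D histology fields.

#' Histology field container
#'
#' A 2-D RGB field with physical pixel size and a stain tag. Pixels are
#' stored as an `height x width x 3` numeric array on the 0-255 scale.
#'
#' @param pixels numeric array `h x w x 3`, values in 0-255.
#' @param pixel_size_um side length of one pixel in micrometers.
#' @param stain `"HE"`, `"PSR"` or `"DAB"`.
#' @param magnification free-text magnification tag (e.g. `"20X"`).
#' @return object of class `field_image`.
#' @export
field_image <- function(pixels, pixel_size_um,
                        stain = c("HE", "PSR", "DAB"),
                        magnification = "") {
  stain <- match.arg(stain)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) stop("`pixels` must be h x w x 3")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 stain = stain, magnification = magnification),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %s, %dx%d px at %.3g um/px%s\n", x$stain,
              dim(x$pixels)[1], dim(x$pixels)[2], x$pixel_size_um,
              if (nzchar(x$magnification)) paste0(", ", x$magnification) else ""))
  invisible(x)
}

#' Read a histology field from PNG or TIFF
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @param pixel_size_um physical pixel size in micrometers.
#' @param stain stain tag.
#' @param magnification magnification tag.
#' @return a [field_image()].
#' @export
read_field <- function(path, pixel_size_um, stain = "HE", magnification = "") {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF fields")
    tiff::readTIFF(path)
  } else {
    stop("unsupported field format: ", path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  field_image(img[, , 1:3, drop = FALSE] * 255, pixel_size_um, stain,
              magnification)
}

#' Write a histology field to PNG
#' @param field a [field_image()].
#' @param path output `.png` path.
#' @export
write_field <- function(field, path) {
  png::writePNG(pmin(pmax(field$pixels / 255, 0), 1), path)
  invisible(path)
}

#' Grayscale conversion and linear contrast enhancement for H&E fields
#'
#' Converts the RGB field to Rec. 709 luminance and applies a linear
#' contrast stretch mapping the (`p_low`, `p_high`) percentile range onto
#' 0-255 (values outside are clipped). A constant image cannot be stretched
#' and is returned unchanged with a warning.
#'
#' @param field a [field_image()] with stain `"HE"` (other stains are
#'   accepted with a warning, for exploratory use).
#' @param p_low,p_high stretch percentiles in `[0, 1]` (default 0.01/0.99).
#' @return numeric matrix of grayscale intensities in 0-255.
#' @export
preprocess_he <- function(field, p_low = 0.01, p_high = 0.99) {
  stopifnot(inherits(field, "field_image"))
  if (field$stain != "HE")
    warning("preprocess_he called on a ", field$stain, " field")
  px <- field$pixels
  gray <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
  q <- stats::quantile(gray, c(p_low, p_high), names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant image: contrast stretch skipped")
    return(gray)
  }
  pmin(pmax((gray - q[1]) * 255 / (q[2] - q[1]), 0), 255)
}

#' Segment adipocyte lumina by white-channel thresholding
#'
#' Pixels at or above `white_threshold` form candidate lumina; connected
#' components (8-connectivity) are labeled, components smaller than
#' `min_area_um2` are discarded, and components touching the field border
#' are optionally removed. Areas are component pixel counts times the pixel
#' area. When `white_threshold` is `NULL` it is chosen by Otsu's method on
#' the grayscale image.
#'
#' @param gray grayscale matrix (0-255), e.g. from [preprocess_he()].
#' @param pixel_size_um physical pixel size in micrometers.
#' @param white_threshold intensity cutoff; `NULL` for Otsu.
#' @param min_area_um2 minimum cell area kept (default 200).
#' @param exclude_border drop cells touching the field border (default TRUE).
#' @return list with `labels` (integer matrix, relabeled 1..n), `cells`
#'   (data.frame: cell_id, area_um2, area_px), and `threshold` used.
#' @export
segment_adipocytes <- function(gray, pixel_size_um, white_threshold = NULL,
                               min_area_um2 = 200, exclude_border = TRUE) {
  if (is.null(white_threshold)) {
    white_threshold <- 255 * EBImage::otsu(EBImage::Image(gray / 255),
                                           range = c(0, 1), levels = 256L)
  }
  if (white_threshold < min(gray) - 1 || white_threshold > max(gray) + 1)
    warning("white_threshold lies outside the image intensity range")
  mask <- gray >= white_threshold
  lab <- label_components(mask, 8L)
  n <- attr(lab, "n_components")
  if (n == 0L) {
    warning("no adipocytes detected")
    return(list(labels = array(0L, dim(gray)),
                cells = data.frame(cell_id = integer(), area_um2 = numeric(),
                                   area_px = integer()),
                threshold = white_threshold))
  }
  sizes <- component_sizes(lab)
  drop <- sizes * pixel_size_um^2 < min_area_um2
  if (exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop[border[border > 0L]] <- TRUE
  }
  keep <- which(!drop)
  if (length(keep) == 0L) {
    warning("no adipocytes survive filtering")
    return(list(labels = array(0L, dim(gray)),
                cells = data.frame(cell_id = integer(), area_um2 = numeric(),
                                   area_px = integer()),
                threshold = white_threshold))
  }
  relabel <- integer(n)
  relabel[keep] <- seq_along(keep)
  out <- array(0L, dim(gray))
  inside <- lab > 0L
  out[inside] <- relabel[lab[inside]]
  list(labels = out,
       cells = data.frame(cell_id = seq_along(keep),
                          area_um2 = sizes[keep] * pixel_size_um^2,
                          area_px = sizes[keep]),
       threshold = white_threshold)
}

#' Bin cell areas into a size-frequency distribution
#'
#' Bins are half-open `[e_i, e_{i+1})` with the final bin closed at the top
#' edge. Areas outside the binning range are counted in a reported overflow
#' bin. Proportions are relative to all cells (binned + overflow), so they
#' always sum to 1.
#'
#' @param areas numeric vector of per-cell areas (um^2); at least one cell.
#' @param bin_edges strictly ascending bin edges (default 0 to 10,000 um^2
#'   in 500 um^2 steps).
#' @return object of class `size_distribution`: data.frame `bins`
#'   (bin_low, bin_high, count, proportion), `overflow` count,
#'   `mean_area_um2`, `n_cells`, and the input `cell_areas_um2`.
#' @export
size_distribution <- function(areas, bin_edges = seq(0, 10000, by = 500)) {
  if (length(areas) < 1L) stop("at least one cell area is required")
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly ascending")
  nb <- length(bin_edges) - 1L
  # half-open bins, final bin closed
  idx <- findInterval(areas, bin_edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > nb] <- NA_integer_
  counts <- tabulate(idx, nbins = nb)
  overflow <- sum(is.na(idx))
  if (overflow > 0L)
    warning(overflow, " cell(s) outside the binning range (overflow bin)")
  structure(list(
    bins = data.frame(bin_low = bin_edges[-length(bin_edges)],
                      bin_high = bin_edges[-1],
                      count = counts,
                      proportion = counts / length(areas)),
    overflow = overflow,
    mean_area_um2 = mean(areas),
    n_cells = length(areas),
    cell_areas_um2 = areas), class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> %d cells, mean %.1f um^2, %d bins, %d overflow\n",
              x$n_cells, x$mean_area_um2, nrow(x$bins), x$overflow))
  invisible(x)
}

#' Color rule for picrosirius-red staining
#'
#' Classifies a pixel as PSR-positive in HSV space: hue within
#' `hue_deg` of red (wrapped around 0), saturation and value above floors.
#' All parameters are explicit and overridable, since published protocols
#' state only "a threshold for red".
#'
#' @param hue_deg half-width of the red hue window in degrees (default 20).
#' @param min_sat minimum saturation (default 0.3).
#' @param min_val minimum value/brightness (default 0.2).
#' @return predicate function: RGB array (0-255) -> logical matrix.
#' @export
stain_rule_psr <- function(hue_deg = 20, min_sat = 0.3, min_val = 0.2) {
  force(hue_deg); force(min_sat); force(min_val)
  function(pixels) {
    hsv <- rgb_to_hsv(pixels)
    h <- hsv[, , 1] * 360
    (h <= hue_deg | h >= 360 - hue_deg) &
      hsv[, , 2] >= min_sat & hsv[, , 3] >= min_val
  }
}

#' Color rule for DAB (brown chromogen) staining
#'
#' Brown hue window `[hue_low, hue_high]` degrees with saturation and value
#' floors, in HSV space.
#'
#' @param hue_low,hue_high brown hue window in degrees (default 10-45).
#' @param min_sat minimum saturation (default 0.25).
#' @param min_val minimum value (default 0.2).
#' @return predicate function: RGB array (0-255) -> logical matrix.
#' @export
stain_rule_dab <- function(hue_low = 10, hue_high = 45, min_sat = 0.25,
                           min_val = 0.2) {
  force(hue_low); force(hue_high); force(min_sat); force(min_val)
  function(pixels) {
    hsv <- rgb_to_hsv(pixels)
    h <- hsv[, , 1] * 360
    h >= hue_low & h <= hue_high & hsv[, , 2] >= min_sat & hsv[, , 3] >= min_val
  }
}

# RGB (h x w x 3, 0-255) -> HSV (h x w x 3, all in [0,1])
rgb_to_hsv <- function(pixels) {
  d <- dim(pixels)
  m <- rbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
             as.vector(pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  array(c(hsv[1, ], hsv[2, ], hsv[3, ]), d)
}

#' Percent stained area within a region of interest
#'
#' Applies a stain color rule inside an ROI and reports the stained pixel
#' fraction as a percentage of the ROI area.
#'
#' @param field a [field_image()] with stain `"PSR"` or `"DAB"`.
#' @param roi logical matrix; `NULL` uses the full field.
#' @param stain_rule predicate function (see [stain_rule_psr()],
#'   [stain_rule_dab()]); `NULL` picks the rule matching the field's stain.
#' @return object of class `stain_area_result` with `roi_area_px`,
#'   `stained_area_px`, `percent_stained`.
#' @export
quantify_stain_area <- function(field, roi = NULL, stain_rule = NULL) {
  stopifnot(inherits(field, "field_image"))
  if (!field$stain %in% c("PSR", "DAB"))
    stop("quantify_stain_area expects a PSR or DAB field")
  d <- dim(field$pixels)[1:2]
  if (is.null(roi)) roi <- matrix(TRUE, d[1], d[2])
  if (!identical(as.integer(dim(roi)), as.integer(d)))
    stop("roi dimensions do not match the field")
  n_roi <- sum(roi)
  if (n_roi == 0L)
    adp_error("empty ROI: stained fraction undefined", "empty_roi")
  if (is.null(stain_rule))
    stain_rule <- if (field$stain == "PSR") stain_rule_psr() else stain_rule_dab()
  stained <- stain_rule(field$pixels) & roi
  structure(list(roi_area_px = n_roi,
                 stained_area_px = sum(stained),
                 percent_stained = 100 * sum(stained) / n_roi),
            class = "stain_area_result")
}

#' @export
print.stain_area_result <- function(x, ...) {
  cat(sprintf("<stain_area_result> %.2f%% stained (%d / %d px)\n",
              x$percent_stained, x$stained_area_px, x$roi_area_px))
  invisible(x)
}

#' Rasterize a polygonal ROI onto a pixel grid
#'
#' Even-odd (crossing-number) polygon fill sampled at pixel centers.
#'
#' @param vertices two-column matrix of (row, col) polygon vertices in pixel
#'   coordinates.
#' @param dims integer (rows, cols) of the target grid.
#' @return logical matrix.
#' @export
polygon_roi <- function(vertices, dims) {
  m <- rasterize_polygon(vertices[, 1], vertices[, 2], dims[1], dims[2])
  m
}

# Even-odd polygon rasterization at integer pixel centers; vx/vy in pixel
# units (rows/cols). Shared by histology ROIs and PET contour slices.
rasterize_polygon <- function(vx, vy, nx, ny) {
  stopifnot(length(vx) == length(vy), length(vx) >= 3L)
  px <- rep(seq_len(nx), times = ny)
  py <- rep(seq_len(ny), each = nx)
  inside <- rep(FALSE, nx * ny)
  n <- length(vx)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  matrix(inside, nx, ny)
}
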