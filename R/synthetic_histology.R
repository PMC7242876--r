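# Synthetic histology: adipocyte mosaics and stained fields with exact truth.

# Multiplicatively weighted Voronoi assignment of a pixel grid to seeds,
# computed blockwise so each pixel is only tested against nearby seeds.
# Returns an integer matrix of seed indices. Deterministic.
assign_weighted_voronoi <- function(nr, nc, sx, sy, r2, block = 48L) {
  lab <- matrix(0L, nr, nc)
  margin <- 3 * sqrt(max(r2)) + 16
  for (bi in seq_len(ceiling(nr / block))) {
    rs <- (((bi - 1L) * block + 1L):min(bi * block, nr))
    for (bj in seq_len(ceiling(nc / block))) {
      cs <- (((bj - 1L) * block + 1L):min(bj * block, nc))
      cand <- which(sx >= min(rs) - margin & sx <= max(rs) + margin &
                    sy >= min(cs) - margin & sy <= max(cs) + margin)
      if (length(cand) == 0L) cand <- seq_along(sx)
      best <- matrix(Inf, length(rs), length(cs))
      blab <- matrix(0L, length(rs), length(cs))
      for (k in cand) {
        d2 <- outer((rs - sx[k])^2, (cs - sy[k])^2, `+`) / r2[k]
        upd <- d2 < best
        best[upd] <- d2[upd]
        blab[upd] <- k
      }
      lab[rs, cs] <- blab
    }
  }
  lab
}

# Membrane pixels: both sides of every label discontinuity (4-neighborhood),
# plus a one-pixel frame along the field border.
membrane_from_labels <- function(lab, extra_width = 0L) {
  nr <- nrow(lab); nc <- ncol(lab)
  mem <- matrix(FALSE, nr, nc)
  dh <- lab[-nr, ] != lab[-1, ]
  mem[-nr, ][dh] <- TRUE
  mem[-1, ][dh] <- TRUE
  dv <- lab[, -nc] != lab[, -1]
  mem[, -nc][dv] <- TRUE
  mem[, -1][dv] <- TRUE
  mem[c(1, nr), ] <- TRUE
  mem[, c(1, nc)] <- TRUE
  if (extra_width > 0L) mem <- dilate_mask(mem, extra_width)
  mem
}

#' Generate a synthetic adipocyte mosaic with known per-cell areas
#'
#' Tessellates a field into `n_cells` space-filling polygonal cells via a
#' multiplicatively weighted Voronoi diagram whose target areas are drawn
#' from a lognormal distribution with the requested mean, renders bright
#' lumina (~230) separated by dark membranes (~60) as in a contrast-rich
#' H&E adipose field, and records the exact lumen pixel area of every cell.
#' The field size is derived from the requested areas and calibrated in a
#' second tessellation pass so the realized mean lumen area matches the
#' requested mean closely.
#'
#' @param n_cells number of cells (>= 1).
#' @param mean_area_um2 requested mean cell area in um^2.
#' @param sdlog lognormal log-scale SD of cell areas (default 0.35).
#' @param pixel_size_um physical pixel size (default 1 um).
#' @param membrane_extra extra membrane dilation beyond the 2-pixel
#'   discontinuity band (default 0).
#' @param lumen_intensity,membrane_intensity gray levels of lumen/membrane.
#' @param noise_sd Gaussian pixel noise SD (default 6).
#' @param lloyd_iters centroidal relaxation iterations (default 1).
#' @param seed integer seed.
#' @return list with `field` (a [field_image()], stain `"HE"`), `truth`
#'   (data.frame: cell_id, area_um2, area_px, touches_border), `labels`
#'   (cell index per pixel, membranes = 0), and `params`.
#' @export
make_adipocyte_mosaic <- function(n_cells = 200, mean_area_um2 = 2500,
                                  sdlog = 0.35, pixel_size_um = 1,
                                  membrane_extra = 0L,
                                  lumen_intensity = 230,
                                  membrane_intensity = 60,
                                  noise_sd = 6, lloyd_iters = 1L,
                                  seed = 1L) {
  stopifnot(n_cells >= 1, mean_area_um2 > 0, sdlog >= 0)
  with_seed(seed, {
    a_um2 <- stats::rlnorm(n_cells, log(mean_area_um2) - sdlog^2 / 2, sdlog)
    a_px <- a_um2 / pixel_size_um^2
    if (any(a_px < 36))
      stop("cells too small for the membrane width at this pixel size")
    side <- ceiling(sqrt(sum(a_px)))
    # jittered-grid seed placement; areas assigned in random order
    g <- ceiling(sqrt(n_cells))
    cell_w <- side / g
    gx <- ((seq_len(g) - 0.5) * cell_w)
    pos <- expand.grid(x = gx, y = gx)
    pos <- pos[sample.int(nrow(pos), n_cells), , drop = FALSE]
    sx <- pmin(pmax(pos$x + stats::runif(n_cells, -0.3, 0.3) * cell_w, 2), side - 1)
    sy <- pmin(pmax(pos$y + stats::runif(n_cells, -0.3, 0.3) * cell_w, 2), side - 1)
    r2 <- a_px / pi

    tessellate <- function(nr, nc, sx, sy) {
      lab <- assign_weighted_voronoi(nr, nc, sx, sy, r2)
      for (it in seq_len(lloyd_iters)) {
        cx <- tapply(row(lab), lab, mean)
        cy <- tapply(col(lab), lab, mean)
        ids <- as.integer(names(cx))
        sx[ids] <- cx
        sy[ids] <- cy
        lab <- assign_weighted_voronoi(nr, nc, sx, sy, r2)
      }
      lab
    }

    lab1 <- tessellate(side, side, sx, sy)
    mem1 <- membrane_from_labels(lab1, membrane_extra)
    lumen1 <- sum(!mem1)
    scale <- sqrt(sum(a_px) / lumen1)
    side2 <- max(8L, round(side * scale))
    lab <- tessellate(side2, side2, sx * scale, sy * scale)
    mem <- membrane_from_labels(lab, membrane_extra)

    labels <- lab
    labels[mem] <- 0L
    counts <- tabulate(labels, nbins = n_cells)
    if (any(counts < 9L))
      stop("cells too small for the membrane width at this pixel size")
    border_ids <- unique(c(lab[2, ], lab[side2 - 1L, ], lab[, 2], lab[, side2 - 1L]))
    truth <- data.frame(cell_id = seq_len(n_cells),
                        area_um2 = counts * pixel_size_um^2,
                        area_px = counts,
                        touches_border = seq_len(n_cells) %in% border_ids)

    val <- matrix(membrane_intensity, side2, side2)
    val[!mem] <- lumen_intensity
    if (noise_sd > 0) val <- val + stats::rnorm(length(val), 0, noise_sd)
    val <- pmin(pmax(val, 0), 255)
    # eosin-like tint; luminance ordering is preserved
    px <- array(c(val, 0.72 * val, 0.82 * val), c(side2, side2, 3L))
    list(field = field_image(px, pixel_size_um, "HE", "20X"),
         truth = truth,
         labels = labels,
         params = list(n_cells = n_cells, mean_area_um2 = mean_area_um2,
                       sdlog = sdlog, pixel_size_um = pixel_size_um,
                       noise_sd = noise_sd, seed = seed))
  })
}

#' Generate a stained histology field with an exact stained fraction
#'
#' Draws organic-looking stained blobs by thresholding a smoothed Gaussian
#' random field at the quantile that marks exactly
#' `round(stained_fraction * ROI pixels)` pixels, then paints those pixels in
#' the stain's reference color (red on a yellow background for picrosirius
#' red; brown on a pale counterstain for DAB). Small per-pixel color jitter
#' stays inside the default detection windows of [stain_rule_psr()] /
#' [stain_rule_dab()], so the recorded fraction is recovered exactly up to
#' the color rule.
#'
#' @param kind `"psr"` or `"dab"`.
#' @param stained_fraction target stained fraction of the ROI, in `[0, 1]`.
#' @param dims field size in pixels (rows, cols), default `c(400, 400)`.
#' @param pixel_size_um physical pixel size (default 1.38 um, a 10X field).
#' @param roi logical matrix; `NULL` = whole field.
#' @param blob_sigma smoothing sigma (px) of the blob field (default 4).
#' @param color_jitter per-channel uniform jitter amplitude, 0-255 scale.
#' @param seed integer seed.
#' @return list with `field` (a [field_image()]), `stained` (logical truth
#'   mask), `roi`, `true_percent` and `params`.
#' @export
make_stain_field <- function(kind = c("psr", "dab"), stained_fraction = 0.175,
                             dims = c(400, 400), pixel_size_um = 1.38,
                             roi = NULL, blob_sigma = 4, color_jitter = 6,
                             seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(stained_fraction >= 0, stained_fraction <= 1)
  dims <- as.integer(dims)
  if (is.null(roi)) roi <- matrix(TRUE, dims[1], dims[2])
  n_roi <- sum(roi)
  stopifnot(n_roi > 0L)
  k <- round(stained_fraction * n_roi)
  cols <- if (kind == "psr") {
    list(bg = c(235, 205, 90), fg = c(190, 35, 45), stain = "PSR")
  } else {
    list(bg = c(228, 230, 240), fg = c(150, 95, 45), stain = "DAB")
  }
  with_seed(seed, {
    g <- gaussian_blur(matrix(stats::rnorm(prod(dims)), dims[1], dims[2]),
                       blob_sigma)
    stained <- matrix(FALSE, dims[1], dims[2])
    if (k > 0L) {
      w <- which(roi)
      ord <- w[order(-g[w], w)]
      stained[ord[seq_len(k)]] <- TRUE
    }
    px <- array(0, c(dims, 3L))
    for (ch in 1:3) {
      plane <- matrix(cols$bg[ch], dims[1], dims[2])
      plane[stained] <- cols$fg[ch]
      plane <- plane + stats::runif(length(plane), -color_jitter, color_jitter)
      px[, , ch] <- pmin(pmax(plane, 0), 255)
    }
    list(field = field_image(px, pixel_size_um, cols$stain, "10X"),
         stained = stained,
         roi = roi,
         true_percent = 100 * k / n_roi,
         params = list(kind = kind, stained_fraction = stained_fraction,
                       dims = dims, seed = seed))
  })
}
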