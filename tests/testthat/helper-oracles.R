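# Independent oracles used across tests: deliberately slow, simple
# re-implementations that share no code with the package internals.

# Brute-force connected-component labeling by repeated neighbor sweeps.
oracle_label <- function(mask, connectivity) {
  d <- dim(mask)
  if (length(d) == 2L) {
    mask <- array(mask, c(d, 1L))
    connectivity <- if (connectivity == 4L) 6L else 26L
  }
  d3 <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  lab <- array(0L, d3)
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    if (lab[idx[r, 1], idx[r, 2], idx[r, 3]] > 0L) next
    nxt <- nxt + 1L
    queue <- list(idx[r, ])
    lab[idx[r, 1], idx[r, 2], idx[r, 3]] <- nxt
    while (length(queue) > 0L) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + as.integer(offs[k, ])
        if (any(q < 1L) || any(q > d3)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  list(labels = lab, n = nxt)
}

# Same-partition check: two labelings agree up to label permutation.
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  f <- a[a > 0]
  g <- b[b > 0]
  length(unique(paste(f, g))) == length(unique(f)) &&
    length(unique(paste(f, g))) == length(unique(g))
}

# Small noiseless CT test volume: ellipsoid body with optional extras.
tiny_ct <- function(dims = c(32, 32, 40), body_hu = 0, bg_hu = -1000) {
  center <- (dims + 1) / 2
  radii <- dims * 0.35
  x <- ((seq_len(dims[1]) - center[1]) / radii[1])^2
  y <- ((seq_len(dims[2]) - center[2]) / radii[2])^2
  z <- ((seq_len(dims[3]) - center[3]) / radii[3])^2
  inside <- outer(outer(x, y, `+`), z, `+`) <= 1
  dim(inside) <- dims
  vals <- array(bg_hu, dims)
  vals[inside] <- body_hu
  list(volume = voxel_volume(vals, c(0.2, 0.2, 0.2), "CT_HU"),
       body = inside)
}

# Circle contour helper (vertices in mm for unit spacing).
circle_contour <- function(cx, cy, r, slice, n = 64L, spacing = c(1, 1)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(slice = slice,
       vertices = cbind((cx + r * cos(th) - 0.5) * spacing[1],
                        (cy + r * sin(th) - 0.5) * spacing[2]))
}
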