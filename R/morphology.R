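# Voxel-grid morphology on 3-D arrays: shifts, 6-connected dilation,
# seeded connected components, boundary extraction, trilinear interpolation.

# Shift array by one voxel along axis (+1/-1), padding with `fill`.
array_shift <- function(a, axis, step, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  n <- d[axis]
  if (abs(step) >= n) return(out)
  if (step > 0) { idx_dst[[axis]] <- (1 + step):n; idx_src[[axis]] <- 1:(n - step) }
  else { idx_dst[[axis]] <- 1:(n + step); idx_src[[axis]] <- (1 - step):n }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# 6-connected binary dilation by one voxel (no wraparound at image edges).
dilate6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (s in c(-1L, 1L))
    out <- out | array_shift(mask, ax, s, FALSE)
  out
}

# 6-connected connected component of `region` containing seed voxel index
# (length-3 integer).  Frontier dilation, exact and deterministic.
connected_component6 <- function(region, seed_idx) {
  d <- dim(region)
  seed_idx <- as.integer(seed_idx)
  if (any(seed_idx < 1L) || any(seed_idx > d))
    stopf("connected_component6: seed voxel outside the grid")
  if (!region[seed_idx[1], seed_idx[2], seed_idx[3]])
    stopf("connected_component6: seed voxel is not inside the region")
  comp <- array(FALSE, d)
  comp[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  repeat {
    grown <- dilate6(comp) & region
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

# Voxel indices (n x 3) of TRUE entries.
mask_indices <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# Boundary voxels of a binary mask (inside voxels with an outside 6-neighbor).
mask_boundary <- function(mask) {
  mask & !(array_shift(mask, 1, 1, FALSE) & array_shift(mask, 1, -1, FALSE) &
           array_shift(mask, 2, 1, FALSE) & array_shift(mask, 2, -1, FALSE) &
           array_shift(mask, 3, 1, FALSE) & array_shift(mask, 3, -1, FALSE))
}

# Trilinear interpolation of a 3-D array at physical points (n x 3).
# Points outside the grid are clamped to the border.
interp3 <- function(a, spacing, origin, pts) {
  d <- dim(a)
  pts <- matrix(as.numeric(pts), ncol = 3)
  g <- sweep(sweep(pts, 2, origin, `-`), 2, spacing, `/`) + 1  # fractional index
  out <- numeric(nrow(pts))
  i0 <- matrix(0L, nrow(pts), 3); w <- matrix(0, nrow(pts), 3)
  for (ax in 1:3) {
    gx <- pmin(pmax(g[, ax], 1), d[ax])
    f <- pmin(floor(gx), d[ax] - 1L)
    if (d[ax] == 1L) f <- rep(1, length(gx))
    i0[, ax] <- as.integer(f)
    w[, ax] <- gx - f
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- cbind(pmin(i0[, 1] + dx, d[1]), pmin(i0[, 2] + dy, d[2]),
                pmin(i0[, 3] + dz, d[3]))
    wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
          (if (dy == 1) w[, 2] else 1 - w[, 2]) *
          (if (dz == 1) w[, 3] else 1 - w[, 3])
    out <- out + wt * a[ii]
  }
  out
}

# Signed Euclidean distance to the binary interface of `mask` (negative
# inside).  The interface is sampled at the midpoints of all 6-connected
# inside/outside voxel pairs — the exact location where the binary phase
# changes — so the zero level of the field reproduces the binary surface
# without half-voxel bias.
signed_distance <- function(mask, spacing) {
  d <- dim(mask)
  mids <- list()
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    pair <- mask & array_shift(!mask, ax, -s, FALSE) # outside neighbor at +s
    # voxels at the image border count as interface too (no wraparound)
    edge <- mask
    idx <- lapply(d, seq_len)
    idx[[ax]] <- if (s > 0) d[ax] else 1L
    brd <- array(FALSE, d); brd[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
    pair <- pair | (mask & brd)
    ii <- mask_indices(pair)
    if (!nrow(ii)) next
    m <- sweep(ii - 1, 2, spacing, `*`)
    m[, ax] <- m[, ax] + s * spacing[ax] / 2
    mids[[length(mids) + 1L]] <- m
  }
  if (!length(mids)) stopf("signed_distance: mask has no interface")
  cloud <- do.call(rbind, mids)
  all_idx <- mask_indices(array(TRUE, d))
  pts <- sweep(all_idx - 1, 2, spacing, `*`)
  dist <- .nn_min_dist(pts, cloud)
  dd <- ifelse(as.vector(mask), -dist, dist)
  # exactly-zero entries keep a sign encoding the phase
  dd[as.vector(mask) & dd == 0] <- -1e-9
  array(dd, d)
}
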