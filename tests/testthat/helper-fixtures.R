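# Shared fixtures, built in code at test time.

# memoized 50-beat paced CRN state (used by monodomain and acceptance tests)
.fixture_env <- new.env()
get_paced_state <- function() {
  if (is.null(.fixture_env$paced))
    .fixture_env$paced <- pace_to_steady_state(50, 1000, dt = 0.01)
  .fixture_env$paced
}

# voxelized solid sphere as a tagged segmentation (staircase phantom)
make_sphere_seg <- function(h, R, margin = 3 * h) {
  n <- 2L * as.integer(ceiling((R + margin) / h)) + 1L
  ax <- (seq_len(n) - (n + 1) / 2) * h
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  mask <- sqrt(X^2 + Y^2 + Z^2) <= R
  lab <- array(0L, dim(mask))
  lab[mask] <- segmentation_tags()[["aw"]]
  tagged_segmentation(lab, c(h, h, h), c(ax[1], ax[1], ax[1]))
}

# planar annulus triangulation (polar grid), inner radius a, outer b;
# returns surface_mesh with attributes inner_vertices / outer_vertices
make_annulus_mesh <- function(a = 1, b = 2, n_r = 8, n_th = 32) {
  r <- seq(a, b, length.out = n_r + 1)
  th <- seq(0, 2 * pi, length.out = n_th + 1)[-(n_th + 1)]
  vid <- function(i, j) (i - 1L) * n_th + ((j - 1L) %% n_th) + 1L
  verts <- cbind(rep(r, each = n_th) * cos(rep(th, n_r + 1)),
                 rep(r, each = n_th) * sin(rep(th, n_r + 1)), 0)
  tris <- list()
  for (i in seq_len(n_r)) for (j in seq_len(n_th)) {
    v00 <- vid(i, j); v01 <- vid(i, j + 1)
    v10 <- vid(i + 1, j); v11 <- vid(i + 1, j + 1)
    tris[[length(tris) + 1L]] <- rbind(c(v00, v10, v11), c(v00, v11, v01))
  }
  m <- surface_mesh(verts, do.call(rbind, tris))
  attr(m, "inner_vertices") <- seq_len(n_th)
  attr(m, "outer_vertices") <- n_r * n_th + seq_len(n_th)
  m
}

# single-region atlas on a structured sheet: u = 0 on the x = 0 edge,
# u = 1 on the x = max edge
sheet_strip_atlas <- function(sheet) {
  v <- sheet$vertices
  left <- which(abs(v[, 1] - min(v[, 1])) < 1e-12)
  right <- which(abs(v[, 1] - max(v[, 1])) < 1e-12)
  left <- left[order(v[left, 2])]
  right <- right[order(v[right, 2])]
  region_atlas(lines = list(left = left, right = right),
               labels = rep(1L, n_elements(sheet)),
               region_names = "strip",
               bc = list(strip = list(gamma0 = "left", gamma1 = "right",
                                      orthogonal = FALSE)))
}
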