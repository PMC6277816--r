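# transmural coordinate, correspondence tracing, interpolation weights,
# fiber blending

test_that("interpolation weights reproduce the printed tables and stay
          monotone in [0, 1]", {
  # 2-layer / 5-layer table anchors
  expect_identical(interpolation_weight(0.75, "two_layer"), 1)
  expect_identical(interpolation_weight(0.5, "two_layer"), 0)
  expect_identical(interpolation_weight(0.3, "five_layer"), 0.25)
  expect_identical(interpolation_weight(c(0.1, 0.2, 0.41, 0.6, 0.79, 0.81),
                                        "five_layer"),
                   c(0, 0, 0.5, 0.5, 0.75, 1))
  expect_identical(interpolation_weight(0.5, "linear"), 0.5)
  expect_equal(interpolation_weight(0.5, "sigmoid"), 0.5)
  # normalized sigmoid endpoints land inside [0, 1]
  expect_equal(interpolation_weight(0, "sigmoid"), 0.5 * (1 + tanh(-2.5)))
  expect_equal(interpolation_weight(1, "sigmoid"), 0.5 * (1 + tanh(2.5)))
  # domain error
  expect_error(interpolation_weight(1.2, "linear"), "\\[0, 1\\]")
  expect_error(interpolation_weight(-0.1, "five_layer"), "\\[0, 1\\]")
  # nondecreasing with range in [0,1] for every scheme
  phi <- seq(0, 1, by = 0.01)
  for (s in c("two_layer", "five_layer", "linear", "sigmoid")) {
    w <- interpolation_weight(phi, s)
    expect_true(all(diff(w) >= 0))
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("blend_fibers: endpoints, 45-degree case, sign alignment", {
  expect_equal(blend_fibers(c(1, 0, 0), c(0, 1, 0), 0), c(1, 0, 0))
  expect_equal(blend_fibers(c(1, 0, 0), c(0, 1, 0), 1), c(0, 1, 0))
  expect_equal(blend_fibers(c(1, 0, 0), c(0, 1, 0), 0.5),
               c(1, 1, 0) / sqrt(2))
  # antipodal representative flipped before blending: no cancellation
  expect_equal(abs(blend_fibers(c(1, 0, 0), c(-1, 0, 0), 0.5)),
               c(1, 0, 0))
  b <- blend_fibers(c(1, 0, 0), c(-1 / sqrt(2), -1 / sqrt(2), 0), 0.5)
  expect_equal(sum(b^2), 1, tolerance = 1e-12)
  expect_gt(b[1], 0)  # stays in the f_ED hemisphere
})

test_that("transmural Laplace is exact on the slab and matches the
          spherical-shell harmonic", {
  slab <- make_slab_mesh(c(4, 4, 2), 0.5)
  u <- transmural_laplace(slab, attr(slab, "endo_vertices"),
                          attr(slab, "epi_vertices"))
  expect_lt(max(abs(u - slab$vertices[, 3] / 2)), 1e-10)
  expect_gte(min(u), 0); expect_lte(max(u), 1)
  expect_error(transmural_laplace(slab, c(1L, 2L), c(2L, 9L)), "overlap")

  # spherical shell radii (a, b): u = (1/a - 1/r)/(1/a - 1/b) with O(h^2)
  # convergence across a refinement step
  rmse <- c()
  for (n in c(6L, 12L)) {
    sh <- make_shell_atrium(shell_atrium_spec(semi_axes = c(10, 10, 10),
                                              wall_range = c(2, 2), n = n,
                                              nr = 2L, openings = list()))
    bs <- extract_boundary_surfaces(sh$mesh)
    endo_v <- sort(unique(as.vector(bs[[2]]$triangles)))
    epi_v <- sort(unique(as.vector(bs[[1]]$triangles)))
    u2 <- transmural_laplace(sh$mesh, endo_v, epi_v)
    r <- sqrt(rowSums(sh$mesh$vertices^2))
    used <- sort(unique(as.vector(sh$mesh$tets)))
    exact <- (1 / 10 - 1 / r) / (1 / 10 - 1 / 12)
    rmse <- c(rmse, sqrt(mean((u2[used] - exact[used])^2)))
    expect_gte(min(u2[used]), -1e-10); expect_lte(max(u2[used]), 1 + 1e-10)
  }
  expect_lt(rmse[2], 0.01)
  expect_gt(rmse[1] / rmse[2], 3)   # ~4 for O(h^2) on the doubled lattice
})

test_that("correspondence tracing: slab column oracle and phi average", {
  slab <- make_slab_mesh(c(4, 4, 1.5), 0.5)
  u <- transmural_laplace(slab, attr(slab, "endo_vertices"),
                          attr(slab, "epi_vertices"))
  bs <- extract_boundary_surfaces(slab, feature_angle = 60)
  zm <- vapply(bs, function(s) mean(element_centers(s)[, 3]), 0)
  endo_s <- bs[[which.min(zm)]]; epi_s <- bs[[which.max(zm)]]
  corr <- build_correspondence(slab, u, endo_s, epi_s)
  expect_true(all(corr$provenance == "traced"))
  # phi is the mean of the nodal values, clamped
  expect_equal(corr$phi, pmin(pmax(rowMeans(matrix(u[slab$tets], ncol = 4)), 0), 1))
  # hit triangles sit directly above/below the barycenter (vertical columns)
  ctr <- element_centers(slab)
  e_c <- element_centers(endo_s)[corr$endo_triangle, ]
  p_c <- element_centers(epi_s)[corr$epi_triangle, ]
  h_tri <- 0.5  # cell edge = triangle scale
  expect_lt(max(sqrt(rowSums((ctr[, 1:2] - e_c[, 1:2])^2))), h_tri)
  expect_lt(max(sqrt(rowSums((ctr[, 1:2] - p_c[, 1:2])^2))), h_tri)
  # phi is monotone along the trace direction: deeper tets get larger phi
  expect_gt(cor(corr$phi, ctr[, 3]), 0.999)

  # explicit mean example
  expect_equal(mean(c(0.2, 0.3, 0.3, 0.4)), 0.3)
})

test_that("correspondence on a curved shell is radially consistent", {
  sh <- make_shell_atrium(shell_atrium_spec(semi_axes = c(8, 8, 8),
                                            wall_range = c(2, 2), n = 6L,
                                            openings = list()))
  bs <- extract_boundary_surfaces(sh$mesh)
  epi_s <- bs[[1]]; endo_s <- bs[[2]]
  u <- transmural_laplace(sh$mesh, sort(unique(as.vector(endo_s$triangles))),
                          sort(unique(as.vector(epi_s$triangles))))
  corr <- build_correspondence(sh$mesh, u, endo_s, epi_s)
  expect_true(all(corr$provenance == "traced"))
  ctr <- element_centers(sh$mesh)
  rdir <- normalize_rows(ctr)
  ec <- element_centers(endo_s)[corr$endo_triangle, ]
  # endo hit point roughly collinear with the barycenter ray (within one
  # triangle diameter on the endo sphere)
  off <- ec - rowSums(ec * rdir) * rdir
  h_tri <- 2 * pi * 8 / (4 * 6)   # endo cell size on the 8 mm sphere
  expect_lt(max(sqrt(rowSums(off^2))), 1.5 * h_tri)
})

test_that("volume fibers: angle profile, scheme invariance, orthogonality", {
  slab <- make_slab_mesh(c(4, 4, 1.5), 0.5)
  u <- transmural_laplace(slab, attr(slab, "endo_vertices"),
                          attr(slab, "epi_vertices"))
  bs <- extract_boundary_surfaces(slab, feature_angle = 60)
  zm <- vapply(bs, function(s) mean(element_centers(s)[, 3]), 0)
  endo_s <- bs[[which.min(zm)]]; epi_s <- bs[[which.max(zm)]]
  corr <- build_correspondence(slab, u, endo_s, epi_s)
  fE <- matrix(rep(c(1, 0, 0), each = n_elements(endo_s)), ncol = 3)
  fP <- matrix(rep(c(0, 1, 0), each = n_elements(epi_s)), ncol = 3)

  # linear scheme: angle(phi) matches atan2(omega, 1 - omega) within 2 deg
  vol <- assign_volume_fibers(slab, corr, fE, fP, "linear")
  ang <- atan2(vol$fibers[, 2], vol$fibers[, 1]) * 180 / pi
  pred <- atan2(corr$phi, 1 - corr$phi) * 180 / pi
  expect_lt(max(abs(ang - pred)), 2)
  # monotone rotation with depth
  expect_gt(cor(ang, corr$phi), 0.995)
  # all fibers unit and orthogonal to the local field line
  expect_lt(max(abs(sqrt(rowSums(vol$fibers^2)) - 1)), 1e-9)
  dirs <- as.matrix(corr[, c("dir_x", "dir_y", "dir_z")])
  expect_lt(max(abs(rowSums(vol$fibers * dirs))), 1e-6)

  # two-layer: exactly two distinct orientations across depth
  v2 <- assign_volume_fibers(slab, corr, fE, fP, "two_layer")
  expect_identical(length(unique(round(atan2(v2$fibers[, 2], v2$fibers[, 1]), 6))),
                   2L)

  # scheme invariance when endo and epi fields coincide
  for (s in c("two_layer", "five_layer", "linear", "sigmoid")) {
    vs <- assign_volume_fibers(slab, corr, fE, fE, s)
    expect_lt(max(abs(abs(vs$fibers[, 1]) - 1)), 1e-9)
  }

  # blend continuity under sign alignment: small omega change, small angle
  f1 <- blend_fibers(c(1, 0, 0), c(0, 1, 0), 0.50)
  f2 <- blend_fibers(c(1, 0, 0), c(0, 1, 0), 0.51)
  expect_lt(acos(pmin(abs(sum(f1 * f2)), 1)), 0.05)
})
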