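# surface fiber generation: regional Laplace fibers, fill, smoothing,
# tangential projection, rim circulation

test_that("strip region with opposite Dirichlet edges gives uniform x axes", {
  sheet <- make_sheet_mesh(c(4, 2), 0.5)
  atlas <- sheet_strip_atlas(sheet)
  f <- region_fibers(sheet, atlas)
  expect_true(all(f$defined))
  expect_lt(max(abs(abs(f$axes[, 1]) - 1)), 1e-9)
  expect_lt(max(abs(f$axes[, 2:3])), 1e-9)
  # every defined axis is tangent to its triangle
  nrm <- triangle_geometry(sheet)$normals
  expect_lt(max(abs(rowSums(f$axes * nrm))), 1e-6)
})

test_that("annular region with rim BCs gives radial axes; orthogonal flag
          rotates them into circulation", {
  ann <- make_annulus_mesh(1, 2, 8, 48)
  inner <- attr(ann, "inner_vertices")
  outer <- attr(ann, "outer_vertices")
  mk_atlas <- function(orth) region_atlas(
    lines = list(rim = c(inner, inner[1]), out = c(outer, outer[1])),
    labels = rep(1L, n_elements(ann)), region_names = "ring",
    bc = list(ring = list(gamma0 = "rim", gamma1 = "out", orthogonal = orth)))
  ctr <- element_centers(ann)
  rad <- normalize_rows(cbind(ctr[, 1], ctr[, 2], 0))
  f_rad <- region_fibers(ann, mk_atlas(FALSE))
  al <- abs(rowSums(f_rad$axes[f_rad$defined, ] * rad[f_rad$defined, ]))
  expect_gt(min(al), 0.98)          # analytic radial field
  f_circ <- region_fibers(ann, mk_atlas(TRUE))
  ac <- abs(rowSums(f_circ$axes[f_circ$defined, ] * rad[f_circ$defined, ]))
  expect_lt(max(ac), 0.05)          # rotated 90 degrees: circulating
})

test_that("fill_undefined propagates sign-aligned axes to full coverage", {
  sheet <- make_sheet_mesh(c(3, 3), 1)
  adj <- element_adjacency(sheet)
  ne <- n_elements(sheet)
  ax <- matrix(rep(c(1, 0, 0), each = ne), ne, 3)

  # single undefined triangle surrounded by identical axes
  defined <- rep(TRUE, ne); defined[5] <- FALSE
  f <- fill_undefined(surface_fiber_field(ax, defined), adj)
  expect_equal(abs(f$axes[5, 1]), 1, tolerance = 1e-12)
  expect_identical(f$provenance[5], "filled")

  # antipodal neighbors: sign-aligned average is the common line
  ax2 <- ax; ax2[adj[[5]][1], ] <- c(-1, 0, 0)
  f2 <- fill_undefined(surface_fiber_field(ax2, defined), adj)
  expect_equal(abs(f2$axes[5, 1]), 1, tolerance = 1e-12)

  # checkerboard of undefined triangles on a constant field restores it
  defined3 <- (seq_len(ne) %% 2) == 0
  f3 <- fill_undefined(surface_fiber_field(ax, defined3), adj)
  expect_true(all(f3$defined))
  expect_lt(max(abs(abs(f3$axes[, 1]) - 1)), 1e-12)

  # a component with no defined axis errors
  expect_error(fill_undefined(surface_fiber_field(ax, rep(FALSE, ne)), adj),
               "undefined|component")
})

test_that("interregional smoothing is local, decreases discontinuity,
          fixes nothing that is already smooth", {
  sheet <- make_sheet_mesh(c(6, 2), 0.5)
  v <- sheet$vertices
  mid <- which(abs(v[, 1] - 3) < 1e-9)
  mid <- mid[order(v[mid, 2])]
  atlas <- region_atlas(
    lines = list(m = mid,
                 left = { l <- which(v[, 1] == 0); l[order(v[l, 2])] },
                 right = { r <- which(v[, 1] == 6); r[order(v[r, 2])] }),
    labels = 1L + (element_centers(sheet)[, 1] > 3),
    region_names = c("L", "R"),
    bc = list(L = list(gamma0 = "left", gamma1 = "m", orthogonal = FALSE),
              R = list(gamma0 = "m", gamma1 = "right", orthogonal = FALSE)))

  ne <- n_elements(sheet)
  ctr <- element_centers(sheet)
  # constant field is a fixed point
  cst <- surface_fiber_field(matrix(rep(c(1, 0, 0), each = ne), ne, 3),
                             rep(TRUE, ne))
  sm <- smooth_interregional(cst, sheet, atlas, band_width = 2, passes = 3)
  expect_equal(sm$axes, cst$axes, tolerance = 1e-12)

  # 90-degree discontinuity across the line shrinks, and triangles outside
  # the band are bitwise untouched
  disc <- matrix(rep(c(1, 0, 0), each = ne), ne, 3)
  disc[ctr[, 1] > 3, ] <- matrix(rep(c(0, 1, 0), each = sum(ctr[, 1] > 3)),
                                 ncol = 3)
  f0 <- surface_fiber_field(disc, rep(TRUE, ne))
  adj <- element_adjacency(sheet)
  max_adj_angle <- function(ax) {
    worst <- 0
    for (t1 in seq_len(ne)) for (t2 in adj[[t1]])
      worst <- max(worst, acos(pmin(abs(sum(ax[t1, ] * ax[t2, ])), 1)))
    worst
  }
  sm2 <- smooth_interregional(f0, sheet, atlas, band_width = 1, passes = 2)
  expect_lt(max_adj_angle(sm2$axes), max_adj_angle(disc) - 1e-3)
  line_verts <- unique(unlist(atlas$lines))
  on_band <- rowSums(matrix(sheet$triangles %in% line_verts, ncol = 3)) > 0
  band <- unique(c(which(on_band), unlist(adj[which(on_band)])))
  outside <- setdiff(seq_len(ne), band)
  expect_identical(sm2$axes[outside, ], disc[outside, ])
})

test_that("tangential projection is idempotent and handles 45-degree tilt", {
  sheet <- make_sheet_mesh(c(2, 2), 0.5)
  ne <- n_elements(sheet)
  inplane <- matrix(rep(c(1, 0, 0), each = ne), ne, 3)
  f <- surface_fiber_field(inplane, rep(TRUE, ne))
  p1 <- project_tangential(f, sheet)
  expect_equal(p1$axes, inplane, tolerance = 1e-12)

  tilt <- matrix(rep(c(1, 0, 1) / sqrt(2), each = ne), ne, 3)
  p2 <- project_tangential(surface_fiber_field(tilt, rep(TRUE, ne)), sheet)
  expect_equal(p2$axes, inplane, tolerance = 1e-12)
  expect_lt(max(abs(sqrt(rowSums(p2$axes^2)) - 1)), 1e-12)

  # random field: |axis . n| < 1e-6 afterwards
  set.seed(2)
  rnd <- normalize_rows(matrix(rnorm(3 * ne), ne, 3))
  p3 <- project_tangential(surface_fiber_field(rnd, rep(TRUE, ne)), sheet)
  nrm <- triangle_geometry(sheet)$normals
  expect_lt(max(abs(rowSums(p3$axes * nrm))), 1e-6)
})

test_that("shipped atlas yields circulating rims (winding +/-1) and a
          deterministic pipeline", {
  sa <- make_shell_atrium()
  res1 <- surface_fibers(sa$endo, sa$atlas_endo)
  res2 <- surface_fibers(sa$endo, sa$atlas_endo)
  expect_identical(res1$surface$fibers, res2$surface$fibers)
  expect_true(all(res1$field$defined))
  nrm <- triangle_geometry(sa$endo)$normals
  expect_lt(max(abs(rowSums(res1$surface$fibers * nrm))), 1e-6)
  expect_lt(max(abs(sqrt(rowSums(res1$surface$fibers^2)) - 1)), 1e-9)
  for (lp in boundary_loops(sa$endo))
    expect_equal(abs(rim_winding_number(res1$surface, lp)), 1)
  res_epi <- surface_fibers(sa$epi, sa$atlas_epi)
  for (lp in boundary_loops(sa$epi))
    expect_equal(abs(rim_winding_number(res_epi$surface, lp)), 1)
})
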