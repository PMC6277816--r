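# mesh containers, CARP/VTK readers/writers, topology queries

test_that("CARP round trip preserves connectivity, tags and fibers", {
  m <- make_slab_mesh(c(3, 3, 1), 0.5)
  m$fibers <- matrix(rep(c(0, 1, 0), each = n_elements(m)), ncol = 3)
  base <- file.path(tempdir(), "rt_carp")
  write_mesh(m, base, "carp")
  m2 <- read_mesh(base, "carp")
  expect_identical(m2$tets, m$tets)
  expect_identical(m2$element_tags, m$element_tags)
  expect_equal(m2$vertices, m$vertices, ignore_attr = TRUE)
  expect_equal(m2$fibers, m$fibers, ignore_attr = TRUE)

  # single regular tetrahedron: bit-for-bit on connectivity
  tet <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  matrix(1:4, 1))
  write_mesh(tet, file.path(tempdir(), "tet1"), "carp")
  t2 <- read_mesh(file.path(tempdir(), "tet1"), "carp")
  expect_identical(t2$tets, tet$tets)
  expect_identical(t2$vertices, tet$vertices)

  # no fibers -> no .lon
  base2 <- file.path(tempdir(), "rt_nolon")
  write_mesh(make_slab_mesh(c(2, 2, 1), 1), base2, "carp")
  expect_false(file.exists(paste0(base2, ".lon")))

  # .lon with constant unit-x axis
  m3 <- make_slab_mesh(c(2, 2, 1), 1)
  m3$fibers <- matrix(rep(c(1, 0, 0), each = n_elements(m3)), ncol = 3)
  base3 <- file.path(tempdir(), "rt_lonx")
  write_mesh(m3, base3, "carp")
  m4 <- read_mesh(base3, "carp")
  expect_true(all(m4$fibers[, 1] == 1 & m4$fibers[, 2] == 0 & m4$fibers[, 3] == 0))

  # tags land in the last .elem column
  m5 <- make_slab_mesh(c(2, 2, 1), 1)
  m5$element_tags <- rep(c(3L, 7L), length.out = n_elements(m5))
  base5 <- file.path(tempdir(), "rt_tags")
  write_mesh(m5, base5, "carp")
  lines <- readLines(paste0(base5, ".elem"))[-1]
  last_col <- as.integer(vapply(strsplit(lines, "\\s+"), function(x) tail(x, 1), ""))
  expect_identical(last_col, m5$element_tags)
})

test_that("CARP reader errors name the malformed input", {
  base <- file.path(tempdir(), "bad_carp")
  writeLines(c("not_a_count", "0 0 0"), paste0(base, ".pts"))
  writeLines(c("1", "Tr 0 1 2 0"), paste0(base, ".elem"))
  expect_error(read_mesh(base, "carp"), "line 1")
  writeLines(c("2", "0 0 0", "1 0 0"), paste0(base, ".pts"))
  writeLines(c("1", "Qd 0 1 0 1 0"), paste0(base, ".elem"))
  expect_error(read_mesh(base, "carp"), "unsupported|mixed")
})

test_that("VTK round trip carries cell tags and fiber vectors", {
  m <- make_slab_mesh(c(2, 2, 1), 0.5)
  m$fibers <- normalize_rows(matrix(rnorm(3 * n_elements(m)), ncol = 3))
  p <- file.path(tempdir(), "rt.vtk")
  write_mesh(m, p, "vtk")
  m2 <- read_mesh(p, "vtk")
  expect_identical(m2$tets, m$tets)
  expect_equal(m2$fibers, m$fibers, tolerance = 1e-8, ignore_attr = TRUE)
  txt <- readLines(p)
  expect_true(any(grepl("^VECTORS fibers", txt)))
  expect_equal(sum(grepl("^VECTORS", txt)), 1L)
})

test_that("non-unit fibers are rejected before writing", {
  m <- make_slab_mesh(c(2, 2, 1), 1)
  expect_error({m$fibers <- matrix(rep(c(2, 0, 0), each = n_elements(m)), ncol = 3)
                validate_mesh(m)}, "unit")
})

test_that("slab generator counts match the constructive formula", {
  # (nx+1)(ny+1)(nz+1) vertices, 6 nx ny nz tets: 5x5x2 cells -> 108 / 300
  m <- make_slab_mesh(c(5, 5, 2), 1)
  expect_identical(nrow(m$vertices), 108L)
  expect_identical(nrow(m$tets), 300L)
  expect_true(all(tet_volumes(m) > 0))
})

test_that("boundary extraction: closed shell vs solid slab vs open atrium", {
  expect_length(extract_boundary_surfaces(make_slab_mesh(c(3, 3, 1), 0.5)), 1L)

  # closed spherical shell (no openings): exactly two components, epi is the
  # larger-|enclosed volume| one, faces partition the boundary
  sh <- make_shell_atrium(shell_atrium_spec(semi_axes = c(8, 8, 8),
                                            wall_range = c(2, 2), n = 6L,
                                            openings = list()))
  bs <- extract_boundary_surfaces(sh$mesh)
  expect_length(bs, 2L)
  vols <- vapply(bs, function(s) attr(s, "enclosed_volume"), 0)
  expect_gt(abs(vols[1]), abs(vols[2]))
  expect_gt(vols[1], 0)   # outward orientation of the outer surface
  expect_lt(vols[2], 0)   # cavity surface winds inward w.r.t. the solid
  nf <- sum(vapply(bs, n_elements, 0L))
  faces <- atriofiber:::tet_faces_outward(sh$mesh$tets)
  keys <- atriofiber:::face_key(faces[, 1], faces[, 2], faces[, 3],
                                nrow(sh$mesh$vertices))
  expect_identical(nf, sum(table(keys) == 1L))

  # open shell atrium: feature-angle split -> 2 sheets with 6 rim loops each
  sa <- make_shell_atrium()
  bs2 <- extract_boundary_surfaces(sa$mesh, feature_angle = 50)
  big <- bs2[1:2]
  expect_length(attr(big[[1]], "rim_loops"), 6L)
  expect_length(attr(big[[2]], "rim_loops"), 6L)
})

test_that("element adjacency is symmetric, bounded and matches brute force", {
  # two tets sharing a face
  two <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                        c(1, 1, 1)),
                  rbind(c(1, 2, 3, 4), c(4, 2, 3, 5)))
  adj <- element_adjacency(two)
  expect_identical(adj[[1]], 2L)
  expect_identical(adj[[2]], 1L)

  # isolated triangle
  iso <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), matrix(1:3, 1))
  expect_length(element_adjacency(iso)[[1]], 0L)

  # triangulated grid vs brute-force shared-edge scan
  g <- make_sheet_mesh(c(5, 5), 1)
  adj <- element_adjacency(g)
  tri <- g$triangles
  brute <- lapply(seq_len(nrow(tri)), function(i)
    sort(which(vapply(seq_len(nrow(tri)), function(j)
      i != j && length(intersect(tri[i, ], tri[j, ])) == 2L, TRUE))))
  expect_identical(adj, brute)
  expect_true(all(lengths(adj) <= 3L))
  for (i in seq_along(adj)) for (j in adj[[i]]) expect_true(i %in% adj[[j]])
})

test_that("MetaImage round trip preserves data and geometry", {
  img <- voxel_image(array(rnorm(3 * 4 * 5), c(3, 4, 5)),
                     spacing = c(0.5, 0.25, 1), origin = c(-1, 0, 2))
  p <- file.path(tempdir(), "rt.mha")
  write_metaimage(img, p, "MET_DOUBLE")
  i2 <- read_metaimage(p)
  expect_equal(i2$data, img$data)
  expect_identical(i2$spacing, img$spacing)
  expect_identical(i2$origin, img$origin)
  # .mhd + .raw variant
  p2 <- file.path(tempdir(), "rt.mhd")
  write_metaimage(img, p2, "MET_FLOAT")
  i3 <- read_metaimage(p2)
  expect_equal(i3$data, img$data, tolerance = 1e-6)
  # invariants
  expect_error(voxel_image(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)), "positive")
  expect_error(voxel_image(matrix(0, 2, 2)), "3 axes")
})
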