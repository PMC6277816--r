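# landmark transfer/derivation, Dijkstra auxiliary lines, region growing

test_that("landmark transfer: identity, tie-break, and exhaustive oracle", {
  sheet <- make_sheet_mesh(c(4, 3), 0.5)
  v <- sheet$vertices
  lm <- data.frame(name = c("a", "b"), x = v[c(3, 17), 1],
                   y = v[c(3, 17), 2], z = v[c(3, 17), 3])
  tr <- transfer_landmarks(lm, sheet, sheet)
  expect_identical(tr$vertex, c(3L, 17L))
  expect_equal(attr(tr, "mapping_error"), 0)

  # equidistant point between vertices 1 and 2 -> lowest index wins
  mid <- (v[1, ] + v[2, ]) / 2
  lm2 <- data.frame(name = "m", x = mid[1], y = mid[2], z = mid[3])
  expect_identical(transfer_landmarks(lm2, sheet, sheet)$vertex, 1L)

  # jittered positions vs brute-force nearest-vertex scan
  set.seed(9)
  pts <- v[sample(nrow(v), 12), ] + matrix(rnorm(36, sd = 0.05), 12)
  lm3 <- data.frame(name = paste0("p", 1:12), x = pts[, 1], y = pts[, 2],
                    z = pts[, 3])
  tr3 <- transfer_landmarks(lm3, sheet, sheet)
  brute <- vapply(seq_len(12), function(i)
    which.min(colSums((t(v) - pts[i, ])^2)), 0L)
  expect_identical(tr3$vertex, brute)

  # topology mismatch rejected
  expect_error(transfer_landmarks(lm, sheet, make_sheet_mesh(c(4, 3), 1)),
               "topology")
  # transfer is idempotent
  lm4 <- as.data.frame(tr3)[, c("name", "x", "y", "z")]
  expect_identical(transfer_landmarks(lm4, sheet, sheet)$vertex, tr3$vertex)
})

test_that("landmarks on the shell atrium name the features they sit on", {
  sa <- make_shell_atrium()
  lm <- sa$landmarks
  expect_false(anyDuplicated(lm$name) > 0)
  loops <- boundary_loops(sa$endo)
  # every *_rim_superior landmark lies on a rim loop vertex
  rim_lm <- lm[grepl("_rim_superior$", lm$name), ]
  all_loop_verts <- unlist(loops)
  expect_true(all(rim_lm$vertex %in% all_loop_verts))
  # roof_center is the brute-force nearest endo vertex to the +z apex
  used <- sort(unique(as.vector(sa$endo$triangles)))
  tgt <- c(0, 0, max(sa$spec$semi_axes))
  brute <- used[which.min(colSums((t(sa$endo$vertices[used, ]) - tgt)^2))]
  expect_identical(lm$vertex[lm$name == "roof_center"], brute)
})

test_that("derived landmarks: rim subdivision and geodesic midpoint", {
  sa <- make_shell_atrium()
  loops <- boundary_loops(sa$endo)
  mvl <- loops[[which.max(lengths(loops))]]
  base <- landmark_set(c("p", "q"), c(mvl[1], mvl[1 + length(mvl) %/% 2]),
                       sa$endo)
  d <- derive_landmarks(base, sa$endo,
                        list(list(type = "rim_equal_arcs", a = "p", b = "q",
                                  n_arcs = 2, prefix = "mid")))
  expect_setequal(setdiff(d$name, base$name), c("mid_1", "mid_2"))
  expect_true(all(d$vertex[d$provenance == "derived"] %in% mvl))
  # each derived point splits its arc into halves within one vertex spacing
  vv <- sa$endo$vertices
  arc_len <- function(path) sum(sqrt(rowSums((vv[path[-1], , drop = FALSE] -
                                              vv[path[-length(path)], , drop = FALSE])^2)))
  ia <- match(mvl[1], mvl); ib <- match(mvl[1 + length(mvl) %/% 2], mvl)
  fwd <- mvl[ia:ib]
  im <- match(d$vertex[d$name == "mid_1"], fwd)
  h_max <- max(sqrt(rowSums((vv[fwd[-1], ] - vv[fwd[-length(fwd)], ])^2)))
  expect_lt(abs(arc_len(fwd[1:im]) - arc_len(fwd) / 2), h_max)

  # midpoint of coincident landmarks is the same vertex
  same <- landmark_set(c("s", "t"), c(mvl[1], mvl[1]), sa$endo)
  m2 <- derive_landmarks(same, sa$endo,
                         list(list(type = "geodesic_midpoint", a = "s",
                                   b = "t", name = "g")))
  expect_identical(m2$vertex[m2$name == "g"], mvl[1])

  # names stay unique
  expect_error(derive_landmarks(base, sa$endo,
                                list(list(type = "geodesic_midpoint", a = "p",
                                          b = "q", name = "p"))), "collision")
})

test_that("Dijkstra paths are optimal (igraph oracle) and corridor-bound", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (rep in 1:3) {
    sheet <- make_sheet_mesh(c(4, 3), 0.5)
    # jitter interior vertices so edge weights are generic
    v <- sheet$vertices
    int <- v[, 1] > 0 & v[, 1] < 4 & v[, 2] > 0 & v[, 2] < 3
    v[int, 1:2] <- v[int, 1:2] + matrix(runif(2 * sum(int), -0.1, 0.1),
                                        ncol = 2)
    sheet <- surface_mesh(v, sheet$triangles)
    a <- sample(nrow(v), 1); b <- sample(nrow(v), 1)
    if (a == b) next
    p <- auxiliary_line(sheet, a, b)
    tri <- sheet$triangles
    e <- unique(t(apply(rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)]), 1, sort)))
    w <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    expect_equal(attr(p, "length"),
                 igraph::distances(g, a, b, weights = w)[1, 1],
                 tolerance = 1e-10)
  }

  # a == b -> single-vertex path
  sheet <- make_sheet_mesh(c(2, 2), 1)
  p0 <- auxiliary_line(sheet, 4L, 4L)
  expect_identical(as.integer(p0), 4L)

  # corridor excluding the direct route forces a detour inside the corridor
  sheet <- make_sheet_mesh(c(6, 6), 1)
  v <- sheet$vertices
  ctr <- element_centers(sheet)
  corridor <- which(!(ctr[, 1] > 1 & ctr[, 1] < 5 & ctr[, 2] > 1 & ctr[, 2] < 5))
  a <- which(v[, 1] == 0 & v[, 2] == 3)
  b <- which(v[, 1] == 6 & v[, 2] == 3)
  p <- auxiliary_line(sheet, a, b, corridor)
  allowed <- sort(unique(as.vector(sheet$triangles[corridor, ])))
  expect_true(all(p %in% allowed))
  expect_gt(attr(p, "length"), 6)   # detour longer than the straight line

  # unreachable endpoints error
  expect_error(auxiliary_line(sheet, a, b,
                              which(ctr[, 1] < 2 | ctr[, 1] > 5)),
               "no path|corridor")
})

test_that("region growing partitions and detects unsealed lines", {
  # slab sheet, no lines, one seed -> everything in one region
  sheet <- make_sheet_mesh(c(3, 3), 1)
  lab <- partition_regions(sheet, list(), c(all = 1L))
  expect_true(all(lab == 1L))

  # vertical midline splits the sheet into two equal halves
  v <- sheet$vertices
  mid <- which(abs(v[, 1] - 1) < 1e-9)
  mid <- mid[order(v[mid, 2])]
  seeds <- c(left = 1L, right = which.max(element_centers(sheet)[, 1]))
  # midline at x = 1 separates cells left/right of it? x=1 is a grid line
  lab2 <- partition_regions(sheet, list(m = mid), seeds)
  ctr <- element_centers(sheet)
  expect_true(all((lab2 == 1L) == (ctr[, 1] < 1)))
  expect_identical(sum(table(lab2)), n_elements(sheet))

  # unsealed line -> leak error
  expect_error(partition_regions(sheet, list(m = mid[1:2]), seeds),
               "leak|unsealed")

  # shipped shell-atrium atlas reproduces the generator's labels exactly
  sa <- make_shell_atrium()
  lab3 <- partition_regions(sa$endo, sa$atlas_endo$lines, sa$seeds_endo)
  expect_identical(as.integer(lab3), as.integer(sa$atlas_endo$labels))
  lab4 <- partition_regions(sa$epi, sa$atlas_epi$lines, sa$seeds_epi)
  expect_identical(as.integer(lab4), as.integer(sa$atlas_epi$labels))
})

test_that("atlas JSON round trip preserves lines, regions and labels", {
  sa <- make_shell_atrium(shell_atrium_spec(n = 8L))
  p <- file.path(tempdir(), "atlas.json")
  write_atlas(sa$atlas_endo, p, landmarks = sa$landmarks, seeds = sa$seeds_endo)
  rt <- read_atlas(p)
  expect_identical(rt$atlas$labels, as.integer(sa$atlas_endo$labels))
  expect_identical(names(rt$atlas$lines), names(sa$atlas_endo$lines))
  expect_identical(lapply(rt$atlas$lines, as.integer),
                   lapply(sa$atlas_endo$lines, as.integer))
  expect_identical(rt$atlas$region_names, sa$atlas_endo$region_names)
  expect_identical(unname(rt$seeds), unname(sa$seeds_endo))
  for (rn in rt$atlas$region_names) {
    expect_setequal(rt$atlas$bc[[rn]]$gamma0, sa$atlas_endo$bc[[rn]]$gamma0)
    expect_setequal(rt$atlas$bc[[rn]]$gamma1, sa$atlas_endo$bc[[rn]]$gamma1)
  }
})

test_that("shipped example atlas file matches the generator", {
  p <- system.file("extdata", "shell_atrium_atlas_endo.json",
                   package = "atriofiber")
  expect_true(nzchar(p))
  rt <- read_atlas(p)
  sa <- make_shell_atrium()
  expect_identical(rt$atlas$labels, as.integer(sa$atlas_endo$labels))
  expect_identical(rt$atlas$region_names, sa$atlas_endo$region_names)
  # the shipped atlas drives the partition directly
  lab <- partition_regions(sa$endo, rt$atlas$lines, rt$seeds)
  expect_identical(as.integer(lab), rt$atlas$labels)
})
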