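# Synthetic input generators: two-compartment voxel phantoms for the
# segmentation stage, structured slab/sheet meshes for the FEM and EP stages,
# and an idealized ellipsoidal shell atrium (4 PV rims, MV opening, LAA) with
# a simplified ~10-region atlas exercising every boundary-condition pattern.
# Every generator is a pure function of (spec, seed).

#' Voxel phantom specification defaults
#'
#' Two intensity populations emulating a contrast-enhanced acquisition:
#' bright cavity blood (mean 450, SD 40) over darker wall myocardium
#' (mean 250, SD 30) and a dark background (mean 50, SD 10), in
#' Hounsfield-unit-like numbers; 0.4 mm voxels and a 1.5 mm wall by default.
#'
#' @param ... overrides of the named defaults (geometry, wall_thickness,
#'   cavity_radius, spacing, margin, mean_wall, sd_wall, mean_cavity,
#'   sd_cavity, mean_background, sd_background, seed)
#' @return spec list
#' @export
phantom_spec <- function(...) {
  spec <- list(geometry = "spherical_shell", wall_thickness = 1.5,
               cavity_radius = 8, spacing = 0.4, margin = 2,
               mean_wall = 250, sd_wall = 30, mean_cavity = 450,
               sd_cavity = 40, mean_background = 50, sd_background = 10,
               seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(spec))
  if (length(unknown)) stopf("phantom_spec: unknown field(s) %s",
                             paste(unknown, collapse = ", "))
  spec[names(over)] <- over
  spec
}

#' Generate a two-compartment voxel phantom
#'
#' Spherical-shell geometry: a bright spherical cavity (blood pool) wrapped
#' in a darker wall of the requested thickness inside a dark background.
#' Slab geometry: a cavity half-space topped by a wall layer.  Intensities
#' are class-dependent Gaussians.  Three sample-region boxes per class mimic
#' the manual sample selection protocol.
#'
#' @param spec from [phantom_spec()]
#' @return list with `image` ([voxel_image()]), `truth` (list of logical
#'   masks `wall`, `cavity`), `myo_samples`, `blood_samples` (masks),
#'   `seed_point` (physical blood-pool seed), `spec`
#' @export
make_voxel_phantom <- function(spec = phantom_spec()) {
  h <- spec$spacing
  if (spec$wall_thickness < h)
    stopf("make_voxel_phantom: wall (%g mm) thinner than one voxel (%g mm); refine spacing",
          spec$wall_thickness, h)
  r_out <- spec$cavity_radius + spec$wall_thickness
  half <- r_out + spec$margin
  nvox <- 2L * as.integer(ceiling(half / h)) + 1L
  d <- c(nvox, nvox, nvox)
  origin <- -((nvox - 1) / 2) * h * c(1, 1, 1)
  ax <- origin[1] + (seq_len(nvox) - 1) * h
  X <- array(rep(ax, times = nvox * nvox), d)
  Y <- array(rep(rep(ax, each = nvox), times = nvox), d)
  Z <- array(rep(ax, each = nvox * nvox), d)
  if (spec$geometry == "spherical_shell") {
    R <- sqrt(X^2 + Y^2 + Z^2)
    cavity <- R <= spec$cavity_radius
    wall <- R > spec$cavity_radius & R <= r_out
  } else if (spec$geometry == "slab") {
    cavity <- Z <= 0
    wall <- Z > 0 & Z <= spec$wall_thickness
  } else stopf("make_voxel_phantom: unknown geometry '%s'", spec$geometry)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(derive_seed(spec$seed, "voxel_phantom"))
  n <- prod(d)
  img <- array(rnorm(n, spec$mean_background, spec$sd_background), d)
  img[cavity] <- rnorm(sum(cavity), spec$mean_cavity, spec$sd_cavity)
  img[wall] <- rnorm(sum(wall), spec$mean_wall, spec$sd_wall)

  image <- voxel_image(img, rep(h, 3), origin)
  ctr <- physical_to_voxel(image, matrix(0, 1, 3))[1, ]
  box <- function(center_idx, r = 2L) {
    m <- array(FALSE, d)
    i <- lapply(1:3, function(ax2) pmax(1L, center_idx[ax2] - r):pmin(d[ax2], center_idx[ax2] + r))
    m[i[[1]], i[[2]], i[[3]]] <- TRUE
    m
  }
  # 3 cavity boxes near the center, 3 wall boxes along +-x and +y
  off <- as.integer(round(spec$cavity_radius / (3 * h)))
  blood_samples <- box(ctr) | box(ctr + c(off, 0L, 0L)) | box(ctr + c(0L, off, 0L))
  if (spec$geometry == "spherical_shell") {
    rw <- spec$cavity_radius + spec$wall_thickness / 2
    wv <- physical_to_voxel(image, rbind(c(rw, 0, 0), c(-rw, 0, 0), c(0, rw, 0)))
    rbox <- max(1L, as.integer(floor(spec$wall_thickness / (2 * h))))
    myo_samples <- box(wv[1, ], rbox) | box(wv[2, ], rbox) | box(wv[3, ], rbox)
  } else {
    zw <- spec$wall_thickness / 2
    wv <- physical_to_voxel(image, rbind(c(0, 0, zw), c(2, 2, zw), c(-2, -2, zw)))
    rbox <- max(1L, as.integer(floor(spec$wall_thickness / (2 * h))))
    myo_samples <- box(wv[1, ], rbox) | box(wv[2, ], rbox) | box(wv[3, ], rbox)
  }
  myo_samples <- myo_samples & wall
  blood_samples <- blood_samples & cavity
  list(image = image, truth = list(wall = wall, cavity = cavity),
       myo_samples = myo_samples, blood_samples = blood_samples,
       seed_point = c(0, 0, 0), spec = spec)
}

# consistent Kuhn 6-tet split of the unit cube (all tets share the main
# diagonal v000-v111); `vv` is the 8 cube vertex ids in (i,j,k) bit order
# v000 v100 v010 v110 v001 v101 v011 v111.
kuhn_tets <- function(vv) {
  rbind(c(vv[1], vv[2], vv[4], vv[8]),
        c(vv[1], vv[4], vv[3], vv[8]),
        c(vv[1], vv[3], vv[7], vv[8]),
        c(vv[1], vv[7], vv[5], vv[8]),
        c(vv[1], vv[5], vv[6], vv[8]),
        c(vv[1], vv[6], vv[2], vv[8]))
}

# flip tets with negative volume (swap last two nodes)
orient_tets <- function(vertices, tets) {
  v <- vertices
  a <- v[tets[, 2], , drop = FALSE] - v[tets[, 1], , drop = FALSE]
  b <- v[tets[, 3], , drop = FALSE] - v[tets[, 1], , drop = FALSE]
  d <- v[tets[, 4], , drop = FALSE] - v[tets[, 1], , drop = FALSE]
  vol <- a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
         a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
         a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])
  neg <- vol < 0
  tmp <- tets[neg, 3]; tets[neg, 3] <- tets[neg, 4]; tets[neg, 4] <- tmp
  tets
}

#' Structured tetrahedral slab mesh
#'
#' Axis-aligned box meshed by a deterministic 6-tets-per-cube (Kuhn)
#' subdivision; `(nx, ny, nz)` cells give `(nx+1)(ny+1)(nz+1)` vertices and
#' `6 nx ny nz` tetrahedra.  The z = 0 and z = top boundary vertices
#' represent the endo- and epicardial faces.
#'
#' @param extent physical box size (mm), length 3
#' @param h target cell edge (mm)
#' @return a [tet_mesh()] with attributes `endo_vertices` (z = 0),
#'   `epi_vertices` (z = top) and `ncells`
#' @export
make_slab_mesh <- function(extent = c(10, 10, 2), h = 0.5) {
  nc <- pmax(as.integer(round(extent / h)), 2L)
  nx <- nc[1]; ny <- nc[2]; nz <- nc[3]
  hx <- extent[1] / nx; hy <- extent[2] / ny; hz <- extent[3] / nz
  vid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  gi <- 0:nx; gj <- 0:ny; gk <- 0:nz
  verts <- cbind(rep(gi * hx, times = (ny + 1) * (nz + 1)),
                 rep(rep(gj * hy, each = nx + 1), times = nz + 1),
                 rep(gk * hz, each = (nx + 1) * (ny + 1)))
  tets <- vector("list", nx * ny * nz)
  q <- 0L
  for (k in 0:(nz - 1)) for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    vv <- c(vid(i, j, k),     vid(i + 1, j, k),
            vid(i, j + 1, k), vid(i + 1, j + 1, k),
            vid(i, j, k + 1), vid(i + 1, j, k + 1),
            vid(i, j + 1, k + 1), vid(i + 1, j + 1, k + 1))
    q <- q + 1L
    tets[[q]] <- kuhn_tets(vv)
  }
  tets <- do.call(rbind, tets)
  tets <- orient_tets(verts, tets)
  mesh <- tet_mesh(verts, tets, element_tags = rep(0L, nrow(tets)))
  attr(mesh, "endo_vertices") <- which(verts[, 3] == 0)
  attr(mesh, "epi_vertices") <- which(abs(verts[, 3] - extent[3]) < 1e-12)
  attr(mesh, "ncells") <- nc
  mesh
}

#' Structured triangulated sheet (2-D monodomain domain)
#'
#' Rectangle in the z = 0 plane, 2 triangles per cell; used for point-source
#' isochrone (elliptical activation) experiments.
#'
#' @param extent physical size (mm), length 2
#' @param h cell edge (mm)
#' @return a [surface_mesh()] with attribute `ncells`
#' @export
make_sheet_mesh <- function(extent = c(10, 10), h = 0.25) {
  nc <- pmax(as.integer(round(extent / h)), 2L)
  nx <- nc[1]; ny <- nc[2]
  hx <- extent[1] / nx; hy <- extent[2] / ny
  vid <- function(i, j) 1L + i + (nx + 1L) * j
  verts <- cbind(rep((0:nx) * hx, times = ny + 1),
                 rep((0:ny) * hy, each = nx + 1), 0)
  tris <- vector("list", nx * ny)
  q <- 0L
  for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    v00 <- vid(i, j); v10 <- vid(i + 1, j)
    v01 <- vid(i, j + 1); v11 <- vid(i + 1, j + 1)
    q <- q + 1L
    tris[[q]] <- rbind(c(v00, v10, v11), c(v00, v11, v01))
  }
  mesh <- surface_mesh(verts, do.call(rbind, tris),
                       element_tags = rep(0L, 2L * nx * ny))
  attr(mesh, "ncells") <- nc
  mesh
}

#' Shell-atrium specification defaults
#'
#' An ellipsoidal endocardial shell (semi-axes 14 x 11 x 9 mm) with a wall
#' thickness graded 1 to 3 mm from inferior to superior, four pulmonary-vein
#' openings, a mitral-valve opening and an open left-atrial-appendage rim
#' with a local outward bulge.  Deliberately parametric, not anatomical.
#'
#' @param ... overrides (semi_axes, wall_range, n, nr, ring_width_deg,
#'   laa_bulge, openings)
#' @return spec list
#' @export
shell_atrium_spec <- function(...) {
  nrm <- function(x) x / sqrt(sum(x^2))
  spec <- list(
    semi_axes = c(14, 11, 9), wall_range = c(1, 3), n = 10L, nr = 2L,
    ring_width_deg = 14, laa_bulge = 0.25,
    openings = list(
      mv   = list(axis = c(0, 0, -1), angle = 26),
      rspv = list(axis = nrm(c(0.55, 0.45, 0.72)), angle = 12),
      ripv = list(axis = nrm(c(0.85, 0.52, 0)), angle = 12),
      lspv = list(axis = nrm(c(-0.55, 0.45, 0.72)), angle = 12),
      lipv = list(axis = nrm(c(-0.85, 0.52, 0)), angle = 12),
      laa  = list(axis = nrm(c(0, -0.9, 0.44)), angle = 12)))
  over <- list(...)
  unknown <- setdiff(names(over), names(spec))
  if (length(unknown)) stopf("shell_atrium_spec: unknown field(s) %s",
                             paste(unknown, collapse = ", "))
  # whole-field replacement (an empty `openings` list must really mean
  # "no openings", which modifyList's recursive merge would ignore)
  spec[names(over)] <- over
  spec
}

# split a cyclic quad (a, b, c, d) by the diagonal through its minimum
# global vertex id; the rule is symmetric, so shared quads split identically
# on both sides.
split_quad <- function(q) {
  m <- which.min(q)
  rot <- c(q[m:4], q[seq_len(m - 1)])
  rbind(rot[c(1, 2, 3)], rot[c(1, 3, 4)])
}

#' Generate the idealized shell atrium
#'
#' Cube-sphere structured lattice mapped onto the ellipsoidal wall (no polar
#' degeneracy), hexahedral cells split into 12 tetrahedra around cell
#' centroids with a global diagonal rule (conforming everywhere), openings
#' cut through the wall, and a simplified region atlas: one encircling ring
#' region per opening (rim -> gamma0, outer border -> gamma1,
#' orthogonal flag set) and four azimuthal wall patches with
#' parallel-line boundary conditions.  Ground-truth region labels are
#' emitted constructively for partition tests.
#'
#' @param spec from [shell_atrium_spec()]
#' @return list with `mesh` ([tet_mesh()]), `endo`, `epi`
#'   ([surface_mesh()], normals outward from the wall), `labels_endo`,
#'   `labels_epi` (ground-truth region labels), `atlas_endo`, `atlas_epi`
#'   ([region_atlas()]), `seeds_endo`, `seeds_epi`, `landmarks`
#'   (a `landmark_set` on the endo surface), `spec`
#' @export
make_shell_atrium <- function(spec = shell_atrium_spec()) {
  n <- spec$n; nr <- spec$nr
  a <- spec$semi_axes
  # --- lattice points on the cube surface
  grid <- as.matrix(expand.grid(i = 0:n, j = 0:n, k = 0:n))
  on_surf <- apply(grid, 1, function(p) any(p == 0L | p == n))
  lat <- grid[on_surf, , drop = FALSE]
  key <- lat[, 1] * (n + 1)^2 + lat[, 2] * (n + 1) + lat[, 3]
  id_of <- new.env(hash = TRUE)
  for (i in seq_len(nrow(lat))) assign(as.character(key[i]), i, envir = id_of)
  ns <- nrow(lat)
  dirs <- t(apply(lat, 1, function(p) {
    d <- 2 * p / n - 1
    d / sqrt(sum(d^2))
  }))

  ang_to <- function(d, axis)
    acos(pmin(pmax(as.numeric(d %*% axis), -1), 1)) * 180 / pi
  thick <- function(d) spec$wall_range[1] +
    diff(spec$wall_range) * (d[, 3] + 1) / 2
  bulge <- function(d) {
    laa <- spec$openings$laa
    if (is.null(laa)) return(rep(1, nrow(d)))
    ang <- ang_to(d, laa$axis)
    1 + spec$laa_bulge * exp(-(ang / (laa$angle + spec$ring_width_deg))^2)
  }
  endo_r <- 1 / sqrt((dirs[, 1] / a[1])^2 + (dirs[, 2] / a[2])^2 +
                     (dirs[, 3] / a[3])^2)
  endo_r <- endo_r * bulge(dirs)
  th <- thick(dirs)

  # vertex (lattice point s, layer l in 0..nr): id = l*ns + s
  verts <- matrix(0, (nr + 1) * ns, 3)
  for (l in 0:nr) {
    r <- endo_r + th * l / nr
    verts[l * ns + seq_len(ns), ] <- dirs * r
  }

  # --- surface cells (quads) per cube face
  quads <- list()
  for (axis in 1:3) for (side in c(0L, n)) {
    oth <- setdiff(1:3, axis)
    for (aa in 0:(n - 1)) for (bb in 0:(n - 1)) {
      mk <- function(da, db) {
        p <- integer(3); p[axis] <- side
        p[oth[1]] <- aa + da; p[oth[2]] <- bb + db
        get(as.character(p[1] * (n + 1)^2 + p[2] * (n + 1) + p[3]), envir = id_of)
      }
      quads[[length(quads) + 1L]] <- c(mk(0, 0), mk(1, 0), mk(1, 1), mk(0, 1))
    }
  }
  quads <- do.call(rbind, quads)
  qdir <- t(apply(quads, 1, function(q) {
    d <- colSums(dirs[q, ]); d / sqrt(sum(d^2))
  }))

  # --- remove cells inside any opening
  open_of_quad <- rep(NA_character_, nrow(quads))
  in_hole <- rep(FALSE, nrow(quads))
  for (nm in names(spec$openings)) {
    o <- spec$openings[[nm]]
    ang <- ang_to(qdir, o$axis)
    in_hole <- in_hole | (ang < o$angle)
    open_of_quad[ang >= o$angle & ang < o$angle + spec$ring_width_deg &
                 is.na(open_of_quad)] <- nm
  }
  keep <- which(!in_hole)
  quads <- quads[keep, , drop = FALSE]
  qdir <- qdir[keep, , drop = FALSE]
  open_of_quad <- open_of_quad[keep]
  nq <- nrow(quads)

  # --- hexes (quad x layer) -> 12 tets around centroids
  ncent <- nq * nr
  cent_id0 <- (nr + 1) * ns
  cents <- matrix(0, ncent, 3)
  tets <- vector("list", ncent)
  for (l in 0:(nr - 1)) {
    for (qi in seq_len(nq)) {
      hexn <- c(l * ns + quads[qi, ], (l + 1) * ns + quads[qi, ])
      ci <- l * nq + qi
      cents[ci, ] <- colMeans(verts[hexn, ])
      cid <- cent_id0 + ci
      # 6 quad faces of the hex (cyclic vertex order)
      f <- rbind(hexn[c(1, 2, 3, 4)], hexn[c(5, 6, 7, 8)],
                 hexn[c(1, 2, 6, 5)], hexn[c(2, 3, 7, 6)],
                 hexn[c(3, 4, 8, 7)], hexn[c(4, 1, 5, 8)])
      tt <- matrix(0L, 12, 4)
      for (ff in 1:6) {
        tr <- split_quad(f[ff, ])
        tt[2 * ff - 1, ] <- c(tr[1, ], cid)
        tt[2 * ff, ] <- c(tr[2, ], cid)
      }
      tets[[ci]] <- tt
    }
  }
  all_verts <- rbind(verts, cents)
  tets <- do.call(rbind, tets)
  tets <- orient_tets(all_verts, tets)
  mesh <- tet_mesh(all_verts, tets, element_tags = rep(0L, nrow(tets)))

  # --- endo / epi surfaces (consistent with the tet boundary), outward
  # normals with respect to the wall solid
  build_surface <- function(layer, outward_sign) {
    tris <- vector("list", nq)
    for (qi in seq_len(nq)) {
      tr <- split_quad(layer * ns + quads[qi, ])
      # wind so the normal points along outward_sign * dir
      for (r in 1:2) {
        p <- all_verts[tr[r, ], ]
        nn <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
        if (sum(nn * qdir[qi, ]) * outward_sign < 0) tr[r, ] <- tr[r, c(1, 3, 2)]
      }
      tris[[qi]] <- tr
    }
    surface_mesh(all_verts, do.call(rbind, tris))
  }
  endo <- build_surface(0, -1)
  epi <- build_surface(nr, +1)

  # --- ground-truth region labels per surface triangle (two triangles per
  # quad, same label)
  azimuth_patch <- function(d) {
    th2 <- atan2(d[, 2], d[, 1])
    1L + ((floor((th2 + pi) / (pi / 2))) %% 4)
  }
  ring_names <- paste0(names(spec$openings), "_ring")
  patch_names <- paste0("wall_q", 1:4)
  labels_quad <- ifelse(is.na(open_of_quad),
                        patch_names[azimuth_patch(qdir)],
                        paste0(open_of_quad, "_ring"))
  region_names <- c(ring_names[ring_names %in% labels_quad],
                    patch_names[patch_names %in% labels_quad])
  lab_idx <- match(labels_quad, region_names)
  labels_tri <- rep(lab_idx, each = 2L)

  # each region must be edge-connected for single-seed growing: reassign
  # non-largest components (islands pinched off by the rings) to the
  # dominant neighboring region, iterating until stable
  adj0 <- element_adjacency(endo)
  repeat {
    changed <- FALSE
    for (ri in seq_along(region_names)) {
      tri_r <- which(labels_tri == ri)
      if (!length(tri_r)) next
      comp <- integer(length(labels_tri))
      cn <- 0L
      for (s in tri_r) {
        if (comp[s] != 0L) next
        cn <- cn + 1L
        queue <- s; comp[s] <- cn
        while (length(queue)) {
          t1 <- queue[[1]]; queue <- queue[-1]
          for (t2 in adj0[[t1]])
            if (labels_tri[t2] == ri && comp[t2] == 0L) {
              comp[t2] <- cn; queue <- c(queue, t2)
            }
        }
      }
      if (cn <= 1L) next
      sizes <- tabulate(comp[tri_r], cn)
      keep_c <- which.max(sizes)
      for (ci in setdiff(seq_len(cn), keep_c)) {
        isl <- tri_r[comp[tri_r] == ci]
        nb_lab <- unlist(lapply(isl, function(t1) labels_tri[adj0[[t1]]]))
        nb_lab <- nb_lab[nb_lab != ri]
        if (!length(nb_lab)) next
        # prefer merging into wall patches so the rings stay clean annuli
        patch_nb <- nb_lab[!endsWith(region_names[nb_lab], "_ring")]
        pool <- if (length(patch_nb)) patch_nb else nb_lab
        labels_tri[isl] <- as.integer(names(which.max(table(pool))))
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  # --- lines: all boundary edges between differently-labeled triangles,
  # plus the rim loops of each surface
  make_atlas <- function(surface) {
    loops <- boundary_loops(surface)
    # associate each rim loop with its opening by mean direction
    loop_names <- vapply(loops, function(lp) {
      cdir <- colMeans(surface$vertices[lp, , drop = FALSE])
      cdir <- cdir / sqrt(sum(cdir^2))
      angs <- vapply(names(spec$openings),
                     function(nm) as.numeric(ang_to(matrix(cdir, 1),
                                                    spec$openings[[nm]]$axis)),
                     0)
      paste0("rim_", names(which.min(angs)))
    }, "")
    lines <- setNames(lapply(loops, function(lp) c(lp, lp[1])), loop_names)

    # inter-region boundary edge sets -> traced paths
    tri <- surface$triangles
    adj <- element_adjacency(surface)
    nvv <- nrow(surface$vertices)
    pair_edges <- list()
    for (t1 in seq_len(nrow(tri))) for (t2 in adj[[t1]]) {
      if (t2 <= t1) next
      if (labels_tri[t1] == labels_tri[t2]) next
      pr <- paste("b", paste(sort(region_names[c(labels_tri[t1], labels_tri[t2])]),
                             collapse = "|"), sep = "|")
      common <- intersect(tri[t1, ], tri[t2, ])
      pair_edges[[pr]] <- rbind(pair_edges[[pr]], sort(common))
    }
    for (pr in names(pair_edges)) {
      paths <- trace_edge_paths(pair_edges[[pr]])
      for (pi in seq_along(paths)) {
        nm <- if (length(paths) == 1L) pr else sprintf("%s#%d", pr, pi)
        lines[[nm]] <- paths[[pi]]
      }
    }
    # regions named in a border line "b|A|B[#k]"
    line_regions <- lapply(names(lines), function(lnm) {
      if (!startsWith(lnm, "b|")) return(character())
      strsplit(sub("#.*$", "", lnm), "\\|")[[1]][-1]
    })
    names(line_regions) <- names(lines)

    # boundary-condition assignment
    bc <- list()
    for (ri in seq_along(region_names)) {
      rn <- region_names[ri]
      border_lines <- names(lines)[vapply(line_regions,
                                          function(p) rn %in% p, TRUE)]
      if (endsWith(rn, "_ring")) {
        opening <- sub("_ring$", "", rn)
        rim <- paste0("rim_", opening)
        if (!rim %in% names(lines))
          stopf("make_shell_atrium: no rim loop found for opening '%s'", opening)
        bc[[rn]] <- list(gamma0 = rim, gamma1 = border_lines, orthogonal = TRUE)
      } else {
        q <- as.integer(sub("wall_q", "", rn))
        prev <- paste0("wall_q", ((q - 2) %% 4) + 1)
        nxt <- paste0("wall_q", (q %% 4) + 1)
        g0 <- border_lines[vapply(line_regions[border_lines],
                                  function(p) prev %in% p, TRUE)]
        g1 <- border_lines[vapply(line_regions[border_lines],
                                  function(p) nxt %in% p, TRUE)]
        bc[[rn]] <- list(gamma0 = g0, gamma1 = g1, orthogonal = FALSE)
      }
    }
    seeds <- setNames(vapply(seq_along(region_names),
                             function(ri) which(labels_tri == ri)[1], 0L),
                      region_names)
    list(atlas = region_atlas(lines, labels_tri, region_names, bc),
         seeds = seeds)
  }
  at_endo <- make_atlas(endo)
  at_epi <- make_atlas(epi)

  # --- landmarks on the endo surface: superior point of each rim loop and
  # four cardinal wall points
  lm_names <- character(); lm_verts <- integer()
  endo_loops <- boundary_loops(endo)
  for (lp in endo_loops) {
    cdir <- colMeans(endo$vertices[lp, , drop = FALSE])
    cdir <- cdir / sqrt(sum(cdir^2))
    angs <- vapply(names(spec$openings),
                   function(nm) as.numeric(ang_to(matrix(cdir, 1),
                                                  spec$openings[[nm]]$axis)), 0)
    nm <- names(which.min(angs))
    lm_names <- c(lm_names, paste0(nm, "_rim_superior"))
    lm_verts <- c(lm_verts, lp[which.max(endo$vertices[lp, 3])])
  }
  cardinal <- rbind(roof_center = c(0, 0, 1), septum_center = c(1, 0, 0),
                    lateral_center = c(-1, 0, 0), posterior_center = c(0, 1, 0))
  used_endo <- sort(unique(as.vector(endo$triangles)))
  for (ci in seq_len(nrow(cardinal))) {
    tgt <- cardinal[ci, ] * max(a)
    vi <- used_endo[.nn_index(matrix(tgt, 1),
                              endo$vertices[used_endo, , drop = FALSE])[1]]
    lm_names <- c(lm_names, rownames(cardinal)[ci])
    lm_verts <- c(lm_verts, vi)
  }
  landmarks <- landmark_set(lm_names, lm_verts, endo, "manual")

  list(mesh = mesh, endo = endo, epi = epi,
       labels_endo = labels_tri, labels_epi = labels_tri,
       atlas_endo = at_endo$atlas, atlas_epi = at_epi$atlas,
       seeds_endo = at_endo$seeds, seeds_epi = at_epi$seeds,
       landmarks = landmarks, spec = spec)
}

# Order an undirected edge set (m x 2 vertex pairs) into connected vertex
# paths/loops.  Branch vertices (degree > 2) split paths.
trace_edge_paths <- function(edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (!nrow(edges)) return(list())
  vs <- sort(unique(as.vector(edges)))
  nbr <- new.env(hash = TRUE)
  for (i in seq_len(nrow(edges))) {
    for (ab in list(edges[i, ], edges[i, 2:1])) {
      k <- as.character(ab[1])
      assign(k, c(get0(k, envir = nbr, ifnotfound = integer()), ab[2]), envir = nbr)
    }
  }
  used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  deg <- vapply(as.character(vs), function(k) length(get0(k, envir = nbr)), 0L)
  paths <- list()
  start_order <- c(vs[deg != 2L], vs[deg == 2L])
  for (s in start_order) {
    repeat {
      nb <- get0(as.character(s), envir = nbr, ifnotfound = integer())
      nb <- nb[!vapply(nb, function(b) !is.null(get0(ekey(s, b), envir = used)), TRUE)]
      if (!length(nb)) break
      path <- s; cur <- s
      repeat {
        nb2 <- get0(as.character(cur), envir = nbr, ifnotfound = integer())
        nb2 <- nb2[!vapply(nb2, function(b) !is.null(get0(ekey(cur, b), envir = used)), TRUE)]
        if (!length(nb2)) break
        nxt <- min(nb2)
        assign(ekey(cur, nxt), TRUE, envir = used)
        path <- c(path, nxt)
        cur <- nxt
        # stop at branch vertices so every emitted line is a simple path
        dcur <- length(get0(as.character(cur), envir = nbr))
        if (dcur != 2L) break
      }
      if (length(path) >= 2L) paths[[length(paths) + 1L]] <- path
    }
  }
  paths
}
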