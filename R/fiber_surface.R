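# Surface fiber generation: per-region Laplace solves whose normalized
# gradients define the fiber axes at the triangle centers, neighbor fill of
# degenerate elements, interregional smoothing near the auxiliary lines, and
# tangential projection.  Fiber axes are line fields (directionless): all
# averaging is sign-aligned before summing.

#' Surface fiber field container
#'
#' @param axes ntri x 3 matrix (rows unit where defined)
#' @param defined logical per triangle
#' @param provenance character per triangle: `"laplace"`, `"filled"`,
#'   `"smoothed"` or `"undefined"`
#' @return object of class `surface_fiber_field`
#' @export
surface_fiber_field <- function(axes, defined, provenance = NULL) {
  axes <- as.matrix(axes)
  if (is.null(provenance))
    provenance <- ifelse(defined, "laplace", "undefined")
  structure(list(axes = axes, defined = as.logical(defined),
                 provenance = provenance),
            class = "surface_fiber_field")
}

#' Per-region Laplace fibers on a surface
#'
#' For each atlas region independently, solves Laplace's equation on the
#' region's triangles with u = 0 on its gamma0 lines and u = 1 on its gamma1
#' lines (zero-flux elsewhere), and assigns the normalized in-plane gradient
#' as the fiber axis of every triangle.  With the region's `orthogonal` flag
#' the axis is rotated 90 degrees in the triangle plane (gradients point
#' across a rim band; the rotation yields the encircling arrangement).
#' Triangles with degenerate gradients (below `tol`) are left undefined for
#' [fill_undefined()].
#'
#' @param surface a [surface_mesh()]
#' @param atlas a [region_atlas()] whose labels match the surface triangles
#' @param tol gradient degeneracy threshold
#' @return a [surface_fiber_field()]
#' @export
region_fibers <- function(surface, atlas, tol = 1e-8) {
  ntri <- nrow(surface$triangles)
  if (length(atlas$labels) != ntri)
    stopf("region_fibers: atlas labels (%d) do not match surface triangles (%d)",
          length(atlas$labels), ntri)
  axes <- matrix(0, ntri, 3)
  defined <- rep(FALSE, ntri)
  normals <- triangle_geometry(surface)$normals
  for (ri in seq_along(atlas$region_names)) {
    rn <- atlas$region_names[ri]
    tri_idx <- which(atlas$labels == ri)
    if (!length(tri_idx)) next
    b <- atlas$bc[[rn]]
    # submesh with remapped vertices
    tris <- surface$triangles[tri_idx, , drop = FALSE]
    used <- sort(unique(as.vector(tris)))
    remap <- integer(nrow(surface$vertices)); remap[used] <- seq_along(used)
    sub <- surface_mesh(surface$vertices[used, , drop = FALSE],
                        matrix(remap[tris], ncol = 3))
    g0 <- remap[intersect(unique(unlist(atlas$lines[b$gamma0])), used)]
    g1 <- remap[intersect(unique(unlist(atlas$lines[b$gamma1])), used)]
    g1 <- setdiff(g1, g0)
    if (!length(g0) || !length(g1))
      stopf("region_fibers: region '%s' has empty Dirichlet set on the surface", rn)
    u <- solve_laplace(sub, laplace_bc(g0, g1))
    g <- element_gradient(sub, u)
    nrm <- sqrt(rowSums(g^2))
    ok <- nrm > tol
    ax <- matrix(0, length(tri_idx), 3)
    ax[ok, ] <- g[ok, , drop = FALSE] / nrm[ok]
    if (isTRUE(b$orthogonal)) {
      # rotate 90 degrees in-plane: axis <- normal x axis
      ax[ok, ] <- cross_rows(normals[tri_idx[ok], , drop = FALSE],
                             ax[ok, , drop = FALSE])
      ax[ok, ] <- normalize_rows(ax[ok, , drop = FALSE])
    }
    axes[tri_idx, ] <- ax
    defined[tri_idx] <- ok
  }
  surface_fiber_field(axes, defined)
}

# Sign-aligned mean of axis rows: flip each row to the hemisphere of the
# reference (first row unless given), then average.
aligned_mean <- function(axes, reference = NULL) {
  if (is.null(reference)) reference <- axes[1, ]
  s <- sign(axes %*% reference)
  s[s == 0] <- 1
  colMeans(axes * as.numeric(s))
}

#' Fill undefined fiber axes from neighbors
#'
#' Iterative deterministic propagation: in triangle-index order, every
#' undefined triangle with at least one defined edge-neighbor takes the
#' sign-aligned average of its defined neighbors (renormalized); sweeps
#' repeat until full coverage.
#'
#' @param field a [surface_fiber_field()]
#' @param adjacency triangle adjacency from [element_adjacency()]
#' @return fully defined [surface_fiber_field()] (filled triangles get
#'   provenance `"filled"`)
#' @export
fill_undefined <- function(field, adjacency) {
  axes <- field$axes; defined <- field$defined; prov <- field$provenance
  while (any(!defined)) {
    newly <- integer()
    new_axes <- list()
    for (t in which(!defined)) {
      nb <- adjacency[[t]]
      nb <- nb[defined[nb]]
      if (!length(nb)) next
      m <- aligned_mean(axes[nb, , drop = FALSE])
      nrm <- vec_norm(m)
      if (nrm < 1e-12) next
      newly <- c(newly, t)
      new_axes[[length(new_axes) + 1L]] <- m / nrm
    }
    if (!length(newly))
      stopf("fill_undefined: %d undefined axes cannot be reached (component without defined axes)",
            sum(!defined))
    # simultaneous update per sweep keeps the result order-independent
    for (i in seq_along(newly)) axes[newly[i], ] <- new_axes[[i]]
    defined[newly] <- TRUE
    prov[newly] <- "filled"
  }
  surface_fiber_field(axes, defined, prov)
}

#' Interregional fiber smoothing near the auxiliary lines
#'
#' Triangles within `band_width` edge-hops of an auxiliary line are replaced
#' by the sign-aligned average of themselves and their edge-neighbors,
#' re-projected to their tangent plane and renormalized; triangles outside
#' the band are untouched.
#'
#' @param field fully defined [surface_fiber_field()]
#' @param surface the [surface_mesh()]
#' @param atlas a [region_atlas()] (its lines define the bands)
#' @param band_width band radius in edge-hops (default 2)
#' @param passes smoothing passes (default 3)
#' @return smoothed [surface_fiber_field()]
#' @export
smooth_interregional <- function(field, surface, atlas, band_width = 2,
                                 passes = 3) {
  if (!all(field$defined)) stopf("smooth_interregional: field must be fully defined")
  adjacency <- element_adjacency(surface)
  line_verts <- unique(unlist(atlas$lines))
  on_line <- rowSums(matrix(surface$triangles %in% line_verts,
                            ncol = 3)) > 0
  band <- which(on_line)
  frontier <- band
  for (h in seq_len(band_width)) {
    frontier <- setdiff(unique(unlist(adjacency[frontier])), band)
    band <- c(band, frontier)
  }
  band <- sort(band)
  normals <- triangle_geometry(surface)$normals
  axes <- field$axes; prov <- field$provenance
  for (p in seq_len(passes)) {
    new_axes <- axes
    for (t in band) {
      nb <- c(t, adjacency[[t]])
      m <- aligned_mean(axes[nb, , drop = FALSE], reference = axes[t, ])
      n <- normals[t, ]
      m <- m - sum(m * n) * n
      nrm <- vec_norm(m)
      if (nrm > 1e-12) new_axes[t, ] <- m / nrm
    }
    axes <- new_axes
  }
  changed <- band[rowSums(abs(axes[band, , drop = FALSE] -
                              field$axes[band, , drop = FALSE])) > 0]
  prov[changed] <- "smoothed"
  surface_fiber_field(axes, field$defined, prov)
}

#' Project fiber axes onto their triangle tangent planes
#'
#' axis <- normalize(axis - (axis . n) n).  Axes (nearly) parallel to the
#' normal are marked undefined and refilled from neighbors.
#'
#' @param field a [surface_fiber_field()]
#' @param surface the [surface_mesh()]
#' @param tol degeneracy threshold on the projected norm
#' @return tangential [surface_fiber_field()]
#' @export
project_tangential <- function(field, surface, tol = 1e-8) {
  normals <- triangle_geometry(surface)$normals
  axes <- field$axes
  dn <- rowSums(axes * normals)
  proj <- axes - dn * normals
  nrm <- sqrt(rowSums(proj^2))
  ok <- nrm > tol & field$defined
  proj[ok, ] <- proj[ok, , drop = FALSE] / nrm[ok]
  out <- surface_fiber_field(proj, ok, ifelse(ok, field$provenance, "undefined"))
  if (!all(ok)) out <- fill_undefined(out, element_adjacency(surface))
  out
}

#' Full surface fiber pipeline for one surface
#'
#' region solve -> neighbor fill -> interregional smoothing -> tangential
#' projection; returns the surface with its `fibers` slot populated.
#'
#' @param surface a [surface_mesh()]
#' @param atlas a [region_atlas()]
#' @param band_width,passes see [smooth_interregional()]
#' @return list with `surface` (fibers set) and `field`
#' @export
surface_fibers <- function(surface, atlas, band_width = 2, passes = 3) {
  field <- region_fibers(surface, atlas)
  field <- fill_undefined(field, element_adjacency(surface))
  field <- smooth_interregional(field, surface, atlas, band_width, passes)
  field <- project_tangential(field, surface)
  surface$fibers <- field$axes
  validate_mesh(surface)
  list(surface = surface, field = field)
}

#' Discrete winding number of a fiber field around a rim loop
#'
#' Walks the triangles adjacent to a rim loop and accumulates the signed
#' in-plane rotation of the axis field (axes are directionless: each step
#' uses the representative within 90 degrees of the previous one).  A closed
#' circulating arrangement around a PV rim gives +/-1.
#'
#' @param surface a [surface_mesh()] with fibers
#' @param loop integer vertex cycle (from [boundary_loops()])
#' @return winding number (axis field turns in units of full turns)
#' @export
rim_winding_number <- function(surface, loop) {
  if (is.null(surface$fibers)) stopf("rim_winding_number: surface has no fibers")
  # ring of triangles with an edge on the loop (vertex-only contact would
  # pull in triangles of the neighboring region), ordered along the loop
  tri <- surface$triangles
  on_loop <- matrix(tri %in% loop, ncol = 3)
  ring <- which(rowSums(on_loop) >= 2L)
  centers <- element_centers(surface)[ring, , drop = FALSE]
  cen <- colMeans(surface$vertices[loop, , drop = FALSE])
  # local frame of the rim plane from the loop
  pts <- sweep(surface$vertices[loop, , drop = FALSE], 2, cen, `-`)
  sv <- svd(pts)
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  ang_pos <- atan2(sweep(centers, 2, cen, `-`) %*% e2,
                   sweep(centers, 2, cen, `-`) %*% e1)
  ord <- order(ang_pos)
  ax <- surface$fibers[ring[ord], , drop = FALSE]
  ctr <- centers[ord, , drop = FALSE]
  # axis angle in the local (radial, tangential) frame of each ring
  # triangle: for any field with index 1 (circulating or radial) psi is
  # nearly constant around the ring, so the pi-wrapped increments stay
  # small even on coarse rings; the frame itself contributes exactly one
  # full turn.
  nrm_ax <- cross3(e1, e2)
  rad <- sweep(ctr, 2, cen, `-`)
  rad <- rad - (rad %*% nrm_ax) %*% t(nrm_ax)   # in-plane radial direction
  rad <- normalize_rows(rad)
  tng <- cross_rows(matrix(nrm_ax, nrow(rad), 3, byrow = TRUE), rad)
  psi <- (atan2(rowSums(ax * rad), rowSums(ax * tng))) %% pi
  total <- 0
  for (i in seq_along(psi)) {
    a <- psi[i]; b <- psi[if (i == length(psi)) 1 else i + 1]
    d <- b - a
    # wrap to (-pi/2, pi/2]: line field, shortest rotation between axes
    while (d > pi / 2) d <- d - pi
    while (d <= -pi / 2) d <- d + pi
    total <- total + d
  }
  1 + total / (2 * pi)
}
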