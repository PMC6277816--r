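# Transmural fiber interpolation: the wall-crossing Laplace coordinate, the
# endo/epi correspondence map obtained by tracing the normalized gradient
# field from each tetrahedron barycenter, the four interpolation weight
# functions, and the blended, field-line-orthogonal volume fibers.

#' Transmural Laplace coordinate
#'
#' Solves Laplace's equation on the wall volume with u = 0 on the
#' endocardial vertices and u = 1 on the epicardial vertices; the PV/MV/LAA
#' rims are natural zero-flux boundaries.
#'
#' @param mesh a [tet_mesh()]
#' @param endo_vertices,epi_vertices disjoint vertex sets (from
#'   [extract_boundary_surfaces()])
#' @return vertex field u in \[0, 1\]
#' @export
transmural_laplace <- function(mesh, endo_vertices, epi_vertices) {
  if (length(intersect(endo_vertices, epi_vertices)))
    stopf("transmural_laplace: endo and epi vertex sets overlap")
  solve_laplace(mesh, laplace_bc(endo_vertices, epi_vertices))
}

#' Transmural interpolation weight functions
#'
#' The four schemes mapping the normalized transmural coordinate phi (0 at
#' the endocardium, 1 at the epicardium) to the blending weight omega:
#' \describe{
#'   \item{two_layer}{0 for phi <= 0.5, 1 above (abrupt mid-wall switch)}
#'   \item{five_layer}{steps 0, 0.25, 0.5, 0.75, 1 on the intervals
#'     (0.2, 0.4, 0.6, 0.8)}
#'   \item{linear}{omega = phi}
#'   \item{sigmoid}{omega = (1 + tanh(5 (phi - 0.5)))/2; the affine
#'     normalization of the hyperbolic-tangent profile onto \[0, 1\]}
#' }
#'
#' @param phi numeric in \[0, 1\]
#' @param scheme one of `"two_layer"`, `"five_layer"`, `"linear"`,
#'   `"sigmoid"`
#' @return omega, same length as `phi`
#' @export
interpolation_weight <- function(phi,
                                 scheme = c("two_layer", "five_layer",
                                            "linear", "sigmoid")) {
  scheme <- match.arg(scheme)
  phi <- as.numeric(phi)
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stopf("interpolation_weight: phi outside [0, 1]")
  switch(scheme,
    two_layer = ifelse(phi <= 0.5, 0, 1),
    five_layer = ifelse(phi <= 0.2, 0,
                 ifelse(phi <= 0.4, 0.25,
                 ifelse(phi <= 0.6, 0.5,
                 ifelse(phi <= 0.8, 0.75, 1)))),
    linear = phi,
    sigmoid = 0.5 * (1 + tanh(5 * (phi - 0.5))))
}

#' Blend endo- and epicardial fiber axes
#'
#' Normalized convex combination f = ((1-w) f_ED + w f_EP) / ||.|| with
#' sign alignment first (f_EP flipped into the hemisphere of f_ED): fiber
#' axes are directionless, and unaligned blending can cancel.
#'
#' @param f_ed,f_ep unit 3-vectors or n x 3 matrices
#' @param omega weight(s) in \[0, 1\]
#' @return unit vector(s), same shape as the inputs
#' @export
blend_fibers <- function(f_ed, f_ep, omega) {
  ved <- matrix(as.numeric(f_ed), ncol = 3)
  vep <- matrix(as.numeric(f_ep), ncol = 3)
  s <- sign(rowSums(ved * vep)); s[s == 0] <- 1
  vep <- vep * s
  out <- (1 - omega) * ved + omega * vep
  nrm <- sqrt(rowSums(out^2))
  if (any(nrm < 1e-12))
    stopf("blend_fibers: degenerate combination after alignment")
  out <- out / nrm
  if (is.null(dim(f_ed)) && length(f_ed) == 3L) out[1, ] else out
}

# Face->surface-triangle lookup for a boundary surface extracted from `mesh`.
surface_face_lookup <- function(mesh, surface) {
  nv <- nrow(mesh$vertices)
  tri <- surface$triangles
  keys <- face_key(tri[, 1], tri[, 2], tri[, 3], nv)
  env <- new.env(hash = TRUE)
  for (i in seq_along(keys)) assign(as.character(keys[i]), i, envir = env)
  env
}

# Trace the piecewise-constant gradient field from point x in tet e0 along
# direction sgn * g until a boundary face is hit.  Exact element hopping:
# within each tet the direction is constant, so the exit face is found by
# ray/plane intersection.  Returns list(face_key, steps) or NULL on failure.
trace_fieldline <- function(mesh, grads, tet_adj_faces, x, e0, sgn,
                            max_steps = 2000L) {
  v <- mesh$vertices; tets <- mesh$tets
  nvv <- nrow(v)
  e <- e0
  prev <- 0L
  exit_face <- function(faces, x, d, skip = 0L) {
    best_t <- Inf; best_f <- 0L
    for (f in 1:4) {
      if (f == skip) next
      p1 <- v[faces[f, 1], ]; p2 <- v[faces[f, 2], ]; p3 <- v[faces[f, 3], ]
      n <- cross3(p2 - p1, p3 - p1)
      dn <- sum(n * d)
      if (dn <= 1e-14) next
      t <- sum(n * (p1 - x)) / dn
      if (t >= -1e-9 && t < best_t) { best_t <- t; best_f <- f }
    }
    list(t = best_t, f = best_f)
  }
  for (step in seq_len(max_steps)) {
    d <- sgn * grads[e, ]
    nd <- vec_norm(d)
    if (nd < 1e-12) return(NULL)
    d <- d / nd
    tv <- tets[e, ]
    # faces with outward normals; local faces in tet_faces_outward order
    faces <- rbind(tv[c(2, 3, 4)], tv[c(1, 4, 3)], tv[c(1, 2, 4)], tv[c(1, 3, 2)])
    ex <- exit_face(faces, x, d)
    if (ex$f == 0L) return(NULL)
    fk <- face_key(faces[ex$f, 1], faces[ex$f, 2], faces[ex$f, 3], nvv)
    nxt <- tet_adj_faces[[as.character(fk)]]
    nxt <- nxt[nxt != e]
    if (length(nxt) && nxt[1] == prev && ex$t < 1e-8) {
      # discrete field lines of the piecewise-constant gradient can converge
      # at a face (both tets point into it): slide along the face using the
      # face-projected mean direction of the two tets
      p1 <- v[faces[ex$f, 1], ]; p2 <- v[faces[ex$f, 2], ]; p3 <- v[faces[ex$f, 3], ]
      nf <- cross3(p2 - p1, p3 - p1); nf <- nf / max(vec_norm(nf), 1e-300)
      dd <- sgn * (grads[e, ] + grads[nxt[1], ])
      dd <- dd - sum(dd * nf) * nf
      if (vec_norm(dd) < 1e-12) return(NULL)
      d <- dd / vec_norm(dd)
      ex <- exit_face(faces, x, d, skip = ex$f)
      if (ex$f == 0L) return(NULL)
      fk <- face_key(faces[ex$f, 1], faces[ex$f, 2], faces[ex$f, 3], nvv)
      nxt <- tet_adj_faces[[as.character(fk)]]
      nxt <- nxt[nxt != e]
    }
    x <- x + max(ex$t, 0) * d
    if (!length(nxt)) return(list(face_key = fk, point = x, steps = step))
    prev <- e
    e <- nxt[1]
  }
  NULL
}

#' Build the endo/epi correspondence map
#'
#' For every tetrahedron: the normalized transmural coordinate phi (mean of
#' the 4 nodal u values, clamped to \[0, 1\]), the unit field-line direction,
#' and the endo- and epicardial surface triangles hit by tracing the gradient
#' field downhill and uphill from the barycenter.  Trajectories that exit
#' through an open rim fall back to the nearest surface triangle (flagged in
#' the provenance column).
#'
#' @param mesh a [tet_mesh()]
#' @param u transmural field from [transmural_laplace()]
#' @param endo_surface,epi_surface boundary components of `mesh` (from
#'   [extract_boundary_surfaces()])
#' @return data.frame with columns phi, endo_triangle, epi_triangle,
#'   dir_x/dir_y/dir_z (unit field-line direction) and provenance
#'   (`"traced"`, `"endo_fallback"`, `"epi_fallback"`, `"fallback"`)
#' @export
build_correspondence <- function(mesh, u, endo_surface, epi_surface) {
  nt <- nrow(mesh$tets)
  phi <- pmin(pmax(rowMeans(matrix(u[mesh$tets], ncol = 4)), 0), 1)
  grads <- element_gradient(mesh, u)
  gn <- sqrt(rowSums(grads^2))
  dirs <- grads
  ok <- gn > 1e-10
  dirs[ok, ] <- dirs[ok, , drop = FALSE] / gn[ok]
  # degenerate gradients inherit the mean direction of face neighbors later;
  # initialize with the global mean direction for robustness
  if (any(!ok)) {
    mdir <- colMeans(dirs[ok, , drop = FALSE])
    mdir <- mdir / max(vec_norm(mdir), 1e-12)
    dirs[!ok, ] <- matrix(mdir, sum(!ok), 3, byrow = TRUE)
  }

  # face -> owning tets map for hopping
  faces <- tet_faces_outward(mesh$tets)
  keys <- face_key(faces[, 1], faces[, 2], faces[, 3], nrow(mesh$vertices))
  owner <- rep(seq_len(nt), 4L)
  tet_adj_faces <- new.env(hash = TRUE)
  ord <- order(keys)
  sk <- keys[ord]; so <- owner[ord]
  runs <- rle(sk); ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  for (r in seq_along(runs$values))
    assign(as.character(runs$values[r]), so[starts[r]:ends[r]], envir = tet_adj_faces)

  lk_endo <- surface_face_lookup(mesh, endo_surface)
  lk_epi <- surface_face_lookup(mesh, epi_surface)
  endo_cen <- element_centers(endo_surface)
  epi_cen <- element_centers(epi_surface)
  centers <- element_centers(mesh)

  endo_tri <- integer(nt); epi_tri <- integer(nt)
  prov <- character(nt)
  for (e in seq_len(nt)) {
    hit_e <- trace_fieldline(mesh, dirs, tet_adj_faces, centers[e, ], e, -1)
    et <- if (!is.null(hit_e)) get0(as.character(hit_e$face_key), envir = lk_endo)
    hit_p <- trace_fieldline(mesh, dirs, tet_adj_faces, centers[e, ], e, +1)
    pt <- if (!is.null(hit_p)) get0(as.character(hit_p$face_key), envir = lk_epi)
    fb <- character()
    if (is.null(et)) {
      et <- .nn_index(matrix(centers[e, ], 1), endo_cen)[1]
      fb <- c(fb, "endo")
    }
    if (is.null(pt)) {
      pt <- .nn_index(matrix(centers[e, ], 1), epi_cen)[1]
      fb <- c(fb, "epi")
    }
    endo_tri[e] <- et; epi_tri[e] <- pt
    prov[e] <- if (!length(fb)) "traced"
               else if (length(fb) == 2L) "fallback"
               else paste0(fb, "_fallback")
  }
  data.frame(phi = phi, endo_triangle = endo_tri, epi_triangle = epi_tri,
             dir_x = dirs[, 1], dir_y = dirs[, 2], dir_z = dirs[, 3],
             provenance = prov, stringsAsFactors = FALSE)
}

#' Assign volume fibers by transmural interpolation
#'
#' Per tetrahedron: blend the corresponding endo- and epicardial surface
#' axes with the scheme weight omega(phi), then project the result onto the
#' plane orthogonal to the local field-line direction and renormalize.
#' Projection degeneracies (blended axis parallel to the field line) are
#' filled from face neighbors.
#'
#' @param mesh a [tet_mesh()]
#' @param correspondence from [build_correspondence()]
#' @param endo_fibers,epi_fibers per-triangle axis matrices of the endo/epi
#'   surfaces (or surfaces with `fibers` set)
#' @param scheme see [interpolation_weight()]
#' @return the mesh with per-tet `fibers`, plus attribute `provenance`
#'   (data.frame: tet, phi, omega, flags)
#' @export
assign_volume_fibers <- function(mesh, correspondence, endo_fibers, epi_fibers,
                                 scheme = "linear") {
  if (inherits(endo_fibers, "surface_mesh")) endo_fibers <- endo_fibers$fibers
  if (inherits(epi_fibers, "surface_mesh")) epi_fibers <- epi_fibers$fibers
  nt <- nrow(mesh$tets)
  omega <- interpolation_weight(correspondence$phi, scheme)
  f_ed <- endo_fibers[correspondence$endo_triangle, , drop = FALSE]
  f_ep <- epi_fibers[correspondence$epi_triangle, , drop = FALSE]
  blended <- blend_fibers(f_ed, f_ep, omega)
  dirs <- as.matrix(correspondence[, c("dir_x", "dir_y", "dir_z")])
  proj <- blended - rowSums(blended * dirs) * dirs
  nrm <- sqrt(rowSums(proj^2))
  ok <- nrm > 1e-8
  proj[ok, ] <- proj[ok, , drop = FALSE] / nrm[ok]
  if (any(!ok)) {
    adj <- element_adjacency(mesh)
    field <- surface_fiber_field(proj, ok)
    field <- fill_undefined(field, adj)
    # refilled axes must stay orthogonal to their field line
    bad <- which(!ok)
    ax <- field$axes[bad, , drop = FALSE]
    dd <- dirs[bad, , drop = FALSE]
    ax <- ax - rowSums(ax * dd) * dd
    ax <- normalize_rows(ax)
    proj[bad, ] <- ax
    proj[ok, ] <- field$axes[ok, , drop = FALSE]
  }
  mesh$fibers <- proj
  validate_mesh(mesh)
  attr(mesh, "provenance") <- data.frame(tet = seq_len(nt),
                                         phi = correspondence$phi,
                                         omega = omega,
                                         flags = correspondence$provenance,
                                         stringsAsFactors = FALSE)
  mesh
}
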