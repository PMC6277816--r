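# Topology queries: boundary surface extraction (BFS over shared edges),
# element adjacency, rim-loop tracing, enclosed volumes.

# Encode sorted integer tuples as numeric keys (safe below 2^53).
face_key <- function(a, b, c, nv) {
  lo <- pmin(a, b, c); hi <- pmax(a, b, c); mid <- a + b + c - lo - hi
  (as.numeric(lo) * (nv + 1) + mid) * (nv + 1) + hi
}
edge_key <- function(a, b, nv) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  as.numeric(lo) * (nv + 1) + hi
}

# All 16 face slots of a tet mesh, wound so normals point out of the tet
# (valid for positive-volume ordering).
tet_faces_outward <- function(tets) {
  rbind(tets[, c(2, 3, 4), drop = FALSE],
        tets[, c(1, 4, 3), drop = FALSE],
        tets[, c(1, 2, 4), drop = FALSE],
        tets[, c(1, 3, 2), drop = FALSE])
}

#' Extract boundary surfaces of a tetrahedral mesh
#'
#' Boundary faces (faces belonging to exactly one tetrahedron) are wound
#' outward with respect to the solid and grouped into connected components by
#' breadth-first search over shared edges.  For a shell (hollow) topology this
#' yields two components; the epicardial (outer) surface is the one with the
#' larger absolute enclosed volume.
#'
#' For geometries with openings cut through the wall (PV/MV rims) the
#' boundary is a single closed surface; setting `feature_angle` makes the
#' search refuse to cross sharp creases (adjacent boundary faces whose
#' normals differ by more than the angle), which separates the endo- and
#' epicardial sheets from the narrow cut bands at the rims.
#'
#' @param mesh a [tet_mesh()]
#' @param feature_angle crease angle in degrees limiting the BFS
#'   (`NULL` or `Inf` disables feature splitting)
#' @return list of [surface_mesh()] objects sharing the parent vertex array,
#'   ordered by decreasing surface area.  Each carries attributes
#'   `parent_tet` (owning tet per triangle), `enclosed_volume` (signed, mm^3;
#'   positive for an outer surface) and `rim_loops` (list of vertex cycles
#'   bounding unclosed rims, e.g. PV/MV openings).
#' @export
extract_boundary_surfaces <- function(mesh, feature_angle = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  nv <- nrow(mesh$vertices)
  nt <- nrow(mesh$tets)
  faces <- tet_faces_outward(mesh$tets)
  owner <- rep(seq_len(nt), 4L)
  keys <- face_key(faces[, 1], faces[, 2], faces[, 3], nv)
  cnt <- table(keys)
  bnd_keys <- as.numeric(names(cnt)[cnt == 1L])
  sel <- keys %in% bnd_keys
  bfaces <- faces[sel, , drop = FALSE]
  bowner <- owner[sel]
  nb <- nrow(bfaces)
  if (nb == 0L) return(list())

  # Edge incidence among boundary faces; a boundary edge on >2 faces is
  # non-manifold.
  ek <- cbind(edge_key(bfaces[, 1], bfaces[, 2], nv),
              edge_key(bfaces[, 2], bfaces[, 3], nv),
              edge_key(bfaces[, 3], bfaces[, 1], nv))
  all_ek <- as.vector(ek)
  face_of_edge <- rep(seq_len(nb), times = 3L)
  ord <- order(all_ek)
  se <- all_ek[ord]; sf <- face_of_edge[ord]
  runs <- rle(se)
  if (any(runs$lengths > 2L))
    stopf("extract_boundary_surfaces: non-manifold boundary edge (shared by %d faces)",
          max(runs$lengths))
  # adjacency pairs: edges shared by exactly 2 boundary faces
  two <- runs$lengths == 2L
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  f1 <- sf[starts[two]]; f2 <- sf[ends[two]]
  if (!is.null(feature_angle) && is.finite(feature_angle)) {
    bs <- surface_mesh(mesh$vertices, bfaces)
    nrm <- triangle_geometry(bs)$normals
    cosang <- rowSums(nrm[f1, , drop = FALSE] * nrm[f2, , drop = FALSE])
    keep <- cosang >= cos(feature_angle * pi / 180)
    f1 <- f1[keep]; f2 <- f2[keep]
  }
  adj <- vector("list", nb)
  for (i in seq_along(f1)) {
    adj[[f1[i]]] <- c(adj[[f1[i]]], f2[i])
    adj[[f2[i]]] <- c(adj[[f2[i]]], f1[i])
  }

  comp <- integer(nb)
  ncomp <- 0L
  for (s in seq_len(nb)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s; comp[s] <- ncomp
    while (length(queue)) {
      f <- queue[[1]]; queue <- queue[-1]
      for (g in adj[[f]]) if (comp[g] == 0L) { comp[g] <- ncomp; queue <- c(queue, g) }
    }
  }

  v <- mesh$vertices
  out <- vector("list", ncomp)
  vols <- numeric(ncomp)
  for (ci in seq_len(ncomp)) {
    idx <- which(comp == ci)
    tri <- bfaces[idx, , drop = FALSE]
    s <- surface_mesh(v, tri)
    attr(s, "parent_tet") <- bowner[idx]
    # signed enclosed volume by the divergence theorem (outward w.r.t. solid)
    p1 <- v[tri[, 1], , drop = FALSE]; p2 <- v[tri[, 2], , drop = FALSE]
    p3 <- v[tri[, 3], , drop = FALSE]
    vol <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
               p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
               p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
    attr(s, "enclosed_volume") <- vol
    attr(s, "rim_loops") <- boundary_loops(s)
    vols[ci] <- sum(triangle_geometry(s)$areas)
    out[[ci]] <- s
  }
  out[order(vols, decreasing = TRUE)]
}

#' Open-boundary loops of a surface mesh
#'
#' Edges used by exactly one triangle are rim edges; they are traced into
#' closed vertex cycles (e.g. the PV and MV openings of an atrial shell).
#'
#' @param surface a [surface_mesh()]
#' @return list of integer vertex cycles (first vertex not repeated at end);
#'   empty list for a closed surface
#' @export
boundary_loops <- function(surface) {
  tri <- surface$triangles
  nv <- nrow(surface$vertices)
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  k <- edge_key(e[, 1], e[, 2], nv)
  cnt <- table(k)
  rim <- e[k %in% as.numeric(names(cnt)[cnt == 1L]), , drop = FALSE]
  if (nrow(rim) == 0L) return(list())
  # neighbor map along rim edges (each rim vertex has exactly 2 rim edges on
  # a manifold rim); trace loops by walking away from the previous vertex
  nbr <- rep(list(integer()), nv)
  for (i in seq_len(nrow(rim))) {
    a <- rim[i, 1]; b <- rim[i, 2]
    nbr[[a]] <- c(nbr[[a]], b); nbr[[b]] <- c(nbr[[b]], a)
  }
  visited <- logical(nv)
  loops <- list()
  for (s in sort(unique(as.vector(rim)))) {
    if (visited[s]) next
    loop <- integer(); cur <- s; prev <- 0L
    repeat {
      loop <- c(loop, cur)
      visited[cur] <- TRUE
      cand <- nbr[[cur]]
      cand <- cand[cand != prev]
      nx <- if (length(cand)) cand[1] else NA_integer_
      if (is.na(nx) || nx == s) break
      prev <- cur; cur <- nx
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Element adjacency lists
#'
#' Face-adjacency for tetrahedra, edge-adjacency for triangles.  Symmetric and
#' irreflexive; each tet has at most 4 neighbors, each triangle at most 3.
#'
#' @param mesh a [surface_mesh()] or [tet_mesh()]
#' @return list of integer neighbor vectors, one per element
#' @export
element_adjacency <- function(mesh) {
  ele <- mesh_elements(mesh)
  nv <- nrow(mesh$vertices)
  ne <- nrow(ele)
  if (inherits(mesh, "tet_mesh")) {
    faces <- tet_faces_outward(ele)
    keys <- face_key(faces[, 1], faces[, 2], faces[, 3], nv)
    owner <- rep(seq_len(ne), 4L)
  } else {
    e <- rbind(ele[, 1:2], ele[, 2:3], ele[, c(3, 1)])
    keys <- edge_key(e[, 1], e[, 2], nv)
    owner <- rep(seq_len(ne), 3L)
  }
  ord <- order(keys)
  sk <- keys[ord]; so <- owner[ord]
  runs <- rle(sk)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  adj <- vector("list", ne)
  for (r in which(runs$lengths >= 2L)) {
    members <- so[starts[r]:ends[r]]
    for (a in members) adj[[a]] <- c(adj[[a]], members[members != a])
  }
  lapply(adj, function(x) sort(unique(x)))
}

#' Vertex adjacency (edge graph) of a surface mesh
#' @param surface a [surface_mesh()]
#' @return list of sorted neighbor vertex indices per vertex
#' @export
vertex_adjacency <- function(surface) {
  tri <- surface$triangles
  nv <- nrow(surface$vertices)
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  adj <- split(e[, 2], e[, 1])
  out <- rep(list(integer()), nv)
  out[as.integer(names(adj))] <- lapply(adj, function(x) sort(unique(x)))
  out
}
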