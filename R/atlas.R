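# Landmark handling, auxiliary-line construction (Dijkstra on corridors) and
# surface partition into atlas regions with per-region Laplace boundary
# assignments.  The atlas file format is documented JSON (see read_atlas).

#' Landmark set on a surface
#'
#' Named points snapped to surface vertices, with provenance
#' (transferred from an atlas, derived by a rule, or manual).
#'
#' @param names character vector of unique landmark names
#' @param vertices vertex indices on the surface
#' @param surface the [surface_mesh()] the landmarks live on
#' @param provenance character vector (recycled):
#'   `"transferred"`, `"derived"` or `"manual"`
#' @return data.frame of class `landmark_set` with columns name, vertex,
#'   x, y, z, provenance
#' @export
landmark_set <- function(names, vertices, surface, provenance = "manual") {
  names <- as.character(names); vertices <- as.integer(vertices)
  if (anyDuplicated(names)) stopf("landmark_set: duplicate landmark names")
  if (length(vertices) != length(names)) stopf("landmark_set: length mismatch")
  if (length(vertices) && (min(vertices) < 1L || max(vertices) > nrow(surface$vertices)))
    stopf("landmark_set: vertex index out of range")
  xyz <- surface$vertices[vertices, , drop = FALSE]
  out <- data.frame(name = names, vertex = vertices,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    provenance = rep_len(provenance, length(names)),
                    stringsAsFactors = FALSE)
  class(out) <- c("landmark_set", "data.frame")
  out
}

#' Transfer atlas landmarks to a personalized surface
#'
#' Nearest-neighbor transfer: each atlas landmark maps to the nearest vertex
#' of the registered surface (ties broken toward the lowest vertex index),
#' then to the same vertex index on the target surface, which must share the
#' registered surface's topology (registration preserves mesh topology).
#'
#' @param atlas_landmarks data.frame with columns name, x, y, z (atlas-space
#'   positions) or a `landmark_set`
#' @param registered_surface [surface_mesh()] registered to the atlas space
#' @param target_surface [surface_mesh()] with identical connectivity
#' @return a `landmark_set` on `target_surface` (provenance "transferred")
#'   with attribute `mapping_error` (mean atlas-point-to-vertex distance, mm)
#' @export
transfer_landmarks <- function(atlas_landmarks, registered_surface,
                               target_surface) {
  if (nrow(registered_surface$vertices) != nrow(target_surface$vertices) ||
      !identical(dim(registered_surface$triangles), dim(target_surface$triangles)) ||
      !identical(registered_surface$triangles, target_surface$triangles))
    stopf("transfer_landmarks: registered and target surfaces do not share topology")
  pts <- as.matrix(atlas_landmarks[, c("x", "y", "z")])
  vid <- .nn_index(pts, registered_surface$vertices)
  derr <- sqrt(rowSums((pts - registered_surface$vertices[vid, , drop = FALSE])^2))
  out <- landmark_set(atlas_landmarks$name, vid, target_surface, "transferred")
  attr(out, "mapping_error") <- mean(derr)
  out
}

#' Derive additional landmarks from transferred ones
#'
#' Supported rules:
#' \describe{
#'   \item{rim_equal_arcs}{`list(type = "rim_equal_arcs", a =, b =, n_arcs =,
#'     prefix =)` — on the rim loop containing landmarks `a` and `b`, split
#'     each of the two arcs between them into `n_arcs` equal-length arcs and
#'     place the `n_arcs - 1` interior division points per side.}
#'   \item{geodesic_midpoint}{`list(type = "geodesic_midpoint", a =, b =,
#'     name =)` — vertex nearest to half the Dijkstra geodesic length
#'     between `a` and `b`.}
#' }
#' Every derived point is snapped to a surface vertex.
#'
#' @param landmarks a `landmark_set`
#' @param surface the [surface_mesh()]
#' @param rules list of rule lists (see Details)
#' @return combined `landmark_set` (input plus derived; unique names)
#' @export
derive_landmarks <- function(landmarks, surface, rules) {
  lk <- function(nm) {
    i <- match(nm, landmarks$name)
    if (is.na(i)) stopf("derive_landmarks: unknown landmark '%s'", nm)
    landmarks$vertex[i]
  }
  new_names <- character(); new_verts <- integer()
  add <- function(nm, vv) {
    new_names <<- c(new_names, nm); new_verts <<- c(new_verts, vv)
  }
  loops <- boundary_loops(surface)
  for (rule in rules) {
    if (rule$type == "rim_equal_arcs") {
      va <- lk(rule$a); vb <- lk(rule$b)
      li <- which(vapply(loops, function(l) va %in% l && vb %in% l, TRUE))
      if (!length(li))
        stopf("derive_landmarks: no rim loop contains both '%s' and '%s'", rule$a, rule$b)
      loop <- loops[[li[1]]]
      n <- length(loop)
      ia <- match(va, loop); ib <- match(vb, loop)
      # two arcs a->b walking forward and backward around the loop
      fwd <- if (ia <= ib) loop[ia:ib] else c(loop[ia:n], loop[1:ib])
      bwd <- if (ia <= ib) c(loop[ia:1], loop[n:ib]) else loop[ia:ib]
      k <- rule$n_arcs %||% 2L
      cnt <- 0L
      for (arc in list(fwd, bwd)) {
        pts <- surface$vertices[arc, , drop = FALSE]
        seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
        cum <- c(0, cumsum(seg))
        for (j in seq_len(k - 1L)) {
          target <- cum[length(cum)] * j / k
          cnt <- cnt + 1L
          add(sprintf("%s_%d", rule$prefix %||% "derived", cnt),
              arc[which.min(abs(cum - target))])
        }
      }
    } else if (rule$type == "geodesic_midpoint") {
      va <- lk(rule$a); vb <- lk(rule$b)
      if (va == vb) { add(rule$name, va); next }
      path <- dijkstra_path(surface, va, vb)
      pts <- surface$vertices[path, , drop = FALSE]
      seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
      cum <- c(0, cumsum(seg))
      add(rule$name, path[which.min(abs(cum - cum[length(cum)] / 2))])
    } else stopf("derive_landmarks: unknown rule type '%s'", rule$type)
  }
  derived <- landmark_set(new_names, new_verts, surface, "derived")
  combined <- rbind(as.data.frame(landmarks), as.data.frame(derived))
  if (anyDuplicated(combined$name)) stopf("derive_landmarks: name collision")
  class(combined) <- c("landmark_set", "data.frame")
  combined
}

# Deterministic Dijkstra with Euclidean edge weights on (a subset of) the
# surface edge graph.  Ties broken by lexicographic predecessor: when two
# tentative distances are equal (1e-12 relative), the lower predecessor
# index wins.
dijkstra_path <- function(surface, from, to, vertex_subset = NULL) {
  nv <- nrow(surface$vertices)
  adj <- vertex_adjacency(surface)
  allowed <- if (is.null(vertex_subset)) rep(TRUE, nv) else {
    a <- rep(FALSE, nv); a[vertex_subset] <- TRUE; a
  }
  if (!allowed[from] || !allowed[to])
    stopf("dijkstra_path: endpoint outside the corridor")
  dist <- rep(Inf, nv); pred <- rep(NA_integer_, nv); done <- rep(FALSE, nv)
  dist[from] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    if (u == to) break
    done[u] <- TRUE
    for (v in adj[[u]]) {
      if (!allowed[v] || done[v]) next
      w <- sqrt(sum((surface$vertices[u, ] - surface$vertices[v, ])^2))
      nd <- dist[u] + w
      tol <- 1e-12 * max(nd, 1)
      if (nd < dist[v] - tol ||
          (abs(nd - dist[v]) <= tol && (is.na(pred[v]) || u < pred[v]))) {
        dist[v] <- nd; pred[v] <- u
      }
    }
  }
  if (!is.finite(dist[to]))
    stopf("dijkstra_path: no path from %d to %d within the corridor", from, to)
  path <- to
  while (path[1] != from) path <- c(pred[path[1]], path)
  attr(path, "length") <- dist[to]
  path
}

#' Auxiliary line between two landmarks within a corridor
#'
#' Shortest Euclidean-weighted path from `a` to `b` restricted to the vertex
#' set of the corridor triangles (the preselected geodesic corridor),
#' deterministic under a lexicographic-predecessor tie-break.
#'
#' @param surface a [surface_mesh()]
#' @param a,b vertex indices of the endpoints
#' @param corridor triangle indices forming the corridor (`NULL` = whole
#'   surface)
#' @return integer vertex path with attribute `length` (mm)
#' @export
auxiliary_line <- function(surface, a, b, corridor = NULL) {
  vs <- if (is.null(corridor)) NULL
        else sort(unique(as.vector(surface$triangles[corridor, , drop = FALSE])))
  if (a == b) {
    out <- a; attr(out, "length") <- 0
    return(out)
  }
  dijkstra_path(surface, a, b, vs)
}

#' Region atlas
#'
#' Auxiliary lines (named vertex paths), a region partition of the surface
#' triangles, and per-region Laplace boundary assignments: lines in
#' `gamma0` carry u = 0, lines in `gamma1` carry u = 1, every other region
#' boundary is zero-flux.  `orthogonal = TRUE` rotates the resulting fiber
#' axis by 90 degrees in the triangle plane (rim-encircling patterns).
#'
#' @param lines named list of integer vertex paths
#' @param labels integer region label per surface triangle (1..n_regions)
#' @param region_names character vector naming each label
#' @param bc named list per region: `list(gamma0 =, gamma1 =, orthogonal =)`
#'   with line names
#' @return object of class `region_atlas`
#' @export
region_atlas <- function(lines, labels, region_names, bc) {
  if (is.null(names(lines)) || anyDuplicated(names(lines)))
    stopf("region_atlas: lines must be uniquely named")
  labels <- as.integer(labels)
  nr <- length(region_names)
  if (length(bc) != nr) stopf("region_atlas: bc must have one entry per region")
  if (any(is.na(labels)) || (length(labels) && (min(labels) < 1L || max(labels) > nr)))
    stopf("region_atlas: labels outside 1..%d", nr)
  for (rn in region_names) {
    b <- bc[[rn]]
    if (is.null(b) || !length(b$gamma0) || !length(b$gamma1))
      stopf("region_atlas: region '%s' needs nonempty gamma0 and gamma1", rn)
    if (length(intersect(b$gamma0, b$gamma1)))
      stopf("region_atlas: region '%s' gamma0/gamma1 overlap", rn)
    if (!all(c(b$gamma0, b$gamma1) %in% names(lines)))
      stopf("region_atlas: region '%s' references unknown lines", rn)
  }
  structure(list(lines = lines, labels = labels,
                 region_names = as.character(region_names), bc = bc),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("region_atlas: %d regions, %d lines, %d triangles\n",
              length(x$region_names), length(x$lines), length(x$labels)))
  invisible(x)
}

#' Partition a surface into regions by seeded growing
#'
#' Flood fill over triangle edge-adjacency that never crosses an edge lying
#' on an auxiliary line; every triangle must end up in exactly one region and
#' the number of regions equals the number of seeds.
#'
#' @param surface a [surface_mesh()]
#' @param lines named list of vertex paths (sealing curves)
#' @param seeds named integer vector: one seed triangle per intended region
#' @return integer labels (1..length(seeds)) per triangle, with region names
#'   as attribute `region_names`
#' @export
partition_regions <- function(surface, lines, seeds) {
  ntri <- nrow(surface$triangles)
  nv <- nrow(surface$vertices)
  edge_key <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    as.numeric(lo) * (nv + 1) + hi
  }
  blocked <- new.env(hash = TRUE)
  for (ln in lines) {
    if (length(ln) < 2L) next
    ek <- edge_key(ln[-length(ln)], ln[-1])
    for (k in as.character(ek)) assign(k, TRUE, envir = blocked)
  }
  adj <- element_adjacency(surface)
  tri <- surface$triangles
  shared_edge_key <- function(t1, t2) {
    common <- intersect(tri[t1, ], tri[t2, ])
    edge_key(common[1], common[2])
  }
  labels <- integer(ntri)
  for (ri in seq_along(seeds)) {
    s <- seeds[[ri]]
    if (labels[s] != 0L)
      stopf("partition_regions: seed '%s' falls in an already-filled region (unsealed line?)",
            names(seeds)[ri])
    labels[s] <- ri
    queue <- s
    while (length(queue)) {
      t1 <- queue[[1]]; queue <- queue[-1]
      for (t2 in adj[[t1]]) {
        if (!is.null(get0(as.character(shared_edge_key(t1, t2)), envir = blocked)))
          next
        if (labels[t2] == 0L) { labels[t2] <- ri; queue <- c(queue, t2) }
        else if (labels[t2] != ri)
          stopf("partition_regions: regions '%s' and '%s' leak into each other (unsealed line)",
                names(seeds)[labels[t2]], names(seeds)[ri])
      }
    }
  }
  if (any(labels == 0L))
    stopf("partition_regions: %d triangles unreached by any seed", sum(labels == 0L))
  attr(labels, "region_names") <- names(seeds)
  labels
}

#' Write a region atlas (plus landmarks) to JSON
#'
#' Schema: `landmarks` (name, vertex, xyz), `lines` (name -> vertex path),
#' `regions` (name, seed triangle, gamma0/gamma1 line names, orthogonal
#' flag), `labels` (per-triangle region index).
#'
#' @param atlas a [region_atlas()]
#' @param path output path
#' @param landmarks optional `landmark_set`
#' @param seeds optional named seed-triangle vector
#' @return `path`, invisibly
#' @export
write_atlas <- function(atlas, path, landmarks = NULL, seeds = NULL) {
  regions <- lapply(atlas$region_names, function(rn) {
    b <- atlas$bc[[rn]]
    list(name = rn, gamma0 = I(b$gamma0), gamma1 = I(b$gamma1),
         orthogonal = isTRUE(b$orthogonal),
         seed = if (!is.null(seeds)) seeds[[rn]] else NULL)
  })
  obj <- list(lines = lapply(atlas$lines, as.integer),
              regions = regions,
              labels = as.integer(atlas$labels))
  if (!is.null(landmarks))
    obj$landmarks <- as.data.frame(landmarks)[, c("name", "vertex", "x", "y", "z")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region atlas from JSON
#' @param path atlas JSON file (see [write_atlas()])
#' @return list with `atlas` ([region_atlas()]), `seeds`, `landmarks`
#'   (data.frame or NULL)
#' @export
read_atlas <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lines <- lapply(obj$lines, as.integer)
  rn <- obj$regions$name
  bc <- setNames(lapply(seq_along(rn), function(i) {
    list(gamma0 = unlist(obj$regions$gamma0[i]),
         gamma1 = unlist(obj$regions$gamma1[i]),
         orthogonal = isTRUE(obj$regions$orthogonal[i]))
  }), rn)
  seeds <- if (!is.null(obj$regions$seed)) setNames(as.integer(obj$regions$seed), rn)
  atlas <- region_atlas(lines, obj$labels, rn, bc)
  list(atlas = atlas, seeds = seeds, landmarks = obj$landmarks)
}
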