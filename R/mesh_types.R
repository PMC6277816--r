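#' Triangular surface mesh
#'
#' Indexed triangle mesh in physical mm coordinates with optional per-element
#' integer tags and per-element unit fiber axes.  Fibers are line fields
#' (directionless axes) stored per triangle, evaluated at triangle centers.
#'
#' @param vertices n x 3 numeric matrix (mm)
#' @param triangles m x 3 integer matrix of 1-based vertex indices
#' @param element_tags optional integer vector, one per triangle
#' @param fibers optional m x 3 matrix of unit axes
#' @return object of class `surface_mesh`
#' @export
surface_mesh <- function(vertices, triangles, element_tags = NULL, fibers = NULL) {
  m <- structure(list(vertices = as.matrix(vertices),
                      triangles = matrix(as.integer(as.matrix(triangles)), ncol = 3),
                      element_tags = if (!is.null(element_tags)) as.integer(element_tags),
                      fibers = if (!is.null(fibers)) as.matrix(fibers)),
                 class = c("surface_mesh", "fe_mesh"))
  validate_mesh(m)
  m
}

#' Tetrahedral volume mesh
#'
#' @param vertices n x 3 numeric matrix (mm)
#' @param tets m x 4 integer matrix of 1-based vertex indices; positive signed
#'   volume under the ordering convention det(v2-v1, v3-v1, v4-v1) > 0
#' @param element_tags optional integer vector, one per tet
#' @param fibers optional m x 3 matrix of unit axes
#' @return object of class `tet_mesh`
#' @export
tet_mesh <- function(vertices, tets, element_tags = NULL, fibers = NULL) {
  m <- structure(list(vertices = as.matrix(vertices),
                      tets = matrix(as.integer(as.matrix(tets)), ncol = 4),
                      element_tags = if (!is.null(element_tags)) as.integer(element_tags),
                      fibers = if (!is.null(fibers)) as.matrix(fibers)),
                 class = c("tet_mesh", "fe_mesh"))
  validate_mesh(m)
  m
}

#' Element connectivity matrix of a mesh
#' @param mesh a `surface_mesh` or `tet_mesh`
#' @return the m x 3 or m x 4 index matrix
#' @export
mesh_elements <- function(mesh) {
  if (inherits(mesh, "surface_mesh")) mesh$triangles else mesh$tets
}

#' Number of elements in a mesh
#' @param mesh a `surface_mesh` or `tet_mesh`
#' @return integer count
#' @export
n_elements <- function(mesh) nrow(mesh_elements(mesh))

#' Validate mesh invariants
#'
#' Checks index ranges, tag/fiber lengths, unit fiber norms (1e-6) and, for
#' tetrahedra, strictly positive signed volumes.
#'
#' @param mesh a `surface_mesh` or `tet_mesh`
#' @param tol fiber unit-norm tolerance
#' @return `TRUE` invisibly; errors otherwise
#' @export
validate_mesh <- function(mesh, tol = 1e-6) {
  ele <- mesh_elements(mesh)
  nv <- nrow(mesh$vertices)
  if (ncol(mesh$vertices) != 3L) stopf("mesh vertices must be n x 3")
  if (nrow(ele) > 0 && (min(ele) < 1L || max(ele) > nv))
    stopf("mesh element indices out of range [1, %d]", nv)
  for (fld in c("element_tags", "fibers")) {
    if (!is.null(mesh[[fld]]) && NROW(mesh[[fld]]) != nrow(ele))
      stopf("mesh %s length %d != element count %d", fld, NROW(mesh[[fld]]), nrow(ele))
  }
  if (!is.null(mesh$fibers)) {
    bad <- abs(sqrt(rowSums(mesh$fibers^2)) - 1) > tol
    if (any(bad)) stopf("%d fibers are not unit norm (tol %g)", sum(bad), tol)
  }
  if (inherits(mesh, "tet_mesh") && nrow(ele) > 0) {
    vol <- tet_volumes(mesh)
    if (any(vol <= 0)) stopf("%d tetrahedra have non-positive signed volume", sum(vol <= 0))
  }
  invisible(TRUE)
}

#' Signed volumes of all tetrahedra
#' @param mesh a `tet_mesh`
#' @return numeric vector (mm^3)
#' @export
tet_volumes <- function(mesh) {
  v <- mesh$vertices; t <- mesh$tets
  a <- v[t[, 2], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  b <- v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  d <- v[t[, 4], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Triangle areas and (unit) normals
#' @param mesh a `surface_mesh`
#' @return list with `areas` (mm^2) and `normals` (m x 3 unit rows)
#' @export
triangle_geometry <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  e1 <- v[t[, 2], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  e2 <- v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  cr <- cross_rows(e1, e2)
  a2 <- sqrt(rowSums(cr^2))
  list(areas = a2 / 2, normals = normalize_rows(cr))
}

#' Element barycenters
#' @param mesh a `surface_mesh` or `tet_mesh`
#' @return m x 3 matrix of element centers (mm)
#' @export
element_centers <- function(mesh) {
  ele <- mesh_elements(mesh); v <- mesh$vertices
  out <- matrix(0, nrow(ele), 3)
  for (k in seq_len(ncol(ele))) out <- out + v[ele[, k], , drop = FALSE]
  out / ncol(ele)
}

#' @export
print.fe_mesh <- function(x, ...) {
  kind <- if (inherits(x, "tet_mesh")) "tet_mesh" else "surface_mesh"
  cat(sprintf("%s: %d vertices, %d elements%s%s\n", kind, nrow(x$vertices),
              n_elements(x),
              if (!is.null(x$element_tags)) sprintf(", %d tag(s)", length(unique(x$element_tags))) else "",
              if (!is.null(x$fibers)) ", fibers" else ""))
  invisible(x)
}
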