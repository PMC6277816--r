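# Piecewise-linear (P1) Galerkin Laplace solver on triangle and tetrahedral
# meshes with mixed Dirichlet / natural (zero-flux) boundary conditions, and
# exact per-element gradients.  Surface triangles use intrinsic tangent-plane
# gradients (3-D vectors in the triangle plane), so no global parametrization
# is ever needed.

# Per-element P1 basis gradients.
# Triangles: grad(lambda_i) = n_hat x (opposite edge) / (2A), a 3-D vector in
# the triangle plane.  Tets: gradients from the inverse Jacobian.
# Returns list(grads = ne x nn x 3 array, measure = areas or volumes).
p1_basis_gradients <- function(mesh) {
  v <- mesh$vertices
  if (inherits(mesh, "surface_mesh")) {
    t <- mesh$triangles
    p1 <- v[t[, 1], , drop = FALSE]; p2 <- v[t[, 2], , drop = FALSE]
    p3 <- v[t[, 3], , drop = FALSE]
    nrm <- cross_rows(p2 - p1, p3 - p1)
    a2 <- sqrt(rowSums(nrm^2))              # 2*area
    if (any(a2 <= 1e-14))
      stopf("degenerate triangle(s): %s",
            paste(head(which(a2 <= 1e-14)), collapse = ","))
    nhat <- nrm / a2
    g <- array(0, c(nrow(t), 3, 3))
    g[, 1, ] <- cross_rows(nhat, p3 - p2) / a2
    g[, 2, ] <- cross_rows(nhat, p1 - p3) / a2
    g[, 3, ] <- cross_rows(nhat, p2 - p1) / a2
    list(grads = g, measure = a2 / 2)
  } else {
    t <- mesh$tets
    vol <- tet_volumes(mesh)
    if (any(vol <= 1e-16))
      stopf("degenerate tetrahedron(s): %s",
            paste(head(which(vol <= 1e-16)), collapse = ","))
    p1 <- v[t[, 1], , drop = FALSE]; p2 <- v[t[, 2], , drop = FALSE]
    p3 <- v[t[, 3], , drop = FALSE]; p4 <- v[t[, 4], , drop = FALSE]
    g <- array(0, c(nrow(t), 4, 3))
    # grad(lambda_i) = (opposite face normal scaled) / (6V), inward
    g[, 1, ] <- cross_rows(p4 - p2, p3 - p2) / (6 * vol)
    g[, 2, ] <- cross_rows(p3 - p1, p4 - p1) / (6 * vol)
    g[, 3, ] <- cross_rows(p4 - p1, p2 - p1) / (6 * vol)
    g[, 4, ] <- cross_rows(p2 - p1, p3 - p1) / (6 * vol)
    list(grads = g, measure = vol)
  }
}

#' Assemble the P1 stiffness matrix
#'
#' Standard Galerkin stiffness \eqn{K_{ij} = \int \nabla\phi_i\cdot\nabla\phi_j}
#' (cotangent weights on triangles, gradient-product form on tetrahedra).
#' Symmetric with zero row sums (constants are in the nullspace).
#'
#' @param mesh a [surface_mesh()] or [tet_mesh()]
#' @return sparse symmetric `dgCMatrix` (n_vertices x n_vertices)
#' @export
assemble_stiffness <- function(mesh) {
  bg <- p1_basis_gradients(mesh)
  ele <- mesh_elements(mesh)
  nn <- ncol(ele); ne <- nrow(ele); nv <- nrow(mesh$vertices)
  ii <- jj <- xx <- vector("list", nn * nn)
  k <- 0L
  for (a in seq_len(nn)) for (b in seq_len(nn)) {
    k <- k + 1L
    ii[[k]] <- ele[, a]; jj[[k]] <- ele[, b]
    xx[[k]] <- bg$measure * rowSums(bg$grads[, a, , drop = FALSE] *
                                    bg$grads[, b, , drop = FALSE])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nv, nv))
}

#' Lumped P1 mass matrix (diagonal)
#' @param mesh a [surface_mesh()] or [tet_mesh()]
#' @return numeric vector of lumped vertex masses (row sums of the consistent
#'   mass matrix: element measure split equally over its vertices)
#' @export
lumped_mass <- function(mesh) {
  ele <- mesh_elements(mesh)
  measure <- if (inherits(mesh, "tet_mesh")) tet_volumes(mesh)
             else triangle_geometry(mesh)$areas
  nn <- ncol(ele)
  m <- numeric(nrow(mesh$vertices))
  for (a in seq_len(nn)) {
    acc <- tapply(measure / nn, ele[, a], sum)
    idx <- as.integer(names(acc))
    m[idx] <- m[idx] + as.numeric(acc)
  }
  m
}

#' Boundary-condition specification for a Laplace solve
#'
#' @param dirichlet0 vertex indices held at u = 0
#' @param dirichlet1 vertex indices held at u = 1
#' @return object of class `laplace_bc`; all other boundary is natural
#'   (zero-flux)
#' @export
laplace_bc <- function(dirichlet0, dirichlet1) {
  dirichlet0 <- sort(unique(as.integer(dirichlet0)))
  dirichlet1 <- sort(unique(as.integer(dirichlet1)))
  if (length(dirichlet0) == 0L || length(dirichlet1) == 0L)
    stopf("laplace_bc: both Dirichlet sets must be nonempty")
  if (length(intersect(dirichlet0, dirichlet1)))
    stopf("laplace_bc: Dirichlet sets overlap")
  structure(list(dirichlet0 = dirichlet0, dirichlet1 = dirichlet1),
            class = "laplace_bc")
}

#' Solve Laplace's equation with mixed boundary conditions
#'
#' Solves the discrete harmonic problem \eqn{\nabla^2 u = 0} with
#' \eqn{u = 0} on the first Dirichlet set, \eqn{u = 1} on the second, and
#' natural zero-flux conditions on all remaining boundary, by sparse direct
#' factorization of the reduced symmetric positive-definite system.
#'
#' @param mesh a [surface_mesh()] or [tet_mesh()]
#' @param bc a [laplace_bc()]
#' @param K optional pre-assembled stiffness (from [assemble_stiffness()])
#' @return numeric vertex field `u` with attribute `residual` (relative
#'   residual of the reduced system)
#' @export
solve_laplace <- function(mesh, bc, K = NULL) {
  stopifnot(inherits(bc, "laplace_bc"))
  nv <- nrow(mesh$vertices)
  if (max(bc$dirichlet0, bc$dirichlet1) > nv)
    stopf("solve_laplace: Dirichlet vertex index out of range")
  if (is.null(K)) K <- assemble_stiffness(mesh)
  u <- numeric(nv)
  u[bc$dirichlet1] <- 1
  fixed <- c(bc$dirichlet0, bc$dirichlet1)
  # vertices referenced by no element (zero stiffness diagonal) are excluded
  # from the solve and left at 0
  isolated <- which(Matrix::diag(K) == 0)
  free <- setdiff(seq_len(nv), c(fixed, isolated))
  if (length(free)) {
    Kff <- K[free, free, drop = FALSE]
    rhs <- -(K[free, fixed, drop = FALSE] %*% u[fixed])
    sol <- tryCatch(Matrix::solve(Kff, rhs),
                    error = function(e)
                      stopf("solve_laplace: singular reduced system (mesh component without Dirichlet vertices?): %s",
                            conditionMessage(e)))
    u[free] <- as.numeric(sol)
    res <- as.numeric(sqrt(sum((Kff %*% u[free] - rhs)^2)))
    den <- max(sqrt(sum(rhs^2)), 1e-300)
    attr(u, "residual") <- res / den
  } else attr(u, "residual") <- 0
  u
}

#' Per-element gradient of a P1 vertex field
#'
#' Exact (constant-per-element) gradient; for surface triangles the gradient
#' is a 3-D vector lying in the triangle plane.
#'
#' @param mesh a [surface_mesh()] or [tet_mesh()]
#' @param u numeric vertex field
#' @return ne x 3 matrix of gradients
#' @export
element_gradient <- function(mesh, u) {
  if (length(u) != nrow(mesh$vertices))
    stopf("element_gradient: field length != vertex count")
  bg <- p1_basis_gradients(mesh)
  ele <- mesh_elements(mesh)
  g <- matrix(0, nrow(ele), 3)
  for (a in seq_len(ncol(ele)))
    g <- g + u[ele[, a]] * matrix(bg$grads[, a, ], ncol = 3)
  g
}
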