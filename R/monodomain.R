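# Monodomain electrophysiology on fibered meshes:
#   beta_m C_m dV/dt + beta_m I_ion(V, eta) = div(sigma_m grad V) + I_tr
# solved by operator splitting (per-node CRN reaction, implicit lumped-mass
# P1 diffusion), with local activation times (LAT) at the -20 mV upward
# crossing, conduction-velocity measurement and iterative conductivity
# fitting on a 1-D cable.

#' Monodomain tissue model parameters
#'
#' @param sigma_l,sigma_t longitudinal / transverse monodomain conductivities
#'   (S/cm); `sigma_l >= sigma_t > 0`
#' @param beta_m membrane surface-to-volume ratio (1/cm), default 1400
#' @param C_m membrane capacitance per area (uF/cm^2), default 1
#' @param dt global time step (ms), default 0.01 (10 us)
#' @param lat_threshold LAT voltage threshold (mV), default -20
#' @return object of class `monodomain_model`
#' @export
monodomain_model <- function(sigma_l, sigma_t = sigma_l, beta_m = 1400,
                             C_m = 1, dt = 0.01, lat_threshold = -20) {
  if (!(sigma_l >= sigma_t && sigma_t > 0))
    stopf("monodomain_model: need sigma_l >= sigma_t > 0")
  if (dt <= 0) stopf("monodomain_model: dt must be positive")
  structure(list(sigma_l = sigma_l, sigma_t = sigma_t, beta_m = beta_m,
                 C_m = C_m, dt = dt, lat_threshold = lat_threshold),
            class = "monodomain_model")
}

#' Monodomain diffusivity from conductivity
#'
#' D = sigma / (beta_m C_m), converted to mm^2/ms from sigma in S/cm,
#' beta_m in 1/cm and C_m in uF/cm^2.
#'
#' @param sigma conductivity (S/cm)
#' @param beta_m surface-to-volume ratio (1/cm)
#' @param C_m membrane capacitance (uF/cm^2)
#' @return diffusivity (mm^2/ms)
#' @export
conductivity_to_diffusivity <- function(sigma, beta_m = 1400, C_m = 1) {
  1e5 * sigma / (beta_m * C_m)
}

# Anisotropic P1 stiffness with per-element diffusion tensor
# D_e = D_t I + (D_l - D_t) f f^T built from the element fiber axis.
assemble_diffusion <- function(mesh, D_l, D_t, fibers = mesh$fibers) {
  ne <- n_elements(mesh)
  if (is.null(fibers)) {
    if (D_l != D_t) stopf("assemble_diffusion: anisotropy requires fibers")
    fibers <- matrix(rep(c(1, 0, 0), each = ne), ne, 3)
  }
  bg <- p1_basis_gradients(mesh)
  ele <- mesh_elements(mesh)
  nn <- ncol(ele); nv <- nrow(mesh$vertices)
  # D grad_b = D_t grad_b + (D_l - D_t) f (f . grad_b)
  Dg <- vector("list", nn)
  for (b in seq_len(nn)) {
    gb <- matrix(bg$grads[, b, ], ncol = 3)
    fg <- rowSums(fibers * gb)
    Dg[[b]] <- D_t * gb + (D_l - D_t) * fibers * fg
  }
  ii <- jj <- xx <- vector("list", nn * nn)
  k <- 0L
  for (a in seq_len(nn)) {
    ga <- matrix(bg$grads[, a, ], ncol = 3)
    for (b in seq_len(nn)) {
      k <- k + 1L
      ii[[k]] <- ele[, a]; jj[[k]] <- ele[, b]
      xx[[k]] <- bg$measure * rowSums(ga * Dg[[b]])
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nv, nv))
}

#' Simulate monodomain propagation on a fibered mesh
#'
#' Operator-splitting integration at the global time step: a per-node CRN
#' reaction step (Rush-Larsen) followed by an implicit (backward Euler)
#' lumped-mass P1 diffusion step with the anisotropic conductivity tensor
#' built from the element fiber axes.  Zero-flux (natural) boundary
#' conditions everywhere.  LAT is recorded at the first upward crossing of
#' the threshold with linear interpolation in time.
#'
#' @param mesh a [surface_mesh()] or [tet_mesh()] with unit fibers (or no
#'   fibers for isotropic sigma)
#' @param model a [monodomain_model()]
#' @param t_end simulation end time (ms)
#' @param init_state initial CRN state applied to every node (e.g. from
#'   [pace_to_steady_state()])
#' @param stim_vertices vertex indices receiving the transmembrane stimulus
#' @param stim_rate stimulus amplitude (pA/pF = mV/ms), default 50
#' @param stim_start,stim_dur stimulus onset and duration (ms)
#' @param probes vertex indices whose V trace is recorded
#' @param record_dt trace sampling interval (ms)
#' @return list with `lat` (per-vertex, NaN where never activated), `t`,
#'   `traces` (matrix, one column per probe), `V` (final voltages),
#'   `states` (final n x 21 state matrix)
#' @export
simulate_monodomain <- function(mesh, model, t_end, init_state,
                                stim_vertices = integer(), stim_rate = 50,
                                stim_start = 0, stim_dur = 2,
                                probes = integer(), record_dt = 0.5) {
  stopifnot(inherits(model, "monodomain_model"))
  nv <- nrow(mesh$vertices)
  D_l <- conductivity_to_diffusivity(model$sigma_l, model$beta_m, model$C_m)
  D_t <- conductivity_to_diffusivity(model$sigma_t, model$beta_m, model$C_m)
  K <- assemble_diffusion(mesh, D_l, D_t)
  M <- lumped_mass(mesh)
  A <- Matrix::Diagonal(x = M) + model$dt * K
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)

  states <- matrix(rep(as.numeric(init_state), each = nv), nv, 21)
  stim_vec0 <- numeric(nv)
  lat <- rep(NA_real_, nv)
  nsteps <- round(t_end / model$dt)
  rec_every <- max(1L, round(record_dt / model$dt))
  tv <- numeric(0)
  traces <- if (length(probes)) matrix(numeric(), 0, length(probes)) else NULL
  trace_rows <- list()

  for (k in seq_len(nsteps) - 1L) {
    t <- k * model$dt
    if (k %% rec_every == 0L) {
      tv <- c(tv, t)
      if (length(probes))
        trace_rows[[length(trace_rows) + 1L]] <- states[probes, 1]
    }
    Vold <- states[, 1]
    stim <- stim_vec0
    if (t >= stim_start && t < stim_start + stim_dur && length(stim_vertices))
      stim[stim_vertices] <- stim_rate
    states <- .crn_react_step(states, model$dt, stim)
    b <- M * states[, 1]
    states[, 1] <- as.numeric(Matrix::solve(fac, b, system = "A"))
    Vnew <- states[, 1]
    hit <- is.na(lat) & Vold < model$lat_threshold & Vnew >= model$lat_threshold
    if (any(hit))
      lat[hit] <- t + model$dt * (model$lat_threshold - Vold[hit]) / (Vnew[hit] - Vold[hit])
  }
  if (length(probes)) traces <- do.call(rbind, trace_rows)
  list(lat = lat, t = tv, traces = traces, V = states[, 1], states = states)
}

#' Measure conduction velocity on a 1-D cable
#'
#' Runs a planar-wave cable simulation (stimulus at one end) and measures
#' CV between the 25% and 75% cable positions from the LAT map.
#'
#' @param sigma monodomain conductivity along the cable (S/cm)
#' @param init_state CRN state for every node (paced limit-cycle state)
#' @param length_mm cable length (mm), default 20 (2 cm)
#' @param dx node spacing (mm), default 0.2 (200 um)
#' @param dt time step (ms), default 0.01 (10 us)
#' @param beta_m,C_m tissue constants, see [monodomain_model()]
#' @param t_end simulation duration (ms); default sized for CV >= 0.2 m/s
#' @param reverse stimulate the far end instead (symmetry checks)
#' @return CV in m/s, with attributes `lat` and `x` (node positions)
#' @export
measure_cv <- function(sigma, init_state, length_mm = 20, dx = 0.2, dt = 0.01,
                       beta_m = 1400, C_m = 1, t_end = 120, reverse = FALSE) {
  n <- round(length_mm / dx) + 1L
  D <- conductivity_to_diffusivity(sigma, beta_m, C_m)
  res <- .cable_monodomain(n, dx, D, dt, t_end, as.numeric(init_state),
                           n_stim = 3L, stim_amp = 50, stim_start = 0,
                           stim_dur = 2, lat_threshold = -20,
                           probes = integer(), record_dt = 1,
                           stim_from_end = reverse)
  lat <- res$lat
  x <- (seq_len(n) - 1) * dx
  if (reverse) lat <- rev(lat)   # re-express in propagation order
  i25 <- round(0.25 * (n - 1)) + 1L
  i75 <- round(0.75 * (n - 1)) + 1L
  if (is.na(lat[i75]) || is.na(lat[i25]))
    stopf("measure_cv: wave did not reach the probes (sigma = %g S/cm, t_end = %g ms)",
          sigma, t_end)
  cv <- (x[i75] - x[i25]) / (lat[i75] - lat[i25])  # mm/ms = m/s
  attr(cv, "lat") <- lat
  attr(cv, "x") <- x
  cv
}

#' Fit monodomain conductivities to target conduction velocities
#'
#' Iterative multiplicative update sigma <- sigma (CV_target / CV_measured)^2
#' on a 1-D cable (CV scales with sqrt(sigma) in the continuum limit), run
#' independently for the longitudinal and transverse directions, until the
#' re-measured CV is within `tol` of the target.
#'
#' @param target_cv_l,target_cv_t target CVs (m/s); the reference values are
#'   1.20 longitudinal and 0.40 transverse (anisotropy ratio 3)
#' @param init_state paced CRN state (see [pace_to_steady_state()])
#' @param resolution cable node spacing (mm), default 0.2
#' @param dt time step (ms), default 0.01
#' @param tol relative CV tolerance, default 0.005 (0.5%)
#' @param max_iter maximum iterations per direction, default 10
#' @param beta_m,C_m tissue constants
#' @return list with `sigma_l`, `sigma_t` (S/cm), `cv_l`, `cv_t` (re-measured,
#'   m/s) and `trace` (data.frame of the fitting iterations)
#' @export
fit_conductivity <- function(target_cv_l = 1.2, target_cv_t = 0.4,
                             init_state, resolution = 0.2, dt = 0.01,
                             tol = 0.005, max_iter = 10,
                             beta_m = 1400, C_m = 1) {
  stopifnot(target_cv_l > 0, target_cv_t > 0)
  fit_one <- function(target, label) {
    # start from a diffusivity scaled to the target by the sqrt law around a
    # physiological anchor (D = 0.1 mm^2/ms ~ 0.5 m/s range)
    sigma <- 1.75e-3 * (target / 1.2)^2
    rows <- list()
    for (it in seq_len(max_iter)) {
      cv <- tryCatch(
        as.numeric(measure_cv(sigma, init_state, dx = resolution, dt = dt,
                              beta_m = beta_m, C_m = C_m)),
        error = function(e) NA_real_)
      if (is.na(cv)) {
        # discrete propagation failure at low conductivity: scale up and retry
        sigma <- sigma * 3
        rows[[it]] <- data.frame(direction = label, iter = it, sigma = sigma,
                                 cv = NA_real_)
        next
      }
      rows[[it]] <- data.frame(direction = label, iter = it, sigma = sigma, cv = cv)
      if (abs(cv - target) / target < tol)
        return(list(sigma = sigma, cv = cv, trace = do.call(rbind, rows)))
      sigma <- sigma * (target / cv)^2
    }
    stopf("fit_conductivity: %s direction did not converge in %d iterations (last CV %.4f vs target %.4f)",
          label, max_iter, cv, target)
  }
  fl <- fit_one(target_cv_l, "longitudinal")
  ft <- fit_one(target_cv_t, "transverse")
  list(sigma_l = fl$sigma, sigma_t = ft$sigma, cv_l = fl$cv, cv_t = ft$cv,
       trace = rbind(fl$trace, ft$trace))
}

#' Random fiber field (isotropic reference architecture)
#'
#' Per-element axes drawn uniformly on the unit sphere (antipodal
#' identification makes the sign irrelevant); combined with the anisotropic
#' conductivity tensor this realizes the non-physiological isotropic
#' reference material.
#'
#' @param mesh a [surface_mesh()] or [tet_mesh()]
#' @param seed integer seed (reproducible)
#' @return ne x 3 matrix of unit axes
#' @export
random_fiber_field <- function(mesh, seed = 1L) {
  ne <- n_elements(mesh)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  set.seed(seed)
  z <- runif(ne, -1, 1)
  phi <- runif(ne, 0, 2 * pi)
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Vertices incident to elements with a given tag
#' @param mesh a mesh with `element_tags`
#' @param tag integer tag value
#' @return sorted unique vertex indices
#' @export
vertices_of_tag <- function(mesh, tag) {
  if (is.null(mesh$element_tags)) stopf("vertices_of_tag: mesh has no element tags")
  sort(unique(as.vector(mesh_elements(mesh)[mesh$element_tags == tag, ])))
}
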