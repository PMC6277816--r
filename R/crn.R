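# R interface to the Courtemanche-Ramirez-Nattel (CRN) human atrial cell
# model (compiled in src/).  Units: mV, ms, mM; currents in pA/pF.

#' Published resting state of the CRN atrial cell model
#'
#' Resting membrane potential of about -81 mV with the published gate and
#' concentration values; the starting point for steady-state pacing.
#'
#' @return named numeric vector of the 21 state variables (V, 15 gates,
#'   5 concentrations)
#' @export
crn_initial_state <- function() .crn_initial_state()

#' CRN right-hand side
#'
#' Full model right-hand side: the total ionic current (sum of the 12
#' membrane currents, pA/pF) and the time derivative of every state variable.
#'
#' @param state named numeric vector of 21 state variables
#' @param stim stimulus rate (pA/pF, positive depolarizes)
#' @return list with `dstate` (21 derivatives) and `Iion` (pA/pF)
#' @export
crn_rhs <- function(state, stim = 0) .crn_rhs(as.numeric(state), stim)

#' Integrate a single CRN cell
#'
#' Rush-Larsen integration (exponential gate updates, explicit voltage and
#' concentration updates) with optional periodic current-clamp stimulation.
#'
#' @param init initial state (default [crn_initial_state()])
#' @param t_end duration (ms)
#' @param dt time step (ms); default 0.01 (10 us)
#' @param bcl basic cycle length (ms); 0 disables stimulation
#' @param stim_amp stimulus amplitude (pA/pF)
#' @param stim_dur stimulus duration (ms)
#' @param record_dt sampling interval of the returned V trace (ms)
#' @return list with `state` (final), `t`, `V` (trace),
#'   `state_prev_beat` (state one cycle before the end, for convergence
#'   metrics; NA when not paced)
#' @export
crn_integrate <- function(init = crn_initial_state(), t_end = 1000, dt = 0.01,
                          bcl = 0, stim_amp = 0, stim_dur = 2,
                          record_dt = 1) {
  .crn_integrate(as.numeric(init), t_end, dt, bcl, stim_amp, stim_dur, 0,
                 record_dt)
}

#' Pace a single cell to a steady-state (limit cycle)
#'
#' Periodic stimulation at a fixed basic cycle length; the end-diastolic
#' state after the last beat is returned together with the relative change
#' per variable across the final cycle (convergence metric).  The reference
#' protocol is 1000 beats at BCL 1000 ms; tests and the conduction-velocity
#' fit use a 50-beat limit cycle.
#'
#' @param n_beats number of beats (>= 1)
#' @param bcl basic cycle length (ms)
#' @param dt time step (ms)
#' @param stim_amp stimulus amplitude (pA/pF); default 20 for 2 ms is
#'   comfortably suprathreshold
#' @param stim_dur stimulus duration (ms)
#' @return list with `state` (end-diastolic), `convergence` (max relative
#'   state change across the last beat), `V_last_beat` trace of the final
#'   cycle
#' @export
pace_to_steady_state <- function(n_beats = 1000, bcl = 1000, dt = 0.01,
                                 stim_amp = 20, stim_dur = 2) {
  stopifnot(n_beats >= 1)
  res <- .crn_integrate(as.numeric(crn_initial_state()), n_beats * bcl, dt,
                        bcl, stim_amp, stim_dur, 0, 1)
  prev <- res$state_prev_beat
  scale <- pmax(abs(res$state), 1e-8)
  conv <- if (all(is.finite(prev))) max(abs(res$state - prev) / scale) else NA_real_
  keep <- res$t >= (n_beats - 1) * bcl
  list(state = res$state, convergence = conv,
       V_last_beat = list(t = res$t[keep] - (n_beats - 1) * bcl,
                          V = res$V[keep]))
}
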