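# Single-cell ionic dynamics: the Bondarenko mouse ventricular myocyte model.
# All currents are densities in pA/pF (Cm = 1 uF/cm^2, so numerically equal
# to uA/cm^2); inward (depolarizing) currents are negative, and
#   dV/dt = -(sum(I_ion) + I_ChR2 + I_applied) / Cm,
# so a depolarizing applied stimulus has negative sign.

#' Bondarenko mouse ventricular model parameters
#'
#' Returns the parameter set (maximal conductances, pump/exchanger scalings,
#' external ion concentrations, cell geometry) of the Bondarenko mouse
#' ventricular myocyte model.  The apical parameterization is the default;
#' the septal variant differs in the transient-outward and ultrarapid K+
#' conductances.
#'
#' @param variant `"apical"` (default) or `"septal"`.
#' @param ... named overrides of individual parameters, e.g. `g_Na = 10`.
#' @return A named numeric vector of class `"cell_params"`.
#' @examples
#' p <- cell_params()
#' p["g_Na"]
#' @export
cell_params <- function(variant = c("apical", "septal"), ...) {
  variant <- match.arg(variant)
  p <- bond_param_defaults(variant)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown cell parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- as.numeric(ov)
  }
  if (p["Cm"] <= 0) stop("Cm must be positive")
  structure(p, class = "cell_params", variant = variant)
}

#' Published initial state of the cell model
#'
#' The published initial conditions of the Bondarenko model (voltage, gating
#' and concentration variables) with dark ChR2 (all channels in the first
#' closed state).  Use [paced_rest_state()] to relax this to the model's
#' quiescent fixed point.
#'
#' @return A named numeric vector of class `"cell_state"` with 45 entries:
#'   `V` followed by the 40 ionic auxiliary variables and the 4 ChR2
#'   occupancies `cC1, cO1, cO2, cC2`.
#' @export
cell_state_init <- function() {
  structure(bond_state_init(), class = "cell_state")
}

check_state <- function(state) {
  if (length(state) != 45L)
    stop("a cell state must have 45 elements (V, 40 ionic variables, 4 ChR2 occupancies)")
  if (!all(is.finite(state))) {
    bad <- names(state)[!is.finite(state)]
    if (is.null(bad)) bad <- which(!is.finite(state))
    stop("non-finite state variable(s): ", paste(bad, collapse = ", "))
  }
  invisible(state)
}

#' Ionic currents of the cell model
#'
#' Evaluates the 15 membrane currents of the Bondarenko model (and the ChR2
#' photocurrent, reported separately) at a given state.
#'
#' @param state A 45-element cell state (see [cell_state_init()]).
#' @param params Cell parameters from [cell_params()].
#' @param chr2 ChR2 parameters from [chr2_params()].
#' @return Named numeric vector of class `"current_breakdown"`: the 15 ionic
#'   currents, `I_ChR2`, and `total` (the sum of the 15 ionic currents,
#'   excluding `I_ChR2`), all in pA/pF.
#' @examples
#' cur <- ionic_currents(paced_rest_state(settle_time = 100))
#' cur["total"]   # ~0 at rest
#' @export
ionic_currents <- function(state, params = cell_params(), chr2 = chr2_params()) {
  check_state(state)
  structure(bond_currents_cpp(as.numeric(state), params, chr2),
            class = "current_breakdown")
}

#' Time derivatives of the cell state
#'
#' Right-hand side of the coupled cell + ChR2 ODE system:
#' `dV/dt = -(total ionic current + I_ChR2 + I_applied)/Cm`, with the
#' auxiliary (gating, concentration, ChR2) derivatives given by the model
#' kinetics.
#'
#' @inheritParams ionic_currents
#' @param I_applied Applied current density in pA/pF (negative = depolarizing).
#' @param Ee Irradiance in uW/mm^2 (global illumination).
#' @return Named numeric vector of the 45 time derivatives (per ms).
#' @export
cell_derivatives <- function(state, I_applied = 0, Ee = 0,
                             params = cell_params(), chr2 = chr2_params()) {
  check_state(state)
  if (Ee < 0) stop("irradiance must be non-negative")
  bond_derivs_cpp(as.numeric(state), I_applied, Ee, params, chr2)
}

#' Advance a cell state by classical RK4 steps
#'
#' Classical 4th-order Runge-Kutta integration of the coupled cell + ChR2
#' system.  With `dt = 1e-4` ms this is the reference single-cell
#' integration scheme; the stiff intracellular-Ca subsystem makes the
#' explicit RK4 scheme unstable for `dt` much above `1e-3` ms during an
#' action potential.
#'
#' @inheritParams cell_derivatives
#' @param dt Time step in ms (> 0).
#' @param n_steps Number of steps to take.
#' @return The advanced `"cell_state"`.
#' @export
step_cell_rk4 <- function(state, dt, I_applied = 0, Ee = 0, n_steps = 1L,
                          params = cell_params(), chr2 = chr2_params()) {
  check_state(state)
  if (dt <= 0) stop("dt must be positive")
  structure(cell_rk4_cpp(as.numeric(state), dt, as.integer(n_steps),
                         I_applied, Ee, params, chr2),
            class = "cell_state")
}

#' Quiescent (resting) state of the cell model
#'
#' Integrates the model from the published initial conditions with no input
#' until all derivatives are below `tol`, returning the quiescent state used
#' to initialize tissue.
#'
#' @inheritParams step_cell_rk4
#' @param settle_time Maximum settling time in ms.
#' @param tol Convergence tolerance on `|dV/dt|` in mV/ms.
#' @param dt Integration step in ms.
#' @return The settled `"cell_state"`.  If `|dV/dt|` has not dropped below
#'   `tol` within `settle_time`, a warning is raised and the best state is
#'   returned.
#' @export
paced_rest_state <- function(params = cell_params(), chr2 = chr2_params(),
                             settle_time = 1000, dt = 0.01, tol = 1e-3) {
  if (settle_time < 0) stop("settle_time must be non-negative")
  s <- as.numeric(bond_state_init())
  chunk <- 50       # ms between convergence checks
  t <- 0
  while (t < settle_time) {
    n <- as.integer(round(min(chunk, settle_time - t) / dt))
    if (n < 1L) break
    s <- cell_rk4_cpp(s, dt, n, 0, 0, params, chr2)
    t <- t + n * dt
    dv <- abs(bond_derivs_cpp(s, 0, 0, params, chr2)[1L])
    if (dv < tol) return(structure(s, class = "cell_state"))
  }
  warning(sprintf("cell did not settle below |dV/dt| = %g mV/ms within %g ms",
                  tol, settle_time))
  structure(s, class = "cell_state")
}

#' Integrate a single cell and record its trace
#'
#' Runs the coupled cell + ChR2 system with a stimulus and/or irradiance
#' schedule and records voltage and photocurrent.
#'
#' @inheritParams step_cell_rk4
#' @param duration Total duration in ms.
#' @param I_applied Either a scalar (constant) or a numeric vector with one
#'   entry per time step (pA/pF; negative = depolarizing).
#' @param Ee Either a scalar or per-step vector irradiance (uW/mm^2).
#' @param record_dt Trace sampling interval in ms.
#' @return A data frame with columns `t`, `V`, `I_applied`, `I_ChR2` plus the
#'   final state in attribute `"state"`.
#' @export
simulate_cell <- function(state, duration, dt = 1e-3, I_applied = 0, Ee = 0,
                          record_dt = 0.1,
                          params = cell_params(), chr2 = chr2_params()) {
  check_state(state)
  n <- as.integer(round(duration / dt))
  rec <- max(1L, as.integer(round(record_dt / dt)))
  if (length(I_applied) > 1L && length(I_applied) != n)
    stop("per-step I_applied must have length duration/dt = ", n)
  if (length(Ee) > 1L && length(Ee) != n)
    stop("per-step Ee must have length duration/dt = ", n)
  r <- cell_run_cpp(as.numeric(state), dt, n, I_applied, Ee, params, chr2, rec)
  out <- data.frame(t = r$t, V = r$V, I_applied = r$I_applied, I_ChR2 = r$I_ChR2)
  attr(out, "state") <- structure(r$state, class = "cell_state")
  out
}

#' @export
print.current_breakdown <- function(x, digits = 4, ...) {
  cat("Membrane currents [pA/pF]:\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state>  V = %.3f mV, Cai = %.4f uM, Nai = %.0f uM, Ki = %.0f uM\n",
              x[["V"]], x[["Cai"]], x[["Nai"]], x[["Ki"]]))
  cat(sprintf("  ChR2: C1 = %.3f, O1 = %.4f, O2 = %.4f, C2 = %.4f\n",
              x[["cC1"]], x[["cO1"]], x[["cO2"]], x[["cC2"]]))
  invisible(x)
}
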