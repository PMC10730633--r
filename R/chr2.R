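# Four-state channelrhodopsin-2 photocurrent model: two closed states
# (C1, C2) and two open states (O1, O2), light-driven activation C1->O1 and
# C2->O2, inter-open transitions e12/e21, dark recovery C2->C1 (Gr).
# The photocurrent is
#   I_ChR2 = g_ChR2 * G(V) * (O1 + gamma*O2) * (V - E_ChR2),
# with the empirical rectification G(V) = (10.6408 - 14.6408*exp(-V/42.7671))/V.
# G(V)*(V - E_ChR2) is evaluated jointly: with E_ChR2 = 0 the singularity at
# V = 0 is removable and the product equals the numerator itself
# (value -4.0 * g * (O1 + gamma*O2) at V = 0).

#' ChR2 photocurrent model parameters
#'
#' Parameters of the four-state ChR2(H134R) model at 470 nm.  The paper-level
#' constants are `gamma` (open-state conductance ratio O2/O1, 0.1) and
#' `E_ChR2` (reversal potential, 0 mV); the kinetic constants follow the
#' published four-state model: light-activation rates `k1 = kc1*Ee` and
#' `k2 = kc2*Ee` proportional to irradiance (photon flux times retinal
#' cross-section), irradiance-dependent inter-open rates
#' `e12 = e12_dark + e12_log*log(1 + Ee/Ee_ref)` (and likewise `e21`), plus
#' voltage-dependent `Gd1(V)` and recovery `Gr(V)` evaluated internally.
#' `g_ChR2` is the maximal conductance in mS/uF; its default is calibrated so
#' that 20 uW/mm^2 global illumination is sub-threshold in resting tissue
#' while measurably slowing a spiral wave.
#'
#' @param ... named overrides, e.g. `g_ChR2 = 0.5`.
#' @return Named numeric vector of class `"chr2_params"`.
#' @export
chr2_params <- function(...) {
  q <- chr2_param_defaults()
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(q))
    if (length(bad)) stop("unknown ChR2 parameter(s): ", paste(bad, collapse = ", "))
    q[names(ov)] <- as.numeric(ov)
  }
  if (q["g_ChR2"] < 0) stop("g_ChR2 must be non-negative")
  structure(q, class = "chr2_params")
}

#' Light-dependent ChR2 activation rates
#'
#' The activation rates of the two closed-to-open transitions as functions
#' of irradiance: `k1 = kc1 * Ee`, `k2 = kc2 * Ee` (1/ms).  Both vanish in
#' the dark and increase monotonically with irradiance.
#'
#' @param Ee Irradiance in uW/mm^2 (>= 0); vectorized.
#' @param params ChR2 parameters from [chr2_params()].
#' @return A matrix with columns `k1` and `k2` (one row per `Ee` value), or
#'   a named length-2 vector when `Ee` is scalar.
#' @export
chr2_rates <- function(Ee, params = chr2_params()) {
  if (any(Ee < 0)) stop("irradiance must be non-negative")
  k <- cbind(k1 = params[["kc1"]] * Ee, k2 = params[["kc2"]] * Ee)
  if (length(Ee) == 1L) k[1L, ] else k
}

chr2_check_state <- function(state) {
  if (length(state) != 4L) stop("ChR2 state must have 4 elements (C1, O1, O2, C2)")
  if (!all(is.finite(state))) stop("non-finite ChR2 occupancy")
  if (any(state < -1e-6) || any(state > 1 + 1e-6))
    stop("ChR2 occupancies must lie in [0, 1]")
  invisible(state)
}

chr2_vrates <- function(V, Ee, params) {
  list(k1 = params[["kc1"]] * Ee,
       k2 = params[["kc2"]] * Ee,
       e12 = params[["e12_dark"]] + params[["e12_log"]] * log(1 + Ee / params[["Ee_ref"]]),
       e21 = params[["e21_dark"]] + params[["e21_log"]] * log(1 + Ee / params[["Ee_ref"]]),
       Gd1 = 0.075 + 0.043 * tanh(-(V + 20) / 20),
       Gd2 = params[["Gd2"]],
       Gr = 4.34e-5 * exp(-0.0211539274 * V))
}

#' ChR2 state derivatives
#'
#' The four-state kinetics with occupancy-conserving signs (the O1 balance
#' is `dO1/dt = k1*C1 - (Gd1 + e12)*O1 + e21*O2`); the four derivatives sum
#' to zero exactly.
#'
#' @param state Numeric length-4 occupancies `c(C1, O1, O2, C2)`.
#' @param V Membrane voltage in mV.
#' @param Ee Irradiance in uW/mm^2.
#' @param params ChR2 parameters.
#' @return Named numeric length-4 derivative vector (1/ms).
#' @export
chr2_derivatives <- function(state, V, Ee = 0, params = chr2_params()) {
  chr2_check_state(state)
  r <- chr2_vrates(V, Ee, params)
  C1 <- state[[1]]; O1 <- state[[2]]; O2 <- state[[3]]; C2 <- state[[4]]
  c(C1 = r$Gr * C2 + r$Gd1 * O1 - r$k1 * C1,
    O1 = r$k1 * C1 - (r$Gd1 + r$e12) * O1 + r$e21 * O2,
    O2 = r$k2 * C2 + r$e12 * O1 - (r$Gd2 + r$e21) * O2,
    C2 = r$Gd2 * O2 - (r$k2 + r$Gr) * C2)
}

#' ChR2 photocurrent
#'
#' Evaluates `I_ChR2 = g_ChR2 G(V) (O1 + gamma O2) (V - E_ChR2)` with the
#' product `G(V) (V - E_ChR2)` computed jointly so that (for the default
#' `E_ChR2 = 0`) the removable singularity at V = 0 cancels analytically.
#' The current is negative (depolarizing) at diastolic voltages when
#' channels are open.
#'
#' @inheritParams chr2_derivatives
#' @return Photocurrent density in pA/pF.
#' @export
chr2_current <- function(state, V, params = chr2_params()) {
  chr2_check_state(state)
  gfun <- 10.6408 - 14.6408 * exp(-V / 42.7671)
  E <- params[["E_ChR2"]]
  gv <- if (E == 0) gfun else gfun * (V - E) / ifelse(abs(V) < 1e-9, 1e-9, V)
  params[["g_ChR2"]] * gv * (state[[2]] + params[["gamma"]] * state[[3]])
}

#' Steady state of the ChR2 kinetics under constant light
#'
#' Solves for the null-space eigenvector of the (linear, occupancy-
#' conserving) four-state rate matrix at fixed voltage and irradiance,
#' normalized to total occupancy 1.
#'
#' @inheritParams chr2_derivatives
#' @return Named numeric length-4 steady-state occupancies.
#' @export
chr2_steady_state <- function(V, Ee = 0, params = chr2_params()) {
  r <- chr2_vrates(V, Ee, params)
  A <- rbind(
    c(-r$k1,            r$Gd1,             0,                r$Gr),
    c( r$k1,           -(r$Gd1 + r$e12),   r$e21,            0),
    c( 0,               r$e12,            -(r$Gd2 + r$e21),  r$k2),
    c( 0,               0,                 r$Gd2,           -(r$k2 + r$Gr)))
  M <- rbind(A[1:3, ], rep(1, 4))
  x <- solve(M, c(0, 0, 0, 1))
  names(x) <- c("C1", "O1", "O2", "C2")
  x
}
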