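# Stimulation machinery: open-loop periodic global illumination, closed-loop
# resonant feedback pacing, S1-S2 cross-field spiral initiation and
# termination detection.

#' Open-loop periodic illumination train
#'
#' Globally uniform light pulses of fixed width delivered at pacing
#' frequency `fp`.
#'
#' @param fp Pacing frequency in Hz.
#' @param width Pulse duration in ms (default 33, half a spiral rotation
#'   period).
#' @param Ee_on Irradiance during a pulse in uW/mm^2 (default 20,
#'   sub-threshold).
#' @param t_start Onset of the first pulse in ms.
#' @param n_max Optional cap on the number of pulses.
#' @return An object of class `"pulse_train"`.
#' @export
pulse_train <- function(fp, width = 33, Ee_on = 20, t_start = 0, n_max = Inf) {
  if (fp <= 0) stop("pacing frequency must be positive")
  if (Ee_on < 0) stop("irradiance must be non-negative")
  if (width > 1000 / fp)
    stop(sprintf("pulse width %g ms exceeds the pacing period %g ms", width, 1000 / fp))
  structure(list(fp = fp, width = width, Ee_on = Ee_on, t_start = t_start,
                 n_max = n_max),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> fp = %g Hz (period %.2f ms), width = %g ms, Ee = %g uW/mm^2, start %g ms\n",
              x$fp, 1000 / x$fp, x$width, x$Ee_on, x$t_start))
  invisible(x)
}

#' Irradiance of a pulse train at a time point
#'
#' `Ee_on` when `(t - t_start) mod (1000/fp) < width` and the pulse index is
#' below `n_max`, else 0.  Vectorized over `t`.
#'
#' @param t Time(s) in ms.
#' @param train A [pulse_train()].
#' @return Irradiance(s) in uW/mm^2.
#' @export
irradiance_at <- function(t, train) {
  stopifnot(inherits(train, "pulse_train"))
  period <- 1000 / train$fp
  rel <- t - train$t_start
  k <- floor(rel / period)
  phase <- rel - k * period
  ifelse(rel >= 0 & phase < train$width & k < train$n_max, train$Ee_on, 0)
}

#' Closed-loop resonant feedback controller
#'
#' Fires one global light pulse per upward crossing of the critical voltage
#' `Vc` at the sensing electrode.  After firing, the controller is disarmed
#' until the sensed voltage falls below `Vc` again (hysteresis re-arm: one
#' pulse per wavefront passage), and no new pulse is queued while a pulse is
#' still active.
#'
#' @param electrode Electrode position in cm, `c(x, y)`.
#' @param Vc Critical voltage in mV (default -40).
#' @param width Pulse duration in ms.
#' @param Ee_on Irradiance during a pulse in uW/mm^2.
#' @return An object of class `"feedback_controller"` with trigger state
#'   (`armed`, `active_until`, `pulses_fired`).
#' @export
feedback_controller <- function(electrode, Vc = -40, width = 33, Ee_on = 20) {
  stopifnot(length(electrode) == 2)
  if (Ee_on < 0) stop("irradiance must be non-negative")
  structure(list(electrode = as.numeric(electrode), Vc = Vc, width = width,
                 Ee_on = Ee_on, armed = TRUE, active_until = -Inf,
                 pulses_fired = 0L, t_last = -Inf),
            class = "feedback_controller")
}

#' @export
print.feedback_controller <- function(x, ...) {
  cat(sprintf("<feedback_controller> electrode (%.3g, %.3g) cm, Vc = %g mV, width = %g ms, Ee = %g uW/mm^2\n",
              x$electrode[1], x$electrode[2], x$Vc, x$width, x$Ee_on))
  cat(sprintf("  armed: %s, pulses fired: %d\n", x$armed, x$pulses_fired))
  invisible(x)
}

#' Advance the feedback controller by one sensed sample
#'
#' Reference (R-level) implementation of the trigger logic also used inside
#' the compiled tissue engine: on an upward crossing of `Vc` while armed and
#' no pulse active, start a `width`-long global pulse and disarm; re-arm
#' when the sensed voltage falls below `Vc`.
#'
#' @param ctrl A [feedback_controller()].
#' @param V_sensed Voltage at the electrode, mV.
#' @param t Current time, ms (must be non-decreasing across calls).
#' @return List with elements `Ee` (current irradiance) and `ctrl` (updated
#'   controller).
#' @export
feedback_update <- function(ctrl, V_sensed, t) {
  stopifnot(inherits(ctrl, "feedback_controller"))
  if (t < ctrl$t_last) stop("time must be non-decreasing across feedback updates")
  ctrl$t_last <- t
  if (ctrl$armed && V_sensed >= ctrl$Vc && t >= ctrl$active_until) {
    ctrl$active_until <- t + ctrl$width
    ctrl$pulses_fired <- ctrl$pulses_fired + 1L
    ctrl$armed <- FALSE
  } else if (!ctrl$armed && V_sensed < ctrl$Vc) {
    ctrl$armed <- TRUE
  }
  list(Ee = if (t < ctrl$active_until) ctrl$Ee_on else 0, ctrl = ctrl)
}

# translate a protocol object into the list consumed by the C++ engine
protocol_as_list <- function(protocol, grid) {
  if (is.null(protocol)) return(list(mode = "none"))
  if (inherits(protocol, "pulse_train")) {
    return(list(mode = "open_loop", t_start = protocol$t_start,
                period = 1000 / protocol$fp, width = protocol$width,
                Ee_on = protocol$Ee_on,
                n_max = if (is.finite(protocol$n_max)) protocol$n_max else Inf))
  }
  if (inherits(protocol, "feedback_controller")) {
    ij <- nearest_node(protocol$electrode, grid)
    return(list(mode = "feedback", elec_i = ij[1] - 1L, elec_j = ij[2] - 1L,
                Vc = protocol$Vc, width = protocol$width, Ee_on = protocol$Ee_on))
  }
  stop("protocol must be NULL, a pulse_train or a feedback_controller")
}

#' S1-S2 cross-field spiral initiation protocol
#'
#' Geometry and timing of the two stimuli used to start a single spiral
#' wave: S1 is a planar wave launched from the left edge; S2 covers the
#' lower-left quadrant and is delivered inside the vulnerable window so that
#' it captures only the recovered tissue behind the S1 waveback, producing
#' one broken front that curls into a spiral.
#'
#' @param s2_delay S1-to-S2 coupling interval in ms.
#' @param s1_width Width of the S1 strip in nodes.
#' @param amplitude Stimulus amplitude in pA/pF (negative = depolarizing).
#' @param s_dur Stimulus duration in ms.
#' @return Object of class `"spiral_init_spec"`.
#' @export
spiral_init_spec <- function(s2_delay = 45, s1_width = 3,
                             amplitude = -80, s_dur = 1) {
  structure(list(s2_delay = s2_delay, s1_width = s1_width,
                 amplitude = amplitude, s_dur = s_dur),
            class = "spiral_init_spec")
}

# One action-potential cycle of a paced cell, sampled every 0.5 ms, used to
# seed a spiral phase distribution.  Computed with the fast reaction path on
# a tiny uncoupled grid and cached per (variant, period, dt).
ap_cycle_cache <- new.env(parent = emptyenv())

ap_cycle_library <- function(params, chr2, period = 66, dt = 0.005,
                             n_beats = 7L, sample_dt = 0.5) {
  key <- paste(attr(params, "variant") %||% "apical", period, dt, sep = "|")
  if (!is.null(ap_cycle_cache[[key]])) return(ap_cycle_cache[[key]])
  s <- as.numeric(paced_rest_state(params, chr2))
  g9 <- rep(s, 9L)
  none <- list(mode = "none")
  nostim <- matrix(numeric(0), 0, 7)
  sens <- matrix(c(1L, 1L), 1)
  beat <- matrix(c(0, 1, -80, 0, 2, 0, 2), nrow = 1)
  run <- function(states, stims, n) {
    tissue_run_cpp(states, 3L, 3L, 0.025, 0, dt, n, 0, params, chr2, 0L,
                   none, stims, sens, n, 0L, FALSE, -70, -55, 100, 20L)$states
  }
  for (b in seq_len(n_beats))
    g9 <- run(g9, beat, as.integer(round(period / dt)))
  nsamp <- as.integer(round(period / sample_dt))
  lib <- matrix(NA_real_, 45L, nsamp)
  g9 <- run(g9, beat, as.integer(round(sample_dt / dt)))
  lib[, 1L] <- matrix(g9, 45L)[, 5L]
  for (k in 2:nsamp) {
    g9 <- run(g9, nostim, as.integer(round(sample_dt / dt)))
    lib[, k] <- matrix(g9, 45L)[, 5L]
  }
  ap_cycle_cache[[key]] <- lib
  lib
}

#' Initiate a single spiral wave
#'
#' Establishes one spiral in a resting grid and verifies that exactly one
#' phase singularity is present after the transient.  Two methods:
#' \describe{
#'   \item{`"phase_seed"` (default)}{Seeds an Archimedean spiral phase
#'     distribution of one paced action-potential cycle around the domain
#'     center and lets it heal; deterministic and robust, with the core at
#'     the domain center.}
#'   \item{`"cross_field"`}{Classic S1-S2 protocol: planar S1 from the left
#'     edge, quadrant S2 at coupling interval `spec$s2_delay` inside the
#'     vulnerable window.  Errors with a suggestion to adjust the timing if
#'     no re-entry results.}
#' }
#'
#' @param grid A resting `"tissue_grid"`.
#' @param spec A [spiral_init_spec()] (cross-field geometry/timing).
#' @param settle Post-initiation transient to discard, ms (default 200).
#' @param dt Time step, ms.
#' @param method `"phase_seed"` or `"cross_field"`.
#' @param period Rotation period (ms) of the seeded phase pattern.
#' @param mirror If `TRUE`, mirror the seeding geometry, producing a spiral
#'   of opposite chirality.
#' @return The `"tissue_grid"` containing the established spiral, with
#'   attributes `"n_tips"` (tip count after the transient) and
#'   `"init_trace"` (data frame `t`, `V` recorded at the off-core reference
#'   point, usable for dark-frequency estimation).
#' @export
initiate_spiral <- function(grid, spec = spiral_init_spec(), settle = 200,
                            dt = 0.01, method = c("phase_seed", "cross_field"),
                            period = 66, mirror = FALSE) {
  stopifnot(inherits(grid, "tissue_grid"), inherits(spec, "spiral_init_spec"))
  method <- match.arg(method)
  t0 <- grid$t
  tracept <- c((grid$nx - 1) * grid$dx / 4, 3 * (grid$ny - 1) * grid$dx / 4)

  if (method == "phase_seed") {
    lib <- ap_cycle_library(grid$params, grid$chr2, period = period, dt = dt)
    nsamp <- ncol(lib)
    ic <- (grid$nx + 1) / 2; jc <- (grid$ny + 1) / 2
    lam <- 2.8 / grid$dx                      # radial twist ~ one wavelength
    idx <- rep(seq_len(grid$nx), grid$ny) - ic
    jdx <- rep(seq_len(grid$ny), each = grid$nx) - jc
    sgn <- if (mirror) -1 else 1
    ph <- (sgn * atan2(jdx, idx) / (2 * pi) + sqrt(idx^2 + jdx^2) / lam) %% 1
    k <- 1L + as.integer(floor(ph * nsamp))
    k[k > nsamp] <- nsamp
    grid$states <- as.numeric(lib[, k])
    sim <- simulate_tissue(grid, settle, dt = dt, sensors = rbind(tracept),
                           trace_dt = 0.5, snapshot_dt = 2)
  } else {
    jr <- if (mirror) c(floor(grid$ny / 2) + 1L, grid$ny)
          else c(1L, ceiling(grid$ny / 2))
    stims <- list(
      stimulus(t0 + 1, spec$s_dur, spec$amplitude, c(1L, spec$s1_width),
               c(1L, grid$ny)),
      stimulus(t0 + spec$s2_delay, spec$s_dur, spec$amplitude,
               c(1L, ceiling(grid$nx / 2)), jr))
    sim <- simulate_tissue(grid, spec$s2_delay + settle, dt = dt,
                           stims = stims, sensors = rbind(tracept),
                           trace_dt = 0.5, snapshot_dt = 2)
  }

  nt <- dim(sim$snapshots)[3]
  tips <- find_tips(sim$snapshots[, , nt - 1L], sim$snapshots[, , nt],
                    grid$dx)
  n_tips <- nrow(tips)
  if (max(tail(sim$trace$V_max, 20)) < -70 || n_tips == 0L)
    stop("spiral initiation failed (no re-entry after the transient); ",
         if (method == "cross_field")
           "try a different S2 coupling interval (spec$s2_delay)"
         else "try a different seeding period")
  if (n_tips > 1L)
    warning(sprintf("%d phase singularities present after the transient", n_tips))
  out <- sim$grid
  attr(out, "n_tips") <- n_tips
  attr(out, "init_trace") <- data.frame(t = sim$trace$t, V = sim$trace$V1)
  attr(out, "tip") <- tips[1L, ]
  out
}

#' Detect termination (quiescence) of a tissue simulation
#'
#' `TRUE` when the maximum voltage over the grid has stayed below `thresh`
#' for a sustained window, evaluated on the recorded `V_max` trace of a
#' [simulate_tissue()] result.  Samples taken while a sub-threshold light
#' pulse is on are judged against the relaxed `thresh_lit` (lit resting
#' tissue sits a few mV depolarized without being excited).
#'
#' @param sim A `"tissue_sim"` result (needs at least `window` ms of trace).
#' @param thresh Quiescence threshold in mV (default -70).
#' @param thresh_lit Threshold for samples with active light (default
#'   `thresh + 15`).
#' @param window Sustained window in ms (default 100).
#' @return Logical.
#' @export
detect_termination <- function(sim, thresh = -70, thresh_lit = thresh + 15,
                               window = 100) {
  stopifnot(inherits(sim, "tissue_sim"))
  tr <- sim$trace
  if (nrow(tr) < 2L) stop("trace too short")
  if (max(tr$t) - min(tr$t) < window)
    stop("need at least ", window, " ms of recorded history")
  quiet <- ifelse(tr$Ee > 0, tr$V_max < thresh_lit, tr$V_max < thresh)
  r <- rle(quiet)
  dtr <- diff(tr$t[1:2])
  any(r$values & r$lengths * dtr >= window)
}
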