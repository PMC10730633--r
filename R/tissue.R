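# 2D monodomain tissue: dV/dt = D lap(V) - (I_ion + I_ChR2 + I_stim)/Cm on a
# regular grid with no-flux (mirrored ghost node) boundaries.  Node (1,1)
# sits at the domain corner; the physical coordinate of node (i,j) is
# ((i-1)*dx, (j-1)*dx) cm.  Voltage fields are matrices indexed [x, y].

#' Construct a resting tissue grid
#'
#' Builds a 2D monodomain sheet of coupled Bondarenko + ChR2 cells, each
#' initialized to the supplied (or freshly settled) resting state.
#'
#' @param nx,ny Grid dimensions in nodes (default 100 x 100).
#' @param dx Node spacing in cm (default 0.025, i.e. a 2.5 cm square domain).
#' @param D Diffusion coefficient in cm^2/ms.  Default 0.0014 cm^2/ms
#'   (0.14 mm^2/ms), which yields a planar conduction velocity of ~44 cm/s
#'   in this model; see the package vignette for why this differs from a
#'   published figure of 0.00014.
#' @param state A 45-element resting cell state; defaults to
#'   [paced_rest_state()] (settled once and reused).
#' @param params,chr2 Model parameter vectors.
#' @return An object of class `"tissue_grid"`: a list with elements
#'   `nx, ny, dx, D, t, states` (numeric vector, node-major, 45 values per
#'   node), `params`, `chr2`.
#' @export
tissue_grid <- function(nx = 100, ny = 100, dx = 0.025, D = 0.0014,
                        state = NULL, params = cell_params(),
                        chr2 = chr2_params()) {
  if (nx < 3 || ny < 3) stop("grid must be at least 3 x 3")
  if (dx <= 0 || D < 0) stop("dx must be positive and D non-negative")
  if (is.null(state)) state <- paced_rest_state(params, chr2)
  check_state(state)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, D = D,
                 t = 0, states = rep(as.numeric(state), nx * ny),
                 params = params, chr2 = chr2),
            class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  V <- voltage_field(x)
  cat(sprintf("<tissue_grid> %d x %d nodes, dx = %g cm (%.3g x %.3g cm), D = %g cm^2/ms\n",
              x$nx, x$ny, x$dx, x$nx * x$dx, x$ny * x$dx, x$D))
  cat(sprintf("  t = %g ms, V in [%.1f, %.1f] mV\n", x$t, min(V), max(V)))
  invisible(x)
}

#' Voltage field of a tissue grid
#'
#' @param grid A `"tissue_grid"`.
#' @return Matrix of dimension `nx` x `ny` (first index x, second y) in mV.
#' @export
voltage_field <- function(grid) {
  matrix(grid$states[seq(1, length(grid$states), by = 45L)],
         grid$nx, grid$ny)
}

#' Five-point Laplacian with no-flux boundaries
#'
#' Discrete Laplacian `(V[i-1,j] + V[i+1,j] + V[i,j-1] + V[i,j+1] - 4 V[i,j]) / dx^2`
#' with zero-flux boundaries implemented by mirrored ghost nodes.  Exact for
#' fields quadratic in the coordinates.
#'
#' @param V Numeric matrix (at least 3 x 3).
#' @param dx Node spacing.
#' @return Matrix of the same shape.
#' @export
laplacian_5pt <- function(V, dx) {
  if (!is.matrix(V) || nrow(V) < 3 || ncol(V) < 3)
    stop("field must be a matrix of at least 3 x 3")
  laplacian5_cpp(V, dx)
}

as_stim_matrix <- function(stims, grid) {
  if (is.null(stims)) return(matrix(numeric(0), 0, 7))
  if (inherits(stims, "stimulus")) stims <- list(stims)
  out <- do.call(rbind, lapply(stims, function(s) {
    stopifnot(inherits(s, "stimulus"))
    c(s$t_on, s$duration, s$amplitude,
      s$i_range[1] - 1L, s$i_range[2] - 1L,
      s$j_range[1] - 1L, s$j_range[2] - 1L)
  }))
  if (any(out[, 4] < 0 | out[, 5] >= grid$nx | out[, 6] < 0 | out[, 7] >= grid$ny))
    stop("stimulus window outside the grid")
  out
}

#' Rectangular stimulus window
#'
#' A current stimulus applied uniformly over a rectangular node window for a
#' fixed duration; zero outside its active window.
#'
#' @param t_on Onset time in ms.
#' @param duration Duration in ms.
#' @param amplitude Current density in pA/pF (negative = depolarizing).
#' @param i_range,j_range Inclusive 1-based node index ranges (x and y).
#' @return An object of class `"stimulus"`.
#' @export
stimulus <- function(t_on, duration, amplitude, i_range, j_range) {
  stopifnot(duration > 0, length(i_range) == 2, length(j_range) == 2)
  structure(list(t_on = t_on, duration = duration, amplitude = amplitude,
                 i_range = as.integer(i_range), j_range = as.integer(j_range)),
            class = "stimulus")
}

#' Map physical coordinates (cm) to the nearest grid node
#'
#' @param xy Numeric length-2 position in cm.
#' @param grid A `"tissue_grid"`.
#' @return Integer length-2 (i, j) 1-based node index.
#' @export
nearest_node <- function(xy, grid) {
  ij <- round(xy / grid$dx) + 1L
  c(max(1L, min(grid$nx, ij[1])), max(1L, min(grid$ny, ij[2])))
}

#' Simulate the tissue sheet
#'
#' Advances the monodomain sheet by `duration` ms under an optional
#' illumination protocol and stimulus set, with Strang splitting between the
#' explicit 5-point diffusion substep and the per-node reaction substep.
#'
#' The default reaction scheme (`"split"`) uses tabulated voltage-dependent
#' rates with Rush-Larsen gate updates and exponential-Euler/backward-Euler
#' Markov updates, and is stable at `dt` up to ~0.01-0.02 ms.  Scheme
#' `"rk4"` integrates the full coupled ODEs per node with classical RK4
#' (the reference scheme; requires `dt` of order 1e-4 ms during activity).
#'
#' @param grid A `"tissue_grid"`.
#' @param duration Duration in ms.
#' @param dt Time step in ms (default 0.005).  Must satisfy the diffusion
#'   stability bound `dt < dx^2/(4 D)`; violation is an error reporting the
#'   bound.
#' @param protocol `NULL`, a [pulse_train()] or a [feedback_controller()].
#' @param stims A [stimulus()] or list of stimuli.
#' @param sensors Matrix/vector of sensor positions in cm (each row `x, y`),
#'   or `NULL` for a single sensor at the domain center.
#' @param trace_dt Sensor/irradiance trace sampling interval, ms.
#' @param snapshot_dt Voltage snapshot interval in ms; 0 disables snapshots.
#' @param stop_on_termination If `TRUE`, stop as soon as the domain has been
#'   quiescent for `quiet_window` ms (all `V < quiet_thresh` while dark; all
#'   `V < quiet_thresh_lit` while a sub-threshold pulse holds the resting
#'   tissue a few mV depolarized).
#' @param quiet_thresh,quiet_thresh_lit,quiet_window Quiescence thresholds
#'   (mV, dark / lit) and sustained window (ms).
#' @param scheme `"split"` (default) or `"rk4"`.
#' @return An object of class `"tissue_sim"`: list with the advanced `grid`,
#'   `trace` data frame (`t`, one `V<k>` column per sensor, `Ee`, `V_max`),
#'   `snapshots` (nx x ny x n_frames array or `NULL`), `snap_t`, `events`
#'   data frame (pulse log: `t_on, t_off, trigger`), `pulses_fired`,
#'   `terminated`, `t_terminated`, and the updated `protocol`.
#' @export
simulate_tissue <- function(grid, duration, dt = 0.005, protocol = NULL,
                            stims = NULL, sensors = NULL, trace_dt = 0.1,
                            snapshot_dt = 0, stop_on_termination = FALSE,
                            quiet_thresh = -70, quiet_thresh_lit = quiet_thresh + 15,
                            quiet_window = 100,
                            scheme = c("split", "rk4")) {
  stopifnot(inherits(grid, "tissue_grid"))
  scheme <- match.arg(scheme)
  if (dt <= 0) stop("dt must be positive")
  n <- as.integer(round(duration / dt))
  if (n < 1L) stop("duration shorter than one time step")

  if (is.null(sensors)) sensors <- c((grid$nx - 1) * grid$dx / 2,
                                     (grid$ny - 1) * grid$dx / 2)
  sensors <- matrix(sensors, ncol = 2)
  sij <- t(apply(sensors, 1, nearest_node, grid = grid)) - 1L
  storage.mode(sij) <- "integer"

  prot <- protocol_as_list(protocol, grid)
  stm <- as_stim_matrix(stims, grid)

  r <- tissue_run_cpp(grid$states, grid$nx, grid$ny, grid$dx, grid$D, dt, n,
                      grid$t, grid$params, grid$chr2,
                      if (scheme == "split") 0L else 1L,
                      prot, stm, sij,
                      max(1L, as.integer(round(trace_dt / dt))),
                      if (snapshot_dt > 0) as.integer(round(snapshot_dt / dt)) else 0L,
                      stop_on_termination, quiet_thresh, quiet_thresh_lit,
                      quiet_window, 20L)

  grid$states <- r$states
  grid$t <- grid$t + n * dt
  if (isTRUE(r$terminated) && stop_on_termination) grid$t <- r$t_terminated

  trace <- data.frame(t = r$trace_t)
  for (k in seq_len(ncol(r$traces))) trace[[paste0("V", k)]] <- r$traces[, k]
  trace$Ee <- r$trace_Ee
  trace$V_max <- r$trace_vmax

  snaps <- NULL
  if (!is.null(r$snapshots)) {
    snaps <- r$snapshots
    dim(snaps) <- c(grid$nx, grid$ny, length(r$snap_t))
  }
  ev <- as.data.frame(r$events)
  names(ev) <- c("t_on", "t_off", "trigger")
  ev$trigger <- ifelse(ev$trigger == 0, "timer", "crossing")

  upd <- protocol
  if (inherits(protocol, "feedback_controller")) {
    upd$armed <- r$fb_armed
    upd$active_until <- r$fb_active_until
    upd$pulses_fired <- protocol$pulses_fired + r$pulses_fired
  }

  structure(list(grid = grid, trace = trace, snapshots = snaps,
                 snap_t = r$snap_t, events = ev,
                 pulses_fired = r$pulses_fired,
                 terminated = isTRUE(r$terminated),
                 t_terminated = r$t_terminated,
                 protocol = upd, dt = dt, sensors = sensors),
            class = "tissue_sim")
}

#' @export
print.tissue_sim <- function(x, ...) {
  cat(sprintf("<tissue_sim> t = %g ms (dt = %g ms), %d sensor(s)\n",
              x$grid$t, x$dt, ncol(x$trace) - 3L))
  cat(sprintf("  pulses fired: %d;  terminated: %s\n", x$pulses_fired,
              if (x$terminated) sprintf("yes (t = %.1f ms)", x$t_terminated) else "no"))
  if (!is.null(x$snapshots))
    cat(sprintf("  snapshots: %d frames\n", dim(x$snapshots)[3]))
  invisible(x)
}

#' Advance a tissue grid by a single step
#'
#' One `dt` step of the split solver under a fixed irradiance and optional
#' stimulus field; mainly useful for fine-grained control and testing.
#'
#' @inheritParams simulate_tissue
#' @param Ee Global irradiance during the step (uW/mm^2).
#' @return The advanced `"tissue_grid"`.
#' @export
step_tissue <- function(grid, dt, Ee = 0, stims = NULL,
                        scheme = c("split", "rk4")) {
  scheme <- match.arg(scheme)
  prot <- if (Ee > 0)
    list(mode = "open_loop", t_start = grid$t, period = 2 * dt + 1e9,
         width = 2 * dt, Ee_on = Ee, n_max = 1)
  else list(mode = "none")
  r <- tissue_run_cpp(grid$states, grid$nx, grid$ny, grid$dx, grid$D, dt, 1L,
                      grid$t, grid$params, grid$chr2,
                      if (scheme == "split") 0L else 1L,
                      prot, as_stim_matrix(stims, grid),
                      matrix(c(0L, 0L), 1), 1L, 0L, FALSE, -70, -55, 100, 1L)
  grid$states <- r$states
  grid$t <- grid$t + dt
  grid
}

#' Measure planar-wave conduction velocity
#'
#' Builds a thin resting strip, paces one edge, and measures conduction
#' velocity between two sensors aligned with the propagation direction as
#' distance over the difference of upstroke activation times (crossing of
#' `thr`, default -40 mV, on the upstroke).
#'
#' @param D Diffusion coefficient, cm^2/ms.
#' @param dx Node spacing, cm.
#' @param nx,ny Strip dimensions in nodes.
#' @param sensor_x Positions (cm, along the strip) of the two sensors;
#'   must differ by at least 10 nodes.
#' @param dt Time step, ms.
#' @param thr Activation threshold, mV.
#' @param duration Maximum simulated time, ms.
#' @param state Optional pre-settled resting cell state.
#' @param params,chr2 Model parameters.
#' @return List of class `"cv_measurement"` with `cv` (cm/s), activation
#'   times `t1`, `t2` (ms) and the measurement geometry.
#' @export
measure_cv <- function(D = 0.0014, dx = 0.025, nx = 150, ny = 6,
                       sensor_x = c(1.25, 3.25), dt = 0.01, thr = -40,
                       duration = 100, state = NULL,
                       params = cell_params(), chr2 = chr2_params()) {
  if (abs(diff(sensor_x)) < 10 * dx)
    stop("sensors must be separated by at least 10 nodes along the propagation direction")
  g <- tissue_grid(nx, ny, dx, D, state = state, params = params, chr2 = chr2)
  ymid <- (ny - 1) * dx / 2
  sim <- simulate_tissue(g, duration, dt = dt,
                         stims = stimulus(1, 1, -80, c(1, 3), c(1, ny)),
                         sensors = rbind(c(sensor_x[1], ymid), c(sensor_x[2], ymid)),
                         trace_dt = min(0.02, 10 * dt))
  up <- function(V, t) {
    i <- which(V[-1] >= thr & V[-length(V)] < thr)[1]
    if (is.na(i)) stop("no activation detected at a sensor within ", duration, " ms")
    t[i] + (thr - V[i]) / (V[i + 1] - V[i]) * (t[i + 1] - t[i])
  }
  t1 <- up(sim$trace$V1, sim$trace$t)
  t2 <- up(sim$trace$V2, sim$trace$t)
  structure(list(cv = abs(diff(sensor_x)) / (t2 - t1) * 1000,
                 t1 = t1, t2 = t2, sensor_x = sensor_x, D = D, dx = dx),
            class = "cv_measurement")
}

#' @export
print.cv_measurement <- function(x, ...) {
  cat(sprintf("Conduction velocity: %.2f cm/s  (activation %.2f -> %.2f ms over %.3g cm; D = %g cm^2/ms)\n",
              x$cv, x$t1, x$t2, abs(diff(x$sensor_x)), x$D))
  invisible(x)
}

#' Plot the voltage field of a grid or simulation snapshot
#'
#' @param x A `"tissue_grid"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.tissue_grid <- function(x, ...) {
  V <- voltage_field(x)
  image(x = (seq_len(x$nx) - 1) * x$dx, y = (seq_len(x$ny) - 1) * x$dx,
        z = V, xlab = "x [cm]", ylab = "y [cm]", useRaster = TRUE,
        zlim = c(-90, 40), ...)
  invisible(x)
}
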