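# Shared fixtures.  Heavy objects are computed once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fx_rest <- function() {
  if (is.null(.fixtures$rest))
    .fixtures$rest <- paced_rest_state(settle_time = 500)
  .fixtures$rest
}

# a state on the action-potential upstroke (smooth, fast dynamics)
fx_upstroke <- function() {
  if (is.null(.fixtures$up)) {
    s <- step_cell_rk4(fx_rest(), dt = 1e-4, I_applied = -80, n_steps = 10000L)
    .fixtures$up <- step_cell_rk4(s, dt = 1e-4, n_steps = 2000L)
  }
  .fixtures$up
}

# synthetic rotating-spiral voltage movie with a known phase-singularity path
# center_fn(t) returns c(x, y) in cm; returns list(snapshots, times)
make_spiral_movie <- function(n = 61, dx = 0.025, times = seq(0, 40, by = 2),
                              center_fn = function(t) c(0.75, 0.75),
                              omega = 2 * pi / 20, kr = 2 * pi / 1.5) {
  xs <- (seq_len(n) - 1) * dx
  arr <- array(NA_real_, c(n, n, length(times)))
  for (f in seq_along(times)) {
    ctr <- center_fn(times[f])
    X <- outer(xs - ctr[1], rep(1, n))
    Y <- outer(rep(1, n), xs - ctr[2])
    th <- atan2(Y, X)
    r <- sqrt(X^2 + Y^2)
    arr[, , f] <- -40 + 45 * cos(th - omega * times[f] + kr * r)
  }
  list(snapshots = arr, times = times, dx = dx)
}

make_plane_movie <- function(n = 41, dx = 0.025, times = seq(0, 20, by = 2)) {
  xs <- (seq_len(n) - 1) * dx
  arr <- array(NA_real_, c(n, n, length(times)))
  for (f in seq_along(times))
    arr[, , f] <- outer(-40 + 45 * cos(2 * pi * (xs - 0.02 * times[f]) / 0.6),
                        rep(1, n))
  list(snapshots = arr, times = times, dx = dx)
}

# flower-meander trajectory with petals pointing outward (+1) or inward (-1)
# relative to the pattern centroid; one petal per modulation period Tm
make_flower_traj <- function(direction = +1, n_cycles = 6, Tm = 75,
                             Rc = 0.5, rho = 0.18, dt = 1) {
  t <- seq(0, n_cycles * Tm - dt, by = dt)
  Th <- 2 * pi * t / (n_cycles * Tm)          # slow precession (one turn total)
  bulge <- rho * (1 - cos(2 * pi * t / Tm))   # zero at cusps, 2*rho mid-petal
  wob <- 0.3 * rho * sin(2 * pi * t / Tm)
  r <- Rc + direction * bulge
  x <- 1.25 + r * cos(Th) - wob * sin(Th)
  y <- 1.25 + r * sin(Th) + wob * cos(Th)
  structure(data.frame(t = t, x = x, y = y),
            class = c("tip_trajectory", "data.frame"),
            method = "synthetic", n_gaps = 0L)
}

make_drift_traj <- function(v = c(2e-3, 1e-3), Tm = 70, n_cycles = 6,
                            rho = 0.12, dt = 1) {
  t <- seq(0, n_cycles * Tm - dt, by = dt)
  x <- 0.8 + v[1] * t + rho * cos(2 * pi * t / Tm)
  y <- 0.8 + v[2] * t + rho * sin(2 * pi * t / Tm)
  structure(data.frame(t = t, x = x, y = y),
            class = c("tip_trajectory", "data.frame"),
            method = "synthetic", n_gaps = 0L)
}

make_circle_traj <- function(Tm = 66, n_cycles = 6, rho = 0.1, dt = 1) {
  make_drift_traj(v = c(0, 0), Tm = Tm, n_cycles = n_cycles, rho = rho, dt = dt)
}

# upstroke-shaped synthetic voltage spike train at frequency f (Hz)
make_spike_train <- function(f, duration = 600, dt = 0.5, t0 = 3) {
  t <- seq(0, duration, by = dt)
  period <- 1000 / f
  ph <- ((t - t0) %% period) / period
  V <- ifelse(ph < 0.06, -80 + (ph / 0.06) * 110,
              ifelse(ph < 0.4, 30 - ((ph - 0.06) / 0.34) * 100, -80 + (ph - 1) * 5))
  list(t = t, V = V)
}
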