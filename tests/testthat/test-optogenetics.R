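# Four-state ChR2 photocurrent model: activation rates, conservative
# kinetics, rectified current, steady states, and the sub-threshold regime.

test_that("light-activation rates vanish in the dark and grow with irradiance", {
  expect_equal(unname(chr2_rates(0)), c(0, 0))
  k20 <- chr2_rates(20)
  k40 <- chr2_rates(40)
  expect_true(all(k40 >= k20))
  # closed-form evaluation of the linear photon-flux law at 20 uW/mm^2
  q <- chr2_params()
  expect_equal(unname(k20), 20 * c(q[["kc1"]], q[["kc2"]]), tolerance = 1e-12)
  expect_equal(unname(k20["k1"]), 3.7274e-3, tolerance = 1e-4)
  expect_error(chr2_rates(-1), "non-negative")
})

test_that("kinetics conserve total occupancy exactly", {
  # dark closed state is a fixed point
  expect_equal(unname(chr2_derivatives(c(1, 0, 0, 0), V = -80, Ee = 0)),
               rep(0, 4))
  # derivative sum vanishes for arbitrary states, voltages and irradiances
  set.seed(42)
  for (k in 1:25) {
    s <- runif(4); s <- s / sum(s)
    d <- chr2_derivatives(s, V = runif(1, -100, 40), Ee = runif(1, 0, 50))
    expect_lt(abs(sum(d)), 1e-12)
  }
})

test_that("long integration converges to the null-space steady state", {
  # explicit RK4 on the 4-state system vs the linear-algebra steady state
  V <- -75; Ee <- 20
  f <- function(s) chr2_derivatives(s, V, Ee)
  s <- c(1, 0, 0, 0)
  h <- 4
  for (i in 1:40000) {   # 160 s of model time (dark recovery is ~5 s slow)
    k1 <- f(s); k2 <- f(s + h / 2 * k1); k3 <- f(s + h / 2 * k2); k4 <- f(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  ss <- chr2_steady_state(V, Ee)
  expect_lt(max(abs(s - ss)) / max(ss), 1e-6)
})

test_that("photocurrent is rectified, finite at V = 0, and depolarizing", {
  expect_equal(chr2_current(c(1, 0, 0, 0), V = -80), 0)   # closed channels
  # analytic limit at V = 0 (E_ChR2 = 0): numerator 10.6408 - 14.6408 = -4
  q <- chr2_params()
  s <- c(0.5, 0.3, 0.1, 0.1)
  expect_equal(chr2_current(s, V = 0),
               q[["g_ChR2"]] * (-4) * (0.3 + q[["gamma"]] * 0.1),
               tolerance = 1e-10)
  # inward (negative) at diastolic V: drives V toward 0
  expect_lt(chr2_current(s, V = -80), 0)
})

test_that("occupancy stays conserved through 1000 ms of pulsed illumination", {
  rest <- fx_rest()
  n <- 200000   # dt = 5e-3 on the coupled cell (RK4 stays stable sub-threshold)
  Ee <- rep(0, n)
  for (k in 0:12) {   # 13 pulses of 33 ms at ~13.3 Hz
    i0 <- round(k * 75 / 5e-3)
    Ee[seq(i0 + 1, min(n, i0 + 33 / 5e-3))] <- 20
  }
  tr <- simulate_cell(rest, duration = 1000, dt = 5e-3, Ee = Ee, record_dt = 10)
  st <- attr(tr, "state")
  occ <- st[c("cC1", "cO1", "cO2", "cC2")]
  expect_lt(abs(sum(occ) - 1), 1e-8)
  expect_true(all(occ >= 0 & occ <= 1))
  # and the photocurrent was actually engaged
  expect_lt(min(tr$I_ChR2), -0.1)
})

test_that("after light-off the open occupancy decays to darkness", {
  rest <- fx_rest()
  lit <- simulate_cell(rest, duration = 50, dt = 5e-3, Ee = 20, record_dt = 10)
  s_on <- attr(lit, "state")
  expect_gt(s_on[["cO1"]], 1e-3)
  dark <- simulate_cell(s_on, duration = 400, dt = 5e-3, Ee = 0, record_dt = 50)
  s_off <- attr(dark, "state")
  expect_lt(s_off[["cO1"]] + s_off[["cO2"]], 1e-6)
})

test_that("20 uW/mm^2 depolarizes a resting cell without firing an AP", {
  tr <- simulate_cell(fx_rest(), duration = 60, dt = 5e-3,
                      Ee = rep(c(0, 20, 0), c(1000, 6600, 4400)),
                      record_dt = 0.5)
  expect_gt(max(tr$V) - tr$V[1], 1)     # measurable depolarization
  expect_lt(max(tr$V), -55)             # far from threshold
})
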