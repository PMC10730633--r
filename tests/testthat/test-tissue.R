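# Monodomain solver: stencil correctness, no-flux conservation, stability
# guard, splitting self-convergence, and equivalence with the single-cell
# integrator at D = 0.

test_that("5-point Laplacian is exact on quadratics and matches a matrix oracle", {
  n <- 12; dx <- 0.025
  # uniform field -> identically zero
  expect_equal(laplacian_5pt(matrix(7, n, n), dx), matrix(0, n, n))
  # V = x^2: interior Laplacian exactly 2
  xs <- (seq_len(n) - 1) * dx
  Vx <- outer(xs^2, rep(1, n))
  L <- laplacian_5pt(Vx, dx)
  expect_equal(L[2:(n - 1), 2:(n - 1)], matrix(2, n - 2, n - 2),
               tolerance = 1e-9)
  # random field vs dense-matrix assembly of the mirrored-ghost operator
  set.seed(7)
  V <- matrix(rnorm(n * n), n, n)
  A <- matrix(0, n * n, n * n)
  id <- function(i, j) (j - 1) * n + i
  refl <- function(k) if (k < 1) 1 else if (k > n) n else k
  for (j in 1:n) for (i in 1:n) {
    r <- id(i, j)
    A[r, r] <- A[r, r] - 4
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      k <- id(refl(nb[1]), refl(nb[2]))
      A[r, k] <- A[r, k] + 1
    }
  }
  expect_equal(as.numeric(laplacian_5pt(V, dx)),
               as.numeric(A %*% as.numeric(V)) / dx^2, tolerance = 1e-10)
  expect_error(laplacian_5pt(matrix(0, 2, 5), dx), "3 x 3")
})

test_that("explicit diffusion conserves mass and spreads a Gaussian correctly", {
  # diffusion-only integration built on the package's stencil
  n <- 61; dx <- 0.025; D <- 0.0014; dt <- 0.05
  xs <- (seq_len(n) - 1) * dx
  ctr <- xs[(n + 1) / 2]
  s0sq <- 0.01^2  # initial variance per axis, cm^2
  V <- outer(exp(-(xs - ctr)^2 / (2 * s0sq)), exp(-(xs - ctr)^2 / (2 * s0sq)))
  Tend <- 15
  Vt <- V
  for (k in seq_len(Tend / dt)) Vt <- Vt + dt * D * laplacian_5pt(Vt, dx)
  # no-flux conservation of the spatial mean
  expect_lt(abs(mean(Vt) - mean(V)), 1e-8)
  # closed-form variance growth: sigma^2(t) = sigma^2(0) + 2 D t per axis
  wx <- rowSums(Vt) / sum(Vt)
  var_x <- sum(wx * (xs - sum(wx * xs))^2)
  expect_equal(var_x, s0sq + 2 * D * Tend, tolerance = 0.01)
})

test_that("a resting sheet stays uniform and quiescent", {
  g <- tissue_grid(10, 10, state = fx_rest())
  sim <- simulate_tissue(g, 10, dt = 0.01)
  V <- voltage_field(sim$grid)
  expect_lt(max(V) - min(V), 1e-9)           # no spurious spatial structure
  expect_lt(abs(mean(V) - fx_rest()[["V"]]), 1e-3)
})

test_that("the diffusion stability bound is enforced as a hard error", {
  g <- tissue_grid(10, 10, state = fx_rest())
  expect_error(simulate_tissue(g, 1, dt = 0.2), "dx\\^2/\\(4 D\\)")
})

test_that("with D = 0 every node reproduces the single-cell RK4 integrator", {
  g <- tissue_grid(3, 3, D = 0, state = fx_upstroke())
  n <- 2000; dt <- 1e-4
  sim <- simulate_tissue(g, n * dt, dt = dt, scheme = "rk4")
  ref <- step_cell_rk4(fx_upstroke(), dt = dt, n_steps = n)
  states <- matrix(sim$grid$states, nrow = 45)
  for (k in seq_len(9))
    expect_identical(states[, k], as.numeric(ref))
})

test_that("split fast path converges to the rk4 reference on an AP", {
  # same D = 0 segment integrated by the tabulated split scheme at two dt
  st <- fx_upstroke()
  run_split <- function(dt) {
    g <- tissue_grid(3, 3, D = 0, state = st)
    sim <- simulate_tissue(g, 6, dt = dt)
    voltage_field(sim$grid)[1, 1]
  }
  ref <- step_cell_rk4(st, dt = 1e-4, n_steps = 60000L)[["V"]]
  e1 <- abs(run_split(0.01) - ref)
  e2 <- abs(run_split(0.0025) - ref)
  expect_lt(e2, e1)          # self-convergence toward the reference
  expect_lt(e1, 4)           # mV, during the steep repolarization phase
})

test_that("planar-wave activation is symmetric and self-convergent in dt", {
  st <- fx_rest()
  act_times <- function(dt) {
    g <- tissue_grid(60, 8, state = st)
    sim <- simulate_tissue(g, 40, dt = dt,
                           stims = stimulus(1, 1, -80, c(1, 3), c(1, 8)),
                           sensors = rbind(c(0.75, 0.1), c(0.75, 0.075)),
                           trace_dt = 0.02)
    up <- function(V, t) {
      i <- which(V[-1] >= -40 & V[-length(V)] < -40)[1]
      t[i] + (-40 - V[i]) / (V[i + 1] - V[i]) * (t[i + 1] - t[i])
    }
    c(up(sim$trace$V1, sim$trace$t), up(sim$trace$V2, sim$trace$t))
  }
  a1 <- act_times(0.01)
  # symmetry: both sensors are mirror images about the strip midline
  expect_lt(abs(a1[1] - a1[2]), 0.05)
  # halving dt changes the activation time by < 0.5%
  a2 <- act_times(0.005)
  expect_lt(abs(a1[1] - a2[1]) / a2[1], 0.005)
})

test_that("conduction velocity scales approximately as sqrt(D)", {
  st <- fx_rest()
  cv1 <- measure_cv(D = 0.0014, nx = 100, ny = 6, sensor_x = c(0.75, 1.75),
                    duration = 60, state = st)
  cv4 <- measure_cv(D = 4 * 0.0014, nx = 100, ny = 6, sensor_x = c(0.75, 1.75),
                    duration = 60, state = st)
  expect_equal(cv4$cv / cv1$cv, 2, tolerance = 0.1)
  expect_error(measure_cv(sensor_x = c(1, 1.1), state = st), "separated")
})
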