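# Single-cell ionic model: current bookkeeping, derivative conventions,
# RK4 integration order, and the quiescent rest state.

test_that("resting state is a fixed point with consistent current bookkeeping", {
  rest <- fx_rest()
  cur <- ionic_currents(rest)

  # net current vanishes at rest, and I_Na is negligible (closed gates)
  expect_lt(abs(cur[["total"]]), 0.01)
  expect_lt(abs(cur[["I_Na"]]), 0.01)

  # total equals an independent componentwise sum, at rest and mid-AP
  comps <- c("I_Na", "I_CaL", "I_pCa", "I_Kto_f", "I_Kto_s", "I_Kr", "I_Kur",
             "I_Kss", "I_K1", "I_Ks", "I_NaCa", "I_NaK", "I_ClCa", "I_Cab",
             "I_Nab")
  for (st in list(rest, fx_upstroke())) {
    cb <- ionic_currents(st)
    expect_lt(abs(cb[["total"]] - sum(cb[comps])), 1e-12)
  }

  # rest is in the physiological diastolic range and idempotent under settling
  expect_gt(rest[["V"]], -90)
  expect_lt(rest[["V"]], -70)
  d <- cell_derivatives(rest)
  expect_lt(max(abs(d)), 1e-3)
})

test_that("derivatives follow the monodomain sign convention", {
  rest <- fx_rest()
  d0 <- cell_derivatives(rest, I_applied = 0)
  expect_lt(abs(d0[["V"]]), 1e-3)
  # a depolarizing (inward, negative) applied current raises V
  expect_gt(cell_derivatives(rest, I_applied = -80)[["V"]], 0)
  expect_lt(cell_derivatives(rest, I_applied = +80)[["V"]], 0)
})

test_that("derivatives match a finite-difference quotient of the integrator", {
  # central finite difference of the RK4 flow is an independent check of the
  # right-hand side
  st <- fx_upstroke()
  h <- 1e-5
  fwd <- step_cell_rk4(st, dt = h, n_steps = 1L)
  d_num <- (as.numeric(fwd) - as.numeric(st)) / h
  d_ana <- cell_derivatives(st)
  scale <- pmax(abs(d_ana), 1)
  expect_lt(max(abs(d_num - d_ana) / scale), 1e-4)
})

test_that("RK4 integration has 4th-order convergence on an AP upstroke", {
  st <- fx_upstroke()
  Tseg <- 0.2
  ref <- step_cell_rk4(st, dt = Tseg / 256, n_steps = 256L)
  e <- sapply(c(8, 16), function(n)
    abs(step_cell_rk4(st, dt = Tseg / n, n_steps = n)[["V"]] - ref[["V"]]))
  order <- log2(e[1] / e[2])
  expect_gt(order, 3.5)
  expect_lt(order, 4.5)
})

test_that("one zero-input step leaves the settled state unchanged", {
  rest <- fx_rest()
  s2 <- step_cell_rk4(rest, dt = 1e-4, n_steps = 1L)
  expect_lt(abs(s2[["V"]] - rest[["V"]]), 1e-6)
  # quiescence over 500 ms
  s3 <- step_cell_rk4(rest, dt = 0.01, n_steps = 50000L)
  expect_lt(abs(s3[["V"]] - rest[["V"]]), 0.01)
})

test_that("a suprathreshold pulse elicits an action potential with overshoot", {
  tr <- simulate_cell(fx_rest(), duration = 30, dt = 1e-4,
                      I_applied = rep(c(-80, 0), c(10000, 290000)),
                      record_dt = 0.5)
  expect_gt(max(tr$V), 0)
  st <- attr(tr, "state")
  # gating variables stay within [0, 1] through the AP
  gates <- st[c("ato_f", "ito_f", "ato_s", "ito_s", "nKs", "aur", "iur",
                "aKss", "iKss")]
  expect_true(all(gates >= 0 & gates <= 1))
})

test_that("invalid states and steps are rejected with diagnostics", {
  rest <- fx_rest()
  bad <- rest
  bad[["Cai"]] <- NaN
  expect_error(ionic_currents(bad), "Cai")
  expect_error(step_cell_rk4(rest, dt = -1), "positive")
  # a wildly unstable step reports instability rather than returning NaN
  expect_error(step_cell_rk4(fx_upstroke(), dt = 5, n_steps = 50L),
               "unstable")
})

test_that("septal parameter variant differs in the transient-outward currents", {
  pa <- cell_params("apical")
  ps <- cell_params("septal")
  expect_lt(ps[["g_Kto_f"]], pa[["g_Kto_f"]])
  expect_gt(ps[["g_Kto_s"]], 0)
  expect_error(cell_params(g_bogus = 1), "unknown")
})
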