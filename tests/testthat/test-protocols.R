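# Illumination protocol machinery: pulse-train arithmetic, feedback trigger
# semantics, and termination detection.

test_that("open-loop pulse trains are exactly periodic with the right duty cycle", {
  tr <- pulse_train(fp = 12.5, width = 33, Ee_on = 20, t_start = 10)
  expect_equal(irradiance_at(10.001, tr), 20)
  expect_equal(irradiance_at(9.999, tr), 0)
  # onset spacing exactly 1000/fp = 80 ms
  onsets <- 10 + (0:9) * 80
  expect_true(all(irradiance_at(onsets + 1e-6, tr) == 20))
  expect_true(all(irradiance_at(onsets - 1e-6, tr)[-1] == 0 |
                  (onsets - 1e-6)[-1] %% 80 < 33))
  # duty cycle by integrating the on-indicator over whole periods
  tt <- seq(10, 10 + 80 * 10, by = 0.001)
  duty <- mean(irradiance_at(tt, tr) > 0)
  expect_equal(duty, 33 * 12.5 / 1000, tolerance = 1e-3)
  tr2 <- pulse_train(fp = 13.33, width = 33)
  tt2 <- seq(0, 1000 / 13.33 * 12, by = 0.001)
  expect_equal(mean(irradiance_at(tt2, tr2) > 0), 0.44, tolerance = 1e-2)
  # pulse cap
  tr3 <- pulse_train(fp = 12.5, width = 33, n_max = 2)
  expect_equal(irradiance_at(10 + 2 * 80 + 1, tr), 20)
  expect_equal(irradiance_at(2 * 80 + 1, tr3), 0)
})

test_that("a pulse width exceeding the period is rejected", {
  expect_error(pulse_train(fp = 40, width = 33), "exceeds")
  expect_error(pulse_train(fp = -1), "positive")
})

test_that("feedback controller fires once per upward crossing with hysteresis", {
  ctrl <- feedback_controller(c(1, 1), Vc = -40, width = 33, Ee_on = 20)
  # rising crossing fires at the crossing sample
  r <- feedback_update(ctrl, -80, 0)
  expect_equal(r$Ee, 0)
  r <- feedback_update(r$ctrl, -30, 1)
  expect_equal(r$Ee, 20)
  expect_equal(r$ctrl$pulses_fired, 1L)
  # oscillation above Vc without dipping below: no re-trigger
  for (tt in seq(2, 40, by = 1)) {
    v <- if (tt %% 2 == 0) -35 else -10
    r <- feedback_update(r$ctrl, v, tt)
  }
  expect_equal(r$ctrl$pulses_fired, 1L)
  # re-arm below Vc, then a new crossing fires again
  r <- feedback_update(r$ctrl, -60, 41)
  r <- feedback_update(r$ctrl, -20, 42)
  expect_equal(r$ctrl$pulses_fired, 2L)
  # monotone-time contract
  expect_error(feedback_update(r$ctrl, -60, 0), "non-decreasing")
})

test_that("no new pulse is queued while a pulse is active", {
  ctrl <- feedback_controller(c(1, 1), Vc = -40, width = 33)
  r <- feedback_update(ctrl, -20, 0)         # fires, active until 33
  r <- feedback_update(r$ctrl, -60, 5)       # re-armed
  r <- feedback_update(r$ctrl, -20, 6)       # crossing during active pulse
  expect_equal(r$ctrl$pulses_fired, 1L)      # single-pulse channel
  r <- feedback_update(r$ctrl, -60, 34)
  r <- feedback_update(r$ctrl, -20, 35)      # pulse has ended: fires
  expect_equal(r$ctrl$pulses_fired, 2L)
})

test_that("termination detection requires sustained dark quiescence", {
  fake <- function(vmax, Ee) {
    structure(list(trace = data.frame(t = seq(0, 300, by = 1),
                                      V1 = vmax, Ee = Ee, V_max = vmax)),
              class = "tissue_sim")
  }
  expect_true(detect_termination(fake(-82, 0)))
  expect_false(detect_termination(fake(25, 0)))          # active tissue
  expect_true(detect_termination(fake(-62, 20)))         # lit, depolarized rest
  expect_false(detect_termination(fake(-30, 20)))        # lit, still active
  # a brief quiet gap shorter than the window does not count
  vm <- rep(c(25, -82, 25), c(120, 60, 121))
  expect_false(detect_termination(
    structure(list(trace = data.frame(t = 0:300, V1 = vm, Ee = 0, V_max = vm)),
              class = "tissue_sim")))
  expect_error(detect_termination(fake(-82, 0)[["trace"]][1, ] |>
                 (\(d) structure(list(trace = d), class = "tissue_sim"))()),
               "trace too short|history")
})

test_that("sub-threshold global pulses do not excite resting tissue", {
  g <- tissue_grid(20, 20, state = fx_rest())
  sim <- simulate_tissue(g, 160, dt = 0.01,
                         protocol = pulse_train(13.33, width = 33, Ee_on = 20),
                         trace_dt = 0.5)
  expect_lt(max(sim$trace$V_max), -55)       # depolarized but never excited
  expect_gt(max(sim$trace$V_max), fx_rest()[["V"]] + 1)
  expect_gte(sim$pulses_fired, 2L)
  # pulse onsets in the event log are periodic to within one time step
  # (the log records the first step inside each pulse)
  on <- sim$events$t_on
  expect_lt(max(abs(diff(on) - 1000 / 13.33)), 0.01 + 1e-9)
})
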