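# Tip tracking, frequency estimation, meander classification and drift
# velocity, each validated on synthetic constructions with known answers.

test_that("tip tracker recovers a stationary phase singularity within a node", {
  mv <- make_spiral_movie(center_fn = function(t) c(0.75, 0.75))
  traj <- track_tip(mv$snapshots, mv$times, mv$dx)
  expect_gt(nrow(traj), 10)
  err <- sqrt((traj$x - 0.75)^2 + (traj$y - 0.75)^2)
  expect_lt(sqrt(mean(err^2)), mv$dx)
})

test_that("tip tracker follows a drifting singularity with sub-node RMS error", {
  path <- function(t) c(0.6 + 0.004 * t, 0.7 + 0.002 * t)
  mv <- make_spiral_movie(times = seq(0, 50, by = 2), center_fn = path)
  traj <- track_tip(mv$snapshots, mv$times, mv$dx)
  truth <- t(vapply(traj$t, path, numeric(2)))
  err <- sqrt((traj$x - truth[, 1])^2 + (traj$y - truth[, 2])^2)
  expect_lt(sqrt(mean(err^2)), mv$dx)
})

test_that("a plane-wave movie yields an empty trajectory", {
  mv <- make_plane_movie()
  traj <- track_tip(mv$snapshots, mv$times, mv$dx)
  expect_equal(nrow(traj), 0)
})

test_that("upstroke-interval frequency estimation is exact on spike trains", {
  sp <- make_spike_train(15.6)
  est <- estimate_frequency(sp$t, sp$V)
  expect_equal(est$f, 15.6, tolerance = 0.05 / 15.6)
  # spectral cross-check agrees within 0.2 Hz
  est2 <- estimate_frequency(sp$t, sp$V, method = "spectral")
  expect_lt(abs(est2$f - est$f), 0.2)
  # insufficient upstrokes is an error
  short <- make_spike_train(15.6, duration = 100)
  expect_error(estimate_frequency(short$t[short$t < 70], short$V[short$t < 70]),
               "insufficient|upstrokes")
})

test_that("meander classifier labels analytic flower curves by petal direction", {
  out <- classify_meander(make_flower_traj(+1), period = 75)
  expect_equal(out$label, "hypocycloid_outward")
  expect_gt(out$radial_excursion, 0)
  inw <- classify_meander(make_flower_traj(-1), period = 75)
  expect_equal(inw$label, "epicycloid_inward")
  expect_lt(inw$radial_excursion, 0)
})

test_that("meander classifier recognizes linear drift and closed circles", {
  dr <- classify_meander(make_drift_traj(v = c(2e-3, 1e-3)), period = 70)
  expect_equal(dr$label, "linear_drift")
  expect_false(is.null(dr$drift))
  ci <- classify_meander(make_circle_traj(), period = 66)
  expect_equal(ci$label, "circular")
  expect_error(classify_meander(make_circle_traj(n_cycles = 2), period = 66),
               "3")
})

test_that("drift velocity is recovered within 2% on a known drifting circle", {
  v <- c(2e-3, 1e-3)                       # cm/ms
  est <- drift_velocity(make_drift_traj(v = v), period = 70)
  expect_equal(est$speed, sqrt(sum(v^2)) * 1000, tolerance = 0.02)
  expect_equal(atan2(est$direction[2], est$direction[1]),
               atan2(v[2], v[1]), tolerance = 0.02)
  # stationary circle: near-zero speed, undefined direction flagged
  expect_warning(st <- drift_velocity(make_circle_traj(), period = 66),
                 "undefined|not classified")
  expect_lt(st$speed, 0.05)
})
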