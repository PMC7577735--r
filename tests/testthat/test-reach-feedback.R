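test_that("acceleration-dependent cursor transformation", {
  # constant angle or zero gain leave the cursor on the elbow
  flat <- rep(62, 3000)
  expect_equal(accelerationFeedback(flat, 0.01), flat)
  wav <- 55 + 30 * sin(2 * pi * 1.3 * (0:2999) / 1000)
  expect_equal(accelerationFeedback(wav, 0), wav)
  # sinusoid: filtered-acceleration amplitude matches the closed-form
  # second-difference x moving-average frequency response
  f0 <- 1.3; dt <- 1e-3; W <- 100; ka <- 0.01
  cur <- accelerationFeedback(wav, ka, window = W)
  steady <- 1001:3000
  amp <- (max(cur[steady] - wav[steady]) - min(cur[steady] - wav[steady])) / 2
  w <- 2 * pi * f0
  gain_sd <- 4 * sin(w * dt / 2)^2 / dt^2      # causal second difference
  gain_ma <- abs(sin(W * w * dt / 2) / (W * sin(w * dt / 2)))
  expect_equal(amp, ka * 30 * gain_sd * gain_ma, tolerance = 1e-3)
  expect_warning(accelerationFeedback(rep(1, 50), 0.01), "padding")
})

test_that("trailing moving average has a 49.5 ms group delay at 1 kHz", {
  expect_equal(movingAverageGroupDelay(100, 1000), 49.5, tolerance = 1e-9)
  expect_equal(movingAverageGroupDelay(50, 1000), 24.5, tolerance = 1e-9)
})

test_that("angle of first correction: ideal, dysmetric and degenerate cases", {
  # ideal minimum-jerk reach stops exactly at the 30-degree goal
  matched <- reacherParams()
  expect_equal(angleOfFirstCorrection(simulateReach(matched, 0)), 30,
               tolerance = 1e-9)
  # overshooting reacher: value matches a brute-force scan for the first
  # velocity sign change after initiation
  hyper <- reacherParams(internal_inertia = 0.11 * 1.2)
  tr <- simulateReach(hyper, 0)
  fc <- angleOfFirstCorrection(tr)
  expect_gt(fc, 30)
  v <- tr$velocity
  init <- which(v > 0.05 * max(v))[1]
  idx <- init + which(v[(init + 1):length(v)] <= 0)[1]
  expect_equal(fc, tr$elbow[idx] - tr$start_angle)
  # monotone half-reach with no stop is rejected
  half <- list(time = (0:999) / 1000, elbow = 55 + (0:999) * 0.02,
               velocity = rep(20, 1000), start_angle = 55, goal_angle = 85)
  expect_error(angleOfFirstCorrection(half), "incomplete")
})

test_that("reach classification thresholds and scale consistency", {
  expect_equal(classifyReach(30)$label, "on_target")
  expect_equal(classifyReach(31.5)$label, "hypermetric") # ratio 1.05
  expect_equal(classifyReach(28.5)$label, "hypometric")  # ratio 0.95
  expect_equal(classifyReach(30.8)$label, "on_target")
  expect_equal(classifyReach(63, 60)$label,
               classifyReach(31.5, 30)$label)
  expect_error(classifyReach(30, 0), "> 0")
})

test_that("inertial mismatch direction fixes the dysmetria class", {
  hyper <- simulateReach(reacherParams(internal_inertia = 0.11 * 1.2), 0)
  hypo <- simulateReach(reacherParams(internal_inertia = 0.11 * 0.8), 0)
  expect_equal(classifyReach(angleOfFirstCorrection(hyper))$label,
               "hypermetric")
  expect_equal(classifyReach(angleOfFirstCorrection(hypo))$label,
               "hypometric")
})

test_that("block mode majority and tie rules", {
  expect_equal(blockMode(c(rep("hypermetric", 6), rep("on_target", 4))),
               "hypermetric")
  expect_equal(blockMode(rep("on_target", 10)), "on_target")
  expect_equal(blockMode(c(rep("on_target", 5), rep("hypermetric", 5))),
               "on_target")
  tied <- c(rep("hypometric", 5), rep("hypermetric", 5))
  expect_equal(blockMode(tied, previous_direction = -1L), "hypermetric")
  expect_equal(blockMode(tied, previous_direction = 1L), "hypometric")
  expect_equal(blockMode(tied), "on_target")
})

test_that("PEST step rules follow the staircase trace", {
  st <- pestInit()
  # first hypermetric block at ka = 0 steps down by the initial 0.01
  st <- pestStep(st, "hypermetric")
  expect_equal(st$current_ka, -0.01)
  # second step same direction keeps the step size
  st <- pestStep(st, "hypermetric")
  expect_equal(st$current_ka, -0.02)
  expect_equal(st$step_size, 0.01)
  # reversal halves the step: -0.02 + 0.005
  st <- pestStep(st, "hypometric")
  expect_equal(st$step_size, 0.005)
  expect_equal(st$current_ka, -0.015)
  # clamping at +/- 0.02
  st2 <- pestInit(initial_ka = 0.02)
  st2 <- pestStep(st2, "hypometric")
  expect_equal(st2$current_ka, 0.02)
  # two consecutive on-target blocks at the same gain terminate
  st3 <- pestInit()
  st3 <- pestStep(st3, "on_target")
  expect_false(st3$terminated)
  st3 <- pestStep(st3, "on_target")
  expect_true(st3$terminated)
  expect_equal(st3$best_ka, 0)
  expect_error(pestStep(st3, "on_target"), "terminated")
})

test_that("step size bounds and doubling exception are respected", {
  st <- pestInit(initial_step = 0.0035)
  st <- pestStep(st, "hypermetric")
  st <- pestStep(st, "hypometric") # reversal: would halve below the minimum
  expect_equal(st$step_size, 0.0035)
  # third same-direction step doubles (no doubling before last reversal),
  # capped at the maximum step
  st4 <- pestInit(initial_step = 0.008)
  st4 <- pestStep(st4, "hypermetric")
  st4 <- pestStep(st4, "hypermetric")
  expect_equal(st4$step_size, 0.008)
  st4 <- pestStep(st4, "hypermetric")
  expect_equal(st4$step_size, 0.01) # doubled then clipped to the max
})

test_that("PEST converges with the correct sign on simulated reachers", {
  rs <- referenceReachers()
  p_hyper <- runPest(rs$hypermetric, seed = 1L)
  p_hypo <- runPest(rs$hypometric, seed = 2L)
  p_match <- runPest(rs$matched, seed = 3L)
  expect_lt(p_hyper$best_ka, 0)
  expect_gt(p_hypo$best_ka, 0)
  expect_equal(p_match$best_ka, 0)
  expect_equal(p_match$termination_reason, "converged")
  expect_equal(nrow(p_match$history), 2L)
  # bounds hold at every visited block
  for (p in list(p_hyper, p_hypo, p_match)) {
    expect_true(all(abs(p$history$ka) <= 0.02 + 1e-12))
    steps <- vapply(p$state$history, `[[`, numeric(1), "step_size")
    expect_true(all(steps >= 0.0035 - 1e-12 & steps <= 0.01 + 1e-12))
  }
})

test_that("nine-gain sweep is monotone in the dose-response curve", {
  gains <- c(0, 0.005, 0.010, 0.015, 0.020, -0.005, -0.010, -0.015, -0.020)
  # the dose-response itself, free of sampling noise between close medians
  for (ratio in c(1, 1.05, 0.95)) {
    sw <- fixedGainSweep(reacherParams(internal_inertia = 0.11 * ratio),
                         seed = 7L)
    expect_equal(sw$ka, gains)
    o <- order(sw$ka)
    expect_true(all(diff(sw$median_first_correction[o]) >= -1e-9))
  }
  # with motor noise the trend survives end to end
  swn <- fixedGainSweep(referenceReachers()$hypermetric, seed = 7L)
  expect_gt(swn$median_first_correction[swn$ka == 0.02],
            swn$median_first_correction[swn$ka == -0.02])
  # all-zero gain blocks on a noiseless reacher reproduce one median
  sw0 <- fixedGainSweep(reacherParams(), gains = c(0, 0, 0), seed = 7L)
  expect_equal(sw0$median_first_correction, rep(30, 3), tolerance = 1e-9)
})
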