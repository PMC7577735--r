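truth <- referenceParams()
best4 <- referenceStructures()$best4_lowest_err

test_that("model frequency response limits and hand-computed values", {
  f <- default_freqs
  m <- modelFR(truth, f)
  # independent complex-arithmetic evaluation, written out long-hand
  w <- 2 * pi * f
  Lp <- truth[1] / (1i * w)
  hp <- truth[3] * exp(-1i * w * truth[5]) * Lp /
    (1 + exp(-1i * w * truth[7]) * Lp)
  expect_equal(m$patient, hp, tolerance = 1e-12)
  # omega -> 0 with no delays: H -> G
  p0 <- c(2, 2, 0.6, 0.6, 0, 0, 0, 0)
  expect_equal(Mod(modelFR(p0, 1e-6)$control), 0.6, tolerance = 1e-4)
  # open-loop degenerate: |H| = G k / omega
  ol <- modelFR(c(3, 3, 0.5, 0.5, 0.1, 0.1, 0, 0), 0.25,
                variant = "open_loop")
  expect_equal(Mod(ol$patient), 0.5 * 3 / (2 * pi * 0.25), tolerance = 1e-12)
  expect_error(modelFR(truth, c(0.1, 0)), "> 0")
})

test_that("frequency-domain error: zeros, units and loop-sum oracle", {
  f <- default_freqs
  m <- modelFR(truth, f)
  expect_equal(fdError(truth, m$patient, m$control, f), 0)
  # zero model vs unit-gain data: 15 per cohort, 30 total
  ones <- rep(1 + 0i, 15)
  zero_params <- c(1, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(fdError(zero_params, ones, ones, f, variant = "pure_gain"), 30)
  # naive loop-summation oracle on random phasors
  set.seed(9)
  dp <- complex(real = rnorm(15), imaginary = rnorm(15))
  dc <- complex(real = rnorm(15), imaginary = rnorm(15))
  acc <- 0
  for (i in 1:15) {
    acc <- acc + Mod(dc[i] - m$control[i])^2 + Mod(dp[i] - m$patient[i])^2
  }
  expect_equal(fdError(truth, dp, dc, f), acc, tolerance = 1e-12)
  expect_error(fdError(truth, dp[1:3], dc, f), "mismatched")
})

test_that("noiseless fits recover generating parameters exactly", {
  f <- default_freqs
  m <- modelFR(truth, f)
  fit <- fitStructure(best4, m$patient, m$control, f, n_restarts = 20,
                      seed = 1L)
  expect_lt(fit$fd_error, 1e-8)
  expect_equal(unname(fit$params), unname(truth), tolerance = 0.01)
  # more restarts can only improve the best value; same seed reproduces
  f1 <- fitStructure(best4, m$patient, m$control, f, n_restarts = 1, seed = 2L)
  expect_lte(fit$fd_error, f1$fd_error)
  f2 <- fitStructure(best4, m$patient, m$control, f, n_restarts = 5, seed = 3L)
  f3 <- fitStructure(best4, m$patient, m$control, f, n_restarts = 5, seed = 3L)
  expect_identical(f2$params, f3$params)
})

test_that("free-parameter monotonicity of the in-sample fit", {
  cohort <- simulateCohortFR(truth, default_freqs, n_pairs = 4,
                             noise_sd = 0.05, seed = 5L)
  avg <- crossloop:::cohortMeanFR(cohort)
  err_of <- function(st) fitStructure(st, avg$patient, avg$control,
                                      default_freqs, n_restarts = 15,
                                      seed = 4L)$fd_error
  rs <- referenceStructures()
  # best4 is nested in best5 (lowest err) which is nested in the full model
  e4 <- err_of(rs$best4_lowest_err)
  e5 <- err_of(rs$best5_lowest_err)
  e8 <- err_of(rs$full_8)
  expect_lte(e5, e4 + 1e-8)
  expect_lte(e8, e5 + 1e-8)
})

test_that("leave-one-out evaluation shapes, exchangeability and noise", {
  f <- default_freqs
  # identical noiseless pairs: loo error equals the in-sample error per fold
  m <- modelFR(truth, f)
  flat <- lapply(1:4, function(i) list(patient = m$patient,
                                       control = m$control))
  attr(flat, "frequencies") <- f
  loo0 <- looEvaluate(best4, flat, n_restarts = 10, seed = 1L)
  expect_lt(loo0$loo_mean, 1e-8)
  expect_equal(dim(loo0$param_sets), c(4L, 8L))
  expect_lt(consistency(loo0$param_sets), 1e-3)
  # eleven pairs -> eleven folds and an 11 x 8 parameter matrix
  cohort <- simulateCohortFR(truth, f, n_pairs = 11, noise_sd = 0.05,
                             seed = 2L)
  loo <- looEvaluate(best4, cohort, n_restarts = 10, seed = 1L)
  expect_length(loo$loo_errors, 11L)
  expect_equal(dim(loo$param_sets), c(11L, 8L))
  # more phasor noise -> larger mean loo error (fixed seeds)
  noisier <- simulateCohortFR(truth, f, n_pairs = 11, noise_sd = 0.15,
                              seed = 2L)
  loo_n <- looEvaluate(best4, noisier, n_restarts = 10, seed = 1L)
  expect_gt(loo_n$loo_mean, loo$loo_mean)
  expect_error(looEvaluate(best4, flat[1:2], n_restarts = 2), "3 pairs")
})

test_that("consistency is the max singular value of the residual matrix", {
  m0 <- matrix(rep(c(1, 2, 3, 4, 5, 6, 7, 8), each = 5), nrow = 5)
  expect_equal(consistency(m0), 0)
  m1 <- rbind(rep(0, 8), c(2, rep(0, 7)))
  expect_equal(consistency(m1), sqrt(2)) # residuals +-1 in one column
  set.seed(1)
  mr <- matrix(rnorm(40), 5, 8)
  expect_equal(consistency(mr), consistency(mr[sample(5), ]))
  expect_error(consistency(mr[1, , drop = FALSE]), "at least 2")
})

test_that("structure enumeration is complete and canonical", {
  all_st <- enumerateStructures()
  closed <- Filter(function(s) s$variant == "closed_loop", all_st)
  expect_length(closed, 780L) # 15 gain partitions x 52 delay/zero patterns
  nf <- vapply(closed, `[[`, numeric(1), "n_free")
  expect_equal(max(nf), 8)
  expect_equal(sum(nf == 8), 1L) # the fully free model is unique
  # the reference reduced structure is a member of the enumeration
  expect_true(best4$key %in% names(closed))
  # all-delays-zeroed reduces to the delay-free loop
  df <- modelStructure(c(1, 1, 2, 2), c(1, 1, 1, 1), rep(TRUE, 4))
  expect_true(df$key %in% names(closed))
  expect_equal(df$n_free, 2)
  # degenerates appended under their own keys
  expect_true(any(vapply(all_st, function(s) s$variant == "pure_gain",
                         logical(1))))
})

test_that("zeroing must cover whole delay classes", {
  expect_error(modelStructure(c(1, 1, 2, 2), c(1, 1, 2, 2),
                              c(TRUE, FALSE, FALSE, FALSE)),
               "whole delay classes")
})

test_that("Pareto selection keeps non-dominated reports only", {
  mk <- function(name, nf, loo, con) {
    st <- best4; st$name <- name; st$n_free <- nf
    list(structure = st, loo_mean = loo, consistency = con)
  }
  one <- selectModels(list(mk("a", 4, 1, 1)))
  expect_true(one$on_front)
  r <- selectModels(list(mk("a", 4, 1, 2), mk("b", 4, 2, 1),
                         mk("dominated", 5, 3, 3), mk("c", 6, 0.5, 4)))
  expect_equal(sort(r$name[r$on_front]), c("a", "b", "c"))
  expect_false(r$on_front[r$name == "dominated"])
  expect_match(r$label[r$name == "a"], "lowest error")
  expect_match(r$label[r$name == "b"], "lowest variance")
})

test_that("bootstrap intervals are seeded, degenerate at zero noise, and widen", {
  f <- default_freqs
  m <- modelFR(truth, f)
  flat <- lapply(1:5, function(i) list(patient = m$patient,
                                       control = m$control))
  attr(flat, "frequencies") <- f
  b0 <- bootstrapCI(best4, flat, B = 8, n_restarts = 8, seed = 1L)
  expect_lt(max(b0$ci[, 2] - b0$ci[, 1]), 1e-3) # zero-width at zero noise
  lo <- simulateCohortFR(truth, f, n_pairs = 6, noise_sd = 0.03, seed = 3L)
  hi <- simulateCohortFR(truth, f, n_pairs = 6, noise_sd = 0.3, seed = 3L)
  b_lo <- bootstrapCI(best4, lo, B = 12, n_restarts = 8, seed = 2L)
  b_hi <- bootstrapCI(best4, hi, B = 12, n_restarts = 8, seed = 2L)
  expect_gt(mean(b_hi$ci[1:4, 2] - b_hi$ci[1:4, 1]),
            mean(b_lo$ci[1:4, 2] - b_lo$ci[1:4, 1]))
  b_rep <- bootstrapCI(best4, lo, B = 12, n_restarts = 8, seed = 2L)
  expect_identical(b_lo$ci, b_rep$ci)
})

test_that("time-domain simulation validates the fitted model", {
  spec <- default_spec
  traj <- generateSumOfSines(spec)
  pred <- simulateModelTD(truth, traj)
  # exact self-consistency: observation = prediction
  expect_equal(tdError(pred$patient, pred$patient, pred$control,
                       pred$control), 0)
  # constant 1-degree offset contributes 1 deg^2 per cohort term
  off_p <- pred$patient + 1
  expect_equal(tdError(pred$patient, off_p, pred$control, pred$control), 1,
               tolerance = 1e-12)
  # simulated subjects at the same totals: TD error near the noise floor
  subj_p <- subjectParams(k = truth[1], visual_gain = truth[3],
                          visual_delay = truth[5], feedback_delay = truth[7],
                          group_label = "patient")
  subj_c <- subjectParams(k = truth[2], visual_gain = truth[4],
                          visual_delay = truth[6], feedback_delay = truth[8])
  loop0 <- loopConfig(display_delay = 0)
  obs_p <- simulateTracking(subj_p, traj, loop0)[[1]]$elbow
  obs_c <- simulateTracking(subj_c, traj, loop0)[[1]]$elbow
  expect_lt(tdError(pred$patient, obs_p, pred$control, obs_c), 1e-10)
  expect_error(tdError(pred$patient[-1], obs_p, pred$control, obs_c),
               "mismatch")
})

test_that("gain-condition fits move k down and visual gain up at 1.35", {
  # a subject that compensates partially (scaling factor ~1.2) under an
  # applied 1.35 feedback gain behaves as k -> k/1.35, G -> G * 1.35 / 1.2
  f <- default_freqs
  cond <- truth
  cond[1:2] <- truth[1:2] / 1.35
  cond[3:4] <- truth[3:4] * 1.35 / 1.2
  data_cond <- modelFR(cond, f, applied_gain = 1.35)
  fit <- fitStructure(best4, data_cond$patient, data_cond$control, f,
                      n_restarts = 20, seed = 6L, applied_gain = 1.35)
  expect_lt(fit$params[1], truth[1])       # k decreases
  expect_gt(fit$params[3], truth[3])       # visual gain increases
  expect_equal(unname(fit$params[5:8]), unname(truth[5:8]),
               tolerance = 0.01)           # delays unchanged
})
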