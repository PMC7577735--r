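#' Reaching-subject parameters
#'
#' A single-joint (elbow) reacher executing discrete 30-degree flexion
#' movements.  The primary movement is a minimum-jerk plan whose executed
#' acceleration is scaled by the internal-model inertia ratio
#' \eqn{\hat J / J}: over-estimated inertia (\eqn{\hat J / J > 1}) commands
#' too much torque and overshoots (hypermetria), under-estimation stops
#' short (hypometria).  During the deceleration (homing) phase the subject
#' regulates the remaining movement amplitude online from delayed visual
#' feedback of the displayed cursor; corrections after the primary movement
#' ends belong to subsequent submovements and do not move the angle of
#' first correction.  Angles are in degrees throughout.
#'
#' @param inertia True limb (plus robot) inertia J, kg m^2.
#' @param internal_inertia Controller's internal inertia estimate
#'   \eqn{\hat J}, kg m^2.
#' @param correction_gain Rate gain (1/s) of the online amplitude
#'   regulation: commanded extent integrates the perceived cursor shortfall
#'   relative to the intended trajectory during the deceleration phase.
#' @param visual_delay Delay of the corrective pathway, seconds.
#' @param movement_time Duration of the minimum-jerk plan, s.
#' @param start_angle,goal_angle Home and stepped target elbow angles,
#'   degrees (defaults 55 and 85: a 30-degree flexion).
#' @param motor_noise_sd SD of white noise on the executed angular
#'   acceleration, deg/s^2.
#' @return An object of class \code{reacher_params}.
#' @export
reacherParams <- function(inertia = 0.11, internal_inertia = 0.11,
                          correction_gain = 4, visual_delay = 0.15,
                          movement_time = 0.7,
                          start_angle = 55, goal_angle = 85,
                          motor_noise_sd = 0) {
  if (inertia <= 0 || internal_inertia <= 0)
    stop("inertia and internal_inertia must be > 0")
  if (!is.finite(internal_inertia / inertia))
    stop("mismatch ratio must be finite")
  out <- list(inertia = inertia, internal_inertia = internal_inertia,
              correction_gain = correction_gain,
              visual_delay = visual_delay, movement_time = movement_time,
              start_angle = start_angle, goal_angle = goal_angle,
              motor_noise_sd = motor_noise_sd)
  class(out) <- "reacher_params"
  out
}

minJerk <- function(t, D, x0, x1) {
  s <- pmin(pmax(t / D, 0), 1)
  pos <- x0 + (x1 - x0) * (10 * s^3 - 15 * s^4 + 6 * s^5)
  vel <- (x1 - x0) / D * (30 * s^2 - 60 * s^3 + 30 * s^4)
  acc <- (x1 - x0) / D^2 * (60 * s - 180 * s^2 + 120 * s^3)
  list(pos = pos, vel = vel, acc = acc, s = s)
}

#' Acceleration-dependent cursor transformation
#'
#' Implements the altered visual feedback: the cursor is shown at
#' \code{elbow + ka * a_hat}, where \code{a_hat} is a causal estimate of the
#' angular acceleration --- the second difference of the elbow angle passed
#' through a trailing moving average of the previous \code{window} samples
#' (the real-time estimator; its group delay is \code{(window - 1) / 2}
#' samples, i.e. 49.5 ms at 1 kHz with the default window).  Samples before
#' the start of the series are treated as zero acceleration (at-rest
#' padding).
#'
#' @param elbow Elbow-angle series, degrees, sampled at \code{sample_rate}.
#' @param ka Acceleration-dependent feedback gain, s^2.
#' @param window Moving-average window in samples (default 100).
#' @param sample_rate Hz (default 1000).
#' @return Numeric cursor series of the same length.
#' @export
accelerationFeedback <- function(elbow, ka, window = 100,
                                 sample_rate = 1000) {
  if (window < 1) stop("window must be >= 1")
  n <- length(elbow)
  if (n < window)
    warning("series shorter than the averaging window; at-rest padding used")
  dt <- 1 / sample_rate
  acc <- c(0, 0, diff(elbow, differences = 2)) / dt^2
  cs <- cumsum(c(rep(0, window), acc))
  ma <- (cs[(window + 1):(window + n)] - cs[1:n]) / window
  elbow + ka * ma
}

#' Group delay of the trailing moving-average filter
#'
#' Measured numerically from the slope of the filter's phase response; for
#' a W-sample trailing average this is \eqn{(W - 1)/2} samples.
#'
#' @param window Window length in samples.
#' @param sample_rate Hz.
#' @return Group delay in milliseconds.
#' @export
movingAverageGroupDelay <- function(window = 100, sample_rate = 1000) {
  dt <- 1 / sample_rate
  resp <- function(f) {
    w <- 2 * pi * f
    sum(exp(-1i * w * (0:(window - 1)) * dt)) / window
  }
  f1 <- 0.1; f2 <- 0.2
  dphi <- Arg(resp(f2)) - Arg(resp(f1))
  -dphi / (2 * pi * (f2 - f1)) * 1000
}

#' Simulate one discrete reach under acceleration-dependent feedback
#'
#' Kinematic simulation at 1 kHz.  The executed primary movement is the
#' minimum-jerk plan with its acceleration (hence extent) scaled by the
#' internal-model mismatch \eqn{\hat J / J}, plus integrated white motor
#' noise.  The displayed cursor is computed online from the elbow angle via
#' [accelerationFeedback()].  During the deceleration phase the subject
#' integrates the delayed shortfall between its intended cursor trajectory
#' and the displayed cursor into the commanded extent (gain
#' \code{correction_gain}); the extent freezes when the primary movement
#' ends, so the angle of first correction reflects only within-movement
#' corrections.  Because the cursor lags behind the elbow during
#' deceleration when \code{ka > 0} (the estimated acceleration is
#' negative), positive gains drive the reach further (hypermetria) and
#' negative gains shorten it, monotonically in \code{ka}.
#'
#' @param reacher A \code{reacher_params}.
#' @param ka Acceleration-dependent feedback gain, s^2; must satisfy
#'   |ka| <= \code{ka_limit} unless overridden.
#' @param duration Simulated time, s (default 2).
#' @param sample_rate Hz (default 1000).
#' @param seed Integer seed for motor noise (ignored when noise sd is 0).
#' @param ka_limit Clamp on |ka| (default 0.02).
#' @param window Acceleration-filter window, samples.
#' @return A \code{reach_trial}: \code{time}, \code{elbow},
#'   \code{velocity}, \code{acceleration_estimate}, \code{cursor},
#'   \code{ka}, \code{start_angle}, \code{goal_angle},
#'   \code{goal_excursion}.
#' @export
simulateReach <- function(reacher, ka = 0, duration = 2, sample_rate = 1000,
                          seed = 1L, ka_limit = 0.02, window = 100) {
  if (abs(ka) > ka_limit + 1e-12)
    stop("|ka| exceeds the clamp ", ka_limit)
  dt <- 1 / sample_rate
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) * dt
  D <- reacher$movement_time
  A0 <- abs(reacher$goal_angle - reacher$start_angle)
  dir <- sign(reacher$goal_angle - reacher$start_angle)
  plan <- minJerk(t, D, 0, 1) # unit-excursion shape and phase variable
  r <- reacher$internal_inertia / reacher$inertia
  dl <- delaySamples(reacher$visual_delay, sample_rate)
  gam <- reacher$correction_gain
  nacc <- if (reacher$motor_noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(n, 0, reacher$motor_noise_sd))
  } else numeric(n)
  theta <- numeric(n); vel <- numeric(n)
  cursor <- numeric(n); acc_est <- numeric(n)
  A <- A0
  nv <- 0; np <- 0 # integrated motor noise (velocity, position)
  accbuf <- numeric(window); bufsum <- 0; bufpos <- 1L
  i_end <- which(t >= D)[1]
  if (is.na(i_end)) i_end <- n
  moved <- FALSE; stopped <- FALSE
  for (i in seq_len(n)) {
    theta[i] <- reacher$start_angle + dir * r * A * plan$pos[i] + np
    vel[i] <- if (i > 1) (theta[i] - theta[i - 1]) / dt else 0
    dv <- dir * vel[i]
    if (!moved && dv > 10) moved <- TRUE
    if (moved && !stopped && dv <= 0) stopped <- TRUE
    a_raw <- if (i >= 3) (theta[i] - 2 * theta[i - 1] + theta[i - 2]) / dt^2
             else 0
    bufsum <- bufsum - accbuf[bufpos] + a_raw
    accbuf[bufpos] <- a_raw
    bufpos <- if (bufpos == window) 1L else bufpos + 1L
    acc_est[i] <- bufsum / window
    cursor[i] <- theta[i] + ka * acc_est[i]
    id <- i - dl
    # online amplitude regulation: the subject corrects the discrepancy
    # between the displayed cursor and the forward-model prediction of the
    # arm (the prediction shares the miscalibrated internal model, so the
    # inertial mismatch itself is invisible to this in-flight process).
    # Active from the deceleration phase of the (delayed) view until the
    # delayed view of the completed movement has arrived, or until the arm
    # has come to rest -- later corrections are separate submovements and
    # do not move the first correction
    if (!stopped && i < i_end + dl && id >= 1 && plan$s[id] >= 0.5) {
      A <- max(A + dt * gam * dir * (theta[id] - cursor[id]), 0)
    }
    # mean-reverting velocity noise: intrinsic damping returns the limb to
    # rest, so noisy reaches still terminate in a genuine stop
    nv <- nv * (1 - dt / 0.1) + dt * nacc[i]
    np <- np + dt * nv
  }
  out <- list(time = t, elbow = theta, velocity = vel,
              acceleration_estimate = acc_est, cursor = cursor, ka = ka,
              start_angle = reacher$start_angle,
              goal_angle = reacher$goal_angle,
              goal_excursion = A0)
  class(out) <- "reach_trial"
  out
}

#' @export
print.reach_trial <- function(x, ...) {
  cat("Reach trial: ", x$start_angle, " -> ", x$goal_angle, " deg, ka = ",
      x$ka, ", ", length(x$time), " samples\n", sep = "")
  invisible(x)
}

#' Elbow excursion at the first correction
#'
#' Finds reach initiation (first sample whose goal-directed velocity exceeds
#' \code{init_frac} of the peak) and returns the elbow excursion, relative
#' to the start angle, at the first subsequent sample where the velocity
#' falls to zero or below — the point where the subject first corrects.
#'
#' @param trial A \code{reach_trial} (or any list with \code{elbow},
#'   \code{velocity}, \code{start_angle}, \code{goal_angle}).
#' @param init_frac Initiation threshold as a fraction of peak speed.
#' @return Excursion in degrees (positive toward the goal).
#' @export
angleOfFirstCorrection <- function(trial, init_frac = 0.05) {
  dir <- sign(trial$goal_angle - trial$start_angle)
  v <- dir * trial$velocity
  pk <- max(v)
  if (pk <= 0) stop("no goal-directed movement in the trial")
  init <- which(v > init_frac * pk)[1]
  after <- which(v[(init + 1):length(v)] <= 0)
  if (!length(after)) stop("incomplete reach: velocity never returns to zero")
  idx <- init + after[1]
  dir * (trial$elbow[idx] - trial$start_angle)
}

#' Classify a reach as hypometric, on target, or hypermetric
#'
#' The ratio of first-correction excursion to the goal excursion is compared
#' against the on-target band [0.97, 1.03].
#'
#' @param first_correction Excursion at first correction, degrees.
#' @param goal_excursion Goal excursion, degrees (default 30).
#' @param thresholds Lower/upper on-target bounds.
#' @return List with \code{ratio} and \code{label}.
#' @export
classifyReach <- function(first_correction, goal_excursion = 30,
                          thresholds = c(0.97, 1.03)) {
  if (goal_excursion <= 0) stop("goal_excursion must be > 0")
  ratio <- first_correction / goal_excursion
  label <- if (ratio > thresholds[2]) "hypermetric"
  else if (ratio < thresholds[1]) "hypometric"
  else "on_target"
  list(ratio = ratio, label = label)
}

#' Modal classification of a block of reaches
#'
#' Ties involving the on-target class resolve to on_target; a
#' hypometric/hypermetric tie falls back to the previous block's step
#' direction when available, else to on_target.
#'
#' @param labels Character vector of reach labels.
#' @param previous_direction Optional: -1 (was decreasing), +1 (increasing)
#'   or 0/NULL.
#' @return One of "hypometric", "on_target", "hypermetric".
#' @export
blockMode <- function(labels, previous_direction = NULL) {
  lv <- c("hypometric", "on_target", "hypermetric")
  counts <- table(factor(labels, levels = lv))
  top <- lv[counts == max(counts)]
  if (length(top) == 1) return(top)
  if ("on_target" %in% top) return("on_target")
  if (!is.null(previous_direction) && length(previous_direction) &&
      previous_direction != 0)
    return(if (previous_direction > 0) "hypometric" else "hypermetric")
  "on_target"
}

#' Initialise a PEST search state
#'
#' @param initial_ka Starting gain (default 0, veridical).
#' @param initial_step Initial step size, s^2 (default 0.01).
#' @param step_min,step_max Step-size bounds (defaults 0.0035, 0.01).
#' @param ka_max Clamp on |ka| (default 0.02).
#' @return An object of class \code{pest_state}.
#' @export
pestInit <- function(initial_ka = 0, initial_step = 0.01,
                     step_min = 0.0035, step_max = 0.01, ka_max = 0.02) {
  out <- list(current_ka = initial_ka, step_size = initial_step,
              step_min = step_min, step_max = step_max, ka_max = ka_max,
              last_direction = 0L, run_length = 0L,
              last_was_double = FALSE, double_before_reversal = FALSE,
              on_target_streak = 0L, terminated = FALSE,
              termination_reason = NULL, best_ka = NA_real_,
              history = list())
  class(out) <- "pest_state"
  out
}

#' One PEST update from a block mode
#'
#' Applies the sequential-testing step rules: a hypermetric block decreases
#' the gain, a hypometric block increases it, an on-target block leaves it
#' unchanged.  Step sizing follows the classic staircase rules: halve on
#' every reversal; the second step in a direction repeats the first; the
#' fourth and later same-direction steps double; the third doubles unless
#' the step immediately preceding the last reversal was itself a doubling.
#' Steps are clipped to [\code{step_min}, \code{step_max}] and the gain to
#' [-\code{ka_max}, \code{ka_max}].  Two consecutive on-target blocks at the
#' same gain terminate the search with \code{best_ka} set to that gain.
#'
#' @param state A \code{pest_state} (not terminated).
#' @param mode Block mode: "hypometric", "on_target" or "hypermetric".
#' @return The updated \code{pest_state}.
#' @export
pestStep <- function(state, mode) {
  if (state$terminated) stop("PEST state is terminated")
  mode <- match.arg(mode, c("hypometric", "on_target", "hypermetric"))
  state$history[[length(state$history) + 1L]] <-
    list(ka = state$current_ka, mode = mode, step_size = state$step_size)
  if (mode == "on_target") {
    state$on_target_streak <- state$on_target_streak + 1L
    if (state$on_target_streak >= 2L) {
      state$terminated <- TRUE
      state$termination_reason <- "converged"
      state$best_ka <- state$current_ka
    }
    return(state)
  }
  state$on_target_streak <- 0L
  dir <- if (mode == "hypometric") 1L else -1L
  if (state$last_direction == 0L) {
    state$run_length <- 1L
    state$last_was_double <- FALSE
  } else if (dir != state$last_direction) {
    state$double_before_reversal <- state$last_was_double
    state$step_size <- max(state$step_size / 2, state$step_min)
    state$run_length <- 1L
    state$last_was_double <- FALSE
  } else {
    state$run_length <- state$run_length + 1L
    do_double <- state$run_length >= 4L ||
      (state$run_length == 3L && !state$double_before_reversal)
    if (do_double) {
      new_step <- min(state$step_size * 2, state$step_max)
      state$last_was_double <- new_step > state$step_size
      state$step_size <- new_step
    } else state$last_was_double <- FALSE
  }
  state$last_direction <- dir
  state$current_ka <- min(max(state$current_ka + dir * state$step_size,
                              -state$ka_max), state$ka_max)
  state
}

#' Run the full PEST staircase on a simulated reacher
#'
#' Iterates blocks of reaches at the current gain, classifies them, takes
#' the block mode and feeds it to [pestStep()] until convergence (two
#' on-target blocks at the same gain) or the block budget is exhausted, in
#' which case the most successful gain tested (highest on-target count;
#' ties to the most recent) is returned as best-so-far.
#'
#' @param reacher A \code{reacher_params}.
#' @param block_size Reaches per block (default 10).
#' @param max_blocks Block budget (default 40).
#' @param seed Integer seed; reach noise is seeded per block and trial.
#' @param ... Passed to [pestInit()].
#' @return List: \code{best_ka}, \code{history} (data frame: block, ka,
#'   mode, n_on_target), \code{state}, \code{termination_reason}.
#' @export
runPest <- function(reacher, block_size = 10, max_blocks = 40, seed = 1L,
                    ...) {
  state <- pestInit(...)
  hist <- data.frame(block = integer(), ka = numeric(),
                     mode = character(), n_on_target = integer())
  block <- 0L
  while (!state$terminated && block < max_blocks) {
    block <- block + 1L
    labels <- vapply(seq_len(block_size), function(j) {
      tr <- simulateReach(reacher, state$current_ka,
                          seed = seed + 1000L * block + j)
      classifyReach(angleOfFirstCorrection(tr),
                    tr$goal_excursion)$label
    }, character(1))
    mode <- blockMode(labels, state$last_direction)
    hist <- rbind(hist, data.frame(block = block, ka = state$current_ka,
                                   mode = mode,
                                   n_on_target = sum(labels == "on_target")))
    state <- pestStep(state, mode)
  }
  if (!state$terminated) {
    state$terminated <- TRUE
    state$termination_reason <- "budget_exhausted"
    best_idx <- order(hist$n_on_target, hist$block, decreasing = TRUE)[1]
    state$best_ka <- hist$ka[best_idx]
  }
  list(best_ka = state$best_ka, history = hist, state = state,
       termination_reason = state$termination_reason)
}

#' Fixed-gain sweep of the acceleration-dependent feedback
#'
#' Simulates blocks of reaches at each listed gain and returns the median
#' angle of first correction per gain (the dose-response summary).
#'
#' @param reacher A \code{reacher_params}.
#' @param gains Gains to test; default the nine-condition list
#'   0, 0.005, 0.010, 0.015, 0.020, -0.005, -0.010, -0.015, -0.020.
#' @param block_size Reaches per gain (default 5).
#' @param seed Integer seed.
#' @return Data frame with \code{ka} and \code{median_first_correction}
#'   (degrees), in the tested order.
#' @export
fixedGainSweep <- function(reacher,
                           gains = c(0, 0.005, 0.010, 0.015, 0.020,
                                     -0.005, -0.010, -0.015, -0.020),
                           block_size = 5, seed = 1L) {
  med <- vapply(seq_along(gains), function(gi) {
    fc <- vapply(seq_len(block_size), function(j) {
      tr <- simulateReach(reacher, gains[gi], seed = seed + 1000L * gi + j)
      angleOfFirstCorrection(tr)
    }, numeric(1))
    stats::median(fc)
  }, numeric(1))
  data.frame(ka = gains, median_first_correction = med)
}

#' Reference simulated reachers
#'
#' The three canonical reacher templates used by the package's
#' demonstrations and tests: a matched-inertia (on-target) reacher, a
#' mildly hypermetric one (internal inertia 5\% above true) and a mildly
#' hypometric one (5\% below), all with physiological motor noise.
#'
#' @param motor_noise_sd Noise level shared by the templates (deg/s^2).
#' @return Named list of \code{reacher_params}: \code{matched},
#'   \code{hypermetric}, \code{hypometric}.
#' @export
referenceReachers <- function(motor_noise_sd = 150) {
  list(matched = reacherParams(motor_noise_sd = motor_noise_sd),
       hypermetric = reacherParams(internal_inertia = 0.11 * 1.05,
                                   motor_noise_sd = motor_noise_sd),
       hypometric = reacherParams(internal_inertia = 0.11 * 0.95,
                                  motor_noise_sd = motor_noise_sd))
}
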