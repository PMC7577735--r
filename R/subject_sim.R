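#' Tracking-subject parameters
#'
#' Parameters of a closed-loop tracking subject modelled as a delayed, scaled
#' integrator (the McRuer crossover form): the subject integrates the visual
#' error between a gain-scaled, delayed view of the target and a delayed view
#' of their own cursor.  Optionally the subject carries a Smith predictor —
#' an internal copy of the plant plus a matched delay buffer — which cancels
#' the self-feedback delay from the loop.
#'
#' @param k Controller gain, 1/s.  Must be positive.
#' @param visual_gain Dimensionless gain on the perceived target (G).
#' @param visual_delay Delay on the target pathway, seconds (T_v).
#' @param feedback_delay Delay on the self-movement (cursor) pathway,
#'   seconds (T_f).
#' @param group_label "patient" or "control".
#' @param motor_noise_sd Standard deviation of additive white Gaussian noise
#'   on the commanded angular velocity, deg/s.
#' @param use_smith_predictor If \code{TRUE} the subject simulates its own
#'   plant and delay, cancelling \code{feedback_delay} from the effective
#'   loop.
#' @return An object of class \code{subject_params}.
#' @export
subjectParams <- function(k, visual_gain, visual_delay, feedback_delay,
                          group_label = c("control", "patient"),
                          motor_noise_sd = 0,
                          use_smith_predictor = FALSE) {
  group_label <- match.arg(group_label)
  if (k < 0) stop("k must be >= 0")
  if (visual_gain < 0) stop("visual_gain must be >= 0")
  if (visual_delay < 0 || feedback_delay < 0) stop("delays must be >= 0")
  out <- list(k = k, visual_gain = visual_gain,
              visual_delay = visual_delay, feedback_delay = feedback_delay,
              group_label = group_label, motor_noise_sd = motor_noise_sd,
              use_smith_predictor = use_smith_predictor)
  class(out) <- "subject_params"
  out
}

#' Closed-loop configuration
#'
#' Wiring of the experimental loop around a simulated subject: the feedback
#' gain applied to the displayed cursor, the display latency of the apparatus
#' (applied to both the target display and the cursor display), and sampling.
#'
#' @param applied_feedback_gain Gain multiplying the displayed elbow angle
#'   (0.65, 1.0 or 1.35 in the experimental conditions; any positive value
#'   accepted).
#' @param display_delay Display latency in seconds (default 0.0458).
#' @param sample_rate Simulation/recording rate in Hz (default 1000).
#' @param n_trials Number of trials to simulate.
#' @param seed Integer RNG seed for motor noise.
#' @return An object of class \code{loop_config}.
#' @export
loopConfig <- function(applied_feedback_gain = 1, display_delay = 0.0458,
                       sample_rate = 1000, n_trials = 1, seed = 1L) {
  if (applied_feedback_gain <= 0) stop("applied_feedback_gain must be > 0")
  if (display_delay < 0) stop("display_delay must be >= 0")
  out <- list(applied_feedback_gain = applied_feedback_gain,
              display_delay = display_delay, sample_rate = sample_rate,
              n_trials = as.integer(n_trials), seed = as.integer(seed))
  class(out) <- "loop_config"
  out
}

delaySamples <- function(delay_s, rate) {
  as.integer(round(delay_s * rate))
}

# Core discrete-time loop shared by the subject simulator.  Forward Euler at
# the loop sample rate; delays are integer sample counts.  Returns the elbow
# series or NULL if the runaway bound is exceeded.
runTrackingLoop <- function(target, k, G, dv, df, g_fb, dt, noise,
                            smith = FALSE, runaway = 1e4) {
  n <- length(target)
  pad <- max(dv, df, 1L)
  u <- c(numeric(pad), target)
  y <- numeric(n + pad)
  yhat <- if (smith) numeric(n + pad) else NULL
  kdt <- k * dt
  for (i in seq_len(n)) {
    j <- i + pad
    if (smith) {
      # internal plant copy + delay buffer: predicted cursor replaces the
      # delayed measurement except for its (delayed) prediction error
      fb <- (y[j - df] - yhat[j - df]) + yhat[j]
      e <- G * u[j - dv] - g_fb * fb
    } else {
      e <- G * u[j - dv] - g_fb * y[j - df]
    }
    if (i < n) {
      y[j + 1L] <- y[j] + kdt * e + dt * noise[i]
      if (smith) yhat[j + 1L] <- yhat[j] + kdt * e
      if (abs(y[j + 1L]) > runaway) return(NULL)
    }
  }
  y[(pad + 1L):(pad + n)]
}

#' Simulate closed-loop tracking trials
#'
#' Runs the delayed scaled-integrator subject in closed loop against a target
#' trajectory at the loop sample rate (forward Euler).  The subject sees the
#' target delayed by \code{visual_delay + display_delay} and its own
#' gain-scaled cursor delayed by \code{feedback_delay + display_delay};
#' elbow velocity is \code{k} times the visual error plus white motor noise.
#' The recorded cursor channel is the displayed one:
#' \code{applied_feedback_gain} times the elbow, delayed by the display
#' latency.  With \code{use_smith_predictor} the subject's internal plant
#' copy and delay buffer cancel the self-feedback delay, so (noiselessly) the
#' loop behaves as if \code{feedback_delay} were zero.
#'
#' @param subject A \code{subject_params}.
#' @param trajectory A \code{target_trajectory} sampled at the loop rate.
#' @param loop A \code{loop_config}.
#' @return A list of \code{trial_record} objects (fields \code{time},
#'   \code{target}, \code{elbow}, \code{cursor}, \code{mask},
#'   \code{metadata}).  Trials whose elbow exceeds the runaway bound are
#'   flagged \code{aborted} and truncated to the samples computed.
#' @export
simulateTracking <- function(subject, trajectory, loop = loopConfig()) {
  rate <- loop$sample_rate
  if (abs(trajectory$sample_rate - rate) > 1e-9)
    stop("trajectory sample rate does not match the loop configuration")
  dt <- 1 / rate
  dv <- delaySamples(subject$visual_delay + loop$display_delay, rate)
  df <- delaySamples(subject$feedback_delay + loop$display_delay, rate)
  dd <- delaySamples(loop$display_delay, rate)
  n <- length(trajectory$angle)
  noise_all <- if (subject$motor_noise_sd > 0) {
    withr::with_seed(loop$seed,
      matrix(stats::rnorm(n * loop$n_trials, 0, subject$motor_noise_sd),
             nrow = n))
  } else matrix(0, nrow = 1, ncol = loop$n_trials)
  trials <- vector("list", loop$n_trials)
  for (tr in seq_len(loop$n_trials)) {
    noise <- if (subject$motor_noise_sd > 0) noise_all[, tr] else numeric(n)
    elbow <- runTrackingLoop(trajectory$angle, subject$k, subject$visual_gain,
                             dv, df, loop$applied_feedback_gain, dt, noise,
                             smith = subject$use_smith_predictor)
    aborted <- is.null(elbow)
    if (aborted) elbow <- rep(NA_real_, n)
    cursor <- loop$applied_feedback_gain *
      c(numeric(dd), elbow)[seq_len(n)]
    rec <- list(time = trajectory$time,
                target = trajectory$angle,
                elbow = elbow,
                cursor = cursor,
                mask = rep(!aborted, n),
                metadata = list(group = subject$group_label,
                                applied_feedback_gain =
                                  loop$applied_feedback_gain,
                                trial = tr,
                                sample_rate = rate,
                                aborted = aborted))
    class(rec) <- "trial_record"
    trials[[tr]] <- rec
  }
  trials
}

#' @export
print.trial_record <- function(x, ...) {
  cat("Tracking trial: ", length(x$time), " samples at ",
      x$metadata$sample_rate, " Hz, group ", x$metadata$group,
      ", feedback gain ", x$metadata$applied_feedback_gain,
      if (isTRUE(x$metadata$aborted)) " [ABORTED]" else "", "\n", sep = "")
  invisible(x)
}

#' Analytic closed-loop frequency response of a tracking subject
#'
#' Frequency response from target angle to elbow angle for the delayed
#' scaled-integrator subject inside the experimental loop.  Two
#' discretization conventions are available:
#' \describe{
#'   \item{"matched"}{the exact z-domain response of the 1 kHz forward-Euler
#'     simulation loop (integrator \eqn{k\,\Delta t/(z-1)}, integer-sample
#'     delays).  Phasors estimated from noiseless simulated trials agree with
#'     this to numerical precision once the transient has decayed.}
#'   \item{"continuous"}{the ideal continuous-time formula
#'     \deqn{H(j\omega) = \frac{G e^{-j\omega T_v} k/(j\omega)}
#'                             {1 + g_{fb} e^{-j\omega T_f} k/(j\omega)}}
#'     with the display latency folded into both delay paths.}
#' }
#' With a Smith predictor (matched internal model) the self-feedback delay is
#' cancelled and \eqn{T_f} is replaced by zero in either convention.
#'
#' @param subject A \code{subject_params}.
#' @param frequencies Positive frequencies in Hz.
#' @param loop A \code{loop_config}.
#' @param discretization "matched" (default) or "continuous".
#' @return Complex vector of phasors, one per frequency.
#' @export
closedLoopFR <- function(subject, frequencies, loop = loopConfig(),
                         discretization = c("matched", "continuous")) {
  discretization <- match.arg(discretization)
  if (any(frequencies <= 0)) stop("frequencies must be > 0")
  g_fb <- loop$applied_feedback_gain
  w <- 2 * pi * frequencies
  if (discretization == "continuous") {
    Tv <- subject$visual_delay + loop$display_delay
    Tf <- if (subject$use_smith_predictor) 0 else
      subject$feedback_delay + loop$display_delay
    L <- subject$k / (1i * w)
    subject$visual_gain * exp(-1i * w * Tv) * L /
      (1 + g_fb * exp(-1i * w * Tf) * L)
  } else {
    rate <- loop$sample_rate
    dt <- 1 / rate
    dv <- delaySamples(subject$visual_delay + loop$display_delay, rate)
    df <- if (subject$use_smith_predictor) 0L else
      delaySamples(subject$feedback_delay + loop$display_delay, rate)
    z <- exp(1i * w * dt)
    K <- subject$k * dt / (z - 1)
    subject$visual_gain * z^(-dv) * K / (1 + g_fb * z^(-df) * K)
  }
}

#' Build a paired synthetic cohort
#'
#' Draws \code{n_pairs} patient/control subject-parameter pairs around the
#' supplied templates, with optional additive Gaussian jitter per parameter.
#' Jittered gains are clamped to be positive and delays non-negative; a
#' template delay of exactly zero is kept at zero (it encodes a structural
#' absence, not a small value).  Ground-truth parameters are retained for
#' recovery tests.
#'
#' @param n_pairs Number of patient/control pairs (>= 2).
#' @param patient_template,control_template \code{subject_params} templates.
#' @param jitter Named list of additive standard deviations for any of
#'   \code{k}, \code{visual_gain}, \code{visual_delay}, \code{feedback_delay};
#'   omitted entries default to 0.
#' @param seed Integer RNG seed.
#' @return List of pairs; each pair is a list with \code{patient} and
#'   \code{control} \code{subject_params} and a \code{pair_id}.
#' @export
makeCohort <- function(n_pairs, patient_template, control_template,
                       jitter = list(), seed = 1L) {
  if (n_pairs < 2) stop("n_pairs must be >= 2")
  sd_of <- function(nm) if (is.null(jitter[[nm]])) 0 else jitter[[nm]]
  fields <- c("k", "visual_gain", "visual_delay", "feedback_delay")
  withr::with_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      perturb <- function(tmpl) {
        p <- tmpl
        for (nm in fields) {
          s <- sd_of(nm)
          if (s > 0 && !(grepl("delay", nm) && tmpl[[nm]] == 0)) {
            v <- tmpl[[nm]] + stats::rnorm(1, 0, s)
            p[[nm]] <- max(v, if (grepl("delay", nm)) 0 else 1e-6)
          }
        }
        p
      }
      list(pair_id = i,
           patient = perturb(patient_template),
           control = perturb(control_template))
    })
  })
}
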