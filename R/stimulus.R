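#' Sum-of-sines stimulus specification
#'
#' Builds the specification of the pseudo-random tracking stimulus: a sum of
#' sinusoids whose frequencies are distinct prime multiples of a common base
#' frequency.  Because no stimulated frequency is an integer multiple of any
#' other, the target motion is non-harmonic and hence unpredictable to the
#' subject, while each component still lands on an exact DFT bin of the
#' fundamental period.
#'
#' Component amplitudes are capped twice: the positional amplitude of every
#' sinusoid stays at or below \code{positional_cap} and its peak angular
#' velocity \eqn{2\pi f A} stays at or below \code{velocity_cap}.
#'
#' @param base_frequency Base frequency in Hz (default 0.05).
#' @param prime_multipliers Integer vector of distinct primes multiplying the
#'   base frequency.  The default set of 15 primes yields the frequencies
#'   0.1, 0.15, 0.25, 0.35, 0.55, 0.65, 0.85, 0.95, 1.15, 1.45, 1.55, 1.85,
#'   2.05, 2.15 and 2.35 Hz.
#' @param positional_cap Maximum positional amplitude per component, degrees.
#' @param velocity_cap Maximum peak angular velocity per component, deg/s.
#' @param trial_duration Trial length in seconds; must be an integer multiple
#'   of the fundamental period \code{1/base_frequency}.
#' @param sample_rate Sampling rate in Hz.
#' @param phase_seed Integer seed used when drawing random component phases.
#' @return An object of class \code{stimulus_spec}.
#' @seealso [generateSumOfSines()], [generateSingleSine()],
#'   [componentAmplitudes()]
#' @export
stimulusSpec <- function(base_frequency = 0.05,
                         prime_multipliers = c(2L, 3L, 5L, 7L, 11L, 13L, 17L,
                                               19L, 23L, 29L, 31L, 37L, 41L,
                                               43L, 47L),
                         positional_cap = 2,
                         velocity_cap = 720,
                         trial_duration = 100,
                         sample_rate = 1000,
                         phase_seed = 1L) {
  prime_multipliers <- as.integer(prime_multipliers)
  if (anyDuplicated(prime_multipliers))
    stop("prime_multipliers must be distinct")
  not_prime <- prime_multipliers[!vapply(prime_multipliers, isPrime, logical(1))]
  if (length(not_prime))
    stop("multiplier(s) not prime: ", paste(not_prime, collapse = ", "))
  freqs <- base_frequency * prime_multipliers
  if (any(freqs <= 0) || any(freqs >= sample_rate / 2))
    stop("stimulated frequencies must lie in (0, sample_rate/2); offending: ",
         paste(freqs[freqs <= 0 | freqs >= sample_rate / 2], collapse = ", "))
  fundamental_period <- 1 / base_frequency
  n_periods <- trial_duration / fundamental_period
  if (abs(n_periods - round(n_periods)) > 1e-9)
    stop("trial_duration must be an integer multiple of the fundamental ",
         "period ", fundamental_period, " s")
  spec <- list(base_frequency = base_frequency,
               prime_multipliers = prime_multipliers,
               positional_cap = positional_cap,
               velocity_cap = velocity_cap,
               trial_duration = trial_duration,
               sample_rate = sample_rate,
               phase_seed = as.integer(phase_seed))
  class(spec) <- "stimulus_spec"
  spec
}

#' @export
print.stimulus_spec <- function(x, ...) {
  f <- stimulusFrequencies(x)
  cat("Sum-of-sines stimulus spec\n")
  cat("  ", length(f), " components, ", min(f), "-", max(f), " Hz (base ",
      x$base_frequency, " Hz)\n", sep = "")
  cat("  caps: ", x$positional_cap, " deg position, ", x$velocity_cap,
      " deg/s velocity\n", sep = "")
  cat("  ", x$trial_duration, " s at ", x$sample_rate, " Hz (",
      x$trial_duration * x$base_frequency, " fundamental periods)\n", sep = "")
  invisible(x)
}

isPrime <- function(n) {
  n <- as.integer(n)
  if (n < 2L) return(FALSE)
  if (n < 4L) return(TRUE)
  if (n %% 2L == 0L) return(FALSE)
  d <- 3L
  while (d * d <= n) {
    if (n %% d == 0L) return(FALSE)
    d <- d + 2L
  }
  TRUE
}

#' Stimulated frequencies of a spec
#'
#' @param spec A \code{stimulus_spec}.
#' @return Numeric vector of component frequencies in Hz, ascending.
#' @export
stimulusFrequencies <- function(spec) {
  sort(spec$base_frequency * spec$prime_multipliers)
}

#' Component amplitudes under the dual amplitude cap
#'
#' Each component gets the largest amplitude allowed by both caps:
#' \eqn{A_i = \min(\mathrm{positional\_cap},\ \mathrm{velocity\_cap} / (2\pi f_i))}.
#' With the default caps (2 deg, 720 deg/s) the velocity cap is non-binding
#' over the default 0.1--2.35 Hz range, so all amplitudes equal 2 deg.
#'
#' @param spec A \code{stimulus_spec}.
#' @return Numeric vector of amplitudes (degrees), one per ascending frequency.
#' @export
componentAmplitudes <- function(spec) {
  f <- stimulusFrequencies(spec)
  pmin(spec$positional_cap, spec$velocity_cap / (2 * pi * f))
}

makeTrajectory <- function(spec, components) {
  n <- round(spec$trial_duration * spec$sample_rate)
  t <- seq_len(n - 1L)
  t <- c(0, t) / spec$sample_rate
  angle <- numeric(n)
  for (i in seq_len(nrow(components))) {
    angle <- angle + components$amplitude[i] *
      sin(2 * pi * components$frequency[i] * t + components$phase[i])
  }
  traj <- list(time = t,
               angle = angle,
               components = components,
               fundamental_period = 1 / spec$base_frequency,
               sample_rate = spec$sample_rate,
               spec = spec)
  class(traj) <- "target_trajectory"
  traj
}

#' @export
print.target_trajectory <- function(x, ...) {
  cat("Target trajectory: ", length(x$time), " samples at ", x$sample_rate,
      " Hz, ", nrow(x$components), " component(s), fundamental period ",
      x$fundamental_period, " s\n", sep = "")
  invisible(x)
}

#' Generate a sum-of-sines target trajectory
#'
#' Samples \eqn{\theta(t) = \sum_i A_i \sin(2\pi f_i t + \phi_i)} over the
#' trial duration.  Phases are drawn uniformly on \eqn{[0, 2\pi)} from
#' \code{spec$phase_seed} (one draw per component) unless supplied, so the
#' realisation is reproducible.  The DFT of one fundamental period has support
#' only at the stimulated bins.
#'
#' @param spec A \code{stimulus_spec}.
#' @param phases Optional numeric vector of phases (radians), one per
#'   ascending frequency, overriding the seeded random draw.
#' @return A \code{target_trajectory} with fields \code{time} (s),
#'   \code{angle} (degrees, deviation from the 0 deg centerline),
#'   \code{components} (data frame: frequency, amplitude, phase) and
#'   \code{fundamental_period} (s).
#' @export
generateSumOfSines <- function(spec = stimulusSpec(), phases = NULL) {
  f <- stimulusFrequencies(spec)
  a <- componentAmplitudes(spec)
  if (is.null(phases)) {
    phases <- withr::with_seed(spec$phase_seed,
                               stats::runif(length(f), 0, 2 * pi))
  }
  if (length(phases) != length(f))
    stop("phases must have one entry per component")
  comps <- data.frame(frequency = f, amplitude = a, phase = phases)
  makeTrajectory(spec, comps)
}

#' Generate a single-sine target trajectory
#'
#' A standalone sinusoid at one of the stimulated frequencies, with amplitude
#' matched component-wise to the sum-of-sines design (same dual-cap rule).
#' By default only every other sum-of-sines frequency is allowed, mirroring
#' the single-sine probe set.
#'
#' @param frequency Frequency in Hz.
#' @param spec A \code{stimulus_spec} providing caps and sampling.
#' @param phase Phase in radians (default 0).
#' @param strict If \code{TRUE} (default), reject frequencies outside
#'   \code{allowed}.
#' @param allowed Permitted frequencies in strict mode; defaults to
#'   0.1, 0.25, 0.55, 0.85, 1.15, 1.55, 2.05, 2.35 Hz.
#' @return A single-component \code{target_trajectory}.
#' @export
generateSingleSine <- function(frequency, spec = stimulusSpec(), phase = 0,
                               strict = TRUE,
                               allowed = c(0.1, 0.25, 0.55, 0.85, 1.15,
                                           1.55, 2.05, 2.35)) {
  if (strict && !any(abs(allowed - frequency) < 1e-9))
    stop("frequency ", frequency, " Hz is not in the allowed single-sine set")
  amp <- pmin(spec$positional_cap, spec$velocity_cap / (2 * pi * frequency))
  comps <- data.frame(frequency = frequency, amplitude = amp, phase = phase)
  makeTrajectory(spec, comps)
}
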