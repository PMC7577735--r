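#' Analysis configuration for frequency-response estimation
#'
#' @param transient_discard Seconds discarded from the start of every trial
#'   as transient (default 20, one fundamental period).
#' @param n_lowest_for_scaling Number of lowest frequencies used by the
#'   scaling-factor fit and the aggregate tracking error (default 5).
#' @param circle_center,circle_radius Centre and radius of the effort/error
#'   circle on the phasor plane (default 0.5 + 0i, 0.5).
#' @param on_circle_tolerance Half-width of the "on the circle" band.
#' @return An object of class \code{analysis_config}.
#' @export
analysisConfig <- function(transient_discard = 20,
                           n_lowest_for_scaling = 5,
                           circle_center = 0.5 + 0i,
                           circle_radius = 0.5,
                           on_circle_tolerance = 1e-6) {
  out <- list(transient_discard = transient_discard,
              n_lowest_for_scaling = n_lowest_for_scaling,
              circle_center = circle_center,
              circle_radius = circle_radius,
              on_circle_tolerance = on_circle_tolerance)
  class(out) <- "analysis_config"
  out
}

detrendLinear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  t <- t - mean(t)
  x - mean(x) - t * (sum(t * x) / sum(t * t))
}

# Remove offset + linear trend estimated jointly with the stimulated
# sinusoids.  A plain least-squares line is not orthogonal to sinusoids over
# a finite window, so naive detrending bleeds stimulus energy into the trend
# estimate and biases every bin; fitting trend and sinusoids together leaves
# the periodic content exactly intact and makes the estimator exactly
# invariant to added linear trends.
detrendAtBins <- function(x, tsec, freqs) {
  X <- cbind(1, tsec - mean(tsec))
  for (f in freqs) X <- cbind(X, sin(2 * pi * f * tsec),
                              cos(2 * pi * f * tsec))
  beta <- qr.coef(qr(X), x)
  x - X[, 1:2, drop = FALSE] %*% beta[1:2]
}

makeFrequencyResponse <- function(frequencies, phasors, n_trials_used) {
  ord <- order(frequencies)
  fr <- list(frequencies = frequencies[ord],
             phasors = phasors[ord],
             gain = Mod(phasors[ord]),
             phase_lag = (-Arg(phasors[ord]) * 180 / pi) %% 360,
             n_trials_used = n_trials_used)
  class(fr) <- "frequency_response"
  fr
}

#' @export
print.frequency_response <- function(x, ...) {
  cat("Frequency response over", length(x$frequencies), "frequencies (",
      x$n_trials_used, "trial(s) used)\n")
  print(data.frame(freq_hz = x$frequencies,
                   gain = round(x$gain, 4),
                   phase_lag_deg = round(x$phase_lag, 2)), row.names = FALSE)
  invisible(x)
}

asPhasors <- function(x) {
  if (inherits(x, "frequency_response")) x$phasors else as.complex(x)
}

#' Estimate a frequency response from tracking trials
#'
#' The steady-state frequency response is the ratio of the DFT of the
#' subject's elbow movement to the DFT of the target trajectory at each
#' stimulated frequency.  The first \code{transient_discard} seconds are
#' dropped; in averaging mode (sum-of-sines) the elbow series is averaged
#' across trials at each time instant, honouring per-sample masks (a sample
#' masked in every trial is linearly interpolated); the averaged series is
#' linearly detrended before the DFT (the trend is estimated jointly with
#' the stimulated sinusoids so that detrending cannot bias the stimulated
#' bins).  In non-averaging mode (single sines)
#' each trial is processed separately, without masking, and the per-trial
#' phasors are averaged.
#'
#' @param trials List of \code{trial_record}s of equal length and rate.
#' @param stimulated Stimulated frequencies in Hz; each must land exactly on
#'   a DFT bin of the retained window.
#' @param config An \code{analysis_config}.
#' @param average_across_trials Average time series across trials before the
#'   DFT (default \code{TRUE}).
#' @return A \code{frequency_response}: frequencies, complex phasors, gain
#'   (\code{Mod}), phase lag in degrees (positive = lag, in [0, 360)).
#' @export
estimateFrequencyResponse <- function(trials, stimulated,
                                      config = analysisConfig(),
                                      average_across_trials = TRUE) {
  if (!length(trials)) stop("at least one trial is required")
  if (inherits(trials, "trial_record")) trials <- list(trials)
  rate <- trials[[1]]$metadata$sample_rate
  n_full <- length(trials[[1]]$elbow)
  skip <- round(config$transient_discard * rate)
  if (skip >= n_full) stop("transient_discard exceeds the trial duration")
  keep <- (skip + 1L):n_full
  n <- length(keep)
  bins <- stimulated * n / rate
  off <- abs(bins - round(bins)) > 1e-6
  if (any(off))
    stop("stimulated frequency not on a DFT bin of the retained window: ",
         paste(stimulated[off], collapse = ", "), " Hz")
  bins <- round(bins) + 1L
  tsec <- (keep - 1) / rate
  phasorOf <- function(resp, targ) {
    fr_r <- stats::fft(detrendAtBins(resp, tsec, stimulated))
    fr_t <- stats::fft(detrendAtBins(targ, tsec, stimulated))
    fr_r[bins] / fr_t[bins]
  }
  if (average_across_trials) {
    elbows <- vapply(trials, function(tr) tr$elbow[keep], numeric(n))
    masks <- vapply(trials, function(tr) tr$mask[keep], logical(n))
    elbows[!masks] <- NA_real_
    avg <- rowMeans(elbows, na.rm = TRUE)
    if (all(is.nan(avg))) stop("all samples are masked in every trial")
    if (anyNA(avg) || any(is.nan(avg))) {
      bad <- is.nan(avg) | is.na(avg)
      avg[bad] <- stats::approx(which(!bad), avg[!bad], xout = which(bad),
                                rule = 2)$y
    }
    targ <- rowMeans(vapply(trials, function(tr) tr$target[keep], numeric(n)))
    ph <- phasorOf(avg, targ)
  } else {
    per <- vapply(trials, function(tr)
      phasorOf(tr$elbow[keep], tr$target[keep]), complex(length(bins)))
    per <- matrix(per, nrow = length(bins))
    ph <- rowMeans(per)
  }
  makeFrequencyResponse(stimulated, ph, length(trials))
}

#' Per-frequency and aggregate tracking error
#'
#' The error at each frequency is the distance of the phasor from perfect
#' tracking (1 + 0i): the amplitude of the sinusoidal error component as a
#' proportion of the input amplitude.  The aggregate is the sum over the
#' \code{n_lowest_for_scaling} lowest frequencies.
#'
#' @param fr A \code{frequency_response}.
#' @param config An \code{analysis_config}.
#' @return List with \code{per_frequency} (named numeric) and
#'   \code{aggregate}.
#' @export
trackingError <- function(fr, config = analysisConfig()) {
  err <- Mod(fr$phasors - 1)
  names(err) <- fr$frequencies
  low <- order(fr$frequencies)[seq_len(min(config$n_lowest_for_scaling,
                                           length(err)))]
  list(per_frequency = err, aggregate = sum(err[low]))
}

#' Position relative to the effort/error circle
#'
#' Classifies phasors against the circle of radius 0.5 centred at +0.5 on
#' the real axis.  Points on the circle minimise tracking error for their
#' phase lag; points outside indicate excess movement for the achieved lag.
#'
#' @param phasor Complex vector (or \code{frequency_response}).
#' @param config An \code{analysis_config}.
#' @return Character vector in \{"inside", "on", "outside"\}.
#' @export
circlePosition <- function(phasor, config = analysisConfig()) {
  p <- asPhasors(phasor)
  d <- Mod(p - config$circle_center) - config$circle_radius
  ifelse(abs(d) <= config$on_circle_tolerance, "on",
         ifelse(d < 0, "inside", "outside"))
}

#' Fit a real scaling factor between two phasor sets
#'
#' Least-squares real scalar \eqn{s} minimising
#' \eqn{\sum_i |s\,p_i - v_i|^2} over the \code{n_lowest_for_scaling} lowest
#' shared frequencies, where \eqn{p} are the phasors of a feedback-gain
#' condition and \eqn{v} the veridical-condition phasors.  Closed form:
#' \eqn{s = \sum \mathrm{Re}(\bar p_i v_i) / \sum |p_i|^2}.  Scaling is real,
#' so phase is untouched.
#'
#' @param fr_condition,fr_veridical \code{frequency_response} objects sharing
#'   at least the lowest frequencies.
#' @param config An \code{analysis_config}.
#' @return A \code{scaling_result}: \code{scaling_factor}, \code{residual}
#'   (sum of squared moduli at the optimum), \code{frequencies_used}.
#' @export
fitScalingFactor <- function(fr_condition, fr_veridical,
                             config = analysisConfig()) {
  shared <- intersect(fr_condition$frequencies, fr_veridical$frequencies)
  if (length(shared) < config$n_lowest_for_scaling)
    stop("fewer shared frequencies than n_lowest_for_scaling")
  use <- sort(shared)[seq_len(config$n_lowest_for_scaling)]
  p <- fr_condition$phasors[match(use, fr_condition$frequencies)]
  v <- fr_veridical$phasors[match(use, fr_veridical$frequencies)]
  denom <- sum(Mod(p)^2)
  if (denom == 0) stop("condition phasors carry no power at the fit frequencies")
  s <- sum(Re(Conj(p) * v)) / denom
  out <- list(scaling_factor = s,
              residual = sum(Mod(s * p - v)^2),
              frequencies_used = use)
  class(out) <- "scaling_result"
  out
}

#' @export
print.scaling_result <- function(x, ...) {
  cat("Scaling factor ", signif(x$scaling_factor, 4), " (residual ",
      signif(x$residual, 3), ") over ",
      paste(x$frequencies_used, collapse = ", "), " Hz\n", sep = "")
  invisible(x)
}

#' Unit phase-lag vectors and their circular mean
#'
#' Extracts unit-modulus complex vectors carrying only the phase of the
#' response at the requested frequencies (for polar-plot summaries).  The
#' circular mean of a set of lags is the argument of the vector sum.
#'
#' @param fr A \code{frequency_response}.
#' @param frequencies Frequencies to extract (default: all).
#' @return Named complex vector of unit phasors.
#' @export
phaseLagVectors <- function(fr, frequencies = fr$frequencies) {
  idx <- match(frequencies, fr$frequencies)
  if (anyNA(idx)) stop("requested frequency not present in the response")
  v <- fr$phasors[idx] / Mod(fr$phasors[idx])
  names(v) <- frequencies
  v
}

#' @rdname phaseLagVectors
#' @param vectors Complex vector of (unit) phasors, or numeric phase lags in
#'   degrees.
#' @return \code{meanPhaseLag}: circular-mean phase lag in degrees, [0, 360).
#' @export
meanPhaseLag <- function(vectors) {
  if (is.numeric(vectors)) vectors <- exp(-1i * vectors * pi / 180)
  lag <- (-Arg(sum(vectors)) * 180 / pi) %% 360
  if (lag >= 360 - 1e-9) 0 else lag
}
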