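#' Plant/controller description for the Smith-predictor diagram
#'
#' The sensorimotor loop is drawn as: a single visual delay block delaying
#' both the reference (target) and the feedback of the plant output, a
#' visual gain on the reference, and the brain as a controller C driving the
#' plant P.  Only the lumped cascade \eqn{C P = k/s} is identified, so the
#' C/P split is symbolic; the Smith predictor's internal plant copy is
#' parameterised as \code{plant_scale} times the true plant and its internal
#' delay copy as \code{delay_copy}.
#'
#' @param k Lumped controller-plant gain, 1/s.
#' @param visual_gain Gain on the reference input (G).
#' @param visual_delay The shared visual delay T, seconds.
#' @param predictor Whether the brain carries a Smith predictor.
#' @param plant_scale Internal plant copy as a multiple of the true plant
#'   (1 = matched; ignored when \code{predictor} is FALSE).
#' @param delay_copy Internal delay copy \eqn{\hat T}, seconds (defaults to
#'   \code{visual_delay}, i.e. matched).
#' @return An object of class \code{plant_model}.
#' @export
plantModel <- function(k, visual_gain = 1, visual_delay,
                       predictor = TRUE, plant_scale = 1,
                       delay_copy = visual_delay) {
  if (k <= 0) stop("k must be > 0")
  if (visual_delay < 0 || delay_copy < 0) stop("delays must be >= 0")
  out <- list(k = k, visual_gain = visual_gain, visual_delay = visual_delay,
              predictor = predictor, plant_scale = plant_scale,
              delay_copy = delay_copy)
  class(out) <- "plant_model"
  out
}

#' Frequency response of the Smith-predictor loop
#'
#' Block algebra of the diagram: with \eqn{L = k/(j\omega)} the lumped
#' forward path, \eqn{\alpha} the internal plant scale (0 when the predictor
#' is absent) and \eqn{T}, \eqn{\hat T} the loop and internal delays,
#' \deqn{H(j\omega) = \frac{G e^{-j\omega T}}
#'   {1/L + e^{-j\omega T} + \alpha (1 - e^{-j\omega \hat T})}.}
#' A matched predictor (\eqn{\alpha = 1}, \eqn{\hat T = T}) cancels the
#' feedback delay, leaving \eqn{G e^{-j\omega T} L / (1 + L)}; removing the
#' predictor leaves the delayed-feedback loop
#' \eqn{G e^{-j\omega T} L / (1 + e^{-j\omega T} L)}.
#'
#' @param plant A \code{plant_model}.
#' @param frequencies Positive frequencies, Hz.
#' @return Complex phasor vector.
#' @export
smithLoopFR <- function(plant, frequencies) {
  if (any(frequencies <= 0)) stop("frequencies must be > 0")
  w <- 2 * pi * frequencies
  alpha <- if (plant$predictor) plant$plant_scale else 0
  L <- plant$k / (1i * w)
  eT <- exp(-1i * w * plant$visual_delay)
  eTh <- exp(-1i * w * plant$delay_copy)
  plant$visual_gain * eT / (1 / L + eT + alpha * (1 - eTh))
}

#' Verify the Smith-predictor / crossover-model equivalence
#'
#' Compares the full block-diagram response against the corresponding
#' simplified crossover structure: with a matched predictor the loop must
#' equal the delay-free-feedback (control-type) sub-model; without a
#' predictor it must equal the delayed-feedback (patient-type) sub-model
#' whose feedback delay equals the visual delay.
#'
#' @param plant A \code{plant_model} (matched predictor or no predictor).
#' @param frequencies Frequencies to check, Hz.
#' @param tolerance Maximum allowed modulus difference (default 1e-9).
#' @return List: \code{max_diff}, \code{pass}, \code{reference} ("control
#'   sub-model" or "patient sub-model").
#' @export
verifySmithEquivalence <- function(plant,
                                   frequencies = stimulusFrequencies(
                                     stimulusSpec()),
                                   tolerance = 1e-9) {
  h <- smithLoopFR(plant, frequencies)
  matched <- plant$predictor && plant$plant_scale == 1 &&
    plant$delay_copy == plant$visual_delay
  Tf <- if (matched) 0 else plant$visual_delay
  ref_name <- if (matched) "control sub-model" else "patient sub-model"
  if (plant$predictor && !matched)
    ref_name <- "patient sub-model (mismatched predictor; expected to differ)"
  params <- c(plant$k, plant$k, plant$visual_gain, plant$visual_gain,
              plant$visual_delay, plant$visual_delay, Tf, Tf)
  ref <- modelFR(params, frequencies)$patient
  max_diff <- max(Mod(h - ref))
  list(max_diff = max_diff, pass = max_diff < tolerance,
       reference = ref_name)
}
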