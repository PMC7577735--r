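# Shared fixtures, built in code at test time.

default_spec <- stimulusSpec()
default_freqs <- stimulusFrequencies(default_spec)

# a short spec for cheap end-to-end runs: 20 s trial, same base frequency
short_spec <- stimulusSpec(trial_duration = 40)

# wrap raw series into a trial_record (unit test plumbing)
make_trial <- function(target, elbow, rate = 1000, mask = NULL) {
  n <- length(target)
  rec <- list(time = (seq_len(n) - 1) / rate,
              target = target,
              elbow = elbow,
              cursor = elbow,
              mask = if (is.null(mask)) rep(TRUE, n) else mask,
              metadata = list(group = "control", applied_feedback_gain = 1,
                              trial = 1L, sample_rate = rate,
                              aborted = FALSE))
  class(rec) <- "trial_record"
  rec
}

# control-like / patient-like subjects at the reference reduced-model
# parameters (delays are totals; the display latency is subtracted so the
# simulated loop reproduces the printed totals)
control_like <- function(noise = 0, smith = FALSE) {
  subjectParams(k = 2.7, visual_gain = 0.39,
                visual_delay = 0.141 - 0.0458, feedback_delay = 0,
                group_label = "control", motor_noise_sd = noise,
                use_smith_predictor = smith)
}

patient_like <- function(noise = 0) {
  subjectParams(k = 2.7, visual_gain = 0.39,
                visual_delay = 0.210 - 0.0458,
                feedback_delay = 0.141 - 0.0458,
                group_label = "patient", motor_noise_sd = noise)
}

makeFrequencyResponseForTest <- function(freqs, phasors) {
  crossloop:::makeFrequencyResponse(freqs, as.complex(phasors), 1L)
}
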