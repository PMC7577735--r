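PARAM_NAMES <- c("k_patient", "k_control",
                 "visual_gain_patient", "visual_gain_control",
                 "visual_delay_patient", "visual_delay_control",
                 "feedback_delay_patient", "feedback_delay_control")

canonicalRGS <- function(classes) {
  # restricted-growth relabelling: first occurrence order 1, 2, ...
  out <- integer(length(classes))
  nxt <- 0L
  seen <- integer(0)
  lab <- list()
  for (i in seq_along(classes)) {
    key <- as.character(classes[i])
    if (is.null(lab[[key]])) {
      nxt <- nxt + 1L
      lab[[key]] <- nxt
    }
    out[i] <- lab[[key]]
  }
  out
}

#' Define a crossover-model yoking structure
#'
#' A model structure is a yoking pattern over the eight crossover-model
#' parameters: a set partition of the four gains (k and visual gain, patient
#' and control) whose blocks share one fitted value, an analogous partition
#' of the four delays, and a subset of delay blocks pinned to zero.  Gains
#' yoke only with gains and delays only with delays.  Degenerate variants
#' drop the feedback loop entirely.
#'
#' @param gain_classes Integer vector of length 4 assigning
#'   (k_patient, k_control, visual_gain_patient, visual_gain_control) to
#'   yoking classes; equal entries are yoked.
#' @param delay_classes Same for (visual_delay_patient, visual_delay_control,
#'   feedback_delay_patient, feedback_delay_control).
#' @param zero_delays Logical length 4 (slot-level): delays fixed at zero.
#'   An entire yoking class must be zeroed together; zeroing is applied
#'   slot-wise and the remaining partition is canonicalised.
#' @param name Optional label.
#' @param variant "closed_loop" (default), or a degenerate form:
#'   "pure_gain" (response = visual gain), "delayed_gain"
#'   (gain and visual delay, no integrator), "open_loop"
#'   (delayed scaled integrator without feedback).
#' @return An object of class \code{model_structure} with \code{n_free}.
#' @export
modelStructure <- function(gain_classes, delay_classes,
                           zero_delays = rep(FALSE, 4), name = NULL,
                           variant = c("closed_loop", "pure_gain",
                                       "delayed_gain", "open_loop")) {
  variant <- match.arg(variant)
  stopifnot(length(gain_classes) == 4, length(delay_classes) == 4,
            length(zero_delays) == 4)
  gain_classes <- canonicalRGS(gain_classes)
  # members of a zeroed class must all be zeroed (classes move together)
  for (cl in unique(delay_classes)) {
    z <- zero_delays[delay_classes == cl]
    if (any(z) && !all(z))
      stop("zero_delays must cover whole delay classes")
  }
  free_slots <- !zero_delays
  dc <- rep(0L, 4)
  if (any(free_slots)) dc[free_slots] <- canonicalRGS(delay_classes[free_slots])
  n_free <- switch(variant,
    closed_loop = length(unique(gain_classes)) + max(dc, 0L),
    pure_gain = length(unique(gain_classes[3:4])),
    delayed_gain = length(unique(gain_classes[3:4])) +
      length(unique(dc[1:2][dc[1:2] > 0])),
    open_loop = length(unique(gain_classes)) +
      length(unique(dc[1:2][dc[1:2] > 0])))
  key <- paste0(variant, "|g", paste(gain_classes, collapse = ""),
                "|d", paste(dc, collapse = ""))
  out <- list(gain_classes = gain_classes, delay_classes = dc,
              zero_delays = zero_delays, variant = variant,
              n_free = n_free, key = key,
              name = if (is.null(name)) key else name)
  class(out) <- "model_structure"
  out
}

#' @export
print.model_structure <- function(x, ...) {
  cat("Model structure '", x$name, "' (", x$variant, ", ", x$n_free,
      " free parameter(s))\n", sep = "")
  cat("  gain classes : ", paste(PARAM_NAMES[1:4], x$gain_classes,
                                 sep = "=", collapse = "  "), "\n", sep = "")
  dd <- ifelse(x$delay_classes == 0, "0(fixed)", x$delay_classes)
  cat("  delay classes: ", paste(PARAM_NAMES[5:8], dd, sep = "=",
                                 collapse = "  "), "\n", sep = "")
  invisible(x)
}

# map a free-parameter vector to the expanded named 8-vector
expandParams <- function(structure, free) {
  g <- structure$gain_classes
  d <- structure$delay_classes
  ng <- length(unique(g))
  full <- numeric(8)
  full[1:4] <- free[g]
  full[5:8] <- ifelse(d == 0, 0, free[ng + d])
  names(full) <- PARAM_NAMES
  full
}

nFree <- function(structure) {
  length(unique(structure$gain_classes)) + max(structure$delay_classes, 0L)
}

#' Crossover-model frequency response for both cohorts
#'
#' Evaluates the delayed scaled-integrator model
#' \deqn{H(j\omega) = \frac{G e^{-j\omega T_v}\, k/(j\omega)}
#'                         {1 + g_{fb}\, e^{-j\omega T_f}\, k/(j\omega)}}
#' for the patient and control sub-models of an expanded parameter vector.
#' \code{applied_gain} is the experimentally applied feedback gain
#' \eqn{g_{fb}} (1 in the veridical condition).
#'
#' @param params Named 8-vector in the order
#'   (k_p, k_c, G_p, G_c, Tv_p, Tv_c, Tf_p, Tf_c); units 1/s, -, s.
#' @param frequencies Positive frequencies, Hz.
#' @param applied_gain Applied feedback gain (default 1).
#' @param variant Structure variant (see [modelStructure()]).
#' @return List with complex vectors \code{patient} and \code{control}.
#' @export
modelFR <- function(params, frequencies, applied_gain = 1,
                    variant = "closed_loop") {
  if (any(frequencies <= 0)) stop("frequencies must be > 0")
  w <- 2 * pi * frequencies
  sub <- function(k, G, Tv, Tf) {
    switch(variant,
      closed_loop = {
        L <- k / (1i * w)
        G * exp(-1i * w * Tv) * L / (1 + applied_gain * exp(-1i * w * Tf) * L)
      },
      pure_gain = rep(complex(real = G), length(w)),
      delayed_gain = G * exp(-1i * w * Tv),
      open_loop = G * exp(-1i * w * Tv) * k / (1i * w))
  }
  list(patient = sub(params[1], params[3], params[5], params[7]),
       control = sub(params[2], params[4], params[6], params[8]))
}

#' Frequency-domain fitting error
#'
#' Sum over the stimulated frequencies of the squared moduli of the
#' complex differences between data and model phasors, patient and control
#' cohorts added together.
#'
#' @param params Expanded 8-vector (see [modelFR()]).
#' @param fr_patient,fr_control Data phasors: complex vectors or
#'   \code{frequency_response} objects on the same frequency grid.
#' @param frequencies Frequencies of the data grid, Hz.
#' @param applied_gain,variant Passed to [modelFR()].
#' @return Non-negative scalar.
#' @export
fdError <- function(params, fr_patient, fr_control, frequencies,
                    applied_gain = 1, variant = "closed_loop") {
  p <- asPhasors(fr_patient)
  c_ <- asPhasors(fr_control)
  if (length(p) != length(frequencies) || length(c_) != length(frequencies))
    stop("data phasors and frequency grid have mismatched lengths")
  m <- modelFR(params, frequencies, applied_gain, variant)
  sum(Mod(c_ - m$control)^2) + sum(Mod(p - m$patient)^2)
}

drawInits <- function(structure, n_restarts) {
  g <- structure$gain_classes
  ng <- length(unique(g))
  nd <- max(structure$delay_classes, 0L)
  # class type: k-like if it contains a k slot, else a visual gain
  k_like <- vapply(seq_len(ng), function(cl) any(which(g == cl) <= 2),
                   logical(1))
  t(vapply(seq_len(n_restarts), function(i) {
    gains <- ifelse(k_like, exp(stats::runif(ng, log(0.1), log(20))),
                    stats::runif(ng, 0, 1.5))
    c(gains, stats::runif(nd, 0, 0.5))
  }, numeric(ng + nd)))
}

#' Fit one model structure by multi-start Nelder-Mead
#'
#' Minimises the frequency-domain error ([fdError()]) over the structure's
#' free parameters with the Nelder-Mead simplex, restarted from
#' \code{n_restarts} random initialisations (k-type gains log-uniform on
#' [0.1, 20] 1/s, visual gains uniform on [0, 1.5], delays uniform on
#' [0, 0.5] s).  Non-negativity is enforced by optimising through an
#' absolute-value transform.  The best restart is returned.
#'
#' @param structure A \code{model_structure}.
#' @param fr_patient,fr_control Cohort-average phasors (complex vectors or
#'   \code{frequency_response}s).
#' @param frequencies Frequency grid, Hz.
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Integer seed for the restart draws.
#' @param applied_gain Applied feedback gain of the fitted condition.
#' @return List: \code{structure}, \code{params} (expanded 8-vector),
#'   \code{free}, \code{fd_error}, \code{convergence}.
#' @export
fitStructure <- function(structure, fr_patient, fr_control, frequencies,
                         n_restarts = 100, seed = 1L, applied_gain = 1) {
  p <- asPhasors(fr_patient)
  c_ <- asPhasors(fr_control)
  obj <- function(free) {
    fdError(expandParams(structure, abs(free)), p, c_, frequencies,
            applied_gain, structure$variant)
  }
  inits <- withr::with_seed(seed, drawInits(structure, n_restarts))
  best <- NULL
  for (i in seq_len(n_restarts)) {
    x0 <- inits[i, ]
    fit <- if (length(x0) == 1L) {
      o <- stats::optimize(obj, c(0, 50), tol = 1e-10)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(x0, obj, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-10))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    stop("all restarts failed to produce a finite fit")
  free <- abs(best$par)
  list(structure = structure,
       params = expandParams(structure, free),
       free = free,
       fd_error = best$value,
       convergence = best$convergence)
}

cohortFrequencies <- function(cohort) {
  f <- attr(cohort, "frequencies")
  if (is.null(f)) stop("cohort must carry a 'frequencies' attribute")
  f
}

cohortMeanFR <- function(cohort, idx = seq_along(cohort)) {
  np <- length(idx)
  pat <- Reduce(`+`, lapply(cohort[idx], function(pr) asPhasors(pr$patient)))
  ctl <- Reduce(`+`, lapply(cohort[idx], function(pr) asPhasors(pr$control)))
  list(patient = pat / np, control = ctl / np)
}

#' Leave-one-pair-out evaluation of a model structure
#'
#' For each patient/control pair in the cohort: fit the structure to the
#' average frequency responses of the remaining pairs, then evaluate the
#' frequency-domain error on the left-out pair.  Returns the mean left-out
#' error across folds (the generalisation gauge) and the per-fold expanded
#' parameter sets (rows), whose dispersion feeds [consistency()].
#'
#' @param structure A \code{model_structure}.
#' @param cohort List of pairs, each with complex phasor vectors
#'   \code{patient} and \code{control}; must carry a \code{frequencies}
#'   attribute.
#' @param n_restarts,seed,applied_gain Passed to [fitStructure()]; the seed
#'   is advanced per fold.
#' @return List: \code{loo_mean}, \code{loo_errors}, \code{param_sets}
#'   (n_pairs x 8 matrix), \code{fits}.
#' @export
looEvaluate <- function(structure, cohort, n_restarts = 100, seed = 1L,
                        applied_gain = 1) {
  np <- length(cohort)
  if (np < 3) stop("leave-one-out needs at least 3 pairs")
  freqs <- cohortFrequencies(cohort)
  loo <- numeric(np)
  psets <- matrix(NA_real_, np, 8, dimnames = list(NULL, PARAM_NAMES))
  fits <- vector("list", np)
  for (i in seq_len(np)) {
    avg <- cohortMeanFR(cohort, setdiff(seq_len(np), i))
    fit <- fitStructure(structure, avg$patient, avg$control, freqs,
                        n_restarts, seed + i - 1L, applied_gain)
    loo[i] <- fdError(fit$params, asPhasors(cohort[[i]]$patient),
                      asPhasors(cohort[[i]]$control), freqs, applied_gain,
                      structure$variant)
    psets[i, ] <- fit$params
    fits[[i]] <- fit
  }
  list(loo_mean = mean(loo), loo_errors = loo, param_sets = psets,
       fits = fits)
}

#' Model-consistency gauge
#'
#' Residualises each column of the leave-one-out parameter matrix about its
#' mean and returns the largest singular value of the residual matrix.
#' Units are mixed (1/s and s) exactly as the parameters stand; no
#' rescaling is applied.
#'
#' @param param_sets Numeric matrix, one row per leave-one-out fit.
#' @return Largest singular value of the row-residual matrix (>= 0).
#' @export
consistency <- function(param_sets) {
  param_sets <- as.matrix(param_sets)
  if (nrow(param_sets) < 2) stop("need at least 2 parameter sets")
  resid <- sweep(param_sets, 2, colMeans(param_sets))
  max(svd(resid, nu = 0, nv = 0)$d)
}

setPartitions4 <- function() {
  # all restricted-growth strings of length 4 (Bell(4) = 15 partitions)
  out <- list()
  gen <- function(prefix, mx) {
    if (length(prefix) == 4L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) gen(c(prefix, v), max(mx, v))
  }
  gen(integer(0), 0L)
  out
}

#' Enumerate all crossover-model yoking structures
#'
#' All set partitions of the four gains crossed with all set partitions of
#' the four delays (15 x 15), with every subset of delay classes optionally
#' pinned to zero; duplicates arising from zeroing are canonicalised away
#' (780 distinct closed-loop structures).  Optionally appends the named
#' degenerate structures: pure gain, delayed gain (no feedback loop), and
#' open-loop delayed scaled integrator.
#'
#' @param include_degenerate Append the degenerate structures (default TRUE).
#' @return Named list of \code{model_structure}s keyed by canonical key.
#' @export
enumerateStructures <- function(include_degenerate = TRUE) {
  parts <- setPartitions4()
  out <- list()
  for (g in parts) {
    for (d in parts) {
      ncl <- max(d)
      for (mask in seq_len(2^ncl) - 1L) {
        zero_cl <- which(bitwAnd(mask, 2^(seq_len(ncl) - 1L)) > 0)
        zd <- d %in% zero_cl
        st <- modelStructure(g, d, zd)
        if (is.null(out[[st$key]])) out[[st$key]] <- st
      }
    }
  }
  if (include_degenerate) {
    deg <- list(
      modelStructure(c(1, 1, 2, 3), c(1, 2, 3, 4), rep(TRUE, 4),
                     name = "pure gain", variant = "pure_gain"),
      modelStructure(c(1, 1, 2, 3), c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE),
                     name = "delayed gain", variant = "delayed_gain"),
      modelStructure(c(1, 1, 2, 3), c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE),
                     name = "open-loop integrator", variant = "open_loop"))
    for (st in deg) out[[st$key]] <- st
  }
  out
}

#' Reference structures
#'
#' Named yoking patterns used throughout: the fully free 8-parameter model,
#' the four top reduced models (both 4- and 5-free variants, "lowest error"
#' yokes the patient feedback delay to the control visual delay, "lowest
#' variance" yokes it to the patient visual delay), the a-priori
#' hypothesised model (distinct patient/control feedback delays), and the
#' degenerate forms.
#'
#' @return Named list of \code{model_structure}s.
#' @export
referenceStructures <- function() {
  list(
    full_8 = modelStructure(1:4, 1:4, name = "full 8-parameter"),
    best4_lowest_err = modelStructure(
      c(1, 1, 2, 2), c(1, 2, 2, 3), c(FALSE, FALSE, FALSE, TRUE),
      name = "best 4 (lowest error)"),
    best4_lowest_var = modelStructure(
      c(1, 1, 2, 2), c(1, 2, 1, 3), c(FALSE, FALSE, FALSE, TRUE),
      name = "best 4 (lowest variance)"),
    best5_lowest_err = modelStructure(
      c(1, 1, 2, 3), c(1, 2, 2, 3), c(FALSE, FALSE, FALSE, TRUE),
      name = "best 5 (lowest error)"),
    best5_lowest_var = modelStructure(
      c(1, 1, 2, 3), c(1, 2, 1, 3), c(FALSE, FALSE, FALSE, TRUE),
      name = "best 5 (lowest variance)"),
    hypothesised = modelStructure(
      c(1, 1, 2, 2), c(1, 1, 2, 3),
      name = "hypothesised (shared visual delay)"),
    delay_free = modelStructure(
      c(1, 1, 2, 2), c(1, 1, 1, 1), rep(TRUE, 4), name = "delay-free loop"),
    pure_gain = modelStructure(c(1, 1, 2, 3), c(1, 2, 3, 4), rep(TRUE, 4),
                               name = "pure gain", variant = "pure_gain"),
    delayed_gain = modelStructure(c(1, 1, 2, 3), c(1, 2, 3, 4),
                                  c(FALSE, FALSE, TRUE, TRUE),
                                  name = "delayed gain",
                                  variant = "delayed_gain"))
}

#' Rank fitted structures on the error/consistency trade-off
#'
#' Computes the Pareto front over (mean leave-one-out error, consistency):
#' a report is kept unless some other report is at least as good on both
#' axes and strictly better on one.  Front members are ordered by number of
#' free parameters, then error; within each free-parameter stratum the
#' minimum-error member is labelled "lowest error" and the
#' minimum-consistency member "lowest variance".
#'
#' @param reports List of reports, each with \code{structure},
#'   \code{loo_mean} and \code{consistency}.
#' @return Data frame of all reports (name, n_free, loo_mean, consistency,
#'   on_front, label), front members first.
#' @export
selectModels <- function(reports) {
  if (!length(reports)) stop("no reports supplied")
  loo <- vapply(reports, `[[`, numeric(1), "loo_mean")
  con <- vapply(reports, `[[`, numeric(1), "consistency")
  nf <- vapply(reports, function(r) r$structure$n_free, numeric(1))
  nm <- vapply(reports, function(r) r$structure$name, character(1))
  dominated <- vapply(seq_along(reports), function(i) {
    any(loo <= loo[i] & con <= con[i] &
          (loo < loo[i] | con < con[i] |
             (loo == loo[i] & con == con[i] & nf < nf[i])))
  }, logical(1))
  df <- data.frame(name = nm, n_free = nf, loo_mean = loo,
                   consistency = con, on_front = !dominated,
                   label = "", stringsAsFactors = FALSE)
  for (s in unique(nf[!dominated])) {
    idx <- which(!dominated & nf == s)
    i_err <- idx[which.min(loo[idx])]
    i_var <- idx[which.min(con[idx])]
    df$label[i_err] <- paste0(df$label[i_err], "lowest error")
    df$label[i_var] <- paste(df$label[i_var],
                             "lowest variance", sep = if (i_var == i_err)
                               " + " else "")
  }
  df[order(-df$on_front, df$n_free, df$loo_mean), ]
}

#' Bootstrap confidence intervals for a structure's parameters
#'
#' Resamples patient/control pairs with replacement, refits the structure to
#' each resampled cohort's average frequency responses, and returns
#' percentile intervals of the expanded parameters.
#'
#' @param structure A \code{model_structure}.
#' @param cohort As in [looEvaluate()].
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param n_restarts,seed,applied_gain Passed to [fitStructure()].
#' @return List: \code{ci} (8 x 2 matrix of lower/upper), \code{samples}
#'   (B x 8), \code{n_failed}.
#' @export
bootstrapCI <- function(structure, cohort, B = 1000, level = 0.95,
                        n_restarts = 20, seed = 1L, applied_gain = 1) {
  np <- length(cohort)
  if (np < 2) stop("need at least 2 pairs")
  freqs <- cohortFrequencies(cohort)
  draws <- withr::with_seed(seed,
    matrix(sample.int(np, np * B, replace = TRUE), nrow = B))
  samples <- matrix(NA_real_, B, 8, dimnames = list(NULL, PARAM_NAMES))
  n_failed <- 0L
  for (b in seq_len(B)) {
    avg <- cohortMeanFR(cohort, draws[b, ])
    fit <- tryCatch(
      fitStructure(structure, avg$patient, avg$control, freqs,
                   n_restarts, seed + b, applied_gain),
      error = function(e) NULL)
    if (is.null(fit)) n_failed <- n_failed + 1L else samples[b, ] <- fit$params
  }
  a <- (1 - level) / 2
  ci <- t(apply(samples, 2, stats::quantile, probs = c(a, 1 - a),
                na.rm = TRUE))
  list(ci = ci, samples = samples, n_failed = n_failed)
}

#' Simulate a fitted model in the time domain
#'
#' Discrete-time simulation (delay buffers, forward Euler at the trajectory
#' rate) of the patient and control sub-models driven by the target
#' trajectory.  Fitted delays are totals (display latency already absorbed),
#' so no extra display delay is added.
#'
#' @param params Expanded 8-vector.
#' @param trajectory A \code{target_trajectory}.
#' @param applied_gain Applied feedback gain.
#' @return List with numeric elbow-angle series \code{patient},
#'   \code{control} and the \code{time} vector.
#' @export
simulateModelTD <- function(params, trajectory, applied_gain = 1) {
  rate <- trajectory$sample_rate
  dt <- 1 / rate
  sim <- function(k, G, Tv, Tf) {
    runTrackingLoop(trajectory$angle, k, G,
                    delaySamples(Tv, rate), delaySamples(Tf, rate),
                    applied_gain, dt, numeric(length(trajectory$angle)))
  }
  list(patient = sim(params[1], params[3], params[5], params[7]),
       control = sim(params[2], params[4], params[6], params[8]),
       time = trajectory$time)
}

#' Time-domain validation error
#'
#' Mean squared difference between predicted and observed mean elbow-angle
#' series over the last \code{window} seconds (Riemann sum at the sampling
#' rate), patient and control terms added.
#'
#' @param pred_patient,pred_control Predicted series.
#' @param obs_patient,obs_control Observed mean series (same length/rate).
#' @param sample_rate Hz.
#' @param window Averaging window in seconds counted from the end
#'   (default 80).
#' @return Scalar error in squared degrees.
#' @export
tdError <- function(pred_patient, obs_patient, pred_control, obs_control,
                    sample_rate = 1000, window = 80) {
  n <- length(obs_patient)
  if (length(pred_patient) != n || length(pred_control) != length(obs_control))
    stop("prediction/observation length mismatch")
  keep <- (n - round(window * sample_rate) + 1L):n
  mean((obs_control[keep] - pred_control[keep])^2) +
    mean((obs_patient[keep] - pred_patient[keep])^2)
}

#' Simulate a cohort of paired frequency responses from a model
#'
#' Generates per-pair phasor sets from the crossover model at the given
#' parameters, adding independent circular complex Gaussian noise per
#' subject and frequency.  This is the phasor-level synthetic cohort used by
#' parameter-recovery and selection experiments.
#'
#' @param params Expanded 8-vector of ground-truth parameters.
#' @param frequencies Frequency grid, Hz.
#' @param n_pairs Number of pairs (default 11).
#' @param noise_sd Standard deviation of the complex noise per component
#'   (real and imaginary parts each N(0, noise_sd^2/2), so the complex
#'   modulus has sd \code{noise_sd}).
#' @param seed Integer seed.
#' @param applied_gain Applied feedback gain of the simulated condition.
#' @return Cohort list (see [looEvaluate()]) with ground truth attached as
#'   attribute \code{truth}.
#' @export
simulateCohortFR <- function(params, frequencies, n_pairs = 11,
                             noise_sd = 0.05, seed = 1L, applied_gain = 1) {
  m <- modelFR(params, frequencies, applied_gain)
  nf <- length(frequencies)
  cohort <- withr::with_seed(seed, lapply(seq_len(n_pairs), function(i) {
    cnoise <- function() complex(real = stats::rnorm(nf, 0, noise_sd / sqrt(2)),
                                 imaginary = stats::rnorm(nf, 0,
                                                          noise_sd / sqrt(2)))
    list(pair_id = i,
         patient = m$patient + cnoise(),
         control = m$control + cnoise())
  }))
  attr(cohort, "frequencies") <- frequencies
  attr(cohort, "truth") <- params
  cohort
}

#' Ground-truth parameters of the reference reduced model
#'
#' The four-free-parameter reduced model used as the default synthetic
#' ground truth: shared controller gain 2.7 1/s, shared visual gain 0.39,
#' patient visual delay 210 ms, control visual delay and patient feedback
#' delay 141 ms, control feedback delay 0.
#'
#' @return Named expanded 8-vector.
#' @export
referenceParams <- function() {
  p <- c(2.7, 2.7, 0.39, 0.39, 0.210, 0.141, 0.141, 0)
  names(p) <- PARAM_NAMES
  p
}
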