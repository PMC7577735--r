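#' Write a tracking trial to CSV with a JSON sidecar
#'
#' The CSV carries columns \code{time_s}, \code{target_deg},
#' \code{elbow_deg}, \code{cursor_deg}, \code{mask}; the sidecar (same path
#' with \code{.json} appended) carries the metadata.
#'
#' @param trial A \code{trial_record}.
#' @param path Output CSV path.
#' @return Invisibly, the sidecar path.
#' @export
writeTrialRecord <- function(trial, path) {
  df <- data.frame(time_s = trial$time, target_deg = trial$target,
                   elbow_deg = trial$elbow, cursor_deg = trial$cursor,
                   mask = as.integer(trial$mask))
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(trial$metadata, sidecar, auto_unbox = TRUE,
                       digits = NA)
  invisible(sidecar)
}

#' Read tracking trials from CSV + JSON sidecars
#'
#' Columns are header-keyed (order-independent).  Sampling must be uniform
#' and match \code{expected_rate}.
#'
#' @param paths Character vector of CSV paths; each must have a
#'   \code{<path>.json} sidecar.
#' @param expected_rate Required sampling rate in Hz (default 1000).
#' @return List of \code{trial_record}s.
#' @export
readTrials <- function(paths, expected_rate = 1000) {
  lapply(paths, function(p) {
    if (!file.exists(p)) stop("trial file not found: ", p)
    sidecar <- paste0(p, ".json")
    if (!file.exists(sidecar)) stop("missing JSON sidecar for ", p)
    df <- utils::read.csv(p)
    need <- c("time_s", "target_deg", "elbow_deg", "cursor_deg")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("trial CSV ", p, " lacks column(s): ", paste(miss, collapse = ", "))
    dts <- diff(df$time_s)
    if (length(dts) && (max(dts) - min(dts)) > 1e-9)
      stop("non-uniform sampling in ", p)
    rate <- 1 / stats::median(dts)
    if (abs(rate - expected_rate) > 1e-6 * expected_rate)
      stop("sample-rate mismatch in ", p, ": found ", round(rate, 3),
           " Hz, expected ", expected_rate, " Hz")
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta$sample_rate <- rate
    rec <- list(time = df$time_s, target = df$target_deg,
                elbow = df$elbow_deg, cursor = df$cursor_deg,
                mask = if ("mask" %in% names(df)) as.logical(df$mask)
                       else rep(TRUE, nrow(df)),
                metadata = meta)
    class(rec) <- "trial_record"
    rec
  })
}

#' Write / read a frequency response as CSV
#'
#' Columns: \code{freq_hz}, \code{re}, \code{im}, \code{gain},
#' \code{phase_lag_deg}.
#'
#' @param fr A \code{frequency_response}.
#' @param path CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeFrequencyResponse <- function(fr, path) {
  df <- data.frame(freq_hz = fr$frequencies, re = Re(fr$phasors),
                   im = Im(fr$phasors), gain = fr$gain,
                   phase_lag_deg = fr$phase_lag,
                   n_trials_used = fr$n_trials_used)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFrequencyResponse
#' @export
readFrequencyResponse <- function(path) {
  df <- utils::read.csv(path)
  makeFrequencyResponse(df$freq_hz, complex(real = df$re, imaginary = df$im),
                        df$n_trials_used[1])
}

#' Run the tracking-analysis pipeline on a synthetic cohort
#'
#' End-to-end driver: builds the sum-of-sines stimulus, simulates a paired
#' cohort of tracking subjects, estimates per-pair frequency responses,
#' fits and ranks a set of candidate model structures by leave-one-out
#' error and consistency, and (optionally) fits scaling factors for an
#' applied-feedback-gain condition.  Intended as a smoke-testable, seeded,
#' reproducible bundle; heavy settings (restarts, bootstrap) are dialled
#' down by default.
#'
#' @param n_pairs Number of patient/control pairs.
#' @param noise_sd Phasor noise SD for the cohort generator.
#' @param structures Named list of \code{model_structure}s to evaluate
#'   (default: a compact reference set).
#' @param n_restarts Restarts per fit.
#' @param seed Master seed.
#' @param out_dir Optional directory; if given, writes the ranked-model CSV
#'   and a JSON report with provenance (seed, settings).
#' @return List: \code{spec}, \code{cohort}, \code{reports},
#'   \code{ranking}, \code{best_fit}.
#' @export
runPipeline <- function(n_pairs = 11, noise_sd = 0.05,
                        structures = NULL, n_restarts = 10, seed = 1L,
                        out_dir = NULL) {
  spec <- stimulusSpec(phase_seed = seed)
  freqs <- stimulusFrequencies(spec)
  if (is.null(structures)) {
    rs <- referenceStructures()
    structures <- rs[c("full_8", "best4_lowest_err", "best4_lowest_var",
                       "hypothesised", "delay_free", "pure_gain")]
  }
  cohort <- simulateCohortFR(referenceParams(), freqs, n_pairs = n_pairs,
                             noise_sd = noise_sd, seed = seed)
  reports <- lapply(structures, function(st) {
    loo <- looEvaluate(st, cohort, n_restarts = n_restarts, seed = seed)
    list(structure = st, loo_mean = loo$loo_mean,
         consistency = consistency(loo$param_sets),
         param_sets = loo$param_sets)
  })
  ranking <- selectModels(reports)
  avg <- cohortMeanFR(cohort)
  front <- ranking[ranking$on_front, ]
  best_name <- front$name[which.min(front$loo_mean)]
  best_st <- structures[[which(vapply(structures, function(s) s$name,
                                      character(1)) == best_name)[1]]]
  best_fit <- fitStructure(best_st, avg$patient, avg$control, freqs,
                           n_restarts = n_restarts, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ranking, file.path(out_dir, "model_ranking.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, n_pairs = n_pairs, noise_sd = noise_sd,
           n_restarts = n_restarts,
           best_structure = best_st$name,
           best_params = as.list(best_fit$params),
           fd_error = best_fit$fd_error),
      file.path(out_dir, "fit_report.json"), auto_unbox = TRUE, digits = NA)
  }
  list(spec = spec, cohort = cohort, reports = reports, ranking = ranking,
       best_fit = best_fit)
}
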