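#' Default run configuration
#'
#' Bundles the protocol, sensor calibration, encoder parameters, analysis
#' thresholds, observer settings and recruitment geometry into one fully
#' serializable list whose defaults reproduce the published parameter set.
#'
#' @param n_sessions Number of 16-trial sessions for the behavioural stage.
#' @return A list of class `run_config`.
#' @export
default_config <- function(n_sessions = 5) {
  structure(list(protocol = sliding_protocol(),
                 calibration = sensor_calibration(),
                 encoder = encoder_params(),
                 isi_gap_threshold = 25,
                 observer = list(tau = 50, decision_noise_sd = 0),
                 stimulation = list(amplitude_uA = 160, width_us = 100),
                 n_sessions = n_sessions),
            class = "run_config")
}

#' Write / read a raster bundle of spike trains
#'
#' A raster bundle is a tidy event-time table keyed by (session, stimulus,
#' order, repetition) with one row per spike (time in s), plus metadata
#' (velocity, force, stimulation amplitude/width).  The CSV form is the
#' flat table; the JSON form nests trains under their keys.  Writes are
#' atomic.
#'
#' @param bundle A data frame with columns `session`, `stimulus`, `order`,
#'   `repetition`, `time`, with optional `metadata` attribute.
#' @param path Output path; format chosen by extension (`.csv` or
#'   `.json`).
#' @return `write_raster` returns `path` invisibly; `read_raster` the
#'   bundle.
#' @export
write_raster <- function(bundle, path) {
  req <- c("session", "stimulus", "order", "repetition", "time")
  if (!all(req %in% names(bundle)))
    stop("raster bundle needs columns ", paste(req, collapse = ", "))
  if (any(bundle$time < 0)) stop("negative spike time in bundle")
  key <- with(bundle, paste(session, stimulus, order, repetition))
  if (any(tapply(bundle$time, key, function(x) is.unsorted(x))))
    bundle <- bundle[order(key, bundle$time), ]
  if (grepl("\\.json$", path)) {
    trains <- split(bundle$time, key)
    obj <- list(metadata = attr(bundle, "metadata"),
                trains = lapply(names(trains), function(k) {
                  parts <- strsplit(k, " ")[[1]]
                  list(session = parts[1], stimulus = parts[2],
                       order = parts[3], repetition = parts[4],
                       spike_times = round(trains[[k]], 6))
                }))
    .atomic_write(function(f) jsonlite::write_json(obj, f, auto_unbox = TRUE,
                                                   digits = 8), path)
  } else {
    out <- bundle
    out$time <- sprintf("%.6f", out$time)
    .atomic_write(function(f) write.csv(out, f, row.names = FALSE), path)
  }
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    tr <- obj$trains
    if (length(tr) == 0) {
      warning("empty raster bundle")
      return(data.frame(session = character(0), stimulus = character(0),
                        order = character(0), repetition = integer(0),
                        time = numeric(0)))
    }
    bundle <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
      tt <- tr$spike_times[[i]]
      if (length(tt) == 0) return(NULL)
      data.frame(session = tr$session[i], stimulus = tr$stimulus[i],
                 order = tr$order[i], repetition = as.integer(tr$repetition[i]),
                 time = as.numeric(tt))
    }))
    attr(bundle, "metadata") <- obj$metadata
  } else {
    first <- readLines(path, n = 2)
    if (length(first) < 2 || !nzchar(first[2])) {
      warning("empty raster bundle")
      return(data.frame(session = character(0), stimulus = character(0),
                        order = character(0), repetition = integer(0),
                        time = numeric(0)))
    }
    bundle <- read.csv(path, colClasses = c(session = "character",
                                            stimulus = "character",
                                            order = "character"))
  }
  bundle$time <- suppressWarnings(as.numeric(bundle$time))
  bad <- which(!is.finite(bundle$time) | bundle$time < 0)
  if (length(bad))
    stop("malformed spike time at data row ", bad[1])
  bundle
}

#' Spike trains of a session run as a raster bundle
#'
#' @param trials Output of [run_sessions()] is not enough (it has no spike
#'   times); this helper re-encodes the trials of one or more sessions and
#'   collects the slide-phase spikes into a raster bundle.
#' @param n_sessions,seed,protocol,calib,params As in [run_sessions()].
#' @return A raster data frame (`session`, `stimulus`, `order`,
#'   `repetition`, `half`, `time`).
#' @export
sessions_raster <- function(n_sessions = 1, seed = 1,
                            protocol = sliding_protocol(),
                            calib = sensor_calibration(),
                            params = encoder_params()) {
  out <- list()
  counter <- 0
  for (s in seq_len(n_sessions)) {
    plan <- build_session(derive_seed(seed, counter <- counter + 1))
    reps <- list()
    for (i in seq_len(nrow(plan))) {
      pair <- make_stimulus_pair(plan$label[i], plan$order[i])
      key <- paste0(pair$label, pair$order)
      reps[[key]] <- (reps[[key]] %||% 0) + 1
      trace <- synth_sensor_trace(pair, protocol, calib,
                                  seed = derive_seed(seed, counter <- counter + 1))
      enc <- encode_trial(trace, params)
      counter <- counter + 1   # parity with run_sessions' observer draw
      for (h in 1:2) {
        tt <- enc$halves[[h]]$spike_times
        if (length(tt))
          out[[length(out) + 1]] <- data.frame(
            session = s, stimulus = pair$label, order = pair$order,
            repetition = reps[[key]], half = h, time = tt)
      }
    }
  }
  bundle <- do.call(rbind, out)
  attr(bundle, "metadata") <- list(velocity_mm_s = 10, force_mN = 400,
                                   stimulation = list(amplitude_uA = 160,
                                                      width_us = 100))
  bundle
}

#' Run the full simulate-encode-analyse-behave pipeline
#'
#' Composes the whole chain end to end under a single master seed:
#' synthetic sensor traces for randomized 16-trial sessions, Izhikevich
#' encoding, temporal-code metrics, ideal-observer responses, behavioural
#' scoring with exact binomial intervals, the delta-IBI / delta-AFR
#' regressions on delta-SP, and the logistic psychometric fit.
#'
#' @param config A [default_config()] list.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_sessions < 1) stop("config must request at least one session")
  trials <- run_sessions(n_sessions = config$n_sessions,
                         protocol = config$protocol,
                         calib = config$calibration,
                         params = config$encoder,
                         tau = config$observer$tau,
                         decision_noise_sd = config$observer$decision_noise_sd,
                         seed = derive_seed(seed, 1000000))
  sc <- score_trials(trials)
  ci <- clopper_pearson(sc$n_correct, sc$n_trials)
  reg_ibi <- feature_vs_dsp_regression(trials, "delta_ibi")
  reg_afr <- feature_vs_dsp_regression(trials, "delta_afr")
  fd <- fraction_different_by_dsp(trials)
  lf <- logistic_fit(fd$abs_delta_sp, fd$fraction_different, fd$n)
  structure(list(seed = seed, config = config, trials = trials,
                 score = sc, confidence_interval = ci,
                 chance_level = 1 / 3,
                 regression_delta_ibi = reg_ibi,
                 regression_delta_afr = reg_afr,
                 fraction_different = fd, logistic = lf),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (seed %d): %d sessions, %d trials\n",
              x$seed, x$config$n_sessions, x$score$n_trials))
  cat(sprintf("  proportion correct: %.3f (95%% CI %.3f-%.3f; chance %.3f)\n",
              x$score$proportion_correct, x$confidence_interval["lower"],
              x$confidence_interval["upper"], x$chance_level))
  cat(sprintf("  delta-IBI ~ delta-SP: slope %.1f ms/mm, R^2 = %.4f\n",
              x$regression_delta_ibi$slope, x$regression_delta_ibi$r_squared))
  cat(sprintf("  delta-AFR ~ delta-SP: slope %.2f sp/s/mm, R^2 = %.4f\n",
              x$regression_delta_afr$slope, x$regression_delta_afr$r_squared))
  cat(sprintf("  psychometric logistic fit: R^2 = %.3f\n",
              x$logistic$r_squared))
  invisible(x)
}
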