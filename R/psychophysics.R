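#' Build one randomized 16-trial session plan
#'
#' A session is a uniformly random permutation of the fixed trial multiset:
#' 4 presentations of each of the 4 surfaces, of which 2 in SP1-SP2 order
#' (`"+"`) and 2 reversed (`"-"`).
#'
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return A data frame of class `session_plan` with one row per trial:
#'   `trial`, `label`, `order`, `first_sp`, `second_sp`, `delta_sp`.
#' @export
build_session <- function(seed = NULL) {
  base <- expand.grid(label = names(.stimulus_set),
                      order = c("+", "-"), rep = 1:2,
                      stringsAsFactors = FALSE)
  perm <- with_seed(seed, sample.int(nrow(base)))
  base <- base[perm, c("label", "order")]
  rows <- lapply(seq_len(nrow(base)), function(i) {
    p <- make_stimulus_pair(base$label[i], base$order[i])
    data.frame(trial = i, label = p$label, order = p$order,
               first_sp = p$first_sp, second_sp = p$second_sp,
               delta_sp = p$delta_sp)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("session_plan", class(out))
  out
}

#' Ideal-observer decoder for one presentation
#'
#' A synthetic subject standing in for the human: it reads the inter-burst
#' interval difference between the two halves, perturbs it with Gaussian
#' decision noise, and answers `"same"` when the noisy delta-IBI falls
#' within `+/- tau`, otherwise naming the half with the larger IBI (the
#' coarser grating) as coarser.  An undefined delta-IBI forces a random
#' guess among the three responses.
#'
#' @param features A [pair_features()] object.
#' @param tau Decision band, ms (default 50: half the smallest nonzero
#'   delta-IBI in the stimulus set at 10 mm/s).
#' @param decision_noise_sd Gaussian noise on delta-IBI, ms.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return One of `"first_coarser"`, `"second_coarser"`, `"same"`, with
#'   attribute `guessed = TRUE` when the response was a forced guess.
#' @export
ideal_observer <- function(features, tau = 50, decision_noise_sd = 0,
                           seed = NULL) {
  stopifnot(inherits(features, "pair_features"))
  if (tau <= 0) stop("tau must be positive")
  with_seed(seed, {
    if (!features$ibi_defined || !is.finite(features$delta_ibi)) {
      r <- sample(c("first_coarser", "second_coarser", "same"), 1)
      return(structure(r, guessed = TRUE))
    }
    x <- features$delta_ibi +
      if (decision_noise_sd > 0) rnorm(1, 0, decision_noise_sd) else 0
    if (abs(x) < tau) "same" else if (x > 0) "first_coarser" else "second_coarser"
  })
}

# correct response implied by a pair's signed delta_sp
correct_response <- function(delta_sp) {
  if (delta_sp > 0) "first_coarser" else if (delta_sp < 0) "second_coarser" else "same"
}

#' Score a set of trials
#'
#' Tabulates responses into a stimulus-by-response confusion matrix and the
#' overall proportion correct.  A response is correct when it matches the
#' sign of (first SP - second SP), with `"same"` correct only for equal
#' halves.
#'
#' @param trials A data frame with columns `label`, `order`, `delta_sp`
#'   and `response`.
#' @return A list of class `score`: `confusion` (stimulus x response
#'   counts), `n_correct`, `n_trials`, `proportion_correct`, and the
#'   trials with a `correct` column appended.
#' @export
score_trials <- function(trials) {
  if (nrow(trials) < 1) stop("no trials to score")
  trials$correct <- vapply(seq_len(nrow(trials)), function(i)
    trials$response[i] == correct_response(trials$delta_sp[i]), logical(1))
  stim <- factor(paste0(trials$label, trials$order))
  resp <- factor(trials$response,
                 levels = c("first_coarser", "second_coarser", "same"))
  confusion <- table(stimulus = stim, response = resp)
  structure(list(confusion = confusion,
                 n_correct = sum(trials$correct),
                 n_trials = nrow(trials),
                 proportion_correct = mean(trials$correct),
                 trials = trials),
            class = "score")
}

#' @export
print.score <- function(x, ...) {
  cat(sprintf("%d / %d correct (%.1f%%)\n", x$n_correct, x$n_trials,
              100 * x$proportion_correct))
  print(x$confusion)
  invisible(x)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact interval for a binomial proportion: the lower bound is the
#' success probability at which observing `k` or more successes has
#' probability `alpha/2`, and the upper bound that at which observing `k`
#' or fewer has probability `alpha/2`.  Bounds are found by root-finding
#' on the binomial distribution function; `k = 0` pins the lower bound at
#' 0 and `k = n` the upper bound at 1.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param alpha 1 - confidence level (default 0.05 for 95% intervals).
#' @return A named vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (length(k) != 1 || length(n) != 1 || n < 1 || k < 0 || k > n ||
      k != round(k) || n != round(n))
    stop("require integers 0 <= k <= n, n >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  lower <- if (k == 0) 0 else
    uniroot(function(p) 1 - pbinom(k - 1, n, p) - alpha / 2,
            c(0, 1), tol = 1e-12)$root
  upper <- if (k == n) 1 else
    uniroot(function(p) pbinom(k, n, p) - alpha / 2,
            c(0, 1), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

#' Logistic psychometric fit
#'
#' Binomial regression with a logit link of the fraction of `"different"`
#' responses on a one-dimensional stimulus axis (|delta-SP|, |delta-IBI| or
#' |delta-AFR|), with an intercept.  Goodness of fit is the squared Pearson
#' correlation between observed and fitted fractions, with the correlation
#' significance reported.
#'
#' @param delta Stimulus axis values (one per point).
#' @param fraction_different Observed fractions in `[0, 1]`.
#' @param trials_per_point Number of trials behind each fraction (scalar or
#'   vector).
#' @param coef_cap Absolute bound on coefficients beyond which the fit is
#'   flagged as separated/non-converged.
#' @return A list: `intercept`, `slope`, their standard errors, `fitted`,
#'   `r_squared`, `p_value` (Pearson correlation test, `NA` with fewer
#'   than 3 points of variation), and `converged`.
#' @export
logistic_fit <- function(delta, fraction_different, trials_per_point,
                         coef_cap = 50) {
  stopifnot(length(delta) == length(fraction_different))
  if (length(delta) < 3) stop("need at least 3 points")
  if (any(fraction_different < 0 | fraction_different > 1))
    stop("fractions must lie in [0, 1]")
  n <- rep_len(trials_per_point, length(delta))
  succ <- round(fraction_different * n)
  fit <- suppressWarnings(glm(cbind(succ, n - succ) ~ delta,
                              family = binomial()))
  converged <- fit$converged && all(abs(coef(fit)) < coef_cap)
  cf <- pmin(pmax(coef(fit), -coef_cap), coef_cap)
  fitted_frac <- 1 / (1 + exp(-(cf[1] + cf[2] * delta)))
  r2 <- if (sd(fraction_different) > 0 && sd(fitted_frac) > 0)
    cor(fraction_different, fitted_frac)^2 else NA_real_
  p <- if (is.finite(r2) && length(delta) >= 3)
    tryCatch(cor.test(fraction_different, fitted_frac)$p.value,
             error = function(e) NA_real_) else NA_real_
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 2))
  list(intercept = unname(cf[1]), slope = unname(cf[2]),
       se_intercept = unname(se[1]), se_slope = unname(se[2]),
       fitted = fitted_frac, r_squared = r2, p_value = p,
       converged = converged)
}

#' Fraction of trials perceived as different, by |delta-SP|
#'
#' Aggregates responses over presentation orders: a trial counts as
#' "different" when the response is not `"same"`.
#'
#' @param trials A data frame with columns `delta_sp` and `response`.
#' @return A data frame with `abs_delta_sp`, `fraction_different`, `n`.
#' @export
fraction_different_by_dsp <- function(trials) {
  d <- abs(trials$delta_sp)
  if (length(unique(d)) < 2)
    stop("trials must cover at least 2 delta-SP levels")
  agg <- aggregate(list(fraction_different = trials$response != "same"),
                   by = list(abs_delta_sp = d), FUN = mean)
  agg$n <- as.vector(table(d))
  agg
}

#' Run sessions of the 3AFC protocol against the ideal observer
#'
#' Generates `n_sessions` randomized sessions, synthesizes and encodes the
#' sensor trace for every trial, computes pair features, and records the
#' ideal observer's response.
#'
#' @param n_sessions Number of 16-trial sessions.
#' @param protocol A [sliding_protocol()].
#' @param calib A [sensor_calibration()].
#' @param params An [encoder_params()].
#' @param tau,decision_noise_sd Observer settings, ms.
#' @param seed Master seed; per-trial seeds are derived with
#'   [derive_seed()].
#' @return A data frame with one row per trial: session, trial, label,
#'   order, delta_sp, delta_ibi, delta_afr, response.
#' @export
run_sessions <- function(n_sessions = 5, protocol = sliding_protocol(),
                         calib = sensor_calibration(),
                         params = encoder_params(),
                         tau = 50, decision_noise_sd = 0, seed = 1) {
  if (n_sessions < 1) stop("need at least one session")
  out <- list()
  counter <- 0
  for (s in seq_len(n_sessions)) {
    plan <- build_session(derive_seed(seed, counter <- counter + 1))
    for (i in seq_len(nrow(plan))) {
      pair <- make_stimulus_pair(plan$label[i], plan$order[i])
      trace <- synth_sensor_trace(pair, protocol, calib,
                                  seed = derive_seed(seed, counter <- counter + 1))
      enc <- encode_trial(trace, params)
      m1 <- compute_metrics(enc$halves[[1]], protocol$slide_duration)
      m2 <- compute_metrics(enc$halves[[2]], protocol$slide_duration)
      feat <- pair_features(m1, m2, pair)
      resp <- ideal_observer(feat, tau, decision_noise_sd,
                             seed = derive_seed(seed, counter <- counter + 1))
      out[[length(out) + 1]] <- data.frame(
        session = s, trial = i, label = pair$label, order = pair$order,
        delta_sp = pair$delta_sp, delta_ibi = feat$delta_ibi,
        delta_afr = feat$delta_afr, response = as.character(resp))
    }
  }
  do.call(rbind, out)
}
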