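#' Parameters of the Izhikevich artificial mechanoreceptor
#'
#' The published parameter set of the mechano-neuro-transduction encoder.
#' The dynamics follow the canonical millisecond/millivolt Izhikevich
#' convention, `dv/dt = A v^2 + B v + C - u + I` with `a = 0.02`,
#' `b = 0.2`, `c = -65`, `d = 8` (the regular-spiking cell); the sensor
#' drive enters as `I = K * max(S_x, 0)` with `R = C_m = 1`.
#'
#' @param K Input gain applied to the rectified differential signal.
#' @param A,B,C Quadratic membrane coefficients.
#' @param a Recovery time scale.
#' @param b Recovery sensitivity.
#' @param c Post-spike reset potential, mV.
#' @param d Post-spike recovery increment.
#' @param v_th Spike threshold, mV.
#' @param R,C_m Input resistance and membrane capacitance (both 1, so the
#'   drive term is numerically `I`).
#' @param dt Euler integration sub-step, ms.
#' @return An object of class `encoder_params`.
#' @export
encoder_params <- function(K = 15000, A = 0.04, B = 5, C = 140,
                           a = 0.02, b = 0.2, c = -65, d = 8,
                           v_th = 30, R = 1, C_m = 1, dt = 0.1) {
  if (dt <= 0) stop("dt must be positive")
  if (v_th <= c) stop("v_th must exceed the reset potential c")
  structure(list(K = K, A = A, B = B, C = C, a = a, b = b, c = c, d = d,
                 v_th = v_th, R = R, C_m = C_m, dt = dt),
            class = "encoder_params")
}

#' Resting state of the encoder neuron
#'
#' The resting fixed point of the default parameter set: `v0 = -70` mV
#' solves `0.04 v^2 + 5 v + 140 - u = 0` with `u = b v`, and `u0 = b v0`.
#'
#' @param v0 Initial membrane potential, mV.
#' @param b Recovery sensitivity used for `u0 = b * v0`.
#' @return A list with components `v` and `u`.
#' @export
neuron_state <- function(v0 = -70, b = 0.2) list(v = v0, u = b * v0)

#' Differential shear signal
#'
#' Pointwise difference of the two opposing piezoresistive channels,
#' `S_x = S_x+ - S_x-`: the component of the sensor output correlated with
#' the frictional shear along the sliding direction.
#'
#' @param trace A `sensor_trace`, or a list with numeric `s_plus`/`s_minus`.
#' @return Numeric vector, same length as the channels.
#' @export
differential <- function(trace) {
  if (length(trace$s_plus) != length(trace$s_minus))
    stop("channel length mismatch: s_plus has ", length(trace$s_plus),
         " samples, s_minus has ", length(trace$s_minus))
  trace$s_plus - trace$s_minus
}

#' Half-rectified, amplified drive current
#'
#' `I_x = K * S_x` where `S_x >= 0`, and 0 elsewhere.  The output is
#' non-negative at every sample.
#'
#' @param sx Differential signal.
#' @param K Gain (default from [encoder_params()]).
#' @return Non-negative numeric vector.
#' @export
drive_current <- function(sx, K = 15000) {
  K * pmax(sx, 0)
}

#' Encode a drive-current series into a spike train
#'
#' Forward-Euler integration of the Izhikevich membrane equations with the
#' input held constant within each sensor sample (zero-order hold) and
#' sub-stepped at `params$dt` ms; the remainder of each sample interval is
#' absorbed in the last sub-step.  A spike is recorded whenever the membrane
#' potential reaches `v_th`, after which `v` is reset to `c` and `u`
#' incremented by `d`.
#'
#' @param I Drive current at the sensor sampling rate.
#' @param sample_rate Sensor sampling rate, Hz.
#' @param params An [encoder_params()] object.
#' @param initial Initial state from [neuron_state()].
#' @param record_v If `TRUE`, also return the membrane trajectory at
#'   sub-step resolution (for diagnostics).
#' @return An object of class `spike_train`: `spike_times` (s, strictly
#'   increasing), `duration` (s), plus the recorded trajectory if requested.
#' @export
izhikevich_encode <- function(I, sample_rate = 380, params = encoder_params(),
                              initial = neuron_state(b = params$b),
                              record_v = FALSE) {
  stopifnot(is.numeric(I), inherits(params, "encoder_params"))
  sample_dt_ms <- 1000 / sample_rate
  res <- izh_integrate_cpp(I, sample_dt_ms, params$dt,
                           params$A, params$B, params$C,
                           params$R * params$C_m,
                           params$a, params$b, params$c, params$d,
                           params$v_th, initial$v, initial$u,
                           record_v)
  out <- structure(list(spike_times = res$spike_times_ms / 1000,
                        duration = length(I) / sample_rate,
                        provenance = NULL),
                   class = "spike_train")
  if (record_v) out$v_trace <- res$v_trace
  out
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes over %.2f s\n",
              length(x$spike_times), x$duration))
  invisible(x)
}

#' Construct a spike train from raw event times
#'
#' @param spike_times Spike times in seconds (sorted if not already).
#' @param duration Trial duration, s; all times must lie within
#'   `[0, duration]`.
#' @param provenance Optional trial/stimulus identifier.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times, duration, provenance = NULL) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE))
    spike_times <- sort(spike_times)
  if (length(spike_times) && (min(spike_times) < 0 ||
                              max(spike_times) > duration + 1e-9))
    stop("spike times must lie within [0, duration]")
  structure(list(spike_times = spike_times, duration = duration,
                 provenance = provenance),
            class = "spike_train")
}

# window a spike train to [t0, t1), re-referencing times to t0
window_train <- function(train, t0, t1) {
  s <- train$spike_times
  s <- s[s >= t0 & s < t1] - t0
  spike_train(s, t1 - t0, train$provenance)
}

#' Encode one full trial
#'
#' Chains [differential()], [drive_current()] and [izhikevich_encode()] on a
#' sensor trace, and windows the resulting spike train to each sliding
#' phase using the trace's event markers (times re-referenced to slide
#' onset, the behavioural time-lock).
#'
#' @param trace A `sensor_trace` with event markers.
#' @param params An [encoder_params()] object.
#' @return A list of class `encoded_trial`: `full` (whole-trial
#'   `spike_train`), `halves` (list of two slide-windowed `spike_train`s),
#'   and the stimulus `pair` when the trace carries one.
#' @export
encode_trial <- function(trace, params = encoder_params()) {
  stopifnot(inherits(trace, "sensor_trace"))
  m <- trace$event_markers
  if (is.null(m) || !all(c("slide1", "slide2") %in% m$phase))
    stop("trace has no slide-phase event markers; cannot window the trial")
  I <- drive_current(differential(trace), params$K)
  full <- izhikevich_encode(I, trace$sample_rate, params)
  full$provenance <- if (!is.null(trace$pair))
    paste0(trace$pair$label, trace$pair$order) else NULL
  halves <- lapply(c("slide1", "slide2"), function(ph) {
    row <- m[m$phase == ph, ]
    window_train(full, row$onset, row$offset)
  })
  structure(list(full = full, halves = halves, pair = trace$pair),
            class = "encoded_trial")
}
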