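#' Sensor calibration for the synthetic fingertip
#'
#' Calibration of the generative model that stands in for the (unmodelled)
#' skin/sensor mechanics of the MEMS fingertip.  Each ridge crossing injects
#' one shear transient into the differential channel; the transient is a
#' fast raised-cosine attack (the fingertip snapping off the ridge edge)
#' followed by a slower raised-cosine release as it relaxes into the groove.
#' Both the pulse width and its amplitude grow with groove width
#' (SP - ridge width) through power laws, so coarser gratings drive longer
#' and slightly larger transients.
#'
#' Default values were fixed once so that the downstream encoder reproduces
#' the published spikes-per-ridge gradient (one spike per ridge at
#' SP 0.5 mm up to bursts at 2.0-3.0 mm) at near-constant overall firing
#' rate; see the package vignette.
#'
#' @param ridge_pulse_amplitude Pulse amplitude at the reference groove
#'   width of 0.25 mm, arbitrary sensor units.
#' @param amplitude_scaling_exponent Power-law exponent of amplitude vs
#'   (groove / 0.25).
#' @param base_width_ms Pulse width at the reference groove width, ms.
#' @param groove_scaling_exponent Power-law exponent of width vs
#'   (groove / 0.25).
#' @param attack_ms Raised-cosine attack time, ms.
#' @param pulse_shape Kernel name (only `"cos_attack_release"` implemented).
#' @param noise_sd Additive Gaussian noise sd per channel, sensor units.
#' @param gain_jitter_sd Trial-to-trial multiplicative gain jitter
#'   (lognormal sd); emulates contact-force and skin-condition variability
#'   across presentations.
#' @param phase_jitter If `TRUE` (default) the first ridge of each half
#'   passes at a uniformly random fraction of one spatial period after
#'   slide onset, emulating the uncontrolled alignment between grating and
#'   fingertip at the start of the slide.  `FALSE` locks the first ridge
#'   to slide onset.
#' @param baseline Channel baseline, sensor units.
#' @param indent_amplitude Common-mode indentation step amplitude (cancels
#'   in the differential channel).
#' @param indent_tau_s Indentation settle time constant, s.
#' @return An object of class `sensor_calibration`.
#' @export
sensor_calibration <- function(ridge_pulse_amplitude = 9e-4,
                               amplitude_scaling_exponent = 0.52,
                               base_width_ms = 10,
                               groove_scaling_exponent = 0.6,
                               attack_ms = 4,
                               pulse_shape = "cos_attack_release",
                               noise_sd = 3e-5,
                               gain_jitter_sd = 0.03,
                               phase_jitter = TRUE,
                               baseline = 0,
                               indent_amplitude = 0.02,
                               indent_tau_s = 0.3) {
  if (ridge_pulse_amplitude <= 0) stop("ridge_pulse_amplitude must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (gain_jitter_sd < 0) stop("gain_jitter_sd must be >= 0")
  pulse_shape <- match.arg(pulse_shape)
  structure(list(ridge_pulse_amplitude = ridge_pulse_amplitude,
                 amplitude_scaling_exponent = amplitude_scaling_exponent,
                 base_width_ms = base_width_ms,
                 groove_scaling_exponent = groove_scaling_exponent,
                 attack_ms = attack_ms,
                 pulse_shape = pulse_shape,
                 noise_sd = noise_sd,
                 gain_jitter_sd = gain_jitter_sd,
                 phase_jitter = phase_jitter,
                 baseline = baseline,
                 indent_amplitude = indent_amplitude,
                 indent_tau_s = indent_tau_s),
            class = "sensor_calibration")
}

# pulse width (ms) and amplitude for a given spatial period
.pulse_params <- function(sp, ridge_width, calib) {
  groove <- sp - ridge_width
  ratio <- groove / 0.25
  list(width_ms = calib$base_width_ms * ratio^calib$groove_scaling_exponent,
       amp = calib$ridge_pulse_amplitude * ratio^calib$amplitude_scaling_exponent)
}

# kernel sampled at offsets t_ms (>= 0) from the crossing time
.pulse_kernel <- function(t_ms, width_ms, attack_ms) {
  att <- min(attack_ms, width_ms / 2)
  rel <- width_ms - att
  y <- numeric(length(t_ms))
  i1 <- t_ms >= 0 & t_ms < att
  y[i1] <- 0.5 * (1 - cos(pi * t_ms[i1] / att))
  i2 <- t_ms >= att & t_ms <= width_ms
  y[i2] <- 0.5 * (1 + cos(pi * (t_ms[i2] - att) / rel))
  y
}

#' Generate a synthetic two-channel sensor trace for one trial
#'
#' Reproduces the full stimulation sequence of one trial (indent 4 s, slide
#' 2 s, hold 2 s, 3 s gap, then the second half-surface) as seen by the two
#' opposing piezoresistive channels S_x+ and S_x- sampled at the protocol
#' rate.  During each slide the differential channel carries one shear
#' transient per ridge crossing; static phases carry only the common-mode
#' indentation transient, baseline and noise.
#'
#' The generator is a pure function of `(pair, protocol, calib, seed)`.
#'
#' @param pair A [make_stimulus_pair()] object.
#' @param protocol A [sliding_protocol()].
#' @param calib A [sensor_calibration()].
#' @param seed Integer seed for the noise stream (`NULL` uses the current
#'   RNG stream).
#' @param ridge_width Ridge width in mm shared by all gratings.
#' @return An object of class `sensor_trace`: `time` (s), `s_plus`,
#'   `s_minus`, `sample_rate`, and `event_markers` (data frame with
#'   `phase`, `onset`, `offset` in s).
#' @export
synth_sensor_trace <- function(pair, protocol = sliding_protocol(),
                               calib = sensor_calibration(), seed = NULL,
                               ridge_width = 0.25) {
  stopifnot(inherits(pair, "stimulus_pair"),
            inherits(protocol, "sliding_protocol"),
            inherits(calib, "sensor_calibration"))
  p <- protocol
  half <- p$pre_slide_dwell + p$slide_duration + p$post_slide_dwell
  total <- half + p$inter_half_gap + half
  fs <- p$sample_rate
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs

  markers <- data.frame(
    phase = c("indent1", "slide1", "hold1", "gap",
              "indent2", "slide2", "hold2"),
    onset = c(0, p$pre_slide_dwell, p$pre_slide_dwell + p$slide_duration,
              half, half + p$inter_half_gap,
              half + p$inter_half_gap + p$pre_slide_dwell,
              half + p$inter_half_gap + p$pre_slide_dwell + p$slide_duration),
    stringsAsFactors = FALSE)
  markers$offset <- c(markers$onset[-1], total)

  with_seed(seed, {
    # common-mode indentation: step + exponential settle during contact,
    # decay during the gap; identical on both channels
    indent <- numeric(n)
    for (k in c(1, 2)) {
      on <- if (k == 1) 0 else half + p$inter_half_gap
      off <- on + half
      inc <- t >= on & t < off
      indent[inc] <- indent[inc] +
        calib$indent_amplitude * (1 - exp(-(t[inc] - on) / calib$indent_tau_s))
      post <- t >= off
      indent[post] <- indent[post] +
        calib$indent_amplitude * (1 - exp(-half / calib$indent_tau_s)) *
          exp(-(t[post] - off) / calib$indent_tau_s)
    }

    pulses <- numeric(n)
    crossings <- vector("list", 2)
    sps <- c(pair$first_sp, pair$second_sp)
    onsets <- c(markers$onset[markers$phase == "slide1"],
                markers$onset[markers$phase == "slide2"])
    for (k in c(1, 2)) {
      g <- grating_spec(sps[k], ridge_width,
                        length = p$velocity * p$slide_duration)
      pp <- .pulse_params(sps[k], ridge_width, calib)
      gain <- if (calib$gain_jitter_sd > 0)
        exp(rnorm(1, 0, calib$gain_jitter_sd)) else 1
      phase <- if (isTRUE(calib$phase_jitter))
        runif(1, 0, sps[k] / p$velocity) else 0
      cross <- phase + ridge_crossing_times(g, p$velocity, p$slide_duration)
      cross <- onsets[k] + cross[cross < p$slide_duration]
      crossings[[k]] <- cross
      for (tc in cross) {
        idx <- which(t >= tc & t <= tc + pp$width_ms / 1000 + 1 / fs)
        pulses[idx] <- pulses[idx] +
          gain * pp$amp * .pulse_kernel((t[idx] - tc) * 1000,
                                        pp$width_ms, calib$attack_ms)
      }
    }

    s_plus <- calib$baseline + indent + pulses +
      rnorm(n, 0, calib$noise_sd)
    s_minus <- calib$baseline + indent + rnorm(n, 0, calib$noise_sd)

    structure(list(time = t, s_plus = s_plus, s_minus = s_minus,
                   sample_rate = fs, event_markers = markers,
                   ridge_crossings = crossings,
                   pair = pair, protocol = p),
              class = "sensor_trace")
  })
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("Sensor trace: %d samples at %g Hz (%.2f s), stimulus %s%s\n",
              length(x$time), x$sample_rate,
              length(x$time) / x$sample_rate, x$pair$label, x$pair$order))
  invisible(x)
}

#' Write / read a sensor trace as columnar text
#'
#' The trace is written as a three-column table (time, s_plus, s_minus)
#' with the event markers in a sidecar table `<path>.markers`.  Writes are
#' atomic: the file appears complete or not at all.
#'
#' @param trace A `sensor_trace`.
#' @param path Output path.
#' @return `write_sensor_trace` returns `path` invisibly;
#'   `read_sensor_trace` returns a `sensor_trace` (without stimulus
#'   provenance).
#' @export
write_sensor_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  df <- data.frame(time = sprintf("%.6f", trace$time),
                   s_plus = trace$s_plus, s_minus = trace$s_minus)
  .atomic_write(function(f) write.csv(df, f, row.names = FALSE), path)
  .atomic_write(function(f) write.csv(trace$event_markers, f, row.names = FALSE),
                paste0(path, ".markers"))
  invisible(path)
}

#' @rdname write_sensor_trace
#' @export
read_sensor_trace <- function(path) {
  df <- read.csv(path)
  if (!all(c("time", "s_plus", "s_minus") %in% names(df)))
    stop("sensor trace file must have columns time, s_plus, s_minus")
  markers_path <- paste0(path, ".markers")
  markers <- if (file.exists(markers_path)) read.csv(markers_path) else NULL
  fs <- if (length(df$time) > 1) 1 / median(diff(df$time)) else NA_real_
  structure(list(time = df$time, s_plus = df$s_plus, s_minus = df$s_minus,
                 sample_rate = fs, event_markers = markers,
                 pair = NULL, protocol = NULL),
            class = "sensor_trace")
}

# atomic file write: write to a temp file in the target directory, rename
.atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  ok <- TRUE
  invisible(path)
}
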