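#' Grating geometry
#'
#' A grating is a surface of alternating ridges and grooves.  The spatial
#' period SP is the distance between consecutive ridge onsets (ridge +
#' groove); the ridge width is fixed across the stimulus set so that the
#' groove widens with SP.
#'
#' @param spatial_period Spatial period SP in mm.
#' @param ridge_width Ridge width in mm (default 0.25).
#' @param length Grating length in mm (default 20, one 2 s slide at 10 mm/s).
#' @return An object of class `grating_spec`.
#' @export
grating_spec <- function(spatial_period, ridge_width = 0.25, length = 20) {
  stopifnot(is.numeric(spatial_period), length(spatial_period) == 1)
  if (!(ridge_width > 0 && ridge_width < spatial_period))
    stop("ridge_width must satisfy 0 < ridge_width < spatial_period")
  if (length <= 0) stop("grating length must be positive")
  structure(list(spatial_period = spatial_period,
                 ridge_width = ridge_width,
                 length = length),
            class = "grating_spec")
}

# fixed stimulus set: label -> (SP1, SP2) in mm
.stimulus_set <- list(
  "D0.0" = c(1.5, 1.5),
  "D1.0" = c(2.0, 1.0),
  "D2.0" = c(3.0, 1.0),
  "D2.5" = c(3.0, 0.5)
)

#' The four paired grating surfaces of the discrimination protocol
#'
#' Each stimulus is a pair of half-surfaces presented in sequence.  The four
#' surfaces are labelled by the absolute difference in spatial period between
#' their halves: D0.0 (1.5, 1.5), D1.0 (2.0, 1.0), D2.0 (3.0, 1.0) and
#' D2.5 (3.0, 0.5) mm.  Order `"+"` presents SP1 then SP2; `"-"` swaps the
#' halves.
#'
#' @param label One of `"D0.0"`, `"D1.0"`, `"D2.0"`, `"D2.5"` (a leading
#'   Greek delta is also accepted).
#' @param order `"+"` or `"-"`.
#' @return An object of class `stimulus_pair` with fields `label`, `order`,
#'   `first_sp`, `second_sp` and `delta_sp` (signed, mm).
#' @examples
#' make_stimulus_pair("D1.0", "+")  # first 2.0 mm, second 1.0 mm
#' @export
make_stimulus_pair <- function(label, order = c("+", "-")) {
  label <- sub("^Δ", "D", as.character(label))
  order <- match.arg(order)
  if (!label %in% names(.stimulus_set))
    stop("unknown stimulus label '", label, "'; valid labels: ",
         paste(names(.stimulus_set), collapse = ", "))
  sp <- .stimulus_set[[label]]
  if (order == "-") sp <- rev(sp)
  structure(list(label = label, order = order,
                 first_sp = sp[1], second_sp = sp[2],
                 delta_sp = sp[1] - sp[2]),
            class = "stimulus_pair")
}

#' @export
print.stimulus_pair <- function(x, ...) {
  cat(sprintf("Stimulus %s%s: first half SP = %.1f mm, second half SP = %.1f mm\n",
              x$label, x$order, x$first_sp, x$second_sp))
  invisible(x)
}

#' Sliding stimulation protocol
#'
#' Timing and kinematics of one trial: the first half-surface is indented at
#' `indent_force` for `pre_slide_dwell` seconds, slid at `velocity` for
#' `slide_duration` seconds under regulated load, held for `post_slide_dwell`
#' seconds and detached; the second half follows after `inter_half_gap`
#' seconds.
#'
#' @param indent_force Normal load in mN (default 400).
#' @param pre_slide_dwell Static indentation before sliding, s (default 4).
#' @param velocity Sliding velocity, mm/s (default 10).
#' @param slide_duration Sliding time, s (default 2).
#' @param post_slide_dwell Static hold after sliding, s (default 2).
#' @param inter_half_gap Gap between half-surfaces, s (default 3).
#' @param sample_rate Sensor sampling rate per channel, Hz (default 380).
#' @return An object of class `sliding_protocol`.
#' @export
sliding_protocol <- function(indent_force = 400, pre_slide_dwell = 4,
                             velocity = 10, slide_duration = 2,
                             post_slide_dwell = 2, inter_half_gap = 3,
                             sample_rate = 380) {
  vals <- c(indent_force, pre_slide_dwell, velocity, slide_duration,
            post_slide_dwell, inter_half_gap, sample_rate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all protocol parameters must be positive and finite")
  structure(list(indent_force = indent_force,
                 pre_slide_dwell = pre_slide_dwell,
                 velocity = velocity,
                 slide_duration = slide_duration,
                 post_slide_dwell = post_slide_dwell,
                 inter_half_gap = inter_half_gap,
                 sample_rate = sample_rate,
                 slide_length = velocity * slide_duration),
            class = "sliding_protocol")
}

#' Ridge-crossing times during a constant-velocity slide
#'
#' With the fingertip fixed and the grating translating at constant
#' velocity, ridge onsets pass under the sensor at a constant temporal
#' spacing SP / v.  The first ridge is taken to pass at slide onset (time 0).
#'
#' @param grating A [grating_spec()].
#' @param velocity Sliding velocity, mm/s.
#' @param duration Slide duration, s.
#' @return Strictly increasing crossing times in seconds, `< duration`.
#' @export
ridge_crossing_times <- function(grating, velocity, duration) {
  stopifnot(inherits(grating, "grating_spec"))
  if (velocity <= 0) stop("velocity must be positive")
  if (duration < 0) stop("duration must be non-negative")
  period <- grating$spatial_period / velocity
  if (duration == 0) return(numeric(0))
  n <- ceiling(duration / period)
  tt <- seq(0, by = period, length.out = n)
  tt[tt < duration - 1e-12]
}
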