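# Transient flow waveforms: e-cigarette puffs, the sinusoidal exhalation,
# and the bystander's periodic nasal breathing cycle.
#
# Sign convention (package-wide): positive flow is INTO the airway
# (inhalation), negative flow is out (exhalation).

PUFF_KINDS <- c("short_puff", "long_puff", "post_puff", "exhalation", "custom")

#' Construct a flow waveform
#'
#' @param times Strictly increasing time grid starting at 0, s.
#' @param flow Volumetric flow at each grid point, m^3/s. Positive = into
#'   the airway.
#' @param label One of `short_puff`, `long_puff`, `post_puff`,
#'   `exhalation`, `custom`.
#' @return A `flow_waveform`: list with `times`, `flow`, `label`.
#' @export
flow_waveform <- function(times, flow, label = "custom") {
  if (length(times) != length(flow) || length(times) < 2L) {
    stop_invalid("`times` and `flow` must be equal-length vectors (>= 2 points)")
  }
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop_invalid("`times` must start at 0 and be strictly increasing")
  }
  if (!all(is.finite(flow))) stop_invalid("`flow` must be finite everywhere")
  label <- match.arg(label, PUFF_KINDS)
  structure(list(times = times, flow = flow, label = label),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat("<flow_waveform>", x$label, "| support",
      format(max(x$times), digits = 4), "s | volume",
      format(waveform_volume(x), digits = 4), "m^3\n")
  invisible(x)
}

#' Signed volume of a waveform
#'
#' Trapezoidal integral of flow over time. For a waveform built by
#' [build_puff()] this returns the requested volume to 1e-9 relative by
#' construction.
#'
#' @param w A [flow_waveform].
#' @return Signed volume, m^3.
#' @export
waveform_volume <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  trapz_(w$times, w$flow)
}

# Sample a unit-peak shape on [0, T]; area is normalized afterwards so the
# discrete trapezoid integral matches the requested volume exactly.
shape_samples <- function(shape, times, duration, peak_frac = 0.25) {
  switch(shape,
    half_sine  = sin(pi * times / duration),
    triangular = {
      tp <- peak_frac * duration
      ifelse(times <= tp, times / tp, (duration - times) / (duration - tp))
    },
    stop_invalid("unknown waveform shape: ", shape)
  )
}

#' Build an inhalation puff waveform
#'
#' Constructs the transient flow profile of an e-cigarette puff. The
#' default study profiles are a short puff (2.43 s), a long puff (5.0 s)
#' and a post puff (1.34 s, high flow). Short/long puffs default to a
#' half-sine; the post puff defaults to an early-peaking triangle, which
#' gives the higher peak flow that drives vapor toward the bronchi.
#' The sampled flow is scaled so its trapezoidal integral equals `volume`
#' to 1e-9 relative.
#'
#' @param kind Waveform label (`short_puff`, `long_puff`, `post_puff`,
#'   `custom`).
#' @param duration Inhalation time, s.
#' @param volume Puff volume, m^3 (default 55 mL, a standard machine-puff
#'   convention).
#' @param shape `half_sine` or `triangular`.
#' @param dt Sampling step, s.
#' @return A [flow_waveform] with non-negative flow.
#' @export
#' @examples
#' p <- build_puff("short_puff", duration = 2.43)
#' waveform_volume(p) # 5.5e-05
build_puff <- function(kind = "custom", duration, volume = 55e-6,
                       shape = if (identical(kind, "post_puff")) "triangular"
                               else "half_sine",
                       dt = 0.01) {
  check_positive(duration, "duration")
  check_positive(volume, "volume")
  check_positive(dt, "dt")
  shape <- match.arg(shape, c("half_sine", "triangular"))
  times <- unique(c(seq(0, duration, by = dt), duration))
  y <- shape_samples(shape, times, duration)
  area <- trapz_(times, y)
  flow_waveform(times, y * (volume / area), label = kind)
}

#' Build the exhalation waveform
#'
#' Half-sine (sinusoidal) expiratory profile, negative-signed under the
#' package flow convention. Exhaled volume defaults to the inhaled puff
#' volume; expiratory time is 1.8 s after short/long puffs and 2.5 s after
#' a post puff in the default scenarios.
#'
#' @param volume Exhaled volume (magnitude), m^3.
#' @param duration Expiratory time, s.
#' @param dt Sampling step, s.
#' @return A [flow_waveform] with non-positive flow and
#'   `|integral| == volume`.
#' @export
build_exhalation <- function(volume, duration, dt = 0.01) {
  p <- build_puff("custom", duration = duration, volume = volume,
                  shape = "half_sine", dt = dt)
  flow_waveform(p$times, -p$flow, label = "exhalation")
}

#' Nasal breathing cycle
#'
#' Periodic sinusoidal breathing: inhalation during the first half of each
#' period, exhalation during the second, with equal volumes. The peak flow
#' is set so the average inhaled volume per minute equals `minute_volume`.
#'
#' @param minute_volume Respiratory minute volume, m^3/min (default 6 L/min,
#'   resting adult).
#' @param period Breath period, s (default 4 s: three breaths in a 12 s
#'   exposure window).
#' @param inhale_fraction Fraction of the period spent inhaling (0.5 for the
#'   symmetric sinusoid; only 0.5 is currently supported).
#' @return A `breathing_cycle` object.
#' @export
build_nasal_cycle <- function(minute_volume = 6e-3, period = 4,
                              inhale_fraction = 0.5) {
  check_positive(minute_volume, "minute_volume")
  check_positive(period, "period")
  if (!identical(inhale_fraction, 0.5)) {
    stop_invalid("only the symmetric sinusoidal cycle (inhale_fraction = 0.5) is supported")
  }
  structure(
    list(period = period, minute_volume = minute_volume,
         inhale_fraction = inhale_fraction, waveform_shape = "sinusoidal",
         peak_flow = pi * minute_volume / 60),
    class = "breathing_cycle"
  )
}

#' Sample a breathing cycle onto a time grid
#'
#' When the period is an integer number of steps the flow values are taken
#' from a single precomputed period table, so windows shifted by one period
#' reproduce the flow bit-exactly.
#'
#' @param cycle A `breathing_cycle`.
#' @param t_start,t_end Window bounds, s (`t_end > t_start`).
#' @param dt Sampling step, s.
#' @return A [flow_waveform] on `times = seq(0, t_end - t_start, dt)`
#'   holding the flow at absolute times `t_start + times`.
#' @export
sample_cycle <- function(cycle, t_start, t_end, dt = 0.01) {
  stopifnot(inherits(cycle, "breathing_cycle"))
  check_positive(dt, "dt")
  if (t_end - t_start < dt) stop_invalid("window must be at least one `dt` long")
  n <- floor((t_end - t_start) / dt + 1e-9)
  times <- (0:n) * dt
  steps_per_period <- cycle$period / dt
  if (abs(steps_per_period - round(steps_per_period)) < 1e-9) {
    m <- as.integer(round(steps_per_period))
    table <- cycle$peak_flow * sin(2 * pi * (0:(m - 1L)) / m)
    i0 <- as.integer(round(t_start / dt))
    flow <- table[((i0 + 0:n) %% m) + 1L]
  } else {
    tt <- (t_start + times) %% cycle$period
    flow <- cycle$peak_flow * sin(2 * pi * tt / cycle$period)
  }
  flow_waveform(times, flow, label = "custom")
}

#' Concatenate an inhalation and an exhalation waveform
#'
#' Appends `second` after `first` on a common clock (the first sample of
#' `second` lands one step after the last sample of `first`).
#'
#' @param first,second [flow_waveform]s.
#' @return A [flow_waveform].
#' @export
concat_waveforms <- function(first, second) {
  stopifnot(inherits(first, "flow_waveform"), inherits(second, "flow_waveform"))
  t_off <- max(first$times)
  flow_waveform(c(first$times, t_off + second$times[-1]),
                c(first$flow, second$flow[-1]),
                label = "custom")
}
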