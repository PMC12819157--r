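#' Voltage protocol
#'
#' A parametric description of the voltage waveform applied across the
#' membrane. Supported kinds: `"sinusoid"`, `"triangle"` (both periodic,
#' starting at 0 V and rising), `"constant"` (level = `baseline`),
#' `"pulse_train"` (each cycle is a pulse at `amplitude` for `pulse_width`
#' seconds followed by `inter_pulse_wait` seconds at `baseline`), and
#' `"custom"` (explicit samples).
#'
#' @param kind Protocol kind.
#' @param amplitude Peak voltage in V (pulse level for pulse trains).
#' @param frequency Frequency in Hz for periodic kinds.
#' @param baseline Baseline voltage in V.
#' @param pulse_width,inter_pulse_wait,n_pulses Pulse-train parameters
#'   (seconds, seconds, count).
#' @param duration Total duration in s (defaults: one period for periodic
#'   kinds, the full train for pulse trains).
#' @param sample_rate Sampling rate in Hz; must be at least 100 x frequency
#'   for periodic kinds.
#' @param time,voltage Explicit samples for `kind = "custom"`.
#' @return A `voltage_protocol` object.
#' @examples
#' p <- make_protocol("fig2c")   # 0.1 Hz, 200 mV sinusoid
#' s <- protocol_samples(p)
#' range(s$voltage)
#' @export
voltage_protocol <- function(kind = c("sinusoid", "triangle", "constant",
                                      "pulse_train", "custom"),
                             amplitude = 0.2, frequency = 0.1, baseline = 0,
                             pulse_width = 0.005, inter_pulse_wait = 0.01,
                             n_pulses = 30L, duration = NULL,
                             sample_rate = NULL, time = NULL, voltage = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("sinusoid", "triangle")) {
    if (frequency <= 0) stop("frequency must be positive")
    if (is.null(duration)) duration <- 1 / frequency
    if (is.null(sample_rate)) sample_rate <- 1e4
    if (sample_rate < 100 * frequency)
      stop("sample_rate must be >= 100 x frequency for periodic protocols")
  } else if (kind == "pulse_train") {
    if (pulse_width <= 0 || inter_pulse_wait < 0 || n_pulses < 1)
      stop("invalid pulse-train parameters")
    if (is.null(duration)) duration <- n_pulses * (pulse_width + inter_pulse_wait)
    if (is.null(sample_rate)) sample_rate <- 5e4
  } else if (kind == "constant") {
    if (is.null(duration)) stop("constant protocol needs a duration")
    if (is.null(sample_rate)) sample_rate <- 1e4
  } else { # custom
    if (is.null(time) || is.null(voltage) || length(time) != length(voltage))
      stop("custom protocol needs matching time and voltage samples")
    if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
    duration <- time[length(time)] - time[1]
    sample_rate <- 1 / stats::median(diff(time))
  }
  if (duration <= 0) stop("duration must be positive")
  structure(list(kind = kind, amplitude = amplitude, frequency = frequency,
                 baseline = baseline, pulse_width = pulse_width,
                 inter_pulse_wait = inter_pulse_wait,
                 n_pulses = as.integer(n_pulses), duration = duration,
                 sample_rate = sample_rate, time = time, voltage = voltage),
            class = "voltage_protocol")
}

#' Named protocol presets
#'
#' Presets matching the experimental forcing protocols: `"fig2a"` (2 Hz,
#' 200 mV triangle), `"fig2c"` (0.1 Hz, 200 mV sinusoid),
#' `"fig6_potentiation"` (+110 mV / 5 ms pulses, 10 ms waits at a -90 mV
#' baseline, 30 pulses) and `"fig6_depression"` (-110 mV / 10 ms pulses,
#' same waits and baseline).
#'
#' @param kind Preset name or a [voltage_protocol()] kind.
#' @param ... Overrides passed to [voltage_protocol()].
#' @return A `voltage_protocol`.
#' @export
make_protocol <- function(kind, ...) {
  presets <- list(
    fig2a = list(kind = "triangle", amplitude = 0.2, frequency = 2),
    fig2c = list(kind = "sinusoid", amplitude = 0.2, frequency = 0.1),
    fig6_potentiation = list(kind = "pulse_train", amplitude = 0.110,
                             pulse_width = 0.005, inter_pulse_wait = 0.010,
                             baseline = -0.090, n_pulses = 30L),
    fig6_depression = list(kind = "pulse_train", amplitude = -0.110,
                           pulse_width = 0.010, inter_pulse_wait = 0.010,
                           baseline = -0.090, n_pulses = 30L))
  if (kind %in% names(presets)) {
    args <- utils::modifyList(presets[[kind]], list(...))
  } else if (kind %in% c("sinusoid", "triangle", "constant", "pulse_train", "custom")) {
    args <- c(list(kind = kind), list(...))
  } else stop("unknown protocol preset: ", kind)
  do.call(voltage_protocol, args)
}

#' Sample a voltage protocol
#'
#' @param protocol A [voltage_protocol()].
#' @param sample_rate Optional override of the protocol's sample rate (Hz).
#' @return A list with `time` (s) and `voltage` (V), uniformly sampled.
#' @export
protocol_samples <- function(protocol, sample_rate = NULL) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  if (protocol$kind == "custom")
    return(list(time = protocol$time, voltage = protocol$voltage))
  fs <- if (is.null(sample_rate)) protocol$sample_rate else sample_rate
  n <- max(2L, round(protocol$duration * fs))
  t <- (seq_len(n) - 1) / fs
  v <- switch(protocol$kind,
    sinusoid = protocol$baseline +
      protocol$amplitude * sin(2 * pi * protocol$frequency * t),
    triangle = {
      ph <- (protocol$frequency * t) %% 1
      protocol$baseline + protocol$amplitude *
        ifelse(ph < 0.25, 4 * ph, ifelse(ph < 0.75, 2 - 4 * ph, 4 * ph - 4))
    },
    constant = rep(protocol$baseline, n),
    pulse_train = {
      cyc <- protocol$pulse_width + protocol$inter_pulse_wait
      tin <- t %% cyc
      on <- tin < protocol$pulse_width & t < protocol$n_pulses * cyc
      ifelse(on, protocol$amplitude, protocol$baseline)
    })
  list(time = t, voltage = v)
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %s, amplitude %.3g V, %.3g Hz, duration %.3g s @ %.3g Hz\n",
              x$kind, x$amplitude, x$frequency, x$duration, x$sample_rate))
  invisible(x)
}
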