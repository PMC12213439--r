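#' Blood pressure pulse specification
#'
#' Describes one idealized arterial pulse: systolic and diastolic pressures,
#' the beat duration `T`, and the systolic (upstroke) duration `Ts`. By
#' default the upstroke occupies 30% of the beat, a typical systolic
#' fraction at resting heart rates.
#'
#' @param ps,pd Systolic and diastolic pressure, mmHg (`ps > pd`).
#' @param period Beat duration `T`, s.
#' @param systolic_duration Upstroke duration `Ts`, s (`0 < Ts < T`).
#' @return An object of class `bp_pulse`.
#' @export
bp_pulse <- function(ps = 120, pd = 80, period = 1,
                     systolic_duration = 0.3 * period) {
  check_bp(ps, pd)
  if (!is.finite(period) || period <= 0) abort("`period` must be positive.")
  if (!is.finite(systolic_duration) || systolic_duration <= 0 ||
      systolic_duration >= period) {
    abort("`systolic_duration` must lie strictly between 0 and `period`.")
  }
  structure(list(ps = ps, pd = pd, period = period,
                 systolic_duration = systolic_duration),
            class = "bp_pulse")
}

#' Cuff inflation/deflation protocol
#'
#' Fast linear inflation (fixed 5 s), slow linear deflation at
#' `deflation_rate`, then a constant hold. Deflation rates of 2-4 mmHg/s are
#' standard for oscillometric devices; the hold emulates the constant
#' 60 mmHg terminal segment of clinical recordings.
#'
#' @param inflate_to Peak cuff pressure, mmHg.
#' @param deflation_rate Deflation rate, mmHg/s (> 0).
#' @param hold_pressure Terminal hold pressure, mmHg (< `inflate_to`).
#' @param hold_duration Hold duration, s.
#' @param sampling_rate Sampling rate, Hz.
#' @return An object of class `cuff_protocol`.
#' @export
cuff_protocol <- function(inflate_to = 180, deflation_rate = 3,
                          hold_pressure = 60, hold_duration = 10,
                          sampling_rate = 250) {
  if (deflation_rate <= 0) abort("`deflation_rate` must be positive.")
  if (inflate_to <= hold_pressure) {
    abort("`inflate_to` must exceed `hold_pressure`.")
  }
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  structure(list(inflate_to = inflate_to, deflation_rate = deflation_rate,
                 hold_pressure = hold_pressure, hold_duration = hold_duration,
                 sampling_rate = sampling_rate, inflation_duration = 5),
            class = "cuff_protocol")
}

new_waveform <- function(time, value, unit = "mmHg") {
  out <- tibble(time_s = time, value = value)
  attr(out, "unit") <- unit
  class(out) <- c("waveform", class(out))
  out
}

#' Sampling rate of a uniformly sampled waveform
#'
#' @param wf A waveform tibble with a `time_s` column.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(wf) {
  dt <- diff(wf$time_s)
  if (length(dt) == 0) abort("Waveform has fewer than two samples.")
  if (max(dt) - min(dt) > 1e-6) {
    abort("Waveform is not uniformly sampled (time jitter exceeds 1e-6 s).")
  }
  1 / mean(dt)
}

check_waveform <- function(wf, arg = "waveform") {
  if (!is.data.frame(wf) || !all(c("time_s", "value") %in% names(wf))) {
    abort(sprintf("`%s` must be a waveform tibble with columns time_s, value.",
                  arg))
  }
  if (anyNA(wf$value) || any(!is.finite(wf$value))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  wf
}

# Direct evaluation of the triangular pulse at within-beat times tau in [0, T).
triangle_value <- function(tau, pulse) {
  pp <- pulse$ps - pulse$pd
  ts <- pulse$systolic_duration
  ifelse(tau < ts,
         pulse$pd + pp * tau / ts,
         pulse$ps - pp * (tau - ts) / (pulse$period - ts))
}

#' Triangular arterial pressure waveform
#'
#' Samples the piecewise-linear pulse assumed by the closed-form area
#' oscillogram model: per beat, a linear rise from `pd` to `ps` over the
#' systolic duration and a linear fall back to `pd` over the remainder.
#'
#' @param pulse A [bp_pulse()].
#' @param n_beats Number of beats (>= 1).
#' @param sampling_rate Sampling rate, Hz.
#' @return A waveform tibble (`time_s`, `value` in mmHg).
#' @export
triangular_bp <- function(pulse, n_beats = 60, sampling_rate = 250) {
  stopifnot(inherits(pulse, "bp_pulse"), n_beats >= 1)
  t <- seq(0, n_beats * pulse$period - 1 / sampling_rate,
           by = 1 / sampling_rate)
  tau <- t %% pulse$period
  new_waveform(t, triangle_value(tau, pulse))
}

#' Smooth quasi-realistic arterial pressure waveform
#'
#' A band-limited surrogate for an invasive arterial pressure waveform:
#' a truncated Fourier reconstruction of the asymmetric triangular pulse
#' (sharper upstroke than downstroke), rescaled per beat so each beat attains
#' exactly `ps` and `pd`. Optional Gaussian beat-to-beat interval jitter is
#' reproducible under `seed`.
#'
#' @inheritParams triangular_bp
#' @param harmonics Number of Fourier harmonics retained (>= 2; default 8).
#' @param beat_jitter Standard deviation of beat-interval jitter, s.
#' @param seed Integer seed for the jitter (required when `beat_jitter > 0`).
#' @return A waveform tibble (`time_s`, `value` in mmHg).
#' @export
realistic_bp <- function(pulse, n_beats = 60, sampling_rate = 250,
                         harmonics = 8, beat_jitter = 0, seed = NULL) {
  stopifnot(inherits(pulse, "bp_pulse"), n_beats >= 1)
  if (harmonics < 2) abort("`harmonics` must be at least 2.")
  # Fourier coefficients of the asymmetric triangle on one period, evaluated
  # on a fine phase grid; reconstruction keeps DC + `harmonics` terms.
  nref <- 2048L
  phi <- (seq_len(nref) - 1) / nref
  ref <- triangle_value(phi * pulse$period, pulse)
  co <- fft(ref) / nref
  template <- function(ph) {
    # ph in [0, 1)
    v <- Re(co[1])
    for (h in seq_len(harmonics)) {
      v <- v + 2 * (Re(co[h + 1]) * cos(2 * pi * h * ph) -
                      Im(co[h + 1]) * sin(2 * pi * h * ph))
    }
    v
  }
  periods <- rep(pulse$period, n_beats)
  if (beat_jitter > 0) {
    if (is.null(seed)) abort("`seed` is required when `beat_jitter > 0`.")
    periods <- local_seed(seed, {
      pmax(0.5 * pulse$period,
           pulse$period + rnorm(n_beats, sd = beat_jitter))
    })
  }
  dt <- 1 / sampling_rate
  t <- seq(0, sum(periods) - dt, by = dt)
  starts <- cumsum(c(0, periods))
  beat <- findInterval(t, starts, rightmost.closed = FALSE)
  beat[beat > n_beats] <- n_beats
  ph <- (t - starts[beat]) / periods[beat]
  v <- template(ph %% 1)
  # per-beat affine rescale to hit ps/pd exactly
  for (ib in seq_len(n_beats)) {
    idx <- which(beat == ib)
    if (length(idx) < 2) next
    vmax <- max(v[idx]); vmin <- min(v[idx])
    v[idx] <- pulse$pd + (v[idx] - vmin) / (vmax - vmin) *
      (pulse$ps - pulse$pd)
  }
  new_waveform(t, v)
}

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' Cuff pressure ramp for a protocol
#'
#' @param protocol A [cuff_protocol()].
#' @param duration Total duration, s. Defaults to inflation + full deflation
#'   + the protocol's hold duration.
#' @return A waveform tibble (`time_s`, `value` in mmHg).
#' @export
cuff_ramp <- function(protocol, duration = NULL) {
  stopifnot(inherits(protocol, "cuff_protocol"))
  t_inf <- protocol$inflation_duration
  t_def <- (protocol$inflate_to - protocol$hold_pressure) /
    protocol$deflation_rate
  duration <- duration %||% (t_inf + t_def + protocol$hold_duration)
  if (duration < t_inf + t_def) {
    abort("`duration` too short to reach the hold pressure.")
  }
  dt <- 1 / protocol$sampling_rate
  t <- seq(0, duration - dt, by = dt)
  v <- ifelse(
    t < t_inf,
    protocol$inflate_to * t / t_inf,
    ifelse(t < t_inf + t_def,
           protocol$inflate_to - protocol$deflation_rate * (t - t_inf),
           protocol$hold_pressure)
  )
  new_waveform(t, v)
}
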