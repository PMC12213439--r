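#' Scale-factor configuration
#'
#' Converts blood-volume oscillations into observed cuff-pressure
#' oscillations either by a constant factor `k` (mmHg/mL, the reciprocal of
#' the local cuff-arm compliance) or by the pressure-dependent factor
#' `kv(t) = Pc(t)/Patm + 1` that accounts for air compression within the
#' cuff induced by arterial pulsation.
#'
#' @param mode `"constant"` or `"variable"`.
#' @param k Constant scale factor, mmHg/mL (> 0).
#' @param patm Atmospheric pressure, mmHg (variable mode; standard 760).
#' @return An object of class `scale_config`.
#' @export
scale_config <- function(mode = c("constant", "variable"), k = 1, patm = 760) {
  mode <- match.arg(mode)
  if (k <= 0) abort("`k` must be positive.")
  if (patm <= 0) abort("`patm` must be positive.")
  structure(list(mode = mode, k = k, patm = patm), class = "scale_config")
}

#' Cuff-arm-artery system configuration
#'
#' The purely elastic system maps pressures to volume through the static
#' sigmoid alone. The two viscoelastic variants add a first-order unity-gain
#' low-pass with cutoff `cutoff` (rad/s): Hammerstein places the static
#' nonlinearity before the filter, Wiener after it.
#'
#' @param system `"elastic"`, `"hammerstein"` or `"wiener"`.
#' @param cutoff Low-pass cutoff in rad/s (> 0; ignored for elastic).
#' @return An object of class `system_config` with fields `system`, `cutoff`
#'   (rad/s) and `cutoff_hz`.
#' @export
system_config <- function(system = c("elastic", "hammerstein", "wiener"),
                          cutoff = 2 * pi * 3) {
  system <- match.arg(system)
  if (system != "elastic" && (!is.finite(cutoff) || cutoff <= 0)) {
    abort("`cutoff` (rad/s) must be positive for viscoelastic systems.")
  }
  structure(list(system = system, cutoff = cutoff,
                 cutoff_hz = cutoff / (2 * pi)),
            class = "system_config")
}

# First-order unity-gain low-pass (cutoff in rad/s) discretized by the
# bilinear transform, state initialized at the first sample's steady state.
lowpass1 <- function(x, cutoff, fs) {
  a <- cutoff / (2 * fs)
  b0 <- a / (1 + a)
  a1 <- (a - 1) / (1 + a)
  as.numeric(signal::filter(c(b0, b0), c(1, a1), x,
                            init.x = x[1], init.y = x[1]))
}

#' Simulate the arterial blood volume waveform
#'
#' Transforms arterial and cuff pressure waveforms into the blood volume
#' waveform under the chosen system: elastic `V(t) = f(Pa(t) - Pc(t))`;
#' Hammerstein low-pass filters `f(Pa - Pc)`; Wiener applies `f` to the
#' low-pass-filtered transmural pressure.
#'
#' @param pa,pc Arterial and cuff pressure waveforms on the same time grid.
#' @param params A [compliance_params()].
#' @param sys A [system_config()].
#' @return A waveform tibble (`time_s`, `value` in mL).
#' @export
simulate_volume <- function(pa, pc, params, sys = system_config("elastic")) {
  check_waveform(pa, "pa"); check_waveform(pc, "pc")
  check_params(params)
  stopifnot(inherits(sys, "system_config"))
  if (nrow(pa) != nrow(pc) || max(abs(pa$time_s - pc$time_s)) > 1e-9) {
    abort("`pa` and `pc` must share the same time grid.")
  }
  p <- pa$value - pc$value
  fs <- sampling_rate(pa)
  v <- switch(sys$system,
    elastic = artery_volume(p, params),
    hammerstein = lowpass1(artery_volume(p, params), sys$cutoff, fs),
    wiener = artery_volume(lowpass1(p, sys$cutoff, fs), params)
  )
  new_waveform(pa$time_s, v, unit = "mL")
}

#' Convert a volume waveform into cuff-pressure oscillations
#'
#' High-pass filters the blood volume waveform to isolate its oscillatory
#' component, then multiplies samplewise by the constant factor `k` or the
#' variable factor `kv(t) = Pc(t)/Patm + 1`.
#'
#' @param v Blood volume waveform (mL).
#' @param pc Cuff pressure waveform on the same grid (used in variable mode).
#' @param scale A [scale_config()].
#' @param highpass_cutoff High-pass cutoff in Hz; `0` disables filtering.
#' @return A waveform tibble (`time_s`, `value` in mmHg).
#' @export
to_oscillations <- function(v, pc, scale = scale_config(),
                            highpass_cutoff = 0.5) {
  check_waveform(v, "v"); check_waveform(pc, "pc")
  stopifnot(inherits(scale, "scale_config"))
  if (nrow(v) != nrow(pc)) abort("`v` and `pc` must share the same grid.")
  x <- v$value
  if (highpass_cutoff > 0) {
    fs <- sampling_rate(v)
    hp <- signal::butter(1, 2 * highpass_cutoff / fs, type = "high")
    x <- as.numeric(signal::filtfilt(hp, x))
  }
  fac <- if (scale$mode == "constant") scale$k else pc$value / scale$patm + 1
  new_waveform(v$time_s, x * fac)
}

#' Cuff mechanics for the Boyle's-law cuff-arm model
#'
#' @param ec Cuff elasticity scale, mmHg (> 0).
#' @param n Cuff elasticity exponent (> 0).
#' @param vc0 Cuff volume at zero cuff pressure, mL (> 0).
#' @param vi0 Incompressible arm volume, mL (> 0).
#' @param patm Atmospheric pressure, mmHg.
#' @return An object of class `cuff_mechanics`. A warning is raised when
#'   `ec` is not much larger than `vi0 + vc0`, outside the regime in which
#'   the linearized pressure-volume slope approximation holds.
#' @export
cuff_mechanics <- function(ec, n = 1.5, vc0 = 150, vi0 = 500, patm = 760) {
  stopifnot(ec > 0, n > 0, vc0 > 0, vi0 > 0, patm > 0)
  if (ec < 100 * (vi0 + vc0)) {
    warning("`ec` is not >> vi0 + vc0; the linearized slope approximation ",
            "may be inaccurate.", call. = FALSE)
  }
  structure(list(ec = ec, n = n, vc0 = vc0, vi0 = vi0, patm = patm),
            class = "cuff_mechanics")
}

#' Cuff pressure from the Boyle's-law cuff-arm model
#'
#' Solves, per sample, the implicit relation between cuff pressure, pumped
#' air volume and arterial blood volume in which the nonlinear cuff
#' elasticity and air compressibility (Boyle's law) are incorporated:
#' `Pc = Ec ((Patm (Vp + Vc0)/(Pc + Patm) + Vi0 + V)/(Vi0 + Vc0))^(1/n) - 1)^n`.
#' Roots are found by bracketed search on `[0, 10 Ec]` with residual below
#' 1e-9 mmHg.
#'
#' @param v Blood volume waveform (mL).
#' @param vp Pumped-air volume waveform (mL), same grid as `v`.
#' @param mech A [cuff_mechanics()].
#' @return A waveform tibble (`time_s`, `value` = cuff pressure in mmHg).
#' @export
boyle_cuff_pressure <- function(v, vp, mech) {
  check_waveform(v, "v"); check_waveform(vp, "vp")
  stopifnot(inherits(mech, "cuff_mechanics"))
  if (nrow(v) != nrow(vp)) abort("`v` and `vp` must share the same grid.")
  pc <- vapply(seq_len(nrow(v)), function(i) {
    boyle_root(v$value[i], vp$value[i], mech)
  }, numeric(1))
  new_waveform(v$time_s, pc)
}

boyle_residual <- function(pc, v, vp, mech) {
  air <- mech$patm * (vp + mech$vc0) / (pc + mech$patm)
  x <- (air + mech$vi0 + v) / (mech$vi0 + mech$vc0)
  pc - mech$ec * pmax(x^(1 / mech$n) - 1, 0)^mech$n
}

boyle_root <- function(v, vp, mech) {
  lo <- 0; hi <- 10 * mech$ec
  rlo <- boyle_residual(lo, v, vp, mech)
  rhi <- boyle_residual(hi, v, vp, mech)
  if (rlo == 0) return(0)
  if (rlo * rhi > 0) {
    abort(sprintf(
      "Boyle cuff model: no sign change on [0, %.3g] mmHg (residuals %.3g, %.3g).",
      hi, rlo, rhi))
  }
  uniroot(boyle_residual, c(lo, hi), v = v, vp = vp, mech = mech,
          tol = 1e-12)$root
}

#' Synthesize a complete oscillometric cuff recording
#'
#' Composes the forward pipeline into a single fixture generator: cuff ramp
#' from the protocol, arterial waveform (triangular by default), blood volume
#' under the chosen system, volume-to-pressure oscillations, optional white
#' measurement noise, and the sum recorded as the raw cuff-pressure waveform.
#' Ground-truth parameters are embedded in the recording's metadata.
#'
#' @param pulse A [bp_pulse()] (ignored when `bp` is supplied).
#' @param protocol A [cuff_protocol()].
#' @param params A [compliance_params()].
#' @param sys A [system_config()].
#' @param scale A [scale_config()].
#' @param bp Optional arterial waveform; defaults to [triangular_bp()]
#'   spanning the protocol duration.
#' @param noise_sd Additive white Gaussian noise SD on the oscillation
#'   signal, mmHg.
#' @param highpass_cutoff High-pass cutoff (Hz) used to extract volume
#'   oscillations.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return An object of class `cuff_recording`: a list with `waveform` (raw
#'   cuff pressure), `protocol`, `components` (trend, oscillations) and
#'   `truth` (ground-truth metadata).
#' @examples
#' rec <- synthesize_recording(
#'   pulse = bp_pulse(120, 80),
#'   params = compliance_params(11, 14, amplitude = 0.05)
#' )
#' @export
synthesize_recording <- function(pulse = bp_pulse(),
                                 protocol = cuff_protocol(),
                                 params = compliance_params(11, 14,
                                                            amplitude = 0.05),
                                 sys = system_config("elastic"),
                                 scale = scale_config(),
                                 bp = NULL,
                                 noise_sd = 0,
                                 highpass_cutoff = 0.5,
                                 seed = NULL) {
  stopifnot(inherits(protocol, "cuff_protocol"))
  pc <- cuff_ramp(protocol)
  if (is.null(bp)) {
    n_beats <- ceiling(max(pc$time_s) / pulse$period) + 1L
    bp <- triangular_bp(pulse, n_beats = n_beats,
                        sampling_rate = protocol$sampling_rate)
  }
  check_waveform(bp, "bp")
  bp <- bp[seq_len(nrow(pc)), ]
  if (anyNA(bp$value)) {
    abort("`bp` is shorter than the cuff protocol duration.")
  }
  bp$time_s <- pc$time_s
  v <- simulate_volume(bp, pc, params, sys)
  osc <- to_oscillations(v, pc, scale, highpass_cutoff = highpass_cutoff)
  noise <- numeric(nrow(pc))
  if (noise_sd > 0) {
    if (is.null(seed)) abort("`seed` is required when `noise_sd > 0`.")
    noise <- local_seed(seed, rnorm(nrow(pc), sd = noise_sd))
  }
  raw <- new_waveform(pc$time_s, pc$value + osc$value + noise)
  structure(
    list(
      waveform = raw,
      protocol = protocol,
      components = list(trend = pc, oscillations = osc, bp = bp),
      truth = list(
        b = params$width_neg, c = params$width_pos,
        a = params$amplitude, form = params$form,
        ps = if (!is.null(pulse)) pulse$ps else max(bp$value),
        pd = if (!is.null(pulse)) pulse$pd else min(bp$value),
        period = if (!is.null(pulse)) pulse$period else NA_real_,
        system = sys$system,
        cutoff = if (sys$system == "elastic") NA_real_ else sys$cutoff,
        scale_mode = scale$mode, k = scale$k, patm = scale$patm,
        noise_sd = noise_sd, seed = seed %||% NA_integer_
      )
    ),
    class = "cuff_recording"
  )
}

#' @export
print.cuff_recording <- function(x, ...) {
  cat(sprintf(
    "<cuff_recording> %.1f s at %g Hz; %s system, %s scale, noise sd %g mmHg\n",
    max(x$waveform$time_s), sampling_rate(x$waveform),
    x$truth$system, x$truth$scale_mode, x$truth$noise_sd))
  invisible(x)
}
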