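#' Options for constrained oscillogram fitting
#'
#' Search ranges, initial seeds and convergence tolerances for the
#' bound-constrained least-squares fits. Defaults follow the standard
#' choices for this model family: widths searched on 0-60 mmHg from seeds
#' (11, 14) mmHg with tolerance 1e-6, and for viscoelastic fits a cutoff
#' searched on 2*pi*(0.1-20) rad/s from a seed of 2*pi*3 rad/s.
#'
#' @param bounds Length-2 numeric, search range for each width (mmHg).
#' @param seeds Length-2 numeric, initial (b, c) (mmHg), inside `bounds`.
#' @param tolerance Convergence tolerance (optimality/step).
#' @param w_bounds Length-2 numeric, cutoff search range (rad/s).
#' @param w_seed Initial cutoff (rad/s).
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(bounds = c(0, 60), seeds = c(11, 14),
                        tolerance = 1e-6,
                        w_bounds = 2 * pi * c(0.1, 20),
                        w_seed = 2 * pi * 3) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2],
            length(seeds) == 2, length(w_bounds) == 2)
  if (any(seeds < bounds[1] | seeds > bounds[2])) {
    abort("`seeds` must lie within `bounds`.")
  }
  structure(list(bounds = bounds, seeds = seeds, tolerance = tolerance,
                 w_bounds = w_bounds, w_seed = w_seed),
            class = "fit_options")
}

#' Normalized root-mean-square error of an oscillogram fit, percent
#'
#' `100 sqrt( I[(O - Ohat)^2] / I[O^2] )` where `I[.]` is the trapezoid
#' integral over the measured cuff-pressure range. Scale-free: multiplying
#' both oscillograms by the same positive constant leaves it unchanged.
#'
#' @param measured A measured oscillogram tibble (`cuff_pressure_mmHg`,
#'   `amplitude`).
#' @param fitted Fitted amplitudes on the same grid: a numeric vector or an
#'   oscillogram tibble.
#' @return NRMSE in percent.
#' @export
nrmse <- function(measured, fitted) {
  if (is.data.frame(fitted)) fitted <- fitted$amplitude
  pc <- measured$cuff_pressure_mmHg
  o <- measured$amplitude
  if (length(fitted) != length(o)) {
    abort("`fitted` must match the measured grid length.")
  }
  denom <- trapz_num(pc, o^2)
  if (denom <= 0) abort("Measured oscillogram is identically zero.")
  100 * sqrt(trapz_num(pc, (o - fitted)^2) / denom)
}

# Trapezoid weights for a (sorted) grid, so that sum(w * r^2) equals the
# trapezoid integral of r^2.
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(1, n))
  d <- diff(x)
  c(d[1], d[-1] + d[-(n - 1)], d[n - 1]) / 2
}

# Bound-constrained minimization: L-BFGS-B (tight factr/pgtol derived from
# the requested tolerance) followed by a clamped Nelder-Mead polish.
constrained_minimize <- function(par, fn, lower, upper, tolerance) {
  fn_clamped <- function(p) fn(pmin(pmax(p, lower), upper))
  r1 <- optim(par, fn, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(factr = max(tolerance / .Machine$double.eps * 1e-6, 10),
                             pgtol = tolerance * 1e-4, maxit = 500))
  r2 <- optim(r1$par, fn_clamped, method = "Nelder-Mead",
              control = list(reltol = 1e-14, maxit = 2000))
  converged <- r1$convergence == 0 || r2$convergence == 0
  if (r2$value < r1$value) {
    list(par = pmin(pmax(r2$par, lower), upper), value = r2$value,
         counts = unname(r1$counts[1] + r2$counts[1]), converged = converged)
  } else {
    list(par = r1$par, value = r1$value,
         counts = unname(r1$counts[1] + r2$counts[1]), converged = converged)
  }
}

new_oscillogram_fit <- function(par, value, counts, converged, measured,
                                fitted_amp, kind, method, opts, extra = list()) {
  fit <- c(list(
    b_hat = unname(par[1]), c_hat = unname(par[2]),
    w_hat = if (length(par) > 2) unname(par[3]) else NA_real_,
    nrmse = nrmse(measured, fitted_amp),
    objective = value, converged = converged, n_iter = counts,
    seeds = opts$seeds, kind = kind, method = method,
    measured = measured,
    fitted = tibble(cuff_pressure_mmHg = measured$cuff_pressure_mmHg,
                    amplitude = fitted_amp)
  ), extra)
  class(fit) <- "oscillogram_fit"
  fit
}

#' Fit the closed-form oscillogram model to a measured oscillogram
#'
#' Minimizes the trapezoid-discretized integral of the squared difference
#' between the measured normalized oscillogram and the normalized
#' closed-form model over the compliance widths `(b, c)` within bounds,
#' starting from the seeds. Systolic and diastolic pressures are inputs,
#' not fitted.
#'
#' @param measured A normalized `measured_oscillogram` (or any tibble with
#'   `cuff_pressure_mmHg` and `amplitude`).
#' @param kind `"height"` or `"area"`.
#' @param ps,pd Systolic and diastolic pressure, mmHg.
#' @param period Beat duration `T`, s (area model; cancels under
#'   normalization).
#' @param opts A [fit_options()].
#' @param form Compliance form.
#' @param check_complete Refuse to fit an oscillogram flagged incomplete.
#' @return An object of class `oscillogram_fit`.
#' @examples
#' pc <- seq(50, 170, by = 1)
#' target <- normalize_oscillogram(
#'   oscillogram_model(pc, 11, 14, ps = 120, pd = 80))
#' fit <- fit_oscillogram(target, kind = "height", ps = 120, pd = 80)
#' tidy(fit)
#' @export
fit_oscillogram <- function(measured, kind = c("height", "area"), ps, pd,
                            period = 1, opts = fit_options(),
                            form = c("exp_linear", "exp"),
                            check_complete = TRUE) {
  kind <- match.arg(kind)
  form <- match.arg(form)
  check_bp(ps, pd)
  stopifnot(inherits(opts, "fit_options"))
  if (check_complete && isFALSE(attr(measured, "complete"))) {
    abort("Measured oscillogram is flagged incomplete; refusing to fit it.")
  }
  measured <- measured[order(measured$cuff_pressure_mmHg), ]
  pc <- measured$cuff_pressure_mmHg
  o <- measured$amplitude
  w <- trapz_weights(pc)
  lo <- pmax(opts$bounds[1], 1e-6)
  hi <- opts$bounds[2]

  model_amp <- function(b, cc) {
    m <- oscillogram_model(pc, b, cc, ps, pd, scale = 1, period = period,
                           kind = kind, form = form)$amplitude
    mx <- max(m)
    if (mx <= 0) return(NULL)
    m / mx
  }
  fn <- function(p) {
    m <- model_amp(p[1], p[2])
    if (is.null(m)) return(1e12)
    sum(w * (o - m)^2)
  }
  res <- constrained_minimize(opts$seeds, fn, rep(lo, 2), rep(hi, 2),
                              opts$tolerance)
  new_oscillogram_fit(res$par, res$value, res$counts, res$converged,
                      measured, model_amp(res$par[1], res$par[2]),
                      kind, "closed_form", opts,
                      extra = list(ps = ps, pd = pd, form = form))
}

# Beat feet (local minima) of an arterial waveform, padded with endpoints.
beat_feet <- function(bp) {
  v <- local_extrema(bp$value)$valleys
  unique(c(1L, v, nrow(bp)))
}

# Simulated normalized oscillogram for candidate parameters: forward
# simulation of the volume waveform, volume-to-pressure oscillations passed
# through the same band-pass as the measurement pipeline, and per-beat
# feature extraction on beat windows derived from the (known) arterial
# input waveform.
simulated_oscillogram <- function(b, cc, w = NULL,
                                  system = "elastic", bp, pc_trend,
                                  scale = scale_config(),
                                  kind = "height",
                                  highpass_cutoff = 0.5,
                                  smooth_window = 5,
                                  feet = NULL, band_filter = NULL) {
  params <- compliance_params(b, cc, amplitude = 1)
  sys <- if (system == "elastic") system_config("elastic") else {
    system_config(system, cutoff = w)
  }
  v <- simulate_volume(bp, pc_trend, params, sys)
  osc <- to_oscillations(v, pc_trend, scale, highpass_cutoff = highpass_cutoff)
  if (!is.null(band_filter)) {
    osc$value <- as.numeric(signal::filtfilt(band_filter, osc$value))
  }
  if (is.null(feet)) feet <- beat_feet(bp)
  rows <- purrr::map(seq_len(length(feet) - 1L), function(ib) {
    i0 <- feet[ib]; i1 <- feet[ib + 1L]
    if (i1 - i0 < 3) return(NULL)
    idx <- i0:i1
    y <- osc$value[idx]
    t <- osc$time_s[idx]
    base <- y[1] + (y[length(y)] - y[1]) * (t - t[1]) / (t[length(t)] - t[1])
    rel <- y - base
    kpk <- which.max(rel)
    if (rel[kpk] <= 0) return(NULL)
    amp <- switch(kind, height = rel[kpk], area = trapz_num(t, rel))
    if (!is.finite(amp) || amp <= 0) return(NULL)
    c(pc = approx(pc_trend$time_s, pc_trend$value, xout = t[kpk],
                  rule = 2)$y, amp = amp)
  })
  rows <- purrr::compact(rows)
  if (length(rows) < 5) return(NULL)
  m <- do.call(rbind, rows)
  m <- m[order(m[, "pc"]), , drop = FALSE]
  amp <- moving_average(m[, "amp"], smooth_window)
  list(pc = m[, "pc"], amp = amp / max(amp))
}

#' Fit oscillogram models through the forward simulator
#'
#' Fits the compliance widths (and, for viscoelastic systems, the low-pass
#' cutoff) by running the forward simulator plus per-beat oscillogram
#' construction at each candidate parameter vector and minimizing the
#' trapezoid-discretized squared error against the measured normalized
#' oscillogram on its own cuff-pressure grid. The elastic system fits two
#' parameters `(b, c)`; Hammerstein and Wiener fit `(b, c, w)`.
#'
#' @inheritParams fit_oscillogram
#' @param bp Arterial pressure waveform driving the simulator (triangular or
#'   realistic), on the same grid as `pc_trend`.
#' @param pc_trend Applied cuff-pressure trend waveform.
#' @param system `"elastic"`, `"hammerstein"` or `"wiener"`.
#' @param scale A [scale_config()].
#' @param highpass_cutoff High-pass cutoff (Hz) for the simulated volume
#'   oscillations.
#' @param band,band_order Band-pass applied to the simulated oscillations so
#'   the candidate passes through the same filter chain as the measurement
#'   pipeline ([extract_oscillations()] defaults); `band = NULL` disables.
#' @return An object of class `oscillogram_fit` (with `w_hat` for
#'   viscoelastic systems).
#' @export
fit_simulated <- function(measured, kind = c("height", "area"),
                          bp, pc_trend,
                          system = c("elastic", "hammerstein", "wiener"),
                          scale = scale_config(), opts = fit_options(),
                          highpass_cutoff = 0.5,
                          band = c(0.75, 5), band_order = 6) {
  kind <- match.arg(kind)
  system <- match.arg(system)
  stopifnot(inherits(opts, "fit_options"))
  check_waveform(bp, "bp"); check_waveform(pc_trend, "pc_trend")
  measured <- measured[order(measured$cuff_pressure_mmHg), ]
  pc <- measured$cuff_pressure_mmHg
  o <- measured$amplitude
  wts <- trapz_weights(pc)
  feet <- beat_feet(bp)
  band_filter <- if (!is.null(band)) {
    signal::butter(band_order / 2, 2 * band / sampling_rate(pc_trend),
                   type = "pass")
  }

  sim_amp <- function(p) {
    sim <- simulated_oscillogram(
      b = p[1], cc = p[2], w = if (length(p) > 2) p[3] else NULL,
      system = system, bp = bp, pc_trend = pc_trend, scale = scale,
      kind = kind, highpass_cutoff = highpass_cutoff, feet = feet,
      band_filter = band_filter)
    if (is.null(sim)) return(NULL)
    a <- approx(sim$pc, sim$amp, xout = pc, rule = 2)$y
    a / max(a)
  }
  fn <- function(p) {
    a <- sim_amp(p)
    if (is.null(a)) return(1e12)
    sum(wts * (o - a)^2)
  }
  lo <- pmax(opts$bounds[1], 1e-6)
  hi <- opts$bounds[2]
  if (system == "elastic") {
    res <- constrained_minimize(opts$seeds, fn, rep(lo, 2), rep(hi, 2),
                                opts$tolerance)
  } else {
    res <- constrained_minimize(c(opts$seeds, opts$w_seed), fn,
                                c(lo, lo, opts$w_bounds[1]),
                                c(hi, hi, opts$w_bounds[2]),
                                opts$tolerance)
  }
  new_oscillogram_fit(res$par, res$value, res$counts, res$converged,
                      measured, sim_amp(res$par), kind,
                      paste0("simulated_", system), opts,
                      extra = list(system = system, scale_mode = scale$mode))
}

#' Assumption-evaluation grid on synthetic recordings
#'
#' Runs the fitting framework over a factorial grid of modeling assumptions
#' (system type x arterial waveform shape x scale-factor mode) for a list of
#' synthetic recordings with known ground truth, returning one tidy row per
#' recording and cell with parameter estimates, NRMSE, and deltas from
#' truth.
#'
#' @param recordings A list of `cuff_recording` objects carrying ground
#'   truth (from [synthesize_recording()]).
#' @param systems,bp_types,scale_modes Factor levels of the grid.
#' @param kind Oscillogram kind to fit.
#' @param opts A [fit_options()].
#' @return A tibble with columns `recording`, `system`, `bp_type`,
#'   `scale_mode`, `kind`, `b_hat`, `c_hat`, `w_hat`, `nrmse`, `converged`,
#'   `delta_b`, `delta_c`.
#' @export
assumption_grid <- function(recordings,
                            systems = c("elastic", "hammerstein", "wiener"),
                            bp_types = c("triangle", "realistic"),
                            scale_modes = c("constant", "variable"),
                            kind = c("height", "area"),
                            opts = fit_options()) {
  kind <- match.arg(kind)
  if (inherits(recordings, "cuff_recording")) recordings <- list(recordings)
  grid <- tidyr::expand_grid(
    recording = seq_along(recordings),
    system = systems, bp_type = bp_types, scale_mode = scale_modes)
  purrr::pmap_dfr(grid, function(recording, system, bp_type, scale_mode) {
    rec <- recordings[[recording]]
    built <- construct_oscillograms(rec, kinds = kind)
    measured <- built$oscillograms[[kind]]
    trend <- extract_applied_pressure(rec)
    pulse <- bp_pulse(rec$truth$ps, rec$truth$pd, rec$truth$period)
    n_beats <- ceiling(diff(range(trend$time_s)) / pulse$period) + 1L
    fs <- sampling_rate(trend)
    bp <- if (bp_type == "triangle") {
      triangular_bp(pulse, n_beats, fs)
    } else {
      realistic_bp(pulse, n_beats, fs)
    }
    bp <- bp[seq_len(nrow(trend)), ]
    bp$time_s <- trend$time_s
    sc <- scale_config(scale_mode, k = rec$truth$k, patm = rec$truth$patm)
    fit <- fit_simulated(measured, kind = kind, bp = bp, pc_trend = trend,
                         system = system, scale = sc, opts = opts)
    tibble(recording = recording, system = system, bp_type = bp_type,
           scale_mode = scale_mode, kind = kind,
           b_hat = fit$b_hat, c_hat = fit$c_hat, w_hat = fit$w_hat,
           nrmse = fit$nrmse, converged = fit$converged,
           delta_b = fit$b_hat - rec$truth$b,
           delta_c = fit$c_hat - rec$truth$c)
  })
}

# Piecewise-linear scale profile (mmHg/mL) across cuff pressure: slope_low
# below pc_lo, linear ramp to slope_high over [pc_lo, pc_hi], constant above.
scale_profile <- function(pc, slope_low = 0.6, slope_high = 1,
                          pc_lo = 60, pc_hi = 100) {
  frac <- pmin(pmax((pc - pc_lo) / (pc_hi - pc_lo), 0), 1)
  slope_low + frac * (slope_high - slope_low)
}

#' Adjust oscillations for nonlinear cuff-arm compliance
#'
#' The local slope of the cuff pressure-volume relationship of a standard
#' arm cuff rises roughly linearly from 0.6 to 1 mmHg/mL over cuff pressures
#' of 60-100 mmHg and is approximately constant above. `action = "remove"`
#' divides the oscillation signal by this piecewise-linear slope profile
#' evaluated at the applied pressure trend, mathematically removing the
#' nonlinearity's contribution from a measured signal; `action = "apply"`
#' multiplies instead, imposing a known nonlinearity on a simulated signal.
#'
#' @param osc Oscillation waveform.
#' @param pc_trend Applied-pressure trend on the same grid.
#' @param slope_low,slope_high Scale-factor endpoints, mmHg/mL (> 0).
#' @param pc_lo,pc_hi Cuff-pressure range of the linear ramp, mmHg.
#' @param action `"remove"` (divide) or `"apply"` (multiply).
#' @return The adjusted oscillation waveform.
#' @export
adjust_nonlinearity <- function(osc, pc_trend, slope_low = 0.6,
                                slope_high = 1, pc_lo = 60, pc_hi = 100,
                                action = c("remove", "apply")) {
  action <- match.arg(action)
  check_waveform(osc, "osc"); check_waveform(pc_trend, "pc_trend")
  if (pc_lo >= pc_hi) abort("`pc_lo` must be below `pc_hi`.")
  if (slope_low <= 0 || slope_high <= 0) abort("Slopes must be positive.")
  prof <- scale_profile(
    approx(pc_trend$time_s, pc_trend$value, xout = osc$time_s, rule = 2)$y,
    slope_low, slope_high, pc_lo, pc_hi)
  if (any(prof <= 0)) abort("Scale profile reaches a non-positive value.")
  val <- if (action == "remove") osc$value / prof else osc$value * prof
  new_waveform(osc$time_s, val)
}
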