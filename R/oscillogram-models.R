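#' Closed-form oscillogram models
#'
#' Evaluates the analytical height or area oscillogram on a grid of applied
#' cuff pressures. The height oscillogram is the peak-to-peak amplitude of
#' the cuff-pressure oscillations,
#' `OH(Pc) = k (f(Ps - Pc) - f(Pd - Pc))`,
#' with `f` the blood volume sigmoid ([artery_volume()]). The area
#' oscillogram is the per-beat oscillation area above the diastolic level;
#' assuming a triangular arterial pulse it reduces to
#' `OA(Pc) = k T ((F(Ps - Pc) - F(Pd - Pc)) / PP - f(Pd - Pc))`,
#' where `F` is the antiderivative of `f` and `PP = Ps - Pd`. The systolic
#' (upstroke) duration cancels exactly and does not appear.
#'
#' Both models are evaluated as explicit piecewise expressions over the
#' three regions `Pc < Pd`, `Pd <= Pc < Ps` and `Pc >= Ps` (half-open
#' boundary membership; the expressions are continuous across the
#' boundaries). The multiplicative scale `d = a k` (arterial compliance
#' amplitude times the volume-to-pressure scale factor) enters only as a
#' single prefactor and is eliminated by [normalize_oscillogram()].
#'
#' @param cuff_pressure Numeric vector of applied cuff pressures, mmHg.
#' @param width_neg,width_pos Compliance-curve widths `b`, `c` (mmHg > 0).
#' @param ps,pd Systolic and diastolic blood pressure, mmHg (`ps > pd`).
#' @param scale Multiplicative scale `d = a k`; mmHg (height) or set to 1 when
#'   the oscillogram will be normalized.
#' @param period Beat duration `T` in seconds (area model only).
#' @param kind `"height"` or `"area"`.
#' @param form Compliance form passed to [compliance_params()].
#'
#' @return A tibble of class `model_oscillogram` with columns
#'   `cuff_pressure_mmHg` and `amplitude`, and attributes `kind`, `scale`,
#'   `normalized`.
#' @examples
#' pc <- seq(40, 180, by = 1)
#' oh <- oscillogram_model(pc, width_neg = 11, width_pos = 14,
#'                         ps = 120, pd = 80)
#' peak_pressure_height(11, 14, 120, 80)
#' @export
oscillogram_model <- function(cuff_pressure, width_neg, width_pos, ps, pd,
                              scale = 1, period = 1,
                              kind = c("height", "area"),
                              form = c("exp_linear", "exp")) {
  kind <- match.arg(kind)
  form <- match.arg(form)
  check_bp(ps, pd)
  if (!is.numeric(cuff_pressure) || any(!is.finite(cuff_pressure))) {
    abort("`cuff_pressure` must be finite numeric.")
  }
  if (kind == "area" && (!is.finite(period) || period <= 0)) {
    abort("`period` (beat duration, s) must be positive.")
  }
  pars <- compliance_params(width_neg, width_pos, amplitude = 1, form = form)
  amp <- if (kind == "height") {
    scale * height_branches(cuff_pressure, width_neg, width_pos, ps, pd, form)
  } else {
    scale * period * area_branches(cuff_pressure, pars, ps, pd)
  }
  new_model_oscillogram(cuff_pressure, amp, kind = kind, scale = scale,
                        normalized = FALSE)
}

new_model_oscillogram <- function(pc, amp, kind, scale, normalized) {
  out <- tibble(cuff_pressure_mmHg = pc, amplitude = amp)
  class(out) <- c("model_oscillogram", class(out))
  attr(out, "kind") <- kind
  attr(out, "scale") <- scale
  attr(out, "normalized") <- normalized
  out
}

check_bp <- function(ps, pd) {
  if (!is.finite(ps) || !is.finite(pd)) abort("`ps` and `pd` must be finite.")
  if (ps <= pd) abort("Systolic pressure `ps` must exceed diastolic `pd`.")
  invisible(TRUE)
}

# Height oscillogram, explicit piecewise branches in the three cuff-pressure
# regions (unit amplitude a = 1; scale applied by the caller). Written out
# region by region rather than via artery_volume() so that tests can compare
# the two routes independently.
height_branches <- function(pc, b, cc, ps, pd, form) {
  s <- ps - pc
  q <- pd - pc
  out <- numeric(length(pc))
  r1 <- pc < pd          # both transmural pressures positive
  r2 <- pc >= pd & pc < ps
  r3 <- pc >= ps         # both negative or zero
  if (form == "exp_linear") {
    out[r1] <- (q[r1] + 2 * cc) * clamped_exp(-q[r1] / cc) -
      (s[r1] + 2 * cc) * clamped_exp(-s[r1] / cc)
    out[r2] <- 2 * (b + cc) + (q[r2] - 2 * b) * clamped_exp(q[r2] / b) -
      (s[r2] + 2 * cc) * clamped_exp(-s[r2] / cc)
    out[r3] <- (q[r3] - 2 * b) * clamped_exp(q[r3] / b) -
      (s[r3] - 2 * b) * clamped_exp(s[r3] / b)
  } else {
    out[r1] <- cc * (clamped_exp(-q[r1] / cc) - clamped_exp(-s[r1] / cc))
    out[r2] <- b + cc - b * clamped_exp(q[r2] / b) -
      cc * clamped_exp(-s[r2] / cc)
    out[r3] <- b * (clamped_exp(s[r3] / b) - clamped_exp(q[r3] / b))
  }
  out
}

# Area oscillogram (unit scale, unit beat duration): per-beat mean of f over
# the transmural excursion minus the diastolic volume. Equals the closed-form
# branch expression obtained by integrating the triangular pulse analytically.
area_branches <- function(pc, pars, ps, pd) {
  s <- ps - pc
  q <- pd - pc
  pp <- ps - pd
  (volume_antiderivative(s, pars) - volume_antiderivative(q, pars)) / pp -
    artery_volume(q, pars)
}

#' Cuff pressure at the height-oscillogram maximum
#'
#' Closed form `PHmax = Pd + b PP / (b + c)`: a weighted average of systolic
#' and diastolic pressure with weights `b/(b+c)` on `Ps` and `c/(b+c)` on
#' `Pd`. The same expression holds for both compliance forms.
#'
#' @inheritParams oscillogram_model
#' @return Cuff pressure in mmHg, strictly between `pd` and `ps`.
#' @export
peak_pressure_height <- function(width_neg, width_pos, ps, pd) {
  check_bp(ps, pd)
  stopifnot(width_neg > 0, width_pos > 0)
  pd + width_neg * (ps - pd) / (width_neg + width_pos)
}

#' Cuff pressure at the area-oscillogram maximum
#'
#' The stationarity condition of the area oscillogram,
#' `f(Ps - Pc) - f(Pd - Pc) = PP g(Pd - Pc)`, has no closed-form solution
#' and is solved by bracketed root finding (Brent's method, tolerance 1e-8
#' mmHg) on `(Pd - 5 (b + c), Ps)`, expanding the lower end if needed. For
#' the `"exp"` compliance form, `approximate = TRUE` returns instead the
#' closed approximation `PAmax = Pd + b log((b + PP) / (b + c))` obtained by
#' dropping the (typically much smaller) positive-branch term.
#'
#' @inheritParams oscillogram_model
#' @param approximate Use the closed-form approximation (`"exp"` form only).
#' @return Cuff pressure in mmHg.
#' @export
peak_pressure_area <- function(width_neg, width_pos, ps, pd,
                               form = c("exp_linear", "exp"),
                               approximate = FALSE) {
  form <- match.arg(form)
  check_bp(ps, pd)
  stopifnot(width_neg > 0, width_pos > 0)
  pp <- ps - pd
  if (approximate) {
    if (form != "exp") {
      abort("The closed-form approximation is defined for form = \"exp\" only.")
    }
    return(pd + width_neg * log((width_neg + pp) / (width_neg + width_pos)))
  }
  pars <- compliance_params(width_neg, width_pos, amplitude = 1, form = form)
  # d(OA)/d(Pc) changes sign from + to - through the maximum; h below is the
  # negated derivative (up to a positive factor), so h < 0 left of the peak.
  h <- function(pc) {
    artery_volume(ps - pc, pars) - artery_volume(pd - pc, pars) -
      pp * compliance(pd - pc, pars)
  }
  lower <- pd - 5 * (width_neg + width_pos)
  upper <- ps
  tries <- 0L
  while (h(lower) * h(upper) > 0 && tries < 60L) {
    lower <- lower - 2^tries * (width_neg + width_pos)
    tries <- tries + 1L
  }
  if (h(lower) * h(upper) > 0) {
    abort(sprintf(
      "Area-oscillogram peak not bracketed on [%.6g, %.6g] mmHg.",
      lower, upper))
  }
  uniroot(h, c(lower, upper), tol = 1e-8)$root
}

#' Normalize an oscillogram to unit maximum
#'
#' Divides the amplitudes by their maximum, eliminating the scale parameter
#' `d = a k` from the model (and the beat duration from the area model).
#' Idempotent.
#'
#' @param osc A `model_oscillogram` or `measured_oscillogram` tibble (any
#'   data frame with an `amplitude` column).
#' @return The oscillogram with `max(amplitude) == 1` and the `normalized`
#'   attribute set.
#' @export
normalize_oscillogram <- function(osc) {
  if (!is.data.frame(osc) || !"amplitude" %in% names(osc)) {
    abort("`osc` must be an oscillogram data frame with an `amplitude` column.")
  }
  m <- max(osc$amplitude)
  if (!is.finite(m) || m <= 0) {
    abort("Cannot normalize an oscillogram whose maximum amplitude is not positive.")
  }
  osc$amplitude <- osc$amplitude / m
  attr(osc, "normalized") <- TRUE
  osc
}

#' @export
print.model_oscillogram <- function(x, ...) {
  cat(sprintf("<model_oscillogram> kind = %s, %d points, normalized = %s\n",
              attr(x, "kind"), nrow(x), attr(x, "normalized")))
  NextMethod()
}
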