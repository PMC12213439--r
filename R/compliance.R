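#' Arterial compliance curve parameters
#'
#' The package models the arterial blood volume--transmural pressure
#' relationship as a sigmoid whose derivative (the arterial compliance curve)
#' is parameterized by one of two unimodal functions peaking at zero
#' transmural pressure:
#'
#' * `"exp_linear"`: `g(P) = a e^{P/b} (1 - P/b)` for `P < 0` and
#'   `a e^{-P/c} (1 + P/c)` for `P >= 0`;
#' * `"exp"`: `g(P) = a e^{P/b}` for `P < 0` and `a e^{-P/c}` for `P >= 0`.
#'
#' `amplitude` (`a`, mL/mmHg) is the maximal compliance, attained at zero
#' transmural pressure; `width_neg` (`b`, mmHg) and `width_pos` (`c`, mmHg)
#' are the widths of the compliance curve over the negative and positive
#' transmural pressure ranges. The exponential-linear form is the default
#' used throughout; the plain exponential form exists mainly because it
#' admits interpretable closed forms for the oscillogram peak positions.
#'
#' @param width_neg Width over negative transmural pressures (`b`), mmHg > 0.
#' @param width_pos Width over positive transmural pressures (`c`), mmHg > 0.
#' @param amplitude Compliance at zero transmural pressure (`a`), mL/mmHg > 0.
#' @param form `"exp_linear"` (default) or `"exp"`.
#'
#' @return An object of class `compliance_params`.
#' @examples
#' pars <- compliance_params(width_neg = 11, width_pos = 14, amplitude = 0.05)
#' compliance(0, pars) # equals the amplitude
#' @export
compliance_params <- function(width_neg, width_pos, amplitude = 1,
                              form = c("exp_linear", "exp")) {
  form <- match.arg(form)
  for (nm in c("width_neg", "width_pos", "amplitude")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      abort(sprintf("`%s` must be a single finite positive number.", nm))
    }
  }
  structure(
    list(form = form, amplitude = amplitude,
         width_neg = width_neg, width_pos = width_pos),
    class = "compliance_params"
  )
}

#' @export
print.compliance_params <- function(x, ...) {
  cat(sprintf(
    "<compliance_params> form = %s, a = %g mL/mmHg, b = %g mmHg, c = %g mmHg\n",
    x$form, x$amplitude, x$width_neg, x$width_pos
  ))
  invisible(x)
}

check_params <- function(params) {
  if (!inherits(params, "compliance_params")) {
    abort("`params` must be created with `compliance_params()`.")
  }
  params
}

check_transmural <- function(P) {
  if (!is.numeric(P) || anyNA(P) || any(!is.finite(P))) {
    abort("Transmural pressure `P` must be finite and numeric.")
  }
  P
}

# Exponent clamp: beyond this the exponential underflows anyway; clamping
# keeps 0 * Inf out of the linear prefactors.
.EXP_CLAMP <- 700

clamped_exp <- function(x) exp(pmax(pmin(x, .EXP_CLAMP), -.EXP_CLAMP))

#' Arterial compliance at a transmural pressure
#'
#' Evaluates the compliance curve `g(P) = dV/dP` for the chosen parametric
#' form. `g` is continuous, strictly positive, and maximal at `P = 0`, where
#' it equals `amplitude` for both forms. The unit step at zero is resolved by
#' assigning `P = 0` to the positive branch; both branches agree there, so
#' the choice is observationally irrelevant.
#'
#' @param P Transmural pressure(s), mmHg (signed; arterial minus cuff).
#' @param params A [compliance_params()] object.
#' @return Compliance in mL/mmHg, same length as `P`.
#' @seealso [artery_volume()]
#' @export
compliance <- function(P, params) {
  check_transmural(P)
  check_params(params)
  a <- params$amplitude; b <- params$width_neg; cc <- params$width_pos
  neg <- P < 0
  g <- numeric(length(P))
  if (params$form == "exp_linear") {
    g[neg] <- a * clamped_exp(P[neg] / b) * (1 - P[neg] / b)
    g[!neg] <- a * clamped_exp(-P[!neg] / cc) * (1 + P[!neg] / cc)
  } else {
    g[neg] <- a * clamped_exp(P[neg] / b)
    g[!neg] <- a * clamped_exp(-P[!neg] / cc)
  }
  g
}

#' Arterial blood volume at a transmural pressure
#'
#' The sigmoid `f(P)`, the antiderivative of [compliance()] with
#' `f(-Inf) = 0`. It is monotone nondecreasing and saturates at
#' `2 a (b + c)` (exponential-linear form) or `a (b + c)` (exponential form)
#' as `P -> +Inf`.
#'
#' @inheritParams compliance
#' @return Blood volume in mL, same length as `P`.
#' @export
artery_volume <- function(P, params) {
  check_transmural(P)
  check_params(params)
  a <- params$amplitude; b <- params$width_neg; cc <- params$width_pos
  neg <- P < 0
  f <- numeric(length(P))
  if (params$form == "exp_linear") {
    f[neg] <- a * (2 * b - P[neg]) * clamped_exp(P[neg] / b)
    f[!neg] <- 2 * a * (b + cc) -
      a * (2 * cc + P[!neg]) * clamped_exp(-P[!neg] / cc)
  } else {
    f[neg] <- a * b * clamped_exp(P[neg] / b)
    f[!neg] <- a * b + a * cc * (1 - clamped_exp(-P[!neg] / cc))
  }
  f
}

# Antiderivative F(P) of artery_volume with F(-Inf) = 0 (the volume decays
# fast enough that the improper integral converges). Used by the closed-form
# area oscillogram, where the per-beat time integral reduces to a pressure
# integral of f.
volume_antiderivative <- function(P, params) {
  a <- params$amplitude; b <- params$width_neg; cc <- params$width_pos
  neg <- P < 0
  F <- numeric(length(P))
  if (params$form == "exp_linear") {
    F[neg] <- a * b * clamped_exp(P[neg] / b) * (3 * b - P[neg])
    F[!neg] <- 2 * a * (b + cc) * P[!neg] +
      a * cc * clamped_exp(-P[!neg] / cc) * (3 * cc + P[!neg]) +
      3 * a * (b^2 - cc^2)
  } else {
    F[neg] <- a * b^2 * clamped_exp(P[neg] / b)
    F[!neg] <- a * (b + cc) * P[!neg] +
      a * cc^2 * clamped_exp(-P[!neg] / cc) + a * (b^2 - cc^2)
  }
  F
}
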