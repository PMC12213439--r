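#' @export
print.oscillogram_fit <- function(x, ...) {
  cat(sprintf("<oscillogram_fit> %s oscillogram, %s\n", x$kind, x$method))
  cat(sprintf("  b = %.3f mmHg, c = %.3f mmHg%s\n", x$b_hat, x$c_hat,
              if (is.finite(x$w_hat)) {
                sprintf(", w = %.3f rad/s (%.2f Hz)", x$w_hat,
                        x$w_hat / (2 * pi))
              } else ""))
  cat(sprintf("  NRMSE = %.2f%%, converged = %s (%d evaluations)\n",
              x$nrmse, x$converged, x$n_iter))
  invisible(x)
}

#' Tidy an oscillogram fit
#'
#' @param x An `oscillogram_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter (`term`,
#'   `estimate`, `unit`).
#' @method tidy oscillogram_fit
#' @export
tidy.oscillogram_fit <- function(x, ...) {
  out <- tibble(
    term = c("b", "c"),
    estimate = c(x$b_hat, x$c_hat),
    unit = "mmHg"
  )
  if (is.finite(x$w_hat)) {
    out <- dplyr::bind_rows(out, tibble(term = "w", estimate = x$w_hat,
                                        unit = "rad/s"))
  }
  out
}

#' Glance at an oscillogram fit
#'
#' @inheritParams tidy.oscillogram_fit
#' @return A one-row tibble: `kind`, `method`, `nrmse`, `objective`,
#'   `converged`, `n_iter`.
#' @method glance oscillogram_fit
#' @export
glance.oscillogram_fit <- function(x, ...) {
  tibble(kind = x$kind, method = x$method, nrmse = x$nrmse,
         objective = x$objective, converged = x$converged,
         n_iter = x$n_iter)
}

#' Plot an oscillogram fit
#'
#' @param object An `oscillogram_fit`.
#' @param ... Unused.
#' @return A ggplot: measured points and fitted curve vs cuff pressure.
#' @method autoplot oscillogram_fit
#' @export
autoplot.oscillogram_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$measured, series = "measured"),
    dplyr::mutate(object$fitted, series = "fitted")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cuff_pressure_mmHg,
                                   y = .data$amplitude,
                                   colour = .data$series)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$series == "fitted")) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$series == "measured"),
                        size = 0.8) +
    ggplot2::labs(x = "Cuff pressure (mmHg)", y = "Normalized amplitude",
                  colour = NULL,
                  title = sprintf("%s oscillogram fit (NRMSE %.1f%%)",
                                  object$kind, object$nrmse)) +
    ggplot2::theme_minimal()
}

#' Plot an oscillogram
#'
#' @param object A `model_oscillogram` or `measured_oscillogram`.
#' @param ... Unused.
#' @return A ggplot of amplitude vs cuff pressure.
#' @method autoplot model_oscillogram
#' @export
autoplot.model_oscillogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cuff_pressure_mmHg,
                                       y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cuff pressure (mmHg)", y = "Amplitude",
                  title = sprintf("%s oscillogram", attr(object, "kind"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.model_oscillogram
#' @method autoplot measured_oscillogram
#' @export
autoplot.measured_oscillogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cuff_pressure_mmHg,
                                       y = .data$amplitude)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Cuff pressure (mmHg)", y = "Amplitude",
                  title = sprintf("Measured %s oscillogram", attr(object, "kind"))) +
    ggplot2::theme_minimal()
}

#' Plot a waveform
#'
#' @param object A waveform tibble.
#' @param ... Unused.
#' @return A ggplot of value vs time.
#' @method autoplot waveform
#' @export
autoplot.waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)",
                  y = attr(object, "unit") %||% "Value") +
    ggplot2::theme_minimal()
}
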