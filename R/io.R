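#' Read a waveform from CSV
#'
#' Expects a header row with a `time_s` column and one value column whose
#' name carries the unit (`pressure_mmHg` or `volume_mL`). Validates strict
#' monotone time, uniform sampling (jitter below 1e-6 s) and finite values.
#'
#' @param path Path to a CSV file.
#' @return A waveform tibble (`time_s`, `value`) with a `unit` attribute.
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  # base read.csv: strtod parsing is correctly rounded, so values written by
  # write_waveform_csv() round-trip bit-exactly
  df <- utils::read.csv(path)
  if (nrow(df) == 0) abort(sprintf("Empty waveform file: %s", path))
  if (!"time_s" %in% names(df)) {
    abort("Missing `time_s` column (time in seconds).")
  }
  value_col <- setdiff(names(df), "time_s")
  known <- c(pressure_mmHg = "mmHg", volume_mL = "mL")
  value_col <- intersect(value_col, names(known))
  if (length(value_col) != 1) {
    abort("Expected exactly one value column named pressure_mmHg or volume_mL.")
  }
  t <- df$time_s
  v <- df[[value_col]]
  if (anyNA(t) || anyNA(v) || any(!is.finite(t)) || any(!is.finite(v))) {
    abort("Waveform contains non-finite values.")
  }
  if (any(diff(t) <= 0)) abort("`time_s` is not strictly increasing.")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6) {
    abort("Non-uniform sampling: time jitter exceeds 1e-6 s.")
  }
  new_waveform(t, v, unit = unname(known[value_col]))
}

#' Write a waveform to CSV
#'
#' Writes `time_s` plus a unit-suffixed value column (`pressure_mmHg` for
#' mmHg waveforms, `volume_mL` for mL). Values round-trip bit-exactly
#' through [read_waveform_csv()].
#'
#' @param wf A waveform tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wf, path) {
  check_waveform(wf, "wf")
  unit <- attr(wf, "unit") %||% "mmHg"
  col <- if (identical(unit, "mL")) "volume_mL" else "pressure_mmHg"
  out <- setNames(tibble(wf$time_s, wf$value), c("time_s", col))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write an oscillogram to CSV
#'
#' Columns: `cuff_pressure_mmHg`, `amplitude`, `kind`, `normalized`,
#' `complete`.
#'
#' @param osc A measured or model oscillogram tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oscillogram_csv <- function(osc, path) {
  out <- tibble(
    cuff_pressure_mmHg = osc$cuff_pressure_mmHg,
    amplitude = osc$amplitude,
    kind = attr(osc, "kind") %||% NA_character_,
    normalized = isTRUE(attr(osc, "normalized")),
    complete = attr(osc, "complete") %||% NA
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an oscillogram CSV written by [write_oscillogram_csv()]
#'
#' @param path Path to the CSV.
#' @return A `measured_oscillogram` tibble.
#' @export
read_oscillogram_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cuff_pressure_mmHg", "amplitude")
  if (!all(need %in% names(df))) {
    abort("Oscillogram CSV must contain cuff_pressure_mmHg and amplitude.")
  }
  out <- tibble(cuff_pressure_mmHg = df$cuff_pressure_mmHg,
                amplitude = df$amplitude)
  class(out) <- c("measured_oscillogram", class(out))
  attr(out, "kind") <- if ("kind" %in% names(df)) df$kind[1] else NA_character_
  attr(out, "normalized") <- if ("normalized" %in% names(df)) {
    isTRUE(df$normalized[1])
  } else NA
  if ("complete" %in% names(df) && !is.na(df$complete[1])) {
    attr(out, "complete") <- isTRUE(df$complete[1])
  }
  attr(out, "pc_min") <- min(out$cuff_pressure_mmHg)
  attr(out, "pc_max") <- max(out$cuff_pressure_mmHg)
  out
}

#' Write a list as pretty JSON at full precision
#'
#' @param x A list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_config <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
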