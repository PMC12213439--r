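#' @title Automated oscillogram construction
#' @description Functions implementing the automated pipeline that turns a
#'   raw cuff-pressure recording into measured oscillograms: identify the
#'   deflation segment, band-pass the oscillations, low-pass the applied
#'   pressure trend, detect and gate pulses, compute per-pulse shape
#'   features, and assemble smoothed/trimmed/normalized oscillograms.
#' @name construction
NULL

# Deflation segment sample indices of a recording: from the trend maximum to
# the end of the monotone decline (protocol hold pressure when known,
# otherwise the point where the trend flattens out). Margins keep clear of
# the slope discontinuities at inflation-to-deflation and deflation-to-hold,
# whose band-passed transients would otherwise masquerade as pulses.
deflation_segment <- function(rec, trend = NULL,
                              start_margin = 2.5, end_margin = 1) {
  wf <- rec$waveform
  fs <- sampling_rate(wf)
  if (is.null(trend)) trend <- lowpass_trend(wf$value, fs)
  i0 <- which.max(trend)
  hold <- if (!is.null(rec$protocol)) rec$protocol$hold_pressure else NULL
  after <- trend[i0:length(trend)]
  i1 <- if (!is.null(hold)) {
    cand <- which(after <= hold + 1)
    if (length(cand)) i0 + cand[1] - 1 else length(trend)
  } else {
    slope <- c(diff(after), 0) * fs
    cand <- which(slope > -0.2)
    if (length(cand)) i0 + cand[1] - 1 else length(trend)
  }
  i0 <- i0 + round(start_margin * fs)
  i1 <- i1 - round(end_margin * fs)
  if (i1 - i0 < 2 * fs) abort("Recording too short: no usable deflation segment.")
  c(i0, i1)
}

lowpass_trend <- function(x, fs, cutoff = 0.3, order = 4) {
  lp <- signal::butter(order, 2 * cutoff / fs, type = "low")
  as.numeric(signal::filtfilt(lp, x))
}

#' Extract cuff-pressure oscillations from a recording
#'
#' Band-pass filters the raw cuff-pressure waveform over the deflation
#' segment to isolate the beat-to-beat oscillations. The filter is a
#' Butterworth band-pass of designed order 6 with cutoffs 0.75 and 5 Hz,
#' applied forward-backward (zero phase, so pulse timing is not shifted;
#' this doubles the effective attenuation).
#'
#' @param rec A `cuff_recording` (from [synthesize_recording()] or built from
#'   a CSV waveform via [as_cuff_recording()]).
#' @param low,high Band edges in Hz.
#' @param order Designed filter order (must be even; the band-pass is built
#'   as order/2 sections per edge).
#' @return A waveform tibble restricted to the deflation segment.
#' @export
extract_oscillations <- function(rec, low = 0.75, high = 5, order = 6) {
  stopifnot(inherits(rec, "cuff_recording"))
  wf <- rec$waveform
  fs <- sampling_rate(wf)
  if (fs < 2 * high) abort("Sampling rate must be at least twice the upper cutoff.")
  seg <- deflation_segment(rec)
  idx <- seg[1]:seg[2]
  # Filter the full recording, then subset: the deflation segment is then
  # interior to the filtered signal and free of filter edge transients.
  bp <- signal::butter(order / 2, 2 * c(low, high) / fs, type = "pass")
  y <- as.numeric(signal::filtfilt(bp, wf$value))
  new_waveform(wf$time_s[idx], y[idx])
}

#' Extract the applied cuff-pressure trend
#'
#' Low-pass filters the raw recording (4th-order Butterworth, 0.3 Hz,
#' zero phase) and restricts it to the deflation segment, recovering the
#' slowly decreasing applied external pressure.
#'
#' @inheritParams extract_oscillations
#' @param cutoff Low-pass cutoff, Hz.
#' @return A waveform tibble restricted to the deflation segment.
#' @export
extract_applied_pressure <- function(rec, cutoff = 0.3, order = 4) {
  stopifnot(inherits(rec, "cuff_recording"))
  wf <- rec$waveform
  fs <- sampling_rate(wf)
  trend <- lowpass_trend(wf$value, fs, cutoff, order)
  seg <- deflation_segment(rec, trend)
  idx <- seg[1]:seg[2]
  new_waveform(wf$time_s[idx], trend[idx])
}

# Strict local extrema by sign change of the first difference.
local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  s[s == 0] <- 1
  ds <- diff(s)
  list(peaks = which(ds < 0) + 1L, valleys = which(ds > 0) + 1L)
}

#' FFT-based pulse rate estimate
#'
#' Dominant periodogram frequency of the oscillation signal within a
#' physiological search band.
#'
#' @param osc Oscillation waveform.
#' @param band Search band in Hz (default 0.75-3 Hz).
#' @return Pulse rate in Hz.
#' @export
pulse_rate <- function(osc, band = c(0.75, 3)) {
  check_waveform(osc, "osc")
  fs <- sampling_rate(osc)
  x <- osc$value - mean(osc$value)
  n <- length(x)
  sp <- Mod(fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) abort("No periodogram frequencies inside the search band.")
  freq[keep][which.max(sp[keep])]
}

#' Detect and gate oscillometric pulses
#'
#' Finds candidate peaks and valleys of the band-passed oscillation signal
#' and applies the amplitude and interval gating rules: peaks below
#' `peak_min` mmHg and valleys above `valley_max` mmHg are rejected (noise
#' rejection), and a pulse whose peak-to-peak interval to the preceding
#' candidate lies outside `[0.65/PR, 1.35/PR]` seconds is rejected, where
#' `PR` is the FFT-based pulse rate. Each retained pulse is delimited by its
#' flanking valleys (the pulse feet).
#'
#' @param osc Band-passed oscillation waveform.
#' @param peak_min Minimum admissible peak amplitude, mmHg.
#' @param valley_max Maximum admissible valley amplitude, mmHg.
#' @param band Pulse-rate search band, Hz.
#' @return A tibble with columns `foot_start`, `peak`, `foot_end` (sample
#'   indices into `osc`), with attributes `pulse_rate_hz` and `rejections`
#'   (counts per rule).
#' @export
detect_pulses <- function(osc, peak_min = 0.2, valley_max = -0.1,
                          band = c(0.75, 3)) {
  check_waveform(osc, "osc")
  if (nrow(osc) < 3) abort("Oscillation signal too short for pulse detection.")
  fs <- sampling_rate(osc)
  ext <- local_extrema(osc$value)
  rej <- c(peak_amplitude = 0L, valley_amplitude = 0L, interval = 0L,
           no_feet = 0L)

  pk_ok <- osc$value[ext$peaks] >= peak_min
  rej["peak_amplitude"] <- sum(!pk_ok)
  peaks <- ext$peaks[pk_ok]

  vl_ok <- osc$value[ext$valleys] <= valley_max
  rej["valley_amplitude"] <- sum(!vl_ok)
  valleys <- ext$valleys[vl_ok]

  pr <- tryCatch(pulse_rate(osc, band), error = function(e) NA_real_)
  if (length(peaks) > 1 && is.finite(pr)) {
    iv <- diff(osc$time_s[peaks])
    ok <- c(TRUE, iv >= 0.65 / pr & iv <= 1.35 / pr)
    rej["interval"] <- sum(!ok)
    peaks <- peaks[ok]
  }

  rows <- purrr::map(peaks, function(p) {
    before <- valleys[valleys < p]
    after <- valleys[valleys > p]
    if (!length(before) || !length(after)) return(NULL)
    c(foot_start = max(before), peak = p, foot_end = min(after))
  })
  rej["no_feet"] <- sum(purrr::map_lgl(rows, is.null))
  rows <- purrr::compact(rows)
  if (!length(rows)) {
    abort(paste0(
      "No pulses retained. Rejections - ",
      paste(names(rej), rej, sep = ": ", collapse = ", ")))
  }
  out <- as_tibble(do.call(rbind, rows))
  attr(out, "pulse_rate_hz") <- pr
  attr(out, "rejections") <- rej
  out
}

#' Per-pulse shape features
#'
#' Computes, for each detected pulse, the four per-beat shape features
#' relative to the baseline line connecting the leading and trailing feet:
#' height (baseline-to-peak amplitude at the peak abscissa), area (trapezoid
#' integral of signal minus baseline), area-to-height ratio (effective pulse
#' width, s), and the ratio of the areas left and right of the peak (pulse
#' asymmetry). The applied cuff pressure attributed to each pulse is the
#' low-passed trend evaluated at the peak time.
#'
#' @param osc Band-passed oscillation waveform.
#' @param pulses Pulse index tibble from [detect_pulses()].
#' @param pc_trend Applied-pressure trend waveform (from
#'   [extract_applied_pressure()]).
#' @return A tibble with one row per non-degenerate pulse: `foot_start`,
#'   `peak`, `foot_end`, `time_s`, `cuff_pressure_mmHg`, `height`, `area`,
#'   `area_to_height`, `left_right_area_ratio`.
#' @export
pulse_features <- function(osc, pulses, pc_trend) {
  check_waveform(osc, "osc"); check_waveform(pc_trend, "pc_trend")
  rows <- purrr::pmap(
    list(pulses$foot_start, pulses$peak, pulses$foot_end),
    function(i0, ip, i1) {
      idx <- i0:i1
      t <- osc$time_s[idx]
      y <- osc$value[idx]
      base <- y[1] + (y[length(y)] - y[1]) * (t - t[1]) / (t[length(t)] - t[1])
      rel <- y - base
      kpk <- ip - i0 + 1L
      h <- rel[kpk]
      if (!is.finite(h) || h <= 0) return(NULL)
      area <- trapz_num(t, rel)
      left <- trapz_num(t[1:kpk], rel[1:kpk])
      right <- area - left
      if (area <= 0 || right <= 0) return(NULL)
      pc <- approx(pc_trend$time_s, pc_trend$value, xout = osc$time_s[ip],
                   rule = 2)$y
      tibble(foot_start = i0, peak = ip, foot_end = i1,
             time_s = osc$time_s[ip], cuff_pressure_mmHg = pc,
             height = h, area = area, area_to_height = area / h,
             left_right_area_ratio = left / right)
    })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (!nrow(out)) abort("All pulses were degenerate (non-positive height or area).")
  out
}

trapz_num <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, window = 5) {
  half <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- max(1, i - half):min(n, i + half)
    mean(x[j])
  }, numeric(1))
}

#' Assemble a measured oscillogram from per-pulse features
#'
#' Sorts the selected feature against applied cuff pressure, smooths with a
#' 5-point centered moving average, trims the flat tails, flags
#' completeness, and optionally aligns the fiducial point to 0 mmHg and
#' normalizes to unit maximum.
#'
#' Tail trimming walks outward from the oscillogram maximum (minimum for the
#' area-to-height kind) and cuts at the first sample where the smoothed
#' amplitude either reverses direction for `reversal_run` consecutive
#' samples or falls below `floor_frac` of the maximum. The oscillogram is
#' flagged complete when both trimmed ends fall to at most `complete_frac`
#' of the maximum (inverted-U kinds only).
#'
#' @param features Feature tibble from [pulse_features()].
#' @param kind One of `"height"`, `"area"`, `"area_to_height"`,
#'   `"area_ratio"`.
#' @param smooth_window Moving-average window length (samples).
#' @param reversal_run Consecutive rising samples that terminate a tail.
#' @param floor_frac Amplitude floor for trimming, as a fraction of max.
#' @param complete_frac Completeness threshold as a fraction of max.
#' @param align Shift cuff pressures so the fiducial point sits at 0 mmHg.
#' @param normalize Normalize amplitudes to unit maximum.
#' @return A tibble of class `measured_oscillogram` with columns
#'   `cuff_pressure_mmHg`, `amplitude`; attributes `kind`, `pc_min`,
#'   `pc_max`, `complete`, `normalized`, `aligned`.
#' @export
assemble_oscillogram <- function(features,
                                 kind = c("height", "area", "area_to_height",
                                          "area_ratio"),
                                 smooth_window = 5, reversal_run = 3,
                                 floor_frac = 0.1, complete_frac = 0.8,
                                 align = FALSE, normalize = TRUE) {
  kind <- match.arg(kind)
  if (nrow(features) < 5) abort("At least 5 pulses are needed to assemble an oscillogram.")
  col <- switch(kind, height = "height", area = "area",
                area_to_height = "area_to_height",
                area_ratio = "left_right_area_ratio")
  df <- tibble(cuff_pressure_mmHg = features$cuff_pressure_mmHg,
               amplitude = features[[col]])
  df <- df[order(df$cuff_pressure_mmHg), ]
  n_all <- nrow(df)
  df$amplitude <- moving_average(df$amplitude, smooth_window)

  inverted_u <- kind %in% c("height", "area", "area_ratio")
  amp <- if (inverted_u) df$amplitude else -df$amplitude
  ipk <- which.max(amp)
  mx <- amp[ipk]

  trim_end <- function(dir) {
    idx <- if (dir > 0) seq(ipk, nrow(df)) else seq(ipk, 1)
    run <- 0L
    last <- ipk
    prev <- mx
    for (i in idx[-1]) {
      if (inverted_u && df$amplitude[i] < floor_frac * mx) break
      run <- if (amp[i] > prev) run + 1L else 0L
      if (run >= reversal_run) {
        last <- if (dir > 0) i - reversal_run else i + reversal_run
        return(last)
      }
      prev <- amp[i]
      last <- i
    }
    last
  }
  ilo <- trim_end(-1)
  ihi <- trim_end(+1)

  complete <- if (inverted_u) {
    df$amplitude[ilo] <= complete_frac * mx &&
      df$amplitude[ihi] <= complete_frac * mx
  } else TRUE

  # Drop points whose centered smoothing window was incomplete (the absolute
  # ends of the feature series): one-sided averages on a rising/falling tail
  # bias them systematically. Completeness above is judged before dropping.
  half <- (smooth_window - 1) %/% 2
  if (ihi - ilo > 2 * half + 4 && half > 0) {
    ilo <- max(ilo, half + 1)
    ihi <- min(ihi, n_all - half)
  }
  out <- df[ilo:ihi, ]

  fid <- if (inverted_u) which.max(out$amplitude) else which.min(out$amplitude)
  if (align) {
    out$cuff_pressure_mmHg <- out$cuff_pressure_mmHg -
      out$cuff_pressure_mmHg[fid]
  }
  pc_min <- min(out$cuff_pressure_mmHg)
  pc_max <- max(out$cuff_pressure_mmHg)
  normalized <- FALSE
  if (normalize) {
    if (max(out$amplitude) <= 0) abort("Cannot normalize an all-zero oscillogram.")
    out$amplitude <- out$amplitude / max(out$amplitude)
    normalized <- TRUE
  }
  class(out) <- c("measured_oscillogram", class(out))
  attr(out, "kind") <- kind
  attr(out, "pc_min") <- pc_min
  attr(out, "pc_max") <- pc_max
  attr(out, "complete") <- complete
  attr(out, "normalized") <- normalized
  attr(out, "aligned") <- align
  out
}

#' @export
print.measured_oscillogram <- function(x, ...) {
  cat(sprintf(
    "<measured_oscillogram> kind = %s, %d points on [%.1f, %.1f] mmHg, complete = %s\n",
    attr(x, "kind"), nrow(x), attr(x, "pc_min"), attr(x, "pc_max"),
    attr(x, "complete")))
  NextMethod()
}

#' Run the full construction pipeline on a recording
#'
#' Convenience wrapper: oscillation extraction, applied-pressure trend,
#' pulse detection, per-pulse features, and oscillogram assembly for the
#' requested kinds, together with a QC report.
#'
#' @inheritParams extract_oscillations
#' @param kinds Oscillogram kinds to assemble.
#' @param ... Passed to [assemble_oscillogram()].
#' @return A list with elements `oscillograms` (named list of
#'   `measured_oscillogram`), `features`, `qc` (pulse counts, rejections per
#'   rule, pulse rate, trim bounds, completeness flags).
#' @export
construct_oscillograms <- function(rec, kinds = c("height", "area"), ...) {
  osc <- extract_oscillations(rec)
  trend <- extract_applied_pressure(rec)
  pulses <- detect_pulses(osc)
  features <- pulse_features(osc, pulses, trend)
  oscillograms <- purrr::map(setNames(kinds, kinds), function(k) {
    assemble_oscillogram(features, kind = k, ...)
  })
  qc <- list(
    n_candidate_pulses = nrow(pulses) +
      sum(attr(pulses, "rejections")[c("interval", "no_feet")]),
    n_retained_pulses = nrow(features),
    rejections = as.list(attr(pulses, "rejections")),
    pulse_rate_hz = attr(pulses, "pulse_rate_hz"),
    oscillograms = purrr::map(oscillograms, function(o) {
      list(pc_min = attr(o, "pc_min"), pc_max = attr(o, "pc_max"),
           complete = attr(o, "complete"), normalized = attr(o, "normalized"))
    })
  )
  list(oscillograms = oscillograms, features = features, qc = qc)
}

#' Coerce a raw waveform into a cuff recording
#'
#' @param wf Waveform tibble (e.g. from [read_waveform_csv()]).
#' @param protocol Optional [cuff_protocol()] metadata.
#' @param metadata Optional free-form provenance list.
#' @return A `cuff_recording`.
#' @export
as_cuff_recording <- function(wf, protocol = NULL, metadata = list()) {
  check_waveform(wf, "wf")
  structure(list(waveform = wf, protocol = protocol, components = NULL,
                 truth = metadata),
            class = "cuff_recording")
}
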