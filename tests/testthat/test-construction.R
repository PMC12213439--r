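# A minimal recording carrying a known ramp plus an arbitrary additive
# signal, for filter-contract tests.
ramp_recording <- function(extra = 0, duration = 60, fs = 250) {
  pro <- cuff_protocol(sampling_rate = fs,
                       hold_duration = duration - 5 - 40)
  pc <- cuff_ramp(pro, duration = duration)
  wf(pc$time_s, pc$value + extra)
}

test_that("oscillation extraction suppresses the ramp and passes heart-band tones", {
  t <- seq(0, 60 - 1 / 250, by = 1 / 250)
  # drifting ramp alone: output is a tiny fraction of the input swing
  rec0 <- as_cuff_recording(ramp_recording(), protocol = cuff_protocol())
  o0 <- extract_oscillations(rec0)
  expect_lt(max(abs(o0$value)), 0.01 * 120)
  # 1.5 Hz unit tone rides through with near-unit amplitude
  tone <- sin(2 * pi * 1.5 * t)
  rec1 <- as_cuff_recording(ramp_recording(extra = tone),
                            protocol = cuff_protocol())
  o1 <- extract_oscillations(rec1)
  interior <- o1$value[o1$time_s > 15 & o1$time_s < 35]
  expect_gte(max(interior), 0.9)
  expect_lte(max(interior), 1.0)
  # constant input: band-pass output is numerically zero
  flat <- wf(t, rep(100, length(t)))
  seg <- list(waveform = flat, protocol = NULL)
  class(seg) <- "cuff_recording"
  expect_error(extract_oscillations(seg)) # no deflation segment in a constant
})

test_that("applied-pressure extraction recovers the known deflation ramp", {
  rec <- elastic_recording()
  trend <- extract_applied_pressure(rec)
  truth <- approx(rec$components$trend$time_s, rec$components$trend$value,
                  xout = trend$time_s)$y
  expect_lt(max(abs(trend$value - truth)), 1)
  fs <- sampling_rate(trend)
  mid <- trend$value[trend$time_s > 15 & trend$time_s < 35]
  slope <- (mid[length(mid)] - mid[1]) / (length(mid) - 1) * fs
  expect_lt(abs(slope + 3) / 3, 0.05)
  expect_true(all(diff(trend$value) < 0.5 / fs + 1e-6))
})

# Synthetic oscillation train: amplitude-modulated raised-cosine pulses,
# one narrow pulse per beat centered at mid-phase.
pulse_train <- function(n_beats = 60, rate = 1.2, fs = 250, amp = 1) {
  t <- seq(0, n_beats / rate - 1 / fs, by = 1 / fs)
  phase <- (t * rate) %% 1
  x <- amp * (0.7 + 0.3 * sin(2 * pi * t / (n_beats / rate))) *
    ((1 + cos(2 * pi * (phase - 0.5))) / 2)^4
  wf(t, x - mean(x))
}

test_that("pulse detection finds clean beats and estimates the pulse rate", {
  osc <- pulse_train(60, 1.2)
  p <- detect_pulses(osc)
  expect_gte(nrow(p), 58)
  expect_lte(nrow(p), 62)
  expect_lt(abs(attr(p, "pulse_rate_hz") - 1.2), 0.05)
  expect_true(all(p$foot_start < p$peak & p$peak < p$foot_end))
})

test_that("sub-threshold pulses are rejected by the amplitude rule", {
  osc <- pulse_train(30, 1.2, amp = 0.15) # all peaks below 0.2 mmHg
  expect_error(detect_pulses(osc), "peak_amplitude")
})

test_that("a doubled beat interval is rejected by the interval rule", {
  osc <- pulse_train(40, 1.2)
  fs <- 250
  # silence one beat: the pulse after the gap has a doubled interval
  kill <- osc$time_s > 10 & osc$time_s < 10 + 1 / 1.2
  osc$value[kill] <- 0
  p <- detect_pulses(osc)
  expect_gte(attr(p, "rejections")[["interval"]], 1)
  iv <- diff(osc$time_s[p$peak])
  expect_true(all(iv < 1.35 / attr(p, "pulse_rate_hz") + 0.05 | iv > 1.6))
})

test_that("pulse features reproduce analytic geometry", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  tri <- function(peak_frac) {
    v <- ifelse(t <= peak_frac, t / peak_frac, (1 - t) / (1 - peak_frac))
    wf(t, v)
  }
  trend <- wf(t, rep(90, length(t)))
  mk_bounds <- function(o) tibble::tibble(foot_start = 1L,
                                          peak = which.max(o$value),
                                          foot_end = length(t))
  # isosceles triangle, height 1, base 1 s
  o <- tri(0.5)
  f <- pulse_features(o, mk_bounds(o), trend)
  expect_equal(f$height, 1, tolerance = 1e-9)
  expect_equal(f$area, 0.5, tolerance = 1e-3)
  expect_equal(f$area_to_height, 0.5, tolerance = 1e-3)
  expect_equal(f$left_right_area_ratio, 1, tolerance = 1e-3)
  expect_equal(f$cuff_pressure_mmHg, 90)
  # asymmetric triangle: left/right area ratio p/(1-p)
  o <- tri(0.3)
  f <- pulse_features(o, mk_bounds(o), trend)
  expect_equal(f$left_right_area_ratio, 0.3 / 0.7, tolerance = 5e-3)
  # half-sine: area = 2 h tau / pi
  o <- wf(t, sin(pi * t))
  f <- pulse_features(o, mk_bounds(o), trend)
  expect_equal(f$area, 2 / pi, tolerance = 1e-3)
})

test_that("assembly smooths, trims and flags completeness against the closed form", {
  pc <- seq(55, 165, by = 2.5)
  model <- oscillogram_model(pc, 11, 14, 120, 80, scale = 1)
  feats <- tibble::tibble(cuff_pressure_mmHg = pc, height = model$amplitude)
  osc <- assemble_oscillogram(feats, kind = "height", normalize = FALSE)
  ref <- oscillogram_model(osc$cuff_pressure_mmHg, 11, 14, 120, 80)$amplitude
  expect_lt(max(abs(osc$amplitude - ref)) / max(ref), 0.02)
  peak_pc <- osc$cuff_pressure_mmHg[which.max(osc$amplitude)]
  expect_lt(abs(peak_pc - peak_pressure_height(11, 14, 120, 80)), 2)
  # a minimum end reaching only 90% of the maximum is incomplete
  short <- feats[feats$cuff_pressure_mmHg >= 93, ]
  osc2 <- assemble_oscillogram(short, kind = "height")
  expect_false(attr(osc2, "complete"))
  # alignment moves the argmax abscissa to zero
  osc3 <- assemble_oscillogram(feats, kind = "height", align = TRUE)
  expect_equal(osc3$cuff_pressure_mmHg[which.max(osc3$amplitude)], 0)
  expect_error(assemble_oscillogram(feats[1:3, ], kind = "height"), "5 pulses")
})

test_that("smoothing and normalization commute on noiseless data", {
  x <- oscillogram_model(seq(60, 150, by = 3), 11, 14, 120, 80)$amplitude
  ma <- oscillometry:::moving_average
  nrm <- function(v) v / max(v)
  expect_lt(max(abs(nrm(ma(x, 5)) - nrm(ma(nrm(x), 5)))), 1e-6)
})

test_that("pulse count is invariant to a DC offset on the raw recording", {
  rec <- elastic_recording()
  shifted <- as_cuff_recording(wf(rec$waveform$time_s,
                                  rec$waveform$value + 25),
                               protocol = rec$protocol)
  n0 <- nrow(detect_pulses(extract_oscillations(rec)))
  n1 <- nrow(detect_pulses(extract_oscillations(shifted)))
  expect_identical(n0, n1)
})

test_that("end-to-end construction reproduces the closed-form oscillograms", {
  rec <- elastic_recording()
  built <- construct_oscillograms(rec)
  for (kind in c("height", "area")) {
    meas <- built$oscillograms[[kind]]
    expect_true(attr(meas, "complete"))
    model <- normalize_oscillogram(
      oscillogram_model(meas$cuff_pressure_mmHg, 11, 14, 120, 80,
                        kind = kind, period = 1))
    expect_lt(nrmse(meas, model), 5)
  }
  qc <- built$qc
  expect_gt(qc$n_retained_pulses, 15)
  expect_lt(abs(qc$pulse_rate_hz - 1), 0.05)
})
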