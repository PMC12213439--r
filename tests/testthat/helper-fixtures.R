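# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_params <- function() compliance_params(11, 14, amplitude = 0.05)

# Noiseless elastic recording under the default study conditions
# (120/80 mmHg, 1 s beats, 250 Hz, 3 mmHg/s deflation, 60 mmHg hold).
elastic_recording <- function() {
  cached("elastic_recording", synthesize_recording())
}

wiener_recording <- function() {
  cached("wiener_recording",
         synthesize_recording(sys = system_config("wiener",
                                                  cutoff = 2 * pi * 3)))
}

# Triangular arterial waveform matched to a recording's applied-pressure
# trend grid, as fed to the simulator-based fits.
matched_triangle_bp <- function(trend, ps = 120, pd = 80, period = 1) {
  fs <- sampling_rate(trend)
  n_beats <- ceiling(diff(range(trend$time_s)) / period) + 2L
  bp <- triangular_bp(bp_pulse(ps, pd, period), n_beats, fs)
  bp <- bp[seq_len(nrow(trend)), ]
  bp$time_s <- trend$time_s
  bp
}

wf <- function(t, v, unit = "mmHg") oscillometry:::new_waveform(t, v, unit)

# Numerical area-oscillogram oracle: trapezoid quadrature of the per-beat
# volume integral driven by a directly sampled triangular pulse.
area_oracle <- function(pc, b, cc, ps, pd, period, ts, n_t = 20001) {
  pars <- compliance_params(b, cc, amplitude = 1)
  tt <- seq(0, period, length.out = n_t)
  pa <- ifelse(tt < ts, pd + (ps - pd) * tt / ts,
               ps - (ps - pd) * (tt - ts) / (period - ts))
  vapply(pc, function(x) {
    pracma::trapz(tt, artery_volume(pa - x, pars)) -
      period * artery_volume(pd - x, pars)
  }, numeric(1))
}

random_widths <- function() runif(2, 3, 30)
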