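# oscillometry

Analytical modeling and simulation of oscillometric blood-pressure
**oscillograms** — the envelope of cuff-pressure oscillations plotted
against applied cuff pressure during slow cuff deflation.

Oscillometric devices infer blood pressure from the *height oscillogram*:
the per-beat peak-to-peak oscillation amplitude versus cuff pressure. The
per-beat oscillation *area* forms a second, left-shifted inverted-U curve —
the *area oscillogram* — that carries complementary information about blood
pressure and arterial stiffness. This package is for researchers in
cardiovascular signal processing who want to model, simulate, construct and
fit both oscillograms.

## The model in brief

Arterial blood volume follows a sigmoid of transmural pressure
`P = Pa − Pc`, with compliance (its derivative)

```
g(P) = a e^{P/b} (1 − P/b)   for P < 0
g(P) = a e^{−P/c} (1 + P/c)  for P ≥ 0
```

where `b` and `c` (mmHg) are the compliance-curve widths over negative and
positive transmural pressure and `a` is the maximal compliance. With `f` the
integral of `g`, systolic/diastolic pressures `Ps`, `Pd`, and a
volume-to-pressure scale `k`:

* height oscillogram: `OH(Pc) = k [f(Ps − Pc) − f(Pd − Pc)]`, which peaks
  exactly at `PHmax = Pd + b·PP/(b + c)`;
* area oscillogram (triangular arterial pulse, beat duration `T`):
  `OA(Pc) = k T [(F(Ps − Pc) − F(Pd − Pc))/PP − f(Pd − Pc)]` with
  `F = ∫ f`; the systolic upstroke duration cancels exactly, and `OA`
  always peaks below `OH`.

Around the closed forms the package provides:

* a forward simulator of complete cuff recordings (elastic, Hammerstein and
  Wiener viscoelastic systems; constant `k` or variable
  `kv = Pc/Patm + 1` scaling; a Boyle's-law nonlinear cuff–arm model;
  seeded noise) — `synthesize_recording()`, `simulate_volume()`,
  `boyle_cuff_pressure()`;
* the automated oscillogram-construction algorithm (zero-phase band-pass
  0.75–5 Hz, pulse detection with amplitude and interval gating against an
  FFT pulse-rate estimate, per-pulse shape features, moving-average
  smoothing, tail trimming, completeness flagging, normalization) —
  `construct_oscillograms()`;
* constrained least-squares fitting of the models to measured oscillograms
  (widths bounded to 0–60 mmHg, seeds 11/14 mmHg, tolerance 1e-6) and a
  simulator-in-the-loop variant that also fits the viscoelastic cutoff —
  `fit_oscillogram()`, `fit_simulated()`, `assumption_grid()`,
  `adjust_nonlinearity()`.

Everything is tibble-first and pipe-friendly; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a noiseless recording under reference conditions (120/80 mmHg,
1 s beats, widths b = 11, c = 14 mmHg, 250 Hz, 3 mmHg/s deflation with a
60 mmHg hold), construct the measured height oscillogram, and refit the
model:

```r
library(oscillometry)

peak_pressure_height(11, 14, ps = 120, pd = 80)
#> [1] 97.6
peak_pressure_area(11, 14, ps = 120, pd = 80)
#> [1] 90.27

rec   <- synthesize_recording(pulse = bp_pulse(120, 80, period = 1),
                              params = compliance_params(11, 14, amplitude = 0.05))
built <- construct_oscillograms(rec)
fit   <- fit_oscillogram(built$oscillograms$height, kind = "height",
                         ps = 120, pd = 80)
fit
#> <oscillogram_fit> height oscillogram, closed_form
#>   b = 10.885 mmHg, c = 13.732 mmHg
#>   NRMSE = 0.24%, converged = TRUE (113 evaluations)
```

The height oscillogram peaks at 97.6 mmHg — a 0.44/0.56 weighted average of
systolic and diastolic pressure for these widths — while the area
oscillogram peaks 7.3 mmHg lower. The fit recovers the generating widths to
about 0.1–0.3 mmHg with an NRMSE of 0.24%, the residual reflecting the
construction pipeline (filtering, per-beat sampling, smoothing) rather than
the optimizer.

A thin command-line wrapper over the same functions lives in
`inst/cli/oscillometry.R`:

```sh
Rscript inst/cli/oscillometry.R simulate  --seed 4 --out run
Rscript inst/cli/oscillometry.R construct --input run_recording.csv --out run
Rscript inst/cli/oscillometry.R fit       --input run_height.csv --model height --out run
```

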