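test_that("height model piecewise branches equal the volume-difference route", {
  withr::with_seed(31, {
    for (i in 1:10) {
      w <- random_widths()
      pd <- runif(1, 50, 90); ps <- pd + runif(1, 25, 90)
      d <- runif(1, 0.02, 2)
      pc <- seq(pd - 80, ps + 80, length.out = 200)
      m <- oscillogram_model(pc, w[1], w[2], ps, pd, scale = d)
      pars <- compliance_params(w[1], w[2], amplitude = 1)
      oracle <- d * (artery_volume(ps - pc, pars) - artery_volume(pd - pc, pars))
      expect_lt(max(abs(m$amplitude - oracle)) / max(oracle), 1e-9)
      expect_true(all(m$amplitude >= 0))
    }
  })
})

test_that("height model vanishes in the zero-pulse-pressure limit and far tails", {
  pc <- seq(0, 250, by = 1)
  # degenerate ps == pd, exercised through the internal branch evaluator
  amp <- oscillometry:::height_branches(pc, 11, 14, 100, 100, "exp_linear")
  expect_true(all(abs(amp) < 1e-12))
  m <- oscillogram_model(c(120 + 50 * 11), 11, 14, 120, 80)
  peak <- max(oscillogram_model(seq(40, 160, by = 0.5), 11, 14, 120, 80)$amplitude)
  expect_lt(m$amplitude / peak, 1e-10)
})

test_that("area model matches trapezoid quadrature of the per-beat integral", {
  withr::with_seed(37, {
    for (i in 1:3) {
      w <- random_widths()
      pd <- runif(1, 60, 85); ps <- pd + runif(1, 30, 70)
      period <- runif(1, 0.7, 1.1)
      pc <- seq(pd - 60, ps + 60, length.out = 50)
      m <- oscillogram_model(pc, w[1], w[2], ps, pd, kind = "area",
                             period = period)
      oracle <- area_oracle(pc, w[1], w[2], ps, pd, period, 0.3 * period)
      expect_lt(max(abs(m$amplitude - oracle)) / max(oracle), 1e-6)
    }
  })
})

test_that("area model is independent of the systolic duration", {
  # the closed form has no systolic-duration argument; the time-domain oracle
  # confirms the cancellation for very different upstroke fractions
  pc <- seq(30, 170, length.out = 25)
  o1 <- area_oracle(pc, 11, 14, 120, 80, 1, 0.2)
  o2 <- area_oracle(pc, 11, 14, 120, 80, 1, 0.45)
  expect_lt(max(abs(o1 - o2)) / max(o1), 1e-6)
  m <- oscillogram_model(pc, 11, 14, 120, 80, kind = "area", period = 1)
  expect_lt(max(abs(m$amplitude - o1)) / max(o1), 1e-6)
})

test_that("area model is linear in beat duration and scale", {
  pc <- seq(40, 160, by = 2)
  base <- oscillogram_model(pc, 11, 14, 120, 80, kind = "area", period = 1)
  double_t <- oscillogram_model(pc, 11, 14, 120, 80, kind = "area", period = 2)
  double_d <- oscillogram_model(pc, 11, 14, 120, 80, kind = "area", period = 1,
                                scale = 2)
  expect_equal(double_t$amplitude, 2 * base$amplitude, tolerance = 1e-12)
  expect_equal(double_d$amplitude, 2 * base$amplitude, tolerance = 1e-12)
})

test_that("both models are continuous at the region boundaries", {
  withr::with_seed(41, {
    eps <- 1e-9
    for (i in 1:100) {
      w <- random_widths()
      pd <- runif(1, 50, 90); ps <- pd + runif(1, 20, 90)
      for (kind in c("height", "area")) {
        for (edge in c(pd, ps)) {
          vals <- oscillogram_model(c(edge - eps, edge, edge + eps),
                                    w[1], w[2], ps, pd, kind = kind)$amplitude
          expect_lt(max(abs(diff(vals))), 1e-9 * max(1, max(vals)))
        }
      }
    }
  })
})

test_that("models are translation-equivariant in pressure", {
  pc <- seq(30, 170, by = 1)
  shift <- 23.7
  for (kind in c("height", "area")) {
    m0 <- oscillogram_model(pc, 9, 13, 125, 78, kind = kind)
    m1 <- oscillogram_model(pc + shift, 9, 13, 125 + shift, 78 + shift,
                            kind = kind)
    expect_equal(m1$amplitude, m0$amplitude, tolerance = 1e-12)
  }
})

test_that("height-peak closed form equals the grid argmax", {
  expect_equal(peak_pressure_height(10, 10, 130, 70), 100)
  withr::with_seed(43, {
    for (i in 1:25) {
      w <- random_widths()
      pd <- runif(1, 55, 90); ps <- pd + runif(1, 25, 80)
      g <- seq(pd - 30, ps + 10, by = 0.01)
      m <- oscillogram_model(g, w[1], w[2], ps, pd)
      expect_lt(abs(g[which.max(m$amplitude)] -
                      peak_pressure_height(w[1], w[2], ps, pd)), 0.011)
    }
  })
})

test_that("area-peak root equals the grid argmax and sits left of the height peak", {
  withr::with_seed(47, {
    for (i in 1:25) {
      w <- random_widths()
      pd <- runif(1, 55, 90); ps <- pd + runif(1, 25, 80)
      g <- seq(pd - 5 * sum(w), ps, by = 0.01)
      m <- oscillogram_model(g, w[1], w[2], ps, pd, kind = "area")
      expect_lt(abs(g[which.max(m$amplitude)] -
                      peak_pressure_area(w[1], w[2], ps, pd)), 0.011)
    }
  })
  for (b in c(2, 5, 10, 20, 40)) {
    for (cc in c(2, 5, 10, 20, 40)) {
      for (pp in c(30, 60, 90)) {
        expect_lt(peak_pressure_area(b, cc, 80 + pp, 80),
                  peak_pressure_height(b, cc, 80 + pp, 80))
      }
    }
  }
})

test_that("exponential-form area-peak approximation tracks the numeric root", {
  for (b in c(5, 10, 20)) {
    for (cc in c(5, 12, 20)) {
      for (pp in c(40, 60, 80)) {
        exact <- peak_pressure_area(b, cc, 80 + pp, 80, form = "exp")
        approx_ <- peak_pressure_area(b, cc, 80 + pp, 80, form = "exp",
                                      approximate = TRUE)
        # bound frozen from the numeric-root study over this grid: the
        # worst case (narrow negative width, wide positive width, high
        # pulse pressure) deviates by just under 2.5 mmHg
        expect_lt(abs(exact - approx_), 2.5)
      }
    }
  }
})

test_that("normalization has unit maximum, is idempotent and removes scale", {
  pc <- seq(40, 160, by = 1)
  m1 <- normalize_oscillogram(oscillogram_model(pc, 11, 14, 120, 80,
                                                scale = 0.5))
  m2 <- normalize_oscillogram(oscillogram_model(pc, 11, 14, 120, 80,
                                                scale = 2))
  expect_equal(max(m1$amplitude), 1)
  expect_identical(normalize_oscillogram(m1)$amplitude, m1$amplitude)
  expect_equal(m1$amplitude, m2$amplitude, tolerance = 1e-12)
  zero <- oscillogram_model(pc, 11, 14, 120, 80)
  zero$amplitude <- 0 * zero$amplitude
  expect_error(normalize_oscillogram(zero), "maximum amplitude")
})

test_that("model constructors validate their inputs", {
  expect_error(oscillogram_model(1:10, 11, 14, ps = 80, pd = 120), "exceed")
  expect_error(oscillogram_model(c(1, NA), 11, 14, 120, 80), "finite")
  expect_error(oscillogram_model(1:10, 11, 14, 120, 80, kind = "area",
                                 period = -1), "period")
})
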