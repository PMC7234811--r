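test_that("noiseless exponential parameters are recovered", {
  t <- seq(0, 1, by = 2e-3)
  # single phase
  y1 <- 0.2 + 1 * exp(-10 * t)
  f1 <- fit_exponentials(t, y1, 1)
  expect_equal(f1$kobs, 10, tolerance = 1e-6)
  expect_equal(f1$amplitudes, 1, tolerance = 1e-6)
  expect_equal(f1$offset, 0.2, tolerance = 1e-6)

  # two well-separated phases, recovered fast-to-slow
  y2 <- 0.1 + 0.6 * exp(-200 * t) + 0.4 * exp(-20 * t)
  f2 <- fit_exponentials(t, y2, 2)
  expect_equal(f2$kobs, c(200, 20), tolerance = 1e-4)
  expect_equal(f2$amplitudes, c(0.6, 0.4), tolerance = 1e-4)
  expect_true(f2$kobs[1] >= f2$kobs[2])

  # property: recovery for generated parameters with >= 3x separation
  set.seed(1)
  for (i in 1:5) {
    k <- sort(10^runif(2, 0.5, 2.8), decreasing = TRUE)
    if (k[1] / k[2] < 3) k[1] <- 3.5 * k[2]
    A <- runif(2, 0.2, 1)
    y <- 0.3 + A[1] * exp(-k[1] * t) + A[2] * exp(-k[2] * t)
    f <- fit_exponentials(t, y, 2)
    expect_equal(f$kobs, k, tolerance = 1e-4)
    expect_equal(f$amplitudes, A, tolerance = 1e-3)
  }

  # model mismatch: bi-exponential fit of a single-exponential trace
  expect_warning(fit_exponentials(t, y1, 2), "degenerate phases")
})

test_that("AIC model selection finds the generating phase count", {
  t <- seq(0, 0.5, by = 1e-3)
  y1 <- 0.2 + exp(-15 * t) + withr::with_seed(5, rnorm(length(t), 0, 1e-3))
  expect_equal(select_model(t, y1)$n_phases, 1)

  # five-species model transient at 10 uM titrant shows two phases
  ser <- benchmark_series(multiples = 100, n_points = 400)
  sel <- select_model(ser$time, ser$transients[[1]]$intensity)
  expect_gte(sel$n_phases, 2)
})

test_that("fast-phase line recovers kon and koff from Table-1-style data", {
  conc <- c(1, 2, 5, 10, 20) * 1e-6
  kobs <- c(31.8, 50.6, 107, 201, 389)   # 1.88e7 * conc + 13, exactly
  fp <- suppressWarnings(fast_phase_fit(conc, kobs))  # exact-fit summary note
  expect_equal(fp$kon, 1.88e7, tolerance = 1e-10)
  expect_equal(fp$koff, 13, tolerance = 1e-8)
  expect_equal(fp$Kd_app, 13 / 1.88e7, tolerance = 1e-8)
  expect_lt(fp$kon_se, 1)

  # constant kobs: zero slope, Kd undefined
  expect_warning(fp0 <- fast_phase_fit(conc, rep(5, 5)), "Kd_app undefined")
  expect_true(is.na(fp0$Kd_app))
  expect_equal(fp0$koff, 5)

  expect_error(fast_phase_fit(1e-6, 10), "insufficient")
})

test_that("slow-phase hyperbola recovers kslow and K0.5", {
  conc <- c(0.5, 1, 2, 4, 8, 16, 32, 50) * 1e-6
  kobs <- 24 * conc / (2.4e-6 + conc)
  sp <- slow_phase_fit(conc, kobs)
  expect_equal(sp$kslow, 24, tolerance = 1e-4)
  expect_equal(sp$K0_5, 2.4e-6, tolerance = 1e-4)

  # saturation limit: K0.5 ill-determined warning, kslow ~ mean(kobs)
  cs <- c(100, 200, 400, 800) * 1e-6
  expect_warning(sps <- slow_phase_fit(cs, 24 * cs / (2.4e-6 + cs)),
                 "ill-determined|extrapolation")
  expect_equal(sps$kslow, 24, tolerance = 0.05)

  expect_error(slow_phase_fit(1e-6, 10), "insufficient")
})

test_that("series summary reproduces the generating constants", {
  # pre-equilibrium regime: fast conformational exchange, no rearrangement,
  # so each trace is a clean pseudo-first-order relaxation
  r <- rate_constants(k1 = 2e5, k_minus1 = 1e5, kb = 1.5e7, k_minusb = 5,
                      kr = 0, k_minusr = 0)
  des <- titration_design("kinase",
                          titrant_multiples = c(10, 25, 50, 100, 150, 250),
                          scheme = "ACCEPTOR-3", duration = 0.5,
                          sampling = "log", n_points = 300,
                          dead_time = 1.5e-3, noise_sigma = 0.005, seed = 33)
  ser <- generate_titration(r, fret_calibration(1, 0, SC = -0.6,
                                                Baseline = 1), des)
  ps <- suppressWarnings(summarize_titration(ser))
  f <- r[["k1"]] / (r[["k1"]] + r[["k_minus1"]])
  kon_expected <- r[["kb"]] * f       # fast pre-equilibrium slope = 1e7
  expect_equal(ps$fast$kon, kon_expected, tolerance = 0.05)
  expect_true(all(ps$per_transient$kobs_fast > 0))
  both <- ps$per_transient$n_phases == 2
  expect_equal(ps$per_transient$rel_amp_fast[both] +
                 ps$per_transient$rel_amp_slow[both],
               rep(1, sum(both)), tolerance = 1e-8)
  expect_error(summarize_titration(
    structure(list(design = ser$design, time = ser$time,
                   transients = list()), class = "titration_series")),
    "insufficient")
})
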