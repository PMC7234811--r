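test_that("titration generation is deterministic and noise-controlled", {
  des <- titration_design(titrant_multiples = c(0, 25, 100), duration = 0.05,
                          sample_rate = 2000, noise_sigma = 0.02, seed = 7)
  r <- truth_rates()
  calib <- small_calib()
  s1 <- generate_titration(r, calib, des)
  s2 <- generate_titration(r, calib, des)
  expect_identical(s1$transients, s2$transients)   # same seed, bit-identical

  des2 <- des; des2$seed <- 8L
  s3 <- generate_titration(r, calib, des2)
  expect_false(identical(s1$transients[[2]]$intensity,
                         s3$transients[[2]]$intensity))

  # zero noise reproduces the deterministic model curve exactly
  des0 <- titration_design(titrant_multiples = 100, duration = 0.05,
                           sample_rate = 2000, noise_sigma = 0, seed = 1)
  s0 <- generate_titration(r, calib, des0)
  tobs <- s0$time
  I_tot <- 100 * 1e-7                 # exactly the generator's arithmetic
  traj <- simulate_scheme(r, mixing_condition(1e-7, I_tot), c(0, tobs))
  eq <- equilibrium_state(r, 1e-7, I_tot)
  expect_equal(s0$transients[[1]]$intensity,
               fret_intensity(traj, calib, eq)[-1], tolerance = 1e-12)

  # zero titrant: flat baseline-only trace flagged no-binding
  z <- s1$transients[[1]]
  expect_true(z$no_binding)
  s1z <- generate_titration(r, calib,
                            titration_design(titrant_multiples = 0,
                                             duration = 0.05,
                                             noise_sigma = 0, seed = 1))
  expect_true(all(s1z$transients[[1]]$intensity == calib[["Baseline"]]))
})

test_that("transient CSV round-trips bit-exactly", {
  des <- titration_design(titrant_multiples = 50, duration = 0.02,
                          sample_rate = 5000, noise_sigma = 0.01, seed = 3)
  s <- generate_titration(truth_rates(), small_calib(), des)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transient(s$time, s$transients[[1]]$intensity,
                  s$transients[[1]]$titrant_M, "ACCEPTOR-3", path)
  back <- read_transient(path)
  expect_identical(back$time, s$time)
  expect_identical(back$intensity, s$transients[[1]]$intensity)
  expect_identical(back$titrant_M, 50 * 1e-7)
  expect_identical(back$scheme, "ACCEPTOR-3")
})

test_that("peak tables reproduce their ground truth at zero noise", {
  tr <- peak_truth()
  tab <- generate_peak_table(tr, noise_rms = 0, seed = 1)
  m <- peak_table_metrics(tab)
  expect_equal(m$noe, tr$noe, tolerance = 1e-10)
  expect_equal(m$delta_rex, tr$delta_rex, tolerance = 1e-10)
  expect_equal(m$gamma2, tr$gamma2, tolerance = 1e-10)
  expect_equal(m$r2eff_high, tr$r2, tolerance = 1e-10)
  # zero spectral noise propagates to zero metric errors
  expect_true(all(m$noe_sigma == 0))
  expect_true(all(m$gamma2_sigma == 0))

  # constructed PRE: Gamma2 = 50 from decay rates 60 vs 10 at 4/14 ms
  g <- pre_gamma2(exp(-60 * 0.004), exp(-60 * 0.014),
                  exp(-10 * 0.004), exp(-10 * 0.014))
  expect_equal(g$gamma2, 50, tolerance = 1e-12)
})

test_that("undetectable rows arise from broadening beyond detection", {
  tr <- peak_truth(4)
  tr$gamma2 <- c(10, 20, 3000, 30)     # third residue fully broadened
  tab <- generate_peak_table(tr, I0 = 100, noise_rms = 5, seed = 2)
  m <- peak_table_metrics(tab)
  expect_true(m$undetectable[m$residue == 3])
  expect_identical(generate_peak_table(tr, I0 = 100, noise_rms = 5, seed = 2),
                   tab)   # seeded determinism
})

test_that("discrete trajectories follow the generating chain", {
  # identity chain: constant sequences
  cons <- suppressWarnings(      # identity chain is reducible by design
    generate_discrete_trajectories(diag(2), 3, 50, seed = 1))
  expect_true(all(vapply(cons, function(s) length(unique(s)) == 1, TRUE)))

  T2 <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  trajs <- generate_discrete_trajectories(T2, 4, 30000, seed = 11)
  freq <- table(factor(unlist(trajs), levels = 1:2)) / (4 * 30000)
  expect_equal(as.numeric(freq), c(0.75, 0.25), tolerance = 0.02)

  expect_identical(trajs,
                   generate_discrete_trajectories(T2, 4, 30000, seed = 11))
  expect_false(identical(
    trajs, generate_discrete_trajectories(T2, 4, 30000, seed = 12)))
  expect_error(generate_discrete_trajectories(matrix(c(1, 1, 0, 1), 2), 1,
                                              10, 1),
               "row-stochastic")
})

test_that("config and peak-table files round-trip", {
  r <- truth_rates()
  for (ext in c(".yaml", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_rates_config(r, p, P_total_M = 1e-7, I_total_M = 1e-5)
    cfg <- read_rates_config(p)
    expect_equal(unclass(cfg$rates), unclass(r))
    expect_equal(cfg$I_total_M, 1e-5)
  }
  tab <- generate_peak_table(peak_truth(4), I0 = 100, noise_rms = 2, seed = 9)
  p <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(tab, p)
  back <- read_peak_table(p)
  expect_identical(back$intensity, tab$intensity)
  expect_identical(back$undetectable, tab$undetectable)
})
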