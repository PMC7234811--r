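test_that("derivatives implement the mass-action scheme", {
  r0 <- rate_constants(0, 0, 0, 0, 0, 0)
  s <- species_state(P_star = 1e-7, I = 2e-6, I_star = 3e-6,
                     enc = 1e-8, final = 2e-8)
  expect_equal(unname(species_derivative(s, r0)), rep(0, 5))

  # empty system: no inhibitor, no complex
  r <- truth_rates()
  s0 <- species_state(P_star = 1e-7)
  expect_equal(unname(species_derivative(s0, r)), rep(0, 5))

  # independently hand-coded mass-action association term
  r2 <- rate_constants(0, 1, 1.5e7, 0, 0, 0)
  s2 <- species_state(P_star = 1e-7, I_star = 1e-5)
  d <- species_derivative(s2, r2)
  expect_equal(d[["enc"]], 1.5e7 * 1e-7 * 1e-5)   # = 1.5e-5 M/s
  expect_equal(d[["P_star"]], -1.5e-5)

  # conservation of both totals holds for arbitrary states and rates
  set.seed(42)
  for (i in 1:20) {
    rr <- rate_constants(runif(1, 0, 1e5), runif(1, 0, 1e5),
                         runif(1, 0, 1e8), runif(1, 0, 1e3),
                         runif(1, 0, 1e4), runif(1, 0, 1e4))
    ss <- species_state(runif(1, 0, 1e-6), runif(1, 0, 1e-5),
                        runif(1, 0, 1e-5), runif(1, 0, 1e-7),
                        runif(1, 0, 1e-7))
    dd <- species_derivative(ss, rr)
    expect_equal(dd[["P_star"]] + dd[["enc"]] + dd[["final"]], 0,
                 tolerance = 1e-12)
    expect_equal(dd[["I"]] + dd[["I_star"]] + dd[["enc"]] + dd[["final"]], 0,
                 tolerance = 1e-12)
  }

  expect_error(species_derivative(c(P_star = NaN, I = 0, I_star = 0,
                                    enc = 0, final = 0), r),
               "invalid state")
})

test_that("simulation conserves totals and handles null dynamics", {
  tg <- seq(0, 0.1, by = 1e-3)
  r0 <- rate_constants(0, 0, 0, 0, 0, 0)
  traj <- simulate_scheme(r0, mixing_condition(1e-7, 1e-5,
                                               pre_equilibrated = FALSE), tg)
  expect_true(all(traj$states$P_star == 1e-7))
  expect_true(all(traj$states$I == 1e-5))
  expect_true(all(traj$states$enc == 0))

  r <- truth_rates()
  traj <- simulate_scheme(r, mixing_condition(1e-7, 1e-5), c(0, 10^seq(-5, 0, length.out = 200)))
  P_tot <- traj$states$P_star + traj$states$enc + traj$states$final
  I_tot <- traj$states$I + traj$states$I_star + traj$states$enc +
    traj$states$final
  expect_lt(max(abs(P_tot - 1e-7)) / 1e-7, 1e-6)
  expect_lt(max(abs(I_tot - 1e-5)) / 1e-5, 1e-6)
  expect_gt(min(as.matrix(traj$states)), -1e-13 * 10)

  expect_error(simulate_scheme(r, mixing_condition(1e-7, 1e-5),
                               c(0.1, 0.2)), "start at 0")
})

test_that("two-state limit matches the single-site binding quadratic", {
  # kr = 0, instantaneous conformational pre-equilibrium: long-time enc
  # follows the depletion quadratic with Kd = k_minusb / (kb * f)
  r <- rate_constants(k1 = 1e6, k_minus1 = 1e6, kb = 1.5e7, k_minusb = 5,
                      kr = 0, k_minusr = 0)
  P <- 1e-7; I <- 1e-5
  traj <- simulate_scheme(r, mixing_condition(P, I), c(0, 10^seq(-6, 1, length.out = 100)))
  f <- 0.5
  Kd <- 5 / (1.5e7 * f)            # effective Kd on total free inhibitor
  b <- P + I + Kd
  enc_expected <- (b - sqrt(b^2 - 4 * P * I)) / 2
  expect_equal(traj$states$enc[100], enc_expected, tolerance = 1e-5)
})

test_that("algebraic equilibrium agrees with long-time integration", {
  r <- truth_rates()
  eq <- equilibrium_state(r, 1e-7, 1e-5)
  traj <- simulate_scheme(r, mixing_condition(1e-7, 1e-5),
                          c(0, 10^seq(-5, log10(100 / 0.5), length.out = 150)),
                          rtol = 1e-10, atol = 1e-16)
  last <- unlist(traj$states[nrow(traj$states), ])
  expect_equal(unname(last), unname(unclass(eq)), tolerance = 1e-6)

  # equilibrium is a fixed point of the derivatives
  d <- species_derivative(eq, r)
  expect_lt(max(abs(d)), 1e-9 * max(unclass(r)) * max(unclass(eq)))

  # detailed balance at equilibrium
  expect_equal(r[["kb"]] * eq[["P_star"]] * eq[["I_star"]],
               r[["k_minusb"]] * eq[["enc"]], tolerance = 1e-6)
  expect_equal(r[["kr"]] * eq[["enc"]],
               r[["k_minusr"]] * eq[["final"]], tolerance = 1e-6)
})

test_that("equilibrium edge cases behave as specified", {
  r <- truth_rates()
  # no kinase: free inhibitor partitioned by k1/(k1+k_minus1)
  eq <- equilibrium_state(r, 0, 1e-5)
  f <- 1.9e4 / (1.9e4 + 1.5e4)
  expect_equal(eq[["I_star"]], f * 1e-5)
  expect_equal(eq[["enc"]], 0)

  # kr = 0: no rearranged complex at equilibrium
  r2 <- rate_constants(1.9e4, 1.5e4, 1.5e7, 0.5, 0, 0)
  eq2 <- equilibrium_state(r2, 1e-7, 1e-5)
  expect_equal(eq2[["final"]], 0)

  # irreversible binding is degenerate
  r3 <- rate_constants(1.9e4, 1.5e4, 1.5e7, 0, 0, 0)
  expect_error(equilibrium_state(r3, 1e-7, 1e-5), "degenerate")

  # absorbing rearranged state
  r4 <- rate_constants(1.9e4, 1.5e4, 1.5e7, 0.5, 100, 0)
  expect_warning(eq4 <- equilibrium_state(r4, 1e-7, 1e-5), "absorbing")
  expect_equal(eq4[["final"]], 1e-7)
})

test_that("pre-equilibrium limit gives the pseudo-first-order rate", {
  # k1, k_minus1 >> all else and kr = 0: enc relaxes at kb*f*I_total + k_minusb
  kb <- 1e7; kmb <- 20; k1 <- 4e6; km1 <- 6e6
  r <- rate_constants(k1, km1, kb, kmb, 0, 0)
  I_tot <- 2e-5; P_tot <- 1e-9     # pseudo-first-order excess
  f <- k1 / (k1 + km1)
  k_expected <- kb * f * I_tot + kmb
  tg <- c(0, seq(1e-5, 12 / k_expected, length.out = 400))
  traj <- simulate_scheme(r, mixing_condition(P_tot, I_tot), tg)
  eqv <- equilibrium_state(r, P_tot, I_tot)[["enc"]]
  y <- 1 - traj$states$enc[-1] / eqv
  fitk <- -stats::coef(lm(log(y[y > 1e-8]) ~ tg[-1][y > 1e-8]))[[2]]
  expect_equal(fitk, k_expected, tolerance = 0.02)
})

test_that("trajectory CSV round-trips bit-exactly", {
  r <- truth_rates()
  traj <- simulate_scheme(r, mixing_condition(1e-7, 1e-5),
                          c(0, 10^seq(-4, -1, length.out = 50)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_identical(back$time_s, traj$time)
  expect_identical(back$enc_M, traj$states$enc)
  expect_identical(back$final_M, traj$states$final)
})
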