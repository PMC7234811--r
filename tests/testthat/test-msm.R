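test_that("transition counting and normalisation behave as specified", {
  # single observed state
  Tm <- estimate_transition_matrix(list(c(1, 1, 1, 1)), lag = 1)
  expect_equal(Tm$P, matrix(1, 1, 1))

  # deterministic alternation
  Tm2 <- estimate_transition_matrix(list(c(1, 2, 1, 2, 1, 2)), lag = 1)
  expect_equal(Tm2$P, matrix(c(0, 1, 1, 0), 2, byrow = TRUE))

  # long trajectories from a known 3-state chain recover it entrywise
  P3 <- matrix(c(0.80, 0.15, 0.05,
                 0.10, 0.80, 0.10,
                 0.05, 0.25, 0.70), 3, byrow = TRUE)
  trajs <- generate_discrete_trajectories(P3, 5, 40000, seed = 5)
  est <- estimate_transition_matrix(trajs, lag = 1)
  expect_lt(max(abs(est$P - P3)), 0.02)
  expect_equal(rowSums(est$P), rep(1, 3), tolerance = 1e-12)

  # unvisited state gets a self-transition and a warning
  expect_warning(Tm3 <- estimate_transition_matrix(list(c(1, 1, 2)), lag = 1,
                                                   n_states = 3),
                 "disconnected")
  expect_equal(Tm3$P[3, 3], 1)
  expect_error(estimate_transition_matrix(list()), "no trajectories")
})

test_that("stationary distributions solve the balance equations", {
  expect_equal(stationary_distribution(matrix(0.5, 2, 2)), c(0.5, 0.5))
  # hand-solved balance: 0.1 pi1 = 0.3 pi2
  P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  expect_equal(stationary_distribution(P), c(0.75, 0.25), tolerance = 1e-12)
  pi3 <- stationary_distribution(matrix(c(0.80, 0.15, 0.05,
                                          0.10, 0.80, 0.10,
                                          0.05, 0.25, 0.70), 3, byrow = TRUE))
  expect_equal(sum(pi3), 1, tolerance = 1e-10)
  expect_equal(as.numeric(pi3 %*% matrix(c(0.80, 0.15, 0.05,
                                           0.10, 0.80, 0.10,
                                           0.05, 0.25, 0.70), 3,
                                         byrow = TRUE)),
               pi3, tolerance = 1e-10)
  expect_warning(stationary_distribution(diag(2)), "reducible")
})

test_that("macrostate coarse-graining follows the helicity thresholds", {
  h <- data.frame(state = 1:4,
                  har = c(0.9, 0.1, 0.9, 0.1),
                  nes = c(0.9, 0.9, 0.1, 0.1))
  cg <- coarse_grain(h)
  expect_identical(cg$label, c("HLH", "CLH", "HLC", "CLC"))
  expect_equal(unname(lump_populations(rep(0.25, 4), cg)[c("CLC", "CLH", "HLC", "HLH")]),
               rep(0.25, 4))
  expect_error(coarse_grain(data.frame(state = 1, har = NA, nes = 0.5)),
               "missing helicity")
  expect_error(coarse_grain(data.frame(state = 1, har = 2, nes = 0.5)),
               "\\[0, 1\\]")

  # populations invariant to microstate relabeling
  P3 <- matrix(c(0.8, 0.15, 0.05, 0.1, 0.8, 0.1, 0.05, 0.25, 0.7), 3,
               byrow = TRUE)
  h3 <- data.frame(state = 1:3, har = c(0.9, 0.1, 0.8),
                   nes = c(0.9, 0.2, 0.9))
  pop <- lump_populations(stationary_distribution(P3), coarse_grain(h3))
  perm <- c(3, 1, 2)
  Pp <- P3[perm, perm]
  h3p <- data.frame(state = 1:3, har = h3$har[perm], nes = h3$nes[perm])
  popp <- lump_populations(stationary_distribution(Pp), coarse_grain(h3p))
  expect_equal(pop[sort(names(pop))], popp[sort(names(popp))],
               tolerance = 1e-10)
})

test_that("MFPT solves the hitting-time system and matches simulation", {
  # two-state geometric waiting time: MFPT = lag_time / p
  P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  expect_equal(mfpt(P, c("A", "B"), "A", "B", lag_time = 15), 150)
  expect_equal(mfpt(P, c("A", "B"), "B", "A", lag_time = 1), 1 / 0.3)

  # three-state chain against direct Monte-Carlo hitting times
  P3 <- matrix(c(0.85, 0.10, 0.05,
                 0.20, 0.70, 0.10,
                 0.05, 0.15, 0.80), 3, byrow = TRUE)
  lab <- c("A", "A", "B")
  m <- mfpt(P3, lab, "A", "B")
  # vectorised chain simulation from the stationary-weighted source states
  pi3 <- stationary_distribution(P3)
  set.seed(10)
  n_walk <- 200000
  state <- sample(1:2, n_walk, replace = TRUE, prob = pi3[1:2])
  steps <- numeric(n_walk)
  alive <- rep(TRUE, n_walk)
  t <- 0
  while (any(alive)) {
    t <- t + 1
    idx <- which(alive)
    u <- runif(length(idx))
    cum <- t(apply(P3[state[idx], , drop = FALSE], 1, cumsum))
    nxt <- 1L + (u > cum[, 1]) + (u > cum[, 2])
    state[idx] <- nxt
    hit <- nxt == 3
    steps[idx[hit]] <- t
    alive[idx[hit]] <- FALSE
  }
  expect_equal(m, mean(steps), tolerance = 0.02)

  # unreachable target
  Pr <- matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE)
  expect_warning(mi <- mfpt(Pr, c("A", "B"), "A", "B"), "unreachable")
  expect_true(is.infinite(mi))
})

test_that("bootstrap summaries are seeded and honest about failures", {
  P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  h <- data.frame(state = 1:2, har = c(0.9, 0.1), nes = c(0.9, 0.9))
  cg <- coarse_grain(h)
  trajs <- generate_discrete_trajectories(P, 10, 3000, seed = 21)
  b1 <- bootstrap_msm(trajs, 1, cg, n_rounds = 40, seed = 5)
  b2 <- bootstrap_msm(trajs, 1, cg, n_rounds = 40, seed = 5)
  expect_identical(b1$populations, b2$populations)
  expect_identical(b1$mfpt, b2$mfpt)

  # bootstrap mean within ~2 bootstrap SDs of the generating populations
  gen <- lump_populations(stationary_distribution(P), cg)
  for (i in seq_len(nrow(b1$populations))) {
    expect_lt(abs(b1$populations$mean[i] - gen[[b1$populations$label[i]]]),
              2.5 * max(b1$populations$sd[i], 1e-3))
  }

  # identical trajectories: zero spread
  same <- rep(list(trajs[[1]]), 5)
  b0 <- bootstrap_msm(same, 1, cg, n_rounds = 10, seed = 1)
  expect_true(all(b0$populations$sd == 0))
  expect_true(all(b0$mfpt$sd == 0))

  # single round: sd undefined
  bs <- bootstrap_msm(trajs, 1, cg, n_rounds = 1, seed = 2)
  expect_true(all(is.na(bs$populations$sd)))

  expect_error(bootstrap_msm(trajs[1], 1, cg), ">= 2 trajectories")
})
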