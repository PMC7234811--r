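#' Assemble a global fit problem from titration series
#'
#' Collects stopped-flow titration series across labelling schemes into
#' one shared-parameter fitting problem: the six rate constants are
#' common to every trace, each scheme has its own rearranged-complex FRET
#' weight \code{c_star} (the encounter-complex weight is fixed at
#' \code{c = 1}, removing the overall scale degeneracy of the weight
#' pair), and each trace has its own scale \code{SC} and \code{Baseline}.
#' Because \code{SC} and \code{Baseline} enter the observation model
#' linearly, they are profiled out exactly by per-trace linear least
#' squares inside the objective rather than carried in the nonlinear
#' search.
#'
#' @param datasets list of \code{titration_series} objects (zero-titrant
#'   traces carry no kinetic information and are dropped with a message).
#' @param rate_bounds 2 x 6 matrix (rows \code{lo}, \code{hi}) of log10
#'   bounds for the rates; default [-2, 9] for first-order rates, [3, 10]
#'   for kb.
#' @param cstar_bounds log10 bounds for the per-scheme c_star.
#' @return An object of class \code{fit_problem}.
#' @export
fit_problem <- function(datasets,
                        rate_bounds = NULL, cstar_bounds = c(-3, 3)) {
  if (length(datasets) < 1L) stop("at least one dataset is required")
  traces <- list()
  for (ser in datasets) {
    scheme <- ser$design$scheme
    for (tr in ser$transients) {
      tot <- if (ser$design$fixed_species == "kinase") {
        list(P_total = ser$design$fixed_conc, I_total = tr$titrant_M)
      } else {
        list(P_total = tr$titrant_M, I_total = ser$design$fixed_conc)
      }
      if (tot$P_total <= 0 || tot$I_total <= 0 || isTRUE(tr$no_binding)) {
        message("dropping zero-titrant trace (no kinetic information)")
        next
      }
      traces[[length(traces) + 1L]] <- list(
        scheme = scheme, P_total = tot$P_total, I_total = tot$I_total,
        titrant_M = tr$titrant_M, time = ser$time, y = tr$intensity)
    }
  }
  if (length(traces) == 0L) stop("no usable traces")
  schemes <- unique(vapply(traces, `[[`, "", "scheme"))
  if (is.null(rate_bounds)) {
    rate_bounds <- rbind(lo = c(-2, -2, 3, -2, -2, -2),
                         hi = c(9, 9, 10, 9, 9, 9))
  }
  colnames(rate_bounds) <- rate_names()
  par_names <- c(rate_names(), paste0("c_star.", schemes))
  lower <- c(rate_bounds["lo", ], rep(cstar_bounds[1], length(schemes)))
  upper <- c(rate_bounds["hi", ], rep(cstar_bounds[2], length(schemes)))
  names(lower) <- names(upper) <- par_names
  structure(list(traces = traces, schemes = schemes, par_names = par_names,
                 lower = lower, upper = upper),
            class = "fit_problem")
}

rate_names <- function() c("k1", "k_minus1", "kb", "k_minusb", "kr", "k_minusr")

#' @export
print.fit_problem <- function(x, ...) {
  cat(sprintf("Global fit problem: %d traces, %d schemes (%s), %d nonlinear parameters\n",
              length(x$traces), length(x$schemes),
              paste(x$schemes, collapse = ", "), length(x$par_names)))
  cat(sprintf("  (+ %d per-trace scale/baseline pairs profiled linearly)\n",
              length(x$traces)))
  invisible(x)
}

# Run an expression with solver console chatter silenced; stiff-integrator
# step-limit reports are expected while the optimizer traverses bad regions.
quiet_eval <- function(expr) {
  nul <- file(nullfile(), open = "w")
  sink(nul, type = "message")
  sink(nul, type = "output")
  on.exit({ sink(type = "output"); sink(type = "message"); close(nul) })
  suppressWarnings(try(expr, silent = TRUE))
}

# RSS of y ~ SC*m + Baseline with (SC, Baseline) at their exact optimum;
# falls back to intercept-only when the model curve is flat.
profiled_rss <- function(m, y, coefs = FALSE) {
  if (stats::sd(m) < 1e-14) {
    b <- c(0, mean(y))
  } else {
    X <- cbind(m, 1)
    b <- try(solve(crossprod(X), crossprod(X, y)), silent = TRUE)
    if (inherits(b, "try-error")) b <- c(0, mean(y))
  }
  r <- y - b[1] * m - b[2]
  if (coefs) list(rss = sum(r^2), SC = b[1], Baseline = b[2]) else sum(r^2)
}

# Normalized model curve for one trace (Eq.-11 numerator over its
# equilibrium value); error object on solver failure.
trace_model <- function(rates, d, cstar, rtol, atol) {
  quiet_eval({
    traj <- simulate_scheme(rates, mixing_condition(d$P_total, d$I_total),
                            c(0, d$time), rtol = rtol, atol = atol)
    eq <- equilibrium_state(rates, d$P_total, d$I_total)
    den <- eq[["enc"]] + cstar * eq[["final"]]
    if (den <= 0) stop("degenerate equilibrium")
    (traj$states$enc[-1L] + cstar * traj$states$final[-1L]) / den
  })
}

#' Global sum-of-squares objective
#'
#' For each trace: integrate the scheme at the trace's totals, form the
#' normalised FRET curve with the scheme's \code{c_star}, profile out the
#' trace's \code{SC} and \code{Baseline} by linear least squares, and
#' accumulate the squared residuals. Integrator failures for a parameter
#' set are mapped to a large finite penalty so the optimizer can traverse
#' stiff regions.
#'
#' @param theta numeric vector: log10 of the six rates followed by log10
#'   c_star per scheme, in \code{problem$par_names} order.
#' @param problem a [fit_problem()].
#' @param penalty value contributed per failed trace.
#' @param rtol,atol integrator tolerances.
#' @return Scalar sum of squared residuals (deterministic in \code{theta}).
#' @export
global_objective <- function(theta, problem, penalty = 1e10,
                             rtol = 1e-8, atol = 1e-13) {
  sum(global_residuals(theta, problem, penalty_resid = sqrt(penalty),
                       rtol = rtol, atol = atol)^2)
}

# Concatenated per-point residuals; failed traces contribute constant
# penalty residuals so the vector length is stable.
global_residuals <- function(theta, problem, penalty_resid = 1e5,
                             rtol = 1e-8, atol = 1e-13) {
  stopifnot(length(theta) == length(problem$par_names))
  names(theta) <- problem$par_names
  rates <- try(do.call(rate_constants, as.list(10^theta[rate_names()])),
               silent = TRUE)
  out <- vector("list", length(problem$traces))
  for (i in seq_along(problem$traces)) {
    d <- problem$traces[[i]]
    if (inherits(rates, "try-error")) {
      out[[i]] <- rep(penalty_resid / sqrt(length(d$y)), length(d$y))
      next
    }
    cs <- 10^theta[[paste0("c_star.", d$scheme)]]
    m <- trace_model(rates, d, cs, rtol, atol)
    if (inherits(m, "try-error") || any(!is.finite(m))) {
      out[[i]] <- rep(penalty_resid / sqrt(length(d$y)), length(d$y))
      next
    }
    pf <- profiled_rss(m, d$y, coefs = TRUE)
    out[[i]] <- d$y - pf$SC * m - pf$Baseline
  }
  unlist(out)
}

# ---- identifiable reparameterization ---------------------------------------
# The raw rates are strongly correlated in the objective; the refinement
# stages work in coordinates aligned with the scheme's identifiable
# combinations:
#   u1 = log10(kb * f)            (pseudo-first-order fast-phase slope)
#   u2 = log10(k_minusb/(1+Kr))   (effective dissociation rate)
#   u3 = log10(kr + k_minusr)     (rearrangement relaxation rate)
#   u4 = log10(kr / k_minusr)     (rearrangement equilibrium constant)
#   u5 = log10(k1 + k_minus1)     (conformational exchange rate)
#   u6 = log10(k1 / k_minus1)     (conformational equilibrium constant)
# with f = k1/(k1+k_minus1); c_star coordinates are unchanged.
u_from_theta <- function(th) {
  r <- 10^th[1:6]
  f <- r[1] / (r[1] + r[2])
  Kr <- r[5] / r[6]
  c(log10(r[3] * f), log10(r[4] / (1 + Kr)), log10(r[5] + r[6]),
    log10(r[5] / r[6]), log10(r[1] + r[2]), log10(r[1] / r[2]),
    th[-(1:6)])
}

theta_from_u <- function(u) {
  K1 <- 10^u[6]; S1 <- 10^u[5]; Kr <- 10^u[4]; Sr <- 10^u[3]
  f <- K1 / (1 + K1)
  th <- c(log10(S1 * K1 / (1 + K1)), log10(S1 / (1 + K1)),
          u[1] - log10(f), u[2] + log10(1 + Kr),
          log10(Sr * Kr / (1 + Kr)), log10(Sr / (1 + Kr)))
  c(th, u[-(1:6)])
}

u_bounds <- function(problem) {
  ns <- length(problem$schemes)
  list(lo = c(2, -6, -2, -4, -2, -4, problem$lower[-(1:6)]),
       hi = c(11, 7, 9.3, 4, 9.3, 4, problem$upper[-(1:6)]))
}

# Levenberg-Marquardt with central-difference Jacobians. The wide step h
# keeps the finite differences above the integrator noise floor so the
# sloppy directions of the Jacobian are resolved.
lm_refine <- function(par, fn, lo, hi, h = 3e-3, maxit = 60,
                      ftol = 1e-10) {
  par <- pmin(pmax(par, lo), hi)
  r <- fn(par)
  ssr <- sum(r^2)
  lam <- 1e-3
  for (it in seq_len(maxit)) {
    J <- matrix(0, length(r), length(par))
    for (j in seq_along(par)) {
      up <- par; up[j] <- min(par[j] + h, hi[j])
      dn <- par; dn[j] <- max(par[j] - h, lo[j])
      J[, j] <- (fn(up) - fn(dn)) / (up[j] - dn[j])
    }
    g <- crossprod(J, r)
    H <- crossprod(J)
    improved <- FALSE
    for (k in 1:12) {
      step <- try(solve(H + lam * diag(diag(H) + 1e-12), -g), silent = TRUE)
      if (inherits(step, "try-error")) { lam <- lam * 10; next }
      cand <- pmin(pmax(par + as.numeric(step), lo), hi)
      rc <- fn(cand)
      sc <- sum(rc^2)
      if (is.finite(sc) && sc < ssr) {
        done <- (ssr - sc) < ftol * (ssr + 1e-300)
        par <- cand; r <- rc; ssr <- sc
        lam <- max(lam / 5, 1e-12)
        improved <- TRUE
        if (done) return(list(par = par, ssr = ssr, iter = it))
        break
      }
      lam <- lam * 10
    }
    if (!improved) break
  }
  list(par = par, ssr = ssr, iter = maxit)
}

# Profile search over one u-coordinate: all other coordinates re-fitted at
# each trial value. Cleans up the sloppiest valley direction, which the
# Jacobian-based steps cannot resolve reliably.
profile_coordinate <- function(u, j, fn, lo, hi, half_width = 0.6,
                               inner_maxit = 30) {
  idx <- setdiff(seq_along(u), j)
  state <- u
  prof <- function(v) {
    uu <- state
    uu[j] <- v
    o <- lm_refine(uu[idx], function(w) { uu2 <- uu; uu2[idx] <- w; fn(uu2) },
                   lo[idx], hi[idx], maxit = inner_maxit)
    state[idx] <<- o$par            # warm start the next trial value
    o$ssr
  }
  opt <- stats::optimize(prof, c(max(u[j] - half_width, lo[j]),
                                 min(u[j] + half_width, hi[j])), tol = 2e-3)
  out <- state
  out[j] <- opt$minimum
  out
}

#' Global multi-start simplex + genetic-algorithm fit
#'
#' The global fitting protocol for the shared rate constants: dispersed
#' (stratified log-space) starting points are refined by Nelder-Mead
#' simplex searches, the local optima seed a real-coded genetic algorithm
#' (tournament selection, blend crossover, Gaussian mutation in log
#' space, elitism), and the best candidates are then polished by
#' Levenberg-Marquardt with tight integrator tolerances in coordinates
#' aligned with the scheme's identifiable rate combinations, including a
#' profile-likelihood sweep of the sloppiest coordinate (the
#' rearrangement equilibrium constant kr/k_minusr). All randomness
#' derives from \code{seed}; identical inputs give identical results.
#'
#' @param problem a [fit_problem()].
#' @param n_starts number of dispersed local searches.
#' @param local_max_iter Nelder-Mead iteration cap per start.
#' @param evo_population genetic-algorithm population size.
#' @param evo_generations number of generations.
#' @param refine_top number of distinct candidates polished by the
#'   refinement stage (0 disables refinement).
#' @param seed integer seed.
#' @param start optional named vector (natural units) used as one local
#'   start; by default a data-driven start is added from a quick
#'   per-trace exponential analysis ([fast_phase_fit()]).
#' @param fixed optional named numeric vector (natural units) of
#'   parameters held fixed at the given values (refinement then operates
#'   on the free subset in raw log coordinates).
#' @param coarse_rtol,coarse_atol integrator tolerances of the
#'   exploration stages.
#' @param fine_rtol,fine_atol tolerances of the refinement stage.
#' @return An object of class \code{fit_result}: list with \code{par}
#'   (natural units, named), \code{log10_par}, \code{objective} (SSR at
#'   the fine tolerances), \code{rates} (a [rate_constants()]),
#'   \code{c_star}, \code{per_trace} (profiled SC/Baseline and RSS per
#'   trace), \code{trace} (optimizer history), \code{n_eval},
#'   \code{seed}, \code{convergence} codes of the local starts.
#' @export
fit_global <- function(problem, n_starts = 8, local_max_iter = 1e4,
                       evo_population = 50, evo_generations = 500,
                       refine_top = 3, seed = 1L, start = NULL, fixed = NULL,
                       coarse_rtol = 1e-8, coarse_atol = 1e-13,
                       fine_rtol = 1e-10, fine_atol = 1e-16) {
  p <- length(problem$par_names)
  lo <- problem$lower
  hi <- problem$upper
  fix_mask <- rep(FALSE, p)
  fix_val <- rep(NA_real_, p)
  if (!is.null(fixed)) {
    idx <- match(names(fixed), problem$par_names)
    if (anyNA(idx)) stop("unknown fixed parameter: ",
                         paste(names(fixed)[is.na(idx)], collapse = ", "))
    fix_mask[idx] <- TRUE
    fix_val[idx] <- log10(unname(fixed))
  }
  free <- which(!fix_mask)
  if (length(free) == 0L) stop("no free parameters")
  expand <- function(th_free) {
    th <- fix_val
    th[free] <- th_free
    th
  }

  history <- list()
  n_eval <- 0L
  best <- list(value = Inf, par = NULL)
  fn_coarse <- function(th_free) {
    th <- expand(th_free)
    out <- sum(pmax(0, th - hi)^2) + sum(pmax(0, lo - th)^2)
    v <- global_objective(pmin(pmax(th, lo), hi), problem,
                          rtol = coarse_rtol, atol = coarse_atol) *
      (1 + out) + 1e6 * out
    n_eval <<- n_eval + 1L
    if (v < best$value) best <<- list(value = v, par = th_free)
    v
  }
  note <- function(stage) {
    history[[length(history) + 1L]] <<-
      data.frame(stage = stage, evaluations = n_eval, objective = best$value)
  }

  candidates <- list()   # local/GA optima kept for refinement
  convergence <- integer(0)
  withr::with_seed(seed, {
    # stratified log-space starts (independent permutation per dimension)
    starts <- sapply(free, function(j) {
      lo[j] + (hi[j] - lo[j]) *
        (sample(n_starts) - stats::runif(n_starts)) / n_starts
    })
    starts <- matrix(starts, nrow = n_starts)
    if (!is.null(start)) {
      idx <- match(names(start), problem$par_names)
      th <- (lo + hi) / 2
      th[idx] <- log10(unname(start))
      starts[1L, ] <- th[free]
    } else {
      ds <- data_driven_start(problem)
      if (!is.null(ds)) starts[1L, ] <- ds[free]
    }
    convergence <- integer(n_starts)
    for (i in seq_len(n_starts)) {
      o <- if (length(free) == 1L) {
        stats::optim(starts[i, ], fn_coarse, method = "Brent",
                     lower = lo[free], upper = hi[free],
                     control = list(maxit = local_max_iter))
      } else {
        stats::optim(starts[i, ], fn_coarse, method = "Nelder-Mead",
                     control = list(maxit = local_max_iter,
                                    reltol = 1e-12))
      }
      convergence[i] <- o$convergence
      candidates[[length(candidates) + 1L]] <- o[c("par", "value")]
      note("local")
    }
    lvals <- vapply(candidates, `[[`, 0, "value")
    if (all(!is.finite(lvals))) stop("all local starts failed")

    # --- evolutionary refinement, seeded with the local optima -----------
    n_free <- length(free)
    pop <- matrix(NA_real_, evo_population, n_free)
    elite <- order(lvals)
    for (i in seq_len(evo_population)) {
      base <- candidates[[elite[(i - 1L) %% length(elite) + 1L]]]$par
      jit <- if (i <= length(elite)) 0 else stats::rnorm(n_free, 0, 0.25)
      pop[i, ] <- pmin(pmax(base + jit, lo[free]), hi[free])
    }
    fitness <- apply(pop, 1L, fn_coarse)
    if (evo_generations > 0) {
      for (g in seq_len(evo_generations)) {
        sigma <- 0.3 * (0.02 / 0.3)^((g - 1) / max(1, evo_generations - 1))
        newpop <- pop
        newfit <- fitness
        keep <- order(fitness)[1:2]          # elitism
        newpop[1:2, ] <- pop[keep, ]
        newfit[1:2] <- fitness[keep]
        for (i in 3:evo_population) {
          pick <- function() {
            cand <- sample.int(evo_population, 3L)
            cand[which.min(fitness[cand])]
          }
          a <- stats::runif(n_free, -0.25, 1.25)   # blend crossover
          child <- a * pop[pick(), ] + (1 - a) * pop[pick(), ]
          mut <- stats::runif(n_free) < 0.25
          child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, sigma)
          child <- pmin(pmax(child, lo[free]), hi[free])
          newpop[i, ] <- child
          newfit[i] <- fn_coarse(child)
        }
        pop <- newpop
        fitness <- newfit
      }
      ord <- order(fitness)[seq_len(min(3L, evo_population))]
      for (i in ord)
        candidates[[length(candidates) + 1L]] <-
          list(par = pop[i, ], value = fitness[i])
    }
    note("evolutionary")
  })

  # --- deterministic fine refinement of the best distinct candidates -----
  fine_fn_free <- function(th_free) {
    global_residuals(pmin(pmax(expand(th_free), lo), hi), problem,
                     rtol = fine_rtol, atol = fine_atol)
  }
  refined_best <- list(ssr = Inf, th = expand(best$par))
  if (refine_top > 0) {
    ord <- order(vapply(candidates, `[[`, 0, "value"))
    picked <- list()
    for (i in ord) {
      par <- candidates[[i]]$par
      if (!any(vapply(picked, function(q) max(abs(q - par)) < 0.05, TRUE)))
        picked[[length(picked) + 1L]] <- par
      if (length(picked) >= refine_top) break
    }
    all_rates_free <- !any(fix_mask[1:6])
    for (par in picked) {
      if (all_rates_free) {
        ub <- u_bounds(problem)
        u <- u_from_theta(expand(par))
        u <- pmin(pmax(u, ub$lo), ub$hi)
        fn_u <- function(uu) fine_fn_free(theta_from_u(uu)[free])
        o <- lm_refine(u, fn_u, ub$lo, ub$hi)
        u <- profile_coordinate(o$par, 4L, fn_u, ub$lo, ub$hi)
        o <- lm_refine(u, fn_u, ub$lo, ub$hi)
        ssr <- o$ssr
        th <- pmin(pmax(theta_from_u(o$par), lo), hi)
      } else {
        o <- lm_refine(par, fine_fn_free, lo[free], hi[free])
        ssr <- o$ssr
        th <- expand(o$par)
      }
      n_eval <- n_eval + 1L
      if (ssr < refined_best$ssr) refined_best <- list(ssr = ssr, th = th)
    }
    note("refine")
  } else {
    refined_best$ssr <- sum(fine_fn_free(expand(best$par)[free])^2)
  }

  th <- refined_best$th
  names(th) <- problem$par_names
  rates <- do.call(rate_constants, as.list(10^th[rate_names()]))
  cstar <- 10^th[paste0("c_star.", problem$schemes)]
  names(cstar) <- problem$schemes
  per_trace <- do.call(rbind, lapply(problem$traces, function(d) {
    m <- trace_model(rates, d, cstar[[d$scheme]], fine_rtol, fine_atol)
    if (inherits(m, "try-error")) {
      return(data.frame(scheme = d$scheme, P_total = d$P_total,
                        I_total = d$I_total, SC = NA_real_,
                        Baseline = NA_real_, rss = NA_real_))
    }
    pf <- profiled_rss(m, d$y, coefs = TRUE)
    data.frame(scheme = d$scheme, P_total = d$P_total, I_total = d$I_total,
               SC = pf$SC, Baseline = pf$Baseline, rss = pf$rss)
  }))
  structure(list(par = 10^th, log10_par = th, objective = refined_best$ssr,
                 rates = rates, c_star = cstar, per_trace = per_trace,
                 trace = do.call(rbind, history), n_eval = n_eval,
                 seed = seed, convergence = convergence),
            class = "fit_result")
}

# Crude data-driven starting point: single-exponential rates per trace,
# linear concentration fit for the apparent on/off rates; remaining
# coordinates at scheme-typical magnitudes.
data_driven_start <- function(problem) {
  est <- try({
    kobs <- vapply(problem$traces, function(d) {
      f <- suppressWarnings(fit_exponentials(d$time, d$y, 1, n_starts = 6))
      f$kobs[1]
    }, 0)
    conc <- vapply(problem$traces, `[[`, 0, "titrant_M")
    fp <- fast_phase_fit(conc, kobs)
    th <- c(log10(3e4), log10(2e4),
            log10(max(fp$kon, 1e4) * 2), log10(max(fp$koff, 0.1)),
            log10(1000), log10(500),
            rep(0, length(problem$schemes)))
    pmin(pmax(th, problem$lower), problem$upper)
  }, silent = TRUE)
  if (inherits(est, "try-error")) NULL else est
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Global fit result\n")
  cat(sprintf("  objective (SSR): %.6g after %d coarse evaluations\n",
              x$objective, x$n_eval))
  print(x$rates)
  for (s in names(x$c_star))
    cat(sprintf("  c_star[%s] = %.4g\n", s, x$c_star[[s]]))
  invisible(x)
}
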