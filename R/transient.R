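#' Multi-exponential fit of a stopped-flow transient
#'
#' Nonlinear least squares of \eqn{offset + \sum_i A_i e^{-k_{obs,i} t}}
#' with 1-3 phases. Rates are searched in log space from multiple
#' log-spaced starting guesses; for each trial rate set the amplitudes
#' and offset are solved exactly by linear least squares (variable
#' projection), which makes the search robust to poor amplitude guesses.
#' Phases are reported fast to slow.
#'
#' @param time,intensity the trace (post-dead-time; \code{time} in s).
#' @param n_phases number of exponential phases, 1-3.
#' @param n_starts number of multi-start rate guesses.
#' @return An object of class \code{exponential_fit}: list with
#'   \code{n_phases}, \code{amplitudes}, \code{kobs} (s^-1, sorted
#'   descending), \code{offset}, \code{fitted}, \code{residual_ss},
#'   \code{aic}, \code{degenerate} (TRUE when two recovered rates lie
#'   within 5 percent of each other, with a warning).
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' y <- 0.2 + exp(-10 * t)
#' fit_exponentials(t, y, 1)
#' @export
fit_exponentials <- function(time, intensity, n_phases = 2, n_starts = 8) {
  stopifnot(n_phases >= 1, n_phases <= 3, length(time) == length(intensity))
  n <- length(time)
  if (n < 5 * (2 * n_phases + 1))
    stop("insufficient data: need at least ", 5 * (2 * n_phases + 1),
         " samples for ", n_phases, " phases")
  t0 <- time - time[1]                     # fit from the first observed point
  span <- max(t0[t0 > 0])
  # rate guesses spanning the resolvable window
  kmin <- 0.5 / span
  kmax <- 0.5 / min(t0[t0 > 0])
  proj <- function(logk) {
    k <- exp(logk)
    X <- cbind(1, exp(-t0 %o% k))
    b <- try(qr.coef(qr(X), intensity), silent = TRUE)
    if (inherits(b, "try-error") || anyNA(b)) return(list(rss = Inf))
    r <- intensity - X %*% b
    list(rss = sum(r^2), offset = b[1], A = b[-1], fitted = as.numeric(X %*% b))
  }
  best <- NULL
  grid <- seq(log(kmin), log(kmax), length.out = max(n_starts, n_phases + 1))
  starts <- if (n_phases == 1) {
    lapply(grid, function(g) g)
  } else {
    # dispersed combinations with distinct rates
    combs <- utils::combn(seq_along(grid), n_phases, simplify = FALSE)
    idx <- unique(round(seq(1, length(combs), length.out = n_starts)))
    lapply(combs[idx], function(i) grid[i])
  }
  for (s in starts) {
    o <- if (length(s) == 1) {
      stats::optim(s, function(lk) proj(lk)$rss, method = "Brent",
                   lower = log(kmin) - 5, upper = log(kmax) + 5,
                   control = list(maxit = 2000))
    } else {
      stats::optim(s, function(lk) proj(lk)$rss, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14))
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || !is.finite(best$value))
    stop("fit failure: no exponential fit converged")
  p <- proj(best$par)
  ord <- order(exp(best$par), decreasing = TRUE)
  k <- exp(best$par)[ord]
  A <- p$A[ord]
  degenerate <- FALSE
  if (n_phases > 1 && any(k[-1] / k[-n_phases] > 0.95)) {
    degenerate <- TRUE
    warning("degenerate phases: two recovered rates within 5% of each other")
  }
  npar <- 2 * n_phases + 1
  aic <- n * log(p$rss / n) + 2 * (npar + 1)
  structure(list(n_phases = n_phases, amplitudes = A, kobs = k,
                 offset = p$offset, fitted = p$fitted, residual_ss = p$rss,
                 aic = aic, degenerate = degenerate),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("%d-phase exponential fit (AIC %.1f, RSS %.3g)\n",
              x$n_phases, x$aic, x$residual_ss))
  for (i in seq_len(x$n_phases))
    cat(sprintf("  phase %d: kobs = %.4g s^-1, A = %.4g\n",
                i, x$kobs[i], x$amplitudes[i]))
  cat(sprintf("  offset = %.4g\n", x$offset))
  invisible(x)
}

#' Select the number of exponential phases
#'
#' Fits 1 to \code{max_phases} exponentials and picks the phase count.
#' The default criterion is a sequential F-test: phase p+1 is accepted
#' over phase p only when the residual improvement is statistically
#' significant at \code{alpha} and the richer fit is not degenerate (no
#' two rates within 5 percent). \code{criterion = "aic"} instead returns
#' the fit with the lowest AIC; on long finely sampled traces AIC tends
#' to admit spurious low-amplitude phases that fit correlated noise,
#' which is why it is not the default.
#'
#' @inheritParams fit_exponentials
#' @param max_phases largest model tried (up to 3).
#' @param criterion \code{"ftest"} (default) or \code{"aic"}.
#' @param alpha significance level of the sequential F-test.
#' @return The winning \code{exponential_fit}.
#' @export
select_model <- function(time, intensity, max_phases = 3, n_starts = 8,
                         criterion = c("ftest", "aic"), alpha = 1e-3) {
  criterion <- match.arg(criterion)
  fits <- vector("list", max_phases)
  for (p in seq_len(max_phases)) {
    f <- try(suppressWarnings(
      fit_exponentials(time, intensity, p, n_starts)), silent = TRUE)
    if (!inherits(f, "try-error")) fits[[p]] <- f
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("fit failure: no phase count converged")
  if (criterion == "aic") {
    cand <- fits[ok]
    return(cand[[which.min(vapply(cand, `[[`, 0, "aic"))]])
  }
  n <- length(time)
  best <- fits[[which(ok)[1]]]
  for (p in seq_len(max_phases)[-1]) {
    f <- fits[[p]]
    if (is.null(f) || f$degenerate) next
    npar <- 2 * p + 1
    if (n <= npar || f$residual_ss <= 0) { best <- f; next }
    Fstat <- ((best$residual_ss - f$residual_ss) / (2 * (p - best$n_phases))) /
      (f$residual_ss / (n - npar))
    if (is.finite(Fstat) &&
        stats::pf(Fstat, 2 * (p - best$n_phases), n - npar,
                  lower.tail = FALSE) < alpha)
      best <- f
  }
  best
}

#' Linear concentration dependence of the fast phase
#'
#' Ordinary least squares of \eqn{k_{obs} = k_{on} [L] + k_{off}}: the
#' fast observed rate grows linearly with titrant concentration, with
#' slope kon (M^-1 s^-1) and intercept koff (s^-1). The apparent
#' dissociation constant is \eqn{K_d^{app} = k_{off}/k_{on}}, with its
#' standard error by first-order propagation (including the
#' slope-intercept covariance). A negative intercept is reported as-is.
#'
#' @param conc titrant concentrations, M (>= 3 values).
#' @param kobs fast-phase observed rates, s^-1.
#' @return List with \code{kon}, \code{kon_se}, \code{koff},
#'   \code{koff_se}, \code{Kd_app}, \code{Kd_app_se} (all M or s^-1) and
#'   the underlying \code{lm} fit. \code{Kd_app} is \code{NA} with a
#'   warning when the slope is not distinguishable from 0.
#' @examples
#' conc <- c(1, 2, 5, 10, 20) * 1e-6
#' fast_phase_fit(conc, 1.88e7 * conc + 13)
#' @export
fast_phase_fit <- function(conc, kobs) {
  if (length(conc) < 3) stop("insufficient data: need >= 3 concentrations")
  fit <- stats::lm(kobs ~ conc)
  cf <- stats::coef(fit)
  kon <- unname(cf["conc"])
  koff <- unname(cf["(Intercept)"])
  V <- stats::vcov(fit)
  kon_se <- sqrt(V["conc", "conc"])
  koff_se <- sqrt(V["(Intercept)", "(Intercept)"])
  flat <- !is.finite(kon) ||
    abs(kon) * diff(range(conc)) < 1e-10 * (abs(koff) + max(abs(kobs)))
  if (flat) {
    warning("zero slope: Kd_app undefined")
    Kd <- Kd_se <- NA_real_
  } else {
    Kd <- koff / kon
    # first-order propagation with covariance
    g <- c(1 / kon, -koff / kon^2)        # d(Kd)/d(koff, kon)
    Vk <- V[c("(Intercept)", "conc"), c("(Intercept)", "conc")]
    Kd_se <- sqrt(max(0, drop(t(g) %*% Vk %*% g)))
  }
  list(kon = kon, kon_se = kon_se, koff = koff, koff_se = koff_se,
       Kd_app = Kd, Kd_app_se = Kd_se, fit = fit)
}

#' Hyperbolic concentration dependence of the slow phase
#'
#' Nonlinear least squares of
#' \eqn{k_{obs} = k_{slow} [L] / (K_{0.5} + [L])}: the slow observed rate
#' saturates hyperbolically at \code{kslow} with half-saturation
#' concentration \code{K0_5}. No additive offset is fitted by default.
#'
#' @param conc titrant concentrations, M (>= 4 values recommended,
#'   spanning both sides of K0.5; a warning is issued otherwise).
#' @param kobs slow-phase observed rates, s^-1.
#' @param offset fit an additive offset as well (default off).
#' @return List with \code{kslow}, \code{kslow_se}, \code{K0_5},
#'   \code{K0_5_se} (s^-1 and M), the \code{nls} fit, and
#'   \code{extrapolated} (TRUE when K0.5 lies outside the sampled range).
#' @examples
#' conc <- c(0.5, 1, 2, 4, 8, 16, 32) * 1e-6
#' slow_phase_fit(conc, 24 * conc / (2.4e-6 + conc))
#' @export
slow_phase_fit <- function(conc, kobs, offset = FALSE) {
  if (length(conc) < 2) stop("insufficient data: need >= 2 concentrations")
  if (length(conc) < 4) warning("fewer than 4 concentrations: fit is fragile")
  start <- list(kslow = max(kobs), K0_5 = stats::median(conc))
  d <- data.frame(conc = conc, kobs = kobs)
  fit <- if (offset) {
    minpack.lm::nlsLM(kobs ~ kslow * conc / (K0_5 + conc) + c0, data = d,
                      start = c(start, c0 = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(kobs ~ kslow * conc / (K0_5 + conc), data = d,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(cf)))
  extrapolated <- cf[["K0_5"]] < min(conc) || cf[["K0_5"]] > max(conc)
  if (extrapolated)
    warning("K0.5 outside the sampled concentration range (extrapolation)")
  if (all(conc > 5 * cf[["K0_5"]]))
    warning("all concentrations far above K0.5: K0.5 ill-determined")
  list(kslow = cf[["kslow"]], kslow_se = unname(se["kslow"]),
       K0_5 = cf[["K0_5"]], K0_5_se = unname(se["K0_5"]),
       fit = fit, extrapolated = extrapolated)
}

#' Per-construct kinetic summary of a titration series
#'
#' The full transient analysis: each transient is fit with 1-3
#' exponentials (AIC selection), phases are partitioned into fast and
#' slow by rate ordering, the fast-phase rates get the linear
#' concentration fit ([fast_phase_fit()]) and the slow-phase rates the
#' hyperbolic fit ([slow_phase_fit()]). Relative pre-exponential
#' amplitudes per concentration are tabulated. Titrant concentrations
#' below 5x the fixed-partner concentration are flagged (weak
#' pseudo-first-order regime) but kept.
#'
#' @param series a \code{titration_series} from [generate_titration()]
#'   (or assembled with the same shape).
#' @param max_phases largest exponential model tried per transient.
#' @return An object of class \code{phase_summary}: list with
#'   \code{scheme}, the fast-phase fit (\code{kon}, \code{koff},
#'   \code{Kd_app} with SEs), the slow-phase fit (\code{kslow},
#'   \code{K0_5} with SEs, or NULL if < 2 slow-phase points),
#'   \code{per_transient} (data frame: titrant_M, n_phases, kobs_fast,
#'   kobs_slow, rel_amp_fast, rel_amp_slow, weak_pseudo_first_order).
#' @export
summarize_titration <- function(series, max_phases = 3) {
  usable <- Filter(function(tr) !isTRUE(tr$no_binding), series$transients)
  if (length(usable) < 3)
    stop("insufficient data: need >= 3 usable transients")
  rows <- lapply(usable, function(tr) {
    f <- select_model(series$time, tr$intensity, max_phases)
    amps <- abs(f$amplitudes)
    rel <- amps / sum(amps)
    data.frame(titrant_M = tr$titrant_M, n_phases = f$n_phases,
               kobs_fast = f$kobs[1],
               kobs_slow = if (f$n_phases > 1) f$kobs[f$n_phases] else NA_real_,
               rel_amp_fast = rel[1],
               rel_amp_slow = if (f$n_phases > 1) rel[f$n_phases] else NA_real_,
               weak_pseudo_first_order =
                 tr$titrant_M < 5 * series$design$fixed_conc)
  })
  pt <- do.call(rbind, rows)
  fast <- fast_phase_fit(pt$titrant_M, pt$kobs_fast)
  sl <- pt[!is.na(pt$kobs_slow), ]
  slow <- if (nrow(sl) >= 2) {
    tryCatch(suppressWarnings(slow_phase_fit(sl$titrant_M, sl$kobs_slow)),
             error = function(e) NULL)
  } else NULL
  structure(list(scheme = series$design$scheme, fast = fast, slow = slow,
                 per_transient = pt),
            class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf("Phase summary [%s]\n", x$scheme))
  cat(sprintf("  fast: kon = %.3g +/- %.2g M^-1 s^-1, koff = %.3g +/- %.2g s^-1, Kd_app = %.3g M\n",
              x$fast$kon, x$fast$kon_se, x$fast$koff, x$fast$koff_se,
              x$fast$Kd_app))
  if (!is.null(x$slow))
    cat(sprintf("  slow: kslow = %.3g +/- %.2g s^-1, K0.5 = %.3g +/- %.2g M\n",
                x$slow$kslow, x$slow$kslow_se, x$slow$K0_5, x$slow$K0_5_se))
  invisible(x)
}
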