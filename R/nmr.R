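#' Compounded chemical shift perturbation
#'
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_{HN}^2 + (0.154\,\Delta\delta_N)^2}}
#' combining the amide proton and nitrogen shift differences between two
#' states, with the conventional 0.154 scaling for nitrogen.
#'
#' @param delta_HN amide proton shift difference(s), ppm.
#' @param delta_N nitrogen shift difference(s), ppm.
#' @param residue optional residue ids (returned alongside).
#' @return If \code{residue} is NULL, the numeric CSP vector (ppm);
#'   otherwise a data frame \code{residue, csp} with the per-table mean
#'   and standard deviation attached as attributes \code{"mean"} and
#'   \code{"sd"} (for threshold lines).
#' @examples
#' csp(0.10, 1.00)  # sqrt(0.01 + 0.154^2) = 0.1836
#' @export
csp <- function(delta_HN, delta_N, residue = NULL) {
  if (any(!is.finite(delta_HN)) || any(!is.finite(delta_N)))
    stop("shift differences must be finite")
  v <- sqrt(delta_HN^2 + (0.154 * delta_N)^2)
  if (is.null(residue)) return(v)
  if (anyDuplicated(residue)) stop("residue ids must be unique")
  out <- data.frame(residue = residue, csp = v)
  attr(out, "mean") <- mean(v)
  attr(out, "sd") <- stats::sd(v)
  out
}

#' Heteronuclear NOE ratio with propagated error
#'
#' NOE = Isat/Iunsat, the ratio of peak intensities with and without
#' proton saturation; the error follows from the spectral
#' root-mean-square noise of the two spectra:
#' \deqn{\sigma_{NOE} = |NOE|\sqrt{(\sigma_{Isat}/I_{sat})^2 +
#'   (\sigma_{Iunsat}/I_{unsat})^2}}
#'
#' @param Isat,Iunsat peak intensities with / without saturation.
#' @param sigma_Isat,sigma_Iunsat RMS noise of the respective spectra.
#' @return List (vectorised) with \code{noe} and \code{sigma}.
#' @export
het_noe <- function(Isat, Iunsat, sigma_Isat = 0, sigma_Iunsat = 0) {
  if (any(Iunsat == 0)) stop("undefined ratio: Iunsat = 0")
  noe <- Isat / Iunsat
  sigma <- abs(noe) * sqrt((sigma_Isat / Isat)^2 + (sigma_Iunsat / Iunsat)^2)
  list(noe = noe, sigma = sigma)
}

#' Effective transverse relaxation rate from CPMG peak intensities
#'
#' \deqn{R_{2,eff} = \ln(I_0/I)/T} with \code{I0} the intensity without
#' the relaxation period, \code{I} the intensity with it, and \code{T}
#' the total CPMG time (40 ms in the reference acquisition).
#' \code{I >= I0} is allowed (non-positive rate) but flagged.
#'
#' @param I0,I peak intensities (> 0; non-positive values give an
#'   \code{NA} flagged undetectable).
#' @param T_cpmg total relaxation time, s.
#' @return List with \code{r2eff} (s^-1), \code{negative} flags and
#'   \code{undetectable} flags.
#' @examples
#' r2eff(5, 1, 0.040)  # ln(5)/0.04 = 40.24 s^-1
#' @export
r2eff <- function(I0, I, T_cpmg = 0.040) {
  stopifnot(T_cpmg > 0)
  undet <- !is.finite(I0) | !is.finite(I) | I0 <= 0 | I <= 0
  r <- rep(NA_real_, length(I0 + I))
  r[!undet] <- log(I0[!undet] / I[!undet]) / T_cpmg
  neg <- !undet & r < 0
  if (any(neg)) warning("negative R2,eff (I > I0) flagged")
  list(r2eff = r, negative = neg, undetectable = undet)
}

#' Exchange contribution from the relaxation dispersion end points
#'
#' \eqn{\Delta R_{ex}} = R2,eff at the lowest nonzero refocusing
#' frequency minus R2,eff at the highest: slow refocusing leaves
#' exchange broadening in place, fast refocusing quenches it.
#'
#' @param r2eff_low R2,eff at the low refocusing frequency (12.5 Hz in
#'   the reference acquisition), s^-1.
#' @param r2eff_high R2,eff at the high frequency (1000 Hz), s^-1.
#' @return \code{r2eff_low - r2eff_high}, s^-1.
#' @export
delta_rex <- function(r2eff_low, r2eff_high) r2eff_low - r2eff_high

#' Two-time-point PRE-Gamma2 with propagated error
#'
#' The paramagnetic relaxation enhancement from paired
#' paramagnetic/diamagnetic intensity measurements at two relaxation
#' delays Ta < Tb:
#' \deqn{\Gamma_2 = \frac{1}{T_b-T_a}\ln\frac{I_{dia}(T_b)\,I_{para}(T_a)}
#'   {I_{dia}(T_a)\,I_{para}(T_b)}}
#' \deqn{\sigma_{\Gamma_2} = \frac{1}{T_b-T_a}\sqrt{\sum (\sigma/I)^2}}
#' over the four intensities. Any non-positive intensity marks the
#' residue undetectable (broadened beyond detection).
#'
#' @param Ipara_a,Ipara_b paramagnetic intensities at Ta, Tb.
#' @param Idia_a,Idia_b diamagnetic intensities at Ta, Tb.
#' @param Ta,Tb relaxation delays, s (defaults 4 and 14 ms).
#' @param sigma_para,sigma_dia RMS noise of the two spectra.
#' @return List with \code{gamma2} (s^-1), \code{sigma} (s^-1) and
#'   \code{undetectable} flags.
#' @export
pre_gamma2 <- function(Ipara_a, Ipara_b, Idia_a, Idia_b,
                       Ta = 0.004, Tb = 0.014,
                       sigma_para = 0, sigma_dia = 0) {
  stopifnot(Tb > Ta, Ta > 0)
  n <- max(length(Ipara_a), length(Ipara_b), length(Idia_a), length(Idia_b))
  undet <- !is.finite(Ipara_a) | !is.finite(Ipara_b) |
    !is.finite(Idia_a) | !is.finite(Idia_b) |
    Ipara_a <= 0 | Ipara_b <= 0 | Idia_a <= 0 | Idia_b <= 0
  g <- s <- rep(NA_real_, n)
  ok <- !undet
  g[ok] <- log((Idia_b[ok] * Ipara_a[ok]) / (Idia_a[ok] * Ipara_b[ok])) /
    (Tb - Ta)
  s[ok] <- sqrt((sigma_dia / Idia_a[ok])^2 + (sigma_dia / Idia_b[ok])^2 +
                (sigma_para / Ipara_a[ok])^2 + (sigma_para / Ipara_b[ok])^2) /
    (Tb - Ta)
  list(gamma2 = g, sigma = s, undetectable = undet)
}

#' Sigma-band classification of PRE values
#'
#' Classifies per-residue PRE values by their deviation from the table
#' mean in units of the table standard deviation: weak (< 1 sigma),
#' medium (1-2 sigma), elevated (2-3 sigma; the conventional bands leave
#' this range unnamed, the label makes the classification total) and
#' strong (>= 3 sigma). Undetectable rows pass through unlabelled.
#'
#' @param value per-residue PRE values (Gamma2 or intensity-ratio based).
#' @param residue optional residue ids.
#' @param undetectable logical flags; those rows keep band
#'   \code{"undetectable"}.
#' @return Data frame \code{residue, value, z, band} with threshold
#'   attributes \code{"mean"} and \code{"sd"}.
#' @export
classify_pre <- function(value, residue = seq_along(value),
                         undetectable = rep(FALSE, length(value))) {
  ok <- !undetectable & is.finite(value)
  if (sum(ok) < 3) stop("need >= 3 finite values to compute mean and sigma")
  mu <- mean(value[ok])
  sg <- stats::sd(value[ok])
  if (sg == 0) stop("degenerate distribution: all values identical (sigma = 0)")
  z <- (value - mu) / sg
  band <- cut(z, c(-Inf, 1, 2, 3, Inf),
              labels = c("weak", "medium", "elevated", "strong"),
              right = FALSE)
  band <- as.character(band)
  band[!ok] <- "undetectable"
  out <- data.frame(residue = residue, value = value, z = z, band = band)
  attr(out, "mean") <- mu
  attr(out, "sd") <- sg
  out
}

#' Bound-minus-free difference profiles
#'
#' Per-residue differences x(bound) - x(free) for all metric columns
#' present in both tables, matched by integer residue number. Residues
#' present in only one table are reported, not silently dropped.
#'
#' @param free,bound data frames with a \code{residue} column and one or
#'   more numeric metric columns (e.g. \code{r1, r2, noe, rex}).
#' @return List with \code{delta} (data frame of differences, columns
#'   prefixed \code{d_}) and \code{unmatched} (data frame: residue,
#'   which table it came from).
#' @export
delta_profiles <- function(free, bound) {
  stopifnot("residue" %in% names(free), "residue" %in% names(bound))
  common_res <- intersect(free$residue, bound$residue)
  if (length(common_res) == 0) stop("no overlap between the two tables")
  metrics <- intersect(setdiff(names(free), "residue"),
                       setdiff(names(bound), "residue"))
  f <- free[match(common_res, free$residue), , drop = FALSE]
  b <- bound[match(common_res, bound$residue), , drop = FALSE]
  delta <- data.frame(residue = common_res)
  for (mcol in metrics) delta[[paste0("d_", mcol)]] <- b[[mcol]] - f[[mcol]]
  only_f <- setdiff(free$residue, bound$residue)
  only_b <- setdiff(bound$residue, free$residue)
  unmatched <- data.frame(
    residue = c(only_f, only_b),
    only_in = rep(c("free", "bound"), c(length(only_f), length(only_b))))
  list(delta = delta, unmatched = unmatched)
}

#' Mono-exponential decay-rate fit for relaxation series
#'
#' Two-parameter least-squares fit of \eqn{I(t) = I_0 e^{-R t}} to a
#' peak-intensity-versus-delay series (R1/R2 measurement). Replicated
#' delays, when present, provide a residual-based error estimate.
#'
#' @param delay delays, s.
#' @param intensity peak intensities.
#' @return List with \code{rate} (s^-1), \code{rate_se}, \code{I0} and
#'   the \code{nls} fit object.
#' @export
fit_decay_rate <- function(delay, intensity) {
  stopifnot(length(delay) >= 3, all(intensity > 0))
  lf <- stats::lm(log(intensity) ~ delay)
  start <- list(I0 = exp(stats::coef(lf)[[1]]), R = -stats::coef(lf)[[2]])
  fit <- minpack.lm::nlsLM(intensity ~ I0 * exp(-R * delay),
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["R"]],
                 error = function(e) NA_real_)
  list(rate = cf[["R"]], rate_se = se, I0 = cf[["I0"]], fit = fit)
}

#' Recompute every NMR metric from a synthetic peak table
#'
#' Convenience wrapper applying [het_noe()], [r2eff()]/[delta_rex()] and
#' [pre_gamma2()] to a table produced by [generate_peak_table()],
#' returning one row per residue for direct comparison with the stored
#' ground truth.
#'
#' @param tab a \code{peak_table}.
#' @return Data frame: \code{residue, noe, noe_sigma, r2eff_low,
#'   r2eff_high, delta_rex, gamma2, gamma2_sigma, undetectable}.
#' @export
peak_table_metrics <- function(tab) {
  res <- unique(tab$residue)
  noise <- tab$noise_rms[1]
  one <- function(r) {
    d <- tab[tab$residue == r, ]
    pick <- function(ch, cond = TRUE) {
      rows <- d[d$channel == ch & cond, ]
      rows$intensity
    }
    Iuns <- pick("unsat")
    Isat <- pick("sat")
    noe <- if (any(!is.finite(c(Iuns, Isat)))) list(noe = NA, sigma = NA)
           else het_noe(Isat, Iuns, noise, noise)
    cp <- d[d$channel == "cpmg", ]
    I0 <- cp$intensity[cp$nu_cpmg_hz == 0]
    nus <- sort(unique(cp$nu_cpmg_hz[cp$nu_cpmg_hz > 0]))
    r2lo <- r2eff(I0, cp$intensity[cp$nu_cpmg_hz == nus[1]],
                  max(cp$delay_s))
    r2hi <- r2eff(I0, cp$intensity[cp$nu_cpmg_hz == nus[length(nus)]],
                  max(cp$delay_s))
    delays <- sort(unique(d$delay_s[d$channel %in% c("para", "dia")]))
    g <- pre_gamma2(pick("para", d$delay_s == delays[1]),
                    pick("para", d$delay_s == delays[2]),
                    pick("dia", d$delay_s == delays[1]),
                    pick("dia", d$delay_s == delays[2]),
                    delays[1], delays[2], noise, noise)
    data.frame(residue = r, noe = noe$noe, noe_sigma = noe$sigma,
               r2eff_low = r2lo$r2eff, r2eff_high = r2hi$r2eff,
               delta_rex = delta_rex(r2lo$r2eff, r2hi$r2eff),
               gamma2 = g$gamma2, gamma2_sigma = g$sigma,
               undetectable = any(d$undetectable) | g$undetectable)
  }
  out <- do.call(rbind, lapply(res, one))
  rownames(out) <- NULL
  out
}
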