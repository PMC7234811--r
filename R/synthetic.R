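#' Design of a synthetic stopped-flow titration
#'
#' Describes one titration experiment: one binding partner held at a fixed
#' concentration (default 100 nM) while the other is varied as fold-excess
#' multiples of it. The labelled-kinase experiments varied the inhibitor
#' over 0-250x; the doubly labelled inhibitor was titrated with kinase
#' over 0-800x. Sampling may be linear at \code{sample_rate} or
#' logarithmic (the split-timebase mode of stopped-flow instruments, which
#' resolves early fast phases without huge traces). Points before
#' \code{dead_time} are discarded, as in a real instrument.
#'
#' @param fixed_species \code{"kinase"} or \code{"inhibitor"}: which
#'   partner is held at \code{fixed_conc}.
#' @param fixed_conc fixed-partner concentration, M.
#' @param titrant_multiples fold-excess values of the varied partner.
#' @param scheme labelling-scheme tag (\code{"ACCEPTOR-3"},
#'   \code{"ACCEPTOR-28"}, \code{"ACCEPTOR-59"} or \code{"DONOR-ACCEPTOR"}).
#' @param duration trace length, s.
#' @param sample_rate sampling rate, Hz (linear sampling).
#' @param sampling \code{"linear"} or \code{"log"}.
#' @param n_points number of points per trace for log sampling.
#' @param dead_time instrument dead time, s; the pre-dead-time part of the
#'   reaction is simulated but not observed.
#' @param noise_sigma Gaussian noise s.d. as a fraction of |SC|.
#' @param rtol,atol integrator tolerances used to generate the model
#'   curves. The defaults suit noisy realistic traces; noiseless
#'   benchmark data intended for parameter-recovery studies should be
#'   generated much tighter (e.g. 1e-11/1e-17) so that frozen integration
#'   error does not masquerade as signal.
#' @param seed integer seed; generation is a pure function of
#'   (parameters, seed).
#' @return An object of class \code{titration_design}.
#' @export
titration_design <- function(fixed_species = c("kinase", "inhibitor"),
                             fixed_conc = 1e-7,
                             titrant_multiples = c(0, 5, 10, 25, 50, 100, 250),
                             scheme = "ACCEPTOR-3",
                             duration = 1, sample_rate = 1000,
                             sampling = c("linear", "log"), n_points = 250,
                             dead_time = 1.5e-3, noise_sigma = 0.01,
                             rtol = 1e-8, atol = 1e-13,
                             seed = 1L) {
  fixed_species <- match.arg(fixed_species)
  sampling <- match.arg(sampling)
  stopifnot(all(titrant_multiples >= 0), duration > dead_time,
            sample_rate > 0, fixed_conc > 0, noise_sigma >= 0)
  structure(list(fixed_species = fixed_species, fixed_conc = fixed_conc,
                 titrant_multiples = titrant_multiples, scheme = scheme,
                 duration = duration, sample_rate = sample_rate,
                 sampling = sampling, n_points = n_points,
                 dead_time = dead_time, noise_sigma = noise_sigma,
                 rtol = rtol, atol = atol,
                 seed = as.integer(seed)),
            class = "titration_design")
}

# Post-dead-time observation grid of a design.
design_time_grid <- function(design) {
  if (design$sampling == "linear") {
    seq(design$dead_time, design$duration, by = 1 / design$sample_rate)
  } else {
    10^seq(log10(design$dead_time), log10(design$duration),
           length.out = design$n_points)
  }
}

# Totals after mixing for one titrant multiple.
design_totals <- function(design, multiple) {
  fixed <- design$fixed_conc
  varied <- multiple * fixed
  if (design$fixed_species == "kinase") {
    list(P_total = fixed, I_total = varied)
  } else {
    list(P_total = varied, I_total = fixed)
  }
}

#' Generate a synthetic stopped-flow titration series
#'
#' Simulates the five-species scheme for every titrant concentration of
#' the design, maps it through the FRET observation model, discards the
#' dead time and adds i.i.d. Gaussian noise with s.d.
#' \code{noise_sigma * |SC|}. A zero titrant concentration gives no
#' complex, so the trace is emitted as a flat baseline-only trace and
#' flagged \code{no_binding}.
#'
#' @param rates a [rate_constants()].
#' @param calib a [fret_calibration()].
#' @param design a [titration_design()].
#' @return An object of class \code{titration_series}: list with
#'   \code{design}, \code{time} (shared post-dead-time grid, s),
#'   \code{transients} (list, one per titrant multiple, each with
#'   \code{titrant_M}, \code{intensity}, \code{no_binding}) and
#'   \code{truth} (the generating rates and calibration).
#' @examples
#' des <- titration_design(titrant_multiples = c(0, 25, 100),
#'                         duration = 0.1, seed = 42)
#' ser <- generate_titration(published_rates(), fret_calibration(), des)
#' @export
generate_titration <- function(rates, calib, design) {
  tobs <- design_time_grid(design)
  sd_noise <- design$noise_sigma * abs(calib[["SC"]])
  transients <- withr::with_seed(design$seed, {
    lapply(design$titrant_multiples, function(m) {
      tot <- design_totals(design, m)
      titrant <- if (design$fixed_species == "kinase") tot$I_total else tot$P_total
      if (tot$P_total <= 0 || tot$I_total <= 0) {
        fi <- rep(calib[["Baseline"]], length(tobs))
        no_binding <- TRUE
      } else {
        mix <- mixing_condition(tot$P_total, tot$I_total)
        traj <- simulate_scheme(rates, mix, c(0, tobs),
                                rtol = design$rtol, atol = design$atol)
        eq <- equilibrium_state(rates, tot$P_total, tot$I_total)
        fi <- fret_intensity(traj, calib, eq)[-1L]
        no_binding <- FALSE
      }
      if (sd_noise > 0) fi <- fi + stats::rnorm(length(fi), 0, sd_noise)
      list(titrant_M = titrant, intensity = fi, no_binding = no_binding)
    })
  })
  structure(list(design = design, time = tobs, transients = transients,
                 truth = list(rates = rates, calib = calib)),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series (%s): %d transients x %d points, fixed %s at %.3g M\n",
              x$design$scheme, length(x$transients), length(x$time),
              x$design$fixed_species, x$design$fixed_conc))
  invisible(x)
}

#' Write / read a single transient as CSV
#'
#' Layout: metadata header lines \code{# titrant_M=...}, \code{# scheme=...}
#' followed by \code{time_s,intensity} rows at full precision.
#'
#' @param time,intensity the trace.
#' @param titrant_M titrant concentration, M.
#' @param scheme labelling-scheme tag.
#' @param path file path.
#' @return \code{write_transient} returns \code{path} invisibly;
#'   \code{read_transient} returns a list with \code{time}, \code{intensity},
#'   \code{titrant_M}, \code{scheme}.
#' @export
write_transient <- function(time, intensity, titrant_M, scheme, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# titrant_M=%.17g", titrant_M),
               sprintf("# scheme=%s", scheme),
               "time_s,intensity"), con)
  writeLines(sprintf("%.17g,%.17g", time, intensity), con)
  invisible(path)
}

#' @rdname write_transient
#' @export
read_transient <- function(path) {
  hdr <- readLines(path, n = 2L)
  d <- utils::read.csv(path, comment.char = "#", colClasses = "numeric")
  list(time = d$time_s, intensity = d$intensity,
       titrant_M = as.numeric(sub("# titrant_M=", "", hdr[1], fixed = TRUE)),
       scheme = sub("# scheme=", "", hdr[2], fixed = TRUE))
}

#' Generate a synthetic NMR peak-intensity table with known ground truth
#'
#' Builds per-residue peak intensities from mono-exponential decay models
#' so that every NMR metric of the package can be checked against known
#' truth: heteronuclear NOE pairs (Isat = NOE x Iunsat), CPMG pairs at
#' each refocusing frequency (I = I0 exp(-R2eff T)), and two-time-point
#' paramagnetic/diamagnetic pairs (Ipara decays at R2dia + Gamma2).
#' Gaussian spectral noise of s.d. \code{noise_rms} is added; a peak whose
#' clean intensity lies below the noise floor is flagged undetectable (a
#' residue broadened beyond detection), and a row drawn negative is
#' resampled up to \code{retry_cap} times before being flagged too.
#'
#' @param truth data frame with columns \code{residue}, \code{noe},
#'   \code{r2} (intrinsic R2, s^-1), \code{delta_rex} (exchange
#'   contribution at the low refocusing frequency, s^-1), \code{r2dia}
#'   (diamagnetic decay rate for the PRE pair, s^-1), \code{gamma2}
#'   (PRE rate, s^-1).
#' @param I0 reference peak intensity (arbitrary units).
#' @param noise_rms Gaussian spectral noise s.d. (same units as I0).
#' @param cpmg_T total CPMG relaxation time, s.
#' @param nu_cpmg refocusing frequencies, Hz; 0 denotes the reference
#'   spectrum without relaxation period.
#' @param Ta,Tb the two PRE relaxation delays, s.
#' @param seed integer seed.
#' @param retry_cap resampling attempts before a row is flagged
#'   undetectable.
#' @return A data frame of class \code{peak_table} with columns
#'   \code{residue, channel, delay_s, nu_cpmg_hz, intensity, noise_rms,
#'   undetectable}; the generating truth is attached as
#'   \code{attr(, "truth")}.
#' @export
generate_peak_table <- function(truth, I0 = 1e6, noise_rms = 0,
                                cpmg_T = 0.040, nu_cpmg = c(0, 12.5, 1000),
                                Ta = 0.004, Tb = 0.014, seed = 1L,
                                retry_cap = 20L) {
  stopifnot(is.data.frame(truth), Tb > Ta, Ta > 0, cpmg_T > 0)
  need <- c("residue", "noe", "r2", "delta_rex", "r2dia", "gamma2")
  if (!all(need %in% names(truth)))
    stop("truth must have columns: ", paste(need, collapse = ", "))
  rows <- list()
  add <- function(residue, channel, delay, nu, clean) {
    rows[[length(rows) + 1L]] <<- data.frame(
      residue = residue, channel = channel, delay_s = delay,
      nu_cpmg_hz = nu, clean = clean)
  }
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    add(tr$residue, "unsat", NA, NA, I0)
    add(tr$residue, "sat", NA, NA, tr$noe * I0)
    for (nu in nu_cpmg) {
      r2eff <- if (nu == 0) 0 else if (nu <= 100) tr$r2 + tr$delta_rex else tr$r2
      add(tr$residue, "cpmg", if (nu == 0) 0 else cpmg_T, nu,
          I0 * exp(-r2eff * cpmg_T * (nu != 0)))
    }
    for (d in c(Ta, Tb)) {
      add(tr$residue, "dia", d, NA, I0 * exp(-tr$r2dia * d))
      add(tr$residue, "para", d, NA, I0 * exp(-(tr$r2dia + tr$gamma2) * d))
    }
  }
  tab <- do.call(rbind, rows)
  withr::with_seed(seed, {
    tab$intensity <- tab$clean
    tab$undetectable <- FALSE
    if (noise_rms > 0) {
      for (j in seq_len(nrow(tab))) {
        if (tab$clean[j] < noise_rms) {
          # peak below the spectral noise floor: not pickable
          tab$undetectable[j] <- TRUE
          tab$intensity[j] <- NA_real_
          next
        }
        for (try in seq_len(retry_cap)) {
          x <- tab$clean[j] + stats::rnorm(1, 0, noise_rms)
          if (x > 0) break
        }
        if (x <= 0) {
          tab$undetectable[j] <- TRUE
          x <- NA_real_
        }
        tab$intensity[j] <- x
      }
    }
  })
  tab$clean <- NULL
  tab$noise_rms <- noise_rms
  attr(tab, "truth") <- truth
  class(tab) <- c("peak_table", "data.frame")
  tab
}

#' Sample discrete Markov-chain trajectories from a transition matrix
#'
#' @param T_mat row-stochastic square matrix (rows sum to 1 within 1e-12).
#' @param n_traj number of independent trajectories.
#' @param len length (number of steps) of each trajectory.
#' @param seed integer seed.
#' @param init initial distribution; default is the stationary
#'   distribution of \code{T_mat}.
#' @return List of integer vectors with states in \code{1..nrow(T_mat)}.
#' @examples
#' T2 <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
#' trajs <- generate_discrete_trajectories(T2, n_traj = 3, len = 100, seed = 1)
#' @export
generate_discrete_trajectories <- function(T_mat, n_traj, len, seed,
                                           init = NULL) {
  T_mat <- as.matrix(T_mat)
  check_stochastic(T_mat)
  n <- nrow(T_mat)
  if (is.null(init)) {
    init <- stationary_distribution(T_mat)
  }
  withr::with_seed(seed, {
    lapply(seq_len(n_traj), function(k) {
      s <- integer(len)
      s[1] <- sample.int(n, 1L, prob = init)
      if (len > 1L) for (t in 2:len) {
        s[t] <- sample.int(n, 1L, prob = T_mat[s[t - 1L], ])
      }
      s
    })
  })
}

check_stochastic <- function(T_mat) {
  if (!is.matrix(T_mat) || nrow(T_mat) != ncol(T_mat))
    stop("transition matrix must be square")
  if (any(T_mat < 0) || any(abs(rowSums(T_mat) - 1) > 1e-12))
    stop("transition matrix must be row-stochastic (rows sum to 1, entries >= 0)")
  invisible(TRUE)
}

#' Write / read a peak table as CSV
#'
#' Columns: \code{residue, channel, delay_s, nu_cpmg_hz, intensity,
#' intensity_noise, undetectable}, full double precision.
#'
#' @param tab a \code{peak_table} from [generate_peak_table()].
#' @param path file path.
#' @return \code{write_peak_table} returns \code{path} invisibly;
#'   \code{read_peak_table} returns a \code{peak_table} data frame.
#' @export
write_peak_table <- function(tab, path) {
  d <- data.frame(residue = tab$residue, channel = tab$channel,
                  delay_s = tab$delay_s, nu_cpmg_hz = tab$nu_cpmg_hz,
                  intensity = sprintf("%.17g", tab$intensity),
                  intensity_noise = sprintf("%.17g", tab$noise_rms),
                  undetectable = tab$undetectable)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  d <- utils::read.csv(path)
  out <- data.frame(residue = d$residue, channel = d$channel,
                    delay_s = d$delay_s, nu_cpmg_hz = d$nu_cpmg_hz,
                    intensity = as.numeric(d$intensity),
                    noise_rms = as.numeric(d$intensity_noise),
                    undetectable = as.logical(d$undetectable))
  class(out) <- c("peak_table", "data.frame")
  out
}
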