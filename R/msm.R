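#' Estimate a transition matrix from discrete trajectories
#'
#' Counts transitions between integer states at the given lag with the
#' sliding-window estimator (every ordered pair of frames separated by
#' \code{lag} steps) and row-normalises. States never left get a
#' self-transition of 1 and a disconnected-state warning.
#'
#' @param trajectories list of integer state sequences (states 1..n, or
#'   any integers; the state set is their union).
#' @param lag lag time in steps (>= 1).
#' @param n_states optional number of states (default: largest observed).
#' @param lag_time physical time per step (any unit); stored for MFPT
#'   scaling.
#' @return An object of class \code{transition_matrix}: list with
#'   \code{P} (row-stochastic matrix), \code{counts}, \code{lag},
#'   \code{lag_time}, \code{states}.
#' @examples
#' estimate_transition_matrix(list(c(1, 2, 1, 2, 1, 2)), lag = 1)
#' @export
estimate_transition_matrix <- function(trajectories, lag = 1L,
                                       n_states = NULL, lag_time = 1) {
  if (length(trajectories) == 0L) stop("no trajectories given")
  trajectories <- lapply(trajectories, as.integer)
  if (is.null(n_states)) n_states <- max(unlist(trajectories))
  C <- matrix(0, n_states, n_states)
  for (s in trajectories) {
    if (length(s) <= lag) next
    from <- s[seq_len(length(s) - lag)]
    to <- s[seq_len(length(s) - lag) + lag]
    C <- C + table(factor(from, levels = 1:n_states),
                   factor(to, levels = 1:n_states))
  }
  C <- unclass(C)
  dimnames(C) <- NULL
  rs <- rowSums(C)
  P <- C / ifelse(rs == 0, 1, rs)
  if (any(rs == 0)) {
    warning("disconnected state(s) with no outgoing counts: ",
            paste(which(rs == 0), collapse = ", "),
            "; assigned self-transition 1")
    for (i in which(rs == 0)) P[i, i] <- 1
  }
  structure(list(P = P, counts = C, lag = as.integer(lag),
                 lag_time = lag_time, states = 1:n_states),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Transition matrix: %d states, lag %d step(s) (%g time units), %d counted transitions\n",
              nrow(x$P), x$lag, x$lag * x$lag_time, sum(x$counts)))
  print(round(x$P, 4))
  invisible(x)
}

as_p_matrix <- function(T_mat) {
  if (inherits(T_mat, "transition_matrix")) T_mat$P else as.matrix(T_mat)
}

# Strongly-connected reachability check via boolean matrix closure.
is_irreducible <- function(P) {
  A <- (P > 0) | diag(nrow(P)) > 0
  R <- A
  for (i in seq_len(ceiling(log2(nrow(P))) + 1L)) R <- (R %*% R) > 0
  all(R) && all(t(R))
}

#' Stationary distribution of a Markov chain
#'
#' Left fixed point pi P = pi with pi >= 0, sum(pi) = 1, computed by
#' eigen-decomposition with a linear-solve fallback. A reducible chain
#' triggers a warning (the returned vector is then one of possibly
#' several stationary distributions).
#'
#' @param T_mat a \code{transition_matrix} or a row-stochastic matrix.
#' @return Numeric probability vector.
#' @examples
#' stationary_distribution(matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE))
#' @export
stationary_distribution <- function(T_mat) {
  P <- as_p_matrix(T_mat)
  check_stochastic(P)
  if (!is_irreducible(P))
    warning("reducible chain: stationary distribution is not unique")
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  if (min(v) < -1e-8 * max(abs(v)) || abs(Re(e$values[i]) - 1) > 1e-8) {
    # fallback: solve (t(P) - I) pi = 0 with the normalisation row appended
    n <- nrow(P)
    A <- rbind(t(P) - diag(n), rep(1, n))
    v <- stats::setNames(qr.solve(A, c(rep(0, n), 1)), NULL)
  }
  v <- abs(v)
  v / sum(v)
}

#' Macrostate assignment from motif helicity
#'
#' Labels each microstate by the helical content of the two terminal
#' motifs of the inhibitor: the high-affinity region (HAR, residues
#' 1-14) and the nuclear export signal (NES, residues 37-46), with the
#' intervening segment always a loop (L). A motif with mean helical
#' fraction >= \code{threshold} is Helix (H), else Coil (C), giving the
#' four macrostates HLH, HLC, CLH, CLC.
#'
#' @param helicity data frame with columns \code{state} (microstate id),
#'   \code{har} and \code{nes} (mean helical fractions in [0, 1]).
#' @param threshold helicity cutoff for H vs C (default 0.5).
#' @return An object of class \code{macrostate_assignment}: data frame
#'   \code{state, har, nes, label} with the threshold as attribute.
#' @export
coarse_grain <- function(helicity, threshold = 0.5) {
  stopifnot(all(c("state", "har", "nes") %in% names(helicity)))
  if (anyNA(helicity$har) || anyNA(helicity$nes))
    stop("missing helicity for some microstate(s)")
  if (any(helicity$har < 0 | helicity$har > 1 |
          helicity$nes < 0 | helicity$nes > 1))
    stop("helicity fractions must lie in [0, 1]")
  lab <- paste0(ifelse(helicity$har >= threshold, "H", "C"), "L",
                ifelse(helicity$nes >= threshold, "H", "C"))
  out <- data.frame(state = helicity$state, har = helicity$har,
                    nes = helicity$nes, label = lab)
  attr(out, "threshold") <- threshold
  class(out) <- c("macrostate_assignment", "data.frame")
  out
}

#' Lump a stationary distribution into macrostate populations
#'
#' Macrostate population = sum of the stationary weights of its member
#' microstates.
#'
#' @param pi_vec stationary distribution over microstates (or a
#'   \code{transition_matrix}, in which case its stationary distribution
#'   is computed).
#' @param assignment a [coarse_grain()] result (ordered or matched by
#'   \code{state} = microstate index).
#' @return Named numeric vector of macrostate populations over the four
#'   labels present, summing to 1.
#' @export
lump_populations <- function(pi_vec, assignment) {
  if (inherits(pi_vec, "transition_matrix"))
    pi_vec <- stationary_distribution(pi_vec)
  lab <- assignment$label[match(seq_along(pi_vec), assignment$state)]
  if (anyNA(lab)) stop("assignment does not cover all microstates")
  v <- tapply(pi_vec, lab, sum)
  stats::setNames(as.numeric(v), names(v))
}

#' Mean first-passage time between macrostates
#'
#' Expected time for the chain to first reach any microstate of the
#' target macrostate, starting from the source macrostate. Hitting
#' times h solve the standard linear system (I - Q) h = 1 over
#' non-target states (Q = transition matrix restricted to them); the
#' source average weights its microstates by the stationary distribution
#' restricted to the source set, and the result is scaled by the lag
#' time.
#'
#' @param T_mat a \code{transition_matrix} (or row-stochastic matrix,
#'   then \code{lag_time} applies).
#' @param assignment a [coarse_grain()] result, or a character vector of
#'   per-microstate labels.
#' @param from,to macrostate labels.
#' @param lag_time physical time per lag step (ignored when \code{T_mat}
#'   is a \code{transition_matrix}, which carries its own).
#' @return MFPT in physical time units; \code{Inf} with a warning when
#'   the target is unreachable.
#' @examples
#' P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
#' mfpt(P, c("A", "B"), "A", "B", lag_time = 15)  # 15/0.1 = 150
#' @export
mfpt <- function(T_mat, assignment, from, to, lag_time = 1) {
  P <- as_p_matrix(T_mat)
  check_stochastic(P)
  tau <- if (inherits(T_mat, "transition_matrix"))
    T_mat$lag * T_mat$lag_time else lag_time
  lab <- if (inherits(assignment, "macrostate_assignment"))
    assignment$label[match(seq_len(nrow(P)), assignment$state)]
  else as.character(assignment)
  stopifnot(length(lab) == nrow(P))
  A <- which(lab == to)
  S <- which(lab == from)
  if (length(A) == 0 || length(S) == 0) stop("unknown macrostate label")
  notA <- setdiff(seq_len(nrow(P)), A)
  Q <- P[notA, notA, drop = FALSE]
  h_notA <- try(solve(diag(length(notA)) - Q, rep(1, length(notA))),
                silent = TRUE)
  if (inherits(h_notA, "try-error") || any(!is.finite(h_notA)) ||
      any(h_notA < 0)) {
    warning("target macrostate unreachable from some states: MFPT infinite")
    return(Inf)
  }
  h <- numeric(nrow(P))
  h[notA] <- h_notA
  pi_vec <- stationary_distribution(P)
  w <- pi_vec[S] / sum(pi_vec[S])
  sum(w * h[S]) * tau
}

#' Bootstrap uncertainty for Markov-model statistics
#'
#' Resamples trajectories with replacement \code{n_rounds} times
#' (default 150); each round re-estimates the transition matrix, the
#' stationary distribution, the macrostate populations and all pairwise
#' macrostate MFPTs. Rounds whose resampled chain is disconnected (some
#' state unvisited or some MFPT infinite) are recorded as failed and
#' excluded from the summary.
#'
#' @param trajectories list of >= 2 integer state sequences.
#' @param lag lag in steps.
#' @param assignment a [coarse_grain()] result covering all states.
#' @param n_rounds bootstrap rounds.
#' @param seed integer seed (reproducible).
#' @param lag_time physical time per step.
#' @return An object of class \code{kinetic_summary}: list with
#'   \code{populations} (data frame label, mean, sd), \code{mfpt} (data
#'   frame from, to, mean, sd), \code{point} (full-data point
#'   estimates), \code{n_rounds}, \code{n_failed}, \code{seed}. With
#'   \code{n_rounds = 1} the sd columns are \code{NA} (flagged
#'   undefined).
#' @export
bootstrap_msm <- function(trajectories, lag, assignment, n_rounds = 150,
                          seed = 1L, lag_time = 1) {
  if (length(trajectories) < 2) stop("need >= 2 trajectories to bootstrap")
  n_states <- nrow(assignment)
  labels <- sort(unique(assignment$label))
  pairs <- expand.grid(from = labels, to = labels,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  analyse <- function(trajs) {
    Tm <- estimate_transition_matrix(trajs, lag, n_states = n_states,
                                     lag_time = lag_time)
    if (any(rowSums(Tm$counts) == 0)) stop("disconnected chain")
    pops <- lump_populations(stationary_distribution(Tm), assignment)
    pops <- pops[labels]
    m <- mapply(function(f, t) mfpt(Tm, assignment, f, t),
                pairs$from, pairs$to)
    if (any(!is.finite(m))) stop("infinite MFPT")
    list(pops = pops, mfpt = m)
  }
  point <- analyse(trajectories)
  rounds <- withr::with_seed(seed, {
    lapply(seq_len(n_rounds), function(b) {
      idx <- sample.int(length(trajectories), replace = TRUE)
      suppressWarnings(try(analyse(trajectories[idx]), silent = TRUE))
    })
  })
  ok <- !vapply(rounds, inherits, TRUE, "try-error")
  n_failed <- sum(!ok)
  rounds <- rounds[ok]
  agg <- function(get) {
    M <- do.call(rbind, lapply(rounds, get))
    list(mean = colMeans(M),
         sd = if (length(rounds) > 1) apply(M, 2, stats::sd)
              else rep(NA_real_, ncol(M)))
  }
  pa <- agg(function(r) r$pops)
  ma <- agg(function(r) r$mfpt)
  structure(list(
    populations = data.frame(label = labels, mean = unname(pa$mean),
                             sd = unname(pa$sd)),
    mfpt = data.frame(from = pairs$from, to = pairs$to,
                      mean = unname(ma$mean), sd = unname(ma$sd)),
    point = point, n_rounds = n_rounds, n_failed = n_failed, seed = seed),
    class = "kinetic_summary")
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat(sprintf("Markov-model kinetic summary (%d bootstrap rounds, %d failed)\n",
              x$n_rounds, x$n_failed))
  cat("Macrostate populations (mean +/- sd):\n")
  for (i in seq_len(nrow(x$populations)))
    cat(sprintf("  %s: %.3f +/- %.3f\n", x$populations$label[i],
                x$populations$mean[i], x$populations$sd[i]))
  invisible(x)
}
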