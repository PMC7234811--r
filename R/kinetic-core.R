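#' Species state of the binding scheme
#'
#' A single concentration vector over the five species of the scheme:
#' free active kinase \code{P_star}, free inhibitor in its
#' binding-incompetent (\code{I}) and binding-competent (\code{I_star})
#' conformations, the encounter complex \code{enc} (P*I*) and the
#' rearranged complex \code{final} ((PI)*). All concentrations in molar.
#'
#' @param P_star,I,I_star,enc,final concentrations, M.
#' @return A named numeric vector of class \code{species_state}.
#' @export
species_state <- function(P_star = 0, I = 0, I_star = 0, enc = 0, final = 0) {
  x <- c(P_star = P_star, I = I, I_star = I_star, enc = enc, final = final)
  if (any(!is.finite(x))) stop("invalid state: non-finite concentration")
  structure(x, class = "species_state")
}

#' Mixing condition for a stopped-flow shot
#'
#' Total kinase and inhibitor concentrations after mixing. The kinase is
#' assumed nucleotide-saturated, so it exists only in its active form P*;
#' both complexes start at zero (mixing starts the reaction). Free
#' inhibitor is either pre-equilibrated between I and I* at the
#' conformational equilibrium (fraction I* = k1/(k1+k_minus1); the
#' inhibitor equilibrates in the syringe before mixing) or placed
#' entirely in I.
#'
#' @param P_total total kinase concentration, M.
#' @param I_total total inhibitor concentration, M.
#' @param pre_equilibrated logical; partition free inhibitor at the
#'   I <-> I* equilibrium (default) or start all-I.
#' @return An object of class \code{mixing_condition}.
#' @export
mixing_condition <- function(P_total, I_total, pre_equilibrated = TRUE) {
  if (!is.finite(P_total) || !is.finite(I_total) || P_total < 0 || I_total < 0)
    stop("totals must be finite and >= 0")
  if (P_total <= 0 && I_total <= 0) stop("P_total or I_total must be > 0")
  structure(list(P_total = P_total, I_total = I_total,
                 pre_equilibrated = isTRUE(pre_equilibrated)),
            class = "mixing_condition")
}

#' Initial species state for a mixing condition
#'
#' @param mixing a [mixing_condition()].
#' @param rates a [rate_constants()] (used for the I/I* partition when
#'   pre-equilibrated).
#' @return A [species_state()].
#' @export
initial_state <- function(mixing, rates) {
  if (mixing$pre_equilibrated) {
    f <- competent_fraction(rates)
    species_state(P_star = mixing$P_total,
                  I = (1 - f) * mixing$I_total,
                  I_star = f * mixing$I_total)
  } else {
    species_state(P_star = mixing$P_total, I = mixing$I_total)
  }
}

#' Equilibrium fraction of binding-competent free inhibitor
#'
#' k1/(k1 + k_minus1), the stationary fraction of free inhibitor in the
#' binding-competent conformation I*.
#'
#' @param rates a [rate_constants()].
#' @return A fraction in [0, 1].
#' @export
competent_fraction <- function(rates) {
  s <- rates[["k1"]] + rates[["k_minus1"]]
  if (s <= 0) stop("k1 + k_minus1 must be > 0")
  rates[["k1"]] / s
}

#' Time derivatives of the five-species scheme
#'
#' Mass-action derivatives of the scheme
#' I <-> I*;  P* + I* <-> P*I*;  P*I* <-> (PI)*.
#'
#' @param state a [species_state()] (or named numeric with the same names).
#' @param rates a [rate_constants()].
#' @return Named numeric vector of derivatives, M/s, one per species.
#' @examples
#' r <- published_rates()
#' s <- species_state(P_star = 1e-7, I_star = 1e-5)
#' species_derivative(s, r)
#' @export
species_derivative <- function(state, rates) {
  if (any(!is.finite(unclass(state)))) stop("invalid state: non-finite concentration")
  bind <- rates[["kb"]] * state[["P_star"]] * state[["I_star"]] -
    rates[["k_minusb"]] * state[["enc"]]
  conf <- rates[["k1"]] * state[["I"]] - rates[["k_minus1"]] * state[["I_star"]]
  rear <- rates[["kr"]] * state[["enc"]] - rates[["k_minusr"]] * state[["final"]]
  c(P_star = -bind, I = -conf, I_star = conf - bind,
    enc = bind - rear, final = rear)
}

#' Integrate the five-species scheme over a time grid
#'
#' Stiff integration of the mass-action system (the six rates span
#' ~0.5 to ~3e4 s^-1) using deSolve's lsoda with a compiled right-hand
#' side. Conservation of total kinase and total inhibitor is checked at
#' every output point.
#'
#' @param rates a [rate_constants()].
#' @param mixing a [mixing_condition()].
#' @param t_grid time grid in seconds, strictly increasing, starting at 0.
#' @param rtol,atol relative and absolute (M) integration tolerances.
#' @return An object of class \code{species_trajectory}: a list with
#'   \code{time} (s), \code{states} (data frame, one column per species,
#'   M), \code{rates} and \code{mixing}.
#' @examples
#' traj <- simulate_scheme(published_rates(),
#'                         mixing_condition(1e-7, 1e-5),
#'                         seq(0, 0.1, by = 1e-3))
#' @export
simulate_scheme <- function(rates, mixing, t_grid, rtol = 1e-8, atol = 1e-13) {
  if (length(t_grid) < 2L || t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing and start at 0")
  y0 <- unclass(initial_state(mixing, rates))
  out <- deSolve::ode(y = y0, times = t_grid, func = "scheme1_derivs",
                      parms = unname(unclass(rates)), dllname = "pkiakin",
                      initfunc = "scheme1_init", method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("solver error: lsoda failed (istate = ", attr(out, "istate")[1L], ")")
  states <- as.data.frame(out[, -1L, drop = FALSE])
  if (min(as.matrix(states)) < -10 * atol)
    stop("numerical instability: concentration below -10*atol (",
         format(min(as.matrix(states))), " M)")
  traj <- structure(list(time = as.numeric(out[, 1L]), states = states,
                         rates = rates, mixing = mixing),
                    class = "species_trajectory")
  check_conservation(traj)
  traj
}

# Relative drift of both conservation laws over a trajectory; errors beyond tol.
check_conservation <- function(traj, tol = 1e-6) {
  s <- traj$states
  P_tot <- s$P_star + s$enc + s$final
  I_tot <- s$I + s$I_star + s$enc + s$final
  drift <- function(x) if (x[1] > 0) max(abs(x - x[1])) / x[1] else max(abs(x - x[1]))
  d <- max(drift(P_tot), drift(I_tot))
  if (d > tol)
    stop(sprintf("conservation violated: relative drift %.3g > %.3g", d, tol))
  invisible(d)
}

#' Algebraic equilibrium of the binding scheme
#'
#' Closed-form equilibrium of the scheme for given totals. With
#' f = k1/(k1+k_minus1), Kb = kb/k_minusb and Kr = kr/k_minusr, the total
#' bound concentration B = enc + final solves the single-site quadratic
#' B = Keff (P_total - B)(I_total - B) with Keff = (1+Kr) Kb f; the
#' remaining species follow from the detailed-balance ratios
#' I*/I = k1/k_minus1, enc = Kb P* I*, final = Kr enc.
#'
#' @param rates a [rate_constants()]; needs kb > 0 and k_minusb > 0 when
#'   both totals are nonzero.
#' @param P_total,I_total totals, M.
#' @return A [species_state()] at equilibrium.
#' @examples
#' equilibrium_state(published_rates(), 1e-7, 1e-5)
#' @export
equilibrium_state <- function(rates, P_total, I_total) {
  f <- competent_fraction(rates)
  free_split <- function(I_free) {
    c(I = (1 - f) * I_free, I_star = f * I_free)
  }
  if (P_total <= 0 || I_total <= 0) {
    fs <- free_split(I_total)
    return(species_state(P_star = P_total, I = fs[["I"]], I_star = fs[["I_star"]]))
  }
  if (rates[["kb"]] <= 0 || rates[["k_minusb"]] <= 0)
    stop("degenerate equilibrium: kb and k_minusb must be > 0 with nonzero totals")
  if (rates[["kr"]] > 0 && rates[["k_minusr"]] <= 0) {
    # absorbing rearranged state: all bindable material ends in (PI)*
    warning("absorbing rearranged state (kr > 0, k_minusr = 0); ",
            "all bound material reported as final complex")
    B <- min(P_total, I_total)
    fs <- free_split(I_total - B)
    return(species_state(P_star = P_total - B, I = fs[["I"]],
                         I_star = fs[["I_star"]], final = B))
  }
  Kr <- if (rates[["kr"]] > 0) rates[["kr"]] / rates[["k_minusr"]] else 0
  Keff <- (1 + Kr) * (rates[["kb"]] / rates[["k_minusb"]]) * f
  if (Keff <= 0) {
    # f == 0: no binding-competent inhibitor at equilibrium
    fs <- free_split(I_total)
    return(species_state(P_star = P_total, I = fs[["I"]], I_star = fs[["I_star"]]))
  }
  # Keff B^2 - (Keff (Pt + It) + 1) B + Keff Pt It = 0; stable smaller root
  b <- P_total + I_total + 1 / Keff
  B <- 2 * P_total * I_total / (b + sqrt(b^2 - 4 * P_total * I_total))
  enc <- B / (1 + Kr)
  fs <- free_split(I_total - B)
  species_state(P_star = P_total - B, I = fs[["I"]], I_star = fs[["I_star"]],
                enc = enc, final = B * Kr / (1 + Kr))
}

#' Write / read a species trajectory as CSV
#'
#' Column layout: \code{time_s,P_star_M,I_M,I_star_M,enc_M,final_M}, full
#' double precision.
#'
#' @param traj a \code{species_trajectory}.
#' @param path file path.
#' @return \code{write_trajectory} returns \code{path} invisibly;
#'   \code{read_trajectory} returns a data frame with the same columns.
#' @export
write_trajectory <- function(traj, path) {
  d <- data.frame(time_s = traj$time,
                  P_star_M = traj$states$P_star, I_M = traj$states$I,
                  I_star_M = traj$states$I_star, enc_M = traj$states$enc,
                  final_M = traj$states$final)
  utils::write.csv(format(d, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}
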