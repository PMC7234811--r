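#' FRET calibration of a labelling scheme
#'
#' Observation parameters that map complex concentrations to an
#' instantaneous fluorescence intensity: FRET efficiency weights \code{c}
#' (encounter complex) and \code{c_star} (rearranged complex), a scaling
#' factor \code{SC} and a basal fluorescence \code{Baseline}. The
#' (\code{c}, \code{c_star}) pair is identifiable only up to a common
#' scale, so fits fix \code{c = 1}.
#'
#' @param c,c_star dimensionless FRET efficiency weights, >= 0, not both 0.
#' @param SC scaling factor, fluorescence units.
#' @param Baseline basal fluorescence, fluorescence units.
#' @return An object of class \code{fret_calibration}.
#' @export
fret_calibration <- function(c = 1, c_star = 1, SC = 1, Baseline = 0) {
  x <- c(c = c, c_star = c_star, SC = SC, Baseline = Baseline)
  if (any(!is.finite(x))) stop("calibration parameters must be finite")
  if (c < 0 || c_star < 0 || (c == 0 && c_star == 0))
    stop("c and c_star must be >= 0 and not both 0")
  structure(x, class = "fret_calibration")
}

#' Instantaneous fluorescence intensity of a trajectory
#'
#' The observation model of the stopped-flow experiment:
#' \deqn{FI(t) = \frac{c\,enc(t) + c^* final(t)}{c\,enc_{eq} + c^* final_{eq}} \times SC + Baseline}
#' i.e. the complex concentrations weighted by their FRET efficiencies,
#' normalised by the same combination at equilibrium, scaled and offset.
#' The equilibrium in the denominator is computed from the model
#' ([equilibrium_state()]), not from the trace plateau.
#'
#' @param traj a \code{species_trajectory} from [simulate_scheme()].
#' @param calib a [fret_calibration()].
#' @param eq_state optional [species_state()]: the equilibrium for the
#'   trajectory's rates and totals. Computed from the trajectory's own
#'   rates and mixing condition when omitted.
#' @return Numeric vector of intensities on the trajectory's time grid.
#' @examples
#' traj <- simulate_scheme(published_rates(), mixing_condition(1e-7, 1e-5),
#'                         seq(0, 0.2, by = 1e-3))
#' fi <- fret_intensity(traj, fret_calibration(SC = 1, Baseline = 0.1))
#' @export
fret_intensity <- function(traj, calib, eq_state = NULL) {
  if (is.null(eq_state)) {
    eq_state <- equilibrium_state(traj$rates, traj$mixing$P_total,
                                  traj$mixing$I_total)
  }
  denom <- calib[["c"]] * eq_state[["enc"]] + calib[["c_star"]] * eq_state[["final"]]
  if (denom <= 0)
    stop("degenerate equilibrium: c*enc_eq + c_star*final_eq must be > 0 ",
         "(no complex formed at equilibrium)")
  num <- calib[["c"]] * traj$states$enc + calib[["c_star"]] * traj$states$final
  num / denom * calib[["SC"]] + calib[["Baseline"]]
}
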