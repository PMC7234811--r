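#' Rate constants for the five-species binding scheme
#'
#' Bundles the six rate constants of the multistate recognition scheme:
#' a conformational-selection step on the free inhibitor (I <-> I*, rates
#' \code{k1}, \code{k_minus1}, both s^-1), bimolecular encounter-complex
#' formation (P* + I* <-> P*I*, \code{kb} in M^-1 s^-1 and \code{k_minusb}
#' in s^-1) and the induced-fit rearrangement of the bound complex
#' (P*I* <-> (PI)*, rates \code{kr}, \code{k_minusr}, both s^-1).
#'
#' @param k1 forward conformational rate of the free inhibitor, s^-1.
#' @param k_minus1 reverse conformational rate, s^-1.
#' @param kb second-order association rate, M^-1 s^-1.
#' @param k_minusb encounter-complex dissociation rate, s^-1.
#' @param kr forward rearrangement rate of the bound complex, s^-1.
#' @param k_minusr reverse rearrangement rate, s^-1.
#'
#' @return An object of class \code{rate_constants}: a named numeric
#'   vector with the six rates.
#' @examples
#' rate_constants(k1 = 1.9e4, k_minus1 = 1.5e4, kb = 1.5e7,
#'                k_minusb = 0.5, kr = 2400, k_minusr = 720)
#' @export
rate_constants <- function(k1, k_minus1, kb, k_minusb, kr, k_minusr) {
  x <- c(k1 = k1, k_minus1 = k_minus1, kb = kb, k_minusb = k_minusb,
         kr = kr, k_minusr = k_minusr)
  if (!is.numeric(x) || length(x) != 6L) {
    stop("all six rate constants must be single numeric values")
  }
  if (any(!is.finite(x))) stop("rate constants must be finite")
  if (any(x < 0)) stop("rate constants must be >= 0")
  structure(x, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants of the multistate binding scheme\n")
  cat(sprintf("  I -> I*      k1       = %.4g s^-1\n", x[["k1"]]))
  cat(sprintf("  I* -> I      k_minus1 = %.4g s^-1\n", x[["k_minus1"]]))
  cat(sprintf("  P*+I* -> enc kb       = %.4g M^-1 s^-1\n", x[["kb"]]))
  cat(sprintf("  enc -> P*+I* k_minusb = %.4g s^-1\n", x[["k_minusb"]]))
  cat(sprintf("  enc -> (PI)* kr       = %.4g s^-1\n", x[["kr"]]))
  cat(sprintf("  (PI)* -> enc k_minusr = %.4g s^-1\n", x[["k_minusr"]]))
  invisible(x)
}

#' Published global-fit rate constants
#'
#' The six rate constants obtained from the global stopped-flow fit of the
#' PKA-C/PKIa binding transients: kb = 1.5e7 M^-1 s^-1, k_minusb = 0.5 s^-1,
#' kr = 2400 s^-1, k_minusr = 720 s^-1, k1 = 1.9e4 s^-1, k_minus1 = 1.5e4
#' s^-1.
#'
#' @return A \code{rate_constants} object.
#' @export
published_rates <- function() {
  rate_constants(k1 = 1.9e4, k_minus1 = 1.5e4, kb = 1.5e7, k_minusb = 0.5,
                 kr = 2400, k_minusr = 720)
}

#' Published per-construct transient-analysis summary
#'
#' The per-labelling-scheme fast-phase and slow-phase constants from the
#' exponential analysis of the stopped-flow titrations (three
#' acceptor-labelled inhibitor constructs mixed with donor-labelled kinase,
#' plus the doubly labelled inhibitor mixed with unlabelled kinase).
#' Units: kon in M^-1 s^-1, koff and kslow in s^-1, Kd_app and K0_5 in M.
#' \code{NA} marks slow-phase maxima reported as not determined.
#'
#' @return A data frame with one row per labelling scheme and columns
#'   \code{scheme, kon, kon_se, koff, koff_se, Kd_app, Kd_app_se, kslow,
#'   kslow_se, K0_5, K0_5_se}.
#' @export
published_phase_summary <- function() {
  data.frame(
    scheme = c("ACCEPTOR-3", "ACCEPTOR-28", "ACCEPTOR-59", "DONOR-ACCEPTOR"),
    kon = c(1.88e7, 1.40e7, 1.62e7, 0.85e7),
    kon_se = c(0.03e7, 0.02e7, 0.11e7, 0.04e7),
    koff = c(13, 5, 2, 6),
    koff_se = c(3, 1, 10, 7),
    Kd_app = c(700e-9, 390e-9, 150e-9, 700e-9),
    Kd_app_se = c(170e-9, 110e-9, 620e-9, 800e-9),
    kslow = c(24, NA, NA, 37),
    kslow_se = c(2, NA, NA, 2),
    K0_5 = c(2.4e-6, 3.0e-6, 3.8e-6, 17e-6),
    K0_5_se = c(0.4e-6, 0.4e-6, 0.5e-6, 3e-6),
    stringsAsFactors = FALSE
  )
}

#' Read / write rate-constant configuration files
#'
#' Configuration files (YAML or JSON by extension) with the six rates
#' keyed \code{k1, k_minus1, kb, k_minusb, kr, k_minusr}; mixing totals,
#' when present, are keyed \code{P_total_M} and \code{I_total_M}.
#'
#' @param path file path ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @return \code{read_rates_config}: list with \code{rates} (a
#'   [rate_constants()]) and, if present, \code{P_total_M},
#'   \code{I_total_M}. \code{write_rates_config} returns \code{path}
#'   invisibly.
#' @export
read_rates_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  rates <- do.call(rate_constants, cfg[c("k1", "k_minus1", "kb",
                                         "k_minusb", "kr", "k_minusr")])
  out <- list(rates = rates)
  for (k in c("P_total_M", "I_total_M"))
    if (!is.null(cfg[[k]])) out[[k]] <- cfg[[k]]
  out
}

#' @rdname read_rates_config
#' @param rates a [rate_constants()].
#' @param P_total_M,I_total_M optional totals, M.
#' @export
write_rates_config <- function(rates, path, P_total_M = NULL,
                               I_total_M = NULL) {
  cfg <- as.list(unclass(rates))
  if (!is.null(P_total_M)) cfg$P_total_M <- P_total_M
  if (!is.null(I_total_M)) cfg$I_total_M <- I_total_M
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
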