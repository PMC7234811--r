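# Shared fixtures: the published rate constants and small titration designs.

truth_rates <- function() published_rates()

small_calib <- function(c_star = 0.4, SC = -0.6, Baseline = 1) {
  fret_calibration(1, c_star, SC = SC, Baseline = Baseline)
}

# Compact noiseless benchmark series for recovery tests: logarithmic
# sampling from 50 us so the rearrangement and exchange relaxations are
# observed, tight integration so the data carry no frozen solver error.
benchmark_series <- function(scheme = "ACCEPTOR-3",
                             fixed_species = "kinase",
                             multiples = c(10, 25, 50, 100, 150, 250),
                             calib = small_calib(), n_points = 300,
                             seed = 101) {
  des <- titration_design(fixed_species, titrant_multiples = multiples,
                          scheme = scheme, duration = 0.5,
                          sampling = "log", n_points = n_points,
                          dead_time = 5e-5, noise_sigma = 0,
                          rtol = 1e-11, atol = 1e-17, seed = seed)
  generate_titration(truth_rates(), calib, des)
}

# Deterministic small peak-table truth set.
peak_truth <- function(n = 8) {
  data.frame(residue = seq_len(n),
             noe = seq(0.3, 0.85, length.out = n),
             r2 = seq(8, 22, length.out = n),
             delta_rex = rep(c(0, 4), length.out = n),
             r2dia = seq(10, 24, length.out = n),
             gamma2 = seq(0, 70, length.out = n))
}
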