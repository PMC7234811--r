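# pkiakin

Kinetic and dynamic analysis of the multistate recognition of PKIα — the
intrinsically disordered protein kinase A inhibitor — by the catalytic
subunit of protein kinase A (PKA-C). The package is aimed at biophysicists
analysing stopped-flow FRET binding transients, backbone NMR dynamics
tables, and discretised MD trajectories of coupled folding-and-binding
systems.

## The model

Binding follows a five-species scheme combining conformational selection
and induced fit:

```
        k1              kb               kr
   I  ⇌      I*  ;  P* + I*  ⇌  P*I*  ⇌  (PI)*
       k-1              k-b              k-r
```

Free inhibitor interconverts between binding-incompetent (I) and
binding-competent (I\*) ensembles; the active kinase P\* captures I\* into
an encounter complex P\*I\* that rearranges into the final folded complex
(PI)\*. Stopped-flow traces observe

FI(t) = (c·[P\*I\*] + c\*·[(PI)\*]) / (c·[P\*I\*]eq + c\*·[(PI)\*]eq) · SC + Baseline.

The package provides, as separately testable modules:

- `simulate_scheme()` / `equilibrium_state()` — stiff ODE integration
  (compiled right-hand side) and closed-form equilibrium;
- `fret_intensity()` — the observation model;
- `generate_titration()`, `generate_peak_table()`,
  `generate_discrete_trajectories()` — seeded synthetic-data generators
  for every input the pipeline consumes;
- `fit_exponentials()`, `select_model()`, `fast_phase_fit()`,
  `slow_phase_fit()`, `summarize_titration()` — the classical two-phase
  transient analysis (kobs = kon[L]+koff; kobs = kslow[L]/(K0.5+[L]));
- `fit_global()` / `recovery_benchmark()` — the global fit of all six
  rate constants across labelling schemes (multi-start simplex → genetic
  algorithm → Levenberg-Marquardt refinement in identifiable
  coordinates);
- `csp()`, `het_noe()`, `r2eff()`, `delta_rex()`, `pre_gamma2()`,
  `classify_pre()`, `delta_profiles()` — the NMR observable formulas with
  error propagation and σ-band classification;
- `estimate_transition_matrix()`, `stationary_distribution()`,
  `coarse_grain()`, `mfpt()`, `bootstrap_msm()` — Markov-state-model
  populations, mean first-passage times and bootstrap uncertainty.

## Worked example

Simulate a titration with the published rate constants, analyse it, and
compare the fast-phase slope with its theoretical value kb·k1/(k1+k−1):

```r
library(pkiakin)

r <- published_rates()
print(r)
#> Rate constants of the multistate binding scheme
#>   I -> I*      k1       = 1.9e+04 s^-1
#>   I* -> I      k_minus1 = 1.5e+04 s^-1
#>   P*+I* -> enc kb       = 1.5e+07 M^-1 s^-1
#>   enc -> P*+I* k_minusb = 0.5 s^-1
#>   enc -> (PI)* kr       = 2400 s^-1
#>   (PI)* -> enc k_minusr = 720 s^-1

des <- titration_design("kinase", titrant_multiples = c(10, 25, 50, 100, 250),
                        duration = 0.5, sampling = "log", n_points = 300,
                        noise_sigma = 0.005, seed = 1)
ser <- generate_titration(r, fret_calibration(1, 0.4, SC = -0.6, Baseline = 1), des)
ps <- summarize_titration(ser)
print(ps)
#> Phase summary [ACCEPTOR-3]
#>   fast: kon = 7.97e+06 +/- 4.1e+05 M^-1 s^-1, koff = 6.61 +/- 5 s^-1, Kd_app = 8.3e-07 M
r[["kb"]] * r[["k1"]] / (r[["k1"]] + r[["k_minus1"]])
#> [1] 8382353
```

The fitted slope (7.97×10⁶ M⁻¹s⁻¹) is the pseudo-first-order association
rate of the conformational-selection limb, kb scaled by the competent
fraction k1/(k1+k−1) ≈ 0.56 = 8.38×10⁶ M⁻¹s⁻¹ — within 5% of theory on
this noisy synthetic series. The printed Table-1-style constants of the
source experiments are available via `published_phase_summary()`.

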