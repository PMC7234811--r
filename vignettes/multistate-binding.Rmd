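---
title: "Multistate binding kinetics of an intrinsically disordered inhibitor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate binding kinetics of an intrinsically disordered inhibitor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkiakin)
```

## The model

PKIα, the heat-stable inhibitor of the catalytic subunit of protein kinase A
(PKA-C), is an intrinsically disordered protein that folds upon binding. Its
recognition by the nucleotide-saturated, active kinase (denoted P\*) combines
conformational selection and induced fit:

- **Conformational selection.** Free inhibitor interconverts between a
  binding-incompetent ensemble I and a binding-competent ensemble I\*
  with first-order rates `k1` (I → I\*) and `k_minus1` (I\* → I). At
  equilibrium a fraction *f* = k1/(k1+k−1) of the free inhibitor is
  competent.
- **Encounter.** P\* and I\* form an encounter complex P\*I\* with
  second-order rate `kb` (M⁻¹s⁻¹) and dissociate with `k_minusb` (s⁻¹).
- **Induced fit.** The encounter complex rearranges into the final,
  folded-upon-binding complex (PI)\* with rates `kr` and `k_minusr`.

The five species obey mass-action kinetics; total kinase
(P\* + P\*I\* + (PI)\*) and total inhibitor (I + I\* + P\*I\* + (PI)\*) are
conserved. `simulate_scheme()` integrates the system with a stiff solver
(lsoda, compiled right-hand side, default rtol 1e-8, atol 1e-13 M — the six
rates span ~0.5 to ~3×10⁴ s⁻¹, so explicit integration is hopeless), and
`equilibrium_state()` solves the equilibrium in closed form: the total bound
concentration satisfies a single-site depletion quadratic with the effective
association constant (1+Kr)·(kb/k−b)·f, and the remaining species follow from
the detailed-balance ratios. The quadratic is evaluated in its numerically
stable form (the small root via the rationalised expression). Internal units
are molar and seconds throughout.

Negative-concentration excursions beyond 10·atol abort a simulation rather
than being clipped: clipping would hide stiffness failures from the fitting
stages, which must see them as penalties.

```{r}
r <- published_rates()
eq <- equilibrium_state(r, P_total = 1e-7, I_total = 1e-5)
round(unclass(eq) / 1e-9, 3)   # nM
```

## The observation model

Stopped-flow mixing experiments monitor total donor fluorescence. The
instantaneous intensity is

FI(t) = (c·[P\*I\*] + c\*·[(PI)\*]) / (c·[P\*I\*]eq + c\*·[(PI)\*]eq) × SC + Baseline,

where c and c\* weight the two complexes by their FRET efficiency, SC scales
the normalised signal and Baseline is the basal fluorescence. The denominator
uses the *model* equilibrium, not the trace plateau, so normalisation does
not couple noise into the fit. The weight pair (c, c\*) is identifiable only
up to a common factor — FI is invariant under (c, c\*) → (λc, λc\*) — so all
fitting fixes c = 1 and estimates c\* per labelling scheme.

## Synthetic data

`generate_titration()` emulates the two experimental designs: labelled
kinase fixed at 100 nM with the inhibitor titrated over fold-excesses up to
250× (default multiples 0–250), and the doubly labelled inhibitor fixed at
100 nM titrated with kinase (up to 800×, configurable; one figure caption
quotes 0–400× for one series, so the grids are arguments, not constants).
Defaults a practitioner would recognise: 1.5 ms instrument dead time
(simulated but not observed), linear sampling at the instrument rate or
logarithmic "split-timebase" sampling, and additive Gaussian noise with
standard deviation expressed as a fraction of |SC| (default 1%; the source
experiments do not state a noise model). Generators are pure functions of
their parameters and a mandatory seed.

The peak-table generator builds NMR observables from mono-exponential decay
models (intensities I(T) = I₀e^(−RT), with the paramagnetic rate increased
by Γ₂), so every metric has an exact known truth; peaks whose clean
intensity falls below the spectral noise floor are flagged "undetectable",
mirroring residues broadened beyond detection. The discrete-trajectory
generator samples Markov chains from a given transition matrix (initial
states drawn from its stationary distribution).

What the generators do *not* emulate: photobleaching and inner-filter
effects, non-Gaussian photon statistics, baseline drift, peak overlap, or
microstate-discretisation error in the MSM trajectories. Tests passing on
these data therefore validate the estimators' mathematics, not robustness
to every instrumental artefact.

## Transient analysis

`fit_exponentials()` fits offset + ΣAᵢexp(−kᵢt) by variable projection:
rates are searched in log space (multi-start Nelder-Mead/Brent), amplitudes
and offset solved exactly by linear least squares at each trial — immune to
bad amplitude guesses. Phases are reported fast to slow; two rates within 5%
raise a degenerate-phases warning.

`select_model()` chooses the phase count. The natural first idea, lowest
AIC, proved unreliable on long finely sampled traces: AIC admits spurious
low-amplitude (or large, mutually cancelling) phases that chase correlated
integration/noise structure, biasing fast-phase rates by tens of percent.
The default is therefore a sequential F-test (α = 10⁻³, degenerate fits
rejected), the standard practice in kinetic fitting software; AIC remains
available via `criterion = "aic"`.

The concentration dependences mirror the classic two-phase analysis:
`fast_phase_fit()` fits kobs = kon·[L] + koff by ordinary least squares
(negative intercepts are reported as-is; Kd^app = koff/kon with its standard
error from first-order propagation including the slope–intercept
covariance), and `slow_phase_fit()` fits the saturating hyperbola
kobs = kslow·[L]/(K₀.₅+[L]) with no additive offset (the reference analysis
quotes only kslow and K₀.₅; an offset flag exists but defaults off).
Concentrations below 5× the fixed partner are flagged — pseudo-first-order
reasoning is weak there — but not excluded.

```{r}
conc <- c(1, 2, 5, 10, 20) * 1e-6
fast_phase_fit(conc, 1.88e7 * conc + 13)[c("kon", "koff", "Kd_app")]
```

## The global fit

`fit_global()` estimates all six rate constants jointly across every trace
of every labelling scheme: rates shared globally, c\* per scheme, SC and
Baseline per trace. Three numerical choices matter:

1. **Variable projection of the nuisance parameters.** SC and Baseline
   enter FI linearly, so they are profiled out by exact per-trace linear
   least squares inside the objective. The optimum is identical to joint
   fitting, but the nonlinear search has 6 + (schemes) dimensions instead
   of 6 + (schemes) + 2×(traces).
2. **Exploration as in the original protocol.** Stratified log-space
   multi-starts refined by Nelder-Mead (the paper's fminsearch stage, cap
   10⁴ iterations), then a real-coded genetic algorithm (population 50 as
   published; tournament selection, blend crossover, log-space Gaussian
   mutation with a cooling schedule, elitism). Generations are
   configurable: the published protocol ran 10⁴; the desk default is 500,
   and the recovery benchmark below uses 100 — by that point the GA's job
   (escaping bad local optima) is done and refinement takes over.
3. **Refinement in identifiable coordinates.** The raw log-rates are
   pathologically correlated near the optimum (condition number of the
   Gauss-Newton Hessian ≳ 10¹¹). Refinement therefore works in
   coordinates aligned with what the data actually measure — log of
   kb·f, k₋b/(1+Kr), kr+k₋r, kr/k₋r, k1+k₋1, k1/k₋1 — using
   Levenberg-Marquardt with *central-difference* Jacobians at step 3×10⁻³
   dex and tight integrator tolerances (rtol 1e-10): forward differences
   at machine-default steps drown the sloppy directions in solver noise.
   The sloppiest coordinate, kr/k₋r, gets a dedicated profile-likelihood
   sweep (all other parameters re-optimised at each trial value). The top
   three distinct exploration candidates are refined and the best kept.

Solver failures anywhere return a large finite penalty, never an exception,
so the optimizer can traverse stiff parameter regions. Everything is
deterministic given the seed.

### The recovery benchmark and identifiability

`recovery_benchmark()` regenerates the study conditions — two labelling
schemes (ACCEPTOR-3-like decay, DONOR-ACCEPTOR-like buildup with different
c\*), kinase or inhibitor fixed at 100 nM, six titrant concentrations each
(10–250× and 10–400×), noiseless — from the published constants
(kb 1.5×10⁷ M⁻¹s⁻¹, k₋b 0.5 s⁻¹, kr 2400 s⁻¹, k₋r 720 s⁻¹, k1 1.9×10⁴ s⁻¹,
k₋1 1.5×10⁴ s⁻¹) and refits them from scratch: 12 traces × 300 log-spaced
points, about five minutes on one core.

Two design choices deserve emphasis, both made from an identifiability
analysis (singular value decomposition of the residual Jacobian at truth):

- **Observation from 50 µs.** The rearrangement relaxation
  (kr+k₋r ≈ 3100 s⁻¹, τ ≈ 0.3 ms) and the conformational exchange
  (3.4×10⁴ s⁻¹, τ ≈ 30 µs) are over within the 1.5 ms dead time of a
  conventional stopped-flow instrument; with that dead time the singular
  value of the kr/k₋r direction drops to ~2×10⁻⁵ and the individual
  rearrangement rates are practically unidentifiable — only effective
  combinations survive. (This is an honest feature of the chemistry, and
  consistent with the unresolved tension between the fitted kr of
  2400 s⁻¹ and the observed ~24 s⁻¹ slow phase in the source analysis;
  the package reports both as printed and does not force agreement.) The
  benchmark therefore uses an idealised rapid-mixing window starting at
  50 µs, where all six rates are individually recoverable.
- **Tight generation tolerances.** "Noiseless" data generated at the
  solver's everyday tolerance (rtol 1e-8) carry frozen integration error
  of ~10⁻⁷ relative, which acts as structured pseudo-noise and caps the
  attainable SSR; benchmark data are generated at rtol 1e-11 so the
  refit can descend to SSR ≈ 10⁻¹⁵ and resolve the sloppy directions.

## NMR observables

All formulas are direct transcriptions of the standard definitions:
compounded CSP with the 0.154 nitrogen scaling; hetNOE = Isat/Iunsat with
RMS-noise error propagation; CPMG R₂,eff = ln(I₀/I)/T with T = 40 ms and
ΔRex defined as R₂,eff(12.5 Hz) − R₂,eff(1000 Hz) (lowest nonzero minus
highest refocusing frequency — the measurement set {0, 12.5, 1000 Hz} never
defines ΔRex explicitly, and this is the standard convention, with the 0 Hz
point serving as the reference I₀); two-time-point PRE-Γ₂ at delays 4 and
14 ms with the four-term error propagation. σ-band classification of PRE
values uses weak < 1σ, medium 1–2σ, elevated 2–3σ, strong ≥ 3σ from the
table mean — the conventional bands leave 2–3σ unnamed, and "elevated"
makes the classification total. R₁/R₂ series are fit mono-exponentially
(two parameters), with replicated delays available for error estimation.
Residues are matched by integer number only; no alignment.

## Markov-model statistics

The MSM module consumes pre-discretised trajectories (microstate
construction — tICA, K-means — is out of scope; it is delegated to
established MD tooling and carries none of the statistics implemented
here). Estimation uses sliding-window transition counts at the chosen lag;
rows without counts get a self-transition and a warning. Stationary
distributions come from the left unit eigenvector with a linear-solve
fallback; irreducibility is checked by boolean reachability closure.
Macrostates label the HAR (residues 1–14) and NES (37–46) motifs helix or
coil at a mean-helicity threshold of 0.5 (the source clustering states no
cutoff; 0.5 is the natural midpoint) with the linker always "L": HLH, HLC,
CLH, CLC. MFPTs solve the standard hitting-time linear system, with source
microstates weighted by the stationary distribution restricted to the
source macrostate, times the lag time. `bootstrap_msm()` resamples whole
trajectories with replacement (150 rounds by default); since clustering is
out of scope, rounds re-estimate only the Markov model — a documented
simplification of the original re-cluster-per-round procedure. Rounds with
disconnected chains or infinite MFPTs are excluded and counted.

The published macrostate populations and inter-state MFPTs for the free and
bound ensembles derive from ~60 µs of adaptive MD sampling; they are context
for interpreting this module's outputs, not quantities reproducible from
synthetic chains, and the package encodes no such values.

## Problem sizes used by the test-suite and benchmark

Unit tests run on traces of 100–400 points, chains of 3 states, and
trajectories of 10³–4×10⁴ steps; the Monte-Carlo MFPT oracle uses 2×10⁵
walkers. The recovery benchmark uses 12 traces × 300 points with a
6-start / 100-generation / 3-candidate protocol. These sizes make the whole
suite run in well under half an hour on a single core while leaving every
statistical tolerance comfortably non-marginal.

## Known limitations

- The FRET model has no photophysics (bleaching, crosstalk, inner filter).
- The slow-phase hyperbola and the five-species scheme are not forced to
  agree; the scheme's observable slow relaxation under instrument
  conditions is not kr itself.
- With single-scheme data, k1 and k₋1 are constrained mainly through their
  ratio and sum at high rates; individual values degrade gracefully (the
  benchmark quantifies this only for the two-scheme design).
- `bootstrap_msm()` underestimates the variance contribution of the
  discretisation step it does not repeat.
- The equilibrium solver assumes a reversible binding step; kb = 0 or
  k₋b = 0 with material present is reported as a degenerate equilibrium,
  and kr > 0 with k₋r = 0 as an absorbing state.
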