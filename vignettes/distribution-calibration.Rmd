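---
title: "Calibrating populations of atrial AP models to biomarker distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating populations of atrial AP models to biomarker distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomcal)
```

## The calibration problem

A population of models (POM) represents inter-individual variability with
many instances of one mechanistic model differing only in parameter values.
`pomcal` builds POMs of the Courtemanche–Ramirez–Nattel (CRN) human atrial
myocyte model whose simulated action-potential (AP) biomarkers reproduce the
full joint distribution of a measured biomarker table, not merely its
ranges. The pipeline is: estimate the data density by kernel density
estimation, sample parameter vectors with a tempered sequential Monte Carlo
(SMC) sampler targeting densities proportional to `p(M(theta))^gamma`, and
refine the resulting pool by simulated-annealing subset selection against a
Jensen–Shannon divergence matrix.

This vignette records the model, the tunable parameters, the numerical
choices, and the design decisions made where the procedure was genuinely
open — together with what the synthetic test harness does and does not
demonstrate.

## The forward model

The CRN model is a 21-state ODE system: membrane potential, 12
Hodgkin–Huxley gates for the sarcolemmal currents, 3 sarcoplasmic-reticulum
(SR) release gates, and 5 concentration states (intracellular Na+, K+,
Ca2+, and the two SR Ca2+ compartments). The right-hand side is implemented
in C (`src/crn.c`) from the original publication's equation set and
integrated with `deSolve::lsoda`, a stiff variable-order solver. Eleven
current magnitudes are exposed as dimensionless multipliers
(`crn_parameters()`); an optional twelfth multiplier scales the time
constant of the I_Na h (fast-inactivation) gate, used when exploring
variability in upstroke behaviour.

Simulation conditions follow the clinical recordings the calibration is
designed for: T = 309.65 K, [Na+]o = 149.42 mM, [K+]o = 4.5 mM,
[Ca2+]o = 1.8 mM, a 2-ms −2210-pA stimulus (about twice the baseline
model's diastolic threshold), pacing until every state variable changes by
at most 1% between beats and then 90 further beats, the last of which is
measured. Under these conditions the baseline model rests at −85.7 mV and
the chronic-AF (cAF)-remodelled baseline (g_to ×0.3, g_Kur ×0.5, g_Ks ×2,
g_K1 ×2, g_CaL ×0.3, I_NaCa(max) ×1.4) yields APD90 ≈ 122 ms with
RMP ≈ −88.7 mV; the acceptance script recomputes all of these.

Choices the experimental record does not fix, exposed in
`stimulus_protocol()`:

* **Cycle length** — not stated; default 1000 ms (1 Hz), the standard
  pacing rate for human atrial single-cell protocols.
* **Solver configuration** — only the 1-ms maximum step is stated. We add
  `rtol = 1e-6` and per-state absolute tolerances (1e-4 mV on V, 1e-8 on
  gates, down to 1e-10 mM on Ca2+, which reaches 1e-4 mM). Halving the
  maximum step and tightening `rtol` to 1e-8 changes every baseline
  biomarker by well under 1% (tested).
* **Stimulus charge bookkeeping** — the original model leaves the stimulus
  current unassigned to any ion; we keep that convention (`stim_to_K`
  switches it). With it, the protocol reproduces the published resting
  potentials above.
* **Steady-state test** — relative change per state with an absolute floor
  of 1e-10, so near-zero gates (the SR release activation gate rests at
  ~0) cannot stall convergence; beat cap 1000 with a warning.
* **Diastolic threshold rest state** — pulses are applied from the
  published resting state of the model. Letting the cell first relax under
  the study's external concentrations hyperpolarises the rest by ~4.5 mV
  and raises the threshold by ~20%, which is incompatible with the stated
  "twice the diastolic threshold" stimulus; the published-rest convention
  is therefore the default, with a configurable relaxation time.

## Biomarker extraction

From the final beat (stimulus at t = 0, so the first sample is the
pre-stimulus diastole): RMP is the potential immediately before the
stimulus; APA the peak minus RMP; dV/dt_max the maximum of the model
right-hand side over the upstroke (dense output, not finite differences, so
the value does not depend on the sampling grid); activation time the
instant of that maximum; APDx the time from activation to the first
downward crossing of `peak − x% · APA`, located by linear interpolation;
V20 the potential at 20% of APD90 after activation. APD measured from the
activation instant is self-consistent with V20 and is the common
convention; the source protocol states no origin.

Three discard rules reject a trace as invalid — no excitation above
−30 mV, no repolarisation to RMP + 0.1·APA, or a spontaneous
depolarisation, operationalised as any later local maximum above that
level after the first repolarisation below it. We additionally reject a
trace whose *diastolic* potential already sits above −30 mV: degenerate
parameter sets (e.g. all conductances zero, leaving only the unscaled
background currents) drift to a depolarised pseudo-rest around +120 mV and
would otherwise slip past rules written for ordinary APs. All rejection
paths return a typed outcome that the calibration treats as zero density,
never a partial biomarker vector.

## Density estimation

`fit_density()` implements the Gaussian-kernel KDE with diagonal bandwidth
`H_ii = h_opt · sigma_i^2`,
`h_opt = (4 / (N (N_b + 2)))^(2 / (N_b + 4))` (0.282 at N = 469,
N_b = 7). Two conventions are supported because the bandwidth rule as used
multiplies the *variance* by `h_opt` while the classical normal-reference
rule multiplies it by `h_opt^2`: `bandwidth_convention = "linear"`
(default, the rule this calibration is built on) and `"squared"` (the
textbook rule; also what the KDE-convergence test uses, since only the
squared convention is consistent as `N` grows). The APD20 column is
log-transformed when its skewness exceeds 1 — clinical sinus-rhythm APD20
distributions are strongly right-skewed, and the bandwidth rule is optimal
for Gaussian-like data.

During SMC only density *ratios* matter, so the sampler works entirely in
transformed space without the log-Jacobian; `eval_density(jacobian = TRUE)`
applies it when absolute densities over original biomarker space are
reported. Marginal and pairwise grids (`grid_density()`) are exact
analytic marginals of the product-kernel KDE.

## Tempered SMC

`smc_calibrate()` ramps gamma from 0 (uniform over the bounded box,
trivial to sample) to 1 (proportional to `p(M(theta))`). Design decisions,
made where the method description leaves the mechanism open:

* **Increment rule** — gamma grows by bisection so the reweighted
  effective sample size stays at `ess_frac · N` (default N/2), the
  standard adaptive tempering rule in the SMC literature.
* **Resampling** — systematic (low variance); copy counts provably lie in
  `{floor(N w), ceiling(N w)}`.
* **Jumping distribution** — a Gaussian mixture fitted by `mclust` (BIC
  over 1–3 components by default) to the particle cloud jittered by 10% of
  the per-dimension SD, with a 1e-6 covariance floor; large ensembles are
  subsampled to 500 points for the fit. Proposals outside the bounds or
  with invalid forward-map outcomes are rejected, preserving the implicit
  uniform prior on the box.
* **Move count** — a one-step pilot estimates the acceptance rate and the
  total is `ceiling(log(0.01) / log(1 − p_acc))` (capped at 100), giving
  every particle a ≥99% chance of moving at least once after each
  resample.
* **Final rejuvenation** — one extra adaptive move round after gamma
  reaches 1. The sampler is unbiased without it (verified against the
  analytic pushforward at 20 000 particles), but resampling leaves
  residual dependence that inflates goodness-of-fit statistics at moderate
  N; the extra pass restores near-independence.
* **Initialisation** — uniform draws; invalid models are redrawn, because
  at gamma = 0 they would be accepted yet carry zero density for every
  gamma > 0.

The sampler returns the *unique* final particles (typically ≥ 95% of N on
smooth targets) with their cached outputs. One caveat is inherent to the
approach and asserted by the tests: the particles are distributed over
parameter space proportionally to `p(M(theta))`; the implied distribution
of *outputs* is not `p(y)` — that is exactly why refinement exists.

## Refinement

`divergence()` builds, on shared per-dimension grids, KDEs of every
marginal and pair of biomarkers for POM and data, fills the symmetric
matrix P (marginal Jensen–Shannon distances on the diagonal, pairwise off
it; all integrals Riemann sums) and returns `rho = ||P||_2`. We read the
two-norm as the spectral norm of the symmetric matrix; Frobenius is a
config option, and both satisfy `rho_hat <= rho` when the off-diagonal
row/column of the de-emphasised dimension (default dV/dt_max) is zeroed.
Each side gets its own normal-reference bandwidth; which bandwidth the POM
side should use is not specified anywhere, so it is recomputed from the
POM's own size and variances.

`anneal_refine()` minimises rho by toggling uniformly chosen members in or
out, accepting with `min(1, exp(-delta_rho / T))` at fixed T = 0.2,
rejecting outright any removal below `min_size` (default: the number of
data rows), and every 1000 trials resetting to the best configuration if
the current rho exceeds it by more than 1%. Numerical choices:

* **Frozen population bandwidth** — during one anneal the POM-side
  bandwidth is fixed at the full pool's value. Recomputing `h_opt` and the
  variances at every trial would make incremental bookkeeping impossible
  (every kernel would change width when one member toggles); freezing
  makes the add/remove updates exact, which the tests verify against full
  recomputation to 1e-10.
* **Incremental sums** — per-member 1-D kernel rows are precomputed; a
  toggle updates marginal sums by vector addition and pairwise grids by a
  rank-one outer product. Tiny negative residues from floating-point
  cancellation are clamped at zero.
* **Grids** — 128 bins per dimension over the pooled range extended by 3
  bandwidths (both configurable); termination by a fixed trial budget
  (default 200 000), since no stopping rule is otherwise defined.
* **Moves** — one uniform toggle per trial; proposing reintroductions only
  from the removed set would be an equivalent parameterisation.

## Downstream analyses

`lhs_range_calibrate()` reproduces classical range calibration: replicated
Latin hypercube samples (default 10 × 1000, stratified per dimension within
each replicate via the `lhs` package), keeping models whose every biomarker
falls inside the data ranges. `compare_parameter_distributions()` reports
per-parameter median shifts (as ratios of medians; medians of ratios are
the noted alternative) with two-sided Mann–Whitney U p-values
(`wilcox.test`: exact for small samples, normal approximation with tie
correction otherwise; defaults 0.001 for "significant", 0.01 for "no
change"). `median_model()` collapses a POM to component-wise medians.
`drug_block_experiment()` pairs full pre/post pacing runs around a
fractional block of one current, flagging members that repolarise to above
−60 mV or shorten their APD90 under block.

## The synthetic harness

`generate_dataset()` draws biomarker tables with the qualitative structure
of clinical atrial data: SR-like tables have strongly right-skewed APD20
(log-normal tail), a bimodal APD50 (a ~25% subpopulation of cells
repolarising more than half-way during the initial rapid phase), and
|corr(APA, dV/dt_max)| < 0.2; cAF-like tables are unimodal with shorter,
more triangular APs and a more depolarised rest. The location and scale
constants are fixture choices anchored to typical human atrial values
(APD90 around 300 ms in SR and 210 ms in cAF, APA ≈ 100–105 mV,
RMP ≈ −74/−78 mV, upstrokes around 200 V/s); they are deliberately *not*
estimates of any particular study's moments, which are not tabulated
anywhere usable. Rows satisfy the biomarker invariants by construction.

`toy_models()` supplies closed-form forward maps with known pushforwards
(identity; square with density `1/(2*sqrt(y))` under uniform parameters; a
2-D map with built-in output correlation) plus an 11-parameter/7-output
surrogate whose linear-plus-saturating responses mirror the currents'
roles — repolarising conductances shorten the APD analogues, the g_K1
analogue dominates RMP, and APA and dV/dt_max both load on the g_Na
analogue, reproducing the model-induced correlation that motivates
`rho_hat`. It evaluates vectorised in microseconds, so 2000-particle SMC
runs take seconds.

`end_to_end_recovery()` is the pipeline's self-test: truth drawn from a
Gaussian parameter population (SD 0.15 around mildly shifted centres),
pushed through the surrogate to make a data table (default 120 rows),
calibrated with N = 300 particles and refined with a 2000-trial,
48-bin-grid anneal — sizes chosen so ten replicate studies complete in
a couple of minutes while leaving clear separation between the refined and
range-calibrated divergences. The two-group variant shifts the g_Na
analogue by a known −40%: that parameter has a nearly exclusive output
signature (dV/dt_max), so the test isolates the pipeline's recovery
machinery from genuine non-identifiability — shifting a parameter whose
effect the surrogate lets g_Kur or g_Kr compensate (e.g. the g_to
analogue) smears the signal across several parameters, which is a property
of the map, not a pipeline defect.

What passing these tests shows: the sampler targets the stated
distribution, the annealer finds (verified against exhaustive subset
enumeration on small pools) subpopulations that minimise rho, and the
whole chain recovers distinctive parameter shifts. What it does not show:
that the CRN model spans any particular clinical dataset, that biomarker
measurement error is well modelled (the generator has none), or that
parameters with overlapping output signatures are individually
identifiable.

## Limitations

* The CRN implementation is validated against the published deterministic
  behaviours of the model (resting potentials, cAF APD90, diastolic
  threshold, morphology) rather than a second independent code base.
* Full SMC calibration of the CRN model itself (rather than the surrogate)
  is computationally serious: one forward map costs ~0.6 s, so a
  2000-particle run is hours of CPU; the package keeps that path available
  through the same interfaces but the test suite exercises the engine on
  the closed-form models.
* The refinement objective uses marginal plus pairwise distances only; a
  full 7-D Jensen–Shannon distance is intractable on grids, and triple-wise
  structure is invisible to rho.
* Annealing at fixed temperature with restarts has no optimality
  guarantee; the exhaustive-subset agreement is demonstrated at pool size
  12.
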