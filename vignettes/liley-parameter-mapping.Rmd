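---
title: "Mapping Liley neural mass model parameters from EEG-like signals"
author: "lileyfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping Liley neural mass model parameters from EEG-like signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's methodological account: the model and its
assumptions, the objective functions, the evolutionary search, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the known limitations. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The model

`lileyfit` implements the local (spatially homogeneous) Liley neural mass
model: one excitatory and one inhibitory population, each characterised by
a mean soma membrane potential (`h_e`, `h_i`, mV), coupled through four
synaptic pathways with second-order ("alpha-function") kinetics. The
membrane equations weight each synaptic activity by a reversal-potential
factor `(h^eq - h) / |h^eq - h^rest|`, so synaptic drive saturates as the
membrane approaches the corresponding reversal potential — the model's
essential nonlinearity besides the sigmoid firing function

\[ S_j(h) = \frac{S_j^{max}}{1 + \exp(-c\,(h-\mu_j)/\sigma_j)}, \qquad
   j \in \{e, i\}. \]

Two conventions for the sigmoid exponent constant circulate: `c = 2` and
`c = sqrt(2)`. The package defaults to `c = 2` and records the constant in
every simulation's metadata (`liley_sim_config(c_sig = )`), so either
convention is reproducible. The rate constants are pairwise tied,
`gamma_ee = gamma_ei = gamma_e` and `gamma_ie = gamma_ii = gamma_i`.

The deterministic model has 22 free parameters. Extrinsic input to the
excitatory-excitatory pathway is a Gaussian process with mean `p_ee` and
amplitude `xi`; because the resting fits are stochastic, `xi` is searched
together with the model parameters, giving a **23-entry decision vector**
(`liley_param_names()` fixes the canonical order). All internal units are
mV and ms. `liley_bounds()` holds the physiological search box;
`liley_typical()` is the conventional operating point, completed with
range-midpoint reversal potentials and input rates `p_ee = 2`, `p_ei = 5`
(1/ms) at which the deterministic model has a single stable fixed point,
and a moderate noise amplitude `xi = 0.5`.

## Simulation

The ten first-order SDEs are integrated with fixed-step Euler–Maruyama at
`dt = 0.0125` ms from zero initial conditions; a 5 s transient is discarded
and `h_e` is linearly interpolated onto the 256 Hz output grid (the
80 kHz-to-256 Hz ratio of 312.5 is not an integer; interpolation is exact
at sample instants, and no anti-alias filter is applied because the
comparison data receive only a 2 Hz high-pass). The integrator is compiled
(Rcpp); noise deviates are drawn in R from a private Mersenne–Twister
stream, so a simulation is a pure function of `(params, config)` including
the seed, and never perturbs the caller's RNG.

Two noise discretisations are provided because the published description of
`p(t)` is ambiguous about whether `xi` is a standard deviation of a
continuous-time white noise or of per-step draws:

* `white_noise` (default): Euler–Maruyama diffusion increment
  `Gamma_e * gamma_e * e * xi * sqrt(dt) * N(0,1)` on the `J_ee` equation;
  output statistics are independent of `dt`.
* `per_step_gaussian`: `p_k ~ N(p_ee, xi^2)` drawn independently each step;
  the effective forcing spectrum then scales with `1/dt`.

Negative instantaneous input is **not** clipped — the synaptic equations
accept any real forcing, and clipping would bias the noise mean.

A trajectory whose `|h_e|` exceeds `1e4` mV (or becomes non-finite) is
returned with a `divergent` flag instead of raising an error: evolutionary
populations legitimately contain pathological parameter sets, and the
objectives translate the flag into a fixed penalty of `1e6` per objective,
which exceeds any achievable discrepancy by orders of magnitude and makes
every viable parameter set dominate every divergent one. Constant (zero
variance) output is treated the same way, since a z-scored comparison is
undefined for it.

### Accuracy

Euler is first order; the tests verify the error against an adaptive
reference integrator (`deSolve::lsoda` driven by an independently written
drift) and the expected halving of the error with the step. Two regimes
matter:

* the **startup transient** from zero initial conditions, where the
  saturated sigmoid produces accelerations of order `6e2` mV/ms² and a
  first-order scheme at `dt = 0.0125` ms accumulates ~`1e-2` mV RMS — this
  span is discarded in all analyses, exactly as the 5 s transient removal
  prescribes;
* the **operating regime**, where the agreement is ~`1e-4` mV RMS per
  second of simulation.

## Fixed points and attractor classification

Setting the synaptic kinetics to equilibrium
(`I* = Gamma e (N S + input) / gamma`) reduces the steady state to two
equations in `(h_e, h_i)`. `find_fixed_points()` solves them by damped
Newton iteration from a 20 × 20 grid of starts over `[-90, -10]²` mV
(the reduced system can be multistable; roots are merged at `1e-6` mV),
reconstitutes the ten-dimensional state and computes the eigenvalues of the
analytic Jacobian. The returned drift norm is below `1e-10`.
`classify_attractor()` combines stability of the fixed points with a long
noise-free simulation: convergence to a point means the stochastic dynamics
are noise-driven fluctuations around a stable focus; a terminal 2 s
peak-to-peak amplitude of `h_e` above 0.1 mV (configurable; the threshold
separates genuine cycles from numerical ringing) means a noise-driven limit
cycle; divergence is its own class.

## Objective functions

All model output is z-scored before feature extraction, mirroring the
z-scoring of the data, so every objective compares shape, not scale.
Z-scoring is implemented idempotently (an already standardised series is
returned bit-identically), which makes "model equals data implies objective
zero" hold exactly.

**Spectra.** `compute_psd()` is a Welch estimator: Hann-windowed segments
of `rate/resolution` samples with 50% overlap, averaged, restricted to the
band, and normalised to unit sum over the band. The 0.125 Hz resolution of
the full protocol corresponds to 8 s segments of a 20 s epoch (145 bins on
2–20 Hz); a 2 s desk-scale epoch supports at best 0.5 Hz, in which case the
estimator degenerates to a single windowed periodogram. The segment-length
rule (resolution fixes the segment, not the epoch) is this package's
choice; a plain full-length periodogram is available by matching the
resolution to the epoch.

**Pre-whitening.** The 2–45 Hz objective removes the `1/f` background by a
robust linear fit of log power on log frequency (`MASS::rlm`, bisquare
weights), subtracting the fitted trend. Robustness keeps genuine spectral
peaks from dragging the baseline. Power is floored at `1e-15` of the
spectral maximum before the log: bins at the numerical leakage floor of a
noiseless tone would otherwise inject hundreds of log-units of rounding
noise into the fit.

**Weighted horizontal visibility graph.** Each time point is a node; nodes
`i < j` are joined when every intermediate sample lies strictly below both
endpoints, so equal intermediate values block visibility (the criterion is
applied as printed). The edge weight is the signed amplitude difference,
later minus former, and a node's strength is the sum of its incident
signed weights. The builder is a linear-time monotone-stack sweep, verified
edge-for-edge against an `O(N^2)` definitional oracle including ties. The
comparison statistic is the two-sample KS statistic on the raw
node-strength samples (binning into 100-bin densities is used only for
visualisation and JSD), computed at the pooled sample points with
right-continuous empirical CDFs.

**Repeat averaging.** Stochastic objectives are averaged over `n_repeats`
simulations with deterministically derived seeds. The spectral objectives
average the model **PSD** across repeats before computing one squared
error; the wHVG objective averages the per-repeat KS statistics. Divergent
repeats contribute the penalty proportionally.

## The evolutionary search

`nsga2()` is a canonical NSGA-II: Latin hypercube initialisation over the
bounds (`lhs::randomLHS`; each of the `n` strata of every dimension
receives exactly one sample), binary tournament selection on (rank,
crowding distance), scattered crossover (per-gene uniform parent mask) for
a configurable fraction of offspring (default 0.8), per-gene Gaussian
mutation with standard deviation 5% of the bound width, reflected at the
bounds, for the rest, and elitist (rank, crowding) truncation of the pooled
parents and offspring. These operator choices are the package's own — the
reference implementation this mirrors relies on unpublished toolbox
defaults — and all of them are configuration. Parents keep their cached
objective values within a run; offspring-only re-evaluation is standard
generational practice, though with noisy objectives it lets optimistic
evaluations persist (see Limitations).

Ranks are assigned by Deb's non-dominated sort, verified against a
brute-force peeling oracle. The per-generation diagnostics are the
hypervolume of the rank-0 front against a reference point fixed at 1.1
times the component-wise maximum of the initial objectives, and the best
mean-normalised distance from the origin. One caveat is asserted in the
tests rather than hidden: once the non-dominated set saturates the
population, crowding-based truncation may exchange interior front members,
which can decrease the hypervolume by parts in `1e5`; exact monotonicity
holds in the single-objective degenerate mode, where elitism preserves the
best individual.

`select_optimal()` normalises each objective by its mean over the
non-dominated set and returns the member closest to the origin, ties broken
to the lowest index for determinism. `liley_fit()` wraps all of this into
the classed model object with `print`, `summary`, `coef`, `simulate`,
`residuals` and `plot` methods; `liley_replicates()` runs independent
master seeds and pools the selected optima into a `parameter_sample` for
the distributional analyses.

Desk-scale defaults (population 100, 20 generations, 3 repeats, 2 s
epochs) keep a full fit in minutes on one CPU; the full protocol
(population 500, 50 generations, 5 repeats, 20 s epochs, 100 replicates)
is a configuration change. The test suite and the acceptance script use the
desk scale.

## Post-fit analysis

* **Identifiability** — `identifiability_jsd()` bins a recovered
  parameter's marginal into 100 equal bins over its full bound range and
  computes the Jensen–Shannon divergence to the uniform distribution (the
  optimisation's effective prior). Natural logs are used throughout, so
  JSD lies in `[0, ln 2 ≈ 0.693]`; `0 log 0 = 0` with no pseudo-counts.
* **Cohort comparison** — `cohort_compare()` reports per-parameter JSD on
  the shared 100-bin grid and Cohen's d with `(n-1)`-weighted pooled
  variance, sign convention first cohort minus second.
* **Geometry** — `mds_embed()` applies classical (Torgerson) MDS to
  Euclidean distances between bound-normalised decision vectors;
  `silhouette_score()` uses the standard formula with the convention that
  a label's only member scores 0.
* **Physiology** — `population_summaries()` reports time-averaged membrane
  potentials and *pointwise* sigmoid-transformed firing rates (the average
  of the instantaneous rate, which differs from the rate at the average
  potential on oscillatory trajectories).
* Standard significance machinery (Mann–Whitney U, Bonferroni) is left to
  `stats::wilcox.test` and `stats::p.adjust`; the package does not wrap
  them.

## Synthetic data

`generate_synthetic_subject()` simulates the model at known ground-truth
parameters and pushes the output through the same chain as real resting
data — 2 Hz high-pass Butterworth (4th order, forward–backward for zero
phase, so waveform shape, which the wHVG measures, is not distorted) and
z-scoring — storing the truth in the epoch's provenance. The packaged
fixture (`alpha_fixture_params()`, `inst/extdata/alpha_subject.json`) is a
hand-tuned set committed with the package: it was selected by scanning the
physiological bounds for a single weakly stable fixed point (dominant
eigenvalue real part ≈ −0.0055/ms, eigenfrequency ≈ 10.7 Hz) whose
noise-driven output has its normalised spectral peak inside 8–13 Hz across
seeds. It is synthetic and not derived from any recording.

What the generator emulates: the stationary statistics of an alpha-band
neural mass rhythm — spectral shape, amplitude distribution, waveform
asymmetries — under the exact forward model being fitted. What it does not
emulate: measurement artifacts, non-stationarity, volume conduction and
re-referencing effects of multichannel EEG, inter-subject variability.
Passing the recovery tests therefore demonstrates that the pipeline can
invert its own forward model at desk scale; it does not certify performance
on real recordings.

`preprocess_resting()` implements the real-data path: common-average
re-reference (skipped for single-channel records, where it would annihilate
the signal), mean of the occipital channels (default labels O1/O2,
overridable), the same high-pass, and z-scoring. A minimal EDF reader
(256-byte header, int16 records, calibration applied, labels verbatim)
covers the standard acquisition format; CSV (`time_s,value`) covers
everything else. Result archives are JSON and CSV.

## Numerical choices, collected

| Choice | Value | Why |
|---|---|---|
| Sigmoid exponent `c` | 2 (configurable) | as-printed convention; recorded in metadata |
| Integration step | 0.0125 ms | convergence of the first-order scheme |
| Divergence guard | `|h_e| > 1e4` mV | flags Euler blow-up without aborting a population |
| Objective penalty | `1e6` | dominates any achievable discrepancy |
| Fixed-point starts | 20 × 20 over `[-90, -10]²` mV | multistability of the reduced system |
| Root deduplication | `1e-6` mV | Newton accuracy is far below this |
| Limit-cycle threshold | 0.1 mV terminal peak-to-peak | separates cycles from ringing |
| PSD segments | Hann, 50% overlap, `rate/resolution` samples | reproduces the 0.125 Hz grid on 20 s epochs |
| Pre-whitening floor | `1e-15 ×` spectral max | keeps leakage-floor bins out of the robust fit |
| Histogram bins | left-closed, final bin right-closed, `1e-9` edge fuzz | deterministic binning of grid-aligned data |
| JSD logarithm | natural | bounded by `ln 2` |
| Hypervolume reference | `1.1 ×` initial component-wise max | fixed per run so the curve is meaningful |
| Mutation | Gaussian, sd 5% of bound width, reflected | scale-free across heterogeneous parameter units |

## Limitations

* **Single 2 s epochs are noise-limited.** In the noise-driven fixed-point
  regime the z-scored output spectrum's shape is independent of the noise
  amplitude, and independent 2 s realisations of the *same* parameters
  differ by a 2–20 Hz spectral squared error of a few times `1e-2` and a
  wHVG KS distance near `0.1`. Objectives cannot discriminate below this
  floor, which bounds what any optimiser can achieve at desk scale; longer
  epochs lower it.
* **Practical identifiability is partial by nature.** Many parameters admit
  broad recovered distributions; the package quantifies this rather than
  hiding it, and the pooled-replicate distributions are conditional on the
  algorithm's operators, not posterior probabilities.
* **Cached noisy objectives.** Elitism over non-re-evaluated parents
  retains optimistic evaluations; reported optimum objectives are mildly
  biased downward relative to fresh re-evaluation. Re-evaluation policy is
  a natural extension point.
* The model is a single cortical macrocolumn: no spatial extension, no
  forward (lead-field) model, no bifurcation tracking beyond fixed-point
  eigenvalues.
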