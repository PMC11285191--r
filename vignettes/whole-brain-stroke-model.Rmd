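---
title: "Methods: a generative whole-brain model of stroke functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a generative whole-brain model of stroke functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the estimation procedure, the synthetic
study conditions, and the numerical and design choices behind **strokesim**.
It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The local model and its working point

Each brain region is a Stuart–Landau oscillator, the normal form of a
supercritical Hopf bifurcation. Below the bifurcation (`a < 0`) the
deterministic dynamics decay to a fixed point and noise sustains narrowband
fluctuations; above it (`a > 0`) a limit cycle of radius `sqrt(a)` appears.
The pipeline operates just below the bifurcation, `a = -0.01`, homogeneous
across regions: regional BOLD is then a noise-driven oscillation at the
region's intrinsic frequency. Intrinsic frequencies `omega_j` are estimated
as the averaged spectral-peak frequency of the band-passed (0.04–0.07 Hz)
regional signals, the conventional BOLD band at TR = 2 s; the noise standard
deviation is `beta = 0.04`.

Coupling is diffusive, `G * sum_k C_jk (x_k - x_j)`, applied identically to
the real and imaginary parts. Two consequences matter downstream:

* the Jacobian's coupling block is `G (C - diag(rowSums(C)))`, whose row
  sums vanish — for nonnegative `C` every eigenvalue has real part at most
  `a`, so the linearized system is stable for every `G >= 0`;
* the uniform activity mode always decays at the slow rate `|a|`. Near the
  bifurcation this common mode is strongly amplified by the linear model but
  saturated by the cubic term in simulation. This mismatch is intrinsic to
  operating at `a = -0.01` and shapes two design choices below (the sweep
  domain, and the deeper working point used by the analytic equivalence
  tests).

## Simulation

Euler–Maruyama integration with step `dt = 0.1` s (noise scaled by
`sqrt(dt)`, drawn independently for `x` and `y`), a 50 s burn-in, and
subsampling of `x_j` at the TR. All noise is pregenerated with R's RNG so
each subject owns a reproducible seed stream; the integrator itself is
compiled (RcppArmadillo) and deterministic given the noise. A divergence
guard (default `|z| > 10`) turns an unstable `G`/`dt` combination into an
error rather than a silent overflow. Tests that check analytic limits use a
finer step (`dt = 0.002`–`0.02`): the Euler fixed-point radius is biased by
`~ dt * omega^2 / 2`, which must sit below the 1e-3 tolerance of the
limit-cycle check.

A hemodynamic-response convolution hook (`conv_hrf`) exists but is off by
default: the oscillator's real part is taken directly as the BOLD proxy, and
the double-gamma convolution is provided only as an option for users who
want the smoothed variant.

## Linearized FC and time-shifted covariance

For `a < 0` the model is linearized at the origin; the stationary covariance
`K` solves the continuous Lyapunov equation `J K + K J' + beta^2 I = 0`,
computed via the eigendecomposition of `J` (an `2n x 2n` nonsymmetric but in
practice diagonalizable matrix). Model FC is the correlation-normalized
`x`-block of `K`; the model time-shifted covariance is the `x`-block of
`K expm(J' tau)`, normalized per pair by the zero-lag standard deviations —
exactly the normalization applied to the empirical lagged covariance, so
`FS(0) = FC` on both sides. The lag default is `tau = 1` TR (2 s): the lag
must be short enough that autocorrelation survives (the narrowband signal
decorrelates over a few TR) and 1–2 TR is the convention in the effective
connectivity literature; it is exposed in `gec_fit_config()`.

## Estimating the GEC

`fit_gec()` initializes the coupling matrix at the structural connectome
(scaled so its maximum weight is 0.2) and iterates

```
C_jk <- C_jk + eps * (FC_emp - FC_mod)_jk + eps * (FS_emp(tau) - FS_mod(tau))_jk
```

with `eps = 0.001`, re-solving the linearized model after every update.
Design choices:

* **Greedy acceptance.** A step is kept only if the combined error (mean
  squared FC difference over the upper triangle plus mean squared FS
  difference over all off-diagonal entries) decreases; otherwise the
  learning rate is halved and the step retried, up to five halvings, after
  which the fit stops. This guarantees a non-increasing error trace — the
  monotonicity the package's tests assert — at the cost of possibly stopping
  at a local plateau.
* **Support restriction.** By default only entries with nonzero structural
  weight are updated (each structural connection individually adjusted); a
  flag opens the update to all off-diagonal entries. Negative weights are
  clipped to zero: the GEC extends a nonnegative connectome.
* **Target domain.** The default targets are Pearson FC and normalized
  lagged covariance of the *unfiltered* signals. Band-passing only the
  empirical side removes its independent noise floor and inflates its
  correlations relative to the full-band covariance the linearization
  produces; on synthetic ground truth this biases the selected global
  coupling upward by more than a factor of two. The same reasoning sets the
  G sweep's default empirical target to unfiltered FC. Both functions expose
  a `band` argument for the narrowband variant, and a `fc_mode = "phase"`
  option targets the Hilbert phase-locking matrix instead of correlations.
* **Mutual-information transform.** An optional mode fits on
  `-log(1 - r^2)/2`, the Gaussian mutual information of a correlation,
  which removes signs and maps targets to nonnegative values. The default
  is raw correlations; the transform compresses exactly the moderate
  correlation range the update must discriminate, and the raw mode keeps
  the fixed point of the update interpretable (zero FC/FS mismatch).
* **G sweep.** `sweep_g()` scores each candidate by the mean squared upper
  triangle difference between model and empirical FC and returns the
  arg-min, ties broken toward the smaller (less strongly coupled) value.
  Because the diffusive Jacobian is stable for all `G`, instability handling
  exists only as a guard.

The asymmetric FS target is what makes the fitted matrix directional: a
symmetric initialization acquires positive asymmetry whenever the empirical
lagged covariance is asymmetric.

## Lesioning and patient models

An SDC mask stores, per region pair, the fraction of streamlines spared by
the lesion. Lesioning a model is the elementwise product `GEC * spared`;
both directions of an asymmetric entry are multiplied by the same spared
fraction because severed streamlines are direction-blind. No parameter is
refit. The five patient models:

| model | connectome | uses patient's functional data |
|---|---|---|
| full predictive | healthy GEC ∘ own mask | no |
| no mask | healthy GEC | no |
| surrogate mask | healthy GEC ∘ another patient's mask (seeded derangement) | no |
| G-DSC | structural (healthy G only, no GEC fitting) ∘ own mask | no |
| patient specific | GEC refit on the patient's own runs, initialized from the masked structural connectome | yes |

The G-DSC model reuses the healthy `g_opt` rather than re-sweeping after
masking: the sweep is a healthy-group estimate, and re-estimating it per
patient would smuggle patient information into a predictive control.

The total-disconnection score binarizes pairwise disconnection
(`1 - spared`) at 1% and counts regions with at least one supra-threshold
incident pair — the most literal aggregation of "number of disconnected
regions", pinned as the package's convention.

## Evaluation metrics

* **Accuracy**: Pearson correlation and MSE between the strict upper
  triangles of empirical and simulated FC.
* **Z-scored abnormality**: entrywise `(FC - mean_healthy) / sd_healthy`
  (sample SD, `n - 1`); zero-SD entries are excluded rather than
  propagated. Empirical and simulated matrices are z-scored against the
  healthy cohort's empirical and simulated FC respectively, so each is
  calibrated in its own domain.
* **Stroke signatures**: intra-hemispheric DAN–DMN FC (same-hemisphere
  pairs only, both hemispheres pooled), homotopic inter-hemispheric FC
  (averaged within network, then across networks; a flat-mean flag exists),
  and weighted Newman modularity on the fixed resting-state-network
  partition over cortical regions — no community detection, negative edges
  dropped.
* **Graph metrics** (global efficiency, average degree): computed on a
  binarized graph. The default threshold is absolute (FC > 0.25). A
  proportional-density rule fixes the edge count by construction, which
  makes the average degree identical across subjects and empties the
  degree- and efficiency-versus-severity analyses; the proportional mode
  remains available where cross-subject density matching is wanted.
* **FC entropy**: normalized histogram entropy of `|FC|` over `m = 50`
  equal bins on [0, 1] (the bin count is not critical and is exposed).

## Behaviour prediction

Behaviour scores are predicted from vectorized matrices (empirical FC,
simulated FC, z-abnormality, SDC) by partial least-squares regression with
leave-one-out cross-validation: the model — including standardization and
the dropping of fold-constant features — is refit inside every training
fold, out-of-fold predictions are pooled, and `R^2` is the squared
correlation of pooled predictions with the observed scores (robust to scale
offsets; the in-sample `R^2` is reported alongside). Five components by
default, capped well below the subject count. Significance uses a seeded
permutation null of the response. The PLSR solver is mixOmics'
regression-mode PLS; the cross-validation discipline and the permutation
machinery are this package's code.

## The synthetic study conditions

`synthetic_study_config()` fixes the conditions every test runs under:

* 40 regions (20 per hemisphere), 4 mirrored resting-state networks
  including DAN and DMN; every left region homotopically paired with its
  right mirror;
* a modular structural connectome (within-network edge probability 0.9 and
  mean weight 1, between-network 0.3 and 0.25, log-normal heterogeneity),
  homotopic pairs boosted (mean 1.4) so inter-hemispheric homotopic FC is a
  real signature, rescaled to maximum weight 0.2, connectedness enforced;
* a ground-truth GEC obtained by independent log-normal perturbations
  (SD 0.3 per direction) of each nonzero structural entry — directionally
  asymmetric, same sparsity;
* 20 healthy subjects and 20 patients, runs of 896 samples at TR = 2 s,
  generating model `G = 0.75`, `beta = 0.04`;
* focal lesions: a contiguous block of 10–30% of one hemisphere's regions;
  core–core pairs fully severed, partial spillover (spared uniform in
  [0, 0.5]) only on structurally connected pairs — a lesion can only sever
  streamlines that exist — everything else untouched;
* three behaviour domains, each linear in the total-disconnection score
  with negative slope plus Gaussian noise (SD 0.3).

One master seed determines everything; each subject, lesion, and noise draw
uses its own derived stream, so enlarging the patient cohort cannot change
the healthy cohort.

Problem sizes in the test-suite experiments are the package's own choices:
ground-truth GEC recovery uses 20 nodes and 20 subjects; the
linearization-versus-simulation check uses a 10-node system at a deeper
working point (`a = -0.2`), where the linear regime actually holds (at
`a = -0.01` the saturated common mode makes the linear covariance
systematically optimistic — see above); the analytic oscillator checks use
single nodes with `|a|` large enough that the cubic term's variance
correction `~ beta^2 / a^2` sits below the stated tolerances.

## What the synthetic conditions do and do not show

Passing the pipeline's tests shows that the estimation machinery works when
its assumptions hold: frequencies, coupling scale, and effective weights are
recovered from data generated by the model family itself, the lesioned
model predicts lesioned-cohort FC far better than the no-mask and
surrogate-mask controls, z-abnormalities are calibrated on held-out healthy
subjects, and the SDC matrix predicts disconnection-coupled behaviour.

They do not show robustness to the ways real data deviate from the model:
hemodynamic convolution and measurement noise, preprocessing artifacts,
inter-individual variability of the pre-stroke connectome, multi-focal or
graded lesions, or post-stroke reorganization. One consequence is worth
stating explicitly: because patients are generated from the masked
ground-truth GEC, the predictive model's family matches the patient
generator exactly, and prediction accuracy does *not* decline with lesion
severity in the synthetic cohorts — if anything the strong FC contrast of a
large lesion inflates the accuracy correlation. The decline observed in
real cohorts reflects severity-dependent mismatch (e.g. perilesional
dynamics, reorganization) that these conditions deliberately exclude —
altered bifurcation parameters around the lesion are an explicit non-goal.
The accuracy-versus-severity analysis is still computed and reported, but
its sign on synthetic data is not evidence about real data.

## Determinism and reproducibility

Every public entry point that draws randomness takes a seed; `run_study()`
derives all internal seeds from the study seed; the acceptance script
threads its `--seed` through the same path. Two invocations with the same
seed produce identical reports, tables, and JSON output.
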