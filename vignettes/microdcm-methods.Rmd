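---
title: "Model-based assay of cortical microcircuitry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based assay of cortical microcircuitry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdcm)
```

## The problem this package addresses

The auditory mismatch negativity (MMN) — the difference between evoked
responses to rare "deviant" and frequent "standard" tones — is generated by
a bilateral cortical hierarchy of primary auditory cortex (A1), superior
temporal gyrus (STG) and inferior frontal gyrus (IFG). Descriptive MMN
features (peak amplitude, latency) carry little mechanistic information. A
model-based alternative is to fit a biophysical generative model of the
six source timeseries and ask which *circuit parameters* — laminar output
weights, intrinsic gain, inter-regional coupling — differ between groups,
and whether those parameters classify patients better than the evoked
features themselves ("generative embedding"). This matters for dementias
with laminar-specific pathology, where superficial (L2/3) and deep (L5/6)
pyramidal cells degenerate selectively while layer 4 is relatively spared.

`microdcm` implements that full assay as a tested pipeline: a
canonical-microcircuit (CMC) network simulator, variational-Laplace model
inversion, fixed- and random-effects Bayesian model selection over a
21-architecture space, conventional ERP statistics, and a permutation
leave-one-out SVM. Because source-space recordings from the original
clinical cohorts are not publicly deposited, a synthetic-cohort module
generates ground-truth datasets with planted laminar group effects, so
every downstream stage is testable end to end.

## The generative model

### Node dynamics

Each cortical source is a canonical microcircuit of four populations:
superficial pyramidal cells (SP), spiny stellate cells (SS), deep pyramidal
cells (DP) and inhibitory interneurons (II). Each population carries a
membrane voltage $x_v$ and current $x_i$ obeying

$$\dot x_v = x_i, \qquad \dot x_i = K\,U - 2K\,x_i - K^2 x_v,
\qquad U = S d + H + E,$$

where $K$ is the population rate constant, $S d$ the extrinsic drive
(presynaptic firing $d$ weighted by connection gains), $H = G d$ the
intrinsic (within-column) drive, and $E$ exogenous input. Presynaptic
firing is a centred logistic of voltage,
$d(v) = 1/(1+e^{-r(v - v_0)}) - 1/2$, so $d(v_0) = 0$ and the origin is an
exact fixed point of the network — simulations start there, and a
zero-input simulation is identically zero by construction rather than by
tolerance.

Defaults (all overridable in `cmc_node_params()`):

| quantity | value | meaning |
|---|---|---|
| $1/K$ | 2, 2, 28, 16 ms (SP, SS, DP, II) | membrane time constants; DP is the slow population |
| $r$, $v_0$ | 2/3 per mV, 0 mV | sigmoid slope and threshold |
| $G$ | see `cmc_default_G()` | intrinsic coupling, signed |

The intrinsic wiring follows the standard published CMC polarity pattern —
excitatory SS→SP, SS→II and DP→II; inhibitory SP→SS, II→SS and II→DP;
inhibitory self-gain ("decay") on all four populations — with relative
magnitudes 8:4:2:1 across connection classes. The exact layer-specific
magnitudes are not uniquely fixed in the published literature, so this
matrix is an informed reconstruction; its base scale was chosen once so that the
linearised network at default priors has no eigenvalue with positive real
part (verified by test for all 21 architectures) and the impulse response
is a damped oscillation with an ERP-like timecourse.

### Extrinsic connections

Between-node edges obey the laminar rules of hierarchical cortical
circuits: *forward* edges carry SP output to the target's SS and DP;
*backward* edges carry DP output to the target's SP and II. For the
interhemispheric *lateral* edges no canonical laminar rule exists; the
convention adopted here is forward-type targeting (SP → SS+DP)
applied in both directions of the homologous pair. Default edge gains are
6 (forward) and 3 (backward, lateral) — forward-dominant, and inside the
stability region (gain 8 on both destabilises the A1–STG–IFG loop).

### Input and observation model

Exogenous input is a Gaussian bump (onset 60 ms, SD 16 ms) injected into
the granular layer (SS) of both A1s; architectures with a top-down latent
input drive rIFG with the same waveform class at its own onset (120 ms).
A smooth unimodal bump is the conventional waveform choice for
evoked-response modelling.

The virtual-electrode signal of node $k$ is $y_k = L_k \sum_p J_{p}
x_{v,p,k}$: an electrode gain $L$ and laminar contribution weights $J$
with priors $J_{SP} = 0.8$, $J_{SS} = 0.2$, $J_{DP} = 0.2$, $J_{II} = 0$
(three nonzero weights per node), tied across hemispheres so left and
right homologues share one $J$ vector. Observation noise is i.i.d.
Gaussian.

### Parameterisation

All estimable quantities are log-scaling factors around their prior means
(`cmc_priors()`), so positivity is structural: edge gains (block `A`),
deviant-condition modulations (`B`, one shared factor for the modulated
extrinsic edges and one for the modulated SP self-gains), contribution
weights (`J`, 9 free parameters: 3 region pairs × SP/SS/DP, hemisphere
tied), electrode gains (`L`), and intrinsic self-gain scalings (`G`, 12:
3 region pairs × 4 populations, hemisphere tied). Prior variances are
1/8 (`A`, `B`) and 1/16 (`J`, `L`, `G`); blocks not freed are fixed at
zero variance and provably never move.

## Numerical integration

A fixed-step 4th-order Runge–Kutta scheme integrates the 48-dimensional
network over −100…300 ms at `dt = 1` ms, recording at 500 Hz. The
step-halving error at `dt = 1` is ≈ 4 × 10⁻⁵ of the peak signal and
shrinks ~16-fold per halving, as expected at 4th order; `dt = 2` ms (the
"smoke" setting used for bulk fits in the test-suite) stays well inside
the inversion's noise floor. The compiled core (`src/cmc.cpp`) is
allocation-free in the inner loop; one two-condition prediction costs
about 2 ms, which is what makes hundreds of model fits per test run
affordable. Equivalence with an independently coded adaptive-solver
reference is verified on one- and two-node networks to 10⁻⁴ relative
error. Divergent trajectories (|x| > 10⁶) abort with the divergence time.

## Variational-Laplace inversion

`invert()` maximises the free energy
$$F = \langle \log p(y\,|\,\theta,\lambda)\rangle_q
 - KL(q(\theta)\,\|\,p(\theta)) - KL(q(\lambda)\,\|\,p(\lambda)),$$
a lower bound on log model evidence, over a Gaussian posterior
$q(\theta)$ by Levenberg–Marquardt-regularised Gauss–Newton ascent:
response Jacobians by central differences (step 10⁻³), candidate steps
accepted only if they increase $F$ (rejected steps shrink the trust
region), so the recorded $F$ trace is non-decreasing by construction. A
single noise log-precision hyperparameter $\lambda$ (Gaussian hyperprior,
mean 0, variance 16) is updated by Newton steps inside the same loop.
Convergence: improvement < 0.01 nat over two accepted iterations, cap 64
iterations; a stalled trust region after at least one accepted step also
counts as converged. On a linear-Gaussian toy model with known noise the
bound is tight and `free_energy()` reproduces the closed-form log
evidence to 10⁻⁶ — the key correctness anchor for model comparison.

Fitting is done jointly over both conditions, with the deviant-specific
gain modulations applied to the connections flagged by the architecture's
modulation masks. The data enter as the per-condition average ERPs of the
six virtual electrodes; no spatial-mode reduction is applied (those are
sensor-space devices, inapplicable to six source channels). The
two-analysis scheme is `invert_two_pass()`: pass 1 frees `A`, `B`, `J`,
`L`; pass 2 fixes `J`/`L` at their pass-1 posteriors and frees the
intrinsic self-gains `G`.

## The 21-model space

`build_model_space()` enumerates the candidate architectures as a product
of four axes: left-IFG connectivity, interhemispheric lateral edges, a
top-down latent input to right IFG, and which connection classes
(forward / backward / lateral-or-self) carry the deviant modulation (six
combinations). The published family memberships pin the axes down
exactly: models 7, 8, 10–13, 15, 16, 18–21 contain left IFG; models 9 and
17 carry interhemispheric edges; model 14 alone has the rIFG latent input
and is otherwise identical to model 6; every model drives bilateral A1.
The per-id assignment of modulation combinations within those families is
not uniquely determined by the membership constraints and is therefore a
documented convention here; such models carry `reconstructed = TRUE` in
the manifest (`write_model_space()`), and nothing in the selection logic
depends on the unpinned assignments.

## Bayesian model selection

* **FFX** (`ffx_compare()`): posterior model probabilities are the softmax
  of log evidences summed over subjects.
* **RFX** (`rfx_compare()`): variational Dirichlet estimation of
  population model frequencies (prior count 1 per model); exceedance
  probabilities by 10⁵ Dirichlet draws (seeded).
* **Families** (`family_compare()`): prior mass equalised across families
  regardless of size (FFX: rescaled model priors; RFX: rescaled Dirichlet
  counts); family EPs aggregate member frequencies within each draw.
* **Greedy search** (`greedy_family_search()`): level 1 left-IFG, level 2
  interhemispheric within the winner, level 3 rIFG input; both FFX and
  RFX are reported at each level, the RFX family EP decides, exact ties
  are reported as ties and stop the descent. Levels whose partition does
  not intersect the candidate set (e.g. when running on a reduced model
  subspace) are reported as degenerate and skipped.
* **Leave-one-out BMS** (`loo_bms_permutations()`): "leave-one-out with
  replacement" is interpreted as: per permutation, hold out one uniformly
  drawn subject, independently across permutations; rerun model-level BMS
  on the remainder and tally the winner.

## ERP features and group statistics

`difference_wave_peaks()` takes the deviant − standard difference wave
and reports the extremum of largest magnitude in the analysis window plus
its latency, earliest sample winning ties. Two window presets are
shipped because the source conventions differ between uses: 80–200 ms for
per-node mismatch features, 80–300 ms when averaging across the six
sources for the condition-level analysis. The group × condition (2 × 2)
analysis uses a mixed-design ANOVA (`aov` with a within-subject error
stratum) plus paired post-hoc t-tests per group. Parameter-level group
tests (`parameter_group_tests()`) run a group × parameter ANOVA followed
by per-parameter independent t-tests, *uncorrected* — matching the
reporting convention for these laminar hypotheses — with an optional FDR
column off by default.

## Classification

`loo_svm_permutation()` uses a linear SVM (libsvm via `e1071`), cost 1,
features z-scored by training-fold statistics, one uniformly drawn
held-out subject per permutation. Confusion counts are percentages of
permutations (so TP + TN + FP + FN = 100 and each class caps at 50 on a
balanced cohort); accuracy, PPV, NPV, sensitivity and specificity follow
the usual identities exactly. Three feature sets mirror the study design:
`V` (extrinsic coupling strengths + condition modulations), `J` (the nine
hemisphere-tied laminar contribution weights) and `ERF` (six per-region
mismatch amplitudes).

One methodological subtlety is documented here because it is easy to get
wrong: leave-one-out on a *single fixed* label assignment of an exactly
balanced null table does not sit at 50% — it sits well below (≈ 35% at
n = 40 with 6 noise features). Two mechanisms combine: the held-out
subject's own-class training statistics exclude it (its class mean is
anti-correlated with its features, coefficient −1/(n_c−1)), and the
training fold is always one subject short in the held-out class. The
calibrated chance level is obtained with the standard permutation test —
labels re-permuted uniformly at random before every iteration
(`null_permute = TRUE`) — together with inverse-frequency class weights
per training fold (`class_weights = "inverse"`), which removes the
residual majority lean. Under that null the accuracy is 50% within
binomial error (verified by test); the group analyses themselves keep the
fixed-label, unweighted convention.

## The synthetic cohort

`make_cohort()` + `simulate_cohort()` generate everything the real study
measured, with these defaults:

* **Design**: 40 controls vs 33 patients (the analysed cohort sizes);
  the oddball schedule (`make_paradigm()`) reproduces the multi-deviant
  design exactly — 75 ms tones, 500 ms tone-onset-asynchrony, three
  5-minute blocks giving 900 standards and 900 deviants, five deviant
  dimensions in equal proportion. Deviant subtypes are collapsed into one
  "deviant" condition for modelling; per-subject *average* ERPs are
  synthesized, since that is what the inversion fits.
* **Between-subject variability**: every log-scaling parameter jittered
  with SD 0.125 — about ±13% parameter spread, a realistic inter-subject
  range for evoked-response model parameters.
* **Mismatch generation**: all subjects share baseline deviant
  modulations, `B.extrinsic = +0.4` and `B.self = −0.4`. The negative
  self term models deviance detection as a transient *disinhibition* of
  superficial pyramidal cells (the predictive-coding gain increase on
  unexpected input). The sign matters: with it, the planted patient
  increase in STG SP self-gain shunts the mismatch and the patient-group
  mean MMN comes out attenuated — the group-level phenomenon the cohort
  must emulate; with a positive self modulation the same planted effects
  *amplify* the MMN instead.
* **Planted patient effects** (±0.4 log units): STG deep-pyramidal
  contribution `J.STG.DP` down; STG superficial self-gain `G.STG.SP` up
  (faster decay, hypoactive superficial temporal cortex); A1 deep
  self-gain `G.A1.DP` down (more stable deep firing) — the three reported
  laminar abnormalities, in their reported directions.
* **Observation noise**: SD 0.02 on the average ERPs (peak signals are
  order 1), i.i.d. Gaussian. No public SNR exists for the source-space
  averages; this value is calibrated so that the control-group mismatch
  is robust at n = 40 while the *group difference* in ERF amplitude is
  invisible to a t-test at n = 10/group yet strongly detectable in the
  generating J parameters at the same n — the regime in which
  generative embedding should beat amplitude features, which is the
  qualitative ordering the classification tests check.

What the generator does **not** emulate: real MEG noise structure
(correlated sensor noise, source leakage between nearby regions),
artifacts, coregistration error, trial-level variability (trials exist
only in the schedule; noise on averages scales implicitly), deviant
subtype differences, or disease heterogeneity. Passing tests therefore
demonstrate the *internal* validity of the pipeline — parameters are
recoverable, model selection finds the generating architecture, planted
laminar effects are detected in the right places with calibrated false
positives — not that real recordings would yield the same effect sizes.

## Problem sizes and seeds

The test-suite runs everything at desk scale, as a deliberate design
choice: smoke fits use `dt = 2` ms with 4–24 Gauss–Newton iterations;
model recovery uses 10 cohorts of 12 subjects over the {6, 9, 14}
subspace (the three families of the greedy search each keep a
representative); classification ordering uses 12 + 12 subjects and 1000
permutations; null calibrations use 1000–2000 replicates. Every
stochastic routine takes an explicit seed and records it in its output;
the pipeline (`run_pipeline()`) derives per-stage seeds deterministically
from one global seed, caches stage artifacts, and reruns bit-identically.

## Known limitations

* The intrinsic coupling magnitudes and the models-1–6 modulation
  assignments are documented reconstructions (flagged in code and
  manifest), not published values.
* `J` and `L` multiply the same signal, so their product is better
  identified than either factor; hemisphere ties and priors regularise
  this, but recovered `J` group differences are shrunk relative to truth
  (visible in the classification tests: J-feature accuracy on synthetic
  cohorts is well above ERF accuracy but below the near-perfect in-sample
  separation of the generating parameters).
* The inversion optimises a single mode; no multistart or MCMC
  alternative is provided.
* Serialization uses CSV/JSON/YAML text formats throughout.
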