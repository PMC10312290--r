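---
title: "Methods: cortico-cerebellar task connectivity and activity flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortico-cerebellar task connectivity and activity flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ccflow` implements a complete analysis chain for block-design dual-task fMRI
of the cortico-cerebellar system on parcellated BOLD signals (400 cortical
parcels carrying one of seven canonical resting-state network labels, 28
cerebellar parcels carrying lobule labels). This vignette documents the
models, the tunable parameters, the synthetic-data generator used for
validation, and the numerical and design choices that were genuinely open.

## Activation model

Each trial type (balance, calculation, dual task) is modelled as a boxcar at
its event onsets convolved with a canonical double-gamma haemodynamic
response (peak delay 6 s, undershoot delay 16 s, undershoot ratio 1/6,
sampled at the repetition time and scaled to unit peak; `canonical_hrf()`).
Ordinary least squares per parcel yields condition-wise beta maps
(`fit_glm()`); a trial-level variant with one regressor per trial supports
the analyses that operate trial by trial. No autoregressive noise model or
nuisance-regressor suite is fitted: the package targets data whose slow
confounds have been handled upstream, and the synthetic cohorts have white
temporal noise by construction.

The task decoder (`fit_decoder()`) stacks the per-subject balance and
calculation beta maps, demeans each parcel across the stacked observations,
and takes the leading principal component. Its sign is fixed so the loading
correlates positively with the group-mean (calculation − balance) contrast;
dual-task maps are projected onto it after subtracting the training means,
and the projections are tested against zero with a one-sample t test
(`project_dual()`): positive values indicate calculation-like, negative
balance-like dual-task activation.

The proportion of cerebellar observations with positive beta is compared
across conditions with a Pearson chi-square on the 3 × 2 contingency table
(df = 2). The counting unit is ambiguous in principle (parcels vs
parcel-by-subject observations); `positive_beta_test()` therefore takes the
table explicitly, and the pipeline counts parcel-by-subject observations.

## Time-varying connectivity (MTD)

Coupling between parcels i and j is the multiplication of temporal
derivatives: first differences of each series are divided by their
whole-series standard deviation (not per window — this matches the printed
formula and makes the score invariant to linear rescaling of either input),
multiplied pairwise, and smoothed with a simple moving average of `window`
frames (default 20). Two window conventions circulate; the formula as
usually printed sums forward from t, so `align = "forward"` is the default
and a trailing (causal) average is available. Either way the valid series
has `frames − window` samples. Constant signals raise an error naming the
parcel rather than producing silent NaNs.

The cortico-cerebellar edge set (400 × 28 = 11,200 edges) is the default
subset. Edge-wise GLMs reuse the design matrix cropped to the MTD-valid
samples. Dual-task trials are split into correct (accurate calculation AND
balance RMS error strictly below the population median — ties count as
incorrect) versus incorrect, and edges are contrasted between the groups
with a two-sample t statistic whose p value comes from label permutations
with the add-one estimator p = (b + 1)/(n\_perm + 1), so p is never zero.
Significant effects are summarised on a 10-lobule × 7-network grid with
hemispheres pooled and vermal edges excluded.

## Network topology

Condition-wise graphs are time-averaged MTD matrices over all parcels,
restricted to the MTD samples whose window centre falls inside that
condition's trials shifted by a haemodynamic lag (5 s by default — the value
is a package choice; it approximates the canonical response peak). The
average is computed through the identity
mean\_t MTD(t) = t(D) (D · m), with D the normalised derivatives and m the
per-sample window-overlap weights, so the full edge-by-time tensor is never
materialised.

Community structure maximises signed modularity with asymmetric weighting:
the positive term is normalised by the total positive weight and the
negative term additionally down-weighted by the negative share of total
weight. One published verbal gloss describes the null term e\_ij as "the
strength of a connection divided by the total weight of the network"; that
reading conflicts with the degree-based null of the reference brain
connectivity toolbox, and the standard degree-based null
e±\_ij = s±\_i s±\_j / v± is implemented, with the resolution parameter
gamma multiplying the null term. The optimiser is a Louvain algorithm on the
dense signed modularity matrix (compiled code), restarted `n_runs` times;
restarts alternate between agglomerative (singleton) starts with random
node orders and random-partition starts — pure singleton-start agglomeration
is measurably biased away from some optima on small frustrated signed
graphs — and every restart is refined by single-node best-move sweeps. The
consensus re-clusters the module co-assignment agreement matrix (threshold
0.5) until all runs coincide, then applies a Kernighan–Lin refinement
(single-node moves, pairwise cross-community swaps, community merges) on
the original graph; by construction the returned consensus never scores
below the best individual restart. Resolution stability (`gamma_stability()`) reports, per
gamma in 0.5–2.5 (step 0.1, a package choice), the mean pairwise Pearson
correlation of co-assignment vectors across repeated runs.

The participation coefficient PC\_i = 1 − Σ\_s (k\_is / k\_i)² uses positive
weights only; nodes with zero positive strength are assigned PC = 0. The
pipeline computes PC on condition-wise time-averaged graphs; a windowed
variant is available through `mtd_window_matrix()`, which returns the
instantaneous coupling matrix at a single window position. Mean PC
per subject and condition feeds a one-way ANOVA (and a repeated-measures
variant with subject as error stratum, since it is ambiguous whether
subject-condition means should be treated as independent; both are
reported), parcel-wise paired t tests with Benjamini–Hochberg control at
q = 0.05, and the correlation of the group-mean dual-task PC map with the
average of the two single-task maps.

## Activity flow through structural connectomes

Directed tract weight matrices CPC (cortex → cerebellum) and CTC
(cerebellum → cortex) carry log10(streamline count + 1) weights — the +1
keeps absent connections at weight zero rather than minus infinity. The
anatomically consistent direction convention is used throughout: CPC
predicts cerebellar patterns from cortical betas, CTC predicts cortical
patterns from cerebellar betas (printed equation labels sometimes swap the
two; the surrounding anatomy fixes the reading adopted here). Predictions
are weight-mixed sums evaluated against observed patterns by Pearson
correlation; the permutation null shuffles the rows (source assignment) of
the weight matrix — preserving each source's weight profile rather than
destroying the weight distribution — and p uses the add-one estimator.
Per-trial prediction correlations are Fisher-z transformed before the
correct-versus-incorrect t test. No temporal lag enters the prediction: the
flow model relates within-trial beta patterns.

## The synthetic cohort generator

The generator emulates the study conditions: 12 blocks per run, each with
one balance, one calculation and one dual trial (15 s each, a package
choice consistent with a four-beep serial-subtraction trial) in random
order, followed by 15 s rest; TR 0.7 s; 400 + 28 parcels; 20 subjects by
default. The balance disturbance is a sum of 15 sinusoids with log-uniform
frequencies in 0.025–1 Hz, random phases, 1/sqrt(f) amplitude weighting
(postural sway spectra are low-frequency dominated), rescaled to a ±30°
peak; the upright avatar target is a configurable constant (90° by
default).

The forward model plants every statistical structure the downstream stages
estimate:

* **Activation.** Per-condition intrinsic maps assign amplitudes by network
  (balance: sensorimotor; calculation: frontoparietal/default; dual: an
  attenuated superposition) and by cerebellar lobule (anterior lobe + VIII
  vs Crus I/II), plus a condition-specific cerebellar baseline that drives
  the positive-beta proportions. Amplitudes are O(1) signal units against
  noise SD 1 — a moderate single-trial SNR typical of block designs.
* **Connectome.** Streamline counts are lognormal with multiplicative
  source- and target-parcel strength factors (tractography counts are
  hub-dominated) and ~30% absent connections, then log10(count + 1)
  weighted. The hub heterogeneity keeps the leading mode of the weight
  composition well away from a flat profile, which the coupling
  construction below relies on.
* **Structure–function coupling.** Simultaneous bidirectional coupling has
  an exact fixed point only along the leading (Perron) mode of the
  composition t(CTC) t(CPC); condition patterns therefore blend the
  intrinsic maps with this structure-consistent pair at coupling strength
  kappa, which makes the activity-flow closure exact at kappa = 1 without
  noise and expected prediction correlation monotone in kappa. The pair is
  scaled (never centred) so flow predictions remain exactly proportional.
  Cerebellar intrinsic maps additionally inherit a 0.5-SD component of the
  CPC-projected cortical map, emulating mossy-fibre drive of cerebellar
  BOLD; this is what makes matching-condition predictions outperform
  non-matching controls.
* **Behaviour.** Dual-trial coupling is jittered (SD 0.1 around kappa;
  disabled at the degenerate kappa = 0 or 1 so noiseless closure tests are
  exact, and only on dual trials so the single-task PCA decoder is not
  contaminated by coupling variance). Correctness is Bernoulli with a
  logistic link in the trial's coupling (slope `behaviour_link`, baseline
  65% correct); balance RMS error is lognormal with log-mean decreasing in
  the trial's coupling. Correct dual trials therefore carry genuinely higher
  coupling — the effect the accuracy-stratified flow contrast recovers.
* **Modular noise.** Gaussian noise is built from a global factor, a
  module factor and a parcel-unique factor, giving within-module pair
  correlation 0.35 and a condition-dependent between-module correlation
  (0.05 balance, 0.15 dual, 0.25 calculation) on frames inside the
  (lag-shifted) trial windows. Raising between-module correlation raises
  integration, planting the participation ordering
  balance < dual < calculation at unchanged module recoverability.
* **Motion.** Random-walk realignment parameters calibrated to a mean FD
  near 0.13 mm with an essentially sub-threshold tail, emulating a
  compliant cohort where the 10% exclusion rule trips for no one.

What the generator does **not** emulate: voxel-level spatial structure,
physiological (cardiac/respiratory) noise, scanner drift, autocorrelated
BOLD noise, subject-level anatomical variability in the connectome, or
nonlinear neurovascular coupling. Passing recovery tests therefore show the
estimators are correct and calibrated under the planted statistical
structure, not that real acquisitions meet these assumptions.

## Numerical choices and degenerate inputs

* FD converts rotations to arc length on a 50 mm sphere (the conventional
  constant); DVARS is expressed as percent of the grand mean signal so the
  2.5% threshold is meaningful on arbitrary units. Threshold comparisons
  are strict (>), and the first frame of both series is defined as 0.
* All permutation p values use (b + 1)/(n\_perm + 1).
* Zero-variance inputs raise typed errors (`ccflow_degenerate_input`)
  rather than propagating NaN: constant parcels in MTD, constant vectors in
  correlations, all-zero graphs, zero-variance decoder input.
* Benjamini–Hochberg control uses the standard step-up rule via
  `p.adjust`; on p = {0.01, 0.02, 0.04, 0.5} at q = 0.05 exactly the first
  two are rejected (thresholds k/4 × 0.05).
* Module labels are relabelled to contiguous integers from 1; modularity
  and PC are invariant to label permutation, which the tests assert.
* All stochastic steps take explicit seeds; per-stage seeds derive from one
  master seed, and regenerating with the same seed is bit-identical.

## Validation problem sizes

The test suite and the acceptance script validate at deliberately reduced
problem sizes chosen as the package's own trade-off between statistical
resolution and turnaround: exhaustive modularity enumeration on graphs of
up to 8 nodes (the largest size where full enumeration is comfortable),
permutation calibration with 1,000 null cohorts at 200 permutations, MTD
limiting values at 10,000 frames, and 20 replicates of the 20-subject
default cohort for end-to-end recovery with 15 consensus restarts per
condition (the planted module structure is recovered reliably at this
count; the 500-restart default remains for real analyses).

## Known limitations

* Signed Louvain with consensus is deterministic given a seed but, like all
  modularity maximisation, only guaranteed optimal where enumeration can
  verify it (small graphs).
* The condition assignment of MTD samples uses a fixed haemodynamic lag
  rather than deconvolution; windows spanning condition boundaries are
  weighted by their overlap. Whether motion-flagged frames should be
  censored from MTD windows is an open methodological question (cohorts
  passing the exclusion rule rarely have many); a `censor` switch on
  `mtd_condition_matrices()` (pipeline key `qc.censor`) drops windows
  overlapping flagged frames, off by default.
* The edge-wise permutation contrast pools dual trials across subjects and
  permutes trial labels freely; it does not model within-subject clustering
  of trials.
* The chi-square on parcel-by-subject observations treats observations as
  independent; spatial correlation between parcels makes the test
  anti-conservative on real data, which is why the pipeline also reports
  the underlying proportions.
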