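# ccflow

Cortico-cerebellar task connectivity and activity-flow analysis for
block-design dual-task fMRI.

Dual-task experiments — balancing a virtual avatar while performing serial-7
subtractions — probe how the cerebral cortex and cerebellum coordinate
parallel processing. `ccflow` implements the complete systems-level analysis
chain for such studies on parcellated BOLD time series (400 cortical + 28
cerebellar parcels by default):

* **Activation mapping** — block-design GLM with a canonical double-gamma
  HRF, per-condition beta maps β, and a PCA task decoder: the leading
  principal component λ of the demeaned balance/calculation beta maps,
  against which dual-task maps are projected (dot product, one-sample *t*).
* **Motion QC** — framewise displacement
  FD(t) = Σ|Δd| + r·Σ|Δθ| (r = 50 mm) and DVARS in % of mean signal, with
  the strict FD > 0.25 mm / DVARS > 2.5% frame flags and the 10% exclusion
  rule.
* **Time-varying connectivity** — multiplication of temporal derivatives,
  MTD_ijt = (1/w) Σ_t (dt_i dt_j)/(σ_i σ_j), over the 400 × 28 = 11,200
  cortico-cerebellar edges, edge-wise GLMs, and permutation contrasts of
  correct vs incorrect dual-task trials summarised on a 10-lobule ×
  7-network grid.
* **Network topology** — signed modularity
  Q = (1/v⁺) Σ (w⁺ − γe⁺) δ − 1/(v⁺+v⁻) Σ (w⁻ − γe⁻) δ maximised by a
  consensus Louvain algorithm (compiled core, 500 restarts, agreement-matrix
  consensus with fine-tuning, γ-stability sweep 0.5–2.5), and the
  participation coefficient PC_i = 1 − Σ_s (k_is/k_i)² contrasted across
  conditions (ANOVA, paired *t* with FDR q = 0.05).
* **Activity flow** — structure-informed prediction of cerebellar patterns
  from cortical betas through the cortico-ponto-cerebellar tract (CPC) and
  of cortical patterns through the cerebello-thalamo-cortical tract (CTC),
  A = Wᵀ·β with log10(streamline+1) weights, Pearson evaluation,
  row-permutation nulls, and accuracy-stratified comparisons on Fisher-z
  transformed correlations.
* **Synthetic cohorts** — a generator that plants condition-specific
  activation maps, modular noise correlation, structure-function coupling of
  strength κ, and coupling-linked behaviour as recoverable ground truth; all
  validation rests on it.

## Worked example

Simulate and analyse a small cohort (8 subjects, 100 + 14 parcels, 8
blocks) end to end:

```r
library(ccflow)
cfg <- default_pipeline_config(
  sim.n_subjects = 8, sim.n_cortical = 100, sim.n_cerebellar = 14,
  sim.n_blocks = 8, topo.n_runs = 25, perm.n_edge = 200, perm.n_flow = 200,
  out_dir = "ccflow-demo", seed = 1, log_level = "quiet")
report <- run_pipeline(cfg)
report
#> <cc_report>
#>   qc: mean FD 0.125 mm, 0 excluded
#>   glm: decoder projection t = 2.76 (p = 0.028)
#>   topology: mean PC balance 0.670, calculation 0.707, dual 0.693
#>   actflow: accuracy effect t (cbm) = 5.45, t (ctx) = 5.49
#>   recovery: beta TRUE, PC order TRUE, kappa effect TRUE
```

Reading the output: no subject exceeded the motion-exclusion rule; the
dual-task beta maps project calculation-ward on the balance-vs-calculation
decoder in this draw (*t* = 2.76); group-mean participation recovers the
planted integration ordering balance < dual < calculation (0.670 < 0.693 <
0.707), i.e. the dual task sits between the segregated balance and
integrated calculation states; and flow predictions are better on correct
than incorrect dual-task trials in both directions (*t* ≈ 5.5), the planted
coupling-behaviour link. The `recovery` line compares each of these against
the generator's ground truth. Per-condition flow correlations with
permutation p values are in `report$actflow$condition`:

```r
subset(report$actflow$condition, direction == "cbm_to_ctx")
#>     regressor  direction         r           p
#> 2     balance cbm_to_ctx 0.9360599 0.014925373
#> 4 calculation cbm_to_ctx 0.9377606 0.004975124
#> 6        dual cbm_to_ctx 0.9335114 0.004975124
```

A command-line wrapper with subcommands (`simulate`, `qc`, `glm`, `tvfc`,
`topology`, `actflow`, `run`, `report`) is provided:

```sh
Rscript inst/cli/ccflow.R run --config analysis.cfg --seed 1 --out results/
```

with a flat `key = value` configuration file (see
`?read_pipeline_config`).

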