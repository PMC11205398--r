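# nmrxai

Explainable neural-network metabolite profiling from ¹H-NMR spectra.

MLPs can regress analyte concentrations straight from an NMR mixture
spectrum, but give no account of *which* spectral points a prediction
rests on. `nmrxai` closes that gap for a simulated aqueous-metabolite
setting. It provides, end to end:

- **Spectral simulation** — Lorentzian multiplet synthesis of per-mM
  basis spectra for a built-in eight-metabolite panel (taurine, choline,
  creatine, lactate, niacinamide, alanine, valine, glutamine) plus a
  maleic acid quantitative reference fixed at 13.3 mM; mixture generation
  with concentrations uniform in 1–50 mM; and experimental-like
  augmentation (line broadening 0.1–1 Hz, per-analyte shifts up to
  3.4 ppb, noise up to 1.3% and baseline offsets up to 7.5% of the
  reference peak height, and up to three randomly placed interfering
  singlets). Reading/writing two-column text and JCAMP-DX spectra.
- **An MLP regressor** — one hidden layer (default 200 nodes; inputs one
  per grid point, linear mM outputs), trained with Adam on MSE,
  best-test-loss checkpointing, fully seeded.
- **An integrated-gradients engine** — per-datapoint attribution scores
  for each output node,

  IG_i = (x_i − x′_i) · (1/m) Σ_k ∂F(x′ + (k/m)(x − x′)) / ∂x_i,

  against a *reference-only baseline* x′ (maleic acid at 13.3 mM, the
  natural "zero analytes" input). Scores are in mM; the completeness
  identity Σ IG_i = F(x) − F(x′) is monitored and the step count m is
  refined until the residual gap is below tolerance.
- **Attribution analyses** — attribution totals vs. predictions (MAPD),
  half-open ppm region-of-interest sums, cross-analyte overlap
  compensation matrices, audits of attribution assigned to inserted
  non-analyte singlets, and cosine-similarity bias flags for output
  nodes that attribute from identical evidence.
- **Experiment drivers** — completeness, overlap-compensation and
  training-regime-comparison studies at `ci`, `desk` and `full` scales.

## Worked example

Train a desk-scale model on noiseless simulated mixtures and ask where
its concentration estimates come from:

```r
library(nmrxai)

cfg <- experiment_config("desk", seed = 1)
study <- run_completeness_study(cfg)   # trains the MLP, attributes the
                                       # 25 / 5 / 1 mM equimolar fixtures
round(study$mapds, 4)
#> equimolar_25  equimolar_5  equimolar_1
#>       0.0000       0.0019       0.0103
study$reports$equimolar_1$per_node[, 1:4]
#>         node attribution_total prediction percent_diff
#>      taurine           0.99994    1.00000       0.0065
#>      choline           0.99984    0.99999       0.0149
#>     creatine           0.99983    0.99999       0.0154
#>      lactate           0.99987    1.00000       0.0130
#>  niacinamide           0.99987    0.99998       0.0111
#>      alanine           0.99999    0.99998       0.0007
#>       valine           0.99983    0.99997       0.0141
#>    glutamine           0.99993    1.00000       0.0071
```

Each node's attribution scores sum to its predicted concentration to a
few hundredths of a percent — so the per-datapoint scores can be read as
mM contributions. The cross-analyte ROI matrix then shows *how* the model
quantifies: positive attribution at an analyte's own resonances, and
negative attribution at the non-overlapping resonances of an overlapping
partner (glutamine/alanine near 3.7 ppm, taurine/choline near 3.1 ppm),
the model's mechanism for subtracting shared signal:

```r
ov <- run_overlap_study(cfg, model = study$model)
subset(ov$compensation, fixture == "equimolar_25")[, 2:4]
#>       node   partner    sum
#>    alanine glutamine -3.046
#>  glutamine   alanine -2.299
#>    taurine   choline -6.712
#>    choline   taurine -3.187
```

On the six-analyte fixture (glutamine and taurine absent) those negative
sums collapse towards zero (−0.067 and −0.166 mM for the absent
partners) — compensation appears only when there is an overlapping
partner to compensate for. A third study,
`run_regime_comparison()`, contrasts a model trained on clean spectra
(which misattributes inserted non-analyte singlets to nearby analytes,
tens of mM) with one trained on augmented spectra (which rejects them,
|sums| well under 1 mM).

A thin CLI over the same functions lives in `inst/cli/nmrxai`
(`simulate`, `train`, `attribute`, `report`, `experiment`).

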