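---
title: "Explainable MLP metabolite profiling from simulated 1H-NMR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable MLP metabolite profiling from simulated 1H-NMR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrxai)
```

## The problem

Neural networks can regress analyte concentrations directly from ¹H-NMR
mixture spectra, but a trained multi-layer perceptron (MLP) is opaque: it
gives no account of *which* spectral points drive a predicted
concentration. `nmrxai` makes that account quantitative. It couples

1. a simulator for mixture spectra of a small aqueous metabolite panel,
   with augmentations mimicking experimental variation;
2. an MLP regressor mapping a spectrum (one input node per grid point) to
   per-analyte concentrations in mM; and
3. an integrated-gradients (IG) attribution engine with a
   reference-compound-only baseline, plus analyses that audit the
   resulting attribution scores.

## Spectral model

Spectra live on a uniform chemical-shift grid (default 0.48–9.52 ppm at a
400-MHz proton frequency, so 1 ppm = 400 Hz). Every resonance line is
Lorentzian — the lineshape of a Fourier-transformed exponentially decaying
FID:

$$L(\delta) = A\,\frac{\gamma/\pi}{(\delta-\delta_0)^2+\gamma^2},
\qquad \gamma = \tfrac{1}{2}\,\mathrm{FWHM}.$$

Multiplets are sets of Lorentzians spaced by the coupling constant $J$
with binomial weights (1; 1 1; 1 2 1; 1 3 3 1). A *basis spectrum* is the
1 mM spectrum of one analyte; its integral equals a calibration constant
(default 1 intensity·ppm per proton per mM — arbitrary units, only ratios
matter) times the proton count. Quantum-mechanical second-order effects
(strong coupling) are out of scope; multiplets are first-order.

The built-in panel holds eight metabolites — taurine, choline, creatine,
lactate, niacinamide, alanine, valine, glutamine — plus maleic acid (a
2-proton reference singlet at 6.01 ppm, present at 13.3 mM in every
mixture) and an acetic acid singlet used as the generic interfering
signal. Shifts are approximate literature values, arranged so that the
panel exhibits two deliberately overlapping pairs (taurine/choline near
3.1 ppm, glutamine/alanine near 3.7 ppm), an isolated valine methyl near
0.70 ppm, and four well-separated niacinamide aromatic lines. These are
simulation fixtures, not reference data for any real spectrometer.

## Dataset recipes

`generate_dataset()` draws analyte concentrations uniformly from 1–50 mM.
Half of the pool keeps all analytes; in the other half each analyte is
independently left out (set to exactly 0) with probability 0.5, so the
model sees absence as well as presence. The pool is split 80:20 into
train and test; a separate all-analytes validation split is generated.
All spectra are normalized by one constant — the maximum intensity over
train ∪ test — so that maximum is exactly 1.

The *simulated* recipe emits exact noiseless mixtures. The
*experimental-like* recipe perturbs each spectrum, in a fixed order:

| augmentation | magnitude (uniform per spectrum) | units |
|---|---|---|
| rigid per-analyte shift | 0–3.4, random sign | ppb |
| line broadening | 0.1–1.0 | Hz |
| interfering singlets | 0–3 singlets, scale 1–50 | mM-equivalent |
| baseline offset | 0–7.5% of reference peak height | intensity |
| Gaussian noise sd | 0–1.3% of reference peak height | intensity |

Three sampling choices were genuinely open and are package decisions: the
noise sd and baseline offset are drawn uniformly up to their stated
maxima (only maxima are physically specified); shifts get a random sign
per analyte; the singlet scale range mirrors the analyte concentration
range; and one broadening value is applied to the whole mixture, matching
whole-spectrum apodization. "Mean-magnitude" noise, used for noisy
fixtures and the mean-noise baseline, is half the maximum sd (the mean of
the uniform draw), realized once with a recorded seed.

Augmentations not involving noise or baseline are integral-preserving:
broadening is circular convolution with a unit-sum Lorentzian kernel, and
shifting is a Fourier-domain phase ramp that is sub-gridpoint accurate.
One numerical caveat: phase-ramp shifts are exactly invertible only for
band-limited content. A spectrum with significant Nyquist-bin energy —
unresolved spikes, or a strong intensity step between the window edges —
loses a small amount of precision per shift, because the Nyquist
component of a real signal can only be scaled by cos(πd), exactly as in
the common scipy-style implementation. Resolved lines away from window
edges invert to below 1e-9.

## The MLP and its training

The regressor is a fully connected network — by default one 200-node
hidden layer between `n_points` inputs and 8 linear outputs (the output
count is configurable, e.g. 18 for a lipid-parameter panel). Outputs
carry no activation and no non-negativity clamp, so over- and
under-estimates are representable. Choices the architecture description
leaves open, fixed here: ReLU hidden activation (standard for MLP
regression, and piecewise linearity makes attribution behavior easy to
reason about); scaled-uniform fan-in initialization,
U(−1/√fan_in, 1/√fan_in), seeded and deterministic.

Training minimizes mean squared error in mM² with Adam, batch size 128,
evaluating the test split each epoch and returning the checkpoint with
the lowest test loss. The base learning rate defaults to 1e-3 with a
cosine decay to zero; the experiment profiles use 3e-3. This is
deliberately hotter than typical defaults: the scaled-down problems are
noiseless and near-linear, and the quantity the attribution analyses
depend on — the model's prediction on the analyte-free baseline spectrum
— only approaches zero when optimization is pushed well past the point
where the test loss merely looks converged. A timid constant rate leaves
the baseline prediction, and with it the attribution-sum agreement,
orders of magnitude worse for the same epoch budget.

## Integrated gradients

For output node $F$ and baseline $x'$, the attribution of input point $i$
is

$$\mathrm{IG}_i = (x_i - x'_i)\,\frac{1}{m}\sum_{k=1}^{m}
\frac{\partial F\!\left(x' + \tfrac{k}{m}(x - x')\right)}{\partial x_i},$$

a Riemann approximation of the path integral of the gradient along the
straight line from $x'$ to $x$ (a midpoint rule, $(k-\tfrac12)/m$, is
available). The baseline is the natural "no analytes" input for this
domain: a spectrum containing only the quantitative reference at
13.3 mM — noiseless for models trained on clean data, with one seeded
mean-magnitude noise realization for augmentation-trained models.
Because the model outputs mM and attributions are computed in
normalized-input coordinates whose effect is absorbed into the gradient,
scores are directly in mM per datapoint, and the completeness identity

$$\sum_i \mathrm{IG}_i = F(x) - F(x')$$

lets attribution sums be read as predicted-concentration contributions.
The residual of this identity (the *completeness gap*) is the engine's
convergence diagnostic: by default `m` starts at 128 and doubles until
every node's gap is below tolerance (cap 4096). For a one-hidden-layer
network the per-step gradients collapse to a single masked matrix
product, so the whole path costs one forward pass over `m` points — this
is why attribution here is cheap even at `m` = 4096.

Exact properties used as test oracles: for linear models the scores equal
$w_i (x_i - x'_i)$ for any `m` and the gap is zero; a feature with
$x_i = x'_i$ scores exactly zero; for ReLU networks the left-Riemann
error decays like 1/m with a constant set by the density of activation
crossings along the path — so a coarse fixed grid (say m = 64) is
typically a few tenths of a percent off a dense-oracle reference, and
tolerance-driven refinement is what actually buys 1e-3-relative accuracy.

## Attribution analyses

*Totals and MAPD.* Per node, the attribution total is compared with the
predicted concentration as a percent difference; the mean over nodes
(MAPD) is the headline faithfulness figure. Since
$\sum_i \mathrm{IG}_i = F(x)-F(x')$ up to the gap, MAPD is governed by
$|F(x')|$: how close the trained model comes to predicting exactly zero
analyte on the reference-only baseline.

*ROIs.* Regions of interest are half-open ppm windows `[lo, hi)`
(lower-inclusive, so partitions add exactly). Per-analyte ROI sets are
derived programmatically as the contiguous regions where the analyte's
unit basis exceeds a fraction of its maximum — no hand-tuned windows, and
they adapt to the panel's shift table and linewidth. The default fraction
is 1%; the scaled-down study profiles raise it (3% desk, 5% ci) because
Lorentzian support widens with linewidth, and at the widened profile
linewidths a 1% support merges adjacent multiplets (e.g. taurine's two
triplets) into one region, leaving overlap analyses with no
non-overlapping partner region to measure.

*Overlap compensation.* When two analytes share a resonance region, a
correctly functioning model places negative attribution at the partner's
non-overlapping resonances, subtracting the partner's contribution to the
shared region. The cross-analyte ROI matrix makes this visible; the
overlap study asserts the negative sums appear for both overlapping pairs
when the partner is present, and collapse when the partner is absent from
the input.

*Singlet audits.* For fixtures with inserted interfering singlets, scores
are summed in a window of 5 template linewidths around each insertion. A
model trained without interfering signals assigns them to nearby analytes
(sums of order the singlet's mM scale); an augmentation-trained model
rejects them (sums well under 1 mM). The audit window must not contain
analyte resonances — otherwise it mostly measures the analyte's own
attribution — so the regime-comparison study constrains its fixture
singlets to sit at least the audit half-width plus three linewidths away
from every panel resonance. The general fixture (`plus_two_singlets`)
places singlets a few linewidths from a random resonance, mimicking
interferents adjacent to analyte signals.

*Bias flags.* Cosine similarity between per-node score vectors above 0.99
flags node pairs that predict from essentially identical evidence — the
signature of a training panel in which two output quantities are carried
by the same compounds.

## Scaled-down study profiles

The full-scale configuration (39,500-point grid, 200 hidden nodes,
10,000 + 10,000 + 5,000 spectra, thousands of epochs) is hours of CPU
time. The packaged profiles shrink the problem while preserving its
structure:

| profile | grid points | hidden | spectra (all/dropout/val) | epochs sim/exp |
|---|---|---|---|---|
| ci | 768 | 64 | 600/600/200 | 800/800 |
| desk | 1024 | 128 | 3000/3000/500 | 1200/2000 |
| full | 39500 | 200 | 10000/10000/5000 | 5000/100000 |

On the coarse grids a 0.8 Hz line would be a sub-gridpoint spike, so the
ci/desk profiles widen the panel linewidth to two grid spacings. This
keeps lines resolved *relative to the grid*, which matters three times
over: peak heights (the yardstick for noise and baseline magnitudes) are
stable rather than sampling-phase artifacts; Fourier shifting does not
ring; and "is this bump an analyte or an interferent?" remains a
well-posed discrimination. The desk profile trains in minutes on one CPU
and lands in the same MAPD band as the full-scale setting (fractions of
a percent at the 1 mM fixture, the hardest of the three equimolar
fixtures since percent differences scale inversely with concentration).

What the scaled-down synthetic setting does *not* exercise: real spectra
have pH/temperature-dependent shifts, non-rigid multiplet distortions,
solvent artifacts, t₁ noise and phase/baseline roll beyond a constant
offset; the taurine/choline overlap is a feature of the panel's shift
table, not of experimental spectra; and passing tests here show the
attribution machinery is faithful to the trained model, not that any
model transfers to acquired data.

## Reproducibility

Every stochastic step — dataset generation, weight initialization, batch
shuffling, fixture noise and singlet placement, baseline noise — is
seeded, and seeded operations restore the caller's RNG state. Identical
seeds and configuration reproduce datasets, models and attributions
bit for bit.
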