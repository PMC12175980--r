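---
title: "Early-dynamic PET blood flow with the AATH model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early-dynamic PET blood flow with the AATH model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aathflow)
```

## The problem

Blood-flow PET normally requires a freely diffusible tracer (15O-water,
11C-butanol) whose extraction fraction is close to 1, so that the
blood-to-tissue transport rate K1 = F·E approximates flow F directly. FDG is
ubiquitous but poorly extracted in most tissues, so FDG K1 is a poor flow
surrogate. If the first two minutes of a dynamic scan are reconstructed at
high temporal resolution (HTR: 60 frames of 1 s then 30 frames of 2 s), the
vascular transit of the bolus becomes resolvable, and a distributed kinetic
model can separate flow from extraction. `aathflow` implements that method
end to end on synthetic data: forward models, basis-function estimation,
AIC model comparison, identifiability simulation, and voxelwise parametric
imaging with kernel smoothing.

## Models

Both models predict a tissue curve as a delayed convolution
Q(t) = Ca(t − td) ⊗ R(t), with Ca the arterial input, td the arrival delay
between the sampling site and the local vasculature, and R the tissue
impulse response.

**S1TC** (standard one-tissue compartment): instantaneous vascular mixing.
R(0) = vb, R(t) = K1·exp(−k2 t) for t > 0. Under convolution the t = 0
point has measure zero, so the vascular term is implemented as the additive
component vb·Ca(t − td): the intravascular signal is a scaled copy of the
input. Free parameters: vb, K1, k2, td (4).

**AATH** (adiabatic approximation to tissue homogeneity): plug flow through
the voxel's whole vascular volume over a transit time Tc, then an
exponential tissue phase:

R(t) = F for 0 ≤ t < Tc, and K1·exp(−k2 (t − Tc)) for t ≥ Tc,

right-continuous at Tc with value K1. The intravascular component becomes
(F/60)·∫₀^Tc Ca(t − td − s) ds — the input smoothed over the transit time —
and the identities E = K1/F and vb = F·Tc/60 link the parameters. Free
parameters: F, K1, k2, Tc, td (5).

Units follow the perfusion literature: F and K1 in mL/min/cm³, k2 in 1/min,
vb in mL/cm³, all time axes (frames, Tc, td) in seconds. Every place a
per-minute rate multiplies a time in seconds carries an explicit 1/60.

Phosphorylation (k3/k4) is deliberately absent: over the first two minutes
it is not identifiable and the one-tissue approximation holds for both
models.

## Estimation

At fixed (k2, Tc, td) both models are linear in two coefficients, so
fitting is a grid search: the nonlinear parameters live on discrete grids,
and at each node a 2-regressor weighted least-squares problem is solved in
closed form from precomputed Gram entries. Defaults:

* k2: 50 geometric nodes on [0.01, 3]/min (≈12% per step). The range covers
  physiologic early-FDG clearance; geometric spacing makes the resolution
  relative.
* Tc: 0 to 40 s in 0.5 s steps — covers reported regional transit times
  (4.4–29.1 s) with margin.
* td: 0 to 30 s in 0.5 s steps.
* Weights: frame duration (default), equalizing the information content of
  1 s and 2 s frames; uniform and inverse-variance (duration/value with a
  5%-of-peak floor) are available.

The search is exhaustive and seed-free; ties in RSS break toward smaller
td, then Tc, then k2, so results are bit-reproducible. Physical bounds are
enforced by clamp-and-resolve: negative coefficients are fixed at zero and
the partner refit; AATH nodes violating K1 ≤ F are refit on the boundary
K1 = F; the implied blood volume F·Tc/60 is capped at 1. At Tc = 0 the
vascular regressor vanishes and F is not identified; the fit reports F = K1
(complete-extraction convention) there.

All convolutions run on a uniform 0.1 s grid (≥10× finer than the shortest
frame) with trapezoidal exponential recursion, cumulative-trapezoid running
integrals, and linear interpolation implemented as a convex pair of integer
lags — so shifting commutes exactly with the linear time-invariant
operators, and the basis tables reproduce the forward model to machine
precision. Frame averages integrate the piecewise-linear interpolant.
Consequences worth knowing: a noiseless TAC generated at grid nodes is
recovered with zero residual, and the Tc → 0 AATH limit approaches the
S1TC curve only up to a half-sample (0.05 s) offset in the discrete
vascular-phase derivative, i.e. to about 1% on a sharp first-pass peak.

## Model comparison

AIC uses the Gaussian least-squares form n·ln(RSS/n) + 2k with k = 5 (AATH)
and k = 4 (S1TC); the small-sample AICc correction is available but off by
default. Temporal-resolution studies frame-average the HTR curve at 1, 2,
3, 5 or 10 s intervals. Averaging merges but never splits measured frames:
a 1 s target leaves the native 2 s frames intact, while coarser bins use
duration-weighted overlap, so the duration-weighted time-integral of the
curve is conserved exactly. Weights are recomputed from the coarser
schedule; the noise realization is not redrawn per interval.

## The synthetic-data engine

The generator defines the study conditions:

* **Regional presets.** Ten tissue regions with cohort-mean AATH kinetics
  (flow 0.039–2.031 mL/min/cm³, Tc 4.4–29.1 s; lung K1 is the cohort
  median). Lungs are driven by a right-ventricle input; everything else by
  the ascending aorta.
* **k2 derivation.** The regional summaries omit k2, so it is derived as
  K1/vd with a nominal distribution volume per tissue class: 0.3 mL/cm³ for
  brain, lung, muscle and marrow, and 0.6 mL/cm³ for the blood-rich
  visceral organs (spleen, renal cortex). The larger visceral vd keeps the
  derived clearance rates inside the physiologic sub-3/min range that the
  estimator searches; a uniform 0.3 would give the spleen an implausible
  4.0/min. `vd` remains an explicit simulation knob.
* **Arterial inputs.** A gamma-variate first pass plus two exponential
  recirculation tails (Feng-type family). Aorta defaults: arrival 15 s,
  peak 100 kBq/mL at 6 s after arrival, shape α = 4 (≈8 s FWHM), tail
  fractions 0.12 and 0.06 with decay rates 0.02 and 0.001 /s. The
  right-ventricle preset is earlier and sharper (arrival 8 s, ≈5 s FWHM),
  as seen upstream of the lungs.
* **Noise.** Zero-mean Gaussian with per-frame SD
  scale·sqrt(max(Q, floor)/Δt) — the standard count-noise approximation for
  decay-corrected early frames (decay-correction inflation is negligible
  over 2 min of FDG). The floor, 5% of the curve peak, keeps pre-arrival
  frames realistically non-silent. The scale is calibrated per region so
  the peak frame has SNR 25, typical of kernel-smoothed HTR regional
  curves.
* **Truth delay.** Simulated tissue curves use a 2 s arterial-to-tissue
  delay: an aorta-measured input always leads the local vasculature, and
  simulating at the delay-grid boundary (td = 0) would measure a boundary
  artifact -- fitted-delay errors become one-sided and are absorbed by
  collapsing the transit time -- rather than the method itself.
* **Phantoms.** A 24³ digital phantom with ten 4³ cuboid regions over a
  blood-pool background, each voxel an independent noisy realization of its
  region's curve.

What passing tests show — and do not. The simulations exercise the
estimator under calibrated Gaussian count-scaled noise with a known,
shared, delay-consistent input function. They say nothing about motion,
dispersion or delay error in the measured input, spillover (notably
right/left ventricle into myocardium), partial-volume effects, dual-input
organs (liver, lungs with bronchial supply), or reconstruction artifacts —
all of which affect real HTR data.

## Identifiability and its reporting

`identifiability_analysis()` simulates ≥50 (default 100) noisy curves per
region at the preset truth, fits AATH, and reports the mean and SD of the
percent error of F, K1, k2, Tc and vb (truth vb = F·Tc/60, the
forward-model value). Two behaviors are worth understanding:

* With near-zero noise the residual bias is pure grid quantization: Tc
  truth values like 4.4 s sit between 0.5 s nodes, and k2 truths are
  off-grid between geometric nodes.
* With noise, flow in short-transit regions acquires a small positive bias:
  F ≈ 60·vb/Tc is convex in Tc, so symmetric scatter of the quantized Tc
  estimate inflates the mean flow (a Jensen effect). At peak SNR 25 the
  worst-case mean bias sits near the 5% scale (cortical/subcortical gray
  matter) and the worst-case spread near 14% (spleen, whose fast clearance
  makes its tissue component resemble smoothed blood); skeletal muscle
  (Tc ≈ 29 s, F ≈ 0.04) is the conventional exception in the reported
  bound.
* The flow-error distribution is heavy-tailed: in roughly 1-2 replicates
  per thousand the least-squares optimum lands on the small-Tc ridge where
  F · Tc is preserved but F itself explodes severalfold. A single such
  replicate dominates a finite-sample SD, so replicate summaries fluctuate
  between seeds even though the converged spread is inside the bound. This
  is a genuine property of grid least squares on this model, not a seed
  artifact.

`scripts/acceptance.R` re-runs exactly this analysis (150 replicates per
region) and writes the worst-case |mean error| and SD of flow across the
nine non-muscle regions.

## Parametric imaging

Voxelwise fitting shares one precomputed basis across all masked voxels and
deduplicates identical series (a noiseless phantom fits in ten solves).
Voxel-scale grids are typically chosen coarser than the regional defaults
(e.g. Tc in 1 s steps, td limited to 0–10 s) to keep whole-volume runs
inside interactive times; maps then inherit that resolution.

The kernel smoother is built once from composite frames — duration-weighted
means over 0–30, 30–60 and 60–120 s, windows adapted to the 2-minute
early-dynamic scan — and applied to dynamics and, if desired, to parameter
maps (the operator is never rebuilt from the maps themselves). Each masked
voxel's feature vector is its z-scored composite intensities; its neighbors
are the 49 voxels with smallest Euclidean feature distance within a 9×9×9
spatial window (self always included; fewer at edges); weights are Gaussian
in feature distance with the per-voxel median neighbor distance as
bandwidth, uniform when all distances vanish, and row-normalized. Feature
space contains no spatial coordinates — spatial locality comes only from
the window — so piecewise-constant structures with well-separated
intensities are preserved exactly while homogeneous-region variance drops.

## Numerical and degenerate-input conventions

* Fine grid 0.1 s; AIF resampled by linear interpolation, zero before its
  first sample; an input that ends before the last frame is an error.
* An all-zero TAC fits to zero coefficients with zero residual at the
  first grid node (td = Tc = 0, smallest k2).
* AIC applies a 1e-300 floor under the log for exactly-zero residuals.
* `bland_altman()` raises on zero-variance inputs rather than returning a
  conventional value — silent conventions hide upstream bugs.
* Stochastic functions take explicit seeds; everything else is
  deterministic, including RSS tie-breaks.

## Problem sizes used in the shipped checks

Regional work uses the full default grid (≈250k AATH nodes, ~0.1 s per
fit after the one-off basis build). The identifiability runs use 100–150
replicates per region; phantom work uses the 24³/ten-region geometry with
voxel-scale grids. These sizes were chosen to characterize the method at
desk scale; all scale linearly if enlarged.

## Known limitations

* The delay grid models outflow-free tissue delay only; input-function
  dispersion is not modeled.
* Single-input models only: no dual-input liver/lung variants, no
  spillover terms.
* The AIF family and noise law are explicit stand-ins for measured inputs
  and scanner-calibrated noise; absolute identifiability numbers shift with
  those choices even though the qualitative behavior (HTR required for
  AATH preference, flow identifiable except slow-transit muscle) is
  robust.
* The kernel weight function (Gaussian, median-distance bandwidth) is one
  reasonable choice among several used with nonlocal-means-style
  denoisers.
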