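---
title: "Methods: continuous multi-band microstates and the normalizer-free cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous multi-band microstates and the normalizer-free cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mscascade)
```

This vignette is the package's account of what it computes, which choices
were genuinely open, how they were resolved, and what the synthetic tests
do and do not demonstrate.

## Signal model and preprocessing

The unit of analysis is an eyes-closed resting-state scalp EEG recording
with 19 electrodes in the 10–20 montage. The package consumes *cleaned*
EEG: artifact removal (ASR, ICA component rejection) is deliberately out of
scope, since published resting-state datasets ship cleaned derivatives.

Preprocessing is: common-average re-referencing, polyphase resampling to
256 Hz, zero-phase Butterworth band-pass filtering per band, and
sliding-window epoching (10 s windows, 5 s steps). Conventions that the
package fixes:

* **Average reference first.** Topographic clustering and spatial
  correlation assume a zero spatial mean; GFP itself subtracts the spatial
  mean and is therefore invariant under this step (a property the test
  suite asserts).
* **Butterworth order 4, forward–backward.** The filter family is
  standard for EEG; the order is unstated in the source literature, and 4
  is the conventional choice. Zero-phase filtering preserves microstate
  timing. With a true band-pass design this is numerically stable down to
  the delta band at 256 Hz (passband gain within 0.1% across the grid;
  a high-pass/low-pass cascade was rejected because its squared-magnitude
  response loses ~25% of amplitude mid-alpha).
* **Epoch boundary convention.** Windows start at k·S (0-based) and are
  kept only when k·S + W < L *strictly*: the window that ends exactly at
  the recording end is excluded. A 300 s recording at 256 Hz yields 58
  epochs of 2560 samples, and an 88-subject cohort 5104 epochs. The
  inclusive convention would give 59; the strict one is the only
  convention consistent with those published counts, and is frozen here.

## Microstate extraction

Templates are estimated only at GFP peaks (strict local maxima), where the
topographic signal-to-noise ratio is maximal. The clustering is the
microstate variant of k-means:

* assignment by maximal **absolute** spatial correlation (microstate maps
  are polarity-agnostic: oscillation phase flips the sign);
* template update as the dominant eigenvector of the outer-product sum of
  assigned maps — the polarity-proof analogue of the cluster mean;
* selection across 20 random restarts by global explained variance,
  `GEV = Σ (GFP_t ρ_best(t))² / Σ GFP_t²`;
* convergence when assignments stabilise or GEV improves by < 1e-6, with
  a 100-iteration cap; emptied clusters are re-seeded from a random map.

Restart count, tolerance and cap are conventional values and configurable;
none is load-bearing for the results (the planted-template recovery test
passes with a single restart).

**Canonical labels.** Nothing in the clustering itself says which cluster
is "A". The package matches broadband templates against built-in prototype
geometries (A/B: opposed diagonal dipoles, C: anterior–posterior midline,
D: posterior-focal) using the same Hungarian machinery as cross-band
alignment, cost 1 − |ρ|. This is a package convention, stated prominently:
other software may letter clusters differently.

**Cross-band alignment.** Independent clustering per band permutes labels
arbitrarily; narrowband sets are relabelled against the broadband anchor by
minimum-cost bipartite assignment on D = 1 − |C|, solved with an exact
O(n³) Hungarian implementation (validated against exhaustive permutation
search in the tests — for 4×4 problems brute force would suffice, but the
exact algorithm costs nothing and scales).

**Soft backfitting.** Each epoch becomes the trajectory
r_k(t) = |ρ(x(t), m_k)|, a (4 × T) matrix in [0, 1] with **no**
winner-takes-all discretisation — transition periods between states retain
their graded similarity structure. Zero-variance frames (possible in
zero-padded or clipped data) have undefined correlation; they are emitted
as 0 and flagged rather than erroring. A signed mode exists behind a flag
and returns a plain matrix, since the soft-sequence container guarantees
[0, 1] by contract. Classical statistics (coverage, dwell, occurrence,
segment-level transition matrix) are derived by argmax discretisation when
needed for baselines; transition rows are normalised over observed
transitions (a row with none stays zero and is flagged). Note that without
temporal smoothing — deliberately out of scope — argmax dwell times on
noisy data are much shorter than the latent segment durations; the soft
representation, not the discretisation, is what the classifier consumes.

Two-band fusion stacks rows 1–4 (first band, classes A–D) over rows 5–8
(second band): alpha+delta for screening, delta+theta for subtyping.

## The classifier

The network is a 1D CNN over the fused (8 × 2560) tensors: stem convolution
(kernel 15, stride 2 — a ~60 ms receptive field at 256 Hz), normalizer-free
residual blocks (1×1 projection shortcut plus a kernel-7 conv–ReLU–conv
branch), max pooling (stride 4), multi-head self-attention (4 heads,
embedding 64, 1×1 input projection, residual connection, no positional
encoding), global average pooling, dropout 0.5, linear head.

Open details resolved as package defaults:

* **Block count/widths**: stem → 32 channels, three blocks (32, 64, 64).
  The architecture is deliberately lightweight; widths are configurable.
* **No normalization anywhere** in the `proposed` variant; stability is
  delegated to adaptive gradient clipping, applied unit-wise (rows of
  weight matrices; whole bias vectors) to **all** parameters with λ = 0.04
  and ε = 10⁻³. The clip never increases a unit's gradient norm and
  preserves its direction (asserted property-style in the tests).
* **Ablation variants** are first-class configurations: `conv_bn`
  replaces the blocks with conv–batch-norm–ReLU stacks (and demonstrably
  makes training-mode inference depend on batch composition), and
  `nfnet_no_attn` omits the attention module.
* **Attention for interpretability** is the post-softmax map, averaged
  over heads and queries, a distribution over the 320 post-pooling time
  steps; a nearest-neighbour upsampling projects it back to the 2560-sample
  axis for overlays. The *attention allocation score* attributes each
  step's attention mass to a target row set in proportion to its share of
  total row energy, giving a subject-level score in [0, 1].

Training: Adam (lr 10⁻⁴ at the reference scale), batch 32, weighted
cross-entropy with inverse-frequency class weights (w_c = N/(K n_c)),
early stopping after 20 epochs without validation improvement, best-epoch
weights restored, seed 42. All forward/backward passes are deterministic
pure-R matrix operations, so fixed seeds reproduce runs bit-for-bit.

## Evaluation protocol

Leave-one-subject-out, with the remaining subjects split 8:2 into training
and validation **by subject**, stratified by class (falling back with a
warning when a class has a single remaining subject; whether the original
protocol stratified is unstated, and stratification is the safer default).
Fold templates are extracted from an explicit allow-list containing only
the fold's training subjects; the API records that list per fold and the
trainer hard-errors on train/validation subject overlap. Majority voting
breaks ties by mean predicted probability, then toward the disease-positive
class (screening sensitivity is the clinically conservative direction; with
even epoch counts ties are possible and some rule must be fixed).

Stage 2 is evaluated on the true patient cohort, matching a subtyping task
definition; the cascade additionally routes stage-1 false-positive healthy
subjects through a stage-2 model trained on all patients (leakage-free for
those subjects, who never enter patient training data). Two summary
numbers are reported: the realistic composed 3-class balanced accuracy,
and the screening/subtyping composition (mean of stage-1 HC recall and
stage-2 AD/FTD recalls), which treats the two stages as independent
modules. The ROC operating point maximises Youden's J over pooled
out-of-fold subject scores post hoc; it is reported, never fed back.

Statistics: exact two-sided McNemar from discordant counts
(min(1, 2·P(X ≤ min(b,c))), X ~ Bin(b+c, ½)); Friedman with within-block
midranks and no tie-correction denominator (ties are flagged);
Benjamini–Hochberg step-up via `p.adjust`; Mann–Whitney U exact for ≤ 8
per group without ties, else the tie-corrected normal approximation
without continuity correction. The switch point is configurable.

## The synthetic generator

The generator exists so that every downstream stage has known ground
truth. A subject is

    X(t) = Σ_bands carrier_b(t) · m_{L(t)} + noise,

with L(t) a piecewise-constant latent sequence (segment durations uniform
on 60–120 ms, uniform transitions to a different state), carriers
amplitude-modulated sinusoids at each band's geometric-mean frequency, and
spatially white Gaussian noise (sd 0.1). Class effects:

* **HC** — none: sustained posterior-dominant alpha (band amplitude 1.0
  against delta 0.35, theta 0.45, beta 0.25, gamma 0.12).
* **AD** — the alpha carrier is attenuated (factor 0.3 by default), which
  lowers alpha-band SNR against the unchanged noise floor and therefore
  *fragments* the alpha correlation trajectories; plus Poisson-timed
  300 ms delta-frequency bursts carrying a **diffuse vertex-centred
  topography**. The diffuse map is nearly orthogonal to all four canonical
  maps, so bursts appear as deep dips of every delta row — the
  correlation-domain signature of diffuse slow-wave intrusion.
* **FTD** — delta bursts locked to Class-C periods with a
  **frontal-focal** topography (a prefrontal midline Gaussian, |ρ| vs A–D
  ≈ 0.44/0.44/0.62/0.27): C-flavoured but distinct from every canonical
  map, producing moderate-depth, C-dominant dips.

A modelling point worth stating: spatial correlation is amplitude-blind
(|ρ(a·m, m)| = 1 for any a ≠ 0), so class effects that only rescale
amplitudes of the *current* topography are invisible to any
correlation-based feature. Pathological effects must perturb the
topography dynamics — which is also the physiologically faithful reading
of diffuse versus focal slow-wave intrusions. Effect magnitudes are free
parameters of the generator, not empirical claims; three frozen profiles
exist (`default`, `strong` for end-to-end separability runs, `null` with
all effects disabled for chance-level/leakage audits).

What passing synthetic tests shows: the pipeline recovers planted
templates (|ρ| ≥ 0.95 at noise sd 0.1), reproduces planted label sequences
(≥ 99% noise-free), separates classes end-to-end under LOSO when class
effects are strong, and stays at chance on null cohorts (the leakage
guard). What it does not show: performance on clinical EEG, whose
artifacts, inter-subject topographic variability, volume-conduction
structure and non-stationarities the generator deliberately does not
model.

## Problem sizes and numerical choices

The reference configuration (widths 32/64/64, embedding 64, batch 32,
lr 10⁻⁴, patience 20) targets cohorts of tens of subjects with ~58 epochs
each. Synthetic end-to-end runs in the test suite and acceptance script
use a reduced profile for small cohorts: 12 subjects of 40 s (6 epochs
each), widths 8/16, embedding 16, pool stride 8, dropout 0.3 (a 16-unit
pooled feature tolerates less masking than the reference 64), batch 16,
lr 2·10⁻³, patience 8, cap 30 epochs. On this profile the strong-effect
cascade reaches stage-1 balanced accuracy 0.94 and stage-2 1.0; the
null-profile LOSO stays inside the exact 95% chance band. Class labels map
to logit units in a fixed, locale-independent order (negative class first,
disease-positive last); with only ~10² gradient steps the trajectory is
genuinely sensitive to which unit's initial weights serve which class, so
the mapping must never depend on the session's collation locale.

Other numerical details: convolutions run through a sparse block-diagonal
im2col/col2im operator pair (exact, memoised per geometry); max-pool ties
route gradient to the first maximum; the GEV denominator rejects all-zero
GFP; Hungarian costs must be finite; EDF writing quantises to 16 bits over
each channel's physical range (round-trip error ≤ range/65535).

## Known limitations

Pure-R training is CPU-bound and practical up to tens of subjects;
temporal smoothing of microstate sequences, source-space analysis,
artifact simulation and biophysical forward modelling are out of scope;
the canonical-label convention (prototype matching) may disagree with
other packages' lettering on real data; exact reproducibility across BLAS
implementations is expected but only verified within one platform.
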