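# mscascade

Multi-band EEG microstate fusion and two-stage dementia classification in R.

Resting-state EEG decomposes into *microstates*: quasi-stable scalp
topographies lasting roughly 60–120 ms that cluster into four canonical
classes A–D. Alzheimer's disease (AD) and frontotemporal dementia (FTD)
alter these dynamics in frequency-specific ways — posterior alpha rhythms
fragment as thalamocortical integrity degrades, while pathological
low-frequency slow waves intrude with diffuse (AD) or frontally focal (FTD)
topographies. `mscascade` implements a complete, leakage-free pipeline that
turns these observations into a subject-level classifier, and a synthetic
EEG generator with planted ground truth so every stage is testable without
any clinical data.

## The method

**Continuous multi-band microstate extraction.** For each frequency band
(broadband 0.5–45, delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma
30–45 Hz), template topographies are clustered from the EEG at the peaks of
global field power,

    GFP(t) = sqrt( (1/N) * sum_i ( V_i(t) − V̄(t) )² ),

with a polarity-invariant modified k-means (assignment by maximal |ρ|,
template update by dominant eigenvector) selected on global explained
variance (GEV). Narrowband templates are relabelled against the broadband
anchor by minimum-cost bipartite matching (Hungarian algorithm) on the cost
`D_jk = 1 − |ρ(S_j, B_k)|`, so classes A–D mean the same thing in every
band. Instead of winner-takes-all backfitting, each epoch is encoded as the
continuous soft-assignment trajectory `r_k(t) = |ρ(x(t), m_k)|`, a (4 × T)
matrix in [0, 1]; two bands are stacked into an (8 × T) fused tensor.

**Normalizer-free 1D CNN with self-attention.** Fused tensors are
classified by a 1D convolutional network with no normalization layers: a
large-receptive-field stem (kernel 15, stride 2), residual blocks with 1×1
projection shortcuts (kernel 7), max pooling (stride 4), multi-head
self-attention (4 heads, embedding 64), global average pooling, dropout and
a linear head. Stability comes from adaptive gradient clipping: unit-wise,
the gradient is rescaled whenever `‖G‖_F / max(‖W‖_F, ε) > λ` (λ = 0.04,
ε = 10⁻³). Training uses Adam, weighted cross-entropy, and early stopping
on validation loss. Because there are no batch statistics anywhere,
single-subject inference is bit-identical to batched inference.

**Leakage-free two-stage cascade.** Evaluation is leave-one-subject-out:
per fold, microstate templates are re-extracted *from the training subjects
only*, the held-out subject's epochs are predicted independently, and the
subject receives the majority-vote label. Stage 1 screens dementia vs
healthy controls on the alpha+delta fusion; stage 2 differentiates AD vs
FTD on delta+theta. Reports include balanced accuracy, ROC AUC with the
Youden-J operating point, attention allocation scores, and the statistics
used to compare such pipelines (exact McNemar, Friedman, Mann–Whitney U,
Benjamini–Hochberg FDR).

## Worked example

```r
library(mscascade)

spec   <- cohortSpec(nPerClass = c(AD = 1, FTD = 1, HC = 1),
                     durationS = 20, seed = 1)
cohort <- simulateCohort(spec)
cohort$recordings[["sub-001"]]
#> Recording 'sub-001' [AD]: 19 channels x 5120 samples @ 256 Hz (synthetic)

prep <- prepareCohort(cohort$recordings, bands = c("alpha", "delta"))
tmpl <- foldTemplates(prep, prep$subjects, bands = c("alpha", "delta"), seed = 1)
tmpl$anchor
#> TemplateSet band=broadband: 4 x 19 maps [A,B,C,D], GEV=0.901 (n=1893 peak maps)
tmpl$templates$alpha
#> TemplateSet band=alpha: 4 x 19 maps [A,B,C,D], GEV=0.884 (n=1230 peak maps)
```

The broadband clustering explains 90% of the GFP-weighted variance with
four maps, and the alpha-band templates have been Hungarian-aligned so
their rows carry the same A–D labels as the anchor. Backfitting and fusing
gives the classifier input:

```r
ss <- backfitSoft(epochs(prep$epochSets[["sub-001"]][["broadband"]])[[1]],
                  tmpl$anchor, subjectId = "sub-001")
round(microstateStats(ss, rate = 256)$coverage, 3)
#>     A     B     C     D
#> 0.234 0.243 0.236 0.288
```

Coverage is near-uniform by construction (the generator's latent state
sequence has no class bias). Evaluation statistics work on printed counts:

```r
mcnemarExact(17, 6)   # exact two-sided McNemar from discordant counts
#> [1] 0.03468966
chi2Sf(18.21, 5)      # chi-square upper tail, df = 5
#> [1] 0.002694411
```

An end-to-end LOSO cascade on a 12-subject strong-effect cohort
(`cohortSpec(profile = "strong")`, reduced model width and schedule — see
the methods vignette) separates the classes cleanly; with the acceptance
script's seed 1 every subject is classified correctly
(`stage1_balanced_accuracy` 1, `stage1_auc` 1, `stage2_balanced_accuracy`
1), and across other seeds stage-1 balanced accuracy stays at or above
0.94. Expect roughly 12 minutes on one CPU.

A thin command-line front-end is installed as `exec/mscascade`
(`simulate`, `extract`, `loso`, `cascade`, `report`).

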