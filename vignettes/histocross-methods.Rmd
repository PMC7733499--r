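---
title: "HistoCross: models, planted structure, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HistoCross: models, planted structure, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

HistoCross implements a pan-cancer histology analysis as a reusable,
fully testable pipeline. The scientific question behind it: do tumors of
different tissues share morphology that image classifiers can exploit? The
operational form of that question is *cross-classification*: train a
tumor-vs-normal tile classifier on cohort A, apply it to cohort B, and
summarize transfer quality in a train-tissue x test-tissue AUC matrix. This
vignette explains the models, the synthetic cohorts every stage is tested
on, and the numerical choices, in the package's own terms.

## The classification model

Slides are cut into non-overlapping square tiles (512 px at 20x in the
reference setting; 40x inputs are first downsampled by 2 with area
averaging). Background is removed by an HSV-saturation criterion: a pixel
is "tissue" when its saturation exceeds 0.05, and a tile is kept when its
tissue fraction is at least 0.25 (both configurable; unstained fat is
low-saturation and is limited by the same criterion). A pluggable backbone
maps each kept tile to a fixed-length feature vector (a "cache"); caches
are shuffled within a holdout group and stored in shards of 10,000.

The *transfer head* is a one-hidden-layer softmax network over caches
(defaults: 1024 hidden units, 20% dropout, 2000 Adam steps of batch 512).
Class imbalance is handled by rejection undersampling: a drawn example of
class c is accepted with probability min(count)/count(c), so the training
stream is balanced in expectation and the minority class is never
rejected. Classes are ordered by sorted label name; argmax ties break
toward the lowest class index.

Slide-level aggregation uses the **tumor-predicted fraction (TPF)**: each
tile takes its argmax class, and the TPF is the exact fraction of tiles
called tumor. The TPF is used directly as a continuous slide score — no
threshold is needed for AUC; a 0.5 cutoff is applied only when a discrete
label is requested. For mutation classification the slide score is the
mean tile mutant-probability instead. Tile-level agreement between two
classifiers is measured as the Pearson correlation of stabilized logits
log((p + eps)/(1 - p + eps)) with eps = 1e-4.

ROC AUC is the midrank Mann-Whitney statistic (ties count 1/2); PR AUC is
average precision with tied scores grouped. Confidence intervals avoid
bootstrap cost via a binormal stress-strength approximation: AUC maps to
d = sqrt(2) qnorm(AUC), whose variance is approximated by
(n1+n0)/(n1 n0) + d^2/(2(n1+n0-2)); the normal interval on d is mapped
back through pnorm, truncated to [0,1], and widened if needed to bracket
the observed AUC (degenerate AUCs of 0/1 are pulled in by half a
pair-count before the transform). A seeded stratified bootstrap
(`aucBootstrapCI`) cross-checks the analytic interval in the tests.

## Cross-classification analysis

`buildCrossMatrix` fills the n x n grid of slide-level AUCs (train tissue
on rows, test tissue on columns; n(n-1) off-diagonal cells). Rows and
columns are clustered by UPGMA (average linkage, Euclidean distance, via
`stats::hclust`). Association between dendrogram order and an independent
phenotype (organ of origin, adenocarcinoma status) is tested with the
Gamma index Γ = Σ A_ij W_ij, where A marks tissue pairs sharing the
phenotype (tissues labeled "Other" are dropped first) and W marks
immediate neighbors in leaf order. The null permutes phenotype labels —
rows and columns of A jointly — and p = (1 + #{Γ_perm ≥ Γ_obs})/(1 +
n_perm).

A calibration caveat worth stating plainly: Γ is a small integer with
heavy ties, so its permutation p-values are *valid but conservative* —
the probability of p ≤ 0.05 under the null is about 0.02-0.035 in the
regimes this package analyzes, not 0.05. This is intrinsic to a discrete
statistic (atoms at the observed value inflate the p-value) and is not
"fixed" here by smoothing or randomized rejection. The purity permutation
test, whose Pearson-r statistic is continuous, is exact at nominal level.
Both facts are measured by the test suite over 1000 null replicates.

Tile-logit correlation matrices are aggregated over test tissues by mean
and by max (with the argmax tissue recorded). The canonical-tissue tally
lists, for each unordered classifier pair, the k = 3 test tissues with the
highest correlation; under a uniform null each tissue is expected
k·C(n,2)/n times (27 for n = 19), and per-tissue enrichment is scored by
the upper tail of Binomial(C(n,2), k/n). The expectation is
null-model-independent; the binomial form of the tail is a documented
choice. Multiplicity uses Benjamini-Hochberg step-up (via
`stats::p.adjust`); correlation significance uses the Fisher z transform
with SE 1/sqrt(n-3). All correlations in the package are Pearson.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is checked. Each tissue has a *normal*
texture signature and a *specific tumor* signature; tumors are rendered
from the convex mixture `w * shared + (1-w) * specific` of a cohort-wide
shared malignancy signature (high nucleus-blob density, fine
high-contrast texture, purple shift) with the tissue's specific component,
where w is the tissue's `shared_weight`. Textures are oriented band-pass
waves plus Gaussian "nucleus" blobs on a stained background with pixel
noise (sd 0.02 by default) — separable, controllable, and in no way a
claim about real histology.

Two design points carry the planted structure:

* In `defaultTissueSpecs`, the specific tumor component departs from the
  tissue's normal signature *against* the shared malignancy axis (no
  density increase; a green/brighter rather than purple/darker shift;
  rotated texture). A tissue at `shared_weight = 0` therefore remains
  self-classifiable through its color shift but transfers poorly — its
  row and column of the cross-matrix are depressed, which is the testable
  desk-scale analogue of a poorly cross-classifiable cancer type.
* Purity is realized at tile granularity: a tumor slide of purity p has
  exactly round(p · tiles) tumor-textured tiles, so recorded purity equals
  the tumor-tile fraction identically, and the naive training assumption
  ("all tiles in a tumor slide are tumor") is violated exactly as much as
  the purity dictates. Tumor-slide purities default to Uniform(0.4, 0.95).

Mutation status is planted per patient (rate 0.5) as a fine phase-jittered
grating (frequency 0.45 cycles/px, amplitude 0.02) added to tumor tiles of
mutant samples. The amplitude is deliberately small: pooled tile
statistics barely move, so the transfer head lands in a weak-AUC regime,
while a trainable convolution can match the grating frequency — making
"full training outperforms transfer learning for mutation status" a
planted, testable ordering rather than an anecdote.

Seeding is hierarchical and documented: the master seed draws per-slide
seeds, each slide's stream draws its per-tile seeds, so cohorts are
byte-identical under a fixed master seed and insensitive to evaluation
order. Tile coordinates are 0-based, row-major, with half-open windows.

What the generator does **not** emulate: stain variability and
normalization, FFPE/frozen artifacts, scanner differences, spatially
correlated tumor regions (latent tile labels are exchangeable within a
slide), or any real morphological feature. Passing tests demonstrate that
the *pipeline* recovers planted structure; they say nothing about
biological truth on real slides.

## Surrogate backbone and reduced networks

The pretrained backbone behind the reference pipeline is GPU-scale, so the
package ships a deterministic surrogate extractor behind the same
interface: per-channel means and standard deviations plus the mean
rectified responses of a fixed-seed bank of *smoothed* random 5x5 filters
on luminance (default 48 features, seed 20240817). Smoothing makes the
bank low-pass: coarse morphology (blob density, stain color, texture
energy) dominates, and fine gratings are under-represented — which is also
what makes the planted mutation signature hard for the transfer route. A
real pretrained backbone can be plugged in as any closure with an
`extractor_id` attribute.

The "fully trained" mode is a reduced-width network trained end-to-end on
pixels: one trainable convolution layer (8 filters, 5x5, stride 2), ReLU,
coarse 3x3 regional average pooling, linear softmax, Adam. Regional
pooling (rather than global) is load-bearing for the nucleus task: the
class signal sits at the patch center, and global averaging erases its
location. The contract — not the weights — is what mirrors the reference
architecture.

The purity head regresses tile purity through the adjusted logit
log((P + 0.05)/(1.05 - P)). Because sigma(adjustedPurityLogit(P)) =
(P + 0.05)/1.1, a sigmoid-output network trained against that linear
target composes exactly with the published link; predictions invert by
1.1 p - 0.05, clamped to [0,1]. Training runs 20 epochs (256 ReLU units,
25% dropout, elastic-net penalties 1e-4); the kept epoch is the
best-on-test epoch after epoch 10 whose test MSE exceeds its train MSE
(falling back, with a warning, to best-on-test after epoch 10). The
learning rate defaults to 5e-3 — the reference work prints no optimizer
constants, and 1e-3 demonstrably underfits in 20 epochs at desk scale.

## Purity estimation on annotated ROIs

Synthetic ROIs carry two-class nuclei (tumor: radius 5.0 px, intensity
0.25; normal: 2.5 px, 0.60; centers at least 1.1(rT + rN) apart so labels
stay clean) and a stromal blotch whose amplitude is proportional to ROI
purity. The blotch is the planted *intercellular* signal: visible to
overlapping tile windows, uninformative about any single nucleus. This
makes the tile-vs-nucleus comparison a designed property — the tile
regressor can exploit stroma, the nucleus route cannot — mirroring at desk
scale the observation that tile-level purity models capture information
beyond per-cell classification.

Per-window purity targets count annotated nuclei by the center-in-window
rule. Nucleus patches are 32x32 crops after one histogram equalization of
the whole ROI; equalizing per ROI (not per patch) is deliberate — rank
equalization inside a 32x32 patch would make every patch's own nucleus its
darkest region and erase the intensity offset entirely, whereas the
purpose of equalization is normalizing acquisition differences between
datasets. Nucleus-based ROI purity is the mean per-nucleus tumor
probability; ROIs smaller than one tile window are skipped with a message.

## Problem sizes and numerical choices

Desk-scale analyses in the tests and the acceptance script use: 4 tissues,
20 tumor + 20 normal slides per tissue, 8x8 tile grids of 32 px tiles, the
48-feature surrogate extractor, heads with 16 hidden units trained for 300
steps of batch 64, 10 seeds for the ranking experiment, 1000 null
replicates with 199 permutations each for calibration, and 199-9999
permutations for single tests. These sizes are the package's own choice of
a regime where planted effects are comfortably detectable on one CPU;
the reference-scale defaults (2048-feature caches, 1024-unit heads, 2000
steps of 512, shards of 10,000) remain the documented configuration
defaults.

Other numerical choices: probabilities are validated to sum to 1 within
1e-6; logit stabilizers are eps = 1e-4 (tiles) and the 0.05/1.05 shift
(purity); feature standardization statistics are frozen on the training
set; UPGMA tie behavior is `stats::hclust`'s deterministic lowest-index
convention; permutation p-values always use the add-one form
(1 + exceed)/(1 + n); Bonferroni caps at 1; undersampling never rejects
the minority class; all stochastic steps take explicit integer seeds
below 2^31.

## Known limitations

* Texture families are synthetic stand-ins; no claim transfers to real
  H&E morphology.
* The Gamma permutation test is conservative at nominal 5% (discrete
  statistic; see above) — its *power* on planted associations is tested
  separately.
* The reduced full-training network is a contract-compatible stand-in; it
  demonstrates orderings (full ≥ transfer on planted mutation signal),
  not absolute performance.
* Whole-slide container formats, stain deconvolution, nucleus detection
  and genomic purity baselines are out of scope.
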