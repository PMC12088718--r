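---
title: "Weakly supervised stenosis detection on CMR slice stacks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised stenosis detection on CMR slice stacks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(milcta)
```

## The problem

A coronary CT angiography study is routinely summarized by curved
multiplanar reformations (CMRs): resampled 2-D slices that follow one
coronary artery through the volume. A radiologist's report grades the
worst stenosis per artery, so the only supervision available is one weak
binary label per case — *does this artery have a ≥50% stenosis anywhere?*
— attached to a variable stack (6–144) of slices, with no annotation of
*which* slice shows the lesion.

`milcta` implements an end-to-end method for this setting:

1. a multi-attenuation-window edge-fusion preprocessing pipeline,
2. 36-slice *bag* construction with replication padding and leakage-free
   stratified patient-level splits,
3. an attention-based multiple instance learning (MIL) classifier with
   positional encoding and multi-head self-attention,
4. patient-level evaluation (ROC AUC with a CI across repeated splits,
   Brier score, calibration, threshold sweeps),
5. a synthetic-cohort generator with slice-level ground truth, so that the
   whole chain is testable without clinical data.

## Preprocessing

Each HU slice is clipped and linearly rescaled into five attenuation
windows — (−150, −50), (−50, 50), (50, 130), (130, 400), (400, 1000) HU —
targeting fat, water-range soft plaque, fibrous tissue, contrast-filled
lumen, and calcium. Each windowed image passes a 3×3 Sobel operator
(reflect padding); magnitudes are divided by the analytic bound
$4\sqrt2$ so all five edge maps live on a common $[0,1]$ scale *before*
the pointwise maximum-response fusion — per-image rescaling would distort
the balance between windows. The fused map is thresholded
(`edge_threshold`, default 0.10 — the threshold's existence is part of
the method, its value is free and exposed), an 8-px border frame is
zeroed (burned-in annotations hug the border), and connected components
under 20 px are removed (strictly: a 20-px object survives).

Remaining components are labelled (8-connectivity default) and ranked by
the mean of min–max-normalized area, moment-ellipse major axis length and
perimeter; the `keep_top_k` best are retained and mask the fused edge
map. We ship `keep_top_k = 6`: the two vessel-wall edge curves always
occupy the top ranks, and real lesions — spotty calcium, heterogeneous
plaque — fragment into a handful of mid-sized components that a
keep-two rule would delete along with the noise. The retained map is
resized, aspect-preserving with zero padding, to the model input size;
downscaling is preceded by a Gaussian anti-aliasing filter
($\sigma = (1/s-1)/2$ for scale $s$), without which the thin edge curves
alias away almost entirely.

## Labels, bags and splits

Per-segment stenosis percentages map to the clinical grades (0 none,
1–24 minimal, 25–49 mild, 50–69 moderate, 70–99 severe, 100 total
occlusion); an artery inherits its worst segment and is positive at
moderate or above. Slices are packed in manifest order into bags of 36;
`ceiling(n/36)` bags per patient, the last one padded by cycling the
patient's own slices from the start (padded entries are flagged, and
patient-level attention later takes a per-slice *max* over occurrences so
replication cannot inflate a slice's importance). Splits are 70/15/15 at
the patient level, stratified by label, with test and validation counts
allocated by round-half-up within each class — the allocation rule that
reproduces a published cohort table we use as a worked example — and five
repeats use consecutive seeds.

## The classifier

Each slice is embedded by a shared encoder. The desk default
(`small_cnn`) is four 3×3 conv + ReLU + 2×2 mean-pool blocks with
channels (4, 8, 16, 32) on 32×32 inputs, followed by global **max**
pooling and a dense projection to a 128-dimensional embedding. Max
pooling is deliberate: the discriminative evidence is a small localized
structure, and a spatial mean dilutes it ninefold or more. The embedding
is layer-normalized before the sinusoidal positional encoding of the
in-bag index is added — otherwise the unit-amplitude encoding swamps the
content, whose natural scale depends on the sparse edge input. A
`vgg16_style` encoder (the full 13-conv VGG16 stack, sequential layer
numbering including pooling, first 15 stages frozen by default) accepts
externally supplied pretrained weights; no shipped test depends on them.

One pre-norm multi-head self-attention block (4 heads, scaled
dot-product, residual, final layer norm) contextualizes the 36
instances. Its output projection is zero-initialized so the block starts
as the identity and cross-instance mixing grows only as it becomes
useful; with random mixing from step one, instance content is scrambled
before the encoder has learned anything. Gated attention pooling scores
each instance with $w^\top(\tanh(Vh)\odot\sigma(Uh))$, softmax-normalizes
the scores (they sum to 1 and are the interpretable per-slice attention),
and the weighted sum feeds a dropout (0.2) + dense + sigmoid head.
Patient probability is the maximum over the patient's bag probabilities.

With the encoding disabled the whole model is permutation-equivariant;
this is verified numerically in the test suite.

## Training, and what from-scratch training needs

`train_config()` defaults to the fine-tuning recipe: binary
cross-entropy, Adam at 1e-4, early stopping (patience 7, best weights
restored), learning-rate reduction on plateau (×0.2, patience 5),
balanced class weighting, and zoom/shift augmentation only — rotation is
structurally rejected because it would scramble what the positional
encoding represents.

That recipe presumes an encoder that already has features (e.g. a
pretrained VGG16 with 15 frozen stages). Training the small encoder from
scratch under weak labels faces two quantifiable obstacles we observed
directly: the attention path splits each bag's gradient across 36
instances (uniform attention at initialization), and with ~100 training
bags the rich per-bag gradient of memorization beats the diluted gradient
of the true feature — training loss falls while validation worsens. Two
additions fix this, both off by default and documented here as the
package's own design:

* **Slice-level warm-up** (`warmup_epochs`): every training slice
  inherits its patient's weak label and the encoder plus an instance head
  are trained on these noisy labels for a fixed number of cheap
  slice-batch epochs. This is the transfer-learning surrogate: it plays
  exactly the role ImageNet pretraining plays when available, and uses
  nothing but the weak labels already in hand.
* **Max-instance auxiliary loss** (`aux_weight`): during bag training the
  highest-scoring instance of each bag receives the bag label through an
  auxiliary BCE, handing the key instance an undiluted gradient. The
  inference path — attention pooling to a bag probability — is unchanged.
* **Attention–evidence consistency** (`att_consistency`): the attention
  distribution of positive bags is pulled (by a KL term) toward the
  stop-gradient softmax of the instance-head logits. Once the bag loss
  saturates — which happens quickly when lesions are visible on many
  slices — the attention weights otherwise feel no pressure to localize;
  this term keeps the interpretable attention aligned with instance-level
  evidence, which is the property the attention scores are reported for.

`run_experiment()`'s default training configuration is therefore
lr 1e-3, 4 bags per step, patience 12 (early stop) / 8 (plateau),
75 warm-up epochs, attention consistency 0.5, 40 bag epochs maximum. The longer patience matters
because the validation loss of a 15%-split validation set (~19 bags) is
noisy enough that the paper's patience of 7 reliably stops training
during the pre-takeoff plateau.

## The synthetic cohort

The generator emulates what the pipeline needs to see, with slice-level
ground truth for key-instance checks: a smooth soft-tissue background in
roughly [−120, 60] HU; a contrast-filled vessel band (330–470 HU, width
6–12 px) along a quadratic Bézier centreline kept near the horizontal
midline, as reformation software keeps the straightened artery; additive
Gaussian noise (σ = 15 HU); burned-in 5×7 dot-matrix glyphs at 1200 HU
within 8 px of the border (each glyph lights exactly 15 cells, so no
glyph can form a ≥25 px component); and, on designated slices of positive
patients, a lesion:

* *calcified*: spotty calcification — a dominant nodule (core ≥ 25
  connected px above 600 HU) straddling the vessel wall plus 2–4
  satellite deposits, with ±40 HU internal texture;
* *soft*: a heterogeneous low-attenuation (0–40 HU) stretch filling the
  lumen over 24–40 px, with 2–4 denser fibrous components (80–120 HU)
  inside.

Spotty and heterogeneous morphology is how these lesions present on
CCTA, and it is also what makes them visible to the multi-window design:
internal HU transitions cross window boundaries and produce dense local
edge texture rather than a single faint ring. Positive patients carry the
lesion on a fixed number of slices (`plaque_slices_per_positive`,
bounded by the slice-range minimum); since every reformation of an artery
traverses the lesion, the acceptance cohort uses 12 of 12–40 slices,
mirroring the predominantly visible lesions described for real cases,
with visibility on the remaining slices suppressed (obscured/poorly
positioned planes). Labels are independent Bernoulli draws at the
configured prevalence; a configuration (including its seed) maps to a
byte-identical cohort.

What passing on this cohort shows — and what it does not: the synthetic
task validates the *mechanism* (weak-label patient classification with
interpretable key-instance attention surviving the full preprocessing,
bagging and evaluation chain), not clinical performance. Real CMR stacks
add obscuring structures, brightness drift, anatomical variability and
label noise from report extraction that the generator deliberately omits.

## Evaluation

Patient-level AUC is the Mann–Whitney statistic (ties count ½); the CI
across the five repeats is $\bar x \pm t_{0.975,k-1}\,s/\sqrt k$ (the
normal variant is selectable). Brier score is the mean squared error of
the probabilities. The threshold sweep predicts positive at
probability ≥ t over t = 0.01…0.50 (step 0.01 by default), with
precision marked `NA` when nothing is predicted positive. Calibration
uses ten equal-width bins on [0, 1] (last bin right-closed), dropping
empty bins — with few positives, fewer occupied bins is the expected
behaviour, not an error.

## Problem sizes and numerical choices

The shipped end-to-end experiment uses 120 patients (prevalence 0.4,
12–40 slices each, ~3,200 slices), preprocessing to 32×32 model inputs,
five repeated splits, and the same experiment on a label-shuffled null
cohort. Layer norm uses ε = 1e-5; probabilities are clamped to
[1e-12, 1−1e-12] inside cross-entropies; softmax subtracts the row
maximum; component ranking breaks ties by larger area then smaller label
id; `round_half_up(x) = floor(x + 0.5)` is used for split allocation
(base R `round()` rounds half to even). All randomness — cohort
generation, splits, initialization, shuffling, augmentation, dropout —
derives from explicit seeds, and evaluation-mode prediction is
deterministic.

## Known limitations

* The generator draws an independent vessel per slice; real stacks show
  correlated views of one artery, so inter-slice redundancy is
  understated (and positional encoding is therefore exercised only
  weakly).
* The `vgg16_style` path is implemented and shape-tested but not trained
  in the shipped experiments; desk-scale compute cannot fine-tune it.
* Patient-level max aggregation makes the patient probability an upper
  envelope of bag probabilities; with many bags per patient it is biased
  upward, which the calibration table will show as overconfidence in the
  upper range for many-bag patients.
* The warm-up and auxiliary loss are weak-label heuristics; with a
  pretrained encoder both should be disabled to recover the reference
  recipe exactly.
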