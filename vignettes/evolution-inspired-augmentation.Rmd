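---
title: "Evolution-inspired augmentation and the two-stage training curriculum"
author: "augseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution-inspired augmentation and the two-stage training curriculum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(augseq)
```

## The problem

Sequence-to-function models — convolutional networks that map a one-hot
encoded DNA sequence to chromatin accessibility, TF binding, or enhancer
activity — are limited by the amount of labeled data an assay can produce.
Unlike images, DNA admits few label-preserving transformations: beyond the
reverse complement and small shifts, any edit may disturb a regulatory
motif. The idea implemented here is to borrow the *kinds* of perturbation
that evolution applies to non-coding sequence — point mutation,
translocation, insertion, deletion, inversion, strand swap — and apply them
stochastically during training while keeping the wild-type labels. Each
individual perturbation may disrupt a motif, but on average motifs survive,
and the network is pushed toward representations that are robust to
position, order, spacing, and strand. Because the augmentations also impose
symmetries the biology may not share, training happens in two stages:
**pretraining** with online augmentation, then a short **fine-tuning** on
the original data that removes augmentation-induced bias.

## The augmentations

All transforms act on an L x 4 one-hot matrix under the fixed column order
(A, C, G, T); the complement map is A&harr;T, C&harr;G. Each is a pure
function of its input, its hyperparameters, and the RNG stream, and each
maps strictly one-hot input to strictly one-hot output (except Gaussian
noise, whose output is real-valued).

| transform | parameters (Basset defaults) | semantics |
|---|---|---|
| mutation | `mutateFrac` 0.15 | `round(L*frac/0.75)` positions drawn **with replacement**, each resampled uniformly over all 4 bases |
| translocation | `shiftMin` 0, `shiftMax` 30 | circular roll by a signed shift: magnitude uniform on the range, sign uniform |
| insertion | `insertMin` 0, `insertMax` 30 | random-DNA block of uniform random length at a uniform position; output always `L + insertMax` via random flank pads |
| deletion | `deleteMin` 0, `deleteMax` 30 | one contiguous block excised; random flank pads restore L |
| inversion | `invertMin` 0, `invertMax` 30 | one block replaced by its reverse complement in place |
| reverse complement | `rcProb` 0.5 | whole-sequence reverse complement with probability `rcProb` |
| noise | `noiseMean` 0, `noiseStd` 0.3 | i.i.d. Gaussian added elementwise |

The `deepstarrAugSettings()` preset (also used for ChIP-seq-style training)
differs in `mutateFrac` 0.05, `shiftMax`/`insertMax` 20, and `rcProb` 0.

Details worth spelling out:

* **Silent-mutation correction.** Resampling a drawn position uniformly
  leaves it unchanged with probability 1/4, so the draw count is inflated
  by 1/0.75; the *realized* changed fraction then averages `mutateFrac`.
  We round the draw count to the nearest integer. Draws are with
  replacement and no exclusion list is kept, so a position can be resampled
  twice (the last draw stands); for large `mutateFrac` the realized change
  fraction falls slightly below the target because of such collisions.
* **Translocation at zero.** The signed shift is drawn as magnitude times
  an independent sign, so when `shiftMin = 0` a zero shift (identity) is
  reachable; &minus;0 and +0 coincide, so zero is not double-weighted.
* **Endpoint conventions.** The insertion point ranges over `{0, ..., L}`
  (both ends allowed); deletion and inversion starts range over
  `{0, ..., L - len}`.
* **Pad arithmetic.** Leftover insertion length and deletion backfill are
  split as `floor(p/2)` nt 5' and the remainder 3', so odd remainders go to
  the 3' end. Random DNA is always uniform over the four bases.

## Scheduling and the curriculum

`augmentationCurriculum()` fixes the set of augmentations to sample from,
the per-sequence maximum `maxAugs`, and the mode: **hard** applies exactly
`maxAugs` per sequence, **soft** draws the count uniformly from 1 to
`maxAugs` (never 0 — every pretraining sequence receives at least one
augmentation). The subset is drawn without replacement, so a transform is
never applied twice to the same sequence, and is applied in the fixed
priority order inversion &rarr; deletion &rarr; translocation &rarr;
insertion &rarr; reverse complement &rarr; mutation &rarr; noise,
independent of draw order.

When insertion is in the set, every sequence of every batch must reach the
model at length `L + insertMax`; sequences whose own draw skipped the
insertion get a 3' random-DNA pad of length `insertMax`. The same rule
applies at validation and test time through `padForInference()` — no
augmentation is ever applied at evaluation time.

Reproducibility: the per-sequence RNG stream is derived from
`(seed, epoch, batch index, record index)` through a multiplicative mixing
function, so augmentation draws do not depend on processing order. During
validation the pad content is seed-fixed per training run.

## Training protocol

`pretrainConfig()` encodes the pretraining schedule: Adam, learning rate
1e-3, weight decay 1e-6, up to 100 epochs, early stopping at 10 epochs
without validation improvement, and learning-rate decay by 0.1 after 5
such epochs (the two patience counters are independent; "improvement"
means any strict decrease of the epoch's validation loss). The checkpoint
returned is always the one with the lowest validation loss.
`finetuneConfig()` encodes the second stage: learning rate 1e-4, weight
decay 1e-6, 5 epochs, no augmentation.

Two choices the protocol leaves open are made here and documented: the loss
is binary cross-entropy for binary task sets and mean squared error for
regression task sets (the community-standard pairing for these model
families), and the default batch size is 128 (configurable).

## Models

`bassetSpec()`, `deepstarrSpec()` and `chipCnnSpec()` are declarative layer
lists for the three reference architectures (conv blocks with batch norm
and ReLU, max pooling, dense blocks with dropout, sigmoid or linear heads).
`buildModel()` performs shape inference over the chain — convolutions are
valid (unpadded, stride 1) and pooled length is
`floor((len - size)/stride) + 1` — and fails at build time, naming the
offending layer, if any step would collapse the length to zero. Weights use
He-scaled (hidden) and Glorot-scaled (output) Gaussian initialization from
a caller-provided seed. The forward/backward engine lives in the package
(vectorized im2col convolutions in double precision); models are
deterministic at inference (dropout off, batch norm on running statistics).

`miniCnnSpec()` is the miniature used for desk-scale experiments: one conv
block followed by *global* max pooling and a small dense block. Global
pooling matters at small n: with only a few thousand training sequences, a
positionally resolved dense stack can memorize the training set without
ever learning the motif, whereas a translation-invariant detector
generalizes.

## Variant-effect scoring

For a saturation-mutagenesis experiment, each variant is scored
cell-type-agnostically as `log(mean_tasks f(alt) / mean_tasks f(ref))`
(natural log; the base only rescales scores and cancels in correlations).
The ref/alt pair differs at exactly one position, and for insertion-trained
models both members of a pair share the same 3' pad so the pad cancels in
the ratio. Elements shorter than the model window are centered with the
odd leftover base on the 3' side (`elementWindowOffset()`). Performance is
summarized per experiment by the Pearson correlation between measured and
predicted effect sizes and overall by the unweighted mean across
experiments; zero-variance experiments are excluded with a warning.

## Interpretability

`extractFilterPFMs()` aligns, for each first-layer filter, the
filter-width subsequences whose linear activation strictly exceeds half of
that filter's maximum over the scanned set (threshold fraction 0.5, the
activation-alignment convention; strict inequality, so a filter whose
maximum is not positive yields zero sites). Letter counts per offset give
a position frequency matrix; `writeMeme()` exports the probability form in
MEME minimal format for downstream comparison with Tomtom. The scanned set
is a user choice; the test split is a sensible default. Users matching
against JASPAR vertebrates conventionally exclude profiles MA1929.1 and
MA0615.1, which absorb low-information filters.

`attributionMap()` computes expected-gradient attributions with
uniform-random one-hot DNA references (default 1000, one uniform
interpolation sample per reference; the reference count controls estimator
variance). `gradientCorrection()` removes the per-position mean across the
four bases, after which every position's four scores sum to zero; the
correction is idempotent.

## The synthetic data generator

`syntheticDataset()` emulates a single-task binary peak classification:
uniform random background of fixed length, with consensus motifs planted in
positive records at uniform random offsets, perturbed by an independent
per-position substitution rate, and ground-truth placements recorded. This
captures what the augmentation/training machinery needs — a learnable,
position-randomized motif signal with known truth — but deliberately not
the trappings of real genomic data: no GC-content structure, no motif
grammar or cooperativity, no soft-labeled or ambiguous windows, no
assay noise model. Passing tests on it demonstrate that the mechanics
(augmentation semantics, scheduling, optimization, recovery of planted
signal) are correct, not that any particular biological benchmark score
would be reached.

## Problem sizes and numerical choices

The bundled experiments run at desk scale, chosen so the whole suite
completes in minutes on one CPU: the end-to-end check trains the miniature
detector on 2,000 sequences of 200 nt (70/10/20 split) with all seven
augmentations in soft mode (at most 2 per sequence), 5 pretraining epochs
and 2 fine-tuning epochs. Because that schedule allows only a few hundred
optimizer steps, the miniature run uses batch size 16 and a pretraining
learning rate of 5e-3 — a deliberately more aggressive setting than the
full-scale defaults above, which assume hundreds of thousands of sequences
and up to 100 epochs. Monte-Carlo checks of the augmentation statistics use
120,000 mutation draws and 10,000 reverse-complement trials.

Other numerics: batch-norm uses eps 1e-5 and running-statistics momentum
0.9; Adam uses the conventional (0.9, 0.999) moments with eps 1e-8 and L2
weight decay added to the gradient; dropout is inverted (scaling at train
time). PFM consensus ties break toward the alphabetically first base.
Degenerate settings (`mutateFrac = 0`, `max = 0` ranges, `rcProb = 0`,
`noiseStd = 0`) are exact identities, which the test suite asserts
bit-exactly.

## Known limitations

* The CNN engine is plain R: ample for the miniature and for exercising
  the full-size architectures on small batches, but not for training
  Basset-scale models on millions of sequences.
* Indel and shift length distributions are uniform by design; no
  transition/transversion bias or homology-aware augmentation is provided.
* N-containing sequences are rejected at encoding and removed by
  `filterN()` before splitting; soft-encoding ambiguous bases as 0.25 is
  deliberately not offered.
* The dataset container serializes via R's native format; FASTA/BED flow
  through Biostrings/rtracklayer.

## A worked miniature example

```{r example, eval = FALSE}
ds <- syntheticDataset(2000, 200,
                       motifs = list(list(consensus = "TGACTCAG",
                                          subRate = 0.1)),
                       embedProb = 1, seed = 42)
ds <- splitDataset(ds, c(0.7, 0.1, 0.2), seed = 42)
cur <- augmentationCurriculum(augmentationNames(), deepstarrAugSettings(),
                              maxAugs = 2, mode = "soft")
m <- buildModel(miniCnnSpec(220), seed = 42)
pre <- pretrainModel(m, ds, cur,
                     pretrainConfig(learningRate = 5e-3, maxEpochs = 5,
                                    batchSize = 16, seed = 42))
ft <- finetuneModel(pre$model, ds,
                    finetuneConfig(learningRate = 1e-3, maxEpochs = 2,
                                   batchSize = 16, seed = 43),
                    insertMax = 20)
vd <- splitSubset(ds, "valid")
p <- predict(ft$model, padForInference(seqArray(vd), 20, seed = 7))[, 1]
pROC::auc(pROC::roc(labelMatrix(vd)[, 1], p, quiet = TRUE))
```

On the fixed seeds above this reaches validation AUROC 0.91, and two of
the 32 first-layer filters have PFM consensi containing the planted
`TGACTCAG` exactly (see the test suite, which runs this end to end).
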