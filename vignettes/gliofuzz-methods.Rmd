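---
title: "Fuzzy-generated convolution kernels and gradient-free glioma grading: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-generated convolution kernels and gradient-free glioma grading: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliofuzz)
```

## The problem and the model

Discriminating high-grade from low-grade glioma (HGG vs LGG) on multi-modal
3D MRI is usually attacked with convolutional networks whose millions of
kernel coefficients are learned by backpropagation. `gliofuzz` implements a
radically more parsimonious alternative: every convolution kernel is
*synthesized* from two meta-parameters by a fuzzy inference system, and the
few remaining scalars are found by a population metaheuristic. No gradient
is computed anywhere in the package.

The pipeline has four stages:

1. **Kernel generation.** A filter gene `(w, code)` with both entries in
   `[0, 1]` is expanded into an `n`-coefficient kernel. The normalized
   kernel position `p_i = (i + 0.5)/n` and the gene's `code` are pushed
   through an interval type-2 (IT2) Takagi–Sugeno inference engine to give
   an intermediate pattern `Win_i`, and the coefficients are the cosine
   dispersion `W_i = 3 cos(pi * w * Win_i)`. A 3×3×3 filter therefore
   carries 2 trainable scalars instead of 27 — a 92.6 % per-filter
   reduction (`parameter_ledger()` audits this).
2. **Feature extraction.** A five-layer, forward-only 3D fully
   convolutional network (channels 8, 16, 32, 64, 128; same padding; no
   biases) with a single-slope parametric ReLU per layer
   (`max(a·x+b, c·x+d)` with `a = b = d = 0`), 2×2×2 max pooling after
   layers 1–4 and a global average pool after layer 5, yielding a 128-long
   feature vector for any input size.
3. **Gradient-free training.** Stage 1 tunes the genes and the five ReLU
   slopes by maximizing the Fisher trace ratio of the extracted features
   on a small stratified subset; stage 2 freezes them and trains a
   classification head — a softmax fully-connected layer optimized by the
   same metaheuristic, or a linear SVM warm-started from the optimized FC
   weight difference and refined by deterministic subgradient descent.
4. **Evaluation and segmentation.** Confusion-matrix metrics, MAE/RMSE,
   trapezoidal ROC–AUC, stratified K-fold orchestration, and a simplified
   whole-tumor segmenter (fuzzy c-means on brain-voxel intensities plus
   morphological refinement) scored by Dice.

## The IT2 Takagi–Sugeno engine

Each antecedent universe carries three triangular terms Low, Mid, High
with peaks 0, 0.5, 1. The footprint of uncertainty is realized by support
perturbation: upper half-support `h + delta`, lower `h - delta`, with
`h = 0.5`, `delta = 0.1`. These values were fixed once, for three reasons:
full overlap of adjacent terms (every input fires at least one rule), a
non-degenerate membership interval everywhere except the peaks, and a
symmetric layout of the terms themselves.

The rule base maps the 3×3 antecedent product to singleton consequents
`L = 0.25, M = 0.50, H = 0.75` (by `code` column over numin Low/Mid/High:
Low → L, M, H; Mid → H, M, L; High → H, L, H). Firing intervals use the
min t-norm; type reduction is the Nie–Tan closed form — the
average-firing-strength weighted mean of the consequents — chosen over
Karnik–Mendel iteration because it is deterministic, loop-free and exactly
testable.

Two consequences of this design are worth stating explicitly:

* The output always lies in `[0.25, 0.75]`, so with `w ∈ [0, 1]` the
  cosine argument spans less than a full period and kernels stay
  sign-diverse with `|W_i| ≤ 3`.
* The rule map itself is *not* symmetric under jointly reflecting both
  antecedents about Mid (the `(Mid, High) → L` and `(Low, Mid) → H`
  entries break it). The midpoint inference `s(0.5, 0.5)` is therefore not
  the Mid consequent 0.5 but exactly 0.5125: the center rule fires with
  mean strength 1, the eight off-center rules each with mean strength
  1/12, and their consequents sum to 4.25. The unit suite freezes this
  value against an independent pointwise implementation. A fully
  symmetric variant can be obtained by passing a modified rule table to
  `default_rulebase()`, but the shipped default keeps the published rule
  map.

The consequent singletons and the per-position universe `(i + 0.5)/n`
(half-offset to avoid the degenerate endpoints of the Low/High terms) were
design decisions where the method description was silent; they are
exposed as arguments so the sensitivity can be explored.

## Optimizers

All three optimizers minimize over a bounded box, clamp every candidate,
and draw all randomness from a single seeded generator per run, so runs
are bit-reproducible. The evaluation budget is exactly
`population × (iterations + 1)` (the `+1` is the initial population),
which the tests assert.

* **PSO** uses the standard constriction-equivalent constants (inertia
  0.729, cognitive = social = 1.49445) with velocities clamped to half
  the box range.
* **The transit-search-style explorer** gives each host one move per
  iteration: with probability 0.5 a *transit* probe toward the global
  best plus heavy-tailed Cauchy noise (scale 0.05 of the range), with
  probability 0.25 a blend recombination with a random other host, and
  otherwise a Gaussian *exploitation* sample around the global best whose
  radius starts at 0.3 of the range and shrinks by 0.95 per iteration.
  Moves are accepted greedily and the global best is elitist.
* **The hybrid** spends the first half of the iteration budget (the split
  is configurable) on the explorer and hands its final population —
  global best included — to PSO, so the final best can never be worse
  than the explorer's.

The classification objective is supplied in minimization form (negative
Fisher ratio in stage 1, mean cross-entropy in stage 2); non-finite
objective values are mapped to `+Inf` and counted rather than crashing
the swarm.

## Two-stage training

Stage 1 searches the concatenated gene coordinates (each in `[0, 1]`) and
the five ReLU slopes (in `[0.05, 2]`; slopes must be strictly positive
and the upper bound keeps activations from exploding through five
layers). In layer-tied mode — the desk-scale default — one gene serves a
whole layer and the search space has `2 × 5 + 5 = 15` dimensions; untied
mode has `2 × 248 + 5 = 501`.

Because a filter's kernel is replicated across its input channels, the
channel sum commutes with the convolution; the forward pass exploits this
and convolves the channel-sum once per output kernel. This is an exact
algebraic identity, not an approximation, and it is what makes
metaheuristic training (tens of thousands of forward passes) tractable on
one CPU.

Features entering stage 2 are z-scored per dimension with the training
split's statistics (stored in the model); raw deep activations can span
many orders of magnitude depending on the genes, and standardization
keeps the head's box bounds `[-5, 5]` meaningful. Stage 2 never touches
the stage-1 parameters, which the suite verifies by identity comparison
before and after head training.

The SVM head follows the design in which its weights derive from the
optimized fully connected layer: the FC optimization runs first, the
difference vector of its two class columns initializes the SVM, and
full-batch subgradient descent on the L2-regularized hinge loss
(`lambda = 1e-3`, 200 epochs, learning rate `0.5/(1 + 0.05·epoch)`)
refines it deterministically. Decision ties at exactly zero score go to
the negative (LGG) class.

## The synthetic cohort as study conditions

The generator emulates the cohort structure of the real study: 230 HGG
and 70 LGG cases split 220/40/40 (per class 172/32/26 and 48/8/14), four
co-registered channels with T1-, T1ce-, T2- and FLAIR-like contrasts. The
class signal is carried by three effects chosen to mirror what
radiologists use: HGG lesions are larger (radius 0.18–0.28 of the short
axis vs 0.08–0.14), carry a bright contrast rim (+0.5 in the T1ce-like
channel) and extra FLAIR hyperintensity (+0.15), and have multiplicative
core speckle (sd 0.3); LGG lesions are small and homogeneous. All
channels receive Rician-like noise (magnitude of a complex Gaussian,
sd 0.05) because MRI magnitude data is Rician, and the preprocessing
chain should be exercised under that floor. These defaults are the study
conditions of the test battery and are not tuned per experiment.

What the generator does *not* emulate: bias fields, motion, multi-site
intensity shifts, anatomical texture beyond a smooth random field, or
infiltrative lesion geometry. Passing tests therefore demonstrate that
the machinery works and that the method recovers a planted, moderately
noisy class structure — not that the headline real-data performance of
any published system is reproduced.

## Problem sizes and numerical choices

Desk-scale defaults keep the full battery on one CPU in minutes: volumes
32×32×16, layer-tied genes, and for the end-to-end recovery experiment a
100-case cohort (80 train / 20 test, class ratio 70/30), stage-1 subset
40, 30 hybrid iterations with population 12, and an 80-iteration stage-2
head fit. At these sizes two-stage training reaches perfect test accuracy
on the default cohort with both heads; the acceptance suite requires at
least 0.90. The K-fold demonstration uses K = 2 on a 20-case cohort with
a correspondingly reduced stage-1 budget. Full-scale settings
(128×128×N volumes, untied genes, population 16, 50 stage-1 iterations
on a 100-image subset) are reachable through the same configuration
objects.

Other numerical conventions: same-padding convolutions (preserving the
power-of-two pooling ledger); replicate-padding of odd dims before
pooling so any depth is legal; no biases anywhere; softmax computed with
max-logit subtraction; degenerate (constant-brain) channels normalize to
zeros with a warning rather than an error; both-empty Dice defined as 1;
metrics with zero denominators reported as `NA`, never silently 0; the
ROC–AUC is computed by threshold sweep *and* by the rank-sum equivalence
with half-credit ties, and the two must agree to 1e-12 at every call.

## Segmentation stand-in

The network has no decoder, so the segmenter is deliberately simple:
3-cluster fuzzy c-means (fuzzifier 2, tolerance 1e-5, centers initialized
at the 10th/50th/90th intensity percentiles, hence deterministic) on the
brain voxels of one channel, taking the highest-center cluster as the
candidate, then opening (radius 1), closing (radius 2), largest
26-connected component, hole filling. The driving channel defaults to
the contrast-like one; on synthetic HGG cases, whose T1ce signal is
rim-dominated, the FLAIR-like channel segments the whole lesion better,
and the channel is an explicit argument for exactly this reason. On
bright-lesion phantoms the suite requires Dice ≥ 0.8 and near-empty
masks on lesion-free phantoms; no claim is made about real-data Dice.

## Known limitations

* The grading head is binary (HGG/LGG); no multi-class grading.
* Skull stripping is intensity-and-morphology based, adequate for
  phantoms and synthetic data; real clinical use would substitute an
  atlas-based tool.
* The transit-search explorer is a documented scheme with the standard
  transit/neighbor/exploitation phase structure, not a re-derivation of
  any specific published variant.
* Metaheuristic head training is slower and less precise than a convex
  solver; it is kept for fidelity to the two-stage design, and the SVM
  path provides the deterministic alternative.
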