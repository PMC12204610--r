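---
title: "PrimeNet: model, training scheme and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PrimeNet: model, training scheme and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primenet)
```

## The prediction problem

A prime-editing experiment on one target locus yields three outcome
fractions that sum to roughly 100%: the *validly edited* fraction (the
intended edit), the *unedited* fraction, and the *erroneously edited*
fraction (indels and other unintended products). PrimeNet is a
convolutional regression model that predicts this triple for a
pegRNA–target pair from

* the wild-type and edited target sequences (typically 99 nt),
* per-base chromatin accessibility (DNase peaks) and CpG methylation
  (RRBS calls) at the locus, and
* the functional-region layout of the pegRNA on the target: protospacer,
  PAM, primer-binding site (PBS) and reverse-transcriptase template (RT).

The motivation for carrying the epigenetic tracks is mechanistic: Cas9
binding and pegRNA annealing require physical access to the DNA, so
closed chromatin or a hypermethylated protospacer/PAM suppress editing in
ways sequence-only models cannot see.

## Input encoding: the pseudo-image

Each record becomes a binary block of shape **128 positions × 8
channels × 2 sequences** (wild at slice 1, edited at slice 2):

| channel | content |
|---|---|
| 0–3 | one-hot base identity (A→0, G→1, T→2, C→3) |
| 4 | DNase accessibility (1 = accessible) |
| 5 | CpG methylation (1 = methylated) |
| 6 | protospacer ∪ PAM ∪ PBS |
| 7 | RT template |

Sequences are left-aligned and zero-padded on the right to 128; padding
carries no signal by construction. Channel 6 deliberately carries the
union of protospacer, PAM *and* PBS, with RT alone on channel 7 — the
encoding assigns both groups to channel 6 and we follow that assignment
verbatim rather than splitting PBS out.

Two choices the encoding itself leaves open:

* **Edited-sequence epigenetics.** Accessibility and methylation are
  locus properties measured on the unedited genome. For indel edits we
  derive an ungapped correspondence from the longest common prefix and
  suffix of the two sequences; matched positions copy the wild
  annotation, inserted bases get 0. Region channels map through the same
  correspondence, with an inserted base inheriting a region only when
  both flanking matched positions lie in it (so an insertion inside the
  RT template stays RT).
* **Strand.** Tracks are strand-agnostic; for a minus-strand anchor the
  window readout is reversed so channel positions always align with the
  written 5′→3′ wild sequence.

Records without a genomic anchor are encoded with all-false epigenetic
channels (unknown = inaccessible/unmethylated) and a logged note, keeping
the tool usable on sequence-only inputs.

Multi-lab tracks are merged by union: a base is accessible (or
methylated) if *any* contributing dataset marks it. Methylation calls
are treated as 1-bp point intervals; no beta-value thresholding is
applied. Whether a methylation "site" should instead cover the CpG dyad
is left to the caller (supply 2-bp intervals if so).

## Architecture

The forward pipeline is

```
input (128 × 8 × 2)
  → spatial conv-attention (gate on the input)
  → MixConv: kernels 1×2 / 3×2 / 9×2, 16 channels each → 48 channels
  → channel attention (efficient-channel-attention form)
  → 1×1 compression to 32 channels
  → conv (k = 3) → ReLU → conv-attention
  → conv (k = 3) → ReLU → conv-attention
  → flatten → shared trunk (256) → three exclusive branches (64 → 1)
  → sigmoid × 100 per head
```

Internally the wild/edited axis is folded into the channel axis
(8 × 2 → 16 input channels), so the seq-extent 2 of the printed MixConv
kernels is consumed as input channels and every convolution runs along
the 128-position axis with zero "same" padding. The three MixConv scales
capture point features (1), local context (3) and longer-range structure
(9) in one concatenated representation.

The two attention forms are purely multiplicative gates:

* **Conv-attention (spatial).** Per-position mean and max over channels
  (2 maps) → 1-D convolution, kernel 5 → sigmoid → one weight per
  position, broadcast over channels. A softmax variant (weights summing
  to 1 over positions) is kept behind
  `conv_attention_activation = "softmax"` to support the ablation;
  sigmoid is the default because independent per-position weights suit
  inputs where many regions matter at once.
* **Channel attention.** Global average pooling per channel → 1-D
  convolution across the channel axis (kernel 3) → sigmoid → one weight
  per channel. This is the minimal-parameter "adaptive pooling +
  convolution" form.

The head gives each target its own parameters after a shared trunk, so a
gradient on one efficiency never updates another head's exclusive
weights (verified by test). Each branch ends in a sigmoid scaled to
[0, 100]. **No sum-to-100 constraint is imposed on the three outputs**:
the mechanism that would normalize them is not part of the stated model,
so predicted triples may sum slightly off 100 — users needing a
composition should renormalize downstream.

Hidden activations are rectifiers (the stated design is silent on this).
Channel widths (16 per branch → 48 → 32 → 32/32, trunk 256, branch 64)
are defaults exposed through `modelConfig()` and are intended to be
tuned by `tuneHyperparameters()`, not claims about any reference
implementation.

There is no deep-learning framework dependency: forward and backward
passes for every layer are implemented directly on BLAS-backed matrix
products (convolutions as im2col GEMMs with the column matrix shared
between passes). The hand-written gradients are verified against
central finite differences in the test suite, which is also what makes
the attribution methods below exact rather than approximate autodiff.

## Training scheme

* **Orthogonal initialization.** Every weight, viewed as its 2-D
  (output × fan-in) matrix W, is set so WᵀW = I (fan-in ≤ fan-out; WWᵀ =
  I otherwise); biases start at exactly 0. Singular values of 1 at every
  layer keep early gradients from vanishing or exploding.
* **Lookahead-wrapped Adam.** Slow weights φ and fast weights θ; k
  inner Adam steps θᵢ = θᵢ₋₁ + A(L, θᵢ₋₁, d), then
  φ ← φ + α(θ_k − φ) and θ is reset to φ. Defaults k = 5, α = 0.5
  (the values recommended in the original Lookahead work), inner
  learning rate 1e-3, batch 256 — all explicit stand-ins exposed in
  `trainConfig()`, since the original settings are not published.
* **Loss.** Mean squared error on the percent-scale triple, equal head
  weights — the simplest defensible regression loss; configurable in
  principle but deliberately not proliferated.
* **Splits.** 8:1:1 train/validation/test by seeded shuffle and
  contiguous cut; multiple cohorts (e.g. cell lines) are merged and
  re-shuffled with provenance tags retained per sample.
* **Model selection.** The validation Spearman of the validly-edited
  head drives early stopping (patience 10 by default), best-epoch
  selection and the hyperparameter search objective — one consistent
  criterion throughout. The search harness is random search over a
  declared space (learning rate, widths, attention switches, attention
  kernel/activation); the sampler is pluggable and outside the
  correctness surface.

Every training run records its seeds and settings in a manifest, and
checkpoints bundle configuration + parameters + the initialization seed,
so any run is replayable bit-for-bit on one device.

## Evaluation protocol

`evaluateModel()` reports, per head: Spearman ρ (average ranks on ties),
Pearson r, and ROC/PR AUC after binarizing the *observed* value at 50%
(strictly greater than 50 is positive; exactly 50 is negative). The
continuous predicted efficiency serves as the classifier score —
binarizing the predictions too would collapse the curve to a single
point, so the continuous-score reading is used and documented.

`mannWhitneyU()` computes U = #{a > b} + ½·#ties. The two-sided p-value
is exact whenever n₁·n₂ ≤ 400 — the full tie-aware permutation
distribution of U, obtained by dynamic programming over the doubled
ranks (identical to enumerating all group assignments, without the
combinatorial blow-up) — and otherwise uses the normal approximation
with tie and continuity corrections. Records are grouped as "completely
open" (every position of the wild window accessible) vs "presence of
closure", and "with" vs "without methylation" (≥ 1 methylated
position). The whole window defines openness because the stated
grouping does not restrict it; a protospacer∪PAM-only variant is a
one-line change on the annotation slice.

## Interpretability

* **Integrated gradients.** Straight-line path from an all-zeros
  baseline (default; configurable) to the input, Riemann-midpoint rule
  with m = 256 steps, all evaluated in one batched forward/backward
  pass. Completeness (Σ attributions = F(x) − F(baseline)) holds to
  ~0.1% on trained models in the test suite. Note that attribution is
  gradient × input, so a channel that is empty in a record receives
  exactly zero attribution — statements about attribution localization
  are meaningful only on records that carry the feature.
* **Epigenetic channel optimization.** Starting from the top-200
  records by observed efficiency, gradient ascent on one epigenetic
  channel (4 or 5) with all other channels' gradients masked to zero and
  values clamped to [0, 1] each step (defaults: 200 steps, step 0.01);
  the optimized channel is averaged into one 128 × 2 profile. Both the
  wild and edited slices are emitted, since which the original averaged
  is unstated. Masked channels are bit-identical before and after
  (tested).
* **Attention maps.** The spatial weight maps of every conv-attention
  site (input stage and after each trunk conv) are captured during
  forward passes and averaged over images, aligned to the 128-position
  frame.

## Synthetic data: what it emulates, and what it does not

`simulateDataset()` produces records on one synthetic chromosome
("chrS", windows every 200 bp): 99-nt wild sequences with a CpG
enrichment knob, a canonical region layout centred on a 20-nt
protospacer at position 10, NGG-sized PAM, nick after protospacer
position 17, PBS of 8–17 nt ending at the nick and RT template of
10–30 nt starting there (defaults centred on the 13-nt PBS / 15-nt RT
worked layout). Edits are substitutions (85%) or 1–2-nt indels inside
the RT template. Accessibility follows an open/closed block model
(geometric blocks, mean 300 bp, 35% open) emitted as a BED track;
methylation is Bernoulli(0.3) per CpG cytosine emitted as 1-bp
intervals, both on the same coordinates the records are anchored to, so
the interval-annotation path is exercised end to end.

The planted outcome model is a latent score

s = β₀ + β_acc·accFrac(proto∪PAM) − β_meth·methFrac(proto∪PAM)
  + β_gc·GC(PBS) + ε,  ε ~ N(0, σ)

mapped through a 3-way logistic (logits s, −s, and a fixed erroneous
logit of −1) to an expected triple on the 100-simplex, with observed
triples drawn from a Dirichlet around the expectation (concentration
200 by default). Defaults β_acc = 2, β_meth = 1, β_gc = 1, σ = 0.5.

The `recovery` fixture (5000 records, seed 103) strengthens the planted
effects as its purpose demands: β_meth = 1.5, σ = 0.25, concentration
300. Under these settings the best achievable held-out Spearman from
the planted features alone is ≈ 0.81 (the latent noise realization is
not learnable); the trained model reaches ≈ 0.80–0.81, i.e. the
information ceiling, and zeroing channel 4 at prediction time collapses
it to ≈ 0.1–0.2 — the network demonstrably uses the accessibility
channel.

What the generator does **not** emulate: the empirical efficiency
distributions of real screens (real triples are far more skewed), the
real edit-type spectrum, sequence-composition biases around real loci,
correlated multi-mark epigenetics, or measurement error structure
beyond Dirichlet dispersion. Passing the recovery tests therefore shows
the pipeline can extract planted sequence/epigenetic signal end to end —
it does not certify real-data accuracy. One consequence worth noting:
the whole-window methylation grouping is usually *not* significant on
synthetic cohorts (the planted methylation effect is small and confined
to protospacer∪PAM), unlike the strong contrasts reported on real data.

## Numerical and scale choices

* Problem sizes in the checks were chosen to make the suite comfortably
  reproducible on a laptop-class single core: the recovery run trains
  ≤ 15–20 epochs at batch 256 on 4000 training records (a few minutes);
  gradient checks run on a 16-position micro-architecture; exact
  Mann–Whitney enumeration cross-checks stay at n ≤ 9 where literal
  enumeration is feasible.
* The recovery training uses learning rate 3e-3, selected by the
  package's own tuning criterion (validation Spearman of the valid
  head) over a small candidate set; the package-wide default stays at
  the conservative 1e-3.
* Ties in top-sequence selection break by record id; dataset splits cut
  floor(0.8n)/floor(0.1n)/remainder; QR-based orthogonal init fixes the
  sign of the R diagonal so a seed fully determines the draw.
* Degenerate inputs: zero-variance vectors yield NA correlations (not
  errors); single-class labels yield NA AUCs with a warning; unknown
  chromosomes annotate as all-false with a logged note.

## Known limitations

* Predicted triples are not constrained to sum to 100 (see above).
* The Bayesian sampler of the original tuning protocol is replaced by
  seeded random search behind the same objective contract; plugging in
  an adaptive sampler is supported but not bundled.
* Genome alignment is out of scope: genomic anchors must be supplied
  (or epigenetic channels default to empty).
* Training is single-device and CPU-oriented; the architecture defaults
  here are tuned for the synthetic recovery task, not for real screens,
  where a fresh hyperparameter search is advised.
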