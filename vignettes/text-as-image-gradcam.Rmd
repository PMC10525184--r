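---
title: "Text-as-image classification with Grad-CAM explanations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Text-as-image classification with Grad-CAM explanations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`textcam` classifies short documents — the motivating case is clinical
abstracts, where a reader must justify why a text was routed to a disease
category — by recasting text classification as image classification:

1. **Preprocessing.** Each document is tokenized (lower-cased, whitespace
   split, leading/trailing punctuation stripped) and written row-major into
   a fixed `H x W` token grid, 25 x 25 by default. 625 cells accommodate
   documents of up to 600 tokens; shorter documents are padded with the
   `"#"` symbol, longer ones truncated with a warning. Relative token
   positions are preserved in two dimensions, so a convolutional network
   can exploit local co-occurrence the way it exploits neighbouring pixels.
2. **Embedding.** Skip-gram word2vec with hierarchical softmax is trained
   on the *raw* training-split token sequences (never on validation text).
   Each grid cell is replaced by its D-dimensional word vector, giving a
   `D x H x W` array in which embedding dimensions play the role of image
   channels. The pad symbol and all out-of-vocabulary tokens map to the
   zero vector, so pad regions are exactly silent.
3. **Classification.** A ResNet-18 over the `D`-channel grid: 7x7/2 stem,
   3x3/2 max pool, four stages of two basic residual blocks, global average
   pooling, linear head. Transfer learning replaces only the input
   convolution (3 -> D channels) and the head (-> C classes); every interior
   weight is copied from the donor backbone bit-exactly, which the test
   suite verifies by fingerprinting. Training is SGD (lr 0.1, momentum 0.9,
   weight decay 5e-4, batch 128, cross-entropy), and the checkpoint with
   the best validation accuracy is retained.
4. **Explanation.** Grad-CAM: for class score `y_c` (the pre-softmax
   logit — the original formulation; probabilities would couple classes
   through the softmax) and target-layer activations `A_k`, the channel
   weights are `alpha_k = mean_jk dy_c/dA_k[j,k]` and the map is
   `ReLU(sum_k alpha_k A_k)`, bilinearly upsampled to the token grid and
   min-max normalised. Because grid cells are tokens, the map reads
   directly as token importance and is rendered as a heatmap, highlighted
   HTML, and a JSON sidecar.

A LeNet-style 1-D CNN over the unformatted (but length-625 padded) token
sequence and a tf-idf multinomial naive Bayes model serve as baselines for
the question "does the 2-D formatting earn its keep?".

## Parameters that matter

| parameter | default | why |
|---|---|---|
| grid `H x W` | 25 x 25 | 625 slots hold the 600-token maximum of the reference corpus |
| pad symbol | `"#"` | injected after tokenization; embeds to the zero vector |
| embedding dim `D` | 100 | reference configuration; also the CNN input channel count |
| word2vec window | 100 | reference configuration: effectively whole-document context for abstracts |
| word2vec min_count | 1 | every training token stays in vocabulary |
| word2vec epochs | 5 | not fixed by the reference recipe; conventional default |
| learning rate / momentum / weight decay | 0.1 / 0.9 / 5e-4 | reference recipe; momentum and the constant schedule are conventional fill-ins |
| batch size / epochs | 128 / 25 | reference recipe |
| validation fraction | 1/5 | reference protocol, stratified by class |
| Grad-CAM target layer | deepest stage with spatial map >= 5x5 | see below |

## Design choices that were genuinely open

**No deep-learning or word2vec dependency.** The surrounding toolchain has
no R-side neural-network framework, so the convolution/batch-norm/residual
stack (with explicit reverse-mode gradients) and the hierarchical-softmax
skip-gram trainer are implemented in the package, with C++ kernels for the
convolution, pooling and embedding inner loops. The explicit backward pass
is not a liability for the explanation module — it is exactly the hook
Grad-CAM needs: the gradient of a logit at any named node is available by
stopping the reverse sweep there. Gradients are validated against central
finite differences in the test suite.

**Synthetic "pretrained" donor.** Publicly distributed ImageNet weights
cannot be bundled or downloaded in the build environment, so
`pretrained = TRUE` draws interior weights from a *synthetic* donor: the
same backbone pretrained at run time on a generated 3-channel pretext task
(keyword-planted token grids with their own vocabulary, mirroring the RGB
channel count of natural-image pretraining). The transfer-surgery
mechanics — what the method actually prescribes — are faithful: interior
weights preserved bit-exactly, input convolution and head freshly
He-initialised. On the synthetic benchmark the qualitative transfer
pattern reproduces: pretrained-plus-fine-tuned beats training from scratch
at an equal small epoch budget, and both beat the mismatched mode.

**The mismatched ablation mode.** The reference ablation includes a mode
in which pretrained 3-channel weights meet the 100-channel text input — a
shape contradiction that cannot have produced a conventional forward pass
and performs at chance in the source experiments. It is reconstructed
here deliberately and flagged: the donor's 3-channel input convolution is
kept, forward passes read only the first three input channels, the head
is replaced for shape alone, and the model is evaluation-only
(`train_classifier()` refuses it). It exists so the ablation can be run,
not as a usable configuration.

**Grad-CAM target layer.** For 25 x 25 grids the four residual stages have
7x7, 4x4, 2x2 and 1x1 spatial maps; the deepest layers cannot localise.
The initial design rule "deepest stage of at least 4x4" selected stage 2,
but measurement on the planted-keyword benchmark showed 4x4 maps too
coarse to separate keyword from neighbouring non-keyword cells
(localisation ~0.65), while the 7x7 stage-1 output localises at ~0.94 and
the stem at ~1.0. Since the whole point of the rule is to preserve
localisation while staying deep, the default became "deepest stage of at
least 5x5" — stage 1 at this input size — and remains user-overridable
(`cam_config(target_layer = ...)`).

**Eval-mode batch-norm gradients.** In evaluation mode the normalisation
statistics are constants, so the correct gradient is `gamma / sd * dout`;
applying the training-mode formula (which differentiates through the batch
statistics) silently destroys CAM quality while leaving training intact.
This package computes the eval-mode form for eval-mode passes; the
finite-difference tests cover the full residual network in both modes.

**Other numerical conventions.** All-zero raw maps normalise to all-zero
scores (no division by zero). Per-class precision/recall/F1 use the
`0/0 -> 0` convention. Localisation ties count as failures, keeping the
statistic deterministic. Bilinear upsampling aligns corners. Over-length
documents truncate at `H*W` tokens. Class labels are `0..C-1` integers
throughout. The run configuration file is JSON (no YAML/TOML parser is
available in the dependency set).

## What the synthetic generator does and does not establish

The generator plants class signal the way the measurement needs it: each
token of a class-`c` document is, independently, a class-`c` keyword with
probability `keyword_rate` (default 0.3) or a shared-noise token
otherwise; document lengths are uniform on 30–600 tokens; keyword
positions are recorded exactly. Defaults (5 classes, disjoint 20-keyword
sets, 500-token noise vocabulary) emulate the shape of the reference
corpus — five imbalanced-capable categories, bounded length — not its
language: there is no syntax, no polysemy, no shared terminology between
classes, and evidence is scattered rather than phrasal.

Consequently a green end-to-end test establishes that the pipeline learns
and that attention concentrates on the planted evidence
(validation accuracy >= 0.9, localisation >= 0.8 on correctly classified
validation documents at desk scale: 2,000 documents, 16-dim embeddings,
width-16 backbone, 5 epochs, CPU). It does *not* establish the reference
corpus's headline numbers (weighted recall/precision/F1 around 90% after
25 epochs on 14,438 abstracts), which require the external corpus and
full-scale training and are out of scope here.

## Known limitations

- Grad-CAM explains *where* evidence is, not *why*; it is qualitative, and
  the localisation score is a synthetic proxy, not a clinical validation.
- The synthetic donor is a stand-in: absolute transfer gains from real
  ImageNet weights are not reproduced, only the direction of the ablation.
- The 1-D CNN baseline's layer sizes follow a conventional LeNet
  translation and are configurable because no canonical translation
  exists.
- Single-threaded CPU training: practical for desk-scale corpora
  (thousands of documents), not for production-scale training.
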