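---
title: "IIP-Net: channel attention with feed-forward propagation for colonoscopy image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IIP-Net: channel attention with feed-forward propagation for colonoscopy image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Colonic polyps have faint surface texture, vary widely in size and
position, and are easily confused with folds or residue, so classifiers
for colonoscopy frames benefit from channel attention: re-weighting feature
channels by globally pooled evidence.  The IIP-Net family adds one twist to
standard squeeze-style attention — *information interaction*: each
attention block emits its channel weight vector, and the next attention
block consumes it, so attention information flows forward between modules
instead of being recomputed from scratch at every depth.

### The CIIP block

A channel information interaction perception (CIIP) block first deepens the
network through a **convolutional short connection**: a
`1x1 (reduce) -> 3x3 -> 1x1 (restore)` bottleneck, each convolution
followed by LayerNorm and ReLU, added elementwise to its input.  Channels
are reduced by a factor of 4, matching the backbone's bottleneck pattern
(e.g. 256 -> 64 -> 64 -> 256).  Call its output $X \in
\mathbb{R}^{C\times H\times W}$ and let $g = \mathrm{GAP}(X)$ be the
channelwise spatial mean.

The block then dispatches on whether an attention vector arrived from a
predecessor:

* **First branch** (no incoming attention): with $s = \sigma(g)$,
  $$X' = s \otimes X, \qquad \mathrm{Att} = s \otimes g .$$
  This branch has *no learned attention parameters*; serializing it stores
  only the bottleneck weights.

* **Follow-up branch** (incoming $\mathrm{Att}_1$ of length $C_{prev}$):
  the incoming vector is passed through a linear channel-matching map
  followed by LayerNorm and ReLU, $a = \delta(\mathrm{LN}(\ell(\mathrm{Att}_1)))$,
  added elementwise to the pooled features, pushed through a `1x1`
  attention convolution composite ending in a sigmoid,
  $m = \sigma(\mathrm{LN}(W_{att}(a \oplus g)))$, and the single gate $m$
  produces both outputs:
  $$X' = m \otimes X, \qquad \mathrm{Att} = m \otimes g .$$

Design choices worth stating explicitly, since the scheme leaves them open:

* $\oplus$ is elementwise addition of the two length-$C$ vectors (the
  symbol's own definition); the alternative reading — concatenation
  followed by a channel-halving convolution — is noted but not implemented.
* One gate $m$, computed from the *incoming* attention vector, multiplies
  both $X$ and $g$; the two gate equations are not given independent
  parameters.
* The attention "convolution" acts on a length-$C$ vector treated as
  $C\times 1\times 1$, i.e. it is a $C \to C$ linear map; it preserves
  vector length.
* Attention is computed per sample within a batch; no statistics cross the
  batch dimension except in the backbone's BatchNorm.
* LayerNorm uses $\varepsilon = 10^{-5}$ and learnable per-channel affine
  parameters.  For feature maps it normalizes each sample over all of
  $(H, W, C)$.
* `ciip_params(att_norm = FALSE)` removes the LayerNorm inside the
  attention convolution composite.  This exists because LayerNorm can never
  be the identity map, and a pass-through configuration (identity $W_{att}$,
  silent attention path) is the natural way to verify that the follow-up
  gate degenerates to the first-branch gate; real models always keep it on.

### The backbone

`build_model()` assembles IIP-Net54/105/156: a `7x7/64` stride-2 stem with
BatchNorm and ReLU, a `3x3` stride-2 max-pool, four residual bottleneck
stages with channel widths 64/128/256/512 (outputs 256/512/1024/2048) and
stage multipliers (2,3,5,3), (2,3,22,3) or (2,7,35,3), and a CIIP block
after each of stages 1-3.  The first CIIP block takes the first branch;
the second and third consume their predecessor's attention vector, which is
how the chain in `model_forward()` is wired.  Backbone convolutions carry
BatchNorm (momentum 0.1, $\varepsilon = 10^{-5}$) rather than LayerNorm.

Where the published structure table is silent we follow residual-network
convention: stride 2 sits on the `3x3` convolution of the first block of
stages 2-4 (stage 1 keeps stride 1); `1x1` projection shortcuts with
matching stride appear in the first block of each stage and nowhere else;
ReLU follows the residual addition.  Convolutions feeding a normalization
layer carry no bias.  Weights are He-uniform initialised, biases zero,
normalization affine parameters one/zero; everything draws from R's RNG so
`set.seed()` reproduces a model bit for bit.

The depth names count weight-bearing layers: the stem, three convolutions
per bottleneck block, 3 layers for the first CIIP block, 5 for each
follow-up CIIP block (its bottleneck plus the channel-matching FC and the
attention convolution), and one classifier layer — e.g.
$54 = 1 + 3(2{+}3{+}5{+}3) + 3 + 5 + 5 + 1$.  Projection shortcuts and
normalizations are uncounted, as in the ResNet naming convention.

### Classifier heads

All three heads consume the final $H\times W\times D$ map ($8\times 8
\times 2048$ at 256-pixel input) and end in softmax over $k$ classes:

| head | structure | parameters |
|------|-----------|------------|
| FC | one linear layer on the flattened map | $HWDk + k$ |
| GAP-FC | GAP, per-channel scale, one linear layer | $D + Dk + k$ |
| C-GAP | `1x1` convolution, per-position bias, GAP | $HWk + Dk + k$ |

The closed forms are the family's defining parameter budgets; the GAP-FC
per-channel scale and the C-GAP spatial bias grid are how this
implementation realises the $D$ and $HWk$ terms as actual learnable
scalars, so the exhaustive counter in `count_params()` reproduces
`head_params()` exactly.  The GAP heads accept any input size; the C-GAP
bias grid is bilinearly interpolated at non-native sizes (as positional
embeddings usually are), and the FC head is fixed-size by construction.

## Complexity accounting

`count_flops()` counts one multiply-add per convolution or linear
multiply-accumulate: $k_h k_w C_{in} C_{out} H_{out} W_{out}$ per
convolution, $in \times out$ per linear layer; pooling, normalization and
activations are free.  Under this convention the three depths at 256-pixel
input cost 5.34, 10.19 and 15.04 GMACs (FC head), giving depth ratios of
about 1.91 (105/54) and 2.82 (156/54).  The ratios are insensitive to the
input size and to the FLOPs-per-MAC convention — both numerator and
denominator scale identically — so they are a stable fingerprint of the
block layout itself.  They are, however, sensitive to where attention
blocks sit: adding a single further bottleneck-equivalent (for example an
attention stage after stage 4) lowers them to about 1.86 and 2.72.  We
implement exactly three CIIP blocks, as the structure table specifies, and
report the honest counts of that model.

Whole-model parameter counts come from exhaustively summing every learnable
scalar; BatchNorm running statistics are excluded (they are state, not
parameters).  `complexity_report()` exposes a per-component breakdown whose
rows always sum to the totals.

## Training pipeline

The published protocol is followed exactly where stated: SGD with momentum
0.9, learning rate 0.001 (constant — no schedule is mentioned, so none is
applied; `train_model()` is the hook if one is wanted), weight decay 5e-4,
batch size 32 and 100 epochs for the 3-class task (16 and 200 for the
4-class task).  The loss is softmax cross-entropy — the standard choice for
a softmax tail, which is all the protocol implies.  Per-channel
standardization constants are computed on the training split and stored in
the checkpoint.  After every epoch the test split is evaluated and the
best-test-accuracy weights are retained; the protocol evaluates on its test
set directly, so no third validation split is invented.  Images are
preprocessed by cropping any near-white frame (border rows/columns with
mean intensity above 240/255; a fully white image is an error), bilinear
resizing to the configured input size, and rescaling to $[0,1]$.

Training is deterministic given the config seed: initialisation, shuffling
and augmentation all draw from one seeded stream, and the kernels are
plain BLAS, so two runs retrace the same loss trajectory bit for bit.

## Evaluation

`confusion_matrix()` uses the predicted-row/actual-column orientation.
Each class is scored one-vs-rest: precision $TP/(TP{+}FP)$, recall
$TP/(TP{+}FN)$, specificity $TN/(TN{+}FP)$, F1 the harmonic mean.  The
per-class *accuracy* column of the family's report tables numerically
equals precision in every published instance, so `class_metrics()` defines
it that way rather than inventing a different quantity.  The `Average` row
is the unweighted macro mean; overall accuracy is the trace over the total,
which algebraically equals the support-weighted mean of per-class recalls
(a property the tests exercise).  All arithmetic is full precision;
rounding to two decimals (half-up) happens only at presentation.  Cells
with a zero denominator are reported as missing, never as 0 or 100.

## Synthetic data

The clinical datasets behind the method are private, so the package ships
a generator that emulates their *class structure* rather than their
appearance: a mucosa-toned base with smooth texture, vignette, folds and
vessels; **polyp** adds 1-2 bright elliptical protrusions with a specular
highlight and a shadowed rim; **ulcerative colitis** adds 8-18 unevenly
clustered pale ulcer speckles; **others** adds one large irregular flat
dark lesion; **normal** adds nothing.  Geometry and palette ranges live in
`class_recipe()` and were fixed once, at design time, so that (a) the
classes are separable by a single generator-aligned statistic (the
luminance tail asymmetry orders others < normal < polyp with a margin that
a two-threshold rule classifies at well over 70%), and (b) a small CNN can
learn the task in a few epochs.  Everything is deterministic given
(recipe, seed, size); images are integer-valued RGB in $[0, 255]$ and
survive PNG round trips exactly.

What passing tests on this data do **not** show: robustness to endoscope
optics, lighting, occlusion, class overlap (real "other lesions" include
inflammatory polyps), or any clinical distribution.  The synthetic task
certifies the mechanism — data flow, gradients, optimizer, bookkeeping —
not clinical performance.

The augmentation stack follows the published list: horizontal and vertical
flips at probability 0.5 each, rotation uniform in $[-90^\circ, +90^\circ]$
(corners filled with the image's median border colour — the preprocessing
step crops white frames, so white fill would be self-defeating), and
multiplicative brightness and contrast jitter.  The jitter magnitudes are
unstated in the protocol; factors uniform in $[0.8, 1.2]$ are the
conventional mild choice.  Offline five-fold expansion is bookkeeping:
`expand_dataset()` appends seeded virtual rows to the manifest and the
loader applies the augmentation when images are read, which keeps the
published $22{,}809 \times 5 = 114{,}045$ arithmetic testable without
writing half a million pixels to disk.  Whether the original expansion was
offline or on-the-fly is unstated; both are available (`expand_dataset()`
and `train_config(augment = TRUE)`).

## Numerical choices and problem sizes

All numerics are double precision on CPU.  Convolutions are im2col + GEMM
(with a batched zero-copy path for `1x1` stride-1 layers); max-pool ties
break to the first candidate in scan order, deterministically.  The
reverse-mode tape frees intermediate gradients as it walks backwards to
bound memory.

The test suite certifies the training mechanism at desk scale: the smoke
run trains IIP-Net54-GAP-FC on 64-pixel synthetic images (100 training and
30 test images per class, 10 epochs, fixed seeds) and checks that test
accuracy clears 60% against a 33% chance level, that the 3-epoch-smoothed
loss decreases monotonically, and that rerunning the first two epochs
retraces the loss trajectory exactly.  Unit-level descent and
reproducibility properties use smaller runs (20 and 10 images per class);
the properties, not the sizes, are what they certify.  Full-scale training
(256-pixel input, 100+ epochs) uses the same code paths through
`train_model()` and the CLI.

## Known limitations

* CPU-only and single-threaded beyond BLAS; no GPU, no data-parallelism.
* The synthetic generator is a mechanism fixture, not an appearance model;
  accuracies on it say nothing about clinical data.
* The comparison baselines of the original study (ResNet50, VGG16,
  DenseNet121, GoogLeNet, MnasNet, GhostNet) and transfer-learning
  initialisation are out of scope.
* Only the three published head types are implemented; spatial or
  multi-head attention variants are non-goals.
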