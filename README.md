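# iipnet

Colonic polyps are the precursors of most colorectal cancers, and
classifying colonoscopy frames (polyp / normal / other lesions, optionally
ulcerative colitis) is a standard computer-aided-diagnosis task.  Polyp
texture is faint, so attention helps — but conventional channel attention
recomputes its gates at every depth and discards them.  **iipnet**
implements the IIP-Net family of convolutional classifiers, whose channel
information interaction perception (CIIP) block *forwards* its attention
vector to the next attention block, letting attention information flow
feed-forward between modules.

The package is aimed at people studying this architecture family rather
than at clinical deployment: it contains the CIIP block and the full
IIP-Net54/105/156 backbones, exact parameter/multiply-add accounting, the
one-vs-rest evaluation suite used by this literature, a seeded synthetic
colonoscopy-image generator (the original hospital datasets are private),
and a small CPU training pipeline.  All layers, reverse-mode
differentiation and the SGD optimizer are implemented in the package on
top of BLAS-backed im2col convolution kernels, so there are no
deep-learning framework dependencies.

## The model in brief

Each CIIP block applies a residual bottleneck (`1x1 -> 3x3 -> 1x1`, each
with LayerNorm + ReLU, added back to the input), pools its output
`X` to a channel vector `g = GAP(X)`, and gates:

* first block (no incoming attention), with `s = sigmoid(g)`:
  `X' = s (x) X`, `Att = s (x) g`;
* later blocks, given the predecessor's `Att1`:
  `a = ReLU(LN(FC(Att1)))`, `m = sigmoid(LN(Conv1x1(a (+) g)))`,
  `X' = m (x) X`, `Att = m (x) g`,

where `(x)` is channelwise multiplication and `(+)` elementwise addition.
The backbone is a ResNet-style bottleneck network (stem `7x7/64` stride 2 +
max-pool, four stages, CIIP after stages 1–3) with three classifier heads —
FC, GAP-FC, C-GAP — whose parameter counts follow closed forms
(`H*W*D*k + k`, `D + D*k + k`, `H*W*k + D*k + k`).  Depth names count
weight layers exactly: `54 = 1 + 3*(2+3+5+3) + 3 + 5 + 5 + 1`.

## Worked example

```r
library(iipnet)

# architecture accounting
set.seed(1)
model <- build_model(model_spec(depth = 54, head = "GAP-FC",
                                num_classes = 3, input_size = 256))
count_weight_layers(model)   # 54
complexity_report(model)
#> IIP-Net54-GAP-FC complexity at 256x256 input
#>   parameters:    25,488,451 (head: 8,195)
#>   multiply-adds: 5,340,272,640
```

25.5 M parameters, of which only 8,195 sit in the GAP-FC head
(`2048 + 2048*3 + 3` — the closed form for a 2048-channel pooled
descriptor and 3 classes), and 5.34 billion multiply-adds per 256x256
forward pass.

```r
# synthetic data -> training -> evaluation
manifest <- make_dataset(
  list(polyp = c(100, 30), normal = c(100, 30), others = c(100, 30)),
  seed = 11, size = 64, out_dir = "smoke_ds"
)
cfg <- train_config(epochs = 10, seed = 7, depth = 54, head = "GAP-FC",
                    num_classes = 3, input_size = 64)
run <- train_model(cfg, manifest)
#> epoch   1  loss 0.8603  test accuracy 54.44%
#> epoch   2  loss 0.2747  test accuracy 63.33%
#> ...
#> epoch   5  loss 0.0500  test accuracy 100.00%
#> ...
#> epoch  10  loss 0.0056  test accuracy 100.00%
run$report$confusion
#> Confusion matrix (rows = predicted, columns = actual)
#>          actual
#> predicted polyp normal others
#>    polyp     30      0      0
#>    normal     0     30      0
#>    others     0      0     30
#> overall accuracy: 100.00%
```

The loss falls from 0.86 to below 0.01 in ten epochs and the 90-image
synthetic test set is classified perfectly — the synthetic classes are
deliberately separable; this certifies the training mechanism, not
clinical performance (see the methods vignette).  `tidy(run)` returns the
per-epoch history as a tibble, `glance(run)` a one-row summary, and
`autoplot(run)` the training curves; evaluation objects have the same
verbs.

A command-line interface over the same functions lives at
`inst/cli/iipnet.R`:

```sh
Rscript inst/cli/iipnet.R generate --preset dataset-a-mini --seed 1 --out d/
Rscript inst/cli/iipnet.R audit --depth 54 --head gap-fc --classes 3 --input-size 256
```

## Package layout

| where | what |
|---|---|
| `R/ciip.R` | CIIP block: bottleneck short connection, both attention branches, dispatch |
| `R/architecture.R` | model specs, backbone builder, forward pass, checkpoints |
| `R/complexity.R` | `head_params()`, `count_params()`, `count_flops()`, reports |
| `R/metrics.R` | confusion matrix, one-vs-rest metrics, macro averages |
| `R/synthetic.R` | class recipes, image generator, augmentation, manifests |
| `R/pipeline.R` | preprocessing, `train_config()`, `train_model()`, `evaluate_model()` |
| `R/autograd.R`, `R/ops.R`, `src/kernels.cpp` | reverse-mode tape, layer ops, im2col/GEMM kernels |
| `vignettes/iipnet-methods.Rmd` | the model, design decisions, limitations |
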