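# pestfuse

Multi-image pest recognition: activation-map feature localization, gated
multi-head attention fusion of same-class image groups, and soft-voting
integration, trained as a two-branch network with a shared classifier.

## The problem

Single field photographs of crop pests are unreliable inputs: the insect is
small on a cluttered background, some frames contain no pest, and real
collections carry label errors. When several photographs of the *same*
individual or species are cheap to obtain, fusing them is far more robust
than classifying any one of them. pestfuse implements that fusion strategy
as a reusable R toolkit, exercised end-to-end on synthetic desk-scale data
that emulates those failure modes (clutter, target-absent frames, label
noise, blur).

## The method

Two branches share a convolutional trunk and one softmax classifier
`P = softmax(X W + b)`:

- **General branch** (per image): backbone → global average pooling →
  dropout → shared classifier.
- **Improving branch** (per group of n same-class images):
  1. **EFLM** — for each block of the last convolutional stage, sum the
     feature maps over channels into an activation map `A`; keep positions
     with `A(i,j) > λ·Ā` (strict); intersect the per-block masks; crop all
     blocks to the minimal bounding box of the intersection (whole map if
     empty) and bilinearly upsample back. λ rises linearly 0 → 1 over
     training (`λ = epoch/(epochs−1)`) and is 0.5 at test time.
  2. **AFFM** — multi-head self-attention over the group's embedding
     matrix `X ∈ R^{n×d}`, with learned sigmoid gate masks on each head's
     query and key (`M^Q ⊙ Q`, `M^K ⊙ K`), a hard selection mask that
     zeroes post-softmax scores below `p = 1/(2n)`, then
     `BN(concat(h_1..h_H)) + X`.
  3. **Soft voting** — average the group's probability rows and take the
     argmax: `P_j = (1/n) Σ_i p_ij`.

Training minimizes `L_total = L_general + L_improving` (mean cross-entropy
per branch) with SGD momentum. Metrics are accuracy and support-weighted F1.

## Worked example

```r
library(pestfuse)

# 1. synthesize a 5-class study: 57 images/class, 10% wrong labels,
#    10% target-absent frames, 20% blurred
spec <- synthetic_spec(n_classes = 5, images_per_class = 57,
                       label_error_rate = 0.1, no_target_rate = 0.1,
                       blur_rate = 0.2, seed = 101)
gt <- generate_dataset(spec, "study")

# 2. train the two-branch model at desk scale (5 epochs, ~2 min on 1 CPU)
fitted <- fit("study/manifest.csv", desk_config(seed = 11, epochs = 5))
glance(fitted)

# 3. evaluate both branches
mg <- evaluate("study/manifest.csv", fitted, mode = "general")
mi <- evaluate("study/manifest.csv", fitted, mode = "improving", n_test = 5)
glance(mg)
glance(mi)

# 4. deploy-style prediction on one unlabeled group
predict_group(fitted, gt$path[1:5])
```

Output (seed 11):

```
#> glance(fitted):
#>   epochs classes l_general l_improving l_total val_acc_general val_acc_improving
#> 1      5       5      1.16       0.551    1.71           0.717                 1
#> glance(mg):  accuracy 0.741  weighted_f1 0.745  n 85
#> glance(mi):  accuracy 0.929  weighted_f1 0.929  n 14
#> predict_group(fitted, gt$path[1:5]):
#> predicted label: 0
#>   label probability
#> 1     0    0.936
#> 2     2    0.0377
#> 3     3    0.0175
#> 4     4    0.00852
#> 5     1    0.000309
```

Read: after five epochs the single-image (general) branch reaches 74.1%
accuracy on the 85 test images — capped by the injected label errors and
empty frames — while fusing 5 same-class images per decision lifts the
improving branch to 92.9% over the 14 test groups: the multi-image
advantage the method is built around. `predict_group()` reports the
soft-vote class, its top-5 probabilities, and one localization box per
image in pixel coordinates (feature box × backbone stride).

A command-line interface wrapping the same functions ships at
`inst/cli/pestfuse.R` (`train`, `evaluate`, `predict`, `synth`).

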