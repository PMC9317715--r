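# pancseg

Anatomy-guided 3D segmentation of the **pancreatic subregions** — head,
body and tail — inside a pre-delineated pancreas mask in abdominal CT.

## Why

Pancreatic disease is spatially heterogeneous: tumor biology, symptoms,
drug response and prognosis all differ between the head, body and tail.
Region-resolved image analysis therefore needs subregion labels, but the
boundaries between subregions have no visible edge in CT — a purely
appearance-driven segmenter has almost nothing to learn from. What is
stable is anatomy: the three parts always appear in the order
head–body–tail along the organ and occupy roughly fixed proportions of
its length (≈ 40% / 33% / 26%).

`pancseg` turns that anatomy into a prior and fuses it with a learned
appearance model:

1. **Geometric features.** For every pancreas voxel `x`, with `y_f` the
   head endpoint of the organ and `l` the geodesic (mask-constrained)
   organ length:
   - `α′(x) = d(y_f, x) / l` — the voxel's fractional position along the
     organ (0 at the head tip, 1 at the tail tip);
   - `β′(x) = #{v : d(y_f, v) ≤ d(y_f, x)} / A` — the fraction of the
     organ volume swept between the head tip and `x` (`A` = pancreas
     voxel count).
2. **Naive Bayes soft label.** Per subregion `s ∈ {H, B, T}`, univariate
   Gaussians `N(μ_αs, σ_αs)`, `N(μ_βs, σ_βs)` are fit to the training
   voxels; the per-voxel posterior
   `P(s|x) ∝ N(α′; μ_αs, σ_αs) · N(β′; μ_βs, σ_βs) · p(s)²`
   (equal priors by default) is renormalized into a 3-channel
   probability map `X`.
3. **Segmentation network + fusion.** A compact 3D encoder–decoder
   produces its own probability map `Y`; in every training epoch and at
   inference the two are fused voxel-wise, `Ŷ ∝ Y ∗ X` (renormalized to
   sum 1), and the Dice + focal loss (1:1) is taken through `Ŷ`. The
   final labels are the per-voxel argmax of `Ŷ` on the mask.

Evaluation uses the Dice similarity coefficient
`DSC = 2TP / (2TP + FP + FN)` per subregion, the unweighted class mean as
the overall score, plus failure diagnostics: the fraction of errors within
the body/tail border zone and the count of head↔tail confusions (which
anatomy says should be zero).

A synthetic **phantom generator** (curved tapering tubes with
head/body/tail labels at the anatomical length fractions, jittered across
cases) makes the whole pipeline trainable and testable without any
patient data.

## Worked example

```r
library(pancseg)

# 4 synthetic labeled cases; train on 3, hold out the 4th
ds <- generate_phantom_dataset(4, phantom_spec(preset = "J"), seed = 7)
model <- pancseg_fit(ds$cases[1:3],
                     config = net_config(preset = "desk", seed = 7),
                     padding = 2)
print(model)
#> <pancseg_model> trained on 3 cases
#> <subregion_bayes> Gaussian class-conditionals (alpha', beta')
#>      mu_alpha sigma_alpha mu_beta sigma_beta  prior   n
#> head   0.2365      0.1195  0.2996     0.1697 0.3333 695
#> body   0.5944      0.0868  0.7254     0.0779 0.3333 313
#> tail   0.8595      0.0747  0.9292     0.0425 0.3333 169
#> <pancseg_net> depth 2, 4 base channels, image+Bayes input, fusion on
#>   trained 15 epochs, best training DSC 0.9594 at epoch 15

pred <- predict(model, ds$cases[[4]]$volume)
round(dsc_report(pred$labels, ds$cases[[4]]$labels), 1)
#>    head    body    tail overall
#>    99.3    97.0    97.4    97.9
```

The fitted Gaussian means sit near the centers of the anatomical length
fractions (head ≈ 0.40/2, body ≈ 0.40 + 0.33/2, …), which is exactly what
the anatomical prior encodes; the held-out phantom is segmented with
per-class Dice in the high 90s (percent).

There is also a thin command-line interface (installed under
`exec/pancseg`, or call `pancseg_cli()` directly):

```sh
pancseg phantom --n 8 --preset J --seed 7 --out phantoms/
pancseg crossval --dir phantoms/ --folds 4 --preset desk-test --seed 1 --out results/
pancseg bayes-fit --dir phantoms/ --out bayes/
pancseg predict --image img.nii.gz --mask mask.nii.gz --model modeldir/ --out pred/
```

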