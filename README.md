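# odcseg — glaucoma-specialized optic disc / optic cup segmentation

Segmentation models for color fundus photographs are usually trained on
the abundant, easy-to-annotate **normal** class and are therefore biased
toward small optic cups — precisely wrong for the glaucoma-confirmed
eyes where the cup-to-disc ratio (CDR) matters clinically. `odcseg`
implements a glaucoma-specialized training framework for the joint
segmentation of the optic disc (OD) and optic cup (OC), aimed at
researchers studying annotation-efficient and domain-adaptive medical
image segmentation.

The core of the package is a three-part objective for a U-Net segmenter
`S` producing softmax maps over {background, rim, cup}:

    L = w_seg * L_seg  +  w_style * L_style  +  w_domain * (w_e * L_e + w_o * L_o)

* `L_seg` — soft dice supervision on pixel-annotated samples:
  per channel `1 − 2Σpy / (Σp² + Σy²)`, averaged over channels.
* `L_style` — a Gram-matrix style-contrastive loss: with
  `Gram(I) = R(S(I))ᵀ R(S(I))` (R the HW×C reshape of the softmax map),
  `L_style = Σ_rc (Gram(I_n) − Gram(I_g))²_rc / C²`, narrowing the
  channel co-occurrence ("style") gap between normal and glaucoma
  predictions.
* `L_e`, `L_o` — two-space domain adversarial losses: patch
  discriminators on the encoding feature (Up1, 1/8 resolution) and on
  the output probability map are trained to classify the domain
  (glaucoma = 1), while the segmenter minimizes
  `mean(−log σ(D(S(I_n))))`, the cost of its normal-source predictions
  not passing as glaucoma; `w_e = 0.2`, `w_o = 0.8`.

Training alternates one segmenter update (discriminators frozen) with
one discriminator update (segmenter frozen) per iteration, in two
phases: supervised + style first, adversarial refinement last. Three
clinical annotation scenarios are supported (pixel labels on normals /
on a glaucoma subset / on both); scenario 2 reduces to single-style
contrastive learning with zero discriminator updates.

Evaluation is glaucoma-oriented: per-region Dice (OD, OC, rim) and
their mean (M-Dice), the two-direction CDR mean squared error, and the
G-score `(IoU·100)/2 − |vCDR_p − vCDR_g|/vCDR_g · 100` (perfect = 50).

Everything runs on a seeded synthetic fundus-ROI generator (nested
ellipse disc/cup with class-dependent CDR ranges, vessel-like Bézier
clutter, class-dependent color/contrast style), so the whole pipeline
is testable end-to-end on one CPU without external data. All
neural-network primitives (convolutions, batch norm, pooling, bilinear
upsampling, Adam, full backpropagation) are implemented in the package
with Rcpp/Armadillo kernels — no deep-learning framework is required.

## Worked example

```r
library(odcseg)

# a small scenario-1 dataset: annotated normals, unannotated glaucomas
ds <- generate_dataset(
  synth_config(image_size = 64L, n_normal = 20L, n_glaucoma = 12L,
               n_validation = 12L, seed = 11L),
  scenario = 1)

# pixel-supervised baseline vs the full style+domain model
tc   <- train_config(scenario = 1, epochs = 30, image_size = 64L,
                     base_width = 8L, seed = 1L)
base <- fit_odcseg(ds, config = tc, baseline = TRUE)
full <- fit_odcseg(ds, config = tc)

evaluate_model(base, ds, split = "validation")
#> Segmentation metrics over 12 samples
#>   Dice  OD: 0.7585  OC: 0.1853  Rim: 0.3906  (M-Dice 0.4448)
#>   CDR MSE: 0.5490   G-score: -53.86
evaluate_model(full, ds, split = "validation")
#> Segmentation metrics over 12 samples
#>   Dice  OD: 0.6077  OC: 0.2662  Rim: 0.2648  (M-Dice 0.3796)
#>   CDR MSE: 0.2535   G-score: -36.02
```

The baseline, trained on normal eyes only, underestimates glaucomatous
cups: its cup Dice, CDR error and G-score on glaucoma validation are
poor. The class-level supervision pulls the predicted cup statistics
toward the glaucoma class — cup Dice rises (0.19 → 0.27), the CDR mean
squared error halves and the G-score improves by ~18 points — while the
adversarial refinement trades away some raw overlap on disc and rim
(M-Dice).
`plot(full)` draws the per-epoch style gap between validation
predictions and glaucoma ground truth; `predict(full, ds)` returns
decoded OD/OC masks.

A command-line front end over the same functions is installed at
`inst/cli/odcseg.R` with subcommands `synth`, `preprocess`, `train`,
`predict`, `evaluate` and `benchmark`.

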