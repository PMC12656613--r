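# plumgrade

Non-destructive plum quality grading from two complementary modalities:
RGB appearance and visible/near-infrared (350–1700 nm) transmittance
spectra. A camera sees peel colour and shape but not sweetness; NIR
transmittance reads internal chemistry (water and sugar O–H/C–H
absorption) but is nearly blind to colour and shape. plumgrade implements
a feature-level fusion grading system for researchers and engineers in
agri-food quality assessment, together with a seeded synthetic plum
generator so every stage is testable without any external dataset.

## The grading model

Each fruit receives a comprehensive score over three min–max normalized
indicators — soluble solids content (SSC, °Brix), peel red-colour ratio,
and contour circularity `C = 4πA/p²`:

```
Score = 0.5·SSC + 0.3·Color + 0.2·Circularity
```

with grades premium (Score ≥ 0.7), standard (0.3 ≤ Score < 0.7) and
processing (Score < 0.3).

The classifier fuses a 4096-d VGG16-topology image feature vector with a
512-d 1D-CNN spectral feature vector (spectra are calibrated as
`T = (S−D)/(R−D)`, moving-average denoised, and restricted to the
900–1350 and 1400–1600 nm absorption bands) into a 4608-d input for a
fully connected grading head 4608 → 512 → 256 → 3 with batch
normalization, ReLU, dropout and residual projections. Training uses
AdamW (lr 0.001, batch 32, ≤ 100 epochs, early stopping), premium
augmentation to 15% of the training split, and information-entropy class
weighting (α = 0.65). An adversarial label-noise protocol (33% training
flips, clean test set) probes robustness.

## Worked example

```r
library(plumgrade)

# grade indicators directly
b <- norm_bounds(ssc = c(3, 13), color = c(0, 1), circularity = c(0.6, 1))
q <- quality_indicators(ssc = 11.2, red_fraction = 0.85, circularity = 0.97, b)
q$score
#> [1] 0.85
as.character(q$grade)
#> [1] "premium"

# full synthetic benchmark: fusion vs single-modal baselines
bm <- plum_benchmark(seed = 7)   # ~10 min on one CPU
bm$accuracy
#>    fusion     image  spectral
#> 1.0000000 0.8333333 0.9000000
```

The score 0.85 is `0.5·(11.2−3)/10 + 0.3·0.85 + 0.2·(0.97−0.6)/0.4`,
crossing the 0.7 premium threshold. In the benchmark, the fusion model
grades the held-out test split perfectly while each single-modal baseline
fails exactly where its modality is blind: the image model cannot
distinguish premium fruit from red-but-unripe "negative" samples, and the
spectral model cannot see peel colour or shape. `bm$reports` carries the
full confusion matrices and precision/recall/F1 per model.

A command-line interface over the same functions lives at
`inst/cli/plumgrade.R`
(`Rscript plumgrade.R generate|features|train|evaluate|grade|robustness
--config run.yaml`).

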