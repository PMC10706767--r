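# marginseg

Margin-aware tumor segmentation for intra-operative ultrasound, in R.

## The problem

In colorectal cancer surgery the resection margin — the rim of healthy
tissue between the tumor and the cut surface — decides whether the operation
succeeded. Intra-operative B-mode ultrasound with the probe on the specimen
surface images the margin directly: image row 1 is the resection surface,
and the depth of the shallowest tumor pixel is the margin in millimeters.
Automatic segmentation for this task has an asymmetric cost: a one-pixel
mistake at the *top* of the tumor changes the clinical answer, the same
mistake at the bottom changes nothing.

`marginseg` implements a complete desk-scale stack for this problem, aimed
at researchers in medical image analysis:

* **Losses** — the generalized Dice loss with inverse-squared-area class
  weights,
  `L = 1 − 2 Σₖ wₖ Σₙ gₖₙ pₖₙ / Σₖ wₖ Σₙ (gₖₙ + pₖₙ)`, `wₖ = 1/(Σₙ gₖₙ)²`,
  and its gradient-weighted extension: tumor pixels are re-weighted by
  `t(x) = ((x − max M)/(max M − min M))²` (weight 1 at the shallowest tumor
  row, 0 at the deepest), so missing the top margin costs more than missing
  an equal area at the bottom. Both with analytic gradients.
* **Metrics** — Dice coefficient, tumor margin error (vertical top-pixel
  distance, mm), pixel-pooled ROC/AUC, and a Dice-vs-margin threshold sweep.
* **Pre/post-processing** — crop to the top half, resize + normalize,
  flip/rotation/gamma augmentation; largest-connected-component +
  disk-closing cleanup.
* **Ensembling** — unweighted/weighted averaging, voting, and a pixel-level
  logistic classifier over five models' probability maps, with
  validation-split optimization of weights, vote counts, and thresholds.
* **Phantom simulator** — speckle phantoms with hypoechoic lesions whose
  top-margin distribution matches a clinical cohort (6.4 ± 3.7 mm), with a
  controllable source/target domain gap, so the whole pipeline runs with no
  private data.
* **Training harness** — small encoder-decoder networks written in plain R
  (im2col convolutions, hand-derived backprop, Adam), five variants standing
  in for an ensemble of architectures, scratch training, and transfer
  learning with the ×0.1 fine-tuning rule and no frozen layers.

## Worked example

Simulate a small target-domain cohort, train one model, and evaluate it:

```r
library(marginseg)

spec <- phantom_spec(n_patients = 12, size = c(64, 64))
ds   <- generate_dataset(spec, seed = 42)
ds
#> <phantom_dataset: 19 images / 12 patients (test=3, train=13, val=3), domain target>

ck <- train(train_config("v1", loss = "gen_dice", lr = 3e-3, epochs = 15,
                         dropout = 0, seed = 1), ds)
ck
#> <seg_checkpoint v1 (gen_dice), best epoch 15/15, val dice 0.948>

te    <- Filter(function(s) s$split == "test", ds$samples)
maps  <- predict_prob_map(ck, lapply(te, function(s) s$image))
rep   <- evaluate_predictions(list(v1 = maps),
                              lapply(te, function(s) s$mask),
                              row_spacing_mm = spec$row_spacing_mm)
rep
#> Evaluation of 1 method(s) on 3 image(s), 0.2344 mm/px
#>  method mean_dice mean_margin_error_mm   auc margin_corr
#>      v1     0.984               0.0781 0.993       0.997
```

The report reads: mean Dice overlap 0.984 between predicted and true tumor
masks; the predicted resection margin is off by 0.078 mm on average (a
fraction of a pixel at 0.234 mm/px); pixel-pooled AUC 0.993; and predicted
vs true margins correlate at 0.997 across the test images.

The ensemble and transfer-learning layers follow the same pattern — see
`?fine_tune`, `?optimize_fusion`, `?threshold_sweep`, and the methods
vignette (`vignettes/margin-aware-segmentation.Rmd`) for the full protocol.
A thin command-line interface wrapping these functions is installed at
`inst/cli/marginseg.R` (`simulate`, `train`, `finetune`, `predict`,
`ensemble`, `evaluate`, `sweep`).

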