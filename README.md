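# ovineid

Age-invariant individual identification of sheep from face images.

## The problem

Sheep faces change dramatically between 1 and 12 months of age: rapid
morphological growth up to month 4, stabilization after month 8, and
increasing fur coverage in the last months. A recognition model trained on
young animals therefore loses accuracy as the herd ages. `ovineid` is for
researchers in animal biometrics and precision livestock farming who need
an identification pipeline whose embeddings are explicitly purged of
age-related variation — and a fully controlled synthetic benchmark to
validate such pipelines on, since no public longitudinal sheep-face
dataset exists.

## The model

The pipeline learns, end to end with SGD:

* a **feature backbone** — bottleneck residual stages with
  squeeze-and-excitation channel recalibration
  (`g = sigmoid(W2 relu(W1 GAP(F)))`, reduction `r`), presets `fe_net50`
  (256/512/1024/2048 channels, blocks 3/4/6/3, r = 16) and `fe_net_tiny`
  (32/64/128/256, CPU-trainable at 64x64);
* an **attention + decoupling head** — ECBAM (two unshared 1-D channel
  convolutions on GAP/GMP descriptors blended by a trainable alpha, then
  spatial attention) feeds an MLP that produces the age code `x_age`; a
  residual MLP maps it back so that `x_id = x - R(x_age)` exactly;
* an **adversarial correlation module** — MLP kernel maps and projection
  vectors u, v maximize the batch Pearson correlation
  `rho = corr(u(x_id), v(x_age))` by gradient ascent while the encoder
  minimizes `beta rho^2`, decorrelating the two codes;
* three **objectives** combined as `L = L_id + alpha L_grow + beta L_id,grow`:
  CosFace (scaled cosine softmax with true-class margin, s = 30, b = 0.35),
  half-MSE linear age regression, and the squared correlation
  (defaults alpha = 0.01, beta = 1).

Evaluation covers precision/recall/F1/accuracy, IoU and mAP@0.5, both EER
definitions (pooled misclassification and the ROC FAR = FRR rate) with
FAR/FRR curves, per-age-group tables (1-3, 4-6, 7-9, 10-12 months),
decoupling leakage diagnostics (cross-fitted age-R² from each code), and
gradient-weighted saliency maps.

## Worked example

```r
library(ovineid)

# 1. generate a longitudinal synthetic cohort: 20 sheep x 12 months x 8
#    images, ages 1-4 train / 5-8 validation / 9-12 test
dir <- file.path(tempdir(), "cohort")
man <- generate_dataset(n_ids = 20, ages = 1:12, reps_per_cell = 8,
                        protocol = "age_based", seed = 101, out_dir = dir)
man
#> <dataset_manifest> 1920 records (age_based protocol): train=640 val=640 test=640

# 2. train the full model at desk scale (~8 min on one CPU)
fit <- train(man, dir, training_config(tiny_run = TRUE, seed = 7))

# 3. evaluate on the held-out old-age test split
rep <- evaluate(fit, man, dir, split = "test")
rep
#> <eval_report> split=test n=640 top1=1.000 P=1.000 R=1.000 F1=1.000 mAP@0.5=1.000
#>   eer_eq11=0.0000 eer_roc=0.0000 | R2(age|x_age)=0.137 R2(age|x_id)=0.035 |rho|=0.003

# 4. leakage diagnostics over the training age range, where age varies
decoupling_report(fit, man, dir, split = "train")
#> $r2_age_code   0.902
#> $r2_id_code    0.871
#> $r2_embedding  0.889
#> $abs_rho       0.0144
```

Read: the model identifies 9-12-month-old test animals it only ever saw
as 1-4-month lambs with perfect top-1 accuracy and zero equal-error rate.
The within-test-split R² values are near zero for *every* code because
ages 9-12 are past the growth plateau — age is unidentifiable there — so
the leakage question is asked on the training age range: the age code
predicts age well (R² 0.90), the adversary's projected correlation is at
noise level (|rho| 0.014), but a linear probe can still decode age from
the identity code (R² 0.87) — the single-pair batchwise min-max controls
the correlation it optimizes, not full linear decodability. The methods
vignette discusses this distinction. (All numbers are the printed output
of the run above; the seeds reproduce them exactly.)

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/ovineid.R synth --ids 20 --reps 8 --out cohort/ --seed 101
Rscript inst/cli/ovineid.R train --data cohort/ --out run/ --seed 7
Rscript inst/cli/ovineid.R evaluate --data cohort/ --checkpoint run/checkpoint.rds --out run/
```

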