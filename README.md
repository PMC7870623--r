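# kneeage

Fully automated age estimation from 3D knee MRI.

In forensic practice the age of a living person must often be assessed
without valid documents. The growth plates of the knee ossify on a
predictable schedule during male adolescence: the dark epiphyseal gap
visible on T1-weighted MRI narrows with age and closes around 18–19 years.
`kneeage` implements an automated pipeline that converts a raw 3D knee MR
volume into a chronological-age estimate and a minor/adult classification
(subjects under 18 are the positive class):

1. **Pre-processing** — resampling to a common 448 × 448 in-plane grid,
   polynomial bias-field correction, template-matching localization of the
   characteristic knee region by zero-normalized cross-correlation, and
   extraction of a fixed 130 mm volume of interest.
2. **Bone extraction** — an encoder–decoder segmentation CNN labels bone
   and growth-plate structures; the VOI is masked and reduced to exactly
   12 informative slices (strict >2 % bone-fraction filter, then even
   selection anchored at the centre of gravity of the bone-per-slice
   distribution).
3. **Age estimation** — a compact CNN (five Down Blocks of
   `3×3 conv → elu → bn → do`, 2×2 max-pooling, channels 16→256,
   `gap → do → fc → lin` head; 1.18 M trainable parameters) regresses an
   age per slice, trained with Adam on the mean-squared-error loss

   MSE = (1/n) Σᵢ (yᵢ − ŷᵢ)²,

   optionally transfer-initialized from the segmentation encoder. An
   extremely-randomized-trees regressor aggregates the 12 slice
   predictions into the final age; a random-forest classifier separates
   minors from adults. Metrics: MAE = (1/n) Σᵢ |yᵢ − ŷᵢ| with SD and 95 %
   CI, plus accuracy, sensitivity, specificity and AUC, all evaluated
   under repeated stratified 5-fold cross-validation against
   best-available-guess baselines (training-mean regressor, all-minors
   classifier).

Because clinical MRI cohorts cannot be redistributed, the package ships a
synthetic phantom generator (`generate_cohort()`) producing knee-like
volumes with an age-dependent growth-plate gap, ground-truth masks and
subject records, so the entire pipeline is testable end to end. The CNN
engine itself (Rcpp/Armadillo kernels, batch norm, dropout, Adam) is part
of the package and its gradients are verified against finite differences
in the test suite.

## Worked example

A desk-scale end-to-end run (synthetic cohort of 60 subjects, 64 px
network inputs, short training budgets) on one CPU:

```r
library(kneeage)

cfg <- pipeline_config(seed = 1, desk_scale = TRUE, n_subjects = 60,
                       cv_repeats = 1)
res <- run_end_to_end(cfg)

round(res$report$pooled$mae, 2)          # cross-validated MAE, years
round(mean(res$report$baseline$mae), 2)  # best-available-guess MAE
res$report$best$mae                      # best fold
```

prints (seed 1)

```
[1] 0.62
[1] 2.02
[1] 0.4800175
```

i.e. the pipeline estimates age with a pooled cross-validated MAE of
0.62 years on held-out synthetic subjects, versus 2.02 years for the
training-mean constant predictor; the best fold reaches 0.48 years.
(Synthetic phantoms carry a much cleaner age signal than clinical MRI, so
these figures characterize signal recovery, not clinical accuracy.)
Classification columns (accuracy/sensitivity/specificity/AUC) are in
`res$report$per_fold`. Phantom cohorts can also be written to disk as
NIfTI + CSV via `write_cohort()`, and a thin command-line front end is
available at `inst/cli/kneeage.R` (`phantom` and `run` subcommands).

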