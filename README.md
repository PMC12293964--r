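# strokeconn

Lesion volume and resting-state network connectivity models of acute
stroke severity.

After an acute subcortical ischemic stroke, how much of the clinical
deficit — the NIHSS score — is explained by how much tissue was destroyed,
and how much by the disturbance the lesion induces in distributed brain
networks? `strokeconn` implements the full analysis pipeline for that
question, for neuroimaging researchers working with resting-state fMRI in
acute stroke cohorts:

- **Lesion volumetrics**: lesion volume in mm³ from a binary mask
  (foreground voxels × voxel volume), with NIfTI-1 I/O.
- **Connectivity features**: zero-phase 0.01–0.1 Hz band-pass filtering,
  ROI time-series extraction from 4D volumes, and Fisher z-transformed
  intra-/inter-network aggregates. Six predefined AAL3-based networks
  (four motor-related, default mode, frontoparietal) crossed with three
  hemisphere scopes give 18 network configurations and
  18 + C(18,2) = **171 named connectivity predictors**, e.g.
  `intra|MotorI:left`, `inter|MotorI:both|MotorIV:left`.
- **Incremental modelling**: OLS models of NIHSS built by greedy forward
  selection on training R² with a VIF < 2 collinearity gate and a
  five-predictor cap, cross-validated with a shared 5-fold partition
  (fold R² = 1 − SSE/SST about the held-out fold's mean).
- **Model comparison**: paired t-tests across CV folds, ΔAIC, and
  likelihood-ratio tests (χ² = 2Δℓ = n·log(RSS₀/RSS₁), df = added
  predictors) between hemisphere-specific and nested models.
- **Synthetic cohorts**: a generator with block-structured network
  covariance (latent factor model), lesion volumes coupled to
  within-network connectivity damping, and a linear NIHSS outcome with a
  calibrated design R² — so the whole pipeline is testable without any
  clinical data.

Everything is tidyverse-native: cohorts are tibbles (subjects × variables),
fitted objects support `tidy()`, `glance()` and `autoplot()`, and all
functions compose with the pipe.

## Worked example

```r
library(strokeconn)

cfg <- simulation_config(seed = 1)   # 44 subjects, 260 volumes at TR 1.78 s
cohort <- simulate_cohort(cfg)
cohort
#> <synthetic_cohort>: 44 subjects, 171 connectivity features
#>   design R^2 = 0.7, noise sd = 2.06 NIHSS points

suite <- run_model_suite(cohort, seed = 1)
suite
#> <stroke_suite>: 7 models, 5-fold CV (seed 1), n = 44
#>   lesion_only              R^2 0.631  adjR^2 0.622  AIC   210.01  CV R^2   0.373  CV MSE   6.918
#>   best_connectivity_only   R^2 0.689  adjR^2 0.682  AIC   202.46  CV R^2   0.602  CV MSE   5.596
#>   best_without_lesion      R^2 0.845  adjR^2 0.825  AIC   179.84  CV R^2   0.749  CV MSE   3.807
#>   best_with_lesion         R^2 0.859  adjR^2 0.840  AIC   175.76  CV R^2   0.763  CV MSE   3.154
#>   left_hemisphere          R^2 0.790  adjR^2 0.762  AIC   193.21  CV R^2   0.558  CV MSE   5.828
#>   right_hemisphere         R^2 0.486  adjR^2 0.418  AIC   232.62  CV R^2  -0.078  CV MSE  13.219
#>   both_hemispheres         R^2 0.845  adjR^2 0.825  AIC   179.84  CV R^2   0.749  CV MSE   3.807

suite$lrt
#> # A tibble: 1 × 5
#>   comparison                      baseline          chi_squared    df   p_value
#> 1 motor_baseline_vs_left_extended intra|MotorI:left        24.2     4 0.0000740
```

Reading the table: the cohort was generated with a design R² of 0.70 split
between lesion volume and left-lateralized motor connectivity. Lesion
volume alone explains 63 % of NIHSS variance in-sample; seeding it and
adding connectivity features greedily raises training R² to 0.86 with a
cross-validated R² of 0.76 — connectivity adds predictive information
beyond lesion size. Left-hemisphere-restricted models outperform
right-restricted ones (the generating signal is left-lateralized), and the
likelihood-ratio test shows the four left-sided predictors significantly
extend the primary-motor baseline. Negative CV R² (right hemisphere) is
expected for models that generalize worse than the held-out mean.

The same machinery runs on real data: read ROI series with
`read_roi_tsv()` or `extract_roi_timeseries()` from NIfTI volumes, filter
with `bandpass_filter()`, build features with
`connectivity_feature_matrix()`, compute `compute_lesion_volume()` from
masks, assemble the cohort tibble, and call `run_model_suite()`.

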