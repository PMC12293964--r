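---
title: "Modelling acute stroke severity from lesion volume and network connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling acute stroke severity from lesion volume and network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeconn)
```

## The problem

After an acute ischemic stroke, the clinical deficit measured by the NIHSS
(National Institutes of Health Stroke Scale, an integer severity score)
reflects both the tissue destroyed by the infarct and the disturbance it
induces in distributed brain networks. `strokeconn` implements a complete,
testable pipeline for quantifying both contributions and weighing them
against each other in a mild-to-moderate subcortical stroke cohort
(n = 44 in the reference design):

1. **lesion volumetrics** — lesion volume in mm³ from a binary mask
   (foreground voxel count × voxel volume);
2. **connectivity features** — seed-based resting-state functional
   connectivity summarized as Fisher z-transformed intra- and
   inter-network aggregates over lateralized network configurations;
3. **incremental modelling** — VIF-gated greedy forward selection of
   ordinary least-squares models of NIHSS, capped at five predictors,
   with shared-partition 5-fold cross-validation;
4. **model comparison** — paired fold t-tests, AIC differences and
   likelihood-ratio tests between hemisphere-specific and nested models.

Because the clinical dataset the design derives from is not publicly
deposited, the package ships a first-class synthetic cohort generator that
reproduces the statistical structure the analysis assumes, so every stage is
exercised end to end without any download.

## Networks, configurations and the 171 features

Six networks are predefined over AAL3 atlas regions: four motor-related
networks (primary sensorimotor: precentral and postcentral gyri,
paracentral lobule; premotor/prefrontal; cingulo-insular; basal ganglia),
the default mode network and the frontoparietal network. Regions are
lateralized (`_L`/`_R`), and every network is instantiated at three
hemisphere scopes — `left`, `right`, `both` — giving
$C = 6 \times 3 = 18$ *network configurations*. The `both` scope takes the
union of left and right instances as separate nodes, so interhemispheric
homologue pairs contribute to intra-network connectivity, consistent with
the interhemispheric-connectivity literature.

For one subject, each region's mean BOLD series yields a Pearson
correlation matrix; correlations are mapped through the Fisher
transformation $z = \operatorname{artanh}(r)$ and averaged:

- **intra-network** features: mean $z$ over all unordered pairs of a
  configuration's members ($C$ features);
- **inter-network** features: mean $z$ over all cross pairs of two
  configurations ($\binom{C}{2}$ features).

With $C = 18$ this gives $18 + 153 = 171$ named predictors, e.g.
`intra|MotorI:left` and `inter|MotorI:both|MotorIV:left`. Three numerical
conventions matter:

- *Shared regions.* Networks overlap (the medial superior frontal gyrus
  belongs to a motor network and the DMN; the angular gyrus to the DMN and
  the frontoparietal network). In a cross-network average, a region paired
  with itself has $r = 1$ and infinite $z$; such identical-region
  self-pairs are excluded. Distinct shared members are kept. This is the
  only finite-valued reading.
- *Clipping.* $|r|$ is clipped at $1 - 10^{-7}$ before `artanh`, keeping
  features finite on degenerate inputs.
- *Canonical order.* Networks in registry order, scopes ordered left,
  right, both; intra features first, inter features over pairs in
  configuration order. The order is arbitrary but fixed: it makes feature
  vectors reproducible and serves as the deterministic tie-break in
  selection.

Band-pass filtering (0.01–0.1 Hz, the standard resting-state fluctuation
band) is provided as a zero-phase Butterworth filter (effective order 4,
doubled by the forward–backward pass; series are demeaned first so DC is
removed exactly). The upper edge must lie below the Nyquist frequency
$1/(2\,\mathrm{TR})$ — about 0.281 Hz at the design's TR of 1.78 s.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, not tuned.

**Time series.** Each subject's $T \times R$ matrix (defaults
$T = 260$ volumes at TR 1.78 s, $R = 44$ lateralized regions) is a
stationary Gaussian process realized through a latent factor model:

- a **global factor** carries the between-network correlation
  $r_b$ (default 0.15);
- one factor per **network and hemisphere** carries the within-network
  correlation $r_w$ (default 0.50); left and right factors of a network
  are coupled at 0.9 (homotopic coupling), so interhemispheric homologue
  pairs correlate slightly below within-hemisphere pairs;
- **region noise** makes up the remaining unit variance.

A direct "write the block values into a correlation matrix" construction is
*not* positive definite for the default registry, because the networks
overlap; the factor model is PSD by construction, reproduces the block
values exactly for disjoint registries, and splits hub regions' loadings
across their memberships (hub pairs correlate somewhat below $r_w$, a
realistic consequence of shared membership). Configurations that would
push a region's implied variance past one, or a within-network correlation
below the between-network level, are rejected with a diagnostic naming the
offending region or network. For this construction $r_b \ge 0$ is
required; negative global between-network correlation is outside the
modelled regime.

**Lesion coupling and subject variation.** Lesion volumes are uniform on
100–25\,000 mm³ (subcortical range, rounded to whole mm³ so 1 mm isotropic
masks are exactly achievable). The within-network correlation of the
*affected networks* (defaults: primary sensorimotor and basal ganglia) is
attenuated by `1 − slope × volume` with slope $1.6\times10^{-5}$ per mm³ —
up to 40 % at the largest lesions. Independently, every network ×
hemisphere correlation receives a per-subject Gaussian offset
(sd 0.06, clipped at 2.5 sd): individual differences that give
connectivity predictive signal beyond lesion volume. Damping is applied in
both hemispheres at network level; ipsilesional-only damping would require
a lesion-side concept the generator deliberately does not model.

**Outcome.** NIHSS is linear in the generating predictors plus Gaussian
noise. The default coefficients put roughly comparable signal into lesion
volume (≈ 5.5 points across the volume range) and three intra-network
features; the intercept centres the outcome in the mild-to-moderate range.
Rather than fixing the noise sd, the default calibrates it per cohort so
the *design* $R^2 = \mathrm{var}(\hat y)/(\mathrm{var}(\hat y)+\sigma^2)$
equals 0.70, matching the combined-model regime of the reference design;
`null_simulation_config()` provides the no-signal variant (sd 3.35 points
around a mean of 4.3). Outcomes are continuous by default — the reference
analysis fits linear models to NIHSS without a stated transform — with an
opt-in integer mode that rounds and clips to [0, 14].

**Determinism.** Every generator is a pure function of the configuration
and master seed. Per-subject streams are derived by a prefix-stable draw,
so enlarging the cohort never reshuffles earlier subjects; time series,
lesion masks and outcome noise for subject *i* are bit-reproducible from
`(seed, i)` alone.

**What the generator does not emulate:** hemodynamic convolution, motion
and physiological artifacts, spatial autocorrelation and anatomy, scanner
drift, or integer NIHSS measurement error. Temporal autocorrelation is
available as an opt-in AR(1) knob (off by default — the analysis consumes
only lag-zero correlations, which the AR(1) rescaling leaves unchanged),
mainly so that the band-pass stage can be exercised on temporally
structured input. Passing tests therefore demonstrate the *statistical
machinery* is correct under the assumed data model, not that the pipeline
is robust to real-world acquisition artifacts.

## The modelling engine

**Fits.** Ordinary least squares with intercept. AIC/BIC use the Gaussian
log-likelihood including constants, with the error variance counted as a
parameter ($k + 2$ parameters for $k$ predictors). The reference analysis
never states its convention; all suite comparisons use AIC *differences*,
which are convention-invariant given internal consistency.

**Selection.** Greedy forward selection on training $R^2$: at each step
the candidate with the largest $R^2$ increase is added, provided every VIF
of the resulting set stays below 2 — the gate is enforced *during*
selection, the only reading that guarantees the reported bound. Selection
stops at five predictors (about one per nine subjects at n = 44) or when
no admissible candidate improves the fit. Cross-validated metrics are
computed per step for reporting; they never drive selection. Ties are
broken by canonical feature order. Lesion volume enters untransformed (a
log-volume variant is a caller-side transform away; the design treats
volume as a continuous variable).

**Cross-validation.** Subjects are randomly partitioned into five folds
with sizes differing by at most one (9/9/9/9/8 at n = 44). Fold
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ with SST about the held-out fold's
own mean; CV $R^2$ and MSE are unweighted fold means (a pooled-prediction
$R^2$ is reported alongside). The partition is a pure function of the
seed, shared across all models of a suite so fold-paired comparisons are
meaningful. CV $R^2$ can be negative for poor models. Note that selection
uses the full cohort, so CV of a selected model inherits the mild optimism
of the reference protocol; the null-calibration tests quantify it
(mean CV $R^2$ of selected null models stays below 0.05).

**Comparisons.** Paired two-sided t-test on per-fold $R^2$ differences
(K − 1 = 4 degrees of freedom; folds are correlated, so a
Nadeau–Bengio-style corrected variance is available as an option),
$\Delta\mathrm{AIC} = \mathrm{AIC}_a - \mathrm{AIC}_b$ (positive favours
b), and the likelihood-ratio test
$\chi^2 = 2(\ell_{\mathrm{full}} - \ell_{\mathrm{nested}})
= n \log(\mathrm{RSS}_{\mathrm{nested}}/\mathrm{RSS}_{\mathrm{full}})$
with df the number of added predictors. For nested Gaussian fits
$\chi^2 = \Delta\mathrm{AIC}_{\mathrm{nested}-\mathrm{full}} + 2\,df$
exactly.

**The seven-model suite.** `run_model_suite()` builds, on one shared fold
partition: lesion-only; best single connectivity predictor; best
predictors without lesion; best predictors with lesion seeded first; and
left-, right- and bilateral-restricted models. Hemisphere-restricted
candidate sets keep features whose every scope tag matches (21 features
per pure hemisphere under the default registry). The bilateral set
defaults to *all* features — the design contrasts it with single-hemisphere
restriction — which makes it coincide with the best-without-lesion row by
construction; a strictly both-scope-only variant (21 features) is
available via `bilateral_candidates = "both_scope_only"`. The
likelihood-ratio comparison extends a single-feature primary-motor
baseline (`intra|MotorI:left` by default, exposed as a parameter since the
reference design names the baseline without pinning the feature) with up
to four further left-lateralized predictors.

## Design choices in open territory

- **Mixed-scope inter-network pairs** (e.g. `both` × `left`) are included:
  the arithmetic $18 + \binom{18}{2} = 171$ matches the printed predictor
  count only under this reading, and the named best single predictor
  (bilateral primary motor vs left basal ganglia) is itself mixed-scope.
- **Fold partition** is unstratified; whether the original partition was
  stratified by outcome is unknown.
- **No demographic or treatment covariates** are entered, matching the
  reference models.
- **LRT calibration df.** The finite-sample null of the Gaussian-OLS LRT
  is a monotone transform of an F statistic; at n = 44 its
  Kolmogorov–Smirnov distance from $\chi^2_{df}$ is 0.014 at df = 1 but
  0.066 at df = 4. The package's calibration test therefore runs at
  df = 1, where the chi-square approximation is adequate at this sample
  size; df = 4 tests remain available and exact inference would use the F
  form.
- **Selection identity under collinearity.** The 171-feature family is
  intrinsically aliased: a network's left, right, both-scope and
  cross-scope configurations carry overlapping subject-level signal, and
  lesion damping couples affected-network features further. Simulation
  shows greedy selection then recovers a *predictive representative* of
  the true signal rather than the unique generating feature name (and the
  VIF gate admits only one representative of a correlated group). With
  those couplings removed — distinct candidate features and no
  lesion–connectivity damping — the selector recovers truly informative
  predictors (partial $R^2 > 0.10$) in well over 80 % of cohorts, which
  is how the parameter-recovery property is tested. Interpreting *which*
  feature a forward-selected stroke model names therefore deserves
  caution; interpreting *how much* it predicts does not.

## Problem sizes used by the tests

The package's own validation uses: single cohorts at the full design size
(44 subjects × 260 timepoints × 44 regions); 50-cohort replications for
design-$R^2$ recovery (mean CV $R^2$ within ±0.10 of 0.70); 200-cohort
replications for null calibration of all seven suite rows; 2000
replications for diagnostic calibration (Shapiro–Wilk type-I error
0.05 ± 0.02 at n = 44; null LRT vs $\chi^2_1$ within KS 0.05, on a compact
two-network registry at 60 timepoints); and 16-seed replications for noise
-scaling sanity. Correlation-fidelity checks run at 2000–5000 timepoints
against the model-implied matrix.

## Worked example

```{r example, eval = FALSE}
library(strokeconn)

cfg <- simulation_config(seed = 1)      # 44 subjects, design R^2 = 0.70
cohort <- simulate_cohort(cfg)
suite <- run_model_suite(cohort, seed = 1)
suite
tidy(suite)                             # the seven-model metrics table
suite$comparisons                       # paired fold t-tests + delta AIC
suite$lrt                               # motor-baseline likelihood ratio
autoplot(suite)
```

## Limitations

Beyond the generator's idealizations listed above: the pipeline assumes
ROI time series are already preprocessed (motion-corrected, normalized,
nuisance-handled) upstream; lesioned voxels are not excluded from ROI
averages; masks are expected binary in native 1 mm space (interpolated
masks require an explicit threshold); and cross-validated metrics of
full-cohort-selected models retain the optimism inherent in that protocol.
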