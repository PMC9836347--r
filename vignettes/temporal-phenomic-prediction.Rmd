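---
title: "Temporal phenomic prediction: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal phenomic prediction: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tppr)
```

## The problem

Selecting the best hybrids in a maize breeding trial usually means either
waiting for end-of-season measurements or predicting them from genome-wide
markers (genomic prediction, GP). Drone surveys flown repeatedly through the
season offer a third source of information: dozens of vegetation indices
(VIs) and canopy heights per plot at each of 12--16 flights. `tppr`
implements temporal phenomic prediction (TPP) — predicting grain yield (GY,
t/ha at 15.5% moisture), days to anthesis and silking (DTA, DTS) and
terminal plant height (PHT) from those temporal features — and benchmarks it
against GBLUP genomic prediction under shared cross-validation schemes.

## The flight-nested variance model

Plot-level temporal phenotypes are decomposed with all terms random and the
intercept fixed:

$$y_{ijk} = \mu + \beta_i + R_{j(i)} + \Omega_{k(i)} + \varepsilon_{ijk},$$

where $\beta_i$ is the flight (survey date) effect, $R_{j(i)}$ the replicate
nested within flight, $\Omega_{k(i)}$ the genotype nested within flight and
$\varepsilon$ the plot residual. Nesting genotypes within flights is what
lets the *same* genotype express a different genetic signal at each growth
stage — the premise of temporal prediction. Two estimation paths give the
components:

* **EM-REML** through Henderson's mixed-model equations, for arbitrary
  (including unbalanced) designs. The EM update is monotone in the
  restricted likelihood; iteration stops when every component's relative
  change falls below `tol` (default 1e-8) or after `max_iter` (default
  10^4) iterations. Components that collapse toward zero are pinned at the
  boundary and their term dropped, which keeps the equations well
  conditioned. Because each iteration inverts the dense coefficient matrix
  for the per-block traces, this path is intended for mixed-model equations
  up to a few thousand rows.
* **Balanced ANOVA method of moments**, the closed form from expected mean
  squares, used automatically for balanced designs (negative estimates
  truncated to zero, the raw values kept for diagnostics). On balanced data
  the two paths agree to numerical precision when the ANOVA estimates are
  interior, which the test suite asserts at 1e-6 relative.

Genotypic values per flight are BLUPs, $\hat\mu + \hat\beta_i +
\hat\Omega_{k(i)}$, obtained from one sparse mixed-model-equation solve at
the estimated components; they are shrunken toward the flight mean, which
is what makes them usable predictors rather than noisy cell means.

Temporal repeatability is entry-mean repeatability,

$$TR = \frac{\sigma^2_\Omega}{\sigma^2_\Omega + \sigma^2_\varepsilon/n_{rep}},$$

clamped to [0, 1]. Whether the original analysis used BLUPs or adjusted
means for its genotypic values, and its exact repeatability formula, are not
fully specified in the available description; BLUPs and entry-mean
repeatability are the standard choices and are pinned here.

## Imaging

The VI registry ships 22 RGB-only and 21 red-edge/near-infrared indices as
documented arithmetic over reflectance bands scaled to [0, 1] (8-bit input
is divided by 255 on read). Division-by-zero pixels become missing, never
infinite. Plot extraction uses pixel-center containment with half-open
edges (PNPOLY ray casting): a pixel on the shared boundary of two adjacent
plots belongs to exactly one of them, so adjacent plots partition the
raster deterministically. Canopy height is the 99th percentile of in-plot
heights under the linear-interpolation quantile convention (R type 7),
pinned because percentile conventions otherwise differ across tools. No
soil mask is applied by default; an ExG threshold mask is available as
`exg_soil_mask()` for users who want one.

## Derived features

Canopy growth is summarized by the asymptotic Weibull curve
$H(t) = A\,(1 - e^{-(t/B)^C})$ — $A$ the asymptotic height, $B$ the day at
which 63.2% of $A$ is reached, $C$ the steepness — fitted by
Levenberg–Marquardt with positivity bounds, a self-starting initialization
($A_0 = 1.05\,\max H$, $B_0$ = time at half maximum, $C_0 = 2$) and jittered
restarts. Note that fitted BLUP trajectories ride on a nonzero early-season
baseline, so the fitted $C$ describes the *trajectory of genotypic values*,
not a from-emergence growth curve. Area under the temporal curve uses the
trapezoidal rule over the observed flight window only — no extrapolation
toward planting or harvest.

The feature matrix has one column per (trait, flight) pair, ordered by
trait then flight day, with AUC and Weibull columns appended on request.
The column-count convention follows the printed products (35 traits x 15
flights = 525; 89 x 12 = 1,068); a 36-trait x 15-flight panel (540 columns)
is equally representable by passing the corresponding matrices, since the
source's feature accounting is internally inconsistent on this point.

## Prediction

One `make_split_plan()` draws `n_iter` random 70/30 genotype partitions
(floor rule for the training size) and every method consumes the same plan;
`compare_methods()` refuses results whose plan fingerprints differ, which
is what makes per-iteration accuracies directly comparable. The four
schemes: CV1 predicts the training genotypes in the optimal-management
trial (resubstitution — the overfitting control), CV2 the held-out
genotypes in the same trial, CV3 the training genotypes in the stressed
trial, CV4 the held-out genotypes in the stressed trial. For CV3/CV4 the
phenomic models apply the OM-trained model to OM-measured features — an
untested environment contributes no data at prediction time; whether the
original analysis instead used stress-trial features is not stated, and
this reading is the stricter one.

Families: exact SVD ridge (so the closed-form oracle test is a genuine
independent route), lasso and elastic net via coordinate descent (glmnet),
minimum-norm unpenalized linear regression (which interpolates when
features outnumber genotypes — hence CV1 accuracy 1 there), random forests
(500 trees, p/3 features per split, leaf size 5, seeded), and GBLUP on the
VanRaden method-1 kernel $G = ZZ'/(2\sum p_m(1-p_m))$ with a MAF 0.025
filter. Features are standardized with training means/SDs only; penalties
are tuned by 5-fold inner CV on training rows over a 25-point log grid
10^-4..10^4 (elastic-net mixing over 0.1..0.9). Accuracy is the Pearson
correlation between predicted and observed genotype-level values, averaged
over iterations; RMSE, MAE and R^2 accompany it.

The GBLUP variance ratio $\lambda = \sigma^2_e/\sigma^2_g$ is estimated per
training set by exact profiled REML in the eigenspace of the training
kernel (a 1-D optimization over $\log\lambda$), rather than by EM
iterations — same estimand, fewer failure modes for a single ratio. GBLUP
predictions equal RR-BLUP marker-effect ridge with penalty $\lambda$ times
the VanRaden denominator; the suite asserts this equivalence at 1e-8.

## The synthetic-trial generator

All tests and the acceptance analysis run on `simulate_trial()`, which
emulates the study conditions end to end: ~280 hybrids from crosses of
inbred parents (230 under stress), biallelic markers with a realized-MAF
window, an RCBD with 2 replications, 15 flights from 27 to 144 days after
planting, and temporal traits whose plot values are grand mean + flight +
replicate-within-flight + genotype-within-flight + residual. Defaults place
90% of variance on flights, 2% on replicates, 4% on genotypes-within-flight
and 4% residual — inside the reported ranges (flights dominant at 31–96%,
genotype 1.5–5.2%) — and give GY/DTA/DTS/PHT heritabilities of
0.6/0.8/0.8/0.7 with realistic means, SDs and a DTA–DTS genetic correlation
of 0.9.

Calibration choices, fixed once as the generator's definition of the study
conditions:

* Flight, replicate and genotype effects are rescaled to their **exact**
  target variances (flight effects additionally follow a growth-shaped
  trajectory — Weibull-like for canopy height, a mid-season bump for VIs —
  plus jitter). With only 15 flight levels, unscaled draws would make the
  realized shares drift tens of percent from the configuration, and the
  recovery tests would measure sampling noise instead of estimator quality.
  Replicate effects are centered within flight and calibrated to the pooled
  within-flight variance, the quantity the nested decomposition estimates.
* Marker effects on temporal traits are drawn per flight with a
  configurable across-flight correlation (default 0.9), so genotype
  rankings drift over growth stages; per-flight weights can scale the
  genetic share up or down to emulate stages of higher or lower genetic
  determination.
* The shared component of each VI's marker effects correlates with the GY
  marker effects (`vi_gy_genetic_corr`, default 0.4): vegetation indices
  are genetically informative about yield, which is the premise of phenomic
  prediction.
* Optionally, a fraction `vi_trait_env_link` of the genotype-within-flight
  variance is a trial-specific, non-marker genotype factor (permanent
  micro-environment / GxE response) that can also enter grain yield with
  weight `gy_env_link`. The mixture is variance-preserving, so the
  decomposition shares are unchanged; what changes is that phenomic
  features then carry predictive signal that genome-wide markers cannot
  see. This is the regime in which TPP out-predicts GP for untested
  genotypes in a tested environment, and it is how the package's
  constructed-advantage check reproduces that ordering qualitatively.
* The stressed trial reuses the optimal trial's genotype effects mixed
  with an independent draw at weights $(\rho, \sqrt{1-\rho^2})$,
  $\rho$ = `gxe_corr` (default 0.7), plus per-trait mean shifts (e.g.
  -2.5 t/ha GY, +2 d DTA, -25 cm PHT).
* Distributional form of flight and residual effects is not stated in the
  source; Gaussian is the default, with a heavy-tailed Student-t(5)
  alternative exposed (`effect_dist = "t5"`).
* Rasters: each plot's pixels are drawn by inverting the index formula
  per pixel around the simulated plot value (plus optional pixel noise), so
  extraction round-trips exactly at zero noise. Fixture rasters stay small
  (tens of plots, 10–20 px plots).

What the generator does **not** emulate: photogrammetric artifacts (lens
distortion, mosaicking seams, georeferencing error), spatial field trend
within replicates, weather-driven trajectories, linkage disequilibrium
beyond the inbred-cross structure, and real soil/canopy reflectance
spectra. Green tests therefore demonstrate correctness of the estimators
and the pipeline's plumbing on data with the paper's statistical skeleton —
not robustness to everything real imagery does.

## Problem sizes used in the checks

The recovery checks run the full 280 x 15 x 2 design (8,400 plot rows per
trait) over 20 seeds with the balanced-ANOVA path; estimator-equivalence
checks use smaller balanced designs where the dense EM path is fast; the
heritability-ceiling and method-ordering checks use 120–150 hybrids with
100 and 30 iterations respectively, sizes at which the quantities of
interest are stable but the whole suite stays in the minutes range. The
`analysis/` scripts run the same stages at the full simulated-trial scale
with 30 shared iterations for six model families.

## Known limitations

* The EM path's per-iteration dense inverse bounds practical model sizes;
  a sparse-inverse (Takahashi) implementation would lift this.
* CV3/CV4 semantics (whose features represent an untested environment) are
  pinned to OM features; results under SM features would differ.
* The nested model has no spatial row/column adjustment and a single
  residual variance across flights.
* `evaluate_predictions()` follows the standard RMSE definition
  $\sqrt{\mathrm{mean}(e^2)}$.
* Acceptance of the original study's headline accuracies (0.80/0.72/0.71)
  is qualitative: those numbers came from real imagery and ~153k GBS
  markers, not reproducible at package-test scale. Users with the original
  supplementary phenomic tables and G2F marker data can reproduce that
  comparison directly: `read_phenomic_table()` + `read_marker_table()`
  accept those formats, and `run_cv_scheme()`/`compare_methods()` run the
  same harness on them.
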