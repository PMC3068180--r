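---
title: "Methods: maximum-entropy niche models, their validation, and range-change projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy niche models, their validation, and range-change projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

This vignette is the package's own account of the science it
implements: the presence-background model and its assumptions, the
validation machinery, the range-change statistics, the synthetic
test bed, and the numerical choices that were genuinely open.

## The presence-background model

Presence-only data tell us where a species was recorded, not where it
is absent. The maximum-entropy approach treats the modelled
distribution as a probability distribution `q_λ` over a finite set of
*background* cells that represent the available environment:

$$q_\lambda(x) = \frac{\exp\big(\sum_j \lambda_j f_j(x)\big)}{Z(\lambda)},
\qquad Z(\lambda) = \sum_{x \in B} \exp\Big(\sum_j \lambda_j f_j(x)\Big).$$

Among all distributions whose feature expectations match the presence
sample, the Gibbs form above is the one of maximum entropy; fitting it
is equivalent to minimising the convex penalised negative presence
log-likelihood

$$J(\lambda) = -\frac{1}{|P|}\sum_{x \in P} \log q_\lambda(x)
  \;+\; \sum_j \beta_j |\lambda_j|.$$

**Features.** Each predictor contributes a linear and a quadratic
feature (its value scaled into $[0,1]$ from the training range, and the
square of that), and forward/reverse hinge features
$\max(0, (x-t)/(\mathrm{hi}-t))$ and $\max(0, (t-x)/(t-\mathrm{lo}))$
at 20 knots per direction placed at equally spaced background
quantiles. Linear + quadratic + hinge is the combination generally
recommended for several hundred presence records; hinge features give
the response curves their flexible, piecewise shape.

**Assumptions worth stating.** The species is assumed to be in
(quasi-)equilibrium with its environment, the niche is assumed
transferable across space and into the projected climates, and the
background is assumed to describe the environment actually available —
which is why the package restricts background sampling to the habitat
mask (water cells, for an aquatic species) rather than all land.

## Fitting: the optimiser and its safeguards

The optimiser is cyclic coordinate descent with soft-thresholding: for
each coefficient a one-dimensional Newton step on the smooth part of
$J$ is soft-thresholded by $\beta_j$, then verified against the *exact*
objective with step-halving, so $J$ is monotonically non-increasing and
the convex optimum is reached regardless of feature correlation. A full
sweep that decreases $J$ by less than `tol` (default $10^{-6}$) stops
the fit. The per-coordinate bookkeeping of objective decrease yields
the percent-contribution report: each variable is credited with the
decrease produced by updates to its own features, normalised to 100%.

Two safeguards matter in practice:

* **Presences join the background support** (the
  `add_samples_to_background` default, shared with the reference
  implementations of this model family). Without it, a presence set
  that is linearly separable from the background in feature space — easy
  to achieve with hinge features — makes $J$ unbounded below and the
  coefficients diverge. With the presences in the support the objective
  has a finite minimiser for any $\beta \ge 0$.
* **Regularisation floors.** The automatic weights are
  $\beta_j = m \cdot c_{\mathrm{class}} \cdot s_j/\sqrt{|P|}$ with
  $s_j$ the presence-sample standard deviation of the feature (floored
  at 0.01), class constants 1.0 for linear/quadratic and 0.5 for hinge,
  and multiplier $m = 1$ by default. When the fixed-background mode is
  used, each $\beta_j$ is additionally floored just above the gap
  between the presence feature mean and the background's attainable
  expectations, the axis-wise condition for a finite optimum.

The logistic output $p = c\,q/(1+c\,q)$ with $c = \tau/(1-\tau)\,e^H$
($H$ the entropy of the fitted distribution, $\tau = 0.5$) calibrates
raw scores so that a "typical" presence site scores about 0.5; for the
uniform model it returns exactly $\tau$ everywhere.

## Validation

**AUC.** The presence-background AUC is computed in its Mann–Whitney
form (wins + half-ties over all presence × background score pairs). It
is invariant under monotone transforms of the scores, so raw and
logistic outputs give the same value.

**Cross-validation.** Ten independent random 75/25 presence splits;
the package reports the mean ± SD (n−1) of training and test AUC across
replicates. The splits are independent draws rather than a 10-fold
partition because the 75/25 proportion is the primary contract; a
k-fold mode is available behind a flag.

**Null models.** A high AUC can be an artefact of the background
choice, so the model is compared against chance: 99 pseudo-presence
sets of the actual presence size are drawn without replacement from the
(habitat-restricted) pool, the full pipeline is refitted to each, and
the actual AUC is declared significant when it exceeds the nearest-rank
97.5th percentile — the upper limit of the distribution-free 95% CI —
of the null AUCs. Two p-values are reported under distinct names: the
permutation-rank p-value $(1 + \#\{\mathrm{null} \ge
\mathrm{actual}\})/(n_{\mathrm{null}}+1)$, whose smallest attainable
value with 99 nulls is 0.01, and a normal-approximation tail
probability computed from the null mean and SD, which can be smaller
and is flagged as an approximation.

**Threshold.** Binary range maps use the 10th-percentile training
presence rule: the $\lfloor 0.1\,n\rfloor + 1$-th smallest training
suitability, so at most 10% of training presences fall strictly below
it; cells at or above the threshold are "suitable". The same threshold
is reused unchanged for future projections, so current and future
binary maps are directly comparable.

## Range change

Current and future binary maps classify each cell as retained (1→1),
loss (1→0), gain (0→1) or unsuitable (0→0). With $CR = R + L$ the
current range, turnover is

$$T = 100 \cdot \frac{L + G}{CR + G},$$

0 when nothing changes and 100 when the future range shares no cell
with the current one. Scenario projections are combined as equal-weight
cell-wise means (*consensus*) before thresholding — predictions are
averaged, not climate inputs. Latitudinal structure is summarised by
half-open 1-degree bands (membership by cell-centre latitude) and by
the mean centre latitude of gain and of loss cells; under a warming
scenario on a northern-hemisphere domain the gain centroid lying
poleward of the loss centroid is the testable form of a poleward range
shift. Full dispersal is the default (every newly suitable cell is
counted as gained); a no-dispersal mode zeroes gains outside the
current range. Regional tables express retained/gain/loss as
percentages of the union $R+G+L$, so each region's triple sums to 100.

## The synthetic test bed

The generator produces the complete input bundle from scratch, with a
known truth, so parameter recovery and calibration can be tested
without any downloaded data.

* **Domain.** 100 × 100 cells spanning latitudes 0–70 N. The
  coldest-month minimum temperature follows a sigmoid profile — a warm
  tropical plateau near +22 °C dropping steeply across the mid-latitudes
  to about −33 °C — rather than a linear lapse, because that is the
  shape of hemispheric winter-minimum fields and it keeps intermediate
  temperatures (where the niche optimum sits) geographically rare, as
  they are on real continents. Dry-quarter precipitation ramps
  west-to-east as a cubic (0–1200 mm with most mass below 300 mm),
  reproducing the strong right skew of dry-season rainfall over land.
  Smoothed Gaussian noise (kernel width 3 cells) supplies spatial
  autocorrelation; a smoothed-noise human-influence field is scaled to
  0–100; the water-habitat mask flags 35% of cells.
* **Truth.** Suitability is a product of response curves: a Gaussian
  bell in T_min (optimum 0 °C, SD 6 °C), a Gaussian bell in Prec_dry
  (optimum 195 mm, SD 110 mm), and an increasing logistic response to
  human influence (slope 0.05 per unit, centre 40). The two bells place
  the optimum inside an intermediate band of both gradients; the
  human-influence response reflects the commensal association commonly
  reported for aquatic invaders. Gaussian bells were chosen over other
  unimodal shapes because they give closed-form optima for recovery
  tests.
* **Presences.** 500 records are drawn cell-wise with probability
  proportional to suitability (optionally times a bias layer), with one
  point placed uniformly inside each drawn cell — so grid deduplication
  is a real, lossy step, as with museum records.
* **Scenarios.** "Strong" (+2.0 °C, precipitation × 0.85) and "mild"
  (+1.2 °C, × 0.95) presets emulate a severer and a milder emission
  pathway; human influence and the mask are held constant, mirroring
  the conservative convention of holding non-climate layers fixed.

**What passing tests do and do not show.** The generator's fields are
smooth, stationary and free of coastlines, observation error and
spatially structured survey bias; its truth is exactly a product of
three curves. Recovery of the optimum and well-calibrated null tests on
this landscape validate the machinery — they do not certify performance
on real occurrence compilations, where sampling bias and niche
disequilibrium dominate the error budget.

## Numerical choices and open decisions

* **Grid convention**: cell-registered lower-left corner, row 1 =
  north, half-open cells (east/north edges exclusive) — matching ESRI
  ASCII semantics. Corner-vs-centre registration is asserted by this
  package, not inherited from any data source.
* **Bilinear edges**: output centres outside the source centre lattice,
  or with a missing stencil member, become nodata; no extrapolation.
* **Percentiles** are nearest-rank everywhere (thresholds and CIs) for
  determinism; ties in the AUC are handled by average ranks.
* **Collinearity screen**: complete-case sampling over the 1000 random
  cells; the retention priority list is explicit user input (default:
  T_min, Prec_dry, T_max, Prec_wet, human influence — the
  physiological-constraint ordering), and dropping is invariant to
  layer input order given the list.
* **Quarters** are any three consecutive calendar months including the
  December–January wrap, the standard convention for driest/wettest
  quarter variables.
* **Response-optimum estimation** (used in the recovery analysis): the
  single-variable response is refitted in the linear+quadratic family —
  exactly Gaussian in the predictor, matching the truth's family — with
  a light penalty (`beta_multiplier = 0.05`). Default-strength L1
  shrinkage visibly widens the fitted bell and destabilises its mode;
  a near-ML two-parameter fit agrees with a case-control logistic
  regression oracle. The optimum is read as the midpoint of the
  arg-max plateau of the fitted curve.
* **Problem sizes** used by the test suite: the recovery analysis runs
  on the 100 × 100 default landscape with 500 presences and a
  2000-cell background; null-model calibration uses a 60 × 60
  landscape, a 1000-cell background, 49 nulls and 40 repetitions with a
  linear+quadratic feature set. These sizes give stable statistics
  while keeping a full run of the suite under a minute.
* **Seed discipline**: every random stage derives its seed from one
  master seed and the stage name (`derive_seed`), so pipeline outputs
  are bit-reproducible and stages can be re-run independently.

## Known limitations

* The raster container handles geographic lon/lat lattices only — no
  projections, datum transformations or global tiling; cell areas are
  treated as equal in all counts, which is only locally true on a
  geographic grid.
* Product, threshold and categorical feature classes of the original
  MaxEnt family are not implemented, and the sample-size-dependent
  interpolation tables for regularisation constants are deliberately
  replaced by fixed per-class constants.
* The null-model test refits the *same* pipeline to random
  pseudo-presences; it guards against background artefacts, not against
  spatially autocorrelated sampling bias shared by presences and
  pseudo-presences.
* GeoTIFF input is not supported; ESRI ASCII grids are the canonical
  format.
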