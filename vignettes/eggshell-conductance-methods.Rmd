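---
title: "Methods: eggshell conductance, pore structure, and phylogenetic comparative inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eggshell conductance, pore structure, and phylogenetic comparative inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovocond)
```

`ovocond` implements the analytical pathway behind comparative studies of
avian eggshell function along environmental gradients: estimate water-vapor
conductance from egg mass-loss experiments, quantify eggshell pores from
calibrated SEM-style imagery, and ask — with phylogenetic corrections —
whether these traits track elevation. This vignette explains the models,
the tunable parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Water-vapor conductance

An egg in a desiccator over silica gel sits in an atmosphere of effectively
zero humidity, so the water-vapor pressure difference across the shell,
$\Delta P_{H_2O}$, equals the saturation vapor pressure at the egg's
temperature. Daily weighing gives a near-linear mass decline whose OLS
slope (converted to mg/day) is the water-loss rate $M_{H_2O}$, and

$$G_{H_2O} = \frac{M_{H_2O}}{\Delta P_{H_2O}} \quad
  [\mathrm{mg\,day^{-1}\,torr^{-1}}].$$

`saturation_vapor_pressure()` uses the Arden Buck equation over liquid
water converted to torr (23.77 torr at 25&nbsp;°C, 4.58 torr at 0&nbsp;°C). Two
$\Delta P$ modes are provided because field protocols state both a
temperature-dependent value and a standardized 23.77-torr convention for
cross-study comparability: `delta_p_mode = "temperature"` (default; each
egg uses its chamber temperature) and `"standard"` (fixed
`standard_delta_p = 23.77`).

**Quality control.** An egg is retained when (i) the mass-on-day regression
has $R^2 > 0.8$, (ii) the raw slope is negative, and (iii) no single
between-day drop exceeds `max_drop_mult` (default 5) times the *median*
per-interval drop. The third rule operationalizes "unusual weight loss"
from shell fractures. The median — not the fitted slope — is the reference
on purpose: a fracture is a step change that inflates the OLS slope itself
(by roughly one fifth of the step for a mid-series break over eight days),
so a slope-referenced rule would mask exactly the events it is meant to
catch, while the median of seven interval drops is unaffected by a single
step. Species means average the conductance of at most the first three
QC-passing eggs in stable input order.

**Size correction.** Egg volume uses the empirical relation
$V = 0.51\,L\,W^2$ (cm). Conductance and structural traits are
log-transformed and regressed on log egg mass (or log volume);
`allometric_residuals()` returns residuals together with a
`significant` flag — when the allometric slope is not significant at 0.05
the convention is to analyze absolute trait values instead, and the
pipeline follows that flag automatically.

**Elevation bands.** Stations fall in three bands (lowland 340–850 m, mid
1200–2000 m, highland 2500–3000 m). The bands are gapped, so
`elevation_category()` assigns in-gap values to the nearest band edge with
a warning rather than failing; analyses of band effects are insensitive to
how the rare gap value is resolved, and the warning keeps the decision
visible.

## Pore detection

SEM surface fields show shell pores as holes against a bright shell
matrix: open ("functional") pores are dark, while occluded or superficial
holes are lighter gray. The detector works on percentile-normalized
intensities (1st percentile → 0, 99th → 1, clipped), which makes it
invariant to affine changes in brightness/contrast and hence to detector
gain. Candidate pixels fall below the `occluded_threshold` (default 0.5);
8-connected components smaller than `min_area_um2` (default 0.05 µm²) or
touching the field border are discarded (partial pores would bias areas);
surviving components are classed functional when their mean interior
intensity is at most `dark_threshold` (default 0.2). Fixed thresholds on
the normalized scale are the default because the functional/occluded
dichotomy is tonal and the normalization already absorbs global intensity
shifts; an `otsu = TRUE` mode adapts the candidate threshold for real
images with different histogram shapes. Areas are pixel counts times the
squared µm-per-pixel scale (no sub-pixel contour fitting — adequate to
within ~10% for disk-like pores of radius ≥ 3 px); pore density is
functional pores per mm² of field. The scale must be supplied with the
image; it is never guessed from content.

Replicate fields (three per specimen) are averaged by
`summarize_structure()`, and the replicate triples feed
`repeatability_icc()`.

## Trait-evolution models and phylogenetic signal

Four classical models give the among-species covariance of a continuous
trait on a rooted, ultrametric phylogeny with BM covariance $C$ (entries =
MRCA depths):

* **BM** — $\sigma^2 C$;
* **Pagel's λ** — off-diagonals of $C$ scaled by $\lambda \in [0, 1]$;
* **OU** — stationary Ornstein–Uhlenbeck with pull $\alpha$:
  $V_{ij} = \frac{1}{2\alpha} e^{-2\alpha (T - s_{ij})}
  (1 - e^{-2\alpha s_{ij}})$ with $T$ the tree height and $s_{ij}$ the MRCA
  depth. The stationary form assumes equal tip depths, so non-ultrametric
  trees are rejected explicitly rather than silently approximated;
* **EB** — early burst, node depths remapped by
  $d' = (e^{a d} - 1)/a$, $a \le 0$.

`fit_model()` profiles the root state (GLS mean) and the rate (ML, not
REML, variance) analytically at each shape value, leaving a 1-D likelihood
in the shape parameter, maximized by a 20-point grid pre-scan plus Brent
search in the bracketing interval (tolerance $10^{-6}$); single-parameter
profiles are cheap and only mildly multimodal, so this is both robust and
fast. Search ranges: $\lambda \in [0,1]$,
$\ln\alpha \in [\ln 10^{-4}, \ln 10^{2}]$ on a unit-height tree, and
$a \in [-10, 0]$. Trees are rescaled to unit height internally (this
conditions the $\alpha$ search) and estimates are back-transformed to the
original time scale. Near-singular covariances get a single ridge of
$10^{-10}\cdot\overline{\mathrm{diag}}$ with a warning. Models are ranked
by AICc ($k = 2$ for BM, 3 otherwise) with Akaike weights.

Phylogenetic signal is reported as $\hat\lambda$ with a likelihood-ratio
test against $\lambda = 0$ referred to $\chi^2_1$. The LRT-versus-zero
convention is a package choice — signal strength is often reported without
a test — and is flagged as such here; on a star tree λ is unidentifiable
and the fit carries a `degenerate` flag.

## Comparative tests

**PGLS.** `pgls()` computes
$\hat\beta = (X^\top C^{-1}X)^{-1}X^\top C^{-1}y$ via Cholesky whitening,
with $t$ tests on $n-p$ df and
$R^2 = 1 - e^\top C^{-1} e / e_0^\top C^{-1} e_0$ against the
intercept-only GLS fit. The covariance is the best-AICc model per trait,
re-selected per dataset rather than hard-coded. With $C = I$ the estimates
equal OLS exactly — a property used as a test.

**Phylogenetic ANOVA.** The observed statistic is the ordinary one-way F;
its null distribution comes from simulating BM trait evolution on the tree
(rate = the data's ML BM rate) with group labels fixed, and
$p = (1 + \#\{F_{null} \ge F_{obs}\})/(n_{sim}+1)$ — the add-one
convention avoids zero p-values. A Levene-type variant
(`group_variance_test()`) applies the same null scheme to absolute
deviations from group medians to compare trait *variances* among bands; the
specific variance test is a package choice, as the procedure is usually
left unnamed in field reports.

**Residual-then-test workflow.** The pipeline regresses the trait on size,
takes residuals, and then tests those residuals against elevation — the
convention in this literature — even though a joint model would be
statistically cleaner; both entry points are exported, and the residual
workflow is the default.

**Repeatability.** The ICC uses the one-way ANOVA estimator
$R = (MS_B - MS_W)/(MS_B + (k-1)MS_W)$ (generalized $k$ for unbalanced
groups), truncated to $[0,1]$ with $R = 0$ whenever the between-group
variance estimate is non-positive. Confidence intervals resample whole
groups with replacement (default 1000 draws); the variance-component LRT
fits a random-intercept mixed model by ML and refers the statistic to the
boundary mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$.

Per-family PGLS p-values are reported raw, matching field practice; a Holm
adjustment can be applied by the caller. Categorical predictors use
treatment contrasts with the alphabetically first level as reference.

## What the synthetic generators emulate — and what they do not

The generators exist so that every stage can be tested against known
truth:

* `simulate_tree()` — pure-birth trees rescaled to height 1 (ultrametric
  to $10^{-10}$), standing in for a dated supertree.
* `assign_elevations()` — band label then uniform-within-band, reproducing
  the clumped, gapped elevation distribution of a three-station design;
  an option draws bands from a thresholded BM trait to create
  phylogenetically clustered elevations.
* `simulate_trait()` — multivariate normal with mean
  $z_0 + \beta\,\mathrm{elev}/1000$ and covariance $\sigma^2 C_{model}$,
  sharing the covariance code path with the fitting routines.
* `simulate_mass_series()` — linear loss $G\,\Delta P/1000$ g/day plus iid
  balance noise; an optional fracture adds a step drop (default 10× the
  daily loss) for QC testing.
* `generate_sem_image()` — bright speckled background (mean 0.8, sd 0.05)
  with rejection-placed dark (0.05) and gray (0.35) disks and a truth
  sidecar of centers, radii, and classes.

The default study bundle (`simulate_egg_study()`) encodes the field
conditions: 32 species, λ-model trait evolution with low signal
(λ = 0.4, σ² = 0.25 on log G), elevation effect −0.4 per km on log
conductance, baseline $z_0 = 0.65$ chosen so the grand-mean conductance is
about 1.2 mg day⁻¹ torr⁻¹ (the magnitude reported for Andean
communities), 1–3 eggs per species weighed for 8 days with 0.005 g balance
noise, and desiccator temperatures of 22.9 / 17.7 / 12.6 °C by band.

The generators deliberately do **not** model: temporal drift in chamber
conditions, within-egg regional variation in shell structure, SEM charging
artifacts or cuticle texture, non-circular or branched pore canals, or
measurement error in elevations. Passing the recovery tests therefore
shows the estimators are correct *under the stated generating model*, not
that real SEM fields or field mass series are this clean; the `otsu` mode
and configurable QC thresholds are the knobs real data will need.

## Problem sizes and determinism

The validation suites use 100-tip trees with 200 replicates for parameter
recovery, 500 outer replicates × 1000 null simulations for ANOVA
calibration, 1000 synthetic eggs for conductance error, 100 seeded image
fields for detection accuracy, and 200/100 end-to-end pipeline runs for
type-I error and power — sizes at which Monte-Carlo error is comfortably
inside the tolerances being checked. All generators are pure functions of
their seed; pipelines re-run with the same inputs and seed produce
byte-identical output tables.

## Known limitations

* The OU covariance is the stationary form and requires ultrametric trees.
* The ICC machinery covers the one-way (species × replicate) design only.
* Pore areas are pixel-count areas; heavily overlapping pores merge into
  one component (generator placements keep separations above this regime).
* The within-species analyses are ordinary regressions, as no phylogeny
  applies below the species level.
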