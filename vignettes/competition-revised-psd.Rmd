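---
title: "Competition-revised potential species distributions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competition-revised potential species distributions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compsd)
```

## The problem

Abiotic species distribution models predict where a tree species *could*
grow from climate and site variables alone. They systematically
over-predict: a species rarely occupies all of its tolerable climatic
space, because other species out-compete it over the decades of stand
development. `compsd` implements a two-stage mapping framework for this
problem. Stage one maps **potential species distribution (PSD)** — a 0–1
suitability index per raster cell — from three abiotic response kernels.
Stage two revises those maps with **relative competitive ratings** derived
from an individual-based forest gap model run to 100 years, upscaled to the
landscape through a classification of the area into forestland types. Both
map variants are validated against plot observations with overall agreement
and Cohen's kappa.

## Abiotic response kernels

Each species carries a parameter set (`species_params()`) defining three
closed-form responses, each scaled to $[0, 1]$ where 0 is unsuitable and 1
optimal.

**Light.** Response to normalized photosynthetically active radiation
(nPAR, 0–1):
$$R_{PAR} = c_1\{1 - \exp[-c_2\,(nPAR - c_p)]\}$$
with scaling factor $c_1$, slope $c_2$ and light compensation point $c_p$
(the light level at which photosynthetic gain balances respiration). The
raw curve is negative below $c_p$ and exceeds 1 when $c_1 > 1$; because the
suitability index is defined on $[0,1]$, the implementation clamps the
output to that interval. Per-species curves follow shade-tolerance-class
archetypes (`light_archetype()`): the most tolerant class rises steeply
from a low compensation point ($c_1{=}1$, $c_2{=}4.64$, $c_p{=}0.05$), the
least tolerant saturates slowly from a higher one ($c_1{=}2.24$,
$c_2{=}1.136$, $c_p{=}0.08$), with linear interpolation between classes.

**Soil water.** A unimodal kernel on soil water content (SWC), scaled so 0
is the permanent wilting point and 1 field capacity. With tolerance limits
$SWC_{min} < SWC_{max}$ and optimum $\psi$, the normalized position is
$\xi = (SWC - SWC_{min})/(SWC_{max} - SWC_{min})$ and
$$R_{SWC} = \max[0,\; \kappa\, \xi^{\alpha} (1-\xi)^{1/\alpha}],$$
where $\chi$ is the normalized position of $\psi$, $\alpha = \chi/(1-\chi)$
places the mode at $\chi$, and $\kappa = 1/[\chi^\alpha (1-\chi)^{1/\alpha}]$
normalizes the mode to exactly 1. Outside $(SWC_{min}, SWC_{max})$ the
power terms are undefined; the implementation returns 0 there, consistent
with the $\max[0,\cdot]$ guard and the tolerance-limit semantics.

**Growing degree days.** GDD accumulates daily mean temperature excess
over a 5 °C base (`growing_degree_days()`). The response is a symmetric
parabola between the degree-day tolerance limits,
$$R_{GDD} = \frac{4\,(GDD - GDD_{min})(GDD_{max} - GDD)}{(GDD_{max} - GDD_{min})^2},$$
clamped to $[0,1]$: 1 at the window midpoint, 0 at and beyond both limits
(the northern and southern range limits).

The original PSD is the cellwise product
$PSD = R_{PAR} \times R_{SWC} \times R_{GDD}$, so it can never exceed its
most limiting factor, and a nodata cell in any factor is nodata in the
product.

```{r}
p <- species_params("demo", c1 = 1, c2 = 4.64, cp = 0.05,
                    swc_min = 0, swc_max = 1, psi = 0.5,
                    gdd_min = 1000, gdd_max = 3000)
c(par = response_par(0.8, p), swc = response_swc(0.35, p),
  gdd = response_gdd(1500, p))
```

## The gap model

The competition signal comes from an individual-based simulator of the
JABOWA family (`simulate_stand()`). The source framework names the model
family but not its equations, so this package adopts the published
canonical forms; every constant below is an exposed argument.

* **Height allometry.** $H = 137 + b_2 D - b_3 D^2$ cm with
  $b_2 = 2(H_{max}-137)/D_{max}$, $b_3 = (H_{max}-137)/D_{max}^2$, so a
  seedling starts at breast height and $H(D_{max}) = H_{max}$ exactly.
* **Optimal growth.**
  $\Delta D = G D\,[1 - D H/(D_{max} H_{max})] / (274 + 3 b_2 D - 4 b_3 D^2)$,
  floored at 0; growth vanishes as a tree approaches maximum size.
* **Light competition.** Trees are ranked by height; available light at a
  crown is Beer–Lambert extinction through the leaf area of strictly
  taller trees, $AL = e^{-k\,LAI_{above}}$ with $k = 0.4$ per unit LAI. A
  tree's light multiplier is its tolerance-class light curve at $AL$. Leaf
  area per tree is $0.16\,D^2$ m² on a 100 m² patch (the classic gap-model
  plot area); ties in height shade each other not at all rather than
  asymmetrically.
* **Realized growth** multiplies the optimal increment by the light
  multiplier, $R_{GDD}$ and $R_{SWC}$ at the site, and a 0–1
  `nutrient_index`. Soil nutrients are collapsed to this single
  multiplicative index because the landscape maps carry no nutrient
  surface.
* **Mortality.** Intrinsic annual probability $4/age_{max}$, so roughly
  $e^{-4} \approx 1.8\%$ of a cohort reaches its maximum age; after two
  consecutive years of growth below 0.01 cm the tree additionally faces a
  0.368 stress mortality, giving a stressed 10-year survival near 1%.
* **Establishment.** A species recruits only where site GDD and SWC fall
  strictly inside its tolerance windows and forest-floor light exceeds its
  compensation point; eligible species add Poisson-distributed saplings
  (0.5–2.5 cm dbh) at the species' `recruit_rate` per plot-year.
* **Sub-step order** is fixed as growth → mortality → establishment each
  year; yearly records hold per-species stems, basal area and aboveground
  biomass ($a D^b$ power-law allometry).

No exogenous disturbance is simulated beyond gap formation through
mortality and self-thinning through shading and stress. Replicate runs
(`replicate_mean_biomass()`, default 50 replicates × 100 years) average
the final-year biomass per species; replicate $r$ draws its RNG stream
from `seed + r`, making results bit-reproducible.

## From biomass to revised maps

`classify_forestland()` partitions the landscape into forestland types —
distinct species combinations a site can carry — by seeded k-means on the
per-cell vector of species PSD values (default 12 types, mirroring the
study system). The original classification scheme for the study area was a
hybrid unsupervised–supervised procedure that is not restated in the
source; seeded k-means plus a labeling step is this package's documented
stand-in, and `label_types()` names each type from its dominant centroid
species (e.g. `rS-wP-eH`).

For each type, a gap-model run at the type's mean site conditions yields
mean final biomass $AGB_{lk}$ per species $k$ in type $l$. The relative
competitive rating is the within-type biomass share rescaled by the
largest share:
$$P100_{lk} = \frac{AGB_{lk}}{\sum_k AGB_{lk}} \cdot
  \left\{\max_k \frac{AGB_{lk}}{\sum_k AGB_{lk}}\right\}^{-1},$$
so every type's best performer scores exactly 1 and species eliminated
from the community score 0. The sum and max run over species within a
type — the only reading under which every published rating row contains a
1.0. The transform is scale-invariant, permutation-equivariant and
idempotent; ties at the row maximum all receive 1. An alternative
definition found in prose descriptions — biomass as a proportion of the
species' own monoculture-optimum biomass — is provided separately as
`monoculture_rating()` and is not used in the pipeline.

The revised map is $PSD_{revised} = P100_{lk} \times PSD_{original}$ per
cell, which can only lower suitability. Cells without an assigned
forestland type become nodata rather than silently keeping their original
values.

```{r}
r <- acadian_ratings()   # published 12-type x 16-species rating table
r[1:3, 1:6]
```

## Accuracy assessment

A species is predicted present in a cell when its PSD is **strictly
greater than 0.25**; plot observations are cross-tabulated against this
prediction into a 2×2 table per species. Overall agreement is the diagonal
percentage; Cohen's kappa corrects it for chance agreement from the
marginals, and kappa is classed verbally on the Monserud–Leemans scale
(half-open bins: poor < 0.20, fair, moderate, good, very good,
excellent ≥ 0.80). Table totals are taken as the sum of the four cells
(the printed per-species plot counts occasionally disagree with their own
cells). Across-species summaries are unweighted arithmetic means — the
convention under which the published per-species agreements average to
exactly their printed headline values. Plots falling off the grid or on
nodata cells are excluded and counted.

```{r}
t3 <- acadian_validation_counts("original")
rep3 <- accuracy_report(mapply(contingency_table, t3$n_pp, t3$n_pa,
                               t3$n_ap, t3$n_aa, SIMPLIFY = FALSE))
c(mean_agreement = mean(t3$agreement_reported),
  mean_kappa = mean(t3$kappa_reported))
```

## The synthetic landscape

Because no deposited gridded inputs exist, `synthetic_scenario()` defines
fully synthetic study conditions with known ground truth. Abiotic surfaces
are seeded white noise smoothed by a separable Gaussian kernel (the
autocorrelation length, default 10 cells, is its standard deviation) and
rescaled to each variable's range: nPAR and SWC to 0–1, GDD to
900–2500 °C·day, a plausible humid-temperate span. The default grid is
200 × 200 cells of 70 m and 1,240 plots, matching the working resolution
and inventory density of the study system; observation noise flips each
plot flag independently with rate $\varepsilon$.

What the generator emulates: smooth spatial gradients, species with
staggered climatic windows and a tolerance–growth trade-off, plot networks
with known truth. What it does not emulate: topographically driven
radiation and moisture fields, spatially correlated observation error,
disturbance history, or real Acadian species parameters (the shipped
16-species tables are synthetic, generated from documented ranges and so
flagged in their filenames). Passing end-to-end tests therefore
demonstrates internal consistency of the method — perfect recovery at
$\varepsilon = 0$, agreement $100(1-\varepsilon)$ at $\varepsilon > 0$ —
not predictive skill on real landscapes.

## Numerical choices and degenerate inputs

* Kernel outputs are clamped to $[0,1]$; the soil-water mode evaluates to
  exactly 1 at $\psi$ by construction of $\kappa$.
* Raster cells are half-open on their right and bottom edges when mapping
  plot coordinates, so boundary points resolve uniquely.
* A forestland type in which nothing grows cannot be rated; the pipeline
  substitutes a uniform rating row rather than failing the whole run.
* Degenerate kappa (all mass in one agreeing cell) is defined as 1; the
  marginal-product expectation cannot reach 1 any other way in a 2×2
  table.
* Site-quality cuts default to 0.25/0.5 — the lower cut aligned with the
  presence threshold, the upper halfway to certainty — and are
  configurable, since the source maps never define their class limits
  numerically.
* The test and acceptance runs use reduced problem sizes chosen for
  desk-scale iteration (grids of 30–60 cells a side, 2–8 replicates for
  pipeline smoke runs, and one full 50-replicate × 100-year stand run);
  the statistical checks use cohort sizes of 5,000–20,000 trees.

## Known limitations

* The gap-model constants are the canonical family forms, not a
  calibration to any inventory; published rating values are shipped as
  data, not regenerated by simulation.
* The k-means classification is a stand-in for the original hybrid
  classification scheme; with strongly non-spherical suitability clusters
  the partitions will differ.
* Raster I/O supports the ESRI ASCII grid format only; georeferencing is
  carried as plain metadata with no projection handling.
* Within-cell heterogeneity is ignored: one gap-model site per forestland
  type, at the type's mean conditions.
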