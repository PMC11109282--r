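---
title: "Delineating mega-environments from envirotypes and GGE biplots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating mega-environments from envirotypes and GGE biplots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megaenv)
```

## The problem

A multi-environment trial (MET) network evaluates candidate genotypes at
many locations. When genotype-by-environment interaction (GEI) is large
and partly repeatable, the network can be split into *mega-environments*
(MEs): groups of locations in which the same genotypes win and crossover
interaction is minimal. Breeding and variety recommendation then operate
per ME rather than per location. `megaenv` implements two complementary
delineation tracks for a rain-fed soybean network of nineteen Indian test
locations, and a consensus step that merges them:

1. an **envirotyping** track driven purely by long-term daily weather, and
2. a **phenotypic (GGE biplot)** track driven purely by trial yields,

with a seeded synthetic-data module that emulates both input streams so
the whole pipeline is testable end to end without any external service.

## Envirotyping track

### The 19 covariables

Daily weather in the NASA-POWER agroclimatology dialect (mean/max/min
temperature, rainfall, wind speed, relative humidity, dew point, downward
long- and shortwave radiation) is expanded into 19 covariables: the nine
raw variables plus ten eco-physiological quantities. The source study
names the covariables without printing formulas, so this package adopts
the FAO-56 conventions together with Priestley–Taylor potential
evapotranspiration — the standard choices of the envirotyping literature:

* Tetens saturation vapour pressure $e_s(T) = 0.6108\,
  e^{17.27T/(T+237.3)}$ kPa, and its slope
  $\Delta = 4098\,e_s(T)/(T+237.3)^2$;
* vapour pressure deficit
  $\mathrm{VPD} = \tfrac12(e_s(T_{max})+e_s(T_{min})) - e_s(T_{dew})$,
  floored at 0;
* growing degree-days $\max(0, (T_{max}+T_{min})/2 - T_b)$ with
  $T_b = 10\,^\circ$C (soybean default, configurable);
* FRUE, the temperature limitation on radiation-use efficiency: a
  piecewise-linear trapezoid over cardinal temperatures
  $8/25/35/44\,^\circ$C (standard soybean values, configurable);
* astronomical daylight hours $N$ and extraterrestrial radiation RTA from
  latitude and Julian day (FAO-56 closed forms; day-of-year 366 is folded
  onto 365, a sub-0.3 % approximation);
* actual sunshine hours by inverting the Ångström–Prescott relation with
  $a_s = 0.25$, $b_s = 0.50$;
* Priestley–Taylor ETP with $\alpha = 1.26$,
  $\gamma = 0.0665$ kPa/°C, $\lambda = 2.45$ MJ/kg and net radiation
  simplified to $(1-0.23)\,SW$ — longwave enters the pipeline as its own
  covariable, and ETP feeds only *relative* site contrasts, so the full
  net-radiation balance adds nothing the clustering could use;
* PETP = rainfall − ETP, and the daily temperature range.

All constants are exposed as arguments of `compute_panel()`, so either
convention of any later reference dataset can be reproduced.

### W matrix, kernel, clustering

Each covariable is averaged over four crop-cycle windows (15 Jun–15 Jul,
16 Jul–15 Aug, 16 Aug–15 Sep, 16 Sep–15 Oct; closed intervals) in each of
20 years (2002–2021), giving the envirotype matrix **W** of 19 sites ×
1520 (year × covariable × window) columns. Columns are centered and
scaled to unit variance by default: the covariables carry incommensurate
units (mm, °C, hours, MJ), and without scaling the kernel is dominated by
the large-unit variables. Zero-variance columns are dropped with a
warning and recorded in `col_meta`; the unscaled variant is one flag
away (`build_w(..., scale = FALSE)`).

The enviromic kernel is
$$K_E = \frac{WW'}{\mathrm{trace}(WW')/n},$$
whose trace equals the number of environments by construction — the
package asserts this to $10^{-8}$ on every computation. Locations are
clustered by average linkage (UPGMA) on the kernel-induced metric
$d_{ij} = \sqrt{K_{ii}+K_{jj}-2K_{ij}}$ — the canonical feature-space
distance of a kernel, which on scaled rows reduces to the Euclidean
distance between envirotype profiles. The number of MEs `k` is a user
parameter defaulting to 4; no automatic selection rule is applied because
none is established for this use. Sites are sorted by code before
agglomeration so the result is independent of input order.

## Phenotypic track

### Joint RCBD ANOVA

Trials follow a randomized complete block design in every environment.
`anova_joint()` computes the fixed-effects partition
$$y_{ijk} = \mu + E_j + B_{k(j)} + G_i + GE_{ij} + \varepsilon_{ijk}$$
from closed-form sums of squared cell totals (no iterative fitting), with
F ratios against the pooled residual. Blocks nested in environments are
always fitted and reported as their own row: published pooled-ANOVA
tables for such networks typically omit the block row because its share
of the total SS is negligible, and the generator mirrors that (block
variance defaults to 1 % of residual variance). Unbalanced tables are
rejected with the offending cells listed rather than silently reweighted;
analysis of unbalanced data belongs to mixed models, which are outside
this package's scope.

### GGE biplot

`fit_gge()` centers the genotype × environment means matrix by
environment means — removing the grand mean and environment main effect,
retaining genotype main effect plus GEI — and decomposes it by SVD:
$$\bar Y_{ij} - \mu - \beta_j = \sum_n \lambda_n \alpha_{in}\eta_{jn}.$$
Singular-value partitioning (SVP) is a flag: `symmetric`
($\sqrt{\lambda}$ on both sides) is the default for which-won-where,
`environment` ($\lambda$ on environment scores) is auto-applied for
discriminativeness/representativeness — the standard pairings for the two
readings. No pre-scaling by environment standard deviation is applied
(GGE "scaling 0"); geometry always uses the first two PCs while the full
spectrum is kept in the model object.

`which_won_where()` takes the convex hull of genotype scores in PC1–PC2;
rays from the origin perpendicular to hull edges cut the plane into
sectors, and each environment belongs to the sector of the hull genotype
maximizing the inner product with its score vector — equivalently, the
rank-2 predicted winner (the package tests this equivalence against a
brute-force argmax oracle). Environments on a boundary are assigned
counter-clockwise of it, a deterministic tie-break. Environments sharing
a sector form the GGE ME grouping; `env_similarity_groups()` provides the
per-year partition by average-linkage clustering on angular distance
between environment vectors.

`discrim_vs_repres()` reads environment-focused scores: vector length is
the environment's discriminating power (proportional to its standard
deviation in the rank-2 model), and the cosine of the angle to the
average-environment axis (AEA) is its representativeness. Because no
numeric rule is established for "both discriminative and representative",
the package operationalizes it as *above the median on both measures* —
a transparent, scale-invariant rule (classifications are unchanged when
all yields are multiplied by a positive constant).

## Consensus

`propose_mes()` merges the envirotype partition with the per-year GGE
partitions: the co-membership matrix records the fraction of input
partitions grouping each pair, sites are clustered by average linkage on
`1 − co-membership`, and exact ties are broken toward the anchor
partition (an infinitesimal 10⁻⁹ distance discount on anchor-co-clustered
pairs). The anchor defaults to the envirotype partition, which the
consensus of the motivating network tracks most closely. Labels of the
proposal are aligned to the anchor's by greatest overlap, and agreement
of every input with the proposal is reported as an adjusted Rand index.

## The synthetic-data module

The generators are first-class, tested code — they define the conditions
under which every downstream claim is verified.

* **Sites** (`gen_sites()`): the 19-location network with its four
  climate archetypes sized 4/8/2/5 (semiarid south-plateau, semiarid
  plains, arid north, humid highland).
* **Weather** (`gen_daily_weather()`): each continuous variable follows
  an annual sinusoid (archetype mean and amplitude, peak pre-monsoon)
  plus AR(1) Gaussian noise (ρ = 0.6); rainfall is a two-part model —
  wet-day Bernoulli with a smooth monsoon bump peaking near day 200, and
  gamma amounts. Physical clamps: RH ∈ [0, 100], SW ≥ 0, rain ≥ 0, and
  Tmax ≥ Tmin enforced by swapping. Archetype parameters are set so that
  June–October window means separate archetypes well beyond
  within-archetype noise; a single annual sinusoid suffices because the
  pipeline consumes only crop-cycle window means. What the generator does
  **not** emulate: spatial correlation between sites, multi-day storm
  persistence beyond AR(1), trends or ENSO-scale interannual structure,
  and observational artefacts of satellite-derived weather. Passing
  recovery tests therefore demonstrates correctness of the machinery
  under clean separation, not clustering performance on real weather.
* **Trials** (`gen_trial_yields()`): balanced G × E × rep tables from
  centered normal effects. Default variance components
  (`var_E = 2.2e5`, `var_GE = 1.2e5`, `var_G = 2.8e4`,
  `var_eps = 2.4e4` (kg/ha)²) mirror the variance shares typical of
  rain-fed soybean MET networks (environment ≈ 55 %, GEI ≈ 30 %,
  genotype ≈ 7 % of total SS). `empirical = TRUE` rescales each drawn
  effect vector to its exact target sample variance (the
  `MASS::mvrnorm(empirical = TRUE)` idea), which makes realized variance
  shares controllable at small design sizes;
  `components_for_shares()` inverts the expected SS for that mode.

### Planting a which-won-where truth

A subtlety worth recording: a per-ME winner bonus added as a constant
block to the GE matrix creates a rank-4 pattern for four MEs, and a
rank-2 biplot *cannot* separate four orthogonal block directions — two of
the four MEs project near the origin even in the noise-free limit. The
planted truth must live in the plane the biplot retains. The generator
therefore plants a rank-2 GE structure: each ME occupies a direction at
an equally spaced angle in a latent 2-D GE plane, its environments sit on
that direction with small angular jitter (σ = 0.08 rad), the designated
winner of ME *m* points exactly along its ME's direction, and rival
genotypes get random directions at half length. The winner then leads its
ME by about `winner_bonus` kg/ha (1500 by default in planted runs —
roughly the span of environment main effects). Under these conditions
both tracks recover the planted four-ME partition exactly (ARI = 1)
across 20 generator seeds.

## Numerical choices and degenerate inputs

* Kernel trace and PSD are asserted (minimum eigenvalue ≥ −10⁻⁸); an
  all-zero W raises a degenerate-kernel error.
* `which_won_where()` requires a genuinely 2-D genotype cloud: rank-1
  fits (collinear scores) raise a degenerate-hull error, detected from
  the singular-value ratio and the hull area.
* A zero average-environment axis (perfectly balanced antipodal
  environments) is an error, not a silent NaN.
* Zero-variance covariable columns are dropped from W with a warning;
  constant yield tables yield zero SS and `NA` F ratios, and
  `percent_tss()` refuses a zero total SS.
* UPGMA merge ties are made deterministic by pre-sorting sites by code.

## Problem sizes used in the tests

The packaged checks run the full 19-site × 20-year envirotyping design
(W is 19 × 1520) once, and use 1–3 year weather runs and 20-genotype
trials for the 20-seed stability loops — sizes chosen so the whole suite
exercises every study-scale identity while remaining quick to run
anywhere. The moment-recovery check uses a 50 × 50 × 3 design where
ANOVA-based component estimates are expected within 15 % of the
generating values.

## Limitations

* The phenotypic track analyzes environments; genotype stability,
  ideal-genotype and AMMI views are out of scope.
* Delineation only: the enviromic kernel is not wired into genomic
  prediction.
* Unbalanced trials are rejected, not modeled.
* Real-data MEs depend on real weather and yields; the package
  demonstrates recoverability under controlled synthetic conditions and
  provides drop-in CSV interfaces (`validate_inputs()`) for real inputs.

## A worked run

```{r, eval = FALSE}
out <- run_pipeline(run_config(out_dir = "megaenv-run", seed = 1,
                               n_years = 20))
out$consensus$proposed       # consensus mega-environments
percent_tss(out$anova[[1]])  # variance partition of the first trial year
```
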