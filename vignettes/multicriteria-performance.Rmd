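---
title: "Multi-criteria performance analysis of rice-based cropping systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-criteria performance analysis of rice-based cropping systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(croppsi)
library(dplyr)
```

## The problem

Smallholder farmers in the coastal polder zone of south-central Bangladesh
grow one rainfed monsoon (kharif-2) *aman* rice crop on essentially every
farm, and may add a second crop in the dry winter (rabi) season: mungbean,
lathyrus, groundnut, chili, or irrigated *boro* rice. Intensifying or
diversifying the baseline fallow–fallow–aman (FFA) system raises food
production but changes input use, costs, energy flows and fertilizer-derived
emissions. Whether a given rotation is "better" therefore depends on several
criteria at once. `croppsi` implements that multi-criteria assessment as a
reusable pipeline: per-household indicators, within-household synergy /
trade-off analysis, a factor-analytic composite index, top-performer
benchmarking, and the supporting ANOVA machinery — driven either by a survey
CSV or by a bundled synthetic-survey generator so every stage is testable
without access to the original data.

Households are analysed separately **within** and **outside** polders
(embanked land units with dykes and sluice gates), because the two strata
face different flooding and salinity regimes and support different crop
choices.

## Indicators

All indicators are computed per household × cropping system over a full
annual cycle (rabi, kharif-1, kharif-2), per hectare. For a household with
rice price $P_r$ (its own aman selling price, BDT/t):

* **Rice equivalent yield** $\mathrm{REY} = \sum_x Y_x \, P_x / P_r$
  (t/ha/yr), where for rice crops $Y_x$ is grain yield plus straw converted
  to grain-equivalent mass by the straw/grain price ratio. Using the
  household's own $P_r$ keeps the conversion consistent with what that
  household actually faces.
* **Economics**: gross returns $\sum Y_x \cdot \text{price}$ (straw value
  included for rice), cost of cultivation = inputs + labor + land
  preparation + irrigation, net returns = gross − cost. Stored in BDT; a
  USD view is derived at the configured exchange rate (default 77.87
  BDT/USD) and never stored twice.
* **Agronomic energy input (AEI)**, GJ/ha/yr: embedded energy of N, P2O5,
  K2O, pesticide a.i. and diesel, plus labor person-hours × 1.96 MJ/h.
* **Total energy production (TEP)**, GJ/ha/yr: grain yields only, converted
  at 14.7 MJ/kg for rice and per-crop factors for non-rice crops. Straw
  enters REY and gross returns but **not** TEP — an intentional asymmetry
  of the accounting scheme that the package preserves.
* **Net energy yield** NEY = TEP − AEI (may be negative), and
  **energy efficiency** = NEY/AEI, so TEP/AEI = efficiency + 1 holds as an
  exact identity and is enforced by tests.
* **Partial N / K productivity** = TEP divided by total system N or K2O
  (summed over all crops of the annual system; per-crop variants can be
  derived from the records but the system level is the default unit of
  analysis).
* **Benefit–cost ratio** = gross returns / total cost.
* **Partial GHG footprint**, kg CO2e per GJ produced: embedded emissions of
  input production and use plus fertilizer N2O, divided by TEP. Soil
  methane from flooded fields is deliberately out of scope (the footprint
  is *partial*); only the boro system grows a second flooded rice crop, so
  relative comparisons among the other systems are unaffected by this
  exclusion.
* **Hired labor energy productivity** = TEP per hired person-day. Note the
  deliberate unit split: total person-*hours* enter the energy account,
  hired person-*days* the labor-productivity account.

Fertilizer N2O follows the IPCC Tier-1 pathway: direct emission
(EF1 = 0.01), indirect emission of re-deposited volatilized N
(FracGASF = 0.10 × EF4 = 0.010) and of leached N
(FracLEACH = 0.30 × EF5 = 0.0075); N2O-N × 44/28 × GWP. The GWP default is
265 (AR5, 100-yr, no feedbacks) and is configurable like every other
factor.

**Zero denominators.** An indicator with a zero denominator (e.g. partial
N productivity on an unfertilized system) is *masked* (NA) — never 0 and
never infinite — and masked rows are excluded listwise per indicator, not
per household, so one undefined ratio does not discard an observation's
other indicators.

## The coefficient table

Energy and emission factors are not part of the survey; they are a
configuration input (`load_coefficients()`, YAML) with a fully annotated
default shipped in `inst/extdata/coefficients.yaml` (N 60.6 MJ/kg, P2O5
11.1, K2O 6.7, diesel 47.8 MJ/L, labor 1.96 MJ/h, rice grain 14.7 MJ/kg,
and so on). **Every result is conditional on this table.** Two per-crop
choices deserve mention because the produce is not a dry grain: groundnut
is valued at 12.5 MJ/kg (fresh in-shell pods) and chili at 5.0 MJ/kg (a
partially dried marketable basis). Users with locally measured factors
should override the defaults; the pipeline records a hash of the table in
every report bundle.

The reader also accepts fertilizer *product* columns (urea/TSP/MoP) with
the standard nutrient fractions 0.46/0.46/0.60, and a flag records whether
pesticide is active ingredient (default) or product mass.

## Trade-off analysis

For every double-cropped system and indicator, the relative change against
the *same household's* FFA baseline is
$(\text{system} - \text{baseline}) \times 100 / \text{baseline}$.
Mean changes per stratum × system × indicator carry t-based 95% CIs and a
synergy/trade-off label from an explicit desirability table (higher is
better for everything except the GHG footprint). Because the mean of
household-level relative changes is not the relative change of group means,
the summary reports both, clearly labelled.

## The multi-criteria performance index

Seven indicators enter the index: REY, partial N and K productivity,
energy efficiency, benefit–cost ratio, GHG footprint and hired-labor
energy productivity. TEP is excluded because most efficiency indicators
already carry it in their numerator. Per stratum, the pipeline:

1. drops rows with any masked indicator (listwise, within the model only);
2. standardizes each indicator within the stratum — strata are modelled
   separately throughout, so polder and non-polder households never share
   a scale;
3. checks sampling adequacy with the Kaiser–Meyer–Olkin MSA (anti-image
   partial correlations from the inverse correlation matrix; a singular
   matrix falls back to a pseudo-inverse with a warning);
4. extracts principal components of the correlation matrix (loadings are
   eigenvectors scaled by the root eigenvalue);
5. varimax-rotates when more than one factor is retained (with one factor
   — the default, since a single factor dominates — rotation is the
   identity; the general-k rotation exists for sensitivity analysis and is
   oracle-tested against a planar grid search);
6. takes the first-factor score as the index. Scores use the regression
   (Thurstone) method by default, switchable to Bartlett.

Factor models are sign-indeterminate; the package anchors the sign by
forcing the partial-N-productivity loading positive, under which the GHG
footprint loads negative whenever the expected efficiency structure is
present. A guard refuses to fit on fewer than 30 complete rows
(configurable).

**Numerical choices.** Standardization uses the population (1/n) standard
deviation so that duplicating every observation leaves z-scores — and
therefore loadings *and* scores — exactly unchanged; with this convention
the mean square of the first-factor scores is exactly 1. PCA column signs
are fixed deterministically (largest-magnitude loading positive) before
the domain anchor is applied. Varimax uses Kaiser row normalization, an
SVD-based update, a relative criterion tolerance of 1e-10 and an iteration
cap of 5000; hitting the cap returns the best iterate with a warning. The
rotation matrix is orthonormal to 1e-10 by construction of the SVD step.

## Benchmarking against top performers

Per stratum × system × indicator, the benchmark $P_{fy}$ is the mean of
the best $\lceil 0.2\,n \rceil$ household values (ties at the cutoff are
all included, making the set deterministic); each household's scope is
$(P_{fy} - A_{FY})/A_{FY} \times 100$. "Best" means largest except for the
GHG footprint, where the bottom quintile is used and the output flags the
magnitude as a potential reduction. Cells with fewer than 5 usable values
are skipped with a diagnostic. Benchmarks are computed within stratum ×
system — pooling strata would compare households facing different
hydrology, which is what stratification exists to avoid.

## Statistical reporting

Group comparisons use fixed-effects one-way ANOVA per indicator and
stratum. LS means equal arithmetic group means in this layout; CIs use the
pooled error mean square with per-group n. Pairwise separation uses the
Tukey–Kramer studentized-range procedure (exact for unequal n), and a
compact letter display is assembled by insert-and-absorb so that sharing a
letter is equivalent to a non-significant pair at alpha = 0.05. The same
household can appear in several system groups; rows are treated as
independent observations, a simplification of the survey's structure that
users should keep in mind when reading p-values.

## The synthetic survey generator

`generate_survey()` emulates the survey's structure: 297 households within
and 204 outside polders, each growing one aman crop (shared across all of
its systems, and defining its rice price $P_r$), and practicing each
double-cropped system independently with the observed marginal prevalences
(92.9% mungbean and 37.7% lathyrus within polders; 79.4% and 51.0%
outside; boro, groundnut and chili are minor). The joint distribution of
system membership is not reported anywhere, so independence across systems
is an assumption, flagged here.

Quantities are drawn from a log-normal distribution (switchable to gamma
or degenerate) with configured mean and CV. Three structural features
mirror real smallholder surveys:

* a shared household multiplier (log-SD 0.12) on yields and prices induces
  within-household correlation across seasons and systems;
* input rates, labor and costs track the record's own yield draw with an
  elasticity of 0.8 (management intensity follows expected production).
  Without this coupling, ratio indicators such as partial N productivity
  inherit the full yield noise and the data behave unlike any real survey:
  within-group CVs become implausibly large and REY correlates strongly
  with the efficiency factor. Draws are mean-corrected so configured means
  are preserved exactly;
* residual CVs default to 0.25 for yields, 0.08 for prices, 0.15 for input
  rates and labor, 0.12 for costs.

Crop parameter means are calibrated so the generated data reproduce the
published group structure of this farming system: group mean REY rising
from ~2.5 t/ha/yr (FFA, within polders) through lathyrus (~4.0), mungbean
(~4.8), groundnut/boro (~6.2) to chili (~7.8), with the boro system worst
on every efficiency indicator and highest on the GHG footprint, and the
baseline best on energy efficiency and N productivity. The calibration
targets are recorded in `default_config()$targets` and the implied means
can be recomputed with `config_rey_targets()`. Absolute levels of the
efficiency indicators depend on the coefficient table and are *not*
calibration targets: with a grain-only energy account at ~14.7 MJ/kg no
coefficient choice can reproduce some published absolute productivity
levels, so orderings — which drive every qualitative conclusion — are the
calibrated quantity.

**What passing tests on synthetic data do and do not show.** They show the
pipeline's arithmetic, masking, model fitting and ordering logic are
correct under a data-generating process with the right structure. They do
not validate the generator's distributional details against the real
survey (no spatial fields, no land-elevation classes, no multi-year
panels, independence of system membership), and they cannot confirm
absolute indicator levels, which are conditional on the coefficient table.

## Problem sizes used in the shipped checks

The test suite exercises the oracle arithmetic on toy households, the
energy identities on 10,000 randomized observations, factor-analysis
oracles on random 7-variable problems, sign-pattern recovery and ordering
reproduction on 100 seeded replicates at 300 households per stratum, and
the ANOVA type-I calibration on 500 equal-mean replicates — sizes chosen
to make Monte-Carlo rates stable to a couple of percentage points.

## Known limitations

* Soil methane, water footprints and machinery-embodied energy beyond
  diesel are out of scope; the GHG footprint is partial by design.
* The ANOVA treats household × system rows as independent.
* The index is descriptive (a variance-dominant contrast), not a welfare
  measure; it omits risk and capital constraints that matter to adoption.
* Report CSVs are plain tables; provenance (package version, seed,
  coefficient hash, missing stages) lives in `run_metadata.json` beside
  them rather than in per-file headers, keeping every CSV round-trippable.
```{r}
sessionInfo()
```
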