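---
title: "Methods: cell-size analysis of coffee yield, fertilization and profitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-size analysis of coffee yield, fertilization and profitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellfarm)
library(dplyr)
```

## The cell-size model

A farm is partitioned into its existing plots, treated as *cells*. Each
cell is represented each season by a single composite value per variable:
one yield figure (Mg ha⁻¹ of processed coffee), one value per soil
attribute (15-attribute panel: pH, P rem, P, K, Ca, Mg, H+Al, CEC, OM, S,
Mn, Fe, Cu, Zn, B), optionally one leaf-nutrient panel. The modelling
assumption is that within-cell variability is averaged away by dense
subsampling, so all analysis operates on the cell-by-season table. No
spatial interpolation is ever performed; cell polygons, when supplied as
GeoJSON, are carried opaquely for choropleth export only.

### Yield measurement

Harvest is recorded as total wet volume per cell. `volume_to_yield()`
multiplies by a calibration factor — the mean dry-mass-to-volume ratio of
the calibration samples (typically ten 2-L samples) — and by a
`processing_factor` in (0, 1] for mass retained through grain processing,
then normalizes by area. The processing factor defaults to 1 because no
universal retention constant exists; growers should set it from their own
processing records. The conversion is linear in volume by construction.

### Biennial bearing

Arabica coffee alternates reproductive (high) and vegetative (low)
seasons. Over a four-season window split into high years with yields
$P_1, P_2$ and low years with $P_3, P_4$,

$$\mathrm{MB} = \frac{P_1 + P_2}{2} - \frac{P_3 + P_4}{2}
\quad (\text{Mg ha}^{-1}).$$

MB is antisymmetric under swapping the pairs, invariant to adding a
constant to all four yields, and scales linearly with the yields; the test
suite checks all three laws on randomized inputs. The statistic is defined
for exactly four seasons — longer records must be windowed by the caller.

Pair classification (`classify_years()`) defaults to `"auto"`: the
calendar-year parity (even vs odd years) with the larger mean yield is the
high pair, which matches the even-high/odd-low phase of the reference
farms. A tie in parity means is an error demanding an explicit pairing —
a silent arbitrary choice would flip the sign of every MB. At cell level,
the farm-level series fixes one pairing for all cells, so phase-inverted
cells appear as negative MB rather than being silently re-paired.

Zero-harvest seasons (skeletonization pruning) enter MB as 0 Mg ha⁻¹, not
as missing: the forgone harvest is a real feature of the low season.

## Fertilizer recommendation

### Export dosing

The dose for the coming season replaces what the reference year's harvest
exported. With the 60-kg bag as the trade unit, a reference yield $y$
(Mg ha⁻¹) is $y \cdot 1000/60$ bags ha⁻¹, and the whole-plant demand per
bag is 0.60 kg P₂O₅ and 5.90 kg K₂O (configurable in
`export_coefficients()`), so

$$d = \frac{1000\,y}{60}\,c_{\text{nutrient}} \quad (\text{kg ha}^{-1}).$$

Data of year $t$ drive the doses of year $t+1$; this convention lives in
`recommend()`, not in the I/O layer.

### Soil-availability fallback

Units with no usable reference harvest get a dose from a lookup table
keyed by the soil test value of the nutrient (P or K, mg dm⁻³) and an
expected-yield class (bags ha⁻¹). The shipped
`default_recommendation_table()` is **reverse-engineered and synthetic**:
its per-hectare doses (P₂O₅ 18 and 25; K₂O 225 and 300 kg ha⁻¹) are those
recoverable from the reference farms' published totals, and the
breakpoints (soil P at 10 and 20 mg dm⁻³, soil K at 120 mg dm⁻³, yield
classes split at 30 bags ha⁻¹) were chosen so that the farms' average
soil values resolve to those doses. It is a working default with the
right structure — doses non-negative, monotone non-increasing in soil
availability within a yield class, classes tiling the positive reals —
not an official regional guideline; production users should supply their
own table in the same format. An uncovered (soil, yield) combination is a
hard error, never a silent zero, because "no dose" and "no rule" must not
be confounded.

The expected yield entering the lookup is the mean of the unit's
*positive* yields up to the reference year: skeletonized seasons reflect
pruning schedules, not yield potential, and including their zeros would
push units into a lower yield class precisely in the years the lookup is
used. A unit with no positive history falls in the lowest class.

### Basis rule and the `yield_threshold`

A unit doses by export iff its reference yield strictly exceeds
`yield_threshold` (default 0 Mg ha⁻¹) and the season is not flagged
zero-harvest; otherwise it uses the lookup. The default threshold treats
only true zero-harvests as non-representative. The reference farms'
published recommendation pattern, however, shows soil-based uniform rows
after reference seasons with low but *nonzero* farm means (0.76 and
0.29 Mg ha⁻¹) — seasons dominated by skeletonized cells, whose farm mean
understates the bearing cells' demand. Raising the threshold to
1 Mg ha⁻¹ reproduces that pattern exactly for all eight farm-year rows,
which is what the acceptance checks do; the parameter documents this
management judgement rather than hard-coding it.

### Uniform vs localized

Under **UM** one dose per nutrient, from the farm-mean reference yield
(or farm-mean soil values when the lookup applies), is applied to every
hectare; under **LM_cell** each cell is dosed from its own values. The UM
farm mean is area-weighted by default and includes zero-harvest cells,
both configurable (`um_weight`, `include_zero_harvest`). One consequence
worth knowing: because export dosing is linear in yield, an area-weighted
UM mean makes UM and LM_cell *farm totals* identical whenever every cell
doses by export — the strategies then differ only in allocation across
cells. Farm totals diverge when any cell needs the lookup, or when the UM
mean is the plain cell mean (`um_weight = "none"`), which aggregates
large and small cells equally.

Comparison follows the convention
$\%\,=\,100\,(\mathrm{LM}-\mathrm{UM})/\mathrm{UM}$ for $\mathrm{UM}>0$;
$100$ when $\mathrm{UM}=0<\mathrm{LM}$ (localized management recommends
where uniform recommends nothing); $0$ when both are zero. Multi-year
summaries are plain arithmetic means of the yearly percentages.

Nitrogen is deliberately excluded: the reference data carry no usable N
panel, and an N module would have had to invent its entire basis.
Lime/gypsum and micronutrient dosing are likewise out of scope.

## Economics

Revenue is bags times the year's price (USD per 60-kg bag); BRL amounts
convert at yearly average rates (`convert_currency()`). Costs come from a
yearly ledger at three nested levels — effective operating, + depreciation
(total operating), + return on capital (total) — with `"total"` as the
default `cost_level`, matching the definition of profitability as income
minus *total* production cost. Allocation is uniform per hectare for
every category by default, because the reference ledgers are farm-level
yearly figures; flagging categories (e.g. harvesting, around a fifth of
effective operating cost) as `harvested_cells_only` or
`proportional_to_yield` is opt-in via `allocation_policy()` and requires
a category breakdown in the ledger. Profit is computed as revenue minus
cost record-wise, so the identity holds exactly; zero-harvest cells earn
zero revenue and pay full maintenance, yielding the expected negative
seasons.

## Screening statistics

`describe_panel()` reports min/mean/max, sample (n−1) standard deviation
and CV = 100·sd/mean per attribute-year. CV is *undefined* — flagged, not
infinite — when the mean is zero, and sd/CV are undefined for singleton
groups. `pearson_matrix()` computes product-moment correlations with
two-sided p-values from the t transform on n−2 degrees of freedom
(delegated to `stats::cor.test`), pairwise-complete over missing values;
pairs with fewer than three complete observations or zero variance are
marked not computable. The default mask is α = 0.05 with no
multiple-testing correction, mirroring the screening (not confirmatory)
role of the matrix; treat flagged correlations as candidates, not
findings.

## The synthetic-farm generator

`simulate_farm()` draws, per cell $c$: area (lognormal), base yield $b_c$
(lognormal, arithmetic-mean/CV parameterization), relative biennial
amplitude $a_c$ (normal, truncated to $[0, 0.95]$), and phase
$\phi_c \in \{+1, -1\}$. Season $t$ yields

$$y_{c,t} = \max\!\big(0,\; b_c\,(1 + s_t\,\phi_c\,a_c) + \varepsilon_{c,t}\big),
\qquad \varepsilon_{c,t} \sim N(0, \sigma^2),$$

with $s_t$ alternating $+1,-1$ from the first study year. In each of a
cell's *own* low seasons it is skeletonized with probability
`zero_harvest_prob` (yield forced to 0, flag set). Soil attributes are
lognormal around configured means (positive support by construction);
costs and prices default to the shipped ledgers. The generator returns
the per-cell parameters as ground truth, with farm-level
$\mathrm{MB}_{\text{true}} = \mathrm{mean}_c(2\,a_c\,b_c\,\phi_c)$.

Default study conditions: 15 cells of ~5.5 ha, four seasons, base yield
mean 1.8 Mg ha⁻¹ (CV 0.35) and amplitude mean 0.5 (CV 0.3) — chosen so
the farm-level mean yield (~1.8 Mg ha⁻¹) and swing (2·0.5·1.8 =
1.8 Mg ha⁻¹) sit in the range of the reference farms — noise
σ = 0.2 Mg ha⁻¹, 10% inverted-phase cells, 20% skeletonization per low
season, and soil means from the shipped farm-1 2018 profile with CV 0.3,
consistent with the 30–100% CVs the cell approach is meant to expose.

What the generator does *not* emulate: spatial autocorrelation between
neighbouring cells (composite sampling erases within-cell structure, and
no between-cell covariance model is attempted), weather-driven yield
trends, price volatility within a year, and soil-yield coupling (soil
panels are drawn independently of yields). Passing recovery tests
therefore demonstrate correctness of the *estimators* under the stated
model, not the field realism of any particular dataset.

`recovery_report()` replicates the generator, re-estimates farm MB, and
checks dose conservation and the profit identity. With noise off, all
errors are exactly zero. The unbiasedness check in the acceptance suite
runs 200 replicates at the default 15 cells and σ = 0.2 with
`zero_harvest_prob = 0` — skeletonization changes the estimand itself
(a zeroed low season raises measured MB above $2ab$), so the recovery
target is only $2ab$ in its absence — and asserts that the 95%
Monte-Carlo interval of the mean error covers zero. The truncation at
zero yield can in principle bias low-season yields upward for cells with
$b_c(1 - a_c)$ within a few σ of zero; at the default conditions this
effect is well inside the Monte-Carlo interval.

## Numerical conventions and degenerate inputs

* All arithmetic at full double precision; 2-decimal rounding is a
  *display* convention of the result tables, never applied to stored
  values. CSV output round-trips exactly.
* Published totals are printed at 2 decimals; recomputed differences are
  compared at 0.011 kg (the published difference column is rounded from
  internal precision and can disagree with the difference of the printed
  totals by one last-digit unit) and recomputed export totals at 0.5%,
  the rounding slack of two-decimal mean yields.
* Lookup class intervals are $[\text{lower}, \text{upper})$;
  `lookup_dose()` validates monotonicity and tiling before use.
* Degenerate inputs fail loudly: fewer/more than four seasons, tied
  parity means, empty calibration sets, zero areas, uncovered lookup
  classes, missing price or ledger years, comma decimal separators.
* Tests and recovery runs use deliberately small problem sizes (farms of
  2–15 cells, up to 1,000 replicate farms for conservation properties,
  200 replicates for the Monte-Carlo check) — large enough for the
  asymptotics they probe while keeping the default suite fast.

## Known limitations

* Per-cell validation against the reference study is property-based: the
  study's per-cell doses, MB values and cost ranges live in an appendix
  that is not machine-readable, so only farm-level figures are reproduced
  numerically.
* The shipped recommendation table is a structural stand-in (see above);
  regional guideline tables must be supplied by the user.
* The published multi-year mean for farm-1 P₂O₅ (18.83%) does not equal
  the mean of that row's yearly percentages (18.33%); the discrepancy is
  documented here and the quantity is not reproduced.
* Exact equality with the published farm-1 lookup row (1491.79 /
  24863.10 kg) is unattainable from the printed dose-times-area values
  (18.0 × 82.88 = 1491.84; 300 × 82.88 = 24864.00); agreement is to
  ~4·10⁻⁵ relative, suggesting the study used a slightly different
  effective area.
* Geometry support is attribute-join only (WGS84 pass-through); no
  reprojection, no shapefiles, no web maps.
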