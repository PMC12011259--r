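---
title: "Measuring forest carbon sinks by the biomass method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring forest carbon sinks by the biomass method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcarbon)
```

## The measurement problem

A voluntary forestry carbon project must demonstrate, year by year, how
much CO~2~ its stands have removed from the atmosphere. Measuring every
stem is impossible, so the standard workflow is plot-based: stratify the
project area into homogeneous carbon layers, place a statistically
sufficient number of monitoring plots, estimate per-tree biomass from
diameter at breast height (DBH) and height, convert biomass to carbon and
carbon changes to CO~2~-equivalents, and subtract project emissions,
leakage and the baseline trajectory. `forestcarbon` implements each of
those stages as composable functions plus a command-line front end.

## Sampling design

With strata $i$ carrying area weights $W_i$ and per-plot carbon-stock
standard deviations $S_i$ (t/hm^2^), a reliability index $t_{VAL}$ and an
absolute error bound $E$ (t/hm^2^), the required plot count is

$$
n \;=\; \frac{N\, t_{VAL}^2 \sum_i W_i S_i^2}
             {N E^2 + t_{VAL}^2 \sum_i W_i S_i^2},
\qquad N = A / A_p ,
$$

where $A$ is the project area and $A_p$ the plot area. When the sampled
fraction is small (below about 5%) the finite-population adjustment
$n_a = n / (1 + n/N)$ refines the count, and in the $N \to \infty$ limit
the simplified form $n = (t_{VAL}/E)^2 \sum_i W_i S_i^2$ applies. Plots
are then spread over strata by Neyman optimal allocation,
$n_i = n\, W_i S_i / \sum_i W_i S_i$.

Three numerical choices are deliberate:

* **$t_{VAL}$ defaults to 1.645**, the two-sided 90% normal quantile,
  matching the conventional "90% accuracy at 90% reliability" precision
  requirement. It is a plain argument, so a Student-$t$ quantile can be
  substituted for small designs.
* **Rounding is conservative**: totals are rounded *up* (never
  under-sample) while the allocation uses largest-remainder rounding so
  that $\sum_i n_i = n$ holds exactly for every input — this conservation
  is property-tested over a thousand random stratifications.
* **The simplified formula is read as $(t_{VAL}/E)^2\sum W_i S_i^2$.**
  Printed renderings of this formula are typographically ambiguous; this
  reading is adopted because it is the exact $N \to \infty$ limit of the
  full formula, and the consistency of the two routes (within one plot as
  $A_p/A \to 0$) is asserted in the test suite. Likewise the trigger for
  the second-iteration adjustment is exposed as an option
  (`design_sampling(fpc = "auto"/"always"/"never")`) rather than
  hard-coded, because published guidance states it inconsistently.

```{r}
st <- stratum_table(c("broadleaf", "conifer"), c(0.6, 0.4), c(20, 30))
cfg <- sampling_config(total_area = 100, plot_area = 0.08, error_bound = 5)
design_sampling(st, cfg)
```

## Inventory ingestion and cleaning

Field tallies arrive as heterogeneous spreadsheet exports. The package
standardizes on UTF-8 CSV (an Excel-to-CSV export step is assumed
upstream); `read_tree_tally()` accepts a column map so file headers can
vary, and enforces the canonical units — DBH in cm, height in m, biomass
in kg, region as an integer code 0–5. Species names are folded through a
synonym table (`normalize_species()`); unknown names are **kept with a
warning**, never dropped, because cleaning decisions must stay auditable.
`splice_tables()` outer-unions heterogeneous tables, conserving rows and
recording provenance. Dual data entry is supported as a cell-level table
diff (`diff_entries()`) rather than an interactive mode.

`clean_records()` applies three rules: stems with no biomass information
are dropped; a single missing organ is imputed from the recorded total;
and stems whose biomass deviates from a reference allometric prediction
by more than a relative tolerance are discarded as recording errors. The
tolerance **defaults to 0.5** (50% of the predicted value): published
cleaning guidance appeals to an unquantified "error range", so the
package states a conservative, configurable value and logs every
decision in a machine-readable `cleaning_report`. Row conservation
(`input = retained + dropped`) is an enforced invariant, and cleaning an
already-clean table is a no-op (idempotence, tested).

## Biomass models

The workhorse is the power-law allometry $M = aD^b$ (optionally
$aD^bH^c$), fitted by least squares in log space — the standard approach
for multiplicative, lognormal residuals. Noiseless power-law data are
recovered exactly; on noisy data the estimate is cross-checked in the
test suite against an independent profile/grid-search minimizer. The
lognormal back-transform correction $\exp(\hat\sigma^2/2)$ is available
(`bias_correct = TRUE`) but off by default so that the plain $aD^b$ form
is what a parameter file specifies.

The alternative estimator is a small feed-forward ("BP") network,
implemented from first principles in R: features are DBH, height, age
and a one-hot region code; one hidden layer of **16 units** (a stated
default — published accounts of such networks rarely name the width);
sigmoid or ReLU activation; full-batch Adam with a fixed epoch budget so
that identical seed and data give **bit-identical** predictions; outputs
clamped at zero. A `binary_crossentropy` variant trains against min-max
scaled targets in (0,1) through a sigmoid output unit; it is provided
for completeness but `mse` is the default. Evaluation metrics
(`evaluate_model()`) are the standard $R^2$, MAE, RMSE, MSE, with
$\mathrm{RMSE}^2 = \mathrm{MSE}$ enforced as an invariant and $R^2$
reported as missing for zero-variance observations.

Belowground biomass is derived from aboveground stocks through a
root–shoot ratio, **default 0.25**, overridable per species from the
parameter file — excavation data are rarely available, and 0.2–0.3 is
the range conventionally reported for the conifer plantations this
toolkit targets.

## Carbon accounting

The pool ledger keys carbon stocks by (stratum, species, age class,
year, pool), with pools restricted by default to tree and shrub
aboveground (AA) and belowground (BB) biomass — the pools a
cost-effective project measures; soil, litter and deadwood change slowly
and are excluded from the default accounting. A pool's stock is

$$ C = B \cdot CF_j \cdot A_{ijk} \quad [\mathrm{t\,C}], $$

with $B$ per-hectare biomass (t d.m./hm^2^), $CF_j$ the species carbon
fraction and $A_{ijk}$ the stand area (hm^2^). Biomass is stored
per-hectare and multiplied by area, the reading consistent with the area
term appearing explicitly in the stock formula. Stock changes convert to
CO~2~e only through the molecular-weight operator $44/12$
(`stock_change_co2e()`), preserving sign: rising stocks are a sink,
falling stocks a source. The yearly project change $\Delta C_{P,t}$
triple-sums AA+BB changes over strata, species and age classes; a pool
cell present in only one of two adjacent years counts as zero stock in
the other, with a warning; duplicate keys are an error.

The net sink identity is

$$ C_{P,t} = \Delta C_{P,t} - GHG_{E,t} - LK_t - \Delta C_{BSL,t}, $$

with GHG emissions the sum of fuel-machinery and fertilizer-induced
CO~2~e (the fertilizer term is accepted as a CO~2~e input; no N~2~O
factor is imposed), leakage defaulting to 0 (the conventional
simplification for afforestation projects), and the baseline zero for
cleared sites (`baseline_cleared()`). When a species has no entry in the
parameter file, $CF_j$ **defaults to 0.5** and the default is logged.
Yearly sinks telescope: summed over years they equal the endpoint stock
change minus summed emissions/leakage/baseline, an identity the suite
asserts to 1e-9.

## Validation statistics

`error_summary()` recomputes, from raw predicted and observed stocks,
per-row absolute errors $|p - o|$ and relative errors $100|p - o|/o$ —
the denominator is the **observation**, a convention verified against
every row of the packaged 17-row Chinese-fir reference table — then
aggregates the arithmetic mean relative error and the absolute-error
range. The packaged table's quoted range endpoint (4.262 t/hm^2^)
disagrees with its own column maximum (4.340 at age 10); the summary
reports the true column maximum, and only internally consistent
quantities are asserted in the acceptance tests.

```{r}
error_summary(read_prediction_table())
```

## What the synthetic generator emulates — and what it does not

`growth_scenario()` fixes monotone piecewise-linear age→DBH and
age→height curves; `chinese_fir_scenario()` anchors them to the packaged
per-age mean table (ages 5–22), keeping fixtures traceable. The
reference heights tie once (12.87 m at ages 18 and 19); that single
anchor is repaired to its neighbours' midpoint (13.07 m) so the curve
stays strictly increasing — every other anchor is exact. Tree-level
variation is lognormal and multiplicative (positivity-preserving): DBH
and height with σ = 0.1 around the curves, biomass $aD^b e^\varepsilon$
with σ = 0.1, defaults $a = 0.1$, $b = 2.4$ — a realistic magnitude for
a plantation conifer (a 15.75 cm stem weighs ≈ 74 kg). Mortality is
Bernoulli at 0.005/yr compounded over stand age, consistent with the
~97% volume-survival ratios typical of the monitored plots. Seeds are
mandatory and the generators restore the caller's RNG stream.

The generator emulates age-indexed growth, species mixes and mortality;
it does **not** emulate spatial autocorrelation, competition, site-index
gradients within a stratum, measurement rounding, or the heavy-tailed
transcription errors real inventories contain. A green round-trip test
therefore establishes that the accounting pipeline is *algebraically*
correct on data with the assumed structure — not that the trained
network would reproduce any published fit statistics on real inventory
data, which are not redistributable and whose evaluation tables are not
desk-reproducible (and are printed identically for the aboveground and
belowground cases, almost certainly a duplication).

## Degenerate inputs and tie-breaks

* All-zero stratum SDs: the sample-size formula yields 0; the package
  returns a configured minimum (default 1 plot) with a warning.
* Allocation ties: largest-remainder with ties broken by stratum order,
  so results are deterministic.
* Zero-variance observations: $R^2$ is `NA`, never `Inf`.
* DBH 0 predicts 0 kg; negative biomass predictions are impossible by
  construction (power law) or clamped (network).
* Empty table splices return an empty table; empty projects have zero
  stock change.

## Known limitations

Single-tree volume equations are out of scope (the plot volume tables
are consumed as given); fire-event CH~4~/N~2~O emission factors are not
modelled (no defensible published factor to encode — the GHG term
accepts CO~2~e inputs instead); and the packaged plot fixtures carry the
published tables' own internal inconsistencies (a text/table volume
conflict for plot 1; a volume subtotal off by 0.01 m^3^ from its column
sum), which are documented rather than silently repaired — tests assert
only the exact count subtotals and internally consistent ratios.
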