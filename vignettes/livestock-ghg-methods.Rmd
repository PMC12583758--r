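---
title: "Accounting and spatial analysis of livestock greenhouse-gas emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting and spatial analysis of livestock greenhouse-gas emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdghg)
```

`herdghg` implements a cradle-to-market account of the greenhouse-gas
emissions of a regional livestock sector, observed as a city-by-year panel,
together with the three spatial-statistical analyses usually run on such an
emission surface: Theil-index inequality decomposition, Tapio decoupling
against economic output, and conventional/spatial Markov chains of emission
types. This vignette is the package's methodological account: the model and
its assumptions, the parameters that matter, the numerical choices, and what
the bundled synthetic generator does and does not emulate.

## The life-cycle emission model

Livestock emissions are decomposed into six stages spanning the supply
chain. For a city and year, with product outputs $Q_T$ (t/yr), per-product
feed-consumption factors $t$ (t feed / t product), grain formulation shares
$q_j$, species inventories $N_i$ (average annual head), and per-head energy
expenditures:

* **Feed-grain cultivation** $EFC = \sum_T Q_T\, t_T \sum_j q_j\, ef_{j1}$
  (t CO2-eq), with $ef_{j1}$ the cultivation factor of grain $j$.
* **Feed-grain transport & processing** $EFT$: same form with $ef_{j2}$.
* **Enteric fermentation** $EFG = \sum_i N_i\, ef_{i1}$ (kg CH4).
* **Manure management** $EFM = \sum_i N_i\, ef_{i2}$ (kg CH4) and
  $EFS = \sum_i N_i\, ef_{i3}$ (kg N2O).
* **Feeding energy** $EFE$: electricity expenditure / unit price gives kWh
  per head, coal expenditure / unit price gives tonnes of coal; both are
  multiplied by their CO2 emission factors.
* **Product processing** $EFP$: product mass (kg) times an MJ/kg intensity,
  converted to electricity via the 3.60 MJ/kWh heating value, then to CO2.

The total puts the non-CO2 gases on the CO2 scale with global-warming
potentials:

$$E_{total} = EFC + EFT + (EFG + EFM)\,\frac{GWP_{CH_4}}{1000}
  + EFS\,\frac{GWP_{N_2O}}{1000} + EFE + EFP .$$

Two unit bridges are applied explicitly and nowhere else: kWh are divided
by 1000 before the electricity factor (printed in t CO2 per MWh), and gas
masses in kg are divided by 1000 before GWP weighting (so the total is in
t CO2-eq). The factor tables are stored in their source units and never
converted inside the registry (`default_factors()`); the accounting
functions own every conversion.

Roughage is excluded from the feed stage (its upstream emissions are
treated as negligible, as is conventional for by-product feeds); only
concentrate grains enter $EFC$/$EFT$. Poultry carry an exact-zero enteric
factor — monogastric birds have no rumen fermentation worth counting, and
an explicit zero keeps the species total well-defined. Soybean ships with a
transport/processing factor but no cultivation factor; rather than guess
one, the cultivation stage skips soybean with a one-time warning, and a
user override (`load_factors()`) can supply a value, at which point soybean
re-enters the sum.

Two GWP sets are built in: the 100-year horizon (CH4 27, N2O 273) used in
long-term climate policy, and the 20-year horizon (CH4 81.2, N2O 273) that
weights short-lived gases more heavily. Since only the CH4 weight differs,
$E_{total}$ under GWP20 dominates GWP100 whenever any CH4 is emitted — a
property the test suite checks on random panels.

## Rates, correlations, imputation

The "average annual rate of change" of a series is geometric:
$(x_{y_1}/x_{y_0})^{1/(y_1-y_0)} - 1$. The geometric form was chosen over
the arithmetic mean of annual changes because it is the compounding-
consistent definition: it depends only on the endpoints, is invariant to
rescaling, and composes across adjacent periods.

Stage-total association is plain Pearson correlation of the provincial
annual series, with two-sided p-values from the $t$ distribution on $n-2$
degrees of freedom (`stats::cor.test`). A zero-variance series is reported
as undefined rather than raising an error, because a stage can legitimately
be constant (e.g. constant per-head costs and inventories).

Missing panel cells are filled per (city, series) with the inverse-
distance-in-years weighted average of the two nearest observed values —
i.e. linear interpolation in the year axis — with nearest-value extension
at the boundaries. The weighting is the natural reading of "weighted
average" filling for a time series with gaps; it is idempotent, never
extrapolates beyond the observed range, and every filled cell is logged in
the `"imputed"` attribute.

## Theil decomposition

City inequality in a positive variable $E_i$ is measured by the Theil T
index $T = \frac{1}{n}\sum_i \frac{E_i}{\mu}\ln\frac{E_i}{\mu}$. Among the
generalized-entropy family this is the unique member (up to affine
transformation) that decomposes additively by groups with *value-share*
weights $s_g = n_g\mu_g/(n\mu)$:

$$T = \underbrace{\sum_g s_g T_g}_{\text{within}}
    + \underbrace{\sum_g s_g \ln(\mu_g/\mu)}_{\text{between}} .$$

The package adopts exactly this decomposition, and the identity
within + between = total is enforced to $10^{-12}$ in a 1000-instance
property test. Contribution percentages are component/total × 100; with a
zero total (perfect equality) they are reported as `NA` rather than 0/0.
Note the index is bounded by $\ln n$, not 1; nothing in the package relies
on a unit upper bound. For the economic-inequality series, total (not
per-capita) output value is used, since the panel carries no population.

## Tapio decoupling

For consecutive years the elasticity is
$E = \frac{\Delta C/C_0}{\Delta G/G_0}$. The eight states are a function of
the sign of $\Delta G$ and the band of $E$: with growth,
$E<0$ strong decoupling, $0 \le E < 0.8$ weak decoupling,
$0.8 \le E \le 1.2$ expansive coupling, $E>1.2$ expansive negative
decoupling; with contraction, the mirrored four (strong negative / weak
negative / recessive coupling / recessive decoupling). Choices worth
stating:

* The band boundaries 0.8 and 1.2 belong to the *coupling* band, matching
  the conventional closed-interval statement of the criteria.
* $\Delta G = 0$ yields an explicit `undefined` state, never an exception,
  so a flat economy does not abort a batch run.
* `classify_decoupling()` trusts a supplied elasticity over the ratio of
  the two relative changes. Published tables print rounded deltas next to
  an elasticity computed from unrounded data; recomputing the ratio from
  the rounded deltas can cross a band boundary the original value did not.
* $\Delta C = 0$ with growth classifies as weak decoupling ($E = 0$ lies in
  $[0, 0.8)$).

An exhaustive enumeration test sweeps both signs of $\Delta G$ against a
dense elasticity grid including the boundaries and checks the classifier is
a total function onto exactly four states per sign.

## Markov analysis of emission types

City-year emission values are pooled across the whole panel and cut at the
empirical quantiles $j/K$ (default $K = 4$: low, medium-low, medium-high,
high). Bins are lower-closed and upper-open with the top bin closed, so a
value sitting exactly on a cut belongs to the upper bin; the classification
is rank-based and therefore invariant to monotone transformations. The cut
points are recomputed per run and written to `type_thresholds.csv` so a
report is reproducible from its artifacts. Pooled (rather than per-year)
thresholds are used so that a type means the same emission level in every
year and transitions reflect real change, not re-ranking.

Transition probabilities are maximum-likelihood row frequencies
$\hat p_{ij} = n_{ij}/n_i$ over all cities and year pairs. Rows never
visited are reported as all zeros and flagged — matching how published
spatial matrices print unvisited strata rows — rather than dropped.

The spatial variant computes each city's *spatial lag*: the unweighted mean
of its neighbours' emission values under binary contiguity weights
(row-standardised), binned with the same pooled thresholds so neighbourhood
types live on the same scale. Each transition is assigned to the stratum
given by the city's lag class in the *origin* year (the standard
spatial-Markov convention), and a separate matrix is estimated per stratum.
Stratum counts sum to the conventional counts exactly — an identity the
tests enforce on every instance. The lag is computed on continuous values
and then binned, not as the mode of neighbour types, because value
averaging is the standard spatial-lag construction and keeps the strata
labels on the I..K scale.

Adjacency is supplied as an explicit symmetric edge list (no shapefile
machinery); the generator emits a ring by default and a rook-contiguity
lattice as an alternative.

## The synthetic generator

`generate_panel()` emulates the statistical structure the analyses assume:
18 cities in 5 regions over 2001–2021; city base inventories lognormal
around species medians (default scatter `city_sdlog = 0.5`), scaled by a
region multiplier with one dominant region (Southern, 2× the reference) so
regional concentration and a meaningful between-region Theil component are
present; geometric inventory decline (default −1.2 %/yr) with mean-one
multiplicative lognormal noise (`noise_cv = 0.1`); product outputs exactly
proportional to the source-species inventory; constant per-head energy
costs; and output value growing geometrically (mean 9 %/yr, sd 4) with
negative growth forced in the recession years 2006, 2009, 2014, 2015, which
produces the mix of decoupling states (including the negative-decoupling
ones) the classifier must handle.

Growth is geometric, $(1+\text{trend})^{\,\text{year}-\text{start}}$, not
exponential $e^{\text{trend}\cdot t}$, so that at zero noise the accounted
provincial series recovers the configured trend *exactly* through the
geometric annualized-rate definition — the property the parameter-recovery
test asserts to $10^{-12}$.

What the generator does **not** emulate: real spatial autocorrelation
(cities are independent given their region, so the spatial-Markov strata
should differ only by sampling noise — which is exactly what makes it a
null oracle for the stratified estimator), epidemic shocks to specific
species, year-varying emission factors, and any calibration to real
provincial totals. Passing tests therefore demonstrate correctness of the
estimators and accounting identities, not agreement with any particular
real series; published endpoint totals, decoupling triples and transition
matrices are used directly as fixture inputs where exact numerical checks
are possible.

`generate_typed_sequences()` provides the estimator-recovery oracle: n
independent chains from a known row-stochastic matrix. At n_units = 100 and
n_years = 300 the MLE recovers a diagonally dominant 4×4 generator to a
maximum row L1 error below 0.05; stratum-equality checks use rows with at
least 1000 transitions, where the multinomial L1 sampling error sits well
below the 0.1 comparison band.

## Problem sizes and determinism

The default study shape (18 × 21 panel; 360 annual transitions) runs in
well under a second; the simulation-based estimator checks use up to
200 units × 200 years (≈40k transitions) and complete in seconds. All
randomness flows from explicit integer seeds passed to the generator
functions; the analysis stages themselves are deterministic, so a report
re-run from the same panel is byte-identical (checked in the test suite).

## Limitations

* The accounting is linear tier-1 style: constant per-head and per-tonne
  factors, no herd structure, diet, or manure-system detail.
* One processing intensity per product; product indices in the feed and
  processing stages are assumed to refer to the same annual output.
* No sequestration or land-use terms; roughage is out of scope.
* The Theil economic series uses total output value; per-capita variants
  would need a population series the panel does not carry.
* Spatial weights are binary contiguity only; distance or flow weights are
  not implemented.
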