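---
title: "Measuring equity and efficiency of provincial primary-care resources"
author: "equidea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring equity and efficiency of provincial primary-care resources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equidea)
```

## The measurement problem

Health planners ask two distinct questions about how primary health care
(PHC) resources — institutions, beds and health workers — are spread over
provinces. The *equity* question asks whether each province holds a share of
resources commensurate with its population (demographic dimension) or its
land area (geographic dimension). The *efficiency* question asks whether a
province's PHC sector converts its resource stocks into services — average
visits per person and the annual hospitalization rate — as well as the best
performers do, and how that ability evolves over time.

`equidea` implements the standard toolkit for both questions on a
province-by-year panel (a `resource_panel`): Lorenz curves and weighted Gini
coefficients, the Theil index with an exact within/between-region
decomposition, the health resource density index (HRDI), input-oriented
radial DEA (CCR and BCC envelopment models), and the adjacent-period
Malmquist productivity index with its full decomposition.

## Equity measures

**Lorenz/Gini.** Provinces are sorted ascending by resource per unit of the
chosen dimension (per capita or per km²); ties are broken by province name
so the curve is reproducible — the trapezoid formula presumes *a* sort
order but none is canonical. With cumulative weight shares $X_i$ and
resource shares $Y_i$ (both starting at 0),

$$G = 1 - \sum_i (Y_{i+1} + Y_i)(X_{i+1} - X_i).$$

This trapezoid value equals the population-weighted mean-absolute-difference
form $\sum_i \sum_j p_i p_j |r_i - r_j| / (2\bar r)$, which the test suite
verifies on hundreds of random panels — the double sum is the independent
oracle, the trapezoid is the implementation. Bands follow the conventional
five-way scheme; the interval edges are taken left-closed
($[0.2, 0.3)$ …) because the verbal convention ("0.2–0.3") does not decide
the boundaries.

**Theil.** With population shares $P_i$ and resource shares $Y_i$,
$T = \sum_i P_i \ln(P_i/Y_i)$. For any partition into regions $g$,

$$T = \underbrace{\sum_g P_g T_g}_{\text{within}} +
      \underbrace{\sum_g P_g \ln(P_g/Y_g)}_{\text{between}},$$

where $T_g$ is the Theil index of within-group shares. Natural logarithms
are used throughout: they are the only base under which the decomposition
identity is exact, and the identity (checked to $10^{-10}$ on arbitrary
partitions, including the one-group and singleton partitions) is the main
correctness guarantee. Provinces holding none of a resource are an *error*,
not silently dropped — dropping them would change everyone's population
shares invisibly. The weighting dimension is a parameter: the conventional
demographic index weights by population, but an area-weighted variant is
one argument away, since published tables do not always state the dimension.

**HRDI.** The geometric mean of the per-1000-persons and per-km² densities,
$\sqrt{d_{pop} \cdot d_{area}}$ — a single number balancing the two
dimensions. It is homogeneous of degree 1 in the resource and satisfies
`hrdi^2 = per_capita * per_area` to machine precision.

## Efficiency measures

**Envelopment DEA.** Each province-year is a decision-making unit (DMU)
with inputs $x \in \mathbb{R}^3_{>0}$ (institutions, beds, health workers)
and outputs $y \in \mathbb{R}^2_{\ge 0}$ (average visits, hospitalization
rate in percent, used directly as a level). The input-oriented envelopment
program for DMU 0 is

$$\min_{\theta, \lambda}\ \theta \quad \text{s.t.}\quad
X^\top \lambda \le \theta x_0,\quad Y^\top \lambda \ge y_0,\quad
\lambda \ge 0,\ (\textstyle\sum_j \lambda_j = 1 \text{ under VRS}).$$

The CCR (constant-returns) score is overall technical efficiency TE, the
BCC (variable-returns) score is pure technical efficiency PTE, and scale
efficiency is SE = TE/PTE ≤ 1. An input orientation fits a sector with
administratively set service obligations and little demand elasticity:
managers control inputs, not demand.

Numerical choices:

* Columns are rescaled to mean 1 before solving (radial scores are
  units-invariant — itself a tested property — and the raw data span five
  orders of magnitude, which would strain the LP otherwise).
* The LPs are solved by a small dense two-phase primal simplex with Bland's
  rule (`lp_solve()`), which terminates on the heavily degenerate programs
  DEA produces; it is verified against `pracma::linprog` on random programs
  and against direct convex-hull enumeration on all small one-input/
  one-output instances.
* A second phase maximises the slack sum at fixed $\theta^*$, the standard
  two-phase treatment: the radial score is never sacrificed to slacks.
  Projection targets are $\theta^* x - s^-$ and $y + s^+$; the adjustment
  table reports input deltas as negative numbers and output deltas as
  non-negative slacks. Re-solving with a DMU replaced by its target yields
  $\theta = 1$ with zero slacks (tested).
* Returns-to-scale classes come from $\sum_j \lambda_j$ in the CRS program.
  Because alternate optima are common, the implementation solves
  $\max \sum \lambda$ and $\min \sum \lambda$ at the optimal $\theta$ and
  declares constant returns iff 1 lies in that interval — deterministic
  under degeneracy.
* Scores within $10^{-6}$ of 1 are reported as exactly 1; slacks below
  $10^{-6}$ (on rescaled data) as 0.
* Fewer than $3(m+s)$ DMUs triggers a warning, not an error: 31 provinces
  against the rule's minimum of 15 is comfortable, but small fixtures are
  legitimate test inputs.

**Malmquist.** For adjacent years $t, t+1$, with $D_t(s)$ the CRS radial
score of the period-$s$ observation against the period-$t$ frontier:

$$\mathrm{TEC} = \frac{D_{t+1}(t+1)}{D_t(t)}, \qquad
\mathrm{TC} = \left[\frac{D_t(t+1)}{D_{t+1}(t+1)}\cdot
\frac{D_t(t)}{D_{t+1}(t)}\right]^{1/2}, \qquad
\mathrm{TFPC} = \mathrm{TEC}\times\mathrm{TC},$$

the adjacent-period geometric-mean construction — the only one under which
the stated identities hold exactly and the one implemented by the classic
DEAP software. PTEC is the ratio of the two *within-period* VRS scores and
SEC = TEC/PTEC; consequently no cross-period VRS program is ever needed for
the decomposition, sidestepping the well-known infeasibility of
cross-period VRS evaluations (`cross_period_distance()` still exposes VRS
evaluation directly and returns `NA` with a warning when infeasible).
Summary means are geometric everywhere — over DMUs for annual rows, over
period pairs for province rows, and over annual means for the grand mean
(with a balanced panel the grand mean equals the geometric mean over all
cells, which is asserted in tests). Aggregating published annual values
(1.018, 0.971, 0.973, 1.014) geometrically reproduces the published mean
0.994 where an arithmetic mean does not — that check fixed the design.
Frequency tables count indices above/at/below 1, with "at 1" meaning within
$10^{-6}$, matching how published tables count DMUs printed as 1.000.

## The synthetic panel generator

Province-level yearbook micro-data are not redistributable, so
`simulate_panel()` generates panels that emulate their structure and — more
importantly — carry a *known ground truth* for every downstream stage.

Defaults encode the study conditions: 31 provinces split 11/8/12 into
east/central/west, five years from 2012, log-normal populations and areas
with region-specific locations, and per-capita resource rates whose
regional means are the observed 2012–2016 regional averages
(institutions 0.588/0.690/0.786 per 1000 persons for east/central/west,
beds 0.804/1.114/1.218, health workers 2.553/2.616/2.680). The rate
dispersions (`rate_sdlog` = 0.34/0.32/0.13) are chosen so the implied
demographic Ginis sit near the observed 0.19/0.18/0.07; annual drift
(0.999/1.016/1.012 on rates, 1.005 on population) reproduces the observed
compound growth of totals (≈0.4 %, 2.2 %, 1.7 % per year). Eastern
provinces are drawn more populous on smaller areas, so per-km² densities
order east > central > west in expectation, as observed.

The production side is a Cobb–Douglas frontier
$g(x) = \prod_k (x_k / c_k)^{a_k}$ with default exponents
$(0.32, 0.16, 0.32)$ summing to 0.8 — decreasing returns, mirroring the
observed predominance of decreasing-returns provinces. True efficiency $u$
is drawn per province-year from a Beta(2, 2.5) (mean ≈ 0.44, the observed
TE range), a fixed quantile-spread set of provinces is forced to $u = 1$
every year (default 5, the observed count of efficient provinces), and
observed inputs are $x = x^*/u$ where $x^* $ is the efficient bundle — so
$u$ *is* the input-radial distance to the truth, by construction. Outputs
sit exactly on the frontier at $x^*$: visits $O_1 = A\,g(x^*)$ and the
hospitalization rate squashed into (0, 7 %) by a logistic in $\log O_1$,
keeping it a bounded percentage. Setting `o2_mode = "proportional"`
together with exponents summing to 1 produces an exactly constant-returns
world in which CCR scores must bound the true $u$ from above DMU-wise and
recover it with small error (MAE ≤ 0.05 at $n = 31$ with 6 frontier DMUs —
both tested); the analytic Gini of a log-normal rate law,
$2\Phi(\sigma/\sqrt2) - 1$, is recovered within ±0.02 at $n = 500$.

What the generator does **not** emulate: spatial autocorrelation and
migration, serially correlated efficiency shocks, measurement error in
outputs (synthetic outputs lie exactly on the frontier), and the real
panel's urban/rural resource allocation dynamics beyond a constant mix with
drifting urban population share. Passing recovery tests therefore show the
estimators are correct *under the model's assumptions*, not that real
yearbook data satisfy those assumptions.

```{r example}
sim <- simulate_panel(simulation_config(seed = 20120))
lorenz_gini(sim$panel, 2016, "beds", "population")
theil_decomp(sim$panel, 2016, "institutions")
head(efficiency_suite(sim$panel, 2016)[, c("dmu", "te", "pte", "se",
                                           "rts_class")])
```

## Problem sizes and reproducibility

All analyses run at the study scale: 31 DMUs, 3 inputs, 2 outputs, 5 years
(≈ 2,200 small LPs for a full pipeline including Malmquist), which
completes in seconds. Recovery studies use $n = 500$ provinces for the
Gini law and $n = 31$ for DEA recovery. `run_pipeline()` stamps every table
with a hash of its configuration and writes a JSON manifest; identical
configurations yield byte-identical outputs, and the generator restores the
session RNG state so simulation is a pure function of its config.

## Known limitations

* DEA scores are not bias-corrected (no bootstrap); finite-sample DEA
  efficiency is biased upward relative to the true frontier, which the
  recovery tests make visible (scores ≥ true $u$).
* The hospitalization-rate output is treated as a given non-negative level;
  no account is taken of case mix or need.
* Population is taken as given (resident vs registered population and
  migration are outside the model).
* Cross-period VRS distances, where requested directly, can be infeasible;
  the decomposition avoids them by design rather than imputing values.
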