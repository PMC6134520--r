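# equidea

Equity and efficiency analysis of provincial primary health care (PHC)
resources — institutions, beds and health workers — from a province-by-year
panel of populations, land areas, resource stocks and service outputs.

The package is written for health-services researchers and planners who need
the standard allocation toolkit in one tested place:

* **Equity** — Lorenz curves and weighted Gini coefficients by demographic
  (per-capita) or geographic (per-km²) dimension, with the conventional
  five-band classification; the Theil index
  `T = Σ Pᵢ ln(Pᵢ/Yᵢ)` with its exact decomposition
  `T = Σ P_g T_g + Σ P_g ln(P_g/Y_g)` into within- and between-region
  components and their contribution rates; and the health resource density
  index, `HRDI = √(density_per_1000 × density_per_km²)`.
* **Efficiency** — input-oriented radial data envelopment analysis:
  the CCR (constant-returns) and BCC (variable-returns) envelopment linear
  programs `min θ s.t. Xᵀλ ≤ θx₀, Yᵀλ ≥ y₀, λ ≥ 0 (Σλ = 1 under VRS)` with
  two-phase slack maximisation, TE = PTE × SE, returns-to-scale
  classification robust to alternate optima, and projection targets
  (how much each inefficient province must shrink inputs / raise outputs).
* **Productivity** — the adjacent-period Malmquist index with its full
  decomposition TFPC = TEC × TC and TEC = PTEC × SEC, geometric-mean
  summaries per year pair and per province, and frequency tables.
* **Ground truth** — a synthetic panel generator (log-normal populations,
  areas and per-capita rates with region-specific means; a Cobb–Douglas
  frontier with known input-radial inefficiency) so every estimator has a
  recovery test against known truth.

The envelopment LPs are solved by a small built-in two-phase simplex with
Bland's rule, verified in the test suite against `pracma::linprog` and
against direct convex-hull enumeration on small instances.

## Worked example

```r
library(equidea)

sim <- simulate_panel(simulation_config(seed = 20120))
panel <- sim$panel   # 31 provinces x 5 years, balanced

lorenz_gini(panel, 2016, "beds", "population")
#> Lorenz/Gini of beds by population, 2016: G = 0.1760 (absolute equality)
lorenz_gini(panel, 2016, "beds", "area")
#> Lorenz/Gini of beds by area, 2016: G = 0.6793 (severe inequality)
```

Allocation by population is near-equitable while allocation by land area is
severely inequitable — the signature pattern of population-based planning
over a territory with very uneven population density.

```r
theil_decomp(panel, 2016, "institutions")
#> Theil index of institutions by population, 2016: T = 0.0733 (within 0.0329, between 0.0404)
#>   contribution rates: within 44.83%, between 55.17%

summarize_efficiency(efficiency_suite(panel, 2016))
#>   year statistic        te       pte        se n_efficient
#> 1 2016      mean 0.5595349 0.6951373 0.8059728           3
#> ...
```

Mean TE ≈ 0.56 with 3 of 31 provinces on the efficient frontier: most
provinces could produce the same services with roughly half the inputs, and
SE < 1 shows part of that is scale, not management. On real national
aggregates the package reproduces published values exactly, e.g. compound
annual growth of institutions `aagr(912620, 926518, 4)` → **0.379 %** and
the national HRDI for institutions in 2016
`hrdi_index(0.6715, 0.0964)` → **0.2544**.

`run_pipeline(list(sim_config = simulation_config(seed = 1), out_dir = "out"))`
runs every stage and writes 13 CSV tables plus a JSON manifest; reruns with
the same config are byte-identical.

## The analysis workflow

Numbered drivers under `analysis/` replay the full study on a synthetic
panel plus the bundled national aggregates, writing tables to
`results/analysis/`:

```sh
Rscript analysis/01_simulate.R      # generate the panel + ground truth
Rscript analysis/02_descriptives.R  # totals, densities, compound growth
Rscript analysis/03_equity.R        # Gini, Theil decomposition, HRDI
Rscript analysis/04_dea.R           # TE/PTE/SE, RTS, adjustments, recovery
Rscript analysis/05_malmquist.R     # MPI decomposition and summaries
```

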