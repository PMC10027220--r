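# pmadjoint

Adjoint source attribution of PM2.5-related premature mortality, as a
reusable, fully verifiable desk-scale analysis system.

## What this is and who it is for

Fine particulate matter (PM2.5) drives a large share of air-pollution
mortality, and policy questions are attribution questions: which country,
sector, species and month of emissions is responsible for the deaths a
region experiences? Adjoint chemical-transport modeling answers this
receptor-side: one reverse sweep computes the sensitivity of a scalar cost
function — the total number of PM2.5-attributable premature deaths *J* over
a receptor region — to **every** emission input at once,

&nbsp;&nbsp;&nbsp;&nbsp;λ<sub>E</sub>[s, m, i] = ∂J / ∂E[s, m, i] (deaths per kg emitted),

after which first-order contributions are the entrywise ledger
λ<sub>E</sub> ⊙ E, summable by species, sector, country or month.

`pmadjoint` is for researchers and students of exposure and health-impact
modeling who want the full attribution machinery — toy chemical-transport
model, discrete adjoint, GBD-style health model with uncertainty bounds,
satellite exposure fusion, boundary-perturbation regional splits,
contribution-ratio maps, emission counterfactuals — in a form where every
claimed identity is testable: the adjoint is the exact transpose of the
discrete forward chain, so gradients verify against finite differences to
~1e-8 and attribution closures hold to machine precision. All inputs come
from a seeded synthetic-world generator that emulates the statistical
structure of real inventories, population rasters, mortality tables and
satellite products; nothing here reproduces real-world death counts.

The core chain, per month m (independent steady states on the coarse grid):

1. transport: 0 = T<sub>m</sub>c − k c + y·E·10⁹/(V·Δt) + b (upwind
   advection + diffusion + deposition + converted emissions + boundary
   inflow), solved sparsely; PM2.5 = sulfate + nitrate + ammonium + OC +
   BC + SOA + dust;
2. exposure: satellite rescaling (ratios clamped to [0.25, 4], frozen for
   perturbed runs) then satellite-pattern downscaling to the fine grid;
3. health: deaths = P · y₀/10⁵ · (RR(C) − 1)/RR(C) per cause, summed over
   receptor cells → J;
4. adjoint: the reverse sweep through 3 → 2 → 1 with transposed operators
   gives λ<sub>E</sub>; contributions, splits and counterfactuals follow.

## Worked example

```r
library(pmadjoint)
res <- run_pipeline(world_config(seed = 1))
print(res)
#> pipeline_result: J = 683690.9 deaths, anthropogenic ledger 394401.6 (57.7%),
#>   extra-regional 193883.8 (28.4%), counterfactual net change -97358.7
print(res$split)
#> regional_split: total 683690.9 = extra-regional 193883.8 (28.4%) +
#>   anthropogenic 394401.6 (57.7%) + residual 95405.5 (14.0%)
res$tables$species[, c("species", "value", "share_pct", "rank")]
#>   species    value share_pct rank
#> 1     NOx 93212.86 23.633997    1
#> 2      OC 82106.87 20.818087    2
#> 3      BC 68258.84 17.306938    3
#> 4     SO2 63196.90 16.023490    4
#> 5    SOAP 52029.09 13.191906    5
#> 6     NH3 35597.04  9.025582    6
```

Reading these numbers: the synthetic 2015 world produces 683,691
PM2.5-attributable deaths among its 599 million inhabitants at a
population-weighted exposure of 14.1 µg m⁻³. The contribution ledger
attributes 57.7% of them to the six domestic anthropogenic species, with
NOx the largest contributor (23.6% of the anthropogenic total); the BC−20
boundary experiment (reduce all boundary inflow 20%, multiply the death
difference by 5) attributes 28.4% to extra-regional inflow; the 14.0%
residual collects natural boundary dust plus the concavity gap of
first-order attribution under the GBD response. The counterfactual — 2005
emissions under fixed 2015 sensitivities — shows the decade's emission
reductions avoiding ~97,000 deaths. Health-assessment bounds (population,
mortality and risk curves all-low / all-high) put J between 44% and 248% of
the mid estimate (`res$bounds`).

The numbered scripts under `analysis/` run the same study step by step —
generation, forward + fusion, adjoint + verification, attribution tables,
regional split and contribution ratios, counterfactual, report — each
printing what it found and writing its tables under `results/`:

```sh
Rscript analysis/01_generate_world.R
Rscript analysis/02_forward_exposure.R
# ... through 07_report.R
```

## Layout

- `R/` — grids and I/O, the synthetic-world generator, forward CTM,
  exposure fusion, health model, adjoint, attribution ledger, regional
  analysis, counterfactual, report/pipeline layers.
- `analysis/` — the numbered narrative drivers.
- `vignettes/adjoint-attribution.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical decisions, limitations.
- `tests/testthat/` — unit, property and acceptance suites with
  brute-force oracles.
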