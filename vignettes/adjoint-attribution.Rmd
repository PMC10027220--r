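---
title: "Adjoint source attribution of PM2.5-related premature mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjoint source attribution of PM2.5-related premature mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmadjoint)
```

## The problem

Ambient fine particulate matter (PM2.5) is the leading environmental risk
factor for premature death. Regulators want to know not only how many deaths
a region's PM2.5 burden causes, but *which emissions* — which country,
sector, chemical species, and month — are responsible, at a resolution fine
enough to see individual cities, power plants and shipping lanes. Forward
chemical-transport simulations answer this one source at a time; an
*adjoint* model answers it for every source at once: a single reverse sweep
computes the gradient of a scalar receptor quantity (here the total number
of PM2.5-attributable premature deaths, the cost function $J$) with respect
to every emission input.

`pmadjoint` implements that full chain as a desk-scale, fully synthetic,
fully verifiable system:

1. a seeded generator for all study inputs (emissions, population, mortality
   baselines, exposure–response curves, satellite-style PM2.5, meteorology,
   boundary inflow);
2. a toy monthly steady-state chemical-transport model (CTM) on a coarse
   grid;
3. satellite-based bias correction and fine-grid downscaling of exposure;
4. a GBD-style health-impact model;
5. the discrete adjoint of the entire chain, giving sensitivities
   $\lambda_E = \partial J / \partial E$ in deaths per kilogram for every
   (species, month, grid cell);
6. the first-order contribution ledger $\lambda_E \odot E$ and everything
   built on it: sectoral/species/country/monthly attribution, a
   boundary-perturbation split into extra-regional, domestic anthropogenic
   and residual deaths, contribution-ratio (exporter/importer) maps, and a
   two-inventory emission counterfactual.

The design goal is *structural* fidelity: the synthetic system reproduces
the qualitative regimes of a continental source-attribution study (mostly
domestic burden, meaningful boundary inflow, winter-peaked residential
contributions, circulatory-disease dominance) while every numerical claim
the package makes — gradients, closures, extrapolations — is checkable to
machine precision or against independent brute-force oracles.

## Grids, fields and the synthetic world

All fields live on cell-centered regular latitude–longitude grids with
half-open cell bounds. The default pair is a 30 × 40 coarse grid spanning
32.75–61.25°N, −15–40°E (cells of roughly 0.95° × 1.375°, a stand-in for a
nested regional simulation grid) refined by a factor 4 to a 120 × 160 fine
grid on which emissions, population and exposure are kept. Relative cell
areas are $\cos(\text{latitude})$, normalized to mean one; true spherical
areas add nothing at this scale. Intensive fields move between grids by
area-weighted averaging (fine → coarse) and by pattern-weighted
disaggregation (coarse → fine) that conserves each parent's area-weighted
mean exactly.

`generate_world()` builds every input from one integer seed. Each component
draws from its own named substream, so changing, say, the emission totals
cannot perturb the population field. The defaults were fixed once, as the
package's emulation of a realistic continental study year, and define the
study conditions of every test and script:

* **Countries.** The westernmost 15% of columns are ocean (exercising the
  "unassigned" path and hosting shipping lanes); the land is tiled by 12
  contiguous country blocks, all receptor-flagged by default.
* **Population.** 598.97 million people: 80% in 25 log-normally weighted
  Gaussian urban clusters, 20% as a uniform rural floor.
* **Emissions.** Annual totals per (species, main sector) of order
  10⁷–10⁸ kg/yr for NOx, NH3, SO2, OC, BC and SOAP (a lumped
  secondary-organic-aerosol precursor treated as an emitted species),
  distributed over 16 detailed sectors nested in the 8 main sectors
  (shipping, aviation, energy, industry, ground transport, waste,
  agricultural, residential). Each detailed sector has a spatial archetype —
  log-normal point sources for energy and industry, population-proportional
  area sources for residential and waste, rasterized inter-city corridors
  for ground transport, ocean lanes for shipping, rectangular cropland
  patches for agriculture — and a seasonal profile (12 weights summing
  to 12): residential peaks in winter (amplitude 0.8), agricultural crops
  and waste burning peak in February–April, aviation mildly in summer. The
  totals were chosen so the base run sits in the intended regime:
  population-weighted exposure near 15 µg m⁻³ and a domestic anthropogenic
  share of deaths between one half and two thirds.
* **The 2005 inventory** is the 2015 inventory rescaled per species by the
  printed decade-scale reductions (NOx −19.3%, SO2 −34.9%, SOAP −26.8%,
  NH3 −1.3%, inverted to recover 2005), with −12% (OC) and −18% (BC) chosen
  as plausible magnitudes where no species value is printed, and sector-level
  adjustments that make aviation (+26.2% cruise), agricultural crops (+5.3%)
  and waste burning (+5.1%) *grow* over the decade, so the counterfactual
  exercises both signs.
* **Health inputs.** Six causes (COPD, IHD, LRI, LC, T2D, stroke).
  Cause-specific baseline mortality rates sum, per country, to a six-cause
  total that rises from ≈295 per 100k/yr at the western edge to ≈1025 at the
  eastern edge (an east–west health gradient; IHD and stroke carry 45% and
  24% of the total, so they dominate attributable deaths as expected for
  this cause set). Relative-risk curves are concave power laws
  $RR = 1 + a\,((C - \text{TMREL})/10)^{0.9}$ tabulated on fixed knots with
  TMREL = 2.4 µg m⁻³, with low/high bounds scaling the excess risk by 0.55
  and 1.65, and population carries −20%/+54% bounds.
* **Satellite.** A fine-scale annual PM2.5 proxy (smoothed emission density
  on a 4 µg m⁻³ floor, scaled to a 12 µg m⁻³ domain mean) times
  multiplicative log-normal noise with mean 1 and CV 0.15.
* **Meteorology and boundary.** Monthly westerly wind (3 ± 1.2 m s⁻¹
  seasonal cycle plus smooth spatial texture), constant eddy diffusivity
  2.5 × 10⁴ m² s⁻¹, a 1000 m mixing height, per-component deposition rates
  of 0.15–0.3 day⁻¹, and per-component boundary inflow concentrations
  (including mineral dust, which has *no* interior source) totalling
  ≈3.9 µg m⁻³.

What the generator deliberately does **not** emulate: real geography and
real inventory magnitudes, vertical structure, day/night and synoptic
variability, aerosol thermodynamics, and inter-month memory. Passing tests
therefore demonstrate the correctness of the attribution *machinery* and
the qualitative regimes, not agreement with any real-world death count.

## The forward model

For each month $m$ and each transported precursor, the model solves the
steady-state balance on the coarse grid:

$$ 0 \;=\; T_m c \;-\; k\,c \;+\; q \;+\; b, $$

where $T_m$ is a finite-volume transport operator (first-order upwind
advection on face-averaged winds plus a 5-point diffusion stencil, assembled
in flux form so interior faces conserve volume-integrated mass exactly;
advective boundaries are open, with inflow faces carrying the boundary
concentration and outflow faces removing mass), $k$ is the component's
first-order deposition rate, $q = y\,E \cdot 10^9 /(V\,\Delta t)$ converts
the month's emission mass to a volumetric source through the species yield
$y$ (NOx → nitrate 0.35, NH3 → ammonium 0.40, SO2 → sulfate 0.55,
SOAP → SOA 0.50, OC and BC primary), and $b$ is the advective boundary
source. Months are independent steady states — the monthly bookkeeping of
sensitivities needs no cross-month adjoint checkpointing, and inter-month
memory is explicitly out of scope. Each system is solved directly as a
sparse linear solve (`Matrix`); the operator is an M-matrix, so
concentrations and sensitivities are automatically nonnegative. A direct
solve rather than pseudo-time substepping keeps the adjoint an *exact*
transpose solve and needs no stability bookkeeping.

PM2.5 is the sum of seven components — sulfate, nitrate, ammonium, OC, BC,
SOA, and boundary-supplied fine dust — and the annual field is the plain
mean of the 12 months.

The single chemical nonlinearity, enabled by `ctm_params(nonlinear = TRUE)`,
is ammonia-limited nitrate formation:

$$ \text{nitrate} = \operatorname{smin}\!\big(N_p,\; y_f \cdot
   \operatorname{softplus}(N_3 - d\,S)\big), $$

with nitrate potential $N_p$ (from NOx), free-ammonia proxy $N_3$ (the
transported NH3 field), sulfate $S$, ammonia demand $d = 1.2$, and smooth
min/rectifier with sharpness β = 1.5 (µg m⁻³)⁻¹ so the model remains
differentiable everywhere — the property the adjoint needs. The smooth
operators bias nitrate low by at most $\ln 2 / \beta \approx 0.46$ µg m⁻³
near the crossover; tests use that bound as the smoothing tolerance.

## Exposure fusion

The modeled coarse monthly PM2.5 is corrected toward the satellite field:
per coarse cell, the ratio of the satellite annual mean (aggregated to the
coarse grid) to the model annual mean, clamped to $[0.25, 4]$, multiplies
all 12 months; multiplicative correction was chosen over additive because a
ratio preserves nonnegativity and the monthly cycle (a `rescale_mode`-style
additive variant would not), and the symmetric clamp bounds the correction
where the toy model is weakest. Corrected coarse months are then downscaled
to the fine grid using the satellite annual field as the spatial pattern —
per parent cell the area-weighted mean is conserved, so downscaling
redistributes rather than invents mass. The fused fine annual mean defines
the exposure entering the health model.

Two consequences matter for interpretation. First, the toy CTM
underpredicts the satellite level by design headroom, so many cells sit at
the upper clamp and the exposure *pattern* is largely satellite-driven;
that is the intended role of the correction, but it means the toy's
absolute concentrations should never be read as predictions. Second, when a
*perturbed* run is evaluated (boundary reduction, emission scaling, finite
differences), the correction ratios are **frozen** at their base-run values:
recomputing them would let the correction silently absorb the perturbation
being measured. The adjoint likewise differentiates through the frozen
ratios.

## The health model and the cost function

Attributable deaths per fine cell $i$ and cause $d$ follow the
population-attributable-fraction form

$$ \Delta M_{i,d} = P_i \cdot \frac{y^0_{c(i),d}}{10^5} \cdot
   \frac{RR_d(C_i) - 1}{RR_d(C_i)}, $$

with piecewise-linear interpolation of $RR_d$ on its knots, $RR = 1$ at or
below the TMREL, and flat extrapolation above the last knot. The cost
function $J$ sums over receptor-flagged cells and the six causes.
Uncertainty bounds evaluate $J$ with population, mortality and RR all at
their low and all at their high bounds (no covariance model — the
reported range *is* the health-assessment uncertainty), and report the
bounds as rounded percentages of the mid estimate.

A second response mode, `response = "linear"`, replaces the PAF term by
$s_d \, C$ with a per-cause slope and zero threshold. This is the *tangent
health model*: $J$ becomes exactly linear in exposure (hence in emissions
and boundary inflow when the chemistry is linear), which is the regime in
which first-order attribution is an identity rather than an approximation.
The package uses it wherever an exactness property is asserted:

* **completeness** — with zero boundary inflow,
  $\sum \lambda_E \odot E = J$ to ≈10⁻¹⁶ relative;
* **boundary extrapolation** — $5\,(J_{\text{base}} - J_{\text{BC-20}})$
  equals the full-removal difference exactly.

Under the GBD response those identities hold only to first order: the PAF
is concave in exposure, so the tangent ledger *understates* the anthropogenic
share and the difference appears as a positive residual (below). One
numerical subtlety is documented rather than hidden: because the GBD curves
are piecewise-linear, $J$ has kinks, and a central finite difference whose
exposure reach straddles a knot measures the kink, not the derivative — the
adjoint is the exact derivative almost everywhere. The exact 10⁻⁶-level
gradient verification therefore runs on the everywhere-differentiable
linear-response system, and the GBD/nonlinear chains are verified at 10⁻³.
Similarly, finite-difference samples are drawn only from entries whose
predicted response exceeds ~10⁻⁸ of $J$; below that, the difference of two
~10⁶-magnitude sums is floating-point noise.

## The adjoint

The adjoint is the discrete (transpose-of-discretization) adjoint of the
exact forward chain, built by composing the transposes of each stage:

1. the health seed $\partial J / \partial C^{\text{ann}}_i$ (analytic PAF
   derivative, restricted to receptor cells);
2. the annual mean: each month receives $1/12$ of the annual adjoint;
3. downscaling: fine adjoints are gathered onto parents with the same
   pattern weights the forward map used;
4. the frozen rescale ratios (a diagonal operator);
5. the PM2.5 sum: every component receives the same seed; in nonlinear mode
   the ammonia-limitation Jacobian (evaluated at the stored monthly
   linearization point — one checkpoint per month, no tape) distributes the
   nitrate seed onto $N_p$, $N_3$ and $S$;
6. transport: $\lambda_c = (kI - T_m)^{-\top} g$, one transpose solve per
   precursor and month;
7. the source scaling, returning $\lambda_E$ in deaths per kilogram.

Because every forward operator is available as an explicit sparse matrix or
a closed-form diagonal/gather, `adjoint_identity_check()` can verify
$\langle A u, w\rangle = \langle u, A^\top w\rangle$ for random $u, w$ for
each building block (observed ≈10⁻¹⁴) and `gradient_check()` verifies the
composed gradient against central finite differences (≈10⁻⁸ at full scale).
Sensitivities are replicated, not pattern-scaled, when moved to the fine
grid: deaths-per-kilogram is an intensive quantity, identical for every
fine child of a coarse cell.

## Attribution, regional split, counterfactual

The **contribution ledger** is the semi-normalized first-order product
$\text{ledger}[s,k,m,i] = \lambda_E[s,m,i]\, E[s,k,m,i]$ — deaths attributed
to each (species, detailed sector, month, fine cell). It is not
renormalized to $J$ (the un-renormalized product is the default reading;
under nonlinearity the ledger may overshoot $J$ by a few percent, which the
pipeline tolerates and reports rather than rescales away). Every marginal —
species, detailed/main sector, country (plus "unassigned"), month, and the
two-way tables — sums to the same total by construction; tests hold the
closure to 10⁻⁹ relative. Monthly share tables normalize each month by that
month's anthropogenic total; seasonal ratios compare DJF to JJA sums.

The **regional split** estimates the extra-regional contribution by the
boundary-perturbation experiment: reduce all boundary inflow by 20% with
frozen correction ratios, multiply the induced death difference by five.
The residual $J - J_{\text{extra}} - J_{\text{anthro}}$ collects natural
boundary components (dust), and the concavity gap of the first-order
ledger; in the default configuration it is ≈14% of $J$, reported on both
the total and the within-domain basis. The admissibility check
$J_{\text{extra}} + J_{\text{anthro}} \le J_{\text{total}}$ uses a 10⁻⁶
relative tolerance for the fully linear tangent system and 5% whenever the
health response or the chemistry is nonlinear.

**Contribution-ratio maps** divide each cell's (or country's) deaths caused
anywhere by the deaths incurred locally — the exporter/importer view. Two
variants: against total incurred deaths, and within-region (extra-regional
deaths removed from the denominator, death-based per cell). Cells with zero
incurred but positive caused carry an infinite sentinel; classification
thresholds are CR > 1 (over-contributing), CR > 3 (strongly so) and
within-region CR < 0.42 (over-burdened), and are scale-invariant.

The **counterfactual** applies the fixed base-year sensitivities to the
inventory difference: $\Delta = \lambda_{2015} \odot (E_{2015} - E_{2005})$,
exactly the difference of the two year ledgers, with population and
mortality held at base-year values so the tables isolate emission-driven
change. Change reports give absolute and relative changes per category,
flag increases, and express each decreasing category's share of the total
avoided deaths.

## Numerical choices and degenerate inputs

* Direct sparse LU solves; no iteration, no tolerance beyond machine
  precision; the steady operator is strictly diagonally dominant for
  $k > 0$.
* Ties in attribution rankings break lexicographically by label.
* Zero-pattern parents in disaggregation fall back to uniform copies with a
  warning; an all-zero satellite makes rescaling the identity with a
  warning; zero-model cells take the satellite annual directly (and a zero
  derivative).
* Months with zero total contribution yield missing monthly shares rather
  than NaN fractions.
* Zero-emission entries in the gradient check use a one-sided absolute
  step.
* Reported percentages round half away from zero at one decimal (integer
  for bound ratios), matching the convention of the printed shares the
  report layer reproduces.
* Gridded text files store doubles as `%.17g`, so write-then-read
  roundtrips are bit-exact.

## Problem sizes

The default study configuration (30 × 40 coarse, 120 × 160 fine, 12 months,
6 species, 16 sectors) was chosen so a full pipeline run — generation,
forward, adjoint, ledger, boundary experiment, counterfactual, report —
completes in well under a minute, and the complete verification suite
(including two 30-sample finite-difference sweeps at full scale) in a few
minutes. Unit tests run on 6 × 8 and 8 × 10 coarse worlds; the
pipeline-level tests raise emission totals on the coarser test grid to keep
it in the same exposure regime as the default configuration.

## Known limitations

* The toy CTM has no vertical dimension, no real meteorology and no real
  chemistry; its fidelity target is the linear/nonlinear *structure* of the
  attribution problem, never agreement with observed concentrations.
* First-order attribution under the concave health response is a lower
  bound on the anthropogenic share; the residual conflates natural
  contributions with the linearization gap.
* The all-low/all-high bound combination ignores covariance between
  population, mortality and risk-curve uncertainty.
* No age stratification: one aggregate curve per cause.
* Country shapes are synthetic blocks; "country-level" results demonstrate
  the aggregation machinery, not geography.
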