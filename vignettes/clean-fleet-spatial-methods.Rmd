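---
title: "Methods: bus-fleet exposure construction and spatial error modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bus-fleet exposure construction and spatial error modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fleetshift)
```

## The problem

A city's bus fleet modernizes unevenly: new hybrid-electric, CNG and
low-sulfur buses are assigned to particular depots, depots serve particular
routes, and so some neighborhoods see a much larger shift toward clean bus
service than others. If bus exhaust matters for local air quality, cells with
a larger clean shift should show systematically different changes in
traffic-related pollutant concentrations (NO, NO~2~, black carbon) between two
study years. `fleetshift` implements the full chain from depot rosters to that
inference, on a regular grid of square analysis cells.

Three design facts shape everything downstream:

1. **Exposure is constructed, not measured.** Per-cell bus VMT comes from
   clipping route polylines to cells and weighting by service frequency;
   the clean share of that VMT comes from depot rosters, apportioned evenly
   across the depots serving each route.
2. **Cells are spatially dependent.** Concentration changes on a 300 m
   lattice are strongly autocorrelated, so ordinary least squares understates
   uncertainty; a simultaneous-autoregressive error model is fitted by
   maximum likelihood instead.
3. **The real inputs are not redistributable.** Roster and traffic data of
   this kind are typically obtained by records request or held under
   proprietary license, so the package ships a synthetic-city generator with
   a known data-generating process (DGP) and validates itself by parameter
   recovery rather than by reproducing any published coefficient.

## Exposure model

For route $r$ with weekday frequency $f_w$ (trips/day) and weekend frequency
$f_e$, the average annual number of buses is $f_w \cdot 261 + f_e \cdot 104$;
the 261/104 calendar is the package default and configurable (a leap-year
262/104 split is accepted). Cell $i$'s total bus VMT in year $t$ is

$$\mathrm{VMT}_{it} = \sum_r L_{ir} \, b_{rt},$$

with $L_{ir}$ the length of route $r$ inside cell $i$ (meters) and $b_{rt}$
the annual bus count. Clean VMT multiplies each term by the route's clean
fraction: the unweighted mean over serving depots of the depot's clean share
of buses. Averaging depots without size weights follows the convention that
bus types are evenly apportioned from each depot serving a route; a
size-weighted variant would need within-route allocation data that rosters do
not carry.

Two classification rules are built in. The *broad* rule counts hybrid, CNG
and ULSD buses plus anything of model year 2007 or later (the vintage at
which substantially stricter emission standards bind); the *narrow* rule
counts hybrid and CNG only, isolating locally driven procurement from
federally driven vintage turnover. Narrow-clean VMT can never exceed
broad-clean VMT, and replacing any non-clean bus by a clean one can never
decrease a clean fraction; both properties are enforced by test.

The policy exposure is the difference in clean proportions,
$\Delta\mathrm{Prop} = C_{i,2}/T_{i,2} - C_{i,1}/T_{i,1} \in [-1, 1]$,
defined only where both years have positive total bus VMT. Cells served in
only one year are treated as unserved: their shift is set to 0 and they are
excluded from the served descriptive groups, because a proportion change is
undefined on an empty denominator.

**Geometry.** Clipping is exact and parametric: each polyline segment is cut
at its crossings of the grid lines and each piece is assigned by the cell
containing its midpoint, so per-route cell lengths sum to the polyline length
to floating-point precision (tested at relative tolerance $10^{-9}$, and
against 0.1 m midpoint sampling for the VMT totals). A segment lying exactly
on a shared edge is assigned to the cell with the lexicographically smaller
(row, col); this affects only measure-zero geometry and never the total.
Coordinates are abstract planar meters — no CRS or geodesy, since only
Euclidean lengths enter the pipeline.

## Spatial error model

The outcome $y$ (per-cell concentration change, in the input's units) follows

$$y = X\beta + u, \qquad u = \lambda W u + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma^2 I),$$

where $W$ is the row-standardized queen-contiguity matrix (cells sharing an
edge or corner are neighbors; rook contiguity is available by option). Queen
contiguity on a raster lattice is the conventional default when no weights
specification is given; the choice is recorded in output metadata.

The log-likelihood is

$$\ell = -\tfrac{n}{2}\log(2\pi\sigma^2) + \log|I - \lambda W|
  - \tfrac{1}{2\sigma^2}\lVert (I - \lambda W)(y - X\beta) \rVert^2 .$$

Because $W = D^{-1}B$ with $B$ symmetric, its spectrum is real and
$\log|I-\lambda W| = \sum_i \log(1-\lambda\omega_i)$; the eigenvalues are
computed once per lattice shape by a dense symmetric eigendecomposition of
$D^{-1/2}BD^{-1/2}$ and cached (practical to a few thousand cells, which
covers the default 2500-cell study grid). For fixed $\lambda$, $\beta$ and
$\sigma^2$ have closed-form GLS/ML solutions on the filtered data
$(I-\lambda W)y$, $(I-\lambda W)X$, so estimation reduces to a 1-D search:
Brent's method on the concentrated likelihood over 99% of the feasible
interval $(1/\omega_{\min},\, 1/\omega_{\max})$, tolerance $10^{-8}$, fully
deterministic. Standard errors for $\beta$ use $\sigma^2 (X_s'X_s)^{-1}$ at
the optimum ($\beta$ is asymptotically information-orthogonal to
$(\lambda,\sigma^2)$ here); the $\lambda$ standard error uses the numerical
curvature of the profile likelihood. Collinear designs are rejected with the
offending columns named; fixing $\lambda = 0$ reproduces OLS exactly and is
exposed for testing.

**Model ladder.** Model 1 regresses the concentration change on the clean
shift alone; Model 2 adds log total traffic VMT and truck-route presence
(the two standard confounders that co-occur with bus service); Model 3 adds
log first-year bus VMT, separating "more buses" from "cleaner buses". The
clean shift enters as a proportion (not a percentage); traffic and bus VMT
are log-transformed as $\log(x+1)$ with $x$ in meters, because unserved cells
contribute exact zeros. The offset and unit are stamped into the analysis
table attributes and the fit log, since the coefficient scale depends on
both. All grid cells enter the regression by default (unserved cells with
zero shift and zero bus VMT); restricting to served cells is a switchable
inclusion rule for the descriptive tables, while regression always runs on
the full lattice so the contiguity structure stays intact.

**Descriptives.** The clean shift is dichotomized at the median of served
cells (ties to the lower group, so equal values never straddle the split),
yielding three groups — no service, at/below median, above median — whose
sizes partition the grid. Group tables report mean and sample (n−1) SD,
proportions as percentages, single-cell groups with blank SDs. VMT is stored
in meters throughout; rendering in km is a formatting decision at output
time.

## The synthetic city

`sim_config()` fixes the study conditions; its defaults are chosen once to
mirror the scale and structure of a large-city clean-bus program evaluation:

| parameter | default | rationale |
|---|---|---|
| grid | 50 × 50 cells of 300 m | large enough for stable SEM estimation, desk-scale runtime |
| depots / routes | 12 depots, 5–9 routes each, 25–50 cells long | calibrated so ~40% of cells have no bus service (realized 0.30–0.45 across seeds) |
| service frequency | 40–240 weekday, 20–160 weekend trips/day | spans quiet to trunk routes; year-2 drift ×0.9–1.1 |
| fleet totals | 5838 → 5730 buses | stable fleet size with slight decline |
| fuel shares | ULSD 65.3→57.7%, hybrid 22.0→29.2%, CNG 10% both years | CNG held constant; conventional diesel takes the remainder |
| post-2007 vintage | 16.9% → 48.7% | federal-standard turnover during the study window |
| depot heterogeneity | Dirichlet concentration 12 | spreads depot clean fractions so the clean shift varies in space; shares re-centered so citywide targets are met within ±3 points |
| truck routes | P = 0.65 served / 0.10 unserved | truck routes co-occur with bus corridors |
| traffic | log-normal, meanlog 22.4/20.6, sdlog 1.0/1.5 (m/yr) | strong right skew; heavier traffic where buses run |
| DGP | β = (−3.0, −0.05, −0.001, −0.03) on (1, ΔProp, log traffic, truck); λ = 0.5; σ = 1 (NO); scaled analogs for NO~2~ and BC | declining concentrations with a small clean-shift benefit and spatially correlated errors |

Routes are lattice walks through cell centers with directional momentum —
not street networks. This preserves the only property the pipeline consumes
(per-cell intersection lengths) and keeps the geometry exactly checkable.
Rosters draw citywide fuel/vintage counts to target and distribute them
across depots with mean-preserving Dirichlet/Beta heterogeneity, because the
policy signal lives in *between-depot* differences; without it the clean
shift would be spatially flat. The bus-stop count of real data is emulated
only as a count of route vertices per cell and labeled a proxy.

Outcome surfaces are generated exactly: $\varepsilon$ is drawn iid normal and
$u$ solved from the sparse system $(I - \lambda W)u = \varepsilon$, so the
noiseless limit ($\sigma = 0$) inverts to machine precision and the
independence limit ($\lambda = 0$) reduces to iid errors — both tested. The
truth record (coefficients and latent $u$) is persisted beside every
simulated bundle.

**What the generator does not emulate.** One route map serves both years
(real networks change slightly; the exposure code accepts per-year schedules
and would accept per-year geometry). Concentration changes are treated as
directly observed — measurement error from the monitoring-and-land-use-
regression surfaces that real studies use is not propagated, because no
error model for it is available; recovery results therefore show estimator
correctness under the stated DGP, not robustness to outcome measurement
error. There is no street network, ridership, deadheading, paratransit or
private bus traffic, and no secondary-chemistry link between NO~x~ and
particulate formation. Passing tests certify the pipeline's arithmetic and
its statistical calibration under these conditions — not substantive
conclusions about any real city.

## Validation design

The test suite works oracle-first:

- the SEM likelihood is checked against a dense brute-force evaluation
  (direct determinant) to $10^{-8}$ on random instances;
- the optimizer is checked against an exhaustive $\lambda$ grid at step
  $10^{-3}$;
- geometry is checked for conservation and against fine midpoint sampling;
- the estimator is checked by 100-replicate parameter recovery on the
  default city (mean $\hat\lambda$ within ±0.05 of 0.5; per-coefficient 95%
  CI coverage required to land in [90%, 98%]), by a null study (zero
  clean-shift effect: the CI covers zero about 95 times in 100), and by a
  power study at a pilot effect size of −5.0 on the clean-shift coefficient,
  chosen from the pilot per-fit standard error (≈1.1–1.3) to give roughly
  97% power, and frozen.

Problem sizes are the package's own choices: 5×5–20×20 lattices for oracle
comparisons, 15×15 cities for geometry and file-pipeline tests, and the
50×50 default city (100 replicates) for recovery, null and power studies.

## Known limitations

- Dense eigendecomposition bounds the lattice at a few thousand cells;
  larger grids would need sparse log-determinant updates (Cholesky per
  $\lambda$), which the current study scale does not require.
- The profiled-$\lambda$ ML estimator carries a small finite-sample bias on
  heavily spatially clustered regressors (a fraction of one sampling SD for
  the clean shift at default conditions); interval coverage is unaffected
  and is what the acceptance checks certify.
- Even apportionment across depots ignores depot size; alternatives require
  data rosters do not contain.
- No spatial-lag or CAR models, no REML, no robust standard errors: the
  estimand is the SEM as specified.
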