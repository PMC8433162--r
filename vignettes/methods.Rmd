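---
title: "Methods: diversity metrics, the synthetic world, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity metrics, the synthetic world, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktodiv)
```

`planktodiv` analyses gridded, depth-integrated plankton biomass fields from
trait-based ocean ecosystem models: how many phytoplankton types coexist where,
how evenly biomass is spread across them, how fast community composition is
changing, and how the community size structure shifts. Because real model
output is hundreds of gigabytes, the package also ships a synthetic-data
module so the whole pipeline can be exercised, tested and demonstrated at desk
scale. This vignette documents the scientific definitions, every model
parameter, the realism and the limitations of the generators, and the
numerical choices.

## Data model

The central container is the `biomass_field`: a `time × lat × lon × type`
array of annual-mean, depth-integrated biomass (default units mgC m⁻²) plus a
`plankton_grid` (cell-centre coordinates, ocean mask, cosine-latitude area
weights) and a *type registry*. The registry describes each plankton type:
functional group, equivalent spherical diameter (ESD, the diameter of a sphere
with the cell's volume), phytoplankton size class, and trophic role.

The default registry mirrors a trait-based model configuration with 35
phytoplankton types — (functional group × size class) combinations over 16
log-uniform size classes from 0.6 to 228 µm ESD — in six groups (2
prokaryotes, 2 picoeukaryotes, 5 coccolithophores, 5 diazotrophs, 11 diatoms,
10 mixotrophic dinoflagellates), plus 16 zooplankton size classes at 10× the
phytoplankton class-centre ESDs. Zooplankton are carried in fields and in the
simulator but never enter phytoplankton diversity metrics.

Land cells are `NA` throughout and are excluded from every statistic; missing
values are never silently zero-filled (the netCDF reader treats a partially
missing ocean cell as a validation error).

## Diversity metrics

**Presence threshold.** A type is *present* at a cell when its share of total
phytoplankton biomass is at least 0.1 % (`threshold_fraction = 0.001`,
boundary inclusive). The threshold removes numerically surviving trace types
that a plankton counter would never see; it is applied uniformly to richness,
Shannon, evenness, turnover and appearance/disappearance.

**Functional richness** is the count of present types.

**Shannon index** (nats):

$$H = -\sum_{i \in \text{present}} p_i \ln p_i,$$

where the shares $p_i$ are *renormalised over the present types* so they sum
to one — without renormalisation $H$ would depend on how much biomass the
excluded trace types hold, which is exactly what the threshold is meant to
ignore. $H = 0$ where at most one type is present.

**Evenness** is $H / \ln S$ with $S$ the richness; it is 1 when all present
types hold equal biomass and undefined (`NA`) where $S \le 1$ because
$\ln 1 = 0$.

**Turnover** between two timepoints is

$$\tau = \frac{N_G + N_L}{N_T},$$

with $N_G$ types gained, $N_L$ types lost, and $N_T$ the number of types
observed across *both* timepoints, i.e. the union of the two presence sets.
The union reading is the only one under which $\tau \in [0, 1]$ with 0 = all
types persist and 1 = all types change; it makes $\tau$ the Jaccard distance
between presence sets. Cells where both sets are empty are `NA`. Turnover is
computed on *period-mean* biomass (then thresholded), not on yearly presence,
so a type intermittently present within a period still counts if its mean
share clears the threshold. The **turnover-rate change** compares a late pair
of periods against an early pair (defaults 2061–80 vs 2081–2100, minus
2011–30 vs 2031–40); positive values mean composition is changing faster at
the end of the run.

**Size spectrum.** Per cell, period-mean biomass is summed into the 16
phytoplankton size classes (class ESD = geometric mean of member-type ESDs,
natural on a log axis), empty classes are dropped, and a Theil–Sen slope of
$\ln(\text{biomass})$ against $\ln(\text{ESD})$ is fitted. The *reported*
slope is the raw slope **plus 3**, converting an area-based to a volume-based
(biovolume) spectrum exponent for spherical cells. More negative reported
slopes mean relatively more biomass in small types. The presence threshold is
*not* applied before binning by default — the spectrum is a biomass
description, not a presence statistic — and `apply_threshold = TRUE` is
available for sensitivity checks. Theil–Sen (median of all pairwise slopes)
is used because class biomasses span orders of magnitude and a single
near-empty class would dominate a least-squares fit; it is hand-implemented
(no installed package provides it) and tested against a brute-force oracle,
against OLS on collinear data, and for single-outlier invariance.

**Regional summaries.** Area weights are proportional to
$\cos(\text{lat})\,\Delta\text{lat}\,\Delta\text{lon}$ and zero on land; only
area *fractions* are reported, so the spherical-cap constant cancels.
"Decline" and "increase" are strict (< 0, > 0); cells where a metric is
undefined leave both numerator and denominator. Latitude bands use half-open
`[south, north)` intervals so touching bands never double-count a row. The
Southern Ocean boundary (45°S) and the subtropics band (23°–40°) have no
canonical definition and are explicit, configurable defaults — report
sensitivity to them when comparing against other analyses.

## The toy mechanistic simulator

`sim_scenario()`/`simulate_cell()` integrate a single-cell
nutrient–phytoplankton–zooplankton model, with one nutrient $N$, the 35
phytoplankton types $P_i$ and 16 zooplankton classes $Z_j$:

$$\frac{dP_i}{dt} = \mu_i(N, T) P_i - m_P P_i - \sum_j G_{ij},\qquad
  \mu_i = \mu_{\max,i}\, e^{E_a (T - T_{\mathrm{ref}})} \frac{N}{N + k_{N,i}}$$

$$G_{ij} = g_{\max,j}\,\phi_{ij} P_i \frac{\Pi_j}{k_g^2 + \Pi_j^2} Z_j,\qquad
  \Pi_j = \sum_i \phi_{ij} P_i$$

$$\frac{dZ_j}{dt} = \lambda \sum_i G_{ij} - m_Z Z_j^2 - m_{Z,\mathrm{lin}} Z_j$$

$$\frac{dN}{dt} = S - \sum_i \mu_i P_i + r \cdot (\text{all losses})$$

| Parameter | Default | Units | Why |
|---|---|---|---|
| `mu0` | 2.0 | d⁻¹ | peak growth rate, typical of fast small phytoplankton |
| `mu_opt_esd`, `mu_size_width` | 3, 2.5 | µm, ln ESD | unimodal size scaling of µ_max peaking near 3 µm: the smallest cells are diffusion-limited, large cells are slower |
| `k_N0`, `k_N_exp` | 0.1, 0.6 | µM, – | half-saturation rises strictly with ESD, so the smallest cells have the highest nutrient affinity and win under oligotrophy |
| `g_max0`, `g_size_exp` | 1.0, −0.25 | d⁻¹, – | grazing rate falls allometrically with grazer size |
| `k_graze` | 0.5 | biomass | Holling type III half-saturation; the squared form gives prey refuges at low density |
| `pref_ratio`, `pref_range` | 10, (5, 15) | – | triangular log-ratio feeding kernel: zero outside predator:prey ratios 5–15, peak at 10 — the minimal shape consistent with a stated range and preference |
| `assimilation` | 0.3 | – | fraction of grazed biomass reaching the grazer |
| `m_P` | 0.05 | d⁻¹ | linear phytoplankton mortality |
| `m_Z`, `m_Z_lin` | 0.25, 0.01 | (biomass d)⁻¹, d⁻¹ | quadratic closure plus a small linear term; see "numerical choices" |
| `recycle` | 0.5 | – | fraction of all losses remineralised; 1 closes the nitrogen budget exactly |
| `E_a`, `T_ref` | 0.0639, 20 | K⁻¹, °C | Arrhenius factor ≈ doubling per ~11 °C (Q₁₀ ≈ 1.9) |
| `nutrient_supply`, `temperature` | 0.02, 20 | µM d⁻¹, °C | yearly forcing nodes, linearly interpolated within years |

The simulator supports exactly the experiments the metrics need: under
*declining nutrient supply* the large, high-`k_N` types drop below the
presence threshold first, so richness falls and the size spectrum shifts
toward small cells (a lower reported slope); under *warming* realised growth
rises. Two closed-form behaviours anchor the physics tests: with
`recycle = 1` and zero supply, total nitrogen is conserved to integrator
tolerance; and a single-type run settles to the chemostat equilibrium
$N^* = k_N m_P / (\mu_{\max} a(T) - m_P)$.

```{r chemostat, eval = FALSE}
sc <- sim_scenario(toy_registry(1), years = 2001:2002,
                   nutrient_supply = 0.05, spinup_years = 60)
simulate_cell(sc)$N_final                       # ~ k_N m_P / (mu_max - m_P)
sc$k_N * sc$m_P / (sc$mu_max - sc$m_P)
```

## The parametric generator

`parametric_scenario()`/`generate_parametric()` build fields whose diversity
structure is *known by construction*, so the pipeline can be tested against
exact targets rather than another model:

- **Richness** is exact: each cell holds exactly `richness` present types;
  absent types have zero biomass.
- **Evenness** is met to 1e-6 via a one-parameter geometric family
  $p_i \propto q^{i-1}$, solving for $q$ numerically (evenness is monotone in
  $q$, so a bracketed root-find suffices). Combinations whose smallest share
  would fall below the presence threshold are rejected as parameter errors —
  they would silently break the exact-richness guarantee.
- **Turnover**: each year, `ceiling(turnover_per_step × richness)` = $k$
  present types are replaced by absent ones, which makes every
  consecutive-step turnover exactly $2k/(s+k)$.
- Richness, evenness and the total-biomass trend may be per-year vectors, so
  prescribed trends (e.g. declining evenness) can be generated directly.

`generate_world()` assembles a global field from per-latitude-band scenarios
and adds mean-one multiplicative lognormal noise
($\sigma = 0.1$, $\mathbb{E}[\text{noise}] = 1$ via the $-\sigma^2/2$ log-mean
correction, so expected biomass is unchanged). Mechanistic bands run the
simulator once and broadcast the result across the band's cells; parametric
bands draw every cell independently.

### Realism and limitations

The synthetic world reproduces the *mechanisms* the metrics are designed to
detect, not any particular ocean:

- **Broadcast bands**: all cells in a mechanistic band share one community
  before noise; there is no advection, mixing or within-band gradient.
- **No colonisation**: each simulated column is closed, so richness can only
  be lost, never gained by range expansion. Poleward richness *increases*
  — a real consequence of warming oceans — cannot emerge from the simulator;
  use a parametric band with a rising richness profile to represent them.
  The shipped `century` preset accordingly reports a zero
  polar-richness-increase fraction.
- **Evenness under decline**: in the simulator, specialist Holling III
  grazing buffers dominance, so evenness does not reliably fall as nutrients
  decline even while richness and the spectrum slope do. Prescribed evenness
  trends belong in parametric bands.
- The lognormal noise is independent across cells, years and types — no
  spatial or temporal autocorrelation.

## Numerical choices

- **Integrator**: fixed-step classical RK4 (in compiled code) at
  `dt = 0.05` d. A timestep-halving check (`check_dt_stability()`) confirms
  final states move by far less than 1 %. After each step, biomass below the
  `extinction_floor` (10⁻¹²) is set to zero: without it, dying types decay
  through hundreds of log-decades and their ~10⁻³⁰⁰ residuals corrupt the
  log-biomass spectrum fit.
- **Spin-up**: `spinup_years = 50` at first-year forcing are integrated and
  discarded, so reported runs start from an equilibrated community rather
  than the arbitrary initial condition (which otherwise contaminates
  base-period means).
- **Zooplankton closure**: the quadratic term alone approaches steady state
  only algebraically (~1/t); the small linear `m_Z_lin` makes the approach
  exponential, giving clean steady-state diagnostics.
- **Theil–Sen**: median of pairwise slopes over pairs with distinct x; even
  pair counts average the two central values, matching `stats::median()`.
- **Evenness root-find**: `uniroot` at tolerance 1e-14 on $q \in (0, 1)$,
  well inside the 1e-6 contract.

## Problem sizes

The shipped sizes are package choices, set so every workflow runs on one CPU
in seconds to minutes: the `tiny` preset (4 × 4 cells, 8 types, 10 years,
parametric) for examples and round-trip tests, and the `century` preset —
a 20 × 36 global grid (8° × 10° cells), the full 51-type registry, annual
fields 2005–2100, seven climate-emulating latitude bands — for end-to-end
runs (`scripts/acceptance.R`, about a minute). The metric pipeline itself is
vectorised over cells and scales linearly in `time × lat × lon`; nothing in
it depends on these particular sizes.

```{r century, eval = FALSE}
field <- preset_field("century", seed = 1)
summary_report(field)
```
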