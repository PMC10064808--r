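---
title: "Modelling soil heating and microbial survival in a pyrocosm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling soil heating and microbial survival in a pyrocosm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrocosm)
```

## The problem

When a fire passes over soil, the microbes living in the top centimetres —
biocrust cyanobacteria, algae, and heterotrophic bacteria — experience a
steep, transient temperature gradient: the surface may exceed 450–600 °C
while a few centimetres down the pulse is attenuated and delayed. Whether a
community survives is largely a question of how deep the lethal
temperatures reach. Pyrocosm experiments probe this with a torch-heated
soil core, thermocouples at a few depths, and per-centimetre culturing
after the burn. This package provides the model half of that workflow: a
physically explicit simulation of the temperature field, a classification
of the heat mortality zone, and the statistics applied to the
thermocouple and culture-plate readouts.

## Surface forcing model

The torch is represented by a prescribed surface temperature with three
phases: a linear ramp from basal `t_basal` to maximum `t_max` over
`t_ramp` seconds, a hold at `t_max` for `t_hold` seconds, and an
exponential relaxation over `t_decay` seconds. The decay constant is
chosen as $k = \ln(100)/t_{decay}$ so the curve sits exactly 1 % of the
rise above basal when the decay phase ends — a concrete way to pin "has
returned to basal" to the stated phase duration without adding a free
parameter. The piecewise form itself is this package's choice: burn
protocols state phase durations, not equations, and a
linear/constant/exponential composition is the simplest curve that honours
all three durations, never overshoots, and is right-skewed whenever the
decay is longer than the ramp (with the defaults, 3× longer).

Defaults (all configurable): `t_basal` 20 °C, `t_ramp` 600 s, `t_hold`
60 s, `t_decay` 1800 s, `dt` 1 s, and `t_max` 450 °C (low severity) or
600 °C (high severity). One ambiguity deserves note: burn protocols of
this kind sometimes hold the maximum for 60 s and sometimes describe a
ten-minute burn at the treatment temperature. The package defaults to the
60 s hold and exposes `t_hold` in the configuration; the simulated fields
here use 60 s throughout, and users reproducing a longer burn should set
`t_hold: 600`.

## Soil thermal properties

Volumetric heat capacity uses de Vries-style mixing over the solid and
water fractions,

$$C = 1.92\,x_{mineral} + 2.51\,x_{organic} + 4.18\,\theta
\quad [\mathrm{MJ\,m^{-3}\,K^{-1}}],$$

with the air fraction neglected. The default composition ($x_{mineral} =
0.45$, $x_{organic} = 0.05$, $\theta = 0.10$, bulk density 1.40 g cm⁻³)
describes a loam-like soil typical of semi-arid shrubland; it gives $C =
1.4075$ MJ m⁻³ K⁻¹. Thermal conductivity is fixed at 0.03 W cm⁻¹ K⁻¹
(3 W m⁻¹ K⁻¹) independent of depth, moisture and temperature — moisture
enters only through the heat capacity. Together these give a diffusivity
$\alpha = k/C \approx 2.1\times10^{-6}$ m² s⁻¹. All values are pinned
defaults, overridable under the `soil:` block of the YAML configuration,
so results are exactly reproducible.

An optional latent-heat variant treats each node's water as an energy
sink: while a node sits at 100 °C with water remaining, incoming heat
depletes a store of $\theta \rho_w L_v$ (with $L_v = 2.26$ MJ kg⁻¹)
before the temperature rises. It is implemented as enthalpy clipping
after each time step — a first-order approximation that caps and delays
deep heating without modelling vapour transport. It is off by default and
off in every result quoted here.

## Numerical scheme

The 1-D heat equation is discretized on a uniform grid (default 0.1 cm
over a 15 cm column, output every 1 s) with Crank–Nicolson time stepping.
The choice is forced: at the stated resolution the explicit stability
number $\alpha\,\Delta t/\Delta z^2 \approx 2$, so forward Euler would be
unstable, while Crank–Nicolson is unconditionally stable and second-order
in both variables. The constant tridiagonal system is LU-factored once
(sparse `Matrix` factorization) and re-solved each step.

Boundary conditions: the top node follows the forcing curve exactly
(Dirichlet); the bottom is held at the initial temperature at 15 cm,
emulating the sand tray that acts as a heat sink beneath the mug — a
zero-flux alternative is available. The initial condition is uniform at
20 °C. When the requested duration outruns the forcing curve, the surface
is clamped to the curve's final value. "Temperature at $d$ cm" always
means the grid node at exactly $d$ cm; reporting bins for the 1–10 cm
culture samples are labelled by their node depth.

Verification is against the closed-form half-space solution for step
heating, $T = T_0 + \Delta T\,\operatorname{erfc}(z/2\sqrt{\alpha t})$:
on a 30 cm column (bottom boundary out of play) the solver agrees within
2 % of the rise over 0.5–10 cm and 60–600 s. The test suite additionally
checks the discrete maximum principle, monotone attenuation of the peak
with depth, a discrete energy balance (interior enthalpy change equals
the time-averaged boundary flux integral), and grid convergence: halving
both steps moves the 3 cm peak by well under 1 %.

Under the default high-severity parameterization the 3 cm node peaks near
292 °C and the 100 °C lethal threshold is crossed down to 9 cm; the
acceptance script (`scripts/acceptance.R`) recomputes both numbers from
scratch.

## Exposure metrics and the mortality zone

Per depth bin the package reports peak temperature and its time, the mean
over an analysis window (default the first 1800 s, covering ramp-up and
early cooling; truncated with a warning if the run is shorter), and
time/degree-seconds at or above each threshold (defaults 50, 60, 100 °C).

The mortality zone is classified on **peak temperature only**: the zone is
$[0, D]$ with $D$ the deepest whole-centimetre bin whose peak meets the
lethal threshold, 100 °C by default. Peak rather than a duration-weighted
dose was chosen because thermotolerance thresholds for soil phototrophs
are conventionally quoted as temperatures, and because it makes the
classifier monotone in the threshold and independent of the analysis
window; degree-second metrics are still reported for users who want a
dose criterion. Non-contiguous super-threshold bins (possible under
exotic forcings) still yield the interval to the deepest qualifying bin,
with a warning listing the gaps.

## Thermocouple statistics

`compare_treatments()` reproduces the conventional analysis of paired
burn thermocouples: per (depth, fire) stratum, all samples within the
window are pooled across replicates per cover type and compared with a
Welch unequal-variance *t*-test (two-sided, Welch–Satterthwaite degrees of
freedom, no multiple-testing correction). Per-second samples are treated
as independent observations — deliberately mirroring field practice rather
than improving on it; consecutive readings of a conduction process are
strongly autocorrelated, so these p-values are descriptive, and the
pipeline report says so.

`model_vs_observed()` quantifies probe placement error: it computes the
RMSE between a trace and the simulated field at the nominal depth, then
searches depth offsets at grid resolution within ±2 cm for the
RMSE-minimizing shift, ties broken toward the smaller magnitude. Probes
placed by hand can shift by a centimetre when the core is moved; this
diagnostic recovers such offsets exactly for clean slices and to within
0.2 cm (median) at 2 °C reading noise.

A reference table of published per-depth comparisons ships as a fixture
(`table1_reference()`) for annotating reports; the raw series behind it
are not published, so those numbers are reference values, not
recomputable outputs.

## CFU statistics

Culture grids are 0/1 presence of growth per plate over
2 covers × 3 fire levels × 10 depths × `R` replicates (default 6; 360
plates). `growth_summary()` reports overall, per-treatment and per-depth
fractions; `chi_squared_presence()` runs Pearson chi-squared without
continuity correction on the factor × outcome table, pooling across
depths and the other factor — both layouts (3×2 by fire level, 2×2 by
cover) are emitted, since pooled tests at this granularity are the
convention for such grids. `min_growth_depth()` scans for the shallowest
depth with any growth per treatment.

## Synthetic data and the survival model

The generators exist so every pipeline stage is testable without field
data; their defaults are the study conditions, not tuning knobs.

*Thermocouple traces* are field slices at the nominal depth plus one
per-probe placement jitter draw (sd 0.5 cm — haphazard manual placement)
with per-sample Gaussian reading noise (sd 2 °C). The nominal label is
retained, so the jitter is recoverable by `model_vs_observed()`. The
pipeline applies a constant cover offset (default 10 °C) to biocrust
traces, emulating the insulating effect of an intact crust.

*CFU grids* draw plates independently from a logistic peak-temperature
survival model,

$$p(\text{growth}) = p_{base}\,
  \operatorname{logit}^{-1}\!\bigl((T_{50} - T_{peak})/s\bigr),$$

with $T_{peak}$ the simulated per-depth peak for that fire level and
controls assigned $T_{peak} = T_{init}$, so control plates grow at the
baseline culturability $p_{base}$. Defaults: $T_{50} = 100$ °C (chosen to
coincide with the lethal-peak threshold of the zone classifier),
$s = 10$ °C, $p_{base} = 0.9$. Survival depends on peak temperature only,
consistent with the zone classifier; no heat-dose memory is modelled. No
quantitative survival-versus-temperature curve exists for these
communities, so these values are the package's own, used for synthetic
validation only.

`fit_lethal_midpoint()` inverts the model: with $s$ and $p_{base}$ held
fixed it maximizes the Bernoulli likelihood over $T_{50}$ by grid search
(20–400 °C, 1 °C steps, ties to the lower value — a deliberate
conservative tie-break). All-positive or all-negative grids are
non-identifiable; the fit then returns the corresponding search bound,
flagged. At the default design size the median recovery error over 50
seeds is under 10 °C, and it shrinks with replication.

Randomness is split per probe and per plate: each stratum's stream seed
is a deterministic hash of the global seed and its indices, so enlarging
the design never perturbs existing draws, and all outputs are
byte-reproducible for a fixed configuration and seed.

What the synthetic data do **not** emulate: real plate outcomes are not
independent (shared slurry dilutions, within-core spatial correlation),
reading noise is not white (sensor lag, radiative spikes), and real
survival depends on exposure duration, moisture and taxon, not peak
temperature alone. Passing tests therefore demonstrate that the pipeline
recovers parameters under its own generative assumptions — necessary, not
sufficient, for inference about field data.

## Problem sizes and runtime choices

The default simulation (151 nodes × 2461 s) solves in about a second; the
test suite uses that grid for the physics checks, a 30 cm column for the
oracle comparison, and scales Monte-Carlo studies to 20–200 seeds per
property, keeping the full suite under a minute while leaving every
statistical bound at least 3 standard errors wide. The refinement study
doubles resolution in both dimensions once; further halving changes the
3 cm peak at the fourth significant figure and was not retained.

## Known limitations

* One-dimensional conduction: no mug-wall effects, surface radiation
  losses, or lateral heterogeneity.
* Constant conductivity; no coupled heat–moisture transport (the
  latent-heat option is an energy sink, not a vapour model).
* The mortality threshold is a single temperature; organism-specific
  death-time kinetics are out of scope.
* The Welch comparison inherits the independence assumption of pooled
  per-second samples; treat its p-values as descriptive.
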