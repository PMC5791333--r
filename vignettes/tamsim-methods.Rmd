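---
title: "Modeling tumor-associated macrophage subtypes in a vascularized lesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor-associated macrophage subtypes in a vascularized lesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamsim)
```

## The model

`tamsim` simulates a small metastatic lesion growing in a highly
vascularized host tissue (liver- or lung-like), coupled to three discrete
tumor-associated macrophage (TAM) phenotypes:

* **M1** — classically activated, tumoricidal. Each M1 agent releases
  nitric oxide in its immediate 4-neighbourhood; NO has a short in-vivo
  half-life, so the kill term `lambda_M1 = lambda_NO * 1_M1` acts only at
  M1-adjacent lattice sites and subtracts from net proliferation in both
  cycling and quiescent tissue.
* **M2** — alternatively activated, tumor-promoting. M2 agents secrete a
  diffusible growth factor `F` that (i) raises the local proliferation
  rate, `d lambda_M2/dt = lambda_F F (1 - (lambda_M + lambda_M2))`,
  saturating so the total mitosis rate cannot exceed 1/day, and (ii)
  transiently lowers the viable-oxygen level `Q_OL` toward its floor,
  keeping oxygen-starved tissue alive:
  `dQ_OL/dt = lambda_OL (1-F)(Qbar - Q_OL) - lambda_OT F (Q_OL - Q_min)`.
* **TEM** — Tie2-expressing macrophages. TEMs chemotax up angiopoietin-2
  gradients secreted by the neovasculature, cluster on the abluminal
  vessel surface, sensitize sprouting (a multiplicative gain on sprout
  initiation and extension within contact range), shield adjacent vessels
  from the natural shrinking tendency
  (`dR = (S_wss+S_p+S_m - S_s (1 - 1_TEM)) R dt`), and secrete IL-10,
  which biases monocyte differentiation toward M2.

The tumor itself is a continuum: a volume-fraction field advanced by
conservative upwind advection under the Darcy velocity `v = -mu grad(P)`,
where the oncotic pressure solves `lap(P) = -lambda_p/mu` on the tumor
with `P = 0` in the host (uniform extracellular matrix, so the haptotaxis
term vanishes). Tissue is classified per site as proliferating
(`sigma >= 0.5750`), hypoxic (viable but non-cycling, down to the
effective viability bound `Q_OL`), or necrotic; necrosis is absorbing —
debris is degraded at rate `G_N` and fully degraded sites revert to host —
because re-oxygenating dead tissue must not resurrect it (without this
rule the coupled system oscillates between fully-oxygenated and
fully-necrotic states and the hypoxic TAF source flickers off).

Oxygen and all cytokines are steady-state reaction-diffusion fields
(re-solved every few macro-steps; the transport time scale is minutes
against a 0.05-day step), discretized with the 5-point Laplacian,
zero-flux domain boundaries, and solved by red-black successive
over-relaxation with a residual tolerance of `1e-7` (oxygen `1e-6`). The
relaxation factor is chosen per field from the Jacobi spectral-radius
estimate; a warm start from the previous step keeps the per-step cost to
a few dozen sweeps.

Monocytes extravasate from perfused vessel sites in proportion to the
local tumor angiogenic factor (TAF), capped at about 25% of the in-vivo
macrophage density (2.78e4/mm^3) inside the lesion. They differentiate by
a single uniform draw against subintervals proportional to
`k_M1 C_M1f`, `k_M2 (C_M2f + k_T2M2 C_IL10)` and
`k_T2 C_T2f + k_Ang2 C_Ang2`, scaled by a per-day rate `diff_rate` so
per-step probabilities stay below one. Subtypes disabled by a scenario
are still drawn but become inert agents — they occupy space and move but
exert no effect and are excluded from differentiated counts — which keeps
the monocyte pool and the entire draw sequence identical across the eight
scenarios. (For the same reason the no-macrophage scenario carries inert
monocytes; "no macrophages" means no macrophage *effects*.) Movement is
semi-stochastic: per-direction scores from oxygen, pressure and
chemoattractant differences (Ang2 only, for TEMs), negative scores
clamped to zero, scaled into probabilities and resolved by one uniform
draw with occupancy exclusion (at most one agent per site).

## Unit system and the reconciliation of table rates

Lengths are nondimensionalized by 200 um (the oxygen-diffusion scale of
the lesion's transport problem); the default 100 x 100 lattice at
20 um/site spans the 2 x 2 mm panel, with the capillary grid every 12
sites (240 um ~ the 250-um spacing). Rates are per simulated day, and a
single clock scale (`clock_scale = 0.72`) maps nondimensional time to
days; it is the one calibration of the growth phase, balancing the
timing of hypoxia onset — which triggers monocyte infiltration and is
observed at 7.35 days post inception, at a lesion diameter near 200 um;
the default places onset at day 6.45 and 175 um — against the length of
the post-onset window in which the angiogenic and population dynamics
unfold.

The literature tables behind this model mix several nondimensional
conventions, and three reconciliations are package design decisions:

* **Macrophage cytokines** (M1f, M2f, IL-10, T2f and the growth factor
  F). Their wash-out (0.006) and decay (0.001) rates descend from a
  pixel-based proteomic model whose natural length is the 20-um cell;
  expressed on the 200-um transport unit they scale by 100 (0.6 and 0.1).
  Read instead on the transport unit directly, every tumor cytokine would
  blanket the whole domain, the TEM-differentiation field would equal the
  M1 field everywhere (identical equations), and the TEM share of
  differentiation would be capped near 25% — inconsistent with the
  55-70% calibration anchor the model family reports. The pixel-scale
  reading gives each factor a halo of one to a few hundred um around its
  source, which is also what "transient local" effects require.
* **Production scales.** Production enters as `p (1 - C)` on the source
  mask and the absolute scale of `p` is tied to an external reference
  (VEGF-A production). Tumor-sourced factors use `p = 0.05`, the
  low-saturation regime in which local concentrations are O(0.1) — the
  scale at which the differentiation coefficients (20, 20, 8.21, 0.95)
  produce sensible competition — and in which a higher-diffusivity factor
  dilutes itself more, so the M1 factor modestly exceeds the M2 factor
  inside the lesion (the observed stationary M1:M2 of about 1.2 cannot
  arise in the saturating regime, where both factors pin at 1). The
  TEM-eluted IL-10 and the vascular guidance fields (Ang2, TAF) use
  `p = 1`: IL-10's absolute level is anchored by its observed 5.6-37
  pg/mL range (the package maps concentration 1 to 20 pg/mL), and the
  guidance fields act through thresholds and long-range gradients, for
  which they keep the slow transport-unit decay (tails of hundreds of um).
* **Per-second effect strengths.** Three rates are quoted per second
  (lambda_F = 1000, lambda_OT = 200, lambda_NO = 3), dimensionally
  incompatible with day-scale proliferation. The first two act as
  saturating switches — any plausible reconciliation drives their
  first-order dynamics to equilibrium within a step, so the package
  integrates both ODEs with their exact exponential solutions
  (unconditionally stable, same fixed points) and their precise values
  barely matter. The NO kill rate, in contrast, sets a rate directly; it
  is calibrated to `0.16`/day so that M1-driven growth arrest produces
  the reported plateau rather than extinguishing lesion and macrophage
  recruitment together.

Oxygen uptake rates are additionally scaled by a single factor 1.45,
placing the tumor oxygen-diffusion length (~120 um) below the capillary
half-spacing; without this the host bath is so well supplied that any
engulfed capillary line re-floods the interior and hypoxia cannot
persist.

## Vasculature

The pre-existing grid is fully perfused; a segment stays perfused while
it is non-collapsed and connected through such segments to the domain
boundary. The structural-adaptation stimuli (`S_wss + S_p + S_m`) live in
prior work; the package's default closure is a lumped restoring term
`k_s + min(k_R (1 - R/R_ref), 0.05 k_R)` for segments carrying (or
pressed against) flow and 0 otherwise. This keeps a stable operating
radius of 5 um, lets a collapsed segment with a live endpoint reopen when
tumor pressure relents ("partial recovery"), and, because the restoring
excess is clipped, lets sustained pressure above
`P_CT + 0.05 k_R / k_PC` win and drive full collapse. Radii are floored
at 0.1 um (a multiplicative law cannot leave zero) and capped at 6.5 um.
Oxygen delivery scales with the segment's caliber as `(R/R_ref)^2`
(Poiseuille-flavoured) and with a type hematocrit (0.45 mature, 0.3
immature neovessels), so recovering stubs and young sprouts feed little.

Sprouts initiate on the grid where TAF exceeds a threshold, extend one
site at a time with direction probabilities proportional to the positive
TAF-gradient components, and become perfusable only when the tip — after
at least `sprout_min_age` extensions — fuses with another vessel
(anastomosis). Unperfused sprouts shrink at the full `S_s`, so a sprout
that cannot fuse in time collapses unless a TEM shields it; together with
the TEM sensitization gain this is what carries the TEM-ablation
vascular fold-changes.

## Scenario design and metrics

The eight cases enable subsets of {M1, M2, TEM} (1: all, 2: M1+TEM,
3: M1+M2, 4: M2+TEM, 5: M1, 6: none, 7: TEM, 8: M2) over a 13-day
horizon from a 100-um proliferating disk centred in a capillary-grid
cell. Metrics per recorded time: equivalent-disk tumor radius,
intratumoral vascular surface area with actual radii and with a fixed
10-um diameter, region site counts, subtype counts (standing and
cumulative), the TEM share of active differentiation events, the M2:M1
count ratio, and the intratumoral vascular-to-tumor volume ratio with
sites as 20-um voxels. The TEM share uses cumulative counts so that it
remains defined when a standing population has turned over; the
stationary M1:M2 ratio averages the final quarter of the run.

## Numerical choices

* Macro-timestep 0.05 day; fields re-solved every 3 steps (guidance
  fields every 6). Halving `dt` to 0.025 changes the day-13 radius of the
  no-macrophage case by under 2% (see below).
* Agents move at most one site per step; the score scale 0.12 makes
  strong near-rim gradients saturating (about one site per step) while
  distant agents drift slowly.
* The movement orientations are package choices where the source is
  silent: down the oxygen gradient (toward hypoxia, with the
  chemoattractant), and up the pressure gradient — the latter implements
  the deep TAM infiltration observed in this model family; with the
  opposite sign agents pile into a ring just outside the interface and
  never sample the lesion interior.
* Tie-breaks are fixed: tips extend in index order, agents move in a
  randomized order drawn from a dedicated stream, and the four named RNG
  streams (spawn, differentiation, movement, vessels) make the draw
  sequence of each concern independent of the others, which is what
  guarantees the cross-case consistency of the monocyte pool.
* Replicate design: ten seeds per case for numeric comparisons (five for
  the none/TEM-only reference cases, which enter only ordering checks).

## What the synthetic scenarios do and do not show

All inputs are synthetic: the generator reproduces the *study
conditions* (domain, capillary spacing, initial lesion, parameter
tables), not any measured dataset. Passing checks show that the coupled
mechanisms reproduce the reported population structure, vascular
fold-changes and growth orderings under those conditions; they say
nothing about real lesions beyond the model family's own validation.
Known limitations: 2D only; a simplified perfusion model (binary
connectivity with type hematocrit) instead of a full flow/hematocrit
network solve; a volume-fraction interface instead of level-set/ghost
cells; uniform ECM with no haptotaxis or remodeling; one-way monocyte
differentiation with a fixed lifespan.

Two reported quantities resist this reimplementation and are documented
as open gaps rather than tuned away. The transient M2:M1 peak of 2.2
requires the IL-10 term `k_M2 k_T2M2 C_IL10 <= 0.12` to dominate the M1
weight somewhere monocytes actually differentiate; under any
concentration regime consistent with the *stationary* M1:M2 of 1.2, the
peak stays near 1. And the vascular fold-change on the M2-only
background tends to run above its reported 1.9 while the M1-background
folds sit near theirs; a single TEM sensitization gain cannot hit both
ends exactly.

## Worked example

```{r example, eval = FALSE}
library(tamsim)
cfg <- default_config()
res <- run_case(case_spec(1, seed = 1), cfg)
tail(res$metrics[, c("time", "tumor_radius_mm", "vascular_area_actual",
                     "n_M1", "n_M2", "n_TEM", "fraction_TEM_cum")], 3)
res$onset_day          # hypoxia-triggered monocyte onset, day
```

A dt-convergence spot check:

```{r convergence, eval = FALSE}
r1 <- run_case(case_spec(6), default_config(dt = 0.05))
r2 <- run_case(case_spec(6), default_config(dt = 0.025))
abs(tail(r1$metrics$tumor_radius_mm, 1) /
    tail(r2$metrics$tumor_radius_mm, 1) - 1)   # < 0.02
```
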