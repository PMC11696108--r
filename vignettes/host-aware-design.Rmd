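---
title: "Host-aware design of microbial cell factories for batch production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-aware design of microbial cell factories for batch production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostfactory)
```

## The problem

Engineering a bacterium to make a chemical product means diverting its
metabolism and its gene-expression machinery away from growth. Because
ribosomes, translation precursor and carbon flux are shared, every extra
heterologous enzyme slows growth, and every unit of growth forgone changes
how a *culture* of these cells performs over a whole batch. `hostfactory`
asks the culture-level question directly: which enzyme expression levels,
and which inducible genetic circuits, maximise **volumetric productivity**
(`vP`, product made per unit time of batch) and **product yield** (`pY`,
product made per unit of substrate supplied)?

The package has four layers:

1. a mechanistic single-cell model with explicit resource competition;
2. a batch-culture simulator with the cell model embedded;
3. multiobjective (Pareto) optimisation of strain and circuit designs;
4. a robustness measure for optimised designs under parameter perturbation.

## The host-aware cell model

The cell expresses seven genes: nutrient transporter `T`, host metabolic
enzyme `E`, heterologous synthesis enzyme `Ep`, product exporter `Tp`, the
circuit transcription factor `TF`, a non-specific transporter `X`, and
ribosomes `R`. Each gene `x` has mRNA `m_x`, translating ribosome-mRNA
complexes `c_x`, and free protein. Metabolite pools are the internal
substrate `s_i`, the translation precursor `e`, the internal product `p_i`
and the internal inducer `i_i`.

Fluxes are Michaelis-Menten throughout: `T` imports external substrate,
`E` converts `s_i` into `n_s` units of `e`, `Ep` converts `s_i` (or, in the
*precursor-drain* product variant, `e` itself) into `p_i`, and `Tp` plus a
slow non-specific route through `X` export `p_i`. mRNA-ribosome binding is
mass action (`k_b`, `k_u`); translation elongates at
`gamma(e) = gamma_max * e / (K_gamma + e)` and consumes one unit of `e` per
amino acid. Transcription of every gene saturates in `e`, with the
ribosomal gene given a much higher half-saturation (`theta_R >> theta`), so
scarcity of precursor hits ribosomal transcripts first — this asymmetry is
what lets resource competition re-balance the proteome towards enzymes when
metabolism is switched off. Growth is not a parameter but an output:

```
lambda = gamma(e) * sum_x(c_x) / M0
```

i.e. total translation over total protein mass, and every species is
diluted at `lambda`. Protein decay `d_p` is zero by default (a stable
proteome); `half_life_to_decay_rate()` converts half-lives for the
degradation studies.

### Parameter choices

Defaults (see `?cell_params`, units: minutes, molecules per cell) follow
the canonical calibration of this class of coarse-grained E. coli
resource-allocation models: `M0 = 1e8` aa, `gamma_max = 1260` aa/min,
`K_gamma = 7`, ribosome length 7549 codons versus 300 for the enzymes,
`k_b = 1`, `k_u = 1`, mRNA decay `0.1`/min, transporter and enzyme
turnovers `kcat_T = 726`/min and `kcat_E = 5800`/min with `Km = 1000`, and
maximal transcription rates of 4.14 transcripts/min for enzyme-class genes
against 930 for the ribosomal gene (`theta_R = 426.87` vs `4.38`). The
heterologous pathway enzymes deliberately share the host enzymes' kinetics
so that the only engineered difference is expression. `X` doubles as the
housekeeping mass sector: it carries the negative autoregulation
(`Kq_X = 1.522e5`, Hill 4) that pins roughly half the proteome, preserving
the calibrated proteome partition, and contributes only a very slow export
activity (`kcat_X = 0.01`/min). With these defaults the unburdened cell
grows at `lambda ~ 0.026`/min (doubling time ~27 min), an E. coli-like
operating point.

```{r}
cp <- cell_params()
st <- exponential_steady_state(cp)
attr(st, "rates")[c("lambda", "r_T")]
```

### The steady-state operating point

`exponential_steady_state()` clamps the external substrate and integrates
(compiled right-hand side, `deSolve::lsoda`) until the largest relative
state change over a trailing 100-minute window falls below `1e-6`. Three
numerical choices matter:

* **Seeding.** The solve starts from a generically expressed living state
  (1000 molecules of every protein). A strain whose circuit needs TF to
  activate metabolism has a second, dead attractor at the empty state; the
  biological object of interest is the grown-up culture, which sits on the
  living branch.
* **Staged continuation.** Slow-growing designs relax on the `1/lambda`
  dilution timescale, which can exceed the nominal 5e4-minute cap; the
  solver continues with coarser windows (tolerance rescaled per 100 min)
  up to 20x the cap before giving up.
* **Degenerate designs.** Effectively non-growing cells
  (`lambda < 1e-6`/min) never equilibrate their undiluted pools (they creep
  algebraically); they are accepted at the end of the first stage, and a
  design whose *states* still drift while every *rate* the caller uses is
  flat is accepted once the rates converge. Both cases correspond to
  designs that score zero in any culture optimisation.

## The batch culture

`simulate_batch()` integrates culture biomass `B`, substrate `S_x`,
product `P_x` and inducer `I_x` in the same state vector as the cell:

```
dB/dt = lambda * B,  dS_x/dt = -r_T * B,  dP_x/dt = r_Tp * B,
dI_x/dt = -r_uInd * B
```

with `B` in cells and external pools in molecules per culture (the per-cell
to culture conversion constant is therefore 1). Uptake is written with a
minus sign so substrate depletes; the batch ends at the root event
`S_x = eps_S` (default `1e-3 * S0`, since the depletion ODE approaches zero
only asymptotically) or at the horizon `t_max = 1440` min. Cells start at
the pre-induction steady state for `S0`: no arbitrary lag phase. Defaults
`S0 = 1e12` molecules and `B0 = 1` cell give ~12 doublings before
exhaustion at wild-type growth — a realistic inoculum ratio — and the
external `Km` of the transporter is set at `1e-3 * S0` so depletion is
Michaelis-shaped near the end. The metrics are
`vP = P(t_end)/t_end` and `pY = P(t_end)/S0`, so `vP * t_end = pY * S0`
holds identically.

## Genetic circuits

A design is a topology `g = (g_T, g_E, g_Ep, g_Tp, g_TF)` with
`g in {-1, 0, +1}`, transcription scalings `sTX`, control strengths `K`,
and an induction time `tau`. The convention, fixed against the behaviour
of the constrained design problems, is that **the TF is active in its
inducer-free form**: it acts on its targets throughout the growth phase,
and the inducer bolus (added at `tau`, saturating by default) deactivates
it. `g_E = +1` therefore reads "E is activated while growing and collapses
to the basal leak after induction" — the *inducer-deactivation of the host
enzyme* motif — while `g_Ep = -1` keeps the pathway repressed until
induction de-represses it. Regulation is Hill-1 in the active TF with
per-molecule strength `K in [1e-6, 1]` (half-effect at `1/K` molecules,
spanning 1 to 1e6); a shared basal leak of `1e-3` of the full rate keeps
activated genes expressible at zero TF, without which positive TF
autoregulation could never bootstrap. `K` must be exactly zero where
`g = 0`; `validate_circuit_design()` enforces this structurally.

## Optimisation

Three problems are solved, all as maximise-maximise Pareto searches with
an elitist genetic algorithm of the NSGA-II family (fast nondominated
sorting, crowding distance, simulated binary crossover, polynomial
mutation), implemented in the package:

* **genotype**: `(r_Tp, lambda)` over `sTX_E, sTX_Ep, sTX_Tp in [1e-3, 1]`
  at the cell's steady state;
* **one-stage**: `(vP, pY)` over the same dials, from batch simulations;
* **two-stage**: normalised `(vP, pY)` over topology, `sTX in [1e-3, 2]`,
  active `K in [1e-6, 1]` and `tau in [0, 1440]` min, with the topology
  enumerated exhaustively in an outer loop (at most 24 per constraint) and
  the continuous dials searched inside.

Numerical choices: dials spanning decades (`sTX`, `K`) are searched in
log10 space; every run is seeded and bitwise reproducible; evaluation
failures and batches that do not exhaust their substrate score `(0, 0)`
rather than aborting the search; the initial population is warm-started
with the box midpoint and the baseline (all scalings 1) strain, since most
random corners of the circuit box describe non-growing cells; and the
returned front is an external archive of every nondominated solution
encountered, which makes front quality provably non-decreasing in budget
for a fixed seed. Pareto membership and topology rankings are invariant to
positive rescaling of the objectives, so comparisons may run on raw
`(vP, pY)`; `normalization_constants()` estimates `vP_max, pY_max` by
separate single-objective maximisation (on the constraint's fully
controlled topology and on the circuit-free strain, keeping the larger)
when normalised reporting is wanted. Topologies count as *top-performing*
when their front hypervolume is within 2% of the best — an operational
reading of "overlapping" fronts.

## Robustness

`robustness_area()` perturbs every continuous dial of a design (typically
a front's knee point, `knee_point()`: maximal perpendicular distance from
the chord between the front extremes, in unit-square-normalised objective
space) by independent multiplicative `Uniform(1-f, 1+f)` factors — the
multiplicative form is scale-invariant across dials spanning decades —
re-evaluates `(vP, pY)` `n` times, and reports the area of the convex hull
of the performance cloud (collinear clouds get area 0 with a warning).
Larger area means performance moves more under the same relative
mis-tuning: a less robust, harder-to-engineer design.

## What the defaults emulate, and what they do not

The default parameter set is a calibrated *representative* E. coli-like
host, not a fit to any particular dataset: absolute growth rates, fluxes
and therefore `vP` magnitudes carry its scale. Qualitative structure — the
growth-synthesis trade-off, the interior productivity optimum in host
enzyme expression, the superiority of growth-phase-activated `E` switches,
resource-mediated indirect upregulation after induction — is the model's
content, and it is what the test suite asserts. Passing tests therefore
support the design *principles*, not quantitative predictions for a
specific organism or pathway. Known limitations: with a stable proteome
(`d_p = 0`) a switched-off enzyme disappears only by growth dilution, so
proteome re-allocation after induction is slow and the two-stage advantage
is bounded by it; there is no cell-to-cell heterogeneity (one average cell
scaled by `B`); metabolism is two-branch only; and induction is a single
saturating bolus.

## Problem sizes used in the checks

The packaged tests run the optimisers at reduced, seeded budgets
(populations 12-60, 2-60 generations; the full one-stage solve used for
the headline growth-sacrifice number is population 60 x 60 generations,
~3,700 batch simulations), chosen so the whole suite completes in minutes
on one core while every pipeline still runs end to end. `degradation_sweep()`,
`burden_sweep()` and `transporter_retuning()` expose the corresponding
parameter studies at configurable budgets.
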