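# hostfactory

Host-aware design of microbial cell factories for batch chemical
production.

Engineered bacteria make chemicals, but every heterologous enzyme competes
with the host for ribosomes and metabolic precursor, so strain design is a
trade-off between growth and synthesis — and what matters industrially is
not either rate but what a whole batch culture delivers. `hostfactory`
implements a mechanistic single-cell resource-competition model embedded
in a batch-culture simulator, and searches enzyme expression levels and
inducible genetic-circuit designs for the Pareto fronts of **volumetric
productivity** and **product yield**. It is aimed at computational
synthetic biologists and metabolic engineers exploring design principles
for one-stage and two-stage (grow, then induce a synthesis switch)
bioprocesses.

## The model in brief

A cell expresses transporter *T*, host enzyme *E*, pathway enzymes
*E<sub>p</sub>* and *T<sub>p</sub>*, a transcription factor, a
housekeeping/non-specific transporter *X* and ribosomes *R*. All fluxes
are Michaelis–Menten; translation draws on a shared precursor *e* and a
shared free-ribosome pool; growth is emergent,

&nbsp;&nbsp;&nbsp;&nbsp;λ = γ(e) · Σ<sub>x</sub> c<sub>x</sub> / M₀,

with γ(e) the elongation rate and c<sub>x</sub> the translating
ribosome–mRNA complexes, and every species is diluted at λ. The culture
layer integrates dB/dt = λB, dS/dt = −r<sub>T</sub>B,
dP/dt = r<sub>Tp</sub>B until substrate exhaustion, then scores

&nbsp;&nbsp;&nbsp;&nbsp;vP = P(t<sub>end</sub>)/t<sub>end</sub>,&nbsp;&nbsp;
pY = P(t<sub>end</sub>)/S(0).

Design searches (constitutive scalings sTX, circuit topology g ∈ {−1,0,+1}
per gene, control strengths K, induction time τ) use an NSGA-II-class
elitist genetic algorithm with an external nondominated archive.
Robustness of a design is the convex-hull area of its (vP, pY) cloud under
±20% multiplicative parameter perturbation.

## Worked example

```r
library(hostfactory)

cp <- cell_params()                      # E. coli-like defaults

# wild-type-ish strain: pathway nearly off
st <- exponential_steady_state(cp)
attr(st, "rates")[["lambda"]]
#> [1] 0.025685           # doubling time ~27 min

# a production strain: host enzyme turned down, pathway on
d <- circuit_design(sTX = c(T = 1, E = 0.2, Ep = 1, Tp = 1, TF = 0),
                    sTX_bounds = rbind(lo = c(T = 1, E = 1e-3, Ep = 0,
                                              Tp = 0, TF = 0),
                                       hi = c(T = 1, E = 1, Ep = 1,
                                              Tp = 1, TF = 0)))
b <- simulate_batch(cp, d, batch_options())
b
#> <batch_result>
#>   t_end = 1172.2 min (substrate exhausted)
#>   titre = 8.325e+11 molecules; vP = 7.102e+08 /min; pY = 0.8325

# optimise the one-stage culture objectives
front <- optimize_one_stage(cp, optimizer_budget(pop_size = 60,
                                                 generations = 60,
                                                 seed = 1))
best <- which.max(front$front$vP)
front$front[best, c("sTX_E", "sTX_Ep", "sTX_Tp", "vP", "pY")]
#>    sTX_E sTX_Ep sTX_Tp         vP     pY
#>   0.0505 0.0776  0.603 1054663057 0.6053

genotype_objectives(cp, front$designs[[best]])$lambda
#> [1] 0.013229
```

The last number is the "optimal growth sacrifice": the productivity-maximal
strain grows at about half the unburdened rate — faster strains turn
substrate into biomass instead of product, slower ones make product too
slowly. `autoplot()` methods plot fronts, batch trajectories and
robustness clouds; `tidy()`/`glance()` return tibbles.

Two-stage designs are explored per topology constraint, e.g.

```r
res <- optimize_two_stage(cp, topology_constraint("5.1"),
                          optimizer_budget(24, 16, seed = 12),
                          norm = c(vP_max = 1, pY_max = 1))
compare_topologies(cp, topology_constraint("5.1"), result = res)
```

which ranks all eight admissible circuits and flags the top-performing
group (every member of which deactivates host enzyme *E* on induction).
The command-line driver `inst/cli/hostfactory.R` runs named experiments
(`run --config cfg.yaml`, `list-experiments`, `validate-config`) from YAML
configs and writes CSV tables plus a reproducibility manifest.

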