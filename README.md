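# vrankcascade

Agent-based simulation of how a natural-disaster shock to food production
cascades through an agriculture-dependent economy, modelled as a spatially
explicit multi-layer behavioral network, together with **VRank**, a
multi-layer food-security vulnerability index.

## The problem

Disasters destroy output locally, but the losses do not stay local: price
spikes and income collapse in the affected region trigger trade re-routing
and out-migration, which shift demand and labor into unaffected regions and
drag them into the adjustment. Quantifying *where* and *when* that indirect
vulnerability lands — and how it depends on network density and distance
from the epicenter — is what this package is for. Its audience is
researchers in disaster-risk and food-security modelling who want a
controlled, fully synthetic testbed for cascade mechanisms.

## The model in brief

Locations are nodes of one spatial network carrying three link sets
(population, food, non-food flows). Each node runs a circular-flow economy:

- real output `y = 0.9·x_F + 0.1·x_G` for food producers (weights swapped
  otherwise), capacities fixed in the short run;
- wages `w = ρ·y / L` — all labor employed, income fully spent;
- market-clearing prices `p_F = α·w·L / m_F`, `p_G = (1−α)·w·L / m_G` on
  the quantities `m` actually marketed, price index `p = (p_F + p_G)/2`;
- an endogenous food budget share `α = clamp(p_F·c̄/w, ᾱ, 1)` defending a
  minimum per-capita food bundle `c̄`; a node pinned at `α = 1` cannot
  afford the bundle and is food-insecure.

Flows follow a gravity logic with behavioral thresholds: producers sell
only in connected markets covering unit cost (`p ≥ ρ`), reallocating supply
shares toward higher relative prices; households migrate toward strictly
higher real incomes `w/p`, with distance damping choice probabilities
through a logistic curve and a diffusion fraction `μ` capping per-tick
moves. A disaster removes a fraction `s` of food capacity from the food
producers inside a circular epicenter, permanently.

The vulnerability index is a dampened geometric mean of
minimum-bundle-cost-to-income ratios over a node and its neighbors:

```
VRank_it = sqrt( (p_it·c̄·L_i)/(w_it·L_it) · β · Σ_j p_jt·c̄·L_j / Σ_j w_jt·L_jt ),
```

`β = 0.85`; higher values mean higher vulnerability.

## Worked example

```r
library(vrankcascade)

sc <- cascade_scenario(network = list(n_nodes = 30, target_mean_degree = 6),
                       shock = list(s = 0.8), seed = 2)
run <- run_cascade(sc)
summary(run)
#> Cascade run summary
#>   shock s=0.80 at tick 1041 of 2133; converged
#>   pre-shock equilibrium: CV(w)=6.70e-02, CV(p)=6.70e-02
#>   food-to-labor price ratio: 1.2345 -> 1.9503
#>   per-capita food consumption: 0.3500 -> 0.3465
#>   total labor: 3000.00
```

The run burns in to its pre-shock equilibrium (1041 ticks), loses 80% of
food capacity at four epicenter food producers, and converges again 1092
ticks later. The food-to-labor price ratio `p_F/w` — affordability stress —
rises from 1.23 to 1.95, while mean per-capita food consumption ends just
below the defended bundle `c̄ = 0.35`: a few nodes stay pinned at the full
food budget share and remain food-insecure. Total labor is conserved
exactly; people moved, nobody vanished.

```r
vrank_panel(run)
#> VRank series
#>   2133 ticks x 30 nodes, beta = 0.85, shock at tick 1041
#>   final mean VRank 0.5116 (baseline 0.4098)

baseline <- run_cascade({sc$shock$s <- 0; sc})
cycle_trace(indicators(run, baseline))
#> Adjustment-cycle trace
#>   1093 ticks, signed area -444.2 (counter-clockwise), amplitude 82.1%
```

Mean vulnerability rises about 25% and stays elevated, and the economy's
path through the (price ratio, consumption) plane is a counter-clockwise
loop: prices spike first, consumption collapses, then migration and trade
re-routing restore consumption while prices slowly normalize — the
transition itself is where most of the vulnerability lives.

The full experiment — shock levels 0.4–0.8 on 10 random 80-node networks,
plus baselines — is `sweep_cascade(cascade_scenario())`; `sweep_indicators()`
summarizes it per run, `heat_bins()` bins indicators by distance-to-epicenter
and node density, and `plot()` methods draw the series, networks and cycles.
A thin CLI wrapper lives in `inst/scripts/vrank-cascade`
(`run` / `sweep` / `vrank` subcommands).

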