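---
title: "Modelling disaster shock cascades on multi-layer behavioral networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disaster shock cascades on multi-layer behavioral networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`vrankcascade` simulates how a localized natural-disaster shock to food
production propagates through an agriculture-dependent economy represented as
a spatially explicit multi-layer network. Locations are nodes; three link
sets carry population (migration), food, and non-food goods flows. A
production layer decides how much is sold where, a household layer decides
how much labor stays where; the two interact through wages and prices, and
the model tracks the resulting spatial-temporal evolution of vulnerability.
This vignette explains the model, its parameters, the numerical choices made
where the design was genuinely open, and what the simulation results do and
do not show.

## The node economy

Each node $i$ produces two goods, food $F$ and other goods $G$, at fixed
short-run capacities $x_{iF}, x_{iG}$. Real output is the product-weighted
sum

$$y_i = \beta_F x_{iF} + \beta_G x_{iG},$$

with weights $(0.9, 0.1)$ for food producers and $(0.1, 0.9)$ for the rest,
so half of randomly chosen nodes mostly grow food. All labor $L_i$ is
employed and earns the full value of production at unit cost $\rho$:

$$w_i = \rho y_i / L_i.$$

Income is spent locally: a share $\alpha_i$ on food, $1-\alpha_i$ on other
goods, and prices clear whatever quantities are marketed this tick:

$$p_{iF} = \frac{\alpha_i w_i L_i}{m_{iF}}, \qquad
  p_{iG} = \frac{(1-\alpha_i) w_i L_i}{m_{iG}},$$

with the price index $p_i = (p_{iF} + p_{iG})/2$ (equal index weights) and
nominal output $Y_i = \sum_k x_{ik} p_{ik}$. The budget identity
$p_{iF} m_{iF} + p_{iG} m_{iG} = w_i L_i$ holds exactly at every transacting
market.

The food share is endogenous. Households defend a minimum per-capita food
bundle $\bar c$ (goods units per worker): the share needed to buy it at
current prices is $p_{iF}\bar c / w_i$, bounded below by a subsistence floor
$\bar\alpha$ and above by 1 — a node pinned at 1 cannot afford $\bar c$ and
is food-insecure. Two readings of this rule are dimensionally possible; only
the share reading keeps $\alpha$ a fraction, so that is what
`update_alpha()` implements, and the node-level bundle is $\bar c L_i$
(per-capita bundle times workers), which makes $\alpha$ invariant to
population size.

## Diffusion: trade and migration

Nodes interact only with connected neighbors, in a gravity-model fashion:
the propensity to send goods or people somewhere rises with the relative
economic gain there and falls with distance. Gains map onto probabilities
through the generic logistic curve $\Pi(z) = 1/(a + b e^{-z})$ (defaults
$a=b=1$), distance enters as the normalized fraction of the farthest
neighbor's distance passed through the same curve centered at $0.5$ with
scale $0.25$ and then reversed ($1-\Pi^d$, so the nearest destinations are
barely penalized), and the joint weight is $\Pi = \Pi^q (1 - \Pi^d)$.
Candidate weights are normalized into shares of the diffused quantity, so
better destinations pull more but nothing is winner-take-all — agents are
allowed to pick next-best options.

**Migration.** Workers compare real incomes $w/p$. For each neighbor with a
strictly positive relative gain $z_{ij}$, the joint gain-distance weight is
computed (relative gains are divided by `gain_scale` = 0.1 before entering
the logistic, so a 10% gain maps to $z=1$); shares are the normalized
weights. The total outflow per tick is $\mu L_i \min(\max_j z_{ij}, 1)$: at
most the diffusion fraction $\mu = 0.1$ of the stock, scaled down smoothly
as gains vanish. The scaling is what makes the system *stabilize*: a
constant $\mu L$ outflow for arbitrarily small gains keeps overshooting the
equilibrium and produces a sustained period-2 oscillation instead of
convergence, whereas gain-proportional outflow contracts exponentially onto
the equal-real-wage fixed point. The fixed point itself does not depend on
$\mu$; $\mu$ only sets the transition speed.

**Trade.** Producers sell only in markets that at least cover the unit cost,
$p_{jk} \ge \rho$ (a market exactly at cost is retained at the margin);
destinations are the node's own market plus its layer neighbors. Two
further mechanisms shape the allocation:

* *Supply-share tatonnement.* Each producer keeps a destination-share
  vector per good and adjusts it multiplicatively to relative prices
  ($\text{weight} \propto s \cdot p_{jk}/\rho$), smoothed at rate $\mu$.
  Markets above cost gain share in proportion to their price, markets at
  cost keep theirs. Normalizing raw profit *margins* instead is
  winner-take-all in discrete time — a market sitting exactly at cost loses
  its entire allocation the moment any other market is a hair above cost,
  which in experiments produced rotating shortages that never died out. A
  producer holding unsold stock also probes any above-cost market with a
  small seed weight (0.01), so abandoned destinations can be re-discovered;
  sold-out producers do not probe, so the seed cannot bias stationary
  allocations.
* *Absorption rationing.* Within the tick, a market accepts goods only up
  to $\text{spend}/\rho$ — the quantity that keeps its price at or above
  cost. Excess shipments are withheld at the source (flagged). Without this
  cap the cost threshold acts as a cliff: markets overshoot below cost, all
  suppliers withdraw the next tick, the price explodes, and the system
  flip-flops with period 2. With it, saturated markets settle at
  $p = \rho$ exactly.

For the goods layer $\mu$ is deliberately the *smoothing rate of the share
vector*, not a hard cap on shipped quantity. Goods are per-tick flows
(output is re-produced every tick, it does not accumulate), so a hard
$\mu x$ export cap would bind in the steady state and permanently starve
net-importing nodes — making both price equalization and $\mu$-invariance
of the long-run outcome impossible. With share smoothing, the stationary
allocation is independent of $\mu$ and $\mu$ again controls only the
transition, which is the intended role of the parameter. The labor layer
keeps the hard cap ($\sum_j \text{flow}_{ij} \le \mu L_i$), since labor is
a genuine stock.

An aggregate accounting fact shapes the baseline: total income $\rho y$ is
strictly less than the cost value of gross output $\rho(x_F + x_G)$
whenever both goods are produced (the $\beta$-weights average, they do not
sum). The economy therefore runs a permanent surplus that cannot all be
sold at cost; prices settle *at* the cost floor wherever supply suffices,
and the excess is withheld. This is a structural consequence of the
production and pricing rules, not a numerical artifact.

## The tick and its numerical choices

One synchronous tick, all nodes reading the same start-of-tick snapshot:

1. production at capacity; 2. wages; 3. trade candidate selection (against
previous-tick prices) and goods flows; 4. market clearing on post-trade
marketed quantities; 5. food-share update; 6. migration selection and
population flows; 7. record.

Three numerical details matter:

* **Price signals on starved markets.** Prices are quoted on at least one
  goods unit of volume, $p = \text{spend}/\max(m, 1)$. A bare machine-level
  quantity floor turns an empty market into a $10^{10}$ price, which then
  wrecks the real-wage signal and migration for several ticks; the one-unit
  quote bounds the signal by local spending (high enough to attract
  suppliers, finite enough not to destabilize anything). Markets with
  transaction volume below $10^{-6}$ are flagged `collapsed` in the output
  panel.
* **Budget-share inertia.** The defended-bundle share is a fast positive
  feedback (higher food price → higher share → higher food spending →
  higher food price). Applied instantaneously at supply-short nodes it
  locks into an undamped relaxation cycle against the slow migration
  response. The simulator therefore relaxes $\alpha$ toward its
  threshold value at the same behavioral rate $\mu$ as every other
  adjustment margin in the model; the fixed point is the threshold share
  itself, unchanged.
* **Convergence.** A phase ends when the largest relative per-tick change
  of all wages and price indices stays below $10^{-6}$ for 10 consecutive
  ticks, or at `t_max` = 5000 ticks per phase; non-convergence is flagged
  in the manifest, never raised. A run is burn-in to the pre-shock
  equilibrium, then the shock (epicenter food producers lose the fraction
  $s$ of food capacity, permanently — recovery is out of scope), then the
  post-shock phase. In the sweep, all shock levels of one network branch
  from the identical burn-in.

In the default `expected_share` mode all flows are expected-value splits
and runs are exactly reproducible (identical panels for identical
config + seed); `sampled` mode draws integer migrant destinations
multinomially under the run seed.

## The synthetic networks and what they (don't) emulate

`generate_network()` places $n = 80$ nodes uniformly in the unit square,
connects all pairs within the radius that yields a target mean degree of 8,
adds minimum-spanning-tree edges to force connectivity, and labels a random
half of the nodes food producers. All three layers share this topology by
default (per-layer edge masks are a configuration hook). The geometric rule
gives the degree heterogeneity and spatial clustering that the
distance-by-density analysis needs; the mean degree is an open choice — the
source setting reports only the node count and producer split.

These networks emulate the *shape* of a food-trade region, not any real
geography: distances are abstract, capacities identical, institutions
absent. A passing test therefore shows that the mechanism produces the
documented qualitative patterns under these idealized conditions, not that
it forecasts any actual region.

The epicenter is a circular region holding 20% of nodes around
$(0.25, 0.25)$ — a corner region, so distance-to-epicenter spans the
network. Only its food producers are shocked.

**A structural caveat: food deserts.** Trade is one-hop (producers sell to
network neighbors; imports are consumed, not re-exported). A low-degree
node whose closed neighborhood produces less food than its population
demands at cost can therefore never be fully supplied at $p = \rho$. The
model still equilibrates: real wages $w/p$ and per-capita consumption
(exactly $\bar c$ wherever the share is interior) equalize, while *nominal*
prices and wages stay dispersed in proportion — a standard spatial
equilibrium with a cost-of-living gradient. On desert-free geometries
(about half of the default seeds) the baseline equalizes nominally too, to
coefficients of variation below $10^{-5}$; on the others a few such nodes
keep the nominal CV at a few percent. The consumption and real-wage
equalization holds either way.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_nodes`, `food_frac` | 80, 0.5 | — | network size, producer split |
| `target_mean_degree` | 8 | links | spatial density |
| `rho` | 1 | money / goods unit | unit production cost and selling threshold |
| `L0` | 100 | workers | initial labor per node |
| `x_food`, `x_nonfood` | (90, 10), (10, 90) | goods units | capacities; both give $y = 82$ |
| `alpha0`, `alpha_min` | 0.5, 0.3 | share | initial / subsistence food share |
| `c_bar` | 0.35 | goods units / worker | minimum food bundle; at the cost-floor baseline this puts $\alpha \approx 0.43$, strictly inside $(\bar\alpha, 1)$ |
| `mu` | 0.1 | per tick | diffusion fraction / adjustment rate, both layers |
| `a`, `b`, `gain_scale` | 1, 1, 0.1 | — | logistic curve and gain scaling |
| `s` | 0.4–0.8 | fraction | food-capacity loss in the epicenter |
| `tol`, `window`, `t_max` | $10^{-6}$, 10, 5000 | — | convergence controls |

`beta_damp` = 0.85 dampens the neighbor term of VRank.

## VRank

The vulnerability index synthesizes affordability of the minimum bundle
across a node and its (union-graph) neighborhood:

$$VRank_{it} = \left[\frac{p_{it}\,\bar c L_i}{w_{it} L_{it}}\;\beta\;
  \frac{\sum_{j\ne i} p_{jt}\,\bar c L_j}{\sum_{j\ne i} w_{jt} L_{jt}}
  \right]^{1/2},$$

a $\beta$-dampened geometric mean of the own and neighborhood
bundle-cost-to-income ratios; higher is more vulnerable. On an
all-identical network with common ratio $r$ it collapses to
$r\sqrt\beta$. A non-food node among cheap-food producers scores lower
than the same node isolated; for an isolated node the neighbor term does
not exist and the own-ratio fallback $r\sqrt\beta$ is returned with an
`isolated` flag rather than silently merged. Whether the bundle in the
neighbor term is per-capita or node-total is an open choice; the node-total
$\bar c L_j$ is used for population invariance. Reported percent changes
are relative to each node's own value at the last pre-shock tick.

## The experiment and analysis layer

The reference experiment crosses shock levels $\{0.4, \dots, 0.8\}$ with 10
random networks (50 runs) plus a no-shock baseline per network. Indicators
are the food-to-labor price ratio $p_F/w$ (affordability stress) and
per-capita food consumption $\alpha w / p_F$, as percent change against the
baseline run of the same network, summarized per run by their post-shock
time means and extremes. `heat_bins()` tracks the indicators on a grid of
normalized distance-to-epicenter (epicenter members pinned to the first
bin) by degree quantiles at eight evenly spaced post-shock snapshots; cell
means conserve the global mean by construction. `cycle_trace()` follows the
spatial-mean indicator pair through time; its shoelace integral
$\oint y\,dx$ is negative for a counter-clockwise adjustment cycle.

Observed patterns at these problem sizes (80 nodes, 10 networks; the full
sweep takes a few minutes on one CPU): the post-shock consumption decline
is monotone in the shock level; VRank rises more near the epicenter than in
the most distal distance bin on every network; the time-to-peak of the
affordability ratio increases with distance from the epicenter (rank
correlation ≈ 0.9–1.0 per network) — the propagating wave; and the
adjustment cycle is counter-clockwise on every network at $s = 0.8$. These
are exactly the quantities `scripts/acceptance.R` recomputes.

## Known limitations

No recovery or reconstruction dynamics (the shock is permanent); no
household savings, food stocks, or assets — migration is the only coping
mechanism; one-hop trade without re-export (hence the food-desert spatial
equilibrium above); fixed capacities and identical endowments; two goods
only; no financial or public-sector layers; abstract time ticks with no
calendar mapping. Monetized transport costs are deliberately absent —
distance only counterweights economic gains in the choice probabilities.
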