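---
title: "Modelling the bio-economics of no-take marine reserves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the bio-economics of no-take marine reserves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reservesim)
```

`reservesim` couples a spatial fish population model to a two-sector
economic model (fishing and dive tourism) to simulate what happens to the
value of a coastline when part of it is closed to fishing. This vignette is
the package's account of the model: its assumptions, its parameters and
units, the numerical and design choices behind the implementation, and what
the bundled tests do and do not demonstrate.

## The biological model

### Delay-difference dynamics

Each species is tracked as biomass per patch with a Deriso–Schnute
delay-difference recursion. This is the standard middle ground between a
surplus-production model (no age structure at all) and a full age-structured
model: it distinguishes recruits from adults, carries a one-year lag so that
last year's survival affects this year's growth accounting, and represents
individual growth through the Brody coefficient $\rho$:

$$B_{i,t+1} = (1+\rho)\,s_t \tilde B_{i,t}
  - \rho\, s_t s_{t-1} \tilde B_{i,t-1}
  - \rho\, s_t w_{k-1} R_{i,t} + w_k R_{i,t+1}$$

with $\tilde B$ the biomass after adult movement, $s_t = s_{nat}(1-u_t)$
the realised annual survival (natural survival times survival from
fishing at harvest rate $u$), $w_k$ and $w_{k-1}$ the mean weights (grams)
of adults and recruits, and $R$ recruitment in individuals. All adults are
equally vulnerable to fishing and all reproduce; biological parameters are
homogeneous along the coastline.

Simulations are initialised at the unfished equilibrium. Setting
$R = R_0$ and $s = s_{nat}$ and solving the stationarity condition gives

$$B_0 = \frac{R_0\,(w_k - \rho\, s_{nat} w_{k-1})}
             {(1 - s_{nat})(1 - \rho\, s_{nat})},$$

which the test suite verifies against long-run iteration of the recursion
itself (the two agree to better than $10^{-6}$ relative for the bundled
species and for randomised parameter draws). The fished burn-in then moves
the system to its exploited equilibrium before the reserve is implemented;
we chose unfished initialisation plus burn-in over solving directly for the
fished equilibrium because it exercises exactly the same code path as the
policy experiment.

### Space, dispersal and recruitment

The domain is a linear coastline of `n_patches` equal patches (default
100, unit length). Distances are centre-to-centre in patch units. Both
larval dispersal and adult movement use a Gaussian kernel
$w_{ij} \propto \exp(-d_{ij}^2 / 2\sigma^2)$, row-normalised so the
proportions leaving any patch sum to one. Two consequences of that
normalisation are worth spelling out:

* **Conservation.** No biomass is lost off the ends of the coastline; mass
  that "would have" dispersed past an end is effectively reflected back.
  This is a coastline, not an island, so there is no wraparound.
* **Edge structure.** Because columns of a row-stochastic kernel need not
  sum to one, a uniform distribution is not an exact fixed point near the
  ends. The reserve is therefore placed at the centre of the coastline (see
  below), and the burn-in absorbs the small edge adjustment.

Egg production each year equals the spawning biomass at the beginning of
the year — post-movement, before catch — and is carried in grams through
dispersal. Settled eggs $E_j$ convert to recruits through a Beverton–Holt
function in the steepness parameterisation:

$$R_j = \frac{4 h R_0 E_j}{(1-h) E_{0,j} + (5h - 1) E_j},$$

where $E_{0,j}$ is the settlement in patch $j$ at the unfished equilibrium
(computed once by pushing the uniform $B_0$ field through the larval
kernel) and steepness $h$ is the fraction of unfished recruitment obtained
when settlement drops to 20% of $E_0$. Keeping $E$ and $E_0$ both in grams
makes the ratio form unit-consistent without an explicit eggs-per-gram
constant, which would cancel anyway.

### Within-year order of operations

The order is fixed and matters for reproducibility: (1) adult movement,
(2) catch and survival from the post-movement biomass, (3) spawning from
the post-movement, pre-catch biomass, larval dispersal and settlement,
(4) recruitment, (5) the delay-difference update, after which the lags
rotate. Spawning before catch means a year's eggs are produced by the
stock that entered the year, which is the natural reading of
"spawning biomass at the beginning of the year".

### Numerical choices

* The lagged recursion can transiently go negative under extreme
  parameter combinations (large lag term, collapsing stock). The update
  clamps at zero per patch, records the clamped mass in the result's
  `clamped` column, and warns once per run; it never raises, because a
  clamped patch is a physically meaningful (empty) state.
* Non-finite state aborts the run with the year and patch, since it can
  only arise from an invalid configuration.
* The MSY harvest rate is located with `stats::optimize()` on the
  closed-form equilibrium yield $u \cdot B(u)$; the acceptance test checks
  the yield curve on a coarse grid of the iterated dynamics has a single
  interior peak consistent with it.
* Kernel rows are normalised in double precision; conservation holds to
  about $10^{-15}$ relative, well inside the $10^{-9}$ the tests demand.

## The economic model

### Fishing

Catch in patch $i$ is $C_i = u_i \tilde B_i$ and annual fishery profit is
$FV = \sum_i (p\, C_i - c_i u_i)$, with $p$ the price per gram and $c_i$
the cost per unit effort. The model does not define effort independently
of harvest, so one unit of effort is the effort producing one unit of
harvest rate — the simplest consistent reading, with the cost scale left
as a configuration knob. Only species with role `"fished"` contribute to
$FV$; a tourism-role species may still be harvested (bycatch) but its
catch is not valued.

### Tourism

The marginal value of a dive is linear in annual dives $q$ and in the
reserve biomass $B$ of the tourism-role species:
$MV = \alpha + \beta q + \gamma B$, with $\beta < 0$ (satiation) and
$\gamma \ge 0$ (more fish, better diving; the linearity is an assumption
that holds for moderate biomass changes, not a law). Inverting at a fee
gives demand; revenue $P q$ is maximised at $q^* = -(\alpha + \gamma B) /
2\beta$ and $P^* = (\alpha + \gamma B)/2$ — half the choke price, as for
any linear demand. Consumer surplus is the area under the demand line
above the fee. "Reserve biomass" means the no-take zone by default;
`include_partial_in_reserve` widens it, a genuine modelling choice for
sites where divers also use the buffer zone.

The demand parameters are rarely observable directly, so
`calibrate_demand()` reconstructs $(\alpha, \beta, \gamma)$ from an
interpretable operating point: the dives actually sold at the going fee, a
choke-price multiple (how much the marginal diver at a deserted site would
pay relative to the fee), and the share of the choke price attributable to
biomass. The calibration is exact and deterministic; its inputs are honest
unknowns that a site study would estimate.

### Fee policies and events

Three policies: a fixed fee (demand clears at the fee each year), an
optimal fee (re-priced each year at $P^*$), and a cap. The `cap_dives`
event models a regulatory ceiling: in its year it freezes the fee and caps
dives at that year's demand; thereafter $q = \min(\text{cap}, \text{demand})$.
Consumer surplus under a binding cap is computed against the fixed fee —
the capped divers are the ones who value dives most, and they still pay
only the fee.

## The Medes Islands scenario

The bundled fixture uses the two-species parameterisation of the Medes
Islands reserve: striped red mullet (fished; $s_{nat} = 0.66$,
$w_k = 53.93$ g, $\rho = 0.77$, $R_0 = 52{,}000$, $\sigma_L = 2$,
$\sigma_A = 1$) and European seabass (tourism; $s_{nat} = 0.9$,
$w_k = 384.9$ g, $\rho = 0.85$, $R_0 = 6{,}100$, $\sigma_L = 2$,
$\sigma_A = 0.01$), both with $h = 0.75$ and $w_{k-1} = 0$. The coastline
is zoned 1% no-take / 12% partial / 87% open; post-reserve harvest is zero
in the no-take zone, halved in the partial zone and unchanged outside. The
timeline is a 100-year burn-in plus 100 post-reserve years, with year 0 the
implementation year (1983 in calendar terms; the historical dive cap maps
to post-reserve year 8, 1991, at the €3.5 access fee).

Several economic constants are not fixed by the biology and are the
package's own defaults, chosen once as field-plausible values and all
overridable:

* **Pre-reserve harvest**: 1.5× the fished species' MSY rate — an
  overfished stock, which is the policy-relevant starting point — and a
  0.1 bycatch rate on the tourism species.
* **Price** 0.01 currency/g (€10/kg, a realistic ex-vessel price for red
  mullet) and **cost** 30,000 per unit effort per patch, giving the
  pre-reserve fleet roughly a 50% profit margin, typical of artisanal
  fisheries.
* **Demand calibration**: 63,000 dives/year at the €3.5 fee when the
  no-take zone holds the tourism species' unfished biomass, choke multiple
  2, biomass share 0.5. Anchoring at unfished biomass makes the target the
  demand of a fully recovered reserve; realised dives stay below it along
  the recovery path.

With these defaults the simulation shows the qualitative trajectory the
model is built to explore: an immediate dip in fishery profit (about 7% in
year 0), recovery above the pre-reserve level within two years as the
partial zone's fishing pressure drops toward MSY and protected patches
export larvae and adults, a monotonically growing tourism value at the
fixed fee, and total value passing its pre-reserve baseline in the first
post-reserve year — comfortably inside the "payback within a handful of
years" regime. `payback_year()` makes that metric explicit: the first
post-reserve year whose total value reaches the mean over the last ten
burn-in years.

## The synthetic scenario generator

`generate_synthetic_scenario()` draws complete, valid configurations —
coastline size and zoning, two species (one fished, one tourism) with
survivals, growth, steepness, dispersal ranges, harvest rates, costs, and
calibrated demand — uniformly within the type invariants, deterministically
per seed. It emulates the *structure* of real scenarios, not their
ecology: parameters are drawn independently, so correlated life histories
(long-lived species tend to have high survival *and* low steepness),
empirically co-varying prices and costs, and multi-species interactions are
all absent. Property tests built on it (non-negativity, conservation,
welfare identities, determinism) therefore demonstrate that the simulator
is well-behaved across the valid parameter space — not that any particular
random scenario is ecologically realistic.

## Problem sizes

The unit suite runs scenarios of 40 + 30 years on the 100-patch coastline
(and 15 + 15 years for randomised scenarios), which is past equilibration
for both bundled species; the headline Medes runs and the acceptance
script use the full 100 + 100 years. Equilibrium oracles iterate 600–1500
years, far beyond the slowest convergence factor involved
($s_{nat} = 0.9$ gives $0.9^{150} \approx 10^{-7}$).

## Known limitations

* Two age classes only; no explicit age structure, sex structure or
  stochastic recruitment.
* Species are simulated independently — no trophic interactions, and the
  dive experience depends only on the biomass of the designated tourism
  species, not on diversity.
* Larval advection is not modelled; dispersal is symmetric Gaussian.
* The economic layer omits multiplier effects of tourism spending,
  discounting, financing, and enforcement costs; the payback metric
  compares undiscounted annual flows.
* The demand line is linear and its biomass effect is assumed linear,
  which is defensible for moderate biomass changes but not for extreme
  recoveries.
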