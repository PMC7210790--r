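---
title: "Methods: simulating OHCA response and siting AED drone bases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating OHCA response and siting AED drone bases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dronaid)
```

## The problem

Out-of-hospital cardiac arrest (OHCA) survival depends sharply on the time
to defibrillation. A network of bases launching AED-carrying drones is a
candidate way to shorten that time, especially in rural areas far from
ambulance stations. `dronaid` estimates the benefit of such a network by
simulation: it generates a synthetic incident load over a region, races
three responders to each incident, and uses a genetic algorithm (GA) to
decide where drone bases should go and a diminishing-returns rule to decide
how many are worth building.

Because real incident registries, facility locations and commercial
travel-time feeds are rarely redistributable, the package is built around a
**synthetic region generator** plus open file schemas (GeoJSON + CSV +
YAML), so real data can be substituted wherever it is available.

## Geometry

All distances are great-circle (haversine) on a sphere:

$$ d = 2r \arcsin\sqrt{\sin^2\tfrac{\Delta\varphi}{2} +
   \cos\varphi_1\cos\varphi_2\sin^2\tfrac{\Delta\lambda}{2}} $$

with radius $r = 6356$ km (the polar radius) by default; every distance
function accepts an override. At the ~100 km scale of a region the
difference from an ellipsoidal geodesic is far below the uncertainty of the
travel-time model, so geodesic refinements are out of scope.

Point-in-polygon tests use ray casting with an **inclusive boundary**
(a point on the edge is inside). No-fly-zone checks project the flight
segment into a local equirectangular plane centred on the zone (longitude
scaled by $\cos$ of the zone latitude) and test the point-to-segment
distance against the zone radius, endpoints inside counting as
intersections. Both conventions are deliberately conservative for
safety-style constraints. The planar approximation is justified because
no-fly radii (5 km) and drone ranges (12 km) are tiny relative to $r$.

## The synthetic region and road model

`generate_region()` tiles a configurable bounding box with trust polygons
built as jittered vertical strips — disjoint convex cells that are cheap to
sample from and to test membership against. Each trust carries a population
density and a set of circular residential areas; facilities (ambulance
stations, public AEDs, candidate drone bases) are scattered around
residential centres with Gaussian jitter, mimicking placement in populated,
high-footfall locations. Default densities span urban (2600 /km²) to rural
(120 /km²), sketching one dense small trust and several sparse large ones.

Driving time is a parametric stand-in for a commercial travel-time API:

$$ t_\text{road} = 60 \cdot \frac{d_\text{haversine}\cdot\text{circuity}}
   {v_\text{free}/m_h} \ \text{minutes} $$

with circuity 1.3 (a standard road-network stylised fact), free-flow speed
50 km/h, and an hour-of-day congestion multiplier $m_h \ge 1$ defaulting to
mild morning/evening peaks (1.3 at 08–09 and 17–18, 1.15 on the shoulder
hours). These constants are calibration knobs, not measurements: any real
travel-time source can replace the model behind the same function
signature. The multiplier is indexed by the incident's hour.

## Incident generation

`generate_incidents()` follows three steps, all deterministic under a seed:

1. **Allocation.** Incidents are apportioned across trusts proportional to
   population density by the largest-remainder method, so counts always sum
   exactly to the requested total. Density is used as the weight as given;
   a user can supply total population instead by editing the trust table.
2. **Location.** Rejection sampling draws points uniformly over the trust
   polygon and keeps those inside a residential disk, emulating the
   restriction of incidents to residential addresses (not lakes or
   mountains). A per-point attempt cap (default 10,000) turns infeasible
   geometry into an error rather than a hang.
3. **Time.** Day-of-week (0 = Monday) and hour-of-day are drawn
   independently from two marginal PMFs, because only marginals — not a
   joint distribution — are typically published. The shipped defaults are
   explicit placeholders (mild weekday elevation; unimodal daytime peak
   around 09:00–17:00) and can be replaced from a two-column CSV.

The default incident count is 10,000.

## Response model

Per incident, three times are computed:

- ambulance: $0.75 \times t_\text{road}$ from the nearest station (the
  25% blue-light reduction; the factor is configurable),
- public AED: $2 \times t_\text{road}$ to the nearest AED — a civilian
  round trip, with no blue-light reduction,
- drone: $60\,d/v$ from the nearest *eligible* base, where eligibility
  means $d \le$ range (inclusive at exactly the range) and a flight path
  clear of every no-fly disk. Because eligibility is checked per base, a
  farther clear base beats a nearer blocked one. With no eligible base the
  drone is *unavailable* — a typed absence, not an error, so the race
  degrades gracefully to the remaining responders.

No dispatch, call-handling, take-off or deployment overheads are added by
default — the model covers travel only — but an additive per-responder
overhead is exposed for sensitivity analysis. Exact ties are broken in the
fixed order ambulance > drone > public AED (professional responder
preferred). The response layer contains no randomness, which yields the
central invariant the reporting relies on: **adding a base can never slow
any incident**, so after-network results dominate the baseline pointwise.

Concurrent incidents competing for the same drone, battery recharge cycles
and ambulance fleet queueing are out of scope.

## Genetic algorithm

A chromosome is a set of exactly $k$ candidate-base ids; its fitness is the
mean winning response time (lower is fitter). Each generation:

1. rank the population by fitness; carry the top `elite_count` (default 2)
   over unchanged;
2. cross consecutive pairs in descending fitness order — (1st, 2nd),
   (3rd, 4th), … — each pair producing one child as a **uniform random
   k-subset of the parents' union**, which preserves set semantics, is
   unbiased between parents, and collapses to the parent when both are
   identical;
3. mutate each child with probability 0.10: one uniformly chosen gene is
   replaced by a uniformly chosen outside candidate;
4. refill with random chromosomes to the fixed population size.

Population size (50) and generation count (100) are defaults of this
implementation — they are not prescribed by the underlying study design —
and all correctness properties are stated relative to instance size, not to
these defaults. Fitness caching keys on the sorted base-id tuple; cached
and fresh evaluations are identical because evaluation is deterministic.
The per-incident ambulance/AED times and the incident × candidate drone
feasibility matrix are precomputed once per GA run, making a chromosome
evaluation a column-subset minimum rather than a fresh simulation.

`brute_force_best()` enumerates all $\binom{n}{k}$ subsets (refusing above
a cap, default 20,000) and is the package's own validation oracle: the GA
can never beat it, and on small instances it should almost always match it.
Both whole-region and per-trust optimisation are supported; per-trust runs
simply pass that trust's incidents.

## Network sizing, reporting and tests

`sweep_bases()` runs the GA for $k = 1..k_\text{max}$ and keeps the
best-so-far envelope, which is monotone even when individual GA runs are
noisy. `select_plateau()` then picks the smallest $k$ after which every
further step improves the envelope by less than a relative threshold
(default 2%); the criterion is a design choice of this package, chosen
because an absolute threshold would not transfer across regions with
different time scales. A per-trust `k_max` expresses caps on saturated
urban trusts.

Reporting covers: coverage fractions at strict `< t` minute thresholds
(default 3–8); the winning-responder mix; five-number summaries (type-7
linear-interpolation quantiles); and a paired Wilcoxon signed-rank test on
before/after times. The signed-rank variant is used because the two
scenarios are paired per incident. The statistic is the smaller signed-rank
sum; the null distribution is exact for ≤ 25 effective pairs (dynamic
programming over sign assignments, with doubled ranks so tied half-ranks
stay integral) and a tie-corrected, continuity-corrected normal
approximation beyond. Zero differences are dropped; an all-zero comparison
is degenerate and reported as $p = 1$.

Cost and workload are simple arithmetic, exposed so their inputs are
auditable: lifetime cost $n \cdot c \cdot (1 + m \cdot y)$ with defaults
$c = 15{,}000$, $m = 0.20$/year, $y = 4$ years; workload
$\text{events}/(12\,n_\text{stations})$ flights per station-month, divided
further per operator.

## Reproducibility and numerical choices

One master seed drives everything: per-stage seeds are derived by hashing
the stage name (`derive_seed()`), so stages can be rerun independently yet
bit-reproducibly, and all of them stay below $2^{31}$. All interface files
are plain text with units in column names (minutes, km, km/h).

The test suite exercises each layer against independent oracles where one
exists: haversine against a spherical-law-of-cosines formula and
`geosphere`; point-in-polygon against `mgcv::in.out`; the signed-rank test
against `wilcox.test`; the GA against exhaustive enumeration. Problem sizes
in the suite and in `scripts/acceptance.R` are scaled to what the
properties need — e.g. 30-incident, 8–10-candidate GA instances with 20
seeds each, 1,000–10,000-incident generator checks, a 2,000-incident
pipeline run — sizes chosen so the stochastic properties are sharp while a
full run stays interactive.

## What passing tests do and do not show

The generator emulates the *structure* of the real problem — density-based
allocation, residential clustering, marginal time-of-day patterns,
range-limited drones, no-fly detours — but not the measured content:
synthetic trust shapes are convex strips, road times ignore the road graph,
and the shipped PMFs are placeholders. Results on synthetic regions
therefore demonstrate that the machinery is correct (monotonicity,
optimality on small instances, calibrated statistics), not that a specific
real region would see a specific improvement. Headline figures for a real
deployment require that region's facility locations, incident history and
travel times, supplied through the documented file formats.
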