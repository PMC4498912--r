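---
title: "Simulating intra-urban mobility: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating intra-urban mobility: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanflow)
```

## The model

`urbanflow` simulates the movements of individual agents across a
synthetic city at 15-minute resolution. Its central assumption is that
human mobility is simultaneously *space-dependent* — destination choice
follows a gravity logic where nearby cells and cells in large land-use
clusters attract more — and *highly regular* — most trips are anchored in
a daily routine of home, work and school. Neither the heavy-tailed trip
lengths nor the emergence of popular locations is imposed top-down; both
emerge from the interaction of routine scheduling with stochastic
gravity-scored destination choice.

### Space

The city is a lattice of square cells (default 100 × 100 cells of
25 m, i.e. a 2.5 × 2.5 km city-centre scale). Six land uses partition the
grid under fixed quotas and maximum-cluster-size caps (cells / max
cluster): residential 3,400 / 1,000; employment 1,000 / 500; public
buildings 1,200 / 200; mixed residential–employment–retail 2,400 / 300;
entertainment & retail 800 / 40; public open space 1,200 / 100.

Allocation is seed-and-grow: a list of cluster specifications (land use +
target size) is drawn first, then specs are placed in random order, each
growing from a random vacant seed cell by annexing uniformly chosen
vacant von-Neumann neighbours until the target size is reached or the
cluster is walled in, in which case the shortfall is re-queued as a new
spec of the same land use. This guarantees exact quota conservation and
full coverage. Because independently placed clusters of one land use can
become adjacent, the allocator additionally tracks merged same-use
connected components with a union-find structure and refuses any seeding
or annexation that would push a component past its land use's cap — so
the cap is a property of the *realized* map, not merely of the spec
list. On the rare end-game layouts where no queued land use can legally
occupy a remaining vacant pocket, the allocation restarts with a fresh
random arrangement (in practice one attempt almost always suffices).

Cluster target sizes are drawn from a per-land-use size distribution.
Which land uses follow a normal versus an exponential law, and with what
parameters, is an open choice; the default is exponential with mean
`max_cluster / 3`, truncated to `[1, max_cluster]`, for every land use —
this yields many small clusters and few large ones, the pattern typical
of parcel-level zoning maps, and is configurable per land use.

Each cell *i* carries a specific attractiveness θᵢ ~ N(1.0, 0.05),
truncated below at 0.05 so the destination score stays positive. The
mean/sd are defaults chosen to put typical values near unity (the worked
example value 0.93 is about 1.4 sd below the mean); they are
configurable.

### Time

A week has 5 working days and a 2-day weekend; a model month is 4 weeks
(2,688 iterations of 15 minutes). Days divide into six periods: morning
06:00–12:00, morning rush 07:30–09:30, noon 12:00–17:00, evening rush
17:00–19:00, evening 19:00–22:00, night 22:00–06:00. The printed morning
and morning-rush windows overlap; we resolve this by giving the rush
window precedence inside the morning, with all intervals half-open. The
run starts Monday 00:00.

### Agents

Four archetypes — teenagers, bachelors, married people, seniors — with
default shares 0.15 / 0.25 / 0.45 / 0.15 and employment rates 0 / 0.60 /
0.85 / 0.30 (teenagers study instead). Homes are uniform over
residential and mixed cells. Teenagers and non-working (student)
bachelors anchor at a public-building cell; working agents anchor at
employment or mixed cells, with probability 0.05 each of a
public-building or entertainment workplace. Every agent favors 40 cells
drawn uniformly from the whole grid. The shares and rates are defaults
(the population mix is configurable); they were picked once as a
plausible city-centre demography and are not fitted.

### Movement

Stage 1 (move or stay): on weekdays from 06:00 until their scheduled
departure, anchored agents away from their anchor move with the routine
probability 0.95; at the departure iteration an agent sitting at its
anchor leaves with the same probability. Departures encode working
hours: teenagers leave school at 14:00, working seniors at 13:00
(shorter hours), other workers at 17:00. In every other situation the
agent draws against a move probability specific to its type, the period
and its location context (at home / at anchor / elsewhere).

Stage 2 (where to): routine movers go to their anchor. Other movers
first draw "head home" with a type- and period-specific stay-home
probability (an agent already at home then simply stays, generating no
event). Otherwise a land use is drawn from the type × period weights and
every candidate cell of that use is scored with

IACᵢ = d^δᵢ · g^γᵢ · θᵢ · mᵢ · f,

with d = 0.95, g = 1.02, δᵢ the raw Euclidean distance in cell units
from the agent's position (the worked example — δ = 27.22, γ = 29,
θ = 0.93, m = 1.03, f = 1 → IAC = 0.42 — is reproduced exactly under
this reading, so no further normalization is applied), γᵢ the size of
the cell's *connected* land-use cluster, mᵢ ~ N(1, 0.05) truncated at
0.5 drawn fresh per candidate cell per decision (the subscript-i reading
of the mood factor), and f = 1.5 on the agent's 40 favored cells. Cells
are ranked by IAC with ties broken by cell index, and the destination is
drawn uniformly from the top 10. The agent's current cell is never a
candidate. Agents update in a fresh random permutation each iteration to
avoid positional artifacts. Trips are point-to-point on the grid; no
routing, congestion or transport-mode choice is modelled.

## The behavioural tables

The full 4 × 6 tables of move probabilities, land-use choice weights and
stay-home probabilities ship as an editable CSV rather than constants in
code. They are *reconstructed defaults*: the published constraints pin
only two cross-type ratios (married : teenager public-building weight at
morning rush = 2.5; bachelor : married entertainment weight at night
= 25) plus qualitative structure (very high routine-morning movement, low
night-time movement). Everything else was set once to plausible values —
e.g. evening entertainment weights peak for bachelors, night stay-home
probabilities are high for married people and seniors — and validated
only against the invariants (`validate_probability_table()` checks
ranges, normalization and both ratios). Consequently the package targets
the *qualitative* emergent statistics, not magnitudes that depend on the
exact tables (such as absolute visit counts per cell).

## Numerical and design choices

- **Adjacency** for cluster growth, components and boundary distances is
  the 4-neighbour von Neumann lattice (simplest contiguity reading;
  8-neighbour Moore is available via a parameter).
- **Boundary distance** of a cell is the minimum number of lattice steps
  to any cell of a different land use (1 = touches a boundary), computed
  by multi-source BFS; on a single-land-use grid it is undefined and
  reported as absent.
- **Visits** are counted per arrival: each movement event credits its
  destination once, and each agent's starting home counts as one initial
  visit. Staying put accrues nothing. Occupancy-time weighting would
  inflate counts at long-dwell locations and is not used.
- **Tail fitting** is a continuous power-law MLE (Hill estimator) with
  the lower cutoff chosen by KS minimization over up to 100 candidate
  cutoffs below the top decile, and a Vuong-style normalized
  likelihood-ratio comparison against a shifted-exponential tail fitted
  on the same data. On 10,000 synthetic Pareto(α = 2.5) draws the
  estimator recovers α within ±0.15; on exponential data the comparison
  favors the exponential.
- **Seeds**: a master seed determines everything; per-run seeds in
  batches are derived as `(master · 69069 + 104729 · run) mod 2³¹ − 1`,
  with run 0 reserved for the environment so batches share one city while
  regenerating agents ("same city, new people").
- **Tie-breaks** in IAC ranking and rank-size tables are by cell index,
  making every output deterministic given the seed.

## Scale of the shipped checks

The full study scale is 10,000 agents over a 28-day model month (and
20-run batches). The package's test suite exercises the complete
pipeline at a reduced scale chosen to keep the checks sharp but cheap:
a 500-agent, 7-day run for the emergent statistics (with visit
thresholds scaled pro rata by the 80-fold difference in agent-days),
50 × 50 or smaller grids for allocation properties, and oracle
equivalence on 20 × 20 grids. At that scale the shipped defaults
produce ~15 movements per agent-day, 67% of trips under 500 m, fewer
than 0.2% over 2.5 km, at least one non-home repeat location for every
agent, and a three-tier popularity partition whose top tier sits on
land-use boundaries — the same qualitative signatures reported for the
full scale.

## What the synthetic data does and does not show

The generator emulates a statistically plausible city-centre — quota-true
land-use mixing, many-small/few-large cluster size structure,
heterogeneous attractiveness — and a demographically structured
population. It does not emulate street networks, intervening
opportunities, transport modes, household structure or inter-agent
interaction, and its behavioural tables are reconstructions. Passing
tests therefore demonstrate that the mechanism (routine + gravity-scored
irregular movement) generates the observed empirical signatures; they do
not calibrate the model to any real city, and absolute magnitudes
(total visits, exact tier sizes) should be read as scale- and
table-dependent.

## Limitations

- The three-tier popularity thresholds (10,000 / 1,000 visits per month)
  are scale-bound: at other agent counts or run lengths they must be
  rescaled by agent-days, as the test suite does.
- The allocator's bound-preserving growth makes large max-cluster caps
  slightly harder to saturate on small grids (components stop just below
  the cap); quotas are still met exactly.
- Pure-R stepping handles the reduced scales comfortably (a 500-agent
  week in under half a minute); full-scale months are feasible but
  batch-level parallelism is left to the caller.
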