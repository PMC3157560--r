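---
title: "Measuring movement anisotropy in 3D foraging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring movement anisotropy in 3D foraging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forage3d)
```

## The problem

Surface-dwelling rodents are excellent climbers, and a foraging journey
on a vertical or volumetric structure has to trade horizontal travel
against energetically costly vertical travel. The behavioural question
this package operationalises is whether foragers treat the dimensions
isotropically or organise retrieval horizontally — emptying one layer
before moving up or down. Two discretised apparatuses are modelled: a
vertical pegboard analysed as a 5 × 5 grid of 20 cm reward regions
(axes X horizontal, Z vertical), and a 50 cm cubic lattice of
4 × 4 × 4 cubes of 12.5 cm edge (X, Y horizontal, Z vertical). Grid
indices are 0-based with the origin at the front lower-left corner.

## Ordinal distances

Every retrieved food item carries an ordinal number $x \in \{1..N\}$,
its rank in the visit order. For band $k$ along a grouping axis
(layers: constant Z; pegboard columns: constant X; lattice slices:
constant Y or constant X) with $n \ge 2$ retrieved items,

$$\mathrm{OD}_k = \frac{\sum_{i<j} |x_i - x_j|}{n(n-1)/2}, \qquad
\mathrm{OD} = \frac{1}{p}\sum_{k=1}^{p} \mathrm{OD}_k,$$

with $p$ the number of bands holding at least two items; sparser bands
are skipped, and a sequence with $p = 0$ is rejected. Useful
calibration points, all verified in the test suite:

* a strict row-boustrophedon over the pegboard gives layer OD exactly
  2.0 and column OD exactly 10.0;
* a uniformly random complete order has expected OD $(N+1)/3$ on every
  axis ($26/3 \approx 8.67$ for $N = 25$), the Monte-Carlo null
  implemented by `od_expectation_random()`;
* OD is invariant under reversal of the visit order.

Raw ODs conflate strategy with route economy — any short route is
locally clustered — so observed sequences are compared to a
distance-optimal route on the *same* layout via the ratio
observed/optimised (`od_ratio()`), formed per trial and then averaged.

## The distance-optimal reference

`evolve()` searches for the shortest *open* route (no return leg;
foragers do not return to the start) through a trial's baited
positions with a mutation-only genetic algorithm: 100 random routes;
each generation the population is randomly partitioned into 25
disjoint quartets, each quartet's shortest route survives and produces
three offspring by reversing a random contiguous segment (flip),
exchanging its endpoints (swap), and rotating it by one position
(slide); the segment is drawn once per survivor, positions 2..N only.
The search restarts from scratch and the overall incumbent is
returned. The first retrieval position is fixed to the baited position
adjacent to the start on the X axis (operationally: the baited
position nearest the centre of the grid cell one X step inward from
the start corner at equal height), and is never mutated.

Defaults are 20 restarts × 2000 generations. On 24–25 position
instances this is already converged: doubling both changes no best
length in spot checks, and on ≤ 8-position instances the GA matches an
exhaustive permutation oracle in ≥ 95% of seeded runs (it scored
50/50 in the frozen suite). Distances are Euclidean over physical
coordinates in cm — over the jittered peg positions, not region
centres, since the optimal reference should traverse the same points
the forager does. Because the objective is isotropic, the reference
carries no horizontal/vertical bias beyond the anchor's X
displacement; see the limitations section for what that displacement
does.

## Crossing counts

`bin_trajectory()` maps timestamped positions to grid cells
(half-open cells, `floor(coord/cell)`, boundary samples to the
higher-index bin, outer edge clamped; consecutive duplicates
collapsed; an optional running-median filter of odd width is available
and off by default, since no specific smoothing kernel is assumed).
`count_crossings()` accumulates per-axis absolute index changes; a
diagonal bin change increments every changed axis. For retrieval
routes, consecutive positions are connected by the straight segment
between cell centres rasterised onto the grid — a straight segment is
monotone along each axis, so the per-axis count equals the summed
absolute index difference. Counts are invariant to time
reparametrisation and to reversal.

## Synthetic data: what it emulates and what it does not

`generate_layout()` implements the two baiting protocols: every one of
the 25 pegboard regions baited on one of its four pegs (offsets of
±5 cm per axis from the region centre, drawn uniformly per trial), and
24 lattice positions drawn uniformly as 6 of the 25 intersection
points of each of the 4 layers. "Semi-random" placement is read as
uniform draws under those quotas — the quotas are the only stated
constraints. Lattice intersections are snapped to the nearest cube for
grid-level analyses (ties toward the lower index; the layer index is
the protocol's own). Start corners are balanced across trials (all
four pegboard corners; bottom and top lattice corners at the same
horizontal position, the vertical contrast being the one under study).

`simulate_visits()` provides four agents — layer-sweeping and
column-sweeping boustrophedons, a uniformly random order, and greedy
nearest-neighbour — all anchored at the baited position nearest the
start so synthetic, optimised and hand-recorded sequences stay
comparable. `visits_to_trajectory()` turns a visit order into a
constant-speed piecewise-linear track (defaults 10 Hz, 10 cm/s — the
scale of a rat moving briskly between pegs); crossing counts are
invariant to both choices. `simulate_detours()` draws Bernoulli
horizontal-first choices per direction condition.

Deliberately not modelled: trial time-outs (synthetic agents always
complete; the OD machinery tolerates incomplete sequences through the
$n \ge 2$ band rule), revisits to emptied positions, biomechanics,
thigmotaxis, or any speed/dwell structure. Passing tests therefore
demonstrate the correctness and discriminative power of the measures
on idealised complete foraging runs, not behavioural realism.

## What complete sequences can and cannot reproduce

A finding that shapes how pooled magnitudes should be read: for any
complete 25-visit pegboard sequence, exhaustive enumeration on a 3 × 3
toy grid and simulated annealing on the full grid show that

$$\mathrm{OD}_\text{layer} + \mathrm{OD}_\text{column} \ge 12,$$

with equality exactly at the boustrophedon. Clustering in layers can
only be bought by dispersing columns and vice versa. Consequently *any*
ensemble of complete sequences — including distance-optimal ones — has
layer and column ODs that average at least 6 jointly. The pooled
GA references here sit at about 6.4–7.3 per axis (and 6.2–7.7 on the
lattice), and published control values near 5.1 on both pegboard axes
can only arise from sequences carrying fewer ordinals, e.g. truncated
trials in which only a subset of items was retrieved before a time-out:
scaling by the random-order expectation $(N+1)/3$, ODs of ~5.1
correspond to $N \approx 19$ of 25. Since no retrieval-count
distribution is available to calibrate such truncation, the package
reports complete-sequence values and this bound rather than imitating
truncated magnitudes. The *contrasts* that carry the scientific
conclusions — layer vs column/slice symmetry of the gravity-blind
reference, agent classification by ratios, crossing anisotropy — are
unaffected by the bound and are what the acceptance checks assert.

## The anchor and axis symmetry

With the first position anchored one X step inward from the start
corner, the ensemble of optimal routes is not exactly X/Z exchange
symmetric: pooled pegboard references show a layer−column OD
difference of order 1 with a strong negative per-layout correlation
(r ≈ −0.96) between the two — each optimal route tends to sweep one
axis, which axis being decided by the jitter. The pooled contrast
stays within 3 SEM and X vs Z crossings show no significant paired
difference, which is the symmetry property asserted by the acceptance
suite. Anchoring at the corner region itself (the other defensible
reading of "adjacent to the start") restores exact distributional
symmetry; the X-displaced rule is kept because it is the stated one.

## Statistics

The report layer uses per-rat means as the experimental unit by
default (a per-trial switch is a matter of passing different vectors):
`paired_compare()` (paired t), `two_factor_anova()` (balanced
fixed-effects ANOVA, rejecting unbalanced designs rather than choosing
a sum-of-squares type silently), `oneway_anova_bonferroni()` (pairwise
pooled-variance t-tests, p-values multiplied by the number of pairs
and capped at 1), `tally_choices()` (exact binomial intervals;
incomplete trials leave the denominator), and
`per_rat_proportion_test()` (one-sample t on per-rat proportions,
df = rats − 1; a degenerate all-identical set returns t = 0 or ±∞
explicitly rather than erroring mid-pipeline). Under 10,000-seed null
simulations all three inferential tests hold 5% ± 1.5% type-I error,
asserted in the acceptance suite.

## Numerical choices and degenerate inputs

* Seeds: every generator takes an explicit integer seed and restores
  the caller's RNG state; pipeline children derive seeds by fixed
  offsets from one master seed. The GA consumes R's RNG inside
  compiled code, so `set.seed()` governs it too.
* Ties: greedy agents and intersection snapping break ties toward the
  lower (row-major) index; the GA breaks length ties by first
  discovery.
* Problem sizes: pooled reference runs use 80 layouts per maze (40 in
  the workflow scripts) at 20 × 2000 GA settings — chosen as the point
  where pooled SEMs (~0.15–0.3) are small against the contrasts of
  interest.
* Degenerates rejected with messages: empty trajectories, p = 0
  sequences, non-permutation routes, zero-variance paired differences,
  unbalanced two-factor designs, single-bait optimisations, invalid
  corners and modes.

## Known limitations

* Complete-sequence magnitudes are bounded away from truncated-trial
  magnitudes (see above); only contrasts, not raw pooled ODs, should
  be compared across protocols that differ in completeness.
* The movement model behind synthetic trajectories is straight-line
  constant-speed travel; occupancy or dwell-time measures would need a
  richer generator.
* The detour module models choices as independent Bernoulli draws;
  sequential effects (the documented first-trial novelty response) are
  outside its scope.
* Offset-barrier contrasts are reported as per-condition proportions
  with exact intervals; no mixed-effects modelling is attempted.
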