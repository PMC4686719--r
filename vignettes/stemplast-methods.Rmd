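---
title: "Methods: the plasticity model, its theory, and the package's design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the plasticity model, its theory, and the package's design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemplast)
```

## The model

`stemplast` simulates tumor growth on a dynamically expanding 2D lattice
with 10 µm spacing, one cell per site. The population has two phenotypes:
cancer stem cells (CSCs), which divide symmetrically (probability `p_s`,
two CSCs) or asymmetrically (one CSC and one nonstem cell, CC), and CCs,
which carry a finite proliferation capacity ρ — a proxy for telomere length.
Every CC-rule division erodes ρ by one in both resulting cells; a CC whose
capacity has reached 0 dies at its next mitotic attempt. CCs additionally
die spontaneously with probability `alpha` per hour; CSCs are exempt from
both death routes and never erode.

Phenotypic plasticity enters at division: with probability `p_d` a dividing
CSC differentiates into a CC, and with probability `p_dd` a dividing CC
dedifferentiates into a CSC. The defining feature of the model is that the
*current* capacity is memorized across transitions — a dedifferentiating CC
becomes a CSC endowed with whatever ρ it has left, not with the founder's
initial capacity. High plasticity therefore churns capacity out of the
population: every excursion through the CC compartment costs divisions, and
a sufficiently high transition rate drives the whole tumor to spontaneous
remission.

Each hourly step visits the cells alive at the step's start in a fresh
uniformly random permutation. Per cell: (1) a CC dies with probability
`alpha`; (2) a survivor attempts proliferation with probability
`p_p = 1/24`; a CC with ρ = 0 dies at this attempt regardless of available
space, a cell with no vacant Moore (8-site) neighbor stays quiescent, and
otherwise the division executes with the daughter on a uniformly random
vacant Moore neighbor; (3) if no proliferation was attempted, the cell
migrates with probability `p_m = 15/24` to a uniformly random vacant Moore
neighbor (150 µm/day at 10 µm spacing). Defaults (`model_params()`):
ρ = 10, `alpha` = 1%, `p_s` = `p_d` = `p_dd` = 1%.

### Decisions at points the model description leaves open

Several micro-mechanics are not fixed by the verbal model; the package's
choices, isolated in one division kernel so they can be swapped, are:

* **Update order.** A random permutation per step, each cell updated at most
  once; newborns first act in the following step. This avoids double
  updates while preserving "cells are randomly selected and updated".
* **One plasticity draw per division.** The plasticity draw happens first;
  the division then proceeds under the *new* phenotype's rules. A
  just-dedifferentiated cell immediately draws symmetric vs asymmetric; a
  just-differentiated cell divides under CC rules (both cells at ρ − 1). A
  second plasticity draw in the same event is never made.
* **Capacity convention.** The CC daughter of an *asymmetric CSC division*
  inherits the CSC's ρ un-eroded; erosion applies only to CC-rule
  divisions. This is exactly the bookkeeping the branching theory needs: a
  newborn CC that dedifferentiates at its first division recreates a CSC of
  the same capacity index.
* **Exhausted differentiation.** A CSC that draws differentiation while
  holding ρ = 0 (possible only if a founder is seeded that way) dies at
  that mitotic attempt, the same rule as an exhausted CC.
* **Exhaustion beats vacancy.** The ρ = 0 death fires when proliferation is
  *drawn*, even with no vacant neighbor, and no dedifferentiation rescue is
  possible there because plasticity only occurs at successful divisions.
* **Lattice growth.** The grid expands by 50 sites on every side whenever a
  cell comes within 10 sites of an edge; expansion never moves cells.

## Branching-process theory of remission

Track the CSCs of one capacity index *i*. One division event of such a CSC
changes their number by −1, 0, +1 or +2 with probabilities

* `p1 = p_d` (the CSC differentiates and is lost),
* `p2 = (1 − p_d)(1 − p_s)[α′ + (1 − α′)(1 − p_dd)]`,
* `p3 = (1 − p_d)[p_s + (1 − p_s)(1 − α′) p_dd (1 − p_s)]`,
* `p4 = (1 − p_d)(1 − p_s)(1 − α′) p_dd p_s`,

where α′ is the probability that the CC daughter of an asymmetric division
dies before any proliferation attempt. The +1/+2 routes follow that
daughter to its first division: if it survives (1 − α′) and
dedifferentiates there (`p_dd`), it recreates a CSC of index *i*, twice if
that division is symmetric. Grand-daughters have index < *i* and cannot
contribute, which is why the recursion closes after one CC generation.
The four probabilities sum to one identically
(`branching_probabilities()` asserts this over random sweeps).

With jump-chain weights `p = p1/(p1+p3+p4)` and `q = p3/(p1+p3+p4)`, the
extinction probability *P* of the lineage satisfies
`P = p + qP² + (1 − p − q)P³`. Since `P = 1` always solves this,
`extinction_probability()` factors that root out analytically and returns
the smaller of 1 and the positive root of the remaining quadratic
`rX² + (q + r)X − p` (with `r = 1 − p − q`); this avoids polishing a double
root at criticality. When `p4 = 0` (e.g. α′ = 1) the quadratic degenerates
and `P = min(p/q, 1)`.

α′ is a *free input*, never estimated internally: it depends on spatial
inhibition and is only bounded between the hourly death rate `alpha` and 1.
Because *P* is nondecreasing in α′, certainty of extinction at the lower
bound implies certainty everywhere — which is how the certain-remission
claims are evaluated at both extremes. Absent all crowding, the hourly
death-then-proliferation rule implies
`α′ = alpha / (alpha + (1 − alpha) p_p)` (`implied_alpha_prime()`), the
value the vacancy-free consistency check uses.

`critical_plasticity()` finds the smallest `p_d = p_dd` making extinction
certain as the root of the *mean-offspring* condition `p3 + 2p4 = p1` by
bisection to 1e−10 — equivalent to detecting `P = 1` but numerically robust
at the tangency.

### The Monte Carlo oracle and its caps

`simulate_branching()` simulates the Galton–Watson process (offspring
0/1/2/3 with probabilities `p1..p4`) with per-generation binomial thinning.
A lineage that reaches the generation cap (10⁴) or the population cap
counts as surviving; the caps bias the estimate only near criticality,
where survival times are heavy-tailed. The cross-check grid in the test
suite therefore deliberately stays away from the critical manifold (mean
drift per event at least several percent at every point) — a property of
the test design, not of the estimator's honesty.

### The early-death route

A tumor can die essentially at birth: the founding CSC differentiates
before its first symmetric division and every CC descendant dies before any
dedifferentiation. `early_death_probability()` measures this on the *full
spatial simulation* (the event is defined on the simulation, and spatial
inhibition shapes the CC division counts), terminating each replicate at
extinction, at the first symmetric division, or at the first
dedifferentiation. With those two stopping rules, extinction is logically
equivalent to the event — the founder is the only CSC that can ever exist
before a stop fires — so no lineage tracking is needed, and the early
termination keeps 10⁴-replicate runs desk-scale.

## Morphometry

Migration detaches single cells from the tumor mass, so the periphery is
defined on a smoothed mask: each pixel is replaced by the mean occupancy of
its 8 Moore neighbors and thresholded at 3/8 (kept iff ≥ 3 occupied
neighbors). This *adds* vacant sites with three or more occupied neighbors
and removes isolated cells; on solid blocks the original pixels all
survive. Regions are 8-connected components with strictly more than
`min_size` pixels — 10⁴ at full scale, a parameter because desk-scale
tumors are far smaller.

The periphery is the traced *outer* boundary of each selected region
(Moore-neighbor tracing; interior holes are ignored — simulated tumors are
dense). The perimeter sums traced steps, 1 for orthogonal and √2 for
diagonal moves; circularity is `4πA/S²`. This tracer is not the estimator
used by common image-processing toolboxes (which apply corner corrections),
and chain-code lengths overestimate smooth contours by a few percent, so
the disk check accepts circularity in [0.90, 1.10]. When several regions
are selected, the pooled value uses summed areas and perimeters; per-region
rows are attached as an attribute so either convention is available.

A cell is *quiescent* iff all 8 Moore neighbors are occupied. The
boundary-proximal CSC fraction dilates the traced periphery by
`dilation_px` sites with a city-block (plus-shaped) structuring element —
all sites within L1 distance 20, i.e. 200 µm, by default — and reports the
fraction of all CSCs inside the dilated zone.

## The virtual invasion assay

Five circular wells (radius 500 µm = 50 sites) are connected in a row by
canals 100 µm wide and 400 µm long; a blind-ended canal of the same
cross-section follows the last well. Canals are centered on the axis of the
well centers (their vertical placement is not otherwise specified). Cells
may only occupy admissible sites. A single CSC starts at the center of the
first well; the run ends when any CSC occupies a terminal-canal site
("reaching the right boundary" and "entering the last blind-ended canal"
are unified into this one rule), when the population dies out, or at a
day cap. `well_plate_geometry(scale =)` shrinks all dimensions for
desk-scale cohorts, with a floor of 2 sites on canal width.

## Radiotherapy

Fractions follow the linear-quadratic model
`SF(D) = exp(−ξλ(aD + bD²))` with `a = 0.3859`/Gy, `b = 0.01148`/Gy²,
`λ = 0.1376` applied to CSCs and `ξ = 0.5` to quiescent cells (both 1
otherwise); the standard course is 30 × 2 Gy every 24 h. Choices at
unspecified points: the dose is instantaneous at the end of each 24 h
growth block; non-survivors vanish immediately (no mitotic-death delay or
lysis lag); quiescence is re-evaluated per cell at every fraction rather
than frozen at course start.

## Randomness and reproducibility

The lattice engine uses its own counter-seeded xoshiro256++ stream, derived
from `(seed, stream)` where cohort replicate *i* uses stream *i* — so every
experiment is bit-reproducible from its master seed and replicates are
independent of cohort size. Within a step the draw order is fixed: one
uniform drives the death → proliferation → migration chain (a sequential
collapse of the independent Bernoulli draws), one picks among vacant
neighbors, and two more drive the division kernel. Two components use R's
own RNG instead, because they are vector-level rather than agent-level:
the Galton–Watson oracle (binomial thinning) and the per-fraction survival
draws; both are seeded explicitly by their callers.

## What the experiments emulate — and what they do not

The experiment runners regenerate all inputs from parameters; there is no
external data. Defaults are desk-scale: cohorts of ~10–20 replicates over
120–250 days, invasion plates at `scale = 0.3`, radiotherapy on tumors
grown to 1 500–2 000 cells. The published protocol — 100 replicates, 720
days, 250 000-cell pretreatment tumors, full-size plates — is reachable
through the same functions by argument and through the CLI, but takes hours
rather than minutes; the package's tests assert *orderings and trends* at
the reduced sizes (growth acceleration and variance damping by plasticity,
invasion speed-up, majority extinction at 10% plasticity, nadir ordering
under radiotherapy) and reserve exact printed numbers for the desk-scale
quantities (extinction calculus, LQ survival values, shape metrics,
division-outcome frequencies, the early-death fraction). Passing trend
checks at reduced scale shows the mechanisms operate in the right
direction; it does not certify the full-scale magnitudes (e.g. the 16-fold
well-composition gradient or the ~20× nadir), which depend on size and
horizon.

Three scale effects deserve explicit mention. First, cohort summaries
condition on successfully grown tumors: replicates that go extinct within
the horizon are excluded from the per-day mean/SD/CV (they remain in the
replicate table), matching the standard protocol for growth curves.
Second, the invasion-versus-collapse race is geometry-dependent: at high
plasticity the population collapse is intrinsic (scale-independent in
time), while traversal time grows with plate size, so the
majority-extinction outcome only appears once the plate is large enough —
the suite uses a half-size plate, where collapse wins, rather than the
0.3-scale plate used for the speed comparisons, where traversal wins.
Third, the damping of replicate-to-replicate size variation by plasticity
is a genuinely late-time phenomenon: the plastic cohort's coefficient of
variation starts declining only after the growth phase stabilizes, and at
the horizons the test suite can afford it has not yet crossed below the
static cohort's. The suite states that expectation at its largest
affordable horizon anyway, so the one check that demands full scale is
visible rather than silently omitted.

As with any lattice model, contact inhibition is geometric, there are no
nutrient fields, no cell-cycle structure, no senescent compartment, and a
2D section stands in for a 3D tumor.

## Worked example

```{r example, eval = FALSE}
p <- model_params(p_d = 0.01, p_dd = 0.01)
sim <- simulate_tumor(p, days = 120, seed = 1)
tail(tidy(sim))
autoplot(sim)

extinction_profile(c(0, 1e-4, 1e-3, 1e-2, 0.1), alpha_prime = c(0.01, 1))
critical_plasticity(p_s = 0.01, alpha_prime = 0.01)
```
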