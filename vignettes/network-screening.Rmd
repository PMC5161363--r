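---
title: "Screening and combining regulatory sub-networks for a conditioning function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and combining regulatory sub-networks for a conditioning function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavnet)
```

## The problem

Given a biological function, which regulatory network topologies can
perform it robustly? The brute-force answer is to enumerate every signed
directed graph on a handful of nodes, attach kinetics to each edge, sample
the kinetic parameters widely, and score each topology by the fraction of
parameter sets under which it realises the function — its *Q-value*. For
three nodes there are $3^9 = 19683$ candidate topologies (each ordered node
pair, self-pairs included, is either non-regulating, activating, or
inhibiting). For four nodes the space is $3^{16} = 43046721$ and direct
enumeration becomes infeasible.

`pavnet` implements the scaling strategy of *sub-network combination* for a
Pavlovian-like conditioning function: split the function into a **learning
module** (memory turns on only when food and ring signals co-occur, and
persists after they are removed) and a **recall module** (salivation turns
on for food alone, or for memory and ring together), screen the three-node
space for each sub-function separately, and then merge the robust
sub-networks pairwise — identifying one, two or three nodes across the two
modules — into five-, four- and three-node candidates for the whole
function, subject to logical-consistency rules.

## The dynamical model

Nodes are transcriptional species with concentration $A_i \ge 0$. A
positive regulation $i \to j$ contributes a saturating activation term
$V_{ij} H[A_i, k_{ij}, n_{ij}]$ with the Hill function
$H[x, T, n] = x^n/(x^n + T^n)$; a negative regulation contributes
$k_{ij} K_{ij}^{n_{ij}} / (K_{ij}^{n_{ij}} + \alpha_{ij} A_i^{n_{ij}})$,
which supplies a basal rate $k_{ij}$ that the inhibitor suppresses. All
activation terms converging on a node are **multiplied** (AND-like
gating — one missing activator silences the promoter), inhibition terms
are **added** (OR-like), and each node degrades as $-\eta_j A_j$. A node
with no regulation and no signal has zero production: basal transcription
enters this model only through the inhibition term.

External signals (food, ring, memory) are clamped species at level 1 when
on and 0 when off, acting through their own sampled activation term on
their role-designated receiver node. They compose multiplicatively with
the receiver's activation product, with one exception taken from the
recall module's definition: the food signal *adds* to the regulation of
the salivation output, providing the OR branch of "food alone, or memory
and ring". In combined networks the food and ring signals fan out to the
receivers of both modules; a merged receiver gets a single signal term
(one physical signal, one receptor).

Parameter ranges follow the transcription-regulation convention:
$V \in [10^{-3}, 10^2]$, $k \in [10^{-6}, 1]$, $K \in [10^{-3}, 10]$,
$\alpha \in [0, 1]$, $\eta \in [10^{-12}, 1]$, $n \in [1, 3]$. Sampling is
a Latin hypercube: with $m$ draws, every scalar dimension is cut into $m$
equal-probability strata, each hit exactly once, on a $\log_{10}$ scale
except for $\alpha$ (its range touches 0) and $n$ (it spans less than one
decade; a continuous $n$ is the default, with an integer mode available).
Each topology gets an independent cube seeded by `seed XOR topology_id`,
so any slice of a screen can be reproduced or distributed in isolation.

## Simulation and numerical choices

The ODE system is integrated with `deSolve::lsoda` (adaptive,
stiff-capable) with `rtol = 1e-6`, `atol = 1e-9`, over 10000 time units
per signal condition. The right-hand side is compiled C; the ten
initial-condition replicates of a condition are stacked into one system so
a whole condition costs a single integrator call. A fixed-step integration
at step $10^{-4}$ over this span would cost $10^8$ steps per trajectory;
on these smooth Hill dynamics the adaptive solution is indistinguishable
at far lower cost (the package's tests verify free decay against the
closed form to better than $10^{-4}$ relative error). Output is sampled on
a unit grid over the evaluation window; small negative numerical
excursions (bounded in tests by $10^{-9}$) are clipped to zero. The same
`atol` doubles as the observability floor of the whole pipeline: a steady
output below it is numerical noise, counts as steady, and snaps to
exactly zero before any ratio is formed — otherwise the ratio of two
noise levels could fabricate an on state for a network with no production
path at all.

## The function tests

For each parameter set, every signal condition is simulated from 10
initial conditions with non-output nodes drawn uniformly from $[0, 50]$
and output nodes started at 0.1. The steady output value $y_0$ is the mean
over the window $[9000, 10000]$. A condition's output state is the ratio
of its steady value to the no-signal baseline: off below 5, on above 15
(5 and 10 for combined networks); a ratio between the thresholds is not
switch-like and fails the parameter set.

- **Learning**: baseline off; food-only off; ring-only off; food+ring on,
  reaching a plateau; after signal removal the output must retain at
  least 80% of that plateau at $T = 50000$ (the persistence run continues
  from the trained state — the only stage that does so).
- **Recall**: food-only on; memory-only off; ring-only off; memory+ring
  on. No persistence requirement.
- **Pavlovian (combined)**: both outputs are read simultaneously —
  baseline; food-only (salivation on, memory off); ring-only (both off);
  food+ring (memory on); persistence of memory; and finally, continuing
  from the persistent state, ring-only must now turn salivation on — the
  conditioned reflex itself.

### Steadiness and agreement: two operational readings

Two operational details dominate what the screen selects, and the package
makes both explicit configuration choices rather than burying them.

**Steadiness.** The defining rule is $|y - y_0| < 0.01\,y_0$ for a test
value $y$ taken from the window. Requiring *every* unit-grid sample to sit
inside the band (`steady_mode = "band"`) is the strictest deterministic
reading. It has a structural consequence: a persistent memory needs either
a degradation rate $\eta_M \lesssim 5\times10^{-6}$ (so the trained level
survives 40000 signal-free time units), which makes the trained output a
slow ramp that never satisfies the band, or post-removal production, which
under multiplicative gating requires input nodes that never relax — and
those break the baseline instead. Under the band rule *no* three-node
topology can pass the learning test; the screen is empty. The default is
therefore the literal reading: one test sample, drawn uniformly from the
window per parameter set (seeded, so the screen is reproducible),
`steady_mode = "point"`. Near-frozen memory nodes whose trained plateau
drifts a few percent per thousand time units then pass with the
appropriate probability, and the learning screen selects exactly the
near-integrator designs one expects. The strict band remains available
and is the default for the standalone `detect_steady_state()` /
`converged_unique_state()` operations.

**Agreement across initial conditions.** Multistable designs whose output
depends on the starting point must be rejected. Requiring the ten steady
values to agree to 1% (`ic_agreement = "value"`) again interacts badly
with near-frozen outputs, which remember their (initial-condition
dependent) approach transients: it rejects essentially every persistent
memory. The default, `ic_agreement = "class"`, requires all ten runs to
yield the same on/off classification, each judged against its own
baseline — "the same steady state" read functionally. Value agreement
remains available, and `converged_unique_state()` keeps it as its
contract.

With the survey defaults the screen produces Q-values on the expected
scale for robust topologies (about $10^{-3}$ to $10^{-2}$): at seed 1, the simplest direct learning wiring
(positive regulation from each input onto the memory node) has
$Q = 10^{-3}$ at 1000 parameter sets, the direct recall wiring has
$Q = 8\times10^{-3}$, an unwired network has $Q = 0$ everywhere, and the
learning Q is symmetric under exchanging the two input receivers (the
two signal roles are dynamically interchangeable for this module).

## Combination rules

A merge map identifies $k \in \{1,2,3\}$ learning nodes with $k$ recall
nodes (9, 18, 6 matchings before filtering). Role constraints forbid a
food receiver from doubling as a ring receiver and the memory output from
being the recall output, leaving 6 / 8 / 2 role-legal maps. A combination
is logically possible when, for every ordered pair of merged slots
(self-pairs included), the two modules' regulation signs do not
contradict (equal, or one absent). The merged network keeps the union of
both edge sets on $6 - k$ nodes. When the learning memory output is not
identified with the recall memory input, an activation edge is added from
the former to the latter so the stored state can drive recall; a
combination whose sources already inhibit that slot is rejected as
logically impossible (an interpretation this package makes explicitly —
the alternative would be an unresolvable sign conflict on the added
edge). Combinations are *not* deduplicated across provenances: counts are
counts of (pair, map) candidates, matching how combination spaces are
reported. Each emitted candidate then runs the combined Pavlovian test;
a network counts as able to perform the function when at least one
sampled parameter set passes.

## Analysis operations

**Regulation entropy** quantifies sign conflict converging on promoters:
for each node with incoming edges, the Shannon entropy (bits) of its
in-edge activation/inhibition split, averaged over regulated nodes. There is
no single canonical formula for this score, so the one here is the
package's own documented choice; only directional
comparisons are meaningful, and the tests assert the directional property
that logically-valid combined networks carry less regulation entropy than
size-matched unconstrained random networks (each ordered pair uniform
over the three states). **Clustering** of a pool flattens each topology
to its 9-entry sign vector and applies average-linkage hierarchical
clustering on Hamming distances, the natural metric for categorical sign
vectors. **Combination-space counting** is exact combinatorics (pairs
times role-legal maps), with an optional sign filter that must agree with
the length of the actual enumeration — a property the tests check against
a brute-force oracle.

## Problem sizes and what the tests show

The package's test suite and the desk-scale acceptance script run the
whole machinery at reduced sizes on one CPU: 500–1000 parameter sets per
screened topology, pools of up to ten networks for combination
enumeration, 100–200 random networks for entropy baselines. At these
sizes the suite verifies the exact combinatorial counts, the closed-form
dynamics, the Latin hypercube properties, determinism from seeds, the
truth-table logic on hand-constructed passing and failing designs (fixed
points verified analytically), and the directional entropy ordering. The
full-scale screen (19683 topologies × 10^4 parameter sets per
module, then ~10^4–10^5 combined candidates) is a cluster-scale
computation — on the order of CPU-years in total — driven by
`scripts/full_screen.R`, which shards cleanly by topology ID and reports
the headline counts (pool sizes at the 0.007 / 0.008 thresholds,
combination counts per arity, networks able to perform the combined
function, the top Q, and the Q of the four-node Boolean-logic reference
design). Desk-scale runs exercise every code path of that driver but
cannot reproduce the headline counts themselves; their Q estimates carry
binomial noise of order $\sqrt{Q/m}$.

What passing at desk scale does *not* show about real regulatory
networks: the generator's dynamics are deterministic, well-mixed
transcription kinetics with a single interaction type; no stochasticity,
no delays, no protein-level interactions, no unequal signal amplitudes.
The screen characterises the model's design space, not cellular reality.

## Known limitations

- The two operational readings discussed above change *which* designs
  pass the learning test; under the strict pair (`band` + `value`) the
  learning screen is provably empty. Cross-study comparisons should state
  the chosen modes.
- The sampled-point steadiness rule makes individual verdicts depend on
  the seeded test-point draw; Q-values are unbiased but carry slightly
  more variance than a deterministic rule would give.
- The added memory-link edge for unmerged memory nodes uses freshly
  sampled kinetics like any other edge; no further
  constraint is placed on them.
- Persistence is checked at the absolute time $T = 50000$, i.e. 40000
  units after signal removal, reading the checkpoint as a point on the
  same clock that ends training at 10000.
- `enumerate_topologies()` materialises topology objects and is capped at
  the three-node space; four-node counts are analytic, and combined
  networks are built by merging, never by four-node enumeration.
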