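---
title: "Exact minimum flow decomposition: models, variants and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact minimum flow decomposition: models, variants and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowDecomp)
```

## The problem

A splice graph built from RNA-seq alignments is a directed acyclic graph
whose edges carry read coverage.  When coverage is consistent (conserving at
every internal node), the true transcripts and their abundances form a *flow
decomposition*: a set of source-to-sink paths with positive weights whose
edge-wise superposition equals the flow.  A flow always decomposes into at
most $\min(|E|, |f|)$ paths ($|f|$ being the flow out of the source), but
the biologically meaningful question is the *minimum* number of paths —
an NP-hard problem on DAGs.

flowDecomp solves it exactly.  The key device is that candidate transcripts
are never enumerated: for a fixed number of paths $k$, each path $i$ is
represented by binary edge indicators $x_{uvi}$ constrained to form a unit
flow from source to sink (one unit leaving $s$, one entering $t$,
conservation elsewhere) — in a DAG this is a precise characterisation of an
$s$–$t$ path.  A weight variable $w_i$ and product variables
$\pi_{uvi} = w_i\, x_{uvi}$ then tie the paths to the data:
$$\sum_{i=1}^{k} \pi_{uvi} = f_{uv} \quad \text{for every edge } (u,v).$$
The product is linearised with the standard big-M construction
($\pi \le \bar w x$, $\pi \le w$, $\pi \ge w - (1-x)\bar w$, $\pi \ge 0$),
where $\bar w$ defaults to the largest edge flow — the tightest constant
that is always valid.  The model therefore has $\Theta(k\,|E|)$ variables
and constraints.  The minimum $k$ is found by a linear scan: $k$ is small in
transcript assembly, so a scan beats binary search in practice, but
`binarySearch = TRUE` is available for the problems where feasibility is
monotone in $k$.  The scan starts at a degree-based lower bound (every
positive-flow edge needs a covering path, and a path uses at most one
in-edge and one out-edge per node); `scanFromOne = TRUE` restores the
literal scan from 1.

## Variants

*Subpath and multi-leg constraints.*  Long reads give path fragments that
must appear contiguously in some transcript; paired-end and multi-end reads
give sets of fragments that must co-occur in one transcript.  Both reduce
to the same rows: a binary $r_{ij}$ per (path, constraint) with
$\sum_{(u,v) \in R_j} x_{uvi} \ge |R_j|\, r_{ij}$ and $\sum_i r_{ij} \ge 1$.
Nothing in these rows uses contiguity, which is why arbitrary edge sets
(multiple legs) work unchanged; for a one-leg constraint, containment of
all edges in a simple path implies they occur consecutively.

*Inexact flows.*  When coverage is noisy it is common to ask only that the
superposition fall in a per-edge interval $[\underline f, \bar f]$; the
per-edge equality becomes a two-sided inequality and everything else is
unchanged.

*Imperfect flows.*  Alternatively one keeps the raw (non-conserving) values
and pays for the discrepancy.  With a budget $B$ on the total absolute
error, each edge gets an error variable
$e_{uv} \ge |f_{uv} - \sum_i \pi_{uvi}|$ (two inequalities) and
$\sum e_{uv} \le B$; $B = 0$ on a conserving input collapses to the exact
model.  The problem statement can also be read as bounding each edge's
error individually; the total-error reading is the default here and the
per-edge reading is available via `perEdge = TRUE`.  The minimum-error
variant instead minimises $\sum_{uv} (f_{uv} - \sum_i \pi_{uvi})^2$, a
convex quadratic, and among all $k$ attaining the overall minimum reports
the smallest.  Because integer weights are at least 1, the optimum error is
not necessarily monotone in $k$, which is why the driver scans $k$ rather
than bisecting; it stops early only when the error hits 0, which no larger
$k$ can beat.

*Weight domains.*  Integer weights (the default) match read counts.
`weightDomain = "real"` relaxes $w_i$ to continuous values with lower bound
0 — sound for the plain problem because the scan over increasing $k$ makes
zero-weight paths harmless — but with path constraints a zero-weight path
could be added solely to satisfy a constraint, so there the weight floor is
raised to `realWeightFloor` (default 1).

## The bundled solver

No external mixed-integer solver is required: the package ships an exact
depth-first branch-and-bound written for the bounded-variable models it
builds.  Nodes are processed with bounds-consistency propagation over the
linear rows (activity bounds tighten variable domains to a fixed point,
with integer rounding); the branch order follows the model structure —
edge indicators first, path-major in topological order, so the search
effectively constructs one path at a time and the unit-flow rows prune
aggressively.  Binary variables are branched 1-first, small integer domains
by value enumeration, large ones by bisection.  For the quadratic
objective, each node is bounded below by interval arithmetic on the
per-edge terms and pruned against the incumbent; because all variables are
integral there, the search is exhaustive and the reported optimum exact.
In real-weight mode the continuous variables left free once all integers
are fixed form a small linear feasibility problem, decided by a phase-1
simplex (Bland's rule).  Consequences of this design:

* all arithmetic is on small integers, so "exact equality" in the
  validators really is exact (extraction rounds the solver's values, which
  may carry $\pm10^{-6}$ noise, and re-validates);
* the quadratic objective is supported only for all-integer models —
  combining `weightDomain = "real"` with the minimum-error variant raises a
  capability error;
* solving is deterministic: the same instance always yields the same
  decomposition (`solverSeed` and `threads` are accepted for interface
  compatibility and ignored).

Infeasible scans are the expensive case: proving that *no* k-path solution
exists cannot use the first-solution shortcut.  Two structural facts keep
this manageable: the scan upper bounds ($\min(|E|,|f|)$ exact, $|f|$ with
constraints, $|E|$ for intervals and imperfect flows), and for the
bounded-error driver the observation that any superposition of $s$–$t$
paths is conserving, so the node imbalances of the input bound the
achievable total error from below
($\sum_e e_{uv} \ge \lceil \tfrac12 \sum_v |\text{imbalance}(v)| \rceil$);
budgets below this bound are rejected without search.

## The synthetic generator

`generatePlantedInstance()` emulates how perfect splice graphs are produced
from a transcript set: sample a random topological order on `nNodes` nodes,
draw `kPlanted` distinct source-to-sink paths along it (each interior node
joins a path with probability 1/2, and every node is forced onto at least
one path so the graph has no isolated vertices), weight each path, and
superimpose.  The default weight scheme draws abundances from a lognormal
with mean $-4$ and variance $4$ on the log scale, scales by 1000 and rounds
— the standard simulated-expression setting — with rounded weights clamped
to $\ge 1$ since a zero-abundance transcript is no path.  Instances that
degenerate to a single path are re-drawn (they admit a trivial
decomposition) unless `kPlanted = 1`.  The `uniform` scheme draws integer
weights in `[weightLo, weightHi]` and is what the small oracle-checked
batches use, keeping flow values small enough for exhaustive search.

Perturbations mirror the standard simulation procedures:

* `perturbToIntervals()` draws per edge $f' \sim N(f, (\varepsilon f)^2)$
  with $\varepsilon = 0.05$ by default and forms
  $[\mathrm{round}(0.9 f'), \mathrm{round}(1.1 f')]$ (a 10% tolerance),
  clamped at 0.  Infeasible draws — checked by a lower/upper-bounded flow
  feasibility computation (a max-flow reduction, chosen over an ILP for
  speed and independence from the solver) that also demands at least one
  unit end to end — are re-drawn under an incremented sub-seed.
* `sampleSubpathConstraints()` emits, for four of the ground-truth paths,
  the shortest prefix whose interior passes three nontrivial junctions;
  instances with fewer than four truth paths are excluded via a skip
  signal.  "Nontrivial junction" is read as a node with in-degree or
  out-degree at least 2 — the nodes that survive contraction of unary
  chains — which is an interpretation, since junction structure can be
  defined on either the contracted or the raw graph.  A path with fewer
  junctions contributes the whole path.
* `perturbToImperfect()` adds rounded Gaussian noise (sd = fraction of the
  flow) and clamps at 0, keeping zero-flow edges so the topology is
  preserved.  No standard recipe exists for imperfect-flow simulation;
  this one is the package's own, chosen to break conservation mildly and
  controllably.

Everything is bit-reproducible under a fixed seed; the generator never
touches the caller's RNG stream.

What the generator does *not* emulate: read sampling, alignment artefacts,
genomic coordinates, or the long-tailed path-length distributions of real
annotation.  Passing the oracle-equivalence batteries therefore shows the
solver is correct on splice-graph-like topologies, not that real datasets
are easy; runtime on large real graphs is governed by the MIP search and is
out of scope here.

## Worked example

```{r example}
g5 <- flowNetwork(tail = c("s", "s", "a", "a", "b"),
                  head = c("a", "b", "b", "t", "t"),
                  flow = c(6, 7, 2, 4, 9), graphId = "g5")
solveMFD(g5)
```

The instance needs three paths (weights 4, 2, 7 — here the 3-decomposition
is unique as a multiset).  Relaxing the flows to intervals can reduce the
minimum:

```{r example-interval}
relaxed <- intervalFlowNetwork(
  c("s", "s", "a", "a", "b"), c("a", "b", "b", "t", "t"),
  low = c(4, 5, 0, 4, 7), high = c(6, 7, 2, 4, 9))
solveMIFD(relaxed)@minK
```

## Numerical and design choices

* Zero-flow edges are dropped at load time (`keepZeroEdges = FALSE`): the
  superposition constraint forces $\pi = 0$ on them anyway, and dropping
  shrinks the models.  Parallel edges are rejected — the variables are
  indexed by ordered node pairs, and supporting multi-edges would change
  the encoding.
* Node ids are opaque strings kept as written; the vertex-count line of
  instance files is validated with a warning, not an error, since public
  instance collections vary in whether ids are dense.
* Binary indicators are read off at threshold 0.5 and integer weights
  rounded to the nearest integer at extraction, then re-validated exactly.
* Symmetry breaking ($w_1 \le \dots \le w_k$) is off by default, matching
  the plain formulation; it never changes feasibility (path indices are
  permutation-symmetric) and is exposed as a speed knob.
* Enumeration of all optima re-solves with no-good cuts on the edge
  indicators and deduplicates decompositions as multisets of
  (path, weight) pairs, since index permutations are distinct assignments
  but the same biological answer.
* No MIP gap applies: feasibility models stop at the first witness, and the
  quadratic search is exhaustive with exact integer bounds.

## Problem sizes used by the test batteries

The oracle-checked batches use uniform weights 1–9 on 5–8 nodes with up to
4 planted paths (200 instances for the plain problem), and 5–6 nodes with
weights 1–5 and 30% noise for the imperfect-flow comparisons (50 instances;
error budgets 0–2; minimum-error scans capped at `maxK = 4` for both the
solver and the oracle, so both compute the same truncated quantity).  These
sizes keep the exhaustive oracle exact and fast; they are a property of the
test design, and the solvers themselves accept arbitrary instances.

## Known limitations

* Cyclic graphs are not supported; the path encoding characterises $s$–$t$
  paths only in DAGs.
* The bundled solver is designed for the small-to-moderate models this
  package builds; it does not implement LP-relaxation bounding, cutting
  planes or warm starts, so very large instances (hundreds of edges with
  large $k$) will be slow, and proving infeasibility over wide weight
  ranges is exponential in the worst case.
* The minimum-error driver's default scan to $|E|$ is exhaustive per $k$;
  cap it with `maxK` when the instance is not tiny.
* Real-weight mode reports solver values as-is (no rationalisation); exact
  validation applies a $10^{-9}$ tolerance there.
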