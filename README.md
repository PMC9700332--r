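# flowDecomp

Exact minimum flow decomposition (MFD) for directed acyclic graphs, aimed at
RNA-seq splice graphs and related multiassembly problems.

## The problem

A splice graph is a DAG whose edges carry read coverage.  When coverage is
consistent, the transcripts of a gene and their abundances form a **flow
decomposition**: s–t paths P₁…P_k with positive weights w₁…w_k such that for
every edge (u,v)

    f(u,v) = Σ_{i : (u,v) ∈ P_i} w_i .

Finding a decomposition with the *minimum* number of paths is NP-hard, so
practical assemblers use heuristics or restricted path sets.  flowDecomp
solves MFD exactly by integer linear programming **without enumerating
candidate paths**: for a fixed k, each path i is a set of binary edge
indicators x(u,v,i) constrained to a unit s–t flow (a precise
characterisation of an s–t path in a DAG), a weight w_i, and products
π(u,v,i) = w_i·x(u,v,i) linked by big-M linearisation, giving Θ(k·|E|)
variables.  The minimum k is found by a linear scan starting at a degree
lower bound.  Also implemented, on the same encoding:

* **subpath / paired-end / multi-end constraints** — edge sets that must
  co-occur in one reported path (`solveMFDSubpath`);
* **inexact flows** — per-edge intervals instead of exact values
  (`solveMIFD`);
* **imperfect flows** — non-conserving values with a bounded total absolute
  error (`solveImperfectBounded`) or a minimised total squared error
  (`solveImperfectMinErr`);
* **enumeration of all optima** at the minimal k
  (`enumerateOptimalDecompositions`);
* a **brute-force oracle** (`oracleMinK`) for small instances and a
  deterministic **synthetic splice-graph generator**
  (`generatePlantedInstance`, `perturbToIntervals`,
  `sampleSubpathConstraints`, `perturbToImperfect`).

Models are solved by a bundled exact branch-and-bound solver (compiled
code, no external MIP solver needed).

## Worked example

```r
library(flowDecomp)
g5 <- flowNetwork(tail = c("s", "s", "a", "a", "b"),
                  head = c("a", "b", "b", "t", "t"),
                  flow = c(6, 7, 2, 4, 9), graphId = "g5")
solveMFD(g5)
#> MfdResult [mfd] 'g5': status=solved, min k=3
#> Decomposition: 3 path(s), integer weights
#>   w=2  s-a-b-t
#>   w=4  s-a-t
#>   w=7  s-b-t
```

Three weighted paths superpose exactly to the flow (check edge (s,a):
2 + 4 = 6; edge (b,t): 2 + 7 = 9), and no 2-path decomposition exists.
Relaxing the flows to intervals can lower the minimum:

```r
relaxed <- intervalFlowNetwork(
  c("s", "s", "a", "a", "b"), c("a", "b", "b", "t", "t"),
  low = c(4, 5, 0, 4, 7), high = c(6, 7, 2, 4, 9))
solveMIFD(relaxed)@minK
#> [1] 2
```

A command-line interface over the same functions is installed under
`exec/`:

```sh
flowdecomp synth --output inst.graph --seed 3 --n-nodes 8 --k-planted 3 --weights uniform
flowdecomp mfd --graphs inst.graph
# {"graph_id":"planted_seed3","k":3,"paths":[...],"weights":[6,2,8],"status":"solved"}
```

Instance files use the benchmark edge-list dialect: a `# name` header, a
vertex count, then `tail head flow` (or `tail head low high`) per line.

## Documentation

The methods vignette (`vignettes/flow-decomposition-methods.Rmd`) describes
the encoding, the variant models, the bundled solver, the synthetic
generator and the package's design choices in detail.
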