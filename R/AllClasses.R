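# S4 classes for flow networks, decompositions, constraints, models and results.

setClassUnion("DecompositionOrNULL", "NULL")
setClassUnion("MatrixOrNULL", c("matrix", "NULL"))

#' FlowNetwork: a DAG with non-negative integer edge flows
#'
#' A directed acyclic multigraph-free graph whose edges carry non-negative
#' integer flow values.  Internal nodes of a *conserving* network satisfy flow
#' conservation (inflow equals outflow), the setting in which a flow
#' decomposition into weighted source-to-sink paths exists.  Networks read
#' from splice-graph instance files may have several in-degree-0 or
#' out-degree-0 nodes; [ensureSingleSourceSink()] reduces them to a single
#' super source/sink before solving.
#'
#' @slot graphId single identifier string.
#' @slot nodes character vector of node ids (opaque strings).
#' @slot edges `data.frame` with columns `tail`, `head` (character) and
#'   `flow` (non-negative whole numbers); at most one edge per ordered pair.
#' @slot sources,sinks nodes with in-degree 0 / out-degree 0.
#' @slot conserving `TRUE` when every internal node is balanced.
#' @slot superSource,superSink names of the super source/sink added by
#'   normalization (length 0 if none was added).
#'
#' @seealso [flowNetwork()], [checkFlowConservation()], [solveMFD()]
#' @export
setClass("FlowNetwork",
  representation(
    graphId = "character",
    nodes = "character",
    edges = "data.frame",
    sources = "character",
    sinks = "character",
    conserving = "logical",
    superSource = "character",
    superSink = "character"
  )
)

#' IntervalFlowNetwork: a DAG with per-edge flow intervals
#'
#' Variant of [FlowNetwork-class] for inexact flows: each edge carries an
#' integer interval `[low, high]` (`0 <= low <= high`) within which the
#' superposition of path weights must fall.  Used by the minimum inexact flow
#' decomposition solver [solveMIFD()].
#'
#' @slot graphId,nodes,sources,sinks,superSource,superSink as in
#'   [FlowNetwork-class].
#' @slot edges `data.frame` with columns `tail`, `head`, `low`, `high`.
#' @export
setClass("IntervalFlowNetwork",
  representation(
    graphId = "character",
    nodes = "character",
    edges = "data.frame",
    sources = "character",
    sinks = "character",
    superSource = "character",
    superSink = "character"
  )
)

#' Decomposition: weighted source-to-sink paths
#'
#' A set of s-t paths with positive weights.  In `integer` weight domain all
#' weights are positive integers; in `real` mode weights are non-negative and
#' zero-weight paths are dropped before reporting.
#'
#' @slot paths list of character vectors (node sequences).
#' @slot weights numeric vector, one weight per path.
#' @slot weightDomain `"integer"` or `"real"`.
#' @seealso [validateDecomposition()]
#' @export
setClass("Decomposition",
  representation(
    paths = "list",
    weights = "numeric",
    weightDomain = "character"
  )
)
setIs("Decomposition", "DecompositionOrNULL")

#' PathConstraint: edges that must co-occur in one decomposition path
#'
#' A constraint is a set of pairwise edge-disjoint *legs*, each a simple path
#' in the host network.  A decomposition satisfies the constraint when a
#' single path contains every edge of every leg.  One-leg constraints model
#' long-read subpath constraints; two or more legs model paired-end or
#' multi-end reads.
#'
#' @slot constraintId identifier string.
#' @slot legs list of two-column character matrices; each row is an edge
#'   `(tail, head)` of the host network, rows of a leg form a simple path.
#' @export
setClass("PathConstraint",
  representation(
    constraintId = "character",
    legs = "list"
  )
)

#' ValidationReport: result of checking a network, decomposition or constraint set
#'
#' @slot ok `TRUE` iff all residuals and imbalances are zero and no
#'   constraint is violated.
#' @slot edgeResiduals named numeric: observed superposition minus required
#'   flow per edge (for interval checks, signed distance outside the interval,
#'   0 when inside).
#' @slot nodeImbalance named numeric: inflow minus outflow per internal node.
#' @slot violatedConstraints ids of unsatisfied constraints.
#' @export
setClass("ValidationReport",
  representation(
    ok = "logical",
    edgeResiduals = "numeric",
    nodeImbalance = "numeric",
    violatedConstraints = "character"
  )
)

#' SolverConfig: options for model construction and solving
#'
#' @slot backend solver backend identifier (the bundled exact branch-and-bound
#'   solver is `"bnb"`).
#' @slot timeLimit wall-clock limit in seconds for one solve or scan.
#' @slot weightDomain `"integer"` (default, matching read counts) or `"real"`
#'   (mixed-integer variant with continuous path weights).
#' @slot weightUpperBound optional override of the big-M weight bound
#'   (`NA` = derive from the instance: the largest edge flow).
#' @slot symmetryBreaking order path weights increasingly to remove the
#'   path-index permutation symmetry (off by default, matching the plain
#'   formulation).
#' @slot threads solver threads (the bundled solver is single-threaded).
#' @slot solverSeed optional tie-break seed for the backend (`NA` = none).
#' @slot realWeightFloor lower bound imposed on weights when real-valued
#'   weights are combined with path constraints (guards against zero-weight
#'   paths that exist only to satisfy a constraint).
#' @seealso [solverConfig()]
#' @export
setClass("SolverConfig",
  representation(
    backend = "character",
    timeLimit = "numeric",
    weightDomain = "character",
    weightUpperBound = "numeric",
    symmetryBreaking = "logical",
    threads = "numeric",
    solverSeed = "numeric",
    realWeightFloor = "numeric"
  )
)

#' KfdModel: the k-flow-decomposition (I)LP for a fixed number of paths
#'
#' Container for the variables and linear constraints of the k-path model:
#' per path index i, binary edge-use indicators x[e,i] forming a unit s-t
#' flow; a weight w[i]; product variables pi[e,i] = w[i]*x[e,i] linked by
#' big-M linearisation; optional constraint-presence indicators r[i,j] and
#' per-edge error variables e[uv] for the imperfect-flow variants.  Rows are
#' stored as sparse triplets with two-sided bounds `rowLb <= A v <= rowUb`.
#'
#' @slot k number of paths.
#' @slot vars `data.frame`: `name`, `lb`, `ub`, `integer` (logical), `role`
#'   (`"x"`, `"w"`, `"pi"`, `"r"`, `"e"`), `pathIndex`, `edgeIndex`.
#' @slot conI,conJ,conV sparse triplets of the constraint matrix.
#' @slot rowLb,rowUb row bounds (use `-Inf`/`Inf` for one-sided rows).
#' @slot rowLabels row names for debugging/LP export.
#' @slot quadA,quadB optional convex quadratic objective
#'   `sum_r (quadA[r,] %*% v - quadB[r])^2` (min-error variant).
#' @slot objectiveKind `"feasibility"` or `"quadratic_error"`.
#' @slot net the (normalized) network the model was built from.
#' @slot meta list: variant, big-M value `wbar`, weight domain, branch order,
#'   attached constraints.
#' @export
setClass("KfdModel",
  representation(
    k = "numeric",
    vars = "data.frame",
    conI = "integer",
    conJ = "integer",
    conV = "numeric",
    rowLb = "numeric",
    rowUb = "numeric",
    rowLabels = "character",
    quadA = "MatrixOrNULL",
    quadB = "numeric",
    objectiveKind = "character",
    net = "ANY",
    meta = "list"
  )
)

#' SolveOutcome: result of one model solve
#'
#' @slot status `"optimal"`, `"feasible"`, `"infeasible"`, `"time_limit"` or
#'   `"error"`.
#' @slot assignment named numeric variable values (present for
#'   optimal/feasible, and for time_limit when an incumbent was found).
#' @slot objectiveValue objective value (`NA` for feasibility models).
#' @slot wallTime seconds spent in the solver.
#' @slot nodes branch-and-bound nodes explored.
#' @export
setClass("SolveOutcome",
  representation(
    status = "character",
    assignment = "numeric",
    objectiveValue = "numeric",
    wallTime = "numeric",
    nodes = "numeric"
  )
)

#' MfdResult: result of a minimal-k scan
#'
#' @slot graphId instance identifier.
#' @slot problem one of `"mfd"`, `"mfdsc"`, `"mifd"`, `"imperfect_bounded"`,
#'   `"imperfect_minerr"`.
#' @slot minK minimal number of paths (`NA` if unsolved).
#' @slot decomposition the witness [Decomposition-class] (or `NULL`).
#' @slot objective minimised squared error (min-error variant only).
#' @slot perKLog `data.frame` with one row per attempted k: `k`, `status`,
#'   `wallTime`, and `objective` where applicable.
#' @slot status `"solved"`, `"infeasible"` or `"time_limit"`.
#' @export
setClass("MfdResult",
  representation(
    graphId = "character",
    problem = "character",
    minK = "numeric",
    decomposition = "DecompositionOrNULL",
    objective = "numeric",
    perKLog = "data.frame",
    status = "character"
  )
)

#' PlantedInstance: synthetic network with known ground-truth paths
#'
#' The network equals the edge-wise superposition of the truth paths weighted
#' by the truth weights, so it is conserving by construction and its minimum
#' decomposition size is at most the number of planted paths.
#'
#' @slot network the generated [FlowNetwork-class].
#' @slot truthPaths list of node sequences (each an s-t path).
#' @slot truthWeights positive integer weights, one per truth path.
#' @slot seed the seed the instance was generated from.
#' @slot config the generator configuration used.
#' @seealso [generatePlantedInstance()]
#' @export
setClass("PlantedInstance",
  representation(
    network = "FlowNetwork",
    truthPaths = "list",
    truthWeights = "numeric",
    seed = "numeric",
    config = "list"
  )
)
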