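#' @include AllClasses.R AllGenerics.R utils.R
NULL

# ---- internal structural checks ---------------------------------------------

# Checks DAG-ness and absence of parallel edges; returns sources/sinks.
# Names one node on a cycle in the error, which is more useful than a bare
# "graph is cyclic" when debugging instance files.
.checkStructure <- function(edges, nodes, graphId) {
  if (nrow(edges) == 0L)
    .stopf("graph '%s': no edges (empty graph)", graphId,
           class = "flowDecomp_structure_error")
  key <- .edgeKey(edges$tail, edges$head)
  if (anyDuplicated(key)) {
    d <- edges[duplicated(key), , drop = FALSE][1L, ]
    .stopf("graph '%s': duplicate (parallel) edge %s -> %s", graphId,
           d$tail, d$head, class = "flowDecomp_format_error")
  }
  if (any(edges$tail == edges$head))
    .stopf("graph '%s': self-loop at node '%s' (cycle)", graphId,
           edges$tail[edges$tail == edges$head][1L],
           class = "flowDecomp_acyclicity_error")
  g <- igraph::graph_from_data_frame(edges[, c("tail", "head")],
                                     directed = TRUE, vertices = nodes)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1L)][1L]
    .stopf("graph '%s': directed cycle through node '%s'", graphId, bad,
           class = "flowDecomp_acyclicity_error")
  }
  indeg <- table(factor(edges$head, levels = nodes))
  outdeg <- table(factor(edges$tail, levels = nodes))
  list(sources = nodes[indeg == 0L], sinks = nodes[outdeg == 0L])
}

.conserving <- function(edges, nodes, sources, sinks, flowCol = "flow") {
  internal <- setdiff(nodes, c(sources, sinks))
  if (length(internal) == 0L) return(TRUE)
  imb <- .nodeImbalance(edges, internal, flowCol)
  all(abs(imb) < 1e-9)
}

.nodeImbalance <- function(edges, internal, flowCol = "flow") {
  inflow <- vapply(internal, function(v)
    sum(edges[[flowCol]][edges$head == v]), numeric(1))
  outflow <- vapply(internal, function(v)
    sum(edges[[flowCol]][edges$tail == v]), numeric(1))
  stats::setNames(inflow - outflow, internal)
}

# ---- constructors -----------------------------------------------------------

#' Construct a flow network
#'
#' @param tail,head character (or coercible) vectors of edge endpoints.
#' @param flow non-negative whole-number flow values, one per edge.
#' @param graphId identifier for the network.
#' @param nodes optional node universe; defaults to the endpoints seen, in
#'   order of first appearance.  Every node must be incident to an edge.
#' @return a [FlowNetwork-class].
#' @examples
#' g5 <- flowNetwork(tail = c("s", "s", "a", "a", "b"),
#'                   head = c("a", "b", "b", "t", "t"),
#'                   flow = c(6, 7, 2, 4, 9))
#' isConserving(g5)
#' @export
flowNetwork <- function(tail, head, flow, graphId = "graph", nodes = NULL) {
  tail <- as.character(tail); head <- as.character(head)
  if (length(tail) != length(head) || length(tail) != length(flow))
    .stopf("tail, head and flow must have equal length")
  if (any(!.isWhole(flow)) || any(flow < 0))
    .stopf("flow values must be non-negative integers",
           class = "flowDecomp_value_error")
  edges <- data.frame(tail = tail, head = head, flow = as.numeric(round(flow)),
                      stringsAsFactors = FALSE)
  seen <- unique(c(rbind(tail, head)))
  if (is.null(nodes)) nodes <- seen
  else {
    nodes <- as.character(nodes)
    if (!all(seen %in% nodes))
      .stopf("graph '%s': edge endpoints missing from node set", graphId)
    if (!all(nodes %in% seen))
      .stopf("graph '%s': isolated node(s) not allowed: %s", graphId,
             paste(setdiff(nodes, seen), collapse = ", "))
  }
  st <- .checkStructure(edges, nodes, graphId)
  methods::new("FlowNetwork", graphId = graphId, nodes = nodes, edges = edges,
               sources = st$sources, sinks = st$sinks,
               conserving = .conserving(edges, nodes, st$sources, st$sinks),
               superSource = character(0), superSink = character(0))
}

#' Construct an inexact (interval) flow network
#'
#' @inheritParams flowNetwork
#' @param low,high integer interval bounds per edge, `0 <= low <= high`.
#' @return an [IntervalFlowNetwork-class].
#' @export
intervalFlowNetwork <- function(tail, head, low, high, graphId = "graph",
                                nodes = NULL) {
  tail <- as.character(tail); head <- as.character(head)
  if (any(!.isWhole(low)) || any(!.isWhole(high)) || any(low < 0))
    .stopf("interval bounds must be non-negative integers",
           class = "flowDecomp_value_error")
  if (any(high < low))
    .stopf("interval with high < low", class = "flowDecomp_value_error")
  edges <- data.frame(tail = tail, head = head, low = as.numeric(round(low)),
                      high = as.numeric(round(high)), stringsAsFactors = FALSE)
  seen <- unique(c(rbind(tail, head)))
  if (is.null(nodes)) nodes <- seen
  st <- .checkStructure(edges, nodes, graphId)
  methods::new("IntervalFlowNetwork", graphId = graphId, nodes = nodes,
               edges = edges, sources = st$sources, sinks = st$sinks,
               superSource = character(0), superSink = character(0))
}

#' Construct a decomposition
#'
#' @param paths list of node sequences (character vectors), each an s-t path
#'   of the host network.
#' @param weights numeric weights, one per path.
#' @param weightDomain `"integer"` (positive integer weights) or `"real"`
#'   (non-negative; zero-weight paths are dropped).
#' @return a [Decomposition-class].
#' @export
decomposition <- function(paths, weights, weightDomain = c("integer", "real")) {
  weightDomain <- match.arg(weightDomain)
  paths <- lapply(paths, as.character)
  if (length(paths) != length(weights))
    .stopf("paths and weights must have equal length")
  if (weightDomain == "integer") {
    if (any(!.isWhole(weights)) || any(weights < 1))
      .stopf("integer-domain weights must be positive integers",
             class = "flowDecomp_value_error")
    weights <- round(weights)
  } else {
    if (any(weights < -1e-9))
      .stopf("real-domain weights must be non-negative",
             class = "flowDecomp_value_error")
    keep <- weights > 1e-9
    paths <- paths[keep]
    weights <- weights[keep]
  }
  methods::new("Decomposition", paths = paths, weights = as.numeric(weights),
               weightDomain = weightDomain)
}

#' Construct a path constraint
#'
#' @param net host [FlowNetwork-class] or [IntervalFlowNetwork-class].
#' @param legs a single node sequence, or a list of node sequences (each of
#'   length >= 2), or a list of two-column edge matrices.  Legs must be simple
#'   paths of `net` and pairwise edge-disjoint.
#' @param id constraint identifier.
#' @return a [PathConstraint-class].
#' @export
pathConstraint <- function(net, legs, id = "c1") {
  if (!is.list(legs)) legs <- list(legs)
  netKeys <- .edgeKey(edgeTable(net)$tail, edgeTable(net)$head)
  legMats <- lapply(legs, function(leg) {
    if (is.matrix(leg)) {
      m <- matrix(as.character(leg), ncol = 2)
    } else {
      leg <- as.character(leg)
      if (length(leg) < 2)
        .stopf("constraint leg must have at least 2 nodes")
      m <- cbind(leg[-length(leg)], leg[-1])
    }
    miss <- !(.edgeKey(m[, 1], m[, 2]) %in% netKeys)
    if (any(miss))
      .stopf("constraint '%s': edge %s -> %s not in network", id,
             m[miss, 1][1], m[miss, 2][1],
             class = "flowDecomp_structure_error")
    if (anyDuplicated(c(m[, 1][1], m[, 2])))
      .stopf("constraint '%s': leg is not a simple path", id)
    m
  })
  allKeys <- unlist(lapply(legMats, function(m) .edgeKey(m[, 1], m[, 2])))
  if (anyDuplicated(allKeys))
    .stopf("constraint '%s': legs are not edge-disjoint", id)
  if (length(allKeys) < 1) .stopf("constraint '%s': empty", id)
  methods::new("PathConstraint", constraintId = id, legs = legMats)
}

.newReport <- function(ok, edgeResiduals = numeric(0),
                       nodeImbalance = numeric(0),
                       violatedConstraints = character(0)) {
  methods::new("ValidationReport", ok = ok, edgeResiduals = edgeResiduals,
               nodeImbalance = nodeImbalance,
               violatedConstraints = violatedConstraints)
}

# ---- accessors and show methods ---------------------------------------------

#' @describeIn FlowNetwork identifier of the network
#' @param x object.
#' @export
setMethod("graphId", "FlowNetwork", function(x) x@graphId)
#' @export
setMethod("graphId", "IntervalFlowNetwork", function(x) x@graphId)
#' @export
setMethod("graphId", "MfdResult", function(x) x@graphId)

#' @describeIn FlowNetwork edge `data.frame`
#' @export
setMethod("edgeTable", "FlowNetwork", function(x) x@edges)
#' @export
setMethod("edgeTable", "IntervalFlowNetwork", function(x) x@edges)

#' @describeIn FlowNetwork node ids
#' @export
setMethod("nodeIds", "FlowNetwork", function(x) x@nodes)
#' @export
setMethod("nodeIds", "IntervalFlowNetwork", function(x) x@nodes)

#' @describeIn FlowNetwork nodes with in-degree 0
#' @export
setMethod("sourceNodes", "FlowNetwork", function(x) x@sources)
#' @export
setMethod("sourceNodes", "IntervalFlowNetwork", function(x) x@sources)

#' @describeIn FlowNetwork nodes with out-degree 0
#' @export
setMethod("sinkNodes", "FlowNetwork", function(x) x@sinks)
#' @export
setMethod("sinkNodes", "IntervalFlowNetwork", function(x) x@sinks)

#' @export
setMethod("numEdges", "FlowNetwork", function(x) nrow(x@edges))
#' @export
setMethod("numEdges", "IntervalFlowNetwork", function(x) nrow(x@edges))
#' @export
setMethod("numNodes", "FlowNetwork", function(x) length(x@nodes))
#' @export
setMethod("numNodes", "IntervalFlowNetwork", function(x) length(x@nodes))

#' @describeIn FlowNetwork whether internal nodes are balanced
#' @export
setMethod("isConserving", "FlowNetwork", function(x) x@conserving)

#' @describeIn FlowNetwork total flow |f| leaving the source(s)
#' @export
setMethod("totalFlow", "FlowNetwork", function(x)
  sum(x@edges$flow[x@edges$tail %in% x@sources]))

#' @export
setMethod("decompPaths", "Decomposition", function(x) x@paths)
#' @export
setMethod("pathWeights", "Decomposition", function(x) x@weights)
#' @export
setMethod("numPaths", "Decomposition", function(x) length(x@paths))

#' @export
setMethod("constraintLegs", "PathConstraint", function(x) x@legs)
#' @export
setMethod("constraintSize", "PathConstraint", function(x)
  sum(vapply(x@legs, nrow, integer(1))))

#' @export
setMethod("isValid", "ValidationReport", function(x) x@ok)

setMethod("show", "FlowNetwork", function(object) {
  cat(sprintf("FlowNetwork '%s': %d nodes, %d edges, |f| = %g, %s\n",
              object@graphId, length(object@nodes), nrow(object@edges),
              totalFlow(object),
              if (object@conserving) "conserving" else "non-conserving"))
  cat(sprintf("  sources: %s | sinks: %s\n",
              paste(object@sources, collapse = ","),
              paste(object@sinks, collapse = ",")))
})

setMethod("show", "IntervalFlowNetwork", function(object) {
  cat(sprintf("IntervalFlowNetwork '%s': %d nodes, %d edges\n",
              object@graphId, length(object@nodes), nrow(object@edges)))
})

setMethod("show", "Decomposition", function(object) {
  cat(sprintf("Decomposition: %d path(s), %s weights\n",
              length(object@paths), object@weightDomain))
  for (i in seq_along(object@paths))
    cat(sprintf("  w=%g  %s\n", object@weights[i],
                paste(object@paths[[i]], collapse = "-")))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %s\n", if (object@ok) "ok" else "FAILED"))
  bad <- object@edgeResiduals[object@edgeResiduals != 0]
  if (length(bad)) cat("  nonzero residuals:",
                       paste(names(bad), bad, sep = "=", collapse = ", "), "\n")
  imb <- object@nodeImbalance[object@nodeImbalance != 0]
  if (length(imb)) cat("  imbalanced nodes:",
                       paste(names(imb), imb, sep = "=", collapse = ", "), "\n")
  if (length(object@violatedConstraints))
    cat("  violated constraints:",
        paste(object@violatedConstraints, collapse = ", "), "\n")
})

setMethod("show", "MfdResult", function(object) {
  cat(sprintf("MfdResult [%s] '%s': status=%s, min k=%s%s\n",
              object@problem, object@graphId, object@status,
              ifelse(is.na(object@minK), "-", object@minK),
              ifelse(is.na(object@objective), "",
                     sprintf(", objective=%g", object@objective))))
  if (!is.null(object@decomposition)) show(object@decomposition)
})

setMethod("show", "PlantedInstance", function(object) {
  cat(sprintf("PlantedInstance (seed %d): %d planted path(s)\n",
              as.integer(object@seed), length(object@truthPaths)))
  show(object@network)
})

# ---- normalization ----------------------------------------------------------

.freshName <- function(base, nodes) {
  nm <- base
  while (nm %in% nodes) nm <- paste0(nm, "*")
  nm
}

#' Reduce a network to a single source and a single sink
#'
#' Instance files may contain several in-degree-0 or out-degree-0 nodes.  This
#' adds a super source `s*` with one edge to each source, weighted by that
#' source's total out-flow (and symmetrically a super sink `t*`), so the
#' result has a unique source and sink as the path encoding requires.  A
#' network that is already single-source single-sink is returned unchanged.
#' Conservation status is preserved: the added edges balance the former
#' sources/sinks exactly.  Paths reported by the solvers have the super
#' nodes stripped again.
#'
#' @param net a [FlowNetwork-class] or [IntervalFlowNetwork-class].
#' @return a network of the same class with unique source and sink.
#' @export
setMethod("ensureSingleSourceSink", "FlowNetwork", function(net) {
  edges <- net@edges
  src <- net@sources; snk <- net@sinks
  if (length(src) == 0L || length(snk) == 0L)
    .stopf("graph '%s': no source or no sink", net@graphId,
           class = "flowDecomp_structure_error")
  superSource <- character(0); superSink <- character(0)
  if (length(src) > 1L) {
    superSource <- .freshName("s*", net@nodes)
    add <- data.frame(tail = superSource, head = src,
                      flow = vapply(src, function(v)
                        sum(edges$flow[edges$tail == v]), numeric(1)),
                      stringsAsFactors = FALSE)
    edges <- rbind(add, edges)
  }
  if (length(snk) > 1L) {
    superSink <- .freshName("t*", c(net@nodes, superSource))
    add <- data.frame(tail = snk, head = superSink,
                      flow = vapply(snk, function(v)
                        sum(edges$flow[edges$head == v]), numeric(1)),
                      stringsAsFactors = FALSE)
    edges <- rbind(edges, add)
  }
  if (length(superSource) == 0L && length(superSink) == 0L) return(net)
  nodes <- c(superSource, net@nodes, superSink)
  st <- .checkStructure(edges, nodes, net@graphId)
  methods::new("FlowNetwork", graphId = net@graphId, nodes = nodes,
               edges = edges, sources = st$sources, sinks = st$sinks,
               conserving = .conserving(edges, nodes, st$sources, st$sinks),
               superSource = superSource, superSink = superSink)
})

#' @export
setMethod("ensureSingleSourceSink", "IntervalFlowNetwork", function(net) {
  edges <- net@edges
  src <- net@sources; snk <- net@sinks
  if (length(src) == 0L || length(snk) == 0L)
    .stopf("graph '%s': no source or no sink", net@graphId,
           class = "flowDecomp_structure_error")
  superSource <- character(0); superSink <- character(0)
  if (length(src) > 1L) {
    superSource <- .freshName("s*", net@nodes)
    add <- data.frame(tail = superSource, head = src,
                      low = vapply(src, function(v)
                        sum(edges$low[edges$tail == v]), numeric(1)),
                      high = vapply(src, function(v)
                        sum(edges$high[edges$tail == v]), numeric(1)),
                      stringsAsFactors = FALSE)
    edges <- rbind(add, edges)
  }
  if (length(snk) > 1L) {
    superSink <- .freshName("t*", c(net@nodes, superSource))
    add <- data.frame(tail = snk, head = superSink,
                      low = vapply(snk, function(v)
                        sum(edges$low[edges$head == v]), numeric(1)),
                      high = vapply(snk, function(v)
                        sum(edges$high[edges$head == v]), numeric(1)),
                      stringsAsFactors = FALSE)
    edges <- rbind(edges, add)
  }
  if (length(superSource) == 0L && length(superSink) == 0L) return(net)
  nodes <- c(superSource, net@nodes, superSink)
  st <- .checkStructure(edges, nodes, net@graphId)
  methods::new("IntervalFlowNetwork", graphId = net@graphId, nodes = nodes,
               edges = edges, sources = st$sources, sinks = st$sinks,
               superSource = superSource, superSink = superSink)
})

# ---- validators -------------------------------------------------------------

#' Check conservation of flow at every internal node
#'
#' @param net a [FlowNetwork-class].
#' @return a [ValidationReport-class] with `nodeImbalance` filled for every
#'   internal node; `ok` iff all are zero.
#' @examples
#' g5 <- flowNetwork(c("s","s","a","a","b"), c("a","b","b","t","t"),
#'                   c(6, 7, 2, 4, 9))
#' isValid(checkFlowConservation(g5))
#' @export
checkFlowConservation <- function(net) {
  stopifnot(methods::is(net, "FlowNetwork"))
  internal <- setdiff(net@nodes, c(net@sources, net@sinks))
  imb <- .nodeImbalance(net@edges, internal)
  .newReport(ok = all(abs(imb) < 1e-9), nodeImbalance = imb)
}

# superposition of weighted paths over the edges of `edges`; errors on a
# path using a missing edge or not running source-to-sink.
.superposition <- function(net, dec) {
  edges <- net@edges
  keys <- .edgeKey(edges$tail, edges$head)
  sup <- stats::setNames(numeric(nrow(edges)), keys)
  for (i in seq_along(dec@paths)) {
    p <- dec@paths[[i]]
    if (length(p) < 2)
      .stopf("path %d has fewer than 2 nodes", i,
             class = "flowDecomp_structure_error")
    if (!(p[1] %in% net@sources) || !(p[length(p)] %in% net@sinks))
      .stopf("path %d (%s) is not source-to-sink", i,
             paste(p, collapse = "-"), class = "flowDecomp_structure_error")
    if (anyDuplicated(p))
      .stopf("path %d (%s) repeats a node", i, paste(p, collapse = "-"),
             class = "flowDecomp_structure_error")
    pk <- .edgeKey(p[-length(p)], p[-1])
    miss <- !(pk %in% keys)
    if (any(miss))
      .stopf("path %d (%s) uses edge absent from the network", i,
             paste(p, collapse = "-"), class = "flowDecomp_structure_error")
    sup[pk] <- sup[pk] + dec@weights[i]
  }
  sup
}

#' Validate a decomposition against a network
#'
#' Exact mode: per edge, the residual is the superposition of path weights
#' minus the required flow; the decomposition is valid iff every residual is
#' exactly zero.  Interval mode: valid iff the superposition lies within
#' `[low, high]` on every edge; residuals report the signed distance outside
#' the interval (0 when inside).
#'
#' @param net host network ([FlowNetwork-class]; ignored for interval mode if
#'   `intervalNet` is given).
#' @param dec a [Decomposition-class].
#' @param mode `"exact"` or `"interval"`.
#' @param intervalNet the [IntervalFlowNetwork-class] for interval mode.
#' @return a [ValidationReport-class].
#' @export
validateDecomposition <- function(net, dec, mode = c("exact", "interval"),
                                  intervalNet = NULL) {
  mode <- match.arg(mode)
  if (mode == "interval") {
    inet <- if (!is.null(intervalNet)) intervalNet else net
    stopifnot(methods::is(inet, "IntervalFlowNetwork"))
    sup <- .superposition(inet, dec)
    lo <- inet@edges$low; hi <- inet@edges$high
    res <- ifelse(sup > hi, sup - hi, ifelse(sup < lo, sup - lo, 0))
    names(res) <- paste(inet@edges$tail, inet@edges$head, sep = "->")
    return(.newReport(ok = all(res == 0), edgeResiduals = res))
  }
  stopifnot(methods::is(net, "FlowNetwork"))
  sup <- .superposition(net, dec)
  res <- sup - net@edges$flow
  names(res) <- paste(net@edges$tail, net@edges$head, sep = "->")
  .newReport(ok = all(abs(res) < 1e-9), edgeResiduals = res)
}

#' Check that a decomposition satisfies path constraints
#'
#' A constraint is satisfied when a single path of the decomposition contains
#' every edge of every leg.  For one-leg constraints this is equivalent to
#' subpath containment: a simple path that contains all edges of another
#' simple path contains them consecutively.
#'
#' @param dec a [Decomposition-class].
#' @param constraints list of [PathConstraint-class] objects.
#' @param net optional host network; when supplied, constraints referencing
#'   edges absent from the network raise a structural error.
#' @return a [ValidationReport-class] whose `violatedConstraints` lists the
#'   unsatisfied constraint ids.
#' @export
validateConstraints <- function(dec, constraints, net = NULL) {
  if (methods::is(constraints, "PathConstraint")) constraints <- list(constraints)
  if (!is.null(net)) {
    netKeys <- .edgeKey(net@edges$tail, net@edges$head)
    for (cc in constraints) {
      ek <- unlist(lapply(cc@legs, function(m) .edgeKey(m[, 1], m[, 2])))
      if (!all(ek %in% netKeys))
        .stopf("constraint '%s' references an edge absent from the network",
               cc@constraintId, class = "flowDecomp_structure_error")
    }
  }
  pathKeys <- lapply(dec@paths, function(p)
    .edgeKey(p[-length(p)], p[-1]))
  violated <- character(0)
  for (cc in constraints) {
    ek <- unlist(lapply(cc@legs, function(m) .edgeKey(m[, 1], m[, 2])))
    hit <- any(vapply(pathKeys, function(pk) all(ek %in% pk), logical(1)))
    if (!hit) violated <- c(violated, cc@constraintId)
  }
  .newReport(ok = length(violated) == 0L, violatedConstraints = violated)
}

#' Degree lower bound on the size of any flow decomposition
#'
#' Every positive-flow edge must be covered by some path, and a path uses at
#' most one in-edge and one out-edge at each node; hence no decomposition can
#' have fewer paths than the maximum, over nodes, of the larger of the
#' positive-flow in-degree and out-degree.  For interval networks only edges
#' with `low > 0` force coverage and are counted.
#'
#' The minimal-k drivers start their scan here instead of at k = 1, which is
#' sound by the argument above and saves solves.
#'
#' @param net a [FlowNetwork-class] or [IntervalFlowNetwork-class].
#' @return integer lower bound (0 for a network with no forced edges).
#' @export
lowerBoundK <- function(net) {
  e <- net@edges
  pos <- if (methods::is(net, "IntervalFlowNetwork")) e$low > 0 else e$flow > 0
  e <- e[pos, , drop = FALSE]
  if (nrow(e) == 0L) return(0L)
  indeg <- table(factor(e$head, levels = net@nodes))
  outdeg <- table(factor(e$tail, levels = net@nodes))
  as.integer(max(pmax(indeg, outdeg)))
}
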