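#' @include flownet.R
NULL

#' Solver configuration
#'
#' @param backend backend identifier; `"bnb"` is the bundled exact
#'   branch-and-bound solver (the only backend available by default).
#' @param timeLimit wall-clock limit in seconds (per instance; a minimal-k
#'   scan shares it across its solves).
#' @param weightDomain `"integer"` for positive integer path weights (the
#'   read-count setting) or `"real"` for continuous weights (mixed-integer
#'   variant).
#' @param weightUpperBound optional big-M override; must be at least the
#'   largest edge flow.  `NA` derives it from the instance.
#' @param symmetryBreaking add `w_1 <= ... <= w_k` ordering rows.  Off by
#'   default to match the plain formulation; it can speed up search since
#'   path indices are otherwise permutation-symmetric.
#' @param threads reserved; the bundled solver is single-threaded.
#' @param solverSeed reserved; the bundled solver is deterministic.
#' @param realWeightFloor weight lower bound applied in real mode when path
#'   constraints are attached (default 1), preventing zero-weight paths that
#'   exist only to satisfy a constraint.
#' @return a [SolverConfig-class].
#' @export
solverConfig <- function(backend = "bnb", timeLimit = 60,
                         weightDomain = c("integer", "real"),
                         weightUpperBound = NA_real_,
                         symmetryBreaking = FALSE, threads = 1,
                         solverSeed = NA_real_, realWeightFloor = 1) {
  weightDomain <- match.arg(weightDomain)
  if (timeLimit <= 0) .stopf("timeLimit must be positive")
  methods::new("SolverConfig", backend = backend, timeLimit = timeLimit,
               weightDomain = weightDomain,
               weightUpperBound = as.numeric(weightUpperBound),
               symmetryBreaking = isTRUE(symmetryBreaking),
               threads = as.numeric(threads),
               solverSeed = as.numeric(solverSeed),
               realWeightFloor = as.numeric(realWeightFloor))
}

# topological position of each node, for a deterministic edge branch order
.topoEdgeOrder <- function(net) {
  g <- igraph::graph_from_data_frame(net@edges[, c("tail", "head")],
                                     directed = TRUE, vertices = net@nodes)
  topo <- names(igraph::topo_sort(g, mode = "out"))
  pos <- match(net@nodes, topo)
  names(pos) <- net@nodes
  order(pos[net@edges$tail], pos[net@edges$head])
}

# Shared builder for the k-path models.  variant selects how the per-edge
# superposition sum_i pi[e,i] is tied to the instance:
#   exact    -> equality with f (flow decomposition)
#   interval -> low <= sum <= high (inexact flow)
#   bounded  -> |f - sum| <= err[e], sum(err) <= B (imperfect, bounded error)
#   minerr   -> objective sum_e (f - sum)^2 (imperfect, minimum error)
.buildPathModel <- function(net, k, config, variant, B = 0) {
  if (!is.numeric(k) || length(k) != 1 || !.isWhole(k) || k < 1)
    .stopf("k must be a positive integer", class = "flowDecomp_argument_error")
  if (length(net@sources) != 1L || length(net@sinks) != 1L)
    .stopf("model requires a normalized network (unique source and sink); %s",
           "apply ensureSingleSourceSink() first")
  isInterval <- methods::is(net, "IntervalFlowNetwork")
  edges <- net@edges
  E <- nrow(edges)
  s <- net@sources; tk <- net@sinks
  intMode <- config@weightDomain == "integer"
  if (variant == "minerr" && !intMode)
    .stopf(paste("backend 'bnb' supports the quadratic objective only with",
                 "integer variables (no continuous MIQP capability)"),
           class = "flowDecomp_capability_error")
  maxFlowVal <- if (isInterval) max(edges$high) else max(edges$flow)
  wbar <- if (!is.na(config@weightUpperBound)) {
    if (config@weightUpperBound < maxFlowVal)
      .stopf("weightUpperBound %g is below the largest edge value %g",
             config@weightUpperBound, maxFlowVal)
    config@weightUpperBound
  } else switch(variant,
    exact = maxFlowVal,
    interval = maxFlowVal,
    bounded = maxFlowVal + B,
    minerr = maxFlowVal)

  nx <- k * E
  xCol <- matrix(seq_len(nx), nrow = E, ncol = k)          # [e, i]
  wCol <- nx + seq_len(k)
  piCol <- matrix(nx + k + seq_len(nx), nrow = E, ncol = k)
  errCol <- if (variant == "bounded") nx + k + nx + seq_len(E) else integer(0)
  n <- nx + k + nx + length(errCol)

  wLb <- if (intMode) 1 else 0
  vars <- data.frame(
    name = c(sprintf("x_%s_%s_%d", edges$tail[rep(1:E, k)],
                     edges$head[rep(1:E, k)], rep(1:k, each = E)),
             sprintf("w_%d", 1:k),
             sprintf("pi_%s_%s_%d", edges$tail[rep(1:E, k)],
                     edges$head[rep(1:E, k)], rep(1:k, each = E)),
             if (length(errCol)) sprintf("e_%s_%s", edges$tail, edges$head)),
    lb = c(rep(0, nx), rep(wLb, k), rep(0, nx), rep(0, length(errCol))),
    ub = c(rep(1, nx), rep(wbar, k), rep(wbar, nx),
           rep(B, length(errCol))),
    integer = c(rep(TRUE, nx), rep(intMode, k), rep(intMode, nx),
                rep(intMode, length(errCol))),
    role = c(rep("x", nx), rep("w", k), rep("pi", nx),
             rep("e", length(errCol))),
    pathIndex = c(rep(1:k, each = E), 1:k, rep(1:k, each = E),
                  rep(NA_integer_, length(errCol))),
    edgeIndex = c(rep(1:E, k), rep(NA_integer_, k), rep(1:E, k),
                  if (length(errCol)) 1:E),
    stringsAsFactors = FALSE)

  # triplet accumulator
  acc <- new.env(parent = emptyenv())
  acc$i <- vector("list", 0); acc$j <- vector("list", 0)
  acc$v <- vector("list", 0); acc$lb <- numeric(0); acc$ub <- numeric(0)
  acc$lab <- character(0); acc$r <- 0L
  addRow <- function(cols, vals, lb, ub, label) {
    acc$r <- acc$r + 1L
    acc$i[[acc$r]] <- rep.int(acc$r, length(cols))
    acc$j[[acc$r]] <- as.integer(cols)
    acc$v[[acc$r]] <- as.numeric(vals)
    acc$lb[acc$r] <- lb; acc$ub[acc$r] <- ub; acc$lab[acc$r] <- label
  }

  outS <- which(edges$tail == s)
  inT <- which(edges$head == tk)
  internal <- setdiff(net@nodes, c(s, tk))
  inE <- lapply(internal, function(v) which(edges$head == v))
  outE <- lapply(internal, function(v) which(edges$tail == v))
  for (i in 1:k) {
    # unit out-flow at s, unit in-flow at t, conservation of x inside
    addRow(xCol[outS, i], rep(1, length(outS)), 1, 1, sprintf("src_%d", i))
    addRow(xCol[inT, i], rep(1, length(inT)), 1, 1, sprintf("snk_%d", i))
    for (vi in seq_along(internal))
      addRow(c(xCol[inE[[vi]], i], xCol[outE[[vi]], i]),
             c(rep(1, length(inE[[vi]])), rep(-1, length(outE[[vi]]))),
             0, 0, sprintf("cons_%s_%d", internal[vi], i))
  }
  # per-edge superposition rows
  if (variant == "exact") {
    for (e in 1:E)
      addRow(piCol[e, ], rep(1, k), edges$flow[e], edges$flow[e],
             sprintf("flow_%d", e))
  } else if (variant == "interval") {
    for (e in 1:E)
      addRow(piCol[e, ], rep(1, k), edges$low[e], edges$high[e],
             sprintf("ival_%d", e))
  } else if (variant == "bounded") {
    for (e in 1:E) {
      addRow(c(piCol[e, ], errCol[e]), c(rep(1, k), 1), edges$flow[e], Inf,
             sprintf("errlo_%d", e))
      addRow(c(piCol[e, ], errCol[e]), c(rep(1, k), -1), -Inf, edges$flow[e],
             sprintf("errhi_%d", e))
    }
    addRow(errCol, rep(1, E), -Inf, B, "errsum")
  }
  # big-M linearization: pi = w * x
  for (i in 1:k) for (e in 1:E) {
    addRow(c(piCol[e, i], xCol[e, i]), c(1, -wbar), -Inf, 0,
           sprintf("lin1_%d_%d", e, i))
    addRow(c(piCol[e, i], wCol[i]), c(1, -1), -Inf, 0,
           sprintf("lin2_%d_%d", e, i))
    addRow(c(piCol[e, i], wCol[i], xCol[e, i]), c(1, -1, -wbar), -wbar, Inf,
           sprintf("lin3_%d_%d", e, i))
  }
  if (config@symmetryBreaking && k > 1)
    for (i in 1:(k - 1))
      addRow(c(wCol[i], wCol[i + 1]), c(1, -1), -Inf, 0, sprintf("sym_%d", i))

  quadA <- NULL; quadB <- numeric(0)
  if (variant == "minerr") {
    quadA <- matrix(0, nrow = E, ncol = n)
    for (e in 1:E) quadA[e, piCol[e, ]] <- 1
    quadB <- edges$flow
  }

  # branch path-major: the edge indicators of path 1 (in topological order)
  # first, so the search constructs one path at a time
  eo <- .topoEdgeOrder(net)
  branchOrder <- c(as.vector(xCol[eo, , drop = FALSE]), wCol, errCol,
                   as.vector(piCol))

  methods::new("KfdModel", k = as.numeric(k), vars = vars,
               conI = as.integer(unlist(acc$i)), conJ = as.integer(unlist(acc$j)),
               conV = as.numeric(unlist(acc$v)),
               rowLb = acc$lb, rowUb = acc$ub, rowLabels = acc$lab,
               quadA = quadA, quadB = quadB,
               objectiveKind = if (variant == "minerr") "quadratic_error"
                               else "feasibility",
               net = net,
               meta = list(variant = variant, wbar = wbar, B = B,
                           config = config, xCol = xCol, wCol = wCol,
                           piCol = piCol, errCol = errCol,
                           branchOrder = as.integer(branchOrder),
                           nConstraints = 0L))
}

#' Build the k-flow-decomposition model
#'
#' Encodes all s-t paths implicitly: per path index i, binary edge indicators
#' x[e,i] constrained to a unit s-t flow (one unit out of the source, one
#' into the sink, conservation elsewhere); a weight variable w[i] (integer
#' >= 1, or continuous >= 0 in real mode); and product variables
#' pi[e,i] = w[i] x[e,i] obtained by big-M linearisation with constant
#' `wbar` (default: the largest edge flow).  The flow is matched exactly:
#' for every edge, `sum_i pi[e,i] = f[e]`.
#'
#' @param net a normalized, conserving [FlowNetwork-class].
#' @param k number of paths (>= 1).
#' @param config a [SolverConfig-class].
#' @return a [KfdModel-class] (feasibility objective).
#' @examples
#' net <- flowNetwork("s", "t", 5)
#' m <- buildKfdModel(net, 1)
#' solveModel(m)@status
#' @export
buildKfdModel <- function(net, k, config = solverConfig()) {
  stopifnot(methods::is(net, "FlowNetwork"))
  if (!net@conserving)
    .stopf(paste("network is not conserving; use the imperfect-flow variants",
                 "(buildBoundedErrorModel / buildMinErrorModel)"))
  .buildPathModel(net, k, config, "exact")
}

#' Build the inexact (interval) k-decomposition model
#'
#' Identical to [buildKfdModel()] except that the per-edge equality is
#' replaced by `low[e] <= sum_i pi[e,i] <= high[e]`; the default big-M bound
#' is the largest interval upper bound.
#'
#' @param intervalNet an [IntervalFlowNetwork-class] (normalized).
#' @inheritParams buildKfdModel
#' @export
buildInexactModel <- function(intervalNet, k, config = solverConfig()) {
  stopifnot(methods::is(intervalNet, "IntervalFlowNetwork"))
  .buildPathModel(intervalNet, k, config, "interval")
}

#' Build the bounded-total-error k-decomposition model
#'
#' For imperfect flows (conservation not required): per edge a non-negative
#' error variable `e[uv] >= |f[uv] - sum_i pi[uv,i]|` (absolute value
#' linearised as two inequalities), with the total error capped:
#' `sum(e) <= B`.  `B = 0` on a conserving network collapses to the exact
#' k-decomposition model.
#'
#' @param net a normalized [FlowNetwork-class] (imperfect flows allowed).
#' @param B non-negative integer bound on the total absolute error.
#' @param perEdge apply the bound to each edge individually instead of to the
#'   total (alternative reading of the bounded-error problem).
#' @inheritParams buildKfdModel
#' @export
buildBoundedErrorModel <- function(net, k, B, config = solverConfig(),
                                   perEdge = FALSE) {
  stopifnot(methods::is(net, "FlowNetwork"))
  if (!is.numeric(B) || length(B) != 1 || B < 0 || !.isWhole(B))
    .stopf("B must be a non-negative integer",
           class = "flowDecomp_argument_error")
  m <- .buildPathModel(net, k, config, "bounded", B = B)
  if (perEdge) {
    # drop the total-sum row; per-edge bound comes from the e-variable upper
    # bounds (each e[uv] <= B already)
    keep <- m@rowLabels != "errsum"
    sel <- m@conI %in% which(keep)
    newIdx <- cumsum(keep)
    m@conI <- as.integer(newIdx[m@conI[sel]])
    m@conJ <- m@conJ[sel]; m@conV <- m@conV[sel]
    m@rowLb <- m@rowLb[keep]; m@rowUb <- m@rowUb[keep]
    m@rowLabels <- m@rowLabels[keep]
  }
  m
}

#' Build the minimum-total-squared-error k-decomposition model
#'
#' For imperfect flows: keeps all path-encoding and linearisation rows and
#' minimises the convex quadratic objective
#' `sum_e (f[e] - sum_i pi[e,i])^2`.  Requires a backend with quadratic
#' (MIQP) capability; the bundled solver provides it for all-integer models,
#' so real-valued weights raise a capability error.
#'
#' @inheritParams buildBoundedErrorModel
#' @export
buildMinErrorModel <- function(net, k, config = solverConfig()) {
  stopifnot(methods::is(net, "FlowNetwork"))
  .buildPathModel(net, k, config, "minerr")
}

#' Attach path constraints to a k-decomposition model
#'
#' For each constraint R_j and path index i a binary presence indicator
#' r[i,j] is added with
#' `sum_{(u,v) in R_j} x[uv,i] >= |R_j| r[i,j]` and `sum_i r[i,j] >= 1`,
#' where `|R_j|` counts the edges over all legs.  Legs need not be
#' contiguous, so multi-leg (paired-end / multi-end) constraints use the
#' same rows.  In real-weight mode the weight lower bound is raised to
#' `realWeightFloor` to forbid zero-weight paths that exist only to satisfy
#' a constraint.
#'
#' @param model a [KfdModel-class].
#' @param constraints list of [PathConstraint-class] (possibly empty, in
#'   which case the model is returned unchanged).
#' @return the extended [KfdModel-class].
#' @export
addPathConstraints <- function(model, constraints) {
  if (methods::is(constraints, "PathConstraint"))
    constraints <- list(constraints)
  if (length(constraints) == 0L) return(model)
  net <- model@net
  keys <- .edgeKey(net@edges$tail, net@edges$head)
  k <- model@k
  n <- nrow(model@vars)
  conI <- model@conI; conJ <- model@conJ; conV <- model@conV
  rowLb <- model@rowLb; rowUb <- model@rowUb; rowLab <- model@rowLabels
  r0 <- length(rowLb)
  rCols <- matrix(0L, nrow = k, ncol = length(constraints))
  newVars <- list()
  for (j in seq_along(constraints)) {
    cc <- constraints[[j]]
    ek <- unlist(lapply(cc@legs, function(m) .edgeKey(m[, 1], m[, 2])))
    eIdx <- match(ek, keys)
    if (anyNA(eIdx))
      .stopf("constraint '%s' references an edge absent from the network",
             cc@constraintId, class = "flowDecomp_structure_error")
    sz <- length(eIdx)
    for (i in 1:k) {
      n <- n + 1L
      rCols[i, j] <- n
      newVars[[length(newVars) + 1L]] <-
        data.frame(name = sprintf("r_%d_%s", i, cc@constraintId),
                   lb = 0, ub = 1, integer = TRUE, role = "r",
                   pathIndex = i, edgeIndex = NA_integer_,
                   stringsAsFactors = FALSE)
      r0 <- r0 + 1L
      conI <- c(conI, rep.int(r0, sz + 1L))
      conJ <- c(conJ, model@meta$xCol[eIdx, i], n)
      conV <- c(conV, rep(1, sz), -sz)
      rowLb <- c(rowLb, 0); rowUb <- c(rowUb, Inf)
      rowLab <- c(rowLab, sprintf("sc_%s_%d", cc@constraintId, i))
    }
    r0 <- r0 + 1L
    conI <- c(conI, rep.int(r0, k))
    conJ <- c(conJ, rCols[, j])
    conV <- c(conV, rep(1, k))
    rowLb <- c(rowLb, 1); rowUb <- c(rowUb, Inf)
    rowLab <- c(rowLab, sprintf("cover_%s", cc@constraintId))
  }
  vars <- rbind(model@vars, do.call(rbind, newVars))
  cfg <- model@meta$config
  if (cfg@weightDomain == "real") {
    wsel <- vars$role == "w"
    vars$lb[wsel] <- pmax(vars$lb[wsel], cfg@realWeightFloor)
  }
  meta <- model@meta
  meta$constraints <- c(meta$constraints, constraints)
  meta$nConstraints <- meta$nConstraints + length(constraints)
  meta$rCols <- if (is.null(meta$rCols)) rCols else cbind(meta$rCols, rCols)
  # branch r indicators right after the edge indicators
  xs <- meta$branchOrder[vars$role[meta$branchOrder] == "x"]
  rest <- setdiff(meta$branchOrder, xs)
  meta$branchOrder <- as.integer(c(xs, as.vector(rCols), rest))
  methods::initialize(model, vars = vars, conI = as.integer(conI),
                      conJ = as.integer(conJ), conV = as.numeric(conV),
                      rowLb = rowLb, rowUb = rowUb, rowLabels = rowLab,
                      meta = meta)
}

#' @describeIn KfdModel number of variables
#' @param x a model.
#' @export
numVariables <- function(x) nrow(x@vars)

#' @describeIn KfdModel number of constraint rows
#' @export
numConstraints <- function(x) length(x@rowLb)

setMethod("show", "KfdModel", function(object) {
  cat(sprintf("KfdModel (%s, k=%d): %d variables, %d rows, wbar=%g\n",
              object@meta$variant, as.integer(object@k),
              nrow(object@vars), length(object@rowLb), object@meta$wbar))
})
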