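#' @include solver.R
NULL

.newMfdResult <- function(graphId, problem, minK = NA_real_,
                          decomposition = NULL, objective = NA_real_,
                          perKLog = data.frame(), status = "infeasible") {
  methods::new("MfdResult", graphId = graphId, problem = problem,
               minK = as.numeric(minK), decomposition = decomposition,
               objective = as.numeric(objective), perKLog = perKLog,
               status = status)
}

# Shared linear-scan driver: tries k in increasing order within a shared
# time budget, returns at the first feasible k.
.scanMinK <- function(graphId, problem, kRange, buildFun, config,
                      binarySearch = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  log <- list()
  budget <- function() config@timeLimit - (proc.time()[["elapsed"]] - t0)
  solveAt <- function(k) {
    rem <- budget()
    if (rem <= 0) return(NULL)
    cfg <- config; cfg@timeLimit <- rem
    model <- buildFun(k)
    out <- solveModel(model, cfg)
    log[[length(log) + 1L]] <<- data.frame(k = k, status = out@status,
                                           wallTime = out@wallTime)
    list(model = model, out = out)
  }
  finish <- function(minK, dec, status)
    .newMfdResult(graphId, problem, minK = minK, decomposition = dec,
                  perKLog = do.call(rbind, log), status = status)
  if (length(kRange) == 0)
    return(finish(NA, NULL, "infeasible"))
  if (binarySearch) {
    # feasibility is monotone in k within the scan range for the exact and
    # interval problems, so bisection is sound there
    lo <- min(kRange); hi <- max(kRange)
    bestK <- NA; bestPair <- NULL
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2
      pr <- solveAt(mid)
      if (is.null(pr)) return(finish(bestK, NULL, "time_limit"))
      if (pr$out@status == "optimal") { bestK <- mid; bestPair <- pr; hi <- mid - 1 }
      else if (pr$out@status == "infeasible") lo <- mid + 1
      else return(finish(NA, NULL, "time_limit"))
    }
    if (is.na(bestK)) return(finish(NA, NULL, "infeasible"))
    dec <- extractDecomposition(bestPair$model, bestPair$out)
    return(finish(bestK, dec, "solved"))
  }
  for (k in kRange) {
    pr <- solveAt(k)
    if (is.null(pr)) return(finish(NA, NULL, "time_limit"))
    if (pr$out@status == "optimal") {
      dec <- extractDecomposition(pr$model, pr$out)
      return(finish(k, dec, "solved"))
    }
    if (pr$out@status == "time_limit")
      return(finish(NA, NULL, "time_limit"))
  }
  finish(NA, NULL, "infeasible")
}

#' Minimum flow decomposition
#'
#' Scans k upward from the degree lower bound (see [lowerBoundK()]; use
#' `scanFromOne = TRUE` for the literal scan from 1) to `min(|E|, |f|)` and
#' returns the first feasible k with its decomposition.  A conserving
#' network always decomposes within that bound (there is always a
#' decomposition with |f| unit-weight paths).
#'
#' @param net a conserving [FlowNetwork-class] (normalized automatically).
#' @param config a [SolverConfig-class].
#' @param scanFromOne start the scan at k = 1 instead of the degree bound.
#' @param binarySearch bisect on k instead of scanning linearly (feasibility
#'   is monotone in k for this problem).
#' @return an [MfdResult-class].
#' @examples
#' fan <- flowNetwork(c("s","s","s","a","b","c"), c("a","b","c","t","t","t"),
#'                    c(1, 2, 4, 1, 2, 4))
#' solveMFD(fan)
#' @export
solveMFD <- function(net, config = solverConfig(), scanFromOne = FALSE,
                     binarySearch = FALSE) {
  stopifnot(methods::is(net, "FlowNetwork"))
  if (!net@conserving)
    .stopf(paste("network is not conserving; use solveImperfectBounded()",
                 "or solveImperfectMinErr()"))
  nn <- ensureSingleSourceSink(net)
  lb <- if (scanFromOne) 1L else max(1L, lowerBoundK(nn))
  ub <- min(nrow(nn@edges), totalFlow(nn))
  .scanMinK(net@graphId, "mfd", seq_len(ub)[seq_len(ub) >= lb],
            function(k) buildKfdModel(nn, k, config), config,
            binarySearch = binarySearch)
}

#' Minimum flow decomposition with path constraints
#'
#' As [solveMFD()], with subpath / paired-end constraints attached.  The
#' scan runs up to |f| (any integer-weight decomposition has at most |f|
#' paths); if no k admits a constrained decomposition the result status is
#' `"infeasible"`.
#'
#' @inheritParams solveMFD
#' @param constraints list of [PathConstraint-class].
#' @export
solveMFDSubpath <- function(net, constraints, config = solverConfig(),
                            scanFromOne = FALSE) {
  stopifnot(methods::is(net, "FlowNetwork"))
  if (!net@conserving)
    .stopf("network is not conserving; use the imperfect-flow variants")
  nn <- ensureSingleSourceSink(net)
  lb <- if (scanFromOne) 1L else max(1L, lowerBoundK(nn))
  ub <- totalFlow(nn)
  .scanMinK(net@graphId, "mfdsc", seq_len(ub)[seq_len(ub) >= lb],
            function(k) addPathConstraints(buildKfdModel(nn, k, config),
                                           constraints),
            config)
}

#' Minimum inexact flow decomposition
#'
#' Scans k from the degree bound over edges with `low > 0` up to |E| (a
#' within-interval integral flow decomposes into at most |E| paths).
#'
#' @param intervalNet an [IntervalFlowNetwork-class].
#' @inheritParams solveMFD
#' @export
solveMIFD <- function(intervalNet, config = solverConfig(),
                      scanFromOne = FALSE, binarySearch = FALSE) {
  stopifnot(methods::is(intervalNet, "IntervalFlowNetwork"))
  nn <- ensureSingleSourceSink(intervalNet)
  lb <- if (scanFromOne) 1L else max(1L, lowerBoundK(nn))
  ub <- nrow(nn@edges)
  .scanMinK(intervalNet@graphId, "mifd", seq_len(ub)[seq_len(ub) >= lb],
            function(k) buildInexactModel(nn, k, config), config,
            binarySearch = binarySearch)
}

#' Minimum imperfect decomposition with bounded total error
#'
#' Scans k = 1..|E| and returns the first k admitting a set of weighted
#' paths whose per-edge superposition differs from the observed values by at
#' most B in total.  The degree lower bound does not apply here (an edge may
#' be left uncovered at the cost of its flow value in error), so the scan
#' starts at 1.
#'
#' @param net a [FlowNetwork-class] (conservation not required).
#' @param B non-negative integer total-error bound.
#' @inheritParams solveMFD
#' @param perEdge bound each edge's error by B individually instead of the
#'   total.
#' @export
solveImperfectBounded <- function(net, B, config = solverConfig(),
                                  perEdge = FALSE) {
  stopifnot(methods::is(net, "FlowNetwork"))
  nn <- ensureSingleSourceSink(net)
  # any superposition of s-t paths is conserving, so the node imbalances of
  # the observed flow bound the achievable total error from below:
  # sum_v |imbalance(v)| counts each edge error at most twice
  if (!perEdge) {
    imb <- .nodeImbalance(nn@edges,
                          setdiff(nn@nodes, c(nn@sources, nn@sinks)))
    if (B < ceiling(sum(abs(imb)) / 2))
      return(.newMfdResult(net@graphId, "imperfect_bounded",
                           status = "infeasible"))
  }
  .scanMinK(net@graphId, "imperfect_bounded", seq_len(nrow(nn@edges)),
            function(k) buildBoundedErrorModel(nn, k, B, config,
                                               perEdge = perEdge),
            config)
}

#' Minimum imperfect decomposition with minimum total squared error
#'
#' Computes the minimum of `sum_e (f[e] - superposition[e])^2` over
#' decompositions with k paths, for k = 1..`maxK`, and returns the smallest
#' k attaining the overall minimum together with that decomposition and
#' objective.  The scan stops early when an error of 0 is reached (it cannot
#' be improved, and smaller k were already inspected).
#'
#' @inheritParams solveImperfectBounded
#' @param maxK largest k to consider (default |E|).
#' @export
solveImperfectMinErr <- function(net, config = solverConfig(), maxK = NULL) {
  stopifnot(methods::is(net, "FlowNetwork"))
  nn <- ensureSingleSourceSink(net)
  if (is.null(maxK)) maxK <- nrow(nn@edges)
  t0 <- proc.time()[["elapsed"]]
  log <- list()
  best <- NULL
  for (k in seq_len(maxK)) {
    rem <- config@timeLimit - (proc.time()[["elapsed"]] - t0)
    if (rem <= 0) {
      return(.newMfdResult(net@graphId, "imperfect_minerr",
                           minK = if (is.null(best)) NA else best$k,
                           decomposition = best$dec, objective =
                             if (is.null(best)) NA else best$obj,
                           perKLog = do.call(rbind, log),
                           status = "time_limit"))
    }
    cfg <- config; cfg@timeLimit <- rem
    model <- buildMinErrorModel(nn, k, config)
    out <- solveModel(model, cfg)
    log[[length(log) + 1L]] <- data.frame(k = k, status = out@status,
                                          wallTime = out@wallTime,
                                          objective = out@objectiveValue)
    if (out@status == "time_limit")
      return(.newMfdResult(net@graphId, "imperfect_minerr",
                           minK = if (is.null(best)) NA else best$k,
                           decomposition = best$dec, objective =
                             if (is.null(best)) NA else best$obj,
                           perKLog = do.call(rbind, log),
                           status = "time_limit"))
    if (out@status == "optimal" &&
        (is.null(best) || out@objectiveValue < best$obj - 1e-9)) {
      best <- list(k = k, obj = out@objectiveValue,
                   dec = extractDecomposition(model, out))
    }
    if (!is.null(best) && best$obj <= 1e-9) break
  }
  if (is.null(best))
    return(.newMfdResult(net@graphId, "imperfect_minerr",
                         perKLog = do.call(rbind, log),
                         status = "infeasible"))
  .newMfdResult(net@graphId, "imperfect_minerr", minK = best$k,
                decomposition = best$dec, objective = best$obj,
                perKLog = do.call(rbind, log), status = "solved")
}

#' Enumerate optimal decompositions at a fixed k
#'
#' Repeatedly re-solves the k-decomposition model, each time adding a
#' no-good cut that excludes the previous assignment of the binary edge
#' indicators, until the model becomes infeasible or `limit` distinct
#' decompositions were collected.  Decompositions that coincide as multisets
#' of (path, weight) pairs — e.g. index permutations of one another — are
#' deduplicated.
#'
#' @param net a conserving [FlowNetwork-class].
#' @param k decomposition size (typically the solved minimum).
#' @param limit maximum number of decompositions to return (>= 1).
#' @param config a [SolverConfig-class].
#' @param constraints optional list of [PathConstraint-class].
#' @return list of [Decomposition-class].
#' @export
enumerateOptimalDecompositions <- function(net, k, limit = 100,
                                           config = solverConfig(),
                                           constraints = list()) {
  if (!is.numeric(limit) || limit < 1)
    .stopf("limit must be >= 1", class = "flowDecomp_argument_error")
  stopifnot(methods::is(net, "FlowNetwork"))
  nn <- ensureSingleSourceSink(net)
  model <- addPathConstraints(buildKfdModel(nn, k, config), constraints)
  found <- list(); sigs <- character(0)
  repeat {
    out <- solveModel(model, config)
    if (out@status != "optimal") break
    dec <- extractDecomposition(model, out)
    sig <- paste(sort(sprintf("%g|%s", dec@weights,
                              vapply(dec@paths, paste, character(1),
                                     collapse = ","))), collapse = ";")
    if (!(sig %in% sigs)) {
      sigs <- c(sigs, sig)
      found[[length(found) + 1L]] <- dec
      if (length(found) >= limit) break
    }
    model <- .addNoGoodCut(model, out@assignment)
  }
  found
}
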