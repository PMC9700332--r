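#' @include model.R
NULL

#' Solve a k-decomposition model
#'
#' Dispatches the model to the configured backend.  The bundled backend
#' `"bnb"` is an exact depth-first branch-and-bound: bounds-consistency
#' propagation over the linear rows, value enumeration / domain bisection on
#' the integer variables (edge indicators first, path-major in topological
#' order), an interval lower bound for the quadratic objective, and a
#' phase-1 simplex for any continuous variables left free at a leaf.
#'
#' @param model a [KfdModel-class].
#' @param config a [SolverConfig-class]; defaults to the configuration the
#'   model was built with.
#' @param nodeLimit optional cap on search nodes (0 = none).
#' @return a [SolveOutcome-class].  `status` is `"optimal"` when the search
#'   completed (for feasibility models: a witness was found), `"infeasible"`
#'   when exhaustion proved there is none, and `"time_limit"` when a limit
#'   was hit (with the best incumbent attached, if any).
#' @export
solveModel <- function(model, config = NULL, nodeLimit = 0) {
  if (is.null(config)) config <- model@meta$config
  if (!identical(config@backend, "bnb"))
    .stopf("solver backend '%s' is not available", config@backend,
           class = "flowDecomp_environment_error")
  n <- nrow(model@vars)
  res <- .bnb_solve_cpp(model@conI, model@conJ, model@conV,
                        length(model@rowLb), n,
                        model@rowLb, model@rowUb,
                        model@vars$lb, model@vars$ub,
                        model@vars$integer, model@meta$branchOrder,
                        model@quadA, model@quadB,
                        config@timeLimit, nodeLimit)
  status <- if (res$status == 1L) "infeasible"
            else if (res$status == 2L) "time_limit"
            else "optimal"
  assignment <- numeric(0)
  if (res$hasSolution)
    assignment <- stats::setNames(res$solution, model@vars$name)
  methods::new("SolveOutcome", status = status, assignment = assignment,
               objectiveValue = as.numeric(res$objective),
               wallTime = res$wallTime, nodes = res$nodes)
}

#' Extract the decomposition from a solved model
#'
#' For each path index the edge indicators with value >= 0.5 are walked from
#' the source to the sink (each step must offer exactly one used out-edge).
#' Integer-mode weights are rounded to the nearest integer (solver values can
#' carry tiny floating-point noise) and the result should be re-validated
#' exactly by the caller; real-mode weights are taken as is and zero-weight
#' paths are dropped.  Super source/sink nodes added by normalization are
#' stripped from the reported paths.
#'
#' @param model the solved [KfdModel-class].
#' @param outcome the [SolveOutcome-class] from [solveModel()].
#' @param net network used for reporting (defaults to the model's network).
#' @return a [Decomposition-class].
#' @export
extractDecomposition <- function(model, outcome, net = NULL) {
  if (!length(outcome@assignment))
    .stopf("outcome of status '%s' carries no assignment", outcome@status)
  if (is.null(net)) net <- model@net
  v <- outcome@assignment
  edges <- model@net@edges
  k <- as.integer(model@k)
  s <- model@net@sources; tk <- model@net@sinks
  intMode <- model@meta$config@weightDomain == "integer"
  paths <- vector("list", k)
  weights <- numeric(k)
  for (i in seq_len(k)) {
    used <- which(v[model@meta$xCol[, i]] >= 0.5)
    node <- s
    p <- node
    guard <- 0L
    while (node != tk) {
      outs <- used[edges$tail[used] == node]
      if (length(outs) != 1L)
        .stopf("x-assignment of path %d does not form a single s-t unit flow",
               i, class = "flowDecomp_extraction_error")
      node <- edges$head[outs]
      p <- c(p, node)
      guard <- guard + 1L
      if (guard > nrow(edges))
        .stopf("x-assignment of path %d does not terminate", i,
               class = "flowDecomp_extraction_error")
    }
    # strip super source/sink introduced by normalization
    ss <- model@net@superSource; st <- model@net@superSink
    if (length(ss) && p[1] == ss) p <- p[-1]
    if (length(st) && p[length(p)] == st) p <- p[-length(p)]
    paths[[i]] <- p
    wv <- v[model@meta$wCol[i]]
    weights[i] <- if (intMode) round(wv) else wv
  }
  decomposition(paths, weights,
                weightDomain = if (intMode) "integer" else "real")
}

# no-good cut excluding one binary x-assignment (used by the enumerator):
# sum over x fixed at 1 of (1 - x) + sum over x fixed at 0 of x >= 1
.addNoGoodCut <- function(model, assignment) {
  xAll <- as.vector(model@meta$xCol)
  ones <- xAll[assignment[xAll] >= 0.5]
  zeros <- xAll[assignment[xAll] < 0.5]
  r <- length(model@rowLb) + 1L
  methods::initialize(model,
    conI = c(model@conI, rep.int(r, length(xAll))),
    conJ = as.integer(c(model@conJ, zeros, ones)),
    conV = c(model@conV, rep(1, length(zeros)), rep(-1, length(ones))),
    rowLb = c(model@rowLb, 1 - length(ones)),
    rowUb = c(model@rowUb, Inf),
    rowLabels = c(model@rowLabels, sprintf("nogood_%d",
                                           model@meta$nGood %||% 1L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a model in CPLEX LP text format (for debugging)
#'
#' @param model a [KfdModel-class].
#' @param file path or connection.
#' @export
writeModelLP <- function(model, file) {
  v <- model@vars
  rows <- split(seq_along(model@conI), model@conI)
  term <- function(js, vs)
    paste(sprintf("%+g %s", vs, v$name[js]), collapse = " ")
  lines <- c("Minimize", " obj: 0", "Subject To")
  for (rn in names(rows)) {
    r <- as.integer(rn)
    js <- model@conJ[rows[[rn]]]; vs <- model@conV[rows[[rn]]]
    lb <- model@rowLb[r]; ub <- model@rowUb[r]
    lhs <- term(js, vs)
    nm <- model@rowLabels[r]
    if (is.finite(lb) && is.finite(ub) && lb == ub)
      lines <- c(lines, sprintf(" %s: %s = %g", nm, lhs, lb))
    else {
      if (is.finite(ub)) lines <- c(lines, sprintf(" %s_u: %s <= %g", nm, lhs, ub))
      if (is.finite(lb)) lines <- c(lines, sprintf(" %s_l: %s >= %g", nm, lhs, lb))
    }
  }
  lines <- c(lines, "Bounds",
             sprintf(" %g <= %s <= %g", v$lb, v$name, v$ub),
             "Generals",
             paste(" ", paste(v$name[v$integer], collapse = " ")),
             "End")
  writeLines(lines, file)
  invisible(NULL)
}
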