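#' @include flownet.R
NULL

# Brute-force reference solver.  Exponential by design; every cap overrun is
# a hard error, never a silent truncation — the oracle must not approximate.

#' Enumerate all simple s-t paths of a normalized DAG
#'
#' @param net a normalized network (unique source and sink).
#' @param cap hard limit on the number of paths (size error above it).
#' @return list of node sequences, in lexicographic order of the node ids.
#' @examples
#' g5 <- flowNetwork(c("s","s","a","a","b"), c("a","b","b","t","t"),
#'                   c(6, 7, 2, 4, 9))
#' enumerateSTPaths(g5)
#' @export
enumerateSTPaths <- function(net, cap = 10000) {
  if (length(net@sources) != 1L || length(net@sinks) != 1L)
    .stopf("network has %d sources and %d sinks; normalize first",
           length(net@sources), length(net@sinks))
  g <- igraph::graph_from_data_frame(net@edges[, c("tail", "head")],
                                     directed = TRUE, vertices = net@nodes)
  ps <- igraph::all_simple_paths(g, from = net@sources, to = net@sinks,
                                 mode = "out")
  if (length(ps) > cap)
    .stopf("path count %d exceeds the oracle cap %d", length(ps), cap,
           class = "flowDecomp_size_error")
  paths <- lapply(ps, function(p) names(p))
  # lexicographic order on node-id sequences (prefix sorts before extension)
  lev <- sort(unique(net@nodes))
  key <- vapply(paths, function(p)
    paste(sprintf("%06d", match(p, lev)), collapse = ""), character(1))
  paths[order(key)]
}

# depth-first search over integer weights for a fixed set of paths.
# M: E x j incidence (logical); bounds/mode specifics via the mode argument.
# Returns a weight vector, or NULL; for minerr returns list(obj, weights).
.oracleWeights <- function(M, mode, f = NULL, low = NULL, high = NULL,
                           B = 0, totalOut = NULL, srcMask = NULL,
                           minTotal = 0, best = Inf) {
  j <- ncol(M)
  E <- nrow(M)
  # per-path upper bounds
  ub <- vapply(seq_len(j), function(q) {
    ed <- which(M[, q])
    switch(mode,
           exact = min(f[ed]),
           interval = min(high[ed]),
           bounded = min(f[ed]) + B,
           minerr = max(max(f), minTotal))
  }, numeric(1))
  if (any(ub < 1)) {
    if (mode != "minerr") return(NULL)
  }
  lastUse <- apply(M, 1, function(r) if (any(r)) max(which(r)) else 0L)
  # edges never used must already be consistent
  un <- which(lastUse == 0L)
  if (mode == "exact" && any(f[un] != 0)) return(NULL)
  if (mode == "interval" && any(low[un] > 0)) return(NULL)
  baseErr <- if (mode == "bounded") sum(f[un]) else 0
  baseSq <- if (mode == "minerr") sum(f[un]^2) else 0
  if (mode == "bounded" && baseErr > B) return(NULL)

  w <- numeric(j)
  sup <- numeric(E)
  bestW <- NULL
  bestObj <- best

  rec <- function(q) {
    if (q > j) {
      if (mode == "exact") { bestW <<- w; return(TRUE) }
      if (mode == "interval") {
        if (all(sup >= low)) { bestW <<- w; return(TRUE) }
        return(FALSE)
      }
      if (mode == "bounded") {
        if (sum(abs(f - sup)) <= B) { bestW <<- w; return(TRUE) }
        return(FALSE)
      }
      obj <- sum((f - sup)^2)
      if (obj < bestObj - 1e-12 && sum(w) >= minTotal) {
        bestObj <<- obj; bestW <<- w
      }
      return(FALSE)
    }
    ed <- which(M[, q])
    for (val in 1:max(1, ub[q])) {
      if (val > ub[q]) break
      sup[ed] <<- sup[ed] + val
      w[q] <<- val
      ok <- TRUE
      done <- lastUse <= q
      if (mode == "exact") {
        if (any(sup[ed] > f[ed])) ok <- FALSE
        if (ok && any(sup[done] != f[done])) ok <- FALSE
        if (ok && !is.null(totalOut)) {
          rest <- j - q
          need <- totalOut - sum(w[seq_len(q)][srcPaths[seq_len(q)]])
          # paths all leave the source: remaining source paths must make up
          # exactly the remaining flow out of s
          restSrc <- sum(srcPaths[seq(q + 1, length.out = j - q)])
          if (need < restSrc || need > sum(ub[seq(q + 1, length.out = rest)][
            srcPaths[seq(q + 1, length.out = rest)]])) ok <- FALSE
        }
      } else if (mode == "interval") {
        if (any(sup[ed] > high[ed])) ok <- FALSE
        if (ok && any(sup[done] < low[done])) ok <- FALSE
      } else if (mode == "bounded") {
        over <- sum(pmax(0, sup - f))
        underDone <- sum(pmax(0, (f - sup)[done]))
        if (over + underDone > B) ok <- FALSE
      } else {
        lbObj <- sum(pmax(0, sup - f)^2) + sum(pmax(0, (f - sup)[done])^2)
        if (lbObj >= bestObj - 1e-12) ok <- FALSE
      }
      if (ok && rec(q + 1)) return(TRUE)
      sup[ed] <<- sup[ed] - val
      w[q] <<- 0
    }
    FALSE
  }
  # which paths leave the source (all of them, for s-t paths); kept for the
  # total-flow pruning rule in exact mode
  srcPaths <- rep(TRUE, j)
  rec(1)
  if (mode == "minerr") list(obj = bestObj, weights = bestW)
  else bestW
}

#' Brute-force minimum decomposition size on a tiny instance
#'
#' Exhaustively searches subsets of the enumerated s-t paths and integer
#' weight assignments, with per-edge pruning.  This is the independent
#' ground truth the solvers are tested against; it never approximates.
#'
#' For `mode = "minerr"` the search mirrors the k-path semantics of the
#' quadratic model, where two path indices may carry the same path: a
#' multiset of k paths is equivalent to at most k distinct paths whose
#' weights sum to at least k.  It returns the smallest k attaining the
#' overall minimum of the squared error.
#'
#' @param net a [FlowNetwork-class] (exact/bounded/minerr) or
#'   [IntervalFlowNetwork-class] (interval).  Normalized automatically.
#' @param constraints optional list of [PathConstraint-class]; a subset of
#'   paths is admissible only if each constraint's edges all lie on a single
#'   selected path.
#' @param mode `"exact"`, `"interval"`, `"bounded"` or `"minerr"`.
#' @param B total-error bound for `"bounded"`.
#' @param maxK largest k to try (defaults: `min(|E|, |f|)` exact, else |E|).
#' @param pathCap hard cap on enumerated paths.
#' @return list with `minK` (NA if infeasible), `objective` (minerr only)
#'   and `witness` (a [Decomposition-class] or NULL).
#' @export
oracleMinK <- function(net, constraints = NULL,
                       mode = c("exact", "interval", "bounded", "minerr"),
                       B = 0, maxK = NULL, pathCap = 10000) {
  mode <- match.arg(mode)
  nn <- ensureSingleSourceSink(net)
  paths <- enumerateSTPaths(nn, cap = pathCap)
  nP <- length(paths)
  edges <- nn@edges
  E <- nrow(edges)
  keys <- .edgeKey(edges$tail, edges$head)
  M <- vapply(paths, function(p) keys %in% .edgeKey(p[-length(p)], p[-1]),
              logical(E))
  M <- matrix(M, nrow = E)
  isInterval <- mode == "interval"
  f <- if (isInterval) NULL else edges$flow
  low <- if (isInterval) edges$low else NULL
  high <- if (isInterval) edges$high else NULL
  totalOut <- if (mode == "exact") sum(f[edges$tail == nn@sources]) else NULL
  if (is.null(maxK)) {
    # without constraints any flow decomposes within min(|E|, |f|) paths;
    # with constraints only the |f| bound (integer weights >= 1) is sound
    maxK <- if (mode == "exact") {
      if (length(constraints)) totalOut else min(E, totalOut)
    } else E
  }
  if (mode == "exact") maxK <- min(maxK, totalOut)

  conEdgeIdx <- NULL
  if (length(constraints)) {
    conEdgeIdx <- lapply(constraints, function(cc) {
      ek <- unlist(lapply(cc@legs, function(m) .edgeKey(m[, 1], m[, 2])))
      idx <- match(ek, keys)
      if (anyNA(idx))
        .stopf("constraint '%s' references an edge absent from the network",
               cc@constraintId, class = "flowDecomp_structure_error")
      idx
    })
  }
  comboAdmissible <- function(idx) {
    if (is.null(conEdgeIdx)) return(TRUE)
    all(vapply(conEdgeIdx, function(ce)
      any(vapply(idx, function(p) all(M[ce, p]), logical(1))), logical(1)))
  }
  stripSupers <- function(p) {
    if (length(nn@superSource) && p[1] == nn@superSource) p <- p[-1]
    if (length(nn@superSink) && p[length(p)] == nn@superSink)
      p <- p[-length(p)]
    p
  }
  witnessOf <- function(idx, w)
    decomposition(lapply(paths[idx], stripSupers), w)

  if (mode != "minerr") {
    kStart <- if (mode == "exact") max(1L, lowerBoundK(nn)) else 1L
    for (k in seq.int(kStart, length.out = max(0, maxK - kStart + 1))) {
      if (k > nP) break
      combos <- utils::combn(nP, k)
      for (ci in seq_len(ncol(combos))) {
        idx <- combos[, ci]
        if (!comboAdmissible(idx)) next
        w <- .oracleWeights(M[, idx, drop = FALSE], mode, f = f, low = low,
                            high = high, B = B, totalOut = totalOut)
        if (!is.null(w))
          return(list(minK = k, objective = NA_real_,
                      witness = witnessOf(idx, w)))
      }
    }
    return(list(minK = NA_real_, objective = NA_real_, witness = NULL))
  }

  # minerr: E_k = min over <= k distinct paths with weights summing to >= k
  bestObj <- Inf; bestK <- NA; bestWit <- NULL
  for (k in seq_len(maxK)) {
    ek <- Inf; ekWit <- NULL
    for (j in seq_len(min(k, nP))) {
      combos <- utils::combn(nP, j)
      for (ci in seq_len(ncol(combos))) {
        idx <- combos[, ci]
        if (!comboAdmissible(idx)) next
        r <- .oracleWeights(M[, idx, drop = FALSE], "minerr", f = f,
                            minTotal = k, best = ek)
        if (!is.null(r$weights)) {
          ek <- r$obj
          ekWit <- witnessOf(idx, r$weights)
        }
      }
    }
    if (ek < bestObj - 1e-12) {
      bestObj <- ek; bestK <- k; bestWit <- ekWit
    }
    if (bestObj <= 1e-12) break
  }
  list(minK = bestK, objective = bestObj, witness = bestWit)
}
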