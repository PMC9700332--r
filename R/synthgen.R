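#' @include flownet.R
NULL

#' Generator configuration for synthetic splice-graph instances
#'
#' The generator plants a known set of weighted source-to-sink paths on a
#' random DAG and emits their superposition, emulating how perfect splice
#' graphs are built from a transcript set with abundances.  The default
#' weight scheme draws abundances from a lognormal distribution with mean -4
#' and variance 4 on the log scale, multiplies by 1000 and rounds — the
#' standard simulated-expression setting — clamping rounded weights to >= 1
#' (a zero-abundance transcript is no path).  `uniform` draws integer
#' weights in `[weightLo, weightHi]`.
#'
#' @param nNodes number of nodes (>= 2) of the instance.
#' @param kPlanted number of planted paths (>= 1).
#' @param weightScheme `"lognormal"` or `"uniform"`.
#' @param weightLo,weightHi integer range for the uniform scheme.
#' @param meanlog,sdlog,scale lognormal parameters (mean -4, sd 2 on the log
#'   scale, i.e. variance 4; values scaled by 1000 and rounded).
#' @param epsilon relative standard deviation of the Gaussian flow
#'   perturbation used by [perturbToIntervals()] (0.05 by default).
#' @param tolerance half-width of the relative interval around the perturbed
#'   flow (0.10 = 10\% error tolerance).
#' @param nConstraints number of subpath constraints sampled per instance.
#' @param junctionsPerConstraint junction count defining constraint prefixes.
#' @param seed integer seed; every generator routine is deterministic in it.
#' @return a named list of generator settings.
#' @export
generatorConfig <- function(nNodes = 10, kPlanted = 3,
                            weightScheme = c("lognormal", "uniform"),
                            weightLo = 1, weightHi = 9,
                            meanlog = -4, sdlog = 2, scale = 1000,
                            epsilon = 0.05, tolerance = 0.10,
                            nConstraints = 4, junctionsPerConstraint = 3,
                            seed = 1) {
  weightScheme <- match.arg(weightScheme)
  stopifnot(nNodes >= 2, kPlanted >= 1, epsilon >= 0, tolerance >= 0,
            nConstraints >= 1, junctionsPerConstraint >= 1,
            weightLo >= 1, weightHi >= weightLo)
  list(nNodes = as.integer(nNodes), kPlanted = as.integer(kPlanted),
       weightScheme = weightScheme, weightLo = weightLo,
       weightHi = weightHi, meanlog = meanlog, sdlog = sdlog, scale = scale,
       epsilon = epsilon, tolerance = tolerance,
       nConstraints = as.integer(nConstraints),
       junctionsPerConstraint = as.integer(junctionsPerConstraint),
       seed = as.integer(seed))
}

.sampleWeights <- function(config, k) {
  if (config$weightScheme == "uniform")
    sample(config$weightLo:config$weightHi, k, replace = TRUE)
  else
    pmax(1, round(stats::rlnorm(k, meanlog = config$meanlog,
                                sdlog = config$sdlog) * config$scale))
}

#' Generate a planted synthetic instance
#'
#' Samples a random topological order on `nNodes` nodes, then `kPlanted`
#' distinct source-to-sink paths along it (every node is forced onto at
#' least one path), assigns each a weight from the configured scheme, and
#' returns the superposition network together with the ground truth.  The
#' network is conserving by construction and its minimum decomposition size
#' is at most `kPlanted`.  Instances that collapse to a trivial single path
#' are re-drawn unless `kPlanted = 1`; if the node budget cannot host
#' `kPlanted` distinct paths after bounded retries a generation error is
#' raised.
#'
#' @param config a [generatorConfig()] list.
#' @param seed overrides `config$seed`.
#' @return a [PlantedInstance-class].
#' @examples
#' inst <- generatePlantedInstance(generatorConfig(nNodes = 8, kPlanted = 3,
#'                                                 seed = 42))
#' inst
#' @export
generatePlantedInstance <- function(config = generatorConfig(),
                                    seed = config$seed) {
  n <- config$nNodes; k <- config$kPlanted
  .withSeed(seed, {
    for (attempt in 1:200) {
      ord <- paste0("v", sample.int(n))  # random topological order
      paths <- lapply(seq_len(k), function(i) {
        if (n == 2) return(ord)
        keep <- stats::runif(n - 2) < 0.5
        c(ord[1], ord[2:(n - 1)][keep], ord[n])
      })
      # force every node onto at least one path (no isolated nodes)
      covered <- unique(unlist(paths))
      for (p in seq_len(max(0, n - 2)) + 1L) {
        if (!(ord[p] %in% covered)) {
          pi <- sample.int(k, 1)
          path <- paths[[pi]]
          at <- sum(match(path, ord) < p)
          paths[[pi]] <- append(path, ord[p], after = at)
        }
      }
      sig <- vapply(paths, paste, character(1), collapse = ",")
      if (anyDuplicated(sig) && k > 1) next  # needs k distinct paths
      weights <- .sampleWeights(config, k)
      tails <- unlist(lapply(paths, function(p) p[-length(p)]))
      heads <- unlist(lapply(paths, function(p) p[-1]))
      wrep <- rep(weights, vapply(paths, length, integer(1)) - 1L)
      agg <- stats::aggregate(list(flow = wrep),
                              by = list(tail = tails, head = heads), sum)
      net <- flowNetwork(agg$tail, agg$head, agg$flow,
                         graphId = sprintf("planted_seed%d", seed))
      return(methods::new("PlantedInstance", network = net,
                          truthPaths = paths,
                          truthWeights = as.numeric(weights),
                          seed = as.numeric(seed), config = config))
    }
    .stopf("could not place %d distinct paths on %d nodes after 200 retries",
           k, n, class = "flowDecomp_generation_error")
  })
}

# feasibility of an interval instance: does an integral s-t flow within the
# bounds exist, with total value >= 1?  Standard reduction of lower/upper
# bounded flow feasibility to max-flow (works because bounds are integral).
.boundedFlowFeasible <- function(inet) {
  nn <- ensureSingleSourceSink(inet)
  e <- nn@edges
  s <- nn@sources; tk <- nn@sinks
  excess <- stats::setNames(numeric(length(nn@nodes)), nn@nodes)
  tails <- e$tail; heads <- e$head
  caps <- e$high - e$low
  for (i in seq_len(nrow(e))) {
    excess[e$head[i]] <- excess[e$head[i]] + e$low[i]
    excess[e$tail[i]] <- excess[e$tail[i]] - e$low[i]
  }
  bigCap <- sum(e$high) + 1
  # circulation arc t -> s with lower bound 1 (demand one unit end to end)
  tails <- c(tails, tk); heads <- c(heads, s); caps <- c(caps, bigCap)
  excess[s] <- excess[s] + 1
  excess[tk] <- excess[tk] - 1
  posN <- names(excess)[excess > 0]
  negN <- names(excess)[excess < 0]
  if (length(posN) == 0L) return(TRUE)
  tails <- c(tails, rep("S+", length(posN)), negN)
  heads <- c(heads, posN, rep("T-", length(negN)))
  caps <- c(caps, excess[posN], -excess[negN])
  g <- igraph::graph_from_data_frame(
    data.frame(from = tails, to = heads, stringsAsFactors = FALSE),
    directed = TRUE)
  fl <- igraph::max_flow(g, source = "S+", target = "T-", capacity = caps)
  abs(fl$value - sum(excess[posN])) < 1e-9
}

#' Perturb a planted instance into an interval (inexact) instance
#'
#' Per edge, a perturbed flow f' is drawn from a Gaussian with mean f and
#' standard deviation `epsilon * f`; the interval is
#' `[round((1 - tolerance) f'), round((1 + tolerance) f')]`, clamped at 0.
#' Draws yielding an infeasible instance (no integral within-bounds s-t
#' flow) are re-drawn under an incremented sub-seed until feasible.
#'
#' @param instance a [PlantedInstance-class] (or a conserving
#'   [FlowNetwork-class]).
#' @param config a [generatorConfig()] list supplying `epsilon`, `tolerance`
#'   and the base `seed`.
#' @param seed overrides `config$seed`.
#' @param maxRetries retry cap (generation error beyond it).
#' @return an [IntervalFlowNetwork-class] on the same topology.
#' @export
perturbToIntervals <- function(instance,
                               config = if (methods::is(instance,
                                                        "PlantedInstance"))
                                 instance@config else generatorConfig(),
                               seed = config$seed, maxRetries = 1000) {
  net <- if (methods::is(instance, "PlantedInstance")) instance@network
         else instance
  stopifnot(methods::is(net, "FlowNetwork"))
  f <- net@edges$flow
  for (r in 0:maxRetries) {
    inet <- .withSeed(seed + r, {
      fp <- stats::rnorm(length(f), mean = f, sd = config$epsilon * f)
      fp <- pmax(0, fp)
      lo <- pmax(0, round((1 - config$tolerance) * fp))
      hi <- pmax(lo, round((1 + config$tolerance) * fp))
      intervalFlowNetwork(net@edges$tail, net@edges$head, lo, hi,
                          graphId = paste0(net@graphId, "_ival"))
    })
    if (.boundedFlowFeasible(inet)) return(inet)
  }
  .stopf("no feasible interval instance after %d redraws", maxRetries,
         class = "flowDecomp_generation_error")
}

#' Sample subpath constraints from the planted truth
#'
#' For `nConstraints` of the ground-truth paths, emits the shortest prefix
#' whose interior visits `junctionsPerConstraint` nontrivial junctions
#' (nodes with in-degree >= 2 or out-degree >= 2 in the network); a path
#' with fewer junctions contributes the whole path.  Instances with fewer
#' ground-truth paths than `nConstraints` are excluded: a [skipSignal()] is
#' returned instead of constraints.
#'
#' @inheritParams perturbToIntervals
#' @return list of single-leg [PathConstraint-class], or a skip signal.
#' @export
sampleSubpathConstraints <- function(instance, config = instance@config,
                                     seed = config$seed) {
  stopifnot(methods::is(instance, "PlantedInstance"))
  if (length(instance@truthPaths) < config$nConstraints)
    return(skipSignal(sprintf("instance has %d < %d ground-truth paths",
                              length(instance@truthPaths),
                              config$nConstraints)))
  net <- instance@network
  e <- net@edges
  indeg <- table(factor(e$head, levels = net@nodes))
  outdeg <- table(factor(e$tail, levels = net@nodes))
  junction <- net@nodes[indeg >= 2 | outdeg >= 2]
  J <- config$junctionsPerConstraint
  .withSeed(seed, {
    sel <- sample.int(length(instance@truthPaths), config$nConstraints)
    lapply(seq_along(sel), function(ci) {
      p <- instance@truthPaths[[sel[ci]]]
      end <- length(p)  # fall back to the whole path
      if (length(p) >= 3)
        for (ee in 3:length(p)) {
          if (sum(p[2:(ee - 1)] %in% junction) >= J) { end <- ee; break }
        }
      pathConstraint(net, p[1:end], id = sprintf("sc%d", ci))
    })
  })
}

#' Perturb a planted instance into an imperfect flow network
#'
#' Adds rounded Gaussian noise with standard deviation
#' `noiseSdFraction * f` to every edge flow, clamped at 0 (zero-flow edges
#' are kept so the topology is preserved).  Conservation is generally broken
#' by the noise; the result is input for the bounded-error and
#' minimum-error solvers.
#'
#' @inheritParams perturbToIntervals
#' @param noiseSdFraction relative noise level (0 returns the flows
#'   unchanged).
#' @return a [FlowNetwork-class] on the same topology.
#' @export
perturbToImperfect <- function(instance, noiseSdFraction = 0.05,
                               seed = if (methods::is(instance,
                                                      "PlantedInstance"))
                                 instance@seed else 1) {
  net <- if (methods::is(instance, "PlantedInstance")) instance@network
         else instance
  stopifnot(methods::is(net, "FlowNetwork"))
  f <- net@edges$flow
  .withSeed(seed, {
    noisy <- pmax(0, f + round(stats::rnorm(length(f), 0,
                                            noiseSdFraction * f)))
    flowNetwork(net@edges$tail, net@edges$head, noisy,
                graphId = paste0(net@graphId, "_noisy"))
  })
}
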