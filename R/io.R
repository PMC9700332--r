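#' @include flownet.R
NULL

# Edge-list instance dialect (as used by flow-decomposition benchmark
# collections): one block per graph, consisting of a `# <free text>` header
# line, a line with the vertex count, then one edge per line as
# `tail head flow` (exact) or `tail head low high` (interval), whitespace
# separated.

#' Read flow networks from an edge-list instance file
#'
#' @param file path or connection.
#' @param dialect `"exact"` (`tail head flow`) or `"interval"`
#'   (`tail head low high`).
#' @param keepZeroEdges keep edges with flow 0?  By default they are dropped
#'   at load time: flow decomposition forces weight 0 on them anyway, and
#'   dropping shrinks the models.  (Interval edges are always kept.)
#' @return list of [FlowNetwork-class] or [IntervalFlowNetwork-class], one
#'   per `#` header, in file order.  The vertex-count line is checked against
#'   the node ids actually seen; a mismatch is a warning, not an error, to
#'   tolerate dialect variation in public instance files.
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "2", "0 1 5"), f)
#' net <- readGraphFile(f)[[1]]
#' edgeTable(net)
#' @export
readGraphFile <- function(file, dialect = c("exact", "interval"),
                          keepZeroEdges = FALSE) {
  dialect <- match.arg(dialect)
  lines <- readLines(file)
  nTok <- if (dialect == "exact") 3L else 4L
  nets <- list()
  i <- 1L
  lineIdx <- function(j) j  # 1-based line numbers in messages
  # skip leading blank lines
  while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  gi <- 0L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!startsWith(ln, "#"))
      .stopf("line %d: expected '#' graph header, got '%s'", i, ln,
             class = "flowDecomp_parse_error")
    gi <- gi + 1L
    gid <- trimws(sub("^#+", "", ln))
    if (!nzchar(gid)) gid <- sprintf("graph%d", gi - 1L)
    i <- i + 1L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > length(lines))
      .stopf("line %d: missing vertex-count line for graph '%s'", i, gid,
             class = "flowDecomp_parse_error")
    nv <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nv) || length(strsplit(trimws(lines[i]), "\\s+")[[1]]) != 1L)
      .stopf("line %d: expected a single vertex count, got '%s'", i, lines[i],
             class = "flowDecomp_parse_error")
    i <- i + 1L
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln)) { i <- i + 1L; next }
      if (startsWith(ln, "#")) break
      tok <- strsplit(ln, "\\s+")[[1]]
      if (length(tok) != nTok)
        .stopf("line %d: expected %d fields, got %d ('%s')", i, nTok,
               length(tok), ln, class = "flowDecomp_parse_error")
      vals <- suppressWarnings(as.numeric(tok[3:nTok]))
      if (any(is.na(vals)) || any(!.isWhole(vals)))
        .stopf("line %d: non-integer value in '%s'", i, ln,
               class = "flowDecomp_parse_error")
      if (any(vals < 0))
        .stopf("line %d: negative value in '%s'", i, ln,
               class = "flowDecomp_value_error")
      if (dialect == "interval" && vals[2] < vals[1])
        .stopf("line %d: high < low in '%s'", i, ln,
               class = "flowDecomp_value_error")
      rows[[length(rows) + 1L]] <- c(tok[1:2], vals)
      i <- i + 1L
    }
    if (length(rows) == 0L)
      .stopf("graph '%s': no edges", gid, class = "flowDecomp_parse_error")
    m <- do.call(rbind, rows)
    tail <- m[, 1]; head <- m[, 2]
    seen <- unique(c(rbind(tail, head)))
    if (length(seen) != nv)
      warning(sprintf("graph '%s': vertex-count line says %d, %d node ids seen",
                      gid, nv, length(seen)))
    if (dialect == "exact") {
      flow <- as.numeric(m[, 3])
      if (!keepZeroEdges) {
        keep <- flow > 0
        if (!any(keep))
          .stopf("graph '%s': all edges have zero flow", gid,
                 class = "flowDecomp_value_error")
        tail <- tail[keep]; head <- head[keep]; flow <- flow[keep]
      }
      nets[[gi]] <- flowNetwork(tail, head, flow, graphId = gid)
    } else {
      nets[[gi]] <- intervalFlowNetwork(tail, head, as.numeric(m[, 3]),
                                        as.numeric(m[, 4]), graphId = gid)
    }
  }
  nets
}

#' Write flow networks in the edge-list instance dialect
#'
#' Inverse of [readGraphFile()]: `readGraphFile(writeGraphFile(x))`
#' reproduces the networks up to node ordering.
#'
#' @param networks list of networks (or a single network).
#' @param file path or connection.
#' @param dialect `"exact"` or `"interval"`; must match the network class.
#' @export
writeGraphFile <- function(networks, file, dialect = c("exact", "interval")) {
  dialect <- match.arg(dialect)
  if (methods::is(networks, "FlowNetwork") ||
      methods::is(networks, "IntervalFlowNetwork")) networks <- list(networks)
  out <- character(0)
  for (net in networks) {
    e <- net@edges
    out <- c(out, paste("#", net@graphId), as.character(length(net@nodes)))
    if (dialect == "exact") {
      stopifnot(methods::is(net, "FlowNetwork"))
      out <- c(out, sprintf("%s %s %g", e$tail, e$head, e$flow))
    } else {
      stopifnot(methods::is(net, "IntervalFlowNetwork"))
      out <- c(out, sprintf("%s %s %g %g", e$tail, e$head, e$low, e$high))
    }
  }
  writeLines(out, file)
  invisible(NULL)
}

#' Read per-graph path constraints
#'
#' One `# <free text>` block per graph (aligned with the graphs of the
#' instance file, in order), then one constraint per line as a
#' space-separated node sequence; generalized (multi-leg, e.g. paired-end)
#' constraints put `;`-separated legs on one line.
#'
#' @param file path or connection.
#' @param networks list of host networks, one per block, used to resolve and
#'   validate constraint edges.
#' @return list (one element per graph) of lists of [PathConstraint-class].
#' @export
readConstraintsFile <- function(file, networks) {
  if (methods::is(networks, "FlowNetwork") ||
      methods::is(networks, "IntervalFlowNetwork")) networks <- list(networks)
  lines <- readLines(file)
  blocks <- list(); cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- character(0)
    } else {
      if (is.null(cur))
        .stopf("line %d: constraint before any '#' header", i,
               class = "flowDecomp_parse_error")
      cur <- c(cur, ln)
    }
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
  if (length(blocks) != length(networks))
    .stopf("constraints file has %d blocks but %d networks were given",
           length(blocks), length(networks))
  lapply(seq_along(blocks), function(b) {
    lapply(seq_along(blocks[[b]]), function(j) {
      legs <- lapply(strsplit(blocks[[b]][j], ";")[[1]], function(s)
        strsplit(trimws(s), "\\s+")[[1]])
      pathConstraint(networks[[b]], legs,
                     id = sprintf("g%d_c%d", b - 1L, j))
    })
  })
}

#' Write a decomposition result
#'
#' JSON output carries `graph_id`, `k`, `paths` (node lists), `weights` and
#' `status`; the TSV alternative has one line per path,
#' `weight<TAB>node1,node2,...`.
#'
#' @param result an [MfdResult-class].
#' @param file path or connection.
#' @param format `"json"` or `"tsv"`.
#' @export
writeDecomposition <- function(result, file, format = c("json", "tsv")) {
  format <- match.arg(format)
  dec <- result@decomposition
  if (format == "json") {
    obj <- list(graph_id = result@graphId,
                k = if (is.na(result@minK)) NULL else result@minK,
                paths = if (is.null(dec)) list() else dec@paths,
                weights = if (is.null(dec)) numeric(0) else dec@weights,
                status = result@status)
    jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- if (is.null(dec)) character(0) else
      sprintf("%g\t%s", dec@weights,
              vapply(dec@paths, paste, character(1), collapse = ","))
    writeLines(lines, file)
  }
  invisible(NULL)
}
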