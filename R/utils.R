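# Internal helpers shared across modules.

.stopf <- function(fmt, ..., class = "flowDecomp_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

.isWhole <- function(x, tol = 1e-9) {
  is.finite(x) & abs(x - round(x)) < tol
}

.edgeKey <- function(tail, head) paste(tail, head, sep = "\r")

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# stream.  All generator entry points run through this, which is what makes
# instances bit-reproducible under a fixed seed.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Skip signal for excluded instances
#'
#' [sampleSubpathConstraints()] emits a skip signal instead of constraints
#' when an instance has fewer ground-truth paths than the number of
#' constraints to sample, mirroring the exclusion of such splice graphs from
#' subpath-constraint experiments.
#'
#' @param reason human-readable reason for skipping.
#' @return an object of class `"flowDecompSkip"`.
#' @export
skipSignal <- function(reason = "instance excluded") {
  structure(list(reason = reason), class = "flowDecompSkip")
}

#' @rdname skipSignal
#' @param x object to test.
#' @export
isSkipSignal <- function(x) inherits(x, "flowDecompSkip")

#' @export
print.flowDecompSkip <- function(x, ...) {
  cat("<skip signal>", x$reason, "\n")
  invisible(x)
}
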