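#' flowDecomp: exact minimum flow decomposition via integer programming
#'
#' Decomposes a flow on a DAG (e.g. an RNA-seq splice graph) into a minimum
#' number of weighted source-to-sink paths, encoding all candidate paths
#' implicitly with a quadratic number of variables, plus the practical
#' variants used by transcript assemblers (subpath/paired-end constraints,
#' interval flows, imperfect flows with bounded or minimised error).
#'
#' @useDynLib flowDecomp, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new is initialize setValidity show
#' @importFrom stats setNames rnorm rlnorm runif aggregate
#' @importFrom utils combn
#' @keywords internal
"_PACKAGE"
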