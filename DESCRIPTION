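Package: flowDecomp
Title: Exact Minimum Flow Decomposition of Splice Graphs by Integer Linear Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact solvers for minimum flow decomposition (MFD) on directed
    acyclic graphs such as RNA-seq splice graphs, where a flow must be
    explained as a superposition of weighted source-to-sink paths. Paths are
    encoded implicitly in an integer linear program with a quadratic number of
    variables (per-path unit-flow edge indicators linked to path weights by
    big-M product linearisation), so candidate transcripts never have to be
    enumerated. Supports the practical variants used by transcript assemblers:
    subpath and paired-end (multi-leg) constraints, inexact flows given as
    per-edge intervals, and imperfect flows with a bounded or minimised total
    error. Includes a bundled exact branch-and-bound solver for the generated
    models, a brute-force oracle for small instances, and a deterministic
    synthetic splice-graph instance generator with planted ground-truth paths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'flownet.R'
    'io.R'
    'model.R'
    'oracle.R'
    'solver.R'
    'solve.R'
    'synthgen.R'
    'zzz.R'
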