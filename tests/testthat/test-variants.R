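test_that("path constraints restrict decompositions as required", {
  g5 <- g5Network()
  cc <- pathConstraint(g5, c("a", "b", "t"))
  m <- addPathConstraints(buildKfdModel(g5, 3), list(cc))
  out <- solveModel(m)
  expect_identical(out@status, "optimal")
  dec <- extractDecomposition(m, out)
  expect_true(isValid(validateDecomposition(g5, dec)))
  expect_true(isValid(validateConstraints(dec, list(cc))))

  dm <- diamondNetwork()
  twoLeg <- pathConstraint(dm, list(c("s", "a"), c("b", "t")))
  for (k in 1:3) {
    m <- addPathConstraints(buildKfdModel(dm, k), list(twoLeg))
    expect_identical(solveModel(m)@status, "infeasible")
  }

  m0 <- buildKfdModel(g5, 2)
  expect_identical(addPathConstraints(m0, list()), m0)

  expect_error(
    pathConstraint(g5, c("a", "c")), "not in network")
})

test_that("interval models generalize the exact ones", {
  g5 <- g5Network()
  e <- edgeTable(g5)
  degen <- intervalFlowNetwork(e$tail, e$head, e$flow, e$flow)
  for (k in 2:3)
    expect_identical(solveModel(buildInexactModel(degen, k))@status,
                     solveModel(buildKfdModel(g5, k))@status)

  one <- intervalFlowNetwork("s", "t", 3, 7)
  m <- buildInexactModel(one, 1)
  out <- solveModel(m)
  expect_identical(out@status, "optimal")
  w <- extractDecomposition(m, out)@weights
  expect_gte(w, 3); expect_lte(w, 7)

  relaxed <- intervalFlowNetwork(
    c("s", "s", "a", "a", "b"), c("a", "b", "b", "t", "t"),
    low = c(4, 5, 0, 4, 7), high = c(6, 7, 2, 4, 9))
  m2 <- buildInexactModel(relaxed, 2)
  o2 <- solveModel(m2)
  expect_identical(o2@status, "optimal")
  d2 <- extractDecomposition(m2, o2)
  expect_true(isValid(validateDecomposition(NULL, d2, "interval", relaxed)))

  expect_error(intervalFlowNetwork("s", "t", 5, 4), "high < low")
})

test_that("bounded-error models collapse to exact at B = 0", {
  g5 <- g5Network()
  for (k in 2:3)
    expect_identical(solveModel(buildBoundedErrorModel(g5, k, 0))@status,
                     solveModel(buildKfdModel(g5, k))@status)
  imp <- imperfect4()
  expect_identical(solveModel(buildBoundedErrorModel(imp, 1, 2))@status,
                   "optimal")
  expect_identical(solveModel(buildBoundedErrorModel(imp, 1, 1))@status,
                   "infeasible")
  expect_identical(solveModel(buildBoundedErrorModel(imp, 2, 1))@status,
                   "optimal")
  expect_error(buildBoundedErrorModel(imp, 1, -1), "non-negative")
})

test_that("bounded-error feasibility is monotone in B", {
  for (seed in 1:6) {
    imp <- perturbToImperfect(tinyPlanted(seed, nNodes = 5, weightHi = 5),
                              0.3, seed = seed)
    prev <- Inf
    for (B in c(0, 1, 2, 3)) {
      r <- solveImperfectBounded(imp, B)
      k <- if (is.na(r@minK)) Inf else r@minK
      expect_lte(k, prev)  # larger budget can only help
      prev <- k
    }
  }
})

test_that("minimum-error objectives match exhaustive search", {
  g5 <- g5Network()
  m <- buildMinErrorModel(g5, 3)
  out <- solveModel(m)
  expect_identical(out@status, "optimal")
  expect_equal(out@objectiveValue, 0)

  ch <- chainNetwork()
  o1 <- solveModel(buildMinErrorModel(ch, 1))
  expect_equal(o1@objectiveValue, 1)  # weight 5 or 6, errors {0,1}

  oi <- solveModel(buildMinErrorModel(imperfect4(), 1))
  expect_equal(oi@objectiveValue, 2)  # path s-a-t at weight 3

  expect_error(
    buildMinErrorModel(ch, 1, solverConfig(weightDomain = "real")),
    class = "flowDecomp_capability_error")
})

test_that("constrained minima dominate unconstrained ones", {
  for (seed in 1:6) {
    inst <- tinyPlanted(seed, kPlanted = 4, nNodes = 6, weightHi = 5)
    base <- solveMFD(inst@network)
    sc <- sampleSubpathConstraints(inst)
    if (isSkipSignal(sc)) next
    rc <- solveMFDSubpath(inst@network, sc)
    expect_gte(rc@minK, base@minK)
    # intervals containing the exact flow can only lower the minimum
    iv <- perturbToIntervals(inst,
                             generatorConfig(epsilon = 0, seed = seed))
    f <- edgeTable(inst@network)$flow
    ivE <- edgeTable(iv)
    if (all(ivE$low <= f & f <= ivE$high))
      expect_lte(solveMIFD(iv)@minK, base@minK)
  }
})
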