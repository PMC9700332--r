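test_that("single-edge model has the unique forced solution", {
  net <- flowNetwork("s", "t", 5)
  m <- buildKfdModel(net, 1)
  out <- solveModel(m)
  expect_identical(out@status, "optimal")
  v <- out@assignment
  expect_equal(unname(v["x_s_t_1"]), 1)
  expect_equal(unname(v["w_1"]), 5)
  expect_equal(unname(v["pi_s_t_1"]), 5)
  dec <- extractDecomposition(m, out)
  expect_identical(dec@paths, list(c("s", "t")))
  expect_equal(dec@weights, 5)
})

test_that("k below the required size is infeasible, k at it is feasible", {
  dm <- diamondNetwork()
  expect_identical(solveModel(buildKfdModel(dm, 1))@status, "infeasible")
  g5 <- g5Network()
  expect_identical(solveModel(buildKfdModel(g5, 2))@status, "infeasible")
  out <- solveModel(buildKfdModel(g5, 3))
  expect_identical(out@status, "optimal")
})

test_that("extracted decompositions superpose to the flow exactly", {
  g5 <- g5Network()
  m <- buildKfdModel(g5, 3)
  out <- solveModel(m)
  dec <- extractDecomposition(m, out)
  expect_true(isValid(validateDecomposition(g5, dec)))
  expect_setequal(dec@weights, c(4, 2, 7))  # the unique 3-decomposition
  for (seed in 1:8) {
    net <- tinyPlanted(seed)@network
    r <- solveMFD(net)
    expect_true(isValid(validateDecomposition(net, r@decomposition)))
    expect_true(all(pathWeights(r@decomposition) ==
                      round(pathWeights(r@decomposition))))
  }
})

test_that("model size grows as k times the edge count", {
  for (k in c(1, 3)) for (net in list(g5Network(), fanNetwork())) {
    E <- numEdges(net)
    m <- buildKfdModel(net, k)
    expect_equal(numVariables(m), 2 * k * E + k)          # x, pi, w
    nInternal <- numNodes(net) - 2
    expect_equal(numConstraints(m), k * (2 + nInternal) + E + 3 * k * E)
  }
})

test_that("feasibility is monotone in k up to the |f| bound", {
  for (seed in 1:8) {
    net <- tinyPlanted(seed, weightHi = 4)@network
    r <- solveMFD(net)
    top <- min(r@minK + 2, totalFlow(net), numEdges(net))
    for (k in seq(r@minK, top))
      expect_identical(solveModel(buildKfdModel(net, k))@status, "optimal")
  }
})

test_that("symmetry breaking leaves feasibility unchanged", {
  cfgOn <- solverConfig(symmetryBreaking = TRUE)
  for (seed in 1:6) {
    net <- tinyPlanted(seed)@network
    k <- oracleMinK(net)$minK
    for (kk in c(max(1, k - 1), k)) {
      a <- solveModel(buildKfdModel(net, kk))@status
      b <- solveModel(buildKfdModel(net, kk, cfgOn))@status
      expect_identical(a, b)
    }
  }
})

test_that("real-valued weight mode solves and drops zero-weight paths", {
  cfg <- solverConfig(weightDomain = "real")
  net <- flowNetwork("s", "t", 5)
  m <- buildKfdModel(net, 1, cfg)
  out <- solveModel(m, cfg)
  expect_identical(out@status, "optimal")
  dec <- extractDecomposition(m, out)
  expect_equal(dec@weights, 5, tolerance = 1e-6)

  g5 <- g5Network()
  m4 <- buildKfdModel(g5, 4, cfg)
  o4 <- solveModel(m4, cfg)
  expect_identical(o4@status, "optimal")
  d4 <- extractDecomposition(m4, o4)
  expect_true(isValid(validateDecomposition(g5, d4)))
  expect_equal(numPaths(d4), sum(o4@assignment[sprintf("w_%d", 1:4)] > 1e-9))
})

test_that("solver contract: argument, backend and limit handling", {
  net <- g5Network()
  expect_error(buildKfdModel(net, 0), "positive integer")
  expect_error(buildKfdModel(chainNetwork(), 1), "not conserving")
  badCfg <- solverConfig(backend = "gurobi")
  expect_error(solveModel(buildKfdModel(net, 1), badCfg), "gurobi")
  out <- solveModel(buildKfdModel(net, 3), nodeLimit = 1)
  expect_identical(out@status, "time_limit")
})

test_that("models export to LP text format", {
  f <- withr::local_tempfile()
  writeModelLP(buildKfdModel(g5Network(), 2), f)
  txt <- readLines(f)
  expect_true(any(grepl("Subject To", txt)))
  expect_true(any(grepl("pi_s_a_1", txt)))
  expect_true(any(grepl("Generals", txt)))
})
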