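test_that("instance files parse into networks, with line-level errors", {
  f <- withr::local_tempfile()
  writeLines(c("# graph 0", "2", "0 1 5"), f)
  nets <- readGraphFile(f)
  expect_length(nets, 1)
  expect_identical(sort(nodeIds(nets[[1]])), c("0", "1"))
  expect_identical(edgeTable(nets[[1]])$flow, 5)

  writeLines(c("# a", "2", "0 1 5", "# b", "3", "0 1 2", "1 2 2"), f)
  nets <- readGraphFile(f)
  expect_length(nets, 2)
  expect_identical(vapply(nets, graphId, character(1)), c("a", "b"))

  writeLines(c("# bad", "2", "0 1 -3"), f)
  expect_error(readGraphFile(f), "negative")

  writeLines(c("# dup", "2", "0 1 3", "0 1 4"), f)
  expect_error(readGraphFile(f), "duplicate|parallel")

  writeLines(c("# cyc", "2", "0 1 3", "1 0 3"), f)
  expect_error(readGraphFile(f), "cycle")

  writeLines(c("# n", "5", "0 1 3"), f)
  expect_warning(readGraphFile(f), "vertex-count")

  writeLines(c("# z", "3", "0 1 3", "0 2 0", "1 2 3"), f)
  expect_equal(numEdges(readGraphFile(f)[[1]]), 2)  # zero edge dropped
  expect_equal(numEdges(readGraphFile(f, keepZeroEdges = TRUE)[[1]]), 3)
})

test_that("write/read round-trips exact and interval networks", {
  f <- withr::local_tempfile()
  for (seed in 1:5) {
    inst <- tinyPlanted(seed)
    writeGraphFile(inst@network, f)
    back <- readGraphFile(f)[[1]]
    expect_identical(edgeTable(back), edgeTable(inst@network))
    expect_identical(graphId(back), graphId(inst@network))
    iv <- perturbToIntervals(inst)
    writeGraphFile(iv, f, dialect = "interval")
    ivb <- readGraphFile(f, dialect = "interval")[[1]]
    expect_identical(edgeTable(ivb), edgeTable(iv))
  }
  # empty network list writes empty output
  writeGraphFile(list(), f)
  expect_identical(readLines(f), character(0))
})

test_that("normalization adds weighted super source/sink only when needed", {
  multi <- flowNetwork(c("a", "b", "a", "b"), c("t", "t", "u", "u"),
                       c(3, 4, 1, 2))
  nn <- ensureSingleSourceSink(multi)
  expect_length(sourceNodes(nn), 1)
  e <- edgeTable(nn)
  expect_setequal(e$flow[e$tail == sourceNodes(nn)], c(4, 6))
  # out-flows 3+1=4 for a, 4+2=6 for b
  g5 <- g5Network()
  expect_identical(ensureSingleSourceSink(g5), g5)

  both <- flowNetwork(c("a", "b"), c("x", "x"), c(2, 3))
  # a,b sources; x sole sink -> only a super source
  nb <- ensureSingleSourceSink(both)
  expect_length(sourceNodes(nb), 1)
  expect_length(sinkNodes(nb), 1)
  expect_true(isConserving(nb))
})

test_that("flow conservation is checked at internal nodes", {
  expect_true(isValid(checkFlowConservation(g5Network())))
  rep <- checkFlowConservation(chainNetwork())
  expect_false(isValid(rep))
  expect_equal(unname(rep@nodeImbalance["a"]), -1)
  expect_true(isValid(checkFlowConservation(flowNetwork("s", "t", 5))))
})

test_that("decomposition validation is exact", {
  single <- flowNetwork("s", "t", 5)
  expect_true(isValid(validateDecomposition(
    single, decomposition(list(c("s", "t")), 5))))
  rep <- validateDecomposition(single, decomposition(list(c("s", "t")), 4))
  expect_false(isValid(rep))
  expect_equal(unname(rep@edgeResiduals["s->t"]), -1)

  dec <- decomposition(list(c("s", "a", "t"), c("s", "a", "b", "t"),
                            c("s", "b", "t")), c(4, 2, 7))
  expect_true(isValid(validateDecomposition(g5Network(), dec)))

  expect_error(validateDecomposition(
    g5Network(), decomposition(list(c("s", "x", "t")), 1)), "absent")
  expect_error(validateDecomposition(
    g5Network(), decomposition(list(c("a", "t")), 1)), "source-to-sink")
})

test_that("constraint satisfaction matches subsequence containment", {
  dec <- decomposition(list(c("s", "a", "b", "t")), 13)
  cc <- pathConstraint(g5Network(), c("a", "b", "t"))
  expect_true(isValid(validateConstraints(dec, list(cc))))

  dec2 <- decomposition(list(c("s", "a", "t"), c("s", "b", "t")), c(6, 7))
  ab <- pathConstraint(g5Network(), c("a", "b"))
  expect_false(isValid(validateConstraints(dec2, list(ab))))

  dm <- diamondNetwork()
  twoLeg <- pathConstraint(dm, list(c("s", "a"), c("b", "t")))
  decd <- decomposition(list(c("s", "a", "t"), c("s", "b", "t")), c(3, 2))
  rep <- validateConstraints(decd, list(twoLeg))
  expect_false(isValid(rep))
  expect_identical(rep@violatedConstraints, "c1")

  # property: single-leg satisfaction == direct node-subsequence check
  for (seed in 1:8) {
    inst <- tinyPlanted(seed, kPlanted = 3)
    dec <- decomposition(inst@truthPaths, inst@truthWeights)
    for (p in inst@truthPaths) {
      if (length(p) < 3) next
      sub <- p[1:3]
      cc <- pathConstraint(inst@network, sub)
      direct <- any(vapply(inst@truthPaths, function(q) {
        i <- match(sub[1], q)
        !is.na(i) && i + 2 <= length(q) && all(q[i:(i + 2)] == sub)
      }, logical(1)))
      expect_identical(isValid(validateConstraints(dec, list(cc))), direct)
    }
  }
})

test_that("degree bound never exceeds the true minimum", {
  expect_equal(lowerBoundK(flowNetwork("s", "t", 5)), 1)
  expect_equal(lowerBoundK(diamondNetwork()), 2)
  expect_equal(lowerBoundK(g5Network()), 2)
  for (seed in 1:10) {
    net <- tinyPlanted(seed)@network
    expect_lte(lowerBoundK(net), oracleMinK(net)$minK)
  }
})

test_that("a conserving flow always admits the |f| unit-weight decomposition", {
  for (seed in 1:6) {
    net <- tinyPlanted(seed, weightHi = 4)@network
    e <- edgeTable(net)
    rem <- e$flow
    paths <- list()
    s <- sourceNodes(net); tk <- sinkNodes(net)
    while (any(rem[e$tail == s] > 0)) {
      node <- s; p <- node
      while (node != tk) {
        i <- which(e$tail == node & rem > 0)[1]
        rem[i] <- rem[i] - 1
        node <- e$head[i]
        p <- c(p, node)
      }
      paths[[length(paths) + 1]] <- p
    }
    dec <- decomposition(paths, rep(1, length(paths)))
    expect_equal(numPaths(dec), totalFlow(net))
    expect_true(isValid(validateDecomposition(net, dec)))
  }
})
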