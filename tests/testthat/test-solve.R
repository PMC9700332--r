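test_that("minimal-k scan returns the minimum with a valid witness", {
  r <- solveMFD(flowNetwork("s", "t", 5))
  expect_identical(r@status, "solved")
  expect_equal(r@minK, 1)
  expect_equal(pathWeights(r@decomposition), 5)

  rf <- solveMFD(fanNetwork())
  expect_equal(rf@minK, 3)
  expect_setequal(pathWeights(rf@decomposition), c(1, 2, 4))

  rg <- solveMFD(g5Network())
  expect_equal(rg@minK, 3)
  expect_true(isValid(validateDecomposition(g5Network(), rg@decomposition)))
})

test_that("the scan log is infeasible below the minimum, feasible at it", {
  r <- solveMFD(g5Network(), scanFromOne = TRUE)
  log <- r@perKLog
  expect_identical(log$status[log$k < r@minK],
                   rep("infeasible", r@minK - 1))
  expect_identical(log$status[log$k == r@minK], "optimal")
  rb <- solveMFD(g5Network(), binarySearch = TRUE)
  expect_equal(rb@minK, r@minK)
})

test_that("constrained scan handles feasibility and identity cases", {
  g5 <- g5Network()
  cc <- pathConstraint(g5, c("a", "b", "t"))
  r <- solveMFDSubpath(g5, list(cc))
  expect_equal(r@minK, 3)
  expect_true(isValid(validateConstraints(r@decomposition, list(cc))))

  dm <- diamondNetwork()
  twoLeg <- pathConstraint(dm, list(c("s", "a"), c("b", "t")))
  expect_identical(solveMFDSubpath(dm, list(twoLeg))@status, "infeasible")

  expect_equal(solveMFDSubpath(g5, list())@minK, solveMFD(g5)@minK)
})

test_that("interval scan matches the exact scan on degenerate intervals", {
  e <- edgeTable(g5Network())
  degen <- intervalFlowNetwork(e$tail, e$head, e$flow, e$flow)
  expect_equal(solveMIFD(degen)@minK, 3)
  relaxed <- intervalFlowNetwork(
    c("s", "s", "a", "a", "b"), c("a", "b", "b", "t", "t"),
    low = c(4, 5, 0, 4, 7), high = c(6, 7, 2, 4, 9))
  expect_equal(solveMIFD(relaxed)@minK, 2)
})

test_that("imperfect drivers find the smallest workable k", {
  g5 <- g5Network()
  expect_equal(solveImperfectBounded(g5, 0)@minK, solveMFD(g5)@minK)
  imp <- imperfect4()
  expect_equal(solveImperfectBounded(imp, 2)@minK, 1)
  expect_equal(solveImperfectBounded(imp, 1)@minK, 2)

  rm0 <- solveImperfectMinErr(g5, maxK = 4)
  expect_equal(rm0@minK, 3)
  expect_equal(rm0@objective, 0)
  rch <- solveImperfectMinErr(chainNetwork(), maxK = 2)
  expect_equal(rch@minK, 1)
  expect_equal(rch@objective, 1)
  rimp <- solveImperfectMinErr(imp, maxK = 3)
  expect_equal(rimp@minK, 2)
  expect_equal(rimp@objective, 0)
})

test_that("optimal decompositions are enumerated without duplicates", {
  single <- flowNetwork("s", "t", 5)
  expect_length(enumerateOptimalDecompositions(single, 1), 1)

  dm <- diamondNetwork()
  decs <- enumerateOptimalDecompositions(dm, 2)
  expect_length(decs, 1)  # index permutations deduplicate
  expect_setequal(pathWeights(decs[[1]]), c(3, 2))

  g5decs <- enumerateOptimalDecompositions(g5Network(), 3)
  sigs <- vapply(g5decs, function(d)
    paste(sort(sprintf("%g|%s", pathWeights(d),
                       vapply(decompPaths(d), paste, character(1),
                              collapse = ","))), collapse = ";"),
    character(1))
  expect_false(anyDuplicated(sigs) > 0)
  expect_true(any(vapply(g5decs, function(d)
    setequal(pathWeights(d), c(4, 2, 7)), logical(1))))
  for (d in g5decs)
    expect_true(isValid(validateDecomposition(g5Network(), d)))

  expect_error(enumerateOptimalDecompositions(dm, 2, limit = 0), "limit")
})

test_that("results are reproducible across repeated runs", {
  net <- tinyPlanted(11)@network
  r1 <- solveMFD(net)
  r2 <- solveMFD(net)
  expect_equal(r1@minK, r2@minK)
  expect_identical(decompPaths(r1@decomposition),
                   decompPaths(r2@decomposition))
  expect_identical(pathWeights(r1@decomposition),
                   pathWeights(r2@decomposition))
})
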