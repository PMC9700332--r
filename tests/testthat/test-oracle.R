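test_that("s-t paths are enumerated exhaustively in lexicographic order", {
  expect_identical(enumerateSTPaths(flowNetwork("s", "t", 5)),
                   list(c("s", "t")))
  expect_length(enumerateSTPaths(diamondNetwork()), 2)
  expect_identical(enumerateSTPaths(g5Network()),
                   list(c("s", "a", "b", "t"), c("s", "a", "t"),
                        c("s", "b", "t")))
  expect_error(enumerateSTPaths(g5Network(), cap = 2),
               class = "flowDecomp_size_error")
})

test_that("oracle reproduces the worked minima", {
  o <- oracleMinK(g5Network())
  expect_equal(o$minK, 3)
  expect_setequal(pathWeights(o$witness), c(4, 2, 7))
  expect_true(isValid(validateDecomposition(g5Network(), o$witness)))

  od <- oracleMinK(diamondNetwork())
  expect_equal(od$minK, 2)
  expect_setequal(pathWeights(od$witness), c(3, 2))

  om <- oracleMinK(chainNetwork(), mode = "minerr", maxK = 2)
  expect_equal(om$minK, 1)
  expect_equal(om$objective, 1)
  expect_true(pathWeights(om$witness) %in% c(5, 6))
})

test_that("oracle witnesses always validate", {
  for (seed in 1:8) {
    net <- tinyPlanted(seed)@network
    o <- oracleMinK(net)
    expect_true(isValid(validateDecomposition(net, o$witness)))
  }
  iv <- perturbToIntervals(tinyPlanted(3))
  oi <- oracleMinK(iv, mode = "interval")
  expect_true(isValid(validateDecomposition(NULL, oi$witness, "interval", iv)))
})

test_that("oracle minimum is invariant under node relabeling", {
  for (seed in 1:5) {
    net <- tinyPlanted(seed)@network
    base <- oracleMinK(net)$minK
    perm <- setNames(sample(sprintf("n%02d", seq_along(nodeIds(net)))),
                     nodeIds(net))
    e <- edgeTable(net)
    relab <- flowNetwork(perm[e$tail], perm[e$head], e$flow)
    expect_equal(oracleMinK(relab)$minK, base)
  }
})

test_that("oracle minimum never exceeds the |f| unit-weight bound", {
  for (seed in 1:8) {
    net <- tinyPlanted(seed, weightHi = 4)@network
    expect_lte(oracleMinK(net)$minK, totalFlow(net))
  }
})
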