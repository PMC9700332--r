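test_that("generated networks equal the superposition of their truth paths", {
  for (seed in 1:10) {
    inst <- tinyPlanted(seed)
    dec <- decomposition(inst@truthPaths, inst@truthWeights)
    expect_true(isValid(validateDecomposition(inst@network, dec)))
    expect_true(isConserving(inst@network))
    expect_lte(solveMFD(inst@network)@minK, length(inst@truthPaths))
  }
})

test_that("generation is deterministic and respects its budget", {
  i1 <- generatePlantedInstance(generatorConfig(seed = 7))
  i2 <- generatePlantedInstance(generatorConfig(seed = 7))
  expect_identical(edgeTable(i1@network), edgeTable(i2@network))
  expect_identical(i1@truthPaths, i2@truthPaths)
  expect_identical(i1@truthWeights, i2@truthWeights)

  one <- generatePlantedInstance(generatorConfig(nNodes = 6, kPlanted = 1,
                                                 seed = 3))
  expect_length(enumerateSTPaths(one@network), 1)
  expect_equal(solveMFD(one@network)@minK, 1)

  # 3 nodes host at most 2 distinct s-t paths
  expect_error(
    generatePlantedInstance(generatorConfig(nNodes = 3, kPlanted = 3,
                                            seed = 1)),
    class = "flowDecomp_generation_error")
})

test_that("zero-epsilon perturbation gives the 10%-tolerance intervals", {
  for (seed in 1:10) {
    inst <- tinyPlanted(seed)
    cfg <- generatorConfig(epsilon = 0, seed = seed)
    iv <- perturbToIntervals(inst, cfg)
    f <- edgeTable(inst@network)$flow
    e <- edgeTable(iv)
    expect_identical(e$low, pmax(0, round(0.9 * f)))
    expect_identical(e$high, round(1.1 * f))
    expect_true(all(e$low[f >= 5] <= f[f >= 5] &
                      f[f >= 5] <= e$high[f >= 5]))
  }
  iv1 <- perturbToIntervals(tinyPlanted(4))
  iv2 <- perturbToIntervals(tinyPlanted(4))
  expect_identical(edgeTable(iv1), edgeTable(iv2))
})

test_that("subpath sampling follows the prefix rule and exclusion rule", {
  few <- generatePlantedInstance(generatorConfig(nNodes = 7, kPlanted = 3,
                                                 seed = 5))
  expect_true(isSkipSignal(sampleSubpathConstraints(few)))

  for (seed in 1:6) {
    inst <- tinyPlanted(seed, nNodes = 7, kPlanted = 4)
    sc <- sampleSubpathConstraints(inst)
    expect_false(isSkipSignal(sc))
    expect_length(sc, 4)
    truth <- decomposition(inst@truthPaths, inst@truthWeights)
    expect_true(isValid(validateConstraints(truth, sc)))
    r <- solveMFDSubpath(inst@network, sc)
    expect_identical(r@status, "solved")
  }

  # a path without nontrivial junctions contributes the whole path
  one <- generatePlantedInstance(generatorConfig(nNodes = 5, kPlanted = 1,
                                                 nConstraints = 1, seed = 2))
  sc1 <- sampleSubpathConstraints(one)
  expect_equal(constraintSize(sc1[[1]]), length(one@truthPaths[[1]]) - 1)
})

test_that("imperfect perturbation is deterministic and vanishes at zero noise", {
  inst <- tinyPlanted(6)
  same <- perturbToImperfect(inst, 0)
  expect_identical(edgeTable(same)$flow, edgeTable(inst@network)$flow)
  r <- solveImperfectMinErr(same, maxK = length(inst@truthPaths))
  expect_equal(r@objective, 0)

  n1 <- perturbToImperfect(inst, 0.3, seed = 9)
  n2 <- perturbToImperfect(inst, 0.3, seed = 9)
  expect_identical(edgeTable(n1), edgeTable(n2))
})
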