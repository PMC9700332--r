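# Shared fixtures, all built in code.

# the worked 5-edge instance: unique 3-decomposition with weights {4, 2, 7}
g5Network <- function() {
  flowNetwork(tail = c("s", "s", "a", "a", "b"),
              head = c("a", "b", "b", "t", "t"),
              flow = c(6, 7, 2, 4, 9), graphId = "g5")
}

diamondNetwork <- function() {
  flowNetwork(c("s", "a", "s", "b"), c("a", "t", "b", "t"),
              c(3, 3, 2, 2), graphId = "diamond")
}

fanNetwork <- function() {
  flowNetwork(c("s", "s", "s", "a", "b", "c"),
              c("a", "b", "c", "t", "t", "t"),
              c(1, 2, 4, 1, 2, 4), graphId = "fan")
}

chainNetwork <- function() {
  flowNetwork(c("s", "a"), c("a", "t"), c(5, 6), graphId = "chain")
}

# the 4-edge imperfect example: paths s-a-t (flow 3) and s-b-t (flow 1)
imperfect4 <- function() {
  flowNetwork(c("s", "a", "s", "b"), c("a", "t", "b", "t"),
              c(3, 3, 1, 1), graphId = "imp4")
}

# small planted instance with uniform weights, sized for the oracle
tinyPlanted <- function(seed, nNodes = 5 + (seed %% 4),
                        kPlanted = 1 + (seed %% 4),
                        weightHi = 9) {
  generatePlantedInstance(generatorConfig(
    nNodes = nNodes, kPlanted = kPlanted, weightScheme = "uniform",
    weightLo = 1, weightHi = weightHi, seed = seed))
}

expect_sameMinK <- function(a, b) {
  expect_identical(as.numeric(a), as.numeric(b))
}
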