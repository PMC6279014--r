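core <- buildModel("core")
t5 <- readStateTable(extfile("table5.tsv"))

test_that("the threshold rule handles excess, deficit and equality correctly", {
  ## Start has no activators and self-degrades: off from any oscillator state
  for (r in c(1, 2, 5, 9))
    expect_identical(thresholdNext(core, tableRowState(t5, r), "Start"), 0L)
  ## start kinases fire from the Start state
  expect_identical(thresholdNext(core, tableRowState(t5, 1), "Cig1/Cdc2"), 1L)
  ## hold at equality for a non-degrading isolated node
  expect_identical(thresholdNext(isolatedNode(FALSE), c(A = 1L), "A"), 1L)
  expect_identical(thresholdNext(isolatedNode(FALSE), c(A = 0L), "A"), 0L)
  ## decay at equality for a self-degrading one
  expect_identical(thresholdNext(isolatedNode(TRUE), c(A = 1L), "A"), 0L)
  ## clamped nodes have no threshold dynamics
  ext <- buildModel("phospho")
  expect_error(thresholdNext(ext, initialState(ext), "Cdc10"), "clamped")
})

test_that("stepState follows the printed transitions and is deterministic", {
  expect_identical(stepState(core, tableRowState(t5, 1)),
                   tableRowState(t5, 2))
  ## G1 state is a fixed point
  g1 <- tableRowState(t5, 10)
  expect_identical(stepState(core, g1), g1)
  ## phospho model: Sep1 and Atf1 switch on entering G2/M
  t7 <- readStateTable(extfile("table7.tsv"))
  m2 <- buildModel("phospho")
  expect_identical(stepState(m2, tableRowState(t7, 5)),
                   tableRowState(t7, 6))
  ## purity
  s <- tableRowState(t5, 4)
  expect_identical(stepState(core, s), stepState(core, s))
  expect_error(stepState(core, c(Start = 1L)), "missing node")
})

test_that("simulation reproduces the core oscillator run and stays binary", {
  traj <- simulateNetwork(core, steps = 18)
  expect_identical(nrow(states(traj)), 19L)
  for (r in 1:19)
    expect_identical(states(traj)[r, ], tableRowState(t5, r))
  expect_true(all(states(traj) %in% 0:1))
  ## zero steps: just the initial state
  t0 <- simulateNetwork(core, steps = 0)
  expect_identical(nrow(states(t0)), 1L)
  expect_identical(states(t0)[1, ], initialState(core))
})

test_that("phase annotation returns the unique matching label", {
  t1 <- readStateTable(extfile("table1.tsv"))
  expect_identical(annotatePhase(core, tableRowState(t1, 4)), "G2")
  expect_identical(annotatePhase(core, tableRowState(t1, 7)), "G2/M")
  allOn <- stats::setNames(rep(1L, 12), nodeNames(core))
  expect_identical(annotatePhase(core, allOn), "unassigned")
  ## the phase labels of the simulated run match the printed ones
  traj <- simulateNetwork(core, steps = 9)
  expect_identical(phaseLabels(traj), t1$Phase)
})

test_that("attractor detection finds the G1 fixed point and the restart cycle", {
  a <- detectAttractor(core)
  expect_identical(a@kind, "fixed_point")
  expect_identical(states(a)[1, ], tableRowState(t5, 10))
  expect_true(is.na(basinSize(a)))

  r <- detectAttractor(buildModel("phospho_dephos_restart"))
  expect_identical(r@kind, "cycle")
  expect_identical(nrow(states(r)), 9L)

  s <- detectAttractor(isolatedNode(TRUE), c(A = 1L))
  expect_identical(s@kind, "fixed_point")
  expect_identical(unname(states(s)[1, ]), 0L)

  expect_error(detectAttractor(core, maxSteps = 1), "no state repeated")
})

test_that("state-space enumeration assigns every state to one attractor", {
  atts <- enumerateStateSpace(twoNodeMutual())
  expect_length(atts, 2)
  expect_identical(vapply(atts, basinSize, integer(1)), c(3L, 1L))  # sorted
  expect_identical(unname(states(atts[[1]])[1, ]), c(1L, 1L))
  expect_identical(unname(states(atts[[2]])[1, ]), c(0L, 0L))

  one <- enumerateStateSpace(isolatedNode(TRUE))
  expect_length(one, 1)
  expect_identical(basinSize(one[[1]]), 2L)

  expect_identical(sum(vapply(enumerateStateSpace(core), basinSize,
                              integer(1))), 4096L)
  expect_error(enumerateStateSpace(core, cap = 10), "sample")
})

test_that("basin sizes sum to 2^N on random networks", {
  for (cfg in list(c(n = 5, seed = 11), c(n = 7, seed = 12),
                   c(n = 9, seed = 13), c(n = 10, seed = 14))) {
    atts <- enumerateStateSpace(randomNetwork(cfg[["n"]], 0.35, 0.5,
                                              seed = cfg[["seed"]]))
    expect_identical(sum(vapply(atts, basinSize, integer(1))),
                     as.integer(2^cfg[["n"]]))
  }
})

test_that("detectAttractor agrees with enumeration from every initial state", {
  for (cfg in list(c(n = 4, seed = 21), c(n = 5, seed = 22),
                   c(n = 6, seed = 23))) {
    net <- randomNetwork(cfg[["n"]], 0.4, 0.5, seed = cfg[["seed"]])
    nn <- nodeNames(net)
    atts <- enumerateStateSpace(net)
    ## canonical key: smallest state string on the attractor cycle
    keyOf <- function(a) min(apply(states(a), 1, paste, collapse = ""))
    enumKeys <- vapply(atts, keyOf, character(1))
    all <- as.matrix(expand.grid(rep(list(0:1), cfg[["n"]])))
    colnames(all) <- nn
    detected <- apply(all, 1, function(s)
      keyOf(detectAttractor(net, stats::setNames(as.integer(s), nn))))
    ## independent brute-force walk as a second opinion
    expect_identical(detected, unname(bruteAttractorKeys(net)))
    expect_setequal(unique(detected), enumKeys)
    ## and the basin tally agrees with the enumeration
    tallied <- table(factor(detected, levels = enumKeys))
    expect_identical(as.integer(tallied),
                     vapply(atts, basinSize, integer(1)))
  }
})

test_that("clamped nodes hold their clamp value at every step", {
  for (v in c("phospho", "phospho_dephos", "phospho_dephos_restart")) {
    traj <- simulateNetwork(buildModel(v), steps = 30)
    expect_true(all(states(traj)[, "Cdc10"] == 1L), info = v)
  }
})

test_that("table validation reports exactly the mismatching cells", {
  expect_identical(nrow(validateAgainstTable(core, extfile("table5.tsv"))),
                   0L)
  ## the extended model deviates from the core run in a single cell
  d <- validateAgainstTable(buildModel("final"), extfile("table5.tsv"))
  expect_identical(nrow(d), 1L)
  expect_identical(d$time, 8L)
  expect_identical(d$node, "Rum1")
  expect_identical(d$expected, 0L)
  expect_identical(d$actual, 1L)

  expect_identical(nrow(validateAgainstTable(buildModel("phospho_dephos"),
                                             extfile("table8.tsv"))), 0L)
  expect_error(validateAgainstTable(core, extfile("table5.tsv"),
                                    columns = "NoSuchNode"),
               "unknown column")
  empty <- readStateTable(extfile("table5.tsv"))[0, ]
  expect_error(validateAgainstTable(core, empty), "empty")
})
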