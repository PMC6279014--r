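test_that("the phase table has ten patterns with the printed labels", {
  pt <- cyclePhaseTable()
  expect_length(pt, 10)
  labs <- vapply(pt, function(p) p@label, character(1))
  expect_identical(unname(labs),
                   c("Start", "G1", "G1/S", "G2", "G2", "G2/M", "G2/M",
                     "M", "M", "G1"))
  expect_identical(unname(labs[3]), "G1/S")
  expect_identical(unname(labs[8]), "M")
  ## every pattern constrains all twelve core nodes exactly
  expect_true(all(vapply(pt, function(p) length(p@constraints),
                         integer(1)) == 12L))
})

test_that("each variant reproduces its golden table cell-for-cell", {
  golden <- c(core = "table5.tsv", final = "table6.tsv",
              phospho = "table7.tsv", phospho_dephos = "table8.tsv",
              phospho_dephos_restart = "table9.tsv")
  for (v in names(golden)) {
    d <- validateAgainstTable(buildModel(v), extfile(golden[[v]]))
    expect_identical(nrow(d), 0L, info = v)
  }
})

test_that("the restart variant is eventually periodic with period 9", {
  traj <- states(simulateNetwork(buildModel("phospho_dephos_restart"),
                                 steps = 26))
  for (t in 10:18)
    expect_identical(traj[t + 9, ], traj[t, ], info = paste("t =", t))
  ## the restart event recreates the initial Start state, so the standard
  ## run is periodic from t = 1 onwards
  expect_identical(traj[10, ], traj[1, ])
})

test_that("without dephosphorylation Sep1 and Atf1 latch on", {
  traj <- states(simulateNetwork(buildModel("phospho"), steps = 18))
  firstOn <- min(which(traj[, "Sep1"] == 1L))
  expect_true(all(traj[firstOn:19, "Sep1"] == 1L))
  expect_true(all(traj[firstOn:19, "Atf1"] == 1L))
  expect_true(all(traj[3:19, "Fkh2"] == 0L))
})

test_that("phosphorylation effect toggles rewire the events but keep a valid model", {
  flipped <- buildModel("final", effects = c(Sep1 = "inhibition",
                                             Atf1 = "inhibition",
                                             Fkh2 = "inhibition"))
  expect_length(validateNetwork(flipped), 0)
  d <- validateAgainstTable(flipped, extfile("table7.tsv"))
  expect_gt(nrow(d), 0)  # no longer the printed behaviour
  expect_error(buildModel("final", effects = c(Slp1 = "activation")),
               "limited to")
  expect_error(buildModel("final", effects = c(Sep1 = "sometimes")),
               "activation")
  expect_error(buildModel("m17"))
})

test_that("variant output columns follow the printed table layouts", {
  expect_length(buildModel("final")@outputNodes, 12)
  expect_length(buildModel("phospho")@outputNodes, 16)
  expect_identical(nodeNames(buildModel("core")),
                   names(readStateTable(extfile("table5.tsv")))[-1])
  expect_identical(nodeNames(buildModel("phospho")),
                   setdiff(names(readStateTable(extfile("table7.tsv"))),
                           "Time"))
})
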