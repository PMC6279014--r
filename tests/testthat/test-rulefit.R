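core <- buildModel("core")

test_that("constraint extraction yields (R-1) x N constraints", {
  c5 <- extractConstraints(extfile("table5.tsv"))
  expect_length(c5, (19 - 1) * 12)
  c9 <- extractConstraints(extfile("table9.tsv"))
  expect_length(c9, (20 - 1) * 16)

  tiny <- data.frame(Time = 1:2, A = c(1L, 0L))
  c1 <- extractConstraints(tiny)
  expect_length(c1, 1)
  expect_identical(c1[[1]]$node, "A")
  expect_identical(c1[[1]]$value, 0L)

  expect_error(extractConstraints(tiny[1, ]), "at least 2 rows")
  bad <- data.frame(Time = 1:2, A = c(1L, 2L))
  expect_error(extractConstraints(bad), "row 2")
})

test_that("fitting recovers the shipped core parameters from the trajectory", {
  cons <- extractConstraints(extfile("table5.tsv"))
  fit <- fitNodeRules(core, cons, grid = c(-0.5, 0, 0.5))
  expect_identical(fit@nConstraints, 216L)
  expect_setequal(names(fit@fits), nodeNames(core))
  nd <- nodeTable(core)
  for (i in seq_len(nrow(nd))) {
    f <- fit@fits[[nd$name[i]]]
    expect_gte(nrow(f), 1)
    expect_true(any(f$threshold == nd$threshold[i] &
                    f$selfDegrading == nd$selfDegrading[i]),
                info = nd$name[i])
  }
  ## Start decays: every consistent parameterisation either self-degrades or
  ## has a strictly positive threshold
  fs <- fit@fits[["Start"]]
  expect_true(any(fs$selfDegrading))
  expect_true(all(fs$selfDegrading | fs$threshold > 0))
  ## Cdc2/Cdc13 must be default-on: unique solution at theta = -1/2
  fc <- fit@fits[["Cdc2/Cdc13"]]
  expect_identical(fc$threshold, -0.5)
})

test_that("every returned parameterisation reproduces every transition", {
  cons <- extractConstraints(extfile("table5.tsv"))
  fit <- fitNodeRules(core, cons, grid = c(-0.5, 0, 0.5))
  evalRule <- function(net, nm, theta, sd, cc) {
    tmp <- net
    i <- match(nm, tmp@nodes$name)
    tmp@nodes$threshold[i] <- theta
    tmp@nodes$selfDegrading[i] <- sd
    thresholdNext(tmp, cc$input, nm)
  }
  for (nm in c("Start", "Ste9", "Slp1", "Cdc2_Tyr15")) {
    nodeCons <- Filter(function(cc) cc$node == nm, cons)
    f <- fit@fits[[nm]]
    for (i in seq_len(nrow(f)))
      for (cc in nodeCons)
        expect_identical(evalRule(core, nm, f$threshold[i],
                                  f$selfDegrading[i], cc), cc$value)
    ## completeness: rejected grid combinations violate some constraint
    allowSd <- nodeTable(core)$selfDegrading[match(nm, nodeNames(core))]
    grid <- expand.grid(threshold = c(-0.5, 0, 0.5),
                        selfDegrading = if (allowSd) c(FALSE, TRUE)
                                        else FALSE)
    rejected <- grid[!mapply(function(th, sd)
      any(f$threshold == th & f$selfDegrading == sd),
      grid$threshold, grid$selfDegrading), , drop = FALSE]
    for (i in seq_len(nrow(rejected))) {
      broke <- any(vapply(nodeCons, function(cc)
        evalRule(core, nm, rejected$threshold[i],
                 rejected$selfDegrading[i], cc) != cc$value, logical(1)))
      expect_true(broke, info = paste(nm, rejected$threshold[i],
                                      rejected$selfDegrading[i]))
    }
  }
})

test_that("contradictory transitions are rejected with the node named", {
  ## the input state (A=1, B=1) occurs twice and maps A to both 0 and 1
  tab <- data.frame(Time = 1:4, A = c(1L, 0L, 1L, 1L), B = rep(1L, 4))
  net <- booleanNetwork(rbind(nodeRow("A"), nodeRow("B")),
                        edgeRow("B", "A", +1))
  expect_error(fitNodeRules(net, extractConstraints(tab)),
               "no consistent parameterisation for node 'A'")
})

test_that("expanded logic equals the threshold rule on every input combo", {
  ## isolated hold node: identity of its own state
  iso <- isolatedNode(FALSE)
  L <- expandToLogic(iso, "A")
  expect_identical(L$inputs, "A")
  expect_identical(L$truthTable$output, L$truthTable$A)
  expect_identical(L$dnf, "(A)")

  ## one +1 input, self-degrading: output equals input
  net <- booleanNetwork(rbind(nodeRow("A", selfDegrading = TRUE),
                              nodeRow("B")),
                        edgeRow("B", "A", +1))
  L <- expandToLogic(net, "A")
  expect_identical(L$truthTable$output, L$truthTable$B)

  ## fitted core rules against the engine, input combination by combination
  core <- buildModel("core")
  for (nm in c("Ste9", "Rum1", "Slp1", "Cdc2/Cdc13", "Wee1/Mik1")) {
    L <- expandToLogic(core, nm)
    tt <- L$truthTable
    base <- stats::setNames(rep(0L, nodeCount(core)), nodeNames(core))
    for (r in seq_len(nrow(tt))) {
      s <- base
      s[L$inputs] <- as.integer(unlist(tt[r, L$inputs]))
      expect_identical(thresholdNext(core, s, nm), tt$output[r],
                       info = paste(nm, "row", r))
    }
  }
})
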