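test_that("patterns match exactly the states satisfying their constraints", {
  t5 <- readStateTable(extfile("table5.tsv"))
  startOn <- statePattern(c(Start = 1))

  expect_true(patternMatches(statePattern(), tableRowState(t5, 3)))
  expect_true(patternMatches(startOn, tableRowState(t5, 1)))
  expect_false(patternMatches(startOn, tableRowState(t5, 2)))
  expect_error(patternMatches(statePattern(c(Nonexistent = 1)),
                              tableRowState(t5, 1)),
               "Nonexistent")
})

test_that("pattern matching is monotone under constraint removal", {
  set.seed(42)
  nn <- paste0("g", 1:6)
  for (rep in 1:25) {
    s <- stats::setNames(sample(0:1, 6, replace = TRUE), nn)
    full <- sample(nn, sample(2:6, 1))
    p <- statePattern(stats::setNames(sample(0:1, length(full),
                                             replace = TRUE), full))
    sub <- statePattern(p@constraints[sample(seq_along(full),
                                             sample(seq_along(full), 1))])
    if (patternMatches(p, s)) expect_true(patternMatches(sub, s))
  }
})

test_that("bundled models pass validation and broken networks yield findings", {
  for (v in c("core", "final", "phospho_dephos_restart"))
    expect_length(validateNetwork(buildModel(v)), 0)

  dangling <- booleanNetwork(nodeRow("A"), edgeRow("A", "Ghost", +1))
  f <- validateNetwork(dangling)
  expect_length(f, 1)
  expect_match(f, "unresolved endpoint")

  dup <- booleanNetwork(rbind(nodeRow("A"), nodeRow("A")))
  expect_match(validateNetwork(dup), "duplicate node name", all = FALSE)

  badSign <- booleanNetwork(rbind(nodeRow("A"), nodeRow("B")),
                            edgeRow("A", "B", 2L))
  expect_match(validateNetwork(badSign), "only \\+1/-1", all = FALSE)
})

test_that("equal-priority events assigning one node are flagged as ambiguous", {
  net <- booleanNetwork(
    rbind(nodeRow("A"), nodeRow("B")),
    patterns = list(pa = statePattern(c(A = 1)),
                    pb = statePattern(c(B = 1))),
    events = list(
      eventRule("e1", trigger = "pa", assignments = c(B = 1), priority = 5L),
      eventRule("e2", trigger = "pb", assignments = c(B = 0), priority = 5L)))
  f <- validateNetwork(net)
  expect_length(f, 1)
  expect_match(f, "ambiguous override")

  ## disjoint triggers cannot fire together: no finding
  net2 <- booleanNetwork(
    rbind(nodeRow("A"), nodeRow("B")),
    patterns = list(pa = statePattern(c(A = 1)),
                    pna = statePattern(c(A = 0))),
    events = list(
      eventRule("e1", trigger = "pa", assignments = c(B = 1), priority = 5L),
      eventRule("e2", trigger = "pna", assignments = c(B = 0), priority = 5L)))
  expect_length(validateNetwork(net2), 0)
})

test_that("overlapping phase patterns are flagged", {
  net <- booleanNetwork(
    rbind(nodeRow("A"), nodeRow("B")),
    patterns = list(pa = statePattern(c(A = 1)),
                    pab = statePattern(c(A = 1, B = 1))),
    phases = data.frame(pattern = c("pa", "pab"),
                        label = c("x", "y"), stringsAsFactors = FALSE))
  expect_match(validateNetwork(net), "overlapping phase patterns",
               all = FALSE)
})

test_that("networks round-trip through the text format field by field", {
  for (v in c("core", "final", "phospho", "phospho_dephos",
              "phospho_dephos_restart")) {
    net <- buildModel(v)
    f <- withr::local_tempfile(fileext = ".net")
    writeNetwork(net, f)
    expect_equal(loadNetwork(f), net, info = v)
  }
  for (seed in 1:4) {
    net <- randomNetwork(6, 0.3, 0.5, seed = seed)
    f <- withr::local_tempfile(fileext = ".net")
    writeNetwork(net, f)
    expect_equal(loadNetwork(f), net, info = paste("seed", seed))
  }
})
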