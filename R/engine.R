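#' @include netmodel.R
NULL

## Compile a network into the numeric pieces the update loop needs: an
## ungated weight matrix (source x target), the gated-edge list, per-node
## thresholds/flags, clamp indices and events sorted by ascending priority
## (so higher priority is applied last and wins).
.compileNetwork <- function(net) {
  nn <- net@nodes$name
  n <- length(nn)
  W <- matrix(0, n, n, dimnames = list(nn, nn))
  gated <- list()
  for (i in seq_len(nrow(net@edges))) {
    e <- net@edges[i, ]
    if (is.na(e$gate)) {
      W[e$source, e$target] <- W[e$source, e$target] + e$sign
    } else {
      gated[[length(gated) + 1L]] <-
        list(source = e$source, target = e$target, sign = e$sign,
             pattern = .resolvePattern(net, e$gate))
    }
  }
  evs <- net@events
  if (length(evs))
    evs <- evs[order(vapply(evs, function(e) e@priority, integer(1)))]
  events <- lapply(evs, function(e) {
    list(trigger = .resolvePattern(net, e@trigger),
         condition = lapply(e@condition, .resolvePattern, net = net),
         assignments = e@assignments)
  })
  list(nodes = nn, W = W, gated = gated,
       theta = net@nodes$threshold, selfDegrading = net@nodes$selfDegrading,
       clampIdx = which(!is.na(net@nodes$clamp)),
       clampVal = net@nodes$clamp[!is.na(net@nodes$clamp)],
       events = events)
}

## Coerce/check a user-supplied state to a complete named vector in node order.
.fullState <- function(net, s) {
  nn <- net@nodes$name
  if (is.null(names(s)))
    stop("state must be a named vector over the network's nodes")
  missing <- setdiff(nn, names(s))
  if (length(missing))
    stop("incomplete state; missing node(s): ",
         paste(missing, collapse = ", "))
  v <- as.integer(s[nn])
  if (any(is.na(v)) || !all(v %in% .BINARY))
    stop("state values must be 0 or 1")
  names(v) <- nn
  v
}

## Synchronous successor of every row of state matrix S (columns = nodes).
## Three stages: threshold rule, clamps, events (ascending priority).
.stepMatrix <- function(cmp, S) {
  m <- nrow(S)
  sigma <- S %*% cmp$W
  for (g in cmp$gated) {
    hit <- .patternMatchesMatrix(g$pattern, S)
    if (any(hit))
      sigma[hit, g$target] <- sigma[hit, g$target] + g$sign * S[hit, g$source]
  }
  up <- sigma > rep(cmp$theta, each = m)
  eq <- sigma == rep(cmp$theta, each = m)
  nxt <- matrix(0L, m, ncol(S), dimnames = dimnames(S))
  nxt[up] <- 1L
  hold <- eq & rep(!cmp$selfDegrading, each = m)
  nxt[hold] <- S[hold]
  if (length(cmp$clampIdx))
    nxt[, cmp$clampIdx] <- rep(cmp$clampVal, each = m)
  for (ev in cmp$events) {
    fired <- .patternMatchesMatrix(ev$trigger, S)
    if (length(ev$condition)) {
      alt <- Reduce(`|`, lapply(ev$condition, .patternMatchesMatrix, S = S))
      fired <- fired & alt
    }
    if (any(fired))
      nxt[fired, names(ev$assignments)] <-
        rep(ev$assignments, each = sum(fired))
  }
  nxt
}

#' Threshold-rule successor value of one node
#'
#' Computes the signed input sum of the node over its in-edges (a gated edge
#' contributes only when its pattern matches the current state) and applies
#' the threshold rule: 1 if the sum exceeds the node's threshold, 0 if it
#' falls below, and at exact equality 0 for a self-degrading node or the
#' node's current value (hold) otherwise. Event rules and clamps are not
#' applied here; see [stepState()].
#'
#' @param net a [BooleanNetwork-class]
#' @param s complete named binary state at time t
#' @param node node name (must not be clamped)
#' @return 0 or 1
#' @export
thresholdNext <- function(net, s, node) {
  s <- .fullState(net, s)
  idx <- match(node, net@nodes$name)
  if (is.na(idx)) stop("unknown node: ", node)
  if (!is.na(net@nodes$clamp[idx]))
    stop("node ", node, " is clamped; its dynamics are fixed")
  sigma <- 0
  for (i in seq_len(nrow(net@edges))) {
    e <- net@edges[i, ]
    if (e$target != node) next
    if (!is.na(e$gate) && !patternMatches(.resolvePattern(net, e$gate), s))
      next
    sigma <- sigma + e$sign * s[[e$source]]
  }
  theta <- net@nodes$threshold[idx]
  if (sigma > theta) 1L
  else if (sigma < theta) 0L
  else if (net@nodes$selfDegrading[idx]) 0L
  else s[[node]]
}

#' Synchronous successor state
#'
#' Pure function computing the state at time t+1 from the state at time t:
#' (1) every non-clamped node is updated by the threshold rule (nodes without
#' in-edges hold their value), (2) clamped nodes take their clamp value,
#' (3) every event rule whose trigger (and optional condition) matches the
#' state at time t applies its forced assignments, higher priority last.
#'
#' @param net a [BooleanNetwork-class]
#' @param s complete named binary state
#' @return named integer successor state
#' @export
stepState <- function(net, s) {
  s <- .fullState(net, s)
  cmp <- .compileNetwork(net)
  .stepMatrix(cmp, matrix(s, 1L, length(s), dimnames = list(NULL, names(s))))[1L, ]
}

#' Simulate a trajectory
#'
#' @param net a [BooleanNetwork-class]
#' @param initial starting state; defaults to the network's initial state.
#' @param steps number of synchronous updates (>= 0); the trajectory has
#'   `steps + 1` rows starting at time 1.
#' @return a [Trajectory-class] with phases annotated via [annotatePhase()]
#' @examples
#' net <- buildModel("core")
#' traj <- simulateNetwork(net, steps = 18)
#' @export
simulateNetwork <- function(net, initial = initialState(net), steps) {
  stopifnot(steps >= 0)
  s <- .fullState(net, initial)
  cmp <- .compileNetwork(net)
  out <- matrix(0L, steps + 1L, length(s),
                dimnames = list(NULL, names(s)))
  out[1L, ] <- s
  row <- matrix(s, 1L, length(s), dimnames = list(NULL, names(s)))
  for (k in seq_len(steps)) {
    row <- .stepMatrix(cmp, row)
    out[k + 1L, ] <- row[1L, ]
  }
  ph <- vapply(seq_len(nrow(out)), function(i) annotatePhase(net, out[i, ]),
               character(1))
  new("Trajectory", states = out, phases = ph)
}

#' Cell-cycle phase label of a state
#'
#' Returns the label of the unique phase-table pattern matching the state
#' (phase patterns constrain core nodes only, so any extra substrate nodes
#' are ignored), or "unassigned" when no pattern matches. Two matching
#' patterns violate the phase-table invariant and raise an error.
#'
#' @param net a [BooleanNetwork-class]
#' @param s named binary state
#' @return a phase label string
#' @export
annotatePhase <- function(net, s) {
  if (!nrow(net@phases)) return("unassigned")
  hits <- vapply(net@phases$pattern, function(pn)
    patternMatches(.resolvePattern(net, pn), s), logical(1))
  if (sum(hits) > 1L)
    stop("state matches several phase patterns: ",
         paste(net@phases$label[hits], collapse = ", "))
  if (any(hits)) net@phases$label[hits] else "unassigned"
}

#' Iterate to an attractor
#'
#' Follows the synchronous dynamics from `initial` until a state repeats;
#' the states from the first occurrence of the repeated state onwards form
#' the attractor (a single state that is its own successor is a fixed point).
#' The basin size is left unset; use [enumerateStateSpace()] for basins.
#'
#' @param net a [BooleanNetwork-class]
#' @param initial starting state; defaults to the network's initial state.
#' @param maxSteps iteration bound (>= 1). A repeat is guaranteed within
#'   2^N steps, so the default always terminates.
#' @return an [Attractor-class] with `basinSize = NA`
#' @export
detectAttractor <- function(net, initial = initialState(net),
                            maxSteps = 2^nodeCount(net) + 1) {
  stopifnot(maxSteps >= 1)
  s <- .fullState(net, initial)
  cmp <- .compileNetwork(net)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  hist <- matrix(0L, 0L, length(s))
  colnames(hist) <- names(s)
  row <- matrix(s, 1L, length(s), dimnames = list(NULL, names(s)))
  for (k in seq_len(maxSteps + 1L)) {
    key <- paste(row[1L, ], collapse = "")
    prev <- seen[[key]]
    if (!is.null(prev)) {
      cyc <- hist[seq(prev, nrow(hist)), , drop = FALSE]
      return(new("Attractor",
                 kind = if (nrow(cyc) == 1L) "fixed_point" else "cycle",
                 states = cyc, basinSize = NA_integer_))
    }
    seen[[key]] <- nrow(hist) + 1L
    hist <- rbind(hist, row)
    if (k > maxSteps) break
    row <- .stepMatrix(cmp, row)
  }
  stop("no state repeated within ", maxSteps, " steps")
}

#' Exhaustive state-space enumeration with basins of attraction
#'
#' Computes the successor of all 2^N states at once, finds every attractor of
#' the resulting functional graph, and assigns each state to the attractor it
#' eventually reaches. Basin sizes therefore sum to 2^N.
#'
#' @param net a [BooleanNetwork-class]
#' @param cap refuse networks with more than this many nodes (memory grows as
#'   2^N); for larger networks sample initial states with [detectAttractor()]
#'   instead.
#' @return list of [Attractor-class] objects sorted by descending basin size
#' @export
enumerateStateSpace <- function(net, cap = 20L) {
  n <- nodeCount(net)
  if (n > cap)
    stop("network has ", n, " nodes (> cap ", cap, "); enumeration over 2^",
         n, " states refused - sample initial states with detectAttractor()",
         " instead")
  nn <- net@nodes$name
  S <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  storage.mode(S) <- "integer"
  colnames(S) <- nn
  cmp <- .compileNetwork(net)
  succS <- .stepMatrix(cmp, S)
  pow <- 2^(seq_len(n) - 1L)
  succ <- as.integer(succS %*% pow) + 1L
  ## pointer doubling: g = succ composed 2^n times maps every state onto its
  ## attractor cycle (transients are shorter than 2^n)
  g <- succ
  for (k in seq_len(n)) g <- g[g]
  cycleId <- rep(NA_integer_, 2^n)
  cycles <- list()
  for (r in unique(g)) {
    if (!is.na(cycleId[r])) next
    id <- length(cycles) + 1L
    idx <- r
    cur <- succ[r]
    while (cur != r) {
      idx <- c(idx, cur)
      cur <- succ[cur]
    }
    ## canonical start: smallest state index on the cycle
    shift <- which.min(idx)
    idx <- c(idx[seq(shift, length(idx))],
             if (shift > 1L) idx[seq_len(shift - 1L)])
    cycleId[idx] <- id
    cycles[[id]] <- idx
  }
  assign <- cycleId[g]
  basin <- tabulate(assign, nbins = length(cycles))
  atts <- lapply(seq_along(cycles), function(id) {
    st <- S[cycles[[id]], , drop = FALSE]
    rownames(st) <- NULL
    new("Attractor",
        kind = if (nrow(st) == 1L) "fixed_point" else "cycle",
        states = st, basinSize = basin[id])
  })
  atts[order(basin, decreasing = TRUE)]
}

#' Compare a simulated trajectory against an expected state table
#'
#' Simulates from the table's first row (restricted to the table's columns and
#' extended by the model's initial state for any further nodes) over the
#' table's time window, and reports every cell where simulation and table
#' disagree. An empty result means the model reproduces the table
#' cell-for-cell.
#'
#' @param net a [BooleanNetwork-class]
#' @param expected a state table: a data.frame with a `Time` column and one
#'   0/1 column per node (a `Phase` column is ignored), or a path to a TSV in
#'   that layout (see [readStateTable()]).
#' @param columns node columns to compare; defaults to all node columns of
#'   the table. Unknown columns raise an error.
#' @return data.frame with columns `time`, `node`, `expected`, `actual`
#'   (zero rows iff the trajectory matches the table)
#' @examples
#' diff <- validateAgainstTable(buildModel("core"),
#'   system.file("extdata", "table5.tsv", package = "PombeCycleBN"))
#' nrow(diff)  # 0
#' @export
validateAgainstTable <- function(net, expected, columns = NULL) {
  if (is.character(expected)) expected <- readStateTable(expected)
  if (!nrow(expected)) stop("expected table is empty")
  if (!"Time" %in% names(expected)) stop("expected table has no Time column")
  tabNodes <- setdiff(names(expected), c("Time", "Phase"))
  if (is.null(columns)) columns <- tabNodes
  unknown <- setdiff(columns, tabNodes)
  if (length(unknown))
    stop("unknown column(s) not in the table: ",
         paste(unknown, collapse = ", "))
  unknown <- setdiff(columns, nodeNames(net))
  if (length(unknown))
    stop("unknown column(s) not in the network: ",
         paste(unknown, collapse = ", "))
  init <- initialState(net)
  first <- unlist(expected[1L, tabNodes])
  common <- intersect(tabNodes, names(init))
  init[common] <- as.integer(first[common])
  traj <- simulateNetwork(net, init, steps = nrow(expected) - 1L)
  sim <- states(traj)[, columns, drop = FALSE]
  exp <- as.matrix(expected[, columns, drop = FALSE])
  storage.mode(exp) <- "integer"
  bad <- which(sim != exp, arr.ind = TRUE)
  data.frame(time = expected$Time[bad[, 1L]],
             node = columns[bad[, 2L]],
             expected = exp[bad],
             actual = sim[bad],
             stringsAsFactors = FALSE)
}
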