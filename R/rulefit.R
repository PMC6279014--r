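#' @include engine.R
NULL

#' Extract per-node transition constraints from a state table
#'
#' Every pair of consecutive rows of the table yields one constraint per node:
#' given the full state at time t, the node must take the printed value at
#' time t+1. A table of R rows over N nodes yields (R-1) x N constraints.
#'
#' @param table a data.frame with a `Time` column and one 0/1 column per node
#'   (a `Phase` column is ignored), or a path to such a TSV.
#' @return list of constraints, each a list with elements `input` (named
#'   binary state at time t), `node` and `value` (required value at t+1)
#' @examples
#' cons <- extractConstraints(
#'   system.file("extdata", "table5.tsv", package = "PombeCycleBN"))
#' length(cons)  # (19 - 1) * 12
#' @export
extractConstraints <- function(table) {
  if (is.character(table)) table <- readStateTable(table)
  nodeCols <- setdiff(names(table), c("Time", "Phase"))
  if (nrow(table) < 2L)
    stop("a state table needs at least 2 rows to define transitions")
  S <- as.matrix(table[, nodeCols, drop = FALSE])
  suppressWarnings(storage.mode(S) <- "integer")
  for (r in seq_len(nrow(S)))
    if (any(is.na(S[r, ])) || !all(S[r, ] %in% .BINARY))
      stop("malformed row ", r, ": state values must be 0 or 1")
  out <- vector("list", (nrow(S) - 1L) * length(nodeCols))
  k <- 0L
  for (r in seq_len(nrow(S) - 1L)) {
    input <- S[r, ]
    for (nm in nodeCols) {
      k <- k + 1L
      out[[k]] <- list(input = input, node = nm,
                       value = unname(S[r + 1L, nm]))
    }
  }
  out
}

## Signed input sum of `node` given a full input state, honouring edge gates.
.inputSum <- function(net, input, node) {
  sigma <- 0
  for (i in seq_len(nrow(net@edges))) {
    e <- net@edges[i, ]
    if (e$target != node) next
    if (!e$source %in% names(input))
      stop("constraint input lacks node '", e$source,
           "' required by the topology")
    if (!is.na(e$gate) &&
        !patternMatches(.resolvePattern(net, e$gate), input)) next
    sigma <- sigma + e$sign * input[[e$source]]
  }
  sigma
}

#' Recover threshold parameters consistent with observed transitions
#'
#' Per-node exhaustive search: thresholds come from `grid` and the
#' self-degradation flag is searched for the nodes where it is allowed. A
#' parameterisation is kept iff it reproduces *every* supplied transition of
#' its node under the threshold-rule semantics of [thresholdNext()]. Because
#' nodes update independently, each node is fitted independently.
#'
#' This is how the unprinted rule table of the bundled core oscillator is
#' recovered from its printed trajectory under the fixed signed topology.
#'
#' @param topology a [BooleanNetwork-class] supplying in-edges and signs;
#'   its thresholds and flags are ignored (except to default `allowSelfDeg`).
#'   Clamped nodes are skipped.
#' @param constraints list from [extractConstraints()].
#' @param grid candidate threshold values.
#' @param allowSelfDeg named logical vector saying for which nodes the
#'   self-degradation flag may be TRUE; defaults to the topology's
#'   `selfDegrading` flags (the self-degradation loops of the network
#'   diagram). Nodes not named are treated as not allowed.
#' @return a [RuleFitResult-class]; error if any constrained node admits no
#'   consistent parameterisation, naming the node and its first violated
#'   constraint.
#' @export
fitNodeRules <- function(topology, constraints, grid = c(-0.5, 0, 0.5),
                         allowSelfDeg = NULL) {
  if (!length(grid)) stop("threshold grid must be non-empty")
  if (is.null(allowSelfDeg))
    allowSelfDeg <- stats::setNames(topology@nodes$selfDegrading,
                                    topology@nodes$name)
  fitNodes <- unique(vapply(constraints, `[[`, character(1), "node"))
  clamped <- topology@nodes$name[!is.na(topology@nodes$clamp)]
  fitNodes <- setdiff(intersect(fitNodes, topology@nodes$name), clamped)
  fits <- list()
  for (nm in fitNodes) {
    cons <- Filter(function(cc) cc$node == nm, constraints)
    sigmas <- vapply(cons, function(cc) .inputSum(topology, cc$input, nm),
                     numeric(1))
    current <- vapply(cons, function(cc) cc$input[[nm]], integer(1))
    target <- vapply(cons, function(cc) cc$value, integer(1))
    sdOptions <- if (isTRUE(allowSelfDeg[[nm]])) c(FALSE, TRUE) else FALSE
    ok <- expand.grid(threshold = grid, selfDegrading = sdOptions,
                      KEEP.OUT.ATTRS = FALSE)
    keep <- logical(nrow(ok))
    firstBad <- NULL
    for (i in seq_len(nrow(ok))) {
      pred <- ifelse(sigmas > ok$threshold[i], 1L,
              ifelse(sigmas < ok$threshold[i], 0L,
              if (ok$selfDegrading[i]) 0L else current))
      bad <- which(pred != target)
      keep[i] <- !length(bad)
      if (length(bad) && is.null(firstBad)) firstBad <- cons[[bad[1L]]]
    }
    if (!any(keep)) {
      stop("no consistent parameterisation for node '", nm,
           "'; first violated constraint: input [",
           paste(names(firstBad$input), firstBad$input, sep = "=",
                 collapse = ", "),
           "] requires ", nm, " -> ", firstBad$value)
    }
    fits[[nm]] <- ok[keep, , drop = FALSE]
    rownames(fits[[nm]]) <- NULL
  }
  new("RuleFitResult", fits = fits,
      nConstraints = length(constraints))
}

#' Expand a node's threshold rule to an explicit Boolean function
#'
#' Enumerates every combination of the node's (ungated) inputs - plus the
#' node's own previous value whenever the hold-at-equality case is reachable -
#' and tabulates the induced successor value, together with a canonical
#' full disjunctive-normal-form string (one conjunction per true row, terms
#' sorted).
#'
#' @param net a [BooleanNetwork-class]
#' @param node node name with at most 12 inputs; nodes with gated in-edges
#'   are refused because their rule depends on the whole network state.
#' @return list with `inputs` (column names), `truthTable` (data.frame of
#'   input columns plus `output`) and `dnf` (string; "0"/"1" for the constant
#'   functions)
#' @export
expandToLogic <- function(net, node) {
  idx <- match(node, net@nodes$name)
  if (is.na(idx)) stop("unknown node: ", node)
  ed <- net@edges[net@edges$target == node, , drop = FALSE]
  if (any(!is.na(ed$gate)))
    stop("node ", node, " has gated in-edges; its rule is state-dependent ",
         "and has no input-local truth table")
  if (!is.na(net@nodes$clamp[idx])) {
    val <- net@nodes$clamp[idx]
    return(list(inputs = character(0),
                truthTable = data.frame(output = val),
                dnf = as.character(val)))
  }
  inputs <- unique(ed$source)
  if (length(inputs) > 12L)
    stop("node ", node, " has ", length(inputs), " inputs (> 12)")
  theta <- net@nodes$threshold[idx]
  selfdeg <- net@nodes$selfDegrading[idx]
  ## weights per input (parallel edges sum)
  w <- vapply(inputs, function(src) sum(ed$sign[ed$source == src]), numeric(1))
  ## is the hold case reachable? only then does the previous value matter
  combos <- as.matrix(expand.grid(rep(list(0:1), length(inputs)),
                                  KEEP.OUT.ATTRS = FALSE))
  sums <- if (length(inputs)) as.numeric(combos %*% w) else 0
  holdReachable <- !selfdeg && any(sums == theta)
  cols <- inputs
  if (holdReachable && !node %in% cols) cols <- c(cols, node)
  if (!length(cols)) {
    ## no inputs and no reachable hold case: the rule is a constant
    val <- if (0 > theta) 1L else 0L
    return(list(inputs = character(0),
                truthTable = data.frame(output = val),
                dnf = as.character(val)))
  }
  tt <- as.matrix(expand.grid(rep(list(0:1), length(cols)),
                              KEEP.OUT.ATTRS = FALSE))
  storage.mode(tt) <- "integer"
  colnames(tt) <- cols
  out <- integer(nrow(tt))
  for (r in seq_len(nrow(tt))) {
    sigma <- if (length(inputs)) sum(w * tt[r, inputs]) else 0
    out[r] <- if (sigma > theta) 1L
              else if (sigma < theta) 0L
              else if (selfdeg) 0L
              else if (node %in% cols) tt[r, node]
              else 0L  # unreachable: no inputs, equality, value unmodelled
  }
  terms <- character(0)
  if (length(cols)) {
    for (r in which(out == 1L)) {
      lits <- ifelse(tt[r, ] == 1L, colnames(tt), paste0("!", colnames(tt)))
      terms <- c(terms, paste0("(", paste(lits, collapse = " & "), ")"))
    }
    terms <- sort(terms)
  }
  dnf <- if (!length(cols)) as.character(out[1L])
         else if (!length(terms)) "0"
         else if (length(terms) == nrow(tt)) "1"
         else paste(terms, collapse = " | ")
  ttdf <- as.data.frame(tt)
  ttdf$output <- out
  list(inputs = cols, truthTable = ttdf, dnf = dnf)
}
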