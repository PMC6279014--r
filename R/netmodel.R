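#' @include AllGenerics.R
NULL

#' Construct a state pattern
#'
#' @param constraints named vector of required 0/1 values (may be empty).
#' @param label free-text annotation.
#' @return a [StatePattern-class]
#' @examples
#' p <- statePattern(c(Start = 1), label = "cycle start")
#' @export
statePattern <- function(constraints = integer(0), label = "") {
  cn <- as.integer(constraints)
  names(cn) <- names(constraints)
  new("StatePattern", constraints = cn, label = as.character(label))
}

#' Construct an event rule
#'
#' @param name identifier.
#' @param trigger pattern name evaluated on the full state at time t.
#' @param assignments named vector of forced 0/1 values at time t+1.
#' @param condition character vector of alternative pattern names (OR); empty
#'   for none.
#' @param priority integer; when two fired rules assign the same node the
#'   higher priority wins.
#' @return an [EventRule-class]
#' @export
eventRule <- function(name, trigger, assignments, condition = character(0),
                      priority = 0L) {
  a <- as.integer(assignments)
  names(a) <- names(assignments)
  new("EventRule", name = as.character(name), priority = as.integer(priority),
      trigger = as.character(trigger), condition = as.character(condition),
      assignments = a)
}

.nodeSpec <- function(name, kind = "core", threshold = 0, selfDegrading = FALSE,
                      clamp = NA_integer_, initialState = 0L) {
  data.frame(name = name, kind = kind, threshold = threshold,
             selfDegrading = selfDegrading, clamp = as.integer(clamp),
             initialState = as.integer(initialState),
             stringsAsFactors = FALSE)
}

.edgeSpec <- function(source, target, sign, gate = NA_character_) {
  data.frame(source = source, target = target, sign = as.integer(sign),
             gate = gate, stringsAsFactors = FALSE)
}

.emptyEdges <- function() {
  data.frame(source = character(0), target = character(0),
             sign = integer(0), gate = character(0), stringsAsFactors = FALSE)
}

.emptyPhases <- function() {
  data.frame(pattern = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a threshold Boolean network
#'
#' Low-level constructor; see [buildModel()] for the bundled cell-cycle
#' models and [loadNetwork()] for the text format. The constructor checks
#' shapes only; use [validateNetwork()] for semantic findings.
#'
#' @param nodes data.frame of node specifications (see
#'   [BooleanNetwork-class]).
#' @param edges data.frame of signed, optionally gated edges.
#' @param patterns named list of [StatePattern-class] objects.
#' @param events list of [EventRule-class] objects.
#' @param phases data.frame with columns `pattern`, `label`.
#' @param outputNodes node names reported by default in trajectory output;
#'   defaults to all nodes.
#' @return a [BooleanNetwork-class]
#' @export
booleanNetwork <- function(nodes, edges = .emptyEdges(), patterns = list(),
                           events = list(), phases = .emptyPhases(),
                           outputNodes = nodes$name) {
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  rownames(phases) <- NULL
  nodes$threshold <- as.numeric(nodes$threshold)
  nodes$clamp <- as.integer(nodes$clamp)
  nodes$initialState <- as.integer(nodes$initialState)
  edges$sign <- as.integer(edges$sign)
  edges$gate <- as.character(edges$gate)
  new("BooleanNetwork", nodes = nodes, edges = edges, patterns = patterns,
      events = events, phases = phases,
      outputNodes = as.character(outputNodes))
}

## ---- accessors -------------------------------------------------------------

#' @describeIn nodeNames node names of a network
#' @export
setMethod("nodeNames", "BooleanNetwork", function(x) x@nodes$name)

#' @describeIn nodeCount number of nodes of a network
#' @export
setMethod("nodeCount", "BooleanNetwork", function(x) nrow(x@nodes))

#' @describeIn initialState initial state of a network (clamped nodes carry
#'   their clamp value)
#' @export
setMethod("initialState", "BooleanNetwork", function(x) {
  s <- x@nodes$initialState
  cl <- !is.na(x@nodes$clamp)
  s[cl] <- x@nodes$clamp[cl]
  names(s) <- x@nodes$name
  s
})

#' @describeIn nodeTable node table of a network
#' @export
setMethod("nodeTable", "BooleanNetwork", function(x) x@nodes)

#' @describeIn edgeTable edge table of a network
#' @export
setMethod("edgeTable", "BooleanNetwork", function(x) x@edges)

#' @describeIn networkPatterns named pattern list of a network
#' @export
setMethod("networkPatterns", "BooleanNetwork", function(x) x@patterns)

#' @describeIn networkEvents event rules of a network
#' @export
setMethod("networkEvents", "BooleanNetwork", function(x) x@events)

#' @describeIn phaseTable phase table of a network
#' @export
setMethod("phaseTable", "BooleanNetwork", function(x) x@phases)

#' @describeIn states states of a trajectory
#' @export
setMethod("states", "Trajectory", function(x) x@states)

#' @describeIn states states of an attractor
#' @export
setMethod("states", "Attractor", function(x) x@states)

#' @describeIn phaseLabels phase labels of a trajectory
#' @export
setMethod("phaseLabels", "Trajectory", function(x) x@phases)

#' @describeIn basinSize basin size of an attractor
#' @export
setMethod("basinSize", "Attractor", function(x) x@basinSize)

#' Coerce a trajectory to a data.frame
#'
#' @param x a [Trajectory-class]
#' @param row.names,optional ignored (base signature)
#' @param phases include a `Phase` column after `Time`?
#' @param ... ignored
#' @return data.frame with a `Time` column, optional `Phase`, then one 0/1
#'   column per node in network order.
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL, optional = FALSE,
                                     phases = FALSE, ...) {
  df <- data.frame(Time = seq_len(nrow(x@states)), stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (phases) df$Phase <- x@phases
  cbind(df, as.data.frame(x@states, check.names = FALSE))
}

setMethod("show", "StatePattern", function(object) {
  cn <- object@constraints
  body <- if (length(cn)) paste(names(cn), cn, sep = "=", collapse = ", ")
          else "<matches any state>"
  cat("StatePattern {", body, "}",
      if (nzchar(object@label)) paste0(' label="', object@label, '"') else "",
      "\n", sep = "")
})

setMethod("show", "EventRule", function(object) {
  cat("EventRule", object@name, "priority", object@priority,
      "trigger", object@trigger, "\n")
  if (length(object@condition))
    cat("  when any of:", paste(object@condition, collapse = ", "), "\n")
  cat("  set", paste(names(object@assignments), object@assignments,
                     sep = "=", collapse = ", "), "\n")
})

setMethod("show", "BooleanNetwork", function(object) {
  cat("BooleanNetwork with", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges,", length(object@events), "event rules\n")
  k <- table(factor(object@nodes$kind, levels = c("core", "substrate")))
  cat("  core:", k[["core"]], " substrate:", k[["substrate"]],
      " clamped:", sum(!is.na(object@nodes$clamp)), "\n")
  cat("  nodes:", paste(object@nodes$name, collapse = ", "), "\n")
  if (nrow(object@phases))
    cat("  phase table:", nrow(object@phases), "patterns\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory of", nrow(object@states), "states over",
      ncol(object@states), "nodes\n")
  print(utils::head(as.data.frame(object, phases = TRUE), 5))
  if (nrow(object@states) > 5) cat("  ...\n")
})

setMethod("show", "Attractor", function(object) {
  cat("Attractor:", object@kind, "of length", nrow(object@states),
      if (!is.na(object@basinSize)) paste0("(basin ", object@basinSize, ")"),
      "\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("Enrichment: %d/%d in subset vs %d/%d background; fold = %g\n",
              object@k, object@n, object@K, object@M, object@fold))
  if (!is.na(object@pValue))
    cat(sprintf("  exact hypergeometric P(X >= %d) = %g\n", object@k,
                object@pValue))
})

setMethod("show", "RuleFitResult", function(object) {
  cat("RuleFitResult over", object@nConstraints, "transition constraints\n")
  for (nm in names(object@fits)) {
    f <- object@fits[[nm]]
    cat(sprintf("  %s: %d consistent parameterisation(s)\n", nm, nrow(f)))
  }
})

## ---- pattern matching ------------------------------------------------------

#' Does a pattern match a state?
#'
#' @param p a [StatePattern-class]
#' @param s a complete named binary state vector
#' @return TRUE iff every constrained node carries its required value; the
#'   empty pattern matches every state.
#' @examples
#' patternMatches(statePattern(c(Start = 1)), c(Start = 1, Ste9 = 0))
#' @export
patternMatches <- function(p, s) {
  stopifnot(is(p, "StatePattern"))
  cn <- p@constraints
  if (!length(cn)) return(TRUE)
  missing <- setdiff(names(cn), names(s))
  if (length(missing))
    stop("pattern constrains unknown node(s): ",
         paste(missing, collapse = ", "))
  all(s[names(cn)] == cn)
}

## Vectorised pattern match over a state matrix (columns named by node).
.patternMatchesMatrix <- function(p, S) {
  cn <- p@constraints
  if (!length(cn)) return(rep(TRUE, nrow(S)))
  missing <- setdiff(names(cn), colnames(S))
  if (length(missing))
    stop("pattern constrains unknown node(s): ",
         paste(missing, collapse = ", "))
  sub <- S[, names(cn), drop = FALSE]
  rowSums(sub == rep(cn, each = nrow(S))) == length(cn)
}

## Two partial patterns are jointly satisfiable iff they do not require
## different values for any shared node.
.patternsCompatible <- function(p, q) {
  shared <- intersect(names(p@constraints), names(q@constraints))
  all(p@constraints[shared] == q@constraints[shared])
}

.resolvePattern <- function(net, name) {
  p <- net@patterns[[name]]
  if (is.null(p)) stop("unknown pattern: ", name)
  p
}

## ---- validation ------------------------------------------------------------

#' Validate a network's semantic invariants
#'
#' Checks that node names are unique, that every edge endpoint, gate, event
#' pattern and event/pattern node reference resolves, that no two jointly
#' satisfiable equal-priority events assign the same node, and that no state
#' can match two phase-table patterns. Findings are returned as data, not
#' raised as errors, so broken networks can be inspected.
#'
#' @param net a [BooleanNetwork-class]
#' @return character vector of findings; empty for a well-formed network.
#' @export
validateNetwork <- function(net) {
  findings <- character(0)
  nn <- net@nodes$name
  dup <- unique(nn[duplicated(nn)])
  if (length(dup))
    findings <- c(findings, paste0("duplicate node name: ", dup))
  pn <- names(net@patterns)
  for (i in seq_len(nrow(net@edges))) {
    e <- net@edges[i, ]
    bad <- setdiff(c(e$source, e$target), nn)
    if (length(bad))
      findings <- c(findings,
        paste0("unresolved endpoint '", bad, "' in edge ", e$source,
               " -> ", e$target))
    if (!e$sign %in% c(-1L, 1L))
      findings <- c(findings,
        paste0("edge ", e$source, " -> ", e$target, " has sign ", e$sign,
               "; only +1/-1 allowed"))
    if (!is.na(e$gate) && !e$gate %in% pn)
      findings <- c(findings,
        paste0("edge ", e$source, " -> ", e$target,
               " gated by unknown pattern '", e$gate, "'"))
  }
  thetaGrid <- getOption("PombeCycleBN.thetaGrid", .DEFAULT_THETA_GRID)
  off <- !net@nodes$threshold %in% thetaGrid
  if (any(off))
    findings <- c(findings,
      paste0("node ", nn[off], " has threshold ", net@nodes$threshold[off],
             " outside the grid {", paste(thetaGrid, collapse = ", "), "}"))
  for (p in net@patterns) {
    bad <- setdiff(names(p@constraints), nn)
    if (length(bad))
      findings <- c(findings,
        paste0("pattern constrains unknown node: ", bad))
  }
  for (ev in net@events) {
    if (!ev@trigger %in% pn)
      findings <- c(findings,
        paste0("event '", ev@name, "' has unknown trigger pattern '",
               ev@trigger, "'"))
    badc <- setdiff(ev@condition, pn)
    if (length(badc))
      findings <- c(findings,
        paste0("event '", ev@name, "' has unknown condition pattern '",
               badc, "'"))
    bada <- setdiff(names(ev@assignments), nn)
    if (length(bada))
      findings <- c(findings,
        paste0("event '", ev@name, "' assigns unknown node: ", bada))
  }
  ## ambiguous overrides: equal priority, shared assigned node, jointly
  ## satisfiable triggers
  evs <- net@events
  if (length(evs) > 1L) {
    for (i in seq_len(length(evs) - 1L)) {
      for (j in seq(i + 1L, length(evs))) {
        a <- evs[[i]]; b <- evs[[j]]
        if (a@priority != b@priority) next
        shared <- intersect(names(a@assignments), names(b@assignments))
        if (!length(shared)) next
        if (!a@trigger %in% pn || !b@trigger %in% pn) next
        if (.patternsCompatible(net@patterns[[a@trigger]],
                                net@patterns[[b@trigger]]))
          findings <- c(findings,
            paste0("ambiguous override: events '", a@name, "' and '",
                   b@name, "' share priority ", a@priority,
                   " and may both assign node(s) ",
                   paste(shared, collapse = ", ")))
      }
    }
  }
  ## overlapping phase patterns
  ph <- net@phases$pattern
  badp <- setdiff(ph, pn)
  if (length(badp))
    findings <- c(findings, paste0("phase table references unknown pattern: ",
                                   badp))
  ph <- intersect(ph, pn)
  if (length(ph) > 1L) {
    for (i in seq_len(length(ph) - 1L)) {
      for (j in seq(i + 1L, length(ph))) {
        if (.patternsCompatible(net@patterns[[ph[i]]], net@patterns[[ph[j]]]))
          findings <- c(findings,
            paste0("overlapping phase patterns: '", ph[i], "' and '",
                   ph[j], "' can match the same state"))
      }
    }
  }
  bado <- setdiff(net@outputNodes, nn)
  if (length(bado))
    findings <- c(findings, paste0("unknown output node: ", bado))
  findings
}
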