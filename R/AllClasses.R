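#' @import methods
NULL

.BINARY <- c(0L, 1L)

## Default grid of admissible activation thresholds. Half-integer values can
## never equal an integer input sum, so nodes with half-integer thresholds have
## no equality (hold/decay) cases.
.DEFAULT_THETA_GRID <- c(-1, -0.5, 0, 0.5, 1)

#' StatePattern: a partial constraint over network states
#'
#' A `StatePattern` fixes a subset of nodes to required binary values. A
#' pattern matches a state when every constrained node carries the required
#' value; the empty pattern matches every state. Patterns serve two purposes:
#' gating edges or event rules to an exact cell-cycle phase state, and
#' labelling states with phase names.
#'
#' @slot constraints named integer vector of required values (0 or 1); names
#'   are node names.
#' @slot label free-text annotation, e.g. the cell-cycle phase the pattern
#'   corresponds to.
#' @export
setClass("StatePattern",
  representation(constraints = "integer", label = "character"),
  prototype(constraints = integer(0), label = "")
)

setValidity("StatePattern", function(object) {
  msg <- character(0)
  cn <- object@constraints
  if (length(cn)) {
    if (is.null(names(cn)) || any(!nzchar(names(cn))))
      msg <- c(msg, "all constraints must be named")
    if (anyDuplicated(names(cn)))
      msg <- c(msg, "constraint node names must be unique")
    if (!all(cn %in% .BINARY))
      msg <- c(msg, "constraint values must be 0 or 1")
  }
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single string")
  if (length(msg)) msg else TRUE
})

#' EventRule: a pattern-triggered forced assignment
#'
#' Event rules are the mechanism by which added regulators act only during a
#' specific phase of the cell cycle: when the full network state at time t
#' matches the trigger pattern (and, if given, at least one of the alternative
#' condition patterns), the rule forces the assigned nodes to fixed values at
#' time t+1, overriding their threshold-rule result. When several fired rules
#' assign the same node, the rule with the higher priority wins; two fired
#' rules of equal priority assigning the same node are a model-validation
#' error.
#'
#' @slot name identifier.
#' @slot priority integer; higher priority overrides lower.
#' @slot trigger name of a pattern in the owning network, evaluated on the
#'   state at time t.
#' @slot condition character vector of pattern names; the rule fires only if
#'   at least one of them also matches (OR semantics). Empty means no extra
#'   condition.
#' @slot assignments named integer vector of forced values at time t+1.
#' @export
setClass("EventRule",
  representation(name = "character", priority = "integer",
                 trigger = "character", condition = "character",
                 assignments = "integer")
)

setValidity("EventRule", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@priority) != 1L || is.na(object@priority))
    msg <- c(msg, "priority must be a single integer")
  if (length(object@trigger) != 1L)
    msg <- c(msg, "trigger must name exactly one pattern")
  a <- object@assignments
  if (!length(a))
    msg <- c(msg, "an event must assign at least one node")
  if (length(a) && (is.null(names(a)) || anyDuplicated(names(a)) ||
                    !all(a %in% .BINARY)))
    msg <- c(msg, "assignments must be uniquely named binary values")
  if (length(msg)) msg else TRUE
})

#' BooleanNetwork: a threshold Boolean network with phase-gated events
#'
#' The central model container. Nodes update synchronously by a signed
#' threshold rule (see [thresholdNext()]); edges carry weight +1 or -1 and may
#' be gated by a [StatePattern-class]; event rules force phase-specific
#' assignments; a phase table maps exact core-node states to cell-cycle phase
#' labels.
#'
#' @slot nodes data.frame with columns `name`, `kind` ("core" or "substrate"),
#'   `threshold` (numeric), `selfDegrading` (logical), `clamp` (integer 0/1 or
#'   NA for unclamped) and `initialState` (integer 0/1). Row order defines the
#'   column order of every trajectory table.
#' @slot edges data.frame with columns `source`, `target`, `sign` (+1/-1) and
#'   `gate` (pattern name or NA for an ungated edge).
#' @slot patterns named list of [StatePattern-class] objects.
#' @slot events list of [EventRule-class] objects.
#' @slot phases data.frame with columns `pattern` (pattern name) and `label`
#'   (phase label), in printed-table order.
#' @slot outputNodes character vector of node names reported by default in
#'   trajectory output (the printed table columns of the model variant).
#' @export
setClass("BooleanNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 patterns = "list", events = "list",
                 phases = "data.frame", outputNodes = "character")
)

## Validity checks shapes and types only; semantic invariants (resolvable
## references, unique names, unambiguous events, non-overlapping phases) are
## reported as data by validateNetwork() so that deliberately broken networks
## can be constructed and inspected.
setValidity("BooleanNetwork", function(object) {
  msg <- character(0)
  ncols <- c("name", "kind", "threshold", "selfDegrading", "clamp",
             "initialState")
  if (!all(ncols %in% names(object@nodes)))
    msg <- c(msg, paste("nodes must have columns:",
                        paste(ncols, collapse = ", ")))
  ecols <- c("source", "target", "sign", "gate")
  if (!all(ecols %in% names(object@edges)))
    msg <- c(msg, paste("edges must have columns:",
                        paste(ecols, collapse = ", ")))
  if (length(object@patterns) &&
      (is.null(names(object@patterns)) ||
       !all(vapply(object@patterns, is, logical(1), "StatePattern"))))
    msg <- c(msg, "patterns must be a named list of StatePattern objects")
  if (length(object@events) &&
      !all(vapply(object@events, is, logical(1), "EventRule")))
    msg <- c(msg, "events must be a list of EventRule objects")
  if (!all(c("pattern", "label") %in% names(object@phases)))
    msg <- c(msg, "phases must have columns pattern and label")
  if (length(msg)) msg else TRUE
})

#' Trajectory: a time-ordered sequence of network states
#'
#' Rows are complete binary states at times 1, 2, ...; the parallel `phases`
#' vector carries the cell-cycle phase label of each state (or "unassigned").
#' Produced by [simulateNetwork()]; each row is the synchronous successor of
#' its predecessor under the generating network.
#'
#' @slot states integer matrix, one row per time step, one column per node
#'   (column names are node names, rows are times starting at 1).
#' @slot phases character vector, one label per row.
#' @export
setClass("Trajectory",
  representation(states = "matrix", phases = "character")
)

setValidity("Trajectory", function(object) {
  msg <- character(0)
  s <- object@states
  if (!is.numeric(s) || is.null(colnames(s)))
    msg <- c(msg, "states must be a numeric matrix with node column names")
  else if (!all(s %in% .BINARY))
    msg <- c(msg, "states must be binary (0/1)")
  if (length(object@phases) != nrow(s))
    msg <- c(msg, "phases must have one label per state")
  if (length(msg)) msg else TRUE
})

#' Attractor: a fixed point or limit cycle
#'
#' @slot kind "fixed_point" or "cycle".
#' @slot states integer matrix of attractor states (one row for a fixed
#'   point); consecutive rows are successors and the last row maps back to the
#'   first.
#' @slot basinSize number of states (attractor states included) whose
#'   trajectories reach this attractor; NA when not computed (e.g. by
#'   [detectAttractor()]).
#' @export
setClass("Attractor",
  representation(kind = "character", states = "matrix", basinSize = "integer")
)

setValidity("Attractor", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("fixed_point", "cycle"))
    msg <- c(msg, "kind must be 'fixed_point' or 'cycle'")
  if (object@kind == "fixed_point" && nrow(object@states) != 1L)
    msg <- c(msg, "a fixed point has exactly one state")
  if (object@kind == "cycle" && nrow(object@states) < 2L)
    msg <- c(msg, "a cycle has at least two states")
  if (length(msg)) msg else TRUE
})

#' RuleFitResult: consistent threshold parameterisations per node
#'
#' Result of [fitNodeRules()]: for every fitted node, all (threshold,
#' self-degradation) combinations on the search grid that reproduce every
#' supplied state transition exactly.
#'
#' @slot fits named list, one data.frame per node with columns `threshold`
#'   and `selfDegrading`.
#' @slot nConstraints number of transition constraints used.
#' @export
setClass("RuleFitResult",
  representation(fits = "list", nConstraints = "integer")
)

#' EnrichmentResult: fold enrichment of a property within a gene subset
#'
#' @slot k number of subset genes with the property (e.g. oscillating
#'   transcription-factor target genes).
#' @slot n subset size.
#' @slot K number of background genes with the property.
#' @slot M background size (genome).
#' @slot fold (k/n)/(K/M).
#' @slot pValue exact hypergeometric upper-tail probability of >= k successes
#'   in n draws; NA unless requested.
#' @export
setClass("EnrichmentResult",
  representation(k = "numeric", n = "numeric", K = "numeric", M = "numeric",
                 fold = "numeric", pValue = "numeric")
)
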