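#' @include netmodel.R
NULL

## ---- network text format ---------------------------------------------------
## One statement per line, '#' starts a full-line comment:
##   node <name> kind=<core|substrate> theta=<v> selfdeg=<0|1> clamp=<0|1|none> init=<0|1>
##   pattern <name> {<node>=<0|1>, ...} label="<text>"
##   edge <source> -> <target> sign=<+|-> gate=<pattern-name|none>
##   event <name> priority=<int> trigger=<pattern-name> when=<names|none> set {<node>=<0|1>, ...}
##   phase <pattern-name> "<label>"
##   outputs <name> <name> ...
## `when=` takes a comma-separated list of pattern names (OR over the list).
## Node names may contain any non-whitespace characters except '=' and ','.

.parseConstraints <- function(body, where) {
  body <- trimws(body)
  if (!nzchar(body)) return(integer(0))
  parts <- strsplit(body, ",", fixed = TRUE)[[1]]
  kv <- regmatches(parts, regexec("^\\s*(\\S+)\\s*=\\s*([01])\\s*$", parts))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    stop("line ", where, ": malformed constraint '", trimws(parts[bad][1]),
         "'")
  vals <- as.integer(vapply(kv, `[[`, character(1), 3L))
  names(vals) <- vapply(kv, `[[`, character(1), 2L)
  vals
}

#' Read a network from the plain-text format
#'
#' Parses the one-statement-per-line network format (see the package
#' vignette), then runs [validateNetwork()]; findings are raised as an error.
#' Syntax errors report the offending line number.
#'
#' @param path file path (UTF-8; CRLF tolerated).
#' @return a validated [BooleanNetwork-class]
#' @examples
#' core <- loadNetwork(
#'   system.file("extdata", "core.net", package = "PombeCycleBN"))
#' @export
loadNetwork <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE, encoding = "UTF-8"))
  nodes <- list(); edges <- list(); patterns <- list()
  events <- list(); phases <- list(); outputs <- NULL
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "node ")) {
      m <- regexec(paste0("^node\\s+(\\S+)\\s+kind=(core|substrate)",
                          "\\s+theta=(-?[0-9.]+)\\s+selfdeg=([01])",
                          "\\s+clamp=(0|1|none)\\s+init=([01])$"), line)
      g <- regmatches(line, m)[[1]]
      if (!length(g)) stop("line ", ln, ": malformed node statement")
      if (g[2] %in% vapply(nodes, function(x) x$name, character(1)))
        stop("line ", ln, ": duplicate node '", g[2], "'")
      nodes[[length(nodes) + 1L]] <-
        .nodeSpec(g[2], kind = g[3], threshold = as.numeric(g[4]),
                  selfDegrading = g[5] == "1",
                  clamp = if (g[6] == "none") NA_integer_
                          else as.integer(g[6]),
                  initialState = as.integer(g[7]))
    } else if (startsWith(line, "edge ")) {
      m <- regexec("^edge\\s+(\\S+)\\s+->\\s+(\\S+)\\s+sign=([+-])\\s+gate=(\\S+)$",
                   line)
      g <- regmatches(line, m)[[1]]
      if (!length(g)) stop("line ", ln, ": malformed edge statement")
      edges[[length(edges) + 1L]] <-
        .edgeSpec(g[2], g[3], if (g[4] == "+") 1L else -1L,
                  gate = if (g[5] == "none") NA_character_ else g[5])
    } else if (startsWith(line, "pattern ")) {
      m <- regexec("^pattern\\s+(\\S+)\\s+\\{([^}]*)\\}\\s+label=\"([^\"]*)\"$",
                   line)
      g <- regmatches(line, m)[[1]]
      if (!length(g)) stop("line ", ln, ": malformed pattern statement")
      if (g[2] %in% names(patterns))
        stop("line ", ln, ": duplicate pattern '", g[2], "'")
      patterns[[g[2]]] <- statePattern(.parseConstraints(g[3], ln),
                                       label = g[4])
    } else if (startsWith(line, "event ")) {
      m <- regexec(paste0("^event\\s+(\\S+)\\s+priority=(-?[0-9]+)",
                          "\\s+trigger=(\\S+)\\s+when=(\\S+)",
                          "\\s+set\\s+\\{([^}]*)\\}$"), line)
      g <- regmatches(line, m)[[1]]
      if (!length(g)) stop("line ", ln, ": malformed event statement")
      cond <- if (g[5] == "none") character(0)
              else strsplit(g[5], ",", fixed = TRUE)[[1]]
      events[[length(events) + 1L]] <-
        eventRule(g[2], trigger = g[4], condition = cond,
                  assignments = .parseConstraints(g[6], ln),
                  priority = as.integer(g[3]))
    } else if (startsWith(line, "phase ")) {
      m <- regexec("^phase\\s+(\\S+)\\s+\"([^\"]*)\"$", line)
      g <- regmatches(line, m)[[1]]
      if (!length(g)) stop("line ", ln, ": malformed phase statement")
      phases[[length(phases) + 1L]] <- data.frame(pattern = g[2],
                                                  label = g[3],
                                                  stringsAsFactors = FALSE)
    } else if (startsWith(line, "outputs ")) {
      outputs <- strsplit(trimws(sub("^outputs", "", line)), "\\s+")[[1]]
    } else {
      stop("line ", ln, ": unrecognised statement: ", line)
    }
  }
  if (!length(nodes)) stop("network file declares no nodes")
  nodes <- do.call(rbind, nodes)
  edges <- if (length(edges)) do.call(rbind, edges) else .emptyEdges()
  phases <- if (length(phases)) do.call(rbind, phases) else .emptyPhases()
  net <- booleanNetwork(nodes, edges, patterns = patterns, events = events,
                        phases = phases,
                        outputNodes = if (is.null(outputs)) nodes$name
                                      else outputs)
  findings <- validateNetwork(net)
  if (length(findings))
    stop("network failed validation:\n  ",
         paste(findings, collapse = "\n  "))
  net
}

.fmtConstraints <- function(cn)
  paste0("{", paste(names(cn), cn, sep = "=", collapse = ", "), "}")

#' Write a network in the plain-text format
#'
#' Serialises a network so that [loadNetwork()] reproduces it field by field.
#'
#' @param net a [BooleanNetwork-class]
#' @param path output file path.
#' @return `path`, invisibly
#' @export
writeNetwork <- function(net, path) {
  out <- character(0)
  for (i in seq_len(nrow(net@nodes))) {
    nd <- net@nodes[i, ]
    out <- c(out, sprintf("node %s kind=%s theta=%s selfdeg=%d clamp=%s init=%d",
                          nd$name, nd$kind, format(nd$threshold),
                          as.integer(nd$selfDegrading),
                          if (is.na(nd$clamp)) "none" else nd$clamp,
                          nd$initialState))
  }
  for (nm in names(net@patterns)) {
    p <- net@patterns[[nm]]
    out <- c(out, sprintf('pattern %s %s label="%s"', nm,
                          .fmtConstraints(p@constraints), p@label))
  }
  for (i in seq_len(nrow(net@edges))) {
    e <- net@edges[i, ]
    out <- c(out, sprintf("edge %s -> %s sign=%s gate=%s", e$source,
                          e$target, if (e$sign > 0) "+" else "-",
                          if (is.na(e$gate)) "none" else e$gate))
  }
  for (ev in net@events) {
    out <- c(out, sprintf("event %s priority=%d trigger=%s when=%s set %s",
                          ev@name, ev@priority, ev@trigger,
                          if (length(ev@condition))
                            paste(ev@condition, collapse = ",")
                          else "none",
                          .fmtConstraints(ev@assignments)))
  }
  for (i in seq_len(nrow(net@phases)))
    out <- c(out, sprintf('phase %s "%s"', net@phases$pattern[i],
                          net@phases$label[i]))
  if (!identical(net@outputNodes, net@nodes$name))
    out <- c(out, paste("outputs", paste(net@outputNodes, collapse = " ")))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

## ---- trajectory tables -----------------------------------------------------

#' Read a binary state table (TSV)
#'
#' Reads tab-separated tables with a `Time` column, an optional `Phase`
#' column and one 0/1 column per node, the layout of the printed temporal
#' evolution tables. CRLF line endings are tolerated; the historical header
#' spelling "Puc1/Cdc" is normalised to "Puc1/Cdc2".
#'
#' @param path file path.
#' @return data.frame with `Time`, optional `Phase`, and integer node columns
#' @export
readStateTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- sub("\r$", "", names(df))
  names(df) <- sub("^Puc1/Cdc$", "Puc1/Cdc2", names(df))
  if (is.character(df[[ncol(df)]]))
    df[[ncol(df)]] <- sub("\r$", "", df[[ncol(df)]])
  for (nm in setdiff(names(df), "Phase")) df[[nm]] <- as.integer(df[[nm]])
  df
}

#' Write a trajectory as TSV
#'
#' Writes `Time`, optionally `Phase`, then one 0/1 column per node in network
#' column order, tab-separated with LF line endings - byte-comparable to the
#' bundled golden tables. Re-reading with [readStateTable()] reproduces the
#' trajectory exactly.
#'
#' @param traj a [Trajectory-class] (must be non-empty).
#' @param path output path or connection.
#' @param phases include the `Phase` column?
#' @param columns node columns to write; defaults to all trajectory columns.
#' @return `path`, invisibly
#' @export
writeTrajectory <- function(traj, path, phases = FALSE, columns = NULL) {
  stopifnot(is(traj, "Trajectory"), nrow(traj@states) > 0L)
  df <- as.data.frame(traj, phases = phases)
  if (!is.null(columns)) {
    unknown <- setdiff(columns, colnames(traj@states))
    if (length(unknown))
      stop("unknown column(s): ", paste(unknown, collapse = ", "))
    df <- df[, c("Time", if (phases) "Phase", columns), drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

## ---- GraphML export --------------------------------------------------------

#' Export a network topology as GraphML
#'
#' Nodes carry `kind`, `threshold`, `selfdeg`, `clamp` and `init` attributes;
#' edges carry `sign` and the gate pattern label (`"none"` for ungated
#' edges). Node and edge counts round-trip through any GraphML reader.
#'
#' @param net a [BooleanNetwork-class]
#' @param path output file path.
#' @return `path`, invisibly
#' @export
exportGraphML <- function(net, path) {
  nd <- net@nodes
  vertices <- data.frame(name = nd$name, kind = nd$kind,
                         threshold = nd$threshold,
                         selfdeg = as.integer(nd$selfDegrading),
                         clamp = ifelse(is.na(nd$clamp), "none",
                                        as.character(nd$clamp)),
                         init = nd$initialState, stringsAsFactors = FALSE)
  if (nrow(net@edges)) {
    ed <- data.frame(from = net@edges$source, to = net@edges$target,
                     sign = net@edges$sign,
                     gate = ifelse(is.na(net@edges$gate), "none",
                                   net@edges$gate),
                     stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                       vertices = vertices)
  } else if (nrow(vertices)) {
    g <- igraph::make_empty_graph(directed = TRUE)
    g <- igraph::add_vertices(g, nrow(vertices), attr = as.list(vertices))
  } else {
    g <- igraph::make_empty_graph(directed = TRUE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

## ---- random networks for property testing ----------------------------------

#' Generate a reproducible random threshold network
#'
#' Draws a network over `nNodes` core nodes: each ordered pair of distinct
#' nodes carries an edge with probability `edgeProb`, signs are +1/-1 with
#' equal probability, thresholds are drawn uniformly from the default fitting
#' grid \{-0.5, 0, 0.5\}, each node self-degrades with probability
#' `selfdegProb`, and initial states are fair coin flips. The generator state
#' of the session is left untouched; the same seed always yields the same
#' network.
#'
#' @param nNodes number of nodes (>= 1).
#' @param edgeProb probability of each directed edge (no self-loops).
#' @param selfdegProb probability of the self-degradation flag.
#' @param seed integer seed.
#' @return a [BooleanNetwork-class] passing [validateNetwork()]
#' @export
randomNetwork <- function(nNodes, edgeProb, selfdegProb, seed) {
  stopifnot(nNodes >= 1, edgeProb >= 0, edgeProb <= 1,
            selfdegProb >= 0, selfdegProb <= 1)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  nn <- sprintf("n%02d", seq_len(nNodes))
  nodes <- .nodeSpec(nn,
                     threshold = sample(c(-0.5, 0, 0.5), nNodes,
                                        replace = TRUE),
                     selfDegrading = stats::runif(nNodes) < selfdegProb,
                     initialState = sample(0:1, nNodes, replace = TRUE))
  pairs <- expand.grid(source = nn, target = nn, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < edgeProb
  pairs <- pairs[keep, , drop = FALSE]
  edges <- if (nrow(pairs))
    .edgeSpec(pairs$source, pairs$target,
              sample(c(-1L, 1L), nrow(pairs), replace = TRUE))
  else .emptyEdges()
  net <- booleanNetwork(nodes, edges)
  findings <- validateNetwork(net)
  if (length(findings))  # should be unreachable
    stop("generated network failed validation: ",
         paste(findings, collapse = "; "))
  net
}
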