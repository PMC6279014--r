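extfile <- function(...) {
  system.file("extdata", ..., package = "PombeCycleBN", mustWork = TRUE)
}

nodeRow <- function(name, kind = "core", threshold = 0, selfDegrading = FALSE,
                    clamp = NA_integer_, initialState = 0L) {
  data.frame(name = name, kind = kind, threshold = threshold,
             selfDegrading = selfDegrading, clamp = as.integer(clamp),
             initialState = as.integer(initialState),
             stringsAsFactors = FALSE)
}

edgeRow <- function(source, target, sign, gate = NA_character_) {
  data.frame(source = source, target = target, sign = as.integer(sign),
             gate = gate, stringsAsFactors = FALSE)
}

## A <-> B mutual activation, theta = 0, no self-degradation: fixed points
## {0,0} (basin 1) and {1,1} (basin 3), worked out over all 4 states by hand.
twoNodeMutual <- function() {
  booleanNetwork(rbind(nodeRow("A"), nodeRow("B")),
                 rbind(edgeRow("A", "B", +1), edgeRow("B", "A", +1)))
}

isolatedNode <- function(selfDegrading = FALSE, initialState = 1L) {
  booleanNetwork(nodeRow("A", selfDegrading = selfDegrading,
                         initialState = initialState))
}

## State of row r of a printed table, as a named binary vector.
tableRowState <- function(tab, r) {
  cols <- setdiff(names(tab), c("Time", "Phase"))
  s <- as.integer(unlist(tab[r, cols]))
  names(s) <- cols
  s
}

## Independent brute-force attractor assignment: walk every state with
## stepState() until a state repeats, and return a canonical key (the
## lexicographically smallest state string on the cycle) per initial state.
bruteAttractorKeys <- function(net) {
  nn <- nodeNames(net)
  n <- length(nn)
  all <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(all) <- nn
  apply(all, 1L, function(s) {
    s <- stats::setNames(as.integer(s), nn)
    seen <- character(0)
    repeat {
      key <- paste(s, collapse = "")
      hit <- match(key, seen)
      if (!is.na(hit)) return(min(seen[seq(hit, length(seen))]))
      seen <- c(seen, key)
      s <- stepState(net, s)
    }
  })
}

## Exact upper-tail hypergeometric probability by enumeration of all
## n-subsets of M elements (feasible for M <= 12).
hyperTailBrute <- function(k, n, K, M) {
  subsets <- utils::combn(M, n)
  hits <- colSums(subsets <= K) >= k  # elements 1..K carry the property
  mean(hits)
}
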