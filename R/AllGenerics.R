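#' @include AllClasses.R
NULL

#' Node names of a network, in table column order
#' @param x a [BooleanNetwork-class]
#' @return character vector
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' Number of nodes
#' @param x a [BooleanNetwork-class]
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' Initial state of a network
#' @param x a [BooleanNetwork-class]
#' @return named integer vector of 0/1 values
#' @export
setGeneric("initialState", function(x) standardGeneric("initialState"))

#' Node table of a network
#' @param x a [BooleanNetwork-class]
#' @return data.frame of node specifications
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' Edge table of a network
#' @param x a [BooleanNetwork-class]
#' @return data.frame with source, target, sign, gate
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Named patterns of a network
#' @param x a [BooleanNetwork-class]
#' @return named list of [StatePattern-class]
#' @export
setGeneric("networkPatterns", function(x) standardGeneric("networkPatterns"))

#' Event rules of a network
#' @param x a [BooleanNetwork-class]
#' @return list of [EventRule-class]
#' @export
setGeneric("networkEvents", function(x) standardGeneric("networkEvents"))

#' Phase table of a network
#' @param x a [BooleanNetwork-class]
#' @return data.frame with pattern and label columns
#' @export
setGeneric("phaseTable", function(x) standardGeneric("phaseTable"))

#' State matrix of a trajectory or attractor
#' @param x a [Trajectory-class] or [Attractor-class]
#' @return integer matrix, rows are time steps
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' Phase labels of a trajectory
#' @param x a [Trajectory-class]
#' @return character vector
#' @export
setGeneric("phaseLabels", function(x) standardGeneric("phaseLabels"))

#' Basin size of an attractor
#' @param x an [Attractor-class]
#' @return integer (NA when not computed)
#' @export
setGeneric("basinSize", function(x) standardGeneric("basinSize"))
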