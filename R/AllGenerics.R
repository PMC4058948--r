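#' Node identifiers of a network
#' @param x a network object.
#' @return character vector of node identifiers.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Edge table of a network
#' @param x a network object.
#' @return data.frame of indexed edges.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Number of nodes
#' @param x a network object.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges
#' @param x a network object.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Profile matrix of a reachability profile
#' @param x a [ReachabilityProfile-class].
#' @return numeric matrix with source ids as row names and target ids as
#'   column names.
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))
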