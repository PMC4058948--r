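#' Construct a probabilistic network from edge vectors
#'
#' @param from,to character vectors of edge endpoints (equal length).
#' @param prob numeric vector of edge existence probabilities. Must lie in
#'   `(0, 1]`; zero is only admitted with `allowZero = TRUE`, which internal
#'   analyses (probability perturbation) use.
#' @param nodes optional character vector of node identifiers; defaults to
#'   the endpoints in order of first appearance. Extra entries add isolated
#'   nodes.
#' @param name optional network label.
#' @param allowZero admit probability-0 edges (internal use).
#'
#' @return A [ProbabilisticNetwork-class].
#' @examples
#' net <- probNetwork(c("a", "b"), c("b", "c"), c(0.5, 0.5))
#' numEdges(net)
#' @export
probNetwork <- function(from, to, prob, nodes = NULL, name = "",
                        allowZero = FALSE) {
  from <- as.character(from)
  to <- as.character(to)
  prob <- as.numeric(prob)
  if (length(from) != length(to) || length(from) != length(prob))
    stop("'from', 'to' and 'prob' must have equal length")
  if (anyNA(prob)) stop("edge probabilities must not be missing")
  bad <- which(prob < 0 | prob > 1 | (!allowZero & prob == 0))
  if (length(bad))
    stop("edge probability out of (0, 1] at edge ", bad[1L], ": ", prob[bad[1L]])
  if (any(grepl("[\x1e\x1f[:space:]]", c(from, to))))
    stop("node identifiers must not contain whitespace or control characters")
  if (is.null(nodes)) nodes <- unique(c(from, to)) else {
    nodes <- as.character(nodes)
    nodes <- unique(c(nodes, from, to))
  }
  edges <- data.frame(index = seq_along(from), from = from, to = to,
                      prob = prob, stringsAsFactors = FALSE)
  new("ProbabilisticNetwork", nodes = nodes, edges = edges, name = name)
}

#' Read a probabilistic network from a whitespace-separated edge list
#'
#' Each non-comment line is `source target probability`. Lines whose first
#' non-blank character is `#` and blank lines are ignored. With
#' `undirected = TRUE` every input line yields two directed edges in
#' opposite directions, both carrying the line's probability and treated as
#' independent events.
#'
#' @param path path to the edge-list file.
#' @param undirected expand each line into two opposite directed edges.
#' @param mergeDuplicates merge `k` parallel duplicate directed edges into
#'   one with `p = 1 - prod(1 - p_k)` instead of rejecting them.
#' @return A validated [ProbabilisticNetwork-class]; edge indices follow
#'   file order (the reverse twin of an undirected line follows it
#'   immediately).
#' @seealso [writeNetwork()]
#' @export
loadNetwork <- function(path, undirected = FALSE, mergeDuplicates = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  lineNo <- seq_along(raw)
  stripped <- trimws(raw)
  keep <- nzchar(stripped) & !startsWith(stripped, "#")
  stripped <- stripped[keep]
  lineNo <- lineNo[keep]
  if (!length(stripped))
    stop("no edges found in ", path)
  fields <- strsplit(stripped, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    i <- which(nf != 3L)[1L]
    stop("malformed line ", lineNo[i], " in ", path,
         ": expected 3 whitespace-separated fields, got ", nf[i])
  }
  m <- do.call(rbind, fields)
  from <- m[, 1L]
  to <- m[, 2L]
  prob <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(prob)) {
    i <- which(is.na(prob))[1L]
    stop("malformed line ", lineNo[i], " in ", path,
         ": third field does not parse as a number")
  }
  bad <- which(prob <= 0 | prob > 1)
  if (length(bad))
    stop("invalid probability ", prob[bad[1L]], " on line ", lineNo[bad[1L]],
         " of ", path, " (must lie in (0, 1])")
  bad <- which(from == to)
  if (length(bad))
    stop("self-loop on line ", lineNo[bad[1L]], " of ", path)
  if (undirected) {
    ord <- rep(seq_along(from), each = 2L)
    swap <- rep(c(FALSE, TRUE), length(from))
    lineNo <- lineNo[ord]
    newFrom <- ifelse(swap, to[ord], from[ord])
    newTo <- ifelse(swap, from[ord], to[ord])
    from <- newFrom; to <- newTo; prob <- prob[ord]
  }
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) {
    if (mergeDuplicates) {
      first <- !duplicated(key)
      mergedP <- 1 - vapply(split(prob, factor(key, levels = key[first])),
                            function(p) prod(1 - p), numeric(1))
      from <- from[first]; to <- to[first]; prob <- unname(mergedP)
    } else {
      i <- which(duplicated(key))[1L]
      stop("duplicate directed edge ", from[i], " -> ", to[i],
           " (line ", lineNo[i], " of ", path,
           "); use mergeDuplicates = TRUE to combine parallel edges")
    }
  }
  probNetwork(from, to, prob, name = basename(path))
}

#' Write a network as a tab-separated edge list
#'
#' Emits one `source<TAB>target<TAB>probability` line per edge in index
#' order, probabilities with 17 significant digits (round-trip exact for
#' doubles). Lines in `header` are written first, prefixed with `#`.
#'
#' @param net a [ProbabilisticNetwork-class].
#' @param path output file path.
#' @param header optional character vector of comment lines.
#' @export
writeNetwork <- function(net, path, header = character()) {
  e <- net@edges
  lines <- c(if (length(header)) paste0("# ", header),
             paste(e$from, e$to, formatC(e$prob, digits = 17, format = "g"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Drop the probabilities: the maximal deterministic network
#'
#' Returns the topology in which every possible interaction is present,
#' with node set and edge indices preserved.
#'
#' @param net a [ProbabilisticNetwork-class].
#' @return A [DeterministicNetwork-class].
#' @export
maximalDeterministic <- function(net) {
  stopifnot(is(net, "ProbabilisticNetwork"))
  new("DeterministicNetwork", nodes = net@nodes,
      edges = net@edges[c("index", "from", "to")])
}

#' Restrict a network to the nodes that can carry an s-t signal
#'
#' Keeps the nodes that are reachable from `s` and from which `t` is
#' reachable in the maximal deterministic network, after first discarding
#' edges into `s` and out of `t` (no simple s-t route uses them, and
#' removing them guarantees that every surviving edge lies in the left-edge
#' set of the final separator `{t}`). `s` and `t` are always retained. The
#' s-t reachability probability is unchanged by pruning; edge indices are
#' re-assigned contiguously with the original index kept in column
#' `origIndex`.
#'
#' @param net a [ProbabilisticNetwork-class].
#' @param s,t source and target node identifiers.
#' @return The pruned [ProbabilisticNetwork-class].
#' @export
pruneForPair <- function(net, s, t) {
  .assertNode(net, s)
  .assertNode(net, t)
  e <- net@edges
  keepEdge <- !(e$to == s | e$from == t)
  g <- .graphIndex(net@nodes, e$from, e$to)
  ok <- rep(FALSE, nrow(e)); ok[which(keepEdge)] <- TRUE
  fwd <- .reachIds(g, g$id[[s]], edgeOK = ok)
  bwd <- .coReachIds(g, g$id[[t]], edgeOK = ok)
  keepNode <- (fwd & bwd)
  keepNode[c(g$id[[s]], g$id[[t]])] <- TRUE
  nodes <- net@nodes[keepNode]
  sel <- keepEdge & (e$from %in% nodes) & (e$to %in% nodes)
  kept <- e[sel, , drop = FALSE]
  out <- data.frame(index = seq_len(nrow(kept)), from = kept$from,
                    to = kept$to, prob = kept$prob,
                    origIndex = if (is.null(kept$origIndex)) kept$index else kept$origIndex,
                    stringsAsFactors = FALSE)
  new("ProbabilisticNetwork", nodes = nodes, edges = out, name = net@name)
}

#' Remove a node and its incident edges
#'
#' @param net a [ProbabilisticNetwork-class].
#' @param g node identifier to remove.
#' @return The reduced network with contiguously re-indexed edges.
#' @export
removeNode <- function(net, g) {
  .assertNode(net, g)
  e <- net@edges
  kept <- e[e$from != g & e$to != g, , drop = FALSE]
  if (nrow(kept)) kept$index <- seq_len(nrow(kept))
  probNetwork(kept$from, kept$to, kept$prob,
              nodes = setdiff(net@nodes, g), name = net@name,
              allowZero = TRUE)
}

.assertNode <- function(net, v) {
  if (length(v) != 1L || !v %in% net@nodes)
    stop("unknown node: ", paste(v, collapse = ", "))
  invisible(TRUE)
}

#' @describeIn nodeIds node identifiers of a probabilistic network
#' @export
setMethod("nodeIds", "ProbabilisticNetwork", function(x) x@nodes)
#' @describeIn nodeIds node identifiers of a deterministic network
#' @export
setMethod("nodeIds", "DeterministicNetwork", function(x) x@nodes)
#' @describeIn edgeTable edge table of a probabilistic network
#' @export
setMethod("edgeTable", "ProbabilisticNetwork", function(x) x@edges)
#' @describeIn edgeTable edge table of a deterministic network
#' @export
setMethod("edgeTable", "DeterministicNetwork", function(x) x@edges)

#' @describeIn numNodes node count of a probabilistic network
#' @export
setMethod("numNodes", "ProbabilisticNetwork", function(x) length(x@nodes))
#' @describeIn numNodes node count of a deterministic network
#' @export
setMethod("numNodes", "DeterministicNetwork", function(x) length(x@nodes))
#' @describeIn numEdges edge count of a probabilistic network
#' @export
setMethod("numEdges", "ProbabilisticNetwork", function(x) nrow(x@edges))
#' @describeIn numEdges edge count of a deterministic network
#' @export
setMethod("numEdges", "DeterministicNetwork", function(x) nrow(x@edges))

setMethod("show", "ProbabilisticNetwork", function(object) {
  cat("ProbabilisticNetwork",
      if (nzchar(object@name)) sprintf("'%s'", object@name), "\n")
  cat(" ", length(object@nodes), "nodes,", nrow(object@edges), "edges\n")
  if (nrow(object@edges))
    cat("  edge probabilities in [",
        format(min(object@edges$prob), digits = 4), ", ",
        format(max(object@edges$prob), digits = 4), "]\n", sep = "")
})

setMethod("show", "DeterministicNetwork", function(object) {
  cat("DeterministicNetwork\n")
  cat(" ", length(object@nodes), "nodes,", nrow(object@edges), "edges\n")
})
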