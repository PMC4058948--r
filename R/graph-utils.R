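# Internal adjacency structure and breadth-first reachability.
#
# The collapsing operators issue very many tiny reachability queries per
# stage; going through a full graph object each time would dominate the
# runtime, so the hot path uses a flat integer adjacency built once per
# network or stage.

.graphIndex <- function(nodes, from, to) {
  n <- length(nodes)
  id <- seq_len(n)
  names(id) <- nodes
  fi <- unname(id[from])
  ti <- unname(id[to])
  outEdges <- split(seq_along(fi), factor(fi, levels = id))
  list(n = n, nodes = nodes, id = id, from = fi, to = ti, outEdges = outEdges)
}

# Logical vector over g's nodes: reachable from `start` (integer ids) using
# only edges with edgeOK TRUE (NULL = all), never entering nodes with
# nodeOK FALSE. Start nodes outside nodeOK are dropped.
.reachIds <- function(g, start, edgeOK = NULL, nodeOK = NULL) {
  vis <- logical(g$n)
  if (!is.null(nodeOK)) start <- start[nodeOK[start]]
  if (!length(start)) return(vis)
  vis[start] <- TRUE
  stack <- integer(g$n)
  stack[seq_along(start)] <- start
  sp <- length(start)
  while (sp > 0L) {
    v <- stack[sp]
    sp <- sp - 1L
    es <- g$outEdges[[v]]
    if (!is.null(edgeOK) && length(es)) es <- es[edgeOK[es]]
    for (e in es) {
      w <- g$to[e]
      if (!vis[w] && (is.null(nodeOK) || nodeOK[w])) {
        vis[w] <- TRUE
        sp <- sp + 1L
        stack[sp] <- w
      }
    }
  }
  vis
}

# Reverse-reachability: nodes from which `start` can be reached.
.coReachIds <- function(g, start, edgeOK = NULL, nodeOK = NULL) {
  rg <- list(n = g$n, nodes = g$nodes, id = g$id, from = g$to, to = g$from,
             outEdges = split(seq_along(g$to), factor(g$to, levels = seq_len(g$n))))
  .reachIds(rg, start, edgeOK = edgeOK, nodeOK = nodeOK)
}

.detGraph <- function(x) {
  edges <- x@edges
  .graphIndex(x@nodes, edges$from, edges$to)
}

# Is there a directed path s -> t avoiding nodes in K (K may be empty)?
.pathAvoiding <- function(g, s, t, K = character()) {
  sid <- g$id[[s]]
  tid <- g$id[[t]]
  nodeOK <- rep(TRUE, g$n)
  nodeOK[unname(g$id[K])] <- FALSE
  vis <- .reachIds(g, sid, nodeOK = nodeOK)
  vis[tid]
}

.asIgraph <- function(net) {
  df <- data.frame(from = net@edges$from, to = net@edges$to,
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df, directed = TRUE,
                                vertices = data.frame(name = net@nodes))
}
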