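# Reference implementations for correctness testing. Both are exponential
# by design and guard their input size with hard caps; a truncated oracle
# would be worse than none.

#' Reachability by exhaustive configuration enumeration
#'
#' A network with `n` probabilistic edges represents `2^n` deterministic
#' configurations. This oracle enumerates all of them, sums the probability
#' mass of the configurations containing a directed s-t path, and returns
#' that sum. The number of configurations actually enumerated is attached
#' as attribute `"nConfigurations"`.
#'
#' @param net a [ProbabilisticNetwork-class].
#' @param s,t source and target node identifiers.
#' @param maxEdges refuse networks with more edges than this (the main
#'   algorithm, [reachabilityProbability()], handles those).
#' @return The reachability probability, exact up to float rounding.
#' @examples
#' bruteForceReachability(fixtureNetwork("bridge5"), "s", "t")  # 15/32
#' @export
bruteForceReachability <- function(net, s, t, maxEdges = 20L) {
  .assertNode(net, s)
  .assertNode(net, t)
  e <- net@edges
  n <- nrow(e)
  if (n > maxEdges)
    stop("network has ", n, " edges (> ", maxEdges, "); enumeration of 2^", n,
         " configurations refused - use reachabilityProbability() instead")
  g <- .graphIndex(net@nodes, e$from, e$to)
  sid <- g$id[[s]]
  tid <- g$id[[t]]
  p <- e$prob
  bit <- 2^(seq_len(n) - 1)
  total <- 0
  nConf <- 0L
  for (mask in seq_len(2^n) - 1) {
    present <- bitwAnd(mask, bit) > 0
    nConf <- nConf + 1L
    w <- prod(ifelse(present, p, 1 - p))
    if (w == 0) next
    vis <- .reachIds(g, sid, edgeOK = present)
    if (vis[tid]) total <- total + w
  }
  structure(total, nConfigurations = nConf)
}

#' Reachability by inclusion-exclusion over simple paths
#'
#' Enumerates every simple directed s-t path, then sums over all non-empty
#' path subsets `Q` the signed probability
#' `(-1)^(|Q|+1) * prod(p_e, e in union of Q)`.
#'
#' @param net a [ProbabilisticNetwork-class].
#' @param s,t source and target node identifiers.
#' @param maxPaths refuse instances with more simple s-t paths than this.
#' @return The reachability probability, with the number of simple paths
#'   attached as attribute `"nPaths"`.
#' @export
inclusionExclusionReachability <- function(net, s, t, maxPaths = 18L) {
  .assertNode(net, s)
  .assertNode(net, t)
  ig <- .asIgraph(net)
  paths <- igraph::all_simple_paths(ig, from = s, to = t, mode = "out")
  k <- length(paths)
  if (k > maxPaths)
    stop("instance has ", k, " simple s-t paths (> ", maxPaths,
         "); inclusion-exclusion over 2^", k, " subsets refused")
  if (k == 0L) return(structure(0, nPaths = 0L))
  e <- net@edges
  edgeKey <- paste(e$from, e$to, sep = "\r")
  n <- nrow(e)
  # k x n logical membership matrix of path edge sets
  M <- matrix(FALSE, nrow = k, ncol = n)
  for (i in seq_len(k)) {
    v <- names(paths[[i]])
    keys <- paste(v[-length(v)], v[-1L], sep = "\r")
    M[i, match(keys, edgeKey)] <- TRUE
  }
  p <- e$prob
  bit <- 2^(seq_len(k) - 1)
  total <- 0
  for (mask in seq_len(2^k - 1)) {
    rows <- bitwAnd(mask, bit) > 0
    u <- colSums(M[rows, , drop = FALSE]) > 0
    sign <- if (sum(rows) %% 2 == 1) 1 else -1
    total <- total + sign * prod(p[u])
  }
  structure(total, nPaths = k)
}
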