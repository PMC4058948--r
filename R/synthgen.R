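#' Scale-free synthetic probabilistic network (preferential attachment)
#'
#' Generates a directed probabilistic network with exactly `2 * nNodes`
#' edges by Barabasi-Albert preferential attachment: a 3-node seed star,
#' then each new node attaches to `m = 2` distinct existing nodes sampled
#' proportionally to their (undirected) degree; uniformly random extra
#' non-duplicate links top the count up to exactly `2 * nNodes`. Each edge
#' receives an independent existence probability drawn uniformly from
#' `(probLow, probHigh]`. The output is connected in the undirected sense
#' and fully reproducible from `seed`.
#'
#' Edge orientation is a modelling knob. The default `"attachment"`
#' orients every link from the newer to the older endpoint - the canonical
#' preferential-attachment direction. It yields a shallow acyclic
#' hierarchy converging on the early hub nodes, much like the feed-forward
#' backbone of transcription regulatory networks, and it is the regime in
#' which separator sequences stay narrow and single-pair queries take
#' milliseconds. `"acyclic"` orients every link along a uniformly random
#' node ordering instead (still acyclic, but deeper and with occasional
#' wide stages that are expensive for any exact method). `"random"` flips
#' each link independently with probability one half; that typically
#' produces one giant strongly connected component in which no good node
#' separator exists between most pairs, so exact reachability degenerates
#' to its exponential worst case - useful for stress tests, not for
#' benchmarks.
#'
#' @param nNodes number of nodes (at least 5).
#' @param seed RNG seed.
#' @param probLow,probHigh bounds of the edge-probability distribution,
#'   `0 <= probLow <= probHigh <= 1`; exact zeros are redrawn so that all
#'   probabilities are valid load-time values in `(0, 1]`.
#' @param orientation `"attachment"` (default), `"acyclic"` or `"random"`.
#' @return A [ProbabilisticNetwork-class] with nodes `g1 ... g<nNodes>`.
#' @examples
#' net <- barabasiAlbert(50, seed = 1)
#' numEdges(net)   # 100
#' @export
barabasiAlbert <- function(nNodes, seed = 0L, probLow = 0, probHigh = 1,
                           orientation = c("attachment", "acyclic", "random")) {
  nNodes <- as.integer(nNodes)
  orientation <- match.arg(orientation)
  if (nNodes < 5L) stop("at least 5 nodes are required")
  if (probLow < 0 || probHigh > 1 || probLow > probHigh)
    stop("need 0 <= probLow <= probHigh <= 1")
  targetEdges <- 2L * nNodes
  set.seed(as.integer(seed))
  # undirected pair list; seed star centred on node 1
  a <- c(1L, 1L)
  b <- c(2L, 3L)
  deg <- c(2L, 1L, 1L, integer(nNodes - 3L))
  for (v in seq(4L, nNodes)) {
    existing <- seq_len(v - 1L)
    tgt <- sample(existing, 2L, prob = deg[existing])
    a <- c(a, v, v)
    b <- c(b, tgt)
    deg[v] <- 2L
    deg[tgt] <- deg[tgt] + 1L
  }
  pairKey <- function(x, y) paste(pmin(x, y), pmax(x, y))
  seen <- pairKey(a, b)
  while (length(a) < targetEdges) {
    cand <- sample.int(nNodes, 2L)
    k <- pairKey(cand[1L], cand[2L])
    if (k %in% seen) next
    a <- c(a, cand[1L])
    b <- c(b, cand[2L])
    seen <- c(seen, k)
  }
  if (orientation == "acyclic") {
    rank <- sample.int(nNodes)        # random topological order
    fwd <- rank[a] < rank[b]
    from <- ifelse(fwd, a, b)
    to <- ifelse(fwd, b, a)
  } else if (orientation == "attachment") {
    newer <- pmax(a, b)
    older <- pmin(a, b)
    from <- newer
    to <- older
  } else {
    flip <- stats::runif(length(a)) < 0.5
    from <- ifelse(flip, b, a)
    to <- ifelse(flip, a, b)
  }
  prob <- stats::runif(length(a), probLow, probHigh)
  while (any(prob == 0)) prob[prob == 0] <- stats::runif(sum(prob == 0), probLow, probHigh)
  probNetwork(paste0("g", from), paste0("g", to), prob,
              nodes = paste0("g", seq_len(nNodes)),
              name = sprintf("ba-%d-seed%d", nNodes, as.integer(seed)))
}

#' Small built-in example networks
#'
#' Named fixtures used across the documentation and test suite, each with
#' probability `p` on every edge:
#' \describe{
#'   \item{series3}{the chain `s -> a -> t`.}
#'   \item{parallel2}{two node-disjoint 2-edge paths `s -> a -> t` and
#'     `s -> b -> t`.}
#'   \item{bridge5}{the directed bridge `s -> a`, `s -> b`, `a -> b`,
#'     `a -> t`, `b -> t`.}
#'   \item{fig2}{an 8-node, 11-edge network with source `1` and target `8`
#'     whose node set `{4, 5}` is a 1-8 separator with left nodes
#'     `{1, 2, 3}`, left edges `{1, 2, 3, 5, 6}` and backward edges
#'     `{4, 8}`; edge-index set `{2, 5, 6, 7, 10}` forms a 1-8 path and
#'     `{3, 5}` a minimal 1-8 edge cut. These structural facts are asserted
#'     programmatically at construction.}
#'   \item{fig3}{a layered 7-node DAG with the two disjoint 1-7 separators
#'     `{2, 3}` and `{4, 5, 6}`.}
#' }
#'
#' @param name one of `"series3"`, `"parallel2"`, `"bridge5"`, `"fig2"`,
#'   `"fig3"`.
#' @param p probability assigned to every edge (default 0.5).
#' @return A [ProbabilisticNetwork-class].
#' @export
fixtureNetwork <- function(name = c("series3", "parallel2", "bridge5",
                                    "fig2", "fig3"),
                           p = 0.5) {
  name <- match.arg(name)
  mk <- function(from, to) {
    probNetwork(from, to, rep(p, length(from)), name = name)
  }
  net <- switch(name,
    series3 = mk(c("s", "a"), c("a", "t")),
    parallel2 = mk(c("s", "a", "s", "b"), c("a", "t", "b", "t")),
    bridge5 = mk(c("s", "s", "a", "a", "b"), c("a", "b", "b", "t", "t")),
    fig2 = mk(c("1", "1", "2", "6", "3", "4", "5", "7", "4", "6", "7"),
              c("2", "3", "4", "2", "4", "5", "6", "4", "7", "8", "8")),
    fig3 = mk(c("1", "1", "2", "2", "3", "3", "4", "5", "6"),
              c("2", "3", "4", "5", "5", "6", "7", "7", "7")))
  if (name == "fig2") .checkFig2(net)
  net
}

# Structural assertions of the fig2 fixture (checked at construction).
.checkFig2 <- function(net) {
  det <- maximalDeterministic(net)
  part <- classifySeparator(det, "1", "8", c("4", "5"))
  stopifnot(
    numEdges(net) == 11L,
    isSeparator(det, "1", "8", c("4", "5")),
    identical(sort(part@leftNodes), c("1", "2", "3")),
    identical(sort(part@rightNodes), c("6", "7", "8")),
    identical(sort(part@leftEdges), c(1L, 2L, 3L, 5L, 6L)),
    identical(sort(part@rightEdges), c(7L, 9L, 10L, 11L)),
    identical(sort(part@backwardEdges), c(4L, 8L))
  )
  # {e2,e5,e6,e7,e10} contains a 1 -> 8 path
  g <- .detGraph(det)
  ok <- rep(FALSE, numEdges(net)); ok[c(2L, 5L, 6L, 7L, 10L)] <- TRUE
  stopifnot(.reachIds(g, g$id[["1"]], edgeOK = ok)[g$id[["8"]]])
  # {e3,e5} is a minimal 1-8 edge cut
  cut <- c(3L, 5L)
  okc <- rep(TRUE, numEdges(net)); okc[cut] <- FALSE
  stopifnot(!.reachIds(g, g$id[["1"]], edgeOK = okc)[g$id[["8"]]])
  for (keep in cut) {
    okm <- rep(TRUE, numEdges(net)); okm[setdiff(cut, keep)] <- FALSE
    stopifnot(.reachIds(g, g$id[["1"]], edgeOK = okm)[g$id[["8"]]])
  }
  invisible(TRUE)
}
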