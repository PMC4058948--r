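#' Is K an s-t node separator?
#'
#' `TRUE` iff deleting the nodes in `K` (with their incident edges) leaves
#' no directed path from `s` to `t` in the deterministic network. By
#' convention the test is `TRUE` whenever `s` or `t` belongs to `K`, which
#' supports the terminal separators `K_0 = {s}` and `K_{c+1} = {t}`.
#'
#' @param detnet a [DeterministicNetwork-class].
#' @param s,t source and target node identifiers.
#' @param K character vector of separator candidates.
#' @export
isSeparator <- function(detnet, s, t, K) {
  stopifnot(is(detnet, "DeterministicNetwork"))
  .assertNode(detnet, s)
  .assertNode(detnet, t)
  if (s %in% K || t %in% K) return(TRUE)
  g <- .detGraph(detnet)
  !.pathAvoiding(g, s, t, K)
}

#' Partition nodes and edges around an s-t node separator
#'
#' Left nodes are those reachable from `s` without entering `K`; right
#' nodes are the remainder. Left edges join nodes of `left + K`; right
#' edges run between right nodes or from `K` to a right node; backward
#' edges run from a right node into `K` or the left nodes.
#'
#' @inheritParams isSeparator
#' @return A [SeparatorPartition-class].
#' @export
classifySeparator <- function(detnet, s, t, K) {
  if (!isSeparator(detnet, s, t, K))
    stop("K = {", paste(K, collapse = ","), "} is not an s-t node separator")
  g <- .detGraph(detnet)
  inK <- detnet@nodes %in% K
  nodeOK <- !inK
  vis <- .reachIds(g, g$id[[s]], nodeOK = nodeOK)
  left <- detnet@nodes[vis & !inK]
  right <- setdiff(detnet@nodes, c(left, K))
  e <- detnet@edges
  fromCls <- .nodeClass(e$from, left, K)
  toCls <- .nodeClass(e$to, left, K)
  isLeft <- fromCls != "R" & toCls != "R"
  isBackward <- fromCls == "R" & toCls != "R"
  isRight <- !isLeft & !isBackward
  new("SeparatorPartition", separator = sort(unique(K)),
      leftNodes = left, rightNodes = right,
      leftEdges = e$index[isLeft],
      rightEdges = e$index[isRight],
      backwardEdges = e$index[isBackward])
}

.nodeClass <- function(v, left, K) {
  out <- rep("R", length(v))
  out[v %in% left] <- "L"
  out[v %in% K] <- "K"
  out
}

#' Is a separator good (free of backward edges)?
#' @param partition a [SeparatorPartition-class] from [classifySeparator()].
#' @export
isGoodSeparator <- function(partition) {
  stopifnot(is(partition, "SeparatorPartition"))
  length(partition@backwardEdges) == 0L
}

#' Is a separator minimal?
#'
#' `TRUE` iff no proper subset of `K` already disconnects `t` from `s`.
#' Separator deletion is monotone (any superset of a separator is a
#' separator), so it suffices to test the subsets obtained by dropping one
#' node.
#'
#' @inheritParams isSeparator
#' @export
isMinimalSeparator <- function(detnet, s, t, K) {
  if (!isSeparator(detnet, s, t, K)) stop("K is not an s-t node separator")
  K <- unique(K)
  if (length(K) == 0L) return(FALSE)
  g <- .detGraph(detnet)
  for (drop in K) {
    sub <- setdiff(K, drop)
    disconnects <- if (s %in% sub || t %in% sub) TRUE
                   else !.pathAvoiding(g, s, t, sub)
    if (disconnects) return(FALSE)
  }
  TRUE
}

#' Check the separator/right-node inheritance property
#'
#' For an s-t separator `K`, every right node `u` must itself be separated
#' from `s` by `K`. This is a structural fact of node separators; the
#' function exists as a test utility and must return `TRUE` on every valid
#' input.
#'
#' @inheritParams isSeparator
#' @export
theorem1Holds <- function(detnet, s, t, K) {
  part <- classifySeparator(detnet, s, t, K)
  g <- .detGraph(detnet)
  for (u in part@rightNodes) {
    sep <- if (s %in% K || u %in% K) TRUE else !.pathAvoiding(g, s, u, K)
    if (!sep) return(FALSE)
  }
  TRUE
}

#' Assemble and validate a separator sequence
#'
#' Builds a [SeparatorSequence-class] from an ordered list of separators
#' `K_0 = {s}, ..., K_{c+1} = {t}`, computing the stages
#' `E_j = L(K_j) \ L(K_{j-1})` from the left-edge sets and verifying the
#' sequence invariants: every `K_i` is a good s-t separator, left-edge sets
#' are nested, stages are disjoint and cover the whole edge set, and for
#' `i < j` every node of `K_j \ K_i` is a right node of `K_i`.
#'
#' @param net a [ProbabilisticNetwork-class] (already pruned for the pair).
#' @param s,t source and target node identifiers.
#' @param separators list of character node sets, `{s}` first, `{t}` last.
#' @return A [SeparatorSequence-class].
#' @export
separatorSequence <- function(net, s, t, separators) {
  det <- maximalDeterministic(net)
  separators <- lapply(separators, function(K) sort(unique(as.character(K))))
  k <- length(separators)
  parts <- lapply(separators, function(K) classifySeparator(det, s, t, K))
  for (i in seq_len(k)) {
    if (!isGoodSeparator(parts[[i]]))
      stop("separator ", i - 1L, " has backward edges; not a good separator")
  }
  lefts <- lapply(parts, function(p) p@leftEdges)
  stages <- vector("list", k - 1L)
  for (j in 2:k) {
    if (!all(lefts[[j - 1L]] %in% lefts[[j]]))
      stop("left-edge sets are not nested between separators ", j - 2L,
           " and ", j - 1L)
    stages[[j - 1L]] <- sort(setdiff(lefts[[j]], lefts[[j - 1L]]))
  }
  covered <- sort(unlist(stages, use.names = FALSE))
  if (!identical(as.integer(covered), sort(det@edges$index)))
    stop("stages do not partition the edge set; prune the network for (s, t) first")
  for (i in seq_len(k - 1L)) {
    laterNodes <- setdiff(unlist(separators[(i + 1L):k]), separators[[i]])
    if (!all(laterNodes %in% c(parts[[i]]@rightNodes)))
      stop("separator sequence violates the right-node ordering at position ", i - 1L)
  }
  new("SeparatorSequence", separators = separators, stages = stages,
      source = s, target = t)
}

.singleStageSequence <- function(net, s, t) {
  separatorSequence(net, s, t, list(s, t))
}

#' Greedy search for a sequence of good s-t node separators
#'
#' The search walks a separator `K` from `{s}` toward `{t}` by batch
#' expansion: in each round, every `K` node without a direct edge to `t` is
#' replaced by its one-hop successors (it retires into the passed region),
#' while nodes adjacent to `t` stay in `K` and only contribute their other
#' successors - consecutive separators may therefore overlap. Every
#' expansion keeps `K` an s-t separator by construction; whenever the
#' current `K` is additionally *good* (no backward edges) it is reduced
#' toward minimality (lexicographic drop scan) and recorded as the next
#' separator of the sequence. The walk ends when no expansion changes `K`,
#' and `K_{c+1} = {t}` closes the sequence. If the recorded snapshots fail
#' the sequence invariants (possible on unpruned input) the always-valid
#' single-stage sequence `({s}, {t})` is returned instead.
#'
#' @param net a [ProbabilisticNetwork-class], pruned for `(s, t)` (see
#'   [pruneForPair()]).
#' @param s,t source and target node identifiers.
#' @return A validated [SeparatorSequence-class].
#' @export
greedySeparatorSequence <- function(net, s, t) {
  .assertNode(net, s)
  .assertNode(net, t)
  if (s == t) stop("source and target must differ")
  det <- maximalDeterministic(net)
  g <- .detGraph(det)
  sid <- g$id[[s]]
  tid <- g$id[[t]]
  outNb <- lapply(seq_len(g$n), function(v) unique(g$to[g$outEdges[[v]]]))
  toT <- vapply(outNb, function(nb) tid %in% nb, logical(1))
  passed <- logical(g$n)
  K <- sid
  seps <- list(s)
  fallback <- function() .singleStageSequence(net, s, t)
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 4L * g$n + 8L) return(fallback())
    fresh <- function(v) {
      nb <- outNb[[v]]
      nb[!passed[nb] & !(nb %in% K) & nb != tid]
    }
    res <- .extractGoodSep(g, sid, tid, K)
    if (!is.null(res)) {
      # a good minimal sub-separator hides in the frontier: record it.
      # Dropped nodes left of it are behind the cut and retire; dropped
      # nodes right of it stay in the walk to be covered by later stages.
      lab <- sort(g$nodes[res$K])
      if (!identical(lab, seps[[length(seps)]])) seps <- c(seps, list(lab))
      if (length(res$leftDrops)) {
        passed[res$leftDrops] <- TRUE
        K <- setdiff(K, res$leftDrops)
      }
      expand <- K
    } else {
      # no good cut in this snapshot: push the nodes with an incident
      # backward edge one hop (finer steps give goodness a chance before
      # the frontier widens)
      bad <- .backwardHeads(g, sid, K)
      expand <- bad
      if (!length(expand)) expand <- K
    }
    retire <- expand[!toT[expand]]
    growExp <- unique(unlist(lapply(expand, fresh), use.names = FALSE))
    K2 <- sort(unique(c(setdiff(K, retire), growExp)))
    if (identical(K2, sort(K)) && !identical(sort(expand), sort(K))) {
      # the targeted nodes cannot move; advance the whole separator instead
      expand <- K
      retire <- expand[!toT[expand]]
      growExp <- unique(unlist(lapply(expand, fresh), use.names = FALSE))
      K2 <- sort(unique(c(setdiff(K, retire), growExp)))
    }
    if (identical(K2, sort(K)) || !length(K2)) break
    passed[retire] <- TRUE
    K <- K2
  }
  seps <- c(seps, list(t))
  tryCatch(separatorSequence(net, s, t, seps),
           error = function(e) fallback())
}

# Heads inside the separator C of backward edges (edges from right nodes
# into C or the left region that land on C nodes).
.backwardHeads <- function(g, sid, C) {
  nodeOK <- rep(TRUE, g$n); nodeOK[C] <- FALSE
  leftVis <- .reachIds(g, sid, nodeOK = nodeOK)
  inC <- logical(g$n); inC[C] <- TRUE
  fromRight <- !leftVis[g$from] & !inC[g$from]
  unique(g$to[fromRight & inC[g$to]])
}

# Extract a minimal good s-t separator from the walk frontier C, if one is
# hiding inside it: drop nodes (lexicographic scan) as long as the set
# still separates, then test the result for goodness. The walk frontier
# over-covers routes (nodes adjacent to t stay in it while their upstream
# continuations are explored), so goodness often holds only for a strict
# subset. Returns NULL, or list(K = minimal good separator ids,
# leftDrops = dropped nodes lying left of it - safe to retire).
.extractGoodSep <- function(g, sid, tid, C) {
  isSep <- function(Cset) {
    nodeOK <- rep(TRUE, g$n); nodeOK[Cset] <- FALSE
    !.reachIds(g, sid, nodeOK = nodeOK)[tid]
  }
  if (!isSep(C)) return(NULL)
  Km <- C
  for (v in Km[order(g$nodes[Km])]) {
    if (length(Km) <= 1L) break
    Csub <- setdiff(Km, v)
    if (isSep(Csub)) Km <- Csub
  }
  nodeOK <- rep(TRUE, g$n); nodeOK[Km] <- FALSE
  leftVis <- .reachIds(g, sid, nodeOK = nodeOK)
  inK <- logical(g$n); inK[Km] <- TRUE
  fromRight <- !leftVis[g$from] & !inK[g$from]
  if (any(fromRight & (leftVis[g$to] | inK[g$to]))) return(NULL)  # not good
  drops <- setdiff(C, Km)
  list(K = Km, leftDrops = drops[leftVis[drops]])
}

setMethod("show", "SeparatorPartition", function(object) {
  cat("SeparatorPartition\n")
  cat("  separator:", paste(object@separator, collapse = ", "), "\n")
  cat("  left nodes:", length(object@leftNodes),
      " right nodes:", length(object@rightNodes), "\n")
  cat("  edges (left/right/backward):", length(object@leftEdges), "/",
      length(object@rightEdges), "/", length(object@backwardEdges), "\n")
})

setMethod("show", "SeparatorSequence", function(object) {
  cat("SeparatorSequence (", object@source, " -> ", object@target, ")\n", sep = "")
  for (i in seq_along(object@separators)) {
    cat(sprintf("  K%d: {%s}", i - 1L,
                paste(object@separators[[i]], collapse = ",")))
    if (i > 1L)
      cat(sprintf("   stage E%d: %d edge(s)", i - 1L,
                  length(object@stages[[i - 1L]])))
    cat("\n")
  }
})
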