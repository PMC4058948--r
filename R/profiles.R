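#' Reachability profile over source and target sets
#'
#' Computes the exact reachability probability for every ordered
#' source-target pair. The profile characterises the signalling state of
#' the whole network: the entry `R[i, j]` is the probability that a signal
#' originating at source `i` can reach target `j`. Pairs with identical
#' source and target are recorded as missing.
#'
#' @param net a [ProbabilisticNetwork-class].
#' @param sources,targets character vectors of node identifiers (need not
#'   be disjoint).
#' @return A [ReachabilityProfile-class].
#' @export
computeProfile <- function(net, sources, targets) {
  for (v in unique(c(sources, targets))) .assertNode(net, v)
  R <- matrix(NA_real_, nrow = length(sources), ncol = length(targets),
              dimnames = list(sources, targets))
  for (i in seq_along(sources)) {
    for (j in seq_along(targets)) {
      if (sources[i] == targets[j]) next
      R[i, j] <- reachabilityProbability(net, sources[i], targets[j])
    }
  }
  new("ReachabilityProfile", sources = as.character(sources),
      targets = as.character(targets), R = R)
}

#' @describeIn computeProfile extract the probability matrix
#' @param x a [ReachabilityProfile-class].
#' @export
setMethod("profileMatrix", "ReachabilityProfile", function(x) x@R)

#' Node-removal centrality from reachability profiles
#'
#' The centrality of gene `g` is the total drop in the reachability profile
#' caused by removing `g` (with its incident edges):
#' `sum over (s, t) of p(s, t) - p_without_g(s, t)`. Pairs in which `g` is
#' itself the source or the target contribute `p(s, t) - 0` by default (a
#' removed gene can neither relay nor receive); set `skipSelfPairs = TRUE`
#' to exclude those pairs instead. Missing profile entries (source equal to
#' target) never contribute. Edge-removal monotonicity makes the result
#' non-negative, bounded by the number of contributing pairs.
#'
#' @param net a [ProbabilisticNetwork-class].
#' @param sources,targets character vectors of node identifiers.
#' @param g the gene (node) whose centrality is measured.
#' @param skipSelfPairs exclude pairs with `g` as source or target.
#' @return A non-negative number.
#' @export
geneCentrality <- function(net, sources, targets, g, skipSelfPairs = FALSE) {
  .assertNode(net, g)
  base <- profileMatrix(computeProfile(net, sources, targets))
  reduced <- removeNode(net, g)
  removedIsTerminal <- outer(sources == g, rep(TRUE, length(targets))) |
    outer(rep(TRUE, length(sources)), targets == g)
  after <- matrix(0, nrow = length(sources), ncol = length(targets))
  for (i in seq_along(sources)) {
    for (j in seq_along(targets)) {
      if (is.na(base[i, j]) || removedIsTerminal[i, j]) next
      after[i, j] <- reachabilityProbability(reduced, sources[i], targets[j])
    }
  }
  diff <- base - after
  drop <- is.na(base) | (skipSelfPairs & removedIsTerminal)
  sum(diff[!drop])
}

# Deterministic per-replicate seed stream derived from one master seed;
# keeps replicates reproducible independently of evaluation order.
.mixSeed <- function(seed, r) {
  as.integer((abs(as.numeric(seed)) * 1103515245 + r * 12345 + 7919) %%
               2147483647)
}

#' Perturb edge probabilities uniformly within a half-width
#'
#' Each edge probability is redrawn uniformly from
#' `[P(e) - delta, P(e) + delta]` intersected with `[0, 1]` (a point
#' interval returns that point). Perturbed probabilities may be exactly 0,
#' which the reachability machinery accepts.
#'
#' @param net a [ProbabilisticNetwork-class].
#' @param delta perturbation half-width in `[0, 1]`.
#' @return A perturbed [ProbabilisticNetwork-class]; draws come from the
#'   current RNG state.
#' @export
perturbNetwork <- function(net, delta) {
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  p <- net@edges$prob
  lo <- pmax(p - delta, 0)
  hi <- pmin(p + delta, 1)
  newP <- stats::runif(length(p), lo, hi)
  probNetwork(net@edges$from, net@edges$to, newP, nodes = net@nodes,
              name = net@name, allowZero = TRUE)
}

#' Network stability under random edge-probability perturbation
#'
#' For each replicate, every edge probability is perturbed within
#' `+/- delta` (clipped to `[0, 1]`), the profile is recomputed and the
#' absolute change `|p_perturbed(s, t) - p(s, t)|` is averaged over all
#' source-target pairs; the grand mean over replicates is the stability
#' statistic (small values mean a stable network). Fully reproducible from
#' `seed`; per-replicate streams are derived deterministically from it.
#'
#' @param net a [ProbabilisticNetwork-class].
#' @param sources,targets character vectors of node identifiers.
#' @param delta perturbation half-width in `[0, 1]`.
#' @param replicates number of perturbation replicates (default 20).
#' @param seed master RNG seed.
#' @return A [StabilityResult-class].
#' @export
networkStability <- function(net, sources, targets, delta, replicates = 20L,
                             seed = 0L) {
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("at least one replicate is required")
  base <- profileMatrix(computeProfile(net, sources, targets))
  perRep <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed(.mixSeed(seed, r))
    pnet <- perturbNetwork(net, delta)
    pert <- profileMatrix(computeProfile(pnet, sources, targets))
    perRep[r] <- mean(abs(pert - base), na.rm = TRUE)
  }
  new("StabilityResult", delta = as.numeric(delta), replicates = replicates,
      meanAbsChange = mean(perRep), perReplicate = perRep,
      seed = as.integer(seed))
}

#' Pair-count bookkeeping for profile computations
#'
#' The number of single-pair reachability computations a profile driver
#' performs: `orderedPairCount(n)` counts all ordered distinct-node pairs
#' of an `n`-node network (every node taken in turn as source and as
#' target), and `profileEntryCount` the entries of a sources-by-targets
#' profile.
#'
#' @param n number of nodes.
#' @return An integer count.
#' @export
orderedPairCount <- function(n) as.integer(n) * (as.integer(n) - 1L)

#' @rdname orderedPairCount
#' @param nSources,nTargets source and target set sizes.
#' @export
profileEntryCount <- function(nSources, nTargets)
  as.integer(nSources) * as.integer(nTargets)

setMethod("show", "ReachabilityProfile", function(object) {
  cat("ReachabilityProfile:", length(object@sources), "source(s) x",
      length(object@targets), "target(s)\n")
  v <- object@R[!is.na(object@R)]
  if (length(v))
    cat("  probabilities in [", format(min(v), digits = 4), ", ",
        format(max(v), digits = 4), "], mean ",
        format(mean(v), digits = 4), "\n", sep = "")
})

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult: delta =", object@delta, "with", object@replicates,
      "replicate(s), seed", object@seed, "\n")
  cat("  mean |change in reachability| =",
      format(object@meanAbsChange, digits = 6), "\n")
})
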