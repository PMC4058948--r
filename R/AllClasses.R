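#' @import methods
NULL

.validEdgeFrame <- function(edges, needProb) {
  req <- c("index", "from", "to", if (needProb) "prob")
  if (!is.data.frame(edges)) return("'edges' must be a data.frame")
  missing <- setdiff(req, names(edges))
  if (length(missing))
    return(paste0("edge table lacks column(s): ", paste(missing, collapse = ", ")))
  n <- nrow(edges)
  if (n == 0L) return(TRUE)
  if (!identical(as.integer(edges$index), seq_len(n)))
    return("edge indices must be unique and contiguous starting at 1")
  if (any(edges$from == edges$to))
    return("self-loops are not allowed")
  if (anyDuplicated(paste(edges$from, edges$to, sep = "\r")))
    return("duplicate directed (source, target) pairs are not allowed")
  if (needProb) {
    p <- edges$prob
    if (!is.numeric(p) || anyNA(p)) return("edge probabilities must be numeric and non-missing")
    if (any(p < 0 | p > 1)) return("edge probabilities must lie in [0, 1]")
  }
  TRUE
}

#' Probabilistic directed network
#'
#' A directed graph in which each edge exists independently with a given
#' probability. Edges carry contiguous integer indices (file/insertion
#' order) that the reachability machinery uses as stable identifiers.
#'
#' Structural invariants enforced by the validity method: indices are
#' `1..n`, no self-loops, no duplicate ordered node pairs, probabilities in
#' `[0, 1]`. The loader and the user-facing constructor additionally require
#' probabilities in `(0, 1]`; zero-probability edges are only admitted
#' internally (perturbation analysis).
#'
#' @slot nodes character vector of node identifiers (opaque, case-sensitive).
#' @slot edges data.frame with columns `index`, `from`, `to`, `prob`
#'   (possibly extra bookkeeping columns such as `origIndex` after pruning).
#' @slot name optional label.
#'
#' @seealso [probNetwork()], [loadNetwork()], [maximalDeterministic()]
#' @export
setClass("ProbabilisticNetwork",
  representation(nodes = "character", edges = "data.frame", name = "character"),
  prototype(nodes = character(),
            edges = data.frame(index = integer(), from = character(),
                               to = character(), prob = numeric()),
            name = ""),
  validity = function(object) {
    msg <- .validEdgeFrame(object@edges, needProb = TRUE)
    if (!isTRUE(msg)) return(msg)
    if (nrow(object@edges) &&
        !all(c(object@edges$from, object@edges$to) %in% object@nodes))
      return("all edge endpoints must be listed in @nodes")
    if (anyDuplicated(object@nodes)) return("duplicate node identifiers")
    TRUE
  })

#' Deterministic directed network
#'
#' The structural skeleton of a [ProbabilisticNetwork-class]: same nodes and
#' indexed edges, probabilities dropped. The topology in which every
#' possible edge is present is the *maximal deterministic network* of a
#' probabilistic network.
#'
#' @slot nodes character vector of node identifiers.
#' @slot edges data.frame with columns `index`, `from`, `to`.
#' @seealso [maximalDeterministic()]
#' @export
setClass("DeterministicNetwork",
  representation(nodes = "character", edges = "data.frame"),
  prototype(nodes = character(),
            edges = data.frame(index = integer(), from = character(), to = character())),
  validity = function(object) {
    msg <- .validEdgeFrame(object@edges, needProb = FALSE)
    if (!isTRUE(msg)) return(msg)
    if (nrow(object@edges) &&
        !all(c(object@edges$from, object@edges$to) %in% object@nodes))
      return("all edge endpoints must be listed in @nodes")
    TRUE
  })

#' Node/edge partition induced by an s-t node separator
#'
#' A separator `K` splits the nodes into *left* nodes (reachable from the
#' source without crossing `K`), the separator itself, and *right* nodes
#' (the remainder). Edges split into left edges (within left nodes and
#' separator), right edges (between right nodes, or separator to right) and
#' backward edges (right to separator or left). A separator with no backward
#' edges is called *good*.
#'
#' @slot separator,leftNodes,rightNodes character node sets.
#' @slot leftEdges,rightEdges,backwardEdges integer edge-index sets.
#' @seealso [classifySeparator()], [isGoodSeparator()]
#' @export
setClass("SeparatorPartition",
  representation(separator = "character", leftNodes = "character",
                 rightNodes = "character", leftEdges = "integer",
                 rightEdges = "integer", backwardEdges = "integer"),
  validity = function(object) {
    ns <- c(object@separator, object@leftNodes, object@rightNodes)
    if (anyDuplicated(ns))
      return("separator, left and right node sets must be pairwise disjoint")
    es <- c(object@leftEdges, object@rightEdges, object@backwardEdges)
    if (anyDuplicated(es))
      return("left, right and backward edge sets must be pairwise disjoint")
    TRUE
  })

#' Ordered sequence of good s-t node separators with induced edge stages
#'
#' Separators `K_0 = {s}, K_1, ..., K_{c+1} = {t}` such that each `K_i` is a
#' good s-t separator and, for `i < j`, every node of `K_j` not in `K_i` is
#' a right node of `K_i`. The induced stages `E_j = L(K_j) \ L(K_{j-1})`
#' (differences of left-edge sets) are pairwise disjoint and cover the whole
#' edge set; stage `j` is the subnetwork the polynomial machinery processes
#' when advancing from `K_{j-1}` to `K_j`.
#'
#' @slot separators list of character node sets, outermost first.
#' @slot stages list of integer edge-index sets, `length(separators) - 1`.
#' @slot source,target the terminal node identifiers.
#' @seealso [greedySeparatorSequence()], [separatorSequence()]
#' @export
setClass("SeparatorSequence",
  representation(separators = "list", stages = "list",
                 source = "character", target = "character"),
  validity = function(object) {
    k <- length(object@separators)
    if (k < 2L) return("at least the two terminal separators are required")
    if (length(object@stages) != k - 1L)
      return("there must be exactly one stage per consecutive separator pair")
    if (!identical(object@separators[[1L]], object@source))
      return("the first separator must be {source}")
    if (!identical(object@separators[[k]], object@target))
      return("the last separator must be {target}")
    TRUE
  })

#' Sparse stage polynomial of the collapsing algorithm
#'
#' A map from term keys to non-negative coefficients. An *uncollapsed* term
#' records the separator subset `S` carried over from the previous stage and
#' the set `I` of stage edges decided present; the decided set `Theta` is
#' shared by all uncollapsed terms and stored once. A *collapsed* term
#' `z_T` records only the subset `T` of the next separator that is reached;
#' the empty label `z_{}` is the absorbing failure term. Coefficients always
#' sum to one (probability conservation).
#'
#' @slot coef named numeric vector; names are encoded term keys.
#' @slot theta integer vector of stage edge indices aggregated so far.
#' @slot stageIndex which stage of the separator sequence is active.
#' @seealso [aggregateEdge()], [collapsePolynomial()], [advanceStage()],
#'   [polynomialTerms()]
#' @export
setClass("StagePolynomial",
  representation(coef = "numeric", theta = "integer", stageIndex = "integer"),
  validity = function(object) {
    if (length(object@coef) && is.null(names(object@coef)))
      return("coefficients must be named by term keys")
    if (any(object@coef < 0)) return("coefficients must be non-negative")
    TRUE
  })

#' Stage context for the polynomial-collapsing operators
#'
#' Bundles everything the indicator functions need for one stage: the
#' bounding separators `K_i` (lower) and `K_{i+1}` (upper), the stage edge
#' table, a precomputed adjacency structure over the stage subgraph, and a
#' per-stage memoisation cache for reachability queries.
#'
#' @slot lower,upper character node sets (consecutive separators).
#' @slot edges data.frame of stage edges (`index`, `from`, `to`, `prob`).
#' @slot nodes node universe of the stage subgraph.
#' @slot graph internal adjacency structure (list).
#' @slot stageIndex integer stage number.
#' @slot cache environment memoising reachability queries.
#' @seealso [stageContext()]
#' @export
setClass("StageContext",
  representation(lower = "character", upper = "character", edges = "data.frame",
                 nodes = "character", graph = "list", stageIndex = "integer",
                 cache = "environment"))

#' Reachability profile
#'
#' Sources-by-targets matrix of exact reachability probabilities
#' `R[i, j] = p(s_i, t_j)`. Entries for pairs with `s_i == t_j` are recorded
#' as missing (`NA`), since the single-pair probability is only defined for
#' distinct terminals.
#'
#' @slot sources,targets ordered node identifier vectors.
#' @slot R numeric matrix, `length(sources)` x `length(targets)`.
#' @seealso [computeProfile()]
#' @export
setClass("ReachabilityProfile",
  representation(sources = "character", targets = "character", R = "matrix"),
  validity = function(object) {
    if (!all(dim(object@R) == c(length(object@sources), length(object@targets))))
      return("matrix shape must be |sources| x |targets|")
    v <- object@R[!is.na(object@R)]
    if (length(v) && (any(v < -1e-12) || any(v > 1 + 1e-12)))
      return("all reachability probabilities must lie in [0, 1]")
    TRUE
  })

#' Stability of a network under edge-probability perturbation
#'
#' Summary of the perturbation experiment: every edge probability is redrawn
#' uniformly from `[P(e) - delta, P(e) + delta]` intersected with `[0, 1]`,
#' and the mean absolute change in pairwise reachability over all
#' source-target pairs is recorded, averaged over replicates.
#'
#' @slot delta perturbation half-width.
#' @slot replicates number of perturbation replicates.
#' @slot meanAbsChange grand mean of `|p_perturbed - p|` over pairs and replicates.
#' @slot perReplicate per-replicate pair means.
#' @slot seed master RNG seed the experiment was run with.
#' @seealso [networkStability()]
#' @export
setClass("StabilityResult",
  representation(delta = "numeric", replicates = "integer",
                 meanAbsChange = "numeric", perReplicate = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@replicates < 1L) return("at least one replicate is required")
    if (length(object@perReplicate) != object@replicates)
      return("perReplicate length must equal replicates")
    if (object@meanAbsChange < -1e-12 || object@meanAbsChange > 1 + 1e-12)
      return("meanAbsChange must lie in [0, 1]")
    TRUE
  })
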