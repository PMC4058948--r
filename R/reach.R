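# Term-key encoding for stage polynomials.
#
# Collapsed:    "Z" <US> T-nodes joined by <RS>
# Uncollapsed:  "U" <US> S-nodes joined by <RS> <US> I-indices joined by ","
# where <US> = "\x1f" and <RS> = "\x1e" cannot occur in whitespace-separated
# node identifiers. Node lists are kept sorted so keys are canonical.
.US <- "\x1f"
.RS <- "\x1e"

.keyZ <- function(T) paste0("Z", .US, paste(sort(T), collapse = .RS))
.keyU <- function(S, I) paste0("U", .US, paste(sort(S), collapse = .RS),
                               .US, paste(sort(as.integer(I)), collapse = ","))

.parseKey <- function(key) {
  parts <- strsplit(key, .US, fixed = TRUE)[[1L]]
  kind <- parts[1L]
  lab <- if (length(parts) >= 2L && nzchar(parts[2L]))
    strsplit(parts[2L], .RS, fixed = TRUE)[[1L]] else character()
  I <- if (length(parts) >= 3L && nzchar(parts[3L]))
    as.integer(strsplit(parts[3L], ",", fixed = TRUE)[[1L]]) else integer()
  list(kind = kind, label = lab, I = I)
}

#' Decode the terms of a stage polynomial
#'
#' @param x a [StagePolynomial-class].
#' @return A list with one element per term: `kind` (`"Z"` collapsed,
#'   `"U"` uncollapsed), `label` (the node subset `T` or `S`), `I` (present
#'   stage-edge indices, uncollapsed terms only) and `coef`.
#' @export
polynomialTerms <- function(x) {
  stopifnot(is(x, "StagePolynomial"))
  keys <- names(x@coef)
  out <- lapply(seq_along(keys), function(i) {
    p <- .parseKey(keys[i])
    p$coef <- unname(x@coef[i])
    p
  })
  out
}

#' Create a stage polynomial
#'
#' The base polynomial of the whole recursion is `1.0 * z_{s}`: the source
#' separator `K_0 = {s}` is reached with probability one.
#'
#' @param label character node subset of the single initial collapsed term
#'   `1.0 * z_label`.
#' @param stageIndex integer stage number.
#' @return A [StagePolynomial-class].
#' @export
newStagePolynomial <- function(label, stageIndex = 0L) {
  coef <- stats::setNames(1.0, .keyZ(label))
  new("StagePolynomial", coef = coef, theta = integer(), stageIndex = as.integer(stageIndex))
}

#' Build the context of one separator stage
#'
#' @param net a [ProbabilisticNetwork-class] holding the stage edges.
#' @param lower,upper the bounding separators `K_i` and `K_{i+1}`.
#' @param edgeIndices integer indices (into `edgeTable(net)`) of the stage
#'   edge set `E_{i+1}`.
#' @param stageIndex integer stage number.
#' @return A [StageContext-class].
#' @export
stageContext <- function(net, lower, upper, edgeIndices, stageIndex = 1L) {
  e <- net@edges[match(sort(as.integer(edgeIndices)), net@edges$index), ,
                 drop = FALSE]
  e <- e[.stageEdgeOrder(e), , drop = FALSE]
  nodes <- unique(c(sort(lower), sort(upper), e$from, e$to))
  g <- .graphIndex(nodes, e$from, e$to)
  g$gidx <- as.integer(e$index)   # stage-edge position -> global index
  new("StageContext", lower = sort(lower), upper = sort(upper),
      edges = e[c("index", "from", "to", "prob")], nodes = nodes, graph = g,
      stageIndex = as.integer(stageIndex), cache = new.env(parent = emptyenv()))
}

# Aggregation order of the stage edges: topological by tail (strongly
# connected components condensed first), ties broken by edge index. The
# result is order-independent, but deciding upstream edges first lets the
# outcome of downstream routes resolve - and terms collapse - as early as
# possible; with arbitrary order the uncollapsed term count can grow
# exponentially in the stage size before the first collapse fires.
.stageEdgeOrder <- function(e) {
  if (nrow(e) <= 1L) return(seq_len(nrow(e)))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to, stringsAsFactors = FALSE),
    directed = TRUE)
  comp <- igraph::components(ig, mode = "strong")
  cond <- igraph::contract(ig, comp$membership)
  cond <- igraph::simplify(cond)
  rank <- integer(igraph::vcount(cond))
  rank[as.integer(igraph::topo_sort(cond, mode = "out"))] <- seq_along(rank)
  tailRank <- rank[comp$membership[e$from]]
  order(tailRank, e$index)
}

# Names of stage nodes reachable from S using only stage edges whose global
# index is in `allowed`.
.stageReachRaw <- function(stage, S, allowed) {
  g <- stage@graph
  start <- unname(g$id[S])
  edgeOK <- g$gidx %in% allowed
  g$nodes[.reachIds(g, start, edgeOK = edgeOK)]
}

# Memoised variant keyed on (S, allowed) for the indicator functions.
.stageReach <- function(stage, S, allowed) {
  key <- paste0("q:", paste(S, collapse = .RS), .US,
                paste(allowed, collapse = ","))
  hit <- stage@cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- .stageReachRaw(stage, S, allowed)
  assign(key, res, envir = stage@cache)
  res
}

#' Path indicator: can u be reached from S through the present edges?
#'
#' Value 1 iff some node of `S` reaches `u` inside the stage subgraph using
#' only edges whose indices lie in `I`; a node of `S` reaches itself through
#' the empty path.
#'
#' @param stage a [StageContext-class].
#' @param S non-empty character set of origin nodes.
#' @param u node identifier inside the stage subgraph.
#' @param I integer set of stage-edge indices decided present.
#' @return 0 or 1.
#' @export
chiIndicator <- function(stage, S, u, I) {
  stopifnot(length(S) >= 1L)
  if (!u %in% stage@nodes) stop("node ", u, " is not part of this stage")
  if (u %in% S) return(1L)
  as.integer(u %in% .stageReach(stage, sort(S), sort(as.integer(I))))
}

#' Cut indicator: is v provably blocked from S by the absent edges?
#'
#' Value 1 iff, for every origin in `S`, some minimal origin-to-`v` edge cut
#' consists entirely of edges decided absent. Operationally: `v` is
#' unreachable from `S` in the stage subgraph even when every edge outside
#' the decided-absent set is present (the equivalence with the literal
#' minimal-cut definition is verified by an enumeration oracle in the test
#' suite).
#'
#' @param stage a [StageContext-class].
#' @param S non-empty character set of origin nodes.
#' @param v node identifier inside the stage subgraph.
#' @param absent integer set of stage-edge indices decided absent.
#' @return 0 or 1.
#' @export
omegaIndicator <- function(stage, S, v, absent) {
  stopifnot(length(S) >= 1L)
  if (!v %in% stage@nodes) stop("node ", v, " is not part of this stage")
  if (v %in% S) return(0L)
  allowed <- setdiff(stage@graph$gidx, as.integer(absent))
  as.integer(!v %in% .stageReach(stage, sort(S), sort(allowed)))
}

#' Subset-reachability indicator for the next separator
#'
#' Value 1 iff every node of `T` is reachable from `S` through the present
#' edges `I` and every node of the upper separator outside `T` is provably
#' blocked given the decided-absent edges `Theta \ I`. For fixed `(S, I)`
#' at most one `T` can indicate 1.
#'
#' @param stage a [StageContext-class].
#' @param S subset of the lower separator.
#' @param T subset of the upper separator.
#' @param I integer set of stage-edge indices decided present.
#' @param theta integer set of all stage-edge indices decided so far.
#' @return 0 or 1.
#' @export
cIndicator <- function(stage, S, T, I, theta) {
  I <- sort(as.integer(I))
  absent <- setdiff(as.integer(theta), I)
  for (u in T) if (chiIndicator(stage, S, u, I) == 0L) return(0L)
  for (v in setdiff(stage@upper, T))
    if (omegaIndicator(stage, S, v, absent) == 0L) return(0L)
  1L
}

# For an uncollapsed term (S, I): the unique candidate T (nodes of the upper
# separator reached through present edges) and whether the outcome is fully
# determined (all other upper nodes blocked even if every undecided edge
# turns out present). `key`, when given, is the canonical term key and is
# reused as the memoisation key (the optimistic query also depends on how
# many edges are decided).
.determineT <- function(stage, S, I, theta, key = NULL, undecided = NULL) {
  if (is.null(key)) key <- .keyU(S, I)
  if (is.null(undecided)) undecided <- setdiff(stage@graph$gidx, theta)
  reached <- stage@cache[[key]]
  if (is.null(reached)) {
    reached <- .stageReachRaw(stage, S, I)
    assign(key, reached, envir = stage@cache)
  }
  T <- intersect(stage@upper, c(reached, S))
  rest <- setdiff(stage@upper, T)
  if (!length(rest)) return(list(determined = TRUE, T = T))
  reachedOpt <- .stageReachRaw(stage, S, c(I, undecided))
  if (any(rest %in% reachedOpt)) list(determined = FALSE, T = T)
  else list(determined = TRUE, T = T)
}

#' Aggregate one edge polynomial into a stage polynomial
#'
#' Each uncollapsed term splits into a present branch (coefficient times
#' `p`, index joining `I` and `Theta`) and an absent branch (coefficient
#' times `1 - p`, index joining `Theta` only). Collapsed terms are absorbed
#' unchanged, since `p + (1 - p) = 1`. Zero-coefficient branches (edges
#' with probability 0 or 1) are dropped immediately. The coefficient sum is
#' preserved exactly.
#'
#' @param poly a [StagePolynomial-class].
#' @param edgeIndex global index of the stage edge being decided.
#' @param p existence probability of that edge (in `[0, 1]`).
#' @return The grown [StagePolynomial-class].
#' @export
aggregateEdge <- function(poly, edgeIndex, p) {
  stopifnot(is(poly, "StagePolynomial"), p >= 0, p <= 1)
  j <- as.integer(edgeIndex)
  if (j %in% poly@theta)
    stop("edge ", j, " has already been aggregated in this stage")
  coef <- poly@coef
  keys <- names(coef)
  isU <- startsWith(keys, "U")
  if (any(isU)) {
    uk <- keys[isU]
    uc <- coef[isU]
    # every term of a stage polynomial receives the edges in the same
    # order, so appending j keeps the key canonical without re-sorting
    presentKeys <- paste0(uk, ifelse(endsWith(uk, .US), "", ","), j)
    newCoef <- c(coef[!isU],
                 stats::setNames(uc * (1 - p), uk),
                 stats::setNames(uc * p, presentKeys))
    newCoef <- newCoef[newCoef != 0]
    coef <- newCoef
  }
  new("StagePolynomial", coef = coef, theta = sort(c(poly@theta, j)),
      stageIndex = poly@stageIndex)
}

#' Apply the collapsing operator to a stage polynomial
#'
#' Every uncollapsed term whose reachability outcome at the upper separator
#' is fully determined is replaced by `gamma * z_T`; coefficients of
#' identical `z_T` labels are summed. Undetermined terms are left verbatim.
#' The coefficient sum is preserved.
#'
#' @param poly a [StagePolynomial-class].
#' @param stage the [StageContext-class] defining `K_i`, `K_{i+1}` and the
#'   stage subgraph.
#' @return The collapsed [StagePolynomial-class].
#' @export
collapsePolynomial <- function(poly, stage) {
  stopifnot(is(poly, "StagePolynomial"), is(stage, "StageContext"))
  coef <- poly@coef
  keys <- names(coef)
  isU <- startsWith(keys, "U")
  if (!any(isU)) return(poly)
  newKeys <- keys
  undecided <- setdiff(stage@graph$gidx, poly@theta)
  for (i in which(isU)) {
    key <- keys[i]
    pk <- paste0("p:", key)
    parsed <- stage@cache[[pk]]
    if (is.null(parsed)) {
      parsed <- .parseKey(key)
      assign(pk, parsed, envir = stage@cache)
    }
    d <- .determineT(stage, parsed$label, parsed$I, poly@theta, key = key,
                     undecided = undecided)
    if (d$determined) newKeys[i] <- .keyZ(d$T)
  }
  if (!identical(newKeys, keys)) {
    agg <- tapply(coef, newKeys, sum)
    coef <- stats::setNames(as.numeric(agg), names(agg))
    coef <- coef[coef != 0]
  }
  new("StagePolynomial", coef = coef, theta = poly@theta,
      stageIndex = poly@stageIndex)
}

#' Advance a collapsed polynomial across one stage
#'
#' Re-opens each collapsed carry-over term `z_S` (non-empty `S` becomes an
#' uncollapsed term with no decided edges; the failure term `z_{}` is
#' absorbing and carried through unchanged), then alternates
#' [aggregateEdge()] and [collapsePolynomial()] over the stage edges in
#' ascending index order. On exit every term has collapsed and the
#' coefficient of `z_T` equals the probability that exactly the subset `T`
#' of the upper separator is reached from the source.
#'
#' @param prev a fully collapsed [StagePolynomial-class] over the lower
#'   separator.
#' @param stage the [StageContext-class] for this stage.
#' @param traceEnv optional environment; when supplied, per-step rows
#'   (`step`, `n_terms`, `n_collapsed`, `coef_sum`) are appended to
#'   `traceEnv$rows`.
#' @param termCap abort (with a condition of class
#'   `netreach_term_overflow`) if the live term count exceeds this bound;
#'   [reachabilityProbability()] uses the abort to switch wide stages to an
#'   equivalent merged-state fold.
#' @return The collapsed [StagePolynomial-class] over the upper separator.
#' @export
advanceStage <- function(prev, stage, traceEnv = NULL, termCap = Inf) {
  stopifnot(is(prev, "StagePolynomial"), is(stage, "StageContext"))
  keys <- names(prev@coef)
  if (any(!startsWith(keys, "Z")))
    stop("the previous polynomial is not fully collapsed")
  newKeys <- vapply(keys, function(k) {
    lab <- .parseKey(k)$label
    if (!length(lab)) k else .keyU(lab, integer())
  }, character(1), USE.NAMES = FALSE)
  poly <- new("StagePolynomial", coef = stats::setNames(prev@coef, newKeys),
              theta = integer(), stageIndex = stage@stageIndex)
  note <- function(p) {
    if (!is.null(traceEnv)) {
      kk <- names(p@coef)
      traceEnv$rows[[length(traceEnv$rows) + 1L]] <- data.frame(
        stage = stage@stageIndex,
        step = length(p@theta),
        n_terms = length(kk),
        n_collapsed = sum(startsWith(kk, "Z")),
        coef_sum = sum(p@coef))
    }
    p
  }
  poly <- note(collapsePolynomial(poly, stage))
  for (pos in seq_len(nrow(stage@edges))) {
    j <- stage@edges$index[pos]
    poly <- note(aggregateEdge(poly, j, stage@edges$prob[pos]))
    poly <- note(collapsePolynomial(poly, stage))
    if (length(poly@coef) > termCap)
      stop(structure(class = c("netreach_term_overflow", "error", "condition"),
                     list(message = sprintf(
                       "stage %d exceeded %d live terms", stage@stageIndex,
                       as.integer(termCap)), call = NULL)))
  }
  if (any(!startsWith(names(poly@coef), "Z")))
    stop("internal error: uncollapsed terms remain after the final stage edge")
  poly
}

#' Exact s-t reachability probability
#'
#' Computes the probability that a signal starting at `s` reaches `t` when
#' every edge of the network exists independently with its stated
#' probability. The network is pruned to the nodes that can carry an s-t
#' signal, partitioned along a sequence of good node separators, and the
#' stage polynomial is folded across the stages; the coefficient of the
#' final `z_{t}` term is the result, which is exact up to floating-point
#' rounding.
#'
#' @param net a [ProbabilisticNetwork-class].
#' @param s,t source and target node identifiers (must differ).
#' @param method `"greedy"` uses [greedySeparatorSequence()];
#'   `"single"` forces the single-stage sequence `({s}, {t})`. Both give
#'   identical probabilities; they differ only in intermediate polynomial
#'   sizes.
#' @param trace when `TRUE` the result carries an attribute `"trace"`: a
#'   data.frame of per-step term counts and coefficient sums.
#' @return The reachability probability in `[0, 1]` (0 when `t` is
#'   unreachable from `s` in the maximal deterministic network).
#' @examples
#' net <- fixtureNetwork("series3")
#' reachabilityProbability(net, "s", "t")   # 0.25
#' @export
reachabilityProbability <- function(net, s, t,
                                    method = c("greedy", "single"),
                                    trace = FALSE) {
  method <- match.arg(method)
  .assertNode(net, s)
  .assertNode(net, t)
  if (s == t)
    stop("source and target must differ; p(s, s) is left undefined")
  pn <- pruneForPair(net, s, t)
  emptyTrace <- data.frame(stage = integer(), step = integer(),
                           n_terms = integer(), n_collapsed = integer(),
                           coef_sum = numeric())
  det <- maximalDeterministic(pn)
  g <- .detGraph(det)
  if (!.pathAvoiding(g, s, t, character())) {
    res <- 0
    if (trace) attr(res, "trace") <- emptyTrace
    return(res)
  }
  sseq <- switch(method,
                 greedy = greedySeparatorSequence(pn, s, t),
                 single = .singleStageSequence(pn, s, t))
  poly <- newStagePolynomial(s, stageIndex = 0L)
  traceEnv <- if (trace) new.env(parent = emptyenv()) else NULL
  if (trace) traceEnv$rows <- list()
  for (i in seq_along(sseq@stages)) {
    stage <- stageContext(pn, sseq@separators[[i]], sseq@separators[[i + 1L]],
                          sseq@stages[[i]], stageIndex = i)
    # verbatim per-term fold first; on live-term overflow redo the stage
    # with the equivalent merged-state fold (identical coefficients)
    attempt <- tryCatch({
      env <- if (trace) new.env(parent = emptyenv()) else NULL
      if (trace) env$rows <- list()
      out <- advanceStage(poly, stage, traceEnv = env,
                          termCap = .termOverflowCap)
      list(poly = out, env = env)
    }, netreach_term_overflow = function(e) NULL)
    if (is.null(attempt)) {
      stage <- stageContext(pn, sseq@separators[[i]], sseq@separators[[i + 1L]],
                            sseq@stages[[i]], stageIndex = i)
      env <- if (trace) new.env(parent = emptyenv()) else NULL
      if (trace) env$rows <- list()
      poly <- .advanceStageMerged(poly, stage, traceEnv = env)
    } else {
      poly <- attempt$poly
      env <- attempt$env
    }
    if (trace) traceEnv$rows <- c(traceEnv$rows, env$rows)
  }
  finalKeys <- names(poly@coef)
  ok <- finalKeys %in% c(.keyZ(t), .keyZ(character()))
  if (any(!ok))
    stop("internal error: unexpected terms in the final polynomial")
  gammaT <- poly@coef[.keyZ(t)]
  res <- if (is.na(gammaT)) 0 else unname(gammaT)
  res <- min(max(res, 0), 1)
  if (trace) {
    attr(res, "trace") <- if (length(traceEnv$rows))
      do.call(rbind, traceEnv$rows) else emptyTrace
  }
  res
}

setMethod("show", "StagePolynomial", function(object) {
  kk <- names(object@coef)
  cat("StagePolynomial (stage ", object@stageIndex, ")\n", sep = "")
  cat("  ", length(kk), " term(s), ", sum(startsWith(kk, "Z")),
      " collapsed; decided edges: ", length(object@theta), "\n", sep = "")
  cat("  coefficient sum:", format(sum(object@coef), digits = 15), "\n")
})

setMethod("show", "StageContext", function(object) {
  cat("StageContext (stage ", object@stageIndex, ")\n", sep = "")
  cat("  K_lower: {", paste(object@lower, collapse = ","), "}  K_upper: {",
      paste(object@upper, collapse = ","), "}\n", sep = "")
  cat("  ", nrow(object@edges), " stage edge(s) over ", length(object@nodes),
      " node(s)\n", sep = "")
})
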