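fig2 <- fixtureNetwork("fig2")

test_that("path indicator follows the documented example and the empty-path rule", {
  st <- wholeStage(fig2, "1", "8")
  expect_equal(chiIndicator(st, "1", "8", c(1, 2, 5, 6, 7, 10, 11)), 1L)
  expect_equal(chiIndicator(st, "1", "8", c(1, 3, 4)), 0L)
  expect_equal(chiIndicator(st, c("4", "7"), "4", integer()), 1L)  # u in S
  expect_equal(chiIndicator(st, "1", "8", integer()), 0L)
})

test_that("cut indicator follows the documented example and refuses optimistic routes", {
  st <- wholeStage(fig2, "1", "8")
  # {e3,e5} is a minimal 1-8 cut inside the decided-absent set {2,3,4,5}
  expect_equal(omegaIndicator(st, "1", "8", c(2, 3, 4, 5)), 1L)
  expect_equal(omegaIndicator(st, "1", "8", integer()), 0L)
})

test_that("the blocked-even-if-present form equals the literal minimal-cut definition", {
  # literal form: some minimal s'-v edge cut lies inside the decided-absent
  # set, for every origin. Enumerate all cuts on small random stages.
  minimalCutInside <- function(net, s, v, absent) {
    e <- edgeTable(net)
    n <- nrow(e)
    g <- igraph::graph_from_data_frame(e[c("from", "to")], directed = TRUE,
                                       vertices = data.frame(name = nodeIds(net)))
    disconnects <- function(idx) {
      sub <- igraph::delete_edges(g, idx)
      !is.finite(igraph::distances(sub, s, v, mode = "out")[1, 1])
    }
    if (!disconnects(integer())) {
      found <- FALSE
      for (k in seq_len(n)) {
        for (cut in combn(n, k, simplify = FALSE)) {
          if (!disconnects(cut)) next
          minimal <- all(vapply(cut, function(d)
            !disconnects(setdiff(cut, d)), logical(1)))
          if (minimal && all(cut %in% absent)) found <- TRUE
        }
        if (found) break
      }
      found
    } else TRUE  # v never reachable: the empty cut works
  }
  set.seed(47)
  for (rep in 1:12) {
    net <- randomNetwork(4, sample(4:7, 1))
    st0 <- sample(nodeIds(net), 2)
    stage <- wholeStage(net, st0[1], st0[2])
    idx <- edgeTable(net)$index
    for (try in 1:6) {
      absent <- sample(idx, sample(0:length(idx), 1))
      v <- sample(setdiff(nodeIds(net), st0[1]), 1)
      expect_equal(omegaIndicator(stage, st0[1], v, absent) == 1L,
                   minimalCutInside(net, st0[1], v, absent))
    }
  }
})

test_that("at most one next-separator subset indicates 1 and full decision yields exactly one", {
  set.seed(53)
  for (rep in 1:15) {
    net <- randomNetwork(4, sample(3:6, 1))
    nodes <- nodeIds(net)
    s <- nodes[1]
    upper <- sample(setdiff(nodes, s), 2)
    stage <- stageContext(net, s, upper, edgeTable(net)$index)
    idx <- edgeTable(net)$index
    subsetsT <- list(character(), upper[1], upper[2], upper)
    for (try in 1:8) {
      theta <- sort(sample(idx, sample(0:length(idx), 1)))
      I <- sort(sample(theta, sample(0:length(theta), 1)))
      hits <- sum(vapply(subsetsT, function(T)
        cIndicator(stage, s, T, I, theta), integer(1)))
      expect_lte(hits, 1L)
      if (length(theta) == length(idx)) expect_equal(hits, 1L)
    }
  }
})

test_that("edge aggregation splits uncollapsed terms and absorbs collapsed ones", {
  uPoly <- function(coef) {  # single uncollapsed term with S = {s}, I empty
    new("StagePolynomial", coef = setNames(coef, "U\x1fs\x1f"),
        theta = integer(), stageIndex = 1L)
  }
  p1 <- aggregateEdge(uPoly(1), 1L, 0.5)
  expect_equal(unname(sort(p1@coef)), c(0.5, 0.5))
  expect_equal(sum(p1@coef), 1)
  expect_error(aggregateEdge(p1, 1L, 0.5), "already")

  # collapsed z_T terms absorb any further edge unchanged
  pz <- new("StagePolynomial", coef = setNames(0.3, "Z\x1fu"),
            theta = integer(), stageIndex = 1L)
  pz2 <- aggregateEdge(pz, 2L, 0.8)
  expect_identical(pz2@coef, pz@coef)

  # probability-1 edges never generate an absent branch
  p3 <- aggregateEdge(uPoly(0.3), 2L, 1)
  expect_length(p3@coef, 1L)
  expect_equal(sum(p3@coef), 0.3)
})

test_that("collapse resolves fully decided stages and early-determined terms", {
  # single-edge stage s -> u with p = 0.8: 0.8 z_{u} + 0.2 z_{}
  net1 <- probNetwork("s", "u", 0.8)
  stage1 <- stageContext(net1, "s", "u", 1L)
  out <- advanceStage(newStagePolynomial("s"), stage1)
  terms <- polynomialTerms(out)
  labels <- vapply(terms, function(tr) paste(tr$label, collapse = ","), "")
  expect_setequal(labels, c("u", ""))
  expect_prob_equal(out@coef[[which(labels == "u")]], 0.8)
  expect_prob_equal(sum(out@coef), 1)

  # a two-route stage collapses a term as soon as the present set contains
  # a full path to every upper node, even with edges still undecided
  net2 <- probNetwork(c("s", "s"), c("u", "v"), c(0.5, 0.5))
  stage2 <- stageContext(net2, "s", "u", edgeTable(net2)$index)
  poly <- new("StagePolynomial",
              coef = setNames(1, "U\x1fs\x1f1"), theta = c(1L),
              stageIndex = 1L)
  col <- collapsePolynomial(poly, stage2)
  expect_true(all(startsWith(names(col@coef), "Z")))
})

test_that("stage advance reproduces subset-reachability probabilities exactly", {
  # brute-force p({s}, T, K1) on the layered example by enumerating the
  # stage-edge configurations (independent oracle for the first stage)
  net <- fixtureNetwork("fig3")
  pn <- pruneForPair(net, "1", "7")
  sq <- greedySeparatorSequence(pn, "1", "7")
  stage <- stageContext(pn, sq@separators[[1]], sq@separators[[2]],
                        sq@stages[[1]], 1L)
  out <- advanceStage(newStagePolynomial("1"), stage)
  expect_prob_equal(sum(out@coef), 1)

  e <- edgeTable(pn)[edgeTable(pn)$index %in% sq@stages[[1]], ]
  K1 <- sq@separators[[2]]
  ref <- setNames(numeric(4), c("T_", "T_2", "T_3", "T_2,3"))
  for (mask in 0:(2^nrow(e) - 1)) {
    present <- bitwAnd(mask, 2^(seq_len(nrow(e)) - 1)) > 0
    w <- prod(ifelse(present, e$prob, 1 - e$prob))
    reached <- sort(unique(e$to[present & e$from == "1"]))
    key <- paste0("T_", paste(intersect(K1, reached), collapse = ","))
    ref[key] <- ref[key] + w
  }
  got <- polynomialTerms(out)
  for (tr in got) {
    lab <- paste0("T_", paste(sort(tr$label), collapse = ","))
    expect_prob_equal(tr$coef, ref[[lab]])
  }
  expect_error(advanceStage(
    new("StagePolynomial", coef = setNames(1, "U\x1fs\x1f"),
        theta = integer(), stageIndex = 1L), stage), "not fully collapsed")
})

test_that("closed-form reachability values are reproduced", {
  expect_prob_equal(reachabilityProbability(fixtureNetwork("series3"), "s", "t"), 0.25)
  expect_prob_equal(reachabilityProbability(fixtureNetwork("parallel2"), "s", "t"),
                    1 - (1 - 0.25)^2)
  expect_prob_equal(reachabilityProbability(fixtureNetwork("bridge5"), "s", "t"), 15 / 32)
  expect_error(reachabilityProbability(fixtureNetwork("series3"), "s", "s"), "differ")
  expect_error(reachabilityProbability(fixtureNetwork("series3"), "s", "zz"),
               "unknown node")
})

test_that("the collapsing method agrees with both oracles on random networks", {
  set.seed(97)
  nChecked <- 0L
  for (rep in 1:110) {
    net <- randomNetwork(sample(4:7, 1), sample(4:12, 1))
    st <- sample(nodeIds(net), 2)
    a <- reachabilityProbability(net, st[1], st[2])
    expect_prob_equal(a, bruteForceReachability(net, st[1], st[2]))
    ie <- tryCatch(inclusionExclusionReachability(net, st[1], st[2], maxPaths = 15),
                   error = function(e) NULL)
    if (!is.null(ie)) expect_prob_equal(a, ie)
    nChecked <- nChecked + 1L
  }
  expect_gte(nChecked, 100L)
})

test_that("greedy and single-stage separator sequences give identical results", {
  set.seed(131)
  for (rep in 1:60) {
    net <- randomNetwork(sample(4:7, 1), sample(4:12, 1))
    st <- sample(nodeIds(net), 2)
    expect_prob_equal(reachabilityProbability(net, st[1], st[2]),
                      reachabilityProbability(net, st[1], st[2],
                                              method = "single"))
  }
})

test_that("coefficients conserve probability mass at every aggregation and collapse", {
  set.seed(139)
  for (rep in 1:25) {
    net <- randomNetwork(sample(4:7, 1), sample(5:12, 1))
    st <- sample(nodeIds(net), 2)
    v <- reachabilityProbability(net, st[1], st[2], trace = TRUE)
    tr <- attr(v, "trace")
    if (nrow(tr)) expect_lt(max(abs(tr$coef_sum - 1)), 1e-12)
  }
})

test_that("the final polynomial carries only the success and failure labels", {
  net <- fixtureNetwork("fig2")
  pn <- pruneForPair(net, "1", "8")
  sq <- greedySeparatorSequence(pn, "1", "8")
  poly <- newStagePolynomial("1")
  for (i in seq_along(sq@stages)) {
    stage <- stageContext(pn, sq@separators[[i]], sq@separators[[i + 1]],
                          sq@stages[[i]], i)
    poly <- advanceStage(poly, stage)
  }
  terms <- polynomialTerms(poly)
  labels <- vapply(terms, function(tr) paste(tr$label, collapse = ","), "")
  expect_true(all(labels %in% c("8", "")))
  expect_prob_equal(sum(poly@coef), 1)
})

test_that("reachability is monotone in edge probabilities and edge additions", {
  set.seed(149)
  for (rep in 1:20) {
    net <- randomNetwork(5, 8)
    st <- sample(nodeIds(net), 2)
    base <- reachabilityProbability(net, st[1], st[2])
    e <- edgeTable(net)
    k <- sample(nrow(e), 1)
    up <- probNetwork(e$from, e$to, pmin(1, replace(e$prob, k, e$prob[k] + 0.3)),
                      nodes = nodeIds(net))
    expect_gte(reachabilityProbability(up, st[1], st[2]), base - 1e-12)
    # adding one absent edge never decreases reachability
    pairs <- expand.grid(from = nodeIds(net), to = nodeIds(net),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    have <- paste(e$from, e$to)
    free <- pairs[!paste(pairs$from, pairs$to) %in% have, ]
    if (nrow(free)) {
      add <- free[sample(nrow(free), 1), ]
      net2 <- probNetwork(c(e$from, add$from), c(e$to, add$to),
                          c(e$prob, 0.5), nodes = nodeIds(net))
      expect_gte(reachabilityProbability(net2, st[1], st[2]), base - 1e-12)
    }
  }
})

test_that("degenerate limits match deterministic reachability", {
  set.seed(151)
  for (rep in 1:15) {
    net <- randomNetwork(5, 8, probs = rep(1, 8))
    st <- sample(nodeIds(net), 2)
    det <- maximalDeterministic(net)
    ig <- igraph::graph_from_data_frame(edgeTable(det)[c("from", "to")],
                                        directed = TRUE,
                                        vertices = data.frame(name = nodeIds(det)))
    reach <- is.finite(igraph::distances(ig, st[1], st[2], mode = "out")[1, 1])
    expect_equal(reachabilityProbability(net, st[1], st[2]),
                 as.numeric(reach))
  }
})

test_that("intermediate polynomial sizes respect the worst-case bound", {
  set.seed(157)
  for (rep in 1:10) {
    net <- randomNetwork(sample(5:7, 1), sample(6:12, 1))
    st <- sample(nodeIds(net), 2)
    pn <- pruneForPair(net, st[1], st[2])
    sq <- greedySeparatorSequence(pn, st[1], st[2])
    v <- reachabilityProbability(net, st[1], st[2], trace = TRUE)
    tr <- attr(v, "trace")
    if (!nrow(tr)) next
    widths <- vapply(sq@separators, length, integer(1))
    for (i in seq_len(nrow(tr))) {
      w <- widths[tr$stage[i]]
      bound <- 2^(w + tr$step[i]) + tr$n_collapsed[i]
      expect_lte(tr$n_terms[i], bound)
    }
  }
})
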