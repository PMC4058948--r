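fig2det <- maximalDeterministic(fixtureNetwork("fig2"))
fig3net <- fixtureNetwork("fig3")

test_that("the example separator {4,5} classifies exactly as documented", {
  part <- classifySeparator(fig2det, "1", "8", c("4", "5"))
  expect_setequal(part@leftNodes, c("1", "2", "3"))
  expect_setequal(part@rightNodes, c("6", "7", "8"))
  expect_setequal(part@leftEdges, c(1L, 2L, 3L, 5L, 6L))
  expect_setequal(part@backwardEdges, c(4L, 8L))
  expect_false(isGoodSeparator(part))
  expect_true(isSeparator(fig2det, "1", "8", c("4", "5")))
})

test_that("chain separators classify with empty backward sets", {
  net <- fixtureNetwork("series3")
  det <- maximalDeterministic(net)
  part <- classifySeparator(det, "s", "t", "a")
  expect_identical(part@leftNodes, "s")
  expect_identical(part@rightNodes, "t")
  expect_length(part@backwardEdges, 0L)
  expect_true(isGoodSeparator(part))
  part23 <- classifySeparator(maximalDeterministic(fig3net), "1", "7", c("2", "3"))
  expect_true(isGoodSeparator(part23))
  expect_error(classifySeparator(det, "s", "t", character()), "not an s-t")
})

test_that("separator detection agrees with exhaustive node-deletion checks", {
  set.seed(7)
  for (rep in 1:15) {
    net <- randomNetwork(sample(4:6, 1), sample(4:10, 1))
    det <- maximalDeterministic(net)
    st <- sample(nodeIds(net), 2)
    inner <- setdiff(nodeIds(net), st)
    subsets <- unlist(lapply(0:length(inner), function(k)
      combn(inner, k, simplify = FALSE)), recursive = FALSE)
    ig <- igraph::graph_from_data_frame(
      edgeTable(net)[c("from", "to")], directed = TRUE,
      vertices = data.frame(name = nodeIds(net)))
    for (K in subsets) {
      ref <- {
        sub <- igraph::delete_vertices(ig, K)
        !is.finite(igraph::distances(sub, st[1], st[2], mode = "out")[1, 1])
      }
      expect_identical(isSeparator(det, st[1], st[2], K), ref)
    }
  }
})

test_that("minimality agrees with brute force over proper subsets", {
  det <- maximalDeterministic(probNetwork(c("s", "a", "b"), c("a", "b", "t"),
                                          rep(0.5, 3)))
  expect_true(isMinimalSeparator(det, "s", "t", "a"))
  expect_false(isMinimalSeparator(det, "s", "t", c("a", "b")))
  set.seed(11)
  for (rep in 1:10) {
    net <- randomNetwork(5, sample(5:10, 1))
    d <- maximalDeterministic(net)
    st <- sample(nodeIds(net), 2)
    inner <- setdiff(nodeIds(net), st)
    for (k in 1:3) {
      for (K in combn(inner, k, simplify = FALSE)) {
        if (!isSeparator(d, st[1], st[2], K)) next
        proper <- c(list(character(0)),
                    if (length(K) > 1L)
                      unlist(lapply(seq_len(length(K) - 1L), function(j)
                        combn(K, j, simplify = FALSE)), recursive = FALSE))
        ref <- !any(vapply(proper, function(Ksub)
          isSeparator(d, st[1], st[2], Ksub), logical(1)))
        expect_identical(isMinimalSeparator(d, st[1], st[2], K), ref)
      }
    }
  }
})

test_that("every right node inherits the separator (structural property)", {
  expect_true(theorem1Holds(fig2det, "1", "8", c("4", "5")))
  det <- maximalDeterministic(fixtureNetwork("series3"))
  expect_true(theorem1Holds(det, "s", "t", "a"))
  set.seed(23)
  for (rep in 1:60) {
    net <- randomNetwork(sample(4:6, 1), sample(5:12, 1))
    d <- maximalDeterministic(net)
    st <- sample(nodeIds(net), 2)
    inner <- setdiff(nodeIds(net), st)
    for (k in 1:min(2, length(inner))) {
      for (K in combn(inner, k, simplify = FALSE)) {
        if (isSeparator(d, st[1], st[2], K))
          expect_true(theorem1Holds(d, st[1], st[2], K))
      }
    }
  }
})

test_that("greedy sequences reproduce the layered example and the chain cases", {
  sq <- greedySeparatorSequence(pruneForPair(fig3net, "1", "7"), "1", "7")
  expect_identical(sq@separators,
                   list("1", c("2", "3"), c("4", "5", "6"), "7"))
  chain <- fixtureNetwork("series3")
  expect_identical(greedySeparatorSequence(chain, "s", "t")@separators,
                   list("s", "a", "t"))
  direct <- probNetwork("s", "t", 0.5)
  sqd <- greedySeparatorSequence(direct, "s", "t")
  expect_identical(sqd@separators, list("s", "t"))
  expect_identical(sqd@stages, list(1L))
})

test_that("generated sequences satisfy the type invariants on random inputs", {
  set.seed(31)
  for (rep in 1:40) {
    net <- randomNetwork(sample(5:8, 1), sample(6:14, 1))
    st <- sample(nodeIds(net), 2)
    pn <- pruneForPair(net, st[1], st[2])
    sq <- greedySeparatorSequence(pn, st[1], st[2])
    det <- maximalDeterministic(pn)
    allStage <- sort(unlist(sq@stages))
    expect_identical(as.integer(allStage), sort(edgeTable(pn)$index))
    expect_equal(anyDuplicated(unlist(sq@stages)), 0L)
    for (K in sq@separators) {
      expect_true(isSeparator(det, st[1], st[2], K))
      expect_true(isGoodSeparator(classifySeparator(det, st[1], st[2], K)))
      expect_true(theorem1Holds(det, st[1], st[2], K))
    }
  }
})

test_that("hand-built separator sequences are validated", {
  pn <- pruneForPair(fig3net, "1", "7")
  sq <- separatorSequence(pn, "1", "7", list("1", c("2", "3"), "7"))
  expect_s4_class(sq, "SeparatorSequence")
  expect_error(separatorSequence(pn, "1", "7", list("1", c("4"), "7")),
               "not an s-t|backward")
})
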