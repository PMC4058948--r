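# Shared generators for property-style tests. All randomness is local:
# callers set the seed.

# A random simple directed network on nNodes with nEdges distinct ordered
# pairs and Uniform(0,1) probabilities.
randomNetwork <- function(nNodes, nEdges, probs = NULL) {
  nodes <- paste0("v", seq_len(nNodes))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- pairs[sample.int(nrow(pairs), min(nEdges, nrow(pairs))), ]
  if (is.null(probs)) probs <- runif(nrow(pick))
  probNetwork(pick$from, pick$to, probs, nodes = nodes)
}

# A random stage context spanning the whole network as a single stage
# ({s}, {t}) - used to exercise the indicator functions directly.
wholeStage <- function(net, s, t) {
  stageContext(net, s, t, edgeTable(net)$index, stageIndex = 1L)
}

# Write an edge-list file from text lines and return its path.
edgeFile <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

expect_prob_equal <- function(a, b, tol = 1e-12) {
  expect_lt(abs(as.numeric(a) - as.numeric(b)), tol)
}
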