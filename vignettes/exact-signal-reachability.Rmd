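---
title: "Exact signal reachability in probabilistic networks: model, algorithm and design notes"
author: "netreach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact signal reachability in probabilistic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netreach)
```

## The model

A probabilistic network is a directed graph $G = (V, E, P)$ in which every
edge $e_i$ exists independently with probability $p_i = P(e_i) \in (0, 1]$.
In transcription-regulatory and signalling networks the nodes are genes or
proteins and $p_i$ is an interaction confidence; a network with $n$
probabilistic edges represents $2^n$ deterministic topologies, each
realised with probability $\prod_{i \in I} p_i \prod_{j \notin I} q_j$,
$q_j = 1 - p_j$. The quantity of interest is the two-terminal reachability
probability
$$
p(s, t) \;=\; \Pr\{\text{some directed } s\!\to\!t \text{ path exists}\},
$$
the probability that a signal at source $s$ can arrive at target $t$.
Computing it exactly is #P-complete, so naive enumeration stops being
usable after a few tens of edges.

Collecting $p(s_i, t_j)$ over source and target sets gives the
*reachability profile* $R[i, j]$, a global description of the signalling
state of a network; node-removal centrality and perturbation stability
(below) are summaries of profiles.

## The algorithm

The solver is a divide-and-conquer over *good node separators*. An s-t
node separator is a node set $K$ whose deletion disconnects $t$ from $s$.
$K$ splits nodes into left nodes (reachable from $s$ without crossing
$K$), $K$ itself, and right nodes, and splits edges into left edges
$L(K)$, right edges, and backward edges (right $\to$ left or right $\to$
$K$). A separator without backward edges is *good*; only good separators
are used, because then every left-to-right route is forced through $K$
and the computation can forget the left part entirely.

Given a sequence $K_0 = \{s\},\, K_1, \dots, K_{c+1} = \{t\}$ of good
separators, the driver tracks, for every subset $S \subseteq K_i$, the
probability $p(\{s\}, S, K_i)$ that exactly the subset $S$ of $K_i$ is
reachable from the source (*subset reachability*). The recurrence
$$
p(\{s\}, T, K_{i+1}) \;=\; \sum_{\emptyset \ne S \subseteq K_i}
  p(\{s\}, S, K_i)\; p(S, T, K_{i+1})
$$
moves one stage at a time; the stage $i{+}1$ only involves the edge set
$E_{i+1} = L(K_{i+1}) \setminus L(K_i)$.

Within a stage the transition is computed in polynomial form. Each edge
carries the polynomial $p_i x_i + q_i y_i$; the product over aggregated
edges enumerates partial topologies. Each term records the carried subset
label ($z_S$), the present set $I$ and the decided set $\Theta$. After
every aggregation the *collapsing operator* replaces any term whose
outcome at $K_{i+1}$ is already determined by the single variable $z_T$,
where $T$ is the reached subset: $u \in T$ iff a present path reaches $u$
(path indicator $\chi$), and every $v \in K_{i+1} \setminus T$ must be
blocked by a minimal edge cut that is already decided absent (cut
indicator $\omega$). A node of $S$ reaches itself through the empty path,
which is what lets consecutive separators share nodes. Collapsed terms
absorb later edge polynomials unchanged because $p_j + q_j = 1$, so their
coefficients simply accumulate. At the end of the final stage the
polynomial is $\gamma_{\{t\}} z_{\{t\}} + \gamma_\emptyset z_\emptyset$
and $\gamma_{\{t\}} = p(s, t)$ exactly. The failure label
$z_\emptyset$ is absorbing across stages: a signal that is provably
blocked stays blocked.

The cut indicator is implemented operationally — $v$ is blocked iff $v$
is unreachable from $S$ even when every still-undecided edge is assumed
present — and the equivalence with the literal minimal-cut definition is
verified in the test suite by exhaustive cut enumeration on small stages.

### Finding the separator sequence

Any sequence of good separators gives the identical result (a tested
invariant); the sequence only controls intermediate polynomial size, so a
greedy heuristic is used. A walk frontier starts at $\{s\}$ and advances
one hop at a time: frontier nodes without a direct edge to $t$ retire and
are replaced by their successors, nodes adjacent to $t$ stay (only
$\{t\}$ itself may be the final separator) while their other successors
open up, and nodes that receive a backward edge are pushed first. By
construction every frontier is a separator. At each step a minimal good
sub-separator is extracted from the frontier by a lexicographic drop scan
(dropping is accepted only while the set still separates); when the
extract is also good it is recorded. Dropped nodes that land left of the
recorded cut retire; drops that land right stay in the walk so their
routes are covered by later stages. The walk is deterministic, terminates
(the passed region grows monotonically), and falls back to the
always-valid single-stage sequence $(\{s\}, \{t\})$ whenever the recorded
snapshots fail validation. Minimality of the recorded separators is
attempted, not guaranteed; correctness never depends on it.

Before any of this, the network is pruned to the nodes that can lie on an
s-t route: edges into $s$ and out of $t$ are discarded (no simple
$s\!\to\!t$ path uses them) and only nodes reachable from $s$ and
co-reachable to $t$ are kept. The pruning provably leaves $p(s, t)$
unchanged — a property the tests check against the enumeration oracle —
and it guarantees that the final separator $\{t\}$ is good, which the
stage decomposition needs.

### Wide stages: the merged-state fold

Some instances contain no good separator through a dense region —
typically route bundles converging on a hub. The per-term fold then keeps
up to $2^{|E_{i+1}|}$ undetermined terms — its term count can double with
every aggregated edge — and is infeasible no matter how edges are
ordered. The package therefore monitors the live term count; if
a stage exceeds 128 live terms it is redone with an equivalent
*merged-state* fold. The key observation is that every later path or cut
query about a term depends on its present set $I$ only through the
reachability relation of the $I$-subgraph restricted to the *boundary*:
the tails and heads of still-undecided edges plus the next separator
(any path through present and future edges decomposes into present-edge
segments joined at boundary nodes). Terms with the same restricted
relation are indistinguishable from then on, so their coefficients can be
summed without changing any later collapse — in particular
$\gamma_{\{t\}}$ is bit-for-bit the same computation up to float
rounding. The state count is then governed by reachability patterns
across the decided/undecided cut (roughly $2^{\text{cutwidth}}$) instead
of $2^{|E_{i+1}|}$; the acceptance script reports the maximum state
count over its sampled single-pair queries on a 300-node synthetic
network. Equivalence of the two folds is property-tested term by term on
random networks and against the enumeration oracle.

Within a stage, edges are aggregated in topological order of their tails
(strongly connected components condensed, ties broken by edge index).
The result is order-independent — also a tested invariant — but deciding
upstream edges first lets downstream outcomes resolve, and terms
collapse, as early as possible.

## Reference oracles

Two independent implementations exist solely to certify the solver:

* `bruteForceReachability()` enumerates all $2^n$ edge configurations
  (default cap: 20 edges) and sums the mass of those containing an
  $s\!\to\!t$ path.
* `inclusionExclusionReachability()` enumerates all simple $s\!\to\!t$
  paths (default cap: 18 paths) and applies inclusion–exclusion over
  path subsets.

Caps are hard errors, never silent truncation — a truncated oracle would
be worse than none. The headline correctness test drives hundreds of
random networks through the solver and both oracles and requires
agreement within $10^{-12}$.

## Downstream analyses

*Profiles.* `computeProfile()` evaluates $R[i, j] = p(s_i, t_j)$ for all
ordered pairs; entries with $s_i = t_j$ are recorded as missing because
$p(s, s)$ is left undefined (a caller who wants the convention
$p(s,s)=1$ can impose it).

*Centrality.* `geneCentrality()` is the total profile drop caused by
removing one gene with its incident edges,
$\sum_{s, t} p(s,t) - p_{\bar g}(s,t)$. Removal monotonicity makes it
non-negative. When the removed gene is itself a source or target, the
post-removal probability of its own pairs is defined as 0 — a removed
gene can neither emit nor receive — which keeps the centrality of hub
terminals meaningful; `skipSelfPairs = TRUE` excludes those pairs
instead. All centrality values are emitted; any display threshold is the
caller's choice.

*Stability.* `networkStability()` redraws every edge probability
uniformly from $[P(e) - \delta,\, P(e) + \delta] \cap [0, 1]$ (point
intervals return the point; zeros are legal internally), recomputes the
profile, and averages $|p^\delta(s,t) - p(s,t)|$ over pairs, then over
replicates (default 20). All replicate streams derive deterministically
from one master seed, so results are independent of evaluation order. At
$\delta = 0$ the change is exactly zero; in expectation the change grows
with $\delta$, which the tests verify as a positive Spearman trend over
$\delta \in \{0, 0.1, 0.2, 0.3\}$.

## The synthetic generator

`barabasiAlbert(n)` builds a scale-free network with exactly $2n$ edges:
a 3-node seed star, preferential attachment with $m = 2$ links per new
node, and uniformly random extra links to reach the exact count. Edge
probabilities are drawn uniformly from `(probLow, probHigh]`, by default
$(0, 1]$ — an uninformative choice, exposed as a knob.

Orientation deserves a note, because the undirected preferential
attachment model does not fix one. The default `"attachment"` orients
every link from the newer to the older endpoint. This gives a shallow
acyclic hierarchy converging on the early hubs — the same qualitative
shape as the feed-forward backbone of a transcription regulatory network
— and it is the regime in which separator sequences stay narrow. The
alternatives illustrate why the choice matters: `"acyclic"` (orientation
along a uniformly random node order) produces deeper graphs whose wide
middle stages are expensive for any exact method, and `"random"`
(independent coin flip per link) almost surely produces one giant
strongly connected component in which good s-t separators do not exist
between most pairs, so exact computation degenerates to its exponential
worst case. These are useful stress regimes, not benchmarks. What the
generator does not emulate: correlated edge existence, degree-corrected
probabilities, self-regulation (self-loops are rejected by the model),
and any biological edge semantics — so passing tests demonstrate
algorithmic correctness and scalability on scale-free topologies, not
biological validity of any particular network.

Named fixtures (`fixtureNetwork()`) provide the small worked examples
used throughout the documentation and tests, including an 8-node cyclic
network whose separator classification, path and minimal-cut facts are
asserted programmatically at construction, and a layered 7-node network
with two disjoint separators that the greedy search must reproduce
exactly.

## Numerical and design choices

* All arithmetic is plain double precision. Aggregation and collapse
  only multiply by $p$, $1-p$ and add non-negative terms, so coefficient
  sums stay at $1$ to within $10^{-12}$ across every step (tested); the
  oracle comparisons use the same tolerance.
* Zero-probability edges are rejected at load time (the model defines
  $P: E \to (0,1]$) but accepted internally, because perturbation can
  push a probability to exactly 0 and pruned branches carry coefficient
  0; zero-coefficient terms are deleted immediately.
* Duplicate directed edges are rejected by default; the loader can merge
  $k$ parallel edges into one with $p = 1 - \prod_k (1 - p_k)$
  (`mergeDuplicates`), which is the exact disjunction of independent
  events.
* Undirected input is expanded into two opposite directed edges that are
  treated as independent events; no correlation is modelled.
* `p(s, s)` is refused rather than defined; profile entries on the
  diagonal are `NA`.
* Node identifiers are opaque, case-sensitive strings without
  whitespace or control characters; comparisons are exact.
* Ties everywhere (separator drop scans, replacement order) are broken
  lexicographically for reproducibility; correctness is order-free.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise: random networks of 4–7
nodes and up to 12–14 edges (hundreds of instances, where exhaustive
enumeration is exact and fast); the in-package fixtures; 300-node,
600-edge synthetic networks for scalability (sampled source–target
pairs); and a 30-node, 60-edge network with 3 sources and 3 targets for
the perturbation experiment at 20 replicates per width. These sizes were
chosen so that every check has an independent oracle or a closed form
where one exists, and so that the full suite runs comfortably on a
laptop; the algorithm itself has no intrinsic size limit beyond the
state growth discussed above.

## Known limitations

* Edge independence is assumed throughout; confidence scores derived
  from shared evidence violate it and the results are then only a model.
* The greedy separator search is a heuristic: it guarantees correctness,
  not minimal work. Networks whose pruned instances are dominated by a
  dense strongly connected core fall back to wide stages, where the
  merged-state fold still grows exponentially in the cutwidth — an
  inherent property of exact #P computation, not an implementation
  limit.
* Estimating edge probabilities from expression data, and selecting
  biologically meaningful source/target sets, are outside the package's
  scope; it consumes a network with probabilities already attached.
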