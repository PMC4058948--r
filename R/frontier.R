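# Frontier-merged stage fold.
#
# The per-term stage fold in advanceStage() keeps every undetermined
# present/absent pattern verbatim, so its term count can approach 2^|E_i|
# on stages without internal good separators (dense route bundles around
# hub nodes). Every future indicator query about a term, however, depends
# on its present-edge set I only through the reachability relation of the
# I-subgraph restricted to the *boundary*: the tails and heads of the
# still-undecided edges plus the upper separator. Terms with identical
# restricted relations are indistinguishable from that point on - any path
# through present and future edges decomposes into I-segments joined at
# boundary nodes - so their coefficients can be summed without changing
# any later collapse, and in particular without changing the final
# coefficients gamma_T. This fold tracks those merged states; its state
# count is governed by the reachability patterns across the decided /
# undecided cut (roughly 2^cutwidth) instead of 2^|E_i|.
#
# Exactness is property-tested against advanceStage() and against the
# configuration-enumeration oracle.

# Fold one stage in merged-state form. prev: fully collapsed
# StagePolynomial over the lower separator. Returns a collapsed
# StagePolynomial over the upper separator, identical (up to float
# rounding) to advanceStage(prev, stage).
.advanceStageMerged <- function(prev, stage, traceEnv = NULL) {
  keys <- names(prev@coef)
  if (any(!startsWith(keys, "Z")))
    stop("the previous polynomial is not fully collapsed")
  e <- stage@edges
  m <- nrow(e)
  g <- stage@graph
  nodes <- g$nodes
  id <- g$id
  kn <- unname(id[stage@upper])
  tails <- unname(id[e$from])
  heads <- unname(id[e$to])

  # boundary row/col node lists after deciding the first j edges
  rowsAt <- vector("list", m + 1L)
  colsAt <- vector("list", m + 1L)
  for (j in 0:m) {
    rest <- if (j < m) seq.int(j + 1L, m) else integer()
    rowsAt[[j + 1L]] <- c(0L, sort(unique(heads[rest])))       # 0 = source row
    colsAt[[j + 1L]] <- sort(unique(c(tails[rest], kn)))
  }

  zAcc <- new.env(parent = emptyenv())       # collapsed z_T accumulator
  bump <- function(key, w) {
    cur <- zAcc[[key]]
    zAcc[[key]] <- if (is.null(cur)) w else cur + w
  }

  # a state is list(R = logical matrix rows x cols, coef)
  sigOf <- function(R) paste(which(R), collapse = ",")

  # per-step boundary positions of the undecided edges and the upper
  # separator (shared by every state at that step)
  knPosAt <- lapply(colsAt, function(cc) match(kn, cc))
  restRowAt <- vector("list", m + 1L)
  restColAt <- vector("list", m + 1L)
  for (j in 0:m) {
    rest <- if (j < m) seq.int(j + 1L, m) else integer()
    restRowAt[[j + 1L]] <- match(heads[rest], rowsAt[[j + 1L]])
    restColAt[[j + 1L]] <- match(tails[rest], colsAt[[j + 1L]])
  }

  # determinedness of the upper separator for a state at step j:
  # now-reached = source row restricted to kn; the outcome is open iff
  # paths through undecided edges could still reach a further kn node.
  # Fixpoint propagation is done with whole-matrix reductions.
  checkState <- function(R, j, cols) {
    knPos <- knPosAt[[j + 1L]]
    src <- R[1L, ]
    nowKn <- src[knPos]
    if (all(nowKn)) return(list(done = TRUE, T = cols[knPos]))
    openKn <- knPos[!nowKn]
    rp <- restRowAt[[j + 1L]]
    cp <- restColAt[[j + 1L]]
    if (length(rp)) {
      Ru <- R[rp, , drop = FALSE]
      X <- src
      repeat {
        act <- X[cp]
        if (!any(act)) break
        cand <- colSums(Ru[act, , drop = FALSE]) > 0
        add <- cand & !X
        if (!any(add)) break
        X <- X | add
        if (any(X[openKn])) return(list(done = FALSE, T = integer()))
      }
    }
    list(done = TRUE, T = cols[knPos[nowKn]])
  }

  note <- function(nStates, j) {
    if (!is.null(traceEnv)) {
      nz <- length(ls(zAcc))
      zsum <- sum(unlist(mget(ls(zAcc), envir = zAcc)))
      ssum <- sum(vapply(states, function(s) s$coef, numeric(1)))
      traceEnv$rows[[length(traceEnv$rows) + 1L]] <- data.frame(
        stage = stage@stageIndex, step = j, n_terms = nStates + nz,
        n_collapsed = nz, coef_sum = zsum + ssum)
    }
  }

  # initial states from the carried z_S terms
  rows <- rowsAt[[1L]]
  cols <- colsAt[[1L]]
  states <- list()
  sigIdx <- new.env(parent = emptyenv())
  addState <- function(R, w, j, rows, cols) {
    chk <- checkState(R, j, cols)
    if (chk$done) {
      bump(.keyZ(nodes[chk$T]), w)
      return(invisible())
    }
    sg <- sigOf(R)
    pos <- sigIdx[[sg]]
    if (is.null(pos)) {
      states[[length(states) + 1L]] <<- list(R = R, coef = w)
      sigIdx[[sg]] <- length(states)
    } else {
      states[[pos]]$coef <<- states[[pos]]$coef + w
    }
    invisible()
  }
  for (i in seq_along(keys)) {
    S <- .parseKey(keys[i])$label
    w <- unname(prev@coef[i])
    if (!length(S)) { bump(.keyZ(character()), w); next }
    sids <- unname(id[S])
    R <- matrix(FALSE, length(rows), length(cols))
    R[1L, ] <- cols %in% sids
    hit <- match(rows[-1L], cols)
    ok <- which(!is.na(hit))
    R[cbind(1L + ok, hit[ok])] <- TRUE   # empty path: head node reaches itself
    addState(R, w, 0L, rows, cols)
  }
  note(length(states), 0L)

  for (j in seq_len(m)) {
    u <- tails[j]; v <- heads[j]; p <- e$prob[j]
    oldRows <- rows; oldCols <- cols
    rows <- rowsAt[[j + 1L]]
    cols <- colsAt[[j + 1L]]
    rKeep <- match(rows, oldRows)
    cKeep <- match(cols, oldCols)
    uPos <- match(u, oldCols)
    vPos <- match(v, oldRows)
    oldStates <- states
    states <- list()
    sigIdx <- new.env(parent = emptyenv())
    for (st in oldStates) {
      R <- st$R
      if (p < 1) addState(R[rKeep, cKeep, drop = FALSE], st$coef * (1 - p),
                          j, rows, cols)
      if (p > 0) {
        Rp <- R | outer(R[, uPos], R[vPos, ], "&")
        addState(Rp[rKeep, cKeep, drop = FALSE], st$coef * p, j, rows, cols)
      }
    }
    note(length(states), j)
  }
  if (length(states))
    stop("internal error: undetermined states remain after the final stage edge")
  outKeys <- ls(zAcc)
  coef <- vapply(outKeys, function(k) zAcc[[k]], numeric(1))
  names(coef) <- outKeys
  new("StagePolynomial", coef = coef[coef != 0],
      theta = sort(as.integer(e$index)), stageIndex = stage@stageIndex)
}

# Live-term cap of the verbatim per-term fold: beyond it the stage is
# redone in merged-state form, which carries far fewer states on wide
# stages. Narrow stages never get near the cap, so the textbook per-term
# traces are preserved wherever they are the natural representation.
.termOverflowCap <- 128L
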