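# Independent brute-force oracles used by the property tests. These stay
# deliberately naive (enumeration, pairwise checks) and never call the
# package's own fast paths.

# All maximal strictly-alternating two-state substrings of a CN sequence
# (O(n^3): every substring is tested), reduced to a disjoint set by
# longest-first selection (ties toward the leftmost run). Returns a data
# frame of (first, last) sorted by first index.
oracle_alternating_runs <- function(cn) {
  n <- length(cn)
  is_alt <- function(i, j) {
    x <- cn[i:j]
    if (length(x) < 2L) return(FALSE)
    if (any(diff(x) == 0)) return(FALSE)
    if (length(unique(x)) != 2L) return(FALSE)
    if (length(x) > 2L && any(x[-(1:2)] != x[seq_len(length(x) - 2L)])) {
      return(FALSE)
    }
    TRUE
  }
  cand <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq(i + 1L, n)) {
      if (is_alt(i, j)) cand[[length(cand) + 1L]] <- c(i, j)
    }
  }
  if (!length(cand)) {
    return(data.frame(first = integer(0), last = integer(0)))
  }
  m <- do.call(rbind, cand)
  maximal <- vapply(seq_len(nrow(m)), function(k) {
    !any(m[, 1] <= m[k, 1] & m[, 2] >= m[k, 2] &
           (m[, 2] - m[, 1]) > (m[k, 2] - m[k, 1]))
  }, logical(1))
  m <- m[maximal, , drop = FALSE]
  m <- m[order(-(m[, 2] - m[, 1]), m[, 1]), , drop = FALSE]
  sel <- NULL
  for (k in seq_len(nrow(m))) {
    clash <- !is.null(sel) &&
      any(m[k, 1] <= sel[, 2] & m[k, 2] >= sel[, 1])
    if (!clash) sel <- rbind(sel, m[k, ])
  }
  sel <- sel[order(sel[, 1]), , drop = FALSE]
  data.frame(first = sel[, 1], last = sel[, 2])
}

# Largest interleave-graph component via pairwise predicate + igraph
# connected components (falls back to a hand-rolled BFS when igraph is
# unavailable).
oracle_interleaved <- function(pos1, pos2) {
  n <- length(pos1)
  if (n < 2L) return(0L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          pos1[i] < pos1[j] && pos1[j] < pos2[i] && pos2[i] < pos2[j]) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  if (!any(adj)) return(0L)
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    keep <- comp$membership %in% which(comp$csize >= 2L)
    return(max(comp$csize[comp$csize >= 2L]))
  }
  best <- 0L
  seen <- rep(FALSE, n)
  for (s in seq_len(n)) {
    if (seen[s] || !any(adj[s, ])) next
    queue <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      size <- size + 1L
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    best <- max(best, size)
  }
  best
}

# Truth-table oracle for the five combined criteria, written directly from
# the published rule list, independent of evaluate_criteria().
oracle_criteria <- function(intra, inter, total, osc, p_joins, p_enrich,
                            p_exp, alpha = 0.05) {
  joins <- !is.na(p_joins) && p_joins >= alpha
  expo <- !is.na(p_exp) && p_exp >= alpha
  enrich <- !is.na(p_enrich) && p_enrich <= alpha
  passed <- character(0)
  if (intra >= 6 && osc >= 7 && joins && (enrich || expo)) {
    passed <- c(passed, "i")
  }
  if (intra >= 3 && inter >= 4 && osc >= 7 && joins) passed <- c(passed, "ii")
  if (intra >= 40 && joins) passed <- c(passed, "iii")
  if (total >= 100 && osc >= 5) passed <- c(passed, "iv")
  if (intra >= 6 && osc >= 4 && osc <= 6 && joins && (enrich || expo)) {
    passed <- c(passed, "v")
  }
  verdict <- if (length(intersect(passed, c("i", "ii", "iii", "iv")))) {
    "positive"
  } else if (identical(passed, "v")) {
    "low_density"
  } else {
    "negative"
  }
  list(passed = passed, verdict = verdict)
}

# Exact multinomial goodness-of-fit p-value by enumerating all 4^n
# class assignments (feasible for tiny n only).
oracle_multinom_p <- function(counts) {
  n <- sum(counts)
  p_obs <- stats::dmultinom(counts, prob = rep(0.25, 4))
  assign_grid <- expand.grid(rep(list(1:4), n))
  tot <- 0
  for (k in seq_len(nrow(assign_grid))) {
    cnt <- tabulate(as.integer(assign_grid[k, ]), 4)
    if (stats::dmultinom(cnt, prob = rep(0.25, 4)) <= p_obs + 1e-9) {
      tot <- tot + 0.25^n
    }
  }
  tot
}

# Upper binomial tail by direct summation.
oracle_binom_tail <- function(k, size, prob) {
  sum(stats::dbinom(k:size, size, prob))
}
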