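# Independent oracles used to validate the implementation. These are
# deliberately naive (enumeration, brute force) and share no code with the
# package internals.

# --- exhaustive DAG enumeration ---------------------------------------------

# All DAGs on p nodes as edge matrices: every unordered pair is absent,
# forward, or backward; cyclic assignments are discarded by DFS.
enumerate_dags <- function(p) {
  pairs <- t(combn(p, 2))
  np <- nrow(pairs)
  states <- as.matrix(expand.grid(rep(list(0:2), np)))
  has_cycle <- function(e) {
    adj <- lapply(seq_len(p), function(v) e[e[, 1] == v, 2])
    color <- integer(p) # 0 white, 1 grey, 2 black
    cyc <- FALSE
    visit <- function(v) {
      if (cyc) return()
      color[v] <<- 1L
      for (w in adj[[v]]) {
        if (color[w] == 1L) { cyc <<- TRUE; return() }
        if (color[w] == 0L) visit(w)
      }
      color[v] <<- 2L
    }
    for (v in seq_len(p)) if (color[v] == 0L) visit(v)
    cyc
  }
  out <- list()
  for (r in seq_len(nrow(states))) {
    e <- matrix(integer(0), 0, 2)
    for (k in seq_len(np)) {
      if (states[r, k] == 1) e <- rbind(e, pairs[k, , drop = FALSE])
      if (states[r, k] == 2) e <- rbind(e, pairs[k, 2:1, drop = FALSE])
    }
    if (!has_cycle(e)) out[[length(out) + 1]] <- e
  }
  out
}

# Total BIC of a DAG: sum of local scores with the DAG's own parent sets.
oracle_dag_score <- function(cache, edges, p, penalty = 1) {
  sum(vapply(seq_len(p), function(v) {
    pa <- if (nrow(edges)) edges[edges[, 2] == v, 1] else integer(0)
    local_bic(cache, v, pa, penalty)
  }, numeric(1)))
}

# Best-BIC pattern by exhaustive enumeration over all DAGs.
oracle_best_pattern <- function(cache, dags, p, penalty = 1) {
  scores <- vapply(dags, oracle_dag_score, numeric(1),
                   cache = cache, p = p, penalty = penalty)
  dag_pattern(dags[[which.max(scores)]], p)
}

# --- brute-force betweenness -------------------------------------------------

# Directed betweenness by explicit enumeration of all simple paths.
oracle_betweenness <- function(edges, p) {
  succ <- lapply(seq_len(p), function(v) edges[edges[, 1] == v, 2])
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1]] <<- path; return() }
      for (w in succ[[v]]) if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    out
  }
  b <- numeric(p)
  for (s in seq_len(p)) {
    for (t in seq_len(p)) {
      if (s == t) next
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (v in setdiff(seq_len(p), c(s, t))) {
        through <- sum(vapply(shortest, function(pp) v %in% pp, logical(1)))
        b[v] <- b[v] + through / sigma
      }
    }
  }
  b
}

# --- small utilities ---------------------------------------------------------

adjacency_keys <- function(pairs) {
  if (!nrow(pairs)) return(character(0))
  paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
}

adjacency_metrics <- function(true_edges, est_pairs) {
  tkey <- unique(adjacency_keys(true_edges))
  ekey <- adjacency_keys(est_pairs)
  tp <- sum(ekey %in% tkey)
  c(precision = if (length(ekey)) tp / length(ekey) else 1,
    recall = if (length(tkey)) tp / length(tkey) else 1)
}

withr_like_tempdir <- function() {
  d <- tempfile("gango-test-")
  dir.create(d)
  d
}

# Build a gango_dag from an explicit edge matrix (weights drawn from the
# generator's default range), for simulating from enumerated structures.
dag_from_edges <- function(edges, p, seed) {
  set.seed(seed)
  remaining <- seq_len(p)
  ord <- integer(0)
  e <- edges
  while (length(remaining)) {
    roots <- remaining[!remaining %in% e[, 2]]
    v <- roots[1]
    ord <- c(ord, v)
    remaining <- setdiff(remaining, v)
    e <- e[e[, 1] != v, , drop = FALSE]
  }
  w <- runif(nrow(edges), 0.3, 0.8) * sample(c(-1, 1), nrow(edges), TRUE)
  structure(list(p = as.integer(p), edges = matrix(as.integer(edges), ncol = 2),
                 weights = w, order = ord, nodes = sprintf("V%d", 1:p)),
            class = "gango_dag")
}

# A cohort of random digraph "subjects" with uniform wiring (group-test null).
null_cohort <- function(n_sub, p, m, seed) {
  lapply(seq_len(n_sub), function(s) {
    random_directed_graph(p, m, seed = sub_seed(seed, s))
  })
}
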