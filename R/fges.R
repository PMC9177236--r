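# Score-based greedy equivalence search over patterns (CPDAGs).
#
# The search state is a completed partially directed acyclic graph stored as
# an integer mark matrix `amat`: amat[i, j] == 1 and amat[j, i] == 0 encodes
# the directed edge i -> j; amat[i, j] == amat[j, i] == 1 encodes the
# undirected edge i -- j. The forward phase greedily applies the
# best-scoring valid Insert(X, Y, T) operator while some operator improves
# the BIC; the backward phase then applies the best-scoring valid
# Delete(X, Y, H) operator while some operator improves the BIC. After every
# applied operator the graph is re-completed to a pattern: a consistent DAG
# extension is found, its v-structures are oriented, and the orientation is
# closed under the Meek rules.

new_pattern <- function(p, amat = NULL, nodes = NULL) {
  if (is.null(amat)) amat <- matrix(0L, p, p)
  structure(list(p = as.integer(p), amat = amat,
                 nodes = node_names(p, nodes)),
            class = "gango_pattern")
}

#' @export
print.gango_pattern <- function(x, ...) {
  nd <- sum(x$amat == 1L & t(x$amat) == 0L)
  nu <- sum(x$amat == 1L & t(x$amat) == 1L) / 2
  cat(sprintf("Pattern (CPDAG) on %d nodes: %d directed, %d undirected edge(s)\n",
              x$p, nd, nu))
  invisible(x)
}

# ---- mark-matrix primitives -------------------------------------------------

adjacent_nodes <- function(amat, v) which(amat[v, ] == 1L | amat[, v] == 1L)
und_neighbors  <- function(amat, v) which(amat[v, ] == 1L & amat[, v] == 1L)
pattern_parents <- function(amat, v) which(amat[, v] == 1L & amat[v, ] == 0L)

is_clique <- function(amat, nodes) {
  if (length(nodes) < 2) return(TRUE)
  for (i in seq_along(nodes)[-1]) {
    for (j in seq_len(i - 1)) {
      a <- nodes[i]; b <- nodes[j]
      if (amat[a, b] == 0L && amat[b, a] == 0L) return(FALSE)
    }
  }
  TRUE
}

# TRUE if a semi-directed path (following i -> j or i -- j marks) from `from`
# to `to` exists that avoids every node in `blocked`.
semi_directed_reachable <- function(amat, from, to, blocked) {
  p <- nrow(amat)
  seen <- rep(FALSE, p)
  seen[blocked] <- TRUE
  if (seen[from]) return(FALSE)
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      succ <- which(amat[u, ] == 1L)
      succ <- succ[!seen[succ]]
      if (to %in% succ) return(TRUE)
      seen[succ] <- TRUE
      nxt <- c(nxt, succ)
    }
    frontier <- nxt
  }
  FALSE
}

subsets_of <- function(x) {
  # deterministic order: increasing size, then lexicographic
  x <- as.integer(x)
  nx <- length(x)
  if (nx == 0) return(list(integer(0)))
  if (nx == 1) return(list(integer(0), x)) # combn(scalar, .) would expand to 1:x
  out <- list(integer(0))
  for (k in 1:nx) out <- c(out, combn(x, k, simplify = FALSE))
  out
}

# ---- scoring ----------------------------------------------------------------

#' Build a BIC score cache from a data matrix
#'
#' Columns are z-scored (resting-state runs are z-scored before analysis and
#' the BIC is scale-sensitive), and the maximum-likelihood covariance and
#' sample count are stored as sufficient statistics. Local scores are
#' memoized.
#'
#' @param ts samples x parcels numeric matrix.
#' @return An object of class `gango_score_cache`.
#' @export
score_cache <- function(ts) {
  x <- standardize_columns(ts, what = "column")
  n <- nrow(x)
  if (n <= 3) stopf("need more than 3 samples, got %d", n)
  S <- crossprod(x) / (n - 1) # unit diagonal for z-scored columns
  structure(list(S = S, n = n, p = ncol(x),
                 nodes = node_names(ncol(x), colnames(ts)),
                 memo = new.env(parent = emptyenv())),
            class = "gango_score_cache")
}

#' Local BIC score of a node given a parent set
#'
#' Returns `-n * log(residual variance of v regressed on parents) -
#' penalty * |parents| * log(n)`; additive constants that do not depend on
#' the parent set are dropped, so higher is better. `penalty` is the
#' penalty-discount multiplier on the complexity term; 1 is the classic BIC.
#'
#' @param cache a `gango_score_cache`.
#' @param v node index.
#' @param parents integer vector of parent indices (may be empty).
#' @param penalty penalty discount (default 1).
#' @return Scalar score (higher is better).
#' @export
local_bic <- function(cache, v, parents, penalty = 1) {
  parents <- sort(as.integer(parents))
  if (v %in% parents) stopf("node %d cannot be its own parent", v)
  key <- paste0(v, "|", paste(parents, collapse = ","), "|", penalty)
  memo <- cache$memo
  if (!is.null(memo[[key]])) return(memo[[key]])
  S <- cache$S; n <- cache$n
  sigma2 <- if (length(parents) == 0) {
    S[v, v]
  } else {
    R <- tryCatch(chol(S[parents, parents, drop = FALSE]),
                  error = function(e) stopf(
                    "collinear parent set {%s} for node %d: %s",
                    paste(parents, collapse = ","), v, conditionMessage(e)))
    w <- backsolve(R, forwardsolve(t(R), S[parents, v]))
    S[v, v] - sum(S[parents, v] * w)
  }
  sigma2 <- max(sigma2, .Machine$double.eps)
  val <- -n * log(sigma2) - penalty * length(parents) * log(n)
  memo[[key]] <- val
  val
}

# Total score of a pattern: score of any consistent DAG extension (the BIC
# is score-equivalent, so the value is class-invariant).
#' Total BIC score of a pattern
#'
#' Sums local scores over a consistent DAG extension of the pattern; by
#' score equivalence of the BIC the value does not depend on which member
#' of the equivalence class is extended.
#'
#' @inheritParams local_bic
#' @param pattern a `gango_pattern`.
#' @return Scalar total score.
#' @export
pattern_score <- function(pattern, cache, penalty = 1) {
  dag <- pdag_to_dag(pattern$amat)
  sum(vapply(seq_len(pattern$p), function(v) {
    local_bic(cache, v, which(dag[, v] == 1L), penalty)
  }, numeric(1)))
}

# ---- pattern completion -----------------------------------------------------

# Consistent DAG extension of a PDAG (sink-elimination): repeatedly find a
# node with no outgoing directed edges whose undirected neighbors are
# adjacent to all of its other adjacencies, orient its undirected edges
# inward, and remove it.
pdag_to_dag <- function(amat) {
  p <- nrow(amat)
  work <- amat
  dag <- matrix(0L, p, p)
  dag[amat == 1L & t(amat) == 0L] <- 1L
  remaining <- rep(TRUE, p)
  while (any(remaining)) {
    found <- FALSE
    for (v in which(remaining)) {
      out_dir <- which(work[v, ] == 1L & work[, v] == 0L)
      if (length(out_dir)) next
      nb <- which(work[v, ] == 1L & work[, v] == 1L)
      adj_v <- which(work[v, ] == 1L | work[, v] == 1L)
      ok <- all(vapply(nb, function(w) {
        others <- setdiff(adj_v, w)
        all(work[w, others] == 1L | work[others, w] == 1L)
      }, logical(1)))
      if (!ok) next
      dag[nb, v] <- 1L
      work[v, ] <- 0L; work[, v] <- 0L
      remaining[v] <- FALSE
      found <- TRUE
      break
    }
    if (!found) stopf("PDAG admits no consistent DAG extension")
  }
  dag
}

# Meek rules R1-R3, iterated to fixpoint. Orientations originate from
# v-structures only, for which these rules are complete.
meek_closure <- function(amat) {
  p <- nrow(amat)
  repeat {
    changed <- FALSE
    und <- which(amat == 1L & t(amat) == 1L, arr.ind = TRUE)
    und <- und[und[, 1] < und[, 2], , drop = FALSE]
    for (r in seq_len(nrow(und))) {
      for (swap in c(FALSE, TRUE)) {
        a <- if (swap) und[r, 2] else und[r, 1]
        b <- if (swap) und[r, 1] else und[r, 2]
        if (!(amat[a, b] == 1L && amat[b, a] == 1L)) next
        # R1: c -> a, a -- b, c and b non-adjacent  =>  a -> b
        cs <- pattern_parents(amat, a)
        if (any(amat[cs, b] == 0L & amat[b, cs] == 0L)) {
          amat[a, b] <- 1L; amat[b, a] <- 0L; changed <- TRUE; next
        }
        # R2: a -> c -> b with a -- b  =>  a -> b
        cs <- which(amat[a, ] == 1L & amat[, a] == 0L &
                    amat[, b] == 1L & amat[b, ] == 0L)
        if (length(cs)) {
          amat[a, b] <- 1L; amat[b, a] <- 0L; changed <- TRUE; next
        }
        # R3: a -- c -> b, a -- d -> b, c and d non-adjacent  =>  a -> b
        cand <- which(amat[a, ] == 1L & amat[, a] == 1L &
                      amat[, b] == 1L & amat[b, ] == 0L)
        if (length(cand) >= 2) {
          pr <- combn(cand, 2)
          nonadj <- amat[cbind(pr[1, ], pr[2, ])] == 0L &
                    amat[cbind(pr[2, ], pr[1, ])] == 0L
          if (any(nonadj)) {
            amat[a, b] <- 1L; amat[b, a] <- 0L; changed <- TRUE; next
          }
        }
      }
    }
    if (!changed) break
  }
  amat
}

# DAG -> CPDAG: keep the skeleton, orient v-structures, close under Meek.
dag_to_cpdag_amat <- function(dag) {
  p <- nrow(dag)
  amat <- matrix(0L, p, p)
  amat[dag == 1L] <- 1L
  amat[t(dag) == 1L] <- 1L # undirected skeleton
  for (z in seq_len(p)) {
    pa <- which(dag[, z] == 1L)
    if (length(pa) < 2) next
    pr <- combn(pa, 2)
    for (k in seq_len(ncol(pr))) {
      x <- pr[1, k]; y <- pr[2, k]
      if (dag[x, y] == 0L && dag[y, x] == 0L) {
        amat[x, z] <- 1L; amat[z, x] <- 0L
        amat[y, z] <- 1L; amat[z, y] <- 0L
      }
    }
  }
  meek_closure(amat)
}

recomplete <- function(amat) dag_to_cpdag_amat(pdag_to_dag(amat))

#' Pattern (CPDAG) of a DAG
#'
#' Returns the completed pattern representing the Markov equivalence class
#' of a DAG: skeleton plus compelled orientations (v-structures closed under
#' the Meek rules).
#'
#' @param edges two-column integer matrix of directed edges (from, to), or a
#'   `gango_dag`.
#' @param p node count (ignored when `edges` is a `gango_dag`).
#' @return A `gango_pattern`.
#' @export
dag_pattern <- function(edges, p = NULL) {
  if (inherits(edges, "gango_dag")) {
    p <- edges$p
    edges <- edges$edges
  }
  dag <- matrix(0L, p, p)
  if (nrow(edges)) dag[edges] <- 1L
  new_pattern(p, dag_to_cpdag_amat(dag))
}

# ---- operator search --------------------------------------------------------

best_insert <- function(amat, cache, penalty) {
  p <- nrow(amat)
  best <- NULL
  for (x in seq_len(p)) {
    for (y in seq_len(p)) {
      if (x == y || amat[x, y] == 1L || amat[y, x] == 1L) next
      nb_y <- und_neighbors(amat, y)
      adj_x <- amat[x, ] == 1L | amat[, x] == 1L
      na_yx <- nb_y[adj_x[nb_y]]
      t0 <- nb_y[!adj_x[nb_y]]
      pa_y <- pattern_parents(amat, y)
      for (tset in subsets_of(t0)) {
        cset <- c(na_yx, tset)
        if (!is_clique(amat, cset)) next
        if (semi_directed_reachable(amat, y, x, cset)) next
        old_pa <- sort(unique(c(cset, pa_y)))
        delta <- local_bic(cache, y, c(old_pa, x), penalty) -
                 local_bic(cache, y, old_pa, penalty)
        if (is.null(best) || delta > best$delta) {
          best <- list(x = x, y = y, tset = tset, delta = delta)
        }
      }
    }
  }
  best
}

apply_insert <- function(amat, op) {
  amat[op$x, op$y] <- 1L # x -> y
  for (t in op$tset) {   # t -- y becomes t -> y
    amat[t, op$y] <- 1L
    amat[op$y, t] <- 0L
  }
  recomplete(amat)
}

best_delete <- function(amat, cache, penalty) {
  p <- nrow(amat)
  best <- NULL
  for (x in seq_len(p)) {
    for (y in seq_len(p)) {
      if (x == y || amat[x, y] != 1L) next # needs x -> y or x -- y
      nb_y <- und_neighbors(amat, y)
      adj_x <- amat[x, ] == 1L | amat[, x] == 1L
      na_yx <- nb_y[adj_x[nb_y]]
      pa_y <- pattern_parents(amat, y)
      for (hset in subsets_of(na_yx)) {
        keep <- setdiff(na_yx, hset)
        if (!is_clique(amat, keep)) next
        with_x <- sort(unique(c(keep, pa_y, x)))
        without_x <- setdiff(with_x, x)
        delta <- local_bic(cache, y, without_x, penalty) -
                 local_bic(cache, y, with_x, penalty)
        if (is.null(best) || delta > best$delta) {
          best <- list(x = x, y = y, hset = hset, delta = delta)
        }
      }
    }
  }
  best
}

apply_delete <- function(amat, op) {
  x <- op$x; y <- op$y
  amat[x, y] <- 0L; amat[y, x] <- 0L
  for (h in op$hset) {
    amat[y, h] <- 1L; amat[h, y] <- 0L # y -- h becomes y -> h
    if (amat[x, h] == 1L && amat[h, x] == 1L) { # x -- h becomes x -> h
      amat[h, x] <- 0L
    }
  }
  recomplete(amat)
}

#' Greedy equivalence search for the causal adjacency structure
#'
#' Starting from the empty graph, a forward phase repeatedly applies the
#' best-scoring valid Insert operator while the best score change is
#' positive (edges are added until the BIC stops improving), then a
#' backward phase repeatedly applies the best-scoring valid Delete operator
#' while the best score change is positive (edges are removed until the BIC
#' stops improving). Operator validity follows the standard clique and
#' semi-directed-path conditions for search over equivalence classes, and
#' the graph is re-completed to a pattern after every step. Ties between
#' equal-scoring operators are broken lexicographically by (source, target,
#' subset), making the search deterministic.
#'
#' @param ts samples x parcels numeric matrix (columns are z-scored
#'   internally), or a `gango_score_cache`.
#' @param penalty BIC penalty discount; 1 (default) is the classic BIC,
#'   larger values give sparser graphs.
#' @return A `gango_pattern` with attribute `"score_trace"`, the vector of
#'   applied score improvements (forward then backward, all positive).
#' @export
#' @examples
#' d <- generate_dag(5, density = 0.3, seed = 2)
#' x <- simulate_lingam(d, n = 500, seed = 2)
#' fges(x)
fges <- function(ts, penalty = 1) {
  cache <- if (inherits(ts, "gango_score_cache")) ts else score_cache(ts)
  p <- cache$p
  amat <- matrix(0L, p, p)
  trace <- numeric(0)
  max_steps <- p * (p - 1) # safety bound: cannot add more edges than exist
  for (step in seq_len(max_steps)) {
    op <- best_insert(amat, cache, penalty)
    if (is.null(op) || op$delta <= 0) break
    amat <- apply_insert(amat, op)
    trace <- c(trace, op$delta)
  }
  for (step in seq_len(max_steps)) {
    op <- best_delete(amat, cache, penalty)
    if (is.null(op) || op$delta <= 0) break
    amat <- apply_delete(amat, op)
    trace <- c(trace, op$delta)
  }
  out <- new_pattern(p, amat, cache$nodes)
  attr(out, "score_trace") <- trace
  out
}

#' Symmetrize a pattern into an undirected adjacency set
#'
#' Every directed or undirected edge of the pattern becomes one unordered
#' adjacency; orientation information is deliberately discarded because the
#' greedy search estimates adjacencies far more accurately than
#' orientations, which are re-estimated from non-Gaussianity downstream.
#'
#' @param g a `gango_pattern`.
#' @return Two-column integer matrix of unordered pairs (first column <
#'   second), class `gango_adjacency`, with attributes `p` and `nodes`.
#' @export
symmetrize <- function(g) {
  stopifnot(inherits(g, "gango_pattern"))
  sym <- g$amat == 1L | t(g$amat) == 1L
  idx <- which(sym & upper.tri(sym), arr.ind = TRUE)
  out <- matrix(as.integer(idx), ncol = 2,
                dimnames = list(NULL, c("i", "j")))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  structure(out, p = g$p, nodes = g$nodes, class = "gango_adjacency")
}
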