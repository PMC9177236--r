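# Directed-graph analytics for connectomes: centralities, participation
# coefficients, global efficiency, random-digraph surrogate nulls with hub
# classification, and comparison Pearson-correlation graphs. Shortest-path
# machinery is delegated to igraph; the statistics layered on top follow
# binary (unweighted) graph semantics throughout.

as_igraph <- function(g) {
  stopifnot(inherits(g, "gango_connectome"))
  ig <- igraph::make_empty_graph(n = g$p, directed = TRUE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

#' In-, out- and total degree of every node
#'
#' @param g a `gango_connectome`.
#' @return Data frame with columns `node`, `k_in`, `k_out`, `k_total`;
#'   attribute `"m"` holds the edge count.
#' @export
degree_centrality <- function(g) {
  stopifnot(inherits(g, "gango_connectome"))
  k_in <- tabulate(g$edges[, 2], nbins = g$p)
  k_out <- tabulate(g$edges[, 1], nbins = g$p)
  out <- data.frame(node = g$nodes, k_in = k_in, k_out = k_out,
                    k_total = k_in + k_out)
  attr(out, "m") <- nrow(g$edges)
  out
}

#' Directed betweenness centrality
#'
#' Unnormalized shortest-path betweenness on the directed, unweighted
#' graph: for every ordered source-target pair (endpoints excluded) the
#' fraction of shortest paths through the node is accumulated. Raw counts
#' are kept (no normalization) since comparisons are within a fixed node
#' count.
#'
#' @param g a `gango_connectome`.
#' @return Numeric vector of length `p`.
#' @export
betweenness_centrality <- function(g) {
  unname(igraph::betweenness(as_igraph(g), directed = TRUE, normalized = FALSE))
}

#' Full nodal centrality table
#'
#' @param g a `gango_connectome`.
#' @return Data frame with `node`, `k_in`, `k_out`, `k_total`,
#'   `betweenness`; attribute `"m"` is the edge count.
#' @export
centrality_table <- function(g) {
  out <- degree_centrality(g)
  out$betweenness <- betweenness_centrality(g)
  attr(out, "m") <- nrow(g$edges)
  out
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (kappa_is / K_i)^2`, where `kappa_is` counts node `i`'s
#' connections to module `s` and `K_i` its total connection count, both
#' restricted to incoming, outgoing, or all edges according to `mode`. A
#' node whose connections stay within its own module scores 0; a node
#' spreading equally over all `N_M` modules scores `1 - 1/N_M`. Isolated
#' nodes (`K_i = 0`) are defined to score 0.
#'
#' @param g a `gango_connectome`.
#' @param partition character vector of module labels, length `p`.
#' @param mode which connections to count: `"all"`, `"in"`, or `"out"`.
#' @return Numeric vector of length `p` in `[0, 1)`.
#' @export
participation <- function(g, partition, mode = c("all", "in", "out")) {
  stopifnot(inherits(g, "gango_connectome"))
  mode <- match.arg(mode)
  if (length(partition) != g$p) {
    stopf("partition covers %d nodes but graph has %d",
          length(partition), g$p)
  }
  partition <- as.character(partition)
  mods <- sort(unique(partition))
  e <- g$edges
  use_out <- mode %in% c("all", "out")
  use_in <- mode %in% c("all", "in")
  kappa <- matrix(0, g$p, length(mods), dimnames = list(NULL, mods))
  if (nrow(e)) {
    if (use_out) {
      t1 <- table(factor(e[, 1], levels = seq_len(g$p)),
                  factor(partition[e[, 2]], levels = mods))
      kappa <- kappa + unclass(t1)
    }
    if (use_in) {
      t2 <- table(factor(e[, 2], levels = seq_len(g$p)),
                  factor(partition[e[, 1]], levels = mods))
      kappa <- kappa + unclass(t2)
    }
  }
  k_tot <- rowSums(kappa)
  p_i <- ifelse(k_tot == 0, 0, 1 - rowSums((kappa / pmax(k_tot, 1))^2))
  unname(p_i)
}

efficiency_from_distances <- function(d) {
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

#' Binary global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs; unreachable
#' pairs contribute 0. Directed connectomes respect edge direction;
#' undirected comparison graphs (class `gango_ugraph`) use unordered
#' semantics (which coincide with the ordered mean by symmetry).
#'
#' @param g a `gango_connectome` or `gango_ugraph`.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  if (inherits(g, "gango_ugraph")) {
    ig <- igraph::make_empty_graph(n = attr(g, "p"), directed = FALSE)
    if (nrow(g)) ig <- igraph::add_edges(ig, t(unclass(g)[, 1:2, drop = FALSE]))
    if (attr(g, "p") < 2) stopf("need at least 2 nodes")
    return(efficiency_from_distances(igraph::distances(ig)))
  }
  stopifnot(inherits(g, "gango_connectome"))
  if (g$p < 2) stopf("need at least 2 nodes")
  efficiency_from_distances(igraph::distances(as_igraph(g), mode = "out"))
}

#' Uniform random directed graph with a fixed edge count
#'
#' `m` distinct ordered off-diagonal pairs drawn uniformly without
#' replacement: the null model for hub classification, matched to observed
#' graphs only in node and connection count (no degree-distribution or
#' small-world constraint).
#'
#' @param p node count.
#' @param m edge count, `0 <= m <= p * (p - 1)`.
#' @param seed integer seed.
#' @return A `gango_connectome`.
#' @export
random_directed_graph <- function(p, m, seed = 1L) {
  if (m < 0 || m > p * (p - 1)) {
    stopf("m must be in [0, %d], got %s", p * (p - 1), m)
  }
  with_seed(seed, {
    idx <- sample.int(p * (p - 1), m)
    # enumerate ordered off-diagonal cells column-major, skipping the diagonal
    col <- (idx - 1) %/% (p - 1) + 1
    row <- (idx - 1) %% (p - 1) + 1
    row <- row + (row >= col)
    new_connectome(p, cbind(row, col), two_cycles_ok = TRUE)
  })
}

#' Build a random-digraph surrogate null for centrality metrics
#'
#' Generates `n_graphs` random directed graphs; each graph's edge count is
#' drawn from `Normal(m_mean, m_sd)`, rounded and clipped to the feasible
#' range, so the surrogate family matches the distribution of connection
#' counts in the observed cohort. Nodal centralities are pooled across all
#' surrogate graphs into one reference distribution per metric, and the
#' per-graph skewness of each metric's nodal distribution is recorded for
#' heavy-tail testing.
#'
#' @param p node count.
#' @param m_mean,m_sd mean and SD of the edge-count distribution.
#' @param n_graphs number of surrogate graphs (default 1000).
#' @param metrics centrality metrics to compute.
#' @param seed integer seed.
#' @return An object of class `gango_null`: list with `n_graphs`, `m_drawn`,
#'   `pooled` (per-metric vector of `n_graphs * p` nodal values), `q95`
#'   (per-metric 95th percentile of the pooled values), and `skewness`
#'   (per-metric, per-graph skewness of the nodal distribution).
#' @export
build_surrogate_null <- function(p, m_mean, m_sd, n_graphs = 1000L,
                                 metrics = c("k_in", "k_out", "k_total",
                                             "betweenness"),
                                 seed = 1L) {
  if (n_graphs < 1) stopf("n_graphs must be >= 1")
  metrics <- match.arg(metrics, several.ok = TRUE)
  m_max <- p * (p - 1)
  m_drawn <- with_seed(seed, pmin(pmax(round(rnorm(n_graphs, m_mean, m_sd)),
                                       0), m_max))
  pooled <- lapply(metrics, function(m) matrix(NA_real_, p, n_graphs))
  names(pooled) <- metrics
  skw <- matrix(NA_real_, n_graphs, length(metrics),
                dimnames = list(NULL, metrics))
  for (gidx in seq_len(n_graphs)) {
    g <- random_directed_graph(p, m_drawn[gidx], seed = sub_seed(seed, gidx))
    tab <- if ("betweenness" %in% metrics) centrality_table(g)
           else degree_centrality(g)
    for (m in metrics) {
      vals <- tab[[m]]
      pooled[[m]][, gidx] <- vals
      skw[gidx, m] <- tryCatch(sample_skewness(vals),
                               error = function(e) NA_real_)
    }
  }
  pooled <- lapply(pooled, as.numeric)
  structure(
    list(p = p, n_graphs = n_graphs, m_drawn = m_drawn, pooled = pooled,
         q95 = vapply(pooled, quantile, numeric(1), probs = 0.95,
                      names = FALSE),
         skewness = skw),
    class = "gango_null")
}

#' Classify hubs against a surrogate null
#'
#' A node is a hub on a metric when its observed centrality exceeds the
#' `q`-th percentile of the pooled surrogate nodal distribution.
#'
#' @param observed numeric vector of observed nodal centralities.
#' @param null a `gango_null`.
#' @param metric metric name present in `null`.
#' @param q percentile threshold (default 0.95).
#' @return Logical vector of hub flags.
#' @export
classify_hubs <- function(observed, null, metric, q = 0.95) {
  stopifnot(inherits(null, "gango_null"))
  if (!metric %in% names(null$pooled)) {
    stopf("metric '%s' not present in the surrogate null (has: %s)",
          metric, paste(names(null$pooled), collapse = ", "))
  }
  thr <- quantile(null$pooled[[metric]], probs = q, names = FALSE)
  observed > thr
}

#' Heavy-tail test of centrality distributions
#'
#' Compares the per-graph skewness of a centrality's nodal distribution
#' between observed graphs and the surrogate null with a Wilcoxon rank-sum
#' test. Heavy-tailed (hub-dominated) centrality shows up as larger
#' skewness than equally dense random graphs.
#'
#' @param observed_graphs list of `gango_connectome` objects (>= 2), or a
#'   numeric vector of per-graph skewness values (>= 2).
#' @param null a `gango_null`.
#' @param metric metric name.
#' @return List with `statistic`, `p_value`, `direction` (`"heavier"` or
#'   `"lighter"`), and the two skewness samples.
#' @export
heavy_tail_test <- function(observed_graphs, null, metric) {
  stopifnot(inherits(null, "gango_null"))
  if (!metric %in% colnames(null$skewness)) {
    stopf("metric '%s' not present in the surrogate null", metric)
  }
  obs_skw <- if (is.numeric(observed_graphs)) {
    observed_graphs
  } else {
    vapply(observed_graphs, function(g) {
      tab <- centrality_table(g)
      sample_skewness(tab[[metric]])
    }, numeric(1))
  }
  null_skw <- null$skewness[, metric]
  null_skw <- null_skw[!is.na(null_skw)]
  if (length(obs_skw) < 2 || length(null_skw) < 2) {
    stopf("need at least 2 graphs per side, got %d observed and %d surrogate",
          length(obs_skw), length(null_skw))
  }
  if (var(obs_skw) == 0 && var(null_skw) == 0) {
    stopf("degenerate (constant) skewness on both sides")
  }
  wt <- wilcox.test(obs_skw, null_skw, exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = if (stats::median(obs_skw) >= stats::median(null_skw))
         "heavier" else "lighter",
       observed_skewness = obs_skw, surrogate_skewness = null_skw)
}

#' Thresholded Pearson-correlation comparison graph
#'
#' The conventional functional-connectivity construction: the Pearson
#' correlation matrix is thresholded by retaining the largest positive
#' off-diagonal values - either a fixed proportion of all unordered pairs
#' (`proportional`, default 15% cost) or an exact edge count
#' (`match_count`, for density-matching a causal graph). The result is
#' binary and undirected.
#'
#' @param ts samples x parcels matrix.
#' @param mode `"proportional"` or `"match_count"`.
#' @param value retained fraction of unordered pairs (proportional mode,
#'   default 0.15) or exact edge count (match_count mode).
#' @return A `gango_ugraph`: two-column matrix of unordered pairs with
#'   attributes `p` and `nodes`.
#' @export
correlation_graph <- function(ts, mode = c("proportional", "match_count"),
                              value = 0.15) {
  mode <- match.arg(mode)
  ts <- as.matrix(ts)
  p <- ncol(ts)
  cm <- cor(ts)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  vals <- cm[ut]
  pos <- vals > 0
  want <- if (mode == "proportional") round(value * p * (p - 1) / 2)
          else as.integer(value)
  n_pos <- sum(pos)
  if (n_pos < want) {
    warnf("only %d positive correlations available; requested %d",
          n_pos, want)
    want <- n_pos
  }
  # deterministic selection: by decreasing correlation, ties by (i, j)
  ord <- order(-vals, ut[, 1], ut[, 2])
  ord <- ord[pos[ord]][seq_len(want)]
  pairs <- ut[ord, , drop = FALSE]
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  structure(matrix(as.integer(pairs), ncol = 2,
                   dimnames = list(NULL, c("i", "j"))),
            p = p, nodes = node_names(p, colnames(ts)),
            class = "gango_ugraph")
}
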