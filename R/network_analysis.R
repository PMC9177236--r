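# Module-level (resting-state network) group statistics and virtual-lesion
# vulnerability analysis. All group tests are nonparametric: Wilcoxon
# signed-rank for paired per-subject contrasts (BH-FDR corrected), Friedman
# across modules with Nemenyi all-pairs post-hocs.

partition_modules <- function(partition) sort(unique(as.character(partition)))

#' Inter-module edge-count matrix of one connectome
#'
#' `C[a, b]` counts node-level directed edges from module `a` to module `b`
#' (`a != b`); the diagonal holds within-module counts. The total over all
#' cells equals the edge count of the graph.
#'
#' @param g a `gango_connectome`.
#' @param partition module labels, length `p`.
#' @return Integer matrix with module-label dimnames.
#' @export
rsn_counts <- function(g, partition) {
  stopifnot(inherits(g, "gango_connectome"))
  if (length(partition) != g$p) {
    stopf("partition covers %d nodes but graph has %d", length(partition), g$p)
  }
  partition <- as.character(partition)
  mods <- partition_modules(partition)
  out <- table(factor(partition[g$edges[, 1]], levels = mods),
               factor(partition[g$edges[, 2]], levels = mods))
  mat <- matrix(as.integer(out), length(mods), length(mods),
                dimnames = list(mods, mods))
  mat
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), via
#' [stats::p.adjust()].
#'
#' @param pvalues numeric vector in `[0, 1]` (NAs passed through).
#' @return Adjusted p-values, same length.
#' @export
bh_fdr <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stopf("p-values outside [0, 1] at position(s): %s",
                      paste(which(!ok), collapse = ", "))
  p.adjust(pvalues, method = "BH")
}

signed_rank_p <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0] # classic handling: zero differences discarded
  if (length(d) < 1) return(NA_real_)
  # exact distribution for small tie-free samples, otherwise the normal
  # approximation with continuity correction
  use_exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  tryCatch(wilcox.test(d, mu = 0, exact = use_exact,
                       correct = TRUE)$p.value,
           error = function(e) NA_real_)
}

paired_cohens_d <- function(diffs) {
  s <- sd(diffs)
  if (is.na(s) || s == 0) return(NA_real_)
  mean(diffs) / s
}

#' Inter-module connectivity and direction tests across subjects
#'
#' For every module `a` and every other module `b`, the per-subject shared
#' edge count `C[a,b] + C[b,a]` is tested (Wilcoxon signed-rank) against
#' the equal-spread null `total out-of-module count of a / (N_M - 1)`;
#' p-values are BH-FDR corrected over all ordered pairs, and significant
#' pairs with a paired Cohen's d below `d_mask` are masked. For each pair,
#' the proportion of edges running a -> b is tested against 0.5
#' (signed-rank, BH-FDR) to establish a preferred direction.
#'
#' @param counts_list list of inter-module count matrices
#'   ([rsn_counts()]), one per subject (>= 6).
#' @param alpha significance level for the FDR-adjusted tests.
#' @param d_mask minimum paired Cohen's d (default 0.2, a small effect) for
#'   a significant pair to be reported as connected.
#' @return List with `pairs` (data frame, one row per ordered module pair:
#'   mean shared count, connectivity p and adjusted p, Cohen's d,
#'   `connected`, mean a->b proportion, direction p and adjusted p,
#'   `directed`) and `consensus` (one row per connected unordered pair with
#'   direction and mean preferred-direction proportion).
#' @export
inter_rsn_tests <- function(counts_list, alpha = 0.05, d_mask = 0.2) {
  n_sub <- length(counts_list)
  if (n_sub < 6) stopf("need at least 6 subjects for signed-rank tests, got %d",
                       n_sub)
  mods <- rownames(counts_list[[1]])
  nm <- length(mods)
  rows <- list()
  for (a in seq_len(nm)) {
    for (b in seq_len(nm)) {
      if (a == b) next
      shared <- vapply(counts_list, function(C) C[a, b] + C[b, a], numeric(1))
      total_a <- vapply(counts_list, function(C) {
        sum(C[a, ]) + sum(C[, a]) - 2 * C[a, a]
      }, numeric(1))
      null_val <- total_a / (nm - 1)
      diffs <- shared - null_val
      p_conn <- signed_rank_p(diffs)
      d <- paired_cohens_d(diffs)
      ab <- vapply(counts_list, function(C) C[a, b], numeric(1))
      prop <- ifelse(shared > 0, ab / shared, NA_real_)
      prop_obs <- prop[!is.na(prop)]
      p_dir <- if (length(prop_obs) >= 6) signed_rank_p(prop_obs, mu = 0.5)
               else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        from = mods[a], to = mods[b],
        mean_shared = mean(shared), null_value = mean(null_val),
        p_connect = p_conn, cohen_d = d,
        mean_proportion = mean(prop, na.rm = TRUE), p_direction = p_dir,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_connect_adj <- bh_fdr(res$p_connect)
  res$p_direction_adj <- bh_fdr(res$p_direction)
  res$connected <- !is.na(res$p_connect_adj) & res$p_connect_adj < alpha &
    !is.na(res$cohen_d) & res$cohen_d >= d_mask
  res$directed <- res$connected & !is.na(res$p_direction_adj) &
    res$p_direction_adj < alpha
  # consensus over unordered pairs: connected if either side's test says so
  cons <- list()
  for (a in seq_len(nm - 1)) {
    for (b in seq((a + 1), nm)) {
      r_ab <- res[res$from == mods[a] & res$to == mods[b], ]
      r_ba <- res[res$from == mods[b] & res$to == mods[a], ]
      if (!(r_ab$connected || r_ba$connected)) next
      dir_sig <- r_ab$directed || r_ba$directed
      forward <- !dir_sig || r_ab$mean_proportion >= 0.5
      cons[[length(cons) + 1]] <- data.frame(
        from = if (forward) mods[a] else mods[b],
        to = if (forward) mods[b] else mods[a],
        bidirectional = !dir_sig,
        proportion = if (forward) r_ab$mean_proportion
                     else 1 - r_ab$mean_proportion,
        stringsAsFactors = FALSE)
    }
  }
  consensus <- if (length(cons)) do.call(rbind, cons) else
    data.frame(from = character(0), to = character(0),
               bidirectional = logical(0), proportion = numeric(0))
  list(pairs = res, consensus = consensus)
}

module_means <- function(tables_list, partition, metric) {
  mods <- partition_modules(partition)
  t(vapply(tables_list, function(tab) {
    vapply(mods, function(m) mean(tab[[metric]][partition == m]), numeric(1))
  }, numeric(length(mods))))
}

#' Classify modules as senders, receivers, or balanced
#'
#' For each module, the subject-wise mean nodal indegree and outdegree are
#' compared with a Wilcoxon signed-rank test; p-values are BH-FDR corrected
#' over modules. A module whose outdegree significantly exceeds indegree is
#' a sender; the reverse, a receiver; otherwise balanced. Modules with no
#' edges in any subject (the test is undefined) are reported balanced with
#' `degenerate = TRUE`.
#'
#' @param tables_list list of centrality tables ([centrality_table()]), one
#'   per subject (>= 6).
#' @param partition module labels, length `p`.
#' @param alpha significance level.
#' @return Data frame: module, mean in/out degree, p, adjusted p,
#'   classification, degenerate flag.
#' @export
sender_receiver <- function(tables_list, partition, alpha = 0.05) {
  if (length(tables_list) < 6) {
    stopf("need at least 6 subjects, got %d", length(tables_list))
  }
  partition <- as.character(partition)
  mods <- partition_modules(partition)
  mean_in <- module_means(tables_list, partition, "k_in")
  mean_out <- module_means(tables_list, partition, "k_out")
  pvals <- vapply(seq_along(mods), function(j) {
    signed_rank_p(mean_out[, j] - mean_in[, j])
  }, numeric(1))
  padj <- bh_fdr(pvals)
  cls <- ifelse(is.na(padj) | padj >= alpha, "balanced",
                ifelse(colMeans(mean_out) > colMeans(mean_in),
                       "sender", "receiver"))
  data.frame(module = mods,
             mean_indegree = colMeans(mean_in),
             mean_outdegree = colMeans(mean_out),
             p_value = pvals, p_adj = padj,
             class = cls, degenerate = is.na(pvals),
             stringsAsFactors = FALSE)
}

#' Nemenyi all-pairs post-hoc test on a blocked design
#'
#' Mean-rank form: within-block (subject) ranks are averaged per group and
#' pairwise differences are referred to the Studentized range distribution,
#' `q = |Rbar_a - Rbar_b| / sqrt(k (k + 1) / (12 n))` with `k` groups and
#' `n` blocks.
#'
#' @param mat numeric matrix, blocks (subjects) x groups (modules).
#' @return Symmetric matrix of p-values (diagonal `NA`).
#' @export
nemenyi_test <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (12 * n))
  pmat <- matrix(NA_real_, k, k, dimnames = list(colnames(mat), colnames(mat)))
  for (a in seq_len(k - 1)) {
    for (b in seq((a + 1), k)) {
      q <- abs(rbar[a] - rbar[b]) / se
      pmat[a, b] <- pmat[b, a] <- ptukey(q, nmeans = k, df = Inf,
                                         lower.tail = FALSE)
    }
  }
  pmat
}

#' Compare module-level centrality across modules
#'
#' Per metric, module means are computed per subject and compared across
#' modules with a Friedman test (module is a within-subject factor); when
#' significant, Nemenyi all-pairs post-hocs identify which modules differ.
#'
#' @param tables_list list of centrality tables, one per subject.
#' @param partition module labels, length `p`.
#' @param metrics which centrality columns to analyse.
#' @param alpha significance level for running post-hocs.
#' @return Named list per metric: `friedman` (htest), `mean_ranks`,
#'   `posthoc` (Nemenyi p-value matrix or `NULL`).
#' @export
rsn_centrality_comparison <- function(tables_list, partition,
                                      metrics = c("k_in", "k_out", "k_total",
                                                  "betweenness"),
                                      alpha = 0.05) {
  partition <- as.character(partition)
  if (length(partition_modules(partition)) < 2) stopf("need >= 2 modules")
  out <- list()
  for (metric in metrics) {
    mm <- module_means(tables_list, partition, metric)
    colnames(mm) <- partition_modules(partition)
    if (all(apply(mm, 1, function(r) length(unique(r)) == 1))) {
      stopf("constant ranks for metric '%s': Friedman test undefined", metric)
    }
    fr <- friedman.test(mm)
    ranks <- t(apply(mm, 1, rank))
    out[[metric]] <- list(
      friedman = fr,
      mean_ranks = colMeans(ranks),
      posthoc = if (!is.na(fr$p.value) && fr$p.value < alpha)
        nemenyi_test(mm) else NULL)
  }
  out
}

delete_nodes <- function(g, nodes) {
  keep <- setdiff(seq_len(g$p), nodes)
  remap <- integer(g$p)
  remap[keep] <- seq_along(keep)
  e <- g$edges
  e <- e[!(e[, 1] %in% nodes) & !(e[, 2] %in% nodes), , drop = FALSE]
  new_connectome(length(keep), cbind(remap[e[, 1]], remap[e[, 2]]),
                 g$nodes[keep], two_cycles_ok = isTRUE(g$two_cycles_ok))
}

#' Loss-of-efficiency curve for one deletion schedule
#'
#' Nodes are deleted cumulatively in the given order; after each deletion
#' the percent change in global efficiency relative to the intact graph is
#' recorded. The curve starts at 0% (zero deletions).
#'
#' @param g a `gango_connectome`.
#' @param schedule integer vector of distinct node indices to delete, in
#'   order; at least 2 nodes must remain.
#' @return Numeric vector of length `length(schedule) + 1`.
#' @export
lesion_curve <- function(g, schedule) {
  stopifnot(inherits(g, "gango_connectome"))
  schedule <- as.integer(schedule)
  if (anyDuplicated(schedule)) stopf("schedule contains duplicate nodes")
  if (any(schedule < 1 | schedule > g$p)) stopf("schedule node out of range")
  if (g$p - length(schedule) < 2) {
    stopf("schedule leaves fewer than 2 nodes")
  }
  e0 <- global_efficiency(g)
  if (e0 == 0) stopf("baseline global efficiency is 0: percent change undefined")
  curve <- numeric(length(schedule) + 1)
  for (k in seq_along(schedule)) {
    gk <- delete_nodes(g, schedule[seq_len(k)])
    curve[k + 1] <- 100 * (global_efficiency(gk) - e0) / e0
  }
  curve
}

#' Targeted and random virtual-attack analysis
#'
#' For every module, nodes of that module are deleted in `n_reps` random
#' orders and the loss-of-efficiency curves are averaged; one additional
#' random-attack schedule draws nodes from the whole graph (length equal to
#' the largest module, so curves share a plot range). The mean pointwise
#' slope of each averaged curve (mean first difference, percent per deleted
#' node) summarizes how rapidly the module's loss degrades communication.
#'
#' @param g a `gango_connectome`.
#' @param partition module labels, length `p`.
#' @param n_reps random deletion orders per schedule (default 10).
#' @param seed integer seed.
#' @return An object of class `gango_lesion`: list with `curves` (named
#'   list, one averaged curve per module plus `"random"`), `slopes` (named
#'   numeric), `n_reps`.
#' @export
targeted_attack <- function(g, partition, n_reps = 10L, seed = 1L) {
  stopifnot(inherits(g, "gango_connectome"))
  if (n_reps < 1) stopf("n_reps must be >= 1")
  partition <- as.character(partition)
  if (length(partition) != g$p) stopf("partition does not cover the graph")
  mods <- partition_modules(partition)
  max_size <- max(table(partition))
  schedules <- c(stats::setNames(lapply(mods, function(m) which(partition == m)),
                                 mods),
                 list(random = NA))
  curves <- list()
  slopes <- numeric(0)
  k <- 0
  for (nm in names(schedules)) {
    k <- k + 1
    pool <- schedules[[nm]]
    reps <- vapply(seq_len(n_reps), function(r) {
      sched <- with_seed(sub_seed(seed, (k - 1) * n_reps + r), {
        if (identical(nm, "random")) sample.int(g$p, max_size)
        else pool[sample.int(length(pool))]
      })
      lesion_curve(g, sched)
    }, numeric(if (identical(nm, "random")) max_size + 1
               else length(pool) + 1))
    avg <- rowMeans(reps)
    curves[[nm]] <- avg
    slopes[nm] <- mean(diff(avg))
  }
  structure(list(curves = curves, slopes = slopes, n_reps = n_reps,
                 modules = mods),
            class = "gango_lesion")
}

#' Single-node deletion efficiency deltas
#'
#' For each node, the change in global efficiency when only that node is
#' deleted. Deleting a disconnected node removes zeros from the pairwise
#' average and therefore increases efficiency; deleting a critical hub
#' decreases it.
#'
#' @param g a `gango_connectome` with `p >= 3`.
#' @return Numeric vector of length `p`.
#' @export
single_node_lesions <- function(g) {
  stopifnot(inherits(g, "gango_connectome"))
  if (g$p < 3) stopf("need at least 3 nodes")
  e0 <- global_efficiency(g)
  vapply(seq_len(g$p), function(v) {
    global_efficiency(delete_nodes(g, v)) - e0
  }, numeric(1))
}
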