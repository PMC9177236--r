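complete_digraph <- function(p) {
  e <- expand.grid(from = 1:p, to = 1:p)
  e <- as.matrix(e[e$from != e$to, ])
  connectome(p, e, two_cycles_ok = TRUE)
}

star_graph <- function(leaves = 4) {
  connectome(leaves + 1, rbind(cbind(1, 1 + seq_len(leaves)),
                               cbind(1 + seq_len(leaves), 1)),
             two_cycles_ok = TRUE)
}

test_that("degree centrality satisfies the handshake identity", {
  g4 <- complete_digraph(4)
  tab <- degree_centrality(g4)
  expect_true(all(tab$k_in == 3) && all(tab$k_out == 3))
  empty <- connectome(5)
  expect_true(all(degree_centrality(empty)$k_total == 0))
  for (s in 1:5) {
    g <- random_directed_graph(30, 80, seed = s)
    tab <- degree_centrality(g)
    expect_equal(sum(tab$k_in), 80)
    expect_equal(sum(tab$k_out), 80)
  }
})

test_that("betweenness matches hand enumeration on canonical graphs", {
  path <- connectome(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(betweenness_centrality(path), c(0, 1, 0))
  expect_true(all(betweenness_centrality(complete_digraph(4)) == 0))
  expect_equal(betweenness_centrality(star_graph(4)), c(12, 0, 0, 0, 0))
})

test_that("betweenness agrees with exhaustive path enumeration on digraphs <= 5 nodes", {
  for (s in 1:10) {
    p <- 4 + s %% 2
    g <- random_directed_graph(p, min(p * (p - 1), 3 + s), seed = 90 + s)
    expect_equal(betweenness_centrality(g), oracle_betweenness(g$edges, p),
                 info = sprintf("seed %d", s))
  }
})

test_that("participation follows the module-diversity equation", {
  # all edges inside own module -> 0
  g <- connectome(4, rbind(c(1, 2), c(3, 4)))
  part <- c("A", "A", "B", "B")
  expect_equal(participation(g, part), rep(0, 4))
  # hub with one connection to each of 12 modules -> 1 - 12*(1/12)^2
  edges <- cbind(1, 2:13)
  g12 <- connectome(13, edges)
  part12 <- c("M0", sprintf("M%d", 1:12))
  expect_equal(participation(g12, part12)[1], 11 / 12)
  # isolated node -> 0 by definition
  giso <- connectome(3, rbind(c(1, 2)))
  expect_equal(participation(giso, c("A", "B", "C"))[3], 0)
})

test_that("participation modes split incoming and outgoing edges", {
  g <- connectome(3, rbind(c(1, 2), c(3, 1)))
  part <- c("A", "B", "C")
  expect_equal(participation(g, part, "out")[1], 0) # one outgoing edge
  expect_equal(participation(g, part, "in")[1], 0)
  expect_equal(participation(g, part, "all")[1], 0.5) # spread over 2 modules
})

test_that("participation is invariant under module relabeling", {
  g <- random_directed_graph(24, 60, seed = 61)
  part <- generate_partition(24, 4, seed = 61)
  relabeled <- c(M01 = "Z9", M02 = "Q1", M03 = "B2", M04 = "A7")[part]
  expect_equal(participation(g, part), participation(g, relabeled))
})

test_that("global efficiency matches hand enumeration and its bounds", {
  expect_equal(global_efficiency(complete_digraph(5)), 1)
  expect_equal(global_efficiency(connectome(4)), 0)
  path <- connectome(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(global_efficiency(path), (1 + 1 + 1 / 2) / 6)
})

test_that("efficiency never increases when an edge is removed", {
  g <- random_directed_graph(15, 50, seed = 62)
  e_full <- global_efficiency(g)
  for (r in c(1, 10, 25)) {
    g2 <- connectome(15, g$edges[-r, ], two_cycles_ok = TRUE)
    expect_lte(global_efficiency(g2), e_full + 1e-12)
  }
})

test_that("random digraphs have the exact requested edge count", {
  g <- random_directed_graph(360, 1452, seed = 63)
  expect_equal(nrow(g$edges), 1452)
  expect_true(all(g$edges[, 1] != g$edges[, 2]))
  expect_false(anyDuplicated(paste(g$edges[, 1], g$edges[, 2])) > 0)
  expect_equal(nrow(random_directed_graph(5, 20, seed = 1)$edges), 20)
  expect_equal(nrow(random_directed_graph(10, 0, seed = 1)$edges), 0)
  expect_error(random_directed_graph(5, 21), "m must be")
  expect_identical(random_directed_graph(20, 40, seed = 7)$edges,
                   random_directed_graph(20, 40, seed = 7)$edges)
})

test_that("surrogate nulls honour their edge-count distribution", {
  nul <- build_surrogate_null(40, m_mean = 80, m_sd = 0, n_graphs = 20,
                              metrics = c("k_in", "k_out", "k_total"),
                              seed = 64)
  expect_true(all(nul$m_drawn == 80))
  expect_equal(length(nul$pooled$k_total), 40 * 20)
  # E[total degree] = 2 m / p
  expect_equal(mean(nul$pooled$k_total), 2 * 80 / 40, tolerance = 0.02)
  nul2 <- build_surrogate_null(40, 80, 10, n_graphs = 30, seed = 65)
  expect_equal(nul2$n_graphs, 30)
  expect_gt(sd(nul2$m_drawn), 0)
})

test_that("hub classification flags only the exceedances", {
  nul <- build_surrogate_null(30, 60, 5, n_graphs = 50, seed = 66)
  med <- median(nul$pooled$k_total)
  expect_false(any(classify_hubs(rep(med, 30), nul, "k_total")))
  big <- c(rep(med, 29), max(nul$pooled$k_total) + 1)
  expect_equal(sum(classify_hubs(big, nul, "k_total")), 1)
  expect_error(classify_hubs(rep(1, 30), nul, "closeness"), "not present")
})

test_that("heavy-tail test rejects preferential-attachment graphs", {
  p <- 60; m <- 180
  nul <- build_surrogate_null(p, m, 0, n_graphs = 60, seed = 67)
  # positive control: scale-free-ish graphs via preferential attachment
  pa_graphs <- lapply(1:12, function(s) {
    set.seed(1000 + s)
    ig <- igraph::sample_pa(p, m = 3, directed = TRUE)
    connectome(p, igraph::as_edgelist(ig), two_cycles_ok = TRUE)
  })
  ht <- heavy_tail_test(pa_graphs, nul, "k_in")
  expect_lt(ht$p_value, 0.01)
  expect_equal(ht$direction, "heavier")
  expect_error(heavy_tail_test(pa_graphs[1], nul, "k_in"), "at least 2")
})

test_that("correlation graphs retain the exact positive-threshold counts", {
  d <- generate_dag(30, density = 0.1, seed = 68)
  ts <- simulate_lingam(d, 600, seed = 68)
  cg <- correlation_graph(ts, "proportional", 0.15)
  expect_equal(nrow(cg), round(0.15 * 30 * 29 / 2))
  cg2 <- correlation_graph(ts, "match_count", 20)
  expect_equal(nrow(cg2), 20)
  # duplicated column is a perfect correlation: always retained
  ts2 <- cbind(ts, ts[, 1] + rnorm(600, sd = 1e-8))
  cg3 <- correlation_graph(ts2, "match_count", 5)
  expect_true("1 31" %in% adjacency_keys(cg3))
  # shortfall: only so many positive correlations exist
  set.seed(69)
  neg <- cbind(a = rnorm(50))
  neg <- cbind(neg, b = -neg[, 1] + rnorm(50, sd = 0.01))
  expect_warning(cgs <- correlation_graph(neg, "match_count", 1),
                 "positive correlations")
  expect_equal(nrow(cgs), 0)
})
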