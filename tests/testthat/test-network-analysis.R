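test_that("inter-module counts conserve the edge total", {
  part <- c("A", "A", "B", "B", "C", "C")
  g_within <- connectome(6, rbind(c(1, 2), c(3, 4)))
  C <- rsn_counts(g_within, part)
  expect_equal(sum(C) - sum(diag(C)), 0)
  g_cross <- connectome(6, rbind(c(1, 3)))
  C2 <- rsn_counts(g_cross, part)
  expect_equal(C2["A", "B"], 1L, ignore_attr = TRUE)
  expect_equal(C2["B", "A"], 0L, ignore_attr = TRUE)
  for (s in 1:5) {
    g <- random_directed_graph(30, 70, seed = s)
    pt <- generate_partition(30, 5, seed = s)
    expect_equal(sum(rsn_counts(g, pt)), 70)
  }
})

test_that("bh_fdr reproduces the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
  # hand computation: p_(i) * m / i, cumulative minimum from the top
  p <- c(0.001, 0.1, 0.02, 0.9)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
})

test_that("inter-module tests recover a planted directional pair", {
  # module A sends 90% of its A<->B edges to B
  set.seed(71)
  part <- rep(c("A", "B", "C", "D"), each = 10)
  cohort <- lapply(1:20, function(s) {
    g <- random_directed_graph(40, 120, seed = 2000 + s)
    e <- g$edges
    a_nodes <- 1:10; b_nodes <- 11:20
    # rewire: plant 30 extra A->B edges and 3 B->A
    extra <- rbind(
      cbind(sample(a_nodes, 30, TRUE), sample(b_nodes, 30, TRUE)),
      cbind(sample(b_nodes, 3, TRUE), sample(a_nodes, 3, TRUE)))
    all_e <- unique(rbind(e, extra))
    rsn_counts(connectome(40, all_e, two_cycles_ok = TRUE), part)
  })
  res <- inter_rsn_tests(cohort)
  ab <- res$pairs[res$pairs$from == "A" & res$pairs$to == "B", ]
  expect_true(ab$connected)
  expect_true(ab$directed)
  expect_gt(ab$mean_proportion, 0.75)
  expect_true(nrow(res$consensus) >= 1)
  cons_ab <- res$consensus[res$consensus$from == "A" & res$consensus$to == "B", ]
  expect_equal(nrow(cons_ab), 1)
  expect_false(cons_ab$bidirectional)
  expect_error(inter_rsn_tests(cohort[1:2]), "at least 6")
})

test_that("sender/receiver classification recovers a planted sender", {
  part <- rep(c("A", "B", "C"), each = 8)
  cohort_tabs <- lapply(1:12, function(s) {
    set.seed(3100 + s)
    g <- random_directed_graph(24, 40, seed = 3000 + s)
    # plant: all of module A's nodes send 3 extra cross-module edges
    extra <- cbind(rep(1:8, each = 3), sample(9:24, 24, replace = TRUE))
    e <- unique(rbind(g$edges, extra))
    centrality_table(connectome(24, e, two_cycles_ok = TRUE))
  })
  sr <- sender_receiver(cohort_tabs, part)
  expect_equal(sr$class[sr$module == "A"], "sender")
  expect_error(sender_receiver(cohort_tabs[1:3], part), "at least 6")
  # all-zero module: balanced and degenerate
  tabs0 <- lapply(1:8, function(s) {
    data.frame(node = 1:6, k_in = c(0, 0, 1, 2, 1, 0),
               k_out = c(0, 0, 2, 1, 1, 0), k_total = 0, betweenness = 0)
  })
  sr0 <- sender_receiver(tabs0, c("Z", "Z", "Y", "Y", "Y", "Y"))
  expect_equal(sr0$class[sr0$module == "Z"], "balanced")
  expect_true(sr0$degenerate[sr0$module == "Z"])
})

test_that("Friedman/Nemenyi comparison matches the closed chi-square form", {
  # worked example with known within-subject ranks
  mat <- rbind(c(1, 2, 3), c(1, 2, 3), c(2, 1, 3), c(1, 3, 2))
  n <- 4; k <- 3
  rank_sums <- colSums(t(apply(mat, 1, rank)))
  chi <- 12 / (n * k * (k + 1)) * sum(rank_sums^2) - 3 * n * (k + 1)
  fr <- friedman.test(mat)
  expect_equal(unname(fr$statistic), chi)

  # identical module means -> constant ranks -> error surfaced
  tabs_flat <- lapply(1:6, function(s) {
    data.frame(node = 1:6, k_in = rep(2, 6), k_out = rep(2, 6),
               k_total = rep(4, 6), betweenness = rep(1, 6))
  })
  expect_error(
    rsn_centrality_comparison(tabs_flat, rep(c("A", "B", "C"), 2),
                              metrics = "k_total"),
    "constant ranks")
})

test_that("a module planted with double degree tops the Nemenyi ranking", {
  part <- rep(c("A", "B", "C", "D"), each = 6)
  tabs <- lapply(1:50, function(s) {
    set.seed(4100 + s)
    g <- random_directed_graph(24, 50, seed = 4000 + s)
    extra <- cbind(rep(1:6, 2), sample(7:24, 12, TRUE))
    centrality_table(connectome(24, unique(rbind(g$edges, extra)),
                                two_cycles_ok = TRUE))
  })
  cmp <- rsn_centrality_comparison(tabs, part, metrics = "k_total")
  expect_lt(cmp$k_total$friedman$p.value, 0.001)
  expect_equal(names(which.max(cmp$k_total$mean_ranks)), "A")
  ph <- cmp$k_total$posthoc
  expect_true(all(ph["A", c("B", "C", "D")] < 0.05))
})

test_that("nemenyi p-values follow the studentized-range form", {
  set.seed(73)
  mat <- matrix(rnorm(40), 10, 4)
  pm <- nemenyi_test(mat)
  ranks <- t(apply(mat, 1, rank))
  q12 <- abs(mean(ranks[, 1]) - mean(ranks[, 2])) /
    sqrt(4 * 5 / (12 * 10))
  expect_equal(pm[1, 2], ptukey(q12, 4, Inf, lower.tail = FALSE))
  expect_true(isSymmetric(pm))
})

test_that("lesion curves start at zero and track hand-enumerated cases", {
  star <- connectome(5, rbind(cbind(1, 2:5), cbind(2:5, 1)),
                     two_cycles_ok = TRUE)
  cv <- lesion_curve(star, 1)
  expect_equal(cv, c(0, -100))
  # disconnected node removal improves efficiency
  g <- connectome(4, rbind(c(1, 2), c(2, 1)), two_cycles_ok = TRUE)
  cv2 <- lesion_curve(g, 4)
  expect_gt(cv2[2], 0)
  expect_equal(lesion_curve(g, integer(0)), 0)
  expect_error(lesion_curve(g, c(2, 2)), "duplicate")
  expect_error(lesion_curve(connectome(4), 1), "efficiency is 0")
})

test_that("single-node lesions expose isolated nodes and hubs", {
  star <- connectome(5, rbind(cbind(1, 2:5), cbind(2:5, 1)),
                     two_cycles_ok = TRUE)
  deltas <- single_node_lesions(star)
  expect_equal(deltas[1], -global_efficiency(star))
  # hand enumeration: E(star, 4 leaves) = (8*1 + 12*0.5)/20 = 0.7;
  # dropping one leaf gives (6*1 + 6*0.5)/12 = 0.75, so leaf deltas are +0.05
  expect_equal(deltas[2:5], rep(0.05, 4))
  g <- connectome(4, rbind(c(1, 2), c(2, 1)), two_cycles_ok = TRUE)
  expect_gt(single_node_lesions(g)[4], 0)
  full <- connectome(3, rbind(c(1, 2), c(2, 3), c(1, 3), c(2, 1), c(3, 2), c(3, 1)),
                     two_cycles_ok = TRUE)
  expect_equal(single_node_lesions(full), rep(0, 3))
})

test_that("targeted attack returns one curve per module plus random", {
  g <- random_directed_graph(36, 120, seed = 75)
  part <- generate_partition(36, 6, seed = 75)
  les <- targeted_attack(g, part, n_reps = 3, seed = 76)
  expect_length(les$curves, 7)
  expect_named(les$curves, c(sort(unique(part)), "random"))
  sizes <- table(part)
  for (m in names(sizes)) {
    expect_length(les$curves[[m]], sizes[[m]] + 1)
    expect_equal(les$curves[[m]][1], 0)
  }
  expect_length(les$curves$random, max(sizes) + 1)
  expect_equal(les$slopes[["M01"]], mean(diff(les$curves$M01)))
  # bit-exact reproducibility
  les2 <- targeted_attack(g, part, n_reps = 3, seed = 76)
  expect_identical(les$curves, les2$curves)
})

test_that("a planted hub module shows the steepest lesion slope", {
  part <- rep(c("A", "B", "C", "D"), each = 8)
  hits <- 0
  for (s in 1:5) {
    g <- random_directed_graph(32, 100, seed = 5000 + s)
    # module A nodes wired to every node outside A
    hub_edges <- as.matrix(expand.grid(1:8, 9:32))
    e <- unique(rbind(g$edges, hub_edges))
    gh <- connectome(32, e, two_cycles_ok = TRUE)
    les <- targeted_attack(gh, part, n_reps = 2, seed = 6000 + s)
    mod_slopes <- les$slopes[c("A", "B", "C", "D")]
    if (names(which.min(mod_slopes)) == "A") hits <- hits + 1
  }
  expect_gte(hits, 5 * 0.95 - 1) # >= 4 of 5
})
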