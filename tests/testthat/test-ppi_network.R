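test_that("build_network applies the evidence filter and pruning semantics", {
  edges <- data.frame(
    gene_a = c("a", "b", "c", "a", "d", "e", "f", "g"),
    gene_b = c("b", "c", "a", "d", "e", "a", "g", "f"),
    ilis_best = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.1, 0.9, 0.9),
    literature_support = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    ortholog_score = c(0, 0, 0, 0, 5, 0, 2, 2))
  # surviving edges: triangle a-b-c, a-d, d-e (e-a fails the threshold, f-g
  # fails ortholog_min); e has degree 1 and is pruned; d drops to degree 1
  # but is NOT re-pruned (single pass)
  g <- build_network(edges, min_degree = 2)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(g), 4)
  # single-pass semantics: pendant removal may leave new degree-1 nodes
  chain <- data.frame(gene_a = c("a", "b", "c", "c", "d"),
                      gene_b = c("b", "c", "d", "e", "e"),
                      ilis_best = 0.9, literature_support = TRUE,
                      ortholog_score = 0)
  star <- rbind(chain, data.frame(gene_a = "a", gene_b = "x", ilis_best = 0.9,
                                  literature_support = TRUE, ortholog_score = 0))
  g2 <- build_network(star, min_degree = 2)
  expect_false("x" %in% igraph::V(g2)$name)   # pendant removed
  expect_true("a" %in% igraph::V(g2)$name)    # neighbor not re-pruned
  g3 <- build_network(star, min_degree = 2, iterative_prune = TRUE)
  expect_false("a" %in% igraph::V(g3)$name)   # iterative mode re-prunes
  expect_error(build_network(edges[6, ]), "no edges survive")
  # random fixture: surviving edge set equals a brute-force filter
  pg <- make_planted_graph(block_sizes = c(15, 15), seed = 7, decoy_frac = 0.5)
  ok <- with(pg$edges, ilis_best >= 0.223 &
               (literature_support | ortholog_score >= 4) & gene_a != gene_b)
  want_keys <- unique(with(pg$edges[ok, ],
    ifelse(gene_a < gene_b, paste(gene_a, gene_b), paste(gene_b, gene_a))))
  gf <- igraph::graph_from_data_frame(pg$edges[ok, 1:2], directed = FALSE)
  gf <- igraph::simplify(gf)
  el <- igraph::as_edgelist(build_network(pg$edges, min_degree = 0))
  got_keys <- ifelse(el[, 1] < el[, 2], paste(el[, 1], el[, 2]), paste(el[, 2], el[, 1]))
  expect_setequal(got_keys, want_keys)
})

test_that("modularity: closed forms and the exhaustive-partition oracle", {
  # two disjoint triangles + bridge-free partition: Q = 0.5
  g <- igraph::graph_from_literal(a - b, b - c, c - a, d - e, e - f, f - d)
  memb <- c(1, 1, 1, 2, 2, 2)
  expect_equal(modularity_q(g, memb), 0.5)
  # single community -> 0 at gamma = 1
  expect_equal(modularity_q(g, rep(1, 6)), 0)
  expect_error(modularity_q(igraph::make_empty_graph(3, directed = FALSE), 1:3),
               "edgeless")
  # agrees with igraph and with direct summation on random graphs/partitions
  set.seed(12)
  for (rep in 1:5) {
    gr <- igraph::sample_gnp(8, 0.45)
    if (igraph::ecount(gr) == 0) next
    mb <- sample(1:3, 8, replace = TRUE)
    el <- igraph::as_edgelist(gr, names = FALSE)
    expect_equal(modularity_q(gr, mb), oracle_modularity(el, 8, mb), tolerance = 1e-12)
    expect_equal(modularity_q(gr, mb), igraph::modularity(gr, mb), tolerance = 1e-12)
    for (gamma in c(0.5, 2))
      expect_equal(modularity_q(gr, mb, gamma), oracle_modularity(el, 8, mb, gamma),
                   tolerance = 1e-12)
  }
  # exhaustive oracle: no partition of a 6-node graph beats the best found
  set.seed(2)
  gr <- igraph::sample_gnp(6, 0.5)
  el <- igraph::as_edgelist(gr, names = FALSE)
  parts <- all_partitions(6)
  qs <- vapply(parts, function(p) oracle_modularity(el, 6, p), numeric(1))
  for (k in seq_along(parts))
    expect_equal(modularity_q(gr, parts[[k]]), qs[k], tolerance = 1e-12)
  # refining the component partition of two disjoint triangles never helps
  tri_el <- cbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4))
  comp_q <- oracle_modularity(tri_el, 6, c(1, 1, 1, 2, 2, 2))
  for (p in parts) expect_lte(oracle_modularity(tri_el, 6, p), comp_q + 1e-12)
})

test_that("Leiden finds planted structure and is seed-deterministic", {
  # two 6-cliques joined by one edge -> the two cliques (exhaustive optimum)
  g <- igraph::make_full_graph(6) + igraph::make_full_graph(6)
  g <- igraph::add_edges(g, c(1, 7))
  memb <- leiden_partition(g, resolution = 1, seed = 42)
  expect_identical(length(unique(memb)), 2L)
  expect_identical(memb[1:6], rep(memb[1], 6))
  expect_identical(memb[7:12], rep(memb[7], 6))
  # complete graph at low resolution -> one community
  expect_identical(length(unique(leiden_partition(igraph::make_full_graph(10),
                                                  resolution = 0.5, seed = 1))), 1L)
  # determinism
  pg <- make_planted_graph(seed = 5)
  gg <- build_network(pg$edges)
  expect_identical(leiden_partition(gg, 1.1, seed = 42),
                   leiden_partition(gg, 1.1, seed = 42))
  # planted-partition recovery (p_in = 0.3, p_out = 0.01, 4 x 30)
  pg2 <- make_planted_graph(block_sizes = rep(30, 4), p_in = 0.3, p_out = 0.01,
                            seed = 8)
  g2 <- build_network(pg2$edges)
  memb2 <- leiden_partition(g2, resolution = 1, seed = 42)
  truth <- pg2$labels[igraph::V(g2)$name]
  expect_gte(ari(memb2, truth), 0.9)
})

test_that("optimize_resolution returns the grid argmax with recomputable Q", {
  expect_identical(length(seq(0.5, 4.0, by = 0.1)), 36L)
  g <- igraph::make_full_graph(6) + igraph::make_full_graph(6)
  g <- igraph::add_edges(g, c(1, 7))
  opt <- optimize_resolution(g, seed = 42)
  expect_equal(opt$modularity, modularity_q(g, opt$membership), tolerance = 1e-12)
  expect_identical(length(unique(opt$membership)), 2L)  # stable dominant split
  # single edge between two nodes handled without crash
  tiny <- igraph::make_graph(c(1, 2), directed = FALSE)
  expect_no_error(optimize_resolution(tiny, seed = 1))
})

test_that("permutation split test is calibrated and accepts real splits", {
  g <- igraph::make_full_graph(6) + igraph::make_full_graph(6)
  g <- igraph::add_edges(g, c(1, 7))
  res <- permutation_split_test(g, rep(1:2, each = 6), seed = 42)
  expect_true(res$accepted)
  expect_gt(res$observed_q, 0.4)
  expect_length(res$null_q, 100)
  # shuffles preserve community sizes: null modularities are those of
  # size-preserving relabelings, all computable without error, and the
  # single-community partition is rejected trivially
  expect_false(permutation_split_test(g, rep(1, 12))$accepted)
  # arbitrary split on an Erdos-Renyi graph: ~5% acceptance
  set.seed(77)
  acc <- vapply(1:60, function(i) {
    gr <- igraph::sample_gnp(40, 0.3)
    permutation_split_test(gr, sample(rep(1:2, 20)),
                           seed = sample.int(1e6, 1))$accepted
  }, logical(1))
  expect_lte(mean(acc), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 60))
})

test_that("recursive clustering recovers a two-level hierarchy", {
  pg <- make_planted_graph(block_sizes = rep(20, 6), p_in = 0.6,
                           super_blocks = c(1, 1, 1, 2, 2, 2),
                           p_mid = 0.08, p_out = 0.005, seed = 13)
  g <- build_network(pg$edges)
  tree <- recursive_cluster(g, seed = 42, level1_resolution = 0.3)
  top <- tree[tree$level == "cluster", ]
  top_assign <- character(0)
  for (k in seq_len(nrow(top))) top_assign[top$members[[k]]] <- top$id[k]
  genes <- igraph::V(g)$name
  expect_gte(ari(top_assign[genes], pg$labels_super[genes]), 0.9)
  subs <- tree[tree$level == "sub", ]
  sub_assign <- character(0)
  for (k in seq_len(nrow(subs))) sub_assign[subs$members[[k]]] <- subs$id[k]
  covered <- genes[genes %in% names(sub_assign)]
  expect_gte(ari(sub_assign[covered], pg$labels[covered]), 0.9)
  # tree invariants: leaves partition the node set; children partition parents
  leaves <- cluster_leaves(tree)
  expect_setequal(names(leaves), genes)
  for (id in unique(tree$parent[!is.na(tree$parent)])) {
    kids <- tree[!is.na(tree$parent) & tree$parent == id, ]
    parent_members <- tree$members[[which(tree$id == id)]]
    expect_setequal(unlist(kids$members), parent_members)
  }
  # determinism
  tree2 <- recursive_cluster(g, seed = 42, level1_resolution = 0.3)
  expect_identical(tree$id, tree2$id)
  expect_identical(tree$members, tree2$members)
})

test_that("hypergeometric enrichment matches the exact tail sum and BH", {
  # population 20, term 5, cluster 5, overlap 3 -> P(X >= 3) ~ 0.0726
  bg <- sprintf("g%02d", 1:20)
  term <- bg[1:5]
  cluster <- c(bg[1:3], bg[10:11])
  ann <- list(T1 = term)
  p_direct <- sum(dhyper(3:5, 5, 15, 5))
  res <- hypergeometric_enrichment(cluster, ann, bg, alpha = 1)
  expect_equal(res$p, p_direct, tolerance = 1e-12)
  expect_equal(res$p, 0.0726, tolerance = 1e-3)
  # cluster equal to a term's gene set is the top hit
  ann2 <- list(exact = bg[1:5], half = bg[3:8], other = bg[10:15])
  res2 <- hypergeometric_enrichment(bg[1:5], ann2, bg, alpha = 1)
  expect_identical(res2$term[1], "exact")
  # BH step-up by hand on {0.01, 0.02, 0.04, 0.5}: adjusted values are
  # (0.04, 0.04, 0.0533, 0.5) -> exactly the first two pass alpha 0.05
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.5), "BH"),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  # zero-annotation terms skipped; background must contain the cluster
  res3 <- hypergeometric_enrichment(bg[1:3], list(empty = c("zz")), bg, alpha = 1)
  expect_true(is.null(res3) || nrow(res3) == 0)
  expect_error(hypergeometric_enrichment(c("nope"), ann, bg), "background")
})
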