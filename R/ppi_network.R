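# Evidence-supported PPI network construction and recursive,
# permutation-validated Leiden community detection.

#' Build the evidence-supported PPI network
#'
#' Keeps edges that are confidently predicted (`ilis_best >= ilis_threshold`)
#' AND supported by prior evidence: literature support, or an ortholog
#' (interolog) score of at least `ortholog_min`.  Self-loops (homodimers) and
#' duplicate unordered pairs are dropped; nodes with degree below
#' `min_degree` are removed in a single pass; the giant connected component
#' is returned.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `ilis_best`,
#'   `literature_support` (logical), `ortholog_score` (integer).
#' @param ilis_threshold iLIS positivity threshold, default 0.223 (the 10%
#'   FPR best-model calibration).
#' @param ortholog_min Minimum ortholog-support score, default 4.
#' @param min_degree Minimum node degree retained, default 2.
#' @param iterative_prune Re-apply the degree filter until stable instead of
#'   the default single pass.
#' @return An undirected [igraph::graph] (giant component).
#' @export
build_network <- function(edges, ilis_threshold = 0.223, ortholog_min = 4,
                          min_degree = 2, iterative_prune = FALSE) {
  if (nrow(edges) == 0) stop("empty edge list")
  keep <- edges$ilis_best >= ilis_threshold &
    (edges$literature_support | edges$ortholog_score >= ortholog_min)
  e <- edges[keep & edges$gene_a != edges$gene_b, , drop = FALSE]
  if (nrow(e) == 0) stop("no edges survive the evidence filter")
  key <- ifelse(e$gene_a < e$gene_b,
                paste(e$gene_a, e$gene_b), paste(e$gene_b, e$gene_a))
  e <- e[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("gene_a", "gene_b")], directed = FALSE)
  repeat {
    low <- igraph::V(g)[igraph::degree(g) < min_degree]
    if (length(low) == 0) break
    g <- igraph::delete_vertices(g, low)
    if (!iterative_prune) break
  }
  if (igraph::vcount(g) == 0) stop("no nodes survive the degree filter")
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  igraph::induced_subgraph(g, which(comp$membership == giant))
}

#' Generalized (resolution-scaled) modularity
#'
#' `Q = sum_c [ e_c / m - gamma * (d_c / 2m)^2 ]` with `m` the edge count,
#' `e_c` the intra-community edge count and `d_c` the total degree of
#' community `c`.
#'
#' @param graph An undirected igraph.
#' @param membership Community id per vertex (vector, graph order).
#' @param gamma Resolution parameter (1 = standard modularity).
#' @return Numeric Q.
#' @export
modularity_q <- function(graph, membership, gamma = 1) {
  m <- igraph::ecount(graph)
  if (m == 0) stop("modularity is undefined on an edgeless graph")
  if (length(membership) != igraph::vcount(graph))
    stop("membership length does not cover all nodes")
  el <- igraph::as_edgelist(graph, names = FALSE)
  comm <- as.integer(factor(membership))
  same <- comm[el[, 1]] == comm[el[, 2]]
  e_c <- table(factor(comm[el[, 1]][same], levels = seq_len(max(comm))))
  deg <- igraph::degree(graph)
  d_c <- tapply(deg, factor(comm, levels = seq_len(max(comm))), sum, default = 0)
  sum(as.numeric(e_c) / m - gamma * (as.numeric(d_c) / (2 * m))^2)
}

#' Leiden community detection
#'
#' RB-configuration objective (modularity with a resolution parameter);
#' deterministic for a fixed seed.
#'
#' @param graph Undirected igraph.
#' @param resolution Resolution parameter gamma.
#' @param seed RNG seed (Leiden uses R's RNG through igraph).
#' @param n_iterations Leiden refinement iterations.
#' @return Integer membership vector (one id per vertex, graph order).
#' @export
leiden_partition <- function(graph, resolution = 1, seed = 42, n_iterations = 5) {
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = n_iterations)
  as.integer(igraph::membership(cl))
}

#' Pick the resolution maximizing standard modularity
#'
#' Runs Leiden at every grid resolution and evaluates each candidate
#' partition with standard (gamma = 1) modularity; returns the argmax (ties
#' broken toward the smallest resolution).
#'
#' @param graph Undirected igraph with at least 2 nodes and 1 edge.
#' @param r_grid Resolution grid, default `seq(0.5, 4.0, by = 0.1)`.
#' @param seed Seed applied to every Leiden run.
#' @return List with `resolution`, `membership`, `modularity`.
#' @export
optimize_resolution <- function(graph, r_grid = seq(0.5, 4.0, by = 0.1),
                                seed = 42) {
  if (igraph::vcount(graph) < 2 || igraph::ecount(graph) < 1)
    stop("need at least 2 nodes and 1 edge")
  best <- list(resolution = NA_real_, membership = NULL, modularity = -Inf)
  for (r in r_grid) {
    memb <- leiden_partition(graph, resolution = r, seed = seed)
    q <- modularity_q(graph, memb, gamma = 1)
    if (q > best$modularity + 1e-12) best <- list(resolution = r, membership = memb,
                                                  modularity = q)
  }
  best
}

#' Permutation test of a community split
#'
#' Shuffles node-to-community assignments (preserving the community-size
#' multiset) `n_shuffle` times; the split is accepted iff the observed
#' modularity strictly exceeds the `percentile`-th order statistic
#' (nearest rank) of the null modularities.
#'
#' @param graph Undirected igraph.
#' @param membership Candidate partition.
#' @param n_shuffle Number of label shuffles, default 100.
#' @param percentile Acceptance percentile, default 95.
#' @param seed RNG seed.
#' @return List with `accepted`, `observed_q`, `null_q` (vector) and
#'   `null_cutoff`.  A single-community partition is rejected trivially
#'   (there is no split to validate).
#' @export
permutation_split_test <- function(graph, membership, n_shuffle = 100,
                                   percentile = 95, seed = 42) {
  if (length(unique(membership)) < 2)
    return(list(accepted = FALSE, observed_q = NA_real_,
                null_q = numeric(0), null_cutoff = NA_real_))
  observed <- modularity_q(graph, membership, gamma = 1)
  set.seed(seed)
  null_q <- vapply(seq_len(n_shuffle), function(i)
    modularity_q(graph, sample(membership), gamma = 1), numeric(1))
  cutoff <- sort(null_q)[ceiling(percentile / 100 * n_shuffle)]
  list(accepted = observed > cutoff, observed_q = observed,
       null_q = null_q, null_cutoff = cutoff)
}

#' Recursive permutation-validated clustering
#'
#' Level 1 partitions the full graph with Leiden at a fixed resolution
#' (default 1.1), unconditionally.  Each level-1 cluster of at least
#' `min_size` genes is sub-clustered with per-cluster resolution
#' optimization ([optimize_resolution()]) and the split kept only if it
#' passes [permutation_split_test()]; accepted sub-clusters are decomposed
#' once more (sub-sub level) under the same criterion.
#'
#' @param graph Graph from [build_network()].
#' @param seed Base RNG seed; per-node seeds are derived deterministically.
#' @param level1_resolution Resolution of the top-level partition.
#' @param min_size Minimum community size eligible for further splitting.
#' @param n_shuffle,percentile Permutation-test parameters.
#' @param max_depth Total depth including the top level (default 3:
#'   cluster, sub, sub-sub).
#' @return A `cluster_tree`: data frame of nodes with columns `id` (path
#'   label like `"C1-4-2"`), `level` (`cluster`/`sub`/`subsub`), `parent`,
#'   `n_members`, `resolution`, `modularity`, `accepted`, `is_leaf`, and a
#'   list-column `members`.
#' @export
recursive_cluster <- function(graph, seed = 42, level1_resolution = 1.1,
                              min_size = 5, n_shuffle = 100, percentile = 95,
                              max_depth = 3) {
  level_names <- c("cluster", "sub", "subsub")
  nodes <- list()
  add_node <- function(id, level, parent, members, resolution, q, accepted) {
    nodes[[length(nodes) + 1L]] <<- data.frame(
      id = id, level = level_names[level], parent = parent,
      n_members = length(members), resolution = resolution,
      modularity = q, accepted = accepted, is_leaf = TRUE,
      stringsAsFactors = FALSE)
    attr(nodes[[length(nodes)]], "members") <<- members
    length(nodes)
  }
  names_of <- function(g) igraph::V(g)$name

  split_node <- function(subgraph, id, level, seed_k) {
    # try to split `subgraph` (node `id` at `level`); returns nothing, but
    # appends accepted children and recurses
    if (level > max_depth) return(invisible())
    if (igraph::vcount(subgraph) < max(2, min_size) ||
        igraph::ecount(subgraph) < 1) return(invisible())
    opt <- optimize_resolution(subgraph, seed = seed_k)
    test <- permutation_split_test(subgraph, opt$membership,
                                   n_shuffle = n_shuffle,
                                   percentile = percentile, seed = seed_k + 1L)
    if (!test$accepted) return(invisible())
    # mark parent non-leaf
    for (k in seq_along(nodes)) if (nodes[[k]]$id == id) nodes[[k]]$is_leaf <<- FALSE
    comms <- sort(unique(opt$membership))
    for (ci in seq_along(comms)) {
      mem <- names_of(subgraph)[opt$membership == comms[ci]]
      child_id <- paste0(id, "-", ci)
      add_node(child_id, level, id, mem, opt$resolution, test$observed_q, TRUE)
      if (length(mem) >= min_size) {
        child_g <- igraph::induced_subgraph(subgraph,
                                            which(names_of(subgraph) %in% mem))
        split_node(child_g, child_id, level + 1L, seed_k + 100L * ci)
      }
    }
    invisible()
  }

  top_mem <- leiden_partition(graph, resolution = level1_resolution, seed = seed)
  comms <- sort(unique(top_mem))
  q_top <- modularity_q(graph, top_mem, gamma = 1)
  for (ci in seq_along(comms)) {
    mem <- names_of(graph)[top_mem == comms[ci]]
    id <- paste0("C", ci)
    add_node(id, 1L, NA_character_, mem, level1_resolution, q_top, TRUE)
    if (length(mem) >= min_size) {
      sub_g <- igraph::induced_subgraph(graph, which(names_of(graph) %in% mem))
      split_node(sub_g, id, 2L, seed + 1000L * ci)
    }
  }
  members <- lapply(nodes, attr, "members")
  tree <- do.call(rbind, nodes)
  tree$members <- members
  structure(tree, class = c("cluster_tree", "data.frame"),
            level1_modularity = q_top)
}

#' Leaf membership of a cluster tree
#'
#' @param tree A `cluster_tree` from [recursive_cluster()].
#' @return Named character vector: leaf id per gene.  Leaves partition the
#'   graph's node set.
#' @export
cluster_leaves <- function(tree) {
  leaves <- tree[tree$is_leaf, , drop = FALSE]
  out <- character(0)
  for (k in seq_len(nrow(leaves))) {
    mem <- leaves$members[[k]]
    out[mem] <- leaves$id[k]
  }
  out
}

#' Hypergeometric term enrichment with BH correction
#'
#' Upper-tail hypergeometric p for the overlap of a gene set with each
#' annotation term, Benjamini-Hochberg adjusted across terms; terms with no
#' annotated gene in the background are skipped.
#'
#' @param genes Cluster gene set (character).
#' @param annotation Named list: term -> character vector of genes.
#' @param background Background gene universe (must contain `genes`).
#' @param alpha Adjusted-p cutoff, default 0.05.
#' @return Data frame `term`, `overlap`, `term_size`, `cluster_size`,
#'   `background_size`, `p`, `p_adj`, sorted by `p`, filtered to
#'   `p_adj < alpha`.
#' @export
hypergeometric_enrichment <- function(genes, annotation, background,
                                      alpha = 0.05) {
  if (!all(genes %in% background))
    stop("background must contain all cluster genes")
  genes <- unique(genes); background <- unique(background)
  N <- length(background); n <- length(genes)
  rows <- lapply(names(annotation), function(term) {
    term_genes <- intersect(annotation[[term]], background)
    K <- length(term_genes)
    if (K == 0) return(NULL)
    k <- length(intersect(term_genes, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = k, term_size = K, cluster_size = n,
               background_size = N, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0) return(res)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res[res$p_adj < alpha, , drop = FALSE]
}
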