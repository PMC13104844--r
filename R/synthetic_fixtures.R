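# Seeded generators for every input the pipeline consumes: toy dimer
# coordinates + PAE bundles with planted interfaces, benchmark score tables
# with separable class distributions, residue tables with a planted
# logit-model mutation process, and (hierarchical) planted-partition graphs
# with evidence columns.  All generators are deterministic given their seed
# and return the ground truth needed for recovery tests.

#' Generate a toy dimer prediction (coordinates + scores)
#'
#' Geometry: each chain is a straight line of residues spaced 20 A apart
#' (far beyond the 8 A contact cutoff within and between chains); for the
#' `n_contacts` planted pairs (residue i of A with residue i of B) chain B's
#' residue is moved to 5 A from its partner, so exactly those pairs are in
#' contact.  The PAE matrix holds `interface_pae` on planted inter-chain
#' pairs (both directions, optionally jittered antisymmetrically) and
#' `background_pae` elsewhere in the inter-chain blocks; intra-chain PAE is
#' a confident 5 A.  Only distances relative to the 8 A cutoff matter to any
#' downstream computation, so no attempt is made at realistic geometry.
#'
#' With `background_pae > 12` and `interface_pae <= 12`, the analytically
#' expected scores are `lis = clis = ilis = (12 - interface_pae) / 12` (the
#' planted pairs are exactly the qualifying and the contacting set).
#'
#' @param chain_lengths Integer vector of the two chain lengths (each >= 3).
#' @param n_contacts Number of planted contacting inter-chain pairs
#'   (may be 0; at most `min(chain_lengths)`).
#' @param interface_pae PAE on planted pairs (A).
#' @param background_pae PAE elsewhere in the inter-chain blocks (A).
#' @param pae_jitter Antisymmetric perturbation: planted-pair PAE becomes
#'   `interface_pae + pae_jitter` in the A->B direction and
#'   `interface_pae - pae_jitter` in B->A (expected scores unchanged while
#'   both stay within the cutoff, since the rescaling is linear).
#' @param plddt_level Constant per-residue pLDDT written to the B-factor.
#' @param ptm,iptm Global scores stored in the JSON.
#' @param seed RNG seed (sequences are random).
#' @param pair_id Pair identifier and filename prefix.
#' @param dir Output directory; when `NULL` nothing is written.
#' @param rank Model rank used in the filenames.
#' @param with_glycine Plant a glycine at position 2 of chain A (exercises
#'   the C-alpha fallback).
#' @return List with `model` ([complex_model()]), `scores`
#'   ([score_bundle()]), `paths` (pdb/json, when written) and `expected`
#'   (analytic `lis`, `clis`, `ilis`, `n_lia_pairs`, `n_contact_pairs`).
#' @export
make_toy_complex <- function(chain_lengths = c(10, 8), n_contacts = 4,
                             interface_pae = 6, background_pae = 30,
                             pae_jitter = 0, plddt_level = 80,
                             ptm = 0.5, iptm = 0.6, seed = 1,
                             pair_id = "toyA_toyB", dir = NULL, rank = 1,
                             with_glycine = FALSE) {
  n_a <- chain_lengths[1]; n_b <- chain_lengths[2]
  if (n_a < 3 || n_b < 3) stop("chain lengths must be >= 3")
  if (n_contacts > min(n_a, n_b))
    stop("n_contacts exceeds the shorter chain length (infeasible geometry)")
  if (interface_pae > 12 && n_contacts > 0 && interface_pae < background_pae)
    warning("interface PAE above the 12 A cutoff: planted pairs will not qualify")
  set.seed(seed)
  seq_a <- paste(sample(names(AA1TO3)[names(AA1TO3) != "G"], n_a, replace = TRUE),
                 collapse = "")
  seq_b <- paste(sample(names(AA1TO3)[names(AA1TO3) != "G"], n_b, replace = TRUE),
                 collapse = "")
  if (with_glycine) substr(seq_a, 2, 2) <- "G"

  coords <- matrix(0, n_a + n_b, 3)
  coords[seq_len(n_a), 1] <- (seq_len(n_a) - 1) * 20       # chain A along x at y=0
  coords[n_a + seq_len(n_b), 1] <- (seq_len(n_b) - 1) * 20 # chain B along x
  coords[n_a + seq_len(n_b), 2] <- 100                     # far from A by default
  if (n_contacts > 0)
    coords[n_a + seq_len(n_contacts), 2] <- 5              # planted pairs at 5 A

  n <- n_a + n_b
  pae <- matrix(background_pae, n, n)
  pae[seq_len(n_a), seq_len(n_a)] <- 5
  pae[n_a + seq_len(n_b), n_a + seq_len(n_b)] <- 5
  if (n_contacts > 0) {
    for (i in seq_len(n_contacts)) {
      pae[i, n_a + i] <- interface_pae + pae_jitter
      pae[n_a + i, i] <- interface_pae - pae_jitter
    }
  }
  diag(pae) <- 0
  pae[pae < 0] <- 0
  if (pae_jitter != 0 && interface_pae + abs(pae_jitter) > 12)
    stop("pae_jitter pushes planted PAE beyond the 12 A cutoff; ",
         "the analytic expectation would not hold")

  plddt <- rep(plddt_level, n)
  model <- complex_model(pair_id, rank, c("A", "B"), c(seq_a, seq_b), coords, plddt)
  scores <- score_bundle(pair_id, rank, pae, ptm, iptm, plddt)

  # analytic expectation, from the construction parameters alone
  resc <- function(p) if (p <= 12) (12 - p) / 12 else NA_real_
  k <- as.integer(n_contacts); n_inter <- as.integer(n_a * n_b)
  if (background_pae <= 12) {
    block_mean <- function(ip) (k * resc(ip) + (n_inter - k) * resc(background_pae)) / n_inter
    lis <- (block_mean(min(interface_pae + pae_jitter, 12)) +
            block_mean(min(interface_pae - pae_jitter, 12))) / 2
    n_lia <- 2L * n_inter
  } else if (k > 0 && interface_pae + abs(pae_jitter) <= 12) {
    lis <- (resc(interface_pae + pae_jitter) + resc(interface_pae - pae_jitter)) / 2
    n_lia <- 2L * k
  } else { lis <- 0; n_lia <- 0L }
  n_lia <- as.integer(n_lia)
  if (k > 0 && interface_pae + abs(pae_jitter) <= 12) {
    clis <- (resc(interface_pae + pae_jitter) + resc(interface_pae - pae_jitter)) / 2
  } else clis <- 0
  expected <- list(lis = lis, clis = clis, ilis = sqrt(lis * clis),
                   n_lia_pairs = n_lia, n_contact_pairs = as.integer(k))

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    stem <- sprintf("%s_unrelaxed_rank_%03d", pair_id, rank)
    pdb <- file.path(dir, paste0(stem, ".pdb"))
    json <- file.path(dir, sprintf("%s_scores_rank_%03d.json", pair_id, rank))
    write_complex_pdb(model, pdb)
    write_scores_json(scores, json)
    paths <- list(pdb = pdb, json = json)
  }
  list(model = model, scores = scores, paths = paths, expected = expected)
}

#' Generate a benchmark score table with separable class distributions
#'
#' Positives draw metric scores from `Beta(pos_shape)` and controls from
#' `Beta(ctrl_shape)` independently per metric and model choice; set labels
#' and pLDDT subgroups are assigned uniformly.  With the default shapes
#' (5, 2) vs (2, 5) the classes are well separated (analytic AUC ~ 0.90).
#'
#' @param n_pos,n_ctrl Class sizes.
#' @param metrics Base metric names; `<metric>_best` and `<metric>_avg`
#'   columns are generated for each.
#' @param pos_shape,ctrl_shape `c(shape1, shape2)` of the Beta draws.
#' @param seed RNG seed.
#' @return A benchmark data frame (`pair_id`, `set_label`, `class`,
#'   `plddt_subgroup`, metric columns) consumable by [calibrate()].
#' @export
make_benchmark_table <- function(n_pos = 200, n_ctrl = 600,
                                 metrics = c("ilis", "iptm"),
                                 pos_shape = c(5, 2), ctrl_shape = c(2, 5),
                                 seed = 1) {
  set.seed(seed)
  n <- n_pos + n_ctrl
  cls <- rep(c("positive", "control"), c(n_pos, n_ctrl))
  set_label <- c(sample(c("PRS-yeast", "PRS-fly", "PRS-human"), n_pos, replace = TRUE),
                 sample(c("RRS", "GFP", "Wg"), n_ctrl, replace = TRUE))
  tab <- data.frame(
    pair_id = sprintf("pair%05d", seq_len(n)),
    set_label = set_label, class = cls,
    plddt_subgroup = sample(c("0-50", "50-70", "70-100"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  for (m in metrics) for (ch in c("best", "avg")) {
    x <- numeric(n)
    x[cls == "positive"] <- stats::rbeta(n_pos, pos_shape[1], pos_shape[2])
    x[cls == "control"] <- stats::rbeta(n_ctrl, ctrl_shape[1], ctrl_shape[2])
    tab[[paste0(m, "_", ch)]] <- x
  }
  tab
}

#' Generate a residue table with a planted mutation model
#'
#' Per residue: `lir_pct` is 0 with probability `zero_frac`, otherwise
#' uniform on (0, 100]; `clir_pct` is 0 outside interaction domains and a
#' Beta(2, 2)-scaled fraction of `lir_pct` inside (so `clir_pct <= lir_pct`
#' everywhere, with a further `clir_zero_frac` of in-domain residues at
#' exactly 0, mirroring domain residues that never touch the partner).
#' PhyloP is Gaussian, independent of the interface geometry unless
#' `phylop_clir_cor` is set.  Mutation status is Bernoulli with
#' `logit(p) = beta0 + beta1 * clir_pct + beta2 * phylop`.
#'
#' @param n_genes,res_per_gene Table dimensions.
#' @param beta0,beta1,beta2 True logit coefficients (beta1 per cLIR
#'   percentage point, beta2 per PhyloP unit).
#' @param zero_frac Fraction of residues outside any interaction domain.
#' @param clir_zero_frac Fraction of in-domain residues with `clir_pct = 0`.
#' @param phylop_clir_cor Optional correlation knob: PhyloP gains
#'   `phylop_clir_cor * clir_pct / 100` on top of the Gaussian draw.
#' @param seed RNG seed.
#' @return List with `table` (gene, position, aa, lir_pct, clir_pct,
#'   phylop, mutated), `mutations` (MutationRecord-style rows for the
#'   mutated residues) and `truth` (the planted coefficients).
#' @export
make_mutation_dataset <- function(n_genes = 200, res_per_gene = 500,
                                  beta0 = -6, beta1 = 0.02, beta2 = 0,
                                  zero_frac = 0.5, clir_zero_frac = 0.3,
                                  phylop_clir_cor = 0, seed = 1) {
  set.seed(seed)
  n <- n_genes * res_per_gene
  gene <- rep(sprintf("g%04d", seq_len(n_genes)), each = res_per_gene)
  position <- rep(seq_len(res_per_gene), n_genes)
  aa <- sample(names(AA1TO3), n, replace = TRUE)
  in_domain <- stats::runif(n) > zero_frac
  lir <- ifelse(in_domain, stats::runif(n, 0, 100), 0)
  clir <- ifelse(in_domain & stats::runif(n) > clir_zero_frac,
                 lir * stats::rbeta(n, 2, 2), 0)
  phylop <- stats::rnorm(n, 0.5, 1) + phylop_clir_cor * clir / 100
  p <- stats::plogis(beta0 + beta1 * clir + beta2 * phylop)
  mutated <- stats::runif(n) < p
  tab <- data.frame(gene = gene, position = position, aa = aa,
                    lir_pct = lir, clir_pct = clir, phylop = phylop,
                    mutated = mutated, stringsAsFactors = FALSE)
  mut_rows <- tab[tab$mutated, c("gene", "position", "aa")]
  names(mut_rows)[3] <- "ref_aa"
  if (nrow(mut_rows)) {
    mut_rows$alt_aa <- vapply(mut_rows$ref_aa, function(r)
      sample(setdiff(names(AA1TO3), r), 1), character(1))
    mut_rows$source <- "synthetic"
  }
  list(table = tab, mutations = mut_rows,
       truth = list(beta0 = beta0, beta1 = beta1, beta2 = beta2))
}

#' Generate a planted-partition graph with evidence columns
#'
#' A stochastic block model, optionally with a two-level hierarchy: blocks
#' are grouped into super-blocks; edge probability is `p_in` within a block,
#' `p_mid` between blocks of the same super-block, `p_out` otherwise.
#' Planted edges carry an `ilis_best` above the classification threshold and
#' qualifying evidence.  With `decoy_frac > 0`, that fraction of extra decoy
#' edges is added which the [build_network()] filter must remove (below
#' threshold or unsupported).
#'
#' @param block_sizes Integer vector of block sizes.
#' @param p_in Within-block edge probability.
#' @param p_out Between-(super)block edge probability.
#' @param super_blocks Optional integer vector assigning each block to a
#'   super-block (enables the hierarchy).
#' @param p_mid Between-block, within-super-block probability (hierarchical
#'   case only).
#' @param decoy_frac Decoy edges to add, as a fraction of planted edges.
#' @param seed RNG seed.
#' @return List with `edges` (gene_a, gene_b, ilis_best,
#'   literature_support, ortholog_score), `labels` (block id per gene),
#'   `labels_super` (super-block id per gene, hierarchical case) and
#'   `n_planted`.
#' @export
make_planted_graph <- function(block_sizes = c(30, 30, 30, 30), p_in = 0.3,
                               p_out = 0.01, super_blocks = NULL, p_mid = 0.05,
                               decoy_frac = 0, seed = 1) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1, p_mid >= 0, p_mid <= 1)
  set.seed(seed)
  n <- sum(block_sizes)
  genes <- sprintf("n%04d", seq_len(n))
  block <- rep(seq_along(block_sizes), block_sizes)
  super <- if (is.null(super_blocks)) block else rep(super_blocks, block_sizes)
  pairs <- utils::combn(n, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  prob <- ifelse(block[i] == block[j], p_in,
                 ifelse(super[i] == super[j], p_mid, p_out))
  take <- stats::runif(length(prob)) < prob
  ia <- i[take]; ja <- j[take]
  n_planted <- length(ia)
  if (n_planted == 0) stop("no planted edges drawn; raise p_in or block sizes")
  edges <- data.frame(
    gene_a = genes[ia], gene_b = genes[ja],
    ilis_best = stats::runif(n_planted, 0.3, 0.9),
    literature_support = stats::runif(n_planted) < 0.5,
    ortholog_score = sample(0:10, n_planted, replace = TRUE),
    stringsAsFactors = FALSE)
  # guarantee planted edges pass the evidence filter
  fix <- !edges$literature_support & edges$ortholog_score < 4
  edges$literature_support[fix] <- TRUE
  if (decoy_frac > 0) {
    n_decoy <- ceiling(decoy_frac * n_planted)
    di <- sample(n, n_decoy, replace = TRUE)
    dj <- sample(n, n_decoy, replace = TRUE)
    keep <- di != dj
    di <- di[keep]; dj <- dj[keep]
    m <- length(di)
    low_score <- stats::runif(m) < 0.5
    decoys <- data.frame(
      gene_a = genes[di], gene_b = genes[dj],
      ilis_best = ifelse(low_score, stats::runif(m, 0, 0.2),
                         stats::runif(m, 0.3, 0.9)),
      literature_support = FALSE,
      ortholog_score = ifelse(low_score, sample(0:10, m, replace = TRUE),
                              sample(0:3, m, replace = TRUE)),
      stringsAsFactors = FALSE)
    edges <- rbind(edges, decoys)
  }
  names(block) <- names(super) <- genes
  list(edges = edges, labels = block, labels_super = super,
       n_planted = n_planted)
}
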