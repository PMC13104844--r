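# Pair-level confidence metrics for predicted dimers.
#
# The central metric is iLIS = sqrt(LIS * cLIS): LIS averages inversely
# rescaled inter-chain PAE over the confident region (PAE <= 12 A maps
# linearly to [0, 1], 12 -> 0, 0 -> 1); cLIS restricts the same average to
# residue pairs in direct C-beta contact (<= 8 A).  The geometric mean
# penalizes predictions whose chains are placed confidently but make no
# physical contact (cLIS ~ 0).
#
# The PAE matrix is asymmetric; both metrics are computed per directional
# inter-chain block (A-rows x B-cols and B-rows x A-cols) and the two block
# means are averaged.  An empty qualifying set contributes 0, not NA: a pair
# with no confident inter-chain region is a non-interaction under this
# metric.

# extract the two directional inter-chain blocks of a square PAE matrix
pae_blocks <- function(pae, chain_offsets) {
  n <- nrow(pae)
  n_a <- chain_offsets[2]
  if (n_a <= 0 || n_a >= n) stop("invalid chain offsets for PAE of size ", n)
  a <- seq_len(n_a); b <- seq.int(n_a + 1L, n)
  list(ab = pae[a, b, drop = FALSE], ba = pae[b, a, drop = FALSE])
}

# mean of (cutoff - x)/cutoff over qualifying entries; 0 when none qualify
rescaled_block_mean <- function(entries, cutoff) {
  q <- entries[entries <= cutoff]
  if (length(q) == 0) return(list(mean = 0, n = 0L))
  list(mean = mean((cutoff - q) / cutoff), n = length(q))
}

#' Local Interaction Score (LIS)
#'
#' @param scores A [score_bundle()].
#' @param chain_offsets Integer vector `c(0, nA)`: 0-based start of each chain
#'   in the concatenated residue order (as in a [complex_model()]).
#' @param pae_cutoff Confident-region cutoff in Angstrom (inclusive),
#'   default 12.
#' @return List with `lis` in \[0, 1\] and `n_lia_pairs`, the number of
#'   inter-chain entries with PAE at most the cutoff over both directional
#'   blocks (the Local Interaction Area size).
#' @export
compute_lis <- function(scores, chain_offsets, pae_cutoff = 12) {
  bl <- pae_blocks(scores$pae, chain_offsets)
  m_ab <- rescaled_block_mean(bl$ab, pae_cutoff)
  m_ba <- rescaled_block_mean(bl$ba, pae_cutoff)
  list(lis = (m_ab$mean + m_ba$mean) / 2,
       n_lia_pairs = m_ab$n + m_ba$n)
}

#' Contact-filtered Local Interaction Score (cLIS)
#'
#' Same rescaled-PAE average as [compute_lis()], but an entry qualifies only
#' if its residue pair is in direct C-beta contact; the single A x B contact
#' mask is applied to both PAE directions.
#'
#' @inheritParams compute_lis
#' @param contacts Logical A x B contact matrix from [contact_map()].
#' @return List with `clis` in \[0, 1\] and `n_contact_pairs = sum(contacts)`.
#' @export
compute_clis <- function(scores, contacts, chain_offsets, pae_cutoff = 12) {
  bl <- pae_blocks(scores$pae, chain_offsets)
  if (!identical(dim(contacts), dim(bl$ab)))
    stop("contact map dimensions (", paste(dim(contacts), collapse = "x"),
         ") do not match the inter-chain block (", paste(dim(bl$ab), collapse = "x"), ")")
  m_ab <- rescaled_block_mean(bl$ab[contacts], pae_cutoff)
  m_ba <- rescaled_block_mean(bl$ba[t(contacts)], pae_cutoff)
  list(clis = (m_ab$mean + m_ba$mean) / 2,
       n_contact_pairs = sum(contacts))
}

#' Integrated Local Interaction Score (iLIS)
#'
#' @param lis,clis Component scores in \[0, 1\].
#' @return The geometric mean `sqrt(lis * clis)`.
#' @export
compute_ilis <- function(lis, clis) {
  stopifnot(lis >= 0, lis <= 1, clis >= 0, clis <= 1)
  sqrt(lis * clis)
}

#' Global companion metrics for one model
#'
#' ifPAE is the mean inter-chain PAE over all residue pairs (both
#' directions); ifPAE_d8 restricts it to C-beta contacts (<= 8 A) and is
#' missing when the model has no contacts.  For both, lower is better.
#' Model Confidence is the AFM ranking aggregate `0.8 * ipTM + 0.2 * pTM`.
#'
#' @inheritParams compute_clis
#' @param plddt Per-residue pLDDT over both chains.
#' @return List with `ifpae`, `ifpae_d8`, `model_confidence`,
#'   `mean_pair_plddt` and `plddt_subgroup` (one of `"0-50"`, `"50-70"`,
#'   `"70-100"`; boundaries half-open on the left edge of 50 and 70).
#' @export
compute_global_metrics <- function(scores, contacts, chain_offsets, plddt = scores$plddt) {
  bl <- pae_blocks(scores$pae, chain_offsets)
  masked <- c(bl$ab[contacts], bl$ba[t(contacts)])
  mean_plddt <- mean(plddt)
  list(
    ifpae = mean(c(bl$ab, bl$ba)),
    ifpae_d8 = if (length(masked)) mean(masked) else NA_real_,
    model_confidence = 0.8 * scores$iptm + 0.2 * scores$ptm,
    mean_pair_plddt = mean_plddt,
    plddt_subgroup = plddt_subgroup(mean_plddt)
  )
}

#' pLDDT subgroup label
#'
#' @param x Mean pLDDT in \[0, 100\].
#' @return `"0-50"` for \[0, 50), `"50-70"` for \[50, 70), `"70-100"` for
#'   \[70, 100\].
#' @export
plddt_subgroup <- function(x) {
  ifelse(x < 50, "0-50", ifelse(x < 70, "50-70", "70-100"))
}

# published pDockQ sigmoid constants (Bryant et al. FoldDock)
PDOCKQ_CONST <- c(L = 0.724, x0 = 152.611, k = 0.052, b = 0.018)

#' pDockQ interface quality score (optional benchmark-parity metric)
#'
#' Sigmoid of `x = mean(interface pLDDT) * log10(number of contacts)` with
#' the published constants L = 0.724, x0 = 152.611, k = 0.052, b = 0.018.
#' Interface residues are those with at least one inter-chain contact at the
#' 8-A C-beta cutoff.
#'
#' @param contacts Logical A x B contact matrix.
#' @param plddt Per-residue pLDDT over both chains (concatenated order).
#' @param chain_offsets As in [compute_lis()].
#' @return pDockQ in \[0.018, 0.742\]; the lower asymptote 0.018 when there
#'   are no contacts.
#' @export
compute_pdockq <- function(contacts, plddt, chain_offsets) {
  n_contacts <- sum(contacts)
  cn <- PDOCKQ_CONST
  if (n_contacts == 0) return(unname(cn["b"]))
  n_a <- chain_offsets[2]
  iface_a <- which(rowSums(contacts) > 0)
  iface_b <- which(colSums(contacts) > 0) + n_a
  x <- mean(plddt[c(iface_a, iface_b)]) * log10(n_contacts)
  unname(cn["L"] / (1 + exp(-cn["k"] * (x - cn["x0"]))) + cn["b"])
}

# metric columns of an interface score row, in output order
METRIC_FIELDS <- c("lis", "clis", "ilis", "iptm", "ptm", "model_confidence",
                   "ifpae", "ifpae_d8", "pdockq", "n_lia_pairs",
                   "n_contact_pairs", "mean_pair_plddt")

#' Score a single model
#'
#' @param model A two-chain [complex_model()].
#' @param scores The matching [score_bundle()].
#' @param pae_cutoff,contact_cutoff Cutoffs for the confident region (12 A)
#'   and direct contact (8 A), both inclusive.
#' @return One-row data frame with all pair-level metrics
#'   (an `InterfaceScore`).
#' @export
score_model <- function(model, scores, pae_cutoff = 12, contact_cutoff = 8) {
  if (nrow(scores$pae) != sum(model$chain_lengths))
    stop("PAE size does not match model residue count")
  offs <- model$chain_offsets
  contacts <- contact_map(model, cutoff = contact_cutoff)
  plddt <- if (length(scores$plddt)) scores$plddt else model$plddt
  l <- compute_lis(scores, offs, pae_cutoff)
  cl <- compute_clis(scores, contacts, offs, pae_cutoff)
  g <- compute_global_metrics(scores, contacts, offs, plddt)
  data.frame(
    pair_id = model$pair_id, rank = model$rank,
    lis = l$lis, clis = cl$clis, ilis = compute_ilis(l$lis, cl$clis),
    iptm = scores$iptm, ptm = scores$ptm,
    model_confidence = g$model_confidence,
    ifpae = g$ifpae, ifpae_d8 = g$ifpae_d8,
    pdockq = compute_pdockq(contacts, plddt, offs),
    n_lia_pairs = l$n_lia_pairs, n_contact_pairs = cl$n_contact_pairs,
    mean_pair_plddt = g$mean_pair_plddt,
    plddt_subgroup = g$plddt_subgroup,
    stringsAsFactors = FALSE
  )
}

#' Score a prediction set: best model and across-model average
#'
#' "Best" is the rank-1 model by the AFM ranking order (not max-iLIS); the
#' average record holds the arithmetic mean of every metric over all provided
#' models, with the pLDDT subgroup re-derived from the averaged pLDDT.
#'
#' @param pred A `prediction_set` from [read_prediction_set()], or a list
#'   with fields `pair_id` and `models` (each `list(model =, scores =)`).
#' @inheritParams score_model
#' @return List of class `pair_scores` with one-row data frames `best` and
#'   `average`, plus `per_model` (all rows).
#' @export
score_pair <- function(pred, pae_cutoff = 12, contact_cutoff = 8) {
  if (length(pred$models) == 0) stop("empty prediction set")
  rows <- do.call(rbind, lapply(pred$models, function(m)
    score_model(m$model, m$scores, pae_cutoff, contact_cutoff)))
  best <- rows[which.min(rows$rank), , drop = FALSE]
  avg <- rows[1, , drop = FALSE]
  avg$rank <- NA_integer_
  for (f in METRIC_FIELDS) avg[[f]] <- mean(rows[[f]])
  avg$plddt_subgroup <- plddt_subgroup(avg$mean_pair_plddt)
  rownames(best) <- rownames(avg) <- NULL
  structure(list(pair_id = pred$pair_id, best = best, average = avg,
                 per_model = rows),
            class = "pair_scores")
}

#' Flatten pair scores into one wide row per pair
#'
#' @param pair_scores_list List of `pair_scores` objects.
#' @return Data frame with `pair_id` plus `best_<metric>` and `avg_<metric>`
#'   columns for every metric; the column names are a stable contract used by
#'   the TSV outputs and the calibration module.
#' @export
pair_scores_table <- function(pair_scores_list) {
  if (inherits(pair_scores_list, "pair_scores"))
    pair_scores_list <- list(pair_scores_list)
  rows <- lapply(pair_scores_list, function(ps) {
    row <- data.frame(pair_id = ps$pair_id, stringsAsFactors = FALSE)
    for (f in METRIC_FIELDS) row[[paste0("best_", f)]] <- ps$best[[f]]
    row$best_plddt_subgroup <- ps$best$plddt_subgroup
    for (f in METRIC_FIELDS) row[[paste0("avg_", f)]] <- ps$average[[f]]
    row$avg_plddt_subgroup <- ps$average$plddt_subgroup
    row
  })
  do.call(rbind, rows)
}
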