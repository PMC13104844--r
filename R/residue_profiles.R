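# Per-residue interface membership flags and their aggregation across all
# predicted partners of a protein.
#
# LIR marks a residue that falls within the confident interaction domain of
# at least one partner residue (min of the two PAE directions <= 12 A); cLIR
# additionally requires a direct C-beta contact (<= 8 A) with a partner
# residue that also satisfies the PAE condition.  Aggregated over partners,
# lir_pct / clir_pct report the percentage of contributing predictions in
# which the residue is flagged; predictions with no inter-chain contact at
# all are excluded from the denominator.

#' Per-residue interface flags for one model
#'
#' @param scores A [score_bundle()] for a two-chain model.
#' @param contacts Logical A x B contact matrix from [contact_map()].
#' @param chain_offsets Integer vector `c(0, nA)`.
#' @param focal_chain Which chain to profile: 1 (chain A) or 2 (chain B).
#' @param pae_cutoff,contact_cutoff Inclusive cutoffs, 12 A and 8 A.
#'   The contact map must already be built at `contact_cutoff`.
#' @return Data frame (`residue_flags`) with columns `position` (1-based
#'   within the focal chain), `lir`, `clir`; attributes `pair_id` and
#'   `n_contacts` (total contacting pairs of the model, used to decide
#'   whether the model contributes to a profile).
#' @export
residue_flags <- function(scores, contacts, chain_offsets, focal_chain = 1,
                          pae_cutoff = 12, contact_cutoff = 8) {
  bl <- pae_blocks(scores$pae, chain_offsets)
  if (!identical(dim(contacts), dim(bl$ab)))
    stop("contact map dimensions do not match the inter-chain block")
  # symmetrize per residue pair: confident if either PAE direction qualifies
  pae_min <- pmin(bl$ab, t(bl$ba))          # A x B
  qual <- pae_min <= pae_cutoff
  if (focal_chain == 1) {
    lir <- rowSums(qual) > 0
    clir <- rowSums(qual & contacts) > 0
  } else if (focal_chain == 2) {
    lir <- colSums(qual) > 0
    clir <- colSums(qual & contacts) > 0
  } else stop("focal_chain must be 1 or 2")
  structure(
    data.frame(position = seq_along(lir), lir = unname(lir), clir = unname(clir)),
    pair_id = scores$pair_id,
    n_contacts = sum(contacts),
    class = c("residue_flags", "data.frame")
  )
}

#' Aggregate per-partner flags into a residue interface profile
#'
#' One representative (rank-1) model per partner pair is expected.  Partners
#' whose model has no inter-chain contact are dropped from the denominator;
#' if none remain, the percentages are missing (`NA`), not zero.
#'
#' @param flags_list List of [residue_flags()] for the same focal protein.
#' @param min_contacts Minimum number of contacting pairs a model must have
#'   to contribute (default 1).
#' @param gene Optional gene/protein identifier stored on the result.
#' @param sequence Optional one-letter sequence of the focal protein; when
#'   given, an `aa` column is added.
#' @return Data frame (`residue_profile`) with columns `position`,
#'   optionally `aa`, `lir_pct`, `clir_pct` (0..100) and attribute
#'   `n_models`.
#' @export
aggregate_profiles <- function(flags_list, min_contacts = 1, gene = NULL,
                               sequence = NULL) {
  if (length(flags_list) == 0) stop("no residue_flags supplied")
  lens <- vapply(flags_list, nrow, integer(1))
  if (length(unique(lens)) != 1)
    stop("residue_flags differ in focal-chain length; not the same protein")
  keep <- vapply(flags_list, function(f) attr(f, "n_contacts") >= min_contacts,
                 logical(1))
  used <- flags_list[keep]
  n <- lens[1]
  if (length(used) == 0) {
    lir_pct <- clir_pct <- rep(NA_real_, n)
  } else {
    lir_pct <- 100 * rowMeans(matrix(unlist(lapply(used, `[[`, "lir")), nrow = n))
    clir_pct <- 100 * rowMeans(matrix(unlist(lapply(used, `[[`, "clir")), nrow = n))
  }
  out <- data.frame(position = seq_len(n))
  if (!is.null(sequence)) {
    if (nchar(sequence) != n) stop("sequence length does not match flag length")
    out$aa <- strsplit(sequence, "")[[1]]
  }
  out$lir_pct <- lir_pct
  out$clir_pct <- clir_pct
  structure(out, gene = gene, n_models = length(used),
            class = c("residue_profile", "data.frame"))
}
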