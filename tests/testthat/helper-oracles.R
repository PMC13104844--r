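# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (explicit double loops, direct formulas) so they share
# no code path with the implementation they check.

# per-entry enumeration of LIS/cLIS-style block means over both PAE
# directions; contacts = NULL disables the contact mask (plain LIS)
oracle_lis <- function(pae, n_a, contacts = NULL, cutoff = 12) {
  n <- nrow(pae)
  ab <- c(); ba <- c(); n_q <- 0L
  for (i in seq_len(n_a)) for (j in seq.int(n_a + 1L, n)) {
    ok <- if (is.null(contacts)) TRUE else contacts[i, j - n_a]
    if (ok && pae[i, j] <= cutoff) { ab <- c(ab, (cutoff - pae[i, j]) / cutoff); n_q <- n_q + 1L }
    if (ok && pae[j, i] <= cutoff) { ba <- c(ba, (cutoff - pae[j, i]) / cutoff); n_q <- n_q + 1L }
  }
  m_ab <- if (length(ab)) mean(ab) else 0
  m_ba <- if (length(ba)) mean(ba) else 0
  list(score = (m_ab + m_ba) / 2, n_qual = n_q)
}

oracle_ifpae <- function(pae, n_a, contacts = NULL) {
  n <- nrow(pae)
  vals <- c()
  for (i in seq_len(n_a)) for (j in seq.int(n_a + 1L, n)) {
    ok <- if (is.null(contacts)) TRUE else contacts[i, j - n_a]
    if (ok) vals <- c(vals, pae[i, j], pae[j, i])
  }
  if (length(vals)) mean(vals) else NA_real_
}

# random score bundle + contact mask for oracle-equivalence sweeps
random_bundle <- function(n_a = 15, n_b = 15, seed = 1, pae_max = 31.75) {
  set.seed(seed)
  n <- n_a + n_b
  pae <- matrix(runif(n * n, 0, pae_max), n, n)
  diag(pae) <- 0
  list(
    scores = score_bundle(paste0("rand", seed), 1, pae,
                          ptm = runif(1), iptm = runif(1),
                          plddt = runif(n, 20, 100)),
    contacts = matrix(runif(n_a * n_b) < 0.2, n_a, n_b),
    n_a = n_a
  )
}

# adjusted Rand index from the contingency-table closed form
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# exhaustive set partitions of 1..n (for the modularity oracle)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  prev <- all_partitions(n - 1)
  out <- list()
  for (p in prev) {
    k <- max(p)
    for (c in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(p, c)
  }
  out
}

# direct-summation modularity oracle on an edge list
oracle_modularity <- function(el, n_nodes, memb, gamma = 1) {
  m <- nrow(el)
  deg <- tabulate(c(el[, 1], el[, 2]), n_nodes)
  q <- 0
  for (c in unique(memb)) {
    e_c <- sum(memb[el[, 1]] == c & memb[el[, 2]] == c)
    d_c <- sum(deg[memb == c])
    q <- q + e_c / m - gamma * (d_c / (2 * m))^2
  }
  q
}

# tiny deterministic residue table for enrichment unit tests
toy_residue_table <- function() {
  data.frame(
    gene = rep(c("gA", "gB"), each = 6),
    position = rep(1:6, 2),
    aa = rep("A", 12),
    lir_pct = c(0, 0, 10, 20, 30, 40, 0, 5, 15, 25, 35, 45),
    clir_pct = c(0, 0, 5, 10, 20, 30, 0, 0, 10, 15, 25, 40),
    phylop = seq(-1, 1.2, length.out = 12),
    mutated = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE,
                FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}
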