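test_that("global alignment: identity, insertion, and DP oracle on a small grid", {
  al <- global_align("ACDE", "ACDE")
  expect_equal(al$score, 4)
  expect_identical(al$map_ab, 1:4)
  # one-letter insertion: D at position 3 maps to position 4
  al2 <- global_align("ACDE", "ACXDE")
  expect_identical(al2$map_ab[3], 4L)
  expect_identical(al2$map_ab[4], 5L)
  # empty vs nonempty is an all-gap alignment
  al3 <- global_align("", "ACD")
  expect_equal(al3$score, -3)
  expect_true(all(is.na(al3$pairs$i)))
  expect_error(global_align("AC1", "AC"), "non-amino-acid")

  # exhaustive DP oracle over every cell of the 4x5 grid
  a <- "ACDE"; b <- "ACXDE"
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  S <- matrix(NA_real_, 5, 6); S[1, ] <- -(0:5); S[, 1] <- -(0:4)
  for (i in 1:4) for (j in 1:5)
    S[i + 1, j + 1] <- max(S[i, j] + ifelse(av[i] == bv[j], 1, -1),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  expect_equal(global_align(a, b)$score, S[5, 6])
})

test_that("mutation mapping: exact, alignment-corrected, and rejections", {
  model <- "MKLVNPQRST"
  expect_identical(map_mutation("g", 4, "V", model),
                   list(accepted = TRUE, position = 4L, reason = "exact"))
  # annotation has a one-residue N-terminal insertion relative to the model:
  # annotation position 5 (V) must land at model position 4
  ann <- paste0("X", model)  # not a real AA... use alanine instead
  ann <- paste0("A", model)
  mp <- map_mutation("g", 5, "V", model, annotation_sequence = ann)
  expect_true(mp$accepted)
  expect_identical(mp$position, 4L)
  expect_identical(mp$reason, "aligned")
  # ref mismatch after alignment -> rejected
  expect_false(map_mutation("g", 5, "W", model, annotation_sequence = ann)$accepted)
  # out of range
  expect_identical(map_mutation("g", 99, "V", model)$reason, "out_of_range")
  # annotation residue aligned to a gap in the model
  ann2 <- "MKLVVVNPQRST"  # two extra V: positions 5,6 align partly to gaps
  mp2 <- map_mutation("g", 6, "V", model, annotation_sequence = ann2)
  expect_true(mp2$reason %in% c("gap", "ref_mismatch", "aligned"))
})

test_that("build_residue_table joins profiles, mutations, conservation", {
  prof <- function(aas, lir, clir) {
    structure(data.frame(position = seq_along(lir),
                         aa = strsplit(aas, "")[[1]],
                         lir_pct = lir, clir_pct = clir),
              class = c("residue_profile", "data.frame"))
  }
  profiles <- list(gA = prof("MKLV", c(0, 10, 20, 0), c(0, 5, 20, 0)),
                   gB = prof("TRP", c(50, 0, 25), c(25, 0, 0)))
  muts <- data.frame(gene = c("gA", "gA", "gB", "gC", "gA"),
                     position = c(2, 2, 3, 1, 4),
                     ref_aa = c("K", "K", "P", "M", "W"))
  cons <- data.frame(gene = "gA", position = 1:4, phylop = c(1, 2, 3, 4))
  tab <- build_residue_table(profiles, muts, cons)
  expect_identical(nrow(tab), 7L)
  expect_identical(tab$mutated, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  # duplicate (gene, position) counted once; unknown gene and ref mismatch rejected
  expect_identical(attr(tab, "n_rejected"), 2L)
  expect_equal(tab$phylop[1:4], 1:4)
  expect_true(all(is.na(tab$phylop[5:7])))
})

test_that("bin_by_lir: quartile edges, Zero bin, degenerate ties", {
  tab <- data.frame(gene = "g", position = 1:6, aa = "A",
                    lir_pct = c(0, 0, 10, 20, 30, 40),
                    clir_pct = 0, phylop = NA, mutated = FALSE)
  b <- bin_by_lir(tab, "lir_pct")
  # percentile oracle: edges of {10,20,30,40} at type-7 quantiles
  expect_equal(attr(b, "edges"), unname(quantile(c(10, 20, 30, 40), c(.25, .5, .75))))
  expect_identical(as.character(b$bin), c("Zero", "Zero", "Q1", "Q2", "Q3", "Q4"))
  # adding a Zero residue moves no edge
  b2 <- bin_by_lir(rbind(tab, within(tab[1, ], position <- 7)), "lir_pct")
  expect_equal(attr(b2, "edges"), attr(b, "edges"))
  # all nonzero equal: every nonzero residue lands in Q1 (right-closed edges)
  tied <- within(tab, lir_pct <- c(0, 0, 7, 7, 7, 7))
  bt <- bin_by_lir(tied, "lir_pct")
  expect_identical(as.character(bt$bin), c("Zero", "Zero", rep("Q1", 4)))
  # all zero: warning, Zero only
  expect_warning(bz <- bin_by_lir(within(tab, lir_pct <- 0), "lir_pct"), "Zero")
  expect_true(all(bz$bin == "Zero"))
  # domain_only restricts to lir_pct > 0 first
  bd <- suppressWarnings(bin_by_lir(tab, "clir_pct", domain_only = TRUE))
  expect_identical(nrow(bd), 4L)
  # bins partition the residue set
  expect_identical(sum(table(b$bin)), nrow(tab))
})

test_that("enrichment rates and folds match counting oracles", {
  tab <- toy_residue_table()
  b <- bin_by_lir(tab, "lir_pct")
  er <- enrichment_rates(b)
  expect_identical(sum(er$bins$n_residues), nrow(tab))
  expect_identical(sum(er$bins$n_mutated), sum(tab$mutated))
  for (k in seq_len(nrow(er$bins))) {
    sel <- as.character(b$bin) == er$bins$bin[k]
    expect_equal(er$bins$rate[k], mean(b$mutated[sel]))
  }
  # fold ratio example: 1/1000 vs 6/1000 -> 6.0
  fake <- data.frame(gene = "g", lir_pct = rep(c(0, 1, 50, 75, 99), c(1000, 250, 250, 250, 250)),
                     clir_pct = 0, mutated = FALSE)
  fake$mutated[1] <- TRUE                       # Zero bin: 1/1000
  fake$mutated[fake$lir_pct == 99][1:6] <- TRUE # Q4: 6/250
  fb <- enrichment_rates(bin_by_lir(fake, "lir_pct"))
  expect_equal(fb$bins$fold_vs_zero[fb$bins$bin == "Q4"], (6 / 250) / (1 / 1000))
  # three-category split
  expect_identical(er$categories$bin, c("No LIR", "LIR-cLIR", "cLIR"))
  expect_identical(sum(er$categories$n_residues), nrow(tab))
})

test_that("Cochran-Armitage matches the direct formula and is antisymmetric", {
  mut <- c(1, 2, 3); tot <- c(100, 100, 100); s <- 0:2
  got <- cochran_armitage(mut, tot, s)
  # direct formula oracle
  N <- 300; M <- 6; p <- M / N
  T_ <- sum(s * (mut - tot * p))
  v <- M * (N - M) / (N - 1) * (sum(tot * s^2) / N - (sum(tot * s) / N)^2)
  expect_equal(got$Z, T_ / sqrt(v), tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(got$Z)))
  # reversing bin order flips the sign
  rev_z <- cochran_armitage(rev(mut), rev(tot), s)$Z
  expect_equal(rev_z, -got$Z, tolerance = 1e-12)
  # no trend -> Z ~ 0
  expect_lt(abs(cochran_armitage(c(5, 5, 5), tot, s)$Z), 1e-10)
  # relation to R's prop.trend.test: binomial vs hypergeometric variance
  # differ by the finite-population factor, Z^2 = chi^2 * (N-1)/N
  pt <- suppressWarnings(prop.trend.test(mut, tot, s))
  expect_equal(got$Z^2, unname(pt$statistic) * (N - 1) / N, tolerance = 1e-10)
  expect_error(cochran_armitage(c(0, 0), c(10, 10)), "degenerate")
})

test_that("within-gene permutation preserves counts and detects planted trends", {
  md <- make_mutation_dataset(n_genes = 15, res_per_gene = 80, beta0 = -3,
                              beta1 = 0.05, seed = 21)
  b <- bin_by_lir(md$table, "clir_pct")
  stat <- trend_statistic()
  # permutation preserves per-gene and total mutation counts: instrument the
  # statistic to record them
  counts <- list()
  probe <- function(tab) {
    counts[[length(counts) + 1L]] <<- tapply(tab$mutated, tab$gene, sum)
    stat(tab)
  }
  res <- within_gene_permutation(b, probe, n_perm = 20, seed = 3)
  base <- tapply(b$mutated, b$gene, sum)
  for (ct in counts[-1]) expect_identical(ct, base)
  # planted strong effect -> extreme tail
  strong <- within_gene_permutation(b, stat, n_perm = 99, seed = 3)
  expect_equal(strong$p, 1 / 100)
  # single gene, single bin -> constant statistic is an error from CA
  # (degenerate table); a one-bin table cannot produce a trend
  one <- data.frame(gene = "g", position = 1:10, lir_pct = 0, clir_pct = 0,
                    mutated = c(TRUE, rep(FALSE, 9)))
  suppressWarnings(one_b <- bin_by_lir(one, "lir_pct"))
  expect_error(stat(one_b), "at least 2 bins")
  # error when a gene has more mutations than residues
  bad <- b[1:3, ]; bad$mutated <- TRUE; bad$gene <- "tiny"
  bad2 <- rbind(b, bad)
  expect_error(within_gene_permutation(bad2[bad2$gene == "tiny", ],
                                       function(t) 0, n_perm = 1),
               NA)  # 3 mutations in 3 residues is still feasible
  # reproducibility under a fixed seed
  r1 <- within_gene_permutation(b, stat, n_perm = 50, seed = 8)
  r2 <- within_gene_permutation(b, stat, n_perm = 50, seed = 8)
  expect_identical(r1$perm_stats, r2$perm_stats)
})

test_that("conservation analysis recovers planted coefficients", {
  md <- make_mutation_dataset(n_genes = 60, res_per_gene = 300, beta0 = -5,
                              beta1 = 0.03, beta2 = 0, seed = 31)
  ca <- conservation_analysis(md$table)
  b1 <- ca$fit$estimate[ca$fit$term == "clir"]
  se1 <- ca$fit$se[ca$fit$term == "clir"]
  expect_lt(abs(b1 - 0.03), 1.96 * se1 * 1.5)
  b2 <- ca$fit$estimate[ca$fit$term == "phylop"]
  expect_lt(abs(b2), 0.3)                      # beta2 = 0 recovered near zero
  expect_false(ca$penalized)
  # attenuation ~ 0 when PhyloP is independent of cLIR
  expect_lt(abs(ca$attenuation), 0.15)
  # grid-search likelihood oracle on a small table (clir-only model)
  set.seed(5)
  small <- data.frame(gene = "g", clir_pct = rep(c(0, 100), each = 50),
                      phylop = rnorm(100),
                      mutated = runif(100) < rep(c(0.05, 0.3), each = 50))
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * small$clir_pct)
    sum(dbinom(small$mutated, 1, p, log = TRUE))
  }
  grid <- expand.grid(b0 = seq(-5, 0, 0.01), b1 = seq(0, 0.1, 0.0005))
  best <- grid[which.max(mapply(ll, grid$b0, grid$b1)), ]
  ca_small <- conservation_analysis(small)
  expect_lt(abs(ca_small$fit_clir_only$estimate[2] - best$b1), 1e-3)  # grid step
  expect_lt(abs(ca_small$fit_clir_only$estimate[1] - best$b0), 2e-2)
  # constant clir -> inestimable
  const <- within(md$table, clir_pct <- 0)
  expect_error(conservation_analysis(const), "constant")
  # strata cover all rows with phylop
  expect_identical(sum(ca$strata$n), sum(!is.na(md$table$phylop)))
})
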