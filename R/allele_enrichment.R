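# Mapping of missense mutations onto predicted structures and enrichment of
# mutated residues at predicted interaction domains (LIR) and contact
# interfaces (cLIR): binning, Cochran-Armitage trend, within-gene permutation
# nulls, conservation stratification and logistic regression.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y","X")

#' Needleman-Wunsch global alignment
#'
#' Identity scoring (match +1, mismatch -1, linear gap -1) with a
#' deterministic traceback: on ties prefer diagonal, then up (gap in `b`),
#' then left (gap in `a`).
#'
#' @param a,b One-letter amino-acid sequences (strings).
#' @param match,mismatch,gap Scoring parameters.
#' @return List with `score`, `pairs` (data frame of aligned indices `i` in
#'   `a` and `j` in `b`, `NA` at gaps) and `map_ab`: integer vector of length
#'   `nchar(a)` giving the position in `b` aligned to each position of `a`
#'   (`NA` when aligned to a gap).
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) && !all(av %in% AA_ALPHABET))
    stop("non-amino-acid character in first sequence")
  if (length(bv) && !all(bv %in% AA_ALPHABET))
    stop("non-amino-acid character in second sequence")
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  if (n > 0 && m > 0) {
    sub <- outer(av, bv, function(x, y) ifelse(x == y, match, mismatch))
    for (i in 1:n) for (j in 1:m)
      S[i + 1, j + 1] <- max(S[i, j] + sub[i, j], S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  # traceback, tie order: diagonal > up > left
  i <- n; j <- m
  pi <- integer(0); pj <- integer(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + sub[i, j]) {
      pi <- c(i, pi); pj <- c(j, pj); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      pi <- c(i, pi); pj <- c(NA, pj); i <- i - 1
    } else {
      pi <- c(NA, pi); pj <- c(j, pj); j <- j - 1
    }
  }
  map_ab <- rep(NA_integer_, n)
  al <- !is.na(pi) & !is.na(pj)
  map_ab[pi[al]] <- as.integer(pj[al])
  list(score = S[n + 1, m + 1],
       pairs = data.frame(i = as.integer(pi), j = as.integer(pj)),
       map_ab = map_ab)
}

#' Map one missense mutation onto a model sequence
#'
#' Exact position matching first: accept if the model residue at the stated
#' position equals the reference amino acid.  Otherwise, when an annotation
#' (isoform) sequence is supplied, align it globally to the model sequence
#' and transfer the position through the alignment; accept only if the model
#' residue at the transferred position still equals the reference.
#'
#' @param gene Gene identifier (carried through).
#' @param position 1-based position in the annotation coordinate system.
#' @param ref_aa One-letter reference amino acid.
#' @param model_sequence Sequence of the predicted model.
#' @param annotation_sequence Optional isoform sequence the position refers
#'   to, used for alignment-based correction.
#' @return List with `accepted` (logical), `position` (mapped position in
#'   the model, `NA` when rejected) and `reason` (`"exact"`, `"aligned"`,
#'   `"out_of_range"`, `"gap"`, `"ref_mismatch"`).
#' @export
map_mutation <- function(gene, position, ref_aa, model_sequence,
                         annotation_sequence = NULL) {
  n <- nchar(model_sequence)
  if (position >= 1 && position <= n &&
      substr(model_sequence, position, position) == ref_aa)
    return(list(accepted = TRUE, position = as.integer(position), reason = "exact"))
  if (is.null(annotation_sequence)) {
    reason <- if (position < 1 || position > n) "out_of_range" else "ref_mismatch"
    return(list(accepted = FALSE, position = NA_integer_, reason = reason))
  }
  if (position < 1 || position > nchar(annotation_sequence))
    return(list(accepted = FALSE, position = NA_integer_, reason = "out_of_range"))
  al <- global_align(annotation_sequence, model_sequence)
  mapped <- al$map_ab[position]
  if (is.na(mapped))
    return(list(accepted = FALSE, position = NA_integer_, reason = "gap"))
  if (substr(model_sequence, mapped, mapped) != ref_aa)
    return(list(accepted = FALSE, position = NA_integer_, reason = "ref_mismatch"))
  list(accepted = TRUE, position = as.integer(mapped), reason = "aligned")
}

#' Build the residue table for enrichment analysis
#'
#' Joins residue interface profiles with mapped mutations and optional
#' conservation scores into the flat table the enrichment statistics
#' consume.  Mutations are deduplicated on (gene, position) after mapping;
#' rejected mutations are dropped.
#'
#' @param profiles Named list (by gene) of [aggregate_profiles()] outputs
#'   (must carry an `aa` column).
#' @param mutations Data frame with columns `gene`, `position`, `ref_aa`
#'   (and anything else, carried along); positions in model coordinates or
#'   correctable via `annotation_sequences`.
#' @param conservation Optional data frame `gene`, `position`, `phylop`.
#' @param annotation_sequences Optional named character vector of isoform
#'   sequences per gene for alignment correction.
#' @return Data frame with one row per residue per gene: `gene`, `position`,
#'   `aa`, `lir_pct`, `clir_pct`, `phylop` (`NA` when absent), `mutated`;
#'   attribute `n_rejected` counts discarded mutations.
#' @export
build_residue_table <- function(profiles, mutations, conservation = NULL,
                                annotation_sequences = NULL) {
  stopifnot(!is.null(names(profiles)))
  tabs <- lapply(names(profiles), function(g) {
    p <- profiles[[g]]
    data.frame(gene = g, position = p$position, aa = p$aa,
               lir_pct = p$lir_pct, clir_pct = p$clir_pct,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  tab$phylop <- NA_real_
  if (!is.null(conservation)) {
    key <- paste(tab$gene, tab$position)
    idx <- match(key, paste(conservation$gene, conservation$position))
    tab$phylop <- conservation$phylop[idx]
  }
  tab$mutated <- FALSE
  n_rejected <- 0L
  if (nrow(mutations)) {
    seqs <- vapply(profiles, function(p) paste(p$aa, collapse = ""), character(1))
    seen <- character(0)
    for (r in seq_len(nrow(mutations))) {
      g <- mutations$gene[r]
      if (!g %in% names(seqs)) { n_rejected <- n_rejected + 1L; next }
      mp <- map_mutation(g, mutations$position[r], mutations$ref_aa[r], seqs[[g]],
                         annotation_sequence = annotation_sequences[[g]])
      if (!mp$accepted) { n_rejected <- n_rejected + 1L; next }
      k <- paste(g, mp$position)
      if (k %in% seen) next                 # unique gene-position pairs
      seen <- c(seen, k)
      tab$mutated[tab$gene == g & tab$position == mp$position] <- TRUE
    }
  }
  structure(tab, n_rejected = n_rejected)
}

#' Bin residues by interface frequency
#'
#' Bins: `Zero` (field exactly 0) and `Q1`-`Q4`, the quartile bins of the
#' pooled nonzero distribution across all genes (edges at the 25/50/75th
#' percentiles; intervals left-open, right-closed).  With `domain_only`,
#' the table is first restricted to residues inside a predicted interaction
#' domain (`lir_pct > 0`) — the setting for the cLIR analysis.
#'
#' @param table Residue table from [build_residue_table()].
#' @param field `"lir_pct"` or `"clir_pct"`.
#' @param domain_only Restrict to `lir_pct > 0` before binning.
#' @return The (possibly restricted) table with a `bin` factor column
#'   (levels `Zero`, `Q1`..`Q4`) and attribute `edges`.
#' @export
bin_by_lir <- function(table, field = "lir_pct", domain_only = FALSE) {
  if (!field %in% names(table)) stop("field '", field, "' not present")
  if (domain_only) table <- table[table$lir_pct > 0, , drop = FALSE]
  v <- table[[field]]
  nz <- v[v > 0 & !is.na(v)]
  levels <- c("Zero", "Q1", "Q2", "Q3", "Q4")
  if (length(nz) == 0) {
    warning("all '", field, "' values are zero; only the Zero bin is populated")
    table$bin <- factor(rep("Zero", nrow(table)), levels = levels)
    attr(table, "edges") <- rep(NA_real_, 3)
    return(table)
  }
  edges <- stats::quantile(nz, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  # left-open / right-closed: value in (edge_{k-1}, edge_k] -> Qk; degenerate
  # (all nonzero equal) edges collapse and every nonzero residue lands in Q1
  q <- 1L + (nz_bin <- function(x) (x > edges[1]) + (x > edges[2]) + (x > edges[3]))(v)
  bin <- ifelse(v == 0, "Zero", paste0("Q", q))
  table$bin <- factor(bin, levels = levels)
  attr(table, "edges") <- edges
  table
}

#' Per-bin mutation rates and fold enrichment
#'
#' @param binned Output of [bin_by_lir()].
#' @return List with `bins` (per-bin `n_residues`, `n_mutated`, `rate`,
#'   `fold_vs_zero`) and `categories`: the three-way split No LIR
#'   (`lir_pct == 0`), LIR-cLIR (`lir_pct > 0`, `clir_pct == 0`) and cLIR
#'   (`clir_pct > 0`) with the same columns.
#' @export
enrichment_rates <- function(binned) {
  per_bin <- function(groups, labels) {
    n <- as.vector(table(factor(groups, levels = labels)))
    mut <- vapply(labels, function(l) sum(binned$mutated[groups == l]), numeric(1))
    rate <- ifelse(n > 0, mut / n, NA_real_)
    data.frame(bin = labels, n_residues = n, n_mutated = as.integer(mut),
               rate = rate, stringsAsFactors = FALSE)
  }
  bins <- per_bin(as.character(binned$bin), levels(binned$bin))
  zero_rate <- bins$rate[bins$bin == "Zero"]
  bins$fold_vs_zero <- if (length(zero_rate) && !is.na(zero_rate) && zero_rate > 0)
    bins$rate / zero_rate else NA_real_
  cat_lab <- ifelse(binned$lir_pct == 0, "No LIR",
                    ifelse(binned$clir_pct == 0, "LIR-cLIR", "cLIR"))
  cats <- per_bin(cat_lab, c("No LIR", "LIR-cLIR", "cLIR"))
  base <- cats$rate[cats$bin == "No LIR"]
  cats$fold_vs_nolir <- if (length(base) && !is.na(base) && base > 0)
    cats$rate / base else NA_real_
  list(bins = bins, categories = cats)
}

#' Cochran-Armitage trend test
#'
#' Trend statistic `T = sum_i s_i (m_i - n_i p)` with `p` the pooled
#' mutation rate, standardized by its variance under the hypergeometric
#' (permutation) null conditional on both margins:
#' `Var(T) = M (N - M) / (N - 1) * Var_pop(s)`.
#'
#' @param mutated Per-bin mutated counts.
#' @param totals Per-bin residue totals.
#' @param scores Per-bin trend scores, default equally spaced `0..k-1`.
#' @return List with `Z` and the normal-approximation two-sided `p`.
#' @export
cochran_armitage <- function(mutated, totals, scores = seq_along(totals) - 1) {
  keep <- totals > 0
  mutated <- mutated[keep]; totals <- totals[keep]; scores <- scores[keep]
  if (length(totals) < 2) stop("need at least 2 bins with nonzero totals")
  N <- sum(totals); M <- sum(mutated)
  if (M == 0 || M == N) stop("degenerate table: no variation in mutation status")
  p <- M / N
  T_stat <- sum(scores * (mutated - totals * p))
  var_pop <- sum(totals * scores^2) / N - (sum(totals * scores) / N)^2
  v <- M * (N - M) / (N - 1) * var_pop
  if (v <= 0) stop("zero trend variance (degenerate scores)")
  z <- T_stat / sqrt(v)
  list(Z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Trend statistic closure for permutation testing
#'
#' Returns a function mapping a residue table (with a precomputed `bin`
#' column) to the Cochran-Armitage Z across bins — the default permutation
#' statistic.
#'
#' @param levels Bin levels in trend order.
#' @return `function(table) -> Z`.
#' @export
trend_statistic <- function(levels = c("Zero", "Q1", "Q2", "Q3", "Q4")) {
  force(levels)
  function(table) {
    g <- factor(as.character(table$bin), levels = levels)
    totals <- as.vector(table(g))
    mutated <- vapply(levels, function(l) sum(table$mutated[g == l]), numeric(1))
    cochran_armitage(mutated, totals)$Z
  }
}

#' Within-gene permutation test
#'
#' Each permutation reassigns every gene's mutated positions uniformly at
#' random (without replacement) among that gene's residues, preserving the
#' per-gene mutation count — a null that controls for gene-level
#' ascertainment bias.  The p-value uses the add-one estimator
#' `p = (1 + #\{perm >= obs\}) / (1 + n_perm)` and is one-sided in the
#' enrichment direction by default.
#'
#' @param table Residue table; any precomputed columns (e.g. `bin`) are kept
#'   so the statistic need not recompute them.
#' @param statistic Function of the (permuted) table returning one number;
#'   default [trend_statistic()].
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return List with `p`, `observed` and `perm_stats`.
#' @export
within_gene_permutation <- function(table, statistic = trend_statistic(),
                                    n_perm = 1000, seed = 1,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 1)
  observed <- statistic(table)
  idx_by_gene <- split(seq_len(nrow(table)), table$gene)
  m_by_gene <- vapply(idx_by_gene, function(i) sum(table$mutated[i]), integer(1))
  bad <- m_by_gene > lengths(idx_by_gene)
  if (any(bad)) stop("gene with more mutations than residues: ",
                     paste(names(idx_by_gene)[bad], collapse = ", "))
  set.seed(seed)
  perm_stats <- numeric(n_perm)
  mut <- logical(nrow(table))
  for (b in seq_len(n_perm)) {
    mut[] <- FALSE
    for (g in seq_along(idx_by_gene)) {
      m <- m_by_gene[g]
      if (m > 0) mut[sample(idx_by_gene[[g]], m)] <- TRUE
    }
    table$mutated <- mut
    perm_stats[b] <- statistic(table)
  }
  p <- if (alternative == "greater")
    (1 + sum(perm_stats >= observed)) / (1 + n_perm)
  else
    (1 + sum(abs(perm_stats) >= abs(observed))) / (1 + n_perm)
  list(p = p, observed = observed, perm_stats = perm_stats)
}

# ridge-penalized logistic IRLS fallback for separated data
penalized_logit <- function(X, y, lambda = 1e-4, tol = 1e-8, max_iter = 100) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0   # do not penalize intercept
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  eta <- drop(X %*% beta); mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  cov <- solve(t(X * w) %*% X + pen)
  list(coef = beta, se = sqrt(diag(cov)))
}

#' Conservation-stratified enrichment and adjusted regression
#'
#' Residues are stratified into pooled PhyloP quartiles; within each stratum
#' the contact-interface fold enrichment (mutation rate at `clir_pct > 0` vs
#' `clir_pct == 0`) is reported.  A logistic regression
#' `mutated ~ clir_pct + phylop` (maximum likelihood, IRLS, convergence
#' 1e-8) quantifies the interface effect adjusted for conservation; the
#' attenuation fraction is `1 - beta_clir(adjusted) / beta_clir(cLIR-only)`,
#' the share of the unadjusted interface effect absorbed by conservation.
#'
#' @param table Residue table with `phylop` (rows lacking it are excluded
#'   and counted), `clir_pct`, `mutated`.
#' @param clir_binary Code cLIR as an indicator (`clir_pct > 0`) instead of
#'   the continuous percentage.
#' @return List: `strata` (per-quartile fold table), `fit` (coefficients,
#'   SEs, Wald z and p for the adjusted model), `fit_clir_only`,
#'   `attenuation`, `n_excluded`, `penalized` (TRUE when the ridge fallback
#'   was needed).
#' @export
conservation_analysis <- function(table, clir_binary = FALSE) {
  n_excluded <- sum(is.na(table$phylop))
  tab <- table[!is.na(table$phylop), , drop = FALSE]
  if (nrow(tab) == 0) stop("no rows with PhyloP scores")
  clir <- if (clir_binary) as.numeric(tab$clir_pct > 0) else tab$clir_pct
  if (stats::var(clir) == 0)
    stop("clir covariate is constant; interface coefficient inestimable")

  qs <- stats::quantile(tab$phylop, c(0.25, 0.5, 0.75), names = FALSE)
  stratum <- 1L + (tab$phylop > qs[1]) + (tab$phylop > qs[2]) + (tab$phylop > qs[3])
  strata <- do.call(rbind, lapply(1:4, function(s) {
    i <- stratum == s
    at <- tab$clir_pct[i] > 0
    r1 <- mean(tab$mutated[i][at]); r0 <- mean(tab$mutated[i][!at])
    data.frame(stratum = paste0("P", s), n = sum(i),
               rate_interface = r1, rate_noninterface = r0,
               fold = if (!is.na(r0) && r0 > 0) r1 / r0 else NA_real_)
  }))

  fit_one <- function(X) {
    y <- as.numeric(tab$mutated)
    fit <- suppressWarnings(stats::glm.fit(X, y,
      family = stats::binomial(), control = list(epsilon = 1e-8, maxit = 100)))
    separated <- !fit$converged ||
      any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
    if (separated) {
      pf <- penalized_logit(X, y)
      list(coef = pf$coef, se = pf$se, penalized = TRUE)
    } else {
      cov <- tryCatch(solve(t(X * fit$weights) %*% X), error = function(e) NULL)
      if (is.null(cov)) {
        pf <- penalized_logit(X, y)
        return(list(coef = pf$coef, se = pf$se, penalized = TRUE))
      }
      list(coef = fit$coefficients, se = sqrt(diag(cov)), penalized = FALSE)
    }
  }
  X_adj <- cbind(intercept = 1, clir = clir, phylop = tab$phylop)
  X_only <- cbind(intercept = 1, clir = clir)
  adj <- fit_one(X_adj)
  only <- fit_one(X_only)
  mk <- function(f, names) data.frame(
    term = names, estimate = unname(f$coef), se = unname(f$se),
    z = unname(f$coef / f$se),
    p = 2 * stats::pnorm(-abs(unname(f$coef / f$se))),
    stringsAsFactors = FALSE)
  attenuation <- if (only$coef[2] != 0) 1 - adj$coef[2] / only$coef[2] else NA_real_
  list(strata = strata,
       fit = mk(adj, c("(Intercept)", "clir", "phylop")),
       fit_clir_only = mk(only, c("(Intercept)", "clir")),
       attenuation = attenuation,
       n_excluded = n_excluded,
       penalized = adj$penalized || only$penalized)
}
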