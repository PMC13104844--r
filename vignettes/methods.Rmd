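---
title: "Local interface confidence scoring: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local interface confidence scoring: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilisr)
```

This vignette is the package's own account of the science it implements:
the scoring model and its assumptions, the statistical procedures
downstream of it, the parameters that matter, and the places where the
design was genuinely open and a choice had to be made. It states no
empirical result that the test suite does not itself compute.

## 1. The scoring model

AlphaFold-Multimer emits, per predicted dimer model, a square PAE matrix
$E$ (entry $E_{ij}$ = expected positional error, in &Aring;, of residue $j$
when the model is aligned on residue $i$'s frame; the matrix is
asymmetric), per-residue pLDDT, and the global scores pTM and ipTM. The
package's central scores are built from the two inter-chain blocks of $E$
and from C&beta; contact geometry:

$$\mathrm{LIS} = \tfrac12\!\left(\overline{r}_{A\to B} + \overline{r}_{B\to A}\right),
\qquad r_{ij} = \frac{12 - E_{ij}}{12}\ \text{for}\ E_{ij} \le 12,$$

where $\overline{r}$ averages the rescaled values over the *qualifying*
entries of a directional block and is defined as 0 when the block has no
qualifying entry. cLIS is the same statistic with the qualifying set
further intersected with the contact set (C&beta;–C&beta; distance
$\le 8$ &Aring;, C&alpha; for glycine; one $A \times B$ mask applied to
both PAE directions), and

$$\mathrm{iLIS} = \sqrt{\mathrm{LIS} \times \mathrm{cLIS}}.$$

Assumptions worth stating explicitly:

- **Dimers only.** All scoring is defined on exactly two chains; a
  homodimer is two identical chains. The readers enforce this.
- **Representative-atom geometry.** Contact detection uses one coordinate
  per residue (C&beta;, or C&alpha; when no C&beta; exists). This is the
  standard contact-map convention; side-chain contact geometry beyond
  C&beta; is deliberately ignored.
- **Empty confident region means non-interaction.** A block with no
  qualifying entries contributes a score of 0, not a missing value. The
  alternative (propagating NA) would make a pair with no confident
  inter-chain signal incomparable rather than negative, which is the wrong
  semantics for large-scale screening.
- **Both PAE directions matter.** LIS/cLIS average the two directional
  block means rather than pooling all entries. The two conventions agree
  whenever the qualifying counts per direction are equal (e.g. every
  uniform or symmetric case); they differ only for asymmetric qualifying
  sets. The choice is isolated in one function (`rescaled_block_mean`
  callers) so it can be flipped; pooling was rejected because averaging
  treats the directions symmetrically regardless of their sizes.

Companion metrics: ifPAE (mean of *all* inter-chain entries, both
directions), ifPAE_d8 (contact-masked mean; missing when the model has no
contact — unlike LIS there is no screening rationale for forcing a
number), Model Confidence $0.8\,\mathrm{ipTM} + 0.2\,\mathrm{pTM}$, and
pDockQ with the published constants $L = 0.724$, $x_0 = 152.611$,
$k = 0.052$, $b = 0.018$ (the source of this metric defines them; they are
adopted verbatim, and the metric is flagged as benchmark-parity only).

Boundary conventions are inclusive throughout: PAE $\le 12$, distance
$\le 8$, classification `score >= threshold`. pLDDT subgroups are
half-open: $[0,50)$, $[50,70)$, $[70,100]$ — the source material prints
"0–50, 50–70, 70–100" without edge handling, so a convention had to be
fixed; it is applied consistently everywhere (scoring, calibration
strata).

### Per-model vs per-pair scores

A prediction set holds up to five ranked models of one pair. `score_pair()`
reports the **best** record (the rank-1 model by the upstream ranking, not
the max-iLIS model — "best" is a property of the predictor's own ranking)
and the **average** record (arithmetic mean of every metric over the
provided models, with the pLDDT subgroup re-derived from the averaged
pLDDT).

## 2. Residue interface profiles

Per model, residue $i$ of the focal chain is **LIR** if
$\min(E_{ij}, E_{ji}) \le 12$ for some partner residue $j$, and **cLIR**
if some such $j$ is additionally in contact with $i$ — both conditions
satisfied by the *same* partner residue, which is what "a contact inside
the confident domain" means; the min-symmetrization says a residue pair is
confidently placed if either direction is confident. Across partners,
`lir_pct`/`clir_pct` are percentages over the contributing models:
one representative (rank-1) model per partner pair, excluding models with
zero inter-chain contacts. Excluding no-contact models keeps the
denominator comparable between well-studied proteins (many predicted
partners, most spurious) and sparsely predicted ones; if no model remains
the percentages are missing, not zero. Using all five ranks per partner
instead of rank 1 is a defensible alternative (it would smooth the
percentages at the cost of pseudo-replicating each partner five times);
the rank-1 convention matches one-representative-per-pair database
semantics.

## 3. Threshold calibration

Thresholds are order statistics of the *control* score distribution: the
threshold at FPR $f$ is the smallest observed control score $t$ with
$\#\{c \ge t\}/n \le f$. With ties, no $t$ may attain $f$; the calibrator
then returns the maximum observed score with its (too-high) achieved FPR
and a warning rather than inventing an unobserved cut point. Because the
threshold is an observed score and classification uses $\ge$, the achieved
FPR can sit slightly below the nominal level — the closest an empirical
distribution gets to "the score at which a fraction $f$ of controls exceed
the threshold".

Defaults: positives are the Y2H positive-reference sets; controls pool the
random-reference set with the GFP and Wg compartment controls (all three
are negatives by construction; a `control_sets` argument restricts the
pool). Thresholds are computed per metric, model choice (best/average),
pLDDT subgroup (plus the pooled total) and FPR level (1%, 5%, 10%).
Lower-is-better metrics (ifPAE, ifPAE_d8) are negated internally and
reported on their natural scale; `classify()` then uses $\le$. Bootstrap
AUC summaries resample pairs with replacement ($B$ configurable, default
1000, seeded); the ROC itself groups tied scores and integrates by the
trapezoidal rule, which makes the AUC exactly the Mann–Whitney statistic.

## 4. Allele enrichment

Mutations are mapped to model sequences by exact position match, falling
back to Needleman–Wunsch global alignment of the annotation isoform to the
model sequence (identity scoring +1/−1, linear gap −1 — the simplest
scheme that resolves coordinate shifts between isoforms; the scoring is a
config constant, not a tuned quantity). Traceback ties break
deterministically diagonal → up → left. A mutation is kept only if the
model residue at the (possibly transferred) position equals the annotated
reference amino acid; (gene, position) pairs are deduplicated.

Residues are binned into **Zero** (interface frequency exactly 0) and
pooled quartiles **Q1–Q4** of the nonzero distribution across all genes
(left-open, right-closed edges at the 25/50/75th percentiles, R type-7
quantiles; pooled rather than per-gene because the analysis reports one
global enrichment, and per-gene quartiles would erase between-gene
differences in interface coverage). If all nonzero values are equal the
edges collapse and every nonzero residue lands in Q1. For contact-level
analyses the table is first restricted to in-domain residues
(`lir_pct > 0`).

The trend statistic is Cochran–Armitage with equally spaced scores and the
**hypergeometric** (conditional-on-margins) variance
$\mathrm{Var}(T) = \frac{M(N-M)}{N-1}\,\mathrm{Var}_{pop}(s)$ — the
variance that matches the permutation null actually used (R's
`prop.trend.test` uses the binomial variant; they differ by the factor
$N/(N-1)$, which a unit test pins down). The permutation null shuffles
each gene's mutated positions uniformly among that gene's residues,
preserving per-gene mutation counts — this is the null of "no positional
preference *within* genes" and controls for gene-level ascertainment
(heavily studied genes have more reported alleles *and* more predicted
partners). The p-value uses the add-one estimator
$(1 + \#\{T^{perm} \ge T^{obs}\})/(1 + B)$, one-sided in the enrichment
direction by default: the scientific question is enrichment, not
depletion, and the add-one form cannot report an exact zero.

Conservation analysis stratifies residues into pooled PhyloP quartiles and
reports the contact-interface fold enrichment within each stratum, plus a
logistic regression `mutated ~ clir_pct + phylop` (IRLS, convergence
1e-8). cLIR enters as the continuous percentage (a binary coding is
exposed as a flag). The **attenuation fraction** is defined as
$1 - \beta_{\mathrm{clir}}^{adj}/\beta_{\mathrm{clir}}^{only}$ — the share
of the unadjusted interface coefficient absorbed when conservation enters
the model; it is the most direct single-number operationalization of "how
much of the interface effect is explained by conservation". On separation
or a singular information matrix the fit falls back to a lightly
ridge-penalized IRLS ($\lambda = 10^{-4}$, intercept unpenalized) and is
flagged `penalized`.

## 5. Network construction and clustering

Edges qualify when confidently predicted (best-model iLIS $\ge 0.223$, the
10%-FPR production threshold) **and** supported by prior evidence
(literature, or ortholog-support score $\ge 4$). Self-loops and duplicate
unordered pairs are dropped. Degree-$<2$ nodes are removed in a **single
pass** (a documented semantics: the removal can create new degree-1 nodes,
which are kept; an iterative mode is available by flag), then the giant
component is extracted.

Clustering is Leiden under the RB-configuration objective. The top level
uses a fixed resolution (default 1.1) and is unconditional — it defines
the coarse map. Below it, each cluster of $\ge 5$ genes is re-clustered
with per-cluster resolution optimization: Leiden at every resolution in
$0.5, 0.6, \ldots, 4.0$ (36 grid points, one seeded run each), and the
candidate maximizing **standard** ($\gamma = 1$) modularity is selected,
ties to the smallest resolution. Standard modularity is used for selection
even though candidates are generated at other resolutions, because the
selection criterion is "highest modularity" without qualifier and a
$\gamma$-dependent criterion would not be comparable across grid points.

A split is kept only if it passes a permutation test: node-to-community
labels are shuffled 100 times preserving community sizes, and the split is
accepted iff the observed modularity strictly exceeds the 95th-smallest
null value (nearest-rank percentile). Accepted sub-clusters are decomposed
once more (sub-sub level) under the same criterion.

**A calibration caveat the user should know.** For a *fixed* partition the
test is exact up to discreteness: the exact null acceptance probability is
$6/101 \approx 0.059$ (observed exchangeable with 100 nulls, strict
inequality against the 95th order statistic), which the acceptance suite
verifies on Erd&#337;s–R&eacute;nyi graphs. For an *optimized* partition
the test is anti-conservative: modularity optimization finds high-Q
partitions even in unstructured random graphs, while label shuffles
destroy any optimized structure, so dense random graphs pass the split
test essentially always. The procedure should therefore be read as
validating that a split is better than size-matched random relabeling —
not as a test against "no community structure". This is a property of the
prescribed procedure itself, reproduced faithfully; sub-sub clusters of
homogeneous regions should be interpreted accordingly.

Term enrichment per cluster is the upper-tail hypergeometric test with
Benjamini–Hochberg correction across terms within the cluster; the default
background is all genes of the full network (configurable — the background
is a modeling choice, and "all assayed genes" would be equally defensible
if that universe were known).

## 6. Synthetic generators: what they emulate, and what a green test shows

The generators produce inputs with exactly the statistical and geometric
structure the methods assume, and return their ground truth:

- `make_toy_complex()` — idealized dimer geometry (straight chains,
  residues 20 &Aring; apart, planted contact pairs moved to 5 &Aring;)
  plus a block-structured PAE. Only distances relative to the 8 &Aring;
  cutoff and PAE values relative to the 12 &Aring; cutoff matter to any
  in-scope computation, so physical realism of the fold is deliberately
  absent. The analytic expected scores are computed from the construction
  parameters, independently of the scoring code. Defaults (interface PAE
  6 &Aring;, background 30 &Aring;, 4 contacts on 10+8 residues) give the
  mid-scale score 0.5.
- `make_benchmark_table()` — positives Beta(5, 2) vs controls Beta(2, 5)
  per metric (well-separated but overlapping classes, AUC ≈ 0.90), labels
  and pLDDT subgroups uniform.
- `make_mutation_dataset()` — planted logit model
  $\mathrm{logit}\,p = \beta_0 + \beta_1\,\mathrm{cLIR\%} +
  \beta_2\,\mathrm{PhyloP}$, with `clir_pct <= lir_pct` by construction,
  about half the residues outside any domain, and PhyloP Gaussian and
  independent of the interface unless a correlation knob is set. The
  recovery experiments use $\beta_0 = -6$, $\beta_1 = 0.02$ (a baseline
  rate of a few per thousand and roughly a 7-fold effect across the cLIR
  range — the order of magnitude a genome-scale allele screen exhibits),
  200 genes × 500 residues.
- `make_planted_graph()` — stochastic block model with an optional
  two-level hierarchy ($p_{in}$ within blocks, $p_{mid}$ between blocks of
  one super-block, $p_{out}$ across), evidence columns arranged so every
  planted edge passes the filter and decoys fail it.

What a green test does **not** establish: real PAE matrices have
correlated, domain-structured error patterns, not i.i.d. blocks; real
benchmark score distributions are not Beta; real mutation ascertainment is
far more structured than a logit in two covariates; and real PPI networks
are not SBMs. The tests establish that the *computations* are correct
(oracle equivalence, analytic fixtures) and that the *statistical
procedures* are calibrated and powerful in a world that satisfies their
assumptions — not that the science of any particular dataset is settled.

## 7. Numerical choices and degenerate inputs

- Quantiles everywhere are R type 7; bin edges left-open/right-closed.
- `fpr_threshold()` on all-tied controls returns the tied value with
  achieved FPR 1.0 and a warning (no unobserved cut point is invented).
- Cochran–Armitage errors on degenerate tables (no variation in mutation
  status, or zero score variance) rather than returning 0/0.
- `aggregate_profiles()` with no contributing model returns missing
  percentages and `n_models = 0`, never zeros.
- Leiden runs are seeded through R's RNG; identical seeds and inputs give
  identical partitions and trees (asserted by tests). Resolution-grid ties
  break to the smallest resolution; a tolerance of $10^{-12}$ guards the
  argmax against float noise.
- PAE matrices are stored exactly as read (no symmetrization at read
  time, no cap on values); every symmetrization downstream is explicit
  (`pmin` of the two directions in the residue-flag predicate).
- The PDB writer emits only CA/CB records at 3-decimal precision; a
  round-trip is exact to 0.01 &Aring;, which is far below the 8 &Aring;
  contact scale.

## 8. Known limitations

- Dimers only; no higher-order assemblies, ligands, heteroatoms or
  post-translational modifications.
- The mmCIF reader handles the whitespace-delimited `_atom_site` loop
  dialect (which covers AFM/ColabFold output), not the full CIF grammar.
- The split-test anti-conservativeness for optimized partitions described
  in section 5.
- Externally defined comparator metrics (ipSAE, actifpTM, pDockQ2) are out
  of scope; pDockQ is included for benchmark parity only.
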