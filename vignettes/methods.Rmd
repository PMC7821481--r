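---
title: "Models and methods behind the tidyexpr verb grammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the tidyexpr verb grammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidyexpr)
```

tidyexpr organises a bulk RNA-seq analysis around a single data structure —
a long-format tibble with one record per (sample, transcript) pair — and a
vocabulary of verbs that consume and return it. This vignette explains the
statistical models each verb implements, the tunable parameters and their
defaults, the numerical choices made where the methods leave room, and what
the synthetic-data generators do and do not emulate.

## The data model

A `tidy_expression_table` is a tibble carrying three registered key columns
(sample id, transcript id, abundance) plus arbitrary annotation columns,
and an *internals* store that travels with the object by value: scaling
factors, the fitted batch model, embedding diagnostics, differential fits,
and the ordered invocation log from which `get_bibliography()` assembles
citations. Key invariants, enforced at construction: each (sample,
transcript) pair occurs at most once, raw abundance is non-negative, and
key names resolve. Identifiers are compared as exact strings; no trimming
or case folding is applied.

Whether a column is sample-wise or transcript-wise is inferred on demand —
a column is element-wise exactly when it takes a single value within every
element group — so no separate schema declaration exists, and a column that
varies within a sample is silently treated as non-sample-wise by
`pivot_sample()`. Every verb obeys the action-mode contract: `add` returns
the full table with new columns broadcast onto matching records (identical
row count; the *endomorphism* property that makes pipes compose), `get`
returns the element-wise pivot with the new columns joined, and `only`
returns just the new columns keyed by element id.

Two core-frame choices deserve a note. `aggregate_duplicates()` sums (or
takes the median of) counts sharing an aggregation key — summing is the
physically meaningful default for reads split across isoforms — and
collapses annotations by keeping constants and comma-joining the rest.
`impute_missing_abundance()` fills a missing (sample, transcript) pair with
the *group-wise median* of observed values, rounded half-up, falling back
to 0 when the transcript is unseen in the whole group; the median is robust
and integer-preserving where a mean would be neither. Imputed records are
flagged in an `imputed` column so downstream analyses can exclude them —
the flag costs one column and removes any ambiguity about data provenance.

## Scaling: TMM factors and log-CPM

`scale_abundance()` removes depth differences with trimmed-mean-of-M-values
(TMM) scaling factors computed natively. Against a reference sample r (the
sample whose 75th-percentile CPM is closest to the mean 75th-percentile
CPM), each sample k contributes gene-wise log-ratios
$M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r}$, average abundances
$A_g = \tfrac12\log_2\!\big(\tfrac{y_{gk}}{N_k}\tfrac{y_{gr}}{N_r}\big)$
and delta-method variances
$v_g = \frac{N_k-y_{gk}}{N_k y_{gk}} + \frac{N_r-y_{gr}}{N_r y_{gr}}$.
Genes with a zero in either sample are excluded; the most extreme 30% of M
values and 5% of A values are trimmed on both sides (the method's published
defaults); the factor is the precision-weighted mean
$f_k = 2^{\sum M_g/v_g \,/\, \sum 1/v_g}$ over surviving genes. Weighting
by the *inverse* variance is essential — weighting by $v_g$ itself would
up-weight the noisiest genes. Factors are rescaled to geometric mean 1, and
scaled counts are $y_{gk}/(N_k f_k)$ times the geometric mean of effective
library sizes, so they stay near raw magnitude. Factors are estimated on
abundant transcripts only but applied to all. A matched unit test verifies
equality with edgeR's `calcNormFactors` to below 1e-10.

`identify_abundant()` implements a count-based rule stated explicitly so it
is testable: CPM cutoff `min_count / median(lib_size) * 1e6`; required
number of passing samples equal to the smallest group size $n_{min}$, or
$10 + 0.7\,(n_{min}-10)$ when $n_{min} > 10$ (large groups can tolerate a
minority of silent samples); plus a total-count floor (`min_total`, 15).
The rule is monotone in `min_count`. `keep_variable()` ranks transcripts by
the variance of log-CPM ($\log_2\frac{y + 0.5}{N + 1}\,10^6$, the shared
transform throughout the package) with lexicographic tie-breaking for
reproducibility.

## Removing known unwanted variation

`adjust_abundance(~ wanted + batch)` implements the empirical-Bayes
location/scale batch model on $Y = \log_2(\tilde y + 1)$ of scaled counts.
Standardization fits batch means plus the wanted covariates by least
squares; the per-gene grand mean is the batch-size-weighted mean of batch
means and the pooled variance the mean squared residual. Per gene and
batch, the standardized data give a location estimate $\hat\gamma_{ig}$ and
scale estimate $\hat\delta^2_{ig}$, shrunk toward moment-matched normal and
inverse-gamma priors by iterating the posterior-mean equations to an
absolute sup-norm tolerance of 1e-4 (capped at 100 iterations with a
warning). Adjusted log values are back-transformed with
$\mathrm{round}(\max(2^{Y_{adj}} - 1, 0))$; because rounding is lossy, the
continuous log-scale column is kept alongside the integer one. With one
batch the verb is the identity on the log scale. Degenerate inputs are
guarded: a noiseless batch (zero within-batch variance) collapses the
moment equations, so variances are floored at 1e-12 and a degenerate scale
prior falls back to no shrinkage — the adjustment then removes the batch
means exactly. Wanted covariates are carried through standardization and
restored afterwards, which protects biological effects; the suite verifies
that spiked twofold group effects survive adjustment within 25% relative
error while between-batch sums of squares drop by more than 90%, and that
the whole pipeline agrees with sva's ComBat to 1e-4 on the log scale.

Note one subtlety the simulator respects: a batch shift *common to every
gene* is indistinguishable from sequencing depth and is removed by TMM
scaling before the batch model ever sees it. Real batch effects are
gene-specific, which is exactly the structure the location/scale model
assumes; `simulate_counts(batch_shift = s)` therefore draws per-gene shifts
from $N(s, s^2)$ in log2 units.

## Embeddings and clustering

`reduce_dimensions()` runs on the log-CPM of scaled abundance after
restriction to abundant transcripts and the `top` (default 500) most
variable ones.

* **PCA** centers each gene and takes the SVD; sample coordinates are the
  right singular vectors scaled by singular values. The sign of each
  component is fixed so its largest-magnitude gene loading is positive —
  an arbitrary but reproducible orientation.
* **MDS** uses *leading log-fold-change distances*: for each sample pair
  the root-mean-square of the `top` largest gene-wise log-CPM differences,
  so the distance between two samples is driven by the genes that most
  distinguish *that* pair. Classical (Torgerson) scaling double-centers the
  squared distances and embeds on the leading non-negative eigenvalues;
  negative eigenvalues (the distances are not guaranteed Euclidean) are
  dropped, shrinking the returned dimensionality with a warning if needed.
* **tSNE** is delegated to Rtsne on the first 50 principal components with
  perplexity 30, seeded; with fewer than $3\times$ perplexity samples the
  verb refuses and suggests a smaller perplexity rather than producing a
  degenerate embedding.

`cluster_elements()` offers two native engines. k-means uses k-means++
seeding, Lloyd iterations, and 10 seeded restarts keeping the lowest
within-cluster sum of squares; empty clusters are reseeded at the farthest
point. SNN clustering builds a shared-nearest-neighbour graph on the
embedding — neighbour sets of size `knn` (default 20) including the point
itself, Jaccard edge weights, pruning below 1/15 — and maximizes modularity
at resolution 0.8 with a native Louvain implementation (seeded node order,
local moves then aggregation). One implementation detail matters for
correctness after aggregation: a super-node's self-loop moves with it and
contributes equally to any community, so it is excluded from the
community-link term of the modularity gain; including it blocks all merges
at the second level. The implementation is cross-checked against igraph's
Louvain on the same graphs.

`remove_redundancy()` is a greedy filter: while any pair exceeds the
correlation threshold (Pearson, on log-CPM of the top 1000 variable
transcripts), the member of the worst pair with the larger mean correlation
to everything else — the more "central", hence more expendable, one — is
removed, with lexicographic tie-breaking; in embedding mode the same loop
runs on Euclidean distance in the first two dimensions. The removal order
is logged in internals.

## Differential abundance

The default engine is a native voom + moderated-t implementation. Log-CPM
with prior 0.5 is fitted per gene by OLS; a lowess curve (span 0.5) of
$\sqrt{s_g}$ against mean log-count captures the mean–variance trend of
count data; observation-level weights are the trend evaluated at fitted
log-counts raised to the power −4, with extrapolation clamped at the trend
endpoints; weighted least squares is then refitted per gene. Gene
variances are moderated through a scaled inverse-chi-square prior fitted by
matching log-variance moments: with residual df $d$,
$e_g = \log s^2_g - \psi(d/2) + \log(d/2)$; the prior df $d_0$ solves
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d/2)$ by Newton inversion of the
trigamma, and $s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$. When the
observed spread does not exceed chi-square sampling noise the prior df is
infinite and every variance shrinks fully to the common mean — the
behaviour of the reference implementation, which the suite reproduces to
1e-10 in both branches against limma. Posterior variances give moderated
t-statistics on $d_0 + d$ df (capped at the pooled residual df).

The alternative `nb_lrt` engine fits per-gene negative-binomial log-link
GLMs with log effective library sizes as offsets, estimates one common
dispersion by golden-section maximization of the profile log-likelihood
summed over genes, and tests the contrast with a 1-df likelihood-ratio
chi-square. It is deliberately simple — a common dispersion, no trended or
tagwise shrinkage — and serves as a second, distribution-based route whose
fold-change directions agree with voom's for strong effects (the suite
checks >99% sign concordance at |logFC| ≥ 2). Both engines test only
abundant transcripts, adjust p-values with a native Benjamini–Hochberg
step-up (validated against `p.adjust` and hand-computed examples), and
flag significance at FDR < 0.05 by default.

`identify_markers()` runs the test over every ordered pair of classes,
keeping transcripts with logFC above 2 and FDR below 0.05, ranked by logFC,
top 10 per pair. Ordered pairs are redundant for a two-sided test, but
keeping both directions yields a per-class marker list directly. FDR is
adjusted within each pair — each pair is its own family of hypotheses; a
global adjustment across pairs would couple unrelated comparisons and is
noted as the alternative. Classes with a single sample are skipped with a
warning rather than fitted without residual df.

`test_gene_overrepresentation()` is the hypergeometric upper tail
$P(X \ge k)$ with the gene sets intersected with the universe, BH across
sets — checked against exhaustive enumeration of all $\binom{10}{5}$ draws
on a small instance. `test_differential_cellularity()` logit-transforms
fractions clamped to $[10^{-3}, 1-10^{-3}]$ and fits ordinary least
squares per cell type; the logit makes effects approximately additive and
keeps OLS residuals homoscedastic away from the boundary, and a constant
response returns coefficient 0 with p = 1 by convention rather than NaN.
Beta regression would model the variance more faithfully but adds an
iterative fit for little gain at these sample sizes.

## Deconvolution

`deconvolve_cellularity()` estimates per-sample cell-type fractions by
constrained least squares against a signature matrix: a native
Lawson–Hanson active-set NNLS solves $\min_f \|Sf - y\|^2,\ f \ge 0$, and
the solution is renormalized to the simplex. Before fitting, each
signature row and the matching entry of $y$ are divided by the row's
standard deviation across cell types. This is scaling, deliberately
*without* centering: dividing by the row sd stops high-magnitude
transcripts from dominating the fit, while centering would subtract a
row-specific constant and break the linear identity $y = Sf$ — noiseless
mixtures would no longer be recovered exactly, and multiplying $y$ by a
positive scalar would change the normalized fractions. With scaling only,
both exact recovery (to 1e-8) and exact scale invariance hold and are
asserted in the suite. An all-zero solution (a sample orthogonal to the
whole signature) falls back to uniform fractions with a warning, and
per-sample goodness of fit (residual RMSE and observed–reconstructed
correlation) is stored so poor fits are visible. A clipped unconstrained
least-squares flavour (`ls_clip`) is available for comparison; the
constraint-based solution is the default because clipping can leave the
feasible optimum.

## Synthetic data: what it emulates and what it does not

`simulate_counts()` draws gene-wise means
$\mu_{gs} = \exp(a_g + x_s b_g + z_s c_g)\,L_s$ and negative-binomial
counts with variance $\mu + \phi\mu^2$. Chosen once, as conditions a bulk
RNA-seq practitioner would call typical: baseline means lognormal with
median 50 and sdlog 1.2 (a realistically heavy-tailed abundance
distribution spanning silent to highly expressed genes); dispersions
Gamma-distributed with shape 2 around mean 0.1 (biological-replicate
variability); library-size factors lognormal with CV 0.3; DE genes get
$\pm$`logfc` (log2) in one non-reference group; gene-specific batch
effects $N(s, s^2)$ in log2 units as discussed above; two batches balanced
within groups so the design stays full rank. `simulate_mixtures()` forms
$y = Sf$ with multiplicative lognormal noise of a given CV, and
`simulate_isoform_table()` multinomially partitions counts across 2–3
isoforms so that aggregation is its exact inverse. All generators are
seeded and pure.

What the generators do *not* emulate: gene–gene correlation, sample
outliers, GC/length biases, isoform switching, dropout, or the
heteroscedastic batch structure of real multi-source compendia. Passing
tests therefore demonstrate correctness of the algorithms under their own
model assumptions — recovery of planted structure, agreement with
independent oracles, and contract invariants — not performance on any
particular real dataset.

## Problem sizes and numerical choices

The test and acceptance workloads use 200–500 transcripts and 8–24
samples, with 100–500 replicates where rates are estimated — sizes at
which every property under test is already exercised (the algorithms are
dimension-independent) while the full suite runs in minutes. Key numerical
choices, gathered in one place: half-up rounding wherever counts are
reconstructed (banker's rounding would bias medians); TMM returns factor 1
for degenerate pairs (no shared nonzero genes, or identical relative
profiles); variance floors of 1e-12 in the batch model; lowess
extrapolation clamped to the trend's endpoint values; the NNLS tolerance
scales with $\max|A^\top b|$; k-means ties broken by first index; Louvain
node order drawn once from the seeded RNG. The delimited reader parses
doubles with exact `strtod` semantics so a write–read–write round trip of
the canonical long TSV is byte-identical — which is also what makes a
shell pipe of CLI verbs reproduce the in-process result exactly, with the
one caveat that the internals store does not survive text serialization:
verbs that need scaling factors recompute them deterministically from the
counts when absent.

## Known limitations

Single-engine gaps are deliberate: no RLE/median-of-ratios scaling, no
gene-length-normalized units (TPM/FPKM), no surrogate-variable estimation,
no non-parametric batch priors or reference-batch mode, no tagwise NB
dispersions, no random-effect designs, no survival models for
composition, and no nu-SVR or other-cell-aware deconvolution engines. The
imputation statistic is the group median by design — callers wanting model
based imputation should impute upstream. The SNN graph is dense
($O(n^2)$ memory), appropriate for bulk sample counts, not for
hundreds of thousands of cells. DESeq2- and edgeR-style quasi-likelihood
engines would slot behind the same `method =` contract of
`test_differential_abundance()` but are not implemented.
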