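---
title: "Methods: rank-pair cell-state trajectories and bulk deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-pair cell-state trajectories and bulk deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Melanoma cells switch between transcriptional states — from a proliferative,
MITF-high, melanocyte-like program towards de-differentiated, invasive,
MITF-low programs — and different studies (patient single-cell RNA-seq,
cell-line bulk RNA-seq, tumour-cohort bulk RNA-seq) see this landscape at
different resolutions. Comparing states across studies requires (i) a
representation robust to the batch and platform differences that dominate
cross-study comparisons, (ii) a common low-dimensional space into which all
datasets can be projected, (iii) markers that define each state, (iv) a way
of reading bulk samples as mixtures of the single-cell states, and (v) a way
of comparing predicted drug susceptibilities of matched states. `pairstate`
implements that pipeline as reusable, tested components, together with a
ground-truthed simulator so every stage can be verified without external
downloads.

# The rank-pair encoding

All expression values are log2(TPM+1). For a single-cell matrix $S$ (cells
$\times$ genes after transposition) and a bulk matrix $B$ the encoding is
built as follows.

1. Intersect the two gene universes (sorted lexicographically for
   determinism).
2. Score each shared gene by the median over cells of the absolute deviation
   from its own median (an un-scaled MAD), and keep the `n_top = 3000`
   highest-scoring genes. Ties are broken by gene name; the classical
   `argsort` leaves ties unspecified, so a deterministic rule is imposed.
3. Enumerate all unordered pairs of distinct selected genes once, with the
   gene earlier in the selected list in first position. This makes the
   first/second slots of each pair well defined for the strict inequality
   below and avoids double-counting reversed pairs.
4. For each pair, the *concordance* $C$ is the fraction of bulk samples in
   which the first gene strictly exceeds the second (ties count 0). Pairs
   with $0.49 \le C \le 0.51$ (both ends inclusive) are retained: pairs that
   split the bulk cohort in half are maximally informative about where a
   sample sits, whereas pairs with $C$ near 0 or 1 are constant facts about
   the transcriptome.
5. Any dataset is then encoded as a binary observation $\times$ pair matrix:
   entry 1 iff the first gene strictly exceeds the second *within that
   observation*.

Because every feature only compares two genes inside the same observation,
the encoding is invariant to any strictly monotone per-observation
transform — per-cell scaling, library-size distortions, and monotone batch
effects vanish by construction. This is the property that lets a PCA space
fitted on single cells accept bulk cohorts from other studies. The
concordance computation is chunked over pairs (`chunk_size`) so the full
3000-gene instance (4,498,500 pairs) runs in bounded memory; chunked and
dense results are bit-identical and tested as such.

# Trajectory fitting and projection

Cells are clustered on the binary matrix by complete-linkage hierarchical
clustering with Euclidean distance; `n_clusters` is a user parameter (the
melanoma analysis that motivates the package uses four states) because no
principled automatic cut is implied by the method. Mean-centred PCA on the
binary matrix gives the trajectory space; the component weights and the
training means constitute the model. External datasets encoded on the same
pairs are projected by centring with the *training* means and taking the dot
product with the component weights — centring is required for the
projection to live in the same affine space as the training coordinates,
even though a bare dot product is sometimes described.

Per-state differential expression is one-versus-rest. The default test is
the Wilcoxon rank-sum (exact when both groups have at most 25 observations
and no ties; otherwise the normal approximation with tie and continuity
correction), with Welch t-tests as an alternative. The reported location
shift is the Hodges–Lehmann estimate (median of pairwise differences) for
the rank-sum test — the natural "location parameter" of that test — and the
mean difference for the t-test. P-values are Bonferroni-corrected over the
widest family, genes $\times$ states, a deliberately conservative choice
when the original family is unstated. Gene–PC associations use Spearman
correlation with Bonferroni correction over genes; the significant genes
ranked from most positive to most negative rho are exportable in the
two-column RNK convention for preranked GSEA tools.

# Marker selection

For gene $j$ and state $c$, let $u_j$ be the vector of per-state detection
fractions (share of cells with expression $> 0$) and $v_c$ the one-hot
indicator of state $c$. The specificity distance is

$$sd_{jc} = 1 - \frac{u_j \cdot v_c}{\lVert u_j\rVert\,\lVert v_c\rVert},$$

0 for a gene detected only in state $c$, 1 for a gene never detected there.
A gene detected nowhere makes the expression 0/0; it is defined as
maximally non-specific ($sd = 1$) and flagged. Per state, the $sd$ values
are grouped into `n_groups = 10` clusters and the group with the lowest mean
is the candidate set; up to `top_n = 80` candidates with the highest
fold-change become markers. Fold-change is computed on linear TPM,
$(\bar x_{\text{state}} + \varepsilon)/(\bar x_{\text{rest}} +
\varepsilon)$ with $\varepsilon = 10^{-9}$; the measurement space of a
"fold-change" is unstated in the source method and linear abundance is the
interpretable choice.

The 1-D k-means step is solved *exactly* by dynamic programming over
contiguous blocks of the sorted values (the optimum of 1-D k-means is always
contiguous) rather than by Lloyd iterations with random restarts. This is a
deliberate design choice: it is deterministic, provably optimal, and lets
the grouping be verified against an exhaustive-partition oracle. The `seed`
argument of `select_markers()` is retained for interface stability but
unused. Grouping is done per state, not jointly, since the specificity
distance is a per-state quantity.

The discordance selection multiplies each significantly upregulated gene's
externally supplied repressive tendency score by its rank-sum location
parameter and keeps the top 500. Genes without a score are excluded rather
than imputed — the scores are an external resource consumed as input.

# Deconvolution and imputation

The signature matrix holds the mean expression of every marker gene per
state. Each bulk profile is regressed on the signature columns with
linear-kernel Nu support vector regression, once per Nu in
$\{0.25, 0.5, 0.75\}$; the Nu whose fitted values minimise the mean squared
error against the observed profile wins. Negative coefficients are clipped
to zero before normalising to sum one (the established convention in
SVR-based deconvolution; negative proportions are meaningless and
normalising mixed-sign vectors is unstable). If every coefficient is
non-positive the mixture is reported as unresolvable rather than silently
normalised.

The Nu-SVR solver is implemented in-package as the standard dual quadratic
program (box constraints at the cost parameter $C$, equality constraints
$\sum(\alpha-\alpha^*) = 0$ and $\sum(\alpha+\alpha^*) = C\,l\,\nu$), solved
with `quadprog` with a tiny ridge ($10^{-8}$ relative to the kernel scale)
for strict positive-definiteness. It was validated against a reference
libsvm implementation during development; the test suite checks it against
an independent non-negative least squares oracle instead, so the two code
paths remain distinct. Two numerical choices matter:

* the response is scaled to unit RMS before solving and the coefficients
  scaled back, so (a) $C = 1$ acts relative to the magnitude of the profile
  and (b) the estimated proportions are *exactly* invariant under positive
  rescaling of the bulk profile — a contract a fixed-box SVR on the raw
  response cannot satisfy;
* no z-scoring of genes is applied by default (whether the original
  CIBERSORT-style standardisation was used upstream is unknowable from the
  method description); the value space (logTPM vs TPM) is a tag carried by
  the inputs.

State-specific expression is imputed from a bulk cohort by per-gene
L1-penalised regression of expression on the estimated proportion matrix,
without intercept and with non-negative coefficients
(`alpha = 1e-4`, matching the `glmnet`/scikit-learn objective
$\tfrac{1}{2n}\lVert y - X\beta\rVert^2 + \alpha\lVert\beta\rVert_1$ with
unstandardised predictors). Since a bulk sample is physically a
proportion-weighted average of state abundances in linear TPM, supplying TPM
values makes the coefficients interpretable as per-state TPM. A
rank-deficient proportion matrix triggers a warning but still returns
coefficients, as the penalty keeps the problem well-posed.

# Drug signature clustering and susceptibility summaries

Per-drug up/down differential-expression gene lists become a signed drugs
$\times$ genes matrix over $\{-1, 0, 1\}$. Distances are plain normalised
hamming over the three-symbol alphabet (any mismatch counts once — up vs
down is deliberately not weighted double, matching the named metric). A
k-nearest-neighbour graph (`k = 15` by default) is symmetrised with
UMAP-style fuzzy connectivity weights — per-drug local scaling calibrated so
the effective neighbour count is $\log_2 k$, then a probabilistic union —
mirroring the neighbour weighting of the standard single-cell toolkits whose
Leiden step this reproduces. The local offset $\rho$ includes zero
distances, so duplicated signatures remain maximally connected. Leiden
community detection (modularity objective, resolution 2.95 by default, seed
recorded) labels the drugs; a 2-D UMAP of the hamming distances is provided
for display only — tests assert seed-determinism, finiteness and class
separation, never coordinates.

Susceptibility scores (for example residual means from an external
per-cell scoring tool) arrive as a drug $\times$ (study, state) table. How
such scores were binarised into "predicted to target" in the motivating
analysis is unstated, so the rule is explicit and recorded with the table:
by default the top `top_n` drugs per column, ties broken by drug identifier.
From the flags, the package computes the symmetric state-by-state overlap
count matrix (diagonal = each column's own count) and the ranking of drugs
by number of targeted (study, state) combinations. The target-expression
summary reports per gene, dataset and state the mean expression and
detection fraction, and flags a target *consistent* when it is detected
above threshold (default 0.1) in the invasive-labelled state of every
dataset — absent genes are inconsistent by definition.

# The synthetic world

The generator states its world once; its defaults are not tuned to tests.

* **States and markers.** Four states, 50 private markers each, in a
  1000-gene universe (tests use scaled-down instances of the same world).
  Baseline log2 means are uniform on $[0.5, 6]$; marker baselines are drawn
  low ($[0.5, 1.5]$), modelling state-restricted programs that are off at
  baseline and induced in their state. A marker's mean TPM is multiplied by
  $(1 + \text{marker\_effect})$ in its own state, so `marker_effect = 0` is
  exactly the null and the default 4 gives a five-fold induction.
* **Cells.** 100 cells per state; each cell belongs to one of 5 patients;
  each patient contributes a per-gene $N(0, 0.3)$ log-space shift — the
  nuisance variation the rank-pair encoding is supposed to remove. Cell
  noise is additive $N(0, 1)$ in log space, clamped at zero.
* **Dropout.** Independent per-entry Bernoulli zeroing with probability
  $d \cdot e^{-\mu/2}$, where $d$ is `dropout_rate` (default 0.3) and $\mu$
  the entry's noiseless state mean — the standard mean-dependent dropout of
  scRNA-seq simulators. A mean-independent rate would leave detection
  fractions uninformative about state, which the specificity distance
  relies on.
* **Bulk.** Mixing happens in linear TPM (physical mixtures average linear
  abundances): each sample is a Dirichlet(1, ..., 1) weighting of the
  noiseless state TPM profiles, log-transformed, plus $N(0, 0.1)$ log-space
  noise.
* **Drugs.** Each mechanism class has a prototype signature
  (80 genes, half up, half down); each drug resamples every gene's symbol
  with probability `flip_rate` (default 0.02), drawing uniformly from the
  other two symbols.

What the simulator does *not* emulate: UMI count noise, gene–gene
correlation beyond state structure, doublets, ambient RNA, immune or stromal
admixture, and platform-specific capture biases. A green test therefore
establishes that the implementation computes its contracts correctly and
that the method recovers planted structure under idealised noise — not that
it would recover biology from any particular real cohort.

One consequence worth knowing: in the fully noiseless world
(`noise_sd = 0, dropout_rate = 0`), every gene is detected in every cell, so
detection-based specificity is uniform and marker *selection* is
undefined there; the noiseless oracle tests therefore build signatures from
the generating marker lists directly.

# Numerical and degenerate-input policies

* Ties in expression score 0 in the binary encoding (strict inequality).
* `filter_pairs` bounds are inclusive at both ends.
* An all-constant binary matrix is a hard error for PCA (zero variance).
* A constant gene gets rank-sum p = 1 (no evidence), never NA.
* An all-zero detection vector has specificity distance 1, flagged.
* Fold-change uses $\varepsilon = 10^{-9}$ in numerator and denominator.
* The QP ridge is $10^{-8}$ relative to the kernel diagonal.
* Proportion rows are normalised to sum to one after clipping; sums are
  asserted to $10^{-9}$ in the tests.
* All randomised stages (generator, Leiden, UMAP) take explicit seeds and
  record them in their outputs; hierarchical clustering, the DP k-means and
  the encoding are fully deterministic.

# Runtime choices

Tests and the acceptance report run on desk-scale instances (300–600 genes,
60–100 cells per state, 20–100 bulk samples) so the whole suite completes in
about half a minute on one CPU; the full-scale code paths (3000 selected
genes, 4,498,500 enumerated pairs, chunked concordance) are exercised once
each. The Nu-SVR cost is cubic in the number of marker genes per sample;
with the default 80 markers per state and four states a sample solves in
well under a second.
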