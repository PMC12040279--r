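---
title: "Spectral network QTL mapping: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral network QTL mapping: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snqtl)
```

## The problem

Classical eQTL analysis asks whether a genetic marker shifts the *expression
level* of individual genes. This package asks a different question: does the
marker shift the *co-expression network* — the pattern of correlations among
genes? A locus whose genotype classes (AA, AB, BB in an intercross) carry
visibly different correlation structures is a network QTL. Testing one
network-level hypothesis per marker avoids the quadratic multiple-testing
burden of pair-by-pair co-expression QTL scans, and the spectral summary
below favours the biologically plausible regime of weak, sparse effects:
a moderate subset of genes whose mutual correlations shift together.

## The model

At a marker, samples are split by genotype into groups A, H, B and a Pearson
correlation matrix is estimated within each group. The null hypothesis is

$$H_0 : N_A = N_H = N_B,$$

equality of the three population correlation matrices. Within-chromosome
entries are zeroed by default (the "set-to-zero" mask), because
same-chromosome correlations are more likely driven by linkage than by
function; the mask is optional (`mask = FALSE`).

The three pairwise differences
$D_{AB} = \hat N_B - \hat N_A$, $D_{AH} = \hat N_H - \hat N_A$,
$D_{BH} = \hat N_H - \hat N_B$ are stacked into a $p \times p \times 3$
differential tensor $\mathcal D$. Note the identity
$D_{BH} = D_{AH} - D_{AB}$: the third slide is linearly dependent on the
first two. The full 3-slide tensor is kept anyway because the loading vector
over the three comparisons is directly interpretable (see below).

### Spectral statistics

The tensor is summarized by its best sparse symmetric rank-1 approximation
(SSTD):

$$\min_{\Lambda \ge 0,\; \|v\|_2 = \|u\|_2 = 1,\; \|v\|_0 \le R}
  \|\mathcal D - \Lambda\, v \circ v \circ u\|_F^2 .$$

The optimal $\Lambda$ — the sparse leading tensor eigenvalue (sLTE) — is the
`tensor` statistic. A matrix analogue, the sparse leading matrix eigenvalue
(sLME) $\lambda(D) = \max_{\|v\|_2=1, \|v\|_0 \le R} |v^\top D v|$, gives the
`max` statistic $\max\{\lambda(D_{AB}), \lambda(D_{AH}), \lambda(D_{BH})\}$,
plus the `sum` (sum of the three sLMEs) and `tensor_sq` (squared sLTE)
variants. All are zero in population under $H_0$.

### Interpretation of the decomposition

* $v^2$ (elementwise) is the **gene leverage**: each gene's share of the
  differential signal; leverages sum to 1.
* $v v^\top$ is the **joint differential network**; the edge weight
  $w_{jk} = v_j v_k$ measures how strongly the pair's co-expression responds
  to the marker, and $\Lambda\, v_j v_k u_l$ reconstructs the signed change
  in comparison $l$ (enhancement vs reduction).
* $u \in \mathbb R^3$ weights the comparisons (AB, AH, BH). Near-equal
  AB and AH coordinates with a near-zero BH coordinate is the signature of a
  **nearly additive** genetic effect (H halfway between A and B).

## Algorithms

### Penalized matrix decomposition (sLME)

The sLME is solved by PMD: soft-thresholded power iteration
$v \leftarrow \mathrm{normalize}(S_\delta(Dv))$, with the threshold
$\delta$ found by bisection so the iterate satisfies the L1 budget. Solutions
always have $\|v\|_2 = 1$. Because the plain ascent targets the maximal
*signed* quadratic form, the solver runs on both $D$ and $-D$ (initialized at
the corresponding extreme eigenvectors) and keeps the larger $|v^\top D v|$.
The inner loop is implemented in C++ and capped at 100 iterations with a
$10^{-6}$ change tolerance.

**Sparsity convention.** The user-facing parameter $R \in [1, p]$ is a target
support size; internally the L1 budget is $\sqrt R$. Under this mapping
$\|v\|_1^2 \le \|v\|_0 \le R$ holds for the solutions, $R = 1$ forces a
1-sparse vector, and $R = p$ is exactly the dense problem (so non-sparse
comparisons use `R = p`). PMD does not guarantee $\|v\|_0 \le R$ in
pathological cases; the achieved support size is reported as `nnz`.

### Alternating SSTD

Starting from a random unit $u^{(0)}$ (iid normal, normalized), iterate:

1. **v-update**: PMD on the contracted matrix $\mathcal D \times_3 u$
   (warm-started at the previous $v$); the update maximizes the *absolute*
   quadratic form, the natural reading of the subproblem given that the
   u-update re-aligns signs.
2. **u-update**: $u \leftarrow \mathrm{normalize}(\mathcal D \times_1 v
   \times_2 v)$, after which $\Lambda = \|\mathcal D \times_1 v \times_2
   v\|_2 \ge 0$ automatically.

Within a restart the trace of $\Lambda$ is non-decreasing by construction: a
PMD step that fails to improve keeps the previous iterate and stops. The
best of `restarts` (default 5) seeded initializations is returned; $v$'s sign
is fixed by making its largest-magnitude entry positive. The default
iteration cap is $T = 50$ with early stop at $|\Delta\Lambda| < 10^{-6}$. A
zero tensor returns $\Lambda = 0$ flagged degenerate.

### BIC selection of R

When no prior sparsity is known, `bic_select_R()` minimizes

$$\mathrm{BIC}(R) = 3p^2 \log\!\Big(\frac{\|\mathcal D - \Lambda_R v_R \circ
v_R \circ u_R\|_F^2}{3p^2}\Big) + (2 + 2\|v_R\|_0)\log 3p^2$$

over a user grid, with an epsilon floor ($10^{-12}$) on the loss so that
noiseless test fixtures do not take $\log 0$; ties go to the smallest $R$.

### Permutation testing and the two-stage scan

Empirical p-values shuffle genotype labels over the pooled samples at the
marker, preserving group sizes, and recompute the *entire* pipeline
(group correlations, masking, tensor, statistic):

$$p = \frac1B \sum_{b=1}^B \mathbb I\{S_b \ge S\}.$$

The plain counting formula can return $p = 0$; an optional
$(1 + \text{count})/(1 + B)$ correction (`correct = TRUE`) is available but
off by default to match the formula above. The genome scan screens every
marker with $B_0 = 100$ permutations and re-tests markers with screening
$p < 0.05$ using $B = 500$ permutations. Each marker has its own RNG stream
keyed by (master seed, marker index), so results are independent of marker
iteration order. Raw p-values are reported; thresholding at 0.05 follows the
method's convention, and Benjamini–Hochberg can be applied downstream if
stricter error control is wanted.

**Design choices** (where the method leaves room):

* *Permutation unit*: labels are shuffled over the union of grouped samples
  at that marker, conditioning on $(n_A, n_H, n_B)$; permutations are drawn
  per marker, not reused across markers.
* *Missing genotypes*: a sample missing at a marker is excluded from that
  marker's test only — no imputation.
* *Small groups*: markers with any non-empty group below `min_group`
  (default 10) are flagged untestable; correlation matrices from tiny groups
  are mostly noise. The power experiment in the acceptance suite lowers this
  to 5 so that $n = 50$ populations remain testable.
* *Zero-variance genes* within a group get correlation 0 to all others
  (with a warning) rather than propagating NaN.
* *Two-genotype markers* (backcross-like): a single pairwise difference
  matrix is built and the sLME used as the statistic; the 3-slide tensor
  statistic is undefined there.
* *Diagonal*: zeroed by the mask (a gene shares a chromosome with itself).

### Preprocessing

Raw counts are normalized to counts-per-million, $\log_2(x+1)$-transformed,
residualized gene-by-gene on the covariates (intercept always included;
factors one-hot encoded with the first level dropped), ranked by
post-normalization mean, and cut to the `top_k` highest-mean genes. The
CPM/log2 recipe is a documented, configurable default — standard, monotone,
reproducible — not a claim about any particular upstream pipeline.
Re-running `preprocess()` on its own output is a no-op (the ranking means are
stored with the object).

### Local baseline

The comparator implemented in `baseline_local_test()` regresses, for every
cross-chromosome gene pair, the per-sample product of standardized residual
expressions on genotype dosage (0, ½, 1) and combines the per-pair F-test
p-values by Bonferroni-adjusted minimum. The pair proxy and combination rule
are this package's reconstruction of the standard local co-expression QTL
approach; they are not uniquely prescribed anywhere.

## The synthetic-data generator

`simulate_dataset()` states a world and the tests live in it:

* **Genotypes**: an F2 intercross between fully homozygous divergent
  parents; each F1 gamete carries exactly one crossover per chromosome at a
  uniform position (no interference, no map distances). Defaults: 200 genes
  = 200 markers on 20 chromosomes, genes co-located with markers so every
  gene is a candidate locus. This reproduces Mendelian 1:2:1 segregation and
  block-diagonal LD along chromosomes. Note the obligate single crossover
  makes chromosome ends *anti*-correlated (recombination fraction above ½) —
  a known artifact of the one-crossover model, irrelevant to the tests.
* **Expression**: counts are Poisson with
  $\log \mu_{ij} = \mu_j + d_i \cdot e \cdot f_i \cdot s_j$, where
  $d_i \in \{0, \tfrac12, 1\}$ is the individual's scaled dosage at one
  planted marker, $f_i \sim N(0,1)$ a per-individual latent factor, and
  $s_j \sim N(0,1)$ fixed gene loadings. With effect $e = 0$ the counts are
  independent Poisson; with $e > 0$ the latent factor is switched on in
  proportion to dosage, so cross-gene correlations rise from the AA to the
  BB class and *all* genes are affected.
* **Parameter defaults**: `baseline_mean = 10` with per-gene log-mean jitter
  sd 0.5 (a right-skewed count histogram typical of tag-based RNA-seq after
  light filtering). The default `effect_size = 0.07` was calibrated
  analytically — once — so that the leading eigenvalue of the planted
  correlation shift (≈ `e² · λ/(1 + e² λ) · p` for unit loadings) crosses
  the random-matrix noise level of a group correlation-difference matrix
  between n = 50 and n = 300. An earlier, stronger default saturated
  detection already at n = 50, which contradicts the reference behaviour the
  generator is meant to emulate: power that *grows* over the 50–500
  population-size range while the pairwise local test stays weak. The
  calibration targets that qualitative shape, not any test threshold.

What the generator does **not** emulate: overdispersion (negative-binomial
noise), library-size variation, cis-regulatory structure, genotyping error,
or more than one causal locus. A green end-to-end test therefore establishes
that the pipeline detects a planted low-rank network effect in idealized
Poisson data — not that it detects every biologically realistic effect.

## Numerical conventions

* Symmetry of solver inputs is checked to 1e-8 and enforced by averaging.
* $\Lambda \ge 0$ by folding signs into $u$; $v$'s largest-magnitude entry is
  made positive.
* Leverages sum to 1 to 1e-8 ($\|v\|_2 = 1$).
* Slide identity $D_{BH} = D_{AH} - D_{AB}$ holds to 1e-10 by construction.
* The `-log10(p)` summaries in the acceptance suite use the corrected
  p-value, since the plain counting formula can be exactly zero.

## Known limitations

* PMD and SSTD solve nonconvex problems approximately; restarts make results
  reproducible, not provably optimal. The oracle-equivalence acceptance test
  tolerates up to 5% misses on random matrices.
* The rank-1 SSTD captures only the strongest joint signal; secondary
  network shifts require a higher-rank extension, out of scope here.
* Permutation p-values have resolution $1/B$; genome-wide significance
  claims at small $\alpha$ need a larger confirmation $B$.
* The scan is serial; per-marker RNG streams make a parallel drop-in
  possible without changing results.
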