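---
title: "Methods: the Clustermatch Correlation Coefficient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Clustermatch Correlation Coefficient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustermatch)
```

## The model

The Clustermatch Correlation Coefficient (CCC) rests on one assumption: if
two variables are related, then clustering the samples using each variable
*separately* should produce matching groups. Each variable is therefore
reduced to a set of candidate partitions of the $n$ samples, and the
coefficient is the best chance-corrected agreement achievable between any
partition of $x$ and any partition of $y$:

$$\mathrm{CCC}(x, y) = \max\Big\{0,\; \max_{\pi_i \in \Pi_x,\, \pi_j \in \Pi_y} \mathrm{ARI}(\pi_i, \pi_j)\Big\}$$

The adjusted Rand index is computed by pair counting. With $n_0$ the number
of sample pairs co-clustered in both partitions, $n_1$ separated in both,
and $n_2, n_3$ co-clustered in only one,

$$\mathrm{ARI} = \frac{2(n_0 n_1 - n_2 n_3)}{(n_0+n_2)(n_2+n_1) + (n_0+n_3)(n_3+n_1)},$$

computed from the cluster-overlap contingency table in $O(n + k_x k_y)$ per
pair (`tests/testthat/helper-oracles.R` carries an independent brute-force
pair enumeration and the Hubert–Arabie form of the index, which the test
suite verifies to agree with this formula exhaustively over all partition
pairs of up to 7 objects; the two forms are algebraically identical).

Properties inherited from the ARI, each covered by a property-style test:

* **symmetry** and **normalization** to $[0, 1]$ after clamping at 0;
* **constant baseline**: for independently drawn partitions the expected ARI
  is $\approx 0$ *whatever the cluster counts*, so maximizing over partition
  pairs of different sizes does not inflate the coefficient for independent
  data — this is the property that makes a single `kmax` knob safe;
* **rank invariance**: numerical partitions depend only on ranks, so any
  strictly increasing transform of an input leaves the coefficient unchanged.

For a constant variable no 2-cluster partition exists and the coefficient is
**undefined**: `ccc()` returns `NA` with a warning rather than 0, because "no
information in the variable" is different from "no detectable relationship".

## Partitioning conventions

**Numerical variables** are binned on the rank scale: sample $i$ joins
cluster $\ell$ when $(\ell-1)/k < r_i/n \le \ell/k$, where $r_i$ is the
average rank. The package adopts this convention, rather than thresholding
raw values at interpolated quantiles, for two reasons:

1. Ties are handled coherently — a block of tied values shares one average
   rank and therefore always moves as a unit, never being split across an
   interpolated cutpoint that happens to fall inside the block.
2. On the canonical Anscombe quartet it reproduces the method's published
   worked examples exactly (1.0, 0.34, 1.0, 0.00 at `kmax = 10`); interpolated
   value cutpoints with either boundary direction do not (they admit finer
   partitions whose maximum on Anscombe II overshoots 0.34).

Empty bins produced by ties are dropped and labels compacted; a candidate
with fewer than two non-empty clusters is discarded. Duplicate partitions
arising from ties at different $k$ are deduplicated (keeping the smallest
$k$), which cannot change any maximum. `quantile_cutpoints()` is provided as
a type-7 interpolated-quantile utility for reporting the value-scale bin
boundaries of tie-free data (e.g. for drawing cluster-boundary lines); it
plays no role in assignment.

**Categorical variables** contribute exactly one partition — one cluster per
category, in order of first appearance (the ARI is invariant to cluster
relabeling, so any fixed order works). Categories are treated as nominal
throughout; no ordering is ever used, and `kmax` does not apply.

## Tunable parameters

* **`kmax`** (default 10, dimensionless) bounds the number of clusters per
  numerical partition. It trades pattern complexity against compute time
  (the grid grows quadratically in `kmax`); thanks to the constant baseline
  it does *not* trade against false positives, which the test suite checks by
  sweeping `kmax` ∈ {2, 5, 10, 20} on independent pairs. A linear pattern is
  already captured at $k = 2$; a quadratic one needs $k \ge 4$ on the
  predictor side. The default 10 captures the patterns of interest in
  expression data at typical sample sizes.
* **Candidate range cap.** Cluster counts are additionally capped at
  $\mathrm{round}(\sqrt{n})$: partitions with more than $\sqrt{n}$ clusters
  are dominated by singletons, which carry no pattern information and only
  add noise terms to the maximum. At $n = 11$ this leaves $k \in \{2, 3\}$ —
  which is exactly what reproduces the published Anscombe II value — while at
  $n \ge 100$ with the default `kmax` the cap is inactive.
* **`permutations`** (default 10,000 in `ccc_perm_test()`): the p-value is
  the plain proportion of permuted coefficients $\ge$ the observed one, the
  natural estimator for a desk-scale test. The smallest attainable p-value is
  limited both by $1/P$ and by the discreteness of the null at small $n$
  (e.g. at $n = 11$ a random permutation reproduces a 5/6 split with
  probability $1/\binom{11}{5} \approx 0.002$, so no amount of permutations
  yields $p < 0.002$). The add-one estimator $(r+1)/(P+1)$ is available via
  `smoothing = TRUE` for users who need strictly positive, slightly
  conservative p-values.
* **`na_action`**: missing values error by default; `"pairwise-complete"`
  opts into dropping samples missing in either member of a pair. Silent
  deletion is too dangerous to be a default in expression pipelines.

## Determinism and parallelism

All randomness flows from explicit seeds. The permutation loop runs in
compiled code but draws its Fisher–Yates shuffles from R's RNG, so
`set.seed()` fully determines it. In `ccc_matrix()` each pair's permutation
stream is seeded from `seed + pair_index`, so results are bit-identical for
any `jobs` value (workers only partition the pair list; no reduction order is
involved). The permutation test never re-sorts data: the partition of a
permuted vector is the same permutation of the original partition labels, so
per-variable partitions are computed once.

Ties on the grid maximum are broken toward the smallest $k_x k_y$, then
smallest $k_x$, so the reported maximizing pair is deterministic and the
least complex description of the relationship (a perfect linear pattern
reports $k_x = k_y = 2$, not one of the equally maximal finer pairs).

Pair-agreement counts grow as $n^2$ and their products as $n^4$; they are
accumulated as doubles, which are exact up to $2^{53}$ — ample for any
expression matrix this package targets ($n^4 < 2^{53}$ up to $n \approx
10^{3.9}$ per product term, and the formula's terms are sums of counts
$\le n^2/2$).

## The synthetic-data generators

The generators produce the canonical relationship patterns used to
characterize not-only-linear coefficients, with seed-deterministic output.
Distributions stated by the characterization are fixed: the
categorical–numerical association draws $z$ uniformly over $\{A, B, C\}$ and
$y \sim N(0, 0.5^2)$, $N(1, 0.25^2)$, $N(1, 0.75^2)$ per category. Where only
the qualitative shape is specified, the defaults are:

| generator | defaults | rationale |
|---|---|---|
| `quadratic` | $x \sim U(-2,2)$, noise sd 0.5 | signal-to-noise where $k=2$ fails but $k \ge 4$ detects the parabola |
| `two_lines` | slopes $(1, -1.3)$, equal mixing, noise sd 0.15 | near-cancelling linear components: expected Pearson $\approx -0.13$ |
| `non_coexistence` | active $U(1,2)$ vs inactive $U(0,0.1)$ | mutually exclusive expression with a clear gap |
| `two_cat_assoc` | $P(\text{blue}\mid A)=0.8$, $P(\text{orange}\mid B)=0.7$ | one strongly and one weakly skewed category |
| `substructure` | $n = 500$, two spherical Gaussians, $5\sigma$ apart | unambiguous cluster substructure |

These emulate the *shape* of relationships, not real expression data: no
count noise, no library-size or batch effects, no heavy tails, no sparsity,
and independent samples. Passing tests on them demonstrates that the
coefficient ranks pattern classes correctly and is calibrated under
exchangeable nulls; it does not demonstrate robustness to the technical
artifacts of RNA-seq, which preprocessing (see `select_top_variance_genes()`,
which applies the conventional $\log(x+1)$ variance-stabilizing selection)
only partially addresses.

## Problem sizes used by the validation suite

Chosen as desk-scale stand-ins for the method's characterization analyses:
the exhaustive formula check enumerates all set-partition pairs up to $n=7$
(877² pairs at $n=7$); the constant-baseline sweep uses 100 independent
standard-normal pairs at $n = 1000$; null calibration uses 500 replicates at
$n = 500$ with 1000 permutations each, tested against uniformity by a
Kolmogorov–Smirnov test at $\alpha = 0.01$; pattern-level checks use
$n = 100$ with 10,000 permutations. The categorical–numerical association is
averaged over 100 generator seeds.

## Known limitations

* The coefficient is a measure of association strength, not direction: a
  perfectly increasing and a perfectly decreasing relationship both give 1.
* At very small $n$ the rank grid is coarse; with $k$ capped at
  $\sqrt{n}$, subtle patterns need tens of samples to be distinguishable
  from the null, and permutation p-values are bounded away from 0.
* Permutation testing is exact but computationally heavy for genome-scale
  screens; large analyses should restrict p-values to the pairs of interest
  (`pairs` allowlist in `ccc_matrix()`/`run_corr()`).
* Variables must be one-dimensional; clustering multivariate blocks is out
  of scope.
* Heavy ties reduce the number of usable partitions; a variable with a
  single repeated value (plus isolated outliers) can only ever form its
  tie-group split, which bounds the detectable structure.
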