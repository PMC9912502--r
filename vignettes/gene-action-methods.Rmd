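---
title: "Methods: estimating and propagating the degree of dominance of transcript abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and propagating the degree of dominance of transcript abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneaction)
```

## The model

For a transcript with mean normalized abundance $X_1$ and $X_2$ in the two
F0 parents and $F_1$ in their hybrid, the additive effect, dominance
effect and degree of dominance are

$$a = \frac{X_1 - X_2}{2}, \qquad
  d = F_1 - \frac{X_1 + X_2}{2}, \qquad
  k = \frac{d}{a}.$$

$k$ is a signed, dimensionless summary of gene action: $0$ when both
alleles contribute equally (the F1 sits at the mid-parent value), $\pm 1$
when one parental allele's phenotype fully masks the other, and beyond the
parental range ($|k| > 1$, conventionally $\ge 1.25$ after noise
allowance) for transgressive over- or underdominance. The categories are

| category | $|k|$ interval |
|---|---|
| additive | $[0, 0.25)$ |
| partially dominant | $[0.25, 0.75)$ |
| dominant-recessive | $[0.75, 1.25)$ |
| transgressive | $[1.25, \infty)$ |

All computation is on **linear** normalized abundances, not log-scale
values, because $a$, $d$ and $k$ are linear functions of the means.
$k$ is only interpreted for transcripts whose parents actually differ, so
the default pipeline computes it for differentially expressed transcripts.

### Boundary and degeneracy conventions

The category bounds are half-open with each boundary value assigned to the
upper (more dominant) category, which makes classification a function:
`classify_gene_action(0.75)` is dominant-recessive, not partially
dominant. The boundaries are a `boundaries = c(0.25, 0.75, 1.25)` argument
throughout for users who prefer another convention.

When $|a|$ is negligible the ratio $d/a$ is numerically meaningless.
`degree_of_dominance()` returns `NA` ("undefined", never $\pm\infty$) when
$|a| \le$ `a_tol`; in `gene_action_table()` the tolerance is relative,
$10^{-8}\max(X_1, X_2, 1)$. Because the DE filter requires
$|\log_2 \mathrm{FC}| > 0.5$, near-ties are rare and undefined rows are
counted and excluded from distribution summaries. $k$ is never clipped for
statistics; plots clip at $|k| = 5$ by default, the range where the vast
majority of transcripts fall.

## Differential abundance between the parents

Counts are normalized with median-of-ratios size factors (each sample's
factor is the median over all-positive transcripts of its count divided by
the transcript's geometric mean). Transcripts with per-cross median raw
count below 5 are removed before testing.

The test is a Wald test on the difference of $\log_2$ group means under a
negative binomial model with variance $\mu + \alpha\mu^2$:

* per-transcript dispersion $\hat\alpha$ by method of moments from the
  pooled within-parent residual variance of normalized counts, floored at
  $10^{-8}$ (shrinkage and trended dispersion estimators are deliberately
  out of scope; an import path, `read_de_table()`, accepts any external
  caller's output in the same schema);
* $\mathrm{Var}(\bar X_g) = (\bar X_g + \hat\alpha \bar X_g^2)/n_g$,
  mapped to the $\log_2$ scale by the delta method;
* the statistic is referred to a $t$ distribution with $n_1 + n_2 - 1$
  degrees of freedom. The SE mixes a component that is a known function of
  the mean (the Poisson part) with an overdispersion component estimated
  on $n_1 + n_2 - 2$ residual df, so the effective df exceeds the residual
  df; with a plain normal reference the per-gene moment noise makes the
  test markedly anticonservative at 3 replicates, while $n_1+n_2-2$ df
  over-corrects. The $n_1+n_2-1$ choice gives a null $p<0.05$ fraction
  statistically indistinguishable from 0.05 in the package's calibration
  simulations (2000 genes, 3+3 replicates), which the test suite and
  acceptance script verify at run time.

Benjamini-Hochberg adjustment runs across tested transcripts only:
transcripts with zero counts in both parents are excluded before testing
(flagged, `p = NA`) rather than set to $p = 1$, so the BH family size
equals the number of tests. A transcript with zero mean in exactly one
parent has a degenerate Wald statistic; inside the statistic only, the
zero mean is floored at $0.5/n$ (half a count), while the reported means
and `log2FC` are untouched — such rows are flagged `zero_one_parent`.
No pseudocount is used for testing.

`log2FC` is oriented parent1/parent2, with parent1 the first-listed (e.g.
domesticated) genotype in the sample sheet; the sign of $k$ inherits this
orientation, while $|k|$ and the category do not (parent swap negates $a$
and $k$ and preserves $d$).

## Comparing crosses and regimes

Crosses are assigned to selection regimes (natural selection,
domestication, inbreds) and finite $k$ values pooled per regime;
reciprocal crosses are treated as separate parent/parent/F1 triplets. The
package pools transcripts across crosses within a regime rather than
fitting a hierarchical cross-within-regime model — a deliberate scope
decision that mirrors common practice for these comparisons.

* `ks_two_sample()` reports the exact ECDF supremum distance $D$ with the
  asymptotic two-sided p-value (the pooled sample sizes here, $10^3$ to
  $10^4$, make exact enumeration unnecessary; `exact = TRUE` is available
  for small samples). KS runs on signed $k$ by default — the distributions
  being compared are signed — with an `absolute = TRUE` rerun always
  available because both readings of "the k distribution" are defensible.
* `additive_fraction_test()` is a two-sided Fisher's exact test on the
  (additive, non-additive) × (regime, regime) table, two-sided by
  summation of hypergeometric point probabilities (conventions differ;
  this matches `fisher.test`). A zero margin returns $p = 1$ with a
  warning instead of failing.
* `regime_summary()` evaluates the ECDF on the pooled support and a
  Gaussian-kernel density with Silverman's rule-of-thumb bandwidth (no
  bandwidth is canonical for these plots; Silverman is the transparent
  default).

## Network connectivity and propagation

A directed regulator→target edge list (e.g. a mutual-information network;
inference itself is out of scope) is the input. Out-degree counts distinct
targets, in-degree distinct regulators; self-edges are permitted, counted
separately, and retained in degrees. The DE sub-network is the induced
subgraph on DE genes (both endpoints DE); nodes with at least one out-edge
in the sub-graph count as regulators, the rest as targets.

`connectivity_correlations()` always computes both Spearman and Pearson
coefficients for $|\log_2\mathrm{FC}|$ and $|k|$ against out-degree
(regulators) and in-degree (targets): reported connectivity correlations
in this literature are sometimes described as Pearson but printed as
$\rho$, so both are emitted and the `method` argument only selects the
leading rows. Degrees from the full network and from the sub-network
answer different questions; compute whichever the analysis needs and label
accordingly. `loess_curve()` uses degree-1 (local linear) tricube-weighted
regression with exact evaluation, so an exactly linear signal is
reproduced to machine precision; the default span is 0.75.

### The similarity index

For each non-self edge whose endpoints both have defined $k$,

$$s = \left|\log_2\frac{|k_{REG}|}{|k_{TAR}|}\right| \ge 0,$$

with $s = 0$ iff the magnitudes agree. Absolute values are used inside the
ratio because signed ratios can be negative and their $\log_2$ undefined;
sign-discordant edges are flagged in a boolean column so analyses can be
rerun excluding them. Edges where either $|k| \le$ `k_floor`
($10^{-3}$ by default) are excluded — a near-zero target $k$ would make
$s$ unbounded — and the exclusion count is reported. Self-edges are
excluded from similarity statistics (a node is trivially similar to
itself, which would bias group medians downward) and counted separately.

Group comparisons use two-sided Wilcoxon rank-sum tests, exact when
$n_1 + n_2 \le 20$ without ties, otherwise the normal approximation with
tie correction; the effect size $r = |Z|/\sqrt{n_1+n_2}$ is back-computed
from the two-sided p-value so exact and approximate branches are treated
identically. Single-regulator questions ("does this regulator have fewer
additive targets than expected?") use the exact binomial tail; the null
probability $p_0$ defaults to the global additive fraction among
sub-network targets and is always echoed in the output, because the
conclusion depends entirely on it.

## The synthetic-data generator

`simulate_cross()` is the generative inverse of the estimation model:
baseline means are log-normal (`meanlog = log 100`, `sdlog = 1`, spanning
the few-counts to high-expression range of a typical RNA-seq library); a
fraction `de_fraction = 0.35` of genes (the average DE fraction seen in
domesticated-wild crosses) receives $|\log_2\mathrm{FC}|$ uniform in
$[1, 3]$ with random direction; every gene draws a true $k$ from a
category mixture whose default weights (additive 0.146, partial 0.266,
dominant 0.248, transgressive 0.340) follow the composition observed for
trans-acting regulators in an Arabidopsis Col × C24 cross, with $|k|$
uniform within each band and capped at 3; the true F1 mean is
$\frac{\mu_1+\mu_2}{2} + k\,\frac{\mu_1-\mu_2}{2}$, and genes whose F1
mean would be negative are redrawn (up to 100 times, counted) so the
linear model remains exact. Counts are NB with dispersion 0.05 (a typical
inter-replicate value) and per-sample log-normal library-size factors
(`sdlog = 0.1`) to exercise normalization. All generators are pure
functions of their parameters and seed.

`simulate_grn()` draws regulator out-degrees from a discrete uniform law
around `mean_out_degree` or a discretized power law (density exponent
2.5, so the tail CCDF slope is −1.5) and samples targets without
replacement. `propagate_gene_action()` encodes three generative rules:
**dominance** ($k_{TAR} = k_{REG} + \mathcal N(0, \sigma)$, faithful
transmission), **beneficial allele** (targets of additive regulators
become transgressive — two functional regulator alleles acting
cumulatively; targets of non-additive regulators follow the dominance
rule, the spec of the additive case being the rule's defining feature),
and **independent** ($k_{TAR}$ resampled from the marginal $k$
distribution — the no-propagation null). Multi-regulator targets follow
the regulator with the highest out-degree, ties broken lexicographically:
a deterministic, documented stand-in for the verbal single-regulator
model.

### What the generator does and does not emulate

It reproduces NB counting noise, library-size variation, a category
mixture of gene action, and network-structured propagation. It does **not**
emulate: transcript-level quantification uncertainty (counts are consumed,
not produced from reads), gene-gene correlation of expression noise,
cis/trans allele-specific structure, dispersion trends with mean, or GO
annotation realism. Tests passing on synthetic data therefore validate
the estimators and tests under the stated model, not the upstream
quantification pipeline or biological annotation quality.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen so the full
suite completes in a few minutes on one CPU: calibration and recovery
simulations use 2000 genes with 3–4 replicates; propagation
discrimination uses 100 replicate networks of ~500 edges; exhaustive
statistical oracles sweep all sample pairs of size ≤ 8 (KS), all 2×2
tables with $n \le 10$ (Fisher), all group splits with $n \le 12$
(Wilcoxon) and universes ≤ 15 (hypergeometric). At these sizes the
estimator of $k$ has sampling SD of roughly 0.2–0.4 per gene at
dispersion 0.05 with 4 replicates — per-gene category assignment near
band boundaries is accordingly noisy even when the pipeline is exact on
noiseless means, which is why distribution-level comparisons (KS, Fisher,
category proportions) are the primary inferential surface rather than
single-gene labels.

## Known limitations

* Dispersion is per-transcript method-of-moments; with 2–3 replicates the
  test leans on the $t$ reference for calibration rather than on
  information sharing across genes. Users wanting shrinkage should import
  an external DE table via `read_de_table()`.
* GO enrichment is the classic hypergeometric test on the supplied
  gene-term map; the GO graph is not an input, so no graph-decorrelation
  (weight01-style) is applied and results with nested terms are
  correlated. Presence flags are reported alongside p-values because
  small categories have little power.
* The hypergeometric universe defaults to the DE transcripts of each
  cross with at least one annotation; whether the universe should instead
  be all expressed transcripts is analysis-dependent and configurable.
* Undefined-$k$ transcripts (parental near-ties that still pass the DE
  filter) are excluded from distributions and counted; there is no
  principled way to place them in a category.
* Pooling transcripts across crosses treats transcripts as exchangeable
  within a regime; cross-level random effects are out of scope.
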