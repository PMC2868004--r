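---
title: "Ordering questions for multi-condition count expression data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering questions for multi-condition count expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdeq)
```

## The problem

Enumeration-based expression technologies (SAGE, MPSS, tag-level RNA-seq)
measure a gene's expression in a library as a count: N tags for the gene out
of T sequenced tags in total. Classical differential-expression analysis
compares two conditions at a time; when an investigator's real hypothesis
spans more than two conditions — "expression rises from the normal tissue
through stage 2 to stage 4" — the usual workaround is to run pairwise tests
and intersect the calls, which compounds the type-I/type-II error of every
pairwise decision.

`mdeq` instead treats the whole hypothesis as a single *question* over the
latent abundances and reports, per gene, the posterior probability that the
question is true. Genes are then ranked by that probability, and the
probability-weighted gene list feeds a randomization-null enrichment
analysis of functional terms.

## Posterior model

The sequencing of a library is modeled as an urn process: each sequenced tag
is the focal gene's with probability equal to its mRNA abundance $\pi$, so
$N \sim \mathrm{Binomial}(T, \pi)$. With a uniform prior on $\pi$, Bayes'
rule gives the conjugate posterior

$$\pi \mid N, T \sim \mathrm{Beta}(a, b), \qquad a = N + 1,\; b = T - N + 1 .$$

`beta_posterior(N, T)` implements exactly this update; its mean is
$(N+1)/(T+2)$, which converges to the observed proportion $N/T$ as $T$
grows. A gene absent from a library is an observation of zero counts out of
$T$ tags — posterior $\mathrm{Beta}(1, T+1)$ — not missing data.

**Replicate groups.** A biological condition sequenced as $m$ replicate
libraries is encoded as an equal-weight mixture of the per-library
posteriors:

$$f(\pi) = \frac{1}{m}\sum_{i=1}^{m}
  \mathrm{BetaPDF}(\pi;\, N_i + 1,\, T_i - N_i + 1).$$

Equal weights $1/m$ are an assumption of this package: each replicate
library is treated as an equally credible witness of the group's abundance,
regardless of its sequencing depth (depth still enters through the
sharpness of each component). With $m = 1$ the mixture *is* the single beta
posterior, and `sample_abundance()` switches automatically between plain
beta draws and component-indicator sampling (pick a component uniformly,
then draw from it), which is exact and cheap.

**Pools.** The question language also offers pooling (`A+B`): counts and
totals are summed *before* the update, giving one
$\mathrm{Beta}(\sum N + 1, \sum T - \sum N + 1)$ posterior. Pooling assumes
the libraries sample one common abundance (it roughly halves the posterior
variance for two equal libraries); groups instead preserve between-library
heterogeneity. Both treatments are available so the user can choose the
assumption, not the package.

## Question semantics

A question is a boolean expression over condition abundances:

* comparison chains: `A < B < C` desugars to `A < B AND B < C`;
* conjunction/disjunction: `AND` binds tighter than `OR`, parentheses
  regroup;
* operands: a library id, a comma-list (`L1,L2` — replicate group), or a
  '+'-list (`L1+L2` — pool).

Only strict inequalities are supported: the posteriors are continuous, so
equality of two draws has probability zero and an `=` operator would be
vacuous.

For each gene, one Monte-Carlo iteration draws **one** abundance per
distinct operand and evaluates the whole boolean tree on those shared
draws. Sharing is a deliberate semantic choice: the `B` in
`A < B AND B < C` is a single quantity, and shared draws are the only
semantics under which the chained and the explicit conjunction forms agree
draw for draw. The reported probability is

$$\hat{P} = S_t / S_n,$$

with $S_t$ the number of iterations in which the question evaluated true
and $S_n$ the total number of iterations. The binomial Monte-Carlo standard
error $\sqrt{\hat P(1-\hat P)/S_n}$, bounded by $\sqrt{0.25/S_n}$, is
reported alongside.

**Defaults and reproducibility.** $S_n$ defaults to 10,000 draws
(standard error at most 0.005, comfortably below any ranking cutoff users
set in practice) and is exposed everywhere as `n_sims`. The draw stream for
a gene is seeded from `(seed, gene id)`, so results are bit-reproducible,
independent of which other genes are scored in the same call, and — because
operands are drawn in a canonical sorted order — a question and its
operator-flipped complement consume identical draws, making
$\hat P(Q) + \hat P(Q') = 1$ hold *exactly*, not just in expectation.

Probability cutoffs are accepted as fractions (`0.8`) or percents (`80`);
any value above 1 is read as a percent. Ranking ties are broken by gene id
so output order is reproducible.

An independent check used throughout the tests: for single-library
operands, $P(\pi_A > \pi_B)$ has the closed quadrature form
$\int_0^1 f_A(x) F_B(x)\,dx$ (`prob_greater_beta()`), evaluated with
`stats::integrate` to $10^{-10}$ relative tolerance. The Monte-Carlo
estimator is validated against it, never calibrated to it.

## Enrichment with a randomization null

The question probabilities are carried into enrichment *as probabilities*,
not thresholded calls, and annotations may themselves be probabilistic
(a membership weight $w_g \in [0,1]$ per gene-term pair). For a term, the
fuzzy contingency table over the gene universe is

$$n_{11} = \sum_g p_g w_g,\quad n_{10} = \sum_g p_g (1-w_g),\quad
  n_{01} = \sum_g (1-p_g) w_g,\quad n_{00} = \sum_g (1-p_g)(1-w_g),$$

which reduces to the classical 2×2 table when both inputs are crisp. The
association statistic is Yule's
$Q = (n_{11}n_{00} - n_{10}n_{01})/(n_{11}n_{00} + n_{10}n_{01}) \in [-1,1]$,
defined as 0 when both cross-products vanish. Significance comes from a
randomization null: the gene-to-probability assignment is permuted over the
universe (annotation structure preserved), and

$$p = \frac{1 + \#\{Q_{\mathrm{null}} \ge Q_{\mathrm{obs}}\}}{n_{\mathrm{perm}} + 1},$$

the add-one form guaranteeing $p \ge 1/(n_{\mathrm{perm}}+1)$ and a valid
test. Since the table margins are fixed under permutation, only $n_{11}$
varies, so one permutation set (a matrix crossproduct) serves every term;
`n_perm` defaults to 1,000. Benjamini–Hochberg adjusted values are emitted
in an extra column, but threshold filtering uses the raw p-value by
default. The gene universe is the expression dataset after tag mapping —
not the annotated genes — because the permutation null must draw from the
genes that could have been scored. This enrichment machinery is our
reconstruction of the published probabilistic-annotation approach this
method family delegates to; the statistic sits behind a small interface
(`fuzzy_table()` + `yules_q()`) so an alternative measure can be plugged
in.

A degenerate but informative case: if every gene has the same probability,
every permutation reproduces the observed table exactly and all p-values
are 1 (the test code asserts this, with a $10^{-12}$ tolerance on the
floating-point comparison of identical sums accumulated in different
orders).

## The simulator and what it does (not) emulate

`simulate_dataset()` generates data under the estimator's own sampling
model: baseline abundances log-uniform on $[10^{-6}, 10^{-3}]$ (the span
from rare transcripts to highly expressed ones in a tag library), counts
$N \sim \mathrm{Binomial}(T, \pi)$ per gene and library. A configured
fraction of genes (default 10%) is *planted* with a monotone profile —
abundance multiplied by `effect_size`$^{k-1}$ in condition $k$ — and the
truth labels drive ROC evaluation (`roc_curve()`, trapezoid AUC, tied
scores grouped; equal to the Mann–Whitney pair-count with half credit for
ties, which the tests verify exactly). Binomial rather than multinomial
sampling per gene is a simplification that is marginally equivalent at the
small abundances used; abundances are renormalized (with a warning) should
a planted configuration push a library's total above 1. With
`effect_size = 1` the planted labels carry no signal, giving the null
calibration case (AUC ≈ 0.5). Study defaults: 200 genes, 3 conditions,
$T = 10^5$ tags per library, effect 4 per step, scored at
`n_sims = 2000` — sizes chosen so a full power study is a desk-scale
computation while keeping Monte-Carlo error well below the effects under
study.

The simulator emulates sampling noise under the urn model with known truth.
It does **not** emulate overdispersion between biological replicates beyond
the mixture structure, tag-to-gene mapping ambiguity, sequencing error, or
library-construction biases — so passing the simulation study shows
correctness and power *under the model's own assumptions*, not robustness
to their violation on real libraries.

The comparison baseline (`naive_pairwise_score()`) is a transparent
stand-in for the classical intersect-the-pairwise-calls practice: a
one-sided two-proportion z-test per adjacent condition pair (replicates
pooled), combined as the minimum of $1 - p$ across pairs. It is labeled
naive deliberately; it is not a reimplementation of any specific published
tool.

## Design choices and limitations

* **Uniform prior, fixed.** No prior hyperparameters are exposed; the
  Beta(1,1) floor keeps every posterior proper, including all-zero genes.
* **Equal mixture weights.** Weighting components by library size would be
  a defensible alternative; it is not offered in this version so that the
  group model has no hidden tuning.
* **Shared-draw conjunctions.** Documented above; independent-draw
  semantics would make chained and explicit conjunctions differ.
* **Input dialect.** The TSV dialect (header of library ids, first column
  of gene/tag ids, optional `TOTAL` row for totals exceeding the retained
  column sums, `#` comments, transparent gzip) is this package's own
  definition, as is the 2–3 column annotation TSV next to standard GMT.
* **No fold-change questions.** `A > 2*B` style magnitude questions and
  Bayes-factor reporting are out of scope.
* **Monte-Carlo granularity.** $\hat P$ is a multiple of $1/S_n$; p-value
  floors and probability resolution are set by `n_sims` and `n_perm`, and
  both are reported in the outputs together with the seed and a config
  hash for provenance.
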