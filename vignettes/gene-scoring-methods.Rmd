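---
title: "Gene-wise scoring of common and rare variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-wise scoring of common and rare variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(generank)
```

## The problem

Genome-wide screens for complex traits face a gap between heritability and
what single common variants explain; rare variants are expected to carry
part of the missing signal, but single-marker tests on rare variants are
hopelessly underpowered at realistic sample sizes. A practical response is
to work gene by gene: collapse a gene's rare variants into a single carrier
indicator, combine it with the gene's common variants, compute one score
per gene, and rank all genes to pick a candidate list for replication.
`generank` implements this workflow end to end — collapsing, four gene-wise
scores, rank-based evaluation over simulation replicates, a mixed-model
comparison of analysis settings, and the characterisation of genes on which
methods disagree — together with the synthetic generators needed to study
it, since the mini-exome dataset that motivated the design (GAW17: 697
unrelated individuals, 24,487 variants, 200 phenotype replicates) is
access-restricted and cannot be redistributed.

Because ranking rather than testing is the goal, scores are used raw: no
genomic-control correction, and p-values (where defined) are stored but
never used for ordering. Ranking is invariant to any monotone
transformation, which also makes the comparison between methods fair when
their null distributions are differently inflated.

## The four gene scores

For a gene with markers $g_1, \dots, g_m$ (additive 0/1/2 coding;
supermarker 0/1) and an endpoint with covariate set $C$:

* **MS (maximum statistic)** — fit each marginal model
  $y \sim g_j + C$ and take $\max_j |t_j|$ of the genotype Wald
  statistics. No adjustment for $m$: this mirrors single-marker screening,
  and the null of the maximum is an order statistic whose exact p-value is
  deliberately not computed here. A signed variant (`signed = TRUE`) is
  available; the absolute maximum is the default since effects may point
  either way in general data.
* **HT (Hotelling's $T^2$)** — the quadratic form
  $t^\top R^{-} t$, where $t$ stacks the usable marginal statistics and
  $R$ is the pairwise Pearson correlation matrix of the genotype columns.
  $R^{-}$ is the Moore–Penrose pseudo-inverse, so collinear or duplicated
  markers contribute once instead of breaking the inverse;
  `df = rank(R)` and a $\chi^2_{df}$ p-value are attached. The phrase
  "correlation matrix of the markers" is read as genotype correlation, not
  correlation of the statistics.
* **MV (multivariate LRT)** — $2(\ell_{full} - \ell_{null})$ comparing the
  joint model with all of the gene's markers against the covariates-only
  null; for linear models this is $n \log(RSS_0 / RSS_1)$. Genetic columns
  collinear with the covariates or with earlier markers are pruned
  deterministically in marker order (squared residual norm below
  $10^{-10}$ relative), and `df` is the retained count.
* **LA (LASSO score)** — an L1 penalty on the genetic coefficients only
  (covariates and intercept unpenalised, via `glmnet` penalty factors),
  $\lambda$ chosen by K-fold cross-validated deviance at `lambda.min` with
  a seeded fold assignment; the score is
  $\mathrm{dev}(null) - \mathrm{dev}(penalised)$ on the same deviance
  scale as MV. It is non-negative by construction (the null model is in
  the feasible set), so tiny negative numerical values are clamped to 0.
  At $\lambda \to 0$ the score converges to MV; at
  $\lambda \ge \lambda_{max}$ it is exactly 0 — both limits are exposed
  through `lambda_override` and tested.

Endpoint models are fixed: Q1 is linear adjusted for Q2, age, sex,
smoking; Q2 linear adjusted for Q1, age, sex, smoking; AFF logistic
adjusted for Q1, Q2, Q4, age, sex, smoking. The mutual Q1/Q2 adjustment
deliberately reduces residual variance. Marginal fits flag rather than
fail: constant markers, covariate-collinear markers, and separated or
non-converged logistic fits return `NA` statistics, and gene scores are
computed over the remaining markers (a gene is `NA` only when every
marginal is unusable).

```{r}
fit_marginal(c(0, 1, 1, 2), endpoint_model("y", family = "linear"),
             data.frame(y = c(1, 2, 3, 4)))
```

## Datasets: collapsing and filtering

`build_analysis_dataset()` turns a genotype study into one of four analysis
datasets. With in-sample MAF $f$ and cutoff $c \in \{0.01, 0.05\}$:
a variant is *common* iff $f > c$ and *rare* iff $0 < f \le c$ (half-open,
so no variant is lost or double-counted at the boundary). CR-datasets add
one supermarker per gene — the indicator of carrying at least one minor
allele across the gene's rare *nonsynonymous* variants (synonymous rare
variants are discarded: collapsing targets direct functional effects,
while synonymous common variants are retained as LD proxies). After
collapsing, every marker with fewer than five minor alleles — supermarkers
included, since they are treated as markers everywhere else — is removed,
and genes left empty are dropped. MAF is computed on the analysed sample
itself; when the coded-allele frequency exceeds 0.5 the minor allele is
the reference allele and frequency and carrier logic flip accordingly.
Missing genotypes are not imputed; VCF import fails fast on a missing GT.

## The synthetic generators

Two generators stand in for data that cannot be shipped. Their defaults
are the study conditions; they are set once and documented here, not tuned.

**Mini-exome** (`simulate_exome`, `simulate_phenotypes`): 697 individuals
by default; gene marker counts uniform on 1–15 (matching a mini-exome
average of roughly 8 markers/gene); 75% of variants rare with MAF uniform
on (0.001, 0.01], the rest uniform on (0.01, 0.5); half of variants
nonsynonymous; genotypes Hardy–Weinberg draws at the marker's MAF. Causal
genes per endpoint default to 9 (Q1), 13 (Q2) and 15 (AFF) — magnitudes in
line with the mini-exome design — with 1–4 causal nonsynonymous markers
per causal gene and per-allele effects uniform on [0.3, 0.8] trait SD,
all deleterious. Q1 and Q2 are additive Gaussian traits over their causal
markers plus small covariate effects (age uniform 20–70, sex
Bernoulli(0.5), smoking Bernoulli(0.3)); Q4 is covariates-plus-noise only;
AFF is a liability threshold on standardised Q1 + Q2 contributions, its
own causal markers and unit Gaussian noise, thresholded at the empirical
quantile matching the configured prevalence (0.3), so observed prevalence
matches the target up to integer rounding. What this emulates is the
*topology* of the reference simulation — correlated quantitative traits, a
binary status driven partly through them, covariates present as
confounder adjustments — not its variant list, pedigrees, LD structure or
the 200 frozen phenotype replicates; population stratification and
genotyping error are absent. Passing tests therefore demonstrate correct
statistical behaviour under this structure, not performance on real
sequence data.

**Case-control scenarios** (`simulate_case_control`): a panel of null genes
with a fixed number of independent markers (allele frequencies uniform on
(0.01, 0.5)), plus one causal gene in which 1–3 markers carry a per-allele
odds ratio. The generating model is a logistic penetrance
$\mathrm{logit}\,P(D=1\mid g) = \mathrm{logit}(p_0) + g \log(OR)$ with
baseline prevalence $p_0 = 0.01$; cases and controls are drawn
retrospectively from the exact genotype-given-status distributions
obtained by Bayes enumeration over $g \in \{0,1,2\}$
(`genotype_given_status`), which matches the stated odds ratio exactly and
avoids rejection sampling. Causal markers are sampled independently given
status, so multi-causal genes carry genuinely independent signals. The
scenario's "common or collapsed markers" are simulated directly as
biallelic columns; no within-scenario collapsing is performed.

## Evaluation and the scenario comparison

Genes are ranked by descending score (rank 1 best), ties get the average
rank, and missing scores are ranked last and flagged. The power surrogate
is the number of truly causal genes among the top
$N \in \{10, 20, 50, 100, 200, 500\}$; a tie straddling $N$ counts only if
the average rank lands below $N + 0.5$. Counts are averaged over
replicates, and scenarios are compared per endpoint and per $N$ with a
linear mixed model (REML, `lme4`): method, AF cutoff, rare-variant use and
the cutoff-by-use interaction as fixed factors, the simulation replicate
as a random intercept. The replication driver holds the exome and its
truth table fixed and draws phenotype replicates on top — mirroring a
mini-exome with frozen genotypes and many phenotype simulations, and the
only mode in which per-gene median ranks over replicates are meaningful;
full re-simulation per replicate is available via
`resimulate_genotypes = TRUE`. The reference analysis ran this per cutoff and
phenotype as well, which is why a univariate model per stratum is the
declared interpretation of its "multivariate" mixed model. Contrasts are
computed as differences of model-implied marginal cell means, so under a
balanced design each method contrast equals the mean paired difference of
counts, and all method contrasts are invariant to per-replicate shifts
(absorbed by the random intercept). Unbalanced designs are rejected with
the missing cells named rather than silently reweighted.

Permutation p-values (`permutation_pvalues`) permute the phenotype table
rows — endpoint and covariates jointly, preserving their mutual structure
while breaking all genotype links — with one shared permutation stream for
all genes, and use the add-one convention
$p = (1 + \#\{S_{perm} \ge S_{obs}\}) / (B + 1)$. Ties are counted with a
$10^{-8}$ relative slack so exact ties are not split by floating-point
noise.

## Characterisation of method disagreements

For each causal gene, the median rank over replicates (midpoint convention,
missing ranks excluded) summarises each method's performance; the ratio
$\mathrm{med}_{MS} / \mathrm{med}_{other}$ classifies the gene as MS-better
(< 0.9), other-better (> 1.1) or neither, and a gene is *undetectable*
unless at least one method achieves a median rank of 1,000 or better. (The
source text's wording of the detectability rule is self-contradictory —
"rank greater than 1,000" alongside "otherwise undetectable" — and the
reading implemented is the only internally consistent one: detectable means
rank at or below the bound. Note also that the 0.9/1.1 band endpoints are
not reciprocal, so classification of a gene and its mirror can disagree in
the narrow zones (0.900, 0.909) and (1.100, 1.111); this boundary effect is
inherent to the published band.) The frequency-adjusted effect size of a
causal marker is $|\beta|\sqrt{2f(1-f)}$ — the SD of an additive HWE
genotype, the only reading of "$\beta$ multiplied by the standard deviation
of the allele frequency" that yields a standardised effect — and for a
supermarker $|\beta|$ times the empirical SD of its 0/1 column, with the
supermarker's $\beta$ taken as the mean effect of its causal contributing
variants (a regression estimate would be used in real-data mode). Group
comparisons use a two-sided Mann–Whitney test, exact for small untied
samples, because the characteristics are skewed counts and ratios; means
are over genes within each dataset, and singleton groups report a mean
with `NA` SD and no p-value.

## Numerical choices

* Hotelling pseudo-inverse: eigenvalues below $10^{-10}$ of the largest
  are treated as zero; when $R$ is nonsingular the result agrees with the
  explicit inverse to well below $10^{-8}$.
* Marginal linear fits use one QR of the covariate design and
  Frisch–Waugh–Lovell residualisation, exactly reproducing per-marker OLS;
  covariate-free logistic fits use a vectorised Newton solver on the
  aggregated 3×2 genotype-by-status tables (the exact per-marker `glm`
  likelihood, unit-tested against it); logistic fits with covariates fall
  back to `glm.fit` with a separation guard at $|\hat\beta| > 15$.
* `glmnet` at a fixed `lambda_override` is fitted along a short decreasing
  path with `thresh = 1e-14`, avoiding single-$\lambda$ warm-start error;
  this is what makes the $\lambda \to 0$ limit meet MV at $10^{-6}$
  relative tolerance.
* Tie-breaks: the MS arg-max takes the first marker in dataset order;
  rank ties get average ranks; MV pruning keeps earlier markers.
* Seeds: every stochastic entry point takes an explicit seed;
  `derive_seed(master, index)` gives reproducible per-replicate and
  per-gene streams inside the 32-bit range.

## Problem sizes

The shipped analysis scripts and acceptance checks run at desk scale,
chosen as this package's own defaults: the crossover study uses 200 null
genes, 100 causal-gene replicates per cell and $N = 1000$ cases (the
reference design used 2,000 null genes and 1,000 replicates), over a
representative sub-grid of the full scenario design — markers/gene
$\{2,3,5,7\}$, causal AF $\{0.05, 0.20\}$, OR $\{1.3, 1.7\}$, causal
markers $\{1,2,3\}$, 44 cells in all. The replication study scripts use
200-400 genes and around 10 replicates instead of a full mini-exome with
200 replicates. These sizes keep every conclusion qualitative: the
crossover (MS wins single-causal genes, HT wins multi-causal genes) is
expected to hold cell-wise, and does; the quantitative Table-style
estimates depend on the restricted real dataset and are reproduced in
structure, not in value.

## Known limitations

* The exome generator does not model LD between markers; HT and MV face a
  friendlier correlation structure here (identity, up to sampling noise)
  than in real genes. The crossover scenarios inherit this: "independent
  causal variants" is exact by construction.
* Logistic marginal fits under heavy separation are flagged missing rather
  than refit with a penalty, keeping the four methods comparable; genes
  scored over few usable markers are noisier.
* The LASSO score depends on the CV fold assignment; it is deterministic
  given the seed but not invariant to it. Score ranks are stable, single
  scores near $\lambda_{max}$ can sit exactly at 0.
* Strong scenario cells saturate (every method ranks the causal gene
  first); median-rank comparisons there are ties, informative only that
  neither method loses.
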