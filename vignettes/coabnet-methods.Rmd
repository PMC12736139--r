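---
title: "Methods: differential co-abundance networks from compositional data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-abundance networks from compositional data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coabnet)
```

# The model

`coabnet` treats a genus-level relative-abundance table as the closure
of an unobserved positive basis: sample $i$ carries latent
log-abundances $z_i \in \mathbb{R}^p$, and we observe
$x_{ij} = e^{z_{ij}} / \sum_k e^{z_{ik}}$, possibly after multinomial
read sampling.  The scientific object is the correlation matrix of the
latent $z$, not of the observed fractions: closure alone induces
spurious negative correlation of order $-1/(p-1)$ among observed parts,
which is why the package never correlates relative abundances directly.

## Latent correlation with an L1 penalty

Only the projection of the latent covariance onto the complement of the
all-ones direction is identifiable from compositions.  With $S$ the
empirical covariance of log-composition and $P = I - \tfrac1p 11^\top$,
`fitLatentCorrelation()` solves

$$\min_{\Sigma \succeq 0,\ \Sigma = \Sigma^\top}\ \tfrac12 \lVert
P(\Sigma - S)P \rVert_F^2 \;+\; \lambda \sum_{i<j} |\sigma_{ij}|$$

by consensus ADMM: a closed-form quadratic step (the normal equation
$P X P + 2\rho X = A$ splits exactly along the eigenspaces of $P$),
projection onto the PSD cone by eigenvalue truncation, and elementwise
soft-thresholding of the off-diagonal entries.  The estimate is
rescaled to a correlation matrix once, at convergence
($D^{-1/2}\Sigma D^{-1/2}$), not per iteration — rescaling inside the
loop would interact with the threshold level.  Identifiability caveat:
components of $\Sigma$ in the $11^\top$ direction are fixed only by the
penalty and the consensus coupling, so two datasets identical up to
per-sample basis rescaling give identical estimates only after closure;
the exported fitter therefore documents closed compositions as its
intended input.

Numerical choices: convergence is declared when successive iterates
agree to `tol = 1e-6` in max-norm; the cap is `maxIter = 2000`, and
hitting it flags the result (`converged = FALSE`) with a warning rather
than failing, so a pipeline over many strata can finish and report.
Zeros are replaced beforehand (`replaceZeros()`) by half of the
smallest non-zero value in the table, followed by re-closure — the
simplest multiplicative replacement; nothing in the downstream chain is
sensitive to the constant as long as it is small and shared.

The penalty defaults to a fixed `lambda = 0.05`; `selectLambda()`
offers k-fold cross-validation minimising the held-out projected loss
$\tfrac12\lVert P(\hat\Sigma_{\text{train}} - S_{\text{test}})P
\rVert_F^2$, applied per network (per group and region) since strata
differ in sample size.  On pure-noise data the procedure picks the
heaviest grid value, which is the behaviour that matters for false
edges.

## Pooling edges across regions

Each unordered taxon pair yields one correlation per (group, region).
Within a group, `poolRandomEffects()` pools the per-region estimates on
the Fisher-Z scale, $z_i = \operatorname{atanh}(r_i)$ with
$se_i = 1/\sqrt{n_i - 3}$, using the DerSimonian–Laird moment estimator

$$\tau^2 = \max\!\left(0,\ \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 /
\sum w_i}\right), \qquad w_i = se_i^{-2},$$

random-effects weights $w_i^* = 1/(se_i^2 + \tau^2)$, and a two-sided
Wald test of the pooled effect.  DL is used because it is the standard
default of the meta-analytic tooling this stage mirrors; no
Hartung–Knapp small-sample adjustment and no REML option are provided
in this version.  The FDR family is all $p(p-1)/2$ pairs within a
group.

## Differential edges

Between the two groups each edge has two pooled effects with standard
errors, compared by the fixed-effect Cochran's Q with one degree of
freedom; $I^2 = \max(0, (Q-1)/Q)$ and the heterogeneity p is the upper
$\chi^2_1$ tail.  An edge is differential when $I^2 > 0.75$ **and**
$p < 0.05$.  A point worth recording: with df = 1 these two criteria
are nested — $I^2 > 0.75 \iff Q > 4$, and $Q > 4$ already implies
$p = P(\chi^2_1 > 4) = 0.0455 < 0.05$ — so the conjunction is
equivalent to the $I^2$ threshold alone.  Both are still computed and
reported, since the thresholds are configurable independently.

The set of edges *eligible* for differential testing defaults to the
union of edges significant (FDR < 0.05) in either group; intersection
and all-pairs alternatives are available (`eligible=` argument).  The
union is the natural family when the question is "which associations
present in at least one group changed", and no multiplicity adjustment
is applied to the heterogeneity p — the differential rule is a
pre-specified conjunction, not a discovery scan.

## Covariate adjustment

For the genera incident to differential edges, the full Pearson
correlation matrix over [log abundances of involved genera +
numerically encoded covariates] is inverted and rescaled
($\mathrm{pcor}_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$).
Each genus pair's partial correlation therefore conditions on **all**
covariates and the other involved genera simultaneously — that is what
the matrix inverse yields, and it is the deliberate reading of an
otherwise ambiguous "adjust the matrix" instruction.  Ordinal
covariates enter as integer scores (never/former/seldom/everyday and
the like, in level order); adjustment runs on the pooled cohort by
default because the correlation matrix over both groups is better
conditioned, with per-group use possible by subsetting first.  The
before/after comparison reuses the df = 1 Q test with the shared
standard error $1/\sqrt{n-3}$ on both coefficients, and robustness
means $p > 0.05$.

## Keystone screening (EPI)

Candidates are taxa with prevalence in the closed window
$[0.25, 0.75]$ — frequent enough that both presence classes are
populated, not so frequent that absence is an anomaly.  For each
candidate the samples are split by presence (> 0 on the raw table,
before any pseudocount), the candidate's column is removed, the rest is
renormalised per sample, and three indicators are computed:

* **D1** — Bray–Curtis distance between the two partitions' mean
  renormalised profiles;
* **D2** — mean over remaining taxa of the two-sample
  Kolmogorov–Smirnov statistic between the partitions;
* **Q** — Newman modularity of the presence bipartition on a k-nearest
  neighbour sample graph (k = 10 by default) weighted by Bray–Curtis
  similarity.

Since no canonical formulas exist for these indicators in the tooling
this package mirrors, these concrete operationalisations are isolated
behind `epiIndicators()` so alternatives can be slotted in; results
should not be assumed numerically comparable to other EPI
implementations.  Significance uses a permutation null (presence labels
shuffled, prevalence preserved exactly, 95th percentile), with the
permutation stream seeded per taxon.

A limitation found while validating on multinomial data: at shallow
sequencing depth, a sample in which the candidate soaks up many reads
leaves fewer reads for everyone else, so the *sampling noise* of the
renormalised profiles differs between presence classes.  D2, which
compares whole distributions, can then exceed its permutation null even
for taxa with no planted effect — the label permutation cannot mimic a
depth artifact that travels with the label.  D1 (a mean comparison) is
much less sensitive.  Keystone claims should therefore rest on the
conjunction of indicators, which is how the test suite asserts them.

## Abundance and function testing

Per feature: rank-based inverse normal transform with the Blom offset
($\Phi^{-1}((r - 0.375)/(n + 0.25))$, average ranks for ties), OLS
residualisation on the covariates, then a Wilcoxon rank-sum test
between groups on the residuals.  The transform-then-residualise-then-
rank-test order is the package's reconciliation of a procedure
description that lists regression adjustment and rank-sum testing side
by side without saying how they compose; the Blom offset is the common
convention and is configurable.  The Wilcoxon p is exact by full
enumeration of $\binom{n}{n_a}$ group assignments when the pooled size
is at most 12, and otherwise uses the normal approximation with tie and
continuity corrections (numerically identical to
`wilcox.test(..., exact = FALSE, correct = TRUE)`).  BH adjustment runs
within each feature family (genera, EC, KO, pathway) — these are
separate analyses, not one family.

## Variance decomposition

For a functional feature $Y$ and genus pair $(\chi_1, \chi_2)$, both
inverse-rank transformed, two nested OLS fits give
$R^2_{\text{ind}}$ (additive) and $R^2_{\text{int}}$ (with the product
term); `extra_var` is their difference and `share` its fraction of
$R^2_{\text{int}}$.  Two p-values are reported because the printed
tables this mirrors are ambiguous about which F-test their column
tracks: `p_ind`, the additive model's overall F (df 2, n−3), and
`p_interaction`, the nested F of the product term
($F = \text{extra\_var} / ((1 - R^2_{\text{int}})/(n-4))$, df 1, n−4).
Models are fitted on the pooled cohort and contain no covariate terms —
the decomposition asks a descriptive question about the feature, not an
adjusted one.

# The synthetic-data generator

`simulateDataset()` is the package's test bed, and its defaults *are*
the study conditions the pipeline was designed around: two groups of
221 and 382 participants split over three regions, 93 genera,
logistic-normal latent structure, and multinomial sampling.  Per
stratum, latent log-abundances are drawn from
$\mathcal N(\mu, R_{g})$ — the logistic-normal model is chosen because
it is exactly the generative assumption under which the latent
correlation estimator is consistent, making planted-edge recovery a
fair test of the estimator rather than of model mismatch.  Zeros arise
only through finite multinomial depth (default 50,000 reads, a typical
long-read 16S per-sample yield; the source cohort's depth and zero
fraction are not public, so this default is chosen for testability,
not fidelity).  Covariates follow the cohort's published demographic
frequency tables (age means/SDs, sex ratios, ordinal lifestyle
frequencies, gamma-distributed dietary intakes) and can load on
configurable taxa via latent shifts.

Planted structures are honoured exactly: group-specific correlation
matrices start from a shared sparse base graph plus the planted
differential values; if the assembled matrix is not PSD the *base*
entries are shrunk (with a diagonal-jitter fallback) until it is, and
if the planted values alone are infeasible the configuration is
rejected with the offending eigenvalue — planted truth is never
silently altered.  Keystones are planted post hoc
(`plantKeystone()`) by shifting latent means of chosen taxa in samples
where the candidate is present and re-sampling counts
deterministically from the dataset seed.

What the generator does **not** emulate: real taxon-abundance
distributions (no heavy-tailed basis beyond log-normal), phylogenetic
structure, batch effects between regions (regions share the group's
correlation matrix and differ only by sampling), longitudinal
dependence, or PICRUSt2-style function prediction (function columns are
direct noisy functions of two latent taxa).  Green tests therefore
demonstrate correctness of the *machinery* under its own model, and
power under idealised conditions; they do not certify performance on
real cohorts.

# Calibration notes and problem sizes

The heterogeneity p-value is exactly uniform under the null when the
two pooled effects share a mean and carry correctly specified standard
errors, and the test suite verifies this (KS < 0.05 over 2000 null
edges).  The *composite* chain — estimate DL $\tau^2$ from three
regions, then test — is only approximately calibrated, because
$\tau^2$ estimated from $k = 3$ is noisy; that is an inherent
small-$k$ property of moment-based random-effects meta-analysis, and it
is controlled empirically by the end-to-end criterion (median ≤ 2
false differential calls at n = 200 per stratum across 10 seeds)
rather than by a uniformity assertion.

Default validation sizes, chosen to exercise each property at the
smallest scale where it is informative: support recovery at
$p = 20$, $n = 500$, 10 planted edges, 10 seeds (median AUC ≥ 0.9 —
observed 1.0); end-to-end recovery at 15 taxa, $n = 200$ per
group/region, 5 planted edges with $\Delta z \approx 0.7$, 10 seeds;
null calibration at 2000 edges; keystone false-flag rate over ~20
exchangeable taxa at $B = 200$ permutations; variance-decomposition
nulls over 300 (pair, feature) fits at $n = 600$.

# Known limitations

* The latent-correlation solver returns a local view of a convex
  problem and is accurate to its tolerance, but the penalty level, not
  a formal error control, governs which small edges survive; inference
  enters only at the meta-analysis stage.
* With df = 1, the $I^2$ and Q-test thresholds are redundant (see
  above); changing either default changes the effective rule.
* The EPI indicators are this package's operationalisation; their
  permutation null does not capture depth-driven heteroscedasticity
  (see the D2 note), and modularity depends on the k-NN graph's k.
* Partial-correlation adjustment assumes approximately linear
  covariate–taxon relations on the log scale and integer scoring of
  ordinal covariates.
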