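---
title: "Measuring two-rater agreement with Cohen's and weighted kappa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring two-rater agreement with Cohen's and weighted kappa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raterkappa)
```

## The model

Two raters independently assign each of $n$ subjects to one of $k$
categories (a fully-crossed design: every subject is rated by both).
Their labels tally into a $k \times k$ contingency table with joint
proportions $p_{ij}$ (row $i$ = rater A's category, column $j$ = rater
B's), row marginals $p_i = \sum_j p_{ij}$ and column marginals
$q_j = \sum_i p_{ij}$. Raw agreement overstates reliability because two
raters who never confer still agree by chance whenever their marginal
category habits overlap. Kappa corrects for that:

$$\kappa \;=\; \frac{P_o - P_e}{1 - P_e}, \qquad
  P_o = \sum_{ij} w_{ij}\, p_{ij}, \qquad
  P_e = \sum_{ij} w_{ij}\, p_i\, q_j ,$$

where the $w_{ij} \in [0,1]$ are agreement weights with unit diagonal.
Identity weights give Cohen's kappa: $P_o$ is the fraction of exact
agreements and $P_e$ the chance-expected fraction, computed per category
as the product of the two raters' marginal proportions. The power scheme

$$w^{(m)}_{ij} = 1 - \left(\frac{|i-j|}{k-1}\right)^{m}, \qquad m \ge 1,$$

defined on the 0-based consecutive integer indices of the ordered
labels, awards partial credit that decays with the distance between the
two categories: $m = 1$ is the linear weighted kappa (LWK), $m = 2$ the
quadratic (QWK). Any real $m \ge 1$ is accepted; only these two have
conventional names. For $k = 2$ the normalised distance is 0 or 1, so
every power collapses to the identity matrix and weighted kappa equals
Cohen's kappa — one of the invariants the test suite checks. Custom
weight matrices are accepted too (weight choice is ultimately expert
judgment) but must be symmetric with unit diagonal.

Assumptions worth stating: the raters are independent given the subject
(mutual influence inflates agreement and is not modelled), every subject
is rated by both raters, and the declared scale — not the observed one —
defines the category set. Categories never used keep their zero row and
column, because the power weights depend on distances over the full
declared scale.

### Which statistic for which scale

`select_statistic()` encodes the selection rule: two categories
$\rightarrow$ Cohen's kappa (there is nothing to weight); three or more
nominal categories $\rightarrow$ Cohen's kappa (nominal labels carry no
distance); three or more ordered categories $\rightarrow$ weighted
kappa, reporting both LWK and QWK, since the two weightings summarise
the disagreement distribution differently and their comparison is
informative.

## Inference

The variance of $\hat\kappa_w$ uses the large-sample *non-null* form of
Fleiss, Cohen and Everitt (1969), with
$\bar w_{i\cdot} = \sum_j w_{ij} q_j$ and
$\bar w_{\cdot j} = \sum_i w_{ij} p_i$:

$$\widehat{\mathrm{var}}(\hat\kappa) = \frac{\sum_{ij} p_{ij}\,
  [\,w_{ij} - (\bar w_{i\cdot} + \bar w_{\cdot j})(1-\hat\kappa)\,]^2
  - [\,\hat\kappa - P_e (1-\hat\kappa)\,]^2}{n\,(1 - P_e)^2}.$$

Cohen's kappa is the identity-weight case of the same formula, so one
estimator serves the whole family, and the SE scales as $1/\sqrt n$.
Design choice: the same non-null SE drives both the Wald interval
$\hat\kappa \pm z_{1-\alpha/2}\,\mathrm{SE}$ and the two-sided test of
$\kappa = 0$, which makes "$p < \alpha$" and "the CI excludes 0"
logically equivalent — the consistency a reader expects between a
printed CI and its significance star. A null-variance test (marginals
held fixed under independence) would be slightly more powerful at
$\kappa = 0$ but breaks that equivalence; we prefer coherence. The test
is two-sided: disagreement beyond chance ($\kappa < 0$) is as reportable
as agreement.

Intervals are clipped to $[-1, 1]$, kappa's parameter space, after
construction. A zero SE with a non-zero point (e.g. a purely diagonal
table) yields a degenerate interval that is flagged rather than hidden.
A table in which both raters assign the single same category to every
subject has $P_e = 1$ and kappa is genuinely undefined: the package
signals a classed `undefined_kappa` error instead of returning a number.

The percentile bootstrap (`bootstrap_ci()`) is the model-light
cross-check: subjects are resampled with replacement (given a table
rather than subject-level ratings, the cell counts are redrawn
multinomially — the same distribution), kappa is recomputed per
replicate, and the $\alpha/2$ and $1-\alpha/2$ quantiles are reported.
Percentile rather than BCa, for transparency. Defaults: $\alpha = 0.05$,
`n_boot = 2000`, and the seed is mandatory — a bootstrap that cannot be
replayed is not evidence. Replicates with undefined kappa are dropped
and counted; more than half undefined aborts with a diagnostic. At small
$n$ the bootstrap distribution is skewed where the Wald interval is
symmetric by construction, so the two methods agree closely near
moderate kappas and diverge (mostly in the lower bound) for strongly
weighted statistics on tables dominated by one category; agreement
within 0.08 on the bundled 31-subject testing comparison is what the
test suite checks, not bound-for-bound identity everywhere.

## Interpretation

`interpret_agreement()` maps magnitudes onto the Landis–Koch bands —
$\le 0$ no agreement, $(0, 0.20]$ slight, $(0.20, 0.40]$ fair,
$(0.40, 0.60]$ moderate, $(0.60, 0.80]$ substantial, $(0.80, 1]$ almost
perfect. The bands are a community convention, not a theorem; the edges
are configurable. Intervals are closed on the right, so a kappa of
exactly 0.40 reads "fair". The significance gate (default on) reports
"no agreement" for any estimate with $p \ge \alpha$ regardless of its
size, mirroring a common reporting rule; it is a flag because the
convention is not universal, and switching it off never relabels a
significant estimate.

## The simulator

`joint_model()` + `sample_ratings()` draw i.i.d. subjects from an
arbitrary joint distribution over category pairs (one multinomial over
the $k^2$ cells, subjects laid out in index order so a seed pins the
sample). `population_kappa()` evaluates the kappa functional on the
model itself, giving the estimand in closed form. This is exactly the
data-generating process the estimator assumes — independent,
fully-crossed, stationary raters — which is what makes it the right
instrument for calibration checks (does the 95% CI cover the true kappa
about 95% of the time? is the estimator unbiased at large $n$?) and
precisely *not* a model of real raters, who drift, confer, and see
non-exchangeable subjects. Passing calibration here validates the
arithmetic and the asymptotics, not the behavioural assumptions.

The test battery fixes the joint model at the empirical proportions of
the bundled 31-subject testing comparison and uses 1000 replicates of
$n = 200$ for CI coverage (accepting 93–97%), a five-seed battery at
$n = 20{,}000$ for bias (mean absolute error below 0.01), and 500
replicates of $n = 1984$ against the closed-form SE — sizes chosen to
make Monte-Carlo error small relative to the tolerances while keeping
the default suite fast.

`prevalence_paradox_demo()` isolates the best-known failure mode of
Cohen's kappa on the cleanest possible case, a $2 \times 2$ table:
holding raw agreement fixed at $P_o$ and skewing both raters' marginals
to $(s, 1-s)$ forces off-diagonal mass $(1-P_o)/2$ per cell, and chance
agreement $P_e = s^2 + (1-s)^2$ grows with $s$, so
$\kappa = 1 - (1-P_o)/(1-P_e)$ falls monotonically — from 0.60 at
balanced marginals with $P_o = 0.8$ to negative values near the
feasibility edge $s = (1+P_o)/2$. Infeasible (agreement, skew)
combinations are returned as flagged rows, not dropped. When one
category dominates, report the raw agreement and the marginals alongside
kappa, or prefer a weighted variant on an ordered scale.

## Numerical and presentation choices

* All computation is in double precision; nothing is rounded
  internally. Rendered reports round half-away-from-zero to 2 decimals,
  the convention of the source tables this package reproduces.
* The category-index convention for the power weights is 0-based in
  label order; the normalised distance $|i-j|/(k-1)$ makes the 0- vs
  1-based choice immaterial, but it is fixed and documented.
* JSON reports serialise at 17 significant digits so that every stored
  statistic replays bit-for-bit from the embedded count matrix.
* Power-weighted kappa is invariant to reversing the label order (the
  distance matrix is), and Cohen's kappa to any label permutation; both
  are invariant to transposing the table. These are regression-tested
  invariants, useful for catching indexing bugs.

## The bundled reanalysis

`recist_fixtures()` ships six 3×3 confusion matrices of RECIST 1.1
response categories (PR < SD < PD, the order that determines the
weights) from a published liver-metastases study: raters R1, R2 and an
automated segmentation method against a reference standard, in a
testing dataset and a validation cohort, $n = 31$ each.
`reproduce_table1()` recomputes Cohen's, linear and quadratic weighted
kappa with CIs and verdicts for all six comparisons:

```{r}
rep <- as.data.frame(reproduce_table1())
rep[, c("id", "statistic", "kappa", "ci_low", "ci_high", "p_value",
        "verdict")]
```

The agreement values the original study reported for these matrices
(stored as `reference_kappa` metadata) were computed by an unstated
method and do not match any statistic in this family; they are carried
for comparison, never recomputed. Of the eighteen statistics, exactly
the three for R2 in the testing dataset are non-significant at
$\alpha = 0.05$ — with the gate on, that comparison reads "no
agreement" however its point estimate might otherwise be labelled.

## Limitations

Two raters only: Fleiss' kappa, intraclass correlation and
Krippendorff's alpha are out of scope, as are missing ratings and
models of inter-rater dependence. The asymptotic SE is a large-sample
result; at $n$ in the low dozens, the bootstrap is the safer citation
and exact small-sample tests are not provided. Interpretation bands are
conventions — report the estimate and interval, not just the label.
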