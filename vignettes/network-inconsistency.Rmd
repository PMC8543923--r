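---
title: "Assessing global inconsistency in networks of interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing global inconsistency in networks of interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdbt)
```

## The problem

Network meta-analysis (NMA) pools randomised trials that compare different
subsets of a common set of interventions, combining direct head-to-head
evidence with indirect evidence that travels around the network through
shared comparators. The validity of that pooling rests on *consistency*:
direct and indirect evidence about the same comparison must agree, up to
heterogeneity and sampling error. When studies with different *designs* —
different sets of compared treatments — systematically disagree, the network
is inconsistent and pooled estimates are unreliable.

`netdbt` implements a frequentist, contrast-based assessment of global
inconsistency for dichotomous outcomes on the odds-ratio scale:

1. arm-level counts are converted to study-level baseline-contrast log odds
   ratios with their exact within-study covariance (multi-arm studies
   contribute correlated blocks);
2. the *consistency model* and the *design-by-treatment interaction (DBT)
   model* are fitted by generalized least squares;
3. all inconsistency parameters are tested jointly with a Wald chi-squared
   statistic;
4. a survey layer batches this over collections of networks and relates the
   resulting p-values to structural network characteristics.

A synthetic network generator with known truth backs every stage with
Monte-Carlo evidence, so the operating characteristics of the test (type-I
error, power, heterogeneity recovery) are themselves testable artifacts.

## Model

For study $i$ with $a_i$ arms, the observed contrasts versus the study's
baseline arm are

$$y_i \sim N(X_i \beta, \; S_i + \tau^2 P_i),$$

where $\beta$ holds the $T-1$ *basic parameters* (log odds ratios of each
treatment versus a reference), $S_i$ is the exact within-study covariance
(off-diagonals $1/e_b + 1/(n_b-e_b)$ from the shared baseline arm), and
$P_i$ is a compound-symmetry matrix with unit diagonal and off-diagonal
$1/2$. The common between-study variance $\tau^2$ multiplied by $P_i$ gives
every pairwise contrast within a multi-arm study the same heterogeneity
variance $\tau^2$ — the only correlation structure compatible with a single
shared $\tau^2$ across all comparisons.

The DBT model replaces $X\beta$ by $X_{\mathrm{dbt}}\theta$, giving every
design its own set of relative-effect parameters. Consistency constrains
$\theta = A\beta$, where $A$ is the embedding with
$X_{\mathrm{dbt}} A = X$. The inconsistency parameters are
$\omega = C\theta$ for any basis $C$ of the left null space of $A$; they
vanish exactly under consistency, and their number is

$$\mathrm{df} = \sum_d (t_d - 1) - (T - 1),$$

the rank surplus of the DBT design matrix over the consistency one. The
global test plugs in the within-design $\hat\tau^2$ (estimated under the
DBT model), fits $\hat\theta$ with covariance $V$, and refers

$$Q_{\mathrm{inc}} = \hat\omega' (C V C')^{+} \hat\omega$$

to $\chi^2_{\mathrm{df}}$. The statistic is invariant to the choice of
basis $C$ (taken orthonormal from the SVD of $A$, singular values below
$10^{-8}$ of the largest treated as zero), to the reference treatment, and
to the baseline-arm convention within studies; an equivalent computation as
the drop in generalized residual sum of squares between the two models at
the same $\tau^2$ is carried along as an internal cross-check.

Two roles of heterogeneity matter for interpretation: the DBT model's
$\hat\tau^2$ measures *within-design* variation only, while the consistency
model's $\hat\tau^2$ also absorbs between-design disagreement. A consistency
fit that is markedly more heterogeneous than the DBT fit is itself a signal
of inconsistency, and the `tau_recovery()` harness reproduces this mechanism
under planted design shifts.

## Estimation

*Contrasts.* The baseline arm of a study is its lexicographically smallest
treatment label (a determinism device; all reported results are invariant
to it, which the test suite verifies by refitting under the opposite
convention). If any cell of any arm of a study is zero, 0.5 is added to
every cell of every arm of that study (events $+0.5$ out of $n+1$) —
a study-level continuity rule matching common NMA software defaults — and
studies with zero events in all arms are retained after correction.

*GLS.* Fits use blockwise Cholesky factorizations of
$S_i + \tau^2 P_i$; cross-products are inverted by Cholesky when full rank
and by Moore–Penrose pseudo-inverse (SVD, relative tolerance $10^{-8}$)
otherwise. Networks whose studies are all two-arm reduce to scalar blocks
and take a vectorized path; the two paths agree to machine precision.

*DerSimonian–Laird.* The matrix method-of-moments estimator
$\hat\tau^2 = \max\{0, (Q - \mathrm{df}) / \mathrm{tr}[(W_0 - W_0 M (M'W_0
M)^{+} M' W_0) P]\}$ with $W_0 = S^{-1}$, which reduces exactly to the
classical DL formula in a pairwise meta-analysis.

*REML.* The restricted likelihood
$-\tfrac12[\log|\Sigma| + \log|M'\Sigma^{-1}M|_+ + \mathrm{RSS}]$ is
maximized by root-finding on its analytic derivative (score), bracketed
from zero and solved to $10^{-10}$. Every term of the score is invariant to
the design-matrix basis, so the estimate cannot depend on the reference
parameterization even at the level of optimizer arithmetic — a property a
golden-section search on the likelihood does not share. A non-positive
score at the origin puts the estimate on the $\tau^2 = 0$ boundary.

*Q and I².* Cochran's Q is the generalized residual sum of squares of the
$\tau^2 = 0$ fit; $I^2 = \max(0, 1 - \mathrm{df}/Q) \cdot 100$, undefined
(reported `NA`) when the model is saturated. Q decomposes exactly as
$Q_{\mathrm{total}} = Q_{\mathrm{within}} + Q_{\mathrm{between}}$, with the
within part computable two ways (per-design pooled fits, or the DBT
residual) — the package computes it the first way and the test suite checks
the identity against the second on random networks.

## Survey statistics

The survey layer records, per network: the structural metrics (studies,
treatments, direct comparisons, designs, independent loops, multi-arm
studies, the inconsistency df, and six ratio metrics), the DBT p-value
under REML and DL, $\hat\tau$ under both models and estimators, and $I^2$.
Several analysis conventions were genuinely open and are fixed as follows:

* **Loops** are counted as the dimension of the cycle space of the simple
  graph of direct comparisons (edges − nodes + components): repeated
  studies and the internal edges of a multi-arm design collapse to single
  edges, so a triangle contributes one loop however it is built.
* **Correlations** are Pearson coefficients of the *raw* DBT p-value
  against the *log* of each characteristic; networks with zero multi-arm
  studies are treated as having one before the log so they are retained.
* **Group comparisons** (outcome type, comparison type, complex
  interventions, single-study comparisons) use the Kruskal–Wallis rank
  test, the natural companion of a box-plot presentation; quartiles are
  reported on the raw and fourth-root scales, the latter display-only.
* **The multivariable regression** of the p-value on studies, treatments,
  direct comparisons and loops is a Gaussian-identity `glm` (ordinary
  least squares) on the raw p-value.
* **Year trends** are assessed with a chi-squared trend test on
  inconsistent-versus-consistent counts per publication year.

Networks failing the eligibility screen — connected, at least four
treatment nodes, at least one closed loop, no single-arm studies — are
skipped with a logged reason rather than analysed.

## The synthetic generator

`sim_config()` describes a data-generating process; `simulate_network()`
draws one network from it. Per study, a baseline logit is drawn (default
logit-normal, mean `qlogis(0.2)`, sd 0.5, so baseline risks and hence
contrast variances vary across studies as in real collections; a fixed-risk
option exists for analytic checks); study-level random effects with
variance $\tau^2$ and compound-symmetry correlation 0.5 are added to the
non-baseline arms; inconsistency is injected as fixed design-level shifts
$\omega_d$ — the DBT model's own alternative hypothesis — rather than
loop-level perturbations. Event counts are binomial. A root seed spawns
per-replicate substreams, so replicate $i$ is reproducible independently of
how many replicates ran before it.

What the generator does *not* emulate: empirically sampled network
geometries, non-randomised designs, selective reporting, dose
fragmentation, or outcome-measure diversity. Passing Monte-Carlo checks
therefore demonstrate the statistical machinery is correct under the stated
model, not that published networks satisfy that model.

## Harness problem sizes

The Monte-Carlo harnesses fix their study conditions once:

* *Type-I error*: a consistent triangle with 10 studies per design and
  1000 patients per arm, $\tau = 0$, 1000 replicates. The Wald test treats
  the within-design $\hat\tau^2$ as known, and its chi-squared calibration
  is adequate only when that variance is estimated with reasonable degrees
  of freedom; 10 studies per design provides 27 of them. With very sparse
  designs the plug-in makes the test conservative, which is a property of
  the method, not of the implementation.
* *Power*: a design shift of 1.5 on the log odds-ratio scale with 10
  studies per design and 2000 patients per arm, 500 replicates.
* *Heterogeneity recovery*: $\tau = 0.5$ with 50 studies per design and
  2000 patients per arm, 200 replicates.
* *Absorption of inconsistency*: $\tau = 0$ with a 0.8 shift on one
  design, 5 studies per design, 200 replicates; the consistency-model
  $\hat\tau$ rises while the within-design $\hat\tau$ stays near zero.

```{r, eval = FALSE}
cfg <- sim_config_triangle(studies_per_design = 10, n_per_arm = 1000, tau = 0)
type_one_error(cfg, reps = 1000, alphas = c(0.05, 0.10), estimators = "reml")
```

## Limitations

The package restricts itself to dichotomous outcomes on the odds-ratio
scale with arm-level data, a single common $\tau^2$ per network, and the
global DBT test; local methods (loop-specific screening, node-splitting),
contrast-level input, other effect measures, and Bayesian estimation are
out of scope. The plug-in Wald test can be mis-calibrated when few degrees
of freedom estimate the within-design variance, and like all global tests
it can lack power — absence of evidence against consistency is not evidence
of consistency. Reported p-values should be read alongside the structural
metrics and the heterogeneity comparison between the two models.
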