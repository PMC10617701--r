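---
title: "Measuring and decomposing wealth-related inequality in a binary health indicator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing wealth-related inequality in a binary health indicator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcindex)
```

## The measurement problem

Health surveys such as the DHS routinely show that binary indicators of
health knowledge or service use — here, comprehensive HIV/AIDS
knowledge, defined as affirming two prevention methods and that a
healthy-looking person can be infected while rejecting the mosquito and
food-sharing misconceptions — are unevenly distributed across living
standards. Quantifying *how* unevenly, and attributing the inequality
to measurable covariates, is the job of the concentration-index
toolkit this package implements.

Three features of the data shape everything downstream:

1. **Complex design.** Respondents come from a two-stage stratified
   cluster sample with unequal selection probabilities, so every
   statistic is weighted and uncertainty must respect clustering.
2. **A proxy for living standards.** There is no income measure; the
   ranking variable is an asset-based wealth score (first principal
   component of household asset indicators).
3. **A bounded outcome.** The indicator is 0/1, which rules out the
   plain concentration index as a bounded inequality measure and
   motivates the Erreygers correction.

## Ranks, curve and indices

Respondents are ranked by the wealth score and assigned weighted
fractional ranks: after sorting, respondent $i$ gets
$r_i = (\sum_{j<i} w_j + w_i/2)/W$. Tie blocks (common when ranking by
quintile or a coarse score) share the midpoint rank of the combined
block, which keeps the weighted mean rank exactly $1/2$. Ranks are by
construction invariant to any strictly monotone transform of the score
and to rescaling the weights; tests assert both.

The concentration curve plots the cumulative weighted outcome share
against the cumulative population share. The standard concentration
index is $C = 2\,\mathrm{cov}_w(h, r)/\mu$, equal to twice the signed
area between the curve and the diagonal; the Erreygers index is
$E = 8\,\mathrm{cov}_w(h, r) = 4\mu C$, which for a 0/1 outcome ranges
over $[-1, 1]$ and attains $\pm 1$ only for a perfect poor/rich split
(with equal weights the covariance of a half split is exactly $1/8$,
so $E = 1$ exactly — a test fixture). Positive values mean the
indicator concentrates among the rich.

Two numerical conventions matter and are fixed deliberately:

- Weighted covariances use the population denominator $W$, not $W-1$;
  this is what makes $E = 8\,\mathrm{cov}_w$ and the weight-scale
  invariance hold exactly rather than approximately.
- The covariance-based and curve-area-based estimators of $C$ are
  algebraically identical under the midpoint-rank convention; the test
  suite checks agreement to $10^{-9}$ on a thousand random tables
  rather than trusting the algebra.

When $\mu = 0$ the standard index is undefined ($C$ = `NA` with a
warning) while $E = 0$ is still returned; an all-ones outcome gives
$C = E = 0$.

## The wealth index

Assets are standardized by weighted mean and SD and the weighted
correlation matrix is eigen-decomposed; scores are the first component.
Eigenvectors are sign-ambiguous, so orientation is pinned by requiring
a positive loading sum: owning assets raises the score. Constant asset
columns are dropped with a warning (they carry no ranking information);
an all-constant matrix is an error rather than a silent zero score.

Weighted quintile groups cut the score distribution at cumulative
weight shares 0.2/0.4/0.6/0.8. A tie block is assigned to the lowest
quintile its cumulative-weight interval overlaps: ties always share a
group, a block ending exactly on a boundary stays below it, and each
group's weighted share is 20% up to one respondent's weight. The
degenerate all-tied case therefore lands entirely in "poorest", which
is the only assignment consistent with the tie-sharing rule.

## Decomposition

A weighted logit model
$\Pr(h=1\mid x) = \mathrm{logit}^{-1}(\beta_0 + x'\beta)$ is fitted by
IRLS (the `glm.fit` engine with a quasi-binomial family so fractional
sampling weights are legitimate case weights; deviance tolerance
$10^{-10}$, at most 100 iterations). At the optimum the weighted mean
of fitted probabilities equals the weighted prevalence — asserted to
$10^{-8}$ as a fit invariant. Collinear columns are dropped with a
warning; coefficients beyond $\pm 15$ trigger a separation warning.

Marginal effects are *average* marginal effects on the probability
scale. For an indicator column the package uses the discrete change
$\beta^m_k = \mathrm{E}_w[p(x_k{=}1) - p(x_k{=}0)]$ with **all other
columns held at observed values — including sibling dummies of the same
categorical covariate**. The alternative (zeroing siblings first) is
equally defensible; the per-column convention was chosen because it
treats every design column identically, reproduces the published
elasticity arithmetic, and is mirrored exactly by the generator's
analytic ground-truth AMEs, so parameter-recovery tests compare like
with like. For continuous columns the weighted mean derivative
$\mathrm{E}_w[p(1-p)]\beta_k$ is used.

Each column then contributes
$a_k = e_k C_k = 8\beta^m_k\,\mathrm{cov}_w(x_k, r)$, with
$e_k = 4\beta^m_k \bar x_k$ the elasticity on the Erreygers scale and
$C_k$ the covariate's concentration index. Two conventions are fixed
after checking them against the published Ethiopian tables:

- the factor 4 (Erreygers scale) rather than the classic
  $\beta \bar x/\mu$ elasticity — the published elasticities reconstruct
  as $4\beta^m \bar x$ (e.g. $4 \times 0.065 \times 0.3668 = 0.0954$
  against a printed $0.096$), while the classic scale is off by a
  factor of about $4\mu$;
- percentage contributions are taken of the *total* index, not the
  explained part — the published totals (65.4%, 87.8%, 81.9%) sit below
  100%, implying an unexplained residual share.

The residual $E - \sum_k a_k$ is reported alongside, so adding-up is
exact by construction and asserted on every synthetic run.

## Uncertainty

Point estimates use the weights alone. For uncertainty the package
resamples primary sampling units with replacement within strata and
recomputes the statistic (percentile intervals, fixed seed =
reproducible replicates). This is honest about what it is: a design
bootstrap, not a survey-linearized variance. On synthetic data with a
known index the 95% intervals cover the truth in at least 90 of 100
replications at $n = 2{,}000$ and $B = 200$ — checked in the acceptance
suite.

## The synthetic generator

`generate_survey()` emulates the structure of a DHS individual-recode
extract: four strata (urban/rural × two zones) with fixed latent-SES
means, cluster effects ($\sigma = 0.35$), household noise
($\sigma = 0.8$), eight Bernoulli asset indicators with increasing
SES loadings, covariates drawn from SES-dependent logistic and
ordered-logistic models, inverse-selection-probability weights with
urban oversampling (weighted urban share ≈ 23%), and an outcome drawn
from a configured logit model on the covariate dummies plus latent SES.
The five ternary items are back-filled from the drawn composite (a
correct pattern for knowers; a random non-qualifying pattern
otherwise), so `build_knowledge_indicator()` reconstructs the drawn
outcome exactly. Never-heard respondents are sampled only among
non-knowers, which makes the "never-heard are coded 0" convention and
the prevalence factorization
$\Pr(h{=}1) = \Pr(h{=}1 \mid \text{heard})\Pr(\text{heard})$ hold by
construction. One root seed feeds documented per-component streams, so
adding a covariate never perturbs earlier columns and identical
configurations are byte-reproducible.

The never-heard convention itself deserves a note: published tables
compute the composite over the full sample while the knowledge items
are asked only of those who ever heard of AIDS, and the overall
prevalence sits below the heard-only rates. Coding never-heard
respondents as 0 (rather than excluding them) is the only reading
consistent with that, and the ingestion metadata records the convention
explicitly.

What the generator does *not* emulate: spatial structure, item-level
response correlation beyond the composite, urban/rural-specific asset
models, or non-response. Passing tests therefore validate the
estimators and their identities, not the substantive Ethiopian
estimates themselves — the microdata are restricted and are not
shipped or approximated respondent-by-respondent.

## Calibrated round fixtures

`round_config()` returns configurations whose covariate marginals
follow the published round compositions (education mix, media exposure,
HIV testing, sex, urban share) and whose outcome coefficients are the
published marginal effects rescaled to the logit scale by
$\beta \approx \beta^m/(\mu(1-\mu))$. The outcome intercept and the
direct SES gradient were then calibrated *once*, by iterative matching
on simulated populations ($n = 150{,}000$ per iteration, verified at
$n = 400{,}000$), to the published prevalence and Erreygers index of
each round (2005: 19.8%, 0.251; 2011: 25.9%, 0.239; 2016: 27.9%,
0.201); the resulting constants are shipped frozen and are never
re-tuned at run time. The default configuration is calibrated the same
way to mid-range conditions (prevalence 0.25, index 0.225), matching
the 20–28% prevalence and 0.2–0.25 index band of the application.

## Validation strategy and problem sizes

The test suite works at three levels, with sizes chosen to keep the
default run in the low minutes:

- **Exact identities** ($E = 4\mu C$, adding-up, $a_k = 8\beta^m
  \mathrm{cov}_w$, rank/weight invariance, curve-vs-covariance
  equivalence) on small random tables — hundreds of cases, tolerances
  $10^{-9}$ to $10^{-14}$.
- **Published-table arithmetic** from the shipped reference estimates:
  trend $r = -0.94$ over the three round indices, elasticity
  reconstruction within 0.002, and the headline percentage
  contributions. Three 2016 rows are excluded as documented errata
  (see `?ethiopia_reference`): their printed values are mutually
  inconsistent beyond what half-ulp rounding of the inputs can explain.
- **Monte-Carlo recovery**: average marginal effects and the index
  estimated at $n = 20{,}000$ over five seeds against analytic truths
  computed from the true coefficients on a $10^6$-draw population;
  calibrated fixtures checked at $n = 200{,}000$ against the published
  prevalence (±0.01) and index (±0.02); bootstrap coverage at
  $n = 2{,}000$, $B = 200$, 100 replications.

## Known limitations

- Standard errors are cluster-bootstrap, not linearized `svy`
  estimates; with very few clusters per stratum percentile intervals
  can undercover.
- The Erreygers index is implemented for outcomes in $[0,1]$ only; the
  general bounded-variable version with range $b-a$ is out of scope.
- No dominance tests between concentration curves, no Wagstaff
  normalization, no between-round (Oaxaca-type) decomposition of the
  *change* in the index.
- Missing data are handled by listwise deletion on the mapped columns,
  appropriate only under missing-completely-at-random; no imputation is
  provided.
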