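---
title: "Best-worst scaling with bwsmaxdiff: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Best-worst scaling with bwsmaxdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwsmaxdiff)
```

## The problem

Object-case best-worst scaling (BWS, also called maxdiff) asks each
respondent to look at a small card of options and mark the one they would
*most* likely choose and the one they would *least* likely choose. Repeated
over a set of cards that covers all options in a balanced way, these
best/worst picks identify the options' positions on a common latent utility
scale far more efficiently than rating scales, and without scale-use
artefacts. The motivating application for this package is a survey of 200
low-income households in peri-urban Nairobi facing a hypothetical 40% raw
milk price increase: nine intrahousehold milk-allocation strategies
(`milk_allocation_options()`), nine cards of four options each, one best and
one worst pick per card.

## Choice-card design

Cards are blocks of a (nearly) balanced incomplete block design: `v` items
in `b` blocks of size `k`, each item replicated `r = b*k/v` times. Perfect
balance requires every pair of items to co-occur `lambda = r(k-1)/(v-1)`
times, which is impossible when `lambda` is not an integer — for the study's
`(v, b, k) = (9, 9, 4)`, `lambda = 1.5`, so the best achievable design has
half the pairs co-occurring once and half twice. `generate_design()` deals a
random equal-replication layout and then hill-climbs on pairwise item
exchanges, minimising the variance of the off-diagonal concurrence counts;
the known floor/ceiling lower bound on that variance is used as a stopping
rule, so at these sizes the search reliably lands on the `{1, 2}` optimum
within a restart or two. The search is deterministic given the seed.

`design_efficiency()` reports the D-efficiency of the within-block
information matrix `C = diag(r) - N N'/k` relative to a hypothetical perfect
BIBD: `100 * gm(eigenvalues) / (v lambda / k)`, with the geometric mean over
the `v - 1` nonzero eigenvalues. Commercial design software prints
similarly-defined but not always identical efficiency measures, so this
number is a diagnostic, not a value to be matched to other tools; a
generated `(9, 9, 4)` design scores about 99.4% here, and 100% is attained
exactly iff all pairs co-occur equally often. Presentation order within a
card is deliberately not modelled — the instrument gives no position-effect
treatment — and blocks are stored as sorted index sets.

## Counting scores

With `B(o)` and `W(o)` the aggregate best/worst counts, the standardized
best-worst score is `(B - W) / (r N)`, bounded in [-1, 1] and zero-sum
across options on any complete panel. The positive ratio scale is
`sqrt(B/W)`; it is reported anchored at 100 for the top option
(standardized ratio scale, weighting factor `100 / max sqrt(B/W)`) and
normalised to sum to 100% (relative importance, weighting factor
`100 / sum sqrt(B/W)`). The `r N` divisor is the number of times each
option is seen across the panel; it reproduces the study's published table
cell-for-cell (e.g. `(45 - 205)/800 = -0.20`).

Two small numerical policies are worth stating. First, a zero worst count
makes `sqrt(B/W)` infinite; on small synthetic panels we substitute
`W = 0.5` (a continuity correction) and flag the option — real panels of
this size never trigger it. Second, per-option dispersion is the
*population* standard deviation of the per-respondent scores
`(B_n - W_n)/r`; the mean of those individual scores equals the aggregate
score by linearity. Display rounding (2 decimals for scores and ratios, 1
for percentages) is applied only at print time; full precision is kept
internally. When checking against published tables bear in mind that
tables themselves sometimes propagate rounded intermediates — the
motivating study's relative-importance column multiplies the *rounded*
sqrt ratio by the rounded weighting factor, which shifts one option's
percentage by a tenth of a point relative to the full-precision value.

## The maxdiff likelihood

The model treats a card answer as a single choice among the `J(J-1)`
ordered (best, worst) pairs of the `J` shown options:

    P(i, j) = exp(beta_i - beta_j) / sum_{k != l} exp(beta_k - beta_l).

This is the *simultaneous* (maxdiff) form; the sequential best-then-worst
form is intentionally out of scope. One option is pinned to zero for
identification (`O9`, "stop buying raw milk", by convention in this
application). All probability computations subtract the maximum exponent
before exponentiating (log-sum-exp), so utilities of any magnitude are
safe.

`fit_pooled()` maximises the conditional-logit likelihood with BFGS and the
analytic gradient, then applies damped Newton polishing until the gradient
sup-norm is below 1e-6 (the likelihood is concave, so this is cheap and
safe); standard errors come from the inverse observed information. Shares
of preference are the softmax of the utilities; they sum to one, are
shift-invariant, and carry a ratio-scale reading (twice the share = twice
as likely to be picked best).

## Mixed logit

`fit_mixed()` lets utilities vary across respondents as independent normals
per option, `beta_n = mu + sigma * z_n` (diagonal mixing — the application
reports one mean and one spread per option, implying no correlations). The
panel structure enters through the product of a respondent's nine card
probabilities inside the simulated likelihood, averaged over `R` draws. The
draws are generalized Halton sequences (one prime base per option, a seeded
random digit permutation per dimension, first 50 points dropped), allocated
in consecutive blocks per respondent; everything is reproducible from
`(R, seed)`. The default `R = 500`; the analytic gradient of the simulated
likelihood (posterior-weighted scores over draws) makes this tractable at
survey scale in a few minutes.

`sigma` enters estimation unconstrained: the likelihood is an even function
of each `sigma` because the mixing draws are symmetric, so only `|sigma|`
is identified and the reported magnitude is what matters (published tables
occasionally print a negative spread for the same reason). A related and
less obvious fact shapes our null-recovery testing: when the true `sigma`
is zero, the likelihood is flat in `sigma` to *second* order (the squared
score and the Hessian term cancel in expectation), so the estimate
converges at the `N^(-1/4)` rate and boundary Wald z-statistics are not
standard normal. The test suite therefore bounds the spurious-`sigma`
magnitude at twice the `N^(-1/4)` scale rather than applying a z-test.
`population_shares()` summarises the fitted heterogeneity by Monte-Carlo:
draw `beta` from the fitted mixing distribution, apply the softmax, report
the per-option mean and spread of the shares. Plug-in softmax of the means
is *not* the population mean share when `sigma > 0`, which is why published
mean-share columns generally cannot be reproduced from published means
alone.

## Latent classes

`em_fit()` estimates a C-class finite mixture by EM: posteriors
`pi_c L_n(beta_c) / sum pi L_n` in the E-step, posterior-weighted pooled
fits per class plus the share update in the M-step. The weighted M-step
reuses the pooled machinery (weights enter the likelihood per card), so
every EM iteration increases the observed-data log-likelihood; that
monotonicity is asserted at every iteration, and `C = 1` reduces exactly to
the pooled fit. Likelihoods of this kind are multimodal, so the default is
20 jittered starts (pooled estimates plus unit-normal noise) with the best
retained; classes are re-ordered by descending share so that seeded refits
are byte-identical. Convergence is declared when the log-likelihood gains
less than 1e-7.

Model size is `k = C(v-1) + (C-1)` free parameters. `information_criteria()`
uses `n = respondents` — not cards — in BIC/CAIC: the respondent is the
independent sampling unit in a panel, and this convention is confirmed by
arithmetic against the published selection table (k = 26 and `ln 200`
reproduce the printed 3-class BIC/CAIC; `ln 1800` does not).
`class_sweep()` tabulates AIC/BIC/CAIC with their percentage improvements
over the previous class count; the table is reported for inspection rather
than auto-selecting, matching how such tables are read in practice (pick
the count where the improvements level off). `profile_classes()`
cross-tabulates modal-posterior assignments against categorical household
covariates as column percentages; formal significance testing of those
profiles is intentionally out of scope.

## Synthetic respondents

`simulate_panel()` generates panels from any of the three DGPs. Each
respondent first draws their latent state — a class label or a normal
coefficient vector — and then answers every card by sampling one ordered
pair from the maxdiff probabilities. The base seed is split per respondent
(a fixed affine hash into R's seeding space), so extending a panel never
changes earlier respondents' data, and every panel carries a sealed truth
record for recovery tests.

`study_fixture()` is the package's stand-in for the study's unavailable raw
responses: 200 respondents on a (9, 9, 4) near-BIBD, generated from the
published three-class utilities with shares 65/21/14%, plus class-dependent
categorical covariates (income tier, head gender, age band, education)
drawn at the published class-conditional rates. These generator settings
are the study's own reported scale and structure, fixed once. The fixture
emulates preference heterogeneity and covariate-class association; it does
not emulate interviewer effects, item non-response, card-order effects or
any misspecification of the maxdiff form, so passing tests demonstrate
correctness of the estimators under the assumed model, not robustness to
real-data pathologies.

## Problem sizes and tolerances in the test suite

Parameter-recovery tests run at the sizes where their pre-registered
tolerances are meaningful: pooled estimation at N = 2000 (tolerance 0.1 on
every utility), mixed logit at N = 1000 with R = 300 draws (0.3 on means,
0.4 on spread magnitudes), latent classes at N = 2000 with 5 starts (0.05
on shares, 0.4 on minority-class utilities). Structural and invariance
properties (zero-sum scores, pair-probability normalisation, shift
invariance, EM monotonicity, seed determinism) run on small panels because
they hold at any size. Optimiser tolerances are 1e-6 on the gradient
sup-norm for the pooled fit, BFGS relative tolerance 1e-10 for the
simulated likelihood, and 1e-7 on the EM log-likelihood gain; all are
overridable through function arguments.

## Known limitations

* Mixing is diagonal-normal only; correlated or non-normal random
  coefficients are not supported.
* Covariates profile classes post hoc; they do not enter the class
  membership or the utilities.
* Incomplete panels are handled card-wise in the counting and pooled
  stages but the mixed and latent-class estimators require complete
  panels.
* The design search is a heuristic: adequate at questionnaire sizes
  (tens of items), not a general-purpose optimal-design tool.
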