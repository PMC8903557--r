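---
title: "Measuring covert contraceptive use and the husband's gender attitude"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring covert contraceptive use and the husband's gender attitude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`covertuse` studies a measurement problem: whether a wife's current use of
a reversible modern contraceptive method is known to her husband. Couple
surveys in the DHS family rarely ask this directly, but they interview
both partners, and the two instruments differ in a useful way — the wife
reports her current method, while the husband is asked whether a
non-barrier method was used *the last time the couple had sex*, with
condom use asked separately. This vignette explains the models and
procedures in the package, the choices we made where the design was open,
and what the synthetic-data-based tests do and do not establish.

```{r setup}
library(covertuse)
```

## The covert-use outcome

The outcome is defined only for wives currently using a reversible modern
female (spacing) method: pill, IUD, injectable, or another modern female
method. Sterilized couples, traditional-method users, and non-users are
excluded upstream, as are polygynous couples, couples in which the
husband's last partner was not his wife (his last-sex questions would not
refer to the marriage), and couples who adopted contraception only after
the last coitus.

Given eligibility, the classifier is a pure function of three fields:

- husband reports **no** non-barrier method *and* **no** condom → **covert**;
- husband reports condom use → open;
- husband reports any female modern method — whether the same as the
  wife's or a different one — → open.

The reason codes distinguish the same-method and different-method open
routes purely for diagnostics; both are open by definition. The husband's
report refers to the last sexual encounter while the wife's refers to
current use, so some discordance is timing noise rather than concealment;
this indirect measure is therefore an upper bound on deliberate secrecy,
a caveat inherent to the design rather than to the implementation.

## Couple sampling weights

Couple files distribute household and individual weights but no couple
weight, and using either spouse's weight biases couple-level estimates
because husbands are interviewed in only a subsample of households and
couple response is clusterwise incomplete. We build the couple weight by
inflating the household weight with the inverse cluster-level couple
response rate:

$$w_{couple} \propto w_{hh} \times
  \frac{\text{eligible couples in cluster}}
       {\text{couples with both partners interviewed in cluster}},$$

normalized so the mean over analyzed couples is exactly 1. Normalization
keeps the effective sample size equal to the analytic N, makes the
chi-square statistics invariant to rescaling all household weights, and
is idempotent. Clusters with no interviewed couples cannot contribute
rows; if such a cluster *does* contribute rows the input is contradictory
and the weight routine stops with an error rather than guessing. The
inflation formula is isolated in `compute_couple_weights()` so an
alternative couple-weight construction is a drop-in replacement.

## The latent class model of the husband's attitude

The husband's egalitarian gender attitude is not observed; it is measured
from 12 binary items in three batteries (justification of wife-beating in
five scenarios; the wife's right to refuse sex in three; the husband's
asserted rights when refused in four), each coded 1 for the egalitarian
(positive) response. The measurement model is a finite mixture with
class-conditionally independent items:

$$P(Y = y) = \sum_{c=1}^{C} \delta_c \prod_{i=1}^{m}
  \tau_{ci}^{y_i} (1-\tau_{ci})^{1-y_i},$$

with class shares $\delta$ and item-response probabilities $\tau$.
`fit_em()` maximizes the observed-data likelihood by EM. Numerical
choices that matter:

- **Pattern collapsing.** Rows are collapsed to distinct response
  patterns with counts before iterating, making each EM step
  $O(P \times C \times m)$ for $P$ observed patterns ($P \le 2^m$, and
  far smaller in practice because the class profiles are concentrated).
  This is exact, not an approximation.
- **Convergence.** Iteration stops when the absolute change in
  log-likelihood falls below `tol = 1e-7`, with a cap of
  `max_iter = 300` iterations; the fit records whether the cap was hit.
- **Restarts.** EM only finds local maxima. Initial responsibilities are
  drawn row-wise from a flat Dirichlet; `n_restarts = 20` by default, and
  the best restart by final log-likelihood wins. The restart count is our
  own default — with the well-separated attitude profiles seen here,
  restarts nearly always agree, but multimodality grows with C.
- **Degeneracy guards.** $\tau$ is clamped to $[10^{-6}, 1-10^{-6}]$ and
  $\delta$ floored at $10^{-8}$ and renormalized, preventing
  $\log 0$ at boundary solutions. The floor/clamp values are far below
  any substantively meaningful probability.
- **Weights.** The likelihood is unweighted by default; a weighted
  variant (weights multiplying per-row log-contributions, equivalent to
  frequency weights) is available via the `weights` argument since
  reasonable analysts disagree on whether design weights belong in a
  measurement model.

The number of classes is chosen by fitting C ∈ {2, 3, 4} with shared
settings and minimizing BIC (`select_num_classes()`; AIC is reported
alongside, with $k = (C-1) + Cm$ free parameters). Mixture classes are
identified only up to permutation; `label_classes()` resolves label
switching by ranking classes on the mean positive-response probability
across items and, for C = 3, naming them high / moderate / low
egalitarian (ties broken by class share). Each husband is then assigned
his modal posterior class, ties to the lower index.
`likelihood_ratio_statistic()` reports the fitted-versus-saturated
$G^2 = 2(\ell_{sat} - \ell_{fit})$ over observed response patterns with
$df = (2^m - 1) - k$; we chose the saturated comparison because it is the
standard absolute-fit statistic for pattern data, noting that published
LCA chi-squares do not always say which comparison they print.

## Association analyses

`weighted_crosstab()` computes weighted per-category Ns and percent
covert, with a Pearson chi-square on the weighted count table
($\sum (O-E)^2/E$). Weights are renormalized to mean 1 inside the
function, so the statistic is computed on an effective N equal to the
sample size — rescaling all weights leaves it unchanged.

`fit_weighted_logit()` fits the two logistic regressions by IRLS with
observation weights: model 1 regresses covert use on the attitude class
alone (unadjusted odds ratios); model 2 adds concordance of the desire
for more children, religion, caste, residence, wife's education, spousal
age-difference and education-difference categories, working status,
wealth group, living-children group, region, mobility, and independent
money use. Reference levels are the first category of each block
(highly egalitarian, concordance "no", Hindu, SC/ST, urban,
non-literate, wife same age or older, no education difference, not
working, poor, no children, North). Standard errors are
plain model-based Wald SEs — no design correction — because that matches
the presentation style of the analyses this package mirrors; a
cluster-robust option (`robust = TRUE`, via `sandwich::vcovCL`) is
provided but off by default. McFadden's pseudo-R²
$1 - \ell_{model}/\ell_{null}$ is computed on the weighted Bernoulli
log-likelihood; we implement McFadden's because the pseudo-R² family is
rarely named in applied reports and McFadden's is the default in the
survey-analysis tradition. Age-difference categories follow the
published table labels (same-or-wife-older, 1–3, 4–5, 6+): the
accompanying prose in our source tradition sometimes says "4–6", an
overlap we resolve in favor of the tables that carry the results.

`vif_report()` computes per-column variance inflation factors on the
expanded, reference-coded design matrix by auxiliary regressions,
$VIF_j = 1/(1-R^2_j)$. Note that per-column VIFs for dummies of the same
multi-level factor are mechanically above 1 (the dummies are negatively
correlated), so the per-column maximum is not directly comparable to
term-level generalized VIFs.

## What the synthetic generator emulates — and what it does not

`default_profiles()` encodes the study conditions: 7,824 couples before
nonresponse; three attitude classes with shares
$\delta = (0.677, 0.134, 0.189)$ (high, moderate, low egalitarian) and
covert-use probabilities $(0.234, 0.353, 0.306)$; a covert-method mix
with pill share 0.672, then IUD, injectable, and other modern female
methods; NFHS-like marginal covariate distributions; 200 clusters with
couple response rates spread evenly over 0.85–1.00; and a 5% per-rule
eligibility-violation fraction whose only purpose is to exercise the
filters.

The class-conditional item profiles are built from published per-class
ranges of negative-response chances, spread evenly across each battery's
items (e.g. the low-egalitarian wife-beating items span 0.27–0.56).
Where only a qualitative description exists — the low class's third
battery is described just as the *most* negative of the three classes —
we fixed negative-response chances of 0.30–0.45, strictly above the other
classes, and did not revisit the choice. The moderate class's second
battery is strikingly *non*-egalitarian (negative-response chances
0.67/0.94/0.89, well beyond the low class); we take that description at
face value, and it is in fact what makes the three classes easy to
separate. The husband's open-report routes (same method / different
method / condom) default to 70/10/20 percent — the routes are defined
qualitatively in the source tradition but their shares are not, so these
are round numbers of our own choosing.

The generator draws covariates independently of class and of each other.
Real couple data have correlated covariates (education with wealth with
region), nonignorable nonresponse, item missingness, and timing noise in
the husband's last-sex report. Passing tests on this generator therefore
establishes that the *pipeline machinery* is correct — filters, weights,
classifier, EM, selection, labeling, regression — and that parameters
are recovered under the stated conditions; it does not establish that
the substantive associations estimated from any real survey are
unbiased.

## Problem sizes and verification

The test suite verifies, among other properties: exact agreement of the
EM log-likelihood with brute-force mixture enumeration on toy matrices
(N ≤ 8, m ≤ 4, to 1e-9) and monotonicity of the likelihood trace;
recovery of $\delta$ within 0.03 and $\tau$ within 0.05 at the study
size (n = 7,824, 20 restarts) after label alignment; BIC selecting three
classes in at least 95 of 100 replicates at n = 5,000 (4 restarts per
candidate, a deliberate economy that still separates the criteria by a
wide margin); the 40-case covert-classification truth table; end-to-end
covert prevalence within 3 binomial SDs of the mixture rate
$\sum_c \delta_c p_c = 0.2635$; closed-form oracles for the odds ratio,
chi-square, and VIF; 95% Wald intervals from model 2 covering generating
class odds ratios of 1.5 (moderate) and 1.4 (low) in at least 90 of 100
replicates at n = 20,000 (using the generator's true class as the
regressor, so the check isolates the estimator rather than compounding
LCA assignment error); and exact mean-1 normalization plus scale
invariance of the couple weights. Interval coverage with model-based SEs
under mildly variable weights runs a shade below nominal (the weights
enter the information matrix as frequency weights), which the 90/100
margin accommodates honestly.

## Known limitations

- The couple-weight formula uses cluster-level response-rate inflation of
  the household weight; published couple-weight constructions differ in
  the base weight (household vs wife's individual weight) and we expose
  only the household-weight base.
- No standard errors for the LCA parameters, no covariate-dependent class
  membership (latent class regression), and no ordinal-item support: the
  12 items are strictly binary here.
- Listwise deletion is the only missing-data strategy, matching
  complete-case analytic Ns; there is no imputation.
- Separation in the logistic models is detected heuristically
  (diverging coefficient with exploding SE) and surfaced as a warning,
  not resolved by penalization.
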