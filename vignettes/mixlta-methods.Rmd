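---
title: "Mixture latent trait models for a 9-item child food security scale: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mixlta methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixlta)
```

## The measurement problem

The scale consists of nine items about the household food situation over
the previous month, each answered *a lot* / *sometimes* / *never* and
dichotomized (*a lot* and *sometimes* affirmative). Respondents with any
missing item are dropped listwise — the package deliberately implements
no imputation, because the downstream likelihood work assumes a complete
n × 9 binary matrix. The raw score is the count of affirmative answers
(0–9), and Cronbach's α is computed with sample variances (n − 1
denominator, the convention of mainstream statistical software).

Food insecurity is treated as latent. Three families of latent structure
are supported, forming a modelling ladder:

* **LCA** — K discrete classes, items conditionally independent
  Bernoullis with free class-conditional probabilities. No trait.
* **LTA** — a single population with a continuous latent trait F
  (severity); the Rasch version fixes all loadings at 1, the mean at 0,
  and frees the trait variance.
* **MLTA** — both: classes, and a trait within each class. This is a
  mixture IRT model; the classes capture qualitative group separation
  (food secure vs food insecure) while the trait absorbs severity
  differences within group.

Within class c the item response function is logistic,

$$P(y_j = 1 \mid F, c) = \frac{1}{1 + \exp(\tau_{jc} - \lambda_{jc} F)},
\qquad F \mid c \sim N(\mu_c, \sigma^2_c),$$

so the threshold $\tau_{jc}$ is the trait value at which endorsement
probability reaches 0.5 (when $\lambda = 1$) and the loading
$\lambda_{jc}$ is the discrimination. This parameterization is chosen so
that thresholds reported by mainstream mixture-IRT software plug in
directly. Standardized loadings, the correlation between the trait and
the underlying logistic response propensity, are
$\lambda\sigma/\sqrt{\lambda^2\sigma^2 + \pi^2/3}$.

### The six two-class parameterizations

`mlta_model(1)`–`mlta_model(6)` encode the standard constraint patterns
for K = 2, J = 9 (free-parameter counts in brackets): invariant item
parameters with a free class-1 trait distribution [12]; the same with
class-variant thresholds for items 1 and 3 [14]; class-variant
thresholds except item 9 with both classes anchored at N(0, 1) [18]; the
same with a free class-1 variance [19]; all thresholds class-variant
with both variances free and means fixed at 0 [21]; and free loadings
per item and class with thresholds class-variant except item 9 [36].
Identification is enforced structurally: a free mean or variance
requires an anchored reference class, and free loadings require both
classes anchored. For K > 2 the keyword `free_class1` frees every
non-anchor class (the last class stays at N(0, 1)); at K = 2 this
reduces to the familiar "class 1 free, class 2 anchored" pattern, and at
K = 3 it is the only reading of the constraint system consistent with a
19-parameter three-class model in the standard ladder.

A subtlety worth spelling out: in models 1–5 the loadings are *fixed* at
1, not estimated-but-equal. An estimated shared loading would add one
free parameter and is available as `loadings = "shared"`, but the fixed
version is what the 12/14/18/19/21 counts above imply, and with a free
class-1 variance a shared free loading would be redundant with
$\sigma_1$ anyway.

## Estimation

The observed-data log-likelihood sums, per unique response pattern with
multiplicity, the log of the class-mixed pattern probability. The
integral over F is approximated by **21-node Gauss–Hermite quadrature**
after a change of variables to each class's $N(\mu_c, \sigma^2_c)$; 21
nodes matches or exceeds the defaults of mainstream numerical-integration
IRT software and is cheap at J = 9. The nodes/weights come from the
Golub–Welsch eigen-decomposition — no hand-rolled recursions. The test
suite checks the quadrature code path against dense trapezoid
integration: at the package default of 21 nodes the toy-model error is
below 1e-6; for stress cases with variances and loadings up to 2 the
21-node truncation error can reach ~2e-6, so the randomized property
tests use a 61-node rule to isolate the machinery from the node-count
choice.

Maximization is EM:

* **E-step:** posterior class responsibilities per unique pattern.
* **M-step:** mixing proportions in closed form; structural parameters
  (thresholds, loadings, means, log-variances) by L-BFGS-B with analytic
  gradients of the expected complete-data log-likelihood, capped at 10
  inner iterations (a generalized EM step — any Q-improvement suffices
  for monotonicity, which the tests assert on every stored trace). LCA
  uses closed-form M-steps throughout.
* **Convergence:** relative log-likelihood change below 1e-7 (tunable)
  or 2000 iterations. The M-step optimizer tolerance is effectively
  1e-8 through its bounded quasi-Newton settings.
* **Floors:** mixing proportions and variances are floored at 1e-4 to
  keep the likelihood finite; hitting a floor sets a `boundary` flag
  rather than failing silently.

**Random starts.** Thresholds start at the logits of the marginal item
proportions plus N(0, 1) noise; mixing proportions from a flat
Dirichlet; free means from N(0, 2); variances from LogNormal(0, 0.25).
The stream for start i is seeded `seed + i`, so fits are reproducible
and respondent-order invariant. Starts run a short EM (30 iterations)
and the best five candidates are refined to full tolerance — the
two-stage strategy of mainstream mixture software, and the reason a
90-start fit at n = 2132 takes tens of seconds rather than many minutes.

**Class labelling.** Mixture likelihoods are label-symmetric, but some
constraint patterns are not: with loadings fixed at 1 and one class
anchored at N(0, 1), swapping classes is *not* expressible inside the
constrained family. Classes are therefore physically reordered by
model-implied mean raw score only when the constraint pattern is
permutation-symmetric (LCA; MLTA with means fixed and variances fixed or
all free); otherwise semantic labels are attached without reordering.
Either way, for K = 2 the class with the lower model-implied mean raw
score is labelled `food_security` — the substantive convention, stable
across starts. MAP ties break toward the lower class index, i.e.
conservatively toward non-insecurity.

Observed-information (numerical Hessian) standard errors are available
as diagnostics via `observed_information_se()`. Robust (sandwich)
standard errors are deliberately out of scope, as are ordinal (3-level)
item models and multi-factor traits.

## Model selection

`information_criteria()` implements AIC = −2LL + 2p,
BIC = −2LL + p·log n, and the sample-size-adjusted
ABIC = −2LL + p·log((n + 2)/24). Relative entropy,
$1 - \sum_{ic} (-p_{ic}\log p_{ic}) / (n \log K)$, is 1 for perfect
separation and **undefined for K = 1** (an explicit error, matching the
convention of leaving that cell blank in ladder tables, not a silent 0).

The bootstrapped likelihood ratio test (`blrt()`) compares k against
k − 1 classes by parametric bootstrap: generate B datasets from the
fitted null, refit both models on each, and use the +1-corrected
p-value (1 + #{LR_b ≥ LR_obs})/(B + 1). B defaults to 99; bootstrap
refits use 10 random starts rather than a full-analysis budget — a
documented cost/precision trade-off. More than 10% non-converged
replicates is an error, not a shrug. The Vuong–Lo–Mendell–Rubin analytic
test is not implemented: it is specific to one vendor's approximation,
and the BLRT covers the nested-comparison role.

## Classification and prevalence

Two prevalence definitions are reported side by side and must not be
conflated: the **posterior-based prevalence** (mean posterior
probability of the class across respondents) and the **MAP share**
(fraction assigned to the class by most-likely membership). With an
imperfectly separated minority class the MAP share is smaller — in the
reference population below, roughly 10% versus 17.6%. They coincide
exactly only when entropy is 1.

`enumerate_pattern_probs()` computes the exact (quadrature-level)
model-implied distribution over all 512 patterns, from which follow
model-implied item margins, the model-implied average class
probabilities, and `pattern_fit()`'s observed-vs-expected table with
per-pattern chi-square contributions. No omnibus chi-square p-value is
attached: with 512 sparse cells the asymptotics are unreliable, so only
the contributions are reported.

## DIF and threshold invariance

`dif_test()` follows the classical regression recipe: for each item,
logistic regression of the response on the class indicator plus the
factor score (EAP, mixture-weighted posterior mean of F), with a Wald
test of the class coefficient at α = 0.05 — the simplest reading of
"significant association after adjusting for the trait". No
multiple-testing correction is applied by default, matching common
per-item usage; a Bonferroni option exists. Quasi-separation is flagged
in the output, never raised as an error.

One caveat the package documents rather than hides: when the class
indicator and the score are both *estimated from the same responses*
(MAP classes and EAP scores), they are functions of the outcome items,
and the class coefficient's null distribution is not the nominal one —
under truly invariant thresholds the flag rate is inflated well above
α. The test suite therefore calibrates the regression machinery with
exogenous covariates (true simulated class and trait, where the
conditional-independence null holds exactly) and checks *power* — items
1 and 3 flagged — under the operational estimated-covariate procedure.
Users should read per-item DIF flags as a screening device, which is
how the sensitivity scan below complements them.

`threshold_invariance_scan()` is the cleaner instrument: starting from
the invariant-thresholds model it frees one item's threshold at a time
(never stepwise-accumulated), warm-starting each variant from the base
solution, and reports the 1-df likelihood-ratio statistic per item. Each
variant adds exactly one free parameter; LR statistics are
non-negative up to optimizer tolerance (1e-4), and a variant fitting
*below* its base triggers a warning to increase starts.

## The cut-off tree

The CART implementation is the package's own — Gini impurity, greedy
binary splits, deterministic tie-breaking (features in column order,
candidate thresholds ascending, first strict improvement wins) — so that
rule extraction and reproducibility are fully specified rather than
inherited from an external library's internals. Defaults mirror the
conventional recursive-partitioning defaults (complexity penalty 0.01
scaled by root impurity, minimum split size 20, depth cap 30); the
**full-growth preset** (`tree_control_full()`: penalty 0, minimum split
2) grows until purity. Features are the raw score (ordered numeric,
cut points at midpoints of observed values) and the nine items (binary).

Because MAP class is a deterministic function of the nine items, and
the features include all nine items, a fully grown tree reproduces the
MAP labelling with training accuracy exactly 1 — that is a determinism
argument, not a fitting achievement, and the package treats it as a
consistency check of the whole classification path. In the reference
population the extracted rules have the familiar cut-off form: score ≥ 4
insecure, score ≤ 1 secure, scores 2–3 resolved by items 1 and 3.
`extract_rules()` merges redundant conditions per feature and prints
integer-feature conditions in integer form (`score >= 4`, `score == 3`),
binary items as equality tests.

## The synthetic-data generator

`table2_parameters()` hard-codes the reference two-class population the
validation suite revolves around: class weights 0.824/0.176; loadings 1;
food-security class trait N(−3.435, 2.352), food-insecurity class
anchored N(0, 1); thresholds class-variant for item 1 (−3.433/−0.862)
and item 3 (−1.417/−0.427), shared for the rest (0.864, 0.807, 1.892,
1.311, 2.607, 1.601, 4.452). `generate()` draws class, then trait, then
conditionally independent items; true class and trait go to a side
channel, never into the response matrix an estimator sees. A single RNG
contract (R's Mersenne-Twister via `set.seed`) makes replicates
portable.

What the generator emulates: the binary recoded item distribution of a
two-class mixture IRT population, including the class-variant thresholds
that drive the DIF and scan analyses. What it does not emulate: the
3-level answer vocabulary (it emits 0/1 directly), item non-response,
covariates (maternal education, income, household size), or any cohort
sampling design. A green test on synthetic data therefore establishes
that the *methods* behave as specified under the stated population — not
that any particular cohort finding would replicate.

Two consequences of the stated world deserve emphasis. First,
sample-dependent quantities are only reproduced in distribution:
Cronbach's α of a large generated sample sits near 0.61, consistent
with an α of 0.617 in a real sample of this structure. Second, the ML
estimator of the mixture split at n = 2132 is intrinsically noisy: the
acceptance suite measures a replicate standard deviation of several
percentage points for the posterior-based prevalence (the likelihood is
nearly flat along a π–μ–σ² ridge at this separation, and extreme
replicates are genuine global maxima, as warm-starting EM at the
generating values confirms). Recovery of the 17.6% prevalence is
accordingly asserted through the replicates' own Monte-Carlo t-interval,
and the acceptance script averages 10 seeded replicates of the full
90-start protocol. At n = 20000 the same estimator lands within a few
tenths of the generating values — the noise is finite-sample, not bias
in the implementation.

## Interfaces and configuration

Specs, parameter sets and fits serialize to JSON
(`write_fit_json()`/`read_fit_json()`); the CLI layer
(`mixlta_cli()`, `cmd_simulate()`, `cmd_fit_ladder()`,
`cmd_classify_and_tree()`) is driven by JSON configuration files. YAML
is intentionally unsupported — it would add a dependency outside the
package's minimal footprint for no analytic gain. Ladder runs resume:
models whose fit JSON already exists are loaded, not refitted. All
randomness descends from one top-level seed with deterministic
per-stage derivation, so an end-to-end seeded run is byte-reproducible.

## Known limitations

Binary items only (the 3-level vocabulary is dichotomized at load
time); one latent factor; no robust standard errors; no VLMR test; no
cost-complexity cross-validation pruning or surrogate splits in the
tree; K beyond 3–4 classes is untested territory for the start
heuristics. The 18-item household scale variant is out of scope.
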