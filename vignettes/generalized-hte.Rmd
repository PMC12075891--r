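---
title: "Discovering heterogeneous treatment effects by parametric G-computation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering heterogeneous treatment effects by parametric G-computation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetefx)
```

## The problem

A treatment rarely works equally well for everyone. In observational
epidemiology the question "for whom does it work, and how much?" is usually
answered either with hand-picked subgroup analyses (prone to multiplicity and
confirmation bias) or with black-box learners such as causal forests (hard to
audit, and their discovered subgroups hard to communicate). `hetefx`
implements a middle road: a fully parametric, data-adaptive pipeline in which
every step is an ordinary, inspectable statistical object — a penalized
regression, a propensity model, a dendrogram, a two-by-two table.

Throughout, $Y$ is the outcome, $X \in \{0,1\}$ the treatment, $C$ a
confounder set chosen by the investigator to satisfy the backdoor criterion,
and $W$ a set of candidate effect modifiers (which may overlap with $C$; a
modifier that is also a confounder must appear in both). The estimand is the
conditional average treatment effect,

$$\tau(w) \;=\; E\!\left(Y^{X=1} - Y^{X=0} \mid W = w\right),$$

identified under conditional exchangeability given $C$, positivity,
consistency and no interference. Per-individual plug-in estimates of
$\tau(w)$ are often called individualized treatment effects (ITEs).

## The seven steps

1. **Roles.** The investigator declares $C$ and $W$
   (`variable_roles()`, checked by `validate_roles()`). Causal judgement —
   backdoor sets, colliders — stays with the investigator; the package only
   verifies structure and warns when a candidate modifier is not also
   adjusted for.
2. **Saturated design.** `build_design()` expands the cohort into the
   treatment main effect, covariate mains, and the treatment interacted with
   every term (`design_spec()`). "Saturated" is operationalized as all
   treatment-by-term interactions up to a configurable product order
   (default 1, covariate-covariate products off): full $n$-way saturation is
   combinatorially explosive, and the CATE step needs exactly the
   treatment-interaction block. Continuous columns are centered and scaled
   on the *training split only*; binary columns (two distinct values) and
   the treatment main are left on their natural scale so coefficients and
   cluster profiles stay interpretable.
3. **Penalized fit + weighting.** `fit_penalized()` minimizes, for the
   gaussian family,
   $$\sum_i \Big(y_i - \beta_0 - \sum_j \beta_j c_{ij}\Big)^2
     + \lambda\Big(\tfrac{1-\alpha}{2}\sum_j \beta_j^2
     + \alpha \sum_j |\beta_j|\Big),$$
   i.e. the elastic net ($\alpha = 1$: LASSO; $\alpha \to 0$: ridge;
   $\lambda = 0$: ordinary least squares — this limit dispatches to an exact
   `lm()`/`glm()` fit). The binomial family replaces the squared error with
   the deviance. $\lambda$ is chosen by 10-fold cross-validation over a
   log-spaced path with folds fixed by a seed. `fit_penalized()` defaults to
   the minimum mean CV deviance (the prediction-oriented choice), but the
   pipeline (`hte_run()`) defaults to the sparser 1-SE rule: discovery rests
   on which interactions survive, and under the minimum rule retained noise
   interactions create small genuine clusters in the fitted CATEs —
   measured on the homogeneous-effect generator, the no-false-modifier rate
   is about 67% under the minimum rule and 100% under 1-SE, with no loss in
   true-modifier recovery at study scale. The intercept and the
   treatment main effect are never penalized — the treatment must not be
   selected out of its own model. Stabilized inverse-probability-of-treatment
   weights from `fit_iptw()` (logistic propensity on confounder mains,
   weights truncated at the 1st/99th percentiles) are applied both as
   observation weights in this fit and again in step 7; balance is reported
   as weighted standardized mean differences. Optional
   `post_double_select()` refits, without penalty, the union of terms
   selected by the outcome regression and confounders selected by a
   propensity regression; its two *selection* fits use the parsimonious
   1-SE rule, because minimum-CV selection is known to admit noise terms.
4. **Recycled predictions.** `predict_potential_outcomes()` evaluates the
   trained model on the held-out test split twice — once with the treatment
   column (and every interaction involving it) set to 1, once to 0 —
   holding covariates fixed, using the training-split scaling parameters.
5. **Contrasts.** `compute_cate()` takes the elementwise difference: a risk
   difference per person for binary outcomes, a mean difference otherwise.
   By construction the mean of this vector *is* the G-computation
   (standardization) estimate of the test-set ATE, exactly.
6. **Cluster + importance.** `discover_modifiers()` adds a whisker of seeded
   noise to the CATEs (jittering, default SD $10^{-3}\,\mathrm{sd}$, with an
   absolute floor of $10^{-8}$ for degenerate vectors — noise below double
   resolution cannot create the distinct values Ward clustering needs),
   builds a Ward minimum-variance tree, picks the number of clusters with a
   Beale-index rule (below), and scores each candidate modifier by the
   difference of its cluster z-scores,
   $$z_g(m) = \frac{\bar m_g - \bar m}{\mathrm{sd}(m)}, \qquad
     \text{importance}(m) = |z_1(m) - z_2(m)|,$$
   with one formula for binary (proportions) and continuous modifiers.
   Modifiers with importance $\ge 0.2$ (configurable) are selected. For a
   selected continuous modifier the binarization cut-off is the average of
   its means in the two clusters. Everything reported — cluster means,
   z-scores, cut-offs — is computed on the *un-jittered* values; jitter only
   shapes the tree and the choice of $k$. When $k > 2$ the importance is the
   maximum pairwise z-difference and the cut-off uses the two extreme-CATE
   clusters; two clusters is by far the common case.
7. **Subgroup MSM.** For each discovered modifier, `fit_msm()` fits the
   marginal structural model with terms $\{1, X, G, XG\}$. Under IPTW the
   saturated weighted fit's cell means are weighted cell proportions, so the
   risk difference and the risk ratio derive from one set of standardized
   risks — the two scales cannot disagree in sign. The linear-probability
   fit carries the RD scale and a log-link fit of the same saturated model
   (log-binomial, falling back to Poisson, which has identical fitted values
   when saturated) carries the RR scale. Inference is robust sandwich
   (HC0) under IPTW and percentile bootstrap (default $B = 500$, resampling
   rows and refitting) under G-computation, with a Wald p-for-interaction
   per scale. Step 7 uses the entire cohort by default, following the
   method's stated convention; because the training split also chose the
   model, `msm_sample = "test"` restricts estimation to the held-out split
   for the cautious.

## The Beale-index decision rule

The number of clusters is chosen by walking $k = 1, 2, \dots$ and testing
whether $k+1$ clusters fit significantly better than $k$ using Beale's
pseudo-F,

$$F_k \;=\; \frac{(W_k - W_{k+1})/W_{k+1}}
  {\big(\tfrac{n-k}{n-k-1}\big)\,2^{2/p} - 1}, \qquad p = 1,$$

where $W_k$ is the total within-cluster sum of squares of the Ward solution.
The first non-significant improvement stops the walk.

The classical calibration refers $F_k$ to an $F(p,\,n-k-1)$ distribution.
In one dimension this reference is badly off for Ward statistics: splitting
a *pure Gaussian* optimally removes about 63.7% of the within-SS, giving
$F_1 \approx 0.58$, while a decisively bimodal mixture (two components
separated by four within-cluster SDs) gives $F_1 \approx 1.5\!-\!2$ — still
below the nominal 5% cut of 3.84. A rule that can reject neither a Gaussian
nor its alternative is uninformative. The default (`method = "mc"`)
therefore keeps Beale's statistic but calibrates its cut by parametric
bootstrap: data are simulated from the Gaussian mixture implied by the
current $k$-cluster solution (for $k=1$, a single Gaussian), the statistic
is recomputed ($B = 40$ replicates, subsampled to at most 800 points for the
$O(n^2)$ null clustering), and the observed $F_k$ must exceed the 95th null
percentile. This preserves the nominal size under homogeneity — a
single-Gaussian CATE yields $k = 1$ about 95% of the time — while giving
essentially full power against separated mixtures. The classical cut
remains available as `method = "ftest"`.

## The bimodality diagnostic

Before any clustering, `summarize_cate_distribution()` reports a descriptive
shape diagnostic: the valley-to-peak ratio of a kernel density estimate (the
density at the deepest point between the two tallest modes, relative to the
lower of those peaks; near 0 for well-separated modes, near 1 for unimodal
wiggles, flagged "bimodal" below 0.8). A dip-style test statistic would
serve the same purpose; the ratio was chosen because it is transparent,
dependency-free, and — like any diagnostic here — purely descriptive: it
never gates the pipeline.

## The synthetic generator

`simulate_cohort()` produces the validation bed for the whole pipeline: an
observational study of intensive blood-pressure control with five baseline
covariates (age, systolic blood pressure, sex, eGFR, aspirin use), about 30%
treated via a logistic model on age, SBP and sex (intercept solved by
root-finding so the expected treated fraction hits the target on each draw;
confounding strength gives pre-weighting standardized mean differences of
roughly 0.3, so weighting demonstrably matters), and a binary outcome whose
risk is a bounded additive baseline plus a treatment effect constant within
each of the four cells defined by aspirin use and eGFR $\ge 73$. Additivity
on the risk scale makes every row's true risk difference exact; it is stored
in a `truth` attribute so estimates can be scored without approximation, and
`true_subgroup_effects()` returns the implied population subgroup effects in
closed form.

Two generator constants deserve comment.

* **Cell effects.** The four cell RDs (−0.2561, −0.1328, 0.0762, 0.1736)
  are not arbitrary: they are the minimum-norm least-squares solution that
  makes the population *marginal* subgroup RDs match a published benchmark
  pattern (−0.12 / +0.05 within eGFR strata, −0.21 / +0.13 within aspirin
  strata, overall ≈ −0.03). The derivation ships as
  `scripts/calibrate_preset.R`; the constants are repo-derived.
* **Aspirin–eGFR correlation.** eGFR is drawn as
  $N(73 \pm 2.3,\ 9.73)$ given aspirin use (correlation ≈ 0.23). If the two
  true modifiers were independent, the two-cluster Ward split of an additive
  fitted CATE would coincide *exactly* with aspirin use, the eGFR cluster
  z-difference would be ≈ 0.03, and no threshold-based importance rule could
  ever find eGFR — a structural fact, not a power problem. The benchmark's
  own reported cluster profile (eGFR cluster means 75.3 and 70.7 against an
  SD of 10) implies exactly this magnitude of dependence, and with it the
  discovered cut-off lands at the midpoint ≈ 73.

Presets `a1`/`a2`/`a3` share this process at $n = 10{,}000$ / $100{,}000$ /
$1{,}000$; `null` equalizes the four cells (a homogeneous effect of −0.036,
for type-I-error control); `hrs_like` mimics only the marginal structure of
an aging-cohort application (59% exposed, ~15% outcome risk, modifiers: an
age indicator, years of education, childhood SES) for format-level testing.

What the generator deliberately does *not* emulate: missing data (assumed
imputed upstream), measurement error, unmeasured confounding, non-additive
baseline risk, time-varying treatment, or the long correlated covariate
blocks of real cohort data. Passing tests on this bed show the machinery is
correct and calibrated under its assumptions — not that those assumptions
hold in any particular application.

## Numerical choices and degenerate inputs

* $\lambda$ path: glmnet's default ≈ 100 log-spaced values down to
  $10^{-4}\lambda_{\max}$; a fixed numeric $\lambda$ is embedded in the path
  so coefficients are solved at it exactly, and $\lambda = 0$ bypasses the
  solver entirely.
* Weight truncation at the 1st/99th percentiles; a mean stabilized weight
  outside $[0.9, 1.1]$ triggers a positivity warning, estimated propensities
  of numerically 0/1 an error.
* Constant subgroup variable: the MSM falls back to the overall effect with
  a warning; an empty treatment-by-subgroup cell is a positivity error (the
  standard remedy is a coarser dichotomy). Bootstrap resamples with empty
  cells are skipped and counted; more than 10% skipped is an error.
* Zero-SD modifiers get importance 0 with a warning; constant CATE vectors
  are flagged "degenerate" and jittered at the absolute floor so the
  clustering step remains well defined (and then finds one cluster).
* Cluster labels are canonicalized by ascending mean CATE, so "cluster 1"
  is always the low-effect group and results are invariant to row order.
* Test-suite problem sizes are scaled to what the checks need: oracle
  comparisons run at $n \le 8$ (exhaustive), calibration checks at
  $n = 2{,}000$ with 200 replicates, discovery checks at $n = 10{,}000$
  with 20 generator seeds.

## Known limitations

* The outcome model is linear in its terms; a threshold-shaped true modifier
  is recovered through its linear projection plus the clustering step, which
  is exactly the intended mechanism, but sharply non-monotone modification
  would need higher interaction order or basis expansion.
* The importance threshold 0.2 is a convention, not a formal error-rate
  control; the null preset shows the realized type-I behaviour under the
  default settings.
* Sandwich inference treats the estimated weights as known (the usual,
  slightly conservative MSM practice); bootstrap inference resamples the
  MSM stage, not the upstream model selection.
* Step 7's default use of the full cohort re-uses the training split that
  selected the model; the `msm_sample = "test"` option exists precisely
  because this is a potential optimism source.
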