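---
title: "Methods: models, standardisation and simulation design in hdrsynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, standardisation and simulation design in hdrsynth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery of `hdrsynth` in enough
detail to audit it: the data model, the transformations, the mixed-model
specification and its numerical conventions, what the synthetic generator
does and does not emulate, and the design choices made where more than one
defensible option existed.

## Data model and grouping

An observation is one measured community response (richness, diversity,
evenness, abundance, biomass) or ecological-process value (grazing,
predation, recruitment, body size) at one heterogeneity level in one plot
of one study. Observations are aggregated into **HDR groups** — the
within-study unit sharing study, heterogeneity facet, response metric,
organismal group, site, date and substrate context. The heterogeneity
gradient, its standardisation and the effect-size baseline are all defined
within an HDR group.

When the full grouping key leaves fewer than `min_replicates` (default 3)
observations in some cell of a study stratum, the key is relaxed stepwise —
site collapsed first, then date, then substrate context — until every cell
reaches the threshold or the stratum is flagged unusable. The collapse
order follows the order in which the contextual factors are listed and is
applied stratum-wide, which keeps the grouping deterministic: the same
observations produce the same groups regardless of row order. Groups
spanning fewer than two distinct heterogeneity levels cannot define a
gradient and are dropped with a logged reason. Keying groups by response
metric and organismal group (in addition to the study context) is a
deliberate choice: mixing metrics within one group would corrupt the lnRR
baseline, which must refer to the same quantity as the responses compared
against it.

Observations with incomplete environmental context are retained for the
objective-1 batteries and removed listwise (and logged) only from models
that request the affected moderator.

## Standardisation

Continuous gradients are z-transformed ((x − mean)/sd, sample sd) and then
min–max mapped to the 0–1 range. Since z-scoring is affine, the composition
equals plain min–max normalisation; the package still implements the
two-step form and the test suite asserts the identity against an
independent min–max oracle at 1e−12 on 1000 random vectors. Consequences
worth knowing: the transformation is invariant to positive affine changes
of units, order-preserving, and the group minimum and maximum sit exactly
at 0 and 1, so the quadratic model is always evaluated on a common support.
Standardisation is performed within the HDR group — the unit on which the
gradient is defined — rather than within study.

Ordered discrete descriptors map level *i* of *k* to (i − 1)/(k − 1). The
two- and three-level cases (0/1 and 0/0.5/1) anchor this rule; even spacing
is the natural extrapolation for k > 3. The ordering must be the authors'
ordinal ordering; it defaults to sorted labels and should be supplied
explicitly when alphabetical order is not ordinal order.

The coefficient of variation (sample sd / mean) of the raw heterogeneity
values is computed in the study's original units and carried as a
gradient-breadth covariate. Discrete descriptors have no raw units; their
CV is computed on the mapped 0–1 values and flagged as such
(`het_cv_on_mapped`). A non-positive raw mean leaves the CV undefined
(logged, set missing) rather than producing a sign-flipped covariate.

## Effect sizes

lnRR_i = ln(y_i / mean(min(y))), with mean(min(y)) the arithmetic mean of
all responses at the group's minimum standardised heterogeneity. All
observations tied at the minimum form the baseline set. Baseline
observations are retained as model rows (their lnRR spreads around zero
and carries information on residual variance); with a single baseline
replicate the baseline lnRR is exactly zero. Observations with a zero
response cannot enter a log ratio and are excluded with a logged count — no
offset constant is invented, since any offset choice distorts lnRR
non-uniformly. A group whose baseline mean is zero has no defined effect
size and is dropped with a log entry.

## The mixed model

Every model in every battery shares the skeleton

```
lnrr ~ x + x2 [+ moderators + retained interactions]
       + (1 + x | study_id) + (1 | hdr_id)
```

* The quadratic term is always carried with the linear term.
* The random structure — correlated study-level intercept and slope on x,
  plus an HDR-level intercept nested in study — is the richest structure
  supported by the grouping (HDR groups are nested in studies by
  construction, so `(1 | hdr_id)` with globally unique ids realises the
  nesting).
* Candidate interactions (always `x:het_cv`; suite-specific moderator
  interactions) are pruned by backward elimination under **ML**: refit,
  compute a drop-one likelihood-ratio p per candidate, remove the largest
  p above alpha (default 0.05), repeat. Main effects and the heterogeneity
  terms are never removed. ML is required for comparing models differing
  in fixed effects; the final model is refit by **REML**. The LRT form
  covers multi-column factor interactions; for a single-df interaction it
  agrees asymptotically with the Wald test on its coefficient. The pruning
  fits skip lme4's post-fit derivative checks (they are deviance
  comparisons only); final fits keep full checking.
* Coefficient tests are Wald t with Satterthwaite denominator df via
  lmerTest; when Satterthwaite fails (for instance in degenerate noise-free
  fits) the residual df n − p is used and the fallback is recorded in
  `df_method_used`.
* Categorical moderators use treatment contrasts with the alphabetically
  first level as reference, making coefficient signs reproducible across
  runs and platforms.

### Numerical conventions

* **Optimiser policy.** nloptwrap first, then bobyqa, then Nelder–Mead on
  convergence failure; if fatal messages persist the fit is raised as an
  error object in suite results, never silently dropped. lme4's
  "Rescale variables?" eigenvalue-ratio message is treated as a recorded
  conditioning note, not a failure: it fires routinely when a covariate in
  natural units (latitude in degrees) sits next to the 0–1 gradient, and
  rescaling would change the reported per-degree coefficient meaning.
* **Singular fits** (a variance component at zero) are retained with a
  flag. They are expected in noise-free validation runs and common in
  small strata.
* **R².** Marginal R² = varF/(varF + varR + varE) and conditional
  R² = (varF + varR)/(varF + varR + varE), with varF the sample variance of
  the fixed-effect predictor over the estimation data and varR the sum of
  the study intercept variance, the slope contribution evaluated at the
  sample's gradient distribution (τ₁²·mean(x²) + 2·cov·mean(x), floored at
  0 as a sum), and the HDR intercept variance. Marginal ≤ conditional by
  construction.
* **Shape classification.** With a non-significant quadratic: flat /
  linear increasing / linear decreasing by the linear term. With a
  significant negative quadratic the vertex x\* = −β₁/(2β₂) decides:
  hump if 0 < x\* < 1, saturating if x\* ≥ 1 (boundary convention: exactly
  1 is saturating), and x\* ≤ 0 — a curve that only declines on [0, 1] —
  is classed with the decreasing forms. A significant positive quadratic
  is U-shaped.
* **Prediction** is fixed-effects only, on the 0–1 support (no
  extrapolation), with delta-method pointwise intervals from the
  fixed-effect covariance matrix.
* **Pairwise contrasts** of a factor moderator are Wald contrasts at the
  mean of x (and covariate means), Holm-adjusted, via emmeans with
  asymptotic df; the compact letter display assigns letters to maximal
  runs of mutually non-significant levels after ordering by estimated
  mean.

## The model batteries

Strata are always fitted separately — one model per facet, per organismal
group, per process — never pooled across strata, so a data-rich stratum
cannot distort a sparse one. The facet battery uses the aggregated micro-
plus macroinvertebrate data for one response metric at a time, with
organismal group (and, for abundance, the per-HDR species count) as
covariates. The organismal-group battery pools all community metrics as the
response within each group, adds response-metric type and its interactions
with x and facet as candidates, and relabels the four sparser facets
(substrate complexity, feature size, feature variation, feature richness)
as one `other_pooled` level — a pure relabelling that preserves row counts.
The process battery fits grazing, predation, recruitment and body size
separately with facet and organismal group as covariates. The environment
battery refits either objective-1 battery with substrate type, depth zone,
season and centred absolute latitude, plus candidate interactions
latitude × season, x × substrate type and x × latitude; a candidate is
admissible only when every participating factor level is backed by at
least two studies, operationalising "where possible" as an explicit,
configurable rule. Latitude enters in absolute degrees centred at the
sample mean — centring decorrelates the main effect from its interactions
without changing the per-degree slope meaning.

Strata with fewer than two studies are skipped with a recorded reason;
moderators left with one observed level in a stratum are dropped from that
stratum's model, logged, never fatal.

## Sensitivity analyses and publication bias

Exclusion rules are pure, composable, idempotent filters: drop large
studies (per-study observation count above the 95th percentile by default —
a leverage-style criterion, configurable), drop HDR groups with fewer than
4 points, drop discrete descriptors, drop multi-facet HDRs, drop studies
confounding heterogeneity with site/date/substrate. The latter two rely on
ingest-supplied design flags, since the underlying judgements are made
during study screening, not recoverable from the data. Each rule is
re-run independently against the base battery and reported as per-stratum
deltas of the heterogeneity terms with significance flips; strata emptied
by a rule are marked not-estimable. Publication bias is probed by adding
standardised sample size and publication year as fixed effects and
reporting their coefficients; a constant covariate (e.g. a single-year
dataset) is dropped with a log entry.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, with
known truth: studies carry correlated random intercepts and slopes
(bivariate normal, Cholesky construction), HDR groups carry intercepts,
and responses are `y = scale · exp(η + ε)` with
`η = u0 + w + (β₁·m + u1 + moderator slope)·x + β₂·x²` and Gaussian ε — so
effects are multiplicative on the response scale and lnRR is the natural
analysis scale. The gradient is an even grid on [0, 1] including x = 0, so
the lnRR baseline is always defined; raw heterogeneity is emitted in
per-study affine units (a·x + b, a > 0) so the standardisation pipeline is
genuinely exercised and provably inverts them; a configurable fraction of
HDRs is emitted as ordinal labels instead. Optional plants: confounded
studies with inflated slopes (flagged), multi-facet studies (flagged), a
publication-bias offset added to all non-baseline effect sizes per decade
of publication year (a slope-side plant would be absorbed by the study
random slopes and invisible to a main-effect diagnostic), and
moderator-dependent slopes (per-degree latitude effect, depth/substrate/
season offsets, a latitude-by-winter interaction).

**Default scenario.** 40 studies × 6 HDRs × 8 levels × 3 replicates;
τ₀² = τ₁² = 0.04, ρ = 0, ω² = 0.01, σ² = 0.09; every facet shares the curve
(β₁, β₂) = (1.2, −0.6); group multipliers 1; moderator effects 0; 15% of
HDRs discrete. The shared curve and unit multipliers are deliberate: they
make the pooled linear and quadratic terms well-defined scalars (1.2 and
−0.6), which is what simulation-based recovery needs. The curve itself is
a positive, decelerating response with vertex at x = 1 — the boundary
between saturating and hump-shaped, where most synthesised reef responses
sit. Study-to-study slope standard deviation 0.2 against a mean slope 1.2
and residual sd 0.3 on the log scale represent moderate, realistic
between-study heterogeneity and within-plot noise. Named constructors
provide the deliberately heterogeneous conditions (facet contrasts with a
null facet, trait-ordered group multipliers, process curves with declining
grazing and rising recruitment, environmental moderation stronger at low
latitude / on biogenic substrate / in the intertidal, confounded studies
with doubled slopes).

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: unbalanced designs and missingness patterns,
empirical taxon or geographic distributions, non-lognormal noise,
zero-inflated responses, heterogeneity measured with error, and correlation
between moderators and study quality. Parameter-recovery results validate
the estimator under the stated model, not the model's adequacy for any
particular dataset.

## Validation design and problem sizes

The test suite validates each stage against independent oracles (plain
min–max for the standardisation, an explicit-loop recomputation for lnRR),
then the whole pipeline against generator truth: noise-free runs must
return the true coefficients to 1e−6 per facet stratum; 200 replicates of
the default scenario must recover β₁ with |bias| < 0.05 and 95% Wald CI
coverage in [0.90, 0.98]; 200 zero-effect replicates must keep the linear
term's type-I rate in [0.03, 0.08] and remove a null x:CV interaction in at
least 90% of replicates; 100 replicates with planted confounded studies
must show the pooled slope falling when they are excluded in at least 95%.
The replicate counts balance Monte-Carlo error (binomial se of a 95%
coverage estimate at n = 200 is about 1.5 points) against a test suite
that completes in minutes; `scripts/acceptance.R` re-derives the same
quantities at 100 replicates. Noise-free exactness runs use 12 studies ×
2 HDRs × 5 levels × 2 replicates — exactness does not improve with size.

## Known limitations

* Discrete descriptors assume even ordinal spacing; a study whose levels
  are substantively uneven (e.g. 0/0.1/1 by design) is mis-scaled.
* Standardised gradients are relative to each group's observed range, so
  coefficients are not transferable to absolute heterogeneity units; this
  is inherent to cross-metric synthesis.
* The CV covariate for discrete descriptors (mapped scale) is not
  comparable in units to the raw-scale CV of continuous groups; models
  treat it as one covariate regardless, which is a pragmatic compromise
  flagged in the data.
* Backward elimination tests candidates sequentially at a fixed alpha; no
  multiplicity adjustment is applied across candidates, matching standard
  practice for covariate selection rather than confirmatory inference.
* Wald coverage relies on adequate study numbers; with very few studies
  (< ~10) the study-slope variance is weakly identified and intervals may
  undercover. Strata with fewer than 2 studies are refused outright.
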