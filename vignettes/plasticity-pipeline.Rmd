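---
title: "Modelling expression plasticity in field-grown trees with plastexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling expression plasticity in field-grown trees with plastexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastexpr)
```

# The problem

Adult trees growing in the field experience continuously varying
temperature, soil water and photoperiod.  Repeated needle sampling of the
same trees across a growing season, at two common-garden sites hosting two
provenances, yields a transcript-by-library count matrix in which several
sources of variation are entangled: stable differences between individual
trees, differences between provenances (genotype), differences between
sites, and the environmental signal that changes from sampling date to
sampling date.  `plastexpr` implements a per-transcript linear mixed-model
pipeline that (i) decomposes expression variance across these factors,
(ii) calls transcripts responsive to specific environmental drivers with a
small-sample-honest test and an effect-size gate, and (iii) summarizes the
responder sets through resampled GO overrepresentation and kappa clustering
of the enriched categories.

# Models

## Preprocessing

Raw counts pass a detection filter (RPM strictly greater than 1 in at least
4 libraries, where RPM uses the per-library aligned-read total, not the
filtered column sum), are corrected for library size by median-of-ratios
size factors, and are transformed as `log2(count / sf + 1)`.  The log base
and pseudocount are conventions — every downstream test is invariant to the
scale — but they are fixed and documented here.  Size correction always
precedes the log transform.  A per-transcript one-sample
Kolmogorov–Smirnov test of the standardized values against the standard
normal serves as advisory QC; because mean and SD are estimated, the test
is conservative, which is acceptable for a non-gating check.

## Variance components

For each transcript the log expression is modelled with a grand mean and
crossed random intercepts for TREE, SITE, PROVENANCE and DATE, fitted by
REML (`lme4::lmer`; this is an ordinary variance-components fit, and lme4
is the standard tool for it — the package's own mixed-model engine is
reserved for the testing path below, where the Kenward–Roger machinery
needs direct access to the profiled fit).  Each variance component is
divided by the sum of all components plus the residual variance, so the
proportions sum to one.  SITE and PROVENANCE have only two levels each;
their variances are weakly identified and frequently estimated at the
boundary (zero).  They are kept as random effects deliberately, and
boundary estimates are reported rather than suppressed.

## Differential expression

All differential-expression models contain a TREE random intercept and are
estimated by a profiled REML fit written for this single-random-intercept
structure: with `V = s2_tree ZZ' + s2_err I`, the GLS coefficients and the
residual variance are closed-form given the variance ratio, so only a
one-dimensional criterion is optimized (Woodbury identity, `O(q p^2)` per
evaluation).  Boundary fits collapse to OLS and are valid results.

Nested models are compared with a first-order Kenward–Roger F-test
computed from the full model's REML fit: the fixed-effects covariance is
adjusted for the uncertainty of the two variance parameters
(`dV/ds2_tree = ZZ'`, `dV/ds2_err = I`; the covariance structure is linear
so no second-order terms arise), and a scaled Wald F with an approximate
denominator df is returned.  On balanced designs the test reduces exactly
to the classical F-test, and at the `s2_tree = 0` boundary to the OLS
F-test — both are asserted in the test suite, alongside agreement with the
independent `pbkrtest` implementation on unbalanced data.

Two model families are tested per transcript:

* **Date/provenance family.**  `DATE * PROVENANCE` is compared against
  `DATE + PROVENANCE` to test the genotype-by-environment interaction; the
  interaction is then removed and `DATE` and `PROVENANCE` are each tested
  by dropping them from the additive model.  Responder calls use the FDR
  gate only (`q < 0.01`, BH-adjusted per term across transcripts).
* **Environmental family.**  Drop-one comparisons against
  `TAW + TEMPERATURE + DAYLENGTH + PROVENANCE`.  An environmental
  responder must pass `q < 0.01` *and* increase the marginal R-squared by
  more than 0.2; PROVENANCE uses the FDR gate only.  The marginal
  R-squared is `s2_fix / (s2_fix + s2_rand + s2_err)` with `s2_fix` the
  population variance (divide by `n`) of the fixed-effect predictor.

`dAIC` is reported from ML refits of both models: REML likelihoods are not
comparable across fixed-effect structures, so ML is the defensible basis
for an AIC difference.  `dR2` uses marginal R-squared for both models.
BH adjustment is applied per tested term, one p-vector per term across
transcripts.  Interactions between provenance and the continuous
regressors, and among the regressors themselves, are not modelled: with
only eight environmental support points they would overfit.

Aliased design columns (an interaction cell emptied by missingness) are
dropped with a warning before fitting, as `lm`/`lmer` would do; a test is
refused only if a tested term loses all its coefficients.

## Environmental regressors

* **TEMPERATURE** — sampling-day midday (10:00–14:00 mean) temperature
  minus the trailing 28-day mean of daily temperature.  The window is
  trailing (ending on the sampling day) because future weather cannot
  influence sampled tissue.  Centering removes the seasonal trend that
  would otherwise confound temperature with photoperiod.
* **DAYLENGTH** — deviation of the photoperiod from the solstice day
  length, signed positive before (and on) June 21 and negative after, so
  lengthening and shortening days have opposite signs and the solstice
  maps to zero.  A sampling day on the solstice takes the positive branch
  with magnitude zero.
* **TAW** — total available soil water on the sampling day, consumed as an
  input column (soil-water modelling is out of scope).
* **PROVENANCE / SITE** — dummy coded, reference level alphabetically
  first.  SITE is always computed and checked with variance inflation
  factors (`VIF = 1 / (1 - R2)`, flagged above 10) but excluded from the
  environmental model: in this design TAW separates the sites almost
  perfectly, and the two columns cannot both be identified.  The model
  family refuses to run if the included regressors themselves exceed the
  VIF threshold.

Continuous regressors enter the models unstandardized; slope signs are
invariant to scaling.

## GO overrepresentation

Annotations are propagated to all is_a ancestors, so a transcript counted
in a category is counted in every parent.  The universe is the set of
detected transcripts carrying at least one annotation.  Overrepresentation
of a responder set in a category uses the one-sided hypergeometric tail —
identical to the one-sided Fisher exact test; "overrepresented" is
directional, so the one-sided alternative is the right one.  Because
assembled transcript sets contain redundant fragments of one gene, each of
100 repeats samples exactly one transcript per best-hit group, restricts
all sets to the sample, and re-runs every test; per-category means of p,
fold enrichment (observed over expected) and observed responder count are
reported, and significance is evaluated on the means: `mean_p < 0.01` and
strictly more than 10 observed responders.  Arithmetic means are the
simplest faithful reading of "averaged"; evaluating the rule on the means
keeps it a deterministic function of the summary.

## Kappa clustering

Significant categories are compared by Cohen's kappa,
`kappa = (O - A) / (1 - A)`, computed from binary membership vectors over
the responder transcripts annotated to at least one significant category
(configurable to the full universe).  Categories are clustered on
euclidean distances between the rows of the kappa matrix — each category's
kappa profile is its feature vector — with average linkage by default
(complete available); `1 - kappa` as a direct distance is available behind
a switch, since the clustering-input convention is genuinely ambiguous.
Rows are sorted by term id before clustering, making the output invariant
to input order.  A parental-term filter (at least five distinct is_a
ancestors, counted as a set) removes uninformative basal terms before
clustering; the pipeline default is lowered to two because the synthetic
ontology is only three levels deep.

# The synthetic-study generator

The generator emulates the study design end to end: two provenances at two
common gardens, 16 trees per provenance split across the sites, four
site-specific sampling dates (eight DATE levels), and uniform missingness
taking the 128 potential libraries to 75.  Per transcript `i` and library
`j`,

```
log2 mean_ij = baseline_i + u_tree + u_date + u_prov + u_site
               + sum_r slope_ir * z_rj
```

with random intercepts drawn per transcript at variances given by the
configured fractions of the total log-scale variance (default total SD 1),
slopes applied to standardized regressors, and counts drawn
negative-binomial with log-uniform library totals (10–40 million).
Defaults: variance fractions TREE 0.40, DATE 0.30, PROVENANCE 0.12, SITE
0.07, residual 0.11 (the ordering the variance decomposition of the real
study shows); responder fractions TAW 0.15, TEMPERATURE 0.10, DAYLENGTH
0.16; slope magnitude 1 log2-unit per SD of regressor.

Numerical choices worth recording:

* **Counting noise is part of the residual budget.**  The NB draw itself
  contributes about `(log2 e)^2 * dispersion` of log2-scale variance.  The
  generator subtracts this from the configured residual fraction so the
  fractions describe the observed log scale that the models see.  The
  default dispersion is 0.05 — technical overdispersion only, since
  biological variation is carried by the explicit random effects — which
  keeps the counting noise (~0.10) inside the residual budget (0.11).
* **Synoptic midday noise.**  The trailing-mean detrend leaves a small
  deterministic seasonal component in TEMPERATURE; with the default midday
  noise SD of 4 °C (day-to-day midday variability is large; the real data
  contain a +7 °C excursion) the regressor is dominated by weather and the
  three regressors are, in expectation, mutually uncorrelated, as reported
  for the real study.
* **Eight support points.**  All environmental regressors take only eight
  values (site × date).  Chance correlation between any two regressors
  therefore has an SD of about `1/sqrt(7)` ≈ 0.38 across weather draws —
  some draws are badly collinear no matter how the generator is
  parameterized.  The `decorrelate_regressors` mode replaces the realized
  regressor columns by their Gram–Schmidt orthogonalization (rescaled, in
  the order TAW, TEMPERATURE, DAYLENGTH) before truth slopes are applied;
  power and error-rate recovery experiments use this mode so that they
  measure the responder rule rather than the luck of the weather draw.
* **Recovery-experiment fractions.**  The responder-rule recovery
  simulation sets the DATE and SITE fractions to zero (redistributed to
  the residual).  Date-to-date variation is environmentally driven and is
  represented by the spiked slopes themselves; independent DATE-level
  noise on null transcripts, or SITE-level noise when SITE is collinear
  with TAW and excluded from the model, is unidentifiable confounding that
  no per-library test can separate from a real environmental response.
  Including it would measure the confounder, not the rule.  The
  variance-decomposition recovery simulation, whose subject *is* the
  fractions, keeps all of them and sets the responder fractions to zero.
* **Best-hit groups** are drawn within responder classes, so fragments of
  one "gene" respond alike — the situation the resampling is designed to
  correct.  GO enrichment is planted by weighted sampling of responder
  transcripts of one (regressor, direction) pair at configurable odds;
  odds of 1 mean nothing is truly enriched.

What the generator does **not** emulate: read-level artifacts (alignment,
assembly, positional bias), secular trends in expression, autocorrelated
residuals within a tree over time, provenance-by-environment interactions
(the real study found almost none), or realistic GO DAG topology beyond a
three-level toy.  Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness to
every artifact of real field data.

# Problem sizes and tolerances

The test suite runs the balanced-design oracles exactly (tolerance 1e-6
relative), calibrates the drop-one KR test on 2000 null simulations at the
study design (n = 75 libraries, 25 trees; empirical size expected in
[0.04, 0.06] at nominal 0.05), recovers variance fractions over 500
transcripts (medians within ±0.07 for TREE and DATE), and recovers spiked
responders over 400 transcripts (sensitivity ≥ 0.9, false discovery
proportion ≤ 0.05).  Fisher p-values are checked against direct tail-sum
enumeration to 1e-12 on tables with margins up to 50.  The optimizer uses
a log-scale search over the variance ratio on [-15, 12] with tolerance
1e-9 plus an explicit boundary candidate at zero; REML/ML criteria agree
with lme4 to 1e-6.  These sizes were chosen so the full suite documents
the statistical claims while remaining quick enough to run routinely.

# Worked example

```{r example, eval = FALSE}
library(plastexpr)

cfg <- sim_config(n_transcripts = 300, seed = 42)
study <- simulate_study(cfg)
res <- run_pipeline(study, repeats = 50, seed = 42,
                    varcomp_transcripts = 100, min_observed = 5)

lengths(res$responders)        # responder counts per term and direction
res$significant                # enriched GO categories (means over repeats)
res$clustering$order           # kappa-clustered category ordering
```

The field-scale significance rule requires more than ten responders per
category; at the 300-transcript toy scale the example lowers
`min_observed` to 5 — the rule itself is unchanged, only the threshold
argument.

# Limitations

* The KR implementation covers the single-random-intercept structure the
  pipeline uses; it is not a general mixed-model testing engine.
* Two-level random factors are reported at the boundary when the data do
  not identify them; no confidence intervals on variance components are
  provided (the analysis reports point proportions only).
* Only is_a edges are traversed in the ontology; part_of propagation is
  not implemented.
* The per-transcript fits are embarrassingly parallel but run serially;
  at the problem sizes above this is a non-issue.
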