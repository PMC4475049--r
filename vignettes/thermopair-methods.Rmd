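---
title: "Methods: thermal requirements and paired invasive/non-invasive inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal requirements and paired invasive/non-invasive inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermopair)
```

## The model

Insect development rate `r = 1/development time` is treated as linear in
rearing temperature over the ecologically relevant range (roughly a 20 °C
window): `r(T) = a + b·T`. Two biologically interpretable constants follow:

* the **lower developmental threshold** `LDT = −a/b` (°C), the temperature
  at which development extrapolates to zero, and
* the **sum of effective temperatures** `SET = 1/b` (day-degrees D°), the
  accumulated heat above the LDT needed to complete a stage, so that the
  time to complete development at constant `T > LDT` is `SET/(T − LDT)`.

The linearity assumption fails near both thermal extremes (rate curves are
sigmoid at the bottom and humped at the top); the package fits only the
linear model and leaves trimming of super-optimal temperatures to the user,
since published rearing designs rarely enter that region and no single
automatic rule is defensible across taxa.

## Estimating LDT and SET

`fit_rate_regression()` is ordinary least squares of per-observation rates
on temperature. Regressing individual replicates (rather than treatment
means) preserves the information in unequal replication; the `on_means`
switch reproduces studies that published means only. At least three
distinct temperatures are required (`min_temperatures = 3`) because two
points fit any line exactly and leave no residual degrees of freedom.

`derive_thermal_constants()` requires a positive slope — a species with no
positive thermal response in the fitted range is excluded with an explicit
error rather than given a meaningless negative SET. Standard errors of LDT
and SET come from the first-order delta method on the coefficient
covariance:

* `Var(LDT) ≈ (1/b²)·se_a² + (a²/b⁴)·se_b² − 2(a/b³)·cov_ab`
* `Var(SET) ≈ se_b²/b⁴`

A test checks these against a 10,000-draw parametric bootstrap from the
bivariate normal of `(a, b)` (agreement within 5%). The SEs are reported
but never used as weights downstream: the comparative analyses average
species and populations unweighted, so a precisely measured laboratory
population cannot dominate a pair.

### Aggregation across populations and stages

Independently studied populations of a species are averaged after an
outlier screen: a population whose LDT (or SET) deviates from the
cross-population median by more than `k × 1.4826 × MAD` (default `k = 3`)
is discarded, each trait screened independently (`joint = TRUE` drops the
whole population when either trait is flagged — which of the two rules a
given literature compilation used is generally unknowable, so both are
available). The median-based rule cannot discard everything, and every
discard is recorded in the result's `discards` attribute.

Across stages, whole (egg-to-adult) development is preferred for both
traits. Without it, stage LDTs are averaged — the working assumption being
that all stages of a population share one LDT — while stage SETs are *not*
summed or averaged (they measure different quantities of heat); with
several stage SETs and no whole-development value the caller must name a
stage explicitly, otherwise SET is returned missing with
`set_choice_required = TRUE`.

## Assembling species pairs

`match_pairs()` implements a deterministic version of the source-area
comparison. For each non-invasive species it searches invasive species from
the **same continent** at the tightest shared taxonomic rank, in the
preference order genus → tribe → subfamily → family (intermediate ranks
missing from the table are skipped, not treated as mismatches; tribe and
subfamily matches additionally require the same family, and everything
requires the same order). All invasive candidates tied at the winning rank
are included and their trait values averaged — more conservative than a
subjective or random single choice, and it removes any need for a random
seed in pairing. Non-invasive species are used at most once; invasive
species may recur across pairs (reuse is tallied in the log). Records
flagged as intentional introductions, stored-product pests or cryptogenic,
and records without an LDT, are excluded up front and logged.

Paired differences are always invasive minus non-invasive; `d_set` is
missing whenever either member lacks SET, which is how a pair set acquires
a smaller SET sample than LDT sample.

## The comparative analyses

Three analyses probe the same status contrast under different independence
assumptions, plus a correlation:

1. **t-tests** (`status_t_test`). The `pooled_two_sample` variant ignores
   the pairing; the `paired_differences` variant is the one-sample t of
   per-pair differences against zero with `n_pairs − 1` df. Degenerate
   zero-variance inputs return `t = 0, p = 1` when the difference is
   exactly zero instead of dividing by zero.
2. **Paired-design mixed model** (`paired_lmm`):
   `value ~ status + (1 | pair)`, REML. The pair intercept splits residual
   variation within pairs from variation between pairs, yielding
   `ICC = σ²_pair/(σ²_pair + σ²_res)` — the within-pair similarity of the
   trait. Fixed-effect tests use Satterthwaite degrees of freedom (the
   convention of `lmerTest`). A boundary fit (`σ²_pair = 0`) is a valid
   result reported with `icc = 0` and `boundary = TRUE`.
3. **Nested-taxonomy mixed models** (`nested_taxonomy_lmm`,
   `lr_test_sequence`): no random effect (plain OLS — algebraically
   identical to the pooled t), a random intercept per order, or intercepts
   per order and per family within order. The likelihood-ratio sequence
   compares adjacent structures with `L = 2(ℓ_alt − ℓ_null)` on 1 df.
   Because all three models share one fixed-effect design, REML
   log-likelihoods are comparable; the no-random-effect member uses the
   closed-form REML log-likelihood of OLS
   (`−2ℓ = log|XᵀX| + (n−p)(1 + log(2π·RSS/(n−p)))`), which a test verifies
   equals `lme4`'s value at a singular fit to 1e−6. Testing a variance
   component on its boundary makes the χ²₁ reference conservative; negative
   `L` (possible numerically) is clipped to zero and flagged. A
   `reml = FALSE` switch fits the whole sequence by maximum likelihood
   instead; the switch applies to the sequence as a unit so criteria are
   never mixed across a comparison.
4. **Difference correlation** (`difference_correlation`): Pearson r between
   `d_ldt` and `d_set` over complete pairs, with the fraction of pairs
   whose differences have strictly opposite signs (zero differences count
   as non-concordant). An inverse correlation means pairs whose invasive
   member has the higher threshold also tend to have the lower heat sum —
   the configuration in which the invasive species overtakes its relative
   above the crossing temperature.

Normality screening (`normality_diagnostics`) reports sample skewness,
*excess* kurtosis (normal = 0; stated to avoid convention drift) and
Shapiro–Wilk. `residual_diagnostics` emits residuals, fitted values and
per-group BLUPs (shrunk toward zero relative to raw group means — a
property the tests assert).

All p-values are two-sided; no multiple-testing correction is applied —
the analyses are three views of one contrast, not a family of independent
hypotheses.

## Phenology

`daily_degree_days_single_sine()` integrates the area above the threshold
under a sine approximation of the diurnal temperature course between the
daily minimum and maximum: with `m = (t_max+t_min)/2`, `w = (t_max−t_min)/2`
and `θ = asin((ldt−m)/w)`, a partial day contributes
`((m−ldt)(π/2−θ) + w·cosθ)/π`, a fully warm day `m−ldt`, a cold day 0. The
function is continuous in the threshold at both boundaries and agrees with
direct numerical integration to better than 1e−6 (tested on a grid). A
simple-average method is included for sensitivity checks; the two coincide
whenever the whole day stays above the threshold. `accumulate_to_completion`
resolves stage completion at day granularity and applies no upper
developmental cut-off — a documented limitation for very hot series.

`crossing_temperature()` solves `(T − LDT_I)/SET_I = (T − LDT_N)/SET_N`:

`T_c = (LDT_I·SET_N − LDT_N·SET_I)/(SET_N − SET_I)`,

above which the smaller-SET species develops faster. Equal SETs are
parallel lines and raise an error.

## The synthetic-data generator

`generate_pair_dataset()` emulates a 100-pair comparative study of invasive
and non-invasive insects. Its defaults *are* the study conditions the
package targets, fixed once from the aggregate statistics such a study
reports:

| parameter | default | origin |
|---|---|---|
| `effect_ldt` | 1.4 °C | reported mean paired LDT difference |
| `effect_set` | −39.3 D° | reported mean paired SET difference |
| `target_icc_ldt` / `target_icc_set` | 0.217 / 0.222 | reported ICCs |
| `rho_diff` | −0.276 | reported correlation of paired differences |
| `set_missing_fraction` | 0.12 | 88 of 100 pairs with SET |
| `sd_res_ldt` | 2.260 °C | from t = 4.38 at n = 100: `sd(d) = 1.4√100/4.38`, `σ_res = sd(d)/√2` |
| `sd_res_set` | 171.5 D° | from t = 1.52 at n = 88, same construction |
| `mean_ldt`, `mean_set` | 10 °C, 400 D° | typical magnitudes in thermal-requirement databases |
| continents | 36/43/15/6% | reported continental composition of pairs |

Per pair, a baseline trait value is the sum of Gaussian order, family and
pair-specific effects whose variances add to `σ²_B = icc/(1−icc)·σ²_res`
(split 0.3/0.3/0.4 across the three levels — no decomposition is reported,
so this is the package's own choice), plus a shared within-pair component
`N(0, σ²_res/2)`. The two members sit at `baseline ∓ d/2` where the
difference vector `(d_ldt, d_set)` is bivariate normal with means
`(effect_ldt, effect_set)`, SDs `√2·σ_res` and correlation `rho_diff`.
This construction makes the marginal between-member covariance exactly
`σ²_B` and each member's variance `σ²_B + σ²_res`, so the population ICC
equals the target and `sd(d)` equals `√2·σ_res` — both verified by moment
tests at 10⁴ pairs. Gaussian components throughout are consistent with the
normality screening the analyses assume; SET missingness is completely at
random. At the default spreads an occasional SET draw can be non-positive
(≈2% of species); values are left as drawn because the pairing and
inference never require positivity and truncation would bias the
configured moments.

Each pair gets its own genus on one shared continent, so generated trait
tables re-pair at genus rank by construction — letting every downstream
stage be exercised end to end from a seed.

`generate_development_dataset()` adds Gaussian noise on the **rate** scale
(the scale on which the estimator is linear), resampling the rare
non-positive draws so development times remain finite; both generators are
fully deterministic given their seed.

### What the generator does and does not emulate

It reproduces the variance structure, effect sizes, missingness and
taxonomic clustering of a real pair table — not literature heterogeneity
(study-level method biases, publication effects), non-Gaussian trait
tails, unbalanced taxonomic sampling, or any real phylogeny. Passing tests
therefore demonstrate that the estimators recover the parameters of this
idealised generating process, not that a particular empirical dataset
satisfies the model.

One consequence of realistic taxonomic clustering deserves note: with the
default 5 orders and 20 families shared across 100 pairs, the *realised*
between-pair variance in any one draw is attenuated by the finite number of
cluster draws (a factor `(k−1)/k` per component once the grand mean is
absorbed), so ICC estimates at n = 100 average ≈ 0.20 against the marginal
target 0.217 — an attribute of clustered designs generally, not of the
estimator or generator, and it vanishes as the component count grows. The
difference correlation, by contrast, is recovered without visible bias.

## Problem sizes and numerical choices

The test suite runs Monte-Carlo loops at sizes chosen to give stable
verdicts in about a minute: 200 replicate studies of 100 pairs for ICC and
correlation recovery and for the null type-I check; 100 replicates for the
null behaviour of the LR statistics; 50 replicate rearing datasets for LDT
recovery; 10⁴–2×10⁵ pairs for moment checks. `scripts/acceptance.R` uses
the same sizes. Exact-algebra checks (noise-free recovery, the three-point
OLS example, the 18 °C crossing) use tolerance 1e−9 or tighter; oracle
equivalences (sine integration, pooled-t/OLS identity, textbook Pearson)
use 1e−6 to 1e−12 as appropriate to the arithmetic involved.

## Known limitations

* Linear-only rate model: no Brière/Lactin/Sharpe–Schoolfield curves, no
  upper thresholds or optima.
* Taxonomic ranks stand in for phylogeny; no PGLS or independent
  contrasts.
* Continent is a single label per species; genuinely transcontinental
  natives need an explicit prior assignment.
* Day-granularity completion dates; no diapause or dormancy handling.
* The nested random-effect LR tests are conservative at the variance
  boundary; their printed p-values should be read accordingly.
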