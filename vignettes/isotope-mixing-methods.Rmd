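---
title: "Methods: the isomixr mixing model, group comparisons and trophic position"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the isomixr mixing model, group comparisons and trophic position}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomixr)
```

# The mixing model

`isomixr` fits the standard Gaussian stable-isotope mixing model for two
tracers (δ¹³C and δ¹⁵N). Writing `p` for the diet-proportion vector over the
K source groups, the signature of consumer *i* on isotope *j* is

$$ y_{ij} \sim \mathcal{N}\!\Big(\textstyle\sum_k p_k(\mu_{kj} + c_j),\;
   \sum_k p_k^2(\sigma_{kj}^2 + \tau_j^2) + \varepsilon_j^2\Big) $$

with source moments $\mu_{kj}, \sigma_{kj}$ (estimated from prey samples by
`summarize_sources()`, sample SD with the $n-1$ denominator), trophic
enrichment factor (TEF) moments $c_j, \tau_j$, and a per-isotope residual SD
$\varepsilon_j$ absorbing unmodelled variation. There is no concentration
dependence: the model assumes all sources contribute carbon and nitrogen in
proportion to their diet share, which is the appropriate default when
elemental concentration data were not collected. Consumers within a group
are exchangeable — no hierarchical individual effects.

Assumptions worth keeping in mind: source groups are Gaussian in δ-space and
temporally stable over the tissue's integration window; the TEF applies one
trophic step uniformly across sources; and consumers must fall inside the
polygon spanned by TEF-corrected source means for the model to be well posed
— `polygon_diagnostic()` checks this (closed convex hull of corrected
*means*, matching the usual iso-space plot; points outside warn but do not
abort, since the polygon is a diagnostic, not a filter).

## Priors and defaults

| Parameter | Default | Why |
|---|---|---|
| TEF mean (δ¹³C, δ¹⁵N) | 3.0 ‰, 0.9 ‰ | decapod-specific (mantis shrimp muscle, diet-shift experiment) |
| TEF SD | 0.6 ‰, 0.3 ‰ | same source |
| Dirichlet α | 1, …, 1 | uniform over the simplex; no prior diet information |
| residual prior | half-Normal, scale 5 ‰ | weakly informative on the δ scale |
| Δₙ (per-level δ¹⁵N) | 3.4 ‰ | standard aquatic food-web value |
| λ (baseline level) | 1 | phytoplankton is a primary producer |
| residence times | muscle 81.1 d, hepatopancreas 19.3 d | crustacean turnover estimates; 19.3 = 13.38 d half-life / ln 2 |

Source or TEF SDs of exactly zero are floored at 10⁻⁶ ‰ so the likelihood
stays proper.

## Sampling

`sample_posterior()` runs an adaptive random-walk Metropolis sampler on an
unconstrained parameterisation: additive log-ratio coordinates for `p`
(reference = last source; the Jacobian $\prod_k p_k$ is included) and log
residual SDs. Three ingredients matter:

1. a scalar proposal scale tuned towards ~30% acceptance during burn-in;
2. a proposal shape set to the empirical covariance of the recent burn-in
   history — with more sources than tracers the posterior concentrates on a
   ridge (see below) and an isotropic walk crosses it very slowly;
3. a 10% mixture component proposing independent draws from the prior, whose
   Metropolis–Hastings ratio reduces to the likelihood ratio. These global
   jumps traverse the prior-dominated parts of the ridge.

All adaptation stops at the end of burn-in, so retained draws come from a
valid fixed-kernel Metropolis chain. Defaults are 4 chains × 10,000
iterations, 1,000 burn-in, thinning 10. Convergence is monitored with
split-chain Gelman–Rubin $\hat R$ per parameter; any $\hat R > 1.05$ raises
a warning and is echoed into the pipeline's `rhat_report.csv`. Seven-source
fits sit near that threshold at the default length; raising `n_iter` to
30,000 brings them below it at ~3 s per fit. A chain that never accepts a
move after burn-in is reported as a convergence failure.

Given identical settings and seed the draws are bit-identical.

## Verification against an exhaustive oracle

`grid_posterior_oracle()` integrates the same posterior by brute force: a
0.01-step lattice on the simplex (K ≤ 3) crossed with a 24-point log-spaced
grid per residual SD, each point weighted by likelihood × prior × local grid
spacing. The tests require MCMC and oracle posterior means to agree within
0.02; in practice they agree within ~0.001. The oracle shares only the
likelihood formula with the sampler — no sampling code.

## Identifiability: why seven-source posteriors stay broad

Two tracers plus the simplex constraint determine at most three proportions.
With K = 7 the likelihood constrains only the two-dimensional projection
$\sum_k p_k(\mu_k + c)$; a four-dimensional set of diets fits any attainable
consumer mean equally well, and the posterior mean lands near the barycentre
of that set rather than at any particular generating truth. Consequences we
make explicit rather than hide:

* per-source posterior means at K = 7 can sit far (±0.2) from the generating
  proportions even with a perfect sampler — this is information loss, not
  bias in the code;
* *identified combinations* behave well: the active/suspension aggregates,
  which is why the hypothesis tests operate on aggregated draws;
* parameter-recovery testing is done at K = 3 (the point-identified case),
  where 100-replicate runs at the design size (n = 10 consumers) give mean
  absolute errors ≈ 0.03 and ~95% credible-interval coverage.

## Source aggregation and p_BIC

`combine_sources()` sums member-source proportions draw by draw, so
aggregate draws are exact posterior draws (linearity of the simplex); the
last aggregate is written as the exact complement so per-draw sums are
exactly 1. `compare_groups()` estimates
$p_{BIC} = P(p^{A}_{s} > p^{B}_{s})$ by pairing draws by index after
truncation to the common length — unbiased because the two group posteriors
are independent fits — with ties counted 0.5 so that
$p_{BIC}(A,B) + p_{BIC}(B,A) = 1$ exactly. Significance is one-sided per
ordered pair at the 0.95 threshold. No multiple-testing correction is
applied, deliberately matching the analysis style this pipeline reproduces.
The full batteries are 24 size comparisons (2 sexes × 4 periods × 3 ordered
size pairs) and 6 sex comparisons (3 sizes × the 2 long periods), both on
the suspension-feeding aggregate by default.

Calibration on the null scenario (identical true diets everywhere) keeps the
false-positive rate at or below 10% over seeded replicates, and the
0.30-suspension-shift scenario is reliably detected at the design sample
size.

# Study design: groups and integration windows

`group_consumers()` partitions records into sex × size × tissue × date cells
(12 per sampling day under the full design), each fitted independently
against the source summaries of its own sampling day — 24 fits for a full
two-day study.

Each tissue integrates diet over a different window. For first-order
turnover the mean residence time is `t_half / ln 2`
(`residence_time_from_half_life()`); `assign_window()` then spans
`floor(rt)` whole days back from the sampling date. This reproduces the
short (hepatopancreas, 19 d) windows exactly. The long (muscle, 81.1 d)
windows in the study design this package mirrors are printed one day earlier
than any single rounding convention yields together with the short windows,
so per-window endpoint overrides are accepted in the pipeline config and
used to replicate the published periods verbatim; the one-day discrepancy is
documented rather than resolved.

# Trophic position

`tp_basic()` implements the classical estimator
$TP = \lambda + (\delta^{15}N_c - \delta^{15}N_{base})/\Delta_n$. For
decapods the per-step enrichment of the consumer itself (0.9 ‰) is far below
the food-web average Δₙ = 3.4 ‰, which would underestimate TP; the corrected
form first subtracts the taxon TEF from the consumer signature (removing its
final trophic step) and then adds the level back:

$$ TP = 1 + \big(\lambda + ((\delta^{15}N_c - 0.9) -
  \delta^{15}N_{base})/\Delta_n\big) $$

so `tp_corrected(x) = 1 + tp_basic(x - 0.9)` holds as an exact identity.
The baseline is the mean of the *day-level* phytoplankton δ¹⁵N means (equal
day weights), so unbalanced per-day sampling cannot tilt it.

`tp_table()` computes TP per tissue measurement, reports per-period mean ±
sample SD, and pools all measurements for the overall row. Whether "overall"
should average measurements, individuals, or period means is ambiguous in
designs like this; under a balanced design all three agree in the mean
(though not in SD), pooled measurements are the default, and
`per_individual = TRUE` averages each individual's tissues first.

# The synthetic-data generator

`simulate_consumers()` is the generative twin of the likelihood: per
consumer it draws a source realisation N(μ, σ) and TEF realisation N(c, τ)
per source and isotope and forms the diet-weighted sum plus residual noise,
so generated data have exactly the first two moments the likelihood assumes
(verified by a law-of-large-numbers test and by a grid check that the
average log-likelihood is maximised near the generating diet).

`simulate_study()` emulates the full design: 10 individuals per
sex × size × day cell (120 individuals, 240 tissue measurements), each
individual measured in both tissues with diets drawn from the
tissue-period's true diet; source samples are drawn around each group's
geometry under 17 taxon labels mapping onto the 7 groups. The default
geometry is invented — seven groups in convex position spread over a
realistic coastal δ-range (δ¹³C −24 to −14 ‰, δ¹⁵N 4 to 13.5 ‰, within-group
SDs 0.8/0.7 ‰, residual 0.5 ‰) — and is documented as illustrative: no
attempt is made to reproduce any real site's values. Preset scenarios cover
the structures the pipeline must distinguish: `null` (one shared diet),
`size_effect` (+0.30/+0.15 suspension share in small/medium vs large, sexes
identical), its alias `sex_null_size_effect`, and `pom_dominant` (POM at
0.45 everywhere).

What passing tests on this generator do **not** show about field data:
real sources drift seasonally, are non-Gaussian, and may violate the
constant-TEF assumption; real consumers are not exchangeable within cells;
and the generator never places consumers outside the mixing polygon unless
asked. Synthetic recovery is a correctness check of the machinery, not a
field validation.

# Numerical choices and problem sizes

* Likelihood evaluated via per-isotope sufficient statistics (one pass over
  consumers), making a 40,000-iteration fit sub-second at K = 7, n = 10.
* Hull tests use a 10⁻⁹·scale tolerance; boundary points count as inside.
* Ties in `p_BIC` count 0.5; aggregate columns are exact complements.
* Degenerate single-sample source groups get SD 0, a `degenerate` flag and a
  warning; zero SDs are floored in the model.
* The test suite runs reduced samplers (2 chains × 3,000–4,000 iterations)
  except where a check is about the defaults; the 100-replicate recovery
  check uses 2 × 4,000 iterations at K = 3, and the acceptance script's
  pipeline stage runs the full 4 × 10,000 defaults for 24 fits. These sizes
  were chosen as the smallest at which the Monte-Carlo error is comfortably
  below each test's tolerance.

# Known limitations

* No concentration-dependent mixing, no informative priors, no hierarchical
  consumer structure.
* Per-source inference with 7 sources and 2 tracers is fundamentally
  underdetermined (see above); report aggregates, or add tracers.
* $\hat R$ near 1.05–1.3 on seven-source fits at default chain lengths;
  lengthen chains for publication-grade runs.
* The residence-time model is a single exponential pool; growth dilution and
  route-specific incorporation are out of scope.
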