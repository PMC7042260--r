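# isomixr

Bayesian stable-isotope mixing models for crustacean diet analysis, with
posterior group comparisons and trophic-position estimation.

`isomixr` targets the standard two-tracer (δ¹³C, δ¹⁵N) diet study: consumers
(here, *Nephrops norvegicus*-style decapods sampled by sex, size class and
tissue on repeated dates) are measured alongside their putative prey, and the
question is what fraction of the diet each prey group contributes, whether
those fractions differ between consumer groups, and where the consumer sits
in the food web.

## The model

For consumer *i* and isotope *j*, the signature is modelled as

    y_ij ~ Normal( Σ_k p_k (μ_kj + c_j),  Σ_k p_k² (σ_kj² + τ_j²) + ε_j² )

where `p` is the diet-proportion vector on the simplex, `μ_kj`/`σ_kj` are the
mean and SD of source group *k*, `c_j`/`τ_j` the trophic enrichment factor
(TEF) mean and SD (defaults 3.0 ± 0.6 ‰ for δ¹³C, 0.9 ± 0.3 ‰ for δ¹⁵N —
decapod-specific values), and `ε_j` a per-isotope residual SD. Priors are
Dirichlet(1, …, 1) on `p` and half-Normal(5 ‰) on each `ε_j`. The posterior
is sampled by a multi-chain adaptive random-walk Metropolis algorithm with
split-chain Gelman–Rubin diagnostics, and is independently checkable against
an exhaustive simplex-grid oracle for up to three sources.

Downstream of the fit:

* `combine_sources()` aggregates posterior draws a posteriori, e.g. into
  "active" vs "suspension" feeding;
* `compare_groups()` computes `p_BIC`, the posterior probability that a
  source's proportion in one group exceeds that in another (`> 0.95` flagged
  significant), with `run_size_comparisons()` / `run_sex_comparisons()`
  batching the full study design;
* `tp_basic()` / `tp_corrected()` estimate trophic position from δ¹⁵N
  relative to a phytoplankton baseline (Δₙ = 3.4 ‰ per level), the corrected
  form accounting for the low decapod δ¹⁵N TEF;
* `tissue_windows()` converts tissue residence times (muscle ≈ 81.1 d,
  hepatopancreas ≈ 19.3 d) into the dietary-integration period each
  measurement reflects;
* `scenario()` / `simulate_study()` generate complete synthetic studies
  (120 individuals: 10 per size × 3 sizes × 2 sexes × 2 days, two tissues
  each) from known diets, so every stage is testable end to end.

## Worked example

```r
library(isomixr)

study   <- simulate_study(preset_scenarios(seed = 42)$pom_dominant)
sources <- summarize_sources(study$sources, default_grouping())

cons <- dplyr::filter(study$consumers, sex == "female", size_class == "small",
                      tissue == "hepatopancreas",
                      sampling_date == as.Date("2014-05-29"))

polygon_diagnostic(cons, sources)
#> Mixing polygon: 10/10 consumers inside (0 outside)

fit <- sample_posterior(cons, mixing_model(sources), seed = 42)
glance(fit)
#>   n_sources n_consumers n_draws n_chains max_rhat mean_accept
#> 1         7          10    3600        4     1.03       0.326
tidy(fit)
#>   source           mean     sd  ...  q97.5 mean_pct
#> 1 Crustaceans    0.0756 0.0561       0.206     7.56
#> 4 POM_susp       0.284  0.119        0.505    28.4
#> 7 Zooplankton    0.281  0.138        0.543    28.1
```

With seven sources and two tracers only certain combinations of proportions
are identified, so single-source posteriors stay broad; the aggregated
feeding modes are much sharper (the generating truth here put 59% of the
diet in suspension sources):

```r
tidy(combine_sources(fit))
#>   source      mean     sd  q2.5  q97.5 mean_pct
#> 1 active     0.318 0.0666 0.181  0.446     31.8
#> 2 suspension 0.682 0.0666 0.554  0.819     68.2
```

Trophic position against the phytoplankton baseline (here 4.15 ‰):

```r
base <- baseline_from_phytoplankton(study$sources)
tp_table(study$consumers, trophic_params(d15N_base = base))
#>   period         mean    sd     n
#> 1 Spring long    3.25 0.221    60
#> 2 Spring short   3.29 0.191    60
#> 3 Summer long    3.30 0.168    60
#> 4 Summer short   3.26 0.154    60
#> 5 Overall (avg)  3.28 0.185   240
```

A mean of ~3.3 is what this scenario should give: its consumers take a fifth
of their diet from fish, which sit well above the primary consumers.

The whole analysis can also be driven from one YAML file
(`inst/extdata/example_config.yaml`) via `run_report()`, or from a shell via
`inst/cli/isomixr.R`.

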