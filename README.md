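# jellytroph

Trophic-ecology inference for gelatinous zooplankton diet studies, as a
tidyverse-native R package. Given the three complementary data streams of a
seasonal jellyfish feeding study — stomach contents versus environmental
prey availability, stable isotopes (δ13C, δ15N) of consumers and plankton
size-class sources, and fatty-acid profiles of gonadic and somatic tissue —
it runs the full analysis chain:

* **Prey electivity** — Pearre's index
  `C = (a_d·b_e − b_d·a_e) / √((a_d+a_e)(b_d+b_e)(a_d+b_d)(a_e+b_e))`
  per taxon × month, tested with the ordinary chi-square `χ² = nC²` (1 df),
  with configurable environment pseudo-count policies.
* **Trophic level** — δ notation `δX = (R_sample/R_standard − 1)·10³` and
  `TL = (δ15N_f − δ15N_ref)/3.2 + TL_ref`, with calanoid copepods as the
  baseline at `TL_ref = 2`.
* **Bayesian mixing model** — consumer isotopes as a Dirichlet-normal
  mixture of TEF-shifted sources
  (`mean_j = Σ p_k(μ_jk + c_jk)`, `var_j = Σ p_k²(ω_jk² + τ_jk²) + σ_j²`),
  TEF defaults 2 ± 0.3 ‰ (C) and 3.2 ± 0.1 ‰ (N), sampled by
  preconditioned random-walk Metropolis MCMC (4 chains × 20,000 iterations)
  with Gelman–Rubin diagnostics.
* **Fatty-acid biomarkers** — shorthand classification (SFA/MUFA/PUFA),
  class totals, and the n-3/n-6, PUFA/SFA and EPA/DHA ratios.
* **PERMANOVA and SIMPER** — sequential-SS partitioning of Euclidean or
  Bray–Curtis distance matrices over 1–3 crossed factors with label
  permutation, and exact decomposition of between-group Bray–Curtis
  dissimilarity into per-variable contributions.
* **Synthetic data** — seeded generators with recorded ground truth for
  every stream, plus a study-like preset (`synth_paper_like()`), so every
  estimator ships with parameter-recovery tests.

Fitted objects support broom-style `tidy()`/`glance()` and ggplot2
`autoplot()`; all tabular functions take a data frame first and return
tibbles.

## Worked example

Generate a study-like dataset and run the whole pipeline from one config:

```r
library(jellytroph)

dir <- tempfile(); out <- tempfile()
paths <- synth_paper_like(dir, seed = 42)      # env, diet, iso, sources, tef, fa + truth.json
res <- run_pipeline(list(
  inputs = paths[c("diet", "env", "isotopes", "sources", "tef", "fa")],
  out_dir = out, seed = 9
))

tidy(res$mixing)
#> # A tibble: 5 × 8
#>   term          kind         mean median lower upper level  rhat
#>   <chr>         <chr>       <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 p_<200 um     proportion  0.457  0.457 0.440 0.475  0.95  1.00
#> 2 p_200-1000 um proportion  0.399  0.399 0.376 0.422  0.95  1.00
#> 3 p_>1000 um    proportion  0.143  0.143 0.119 0.168  0.95  1.00
#> 4 sigma_d13C    residual_sd 0.313  0.310 0.208 0.425  0.95  1.00
#> 5 sigma_d15N    residual_sd 0.372  0.369 0.285 0.479  0.95  1.00
```

The posterior means recover the generating diet proportions
(0.45, 0.40, 0.15 over the three plankton size classes) within ±0.01, with
95% credibility intervals and R-hat ≈ 1 confirming convergence. The
selectivity table flags the taxa the generator actually selected — e.g. in
May:

```r
sel <- res$selectivity$table
sel[sel$month == "May" & sel$testable, c("taxon", "C", "p", "direction")]
#>   taxon                   C      p direction
#> 1 appendicularians  0.0121  0.701  0
#> 4 fish_eggs         0.0691  0.0280 +
#> 7 ostracods        -0.0286  0.363  0
#> ...
```

`fish_eggs` (selectivity weight 2 in the preset) is positively selected;
neutral taxa sit near C = 0. Monthly stomach fullness comes from
`diet_totals()` (e.g. November: 25.8 ± 1.15 prey per medusa over 23
animals), source/consumer geometry from `plot_isotope_biplot()`, and the
month × sex × tissue structure of the fatty acids from the written
`permanova_fa.csv` / `simper_months.csv` tables.

A bundled published monthly diet-composition summary
(`inst/extdata/monthly_prey_composition.csv`) can be expanded into a
per-predator table with `prey_counts_from_means()` and fed through the same
summaries.

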