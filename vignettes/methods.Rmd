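---
title: "Models and methods behind jellytroph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind jellytroph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jellytroph)
```

jellytroph implements the inference chain of a seasonal jellyfish diet
study: prey electivity from stomach contents, trophic level from stable
isotopes, Bayesian diet-source mixing, fatty-acid biomarkers, and
permutational multivariate statistics. This vignette explains each model,
its assumptions and tunable parameters, the numerical choices made where
the design was genuinely open, and what the synthetic-data generator does
and does not emulate.

## Prey electivity

For a focal taxon in a month, a 2x2 contingency table opposes the pooled
stomach counts of all medusae sampled that month (focal vs all other taxa)
to the environmental availability from net tows. Pearre's electivity index

$$C = \frac{a_d b_e - b_d a_e}{\sqrt{(a_d+a_e)(b_d+b_e)(a_d+b_d)(a_e+b_e)}}
\in [-1, 1]$$

is tested with the ordinary (uncorrected) chi-square, which for this table
is exactly $\chi^2 = nC^2$ on 1 df. Counts are pooled per month before
testing: individual medusae often hold a handful of prey, far too few for a
valid per-sample chi-square.

The environment margin is a density (individuals m^-3^), not a count, so it
must be converted to pseudo-counts. Four policies are available
(`env_pseudo_n`): raw rounding, density x filtered volume (`"volume"`, the
default, falling back to matching when volumes are missing), proportions x
the month's pooled diet total (`"match"`, which equalizes the power of the
two margins), or proportions x a fixed n. Rounding is half-away-from-zero.
No multiple-testing correction is applied by default, mirroring per-cell
significance flags in published diet tables; `alpha` defaults to 0.05.

Two caveats are inherent to the index, not to this implementation. First,
electivity is *compositional*: because diet shares sum to one, genuine
selection for a dominant taxon necessarily depresses the apparent share of
every other taxon, producing induced "avoidance" signals. Second, if the
environment margin is treated as fixed (no sampling noise), the chi-square
is strongly conservative; calibration holds when both margins carry
sampling noise, which is how the type-I checks are run.

## Trophic level from nitrogen isotopes

Isotope ratios are expressed in delta notation,
$\delta X = (R_{sample}/R_{standard} - 1)\times 10^3$ (per-mil), and the
consumer's trophic level is estimated as

$$TL = \frac{\delta^{15}N_f - \delta^{15}N_{ref}}{\Delta_N} + TL_{ref},$$

with the per-level nitrogen enrichment $\Delta_N = 3.2$ permil and
mesozooplanktonic calanoid copepods as the baseline at $TL_{ref} = 2$. Both
are arguments, not constants: alternative enrichment factors can produce
unrealistically high trophic positions, so the default follows the
conventional 3.2 permil. The baseline d15N is a per-month (or global) user
input; carbon fractionation (~2 permil per level) is carried as a TEF for
the mixing model but never used for a second TL estimate, since the formula
is nitrogen-based.

## The Bayesian mixing model

Consumers are modelled per isotope $j$ as draws around a mixture of $K$
sources with TEF-shifted signatures:

$$y_{ij} \sim \mathcal{N}\!\Big(\sum_k p_k(\mu_{jk} + c_{jk}),\;
\sum_k p_k^2(\omega_{jk}^2 + \tau_{jk}^2) + \sigma_j^2\Big)$$

where $\mu_{jk}, \omega_{jk}$ are source means and sds, $c_{jk}, \tau_{jk}$
the TEF means and sds (defaults 2 +/- 0.3 permil for carbon, 3.2 +/- 0.1
permil for nitrogen), $p$ lies on the simplex, and $\sigma_j$ is a
per-isotope residual scale. Priors are Dirichlet(1, ..., 1) on $p$ and
half-normal on each $\sigma_j$ with scale equal to the observed consumer sd
— a fully specified version of the classical diet-mixing likelihood with
source and fractionation variance folded into the observation variance.
Concentration dependence, isotope routing and covariates are out of scope.

Sampling is random-walk Metropolis on the unconstrained scale (softmax for
$p$, log for $\sigma$), 4 chains x 20,000 iterations, 50% burn-in, thinning
5 — 8,000 retained draws. Two numerical choices matter:

* **Preconditioning.** The posterior is tight and anisotropic; an isotropic
  random walk mixes badly. Before sampling, a BFGS search finds the
  posterior mode and the inverse-Hessian diagonal sets per-parameter
  proposal scales; chains start overdispersed around the mode. A single
  global scale then adapts toward 20-40% acceptance *during burn-in only*,
  so the retained chain comes from a fixed kernel.
* **Diagnostics.** Gelman-Rubin R-hat is computed per parameter across
  chains; a fit with any R-hat above 1.1 is flagged (never silently
  discarded). With a single chain R-hat is reported as unavailable. Zero
  consumers are allowed, in which case the posterior is the prior — a
  useful correctness check.

Equal-tailed credibility intervals use the default quantile definition of
`stats::quantile` (type 7). With one source the posterior is degenerate at
$p = 1$.

## Fatty-acid biomarkers

Fatty acids are classified purely from the shorthand
`C<carbons>:<double bonds>n-<omega>` (parentheses tolerated): 0 double
bonds SFA, 1 MUFA, >= 2 PUFA; omega-3/6 membership comes only from the
`n-x` suffix, and acids without an omega label join the saturation classes
but not the n-3/n-6 ratio. Common-name aliases resolve canonically (EPA =
C20:5n-3, DHA = C22:6n-3, AA = C20:4n-6); published texts occasionally
cross these labels, and a strict mode refuses aliases entirely. Per-sample
summaries give the total concentration (ug per mg dry tissue), class totals
and percentages, and the three trophic ratios n-3/n-6, PUFA/SFA, EPA/DHA;
zero denominators yield `NA`, never infinity. All detected FA columns enter
the denominators.

## PERMANOVA and SIMPER

`distance_matrix()` applies the optional log(x+1) transform (natural log,
configurable) and computes Euclidean or Bray-Curtis distances via vegan.
`permanova()` partitions the Gower-centered inner-product matrix
$G = CAC$, $A = -\tfrac12 D^2$, by sequential (Type I) projections of the
design: $SS_{term} = \mathrm{tr}(H_{term} G)$, pseudo-F is
$MS_{term}/MS_{residual}$, and p-values come from unrestricted permutation
of sample labels with the observed statistic counted into the null set
(the +1/+1 rule). Design choices: factor order follows the supplied data
frame (month, sex, tissue in the pipeline); multiway designs must be
balanced (the generator always produces balanced layouts); unrestricted raw
permutation is exact for one-way designs and a standard approximation for
balanced crossed ones — results can differ from software that permutes
residuals under reduced models. Exhaustive enumeration (`permutations =
"exact"`) is available for n <= 8 and underlies the small-sample tests.

`simper()` decomposes the average between-group Bray-Curtis dissimilarity
exactly: the contribution of variable $v$ between groups is the cross-pair
average of $|x_{iv} - x_{kv}| / \sum_w (x_{iw} + x_{kw})$, so contributions
sum to the average dissimilarity by construction. Degenerate cases are
defined rather than dropped: identical all-zero sample pairs get distance 0
with a warning, and a zero total SS yields a flagged (all-`NA`) table.

## What the synthetic generator emulates

The generator reproduces the *statistical structure* the analysis assumes,
with recorded ground truth and a single seed stream:

* **Environment** — log-normal densities around seasonal mean profiles
  (copepod spring peak, pteropod early-winter peak; CV 0.2, 10 m^3^ tows).
* **Stomachs** — per-medusa totals Poisson(25), taxa multinomial with
  probability proportional to selectivity weight x availability; the
  study-like preset samples the published per-month medusa counts
  (23, 17, 3, 12, 20, 27, 13, 13) and puts selection on non-dominant taxa
  (fish eggs 2, ostracods and furcilia 0.3) with the dominant copepods
  neutral, because compositional closure would otherwise smear a dominant
  taxon's selection across every other taxon.
* **Isotopes** — consumers drawn from the mixing likelihood at true
  proportions (0.45, 0.40, 0.15) with residual sd 0.3 permil, plus source
  observation samples. The default sources form a non-degenerate triangle
  in isotope space (d15N 1.5/4.5/8.0, d13C -23.0/-16.5/-20.5, sd 0.3):
  with collinear sources only one direction of $p$ is identified and no
  sampler could recover three proportions.
* **Fatty acids** — balanced month x sex x tissue layout, log-normal
  concentrations around a 13-acid panel dominated by palmitic acid, EPA and
  DHA, a sinusoidal month effect (amplitude 0.5 on the log scale), a 10x
  gonad multiplier, and a 1.5x female-gonad boost in April-June emulating
  reproductive FA accumulation.

What it does **not** emulate: overdispersion beyond Poisson-multinomial
(a knob exists via the lognormal CV but counts are not negative binomial),
diel vertical migration biasing the environment margin, isotopic seasonal
drift within the consumer pool, lipid-normalization or Suess corrections,
and any correlation structure among fatty acids beyond shared group means.
Passing recovery tests therefore shows the estimators are correct and
calibrated under the assumed model — not that field data meet those
assumptions.

## Problem sizes and reproducibility

The bundled checks run at deliberately compact sizes chosen to give stable
Monte-Carlo behaviour: 1,000 random tables for the electivity identity,
1,000 simulations for each type-I calibration, 100 datasets for the
ANOVA-equivalence oracle, 20 seeded replicates of the 50-consumer mixing
recovery, and one full synthetic study (128 medusae, 96 FA samples, 999
permutations). Every stochastic step takes an explicit integer seed, child
seeds are derived deterministically, and rerunning any pipeline
configuration reproduces byte-identical CSV output.

```{r example, eval = FALSE}
dir <- tempfile(); out <- tempfile()
paths <- synth_paper_like(dir, seed = 42)
res <- run_pipeline(list(
  inputs = paths[c("diet", "env", "isotopes", "sources", "tef", "fa")],
  out_dir = out, seed = 9
))
tidy(res$mixing)
```
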