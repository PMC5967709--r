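# founderisk

Statistical toolkit for genetic epidemiology in founder (bottlenecked)
populations — written for statistical geneticists and genetic
epidemiologists who work from summary tables (allele counts, dosages,
effect sizes) rather than raw sequencing data.

A recent bottleneck leaves a population with many protein-coding
alleles at far higher frequency than in any outbred reference panel,
and many others lost outright. Those enriched alleles drive
population differences in recessive-disease burden and can carry
detectable disease associations. `founderisk` implements the full
analysis chain around that signature:

* **Enrichment scoring** — per-variant Haldane–Anscombe bias-corrected
  log odds ratio against the maximum-frequency reference population,

  β̂ = log[(0.5+ALT_s)(0.5+REF_r)] − log[(0.5+REF_s)(0.5+ALT_r)],
  SE² = Σ 1/(0.5+cell),

  with exact one-sided Fisher classification at a Bonferroni threshold
  inside the study-frequency window [0.002, 0.1), annotation-class
  summaries, pathogenic-table intersection, and the k → k² recessive
  risk translation under Hardy–Weinberg equilibrium.
* **Association & meta-analysis** — Firth penalized logistic
  regression (finite under complete separation), Wakefield approximate
  Bayes factors, and the correlated- vs independent-effects Bayesian
  meta-analysis with a N(0, 0.2²) effect prior and log₁₀BF > 2
  heterogeneity flagging.
* **Composite-carrier non-additivity** — 1-hit/2-hit odds ratios
  across a gene's risk-allele set and profile-penalized
  likelihood-ratio tests of the log-additive constraint β₂ = 2β₁,
  within or between genes.
* **PRS decomposition** — PRSᵢ = Σ β̂ₘ G₍ᵢₘ₎, closed-form population
  expectations E[PRS]ⱼ = Σ 2β̂ₘ f₍ₘⱼ₎, exact per-variant decomposition
  of between-population differences, genotype-specific extensions, and
  standardization to a reference control group.
* **Liability modelling** — expected prevalence E[p] = ∫ g(η) N(η; μ,
  σ²) dη with μ = logit(p₀) + Σ2fβ and σ² = 2Σf(1−f)β², baseline
  calibration, prevalence ratios with a baseline sweep, probit–logit
  comparison, and Moonesinghe attributable-prevalence factors.
* **QC & ancestry** — the standard sample/variant/relatedness/ancestry
  filters, and deterministic synthetic-data generators for every input.

## Worked example

Score a published founder-enriched allele (p.Asn409Ser in *GBA*,
Gaucher disease) from its allele counts — 129/4356 in the study
population vs 172/63804 in the best reference:

```r
library(founderisk)
b <- bias_corrected_log_or(129, 4356 - 129, 172, 63804 - 172)
fisher_one_sided(129, 4356 - 129, 172, 63804 - 172)
```

```
beta_hat 2.4248   se 0.1174   OR 11.30
p = 2.08e-72
```

An 11.3-fold enrichment (the published table prints 11.16 for this
allele), overwhelmingly significant — and for a recessive disease the
implied homozygote burden scales with the square:
`recessive_risk_enrichment(11.3)` ≈ 128-fold.

Simulate a bottlenecked cohort and classify it end to end:

```r
sim <- sim_bottleneck_counts(10000, founder_chromosomes = 500,
                             n_study = 2178, n_ref = 31902, seed = 418)
res <- classify_enrichment(sim, "AJ", "NFE")
```

```
in-window: 4629   enriched: 472   fraction 0.102   mean fold 4.24
```

A 500-chromosome bottleneck pushes ~10% of in-window variants past the
Bonferroni bar at a mean 4.2-fold enrichment, while ~29% of ancestral
variants are lost entirely; rerunning with `founder_chromosomes = 1e7`
(no bottleneck) classifies none.

Combine association evidence across three cohorts:

```r
meta_bayes(data.frame(study = c("AJ", "NFE", "FIN"),
                      beta_hat = c(0.42, 0.31, 0.38),
                      se = c(0.11, 0.13, 0.21)))
```

```
BF_corr 8289.3   BF_ind 823.9   p 1.5e-06   heterogeneity FALSE
combined_beta 0.375
```

Translate a 0.41 shift in expected risk score into a prevalence ratio
at a 0.5% baseline:

```r
prevalence_ratio(shift_a = 0.41, shift_b = 0,
                 sigma2_a = 0.30, sigma2_b = 0.28, baseline = 0.005)
```

```
ratio 1.516   E[p_a] 0.0076   E[p_b] 0.0050   beta0 -5.432
sweep over baselines 0.001-0.01: ratio 1.511-1.521
```

The ratio moves only in the third decimal across a ten-fold baseline
sweep — the practical content of the liability model's near-log-linear
small-prevalence regime.

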