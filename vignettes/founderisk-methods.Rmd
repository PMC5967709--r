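---
title: "Methods: founder-population enrichment and disease-risk modelling"
author: "founderisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: founder-population enrichment and disease-risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Setting

A population that passed through a recent bottleneck — the Ashkenazi
Jewish (AJ) population is the motivating example — carries a
characteristic signature: a sizeable minority of its protein-coding
alleles sit at much higher frequency than in any large reference
population, while many other alleles were lost outright. `founderisk`
implements the statistical machinery for working with that signature
end to end: scoring per-allele enrichment against reference panels,
testing enriched alleles for disease association across cohorts,
modelling non-additive risk in composite carriers, decomposing
polygenic risk score (PRS) differences between populations, and
translating risk-score shifts into expected disease-prevalence
ratios. Every stage consumes flat summary tables (allele counts,
dosages, effect sizes, QC metrics), so nothing here requires raw reads
or genotype calling; those belong upstream.

## Enrichment scoring

For each biallelic variant we form the 2x2 allele-count table of the
study population against the single reference population with the
highest allele frequency among those with adequate coverage and
frequency at least 1e-4 (comparing against the maximum is deliberately
conservative: an allele must beat its *best* competitor to be called
enriched). The effect estimate is the Haldane–Anscombe bias-corrected
log odds ratio

$$\hat\beta = \log\frac{(0.5+\mathrm{ALT}_s)(0.5+\mathrm{REF}_r)}
{(0.5+\mathrm{REF}_s)(0.5+\mathrm{ALT}_r)},\qquad
\widehat{SE}^2 = \sum_{\text{cells}}\frac{1}{0.5+n},$$

finite for any table, and significance is the exact one-sided
("greater") Fisher test, i.e. the upper hypergeometric tail
conditioning on the margins. A variant is classified *enriched* when
its study frequency lies in the window $[0.002, 0.1)$ — below 0.002
single-cohort counts cannot make enrichment convincing, above 0.1 the
odds-ratio scale compresses — and its p-value beats the Bonferroni
threshold $\alpha/n$. By default $n$ is the number of in-window
variants in the data at hand, because the rule is data-size dependent;
an external constant (such as a published analysis count) can be
supplied instead. Ties between reference populations at identical
frequency go to the larger allele number, then the lexicographically
smaller label — deterministic and favouring the better-measured panel.

Enrichment summaries follow: per-annotation-class enriched fractions
with pooled two-proportion z tests of each functional class against
synonymous variants; intersection with a pathogenic-variant table
(ClinVar-style flat TSV, non-conflicted pathogenic assertions only,
strict p cutoff); and the recessive-risk translation — under
Hardy–Weinberg equilibrium a k-fold allele enrichment is a k²-fold
homozygote enrichment, so a 19-fold enriched recessive allele implies
a 361-fold difference in genetic disease risk.

## Association and meta-analysis

Per-study case-control association uses Firth's penalized logistic
regression: maximize $\ell(\beta) + \tfrac12\log\det I(\beta)$, the
Jeffreys-prior penalty keeping estimates finite under the complete
separation that rare enriched alleles routinely produce. Our fitter
uses Newton scoring on the hat-corrected score with step-halving,
tolerance 1e-8 on the score norm, at most 50 iterations. Variants are
fitted only if they pass minor allele count ≥ 1 and call rate ≥ 0.8;
samples missing the variant's call are dropped for that variant
(association never imputes; contrast the PRS below). Covariates —
typically four principal components — enter the design untouched.

Cross-study combination is Bayesian on summary statistics
$(\hat\beta_k, se_k)$: the Wakefield normal approximation gives each
model a closed-form marginal likelihood. With prior variance
$W = 0.2^2$ on the log odds ratio, the *correlated-effects* model (one
shared true effect; covariance $\mathrm{diag}(se^2) + W J$) is the
headline model; the *independent-effects* model
($\mathrm{diag}(se^2) + W I$) is its heterogeneity foil, and
$\log_{10}(BF_{\mathrm{ind}}/BF_{\mathrm{corr}}) > 2$ flags
heterogeneous effects. The prior standard deviation 0.2 encodes that
most credible complex-disease log odds ratios are modest (OR roughly
0.7–1.5 within two prior standard deviations). Alongside the Bayes
factors we report a p-value approximation from the inverse-variance
fixed-effect z — monotone in the correlated-model BF when per-study
standard errors are held fixed, so rankings agree; it is an
approximation and documented as such. Q-Q annotation uses the
threshold $t = 1/n$ at which the expected number of false discoveries
under the global null is one, and variants are stratified as
gwas/non-gwas by whether they fall within 50 kb of a supplied
credible-set interval on the same chromosome.

## Composite carriers and non-additivity

Within a gene's risk-allele set, each sample's *hit count* is its
total risk-allele dosage; classes are 0, 1, and 2+ — a homozygote for
one variant counts as two hits by default, since phase-free dosage
data cannot distinguish it from a compound heterozygote (a
`carriers_only` mode treats each variant as presence/absence for
sensitivity analysis). The 1-hit and 2-hit odds ratios come from the
class-by-phenotype table with Woolf confidence intervals and Haldane
correction for empty cells. Log-additivity predicts
$OR_{2\text{hit}} = OR_{1\text{hit}}^2$; deviation is tested by a
penalized likelihood-ratio test of the free model (separate 1-hit and
2-hit terms) against the constraint $\beta_{2} = 2\beta_{1}$.

One numerical point deserves emphasis. A naive LRT that penalizes the
free and constrained fits with their *own* Jeffreys penalties is
miscalibrated: the log-determinant difference between designs of
different dimension grows with the sample size, and a parametric
bootstrap shows the null statistic drifting far above
$\chi^2_1$. We therefore use the profile-penalized construction (as
the `logistf` literature does): the constrained fit maximizes the
*full* design's penalized likelihood subject to a linear coefficient
map (`firth_glm(coef_map = )`), so both fits share one penalty. After
this correction the null rejection rate at 0.05 is 0.058 over 120
simulated replicates (KS uniformity p = 0.88).

Between two genes, the same machinery tests a carrier-by-carrier
interaction term against zero: "no deviation" means the joint effect
of carrying mutations in both genes is the sum of the individual
log-odds effects.

## Polygenic scores and their population decomposition

The individual score is $PRS_i = \sum_m \hat\beta_m G_{im}$ on the
log-odds scale; a missing dosage contributes its Hardy–Weinberg
expectation $2f$ (the standard PLINK-style mean imputation — this is
the one place the package imputes). Population expectations are
closed-form: $E[PRS]_j = \sum_m 2\hat\beta_m f_{mj}$, the
between-population difference decomposes exactly into per-variant
contributions $2\hat\beta_m(f_{ma} - f_{mb})$, ranked and flagged at
$|$contribution$| \ge 0.01$, and the genotype-specific extension
$\sum_m [2f(1-f)\beta_{het} + f^2\beta_{hom}]$ reduces algebraically
to the additive form whenever $\beta_{hom} = 2\beta_{het}$.
Standardization scales all scores to a designated reference control
group (mean 0, variance 1), so between-group shifts are reported in
reference standard-deviation units. Gene exclusions (e.g. removing
known large-effect genes from the polygenic background) are a caller
supplied key list, not hard-coded.

## Liability model: from score shifts to prevalence ratios

With additive effects the risk score $\eta$ is approximately normal
across a population, $\mu = \mathrm{logit}(p_0) + \sum 2f\beta$ and
$\sigma^2 = 2\sum f(1-f)\beta^2$ (the HWE variance of the PRS), and
an individual's disease probability is $\mathrm{expit}(\eta)$ (or
$\Phi(\eta)$ under the probit link). Expected prevalence is
$E[p] = \int g(\eta)\,N(\eta;\mu,\sigma^2)\,d\eta$, evaluated by
Gauss–Hermite quadrature — exact for the normal weight — starting at
64 nodes and doubling until successive estimates agree to 1e-10
relative (with a 1e-12 absolute floor for means near zero). The
equivalent p-space density
$f(p) = \phi\{(\mathrm{logit}(p)-\mu)/\sigma\}/\{\sigma p(1-p)\}$ is
exposed for plotting and integrates to the same expectation by change
of variables. The baseline score $\beta_0$ is calibrated by
root-finding (on the log scale, monotone, tolerance 1e-12) so that a
chosen population attains a target baseline prevalence; the prevalence
ratio between two populations is then reported at that calibration and
swept across a baseline-prevalence grid (default 0.001–0.01, the span
of credible Crohn's disease prevalence estimates) to show its mild
dependence on the baseline. In the small-prevalence limit the ratio
approaches $e^{\Delta\mu}$; the implementation always reports the
exact integral, not the limit. The probit comparison maps scores
through equal probability, $\eta_{probit} =
\Phi^{-1}(\mathrm{expit}(\eta_{logit}))$; on $[-1, 1]$ a no-intercept
least-squares fit over a 201-point uniform grid (a declared
convention; the grid density is immaterial at this linearity) gives
slope 0.620 with $r^2 = 0.99998$, so logit and probit analyses are
interchangeable for modest scores.

Attributable prevalence follows Moonesinghe: the prevalence a
population would have without the risk factors is the observed
prevalence divided by the population-average genotype relative risk,
$\prod_m (1 + f_{mj}(GRR_m - 1))^2$ for multiplicative (additive on
log scale) effects. For genotype-specific effects we use the
Hardy–Weinberg average $(1-f)^2 + 2f(1-f)GRR_{het} + f^2 GRR_{hom}
= 1 + 2f(1-f)(GRR_{het}-1) + f^2(GRR_{hom}-1)$. Note the $(1-f)$
factor in the heterozygote term: it is required for the
genotype-specific factor to reduce exactly to the additive factor when
$GRR_{hom} = GRR_{het}^2$, and renderings of this formula that omit it
are internally inconsistent. The attributable fraction of a
between-population prevalence difference is
$((p_2-p_1)-(i_2-i_1))/(p_2-p_1)$, undefined (reported as `NA`) when
the prevalences coincide.

## Quality control and ancestry

Sample-level filters mirror standard exome QC: heterozygous/homozygous
ratio below 1 (contamination), more than 2000 singletons, deletion/
insertion ratio above 1.5, mean genotype quality below 40 — a sample
is excluded if it fails any rule and every exclusion carries its
reasons. Variant filters: call rate below 0.8, or heterozygote allele
balance outside 70:30 (ALT read fraction outside $[0.3, 0.7]$,
boundary passing) in more than 40% of heterozygous samples when at
least 7 heterozygotes were seen — below 7 the balance rule is
inactive. Ancestry assignment from an ADMIXTURE-style Q matrix: a
sample belongs to group k iff its fraction for k is at least 0.4 and
all others are strictly below 0.4, otherwise "admixed"; the
high-ancestry panel rule is a strict > 0.9 on the focal group.
Genotype-level quality masking (GQ < 20) is applied when matrices are
built, upstream of any counting; the ordering of genotype-level
masking versus the sample-level mean-GQ filter is our convention and
is documented rather than asserted.

Relatedness pruning removes samples until no pair exceeds 0.35. For
graphs of up to 25 involved samples we compute an exact minimum vertex
cover by branch and bound (deterministic choice among minima); larger
graphs fall back to a greedy max-degree rule with ties broken by lower
call rate then sample id. We chose the exact solver over pure greedy
because greedy max-degree is not guaranteed minimal even on small
graphs — randomized tests against brute force found counterexamples —
and relatedness graphs after a cutoff are almost always tiny and
sparse, where exactness is free.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, determined
entirely by their arguments and seed (identical calls are
byte-identical).

* `sim_bottleneck_counts`: ancestral frequencies from a $1/x$ spectrum
  truncated to $[10^{-4}, 0.5]$; the founder event is a
  single-generation binomial bottleneck of `founder_chromosomes`
  chromosomes, after which study counts are binomial at the
  post-bottleneck frequency and reference counts binomial at the
  ancestral frequency. This reproduces the two qualitative signatures
  the enrichment stage needs — a heavy upper tail of enriched variants
  *and* a point mass of lost ones — with the study and reference sizes
  defaulting in our tests to 2,178 and 31,902 diploid samples, the
  scale of the motivating AJ panel and its non-Finnish European
  reference. It is deliberately not a 30-generation Wright–Fisher
  trajectory: a single-generation bottleneck of equivalent intensity
  produces the same marginal structure without drift bookkeeping, and
  a multi-generation option would be an extension, not a correction.
  There is no linkage disequilibrium, no site-specific coverage
  variation, and annotation class is independent of frequency — so
  passing tests validate the statistical machinery, not claims about
  real AJ data.
* `sim_case_control`: genotypes at HWE from a frequency column,
  phenotype Bernoulli from the logistic model (additive dosage or
  het/hom genotype-specific coding), optional normal covariate with a
  confounding loading. Phenotype is generated prospectively; the
  log-odds-ratio targets of recovery tests are invariant to
  outcome-dependent sampling, so this also calibrates retrospective
  designs.
* `sim_multistudy_summaries`: per-study $\hat\beta_k \sim N(\beta +
  \delta_k, se_k^2)$ with heterogeneity $\delta_k \sim N(0,
  \tau^2)$.

## Test scale and numerical conventions

The test suite runs every stochastic check at fixed seeds and sizes
chosen to hold Monte-Carlo error well below the asserted tolerances:
Fisher p-values are compared with exhaustive enumeration over all
46,376 tables with total at most 30 (tolerance 1e-12); Firth recovery
uses 200 replicates of n = 8,000; the additivity test is calibrated
over 120 replicates of n = 10,000 and powered over 100 replicates of
n = 20,000 at the published 1-hit/2-hit odds ratios 2.17/9.93; PRS
shift recovery uses 50 replicates of a 40-variant panel engineered so
the true between-population difference is 0.97 reference standard
deviations; liability integrals are cross-checked against $10^7$-draw
Monte-Carlo across a $(\mu, \sigma^2)$ grid. Strictness conventions
follow the definitions throughout: frequency window upper bound
exclusive, pathogenic-overlap p cutoff strict, high-ancestry fraction
strict, allele-balance boundary passing, contribution highlight
threshold inclusive.

## Limitations

Enrichment classification treats sites as independent (no LD); the
reference-maximum rule is conservative by construction; the p-value
reported for the meta-analysis is an approximation tied to the
fixed-effect z rather than an exact BF tail probability; hit-class
coding without phase cannot separate compound heterozygotes from
homozygotes; and all prevalence modelling inherits the liability
model's assumption that the risk score is normal across the
population, which degrades for scores dominated by a few large-effect
alleles — exactly the situation the genotype-specific extensions and
the attributable-prevalence factors are provided to handle separately.
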