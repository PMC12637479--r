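---
title: "Multi-ancestry TWAS with sum-of-single-effects eQTL fine-mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-ancestry TWAS with sum-of-single-effects eQTL fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matwas)
```

# What the package computes

`matwas` implements a transcriptome-wide association study (TWAS) pipeline
for several ancestry groups analyzed jointly: multi-population Bayesian
cis-eQTL fine-mapping produces population-specific expression prediction
weights; those weights are combined with harmonized GWAS summary statistics
and a panel LD reference into per-population association z-scores; the
population-stratified results are meta-analyzed by sample-size weighting and
fine-mapped at the gene level within LD blocks; cross-population concordance
analytics summarize how shared the inferred regulation is. A synthetic-data
module generates three-population genotype, expression, covariate and GWAS
summary data with the statistical structure the analysis assumes, so every
stage is tested end to end without restricted cohort data.

# The fine-mapping model

For population $k = 1..K$, residualized expression $y_k$ and standardized
cis genotypes $X_k$ follow

$$y_k = X_k \sum_{l=1}^{L} b_{l,k} + e_k, \qquad e_k \sim N(0,
\sigma^2_k I),$$

where each of the $L$ single effects picks one causal variant
$\gamma_l \sim \mathrm{Uniform}(1..p)$ *shared across populations*, and the
$K$-vector of that variant's population effects is drawn from
$N(0, C_l)$ with an unstructured $K \times K$ prior covariance. $C_l$ is
re-estimated each iteration by EM, so the cross-population effect
correlation is learned per effect rather than assumed. Inference is
coordinate-ascent variational: given the residual left by the other
effects, each effect is a single-effect regression whose posterior —
inclusion probabilities $\alpha_{l\cdot}$, per-variant posterior mean
effects, and a per-variant $K \times K$ posterior covariance — is available
in closed form. Residual variances are re-estimated per population each
sweep. The evidence lower bound (ELBO) is non-decreasing by construction
and convergence is declared when it changes by less than `tol` (default
`1e-4`, capped at 500 iterations).

Because the data summaries entering one effect's update do not change while
that effect is updated, the EM on $C_l$ is iterated to convergence *inside*
the sweep (up to 50 inner steps); every inner step is an exact ascent, and
unused effects collapse to the variance floor (`1e-6`) within a sweep or
two instead of dragging the ELBO through hundreds of outer iterations.

**Effect-level evidence filter.** The unstructured prior has $K(K+1)/2$
free parameters per effect and will occasionally fit noise: without a
guard, roughly 8–10% of truly null genes acquired a spurious singleton
credible set in our simulations. An effect therefore contributes credible
sets and PIP mass only when its single-effect evidence exceeds the
floored-prior evidence by more than `lbf_min` nats (default $K(K+1)/2$,
the free-parameter count — an AIC-flavoured complexity charge). The weakest
real signals we simulate (cis-$h^2 = 0.05$ at a few hundred samples per
population) sit above 10 nats, null-gene excursions below ~2, so the
default separates cleanly; with it the null false-positive rate is about
2%. The in-loop null check itself uses threshold 0, so the ELBO stays
monotone.

**Credible sets and purity.** Per retained effect, variants are ranked by
inclusion probability and the smallest prefix reaching 90% cumulative
probability forms the credible set. A set's purity is the minimum over
member pairs of the sample-size-weighted average across populations of the
absolute genotype correlation; sets below 0.5 are dropped, singletons have
purity 1. We interpret the inclusion threshold as a 90% *coverage* level
(the sum-of-single-effects convention), not a hard per-variant PIP cutoff;
both the coverage and the purity floor are arguments.

**Weights.** Dense weights are the alpha-weighted posterior means over all
cis variants; sparse weights zero everything outside retained credible
sets. Genotypes are standardized within population before fitting, so
weights are per standardized allele on the standardized-expression scale —
allele-frequency differences between populations live in the weights'
scale, which is also what makes sample-size-weighted meta-analysis of the
resulting z-scores coherent.

**Cis heritability** is a single-GRM REML fit on the eigenbasis of
$XX'/p$, profiled over $h^2$, with the boundary-mixture likelihood-ratio
p-value $0.5\,P(\chi^2_1 > \Lambda)$ (reported as 0.5 at $\Lambda = 0$).

# From weights to associations

`twas_zscore()` computes $Z = W'z / \sqrt{W'\Sigma W}$ with the LD matrix
floored to positive semi-definite and a $10^{-6}$ diagonal ridge; genes
with degenerate weighted variance, no overlapping variants, or all-zero
sparse weights are reported with an explicit skip reason rather than a
statistic. Two-sided normal p-values get Benjamini–Hochberg q-values within
a run; calibration is summarized by
$\lambda_{GC} = \mathrm{median}(z^2)/0.454936$. Genes overlapping the MHC
(chr6, 24–34 Mb) are excluded before testing.

Harmonization matches GWAS variants to the panel by position, keeps exact
matches, negates z for swapped ref/alt, resolves strand complements, and
drops palindromic (A/T, C/G) SNPs, indels, duplicated positions and
irreconcilable alleles with a per-outcome report. Missing z-scores are
imputed from panel LD by the conditional-normal rule
$\hat z_u = \Sigma_{uT}(\Sigma_{TT} + 0.1 I)^{-1} z_T$ with predicted
quality $r^2_u$. Two pipeline-level choices depart from the plainest
rendering of that rule, both for calibration reasons we verified with a
replicated null study (thousands of gene-tests):

* imputed z-scores are standardized by their predicted standard deviation
  (`standardize = TRUE`), since the raw conditional mean has variance
  $r^2 < 1$ while every LD-based test downstream assumes unit variance —
  without this the null TWAS variance sat near 0.96 and
  $\lambda_{GC}$ near 0.93;
* the pipeline wrapper `locus_twas()` drops imputed variants with predicted
  $r^2 < 0.8$ (mirroring the usual genotype-imputation quality convention),
  because poorly proxied variants are shrunk toward zero yet keep full
  variance in the denominator. `impute_zscores()` itself applies no filter
  unless asked.

Meta-analysis uses $z_{meta} = \sum_i \sqrt{n_i} z_i / \sqrt{\sum_i n_i}$
over available populations with case-control effective sizes
$n_i = 4/(1/n_{cases} + 1/n_{controls})$ by default (a `total` switch
exists); inverse-variance weighting is not an option because summary-based
TWAS provides no effect-size standard errors.

# Gene-level fine-mapping

Within an LD block, TWAS z-scores follow
$z \sim N(0, V + \sigma^2_{prior} V_{\cdot c} V_{c \cdot})$ under a causal
configuration $c$, where $V$ is the correlation of genetically predicted
expression induced by weights and LD. Configurations up to `max_causal`
genes (default 3) plus the empty model are enumerated; priors are
independent-Bernoulli with `prior_causal` defaulting to $1/\max(m, 2)$ —
the conventional $1/m$ leaves no prior mass on the no-causal-gene model in
a single-gene block, which breaks the null comparison, so single-gene
blocks get 1/2. `prior_variance` defaults to 40 (an $n\sigma^2$-scale
quantity giving strong signals Bayes factors that dominate the prior).
Multi-population evidence multiplies configuration Bayes factors across
ancestries (independent given the configuration); populations missing a
gene contribute the Bayes factor of the configuration restricted to their
available genes, so absence is uninformative rather than penalizing. A
significant gene is called high-confidence when its population-specific or
combined PIP exceeds 0.8.

# What the generator emulates — and what it does not

`default_population_specs()` encodes the study conditions: panel sizes 235
(NHW), 224 (AA), 292 (HISP); GWAS case/control counts 21,982/44,944,
2,784/5,222 and 3,005/5,894, reproducing the order-of-magnitude power
imbalance between the European-ancestry GWAS and the other two.

Genotypes come from a Gaussian-copula latent model: two AR(1) haplotype
sheets per LD block (latent correlation $e^{-\mathrm{ld\_decay}\cdot
\mathrm{step}}$), thresholded at the variant's allele frequency.
Frequencies are drawn per block and jittered per variant (SD 0.02, clamped
to `maf_range`): with fully independent frequencies, mismatched margins cap
the attainable dosage correlation and the high-LD clusters that make
multi-variant credible sets the norm in imputed panels can never form. The
default decay rates (0.001 NHW, 0.0025 AA, 0.0015 HISP — shortest-range LD
in the African-ancestry panel) were calibrated once so that two-population
fits produce median credible-set sizes in the published mid-single-digit
range; they were not revisited afterwards.

Expression adds genotype effects (per-gene cross-population effect rows
drawn at a chosen correlation, default 0.8 — predominantly shared
regulation), measured covariates, optional hidden factors, and Gaussian
noise scaled so the genetic fraction of non-covariate variance equals the
target cis-$h^2$. A Poisson count rendering with per-sample depth factors
exists solely to exercise TMM and the count filters. GWAS z-scores are
drawn *at summary level* from
$N(\sqrt{N_{eff}}\,\Sigma\lambda,\ \Sigma)$ with $\Sigma$ the full
empirical panel correlation, sampled exactly in $O(nm)$ by projecting
sample-space white noise through the standardized genotypes; the
gene-mediated non-centrality $\lambda$ aggregates per-variant standardized
expression effects times gene-to-trait effects. By default 19% of variants
are withheld (the typed-coverage gap summary imputation fills) and 20% are
reported with swapped alleles, so harmonization is always exercised.

Not emulated: realistic demography or coalescent haplotypes, admixture
tracts, ancestry-unique variants (the model fits shared variants only),
the X chromosome, case-control sampling at the individual level, or
cell-type deconvolution (cell proportions enter only as supplied
covariates). Passing tests therefore demonstrate the statistical machinery
is correct under the stated generative assumptions — not that the pipeline
is robust to everything real cohorts do.

# Quality control

Variant QC applies sample-missingness first (>10% removed), then variant
missingness (>10%), minor allele count (<10, computed on non-missing
genotypes) and the exact Hardy–Weinberg test ($p < 10^{-8}$, two-sided
enumeration without mid-p). Relatedness uses the KING-robust between-family
estimator $\hat\phi = (N_{Aa,Aa} - 2N_{opp}) / (N_{Aa(i)} + N_{Aa(j)})$ on
pairwise-complete genotypes; clusters at $\hat\phi \ge 0.0625$ are pruned
greedily with retention priority: cognitively normal samples of advanced
age (default gate 80 years, descending age), then cases, then controls
carrying e3/e4 or e4/e4, then the rest, ties by sample id. The age gate is
ours: with a pure age ordering every control would outrank every case,
contradicting the intended case-over-ordinary-control priority. Gene
filters drop genes unexpressed (TPM at or below a level) in more than 20%
of samples or supported by fewer than 20% of samples at counts ≥ 6 — we
read the count rule as a support requirement; the thresholds are arguments.
TMM normalization delegates to edgeR's standard implementation (30%/5%
trims, factors rescaled to geometric mean 1). Hidden factors are principal
components of the per-gene standardized matrix whose eigenvalues of
$X'X/n$ exceed the Marchenko–Pastur bulk edge
$\sigma^2(1+\sqrt{\gamma})^2$, $\gamma = G/n$, $\sigma^2 = 1$.

# Validation studies and the problem sizes used

The packaged studies (also driven by `scripts/acceptance.R`) run at desk
scale, chosen to keep the full suite within tens of minutes on one core:

* `cs_recovery_study()`: 100 single-causal genes (cis-$h^2$ 0.4, n = 400
  per population, 60 variants, L = 10) and 100 null genes — first-set
  coverage of the causal variant and the null no-set rate.
* `precision_comparison_study()`: 200 genes, per-gene $h^2 \sim U(0.05,
  0.15)$ (the weak-to-moderate regime where sample size changes what is
  resolvable), 1–2 causal variants, L = 5; three-population versus averaged
  pairwise fits.
* `null_calibration_study()`: 120 fitted genes × 20 independent null-GWAS
  replicates × 3 populations ≈ 7,200 gene-tests through harmonization,
  imputation and the TWAS test; reusing fits across GWAS replicates buys
  the test count that a median-based $\lambda_{GC}$ needs without refitting
  cost.
* `imputation_recovery_study()`: 600 tight-LD variants, 20% withheld;
  recovery correlation among variants with a typed proxy at $|r| > 0.95$.
* `gene_finemap_recovery_study()`: 100 five-gene blocks, each gene's causal
  variant in its own LD sub-block (so the causal-gene question is
  identifiable), one gene carrying the trait effect (γ = 0.1, a TWAS z of
  roughly 6–8 in the largest GWAS); top combined PIP identifies the causal
  gene.

# Known limitations

The enumeration-based gene fine-mapper is exponential in `max_causal` and
guards itself above ~10^5 configurations. The fine-mapper requires the same
variant set in every population, so ancestry-unique regulation is invisible
by design. Purity and LD computations assume in-sample genotypes for all
populations. The REML heritability fit assumes a single variance component;
the LRT p-value is conservative near the boundary by construction.
Credible-set behaviour under model misspecification (e.g. many tiny
effects) inherits the usual sum-of-single-effects caveats: sets are
calibrated for the sparse model they assume.
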