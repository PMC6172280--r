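---
title: "Summary-based multi-tissue TWAS with Bayesian gene prioritization"
author: "sumtwas package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-based multi-tissue TWAS with Bayesian gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumtwas)
```

## The problem

Genome-wide association studies (GWAS) of complex traits such as cancer risk
report thousands of associated SNPs, most of them non-coding and presumed to
act by modulating gene expression. A transcriptome-wide association study
(TWAS) turns this intuition into a test: using a reference cohort in which
both genotypes and expression were measured, one learns per-gene SNP weight
models for the cis-genetic component of expression, and then asks whether
that *predicted* expression associates with the trait. Crucially, the trait
side needs only GWAS summary statistics (per-SNP Wald Z-scores) and a
reference linkage-disequilibrium (LD) panel -- no individual-level trait
data.

`sumtwas` implements this pipeline end to end: summary-statistic QC and
allele harmonization, LD estimation from PLINK filesets, REML estimation of
cis-SNP heritability, penalized weight training with cross-validated model
selection, the summary-based association statistic with an adaptive
permutation test, SNP-level statistics conditional on predicted expression,
and Bayesian prioritization of causal genes at associated regions. A
synthetic-data module generates inputs with the statistical structure the
method assumes, so that every stage -- including the credible-set coverage
guarantee -- is verifiable on a desktop.

## The model

### Expression weights and cis-heritability

For a gene with expression $y$ in $n$ reference samples and $p$ cis SNPs
$X$ (we use a window of TSS $\pm$ 1 Mb), the training model is

$$ y = C\beta + X w + \epsilon, $$

with covariates $C$ (sex, age, genotype PCs, platform, expression factors)
and SNP weights $w$. Before training we residualize $y$ on $C$ and
standardize genotype columns. The cis-SNP heritability comes from the
variance-component model

$$ \mathrm{var}(y') = A\sigma_g^2 + I\sigma_e^2,
   \qquad h^2_g = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2}, $$

with kinship $A = ZZ'/p$ from standardized cis genotypes. We estimate the
components by restricted maximum likelihood, profiled down to one dimension
in $h^2_g$: a spectral decomposition of $A$ makes the likelihood a cheap
function of $h^2_g$, which we maximize by a 51-point grid followed by
golden-section refinement (tolerance $10^{-8}$). This is deliberately
simple -- the 1-D profile cannot diverge, is exactly testable, and at the
sample sizes of expression panels (a few hundred) costs milliseconds per
gene. Significance against $\sigma_g^2 = 0$ uses the likelihood-ratio
statistic referred to the boundary-corrected 50:50 mixture of a point mass
at zero and $\chi^2_1$; genes with $P \ge 0.05$ are pruned before training,
since expression without detectable cis-genetic control cannot be predicted
from cis SNPs.

Weights are trained by a menu of estimators -- ridge-BLUP (penalty
$\lambda = p(1-h^2_g)/h^2_g$, the mixed-model equivalence), LASSO, Elastic
Net with mixing 0.5 and penalty path chosen by inner fivefold
cross-validation, and `top1`, the single best marginal eQTL SNP. Each
candidate is scored by fivefold out-of-sample $R^2$; the winner is the
model with the largest $R^2$ among those whose cross-validated predictions
correlate with observed expression at one-sided $P < 0.05$, refit on all
samples. Because prediction accuracy is bounded by heritability, we report
the normalized accuracy $\min(R^2/h^2_g, 1)$.

A caveat worth stating: the pooled correlation test over concatenated CV
predictions is mildly anticonservative, because folds share training data.
Taking the best of four correlated such tests, a pure-noise gene is still
trained in roughly 13% of cases (at $n = 80$, $p = 10$) rather than the
nominal 5%. We measured a per-fold Stouffer alternative and found it worse
(fold statistics are positively, not negatively, correlated). In the full
pipeline this matters little, as non-heritable genes are removed by the
REML filter before training; the test suite asserts the bound the procedure
actually satisfies.

### The association statistic

With GWAS Z-scores $z_{\mathrm{GWAS}}$ and reference LD $V$ on the model's
SNPs (after allele harmonization), the association between predicted
expression and the trait is

$$ z_{\mathrm{TWAS}} =
   \frac{w' z_{\mathrm{GWAS}}}{\sqrt{w' V w}}, $$

a standard normal under the null, tested two-tailed. The statistic is
invariant to rescaling of $w$, so weights trained on any consistent scale
are usable. Transcriptome-wide significance uses Bonferroni correction over
the number of gene models tested.

Because TWAS conditions on whatever GWAS signal is present at the locus, a
chance alignment between eQTL weights and a strong GWAS peak can produce an
association without any expression mediation. The permutation test guards
against this: the weights are shuffled across the model's SNP slots (the
literal reading of permuting the eQTL weights; the alternative of shuffling
across all cis SNPs changes the null's reference set and is not used) while
$z_{\mathrm{GWAS}}$ stays fixed, and the empirical exceedance probability
of $|z_{\mathrm{TWAS}}|$ is reported as
$(1 + k)/(1 + n_{\mathrm{perm}})$. Sampling stops adaptively after 10
exceedances (cap 10,000 draws); these constants trade precision near the
significance threshold for speed elsewhere. The early-stopped estimator is
upward-biased by construction (it is a screening p-value); uniformity of
the underlying permutation p-value under exchangeable nulls, and agreement
of the sampler with exhaustive enumeration over all $p!$ weight orders at
small loci, are both part of the test suite.

### Conditional SNP statistics

To quantify how much GWAS signal predicted expression explains, let $V$ be
SNP LD, $V_{GE}$ the correlation of predicted expression across the gene
models at the locus, and $C = VWD^{-1}$ the SNP-expression correlations
(with $W$ the weight matrix and $D$ the per-gene scaling). Then

$$ z_i = \frac{[\,z_{\mathrm{GWAS}} - C V_{GE}^{-1} z_{\mathrm{TWAS}}\,]_i}
   {\sqrt{\mathrm{diag}[\,V - C V_{GE}^{-1} C'\,]_{ii}}}. $$

Two degeneracies need decisions the equations leave open. First, gene
models collinear in predicted expression make $V_{GE}$ singular; we prune
pairs with $|r| > 0.95$, keeping the model with the larger
$|z_{\mathrm{TWAS}}|$, and report what was pruned. Second, a SNP whose
variance is fully absorbed (residual diagonal below $10^{-6}$) has an
undefined ratio; it is reported as "fully explained" with conditional Z of
0 and a flag, rather than as a division-by-near-zero artifact.

### Bayes factors and credible gene sets

Regions often hold several associated gene models because predicted
expression is correlated locally. Under a single-causal-gene model with a
normal prior $\alpha \sim N(0, \sigma_\alpha^2)$ on the causal gene's
effect, the marginal of its Z-score is $N(0, 1 + n\sigma_\alpha^2)$, giving

$$ \log \mathrm{BF}_i = -\tfrac{1}{2}\log(1 + n\sigma_\alpha^2) +
   \frac{z_i^2}{2}\cdot\frac{n\sigma_\alpha^2}{1 + n\sigma_\alpha^2}, $$

computed in log space (stable at $|z| \sim 40$). Posteriors are the
softmax of the log Bayes factors over the region's models, and the
$\rho$-credible set adds genes by descending posterior until the mass
reaches $\rho$. The normalization runs over genes only -- no "no causal
gene" configuration -- which is the printed form of the model; a region
with no true causal gene therefore still yields a credible set, which is
why sets are computed only at transcriptome-wide significant regions.

The prior scale is the one genuinely free knob. We default to
$n\sigma_\alpha^2 = 30$ -- a prior expected $\chi^2$ of about 31 at a
causal gene, the order of magnitude of strong risk loci -- and expose an
empirical-Bayes alternative, `empiricalBayesSigmaA2()`, which sets
$n\sigma_\alpha^2 = \max(0, \overline{z^2} - 1)$ over significant models.
Posteriors move smoothly with this scalar; the calibration experiment below
shows coverage is maintained at the default.

Gene models from several panels enter the Bayes-factor sum separately (each
has its own Z-score), but summaries collapse a gene appearing through
multiple panels to one unique gene.

## The synthetic-data generator

The generator emulates exactly the structure the method assumes, with
defaults fixed at the study conditions: an LD reference of 489 samples, an
expression panel of 500, a GWAS of 142,392, 100 cis SNPs per 1 Mb locus,
AR(1) latent correlation 0.7, MAF uniform on (0.05, 0.5), cis-heritability
0.4 from 3 causal eQTL SNPs, 5 gene models per region, and
$n\sigma_\alpha^2 = 30$.

Genotypes are two thresholded AR(1) Gaussian pseudo-haplotypes per
individual. Thresholding attenuates correlation: a latent adjacent
correlation of 0.9 realizes a dosage correlation around 0.7 at matched
MAFs (and lower when MAFs differ). We accept this attenuation and validate
the realized LD empirically rather than compensating the latent parameter;
what matters downstream is that $V$ is estimated from the same kind of
genotypes the GWAS Z-scores are generated under. Expression is built so the
in-sample variance ratio $\mathrm{var}(Xw)/\mathrm{var}(y)$ equals the
target heritability exactly, and the true weights are returned for
recovery tests. GWAS Z-scores come either from simulated individuals
(marginal Wald statistics) or directly from the asymptotic distribution
$z \sim \mathrm{MVN}(\sqrt{n}\,\alpha\, V\tilde w,\, V)$; the two modes are
checked against each other distributionally.

What the generator does *not* emulate: realistic human LD maps (haplotype
blocks, recombination hotspots), population structure, trans-eQTLs,
multiple causal genes per region, and binary case-control ascertainment
(Z-scores are treated as asymptotically normal regardless of trait scale).
Passing tests therefore demonstrate correctness of the statistical
machinery under the model's own assumptions, not robustness to the ways
real data violate them.

## Calibration of credible sets

The coverage experiment re-creates the validation design behind the
credible sets: for each of 1,000 regions, reference LD is simulated, 5
sparse weight models are drawn over it, their predicted-expression
correlation $D^{-1}W'VWD^{-1}$ is formed, one causal gene is picked
uniformly, Z-scores are drawn from the Bayes-factor model's own
multivariate normal, and the greedy 0.90-credible set is computed with the
matched prior. Coverage of the causal gene should then be at least 0.90 up
to binomial noise -- in our runs it is about 0.99 with a mean set size
near 2.2, conservative because the greedy set overshoots $\rho$ and the
per-gene Bayes factors ignore the (known, positive) correlations between
Z-scores. This experiment is `calibrationExperiment()` and is what
`scripts/acceptance.R` reruns.

## Numerical choices and problem sizes

* LD matrices are shrunk as $V \leftarrow (1-\lambda)V + \lambda I$ with
  $\lambda = 0.1$ by default. The TWAS denominator and the conditional
  analysis invert (sub-blocks of) $V$; reference panels of a few hundred
  samples make raw $\hat V$ rank-deficient at 1 Mb loci, and the ridge
  guarantees positive-definiteness at the cost of a small, recorded
  distortion. $\lambda$ is surfaced on every `LDMatrix`.
* Degenerate TWAS denominators ($w'Vw \le 10^{-8}$) are errors naming the
  gene, not NaNs.
* The rank-based inverse-normal transform uses quantiles of
  $r/(n+1)$, keeping transformed values bounded; ties get average ranks.
* Ties in credible-set ordering break lexicographically by gene label, so
  sets are reproducible.
* Strand-ambiguous SNPs (A/T, C/G) are removed in QC, which is what makes
  complement-based strand matching during harmonization safe.
* Test-suite problem sizes are chosen for a laptop-class run: the
  calibration uses the full 1,000 regions; REML recovery uses 200 genes at
  $n = 500$, $p = 50$; the end-to-end recovery experiment uses 100
  replicates of a 3-gene, 40-SNP region with a panel of 500 and a causal
  GWAS $\chi^2$ of about 40.

## Interfaces

The package exposes plain functions over S4 containers; a typical analysis
is `loadSumstats()` then `qcSumstats()` then `harmonizeAlleles()`,
`loadGenotypes()` and `computeLD()`, `estimateCisH2()`/`trainWeights()` per
gene, `twasScan()`, `conditionalZscores()` at loci of interest, and
`partitionRegions()`, `flagNovelRegions()`, `fineMapRegions()`,
`summarizeCredibleSets()` for prioritization. `runRegionPipeline()` chains
all stages on synthetic data and can emit every intermediate file (sumstats
TSV, PLINK fileset, weight TSVs, result tables), so the file-based
interfaces are exercised by code. These functions, together with
`scripts/acceptance.R`, are the package's command surface; no shell
subcommand wrapper is provided because the intended users work in R.

## Known limitations

* Single causal gene per region is an assumption, not an option; regions
  with several truly causal genes will concentrate posterior on one.
* The REML substitute handles one variance component; GCTA-style multi-
  component or AI-REML fits are out of scope.
* BSLMM-type Bayesian sparse models are not in the training menu.
* The permutation test permutes weights within the model's SNP slots;
  models with a single usable SNP cannot be permuted.
* No liftover, INFO filtering, or meta-analysis: summary statistics are
  assumed to be on one build and already meta-analyzed.
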