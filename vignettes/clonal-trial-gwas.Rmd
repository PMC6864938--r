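---
title: "Association analysis of clonal field trials: models and methods"
author: "clonegwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association analysis of clonal field trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonegwas)
```

## The setting

`clonegwas` implements the association-analysis workflow of a clonally
replicated forest-tree trial: a few hundred unrelated clones, each
replicated as one ramet per block in a randomized block design, genotyped
at hundreds of thousands of biallelic SNPs from short-read sequencing and
phenotyped for quantitative traits (growth, ecophysiology, wood
chemistry). The package is modelled on a 461-clone *Populus trichocarpa*
panel genotyped by exome capture at 813,280 post-filter SNPs across 19
chromosomes; the printed per-chromosome and trait summaries of that panel
ship with the package (`ref_chromosome_summary()`, `ref_trait_summary()`)
as reference points.

The pipeline stages, and the model behind each, are described below,
together with the choices that were genuinely open and how the package
resolves them.

## Variant quality control

Post-calling filters retain SNPs with minor allele frequency of at least
5%, missingness of at most 5% of clones, and no strong departure from
Hardy–Weinberg equilibrium. MAF and HWE are computed on non-missing calls;
missingness is relative to the full panel.

The HWE test is the exact conditional test: given the observed allele
counts, the heterozygote count is compared against its exact distribution
under random mating, and the p-value sums all configurations at most as
probable as the observed one. The implementation walks the admissible
heterozygote counts with a log-scale recurrence, so it is stable at any
sample size; the suite checks it against full enumeration for every
table with up to 50 individuals.

Two details are configurable because the original analysis leaves them
open: the HWE cutoff (default `1e-6`, common GWAS practice) and whether
the filters act jointly or sequentially. `filter_variants()` evaluates the
three criteria jointly on the input table — the surviving set is then
identical for any ordering, which the suite verifies — and attributes each
removal to its first failing rule in the fixed order MAF, missingness,
HWE for reporting.

## Clone means, BLUP and heritability

Ramet-level traits are optionally log-transformed and outlier-masked
(default: beyond 4 SD of the trait mean; the original analysis states only
that outliers were excluded, so the rule is a package choice and a
parameter). Clone means are then adjusted with the mixed model

$$y_{cb} = \mu + \beta_b + u_c + e_{cb}, \qquad
  u_c \sim N(0, \sigma^2_c),\; e_{cb} \sim N(0, \sigma^2_e),$$

with block fixed and clone random, fit by REML through `lme4`. The
adjusted mean of a clone is the estimated population mean (averaged over
blocks) plus the clone's BLUP; in the balanced case the BLUP shrinks the
raw clone deviation by $\sigma^2_c / (\sigma^2_c + \sigma^2_e/r)$ with $r$
ramets per clone, a closed form the tests assert exactly. Shrinkage is
why effect sizes estimated from BLUP-adjusted means are attenuated by the
same factor relative to effects simulated on the genetic scale — the
parameter-recovery suite therefore checks unbiasedness on raw clone means
and ranking behaviour on BLUP means, which is what the pipeline uses.

Individual broad-sense heritability follows the clonal-trial
variance-component form

$$H^2_i = \frac{\sigma^2_g + \sigma^2_c + \sigma_{ee'}}
  {\sigma^2_g + \sigma^2_c + \sigma^2_{g\times b} + \sigma^2_e},$$

where $\sigma^2_g$ is the genetic-cluster variance, $\sigma^2_c$ the
clone-within-cluster variance, $\sigma^2_{g\times b}$ the cluster-by-block
interaction and $\sigma_{ee'}$ the residual covariance of a clone across
blocks. Cluster labels come from an external grouping of the panel that
this pipeline does not construct, so `broad_sense_heritability()` takes
the components as inputs (from a mixed-model fit, or from simulation
truth) rather than re-deriving the grouping.

## Kinship and population structure

Kinship is the allele-frequency-standardized genomic relationship matrix

$$K_{jk} = \frac{1}{m} \sum_i
  \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)},$$

with $p_i$ estimated from the sample and missing genotypes skipped
pairwise (each pair keeps its own marker count). Pairwise-complete
estimation can leave the matrix very slightly indefinite; `compute_grm()`
can clamp negative eigenvalues to zero (`ensure_psd = TRUE`, used by the
pipeline) before REML.

Structure covariates are principal coordinates: the kinship-implied
squared distances $d^2_{jk} = K_{jj} + K_{kk} - 2K_{jk}$ are
double-centered and eigendecomposed (`stats::cmdscale`). Axes are
sign-fixed (largest-magnitude loading positive) so results are
deterministic. How many axes enter the association model is decided per
trait by BIC over regressions of the clone means on the leading
$0,\dots,d_{\max}$ axes (default $d_{\max} = 5$); the original analysis
states the criterion but not the dimension it selected, which is why the
selection is data-driven here.

## The mixed-model scan

The single-SNP model is the standard M + K + Q mixed linear model: marker
and structure axes fixed, a polygenic effect with covariance
$\sigma^2_g K$ random, residuals $\sigma^2_e I$. The null model (no
marker) is fit by REML through the eigendecomposition of $K$: rotating by
the eigenvectors diagonalizes the covariance, the fixed effects and
$\sigma^2_g$ are profiled out analytically, and the restricted likelihood
is maximized over $\log(\sigma^2_e/\sigma^2_g) \in [-10, 10]$ by a
bracketed 1-D search (tolerance 1e-8). The suite checks the optimum
against a 100-point grid of the profile.

Each SNP is then tested by generalized least squares with the variance
components fixed from the null fit — the population-parameters-
previously-determined approximation that is standard when the marker
count is large. In the whitened regression the residual scale is
re-estimated per SNP and the Wald statistic for the marker coefficient is
referred to a t distribution with the residual degrees of freedom. This
choice makes the scan *exactly* the ordinary simple-regression t-test
whenever $K \propto I$, an equivalence the suite asserts to 1e-8 and a
useful calibration anchor; under null simulations the p-values are
uniform and the genomic-control factor sits within [0.95, 1.05]. Missing
genotypes are mean-imputed per SNP for testing only, never for the GRM;
monomorphic SNPs report effect 0 and p = 1 and are flagged untestable.
Genome-wide significance uses the Bonferroni threshold $\alpha/m$; with
$\alpha = 0.05$ and $m = 813{,}280$ this is the panel's printed
6.1479e-8.

One known bias is documented rather than removed: when the tested markers
themselves built the GRM, the scan is slightly conservative (genomic
control below 1 in dense panels), the familiar proximal-contamination
effect. Leave-one-chromosome-out kinship would remove it and is out of
scope here.

## The sliding-window Poisson test

Clusters of jointly associated SNPs are detected with overlapping windows
of 10 kb advanced by 1 kb (both configurable). Window starts run
$1, 1001, 2001, \dots$ while they do not exceed the chromosome length;
intervals are half-open and never span chromosomes. For a window holding
$n$ SNPs of which $k$ pass the per-SNP input threshold (default
$p < 10^{-5}$, the normative value; a $10^{-4}$ variant appears in some
reports and is reachable via `input_p`), the expected count under the
genome-wide significant fraction `rate` is $\lambda = \text{rate} \times
n$, and the classical Poisson point mass

$$P = \frac{\lambda^k e^{-\lambda}}{k!}$$

is reported. A point probability is not a tail probability, so the
*test* p-value is the upper tail $P(X \ge k \mid \lambda)$ — the only
reading under which the window p-values are probabilities of outcomes at
least as extreme. The suite verifies the point masses in closed form and
the upper tail against the exact binomial in its limit regime (rate at
most 0.01, window count at least 50, $k(k-1)/2n \le 0.05$; outside that
regime the Poisson limit itself degrades, as theory predicts). Windows
with no SNPs are never tested and are excluded from the Bonferroni
denominator $\alpha / n_{\text{tested}}$; family-wise error under
scattered-null simulation stays below the nominal level. Flagged windows
are intersected positionally with GFF3 gene models (half-open window
intervals; an abutting gene is not an overlap).

## Linkage-disequilibrium decay

LD is composite $r^2$: the squared Pearson correlation of unphased
genotype dosages over pairwise-complete clones, computed for each SNP
against the next 119 SNPs of its chromosome (120-SNP windows, as in the
reference analysis). The decay of $r^2$ with physical distance $d$ is fit
by least squares to the Hill–Weir drift-recombination expectation

$$E[r^2] = \frac{10 + C}{(2 + C)(11 + C)}
  \left(1 + \frac{(3 + C)(12 + 12C + C^2)}{n(2 + C)(11 + C)}\right),
  \qquad C = \beta d,$$

with $n$ the number of genotyped clones. The original analysis names only
"nonlinear regression"; this expectation is the form used by the method
it builds on, and the single parameter makes the fit a 1-D problem solved
by a bracketed search on $\log \beta$ — no starting values, and
non-convergence is reported, never silently defaulted. Raw pairs are fit
(binning at 100 bp is for plotting only); whether the original fit used
binned means is unstated, and raw pairs avoid an arbitrary weighting. The
decay distance is the unique root of the monotone fitted curve at
$r^2 = 0.2$, located by bisection on [1, 10^7] bp to 1 bp. The
per-chromosome summary table reproduces the published convention in which
the mean row averages per-chromosome values (the mean bp/SNP spacing is
not total size over total SNPs).

## The synthetic test bed

Because the real exome data are not redistributable at desk scale, every
stage is exercised against a generator with known truth
(`sim_config()`, `simulate_genotypes()`, `simulate_phenotypes()`).

**Genotypes.** Each chromosome carries a small pool of founder haplotypes
whose alleles are drawn from ancestral frequencies (uniform on
[0.05, 0.95]). Subpopulation pools derive from one shared ancestral pool
by per-SNP reassortment at the Balding–Nichols-style divergence rate, so
block LD stays aligned across subpopulations while allele frequencies
diverge — the community-default structure model, since the original study
states no generative model. A sampled haplotype copies one founder within
each LD block, switches founders between adjacent blocks with the
configured probability, and mutates individual alleles back to a fresh
frequency draw. r^2 therefore decays geometrically with the number of
block boundaries crossed. Two limits anchor the tests: with two founders,
no mutation and one block, every polymorphic pair has $r^2 = 1$; with
1-SNP blocks and switch probability 1/2, adjacent loci are exactly
independent. The defaults (3 founders, 25 kb blocks, switch rate 0.12,
mutation 0.03) were chosen so that genome-wide $r^2$ falls below 0.2 near
26 kbp and short-range mean $r^2$ sits near 0.33, the regime of the
reference panel; clones are unrelated diploids, so kinship arises only
from subpopulation sharing.

**Phenotypes.** A ramet value is the sum of QTL allelic effects (snapped
to the nearest simulated SNP), a clone-level polygenic deviate, a fixed
block shift and a residual, with an optional clone-level shared residual
component giving residuals of the same clone in two blocks a configurable
covariance (trial-specific values are rarely reported, hence a parameter
rather than a constant). Effects are in phenotypic-SD units: the
polygenic variance is the heritability target minus the realized QTL
variance and the residual variance is one minus the target, so the
realized narrow-sense heritability of the additive part matches the
target up to Monte-Carlo error. Defaults mirror the reference trial: 461
clones, 3 blocks with one ramet per clone per block, 19 chromosomes at
the real sizes, heritability 0.3 (the mid-low range of the panel's
traits), block shifts (0, 0.5, 1) SD emulating the reported north–south
field gradient, 2% missing genotype calls.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: coalescent genealogies and recombination
hotspots, allele-frequency spectra from demography, genotyping error
structure correlated with depth, multi-allelic and indel variation,
spatial field trends beyond the block shifts, and
genotype-by-environment interaction. Tests against the generator validate
the estimators' statistical behaviour under a controlled truth, not the
biology of any particular panel.

## Numerical choices and degenerate inputs

* HWE ties: configurations whose probability equals the observed one are
  included in the p-value (tolerance 1e-9 relative, guarding against
  floating-point ties).
* `fit_null_mlm()` rejects kinship matrices whose smallest eigenvalue is
  below −1e-8 of the largest; with $K \propto I$ only the total variance
  is identifiable and the ratio pins at the search boundary — documented,
  and the scan is unaffected because only the whitening matters.
* Monomorphic SNPs: excluded from the GRM with a warning; reported
  untestable (p = 1) in the scan; pairs involving them skipped in LD.
* All-missing SNPs carry undefined-statistics flags through QC instead of
  crashing, and count as missingness failures when filtering.
* BIC ties in structure selection resolve to the smaller dimension.
* Window coordinates are 1-based half-open internally and exported as
  0-based half-open BED.

## Problem sizes used by the bundled checks

The test suite and the acceptance script run entirely on simulated data
sized for a single CPU: null calibration on 10,000 independent SNPs at
200 clones; parameter recovery over 50 generator seeds at 500 clones and
5,000 markers; the end-to-end demonstration on two 10-Mb chromosomes at
the reference panel's ~500 bp marker spacing (40,000 SNPs, 400 clones).
These sizes are the package's choice of a desk-scale standard; every
routine accepts panel-scale inputs unchanged.

## Known limitations

* Variance components are estimated once per trait and reused across
  SNPs; exact per-SNP REML is not exposed.
* No leave-one-chromosome-out kinship (see the proximal-contamination
  note above).
* The heritability formula takes external cluster labels as given.
* LD is composite (dosage-based); no phasing, no inter-chromosomal LD.
* Random-forest variance decomposition of top SNPs and functional gene
  classification are outside the package's scope; gene handling stops at
  positional overlap.
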