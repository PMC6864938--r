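# clonegwas

Genome-wide association analysis for clonally replicated field trials.

Forest-tree association panels are typically a few hundred unrelated wild
clones, replicated as one ramet per block in a randomized block design and
genotyped at several hundred thousand SNPs. `clonegwas` implements the
full association workflow for that setting, modelled on a 461-clone
*Populus trichocarpa* exome-capture panel (813,280 post-filter SNPs on 19
chromosomes):

* **Variant QC** — minor allele frequency (< 5% removed), missingness
  (> 5% removed) and an exact conditional Hardy–Weinberg test
  (`filter_variants()`, `hwe_exact_test()`).
* **Phenotype preparation** — log transforms and outlier masking, volume
  index `Vol = π (DBH/2)² h`, BLUP-adjusted clone means under the model
  `y = block (fixed) + clone (random) + e` fit by REML, and broad-sense
  heritability `H² = (σ²g + σ²c + σee′) / (σ²g + σ²c + σ²gxb + σ²e)`
  (`blup_clone_means()`, `broad_sense_heritability()`).
* **Relatedness and structure** — the standardized genomic relationship
  matrix `K_jk = (1/m) Σ_i (x_ij − 2p_i)(x_ik − 2p_i) / (2p_i(1 − p_i))`
  with pairwise-complete missingness, principal coordinates of the
  kinship-implied distances, and BIC selection of how many axes enter the
  model (`compute_grm()`, `classical_mds()`, `select_q_by_bic()`).
* **M + K + Q mixed-model scan** — EMMA-style REML null fit through the
  eigendecomposition of K, per-SNP generalized least squares with
  variance components fixed from the null, exact t reference (identical
  to OLS when K ∝ I), Bonferroni calling at `α/m` — `0.05/813,280 =
  6.1479e-8` for the reference panel (`fit_null_mlm()`, `scan_snps()`).
* **Sliding-window Poisson test** — 10 kb windows with 1 kb slide; a
  window with `n` SNPs of which `k` pass `p < 1e-5` is tested against the
  genome-wide rate via `λ = rate·n`, reporting the classical point mass
  `P = λᵏ e^(−λ)/k!` and the upper-tail p-value `P(X ≥ k)`, with
  Bonferroni calling over tested windows and GFF3 gene overlap
  (`scan_windows()`, `window_poisson_test()`, `windows_to_genes()`).
* **LD decay** — composite r² in 120-SNP windows and a one-parameter
  Hill–Weir nonlinear fit locating the distance where r² drops to 0.2
  (`pairwise_r2()`, `fit_decay()`, `distance_at_r2()`).
* **Synthetic test bed** — founder-haplotype genotypes with block LD and
  Balding–Nichols-style structure plus clonal-trial phenotypes with known
  QTL and variance components (`sim_config()`, `simulate_genotypes()`,
  `simulate_phenotypes()`, `write_fixtures()`).
* **Pipeline driver** — `run_pipeline()` executes simulate/load → QC →
  BLUP → structure → scan → windows → LD from one (YAML-able)
  configuration, writing TSV/VCF/BED outputs and an MD5 manifest;
  `inst/scripts/clonegwas_pipeline.R` is a thin shell wrapper.

## Worked example

Simulate a 300-clone trial on two 5-Mb chromosomes (10,000 SNPs each)
with one QTL of 0.6 SD at Chr01:2.5 Mb and heritability 0.4, then run the
stages:

```r
library(clonegwas)

cfg <- sim_config(
  n_clones = 300,
  chromosomes = data.frame(name = c("Chr01", "Chr02"),
                           length_bp = c(5e6, 5e6)),
  n_snps_per_chrom = 10000,
  qtl = data.frame(chrom = "Chr01", pos = 2.5e6, effect = 0.6),
  h2_additive = 0.4,
  seed = 11)

sim <- simulate_genotypes(cfg)
out <- simulate_phenotypes(sim$variants, sim$truth, cfg)

qc <- filter_variants(sim$variants)
print(qc$report)
#> variant filter report
#>   input SNPs:        20000
#>   removed (MAF < 0.05):        8060
#>   removed (missing > 0.05):    11
#>   removed (HWE p < 1e-06):      127
#>   kept:              11802

means <- blup_clone_means(out$phenotypes)
vc <- attr(means, "varcomp")
broad_sense_heritability(0, vc$sigma2_clone, 0, vc$sigma2_resid)
#> [1] 0.403  # the simulated trial's clonal repeatability

K   <- compute_grm(qc$variants, ensure_psd = TRUE)
mds <- classical_mds(K, d = 5)
y   <- means$adjusted_mean[match(colnames(qc$variants$geno), means$clone_id)]
d   <- select_q_by_bic(y, mds, 5)$d
Q   <- if (d > 0) mds$axes[, seq_len(d), drop = FALSE] else NULL

res <- scan_snps(y, qc$variants, K = K, Q = Q)
# threshold 4.24e-06; 51 significant SNPs; top hit Chr01_2500543 (p = 3.3e-22)
# the top hit IS the planted causal SNP (out$truth$causal$snp_id)

w <- call_significant_windows(scan_windows(res, c(Chr01 = 5e6, Chr02 = 5e6)))
sum(w$significant)
#> [1] 94   # windows clustered around the causal region

ld <- ld_decay_analysis(qc$variants, c(Chr01 = 5e6, Chr02 = 5e6))
ld$summary
#>   chrom size_mbp n_snps bp_per_snp ld_decay_kbp
#> 1 Chr01        5   5915      845.3        28.96
#> 2 Chr02        5   5887      849.3        29.40
#> 3 Total       10  11802         NA           NA
#> 4  Mean       NA     NA      847.3        29.18
```

The filter report shows the familiar attrition from raw to analyzed SNPs;
the scan recovers the planted QTL genome-wide; the window test flags the
surrounding LD block; and the fitted decay distance (~29 kbp to r² = 0.2)
sits in the range reported for this species.

The same run, driven by configuration instead of code:

```sh
Rscript inst/scripts/clonegwas_pipeline.R --config my_run.yaml --outdir out
```

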