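test_that("identical configurations reproduce identical output", {
  cfg <- sim_config(n_clones = 50,
                    chromosomes = data.frame(name = c("Chr01", "Chr02"),
                                             length_bp = c(1e6, 5e5)),
                    n_snps_per_chrom = 200, n_subpops = 2, seed = 99)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a, b)
  pa <- simulate_phenotypes(a$variants, a$truth, cfg)
  pb <- simulate_phenotypes(b$variants, b$truth, cfg)
  expect_identical(pa, pb)
})

test_that("configuration validation rejects degenerate settings", {
  expect_error(sim_config(n_clones = 0), "at least one clone")
  expect_error(sim_config(n_snps_per_chrom = 0), "at least one SNP")
  expect_error(sim_config(h2_additive = 1), "h2_additive")
  expect_error(sim_config(fst_like_divergence = 1), "fst_like_divergence")
  expect_error(sim_config(block_effects = c(0, 1)), "one entry per block")
  expect_error(sim_config(qtl = data.frame(chrom = "nope", pos = 1,
                                           effect = 1)),
               "must exist")
})

test_that("infinite blocks without mutation give complete linkage", {
  cfg <- sim_config(n_clones = 80,
                    chromosomes = data.frame(name = "Chr01",
                                             length_bp = 1e6),
                    n_snps_per_chrom = 60, n_subpops = 1,
                    fst_like_divergence = 0, ld_block_len = Inf,
                    mutation_rate = 0, n_founders = 2, missing_rate = 0,
                    seed = 3)
  g <- simulate_genotypes(cfg)$variants$geno
  poly <- apply(g, 1, var) > 0
  r2 <- cor(t(g[poly, , drop = FALSE]))^2
  expect_true(all(abs(r2 - 1) < 1e-12))
})

test_that("half-probability founder switching makes 1-SNP blocks independent", {
  # with two founders a switch probability of 0.5 renders consecutive
  # blocks independent; the oracle is the same data with one locus of each
  # pair permuted across clones (exactly independent, same margins)
  set.seed(44)
  gen_mean <- perm_mean <- numeric(200)
  for (rep in 1:200) {
    cfg <- sim_config(n_clones = 60,
                      chromosomes = data.frame(name = "Chr01",
                                               length_bp = 5000),
                      n_snps_per_chrom = 20, n_subpops = 1,
                      fst_like_divergence = 0, ld_block_len = 1,
                      mutation_rate = 0, n_founders = 2,
                      recomb_between_blocks = 0.5, missing_rate = 0,
                      seed = 1000 + rep)
    g <- simulate_genotypes(cfg)$variants$geno
    poly <- apply(g, 1, var) > 0
    g <- g[poly, , drop = FALSE]
    if (nrow(g) < 2) next
    i <- 1:(nrow(g) - 1)
    r_adj <- vapply(i, function(k) cor(g[k, ], g[k + 1, ]), numeric(1))
    r_perm <- vapply(i, function(k)
      cor(g[k, ], sample(g[k + 1, ])), numeric(1))
    gen_mean[rep] <- mean(r_adj^2, na.rm = TRUE)
    perm_mean[rep] <- mean(r_perm^2, na.rm = TRUE)
  }
  mc_se <- sd(gen_mean - perm_mean) / sqrt(200)
  expect_lt(abs(mean(gen_mean) - mean(perm_mean)), 4 * mc_se)
})

test_that("allele frequencies converge to the ancestral configuration", {
  cfg <- sim_config(n_clones = 2000,
                    chromosomes = data.frame(name = "Chr01",
                                             length_bp = 1e6),
                    n_snps_per_chrom = 100, n_subpops = 1,
                    fst_like_divergence = 0, n_founders = 400,
                    mutation_rate = 0.05, missing_rate = 0, seed = 45)
  sim <- simulate_genotypes(cfg)
  p0 <- sim$truth$ancestral_freq
  phat <- rowMeans(sim$variants$geno) / 2
  # founder-pool draw + haplotype sampling variance
  se <- sqrt(p0 * (1 - p0) * (1 / 400 + 1 / (2 * 2000)))
  expect_gte(mean(abs(phat - p0) <= 3 * se), 0.95)
})

test_that("binned r2 decays with distance", {
  cfg <- sim_config(n_clones = 150,
                    chromosomes = data.frame(name = "Chr01",
                                             length_bp = 3e6),
                    n_snps_per_chrom = 1000, n_subpops = 1,
                    fst_like_divergence = 0, missing_rate = 0, seed = 46)
  vt <- filter_variants(simulate_genotypes(cfg)$variants,
                        hwe_alpha = 0)$variants
  pr <- pairwise_r2(vt, 120)
  bins <- cut(pr$dist, breaks = c(0, 1e4, 3e4, 1e5, Inf))
  means <- tapply(pr$r2, bins, mean)
  expect_true(all(diff(means) <= 0.02))  # non-increasing up to noise
  expect_gt(means[1], means[length(means)])
})

test_that("null phenotypes show no clone effect; block shifts are real", {
  chr <- data.frame(name = "Chr01", length_bp = 1e5)
  pf <- vapply(1:200, function(s) {
    cfg <- sim_config(n_clones = 50, chromosomes = chr,
                      n_snps_per_chrom = 20, n_subpops = 1,
                      fst_like_divergence = 0, h2_additive = 0,
                      block_effects = c(0, 0, 0), missing_rate = 0,
                      seed = s)
    sim <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(sim$variants, sim$truth, cfg)$phenotypes
    anova(lm(value ~ block + clone_id, data = ph))["clone_id", "Pr(>F)"]
  }, numeric(1))
  expect_gte(mean(pf > 0.05), 0.9)

  # zero block effects leave block means equal within sampling error
  cfg <- sim_config(n_clones = 400, chromosomes = chr,
                    n_snps_per_chrom = 20, n_subpops = 1,
                    fst_like_divergence = 0, h2_additive = 0,
                    block_effects = c(0, 0, 0), missing_rate = 0, seed = 48)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$variants, sim$truth, cfg)$phenotypes
  expect_gt(anova(lm(value ~ block, data = ph))["block", "Pr(>F)"], 0.01)

  # configured block shifts are realized
  cfg2 <- sim_config(n_clones = 400, chromosomes = chr,
                     n_snps_per_chrom = 20, n_subpops = 1,
                     fst_like_divergence = 0, h2_additive = 0,
                     block_effects = c(0, 1, 2), missing_rate = 0,
                     seed = 49)
  sim2 <- simulate_genotypes(cfg2)
  ph2 <- simulate_phenotypes(sim2$variants, sim2$truth, cfg2)$phenotypes
  bm <- tapply(ph2$value, ph2$block, mean)
  expect_equal(as.numeric(bm - bm[1]), c(0, 1, 2), tolerance = 0.2)
})

test_that("phenotype variance components hit the heritability target", {
  cfg <- sim_config(n_clones = 800,
                    chromosomes = data.frame(name = "Chr01",
                                             length_bp = 1e6),
                    n_snps_per_chrom = 300, n_subpops = 1,
                    fst_like_divergence = 0, h2_additive = 0.4,
                    qtl = data.frame(chrom = "Chr01", pos = 5e5,
                                     effect = 0.3),
                    missing_rate = 0, seed = 50)
  sim <- simulate_genotypes(cfg)
  out <- simulate_phenotypes(sim$variants, sim$truth, cfg)
  vc <- out$truth$var_components
  expect_equal(vc$sigma2_qtl + vc$sigma2_poly, 0.4, tolerance = 0.05)
  expect_equal(vc$sigma2_e, 0.6)
  # realized narrow-sense heritability of clone means at the ramet level
  g <- out$truth$genetic_values
  expect_equal(var(g) / (var(g) + vc$sigma2_e), 0.4, tolerance = 0.05)
  # causal id exists in the emitted table
  expect_true(out$truth$causal$snp_id %in% sim$variants$map$snp_id)
})

test_that("a clone-level shared residual induces the requested covariance", {
  cfg <- sim_config(n_clones = 3000,
                    chromosomes = data.frame(name = "Chr01",
                                             length_bp = 1e5),
                    n_snps_per_chrom = 10, n_subpops = 1,
                    fst_like_divergence = 0, h2_additive = 0,
                    block_effects = c(0, 0, 0), resid_cov = 0.3,
                    missing_rate = 0, seed = 51)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$variants, sim$truth, cfg)$phenotypes
  wide <- reshape(ph[c("clone_id", "block", "value")],
                  idvar = "clone_id", timevar = "block",
                  direction = "wide")
  expect_equal(cov(wide$value.block1, wide$value.block2), 0.3,
               tolerance = 0.15)
})
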