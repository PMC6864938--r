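test_that("pairwise r2 identities: duplicates, allele flips, missing clones", {
  set.seed(40)
  x <- rbinom(100, 2, 0.4)
  G <- rbind(x, x, 2L - x)
  storage.mode(G) <- "integer"
  vt <- make_vt(G, by = 100L)
  pr <- pairwise_r2(vt, window_snps = 120)
  expect_equal(pr$r2[pr$pos1 == 100 & pr$pos2 == 200], 1)   # identical column
  expect_equal(pr$r2[pr$pos1 == 100 & pr$pos2 == 300], 1)   # allele-flipped
  # appending a clone with only missing calls changes nothing
  G2 <- cbind(G, NA_integer_)
  pr2 <- pairwise_r2(make_vt(G2), window_snps = 120)
  expect_equal(pr2$r2, pr$r2)
})

test_that("windowed r2 equals the brute-force quadratic oracle", {
  set.seed(41)
  G <- matrix(rbinom(50 * 200, 2, runif(50, 0.1, 0.9)), 50, 200)
  G[sample(length(G), 300)] <- NA
  storage.mode(G) <- "integer"
  vt <- make_vt(G, by = 37L)
  win <- 10
  pr <- pairwise_r2(vt, window_snps = win)
  # oracle: all pairs, restricted to the SNP-count window
  got <- 0L
  for (i in 1:49) for (j in (i + 1):min(i + win - 1, 50)) {
    r <- suppressWarnings(cor(G[i, ], G[j, ], use = "pairwise.complete.obs"))
    if (is.na(r)) next
    row <- pr[pr$pos1 == vt$map$pos[i] & pr$pos2 == vt$map$pos[j], ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$r2, r^2, tolerance = 1e-12)
    got <- got + 1L
  }
  expect_equal(nrow(pr), got)
  expect_true(all(pr$dist > 0))
  # zero-variance SNP pairs are skipped
  G[3, ] <- 1L
  pr3 <- pairwise_r2(make_vt(G, by = 37L), window_snps = win)
  expect_false(any(pr3$pos1 == 3 * 37 | pr3$pos2 == 3 * 37))
})

test_that("Hill-Weir decay fit recovers beta", {
  # noise-free self-consistency
  d <- exp(seq(log(100), log(2e5), length.out = 300))
  fit <- fit_decay(data.frame(dist = d, r2 = hill_weir_r2(d, 3e-5, 200)),
                   n_samples = 200)
  expect_equal(fit$beta, 3e-5, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-12)
  expect_true(fit$converged)
  # the fitted curve is bounded and monotone decreasing
  grid <- seq(1, 1e6, length.out = 2000)
  vals <- fit$curve(grid)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vals) <= 0) && vals[1] > vals[length(vals)])
  # d -> 0 limit approaches the analytic intercept
  expect_equal(fit$curve(1e-9), hill_weir_r2(0, 3e-5, 200),
               tolerance = 1e-9)
  expect_warning(expect_warning(
    fit_decay(data.frame(dist = c(10, 20), r2 = c(0.5, 0.4)), 100),
    "fewer than 20"), "decades")
})

test_that("decay distance is located to 1 bp on a constructed crossing", {
  # build a curve that equals 0.2 exactly at 26,900 bp
  beta0 <- uniroot(function(b) hill_weir_r2(26900, b, 461) - 0.2,
                   c(1e-7, 1e-2), tol = 1e-14)$root
  d <- exp(seq(log(10), log(1e6), length.out = 400))
  fit <- fit_decay(data.frame(dist = d, r2 = hill_weir_r2(d, beta0, 461)),
                   n_samples = 461)
  expect_equal(distance_at_r2(fit, 0.2), 26900, tolerance = 1 / 26900)
  # a level above the d -> 0 intercept is never reached
  expect_message(res <- distance_at_r2(fit, 0.9), "not reached")
  expect_true(is.na(res))
})

test_that("summary table computes spacing and mean-row conventions", {
  df <- data.frame(chrom = c("Chr01", "Chr02"),
                   size_bp = c(2e6, 1e6), n_snps = c(1000L, 100L),
                   ld_decay_kbp = c(20, 30))
  tab <- ld_summary_table(df)
  expect_equal(tab$bp_per_snp[1:2], c(2000, 10000))
  # mean row averages per-chromosome values (not total size / total SNPs)
  expect_equal(tab$bp_per_snp[tab$chrom == "Mean"], 6000)
  expect_equal(tab$ld_decay_kbp[tab$chrom == "Mean"], 25)
  expect_equal(tab$n_snps[tab$chrom == "Total"], 1100)
  # a single chromosome is its own mean
  one <- ld_summary_table(df[1, ])
  expect_equal(one$bp_per_snp[one$chrom == "Mean"], 2000)
})

test_that("simulated decay distance scales with the LD-block length", {
  decays <- vapply(c(4000, 10000, 25000, 60000), function(bl) {
    cfg <- sim_config(n_clones = 120,
                      chromosomes = data.frame(name = "Chr01",
                                               length_bp = 4e6),
                      n_snps_per_chrom = 900, n_subpops = 1,
                      fst_like_divergence = 0, ld_block_len = bl,
                      missing_rate = 0, seed = 42)
    sim <- simulate_genotypes(cfg)
    vt <- filter_variants(sim$variants, hwe_alpha = 0)$variants
    fit <- fit_decay(pairwise_r2(vt, 120), n_samples = 120)
    suppressMessages(distance_at_r2(fit, 0.2))
  }, numeric(1))
  expect_false(anyNA(decays))
  expect_equal(order(decays), 1:4)  # strictly increasing in block length
})
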