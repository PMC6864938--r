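test_that("window enumeration follows the slide rule", {
  w <- enumerate_windows(c(Chr01 = 10000), 10000, 1000)
  expect_equal(nrow(w), 10L)
  expect_equal(w$start, seq(1, 9001, by = 1000))
  expect_equal(w$end, w$start + 10000)  # overhang retained

  expect_equal(nrow(enumerate_windows(c(C = 500), 10000, 1000)), 1L)
  expect_null(enumerate_windows(c(C = 0), 10000, 1000))
  expect_error(enumerate_windows(c(C = 100), 500, 1000), "window_bp")

  # tiling: brute-force cover count of interior positions
  w2 <- enumerate_windows(c(C = 50000), 10000, 1000)
  for (pos in c(15000, 23001, 40999)) {
    covered <- sum(pos >= w2$start & pos < w2$end)
    expect_equal(covered, 10L)  # window/slide windows in the interior
  }
})

test_that("Poisson window probabilities match closed forms", {
  t1 <- window_poisson_test(0, 100, 0.01)   # lambda = 1
  expect_equal(t1$lambda, 1)
  expect_equal(t1$point_prob, exp(-1))
  expect_equal(t1$p_value, 1)
  t2 <- window_poisson_test(2, 200, 0.01)   # lambda = 2
  expect_equal(t2$point_prob, 2 * exp(-2))
  expect_equal(t2$p_value, ppois(1, 2, lower.tail = FALSE))
  # normalization of the point masses
  lam <- 3.7
  expect_equal(sum(dpois(0:200, lam)), 1, tolerance = 1e-12)
  expect_error(window_poisson_test(1, 10, 1.5), "rate")
  expect_error(window_poisson_test(5, 2, 0.1), "exceed")
  expect_error(window_poisson_test(0, 0, 0.1), "skipped")
})

test_that("upper-tail p agrees with the exact binomial in the Poisson limit", {
  # Poisson approximation error of the tail grows like k^2/n, so the
  # comparison stays in the regime k(k-1)/(2n) <= 0.05
  for (rate in c(0.001, 0.005, 0.01)) for (n in c(50, 200, 1000)) {
    kmax <- max(1, floor((1 + sqrt(1 + 0.4 * n)) / 2))
    for (k in 0:kmax) {
      pp <- window_poisson_test(k, n, rate)$p_value
      pb <- pbinom(k - 1, n, rate, lower.tail = FALSE)
      expect_lt(abs(pp - pb) / pb, 0.10)
    }
  }
})

test_that("tail monotonicity in k and lambda", {
  for (lam in c(0.1, 1, 5)) {
    p <- ppois(0:14, lam, lower.tail = FALSE)  # P(X >= k+1)
    expect_true(all(diff(p) < 0))
  }
  for (k in 1:6) {
    p <- vapply(seq(0.1, 8, by = 0.5),
                function(l) ppois(k - 1, l, lower.tail = FALSE), numeric(1))
    expect_true(all(diff(p) > 0))
  }
})

test_that("window calling flags a planted cluster and nothing else", {
  set.seed(30)
  m <- 20000
  pos <- sort(sample.int(2e6, m))
  p <- runif(m)
  p[p < 1e-4] <- 0.5          # clear the background
  bg <- sample(m, round(m * 1e-4))
  p[bg] <- 1e-6               # genome rate 1e-4
  span <- which(pos >= 1e6 & pos < 1e6 + 5000)
  planted <- span[seq_len(20)]
  p[planted] <- 1e-7
  assoc <- data.frame(chrom = "Chr01", pos = pos, p = p)
  w <- scan_windows(assoc, c(Chr01 = 2e6), input_p = 1e-5)
  cw <- call_significant_windows(w, alpha = 0.05)
  expect_equal(attr(cw, "threshold"), 0.05 / nrow(cw))
  hit_span <- cw$start <= pos[max(planted)] & cw$end > pos[min(planted)]
  expect_true(any(cw$significant[hit_span]))
  expect_false(any(cw$significant[!hit_span]))

  # p-values are invariant to the order SNPs are supplied
  sh <- sample(nrow(assoc))
  w2 <- scan_windows(assoc[sh, ], c(Chr01 = 2e6), input_p = 1e-5)
  expect_equal(w2$p_value, w$p_value)
  expect_equal(w2$k, w$k)
})

test_that("simple Bonferroni arithmetic for windows", {
  w <- data.frame(chrom = "C", start = 1, end = 2, n_snps = 1, k = 0,
                  lambda = 0.1, point_prob = 0.9,
                  p_value = runif(1000))
  w <- w[rep(1, 1000), ]; w$p_value <- runif(1000)
  cw <- call_significant_windows(w, 0.05)
  expect_equal(attr(cw, "threshold"), 5e-5)
})

test_that("window/gene overlap uses half-open window intervals", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "Chr01",
                      start = c(2001L, 1500L), end = c(3000L, 1600L))
  win <- data.frame(chrom = "Chr01", start = 1001L, end = 2001L)
  ov <- windows_to_genes(win, genes)
  # window covers 1001..2000: abutting gA excluded, nested gB included
  expect_identical(ov$gene_id, "gB")
  expect_equal(ov$overlap_bp, 101L)

  # random intervals against a quadratic brute-force oracle
  set.seed(31)
  win2 <- data.frame(chrom = "Chr01",
                     start = sample.int(5000, 40), end = 0L)
  win2$end <- win2$start + sample(50:500, 40, replace = TRUE)
  genes2 <- data.frame(gene_id = sprintf("g%02d", 1:30), chrom = "Chr01",
                       start = sample.int(5000, 30), end = 0L)
  genes2$end <- genes2$start + sample(20:400, 30, replace = TRUE)
  ov2 <- windows_to_genes(win2, genes2)
  brute <- 0L
  for (i in seq_len(40)) for (j in seq_len(30)) {
    if (win2$start[i] <= genes2$end[j] && genes2$start[j] <= win2$end[i] - 1L)
      brute <- brute + 1L
  }
  expect_equal(nrow(ov2), brute)
})
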