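test_that("volume index applies the formula in metres", {
  expect_equal(volume_index(2000, 10), pi)  # 2 m diameter, 1 m height
  expect_equal(volume_index(0, 10), 0)
  # direct-formula oracle on a grid
  set.seed(5)
  dbh <- runif(50, 10, 1000)
  h <- runif(50, 5, 120)
  expect_equal(volume_index(dbh, h),
               pi * (dbh / 1000 / 2)^2 * (h / 10),
               tolerance = 1e-12)
  expect_error(volume_index(-1, 10), "non-negative")
})

test_that("trait transform handles log, identity and outlier masking", {
  expect_equal(transform_trait(rep(1, 10), "log", Inf), rep(0, 10))
  x <- rnorm(20)
  expect_identical(transform_trait(x, "none", Inf), x)
  expect_warning(out <- transform_trait(c(-1, 1, 2), "log", Inf),
                 "non-positive")
  expect_true(is.na(out[1]))
  # a planted 10-SD point is exactly the value masked
  set.seed(6)
  x <- rnorm(100)
  x[17] <- 10 * sd(x[-17])
  masked <- transform_trait(x, "none", outlier_sd = 4)
  expect_true(is.na(masked[17]))
  expect_equal(sum(is.na(masked)), 1L)
})

test_that("BLUP clone means shrink by the balanced closed form", {
  set.seed(7)
  n_c <- 120; r <- 3
  g <- rnorm(n_c, 0, sqrt(0.4))
  ph <- do.call(rbind, lapply(seq_len(r), function(b)
    data.frame(clone_id = sprintf("c%03d", seq_len(n_c)),
               block = paste0("b", b), trait = "t",
               value = g + rnorm(n_c, 0, sqrt(0.6)))))
  bm <- blup_clone_means(ph)
  vc <- attr(bm, "varcomp")
  ybar <- as.numeric(tapply(ph$value, ph$clone_id, mean)[bm$clone_id])
  shrink <- vc$sigma2_clone / (vc$sigma2_clone + vc$sigma2_resid / r)
  expect_equal(bm$blup, shrink * (ybar - mean(ybar)), tolerance = 1e-6)
  # shrinkage: BLUP-adjusted means vary less than raw clone means
  expect_lt(var(bm$adjusted_mean), var(ybar))
})

test_that("BLUPs vanish when clones carry no genetic signal", {
  set.seed(8)
  n_c <- 100
  ph <- do.call(rbind, lapply(1:3, function(b)
    data.frame(clone_id = sprintf("c%03d", seq_len(n_c)),
               block = paste0("b", b), trait = "t",
               value = 5 + rnorm(n_c))))
  bm <- blup_clone_means(ph)
  expect_lt(max(abs(bm$blup)), 0.25)
  expect_lt(sd(bm$adjusted_mean), sd(tapply(ph$value, ph$clone_id, mean)))
})

test_that("estimated block effects recover simulated shifts", {
  set.seed(9)
  shifts <- c(0, 0.8, -0.5)
  errs <- replicate(100, {
    n_c <- 60
    g <- rnorm(n_c, 0, 0.5)
    ph <- do.call(rbind, lapply(1:3, function(b)
      data.frame(clone_id = sprintf("c%02d", seq_len(n_c)),
                 block = paste0("b", b), trait = "t",
                 value = g + shifts[b] + rnorm(n_c, 0, 0.7))))
    bm <- attr(blup_clone_means(ph), "block_means")
    (bm - bm[1])[2:3] - shifts[2:3]
  })
  # mean recovery within 3 SE of the Monte-Carlo error
  se <- apply(errs, 1, sd) / sqrt(ncol(errs))
  expect_true(all(abs(rowMeans(errs)) < 3 * se + 1e-8))
})

test_that("blup_clone_means validates its design", {
  ph <- data.frame(clone_id = "c1", block = c("b1", "b2"), trait = "t",
                   value = c(1, 2))
  expect_error(blup_clone_means(ph), "two clones")
  dup <- data.frame(clone_id = c("c1", "c1", "c2"), block = "b1",
                    trait = "t", value = 1:3)
  expect_error(blup_clone_means(dup), "one ramet")
})

test_that("broad-sense heritability follows the variance-component formula", {
  expect_equal(broad_sense_heritability(1, 0, 0, 1), 0.5)
  expect_equal(broad_sense_heritability(0, 0, 2.3, 0.7), 0)
  set.seed(10)
  for (i in 1:20) {
    v <- runif(4, 0.01, 5)
    ee <- runif(1, -0.1, 0.5)
    expect_equal(broad_sense_heritability(v[1], v[2], v[3], v[4], ee),
                 (v[1] + v[2] + ee) / (v[1] + v[2] + v[3] + v[4]))
    # scale invariance in the variance components
    expect_equal(broad_sense_heritability(3 * v[1], 3 * v[2], 3 * v[3],
                                          3 * v[4], 3 * ee),
                 broad_sense_heritability(v[1], v[2], v[3], v[4], ee))
  }
  # with no interaction or residual covariance: classical intraclass form
  expect_equal(broad_sense_heritability(0.3, 0.2, 0, 0.5),
               (0.3 + 0.2) / (0.3 + 0.2 + 0.5))
  expect_error(broad_sense_heritability(-1, 0, 0, 1), "non-negative")
  expect_error(broad_sense_heritability(0, 0, 0, 0), "positive")
})

test_that("summary statistics reproduce the CV convention", {
  s <- summary_stats(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$cv_pct, 100 * sd(1:4) / 2.5)
  expect_equal(summary_stats(rep(3, 5))$cv_pct, 0)
  expect_error(summary_stats(1), "two non-missing")
  expect_error(cv_percent(0, 1), "zero mean")
})
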