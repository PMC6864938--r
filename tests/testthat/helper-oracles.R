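# Independent oracles and small fixture builders shared across the suite.

# Exact HWE p by direct enumeration of all heterozygote configurations
# consistent with the allele counts (log-formula route, independent of the
# package's recurrence implementation).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  m <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (m == 0) return(1)
  h <- seq(m %% 2, m, by = 2)
  lp <- lfactorial(n) - lfactorial((m - h) / 2) - lfactorial(h) -
    lfactorial(n - h - (m - h) / 2) + h * log(2) - lchoose(2 * n, m)
  pr <- exp(lp)
  obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Build a variant_table from a dosage matrix (SNPs x clones), positions
# spaced `by` bp apart on one chromosome.
make_vt <- function(G, chrom = "Chr01", by = 100L, pos = NULL) {
  m <- nrow(G)
  if (is.null(pos)) pos <- seq.int(by, by * m, by = by)
  map <- data.frame(snp_id = sprintf("%s_%d", chrom, pos), chrom = chrom,
                    pos = pos, ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  if (is.null(colnames(G))) colnames(G) <- sprintf("c%03d", seq_len(ncol(G)))
  variant_table(map, G)
}

# Multivariate normal draw through the Cholesky factor (jittered for
# semidefinite covariances).
mvn_draw <- function(V, jitter = 1e-8) {
  L <- chol(V + diag(jitter, nrow(V)))
  drop(t(L) %*% rnorm(nrow(V)))
}

# RMSE between two configurations after optimal translation + rotation
# (orthogonal Procrustes via SVD).
procrustes_rmse <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$u %*% t(s$v)
  sqrt(mean((Yc - Xc %*% R)^2))
}

# Simple-regression two-sided t-test p-value (per-SNP OLS oracle).
ols_p <- function(y, x) {
  fit <- lm(y ~ x)
  summary(fit)$coefficients[2, 4]
}
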