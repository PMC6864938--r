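#' Fit the null mixed model y = X beta + g + e
#'
#' REML fit of the polygenic null model with fixed effects X = intercept
#' (+ optional structure axes Q) and random effect g ~ N(0, sigma2_g K),
#' e ~ N(0, sigma2_e I). Following the eigendecomposition approach of
#' EMMA-style solvers, K = U S U' is decomposed once, y and X are rotated
#' by U', the fixed effects and the genetic variance are profiled out
#' analytically, and the restricted likelihood is maximized over the
#' variance ratio delta = sigma2_e / sigma2_g by a bracketed 1-D search on
#' log delta in [-10, 10].
#'
#' @param y numeric vector of (BLUP-adjusted) clone means.
#' @param K kinship matrix, positive semidefinite up to `psd_tol`.
#' @param Q optional matrix of structure covariates (columns are axes).
#' @param psd_tol reject K whose smallest eigenvalue is below
#'   `-psd_tol * max(eigenvalue)` (default 1e-8).
#' @return object of class `null_mlm`: variance components `sigma2_g`,
#'   `sigma2_e`, ratio `delta`, REML `loglik`, fixed effects `beta`, the
#'   eigen pair (`U`, `S`), the design `X` and `loglik_fun(log_delta)` for
#'   profiling diagnostics.
#' @export
fit_null_mlm <- function(y, K, Q = NULL, psd_tol = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
    stop("y and K are not conformable")
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    if (nrow(Q) != n) stop("Q is not aligned with y")
    X <- cbind(X, Q)
  }
  p <- ncol(X)
  if (n <= p + 1) stop("too few observations for the fixed effects")

  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -psd_tol * max(abs(e$values), 1))
    stop("K is not positive semidefinite (min eigenvalue ",
         signif(min(e$values), 3), ")")
  S <- pmax(e$values, 0)
  U <- e$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  profile <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (S + delta)
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    beta <- solve(XtWX, XtWy)
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
                  sum(log(S + delta)) +
                  as.numeric(determinant(XtWX, logarithm = TRUE)$modulus))
    list(loglik = ll, sigma2_g = s2, beta = beta)
  }
  loglik_fun <- function(log_delta) profile(log_delta)$loglik

  opt <- optimize(loglik_fun, interval = c(-10, 10),
                  maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, -10, 10)
  ll <- vapply(cand, loglik_fun, numeric(1))
  log_delta <- cand[which.max(ll)]
  fit <- profile(log_delta)
  delta <- exp(log_delta)

  structure(list(sigma2_g = fit$sigma2_g,
                 sigma2_e = delta * fit$sigma2_g,
                 delta = delta, log_delta = log_delta,
                 loglik = fit$loglik,
                 beta = drop(fit$beta),
                 U = U, S = S, X = X, n = n,
                 loglik_fun = loglik_fun),
            class = "null_mlm")
}

#' @export
print.null_mlm <- function(x, ...) {
  cat("null mixed model (REML)\n")
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g (delta = %.4g)\n",
              x$sigma2_g, x$sigma2_e, x$delta))
  cat(sprintf("  REML loglik = %.4f, n = %d, fixed effects = %d\n",
              x$loglik, x$n, length(x$beta)))
  invisible(x)
}

#' Single-SNP mixed-model association scan
#'
#' Generalized least squares test of each SNP against the phenotype with
#' covariance sigma2_g K + sigma2_e I fixed at the null-model REML
#' estimates (the population-parameters-previously-determined
#' approximation, standard for large marker counts). Data are whitened
#' through the eigendecomposition of K, the SNP coefficient is estimated
#' by OLS in the whitened space, and its Wald statistic is referred to a
#' t distribution with the residual degrees of freedom, re-estimating the
#' residual scale per SNP; with K proportional to the identity this is
#' exactly the ordinary simple-regression t-test. Missing genotypes are
#' mean-imputed per SNP for testing only (never for the GRM). Monomorphic
#' SNPs are reported with effect 0, p = 1 and flagged untestable.
#'
#' @param y phenotype vector (clone means), aligned with columns of the
#'   genotype matrix.
#' @param geno variant_table, or a SNP x clone dosage matrix.
#' @param K kinship matrix (needed when `null` is not supplied).
#' @param Q optional structure covariates (must match those used for
#'   `null`).
#' @param null optional [fit_null_mlm()] fit to reuse.
#' @param alpha genome-wide significance level for the Bonferroni
#'   threshold (default 0.05).
#' @param m_total number of tests used in the Bonferroni threshold;
#'   defaults to the number of testable SNPs in the scan.
#' @return data.frame of class `assoc_result`: `snp_id`, `chrom`, `pos`,
#'   `beta`, `se`, `stat`, `p`, `tested`, `significant`; attributes
#'   `threshold`, `alpha`, `m_total`, `null`.
#' @export
scan_snps <- function(y, geno, K = NULL, Q = NULL, null = NULL,
                      alpha = 0.05, m_total = NULL) {
  if (inherits(geno, "variant_table")) {
    G <- geno$geno
    map <- geno$map
  } else {
    G <- as.matrix(geno)
    map <- data.frame(snp_id = rownames(G) %||% paste0("snp", seq_len(nrow(G))),
                      chrom = NA_character_, pos = NA_integer_,
                      stringsAsFactors = FALSE)
  }
  y <- as.numeric(y)
  n <- length(y)
  if (ncol(G) != n) stop("genotypes and phenotype are not aligned")
  if (is.null(null)) {
    if (is.null(K)) stop("either a null model fit or K must be supplied")
    null <- fit_null_mlm(y, K, Q)
  }

  # whitening transform from the null fit
  d <- 1 / sqrt(null$sigma2_g * null$S + null$sigma2_e)
  ty <- d * crossprod(null$U, y)
  tX <- d * crossprod(null$U, null$X)

  rmu <- rowMeans(G, na.rm = TRUE)
  gvar <- apply(G, 1L, var, na.rm = TRUE)
  tested <- !is.na(gvar) & gvar > 0
  Gi <- G
  idx <- which(is.na(Gi))
  if (length(idx)) Gi[idx] <- rmu[((idx - 1) %% nrow(Gi)) + 1]

  tG <- d * crossprod(null$U, t(Gi))
  qrX <- qr(tX)
  yr <- qr.resid(qrX, ty)
  Gr <- qr.resid(qrX, tG)
  gg <- colSums(Gr^2)
  gy <- colSums(Gr * as.vector(yr))
  df <- n - ncol(null$X) - 1
  ok <- tested & gg > 1e-12

  beta <- ifelse(ok, gy / gg, 0)
  rss <- sum(yr^2) - beta * gy
  s2 <- rss / df
  se <- ifelse(ok, sqrt(s2 / gg), NA_real_)
  stat <- ifelse(ok, beta / se, NA_real_)
  p <- rep(1, nrow(G))
  p[ok] <- 2 * pt(abs(stat[ok]), df, lower.tail = FALSE)

  if (is.null(m_total)) m_total <- sum(ok)
  threshold <- bonferroni_threshold(alpha, max(m_total, 1))
  res <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                    beta = beta, se = se, stat = stat, p = p,
                    tested = ok, significant = ok & p < threshold,
                    stringsAsFactors = FALSE)
  attr(res, "threshold") <- threshold
  attr(res, "alpha") <- alpha
  attr(res, "m_total") <- m_total
  attr(res, "df") <- df
  attr(res, "null") <- null[c("sigma2_g", "sigma2_e", "delta", "loglik")]
  class(res) <- c("assoc_result", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests (>= 1).
#' @return per-test threshold alpha / m.
#' @examples
#' bonferroni_threshold(0.05, 813280)  # 6.1479e-08
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.finite(m) || m < 1) stop("m must be at least 1")
  alpha / m
}

#' Summarize significant associations per chromosome
#'
#' Counts of analyzed and significant SNPs per chromosome, and the
#' proportion of significant SNPs per thousand analyzed (the per-mille
#' scale used when reporting hit densities along the genome).
#'
#' @param res `assoc_result` from [scan_snps()].
#' @return data.frame `chrom`, `n_analyzed`, `n_significant`, `per_mille`,
#'   plus a `Total` row.
#' @export
summarize_hits <- function(res) {
  stopifnot(inherits(res, "assoc_result") || is.data.frame(res))
  chroms <- unique(res$chrom)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    r <- res[res$chrom == ch, , drop = FALSE]
    data.frame(chrom = ch,
               n_analyzed = sum(r$tested),
               n_significant = sum(r$significant),
               stringsAsFactors = FALSE)
  }))
  out$per_mille <- ifelse(out$n_analyzed > 0,
                          1000 * out$n_significant / out$n_analyzed, 0)
  total <- data.frame(chrom = "Total",
                      n_analyzed = sum(out$n_analyzed),
                      n_significant = sum(out$n_significant),
                      per_mille = ifelse(sum(out$n_analyzed) > 0,
                                         1000 * sum(out$n_significant) /
                                           sum(out$n_analyzed), 0))
  rbind(out, total)
}

#' Genomic-control inflation factor
#'
#' lambda_GC: the median association chi-square statistic divided by its
#' null expectation, a standard check that the kinship/structure
#' correction has calibrated the test (values near 1 indicate no residual
#' stratification).
#'
#' @param p vector of p-values.
#' @return lambda_GC (scalar).
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values supplied")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}
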