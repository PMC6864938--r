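#' Genomic relationship matrix
#'
#' Standard allele-frequency-standardized GRM:
#' \deqn{K_{jk} = \frac{1}{m}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}
#'       {2p_i(1-p_i)},}
#' with allele frequencies p estimated from the sample. Missing genotypes
#' are skipped pairwise, each pair being averaged over its own marker count
#' m; those counts are recorded in the `n_markers` attribute. Monomorphic
#' SNPs (p = 0 or 1) are excluded with a warning. When missingness makes
#' the pairwise-complete estimate slightly indefinite, `ensure_psd = TRUE`
#' clamps negative eigenvalues to zero (a standard repair before REML).
#'
#' @param vt variant_table (typically after [filter_variants()]).
#' @param ensure_psd project the estimate onto the positive semidefinite
#'   cone by eigenvalue clamping (default `FALSE`; only ever triggered when
#'   missing data are present).
#' @return n x n symmetric kinship matrix with clone dimnames; attributes
#'   `n_markers` (per-pair SNP counts) and `m` (markers used).
#' @export
compute_grm <- function(vt, ensure_psd = FALSE) {
  stopifnot(inherits(vt, "variant_table"))
  g <- vt$geno
  p <- rowMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!all(poly))
    warning(sum(!poly), " monomorphic or all-missing SNP(s) excluded from the GRM")
  if (!any(poly)) stop("no polymorphic SNP available for the GRM")
  g <- g[poly, , drop = FALSE]
  p <- p[poly]

  z <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  obs <- !is.na(z)
  z[!obs] <- 0
  storage.mode(obs) <- "double"
  m_pair <- crossprod(obs)
  if (any(m_pair == 0))
    stop("some clone pairs share no genotyped SNP")
  K <- crossprod(z) / m_pair
  dimnames(K) <- list(colnames(g), colnames(g))

  if (ensure_psd && anyNA(vt$geno)) {
    e <- eigen(K, symmetric = TRUE)
    if (min(e$values) < 0) {
      K <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
      K <- (K + t(K)) / 2
      dimnames(K) <- list(colnames(g), colnames(g))
    }
  }
  attr(K, "n_markers") <- m_pair
  attr(K, "m") <- nrow(g)
  K
}

#' Principal coordinates of a kinship matrix
#'
#' Classical multidimensional scaling (principal coordinates analysis) of
#' the distance implied by a kinship matrix,
#' d^2_jk = K_jj + K_kk - 2 K_jk; the distance matrix is double-centered
#' and eigendecomposed by [stats::cmdscale()]. Axes are ordered by
#' decreasing eigenvalue and sign-fixed so that each axis's
#' largest-magnitude loading is positive, making the output deterministic.
#'
#' @param K symmetric kinship matrix, e.g. from [compute_grm()].
#' @param d number of axes requested (< n). Truncated with a warning when
#'   fewer positive eigenvalues exist.
#' @return list of class `structure_axes`: `axes` (n x d matrix, clones in
#'   rows) and `eig` (all eigenvalues of the double-centered matrix).
#' @export
classical_mds <- function(K, d = 5) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop("K must be a square matrix")
  n <- nrow(K)
  if (d >= n) stop("d must be smaller than the number of clones")
  dk <- diag(K)
  d2 <- outer(dk, dk, "+") - 2 * K
  D <- sqrt(pmax(d2, 0))
  fit <- suppressWarnings(cmdscale(as.dist(D), k = d, eig = TRUE))
  pts <- fit$points
  n_pos <- sum(fit$eig > max(fit$eig) * 1e-12)
  if (ncol(pts) < d || n_pos < d) {
    keep <- min(ncol(pts), max(1L, n_pos))
    warning("only ", keep, " axes with positive eigenvalues available; ",
            "truncating from ", d)
    pts <- pts[, seq_len(keep), drop = FALSE]
  }
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  rownames(pts) <- rownames(K)
  structure(list(axes = pts, eig = fit$eig), class = "structure_axes")
}

#' @export
print.structure_axes <- function(x, ...) {
  cat("structure_axes:", nrow(x$axes), "clones x", ncol(x$axes), "axes\n")
  ev <- x$eig[seq_len(ncol(x$axes))]
  cat("  eigenvalues:", paste(signif(ev, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Choose the number of structure covariates by BIC
#'
#' Regresses the clone means on the leading 0..`d_max` principal-coordinate
#' axes and returns the dimension minimizing BIC = -2 logLik + k log(n),
#' the criterion used to decide per trait whether (and how much of) the Q
#' matrix enters the association model. Ties resolve to the smaller
#' dimension; `d = 0` means no structure covariate.
#'
#' @param y numeric vector of clone means, aligned with the axes rows.
#' @param axes `structure_axes` or a numeric matrix of coordinates.
#' @param d_max maximum dimension tried (default 5, capped at the number of
#'   available axes).
#' @return list: `d` (chosen dimension), `bic` (named vector over 0..d_max).
#' @export
select_q_by_bic <- function(y, axes, d_max = 5) {
  A <- if (inherits(axes, "structure_axes")) axes$axes else as.matrix(axes)
  if (length(y) != nrow(A)) stop("y is not aligned with the axes")
  d_max <- min(d_max, ncol(A))
  if (d_max < 0) stop("d_max must be non-negative")
  bic <- setNames(numeric(d_max + 1), paste0("d", 0:d_max))
  for (d in 0:d_max) {
    df <- if (d == 0) data.frame(y = y)
          else data.frame(y = y, A[, seq_len(d), drop = FALSE])
    bic[d + 1] <- BIC(lm(y ~ ., data = df))
  }
  list(d = as.integer(which.min(bic) - 1L), bic = bic)
}

#' Write / read a kinship matrix as TSV
#'
#' @param K kinship matrix.
#' @param path file path.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_grm <- function(K, path) {
  df <- data.frame(clone_id = rownames(K), K, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  K
}
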