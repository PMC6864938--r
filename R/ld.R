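#' Pairwise LD (r-squared) within SNP-count windows
#'
#' Composite LD on unphased data: r2 is the squared Pearson correlation of
#' genotype dosages over pairwise-complete clones. Each SNP is paired with
#' the next `window_snps - 1` SNPs of its chromosome (default 120-SNP
#' windows), so pairs are always intrachromosomal and distance-limited in
#' marker count. Pairs involving a zero-variance SNP are skipped.
#'
#' @param vt variant_table with sorted positions.
#' @param window_snps window size in SNPs (default 120).
#' @return data.frame `chrom`, `pos1`, `pos2`, `dist` (bp, > 0), `r2`.
#' @export
pairwise_r2 <- function(vt, window_snps = 120) {
  stopifnot(inherits(vt, "variant_table"))
  if (window_snps < 2) stop("window_snps must be at least 2")
  res <- lapply(unique(vt$map$chrom), function(ch) {
    i_ch <- which(vt$map$chrom == ch)
    if (length(i_ch) < 2L) return(NULL)
    G <- t(vt$geno[i_ch, , drop = FALSE])  # clones x SNPs
    storage.mode(G) <- "double"
    pos <- vt$map$pos[i_ch]
    m <- ncol(G)
    out <- vector("list", m - 1L)
    for (i in seq_len(m - 1L)) {
      j <- seq.int(i + 1L, min(i + window_snps - 1L, m))
      r <- suppressWarnings(
        cor(G[, i], G[, j, drop = FALSE],
            use = "pairwise.complete.obs"))[1, ]
      ok <- !is.na(r)
      if (!any(ok)) next
      out[[i]] <- data.frame(chrom = ch, pos1 = pos[i], pos2 = pos[j][ok],
                             dist = pos[j][ok] - pos[i],
                             r2 = r[ok]^2, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos1 = integer(),
                      pos2 = integer(), dist = integer(), r2 = numeric())
  rownames(out) <- NULL
  out
}

#' Expected r-squared under the Hill-Weir drift-recombination model
#'
#' The sample-size-adjusted expectation used for nonlinear LD-decay
#' regression:
#' \deqn{E[r^2](d) = \frac{10 + C}{(2 + C)(11 + C)}
#'   \left(1 + \frac{(3 + C)(12 + 12C + C^2)}{n(2 + C)(11 + C)}\right),}
#' with C = beta d the population recombination parameter scaled to
#' physical distance d (bp) and n the number of genotyped individuals.
#'
#' @param d distance(s) in bp.
#' @param beta decay parameter (> 0), per bp.
#' @param n number of genotyped clones.
#' @return expected r2 values.
#' @export
hill_weir_r2 <- function(d, beta, n) {
  C <- beta * d
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD-decay curve
#'
#' Least-squares fit of [hill_weir_r2()] to observed pairwise r2 versus
#' physical distance, over beta > 0. The single parameter is found by a
#' bracketed golden-section/parabolic search on log beta (no starting
#' value needed); non-convergence against the bracket boundary is reported
#' as a warning, never silently defaulted.
#'
#' @param pairs data.frame from [pairwise_r2()] (columns `dist`, `r2`);
#'   raw pairs, not binned means.
#' @param n_samples number of genotyped clones behind the r2 estimates.
#' @return object of class `ld_decay_fit`: `beta`, `n`, `n_pairs`, `sse`,
#'   `curve` (vectorized evaluator), `converged`.
#' @export
fit_decay <- function(pairs, n_samples) {
  if (!all(c("dist", "r2") %in% names(pairs)))
    stop("pairs must have columns dist and r2")
  d <- as.numeric(pairs$dist)
  r2 <- as.numeric(pairs$r2)
  ok <- is.finite(d) & is.finite(r2) & d > 0
  d <- d[ok]; r2 <- r2[ok]
  if (length(d) < 2L) stop("at least two LD pairs are required")
  if (length(d) < 20L)
    warning("fewer than 20 LD pairs; the decay fit will be unstable")
  span <- diff(range(log10(d)))
  if (is.finite(span) && span < 2)
    warning("LD pairs span less than two distance decades; ",
            "the decay fit may be poorly constrained")

  sse <- function(log_beta)
    sum((r2 - hill_weir_r2(d, exp(log_beta), n_samples))^2)
  lo <- log(1e-9); hi <- log(1)
  opt <- optimize(sse, interval = c(lo, hi), tol = 1e-12)
  beta <- exp(opt$minimum)
  converged <- opt$minimum > lo + 1e-3 && opt$minimum < hi - 1e-3
  if (!converged)
    warning("decay fit ran against the search bracket (beta = ",
            signif(beta, 4), "); inspect the input pairs")
  structure(list(beta = beta, n = n_samples, n_pairs = length(d),
                 sse = opt$objective,
                 curve = function(x) hill_weir_r2(x, beta, n_samples),
                 converged = converged),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("Hill-Weir LD-decay fit: beta = %.4g /bp (n = %d, %d pairs)\n",
              x$beta, x$n, x$n_pairs))
  d02 <- distance_at_r2(x, 0.2)
  if (is.na(d02)) cat("  r2 = 0.2 not reached on [1, 1e7] bp\n")
  else cat(sprintf("  r2 decays below 0.2 at %.1f kbp\n", d02 / 1000))
  invisible(x)
}

#' Distance at which the fitted LD curve reaches a level
#'
#' Root of curve(d) - level by bisection on \[1, 1e7\] bp to 1 bp
#' tolerance. The fitted curve is monotone decreasing, so the root is
#' unique; `NA` (with a message) is returned when the curve never crosses
#' the level on the bracket.
#'
#' @param fit `ld_decay_fit`.
#' @param level target r2 (default 0.2).
#' @param lower,upper search bracket in bp.
#' @return distance in bp, or `NA` when the level is not reached.
#' @export
distance_at_r2 <- function(fit, level = 0.2, lower = 1, upper = 1e7) {
  stopifnot(inherits(fit, "ld_decay_fit"))
  f <- function(x) fit$curve(x) - level
  if (f(lower) < 0 || f(upper) > 0) {
    message("r2 = ", level, " is not reached on [", lower, ", ", upper, "] bp")
    return(NA_real_)
  }
  uniroot(f, c(lower, upper), tol = 0.5)$root
}

#' Per-chromosome LD and marker-density summary
#'
#' Builds the genome summary table: chromosome size, analyzed SNP count,
#' marker spacing (bp/SNP = size / count) and LD-decay distance, with a
#' `Total` row (sums) and a `Mean` row holding the arithmetic mean of the
#' per-chromosome spacing and decay values (the convention of published
#' panel summaries, where the mean spacing is not total size over total
#' SNPs).
#'
#' @param df data.frame with columns `chrom`, `size_bp` (or `size_mbp`),
#'   `n_snps`, optional precomputed `bp_per_snp`, and optional
#'   `ld_decay_kbp`.
#' @return data.frame with per-chromosome rows plus `Total` and `Mean`.
#' @export
ld_summary_table <- function(df) {
  if (!"size_bp" %in% names(df)) {
    if (!"size_mbp" %in% names(df))
      stop("df needs a size_bp or size_mbp column")
    df$size_bp <- df$size_mbp * 1e6
  }
  if (!all(c("chrom", "n_snps") %in% names(df)))
    stop("df needs chrom and n_snps columns")
  if (!"bp_per_snp" %in% names(df))
    df$bp_per_snp <- df$size_bp / df$n_snps
  has_decay <- "ld_decay_kbp" %in% names(df)
  base <- data.frame(chrom = as.character(df$chrom),
                     size_mbp = df$size_bp / 1e6,
                     n_snps = df$n_snps,
                     bp_per_snp = df$bp_per_snp,
                     stringsAsFactors = FALSE)
  if (has_decay) base$ld_decay_kbp <- df$ld_decay_kbp
  total <- data.frame(chrom = "Total", size_mbp = sum(base$size_mbp),
                      n_snps = sum(base$n_snps), bp_per_snp = NA_real_,
                      stringsAsFactors = FALSE)
  mean_row <- data.frame(chrom = "Mean", size_mbp = NA_real_,
                         n_snps = NA_real_,
                         bp_per_snp = mean(base$bp_per_snp),
                         stringsAsFactors = FALSE)
  if (has_decay) {
    total$ld_decay_kbp <- NA_real_
    mean_row$ld_decay_kbp <- mean(base$ld_decay_kbp, na.rm = TRUE)
  }
  rbind(base, total, mean_row)
}

#' Genome-wide LD-decay analysis of a variant table
#'
#' Convenience wrapper: per-chromosome [pairwise_r2()], [fit_decay()] and
#' [distance_at_r2()], assembled with [ld_summary_table()].
#'
#' @param vt variant_table.
#' @param chrom_sizes named lengths in bp (defaults to max position).
#' @param window_snps LD window in SNPs.
#' @param level target r2 for the decay distance.
#' @return list: `summary` (table with Total/Mean rows), `fits` (named
#'   list of `ld_decay_fit`), `pairs` (all LD pairs).
#' @export
ld_decay_analysis <- function(vt, chrom_sizes = NULL, window_snps = 120,
                              level = 0.2) {
  stopifnot(inherits(vt, "variant_table"))
  if (is.null(chrom_sizes)) chrom_sizes <- chrom_lengths(vt)
  n <- ncol(vt$geno)
  pairs <- pairwise_r2(vt, window_snps)
  chroms <- unique(vt$map$chrom)
  fits <- list()
  decay <- setNames(rep(NA_real_, length(chroms)), chroms)
  for (ch in chroms) {
    pc <- pairs[pairs$chrom == ch, , drop = FALSE]
    if (nrow(pc) < 2L) next
    fit <- fit_decay(pc, n)
    fits[[ch]] <- fit
    dd <- suppressMessages(distance_at_r2(fit, level))
    decay[ch] <- dd / 1000
  }
  df <- data.frame(chrom = chroms,
                   size_bp = as.numeric(chrom_sizes[chroms]),
                   n_snps = as.integer(table(vt$map$chrom)[chroms]),
                   ld_decay_kbp = as.numeric(decay),
                   stringsAsFactors = FALSE)
  list(summary = ld_summary_table(df), fits = fits, pairs = pairs)
}
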