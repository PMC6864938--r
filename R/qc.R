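#' Exact test for Hardy-Weinberg equilibrium
#'
#' Exact conditional test on a biallelic genotype table. Conditional on the
#' observed allele counts, the heterozygote count under HWE follows
#' \deqn{P(n_{Aa} = h) = \frac{n!\,2^h}{n_{AA}!\,h!\,n_{aa}!}
#'       \binom{2n}{m}^{-1},}
#' where m is the minor-allele count. The p-value sums the probabilities of
#' all heterozygote counts whose probability does not exceed that of the
#' observed table (two-sided, probability ordering). Probabilities are
#' accumulated through the log-scale recurrence
#' P(h+2)/P(h) = 4 n_AA(h) n_aa(h) / ((h+1)(h+2)), so the routine is stable
#' for large samples.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote). Scalars.
#' @return p-value in (0, 1]. Monomorphic tables give exactly 1.
#' @examples
#' hwe_exact_test(20, 0, 0)   # monomorphic -> 1
#' hwe_exact_test(0, 2, 0)
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (length(counts) != 3L || any(is.na(counts)))
    stop("n_AA, n_Aa, n_aa must be non-missing scalars")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype is required")
  m <- min(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)  # minor-allele copies
  if (m == 0L) return(1)

  h <- seq.int(m %% 2L, m, by = 2L)             # admissible het counts
  lp <- numeric(length(h))
  for (i in seq_along(h)[-1L]) {
    hh <- h[i - 1L]
    rare_hom <- (m - hh) / 2
    common_hom <- n - hh - rare_hom
    lp[i] <- lp[i - 1L] +
      log(4 * rare_hom * common_hom) - log((hh + 1) * (hh + 2))
  }
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  obs <- pr[match(n_Aa, h)]
  if (is.na(obs)) stop("observed heterozygote count is inconsistent with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Per-SNP variant statistics
#'
#' Minor allele frequency, missing rate, genotype counts and the exact HWE
#' p-value for every SNP of a [variant_table()]. MAF and HWE are computed
#' on non-missing calls; the missing rate is relative to the full clone
#' panel. SNPs with no non-missing call are flagged `undefined` and carry
#' `NA` statistics rather than raising an error.
#'
#' @param vt variant_table.
#' @return data.frame with one row per SNP: `snp_id`, `n_AA`, `n_Aa`,
#'   `n_aa`, `n_called`, `maf`, `missing_rate`, `hwe_p`, `undefined`.
#' @export
variant_stats <- function(vt) {
  stopifnot(inherits(vt, "variant_table"))
  g <- vt$geno
  n_clones <- ncol(g)
  n_AA <- rowSums(g == 0L, na.rm = TRUE)
  n_Aa <- rowSums(g == 1L, na.rm = TRUE)
  n_aa <- rowSums(g == 2L, na.rm = TRUE)
  n_called <- n_AA + n_Aa + n_aa
  alt <- n_Aa + 2L * n_aa
  p_alt <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  missing_rate <- 1 - n_called / n_clones
  hwe_p <- rep(NA_real_, nrow(g))
  defined <- n_called > 0
  hwe_p[defined] <- vapply(which(defined), function(i)
    hwe_exact_test(n_AA[i], n_Aa[i], n_aa[i]), numeric(1))
  data.frame(snp_id = vt$map$snp_id,
             n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa, n_called = n_called,
             maf = maf, missing_rate = missing_rate, hwe_p = hwe_p,
             undefined = !defined,
             stringsAsFactors = FALSE)
}

#' Filter variants on MAF, missingness and HWE
#'
#' Applies the panel's post-calling filters: retain SNPs with minor allele
#' frequency at least `maf_min`, missing rate at most `miss_max` and
#' exact-HWE p-value at least `hwe_alpha`. The three criteria are evaluated jointly on the input
#' table; a removed SNP is attributed to its first failing rule in the
#' fixed order MAF, missingness, HWE. All-missing SNPs count as missingness
#' failures.
#'
#' @param vt variant_table.
#' @param stats optional precomputed [variant_stats()] table aligned with
#'   `vt`; recomputed when omitted.
#' @param maf_min,miss_max thresholds in \[0, 1\] (defaults 0.05 each:
#'   MAF below 5 percent, or missing in over 5 percent of clones, removed).
#' @param hwe_alpha HWE significance cutoff in \[0, 1\] (default 1e-6,
#'   common GWAS practice; 0 disables the filter).
#' @return list with elements `variants` (filtered variant_table) and
#'   `report` (class `filter_report`: input/kept counts and removals per
#'   criterion).
#' @export
filter_variants <- function(vt, stats = NULL, maf_min = 0.05,
                            miss_max = 0.05, hwe_alpha = 1e-6) {
  stopifnot(inherits(vt, "variant_table"))
  for (thr in c(maf_min, miss_max, hwe_alpha))
    if (!is.finite(thr) || thr < 0 || thr > 1)
      stop("filter thresholds must lie in [0, 1]")
  if (is.null(stats)) stats <- variant_stats(vt)
  if (nrow(stats) != nrow(vt$map) || !all(stats$snp_id == vt$map$snp_id))
    stop("stats are not aligned with the variant table")

  fail_maf <- !stats$undefined & stats$maf < maf_min
  fail_miss <- stats$undefined | stats$missing_rate > miss_max
  fail_hwe <- !stats$undefined & stats$hwe_p < hwe_alpha
  # attribution by first failing rule: MAF -> missingness -> HWE
  removed_maf <- fail_maf
  removed_miss <- fail_miss & !removed_maf
  removed_hwe <- fail_hwe & !removed_maf & !removed_miss
  keep <- !(removed_maf | removed_miss | removed_hwe)
  if (!any(keep)) stop("no SNP survives the filters")

  report <- structure(list(
    n_input = nrow(stats),
    n_removed_maf = sum(removed_maf),
    n_removed_missing = sum(removed_miss),
    n_removed_hwe = sum(removed_hwe),
    n_kept = sum(keep),
    maf_min = maf_min, miss_max = miss_max, hwe_alpha = hwe_alpha,
    removed = data.frame(
      snp_id = stats$snp_id[!keep],
      reason = c("maf", "missing", "hwe")[
        max.col(cbind(removed_maf, removed_miss, removed_hwe)[!keep, ,
                                                              drop = FALSE])],
      stringsAsFactors = FALSE)
  ), class = "filter_report")
  list(variants = subset_variants(vt, keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("variant filter report\n")
  cat(sprintf("  input SNPs:        %d\n", x$n_input))
  cat(sprintf("  removed (MAF < %g):        %d\n", x$maf_min, x$n_removed_maf))
  cat(sprintf("  removed (missing > %g):    %d\n", x$miss_max,
              x$n_removed_missing))
  cat(sprintf("  removed (HWE p < %g):      %d\n", x$hwe_alpha,
              x$n_removed_hwe))
  cat(sprintf("  kept:              %d\n", x$n_kept))
  invisible(x)
}

#' Write a filter report as TSV
#'
#' @param report filter_report from [filter_variants()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  summary_df <- data.frame(
    metric = c("n_input", "n_removed_maf", "n_removed_missing",
               "n_removed_hwe", "n_kept"),
    value = c(report$n_input, report$n_removed_maf, report$n_removed_missing,
              report$n_removed_hwe, report$n_kept))
  write.table(summary_df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
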