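#' Manhattan plot of an association or window scan
#'
#' -log10 p against cumulative genome position, chromosomes alternately
#' shaded, with the Bonferroni threshold drawn as a horizontal line.
#' Accepts either a single-SNP [scan_snps()] result (column `p`, positions
#' `pos`) or a [scan_windows()] result (column `p_value`, positions taken
#' at window midpoints).
#'
#' @param x `assoc_result` or `window_result`.
#' @param threshold significance threshold for the reference line;
#'   defaults to the object's Bonferroni attribute.
#' @param main plot title.
#' @return invisibly, the plotted data.frame.
#' @export
manhattan_plot <- function(x, threshold = NULL, main = "") {
  if ("p_value" %in% names(x)) {
    p <- x$p_value
    pos <- (x$start + x$end) / 2
  } else {
    p <- x$p
    pos <- x$pos
  }
  chrom <- factor(x$chrom, levels = unique(x$chrom))
  if (is.null(threshold)) threshold <- attr(x, "threshold")
  offsets <- c(0, cumsum(tapply(pos, chrom, max)))
  gx <- pos + offsets[as.integer(chrom)]
  col <- c("grey25", "steelblue")[1 + as.integer(chrom) %% 2]
  plot(gx, -log10(p), pch = 20, cex = 0.5, col = col,
       xlab = "genome position", ylab = expression(-log[10](italic(p))),
       main = main, xaxt = "n")
  mids <- tapply(gx, chrom, median)
  axis(1, at = mids, labels = levels(chrom), las = 2, cex.axis = 0.7)
  if (!is.null(threshold) && is.finite(threshold))
    abline(h = -log10(threshold), col = "red", lty = 2)
  invisible(data.frame(x = gx, neglog10p = -log10(p)))
}

#' LD-decay plot for one chromosome
#'
#' Pairwise r2 binned at `bin_bp` (plotting only; fitting always uses raw
#' pairs) with the fitted Hill-Weir curve overlaid and the target level
#' marked.
#'
#' @param pairs LD pairs from [pairwise_r2()] (one chromosome).
#' @param fit optional `ld_decay_fit` to overlay.
#' @param level reference r2 level (default 0.2).
#' @param bin_bp bin width for the plotted means (default 100).
#' @param main plot title.
#' @return invisibly, the binned means.
#' @export
ld_decay_plot <- function(pairs, fit = NULL, level = 0.2, bin_bp = 100,
                          main = "") {
  bin <- (pairs$dist - 1) %/% bin_bp
  mids <- (unique(bin) + 0.5) * bin_bp
  means <- tapply(pairs$r2, bin, mean)
  plot(sort(unique(bin) + 0.5) * bin_bp, means[order(unique(bin))],
       pch = 20, cex = 0.6, col = "grey40",
       xlab = "distance (bp)", ylab = expression(r^2), ylim = c(0, 1),
       main = main)
  if (!is.null(fit)) {
    xs <- seq(min(pairs$dist), max(pairs$dist), length.out = 400)
    lines(xs, fit$curve(xs), col = "red", lwd = 2)
  }
  abline(h = level, col = "blue", lty = 2)
  invisible(data.frame(dist = mids, r2 = as.numeric(means)))
}
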