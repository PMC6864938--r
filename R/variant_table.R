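#' Construct a variant table
#'
#' The package's genotype container: a SNP map (chromosome, 1-based
#' position, REF/ALT alleles) plus an integer dosage matrix with SNPs in
#' rows and clones in columns. Dosages count copies of the ALT allele
#' (0/1/2, VCF GT semantics); missing calls are `NA`.
#'
#' @param map data.frame with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`. Positions must be strictly increasing within each chromosome
#'   and all sites biallelic (single REF and ALT base).
#' @param geno integer matrix, `nrow(map)` x n_clones, entries in
#'   \{0, 1, 2, NA\}. Column names identify clones.
#' @return An object of class `variant_table`: a list with elements `map`
#'   and `geno`.
#' @examples
#' map <- data.frame(snp_id = c("S1_10", "S1_20"), chrom = "Chr01",
#'                   pos = c(10L, 20L), ref = "A", alt = "G")
#' g <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(map$snp_id, c("c1", "c2")))
#' vt <- variant_table(map, g)
#' @export
variant_table <- function(map, geno) {
  required <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(required %in% names(map)))
    stop("map must have columns: ", paste(required, collapse = ", "))
  if (nrow(map) != nrow(geno))
    stop("map and geno disagree on the number of SNPs")
  if (nrow(map) == 0L) stop("variant table must contain at least one SNP")
  if (ncol(geno) == 0L) stop("variant table must contain at least one clone")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  bad <- nchar(map$ref) != 1L | nchar(map$alt) != 1L | map$ref == map$alt
  if (any(bad))
    stop("only biallelic SNPs with single-base REF/ALT are supported (",
         sum(bad), " offending sites)")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  storage.mode(geno) <- "integer"
  rownames(geno) <- map$snp_id
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("clone", seq_len(ncol(geno)))
  structure(list(map = as.data.frame(map, stringsAsFactors = FALSE),
                 geno = geno),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$map), "SNPs x", ncol(x$geno), "clones on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing rate: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.variant_table <- function(x) dim(x$geno)

#' Subset a variant table by SNP
#'
#' @param vt variant_table.
#' @param i logical or integer index over SNPs (rows).
#' @return variant_table restricted to the selected SNPs.
#' @export
subset_variants <- function(vt, i) {
  stopifnot(inherits(vt, "variant_table"))
  map <- vt$map[i, , drop = FALSE]
  rownames(map) <- NULL
  if (nrow(map) == 0L) stop("subset would leave zero SNPs")
  structure(list(map = map, geno = vt$geno[i, , drop = FALSE]),
            class = "variant_table")
}

#' Per-chromosome lengths implied by a variant table
#'
#' Falls back to the largest observed position when true chromosome sizes
#' are not supplied.
#' @param vt variant_table.
#' @return named numeric vector of lengths (bp).
#' @export
chrom_lengths <- function(vt) {
  stopifnot(inherits(vt, "variant_table"))
  tapply(vt$map$pos, vt$map$chrom, max)[unique(vt$map$chrom)]
}
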