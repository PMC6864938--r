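#' Write genotypes as VCFv4.2
#'
#' Minimal sites + GT VCF: one record per biallelic SNP, genotypes 0/0,
#' 0/1, 1/1 or ./. per clone. Contig headers are emitted when lengths are
#' supplied.
#'
#' @param vt variant_table.
#' @param path output file (plain text `.vcf`).
#' @param contig_lengths optional named vector of chromosome lengths for
#'   `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(vt, path, contig_lengths = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  header <- c("##fileformat=VCFv4.2",
              "##source=clonegwas",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths))
    header <- c(header,
                sprintf("##contig=<ID=%s,length=%d>",
                        names(contig_lengths),
                        as.integer(contig_lengths)))
  header <- c(header,
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(vt$geno)), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(vt$geno), ncol(vt$geno))
  ok <- !is.na(vt$geno)
  gt[ok] <- gt_code[vt$geno[ok] + 1L]
  body <- paste(vt$map$chrom, vt$map$pos, vt$map$snp_id, vt$map$ref,
                vt$map$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses a VCF through `vcfR` and extracts ALT-allele dosages from the GT
#' field (phased separators are treated like unphased ones; half-missing
#' calls are missing). Multi-allelic records and non-SNP alleles are
#' rejected at load with a warning, matching the biallelic-SNP scope of
#' the analysis.
#'
#' @param path VCF file (optionally bgzipped).
#' @return variant_table.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi)) {
    warning(sum(multi), " multi-allelic or non-SNP record(s) dropped at load")
    if (all(multi)) stop("no biallelic SNP left after dropping records")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dosage <- matrix(unname(code[gt]), nrow(gt), ncol(gt))
  colnames(dosage) <- colnames(gt)
  keep <- !multi
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- sprintf("%s_%s", fix$CHROM[noid], fix$POS[noid])
  map <- data.frame(snp_id = ids[keep], chrom = fix$CHROM[keep],
                    pos = as.integer(fix$POS[keep]),
                    ref = fix$REF[keep], alt = fix$ALT[keep],
                    stringsAsFactors = FALSE)
  variant_table(map, dosage[keep, , drop = FALSE])
}

#' Write / read ramet-level phenotypes as TSV
#'
#' One row per ramet with columns `clone_id`, `block`, `trait`, `value`.
#'
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @return `path` (writer) / the data.frame (reader).
#' @export
write_phenotypes <- function(pheno, path) {
  need <- c("clone_id", "block", "trait", "value")
  if (!all(need %in% names(pheno)))
    stop("phenotype frame must have columns: ", paste(need, collapse = ", "))
  write.table(pheno[need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(clone_id = "character",
                                  block = "character",
                                  trait = "character",
                                  value = "numeric"))
  df
}

#' Write / read gene models as GFF3
#'
#' Writer emits one `gene` feature per row; reader accepts any GFF3 and
#' keeps `gene` features (all features when none is typed `gene`), via
#' `rtracklayer`.
#'
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`, optional
#'   `strand`.
#' @param path file path.
#' @return `path` (writer) / gene data.frame (reader).
#' @export
write_gene_models_gff3 <- function(genes, path) {
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(genes)))
    stop("genes must have columns gene_id, chrom, start, end")
  strand <- if ("strand" %in% names(genes)) genes$strand else "+"
  lines <- paste(genes$chrom, "clonegwas", "gene", genes$start, genes$end,
                 ".", strand, ".",
                 sprintf("ID=%s;Name=%s", genes$gene_id, genes$gene_id),
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
read_gene_models <- function(path) {
  gff <- as.data.frame(rtracklayer::readGFF(path))
  if ("type" %in% names(gff) && any(gff$type == "gene"))
    gff <- gff[gff$type == "gene", , drop = FALSE]
  id <- if ("ID" %in% names(gff)) as.character(gff$ID)
        else sprintf("gene%d", seq_len(nrow(gff)))
  out <- data.frame(gene_id = id,
                    chrom = as.character(gff$seqid),
                    start = as.integer(gff$start),
                    end = as.integer(gff$end),
                    strand = as.character(gff$strand),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a simulation truth record as JSON
#'
#' @param truth truth list from [simulate_genotypes()] /
#'   [simulate_phenotypes()].
#' @param path file path.
#' @return `path` (writer) / truth list (reader).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(truth$subpop)) truth$subpop <- unlist(truth$subpop)
  truth
}

#' Write adjusted clone means as TSV
#'
#' @param means data.frame from [blup_clone_means()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_clone_means <- function(means, path) {
  df <- means
  df$trait <- attr(means, "trait") %||% NA_character_
  write.table(df[c("clone_id", "trait", "blup", "adjusted_mean")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
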