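#' Reference per-chromosome summary for the P. trichocarpa panel
#'
#' Published per-chromosome summary of the 461-clone *Populus trichocarpa*
#' association panel this package is modelled on: chromosome size (Mbp),
#' number of analyzed SNPs after filtering (813,280 genome-wide), marker
#' spacing (bp/SNP) and the distance at which intrachromosomal LD decays
#' below r-squared 0.2 (kbp). Used as the default chromosome scaffold of
#' the simulator and by [ld_summary_table()] consumers as a comparison
#' point.
#'
#' @return data.frame with columns `chrom`, `size_mbp`, `n_snps`,
#'   `bp_per_snp`, `ld_decay_kbp` (19 rows, one per chromosome).
#' @export
ref_chromosome_summary <- function() {
  read.delim(system.file("extdata", "reference_chromosome_summary.tsv",
                         package = "clonegwas"),
             stringsAsFactors = FALSE)
}

#' Reference trait summary for the P. trichocarpa panel
#'
#' Published trait summaries (mean, standard deviation, coefficient of
#' variation, individual broad-sense heritability) for the growth,
#' phenology, ecophysiology and wood-chemistry traits measured on the
#' association panel.
#'
#' @return data.frame with columns `trait`, `unit`, `mean`, `sd`,
#'   `cv_pct`, `H2`.
#' @export
ref_trait_summary <- function() {
  read.delim(system.file("extdata", "reference_trait_summary.tsv",
                         package = "clonegwas"),
             stringsAsFactors = FALSE)
}
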