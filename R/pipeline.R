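#' Default pipeline configuration
#'
#' Nested configuration consumed by [run_pipeline()], either built in R or
#' loaded from YAML ([read_pipeline_config()]). Thresholds default to the
#' panel's analysis settings: MAF 0.05, missingness 0.05, alpha 0.05,
#' 10 kb windows with 1 kb slide, 120-SNP LD windows and a 1e-5
#' window-input threshold.
#'
#' @param ... overrides, as `name = value` pairs of top-level keys
#'   (`simulate` may be a `sim_config` or a list of [sim_config()]
#'   arguments; `input` may name `vcf`, `pheno`, `gff3` files instead).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(),
    input = NULL,            # list(vcf=, pheno=, gff3=) to skip simulation
    trait = NULL,
    transform = "none",
    outlier_sd = 4,
    qc = list(maf_min = 0.05, miss_max = 0.05, hwe_alpha = 1e-6),
    structure = list(d_max = 5, use_bic = TRUE),
    scan = list(alpha = 0.05),
    windows = list(window_bp = 10000, slide_bp = 1000, input_p = 1e-5,
                   alpha = 0.05),
    ld = list(window_snps = 120, level = 0.2)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys as in [pipeline_config()].
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.pipeline_stages <- c("simulate", "qc", "pheno", "structure", "scan",
                      "windows", "ld")

#' Run the association pipeline
#'
#' Executes simulate (or load) -> QC -> phenotype prep -> structure ->
#' single-SNP scan -> sliding windows -> LD decay in dependency order,
#' writing every stage's outputs to `outdir` and a `manifest.tsv` of file
#' MD5 hashes. Re-running an identical configuration reproduces identical
#' hashes; no stage mutates its inputs. A stage failure halts the run with
#' the stage name in the error.
#'
#' @param config `pipeline_config` (or list of overrides).
#' @param outdir output directory.
#' @param stages subset of stages to run (dependencies of later stages
#'   must already have run in this call; default all).
#' @return invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = .pipeline_stages) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  res <- list()
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(path) written <<- c(written, path)

  # --- inputs: simulation or files -------------------------------------
  scfg <- NULL
  if (is.null(config$input)) {
    scfg <- if (inherits(config$simulate, "sim_config")) config$simulate
            else do.call(sim_config, c(config$simulate,
                                       list(seed = config$seed)))
    sim <- stage("simulate", {
      s <- simulate_genotypes(scfg)
      p <- simulate_phenotypes(s$variants, s$truth, scfg)
      list(variants = s$variants, truth = p$truth,
           phenotypes = p$phenotypes, genes = toy_gene_models(scfg))
    })
    if ("simulate" %in% stages) {
      f <- file.path(outdir, "genotypes.vcf")
      write_genotypes_vcf(sim$variants, f,
                          setNames(scfg$chromosomes$length_bp,
                                   scfg$chromosomes$name))
      emit(f)
      f <- file.path(outdir, "phenotypes.tsv")
      write_phenotypes(sim$phenotypes, f); emit(f)
      f <- file.path(outdir, "genes.gff3")
      write_gene_models_gff3(sim$genes, f); emit(f)
      f <- file.path(outdir, "truth.json")
      write_truth_json(sim$truth, f); emit(f)
    }
    vt <- sim$variants; pheno <- sim$phenotypes; genes <- sim$genes
    lengths <- setNames(scfg$chromosomes$length_bp, scfg$chromosomes$name)
    res$simulate <- sim
  } else {
    vt <- stage("load", read_genotypes_vcf(config$input$vcf))
    pheno <- stage("load", read_phenotypes(config$input$pheno))
    genes <- if (!is.null(config$input$gff3))
      stage("load", read_gene_models(config$input$gff3)) else NULL
    lengths <- chrom_lengths(vt)
  }

  # --- qc ---------------------------------------------------------------
  if (any(c("qc", "structure", "scan", "windows", "ld") %in% stages)) {
    qc <- stage("qc", filter_variants(vt,
                                      maf_min = config$qc$maf_min,
                                      miss_max = config$qc$miss_max,
                                      hwe_alpha = config$qc$hwe_alpha))
    message(sprintf("[qc] %d -> %d SNPs (maf %d, missing %d, hwe %d removed)",
                    qc$report$n_input, qc$report$n_kept,
                    qc$report$n_removed_maf, qc$report$n_removed_missing,
                    qc$report$n_removed_hwe))
    if ("qc" %in% stages) {
      f <- file.path(outdir, "filter_report.tsv")
      write_filter_report(qc$report, f); emit(f)
      f <- file.path(outdir, "genotypes_filtered.vcf")
      write_genotypes_vcf(qc$variants, f, lengths); emit(f)
    }
    vtf <- qc$variants
    res$qc <- qc$report
  }

  # --- phenotype prep ---------------------------------------------------
  if (any(c("pheno", "structure", "scan", "windows") %in% stages)) {
    means <- stage("pheno", {
      trait <- config$trait %||% unique(pheno$trait)[1]
      d <- pheno[pheno$trait == trait, , drop = FALSE]
      d$value <- transform_trait(d$value, config$transform, config$outlier_sd)
      blup_clone_means(d, trait)
    })
    if ("pheno" %in% stages) {
      f <- file.path(outdir, "clone_means.tsv")
      write_clone_means(means, f); emit(f)
    }
    res$pheno <- means
  }

  # --- structure --------------------------------------------------------
  if (any(c("structure", "scan", "windows") %in% stages)) {
    struct <- stage("structure", {
      K <- compute_grm(vtf, ensure_psd = TRUE)
      mds <- classical_mds(K, d = config$structure$d_max)
      y <- means$adjusted_mean[match(colnames(vtf$geno), means$clone_id)]
      if (anyNA(y)) stop("clones missing from the phenotype table")
      dq <- if (config$structure$use_bic)
        select_q_by_bic(y, mds, config$structure$d_max)$d
      else config$structure$d_max
      list(K = K, mds = mds, d = dq, y = y)
    })
    message(sprintf("[structure] %d MDS axes retained by BIC", struct$d))
    if ("structure" %in% stages) {
      f <- file.path(outdir, "kinship.tsv")
      write_grm(struct$K, f); emit(f)
      ax <- data.frame(clone_id = rownames(struct$mds$axes),
                       struct$mds$axes, check.names = FALSE)
      f <- file.path(outdir, "structure_axes.tsv")
      write.table(ax, f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(f)
    }
    res$structure <- struct[c("d")]
  }

  # --- single-SNP scan --------------------------------------------------
  if (any(c("scan", "windows") %in% stages)) {
    assoc <- stage("scan", {
      Q <- if (struct$d > 0)
        struct$mds$axes[, seq_len(struct$d), drop = FALSE] else NULL
      scan_snps(struct$y, vtf, K = struct$K, Q = Q,
                alpha = config$scan$alpha)
    })
    message(sprintf("[scan] %d SNPs tested, %d significant (threshold %.3g)",
                    sum(assoc$tested), sum(assoc$significant),
                    attr(assoc, "threshold")))
    if ("scan" %in% stages) {
      f <- file.path(outdir, "associations.tsv")
      write.table(assoc, f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(f)
      f <- file.path(outdir, "association_summary.tsv")
      write.table(summarize_hits(assoc), f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit(f)
    }
    res$scan <- assoc
  }

  # --- sliding windows --------------------------------------------------
  if ("windows" %in% stages) {
    win <- stage("windows", {
      w <- scan_windows(assoc, lengths,
                        window_bp = config$windows$window_bp,
                        slide_bp = config$windows$slide_bp,
                        input_p = config$windows$input_p)
      call_significant_windows(w, config$windows$alpha)
    })
    message(sprintf("[windows] %d tested, %d significant",
                    nrow(win), sum(win$significant)))
    f <- file.path(outdir, "windows.tsv")
    write.table(win, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(f)
    f <- file.path(outdir, "windows.bed")
    write_windows_bed(win, f); emit(f)
    if (!is.null(genes) && any(win$significant)) {
      ov <- windows_to_genes(win[win$significant, , drop = FALSE], genes)
      f <- file.path(outdir, "window_genes.tsv")
      write.table(ov, f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(f)
    }
    res$windows <- win
  }

  # --- LD decay ---------------------------------------------------------
  if ("ld" %in% stages) {
    ld <- stage("ld", ld_decay_analysis(vtf, lengths,
                                        window_snps = config$ld$window_snps,
                                        level = config$ld$level))
    f <- file.path(outdir, "ld_pairs.tsv")
    write.table(ld$pairs, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(f)
    f <- file.path(outdir, "ld_summary.tsv")
    write.table(ld$summary, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(f)
    res$ld <- ld
  }

  # --- manifest ---------------------------------------------------------
  written <- sort(unique(written))
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  res$manifest <- manifest
  invisible(res)
}
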