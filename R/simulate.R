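#' Simulation configuration for a clonal association trial
#'
#' Defines the genotype and phenotype generative model used as the
#' package's ground-truth test bed. Genotypes are built from founder
#' haplotypes inside LD blocks: each subpopulation carries `n_founders`
#' founder haplotypes per chromosome whose alleles are drawn from
#' Balding-Nichols-perturbed ancestral frequencies; every sampled
#' haplotype copies one founder within a block, switches founders between
#' adjacent blocks with probability `recomb_between_blocks`, and mutates
#' individual alleles back to a fresh frequency draw with probability
#' `mutation_rate`. This yields r2 that decays geometrically with the
#' number of block boundaries crossed, i.e. with physical distance.
#' Phenotypes follow the clonal randomized block design: one ramet per
#' clone per block, additive QTL plus a clone-level polygenic deviate,
#' fixed block shifts and (optionally clone-correlated) residuals.
#'
#' Defaults emulate the *P. trichocarpa* association panel the package is
#' modelled on: 461 clones in 3 blocks, the 19 real chromosome sizes (from
#' [ref_chromosome_summary()]), mild structure across 3 subpopulations and
#' block-LD parameters chosen so genome-wide r2 falls below 0.2 on the
#' order of 25 kbp. Marker density defaults to 2000 SNPs per chromosome, a
#' desk-scale thinning of the panel's density.
#'
#' @param n_clones number of clones (diploid, unrelated beyond
#'   subpopulation sharing).
#' @param n_blocks field blocks; one ramet per clone per block (default 3).
#' @param chromosomes data.frame with columns `name`, `length_bp`.
#' @param n_snps_per_chrom markers simulated per chromosome.
#' @param n_subpops number of subpopulations.
#' @param fst_like_divergence Balding-Nichols divergence in \[0, 1).
#' @param ld_block_len LD-block length in bp.
#' @param recomb_between_blocks founder-switch probability between
#'   adjacent blocks in \[0, 1\]; with `n_founders = 2`, 0.5 makes blocks
#'   independent.
#' @param n_founders founder haplotypes per subpopulation and chromosome
#'   (2 gives complete within-block LD; the default 3, with the default
#'   mutation and switch rates, reproduces a genome-wide r2 decay to 0.2
#'   near 26 kbp).
#' @param mutation_rate per-SNP, per-haplotype probability of replacing
#'   the copied founder allele with a fresh frequency draw.
#' @param missing_rate genotype missingness injected uniformly.
#' @param qtl data.frame with columns `chrom`, `pos`, `effect` (allelic
#'   effect in trait-SD units); each QTL snaps to the nearest simulated
#'   SNP. `NULL` for none.
#' @param h2_additive target narrow-sense heritability of the additive
#'   genetic part (QTL + polygenic), in \[0, 1).
#' @param block_effects fixed block shifts in trait-SD units (length
#'   `n_blocks`).
#' @param resid_cov covariance between residuals of the same clone in two
#'   blocks (0 <= resid_cov < sigma2_e); exposed as a parameter because
#'   trial-specific values are rarely reported.
#' @param trait_name phenotype column label.
#' @param seed integer seed; identical configurations reproduce
#'   bit-identical outputs.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 461,
                       n_blocks = 3,
                       chromosomes = NULL,
                       n_snps_per_chrom = 2000,
                       n_subpops = 3,
                       fst_like_divergence = 0.05,
                       ld_block_len = 25000,
                       recomb_between_blocks = 0.12,
                       n_founders = 3,
                       mutation_rate = 0.03,
                       missing_rate = 0.02,
                       qtl = NULL,
                       h2_additive = 0.3,
                       block_effects = c(0, 0.5, 1),
                       resid_cov = 0,
                       trait_name = "trait",
                       seed = 1) {
  if (is.null(chromosomes)) {
    ref <- ref_chromosome_summary()
    chromosomes <- data.frame(name = ref$chrom,
                              length_bp = ref$size_mbp * 1e6,
                              stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp") %in% names(chromosomes)))
  if (n_clones < 1) stop("at least one clone is required")
  if (n_snps_per_chrom < 1) stop("at least one SNP per chromosome is required")
  if (any(chromosomes$length_bp <= 0)) stop("chromosome lengths must be positive")
  if (n_blocks < 1) stop("at least one block is required")
  if (n_subpops < 1) stop("at least one subpopulation is required")
  if (fst_like_divergence < 0 || fst_like_divergence >= 1)
    stop("fst_like_divergence must lie in [0, 1)")
  for (pr in c(recomb_between_blocks, mutation_rate, missing_rate))
    if (pr < 0 || pr > 1) stop("probabilities must lie in [0, 1]")
  if (ld_block_len <= 0) stop("ld_block_len must be positive")
  if (n_founders < 1) stop("at least one founder haplotype is required")
  if (h2_additive < 0 || h2_additive >= 1)
    stop("h2_additive must lie in [0, 1): a nonzero residual is always simulated")
  if (length(block_effects) != n_blocks)
    stop("block_effects must have one entry per block")
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl)
    if (!all(c("chrom", "pos", "effect") %in% names(qtl)))
      stop("qtl must have columns chrom, pos, effect")
    if (!all(qtl$chrom %in% chromosomes$name))
      stop("qtl chromosomes must exist in the chromosome set")
  }
  if (resid_cov < 0) stop("resid_cov must be non-negative")
  structure(list(n_clones = as.integer(n_clones),
                 n_blocks = as.integer(n_blocks),
                 chromosomes = chromosomes,
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 n_subpops = as.integer(n_subpops),
                 fst_like_divergence = fst_like_divergence,
                 ld_block_len = ld_block_len,
                 recomb_between_blocks = recomb_between_blocks,
                 n_founders = as.integer(n_founders),
                 mutation_rate = mutation_rate,
                 missing_rate = missing_rate,
                 qtl = qtl,
                 h2_additive = h2_additive,
                 block_effects = block_effects,
                 resid_cov = resid_cov,
                 trait_name = trait_name,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate block-LD genotypes with population structure
#'
#' Draws a [variant_table()] under the founder-haplotype model described
#' in [sim_config()], together with the `truth` record holding the
#' subpopulation labels, per-SNP ancestral frequencies and the causal-SNP
#' assignment of any configured QTL.
#'
#' @param config `sim_config`.
#' @return list with elements `variants` (variant_table) and `truth`
#'   (list: `subpop`, `causal`, `ancestral_freq`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_clones
  Kf <- config$n_founders
  Fd <- config$fst_like_divergence
  mu <- config$mutation_rate
  rcb <- config$recomb_between_blocks

  subpop <- sample.int(config$n_subpops, n, replace = TRUE)
  clone_ids <- sprintf("clone%04d", seq_len(n))
  names(subpop) <- clone_ids

  maps <- list()
  genos <- list()
  freqs <- list()
  for (ci in seq_len(nrow(config$chromosomes))) {
    ch <- config$chromosomes$name[ci]
    len <- config$chromosomes$length_bp[ci]
    m <- config$n_snps_per_chrom
    if (m > len) stop("more SNPs than base pairs on ", ch)
    pos <- sort(sample.int(len, m))
    p0 <- runif(m, 0.05, 0.95)
    blk <- as.integer(factor((pos - 1) %/% config$ld_block_len))
    B <- max(blk)

    G <- matrix(0L, m, n)
    # shared ancestral founder pool: subpopulations diverge from it by
    # per-SNP reassortment, so block LD stays aligned across subpopulations
    ancestral <- matrix(rbinom(Kf * m, 1L, rep(p0, each = Kf)), Kf, m)
    for (s in seq_len(config$n_subpops)) {
      cols <- which(subpop == s)
      if (!length(cols)) next
      H <- 2L * length(cols)
      ps <- if (Fd > 0)
        rbeta(m, p0 * (1 - Fd) / Fd, (1 - p0) * (1 - Fd) / Fd)
      else p0
      ps <- pmin(pmax(ps, 0), 1)
      founders <- ancestral
      if (Fd > 0) {
        re <- matrix(runif(Kf * m) < Fd, Kf, m)
        if (any(re)) {
          redrawn <- matrix(rbinom(Kf * m, 1L, rep(ps, each = Kf)), Kf, m)
          founders[re] <- redrawn[re]
        }
      }

      # founder-index Markov chain across blocks
      fmat <- matrix(0L, B, H)
      fmat[1, ] <- sample.int(Kf, H, replace = TRUE)
      if (B > 1L) for (b in 2:B) {
        prev <- fmat[b - 1, ]
        if (Kf == 1L) { fmat[b, ] <- prev; next }
        sw <- runif(H) < rcb
        draw <- sample.int(Kf - 1L, H, replace = TRUE)
        other <- draw + (draw >= prev)
        fmat[b, ] <- ifelse(sw, other, prev)
      }

      hap <- matrix(0L, m, H)
      for (b in seq_len(B)) {
        rows <- which(blk == b)
        hap[rows, ] <- t(founders[fmat[b, ], rows, drop = FALSE])
      }
      if (mu > 0) {
        mut <- matrix(runif(m * H) < mu, m, H)
        if (any(mut)) {
          fresh <- matrix(rbinom(m * H, 1L, ps), m, H)
          hap[mut] <- fresh[mut]
        }
      }
      G[, cols] <- hap[, seq(1, H, by = 2), drop = FALSE] +
        hap[, seq(2, H, by = 2), drop = FALSE]
    }
    if (config$missing_rate > 0) {
      drop_idx <- which(runif(length(G)) < config$missing_rate)
      G[drop_idx] <- NA_integer_
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    maps[[ch]] <- data.frame(snp_id = sprintf("%s_%d", ch, pos),
                             chrom = ch, pos = pos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE)
    colnames(G) <- clone_ids
    genos[[ch]] <- G
    freqs[[ch]] <- p0
  }
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  geno <- do.call(rbind, genos)
  vt <- variant_table(map, geno)

  causal <- NULL
  if (!is.null(config$qtl) && nrow(as.data.frame(config$qtl))) {
    pal <- rowMeans(geno, na.rm = TRUE) / 2
    maf <- pmin(pal, 1 - pal)
    causal <- do.call(rbind, lapply(seq_len(nrow(config$qtl)), function(i) {
      q <- config$qtl[i, ]
      # snap to the nearest common SNP: a causal allele below the QC MAF
      # cutoff would carry no recoverable signal
      onch <- which(map$chrom == q$chrom & maf >= 0.05)
      if (!length(onch)) onch <- which(map$chrom == q$chrom)
      hit <- onch[which.min(abs(map$pos[onch] - q$pos))]
      data.frame(snp_id = map$snp_id[hit], chrom = map$chrom[hit],
                 pos = map$pos[hit], effect = q$effect,
                 stringsAsFactors = FALSE)
    }))
  }
  truth <- list(subpop = subpop, causal = causal,
                ancestral_freq = setNames(unlist(freqs, use.names = FALSE),
                                          map$snp_id))
  list(variants = vt, truth = truth)
}

#' Simulate clonal-trial phenotypes over simulated genotypes
#'
#' Ramet value = sum of QTL allelic effects + clone-level polygenic
#' deviate + fixed block effect + residual. Effects are in units of the
#' phenotypic SD: the polygenic variance is set to `h2_additive` minus the
#' realized QTL variance (floored at zero with a warning) and the residual
#' variance to `1 - h2_additive`, so the realized narrow-sense
#' heritability of the additive part matches the target up to Monte-Carlo
#' error. `resid_cov` installs a clone-level shared residual component,
#' giving residuals of the same clone in two blocks covariance
#' `resid_cov`.
#'
#' @param geno variant_table from [simulate_genotypes()].
#' @param truth matching truth record.
#' @param config `sim_config`.
#' @return list: `phenotypes` (data.frame `clone_id`, `block`, `trait`,
#'   `value`; one row per ramet) and `truth` extended with realized
#'   variance components (`sigma2_g`, `sigma2_qtl`, `sigma2_poly`,
#'   `sigma2_block`, `sigma2_e`, `resid_cov`) and the clone genetic
#'   values.
#' @export
simulate_phenotypes <- function(geno, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(geno, "variant_table"))
  set.seed(config$seed + 1L)
  n <- ncol(geno$geno)
  clone_ids <- colnames(geno$geno)
  h2 <- config$h2_additive
  sigma2_e <- 1 - h2
  if (config$resid_cov >= sigma2_e && config$resid_cov > 0)
    stop("resid_cov must be smaller than the residual variance 1 - h2_additive")

  g_qtl <- rep(0, n)
  if (!is.null(truth$causal) && nrow(truth$causal)) {
    miss <- setdiff(truth$causal$snp_id, geno$map$snp_id)
    if (length(miss))
      stop("causal SNPs absent from the variant table: ",
           paste(miss, collapse = ", "))
    for (i in seq_len(nrow(truth$causal))) {
      x <- geno$geno[truth$causal$snp_id[i], ]
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      g_qtl <- g_qtl + truth$causal$effect[i] * (x - mean(x))
    }
  }
  var_qtl <- if (n > 1) var(g_qtl) else 0
  var_poly <- h2 - var_qtl
  if (var_poly < 0) {
    warning("realized QTL variance (", signif(var_qtl, 3),
            ") exceeds h2_additive; polygenic background set to zero")
    var_poly <- 0
  }
  g_poly <- rnorm(n, 0, sqrt(var_poly))
  g <- g_qtl + g_poly

  rho <- config$resid_cov
  shared <- rnorm(n, 0, sqrt(rho))
  blocks <- seq_len(config$n_blocks)
  pheno <- do.call(rbind, lapply(blocks, function(b) {
    e <- shared + rnorm(n, 0, sqrt(sigma2_e - rho))
    data.frame(clone_id = clone_ids,
               block = sprintf("block%d", b),
               trait = config$trait_name,
               value = g + config$block_effects[b] + e,
               stringsAsFactors = FALSE)
  }))
  rownames(pheno) <- NULL

  truth$genetic_values <- setNames(g, clone_ids)
  truth$var_components <- list(
    sigma2_g = if (n > 1) var(g) else 0,
    sigma2_qtl = var_qtl,
    sigma2_poly = var_poly,
    sigma2_block = if (length(config$block_effects) > 1)
      var(config$block_effects) else 0,
    sigma2_e = sigma2_e,
    resid_cov = rho)
  list(phenotypes = pheno, truth = truth)
}

#' Toy gene models tiling the simulated chromosomes
#'
#' Deterministic gene models (2 kb genes every `spacing` bp, alternating
#' strand) used for window/gene overlap fixtures.
#'
#' @param config `sim_config`.
#' @param spacing distance between gene starts, bp.
#' @param width gene width, bp.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
toy_gene_models <- function(config, spacing = 50000, width = 2000) {
  stopifnot(inherits(config, "sim_config"))
  out <- lapply(seq_len(nrow(config$chromosomes)), function(ci) {
    ch <- config$chromosomes$name[ci]
    len <- config$chromosomes$length_bp[ci]
    starts <- seq.int(1L, max(1L, len - width), by = spacing)
    data.frame(gene_id = sprintf("%sG%04d", ch, seq_along(starts)),
               chrom = ch, start = starts,
               end = pmin(starts + width - 1L, len),
               strand = rep_len(c("+", "-"), length(starts)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a complete simulated fixture set
#'
#' Simulates genotypes and phenotypes under `config` and writes the
#' standard interchange files: `genotypes.vcf` (VCFv4.2, GT field),
#' `phenotypes.tsv` (one row per ramet), `genes.gff3` (toy gene models)
#' and `truth.json`. All files round-trip losslessly through the package
#' readers.
#'
#' @param config `sim_config`.
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  sim <- simulate_genotypes(config)
  ph <- simulate_phenotypes(sim$variants, sim$truth, config)
  genes <- toy_gene_models(config)
  paths <- c(vcf = file.path(outdir, "genotypes.vcf"),
             pheno = file.path(outdir, "phenotypes.tsv"),
             gff3 = file.path(outdir, "genes.gff3"),
             truth = file.path(outdir, "truth.json"))
  write_genotypes_vcf(sim$variants, paths[["vcf"]],
                      contig_lengths = setNames(config$chromosomes$length_bp,
                                                config$chromosomes$name))
  write_phenotypes(ph$phenotypes, paths[["pheno"]])
  write_gene_models_gff3(genes, paths[["gff3"]])
  write_truth_json(ph$truth, paths[["truth"]])
  invisible(paths)
}
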