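#' Stem volume index from diameter and height
#'
#' Volume index Vol = pi (DBH/2)^2 h with DBH measured in millimetres and
#' height in decimetres, both converted to metres before the formula is
#' applied, so the result is in cubic metres.
#'
#' @param dbh_mm diameter at breast height, mm (vector).
#' @param h_dm total height, dm (vector, recycled against `dbh_mm`).
#' @return volume index in m^3.
#' @examples
#' volume_index(2000, 10)  # pi: 2 m diameter, 1 m height
#' @export
volume_index <- function(dbh_mm, h_dm) {
  if (any(dbh_mm < 0, na.rm = TRUE) || any(h_dm < 0, na.rm = TRUE))
    stop("diameter and height must be non-negative")
  d_m <- dbh_mm / 1000
  h_m <- h_dm / 10
  pi * (d_m / 2)^2 * h_m
}

#' Transform a trait and mask outliers
#'
#' Optional log transform (used to normalize right-skewed traits before
#' association testing) followed by outlier masking. Outliers are replaced
#' by `NA` when they lie more than `outlier_sd` standard deviations from
#' the mean of the transformed values; `outlier_sd = Inf` disables masking.
#'
#' @param values numeric vector.
#' @param transform `"none"` or `"log"` (natural log). Non-positive values
#'   under `"log"` are masked with a warning.
#' @param outlier_sd mask beyond this many SDs from the mean (default 4).
#' @return transformed vector, outliers and invalid values as `NA`.
#' @export
transform_trait <- function(values, transform = c("none", "log"),
                            outlier_sd = 4) {
  transform <- match.arg(transform)
  x <- as.numeric(values)
  if (transform == "log") {
    bad <- !is.na(x) & x <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive value(s) masked before log transform")
      x[bad] <- NA
    }
    x <- log(x)
  }
  if (is.finite(outlier_sd)) {
    m <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if (is.finite(s) && s > 0) {
      out <- !is.na(x) & abs(x - m) > outlier_sd * s
      x[out] <- NA
    }
  }
  x
}

#' BLUP-adjusted clone means under a randomized block design
#'
#' Fits the clonal-trial mixed model y = block (fixed) + clone (random) +
#' residual by REML and returns, for each clone, the adjusted mean: the
#' estimated population mean (averaged over blocks) plus the clone's BLUP.
#' BLUPs shrink raw clone deviations toward zero by
#' sigma2_c / (sigma2_c + sigma2_e / r) in the balanced case with r ramets
#' per clone.
#'
#' @param pheno phenotype data.frame with columns `clone_id`, `block`,
#'   `trait`, `value` (one row per ramet; at most one ramet per clone per
#'   block).
#' @param trait trait name to analyse; defaults to the only trait present.
#' @return data.frame `clone_id`, `blup`, `adjusted_mean`, with attributes
#'   `varcomp` (list: `sigma2_clone`, `sigma2_resid`), `block_means`
#'   (estimated fixed block means) and `grand_mean`.
#' @export
blup_clone_means <- function(pheno, trait = NULL) {
  required <- c("clone_id", "block", "trait", "value")
  if (!all(required %in% names(pheno)))
    stop("phenotype frame must have columns: ", paste(required, collapse = ", "))
  if (is.null(trait)) {
    traits <- unique(pheno$trait)
    if (length(traits) != 1L)
      stop("multiple traits present; specify `trait`")
    trait <- traits
  }
  d <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  if (nrow(d) == 0L) stop("no observations for trait ", trait)
  if (anyDuplicated(d[c("clone_id", "block")]))
    stop("more than one ramet per clone per block")
  d$clone_id <- factor(d$clone_id)
  d$block <- factor(d$block)
  if (nlevels(d$clone_id) < 2L)
    stop("at least two clones are required (singular design)")

  if (nlevels(d$block) > 1L) {
    fit <- suppressMessages(
      lme4::lmer(value ~ block + (1 | clone_id), data = d, REML = TRUE))
  } else {
    fit <- suppressMessages(
      lme4::lmer(value ~ 1 + (1 | clone_id), data = d, REML = TRUE))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_clone <- vc$vcov[vc$grp == "clone_id"]
  sigma2_resid <- vc$vcov[vc$grp == "Residual"]
  blups <- lme4::ranef(fit)$clone_id
  blup <- setNames(blups[["(Intercept)"]], rownames(blups))
  block_means <- predict(fit,
                         newdata = data.frame(block = levels(d$block)),
                         re.form = NA)
  names(block_means) <- levels(d$block)
  grand <- mean(block_means)

  out <- data.frame(clone_id = names(blup),
                    blup = unname(blup),
                    adjusted_mean = grand + unname(blup),
                    stringsAsFactors = FALSE)
  attr(out, "varcomp") <- list(sigma2_clone = sigma2_clone,
                               sigma2_resid = sigma2_resid)
  attr(out, "block_means") <- block_means
  attr(out, "grand_mean") <- grand
  attr(out, "trait") <- trait
  out
}

#' Individual broad-sense heritability of a clonal trial
#'
#' H2 = (sigma2_g + sigma2_c + sigma_ee) /
#'      (sigma2_g + sigma2_c + sigma2_gxb + sigma2_e), where sigma2_g is
#' the genetic-cluster variance, sigma2_c the clone-within-cluster
#' variance, sigma2_gxb the cluster-by-block interaction, sigma2_e the
#' residual variance and sigma_ee the covariance between residuals of the
#' same clone in two blocks. Cluster labels come from an external grouping
#' of the panel, so the components are taken as inputs (e.g. from a
#' mixed-model fit or from simulation truth) rather than re-derived here.
#'
#' @param sigma2_g,sigma2_c,sigma2_gxb,sigma2_e variances (>= 0).
#' @param sigma_ee residual covariance of a clone across blocks (may be
#'   negative; default 0).
#' @return heritability estimate (scalar).
#' @examples
#' broad_sense_heritability(1, 0, 0, 1)  # 0.5
#' @export
broad_sense_heritability <- function(sigma2_g, sigma2_c, sigma2_gxb,
                                     sigma2_e, sigma_ee = 0) {
  if (any(c(sigma2_g, sigma2_c, sigma2_gxb, sigma2_e) < 0))
    stop("variance components must be non-negative")
  den <- sigma2_g + sigma2_c + sigma2_gxb + sigma2_e
  if (den <= 0) stop("total variance must be positive")
  (sigma2_g + sigma2_c + sigma_ee) / den
}

#' Trait summary statistics
#'
#' Mean, standard deviation and coefficient of variation (CV\% =
#' 100 SD / mean), as reported in trait summary tables of association
#' panels.
#'
#' @param values numeric vector (n >= 2 after removing `NA`).
#' @return named list: `n`, `mean`, `sd`, `cv_pct`.
#' @export
summary_stats <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2L) stop("at least two non-missing values are required")
  m <- mean(x)
  s <- sd(x)
  list(n = length(x), mean = m, sd = s, cv_pct = cv_percent(m, s))
}

#' Coefficient of variation from a mean and SD
#'
#' @param mean,sd summary values (mean non-zero).
#' @return CV in percent, 100 sd / mean.
#' @examples
#' cv_percent(53.2, 7.9)
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean == 0)) stop("CV is undefined for a zero mean")
  100 * sd / mean
}
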