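# Synthetic cohort with planted structure: LD-blocked genotypes, an external
# "reference GWAS" replicate providing noisy summary-statistic weights, a
# PRS -> mediators -> outcome causal graph with tunable path strengths, a
# logistic-link binary diagnosis, omics layers with planted correlated modules,
# and genomic coordinates supporting cis-window scans and interval enrichment.
# A ground-truth ledger records every planted effect in closed form.

#' Simulation configuration
#'
#' Defines the generative model for a synthetic cohort. The causal graph is
#' `y = c * P + sum_j b_j * M_j + eps` with mediators `M_j = a_j * P + eta_j`,
#' where `P` is the standardized true polygenic score. Mediators have unit
#' population variance (`var(eta_j) = 1 - a_j^2`), and the outcome's
#' structural variance is normalized to 1, so `a_j`, `b_j` and `c` are on the
#' correlation scale.
#'
#' @param n_samples analysis-cohort size.
#' @param n_snps number of candidate SNPs.
#' @param maf_range range of the uniform law for per-SNP minor-allele
#'   frequencies, within (0, 0.5].
#' @param ld_block_size SNPs per LD block; a trailing shorter block is allowed
#'   (with a warning at genotype generation).
#' @param rho_ld latent correlation between adjacent SNPs within a block
#'   (Gaussian copula on haplotypes), in `[0, 1)`.
#' @param n_causal number of causal SNPs behind the true score.
#' @param effect_profile `"gaussian"` (heterogeneous per-SNP effects, drawn
#'   N(0,1) before scaling) or `"equal"` (equal magnitudes with random signs;
#'   a strongly polygenic architecture).
#' @param h2_gwas variance of the genetic component in the reference GWAS
#'   outcome (per-SNP effects are scaled to reach it).
#' @param gwas_n reference-GWAS replicate size (summary statistics are
#'   estimated there, never on the analysis cohort).
#' @param mediators named list; each element `list(a = , b = )` gives the
#'   PRS->mediator and mediator->outcome path strengths. `|a| < 1` required.
#' @param direct_effect direct PRS->outcome path `c`.
#' @param sigma_eps outcome noise SD, or `NULL` to normalize the structural
#'   outcome variance to 1 (error if the implied variance is negative).
#' @param n_nuisance number of pure-noise continuous traits.
#' @param prevalence target prevalence of the binary diagnosis.
#' @param diag_gamma slope of the diagnosis logistic link on the structural
#'   outcome.
#' @param covariate_effect common effect size of each covariate on continuous
#'   traits (removed downstream by residualization).
#' @param omics named list of layer configurations, each
#'   `list(n_features =, n_modules =, module_size =, rho =, coupling =)`;
#'   `coupling` gives each module latent factor's correlation with the true
#'   score. Features beyond `n_modules * module_size` are unstructured noise
#'   (truth label 0).
#' @param n_cis_pairs number of planted gene--peak couplings between the
#'   expression and acetylation layers (taken from each layer's noise
#'   features).
#' @param cis_coupling correlation of a planted peak with its gene.
#' @param seed RNG seed; regeneration with the same seed is bit-identical.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 1272,
                          n_snps = 500,
                          maf_range = c(0.05, 0.5),
                          ld_block_size = 10,
                          rho_ld = 0.6,
                          n_causal = min(50, n_snps),
                          effect_profile = c("gaussian", "equal"),
                          h2_gwas = 0.3,
                          gwas_n = 2 * n_samples,
                          mediators = list(
                            amyloid = list(a = 0.40, b = 0.128),
                            tangles = list(a = 0.40, b = 0.128),
                            vgf     = list(a = 0.40, b = 0.128)),
                          direct_effect = 0.154,
                          sigma_eps = NULL,
                          n_nuisance = 5,
                          prevalence = 0.4,
                          diag_gamma = 1.5,
                          covariate_effect = 0.15,
                          omics = list(
                            methylation = list(n_features = 120, n_modules = 3,
                                               module_size = 30, rho = 0.6,
                                               coupling = c(0.3, 0, 0)),
                            acetylation = list(n_features = 160, n_modules = 4,
                                               module_size = 30, rho = 0.6,
                                               coupling = c(0.5, 0, 0, 0)),
                            expression  = list(n_features = 120, n_modules = 3,
                                               module_size = 30, rho = 0.6,
                                               coupling = c(0, 0, 0))),
                          n_cis_pairs = 10,
                          cis_coupling = 0.7,
                          seed = 1L) {
  stopifnot(n_samples > 0, n_snps > 0, ld_block_size > 0, n_causal > 0,
            n_causal <= n_snps, gwas_n > 2, h2_gwas > 0, h2_gwas < 1)
  if (!(maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2]))
    stop("maf_range must lie in (0, 0.5]")
  if (!(rho_ld >= 0 && rho_ld < 1)) stop("rho_ld must be in [0, 1)")
  a <- vapply(mediators, function(m) m$a, 0)
  b <- vapply(mediators, function(m) m$b, 0)
  if (any(abs(a) >= 1))
    stop("mediator path 'a' implies negative mediator residual variance")
  struct_var <- (direct_effect + sum(a * b))^2 + sum(b^2 * (1 - a^2))
  if (is.null(sigma_eps)) {
    if (struct_var > 1)
      stop("requested paths imply negative outcome residual variance; ",
           "reduce path strengths or pass sigma_eps explicitly")
    sigma_eps <- sqrt(1 - struct_var)
  }
  effect_profile <- match.arg(effect_profile)
  cfg <- list(n_samples = n_samples, n_snps = n_snps, maf_range = maf_range,
              ld_block_size = ld_block_size, rho_ld = rho_ld,
              n_causal = n_causal, effect_profile = effect_profile,
              h2_gwas = h2_gwas, gwas_n = gwas_n,
              mediators = mediators, direct_effect = direct_effect,
              sigma_eps = sigma_eps, n_nuisance = n_nuisance,
              prevalence = prevalence, diag_gamma = diag_gamma,
              covariate_effect = covariate_effect, omics = omics,
              n_cis_pairs = n_cis_pairs, cis_coupling = cis_coupling,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Path strengths realizing a target causal mediated fraction
#'
#' For a single-mediator graph with total PRS->outcome effect `T`, returns
#' `(a, b, c)` such that the causal mediated fraction `a*b / (a*b + c)` equals
#' `fraction`: `b = fraction * T / a`, `c = (1 - fraction) * T`.
#'
#' @param fraction target mediated fraction in `[0, 1]`.
#' @param total_effect total standardized effect `T` (default `sqrt(0.095)`,
#'   an outcome R^2 of 9.5%).
#' @param a PRS->mediator path strength.
#' @return list with elements `a`, `b`, `c`.
#' @export
plant_mediation <- function(fraction, total_effect = sqrt(0.095), a = 0.4) {
  stopifnot(fraction >= 0, fraction <= 1, abs(a) > 0, abs(a) < 1)
  list(a = a, b = fraction * total_effect / a,
       c = (1 - fraction) * total_effect)
}

# PAEM from a correlation triple (prs-outcome, mediator-outcome, prs-mediator).
# Shared by the population ledger; the sample estimator recomputes the same
# algebra from sample moments, and tests check both against least-squares
# oracles.
.paem_from_cor <- function(r_py, r_my, r_pm) {
  pve1 <- r_py^2
  r2_m <- r_my^2
  r2_full <- (r_py^2 + r_my^2 - 2 * r_py * r_my * r_pm) / (1 - r_pm^2)
  pve2 <- (pve1 + r2_full - r2_m) / 2
  list(pve1 = pve1, r2_mediator = r2_m, r2_full = r2_full,
       ri_prs = pve2 / r2_full, pve_prs2 = pve2,
       paem = 100 * (pve1 - pve2) / pve1)
}

#' Population PAEM implied by a mediation configuration
#'
#' Closed-form path analysis: from the graph `M_j = a_j P + eta_j`,
#' `y = c P + sum b_j M_j + eps` the population correlations of each mediator
#' with the score and the outcome follow directly, and the population value of
#' the PAEM statistic is evaluated from them.
#'
#' @param mediators named list of `list(a =, b =)` path pairs.
#' @param direct_effect direct path `c`.
#' @param sigma_eps outcome noise SD (`NULL`: normalize structural variance
#'   to 1).
#' @return data.frame with one row per mediator: paths, causal mediated
#'   fraction (percent), and population PAEM.
#' @export
population_paem <- function(mediators, direct_effect, sigma_eps = NULL) {
  a <- vapply(mediators, function(m) m$a, 0)
  b <- vapply(mediators, function(m) m$b, 0)
  tot <- direct_effect + sum(a * b)
  struct_var <- tot^2 + sum(b^2 * (1 - a^2))
  if (is.null(sigma_eps)) sigma_eps <- sqrt(max(0, 1 - struct_var))
  var_y <- struct_var + sigma_eps^2
  sd_y <- sqrt(var_y)
  paem <- numeric(length(a))
  for (j in seq_along(a)) {
    r_py <- tot / sd_y
    r_pm <- a[j]
    cov_my <- a[j] * direct_effect + b[j] + a[j] * (sum(a * b) - a[j] * b[j])
    r_my <- cov_my / sd_y
    paem[j] <- .paem_from_cor(r_py, r_my, r_pm)$paem
  }
  data.frame(mediator = names(mediators), a = a, b = b,
             mediated_fraction = 100 * a * b / tot, pop_paem = paem,
             row.names = NULL, stringsAsFactors = FALSE)
}

# SNP map: blocks assigned round-robin to 22 chromosomes, SNPs spaced 100 kb
# within a chromosome.
.snp_map <- function(n_snps, ld_block_size) {
  block <- ceiling(seq_len(n_snps) / ld_block_size)
  n_block <- max(block)
  chrom_of_block <- ((seq_len(n_block) - 1L) %% 22L) + 1L
  chrom <- chrom_of_block[block]
  pos <- integer(n_snps)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- 1e6 + (seq_along(idx) - 1L) * 1e5
  }
  bases <- c("A", "C", "G", "T")
  ea <- bases[((seq_len(n_snps) - 1L) %% 4L) + 1L]
  oa <- bases[(seq_len(n_snps) %% 4L) + 1L]
  list(snps = snp_table(sprintf("rs%06d", seq_len(n_snps)),
                        paste0("chr", chrom), pos, ea, oa),
       block = block)
}

# One cohort of dosages under the blockwise Gaussian-copula haplotype model.
# Does not touch the seed; callers control the RNG state.
.draw_dosages <- function(n, maf, block, rho) {
  m <- length(maf)
  thr <- qnorm(maf)
  dos <- matrix(0, n, m)
  for (h in 1:2) {
    z <- matrix(rnorm(n * m), n, m)
    if (rho > 0) {
      for (j in 2:m) {
        if (m >= 2 && block[j] == block[j - 1])
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
    }
    dos <- dos + (z < rep(thr, each = n))
  }
  dos
}

#' Simulate LD-blocked genotype dosages
#'
#' Dosages are sums of two haplotypes; each haplotype's allele indicators come
#' from thresholding a blockwise AR(1) Gaussian latent vector (correlation
#' `rho_ld` between adjacent SNPs of a block) at the Gaussian quantile of the
#' SNP's allele frequency.
#'
#' @param config a [cohort_config()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  if (config$n_snps %% config$ld_block_size != 0)
    warning("n_snps is not a multiple of ld_block_size; last block shortened")
  map <- .snp_map(config$n_snps, config$ld_block_size)
  maf <- runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  dos <- .draw_dosages(config$n_samples, maf, map$block, config$rho_ld)
  genotype_matrix(dos, map$snps,
                  samples = sprintf("ind%05d", seq_len(config$n_samples)))
}

# Marginal per-SNP linear GWAS, vectorized.
.marginal_gwas <- function(dos, y) {
  n <- length(y)
  gc <- sweep(dos, 2, colMeans(dos))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  sxy <- as.numeric(crossprod(gc, yc))
  syy <- sum(yc^2)
  beta <- ifelse(sxx > 0, sxy / sxx, 0)
  sse <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(ifelse(sxx > 0, sse / ((n - 2) * sxx), Inf))
  tstat <- ifelse(is.finite(se) & se > 0, beta / se, 0)
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(beta = beta, pvalue = p)
}

#' Simulate a full cohort with ground-truth ledger
#'
#' Generates the analysis cohort (genotypes, true polygenic score, mediators,
#' outcome, binary diagnosis, nuisance traits, covariates), an independent
#' reference-GWAS replicate from which summary statistics are estimated (so
#' the score weights carry realistic estimation noise), omics layers with
#' planted modules, gene/peak coordinate tables with planted cis couplings, a
#' chromatin-annotation interval set enriched for one acetylation module, and
#' a `truth` ledger that fully determines every planted effect.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `genotypes`,
#'   `sumstats`, `phenotypes`, `prs_true`, `omics` (per-layer feature x sample
#'   matrices), `genes`, `peaks`, `annotation`, and `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  map <- .snp_map(config$n_snps, config$ld_block_size)
  maf <- runif(config$n_snps, config$maf_range[1], config$maf_range[2])

  dos <- .draw_dosages(n, maf, map$block, config$rho_ld)
  geno <- genotype_matrix(dos, map$snps,
                          samples = sprintf("ind%05d", seq_len(n)))

  # reference GWAS on an independent replicate
  dos_ref <- .draw_dosages(config$gwas_n, maf, map$block, config$rho_ld)
  causal <- sort(sample.int(config$n_snps, config$n_causal))
  beta_raw <- if (config$effect_profile == "equal")
    sample(c(-1, 1), config$n_causal, replace = TRUE)
  else rnorm(config$n_causal)
  g_ref <- dos_ref[, causal, drop = FALSE] %*% beta_raw
  beta_true <- beta_raw * sqrt(config$h2_gwas) / sd(g_ref)
  y_ref <- as.numeric(dos_ref[, causal, drop = FALSE] %*% beta_true) +
    rnorm(config$gwas_n, sd = sqrt(1 - config$h2_gwas))
  gw <- .marginal_gwas(dos_ref, y_ref)
  sumstats <- summary_stats(map$snps, gw$beta, gw$pvalue)

  # true score and causal graph
  prs_true <- as.numeric(scale(dos[, causal, drop = FALSE] %*% beta_true))
  a <- vapply(config$mediators, function(m) m$a, 0)
  b <- vapply(config$mediators, function(m) m$b, 0)
  med_names <- names(config$mediators)
  M <- sapply(seq_along(a), function(j)
    a[j] * prs_true + sqrt(1 - a[j]^2) * rnorm(n))
  M <- matrix(M, nrow = n)
  colnames(M) <- med_names
  y_struct <- config$direct_effect * prs_true + as.numeric(M %*% b) +
    rnorm(n, sd = config$sigma_eps)

  # binary diagnosis via logistic link at target prevalence
  lp <- config$diag_gamma * y_struct
  f <- function(alpha) mean(plogis(alpha + lp)) - config$prevalence
  alpha <- uniroot(f, c(-20, 20))$root
  diagnosis <- rbinom(n, 1, plogis(alpha + lp))

  # covariates (independent of genotype) and their additive trait effects
  age <- rnorm(n, 85, 5)
  sex <- rbinom(n, 1, 0.35)
  educ <- rnorm(n, 16, 3)
  pcs <- matrix(rnorm(3 * n), n, 3)
  cov_std <- cbind(scale(age), sex - mean(sex), scale(educ))
  ce <- config$covariate_effect
  cov_shift <- ce * rowSums(cov_std)
  y_obs <- y_struct + cov_shift
  M_obs <- M + cov_shift
  nuis <- matrix(rnorm(n * config$n_nuisance), n) + cov_shift
  colnames(nuis) <- paste0("nuisance_", seq_len(config$n_nuisance))

  pheno <- data.frame(sample_id = geno$samples, cog_decline = y_obs,
                      ad_diagnosis = diagnosis, M_obs, nuis,
                      age = age, sex = sex, educ = educ,
                      pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3],
                      check.names = FALSE)
  pheno <- phenotype_table(pheno,
                           covariates = c("age", "sex", "educ",
                                          "pc1", "pc2", "pc3"),
                           binary = "ad_diagnosis")

  # omics layers with planted modules
  omics <- list()
  truth_modules <- list()
  for (layer in names(config$omics)) {
    lc <- config$omics[[layer]]
    labels <- rep(0L, lc$n_features)
    mat <- matrix(rnorm(lc$n_features * n), lc$n_features, n)
    for (k in seq_len(lc$n_modules)) {
      idx <- ((k - 1L) * lc$module_size + 1L):(k * lc$module_size)
      labels[idx] <- k
      kap <- lc$coupling[k]
      g <- kap * prs_true + sqrt(1 - kap^2) * rnorm(n)
      mat[idx, ] <- sqrt(lc$rho) * matrix(g, lc$module_size, n, byrow = TRUE) +
        sqrt(1 - lc$rho) * mat[idx, , drop = FALSE]
    }
    rownames(mat) <- sprintf("%s_f%04d", layer, seq_len(lc$n_features))
    colnames(mat) <- geno$samples
    omics[[layer]] <- mat
    truth_modules[[layer]] <- labels
  }

  # coordinates: expression features as genes, acetylation features as peaks;
  # planted cis couplings use noise features of each layer
  expr <- omics$expression
  acet <- omics$acetylation
  genes <- peaks <- annotation <- NULL
  cis_pairs <- NULL
  if (!is.null(expr) && !is.null(acet)) {
    ng <- nrow(expr)
    gchr <- paste0("chr", ((seq_len(ng) - 1L) %% 10L) + 1L)
    gstart <- numeric(ng)
    for (cc in unique(gchr)) {
      idx <- which(gchr == cc)
      gstart[idx] <- 5e6 + (seq_along(idx) - 1L) * 3e6  # 3 Mb spacing
    }
    strand <- rep(c("+", "-"), length.out = ng)
    glen <- 2e4
    tss <- ifelse(strand == "+", gstart, gstart + glen)
    tes <- ifelse(strand == "+", gstart + glen, gstart)
    genes <- gene_table(rownames(expr), gchr, strand, tss, tes)

    np <- nrow(acet)
    # decoy peak positions: far from any gene TSS window on chr20
    pchr <- rep("chr20", np)
    pstart <- 5e6 + (seq_len(np) - 1L) * 2.2e6
    expr_noise <- which(truth_modules$expression == 0L)
    acet_noise <- which(truth_modules$acetylation == 0L)
    n_cis <- min(config$n_cis_pairs, length(expr_noise), length(acet_noise))
    pk_i <- integer(0)
    if (n_cis > 0) {
      gi <- expr_noise[seq_len(n_cis)]
      pk_i <- acet_noise[seq_len(n_cis)]
      lam <- config$cis_coupling
      acet[pk_i, ] <- lam * expr[gi, , drop = FALSE] +
        sqrt(1 - lam^2) * matrix(rnorm(n_cis * n), n_cis, n)
      omics$acetylation <- acet
      # place the coupled peak 50 kb downstream of its gene's TSS
      pchr[pk_i] <- genes$chrom[gi]
      pstart[pk_i] <- genes$tss[gi] + 5e4
      cis_pairs <- data.frame(gene = rownames(expr)[gi],
                              peak = rownames(acet)[pk_i],
                              coupling = lam, stringsAsFactors = FALSE)
    }
    peaks <- interval_set(pchr, pstart, pstart + 1000, rownames(acet))
    # chromatin annotation covering module-1 acetylation peaks (planted
    # enrichment target) plus a handful of decoys
    m1 <- which(truth_modules$acetylation == 1L)
    decoy <- setdiff(acet_noise, pk_i)
    decoy <- head(decoy, 3)
    ann_idx <- c(m1, decoy)
    annotation <- interval_set(pchr[ann_idx], pstart[ann_idx] - 100,
                               pstart[ann_idx] + 1100,
                               paste0("state_", seq_along(ann_idx)))
  }

  pop <- population_paem(config$mediators, config$direct_effect,
                         config$sigma_eps)
  tot <- config$direct_effect + sum(a * b)
  var_y <- tot^2 + sum(b^2 * (1 - a^2)) + config$sigma_eps^2
  sep <- if (config$direct_effect == 0) med_names[a != 0 & b != 0]
         else character(0)
  snp_groups <- ifelse(seq_len(config$n_snps) %in% causal, 1L, 2L)

  truth <- list(causal_snps = map$snps$snp_id[causal],
                beta_true = beta_true,
                mediators = pop,
                direct_effect = config$direct_effect,
                total_effect = tot,
                pop_cor_prs_outcome = tot / sqrt(var_y),
                pop_r2_prs_outcome = tot^2 / var_y,
                separating_set = sep,
                diag_intercept = alpha,
                module_labels = truth_modules,
                snp_groups = snp_groups,
                cis_pairs = cis_pairs,
                enriched_annotation_module = 1L)

  structure(list(config = config, genotypes = geno, sumstats = sumstats,
                 phenotypes = pheno, prs_true = prs_true, omics = omics,
                 genes = genes, peaks = peaks, annotation = annotation,
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", x$config$n_samples, "samples,",
      x$config$n_snps, "SNPs,", length(x$config$mediators), "mediators,",
      length(x$omics), "omics layers\n")
  invisible(x)
}

#' Write a cohort to a directory in the package's file dialects
#'
#' Writes dosages + SNP sidecar, summary statistics, phenotypes, omics
#' matrices, gene/peak/annotation tables and `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_dosages(cohort$genotypes, fp("dosages.tsv"), fp("snps.tsv"))
  write_summary_stats(cohort$sumstats, fp("sumstats.tsv"))
  write_phenotypes(cohort$phenotypes, fp("phenotypes.tsv"))
  for (layer in names(cohort$omics)) {
    m <- cohort$omics[[layer]]
    .write_tsv(data.frame(feature = rownames(m), m, check.names = FALSE),
               fp(paste0(layer, ".tsv")))
  }
  if (!is.null(cohort$genes)) write_genes(cohort$genes, fp("genes.tsv"))
  if (!is.null(cohort$peaks)) write_bed(cohort$peaks, fp("peaks.bed"))
  if (!is.null(cohort$annotation))
    write_bed(cohort$annotation, fp("annotation.bed"))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(cohort$truth, fp("truth.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(dir)
}
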