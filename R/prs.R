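# Polygenic risk score construction: p-value thresholding, significance-
# ordered LD clumping in the analysis cohort, allele-orientation matching,
# averaging of weighted dosages, z-scaling, and region exclusion/restriction.

#' PRS configuration
#'
#' @param p_threshold include SNPs with summary p-value below this (default
#'   0.001).
#' @param r2_threshold LD pruning threshold on squared Pearson correlation of
#'   dosages (default 0.1).
#' @param window_kb pruning window; SNPs more than `window_kb * 1000` bp apart
#'   (or on different chromosomes) are never pruned against each other
#'   (default 2000).
#' @param exclude_snp_ids SNPs removed after pruning (e.g. an APOE/TOMM40-like
#'   region).
#' @param restrict_snp_ids optional: keep only these SNPs (applied after
#'   pruning).
#' @return list of class `prs_config`.
#' @export
prs_config <- function(p_threshold = 0.001, r2_threshold = 0.1,
                       window_kb = 2000, exclude_snp_ids = character(0),
                       restrict_snp_ids = NULL) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            r2_threshold >= 0, r2_threshold <= 1, window_kb > 0)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb,
                 exclude_snp_ids = as.character(exclude_snp_ids),
                 restrict_snp_ids = restrict_snp_ids),
            class = "prs_config")
}

#' LD clumping of candidate SNPs
#'
#' Greedy selection in ascending p-value order (ties broken by chromosome then
#' position): a SNP is discarded when its dosage r^2 with an already-kept SNP
#' on the same chromosome within the window exceeds `r2_threshold`. The
#' returned ids preserve genomic order.
#'
#' @param sumstats a [summary_stats()] table restricted to the candidate SNPs.
#' @param genotypes a [genotype_matrix()] containing all candidates (LD is
#'   estimated in this cohort).
#' @param r2_threshold,window_kb see [prs_config()].
#' @return character vector of kept SNP ids, in genomic order.
#' @export
prune_snps <- function(sumstats, genotypes, r2_threshold = 0.1,
                       window_kb = 2000) {
  miss <- setdiff(sumstats$snp_id, genotypes$snps$snp_id)
  if (length(miss) > 0)
    stop("SNP(s) absent from genotype matrix: ", paste(miss, collapse = ", "))
  ss <- as.data.frame(sumstats)
  ord <- order(ss$pvalue, ss$chrom, ss$pos)
  ss <- ss[ord, , drop = FALSE]
  dos <- genotypes$dosages[, ss$snp_id, drop = FALSE]
  win <- window_kb * 1000
  kept <- integer(0)
  for (i in seq_len(nrow(ss))) {
    ok <- TRUE
    for (k in kept) {
      if (ss$chrom[k] == ss$chrom[i] && abs(ss$pos[k] - ss$pos[i]) <= win) {
        r <- suppressWarnings(cor(dos[, i], dos[, k]))
        if (!is.na(r) && r^2 > r2_threshold) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, i)
  }
  ids <- ss$snp_id[kept]
  # genomic order
  meta <- ss[kept, , drop = FALSE]
  ids[order(meta$chrom, meta$pos)]
}

# orient dosages to the summary-statistics effect allele; returns the dosage
# submatrix (flipped where needed) and betas, errors on incompatible alleles
.orient_dosages <- function(genotypes, sumstats, ids) {
  gs <- genotypes$snps
  gi <- match(ids, gs$snp_id)
  si <- match(ids, sumstats$snp_id)
  dos <- genotypes$dosages[, gi, drop = FALSE]
  same <- sumstats$effect_allele[si] == gs$effect_allele[gi] &
    sumstats$other_allele[si] == gs$other_allele[gi]
  flipped <- sumstats$effect_allele[si] == gs$other_allele[gi] &
    sumstats$other_allele[si] == gs$effect_allele[gi]
  bad <- !(same | flipped)
  if (any(bad))
    stop("allele mismatch (not a strand flip) for: ",
         paste(ids[bad], collapse = ", "))
  if (any(flipped))
    dos[, flipped] <- 2 - dos[, flipped, drop = FALSE]
  list(dosages = dos, beta = sumstats$beta[si])
}

#' Build a polygenic risk score
#'
#' The raw score is the average over included SNPs of dosage x summary effect
#' (dosages re-oriented where the genotype effect allele is the summary
#' statistic's other allele); the scaled score subtracts the cohort mean and
#' divides by the SD.
#'
#' @param genotypes a [genotype_matrix()].
#' @param sumstats a [summary_stats()] table.
#' @param config a [prs_config()].
#' @return list of class `prs_vector`: `sample_id`, `raw`, `scaled`,
#'   `included_snp_ids`, `config`.
#' @export
build_prs <- function(genotypes, sumstats, config = prs_config()) {
  cand <- sumstats[sumstats$pvalue < config$p_threshold, , drop = FALSE]
  cand <- cand[cand$snp_id %in% genotypes$snps$snp_id, , drop = FALSE]
  kept <- prune_snps(cand, genotypes, config$r2_threshold, config$window_kb)
  if (!is.null(config$restrict_snp_ids)) {
    absent <- setdiff(config$restrict_snp_ids, kept)
    if (length(absent) > 0)
      warning("restrict ids not in pruned candidate set: ",
              paste(absent, collapse = ", "))
    kept <- intersect(kept, config$restrict_snp_ids)
  }
  if (length(config$exclude_snp_ids) > 0) {
    absent <- setdiff(config$exclude_snp_ids, kept)
    if (length(absent) > 0)
      warning("exclusion ids not in pruned candidate set: ",
              paste(absent, collapse = ", "))
    kept <- setdiff(kept, config$exclude_snp_ids)
  }
  if (length(kept) == 0)
    stop("zero SNPs survive selection; cannot build a score")
  od <- .orient_dosages(genotypes, sumstats, kept)
  raw <- as.numeric(od$dosages %*% od$beta) / length(kept)
  s <- sd(raw)
  if (!is.finite(s) || s == 0)
    stop("zero variance in raw scores; cannot scale")
  structure(list(sample_id = genotypes$samples, raw = raw,
                 scaled = (raw - mean(raw)) / s,
                 included_snp_ids = kept, config = config),
            class = "prs_vector")
}

#' @export
print.prs_vector <- function(x, ...) {
  cat("prs_vector:", length(x$raw), "samples,",
      length(x$included_snp_ids), "SNPs\n")
  invisible(x)
}

#' Full / region-excluded / region-only score variants
#'
#' Builds three scores under identical pruning: the full score, the score
#' without `exclude_snp_ids`, and the score using exactly `exclude_snp_ids`.
#'
#' @inheritParams build_prs
#' @return named list of three `prs_vector`s: `full`, `without_region`,
#'   `region_only`.
#' @export
prs_variants <- function(genotypes, sumstats, config = prs_config()) {
  if (length(config$exclude_snp_ids) == 0)
    stop("prs_variants requires a non-empty exclude_snp_ids list")
  base_cfg <- config; base_cfg$exclude_snp_ids <- character(0)
  full <- build_prs(genotypes, sumstats, base_cfg)
  without <- build_prs(genotypes, sumstats, config)
  only_cfg <- base_cfg
  only_cfg$restrict_snp_ids <- config$exclude_snp_ids
  region <- build_prs(genotypes, sumstats, only_cfg)
  list(full = full, without_region = without, region_only = region)
}

#' p-value threshold sweep
#'
#' Rebuilds the score at each inclusion threshold and tests its association
#' with a trait via [associate_trait()]. Because clumping visits candidates in
#' ascending p-value order, kept sets are nested and `n_snps` is
#' non-decreasing in the threshold.
#'
#' @inheritParams build_prs
#' @param thresholds ascending p-value thresholds.
#' @param trait numeric trait vector (continuous) or 0/1 (binary), aligned to
#'   the genotype samples.
#' @param covariates data.frame of covariates.
#' @param kind `"continuous"` or `"binary"`.
#' @return data.frame: threshold, n_snps, estimate, p_value; rows where no
#'   SNP passes are flagged `ok = FALSE` rather than fatal.
#' @export
threshold_sweep <- function(genotypes, sumstats, thresholds, trait,
                            covariates, kind = "continuous",
                            config = prs_config()) {
  stopifnot(!is.unsorted(thresholds))
  out <- data.frame(threshold = thresholds, n_snps = NA_integer_,
                    estimate = NA_real_, p_value = NA_real_, ok = FALSE)
  for (i in seq_along(thresholds)) {
    cfg <- config; cfg$p_threshold <- thresholds[i]
    prs <- tryCatch(build_prs(genotypes, sumstats, cfg),
                    error = function(e) NULL)
    if (is.null(prs)) next
    res <- associate_trait(prs, trait, covariates, kind = kind)
    out$n_snps[i] <- length(prs$included_snp_ids)
    out$estimate[i] <- res$estimate
    out$p_value[i] <- res$p_value
    out$ok[i] <- TRUE
  }
  out
}
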