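# LD clumping, score construction, region variants, threshold sweeps.

test_that("greedy clumping keeps the significant representative", {
  # snp1-snp2 correlated above threshold, snp3 essentially independent
  set.seed(21)
  n <- 400
  z <- rnorm(n)
  g1 <- pmin(pmax(round(1 + z + rnorm(n, sd = 0.3)), 0), 2)
  g2 <- pmin(pmax(round(1 + z + rnorm(n, sd = 0.9)), 0), 2)
  g3 <- pmin(pmax(round(1 + rnorm(n)), 0), 2)
  dos <- cbind(g1, g2, g3)
  geno <- make_geno(dos, pos = c(1e4, 2e4, 3e4))  # all within the window
  stopifnot(cor(g1, g2)^2 > 0.1, cor(g1, g3)^2 < 0.1, cor(g2, g3)^2 < 0.1)
  ss <- make_sumstats(geno, beta = c(0.3, 0.2, 0.1),
                      pvalue = c(1e-6, 1e-4, 1e-2))
  kept <- prune_snps(ss, geno, r2_threshold = 0.1, window_kb = 2000)
  expect_setequal(kept, c("snp1", "snp3"))
  # output preserves genomic order
  expect_equal(kept, c("snp1", "snp3"))
})

test_that("window and threshold edges behave as vacuous filters", {
  set.seed(22)
  dos <- matrix(sample(0:2, 300, replace = TRUE), 100, 3)
  # distinct chromosomes: the window never applies
  geno <- make_geno(dos, chrom = c("chr1", "chr2", "chr3"))
  ss <- make_sumstats(geno, rnorm(3), c(0.01, 0.02, 0.03))
  expect_setequal(prune_snps(ss, geno, 0.0, 2000), paste0("snp", 1:3))
  # r2_threshold = 1 keeps everything short of perfect correlation
  geno2 <- make_geno(dos)
  ss2 <- make_sumstats(geno2, rnorm(3), c(0.01, 0.02, 0.03))
  expect_setequal(prune_snps(ss2, geno2, 1.0, 2000), paste0("snp", 1:3))
  # absent SNP is named
  ss3 <- ss2; ss3$snp_id[1] <- "rs_missing"
  expect_error(prune_snps(ss3, geno2, 0.1, 2000), "rs_missing")
})

test_that("clumping equals a literal application of the greedy rule", {
  set.seed(23)
  for (rep in 1:60) {
    m <- sample(3:12, 1)
    n <- 80
    # random dosages with some duplicated (high-LD) columns
    dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    if (m >= 4 && runif(1) < 0.5) dos[, 2] <- dos[, 1]
    geno <- make_geno(dos,
                      chrom = sample(c("chr1", "chr2"), m, replace = TRUE),
                      pos = sample.int(3e6, m))
    ss <- make_sumstats(geno, rnorm(m), runif(m))
    thr <- sample(c(0.05, 0.2, 0.5), 1)
    win <- sample(c(500, 2000), 1)
    kept <- prune_snps(ss, geno, thr, win)
    expect_setequal(kept, oracle_prune(as.data.frame(ss), geno$dosages,
                                       thr, win))
  }
})

test_that("raw score is the average of beta-weighted dosages", {
  dos <- matrix(c(2, 1, 0, 1), 2, 2)
  geno <- make_geno(dos, chrom = c("chr1", "chr2"))
  ss <- make_sumstats(geno, beta = c(0.5, -0.2), pvalue = c(0.1, 0.2))
  prs <- build_prs(geno, ss, prs_config(p_threshold = 1, r2_threshold = 1))
  expect_equal(prs$raw, c(0.5, 0.15))
  expect_equal(mean(prs$scaled), 0, tolerance = 1e-10)
  expect_equal(sd(prs$scaled), 1, tolerance = 1e-10)
})

test_that("score is invariant to SNP order and to allele flips", {
  set.seed(24)
  dos <- matrix(sample(0:2, 200, replace = TRUE), 20, 10)
  geno <- make_geno(dos, chrom = rep(c("chr1", "chr2"), 5),
                    pos = rep(seq(1e4, 5e4, 1e4), 2))
  ss <- make_sumstats(geno, rnorm(10), runif(10, 0.001, 0.9))
  cfg <- prs_config(p_threshold = 1, r2_threshold = 1)
  base <- build_prs(geno, ss, cfg)

  perm <- sample(10)
  geno_p <- genotype_matrix(dos[, perm], geno$snps[perm, ], geno$samples)
  expect_equal(sort(build_prs(geno_p, ss, cfg)$raw), sort(base$raw))
  expect_equal(build_prs(geno_p, ss, cfg)$raw, base$raw)

  # flip genotype orientation for half the SNPs: dosage -> 2 - dosage with
  # alleles swapped; summary statistics untouched
  flip <- c(1, 3, 5, 7, 9)
  dos_f <- dos; dos_f[, flip] <- 2 - dos_f[, flip]
  snps_f <- geno$snps
  tmp <- snps_f$effect_allele[flip]
  snps_f$effect_allele[flip] <- snps_f$other_allele[flip]
  snps_f$other_allele[flip] <- tmp
  geno_f <- genotype_matrix(dos_f, snps_f, geno$samples)
  expect_equal(build_prs(geno_f, ss, cfg)$raw, base$raw, tolerance = 1e-12)
})

test_that("degenerate scores raise informative errors", {
  dos <- matrix(0, 5, 2)
  geno <- make_geno(dos, chrom = c("chr1", "chr2"))
  ss <- make_sumstats(geno, c(0.5, 0.3), c(0.01, 0.02))
  expect_error(build_prs(geno, ss, prs_config(p_threshold = 1)),
               "zero variance")
  expect_error(build_prs(geno, ss, prs_config(p_threshold = 1e-8)),
               "zero SNPs")
})

test_that("region variants decompose the full score", {
  set.seed(25)
  dos <- matrix(sample(0:2, 600, replace = TRUE), 50, 12)
  geno <- make_geno(dos, chrom = rep(paste0("chr", 1:6), 2),
                    pos = rep(c(1e4, 9e6), each = 6))
  ss <- make_sumstats(geno, rnorm(12), runif(12, 1e-4, 0.5))
  excl <- c("snp1", "snp2")
  cfg <- prs_config(p_threshold = 1, r2_threshold = 1,
                    exclude_snp_ids = excl)
  v <- prs_variants(geno, ss, cfg)
  m <- length(v$full$included_snp_ids)
  m2 <- length(v$region_only$included_snp_ids)
  m1 <- length(v$without_region$included_snp_ids)
  expect_equal(m1 + m2, m)
  expect_setequal(v$region_only$included_snp_ids, excl)
  # full raw = weighted combination of the parts
  expect_equal(v$full$raw,
               (m1 * v$without_region$raw + m2 * v$region_only$raw) / m,
               tolerance = 1e-12)
  # empty exclusion list is rejected for variants
  expect_error(prs_variants(geno, ss, prs_config()), "non-empty")
  # but a no-op exclusion leaves the full score unchanged
  cfg2 <- prs_config(p_threshold = 1, r2_threshold = 1,
                     exclude_snp_ids = "rs_not_there")
  expect_warning(p2 <- build_prs(geno, ss, cfg2), "not in")
  expect_equal(p2$raw, v$full$raw)
})

test_that("threshold sweep is monotone in SNP count with nested kept sets", {
  co <- simulate_cohort(cohort_config(n_samples = 300, n_snps = 80,
                                      seed = 17, omics = list()))
  covs <- as.data.frame(co$phenotypes)[, attr(co$phenotypes, "covariates")]
  sw <- threshold_sweep(co$genotypes, co$sumstats,
                        thresholds = c(1e-4, 1e-3, 1e-2, 0.1, 0.5, 0.5, 1.0),
                        trait = co$phenotypes$cog_decline, covariates = covs)
  ok <- sw[sw$ok, ]
  expect_true(all(diff(ok$n_snps) >= 0))
  # duplicate thresholds give identical rows
  d <- sw[sw$threshold == 0.5, ]
  expect_equal(d$n_snps[1], d$n_snps[2])
  expect_equal(d$p_value[1], d$p_value[2])
  # threshold 1.0 includes every pruned candidate
  all_pruned <- prune_snps(co$sumstats[co$sumstats$pvalue < 1, ],
                           co$genotypes, 0.1, 2000)
  expect_equal(ok$n_snps[nrow(ok)], length(all_pruned))
})

test_that("stronger inclusion thresholds strengthen a polygenic association", {
  # planted polygenic outcome: the association sharpens from a 10-SNP score
  # to the score holding every candidate (including all causal SNPs)
  wins <- 0L
  for (rep in 1:25) {
    co <- simulate_cohort(cohort_config(n_samples = 800, n_snps = 60,
                                        n_causal = 30, gwas_n = 2000,
                                        h2_gwas = 0.4,
                                        effect_profile = "equal",
                                        seed = 100 + rep, omics = list()))
    covs <- as.data.frame(co$phenotypes)[, attr(co$phenotypes, "covariates")]
    thr10 <- sort(co$sumstats$pvalue)[10] * (1 + 1e-9)
    sw <- threshold_sweep(co$genotypes, co$sumstats,
                          thresholds = c(thr10, 1.0),
                          trait = co$phenotypes$cog_decline,
                          covariates = covs)
    if (all(sw$ok) && sw$p_value[2] <= sw$p_value[1]) wins <- wins + 1L
  }
  expect_gte(wins, 22)  # ~90% of replicates
})
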