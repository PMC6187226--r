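# Rank-inverse-normal transform, cis eQTH scan, and the three enrichment
# statistics with exact enumeration oracles.

test_that("rank-inverse-normal transform hits the closed-form quantiles", {
  x <- c(3, 1, 4, 2)
  qn <- quantile_normalize(x)
  expect_equal(sort(qn), qnorm(c(0.125, 0.375, 0.625, 0.875)))
  expect_equal(order(qn), order(x))  # monotone

  set.seed(91)
  z <- quantile_normalize(rexp(1000))
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(var(z) - 1), 0.05)

  expect_error(quantile_normalize(rep(2, 5)), "distinct")
  # ties get average ranks
  expect_equal(quantile_normalize(c(1, 1, 2))[1],
               quantile_normalize(c(1, 1, 2))[2])
})

test_that("the cis window is a hard boundary on the peak midpoint", {
  set.seed(92)
  n <- 50
  expr <- matrix(rnorm(n), 1, n,
                 dimnames = list("gA", paste0("s", 1:n)))
  peaks_mat <- matrix(rnorm(2 * n), 2, n,
                      dimnames = list(c("pIn", "pOut"), paste0("s", 1:n)))
  genes <- gene_table("gA", "chr1", "+", tss = 2e6, tes = 2.01e6)
  # midpoints: exactly at the window edge, and 1 bp beyond
  pk <- interval_set(c("chr1", "chr1"),
                     c(2e6 + 1e6 - 500, 2e6 + 1e6 + 501),
                     c(2e6 + 1e6 + 500, 2e6 + 1e6 + 1501),
                     c("pIn", "pOut"))
  res <- map_eqth(expr, peaks_mat, genes, pk, window_bp = 1e6)
  expect_equal(res$peak, "pIn")
  expect_equal(attr(res, "n_tests"), 1)
})

test_that("tested-pair count matches a brute-force double loop", {
  set.seed(93)
  n <- 30
  ng <- 50; np <- 200
  expr <- matrix(rnorm(ng * n), ng, n,
                 dimnames = list(paste0("g", 1:ng), paste0("s", 1:n)))
  pmat <- matrix(rnorm(np * n), np, n,
                 dimnames = list(paste0("p", 1:np), paste0("s", 1:n)))
  gchr <- sample(paste0("chr", 1:3), ng, replace = TRUE)
  gtss <- sample.int(2e7, ng)
  genes <- gene_table(paste0("g", 1:ng), gchr, rep("+", ng), gtss,
                      gtss + 1000)
  pchr <- sample(paste0("chr", 1:3), np, replace = TRUE)
  ps <- sample.int(2e7, np)
  pk <- interval_set(pchr, ps, ps + 1000, paste0("p", 1:np))
  res <- map_eqth(expr, pmat, genes, pk, window_bp = 1e6)
  n_brute <- 0L
  for (g in 1:ng) for (p in 1:np) {
    if (gchr[g] == pchr[p] && abs((ps[p] + 500) - gtss[g]) <= 1e6)
      n_brute <- n_brute + 1L
  }
  expect_equal(attr(res, "n_tests"), n_brute)
  expect_equal(attr(res, "threshold"), 0.05 / n_brute)

  # correlations match a naive per-pair oracle on the transformed data
  for (k in head(seq_len(nrow(res)), 5)) {
    g <- res$gene[k]; p <- res$peak[k]
    expect_equal(res$r[k],
                 cor(quantile_normalize(expr[g, ]),
                     quantile_normalize(pmat[p, ])), tolerance = 1e-10)
  }
})

test_that("a planted cis coupling is detected and results ignore sample order", {
  co <- simulate_cohort(cohort_config(n_samples = 400, n_snps = 30,
                                      seed = 95))
  res <- map_eqth(co$omics$expression, co$omics$acetylation, co$genes,
                  co$peaks)
  sig <- res[res$significant, ]
  planted <- co$truth$cis_pairs
  expect_true(all(paste(planted$gene, planted$peak) %in%
                  paste(sig$gene, sig$peak)))
  perm <- sample(400)
  res2 <- map_eqth(co$omics$expression[, perm],
                   co$omics$acetylation[, perm], co$genes, co$peaks)
  expect_equal(res2$r, res$r, tolerance = 1e-10)
  # disjoint cohorts cannot be scanned
  e2 <- co$omics$expression; colnames(e2) <- paste0("x", seq_len(ncol(e2)))
  expect_error(map_eqth(e2, co$omics$acetylation, co$genes, co$peaks),
               "shared")
})

test_that("Fisher interval enrichment matches exact enumeration", {
  # build intervals realizing the table [[10,10],[100,900]]
  mk <- function(n, prefix) {
    s <- seq(1e4, by = 1e4, length.out = n)
    interval_set(rep("chr1", n), s, s + 1000, paste0(prefix, seq_len(n)))
  }
  universe <- mk(1020, "pk")
  query <- paste0("pk", 1:20)            # 20 query peaks
  annotated_ids <- c(paste0("pk", 1:10),  # 10 of the query
                     paste0("pk", 21:120))  # 100 of the background
  idx <- match(annotated_ids, universe$name)
  annotation <- interval_set(universe$chrom[idx], universe$start[idx],
                             universe$end[idx], paste0("ann", idx))
  fe <- fisher_region_enrichment(query, annotation, universe)
  expect_equal(unname(fe$table[1, ]), c(10, 10))
  expect_equal(unname(fe$table[2, ]), c(100, 900))
  expect_equal(fe$p_value, oracle_fisher2(fe$table), tolerance = 1e-12)

  # equal annotation rates in query and background: OR = 1
  ann_eq <- universe[seq(1, 1020, 2), ]
  tabeq <- fisher_region_enrichment(paste0("pk", 1:500), ann_eq, universe)
  expect_lt(abs(log(tabeq$odds_ratio)), 0.05)

  expect_error(fisher_region_enrichment(character(0), annotation, universe),
               "empty")
  expect_error(fisher_region_enrichment("nope", annotation, universe),
               "outside")
})

test_that("hypergeometric and binomial tails match direct enumeration", {
  expect_equal(hypergeom_enrichment(0, 10, 20, 100), 1)
  expect_equal(hypergeom_enrichment(5, 10, 20, 100),
               oracle_hyper_upper(5, 10, 20, 100), tolerance = 1e-12)
  # set = universe: every draw is a hit
  expect_equal(hypergeom_enrichment(20, 100, 20, 100), 1)
  expect_error(hypergeom_enrichment(25, 10, 20, 100), "inconsistent")

  dom <- interval_set("chr1", 0, 100, "d")
  snps <- data.frame(chrom = rep("chr1", 20), pos = rep(50, 20))
  expect_equal(binomial_snp_enrichment(snps, dom, 100)$p_value, 1)
  expect_equal(binomial_snp_enrichment(snps, dom, 1000)$p_value, 0.1^20)
  # (n = 30, f = 0.25, k = 12) against the summed pmf
  set.seed(96)
  dom2 <- interval_set("chr1", 0, 2.5e5, "d")
  pos <- c(sample.int(2.5e5, 12), 2.5e5 + sample.int(7.5e5, 18))
  snps2 <- data.frame(chrom = "chr1", pos = pos)
  b <- binomial_snp_enrichment(snps2, dom2, 1e6)
  expect_equal(b$k, 12)
  expect_equal(b$fraction, 0.25)
  expect_equal(b$p_value, oracle_binom_upper(12, 30, 0.25),
               tolerance = 1e-12)
  expect_error(binomial_snp_enrichment(snps2[0, ], dom2, 1e6), "no SNPs")
})

test_that("enrichment tails are monotone in the hit count", {
  hp <- vapply(0:10, hypergeom_enrichment, 0, K = 10, n = 20, N = 100)
  expect_true(all(diff(hp) <= 1e-15))
  dom <- interval_set("chr1", 0, 2.5e5, "d")
  bp <- vapply(0:10, function(k) {
    pos <- c(sample.int(2.5e5, k), 2.5e5 + sample.int(7.5e5, 10 - k))
    binomial_snp_enrichment(data.frame(chrom = "chr1", pos = pos), dom,
                            1e6)$p_value
  }, 0)
  expect_true(all(diff(bp) <= 1e-15))
})

test_that("regulatory domains extend, truncate, clip and merge", {
  # isolated gene: body +/- 1 Mb
  g1 <- gene_table("solo", "chr5", "+", tss = 5e6, tes = 5.02e6)
  d1 <- assign_regulatory_domains(g1, list(set = "solo"))$set
  expect_equal(d1$start, 4e6 - 1)          # 1-based 4,000,000 -> 0-based
  expect_equal(d1$end, 6.02e6)

  # neighbor body starting 200 kb downstream truncates the extension there
  g2 <- gene_table(c("g", "nb"), c("chr1", "chr1"), c("+", "+"),
                   tss = c(1e6, 1.22e6), tes = c(1.02e6, 1.24e6))
  d2 <- assign_regulatory_domains(g2, list(s = "g"))$s
  expect_equal(d2$end, 1.22e6)
  # and the left edge clips at position 1
  expect_equal(d2$start, 0)

  # overlapping member domains merge; coverage matches a sweep-line oracle
  g3 <- gene_table(c("a", "b", "c"), c("chr2", "chr2", "chr3"),
                   c("+", "-", "+"),
                   tss = c(3e6, 4.8e6, 9e6), tes = c(3.1e6, 4.5e6, 9.1e6))
  dom <- assign_regulatory_domains(g3, list(s = c("a", "b", "c")))$s
  # each gene's domain recomputed independently (the a--b gap exceeds 1 Mb,
  # so no truncation applies; bodies are a: 3-3.1 Mb, b: 4.5-4.8 Mb), then
  # unioned by sweep line in the same 0-based half-open coordinates
  expected <- oracle_union_length(
    c("chr2", "chr2", "chr3"),
    c(2e6 - 1, 3.5e6 - 1, 8e6 - 1),
    c(4.1e6, 5.8e6, 10.1e6))
  expect_equal(sum(dom$end - dom$start), expected)
  expect_true(all(dom$start < dom$end))
  # merged intervals never overlap
  for (cc in unique(dom$chrom)) {
    dd <- dom[dom$chrom == cc, ]
    dd <- dd[order(dd$start), ]
    if (nrow(dd) > 1) expect_true(all(dd$start[-1] >= dd$end[-nrow(dd)]))
  }
  expect_error(assign_regulatory_domains(g3, list(s = "ghost")), "ghost")
})
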