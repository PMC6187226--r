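# Independent oracles and small fixture builders shared across test files.
# Each oracle recomputes a quantity from its definition, by a route
# independent of the package implementation it checks.

# --- sequential-R^2 (LMG) PAEM oracle via explicit least squares -----------

oracle_paem_lm <- function(y, p, m) {
  r2 <- function(fit) summary(fit)$r.squared
  r2_p <- r2(lm(y ~ p))
  r2_m <- r2(lm(y ~ m))
  r2_pm <- r2(lm(y ~ p + m))
  # incremental R^2 of the score averaged over both orders of entry
  inc_first <- r2_p
  inc_second <- r2_pm - r2_m
  pve2 <- (inc_first + inc_second) / 2
  list(pve1 = r2_p, r2_full = r2_pm, ri_prs = pve2 / r2_pm,
       pve_prs2 = pve2, paem = 100 * (r2_p - pve2) / r2_p)
}

# --- greedy LD-clumping oracle: literal application of the rule ------------

oracle_prune <- function(ss, dosages, r2_threshold, window_kb) {
  ord <- order(ss$pvalue, ss$chrom, ss$pos)
  kept <- character(0)
  for (i in ord) {
    blocked <- FALSE
    for (kid in kept) {
      k <- which(ss$snp_id == kid)
      if (ss$chrom[k] == ss$chrom[i] &&
          abs(ss$pos[k] - ss$pos[i]) <= window_kb * 1000) {
        r <- suppressWarnings(cor(dosages[, ss$snp_id[i]],
                                  dosages[, ss$snp_id[k]]))
        if (!is.na(r) && r^2 > r2_threshold) { blocked <- TRUE; break }
      }
    }
    if (!blocked) kept <- c(kept, ss$snp_id[i])
  }
  kept
}

# --- exact enumeration oracles for the enrichment tests --------------------

# two-sided Fisher p: sum of hypergeometric pmf values not exceeding the
# observed one (with the standard relative-tolerance tie rule)
oracle_fisher2 <- function(tab) {
  k <- tab[1, 1]
  K <- sum(tab[1, ])          # query size
  n <- sum(tab[, 1])          # annotated total
  N <- sum(tab)
  supp <- max(0, K + n - N):min(K, n)
  pmf <- dhyper(supp, n, N - n, K)
  sum(pmf[pmf <= pmf[supp == k] * (1 + 1e-7)])
}

oracle_hyper_upper <- function(k, K, n, N) {
  supp <- max(0, K + n - N):min(K, n)
  pmf <- dhyper(supp, K, N - K, n)
  sum(pmf[supp >= k])
}

oracle_binom_upper <- function(k, n, f) {
  sum(choose(n, k:n) * f^(k:n) * (1 - f)^(n - (k:n)))
}

# --- interval union length by sweep-line -----------------------------------

oracle_union_length <- function(chrom, start, end) {
  tot <- 0
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    o <- order(start[idx])
    s <- start[idx][o]; e <- end[idx][o]
    cur_s <- s[1]; cur_e <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] > cur_e) { tot <- tot + cur_e - cur_s; cur_s <- s[i]; cur_e <- e[i] }
      else cur_e <- max(cur_e, e[i])
    }
    tot <- tot + cur_e - cur_s
  }
  tot
}

# --- adjusted Rand index (contingency-table definition) --------------------

oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  expected <- si * sj / ch2(n)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# --- fixture builders ------------------------------------------------------

# genotype matrix with explicit dosages and a one-chromosome SNP map
make_geno <- function(dosages, chrom = NULL, pos = NULL) {
  m <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1e4
  snps <- snp_table(paste0("snp", seq_len(m)), chrom, pos,
                    rep("A", m), rep("G", m))
  genotype_matrix(dosages, snps)
}

make_sumstats <- function(geno, beta, pvalue) {
  summary_stats(geno$snps, beta, pvalue)
}

# features x samples matrix with two planted correlated blocks
make_two_block <- function(block_size = 50, n = 300, r = 0.8, seed = 1) {
  set.seed(seed)
  g1 <- rnorm(n); g2 <- rnorm(n)
  mat <- rbind(
    sqrt(r) * matrix(g1, block_size, n, byrow = TRUE) +
      sqrt(1 - r) * matrix(rnorm(block_size * n), block_size, n),
    sqrt(r) * matrix(g2, block_size, n, byrow = TRUE) +
      sqrt(1 - r) * matrix(rnorm(block_size * n), block_size, n))
  rownames(mat) <- paste0("f", seq_len(2 * block_size))
  colnames(mat) <- paste0("s", seq_len(n))
  mat
}

# random valid summary-stats table for io round-trips
random_sumstats <- function(m = 20, seed = 1) {
  set.seed(seed)
  snps <- snp_table(paste0("rs", seq_len(m)),
                    sample(paste0("chr", 1:5), m, replace = TRUE),
                    sample.int(1e6, m),
                    sample(c("A", "C"), m, replace = TRUE),
                    sample(c("G", "T"), m, replace = TRUE))
  summary_stats(snps, rnorm(m), runif(m, 1e-8, 1))
}
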