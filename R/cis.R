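# cis expression-acetylation mapping and region-enrichment statistics:
# rank-based inverse-normal transform, windowed correlation scan with
# Bonferroni control, Fisher's exact interval-overlap enrichment against a
# peak universe, hypergeometric module enrichment, GREAT-style regulatory
# domains, and the binomial SNP-in-domain test.

#' Rank-based inverse-normal transform
#'
#' `value -> Phi^-1((rank - 0.5) / n)` with average ranks for ties.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @return transformed vector.
#' @export
quantile_normalize <- function(x) {
  if (length(unique(x[!is.na(x)])) < 2)
    stop("need at least 2 distinct values")
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / sum(ok))
  out
}

#' cis expression-acetylation (eQTH) scan
#'
#' Pearson correlation between each gene's expression and each acetylation
#' peak whose midpoint lies within `window_bp` of the gene's TSS on the same
#' chromosome. Both matrices are rank-inverse-normal transformed per feature
#' before the scan. The significance threshold is Bonferroni:
#' `alpha / n_tests`.
#'
#' @param expr genes x individuals matrix (rownames = gene ids).
#' @param peak_mat peaks x individuals matrix (rownames = peak ids).
#' @param genes a [gene_table()] covering the rows of `expr`.
#' @param peaks an [interval_set()] covering the rows of `peak_mat`.
#' @param window_bp cis window around the TSS (default 1e6).
#' @param alpha family-wise error rate (default 0.05).
#' @param normalize apply [quantile_normalize()] per feature (default TRUE).
#' @return data.frame of class `eqth_result`: gene, peak, r, p_value,
#'   distance (peak midpoint minus TSS, signed), significant; attributes
#'   `n_tests` and `threshold`.
#' @export
map_eqth <- function(expr, peak_mat, genes, peaks, window_bp = 1e6,
                     alpha = 0.05, normalize = TRUE) {
  shared <- intersect(colnames(expr), colnames(peak_mat))
  if (length(shared) == 0) stop("no shared individuals between matrices")
  E <- as.matrix(expr[, shared, drop = FALSE])
  A <- as.matrix(peak_mat[, shared, drop = FALSE])
  if (normalize) {
    E <- t(apply(E, 1, quantile_normalize))
    A <- t(apply(A, 1, quantile_normalize))
  }
  gi <- match(rownames(E), genes$gene_id)
  if (anyNA(gi)) stop("gene coordinates missing for some expression rows")
  pi_ <- match(rownames(A), peaks$name)
  if (anyNA(pi_)) stop("peak coordinates missing for some peak rows")
  mid <- (peaks$start[pi_] + peaks$end[pi_]) / 2
  pchr <- peaks$chrom[pi_]
  n <- length(shared)
  zs <- function(m) {
    mc <- m - rowMeans(m)
    mc / sqrt(rowSums(mc^2))
  }
  R <- tcrossprod(zs(E), zs(A))  # genes x peaks correlations
  rows <- vector("list", nrow(E))
  for (g in seq_len(nrow(E))) {
    sel <- which(pchr == genes$chrom[gi[g]] &
                 abs(mid - genes$tss[gi[g]]) <= window_bp)
    if (length(sel) == 0) next
    r <- R[g, sel]
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    rows[[g]] <- data.frame(gene = rownames(E)[g],
                            peak = rownames(A)[sel], r = r, p_value = p,
                            distance = mid[sel] - genes$tss[gi[g]],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), peak = character(0),
                      r = numeric(0), p_value = numeric(0),
                      distance = numeric(0))
  n_tests <- nrow(out)
  thr <- if (n_tests > 0) bonferroni_threshold(alpha, n_tests) else NA_real_
  out$significant <- out$p_value < thr
  rownames(out) <- NULL
  attr(out, "n_tests") <- n_tests
  attr(out, "threshold") <- thr
  class(out) <- c("eqth_result", "data.frame")
  out
}

#' Fisher's exact interval-overlap enrichment
#'
#' A peak counts as annotated when it overlaps the annotation by >= 1 bp.
#' The 2x2 table query/non-query x annotated/not is tested with the
#' two-sided Fisher exact test against the peak universe.
#'
#' @param query character vector of query peak names (subset of the
#'   universe).
#' @param annotation an [interval_set()] of annotation intervals.
#' @param universe an [interval_set()] of all peaks (the background).
#' @return list: `odds_ratio` (sample OR; `Inf`/0 possible on degenerate
#'   cells), `p_value`, `table`.
#' @export
fisher_region_enrichment <- function(query, annotation, universe) {
  if (length(query) == 0) stop("empty query set")
  if (!all(query %in% universe$name))
    stop("query contains peaks outside the universe")
  hits <- GenomicRanges::countOverlaps(.as_granges(universe),
                                       .as_granges(annotation)) > 0
  isq <- universe$name %in% query
  tab <- matrix(c(sum(isq & hits), sum(isq & !hits),
                  sum(!isq & hits), sum(!isq & !hits)),
                2, 2, byrow = TRUE,
                dimnames = list(c("query", "background"),
                                c("annotated", "not")))
  ft <- fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = ft$p.value, table = tab)
}

#' Hypergeometric (upper-tail) enrichment test
#'
#' `P(X >= k)` where X counts hits in a set of size `K` when `n` hits are
#' drawn from a universe of size `N`.
#'
#' @param k hits in the set; `K` set size; `n` total hits; `N` universe size.
#' @param K,n,N see `k`.
#' @return upper-tail p-value.
#' @export
hypergeom_enrichment <- function(k, K, n, N) {
  if (k > min(K, n) || n > N || K > N || k < 0)
    stop("inconsistent hypergeometric counts")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GREAT-style regulatory domains for gene sets
#'
#' Each gene's domain runs from 1,000 kb upstream of its body to 1,000 kb
#' downstream (the body is TSS..TES regardless of strand), truncated on each
#' side at the nearest point where another gene's body starts (zero extension
#' on a side where bodies overlap), clipped at position 1 and, when
#' `chrom_lengths` is supplied, at the chromosome end. Member-gene domains of
#' a set are merged into non-overlapping intervals.
#'
#' @param genes a [gene_table()].
#' @param gene_sets named list of gene-id vectors.
#' @param extension_bp extension on each side (default 1e6).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return named list of class `regulatory_domain`: one merged
#'   [interval_set()] per gene set.
#' @export
assign_regulatory_domains <- function(genes, gene_sets, extension_bp = 1e6,
                                      chrom_lengths = NULL) {
  body_s <- pmin(genes$tss, genes$tes)
  body_e <- pmax(genes$tss, genes$tes)
  n <- nrow(genes)
  dom_s <- numeric(n); dom_e <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(genes$chrom == genes$chrom[i])
    same <- setdiff(same, i)
    left <- body_s[i] - extension_bp
    right <- body_e[i] + extension_bp
    if (length(same) > 0) {
      overl_l <- same[body_s[same] < body_s[i] & body_e[same] >= body_s[i]]
      overl_r <- same[body_e[same] > body_e[i] & body_s[same] <= body_e[i]]
      lefts <- same[body_e[same] < body_s[i]]
      rights <- same[body_s[same] > body_e[i]]
      if (length(overl_l) > 0) left <- body_s[i]
      else if (length(lefts) > 0) left <- max(left, max(body_e[lefts]))
      if (length(overl_r) > 0) right <- body_e[i]
      else if (length(rights) > 0) right <- min(right, min(body_s[rights]))
    }
    left <- max(left, 1)
    if (!is.null(chrom_lengths) && genes$chrom[i] %in% names(chrom_lengths))
      right <- min(right, chrom_lengths[[genes$chrom[i]]])
    dom_s[i] <- left; dom_e[i] <- right
  }
  out <- list()
  for (set in names(gene_sets)) {
    idx <- match(gene_sets[[set]], genes$gene_id)
    if (anyNA(idx))
      stop("gene set '", set, "' references unknown gene(s): ",
           paste(gene_sets[[set]][is.na(idx)], collapse = ", "))
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      genes$chrom[idx], IRanges::IRanges(start = dom_s[idx],
                                         end = dom_e[idx])))
    out[[set]] <- interval_set(as.character(GenomicRanges::seqnames(gr)),
                               GenomicRanges::start(gr) - 1L,
                               GenomicRanges::end(gr),
                               paste0(set, "_", seq_along(gr)))
  }
  class(out) <- "regulatory_domain"
  out
}

#' Binomial test for SNP enrichment in a regulatory domain
#'
#' With `f` the fraction of the genome covered by the (merged) domain, the
#' number of the `n` SNPs falling inside is compared to `Binomial(n, f)`;
#' upper-tail p-value.
#'
#' @param snps data.frame with `chrom` and `pos` (1-based) columns, e.g. a
#'   [snp_table()].
#' @param domain an [interval_set()] of merged domain intervals (one gene
#'   set's domain).
#' @param genome_length total genome length in bp.
#' @return list: `p_value`, `k` (SNPs inside), `n`, `fraction`.
#' @export
binomial_snp_enrichment <- function(snps, domain, genome_length) {
  n <- nrow(snps)
  if (is.null(n) || n == 0) stop("no SNPs supplied")
  cover <- sum(domain$end - domain$start)
  if (genome_length < cover)
    stop("genome_length smaller than domain coverage")
  f <- cover / genome_length
  inside <- logical(n)
  for (i in seq_len(n)) {
    inside[i] <- any(domain$chrom == snps$chrom[i] &
                     domain$start < snps$pos[i] &
                     snps$pos[i] <= domain$end)
  }
  k <- sum(inside)
  p <- if (f >= 1) 1 else pbinom(k - 1, n, f, lower.tail = FALSE)
  list(p_value = p, k = k, n = n, fraction = f)
}
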