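# Trait/SNP architecture mapping: signed SNP-trait association profiles,
# sign binarization with alignment to a reference diagnosis trait, Jaccard
# distances, a 2-D stochastic-neighbor embedding, and consensus clustering of
# SNPs by their trait-association patterns.

#' Signed SNP-trait association matrix
#'
#' Pearson correlation of each SNP dosage with each residualized trait. If a
#' trait correlates negatively with the reference trait (e.g. the disease
#' diagnosis), its whole row of association signs is flipped so SNP effects
#' are aligned across traits.
#'
#' @param genotypes a [genotype_matrix()] restricted to the score's SNPs.
#' @param traits data.frame of trait vectors (one column per trait), aligned
#'   to the genotype samples.
#' @param covariates data.frame of covariates used to residualize each trait.
#' @param reference reference trait vector for sign alignment (or `NULL` to
#'   skip alignment).
#' @return traits x SNPs numeric matrix of signed correlations, attribute
#'   `flipped` marking re-aligned traits.
#' @export
snp_trait_associations <- function(genotypes, traits, covariates,
                                   reference = NULL) {
  traits <- as.data.frame(traits)
  const <- vapply(traits, function(v) sd(v, na.rm = TRUE) == 0, TRUE)
  if (any(const))
    stop("constant trait(s): ", paste(names(traits)[const], collapse = ", "))
  dos <- genotypes$dosages
  res <- vapply(traits, residualize, numeric(nrow(traits)),
                covariates = covariates)
  stat <- suppressWarnings(t(cor(res, dos, use = "pairwise.complete.obs")))
  stat <- t(stat)  # traits x SNPs
  flipped <- rep(FALSE, ncol(traits))
  names(flipped) <- names(traits)
  if (!is.null(reference)) {
    rr <- vapply(seq_len(ncol(res)), function(j)
      suppressWarnings(cor(res[, j], reference,
                           use = "pairwise.complete.obs")), 0)
    flipped <- !is.na(rr) & rr < 0
    names(flipped) <- names(traits)
    stat[flipped, ] <- -stat[flipped, , drop = FALSE]
  }
  rownames(stat) <- names(traits)
  colnames(stat) <- genotypes$snps$snp_id
  attr(stat, "flipped") <- flipped
  stat
}

#' Binarize association statistics by direction of effect
#'
#' @param stat signed statistic matrix.
#' @return 0/1 matrix; 1 where the statistic is strictly positive.
#' @export
binarize_signs <- function(stat) {
  out <- (stat > 0) * 1
  out[is.na(out)] <- 0
  out
}

#' Jaccard distance between binary row profiles
#'
#' `d(t, u) = 1 - |P_t intersect P_u| / |P_t union P_u|` where `P_t` is the
#' set of columns with a 1 in row `t`; the distance is 0 when both sets are
#' empty.
#'
#' @param bin binary matrix (rows = items).
#' @return symmetric distance matrix with zero diagonal, values in `[0, 1]`.
#' @export
jaccard_distance <- function(bin) {
  bin <- as.matrix(bin) * 1
  if (ncol(bin) < 1) stop("need at least one column")
  inter <- tcrossprod(bin)
  sizes <- rowSums(bin)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(bin), rownames(bin))
  d
}

# exact t-SNE on a precomputed distance matrix (written in base R; no R
# t-SNE implementation is part of this package's dependency set).
# Conditional similarities are perplexity-calibrated by bisection on the
# Gaussian bandwidth; the 2-D map minimizes KL(P || Q) by gradient descent
# with momentum and early exaggeration.
.tsne_exact <- function(D, perplexity, n_iter, seed) {
  n <- nrow(D)
  D2 <- D^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0 } else {
        pj <- w / sw
        H <- -sum(pj[pj > 0] * log(pj[pj > 0]))
      }
      if (abs(H - logU) < 1e-7) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2
                                          else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2
                                 else beta / 2 }
    }
    w <- exp(-di * beta)
    P[i, -i] <- if (sum(w) > 0) w / sum(w) else 1 / (n - 1)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  momentum <- 0.5
  eta <- 100
  exag <- 12
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= min(250, n_iter / 4)) P * exag else P
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    if (it == 250) momentum <- 0.8
    G <- momentum * G - eta * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Embed traits in two dimensions from a distance matrix
#'
#' t-SNE on the precomputed trait-trait distances (perplexity-calibrated
#' Gaussian similarities, Student-t low-dimensional kernel, seeded gradient
#' descent). Coordinates are deterministic given the seed; the contract is
#' neighborhood preservation, not specific coordinates.
#'
#' @param dist_matrix symmetric distance matrix with zero diagonal (>= 4
#'   rows).
#' @param perplexity target perplexity (default 5); clamped with a warning to
#'   `(n - 1) / 3` when too large for the input size.
#' @param n_iter gradient-descent iterations (default 10000).
#' @param seed RNG seed for the map initialization.
#' @return n x 2 coordinate matrix (rownames preserved), attributes
#'   `perplexity`, `n_iter`, `seed`.
#' @export
embed_traits <- function(dist_matrix, perplexity = 5, n_iter = 10000,
                         seed = 1L) {
  D <- as.matrix(dist_matrix)
  if (nrow(D) < 4) stop("need at least 4 items to embed")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(D)
  pmax_perp <- (n - 1) / 3
  if (perplexity >= pmax_perp) {
    warning("perplexity clamped to ", signif(pmax_perp * 0.99, 3),
            " for ", n, " items")
    perplexity <- pmax_perp * 0.99
  }
  Y <- .tsne_exact(D, perplexity, n_iter, seed)
  rownames(Y) <- rownames(D)
  colnames(Y) <- c("dim1", "dim2")
  attr(Y, "perplexity") <- perplexity
  attr(Y, "n_iter") <- n_iter
  attr(Y, "seed") <- seed
  Y
}

#' Cluster SNPs by their trait-association profiles
#'
#' Jaccard distances between SNP columns of the binarized sign matrix;
#' consensus label propagation (as in [detect_modules()]) on the similarity
#' matrix `1 - distance`.
#'
#' @param sign_matrix traits x SNPs 0/1 matrix (from [binarize_signs()]).
#' @param n_runs,co_threshold,edge_threshold,seed consensus parameters, as in
#'   [detect_modules()].
#' @return list of class `module_assignment` labelling every SNP.
#' @export
cluster_snps <- function(sign_matrix, n_runs = 50, co_threshold = 0.5,
                         edge_threshold = 0.2, seed = 1L) {
  bin <- as.matrix(sign_matrix)
  if (ncol(bin) < 2) stop("need at least 2 SNPs")
  if (all(bin == 0))
    warning("all-zero sign matrix; SNP profiles are indistinguishable")
  ids <- colnames(bin)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(bin)))
  sim <- 1 - jaccard_distance(t(bin))
  .consensus_cluster(sim, n_runs = n_runs, co_threshold = co_threshold,
                     edge_threshold = edge_threshold, seed = seed,
                     ids = ids, layer = "snp")
}
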