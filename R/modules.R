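# Omics module detection and summarization: a GTEx-style sample-outlier
# filter, consensus label propagation on the |correlation|-weighted feature
# graph, and per-individual module scores (mean of z-scored members).

#' Sample outlier filter (correlation-with-median statistic)
#'
#' For each sample, `d_i` is the Pearson correlation between its feature
#' vector and the per-feature median across samples. Samples with
#' `d_i < Q1 - k * IQR` (lower-side fence over the `d_i` distribution) are
#' excluded; samples whose `d_i` is undefined (constant feature vector) are
#' excluded with a warning.
#'
#' @param mat features x samples numeric matrix (>= 4 samples).
#' @param k fence multiplier (default 1.5); `Inf` disables exclusion.
#' @return character/integer vector of kept sample identifiers (column names
#'   if present, else indices), preserving order. The `d` statistics are
#'   attached as attribute `d`.
#' @export
sample_outlier_filter <- function(mat, k = 1.5) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 4) stop("need at least 4 samples")
  med <- apply(mat, 1, median)
  d <- suppressWarnings(as.numeric(cor(mat, med)))
  undef <- !is.finite(d)
  if (any(undef))
    warning("excluding ", sum(undef),
            " sample(s) with undefined correlation statistic")
  q <- quantile(d[!undef], c(0.25, 0.75), names = FALSE)
  fence <- q[1] - k * (q[2] - q[1])
  keep <- !undef & !(d < fence)
  ids <- colnames(mat)
  out <- if (is.null(ids)) which(keep) else ids[keep]
  attr(out, "d") <- d
  out
}

# one stochastic label-propagation run on a weighted graph, via igraph;
# returns an integer membership vector
.lp_run <- function(g) {
  igraph::membership(igraph::cluster_label_prop(g))
}

#' Consensus module detection on a feature correlation network
#'
#' Features are nodes of a graph weighted by `|r|` (Pearson correlation
#' across individuals), keeping edges with `|r| >= edge_threshold`.
#' Stochastic label propagation runs `n_runs` times with shuffled update
#' orders; pairs co-assigned in at least `co_threshold` of runs are linked,
#' and final modules are the connected components of those links. Singletons
#' are allowed.
#'
#' @param mat features x individuals numeric matrix (>= 2 features).
#' @param n_runs number of label-propagation runs (default 50).
#' @param co_threshold co-assignment frequency required to link a pair
#'   (default 0.5).
#' @param edge_threshold minimum `|r|` for a graph edge (default 0.2).
#' @param seed RNG seed making the consensus deterministic.
#' @return list of class `module_assignment`: `labels` (named integer vector,
#'   contiguous from 1), `members` (list per module), `n_modules`,
#'   `layer`.
#' @param layer layer name carried through.
#' @export
detect_modules <- function(mat, n_runs = 50, co_threshold = 0.5,
                           edge_threshold = 0.2, seed = 1L,
                           layer = "layer") {
  mat <- as.matrix(mat)
  p <- nrow(mat)
  if (p < 2) stop("need at least 2 features")
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("f", seq_len(p))
  cm <- suppressWarnings(abs(cor(t(mat))))
  cm[!is.finite(cm)] <- 0
  .consensus_cluster(cm, n_runs = n_runs, co_threshold = co_threshold,
                     edge_threshold = edge_threshold, seed = seed,
                     ids = ids, layer = layer)
}

# consensus label propagation on a symmetric similarity matrix in [0,1]
.consensus_cluster <- function(sim, n_runs, co_threshold, edge_threshold,
                               seed, ids, layer) {
  p <- nrow(sim)
  diag(sim) <- 0
  adj <- sim
  adj[adj < edge_threshold] <- 0
  if (all(adj == 0))
    warning("no feature pair passes the edge threshold; all singletons")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  co <- matrix(0, p, p)
  for (r in seq_len(n_runs)) {
    memb <- .lp_run(g)
    co <- co + outer(memb, memb, "==")
  }
  co <- co / n_runs
  link <- (co >= co_threshold)
  diag(link) <- FALSE
  gl <- igraph::graph_from_adjacency_matrix(link, mode = "undirected")
  comp <- igraph::components(gl)$membership
  labels <- as.integer(factor(comp, levels = unique(comp)))
  names(labels) <- ids
  members <- split(ids, labels)
  structure(list(labels = labels, members = members,
                 n_modules = length(members), layer = layer),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  sizes <- lengths(x$members)
  cat("module_assignment (", x$layer, "): ", x$n_modules, " modules over ",
      length(x$labels), " features (", sum(sizes > 1),
      " non-singleton)\n", sep = "")
  invisible(x)
}

#' Per-individual module summary scores
#'
#' Each feature is z-scored across individuals (subtract its mean, divide by
#' its SD); a module's score for an individual is the mean of its members'
#' z-scores.
#'
#' @param mat features x individuals matrix.
#' @param assignment a `module_assignment` over the rows of `mat`.
#' @return modules x individuals matrix of class `module_scores`, rownames
#'   `"<layer>_m<label>"`.
#' @export
summarize_modules <- function(mat, assignment) {
  mat <- as.matrix(mat)
  sds <- apply(mat, 1, sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(rownames(mat)[sds == 0], collapse = ", "))
  z <- (mat - rowMeans(mat)) / sds
  labs <- assignment$labels
  stopifnot(length(labs) == nrow(mat))
  out <- t(vapply(sort(unique(labs)), function(l) {
    colMeans(z[labs == l, , drop = FALSE])
  }, numeric(ncol(mat))))
  rownames(out) <- paste0(assignment$layer, "_m", sort(unique(labs)))
  colnames(out) <- colnames(mat)
  class(out) <- c("module_scores", class(out))
  out
}
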