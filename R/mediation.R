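# The PAEM statistic: percent of a polygenic score's effect on an outcome
# explained by a mediator. PVE1 is the R^2 of outcome ~ score; the score's
# share of the two-regressor model R^2 is its LMG (Chevan-Sutherland) relative
# importance, i.e. its incremental R^2 averaged over both orders of model
# entry, normalized so the two shares sum to the model R^2. Then
#   PVE_prs2 = R^2(y ~ prs + M) * RI_prs
#   PAEM     = 100 * (PVE1 - PVE_prs2) / PVE1
# Inference is by permutation of the mediator across individuals.

.paem_core <- function(y, prs, mediator) {
  use <- !is.na(y) & !is.na(prs) & !is.na(mediator)
  y <- y[use]; prs <- prs[use]; mediator <- mediator[use]
  n <- length(y)
  if (n < 4) stop("too few complete cases")
  if (sd(prs) == 0 || sd(mediator) == 0 || sd(y) == 0)
    stop("constant input vector")
  r_pm <- cor(prs, mediator)
  if (abs(r_pm) >= 0.999)
    stop("mediator is collinear with the score (|r| >= 0.999)")
  r_py <- cor(prs, y)
  r_my <- cor(mediator, y)
  st <- .paem_from_cor(r_py, r_my, r_pm)
  if (st$pve1 <= 0) stop("no PRS effect to decompose (PVE1 <= 0)")
  c(st, list(n = n, ss_total = sum((y - mean(y))^2),
             r_py = r_py, r_my = r_my, r_pm = r_pm))
}

#' PAEM point estimate
#'
#' @param y outcome vector (e.g. a residualized cognitive-decline slope).
#' @param prs scaled polygenic score.
#' @param mediator candidate mediator vector.
#' @param mediator_name label carried into the result.
#' @return one-row data.frame: mediator, n, ss_total, pve1 (R^2 of
#'   y ~ prs), r2_full (R^2 of y ~ prs + mediator), ri_prs (LMG share of the
#'   score, in `[0,1]`), pve_prs2, paem, and `flag` (`"outside[0,100]"` when
#'   the finite-sample value leaves that range; never clamped).
#' @export
compute_paem <- function(y, prs, mediator, mediator_name = "mediator") {
  st <- .paem_core(y, prs, mediator)
  flag <- if (st$paem < 0 || st$paem > 100) "outside[0,100]" else ""
  data.frame(mediator = mediator_name, n = st$n, ss_total = st$ss_total,
             pve1 = st$pve1, r2_full = st$r2_full, ri_prs = st$ri_prs,
             pve_prs2 = st$pve_prs2, paem = st$paem, flag = flag,
             stringsAsFactors = FALSE)
}

#' Permutation null for the PAEM statistic
#'
#' Mediator values are permuted across individuals; the p-value uses the
#' add-one estimator `p = (1 + #[PAEM_null >= PAEM_obs]) / (1 + n_perm)`.
#' Degenerate permutation draws (e.g. a permuted mediator collinear with the
#' score) are scored as 0 and counted in a `n_degenerate` field.
#'
#' @inheritParams compute_paem
#' @param n_perm number of permutations (>= 1).
#' @param seed optional RNG seed for reproducible permutations.
#' @return list: `p_value`, `observed`, `null` (vector of permuted PAEM
#'   values), `n_perm`, `n_degenerate`.
#' @export
permutation_null <- function(y, prs, mediator, n_perm = 10000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  use <- !is.na(y) & !is.na(prs) & !is.na(mediator)
  y <- y[use]; prs <- prs[use]; mediator <- mediator[use]
  obs <- .paem_core(y, prs, mediator)$paem
  n <- length(y)
  ys <- as.numeric(scale(y)); ps <- as.numeric(scale(prs))
  ms <- as.numeric(scale(mediator))
  r_py <- sum(ps * ys) / (n - 1)
  null <- numeric(n_perm)
  ndeg <- 0L
  for (i in seq_len(n_perm)) {
    mp <- ms[sample.int(n)]
    r_my <- sum(mp * ys) / (n - 1)
    r_pm <- sum(mp * ps) / (n - 1)
    if (abs(r_pm) >= 0.999 || r_py^2 <= 0) {
      ndeg <- ndeg + 1L
      null[i] <- 0
      next
    }
    v <- .paem_from_cor(r_py, r_my, r_pm)$paem
    if (!is.finite(v)) { ndeg <- ndeg + 1L; v <- 0 }
    null[i] <- v
  }
  list(p_value = (1 + sum(null >= obs)) / (1 + n_perm), observed = obs,
       null = null, n_perm = n_perm, n_degenerate = ndeg)
}

#' Fit the PAEM mediation model
#'
#' The package's central fitting function: computes the PAEM variance
#' decomposition for one mediator and (optionally) its permutation null.
#'
#' @inheritParams compute_paem
#' @param data optional data.frame; if given, `y`, `prs`, `mediator` may be
#'   column names.
#' @param n_perm permutations for the null (0 to skip).
#' @param seed RNG seed for the permutations.
#' @return object of class `paem`: the fields of [compute_paem()] plus
#'   `perm_p`, `null`, `n_perm`, `n_degenerate`, and the two fitted linear
#'   models (`fit1`: y ~ prs, `fit2`: y ~ prs + mediator).
#' @examples
#' set.seed(1)
#' p <- rnorm(400); m <- 0.5 * p + rnorm(400, sd = sqrt(0.75))
#' y <- 0.2 * p + 0.3 * m + rnorm(400)
#' fit <- paem(y, p, m, n_perm = 199, seed = 1)
#' print(fit)
#' @export
paem <- function(y, prs, mediator, data = NULL, mediator_name = NULL,
                 n_perm = 10000, seed = NULL) {
  if (!is.null(data)) {
    pick <- function(v) if (is.character(v) && length(v) == 1) data[[v]] else v
    if (is.null(mediator_name) && is.character(mediator))
      mediator_name <- mediator
    y <- pick(y); prs <- pick(prs); mediator <- pick(mediator)
  }
  if (is.null(mediator_name)) mediator_name <- "mediator"
  est <- compute_paem(y, prs, mediator, mediator_name)
  use <- !is.na(y) & !is.na(prs) & !is.na(mediator)
  fit1 <- lm(y[use] ~ prs[use])
  fit2 <- lm(y[use] ~ prs[use] + mediator[use])
  perm <- NULL
  if (n_perm > 0)
    perm <- permutation_null(y, prs, mediator, n_perm = n_perm, seed = seed)
  structure(list(estimate = est,
                 perm_p = if (is.null(perm)) NA_real_ else perm$p_value,
                 null = perm$null, n_perm = n_perm,
                 n_degenerate = if (is.null(perm)) 0L else perm$n_degenerate,
                 fit1 = fit1, fit2 = fit2, call = match.call()),
            class = "paem")
}

#' @export
print.paem <- function(x, digits = 4, ...) {
  e <- x$estimate
  cat("PAEM mediation fit (", e$mediator, "), n = ", e$n, "\n", sep = "")
  cat("  PVE1 (R2 y~prs):      ", signif(e$pve1, digits), "\n")
  cat("  R2 full (y~prs+M):    ", signif(e$r2_full, digits), "\n")
  cat("  RI share of score:    ", signif(e$ri_prs, digits), "\n")
  cat("  PVE_prs2:             ", signif(e$pve_prs2, digits), "\n")
  cat("  PAEM (%):             ", signif(e$paem, digits),
      if (nzchar(e$flag)) paste0("  [", e$flag, "]") else "", "\n", sep = "")
  if (!is.na(x$perm_p))
    cat("  permutation p:        ", signif(x$perm_p, digits),
        " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' @export
summary.paem <- function(object, ...) {
  out <- object$estimate
  out$perm_p <- object$perm_p
  out$n_perm <- object$n_perm
  out$n_degenerate <- object$n_degenerate
  out
}

#' @export
coef.paem <- function(object, model = c("full", "marginal"), ...) {
  model <- match.arg(model)
  cf <- coef(if (model == "full") object$fit2 else object$fit1)
  names(cf) <- if (model == "full") c("(Intercept)", "prs", "mediator")
               else c("(Intercept)", "prs")
  cf
}

#' @export
residuals.paem <- function(object, model = c("full", "marginal"), ...) {
  model <- match.arg(model)
  residuals(if (model == "full") object$fit2 else object$fit1)
}

#' @export
plot.paem <- function(x, ...) {
  if (is.null(x$null)) stop("no permutation null stored; refit with n_perm > 0")
  graphics::hist(x$null, breaks = 40, main = "PAEM permutation null",
                 xlab = "PAEM under permuted mediator", col = "grey85",
                 border = "white",
                 xlim = range(c(x$null, x$estimate$paem)), ...)
  graphics::abline(v = x$estimate$paem, col = "red3", lwd = 2)
  invisible(x)
}

# full-rank conditioning design; drops collinear columns with a message
.conditioning_design <- function(conditioning, n) {
  if (is.null(conditioning) || length(conditioning) == 0)
    return(matrix(nrow = n, ncol = 0))
  if (is.list(conditioning) && !is.data.frame(conditioning))
    conditioning <- as.data.frame(conditioning)
  X <- as.matrix(as.data.frame(conditioning))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  q <- qr(cbind(1, X))
  if (q$rank < ncol(X) + 1) {
    keep_piv <- q$pivot[seq_len(q$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep_piv) - 1L
    dropped <- dropped[dropped > 0]
    message("dropping collinear conditioning column(s): ",
            paste(colnames(X)[dropped], collapse = ", "))
    X <- X[, -dropped, drop = FALSE]
  }
  X
}

#' Conditional-independence test of outcome and score given a set
#'
#' Nested-model F-test: the linear model of the outcome on the conditioning
#' set is compared against the model with both the score and the set;
#' `F = ((SSres_reduced - SSres_full)/1) / (SSres_full/(n - p_full))` with
#' `(1, n - p_full)` degrees of freedom. Verdict is "independent" when
#' `p > alpha`.
#'
#' @param y outcome vector.
#' @param prs scaled score.
#' @param conditioning list/data.frame of conditioning vectors (possibly
#'   empty: reduces to the marginal regression F-test).
#' @param alpha significance level for the verdict.
#' @return list of class `conditioning_report`: `set`, `F`, `df1`, `df2`,
#'   `p_value`, `independent`.
#' @export
conditional_independence <- function(y, prs, conditioning = list(),
                                     alpha = 0.05) {
  cc <- !is.na(y) & !is.na(prs)
  if (length(conditioning) > 0) {
    cm <- as.data.frame(conditioning)
    cc <- cc & complete.cases(cm)
    conditioning <- cm[cc, , drop = FALSE]
  }
  y <- y[cc]; prs <- prs[cc]
  n <- length(y)
  X <- .conditioning_design(conditioning, n)
  p_full <- ncol(X) + 2L  # intercept + set + prs
  if (n <= p_full + 1) stop("too few observations for the full model")
  red <- qr(cbind(1, X))
  full <- qr(cbind(1, X, prs))
  ss_red <- sum(qr.resid(red, y)^2)
  ss_full <- sum(qr.resid(full, y)^2)
  df2 <- n - p_full
  Fstat <- max(0, (ss_red - ss_full)) / (ss_full / df2)
  p <- pf(Fstat, 1, df2, lower.tail = FALSE)
  structure(list(set = colnames(X), F = Fstat, df1 = 1L, df2 = df2,
                 p_value = p, independent = p > alpha, alpha = alpha, n = n),
            class = "conditioning_report")
}

#' @export
print.conditioning_report <- function(x, ...) {
  set <- if (length(x$set) == 0) "(empty)" else paste(x$set, collapse = ", ")
  cat("conditioning set:", set, "\n  F(", x$df1, ",", x$df2, ") = ",
      signif(x$F, 4), ", p = ", signif(x$p_value, 4),
      if (x$independent) "  -> independent" else "  -> dependent",
      "\n", sep = "")
  invisible(x)
}

#' Minimal conditioning sets separating outcome from score
#'
#' Enumerates candidate subsets by increasing size; at the first size where
#' any subset renders outcome and score conditionally independent
#' (`p > alpha`), all qualifying subsets of that size are returned.
#'
#' @param y outcome vector.
#' @param prs scaled score.
#' @param candidates named list or data.frame of candidate conditioning
#'   variables (at most 20; exhaustive enumeration).
#' @param alpha significance level.
#' @param max_size largest subset size to try (clamped to the candidate count
#'   with a warning).
#' @return list of class `minimal_sets`: `sets` (list of character vectors,
#'   empty if none qualify up to `max_size`), `size`, `alpha`, `reports`.
#' @export
find_minimal_sets <- function(y, prs, candidates, alpha = 0.05,
                              max_size = 6) {
  cand <- as.data.frame(candidates)
  if (ncol(cand) > 20) stop("more than 20 candidates; enumeration refused")
  if (max_size > ncol(cand)) {
    warning("max_size clamped to the number of candidates")
    max_size <- ncol(cand)
  }
  nm <- names(cand)
  for (k in 0:max_size) {
    subsets <- if (k == 0) list(integer(0))
               else asplit(combn(ncol(cand), k), 2)
    hits <- list(); reports <- list()
    for (s in subsets) {
      rep_ <- conditional_independence(y, prs, cand[, s, drop = FALSE],
                                       alpha = alpha)
      if (rep_$independent) {
        hits[[length(hits) + 1L]] <- nm[s]
        reports[[length(reports) + 1L]] <- rep_
      }
    }
    if (length(hits) > 0)
      return(structure(list(sets = hits, size = k, alpha = alpha,
                            reports = reports),
                       class = "minimal_sets"))
  }
  structure(list(sets = list(), size = NA_integer_, alpha = alpha,
                 reports = list()),
            class = "minimal_sets")
}

#' @export
print.minimal_sets <- function(x, ...) {
  if (length(x$sets) == 0) {
    cat("no conditioning set up to the size limit renders independence\n")
  } else {
    cat(length(x$sets), "minimal set(s) of size", x$size, "at alpha =",
        x$alpha, "\n")
    for (s in x$sets) cat("  {", paste(s, collapse = ", "), "}\n")
  }
  invisible(x)
}
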