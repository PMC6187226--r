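# complete.cases that tolerates a zero-column design
.complete <- function(df, n) {
  if (is.null(ncol(df)) || ncol(df) == 0) rep(TRUE, n) else complete.cases(df)
}

# Phenome-wide association scan of a polygenic score: covariates are removed
# from continuous traits by linear-regression residualization; binary traits
# use logistic regression with covariates in the model; the family-wise
# threshold is Bonferroni over the registered variable count.

#' Residualize a continuous trait on covariates
#'
#' Complete-case least squares; returns residuals aligned to the input (NA
#' where the trait or a covariate is missing). Residuals are orthogonal to
#' every covariate column.
#'
#' @param trait numeric vector.
#' @param covariates data.frame or matrix of covariates (an intercept is
#'   added).
#' @return numeric vector of residuals with NAs preserved.
#' @export
residualize <- function(trait, covariates) {
  covariates <- as.data.frame(covariates)
  use <- !is.na(trait) & .complete(covariates, length(trait))
  X <- cbind(1, as.matrix(covariates[use, , drop = FALSE]))
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("covariate design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  out <- rep(NA_real_, length(trait))
  out[use] <- qr.resid(q, trait[use])
  out
}

#' Test one trait against a polygenic score
#'
#' Continuous traits are residualized on the covariates and regressed on the
#' scaled score; binary traits enter a logistic model with the covariates
#' included. Two-sided Wald test on the score coefficient; the estimate is in
#' per-SD-of-score units.
#'
#' @param prs a `prs_vector` (or a numeric vector of scaled scores).
#' @param trait numeric (continuous) or 0/1 (binary) vector.
#' @param covariates data.frame of covariates aligned to `trait`.
#' @param kind `"continuous"` or `"binary"`.
#' @param trait_name label carried into the result.
#' @return one-row data.frame of class `association_result`: trait, kind, n,
#'   estimate, se, p_value, flag (`""`, or `"separation"` for unstable
#'   logistic fits).
#' @export
associate_trait <- function(prs, trait, covariates, kind = "continuous",
                            trait_name = "trait") {
  score <- if (inherits(prs, "prs_vector")) prs$scaled else as.numeric(prs)
  covariates <- as.data.frame(covariates)
  flag <- ""
  if (kind == "continuous") {
    resid <- residualize(trait, covariates)
    use <- !is.na(resid) & !is.na(score)
    fit <- lm(resid[use] ~ score[use])
    cf <- summary(fit)$coefficients
    est <- cf[2, 1]; se <- cf[2, 2]; p <- cf[2, 4]
    n <- sum(use)
  } else if (kind == "binary") {
    use <- !is.na(trait) & !is.na(score) &
      .complete(covariates, length(trait))
    yv <- trait[use]
    if (length(unique(yv)) < 2)
      stop("binary trait '", trait_name, "' has a single class")
    df <- data.frame(y = yv, score = score[use],
                     covariates[use, , drop = FALSE])
    warned <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ ., data = df, family = binomial()),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    cf <- summary(fit)$coefficients
    est <- cf["score", 1]; se <- cf["score", 2]; p <- cf["score", 4]
    n <- sum(use)
    if (warned || !fit$converged || abs(est) > 15)
      flag <- "separation"
  } else stop("kind must be 'continuous' or 'binary'")
  structure(data.frame(trait = trait_name, kind = kind, n = n,
                       estimate = est, se = se,
                       p_value = max(p, 1e-300), flag = flag,
                       stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

#' Registry of tested variables
#'
#' Bookkeeping for the multiple-testing family: category names mapped to
#' variable counts. The family-wise threshold is `alpha / total`.
#'
#' @param ... named integer counts (a category may be a vector, e.g. one count
#'   per omics layer's modules).
#' @return list of class `phewas_registry` with `counts`, `n_variables`.
#' @export
phewas_registry <- function(...) {
  counts <- list(...)
  if (length(counts) == 0 || sum(unlist(counts)) == 0)
    stop("empty variable registry")
  structure(list(counts = counts, n_variables = sum(unlist(counts))),
            class = "phewas_registry")
}

#' Default variable registry
#'
#' The default family mirrors a full endophenotype scan: clinical diagnoses,
#' cognitive decline measures, lifestyle/personality traits, medical
#' conditions, brain pathologies, one module count per omics layer
#' (methylation, acetylation, expression), miRNAs and proteins.
#'
#' @param clinical,cognitive,lifestyle,medical,pathology,modules,mirna,protein
#'   per-category variable counts.
#' @return a [phewas_registry()].
#' @export
default_registry <- function(clinical = 3, cognitive = 6, lifestyle = 8,
                             medical = 14, pathology = 13,
                             modules = c(methylation = 58, acetylation = 80,
                                         expression = 49),
                             mirna = 292, protein = 67) {
  phewas_registry(clinical = clinical, cognitive = cognitive,
                  lifestyle = lifestyle, medical = medical,
                  pathology = pathology, modules = modules, mirna = mirna,
                  protein = protein)
}

#' @export
print.phewas_registry <- function(x, ...) {
  cat("phewas_registry:", x$n_variables, "variables in",
      length(x$counts), "categories\n")
  invisible(x)
}

#' Bonferroni family-wise threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests in the family.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha <= 1, n_tests >= 1)
  alpha / n_tests
}

#' Run a phenome-wide scan
#'
#' Tests every registered variable against each score variant. The family
#' threshold is recomputed from the registry size (or, if no registry is
#' given, from the number of variables actually tested).
#'
#' @param prs_list named list of `prs_vector`s (e.g. full / without_region /
#'   region_only), or a single `prs_vector`.
#' @param phenotypes a [phenotype_table()]; all non-covariate columns are
#'   tested, binary ones (per its `binary` attribute) via logistic regression.
#' @param module_scores optional module x individual matrix (columns aligned
#'   to `phenotypes$sample_id`) appended to the tested variables.
#' @param alpha family-wise error rate (default 0.05).
#' @param registry optional [phewas_registry()] fixing the family size.
#' @return data.frame of class `phewas_result` (one row per variable x score
#'   variant) with attributes `threshold` and `n_variables`; `significant` is
#'   `p_value < threshold`.
#' @export
run_phewas <- function(prs_list, phenotypes, module_scores = NULL,
                       alpha = 0.05, registry = NULL) {
  if (inherits(prs_list, "prs_vector")) prs_list <- list(prs = prs_list)
  covnames <- attr(phenotypes, "covariates")
  binnames <- attr(phenotypes, "binary")
  covs <- as.data.frame(phenotypes)[, covnames, drop = FALSE]
  traits <- setdiff(names(phenotypes), c("sample_id", covnames))
  vars <- list()
  for (tn in traits)
    vars[[tn]] <- list(values = phenotypes[[tn]],
                       kind = if (tn %in% binnames) "binary" else "continuous")
  if (!is.null(module_scores)) {
    for (mn in rownames(module_scores))
      vars[[mn]] <- list(values = as.numeric(module_scores[mn, ]),
                         kind = "continuous")
  }
  if (length(vars) == 0) stop("empty variable registry")
  n_var <- if (is.null(registry)) length(vars) else registry$n_variables
  thr <- bonferroni_threshold(alpha, n_var)
  rows <- list()
  for (vn in names(prs_list)) {
    prs <- prs_list[[vn]]
    for (tn in names(vars)) {
      v <- vars[[tn]]
      r <- associate_trait(prs, v$values, covs, kind = v$kind,
                           trait_name = tn)
      r$prs_variant <- vn
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < thr
  attr(out, "threshold") <- thr
  attr(out, "n_variables") <- n_var
  class(out) <- c("phewas_result", "data.frame")
  out
}
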