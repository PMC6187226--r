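#' @importFrom stats coef cor lm median pf pnorm pt qlogis qnorm quantile rbinom
#'   rnorm runif sd var complete.cases plogis anova binomial fisher.test glm
#'   pbinom phyper uniroot residuals
#' @importFrom utils combn head read.table write.table
NULL

# ---- constructors / validators -------------------------------------------

#' SNP metadata table
#'
#' Validates a table of SNP records: identifier, chromosome, 1-based position,
#' effect and other allele. Positions are 1-based (SNP convention); interval
#' data elsewhere in the package are 0-based half-open (BED convention).
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome labels.
#' @param pos 1-based base-pair positions (>= 1).
#' @param effect_allele,other_allele single-character bases; must differ per SNP.
#' @return a `data.frame` of class `snp_table`.
#' @export
snp_table <- function(snp_id, chrom, pos, effect_allele, other_allele) {
  x <- data.frame(snp_id = as.character(snp_id), chrom = as.character(chrom),
                  pos = as.integer(pos),
                  effect_allele = as.character(effect_allele),
                  other_allele = as.character(other_allele),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$snp_id))
    stop("duplicate SNP id(s): ",
         paste(unique(x$snp_id[duplicated(x$snp_id)]), collapse = ", "))
  if (any(x$pos < 1L)) stop("SNP positions must be >= 1 (1-based)")
  same <- x$effect_allele == x$other_allele
  if (any(same))
    stop("effect allele equals other allele for: ",
         paste(x$snp_id[same], collapse = ", "))
  class(x) <- c("snp_table", "data.frame")
  x
}

#' Genotype dosage matrix
#'
#' @param dosages numeric matrix, samples x SNPs, values in [0, 2] (count of
#'   effect alleles; fractional values allowed for imputed data).
#' @param snps a [snp_table()] with one row per column of `dosages`.
#' @param samples sample identifiers (defaults to rownames of `dosages`).
#' @return list of class `genotype_matrix` with elements `dosages`, `snps`,
#'   `samples`.
#' @export
genotype_matrix <- function(dosages, snps, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (nrow(snps) != ncol(dosages))
    stop("SNP metadata rows (", nrow(snps), ") != dosage columns (",
         ncol(dosages), ")")
  if (length(samples) != nrow(dosages))
    stop("sample id count != dosage rows")
  bad <- which(!is.na(dosages) & (dosages < 0 | dosages > 2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("dosage outside [0,2] at sample '%s', snp '%s' (value %g)",
                 samples[bad[1, 1]], snps$snp_id[bad[1, 2]],
                 dosages[bad[1, 1], bad[1, 2]]))
  rownames(dosages) <- samples
  colnames(dosages) <- snps$snp_id
  structure(list(dosages = dosages, snps = snps, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x", nrow(x$snps),
      "SNPs\n")
  invisible(x)
}

#' GWAS summary-statistics table
#'
#' @param snps a [snp_table()].
#' @param beta signed per-effect-allele effects (finite).
#' @param pvalue p-values in (0, 1].
#' @return data.frame of class `summary_stats` with SNP metadata plus `beta`
#'   and `pvalue` columns.
#' @export
summary_stats <- function(snps, beta, pvalue) {
  if (any(!is.finite(beta))) stop("non-finite beta")
  bad <- which(!(pvalue > 0 & pvalue <= 1))
  if (length(bad) > 0)
    stop("pvalue outside (0,1] at row(s): ", paste(bad, collapse = ", "),
         " (snp ", paste(snps$snp_id[bad], collapse = ", "), ")")
  x <- cbind(as.data.frame(snps), beta = as.numeric(beta),
             pvalue = as.numeric(pvalue))
  class(x) <- c("summary_stats", "data.frame")
  x
}

#' Phenotype/covariate table
#'
#' One row per sample. Binary traits must contain only 0/1/NA; covariates must
#' be complete for all rows.
#'
#' @param data data.frame with a `sample_id` column, trait columns, and
#'   covariate columns.
#' @param covariates character vector naming covariate columns.
#' @param binary character vector naming binary trait columns (checked to be
#'   0/1/NA).
#' @return data.frame of class `phenotype_table` with attributes `covariates`
#'   and `binary`.
#' @export
phenotype_table <- function(data, covariates = character(0),
                            binary = character(0)) {
  data <- as.data.frame(data)
  if (nrow(data) == 0) warning("empty phenotype table")
  if (!"sample_id" %in% names(data)) stop("missing 'sample_id' column")
  if (anyDuplicated(data$sample_id)) stop("duplicate sample ids")
  miss <- setdiff(c(covariates, binary), names(data))
  if (length(miss) > 0)
    stop("declared column(s) absent: ", paste(miss, collapse = ", "))
  for (cv in covariates)
    if (anyNA(data[[cv]]))
      stop("covariate '", cv, "' has missing values")
  for (b in binary) {
    v <- data[[b]]
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop("binary trait '", b, "' contains values outside {0,1,NA}")
  }
  attr(data, "covariates") <- covariates
  attr(data, "binary") <- binary
  class(data) <- c("phenotype_table", "data.frame")
  data
}

#' Genomic interval set (0-based, half-open)
#'
#' @param chrom,start,end,name interval fields; `start < end`, `start >= 0`.
#' @return data.frame of class `interval_set`.
#' @export
interval_set <- function(chrom, start, end,
                         name = paste0("iv", seq_along(chrom))) {
  x <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), name = as.character(name),
                  stringsAsFactors = FALSE)
  if (any(x$start < 0)) stop("negative interval start")
  bad <- which(x$start >= x$end)
  if (length(bad) > 0)
    stop("interval start >= end at row(s): ", paste(bad, collapse = ", "))
  class(x) <- c("interval_set", "data.frame")
  x
}

#' Gene coordinate table
#'
#' Strand-aware: after orientation normalization the TSS is the 5' end, so
#' `tss < tes` on `+` and `tss > tes` on `-`. Rows violating this are
#' re-oriented (tss/tes swapped) with a warning.
#'
#' @param gene_id,chrom,strand,tss,tes gene fields; strand in `+`/`-`,
#'   positions 1-based.
#' @return data.frame of class `gene_table`.
#' @export
gene_table <- function(gene_id, chrom, strand, tss, tes) {
  x <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  strand = as.character(strand), tss = as.numeric(tss),
                  tes = as.numeric(tes), stringsAsFactors = FALSE)
  if (!all(x$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(x$gene_id)) stop("duplicate gene ids")
  flip <- (x$strand == "+" & x$tss > x$tes) | (x$strand == "-" & x$tss < x$tes)
  if (any(flip)) {
    warning("re-orienting ", sum(flip), " gene(s) so the TSS is the 5' end")
    tmp <- x$tss[flip]; x$tss[flip] <- x$tes[flip]; x$tes[flip] <- tmp
  }
  class(x) <- c("gene_table", "data.frame")
  x
}

# ---- readers / writers ----------------------------------------------------

.read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = c("NA", ""), check.names = FALSE,
             colClasses = NA, comment.char = "")
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}

#' Read GWAS summary statistics
#'
#' Tab-separated file with header columns `SNP CHR BP A1 A2 BETA P`
#' (A1 = effect allele). Rows with unparseable numerics are rejected with
#' their line numbers.
#'
#' @param path file path.
#' @return a [summary_stats()] table.
#' @export
read_summary_stats <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = character(0), colClasses = "character",
                    check.names = FALSE, comment.char = "")
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "P")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("summary-statistics file missing required column(s): ",
         paste(miss, collapse = ", "))
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  bp <- num("BP"); beta <- num("BETA"); p <- num("P")
  bad <- which(is.na(bp) | is.na(beta) | is.na(p))
  if (length(bad) > 0)
    stop("unparseable numeric value(s) at data line(s): ",
         paste(bad, collapse = ", "))
  summary_stats(snp_table(raw$SNP, raw$CHR, bp, raw$A1, raw$A2), beta, p)
}

#' @rdname read_summary_stats
#' @param x a `summary_stats` table.
#' @export
write_summary_stats <- function(x, path) {
  out <- data.frame(SNP = x$snp_id, CHR = x$chrom, BP = x$pos,
                    A1 = x$effect_allele, A2 = x$other_allele,
                    BETA = x$beta, P = x$pvalue)
  .write_tsv(out, path)
  invisible(path)
}

#' Read a genotype dosage matrix with its SNP metadata sidecar
#'
#' The dosage file is a TSV with a `sample_id` column and one column per SNP;
#' the sidecar TSV has columns `snp_id chrom pos effect_allele other_allele`.
#'
#' @param path dosage TSV path.
#' @param snp_path sidecar SNP metadata TSV path.
#' @return a [genotype_matrix()].
#' @export
read_dosages <- function(path, snp_path) {
  d <- .read_tsv(path)
  if (!"sample_id" %in% names(d)) stop("dosage file missing 'sample_id'")
  meta <- .read_tsv(snp_path)
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0)
    stop("SNP metadata missing column(s): ", paste(miss, collapse = ", "))
  snps <- snp_table(meta$snp_id, meta$chrom, meta$pos, meta$effect_allele,
                    meta$other_allele)
  missing_cols <- setdiff(snps$snp_id, names(d))
  if (length(missing_cols) > 0)
    stop("dosage file missing SNP column(s): ",
         paste(missing_cols, collapse = ", "))
  m <- as.matrix(d[, snps$snp_id, drop = FALSE])
  storage.mode(m) <- "double"
  genotype_matrix(m, snps, samples = d$sample_id)
}

#' @rdname read_dosages
#' @param x a `genotype_matrix`.
#' @export
write_dosages <- function(x, path, snp_path) {
  d <- data.frame(sample_id = x$samples, x$dosages, check.names = FALSE)
  .write_tsv(d, path)
  .write_tsv(as.data.frame(x$snps), snp_path)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' TSV with a `sample_id` column; `NA` or empty string denote missing values.
#'
#' @param path file path.
#' @inheritParams phenotype_table
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path, covariates = character(0),
                            binary = character(0)) {
  phenotype_table(.read_tsv(path), covariates = covariates, binary = binary)
}

#' @rdname read_phenotypes
#' @param x a `phenotype_table`.
#' @export
write_phenotypes <- function(x, path) {
  .write_tsv(as.data.frame(x), path)
  invisible(path)
}

#' Read / write BED intervals (0-based half-open)
#'
#' @param path BED file path.
#' @return an [interval_set()].
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) nm <- paste0("iv", seq_along(gr))
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), nm)
}

#' @rdname read_bed
#' @param x an `interval_set`.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(.as_granges(x), path, format = "BED")
  invisible(path)
}

# interval_set (0-based half-open) -> GRanges (1-based closed)
.as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end),
                         name = x$name)
}

#' Read / write a gene coordinate table
#'
#' TSV with columns `gene_id chrom strand tss tes` (1-based, strand-oriented).
#'
#' @param path file path.
#' @return a [gene_table()].
#' @export
read_genes <- function(path) {
  g <- .read_tsv(path)
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  miss <- setdiff(need, names(g))
  if (length(miss) > 0)
    stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  gene_table(g$gene_id, g$chrom, g$strand, g$tss, g$tes)
}

#' @rdname read_genes
#' @param x a `gene_table`.
#' @export
write_genes <- function(x, path) {
  .write_tsv(as.data.frame(x), path)
  invisible(path)
}
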