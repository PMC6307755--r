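# Expression filtering, normalization, and covariate-adjusted
# negative-binomial differential expression.

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / library_size[s] * 1e6`; every column of the
#' result sums to 1e6.
#'
#' @param counts a genes x samples count matrix.
#' @return a numeric matrix of the same shape.
#' @export
compute_cpm <- function(counts) {
  assert_matrix_like(counts, "counts")
  libsize <- colSums(counts)
  zero <- libsize == 0
  if (any(zero))
    stop_invalid("zero library size for sample(s): %s",
                 paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2, libsize, `/`) * 1e6
}

#' Filter genes with low expression
#'
#' Removes genes whose CPM falls below `cpm_threshold` in more than
#' `max_below` samples (strictly more; a gene below threshold in exactly
#' `max_below` samples is retained). With 21 samples and the defaults this
#' excludes genes with CPM < 1 in more than 11 samples. Row order is
#' preserved.
#'
#' @param counts a genes x samples count matrix.
#' @param cpm_threshold CPM threshold (default 1).
#' @param max_below maximum tolerated number of below-threshold samples;
#'   defaults to `floor(ncol(counts) / 2)`.
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 1,
                                  max_below = NULL) {
  assert_matrix_like(counts, "counts")
  max_below <- max_below %||% floor(ncol(counts) / 2)
  if (max_below > ncol(counts))
    stop_invalid("max_below exceeds the sample count")
  cpm <- compute_cpm(counts)
  n_below <- rowSums(cpm < cpm_threshold)
  counts[n_below <= max_below, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted
#' to genes with positive counts in every sample) of the ratio of the
#' sample's count to the gene's geometric mean across samples.
#'
#' @param counts a genes x samples count matrix.
#' @param geo_means optional fixed per-gene geometric means to use as the
#'   ratio reference (named by gene). With a fixed reference the estimator
#'   is exactly equivariant: scaling one sample's counts by `c` scales its
#'   factor by `c` and leaves the others untouched.
#' @return a named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts, geo_means = NULL) {
  assert_matrix_like(counts, "counts")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop_invalid(paste("no gene has positive counts in every sample;",
                       "filter low-expression genes first"))
  logc <- log(counts[all_pos, , drop = FALSE])
  geo <- if (is.null(geo_means)) rowMeans(logc)
         else log(geo_means[rownames(logc)])
  sf <- apply(logc, 2, function(x) exp(median(x - geo)))
  names(sf) <- colnames(counts)
  sf
}

#' Log-transformed normalized expression
#'
#' `log2(count / size_factor + 1)`, the expression scale used for the
#' eQTM correlation and the co-expression screen.
#'
#' @param counts a genes x samples count matrix.
#' @param size_factors per-sample size factors; estimated with
#'   [estimate_size_factors()] when NULL.
#' @param base logarithm base (default 2).
#' @return a numeric matrix of the same shape.
#' @export
log_expression <- function(counts, size_factors = NULL, base = 2) {
  assert_matrix_like(counts, "counts")
  sf <- size_factors %||% estimate_size_factors(counts)
  log(sweep(counts, 2, sf, `/`) + 1, base = base)
}

#' Fit differentially expressed genes
#'
#' Per gene, a negative-binomial log-linear model of counts on the group
#' contrast plus covariates, with median-of-ratios size factors, gene-wise
#' dispersion estimation shrunk toward the mean-dispersion trend, and a
#' Wald test on the contrast coefficient (the DESeq2 engine drives the
#' fit). Genes whose coefficient fit did not converge are flagged, get a
#' missing p-value, and are excluded from the BH adjustment; the count of
#' such genes is attached as an attribute.
#'
#' @param counts a filtered genes x samples count matrix.
#' @param sheet a sample sheet covering the matrix columns.
#' @param contrast character pair `c(groupA, groupB)`; log2 fold changes
#'   are A over B. `"CD"` expands to the union of NINF, INF and STEN.
#' @param covariates character vector among `passage`, `age`, `sex`,
#'   `smoker`, `medication`.
#' @return a data.frame of DEG records: `gene_id`, `log2_fold_change`,
#'   `lfc_se`, `wald_stat`, `p`, `p_adj`, `converged`; attribute
#'   `n_nonconverged`.
#' @export
fit_degs <- function(counts, sheet, contrast,
                     covariates = c("passage", "age", "sex", "medication")) {
  assert_matrix_like(counts, "counts")
  validate_sheet(sheet)
  sel <- sheet[match(colnames(counts), sheet$sample_id), , drop = FALSE]
  if (any(is.na(sel$sample_id)))
    stop_invalid("samples in count matrix absent from sheet")
  groups <- c(expand_group(contrast[[1]]), expand_group(contrast[[2]]))
  keep <- sel$group %in% groups
  sel <- sel[keep, , drop = FALSE]
  cts <- counts[, keep, drop = FALSE]
  in_a <- sel$group %in% expand_group(contrast[[1]])
  if (sum(in_a) < 2 || sum(!in_a) < 2)
    stop_invalid("both contrast groups need >= 2 samples")
  ## reuse the methylation design builder for validation/collapsing, then
  ## hand DESeq2 an equivalent design on the column data
  X <- build_design(sel, contrast, covariates)
  covar_cols <- setdiff(colnames(X), c("(Intercept)", "group"))
  col_data <- data.frame(row.names = sel$sample_id,
                         group = factor(ifelse(in_a, "A", "B"),
                                        levels = c("B", "A")))
  for (cv in covar_cols)
    col_data[[cv]] <- as.numeric(scale(X[, cv]))
  design <- stats::as.formula(
    paste("~", paste(c(covar_cols, "group"), collapse = " + ")))
  dds <- DESeq2::DESeqDataSetFromMatrix(countData = cts,
                                        colData = col_data,
                                        design = design)
  DESeq2::sizeFactors(dds) <- estimate_size_factors(cts)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE, minReplicatesForReplace = Inf))
  res <- DESeq2::results(dds, name = "group_A_vs_B",
                         independentFiltering = FALSE,
                         cooksCutoff = FALSE)
  conv <- S4Vectors::mcols(dds)$betaConv
  conv[is.na(conv)] <- FALSE
  p <- res$pvalue
  p[!conv] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- p.adjust(p[ok], method = "BH")
  out <- data.frame(
    gene_id = rownames(res),
    log2_fold_change = res$log2FoldChange,
    lfc_se = res$lfcSE,
    wald_stat = res$stat,
    p = p,
    p_adj = p_adj,
    converged = conv,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_nonconverged") <- sum(!conv)
  out
}
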