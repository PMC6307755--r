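#' Beta/M-value conversions
#'
#' Methylation Beta fractions are modelled on the M scale,
#' `M = log2(Beta / (1 - Beta))`, which is unbounded and closer to
#' homoscedastic. Beta values are clipped into
#' `[epsilon, 1 - epsilon]` before the transform so boundary values stay
#' finite. `m_to_beta()` is the exact inverse away from the clip bounds.
#'
#' @param beta a numeric matrix (or vector) of Beta values.
#' @param epsilon clip bound in (0, 0.5); default 1e-6.
#' @return a matrix/vector of the same shape.
#' @examples
#' beta_to_m(0.8)   # 2
#' m_to_beta(0)     # 0.5
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (epsilon <= 0 || epsilon >= 0.5)
    stop_invalid("epsilon must lie in (0, 0.5)")
  if (any(!is.finite(beta)))
    stop_invalid("Beta matrix contains non-finite values")
  b <- clip_unit(beta, epsilon)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @param m a numeric matrix (or vector) of M-values.
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m)))
    stop_invalid("M matrix contains non-finite values")
  1 / (1 + 2^(-m))
}

#' Filter a probe manifest
#'
#' Drops probes whose CpG overlaps a common SNP (minor allele frequency >
#' 0.05), cross-reactive (promiscuous) probes, and/or all probes on the
#' sex chromosomes — the standard exclusions for a mixed-sex array cohort.
#' Row order is preserved and the counts dropped per criterion are
#' attached as the `"dropped"` attribute.
#'
#' @param manifest a probe manifest.
#' @param drop_snp,drop_crossreactive,drop_sex_chromosomes logicals.
#' @return the filtered manifest, with attribute `dropped` (named counts).
#' @export
filter_probes <- function(manifest, drop_snp = TRUE,
                          drop_crossreactive = TRUE,
                          drop_sex_chromosomes = TRUE) {
  validate_manifest(manifest)
  drop <- rep(FALSE, nrow(manifest))
  dropped <- c(snp = 0L, crossreactive = 0L, sex_chromosome = 0L)
  if (drop_snp) {
    dropped[["snp"]] <- sum(manifest$snp_flag & !drop)
    drop <- drop | manifest$snp_flag
  }
  if (drop_crossreactive) {
    dropped[["crossreactive"]] <- sum(manifest$crossreactive_flag & !drop)
    drop <- drop | manifest$crossreactive_flag
  }
  if (drop_sex_chromosomes) {
    sex <- manifest$chrom %in% c("chrX", "chrY", "X", "Y")
    dropped[["sex_chromosome"]] <- sum(sex & !drop)
    drop <- drop | sex
  }
  out <- manifest[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Principal-component covariate screen
#'
#' Principal components are computed on the samples (features centered,
#' not scaled) and each component's scores are correlated with each
#' sample-sheet covariate to flag global structure that must be adjusted
#' for. Disease degree is coded ordinally NINF < INF < STEN (0/1/2;
#' non-CD samples are excluded from that covariate), sex as 0/1,
#' medications both per drug and as a pooled any-medication indicator.
#' Both the signed correlation and its square are reported.
#'
#' @param data a features x samples matrix (M-values or log expression).
#' @param sheet a sample sheet covering the matrix columns.
#' @param n_components number of components (<= n samples - 1).
#' @return a data.frame with columns `component`, `covariate`, `r`, `r2`,
#'   and `var_explained` (fraction of total variance carried by the
#'   component).
#' @export
pc_covariate_screen <- function(data, sheet, n_components = 3L) {
  assert_matrix_like(data, "data")
  validate_sheet(sheet)
  missing_samp <- setdiff(colnames(data), sheet$sample_id)
  if (length(missing_samp))
    stop_invalid("samples absent from sheet: %s",
                 paste(missing_samp, collapse = ", "))
  ns <- ncol(data)
  if (n_components > ns - 1)
    stop_invalid("n_components must be <= n samples - 1")
  pca <- prcomp(t(data), center = TRUE, scale. = FALSE)
  scores <- pca$x[, seq_len(n_components), drop = FALSE]
  ve <- (pca$sdev^2 / sum(pca$sdev^2))[seq_len(n_components)]
  sh <- sheet[match(colnames(data), sheet$sample_id), , drop = FALSE]
  degree <- match(sh$group, CD_GROUPS) - 1  # NA for nonCD
  covs <- list(
    degree = degree,
    passage = sh$passage,
    age = sh$age,
    sex = as.integer(sh$sex == "M"),
    smoker = as.integer(sh$smoker)
  )
  for (m in intersect(MEDICATION_COLS, names(sh)))
    covs[[m]] <- as.integer(sh[[m]])
  med <- intersect(MEDICATION_COLS, names(sh))
  if (length(med))
    covs$medication <- as.integer(rowSums(sh[, med, drop = FALSE]) > 0)
  rows <- list()
  for (k in seq_len(n_components)) {
    for (cv in names(covs)) {
      x <- covs[[cv]]
      ok <- is.finite(x) & is.finite(scores[, k])
      if (sum(ok) < 3 || sd(x[ok]) == 0) {
        if (sum(ok) >= 3 && sd(x[ok]) == 0)
          warning(sprintf("covariate '%s' is constant; r2 reported as 0",
                          cv), call. = FALSE)
        r <- 0
      } else {
        r <- cor(scores[ok, k], x[ok])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        component = paste0("PC", k), covariate = cv,
        r = r, r2 = r^2, var_explained = ve[k])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
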