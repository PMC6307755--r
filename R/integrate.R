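# The eQTM core: DMEG intersection, per-region mean methylation, Pearson
# correlation with log expression, percentile-bootstrap confidence
# intervals, and CpG-count-matched null-region permutation p-values.

#' Intersect differentially methylated regions with differentially
#' expressed genes
#'
#' Returns one record per DMR-gene pair in which the region's annotated
#' nearest-TSS gene is a significant DEG; a gene annotated to several
#' regions appears once per region.
#'
#' @param dmrs an annotated DMR data.frame (needs `gene_id`, `p_adj`).
#' @param degs a DEG data.frame from [fit_degs()].
#' @param alpha significance level applied to both adjusted p-values
#'   (default 0.05).
#' @return the subset of `dmrs` paired with the matching DEG columns
#'   (`p_de`, `log2_fold_change`).
#' @export
find_dmegs <- function(dmrs, degs, alpha = 0.05) {
  if (!"gene_id" %in% names(dmrs))
    stop_invalid("DMRs must be annotated with gene ids first")
  sig_dmr <- dmrs[!is.na(dmrs$p_adj) & dmrs$p_adj < alpha, , drop = FALSE]
  sig_deg <- degs[!is.na(degs$p_adj) & degs$p_adj < alpha, , drop = FALSE]
  hit <- sig_dmr$gene_id %in% sig_deg$gene_id
  out <- sig_dmr[hit, , drop = FALSE]
  i <- match(out$gene_id, sig_deg$gene_id)
  out$p_de <- sig_deg$p[i]
  out$log2_fold_change <- sig_deg$log2_fold_change[i]
  rownames(out) <- NULL
  out
}

#' Per-sample mean Beta of a region
#'
#' The unweighted arithmetic mean of the region's member probes, per
#' sample.
#'
#' @param beta a Beta matrix (probes x samples).
#' @param region one DMR record (a one-row data.frame with a `probes`
#'   column of comma-separated probe ids), or a character vector of probe
#'   ids.
#' @return a named numeric vector, one mean Beta per sample.
#' @export
dmr_mean_beta <- function(beta, region) {
  probes <- if (is.character(region)) region
            else strsplit(region$probes[1], ",", fixed = TRUE)[[1]]
  probes <- intersect(probes, rownames(beta))
  if (length(probes) == 0)
    stop_invalid("none of the region's probes are present in the matrix")
  colMeans(beta[probes, , drop = FALSE])
}

#' Pearson correlation between region methylation and expression
#'
#' Correlates per-sample mean Beta with log expression over exactly the
#' shared samples.
#'
#' @param mean_beta named per-sample mean Beta vector.
#' @param log_expr named per-sample log-expression vector.
#' @param shared_samples sample ids to use; defaults to the intersection
#'   of the two names.
#' @return the Pearson correlation.
#' @export
eqtm_correlate <- function(mean_beta, log_expr, shared_samples = NULL) {
  shared <- shared_samples %||%
    intersect(names(mean_beta), names(log_expr))
  if (length(shared) < 3)
    stop_invalid("eQTM correlation requires >= 3 shared samples")
  x <- mean_beta[shared]
  y <- log_expr[shared]
  if (any(is.na(x)) || any(is.na(y)))
    stop_invalid("missing values among shared samples")
  if (sd(x) == 0 || sd(y) == 0)
    stop_invalid("correlation undefined: zero variance on one side")
  cor(x, y)
}

## row-wise Pearson correlation of a matrix against one vector
row_cors <- function(M, y) {
  yc <- y - mean(y)
  Mc <- M - rowMeans(M)
  num <- Mc %*% yc
  den <- sqrt(rowSums(Mc^2) * sum(yc^2))
  as.numeric(num) / as.numeric(den)
}

#' Percentile bootstrap confidence interval for the eQTM correlation
#'
#' Resamples the paired samples with replacement `B` times, recomputes the
#' correlation, and reports the empirical `(1-level)/2` and `1-(1-level)/2`
#' quantiles. Degenerate resamples with zero variance on either side are
#' redrawn; the redraw count is attached as an attribute, and more than
#' `10 * B` redraws aborts (the data are essentially constant).
#'
#' @inheritParams eqtm_correlate
#' @param B number of bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric `c(ci_low, ci_high)` with attribute `n_redraws`.
#' @export
bootstrap_ci <- function(mean_beta, log_expr, B = 10000L, level = 0.95,
                         shared_samples = NULL, seed = 1L) {
  shared <- shared_samples %||%
    intersect(names(mean_beta), names(log_expr))
  if (length(shared) < 3)
    stop_invalid("bootstrap requires >= 3 shared samples")
  x <- as.numeric(mean_beta[shared])
  y <- as.numeric(log_expr[shared])
  if (sd(x) == 0 || sd(y) == 0)
    stop_invalid("correlation undefined: zero variance on one side")
  n <- length(x)
  set.seed(seed)
  r_boot <- numeric(B)
  filled <- 0L
  redraws <- 0L
  while (filled < B) {
    todo <- B - filled
    idx <- matrix(sample.int(n, todo * n, replace = TRUE), nrow = todo)
    xb <- matrix(x[idx], nrow = todo)
    yb <- matrix(y[idx], nrow = todo)
    vx <- rowSums((xb - rowMeans(xb))^2)
    vy <- rowSums((yb - rowMeans(yb))^2)
    ok <- vx > 0 & vy > 0
    k <- sum(ok)
    if (k > 0) {
      xo <- xb[ok, , drop = FALSE]
      yo <- yb[ok, , drop = FALSE]
      num <- rowSums((xo - rowMeans(xo)) * (yo - rowMeans(yo)))
      r_boot[filled + seq_len(k)] <- num / sqrt(vx[ok] * vy[ok])
      filled <- filled + k
    }
    redraws <- redraws + (todo - k)
    if (redraws > 10L * B)
      stop_invalid("bootstrap aborted: data nearly constant (%d redraws)",
                   redraws)
  }
  qs <- quantile(r_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  out <- c(ci_low = qs[1], ci_high = qs[2])
  attr(out, "n_redraws") <- redraws
  out
}

## all runs of exactly n_cpgs consecutive probes in the manifest, as a
## matrix of manifest row indices (one run per row)
candidate_runs <- function(manifest, n_cpgs) {
  runs <- list()
  for (ch in unique(manifest$chrom)) {
    rows <- which(manifest$chrom == ch)
    k <- length(rows) - n_cpgs + 1L
    if (k < 1) next
    st <- seq_len(k)
    runs[[length(runs) + 1L]] <-
      outer(rows[st], 0:(n_cpgs - 1L), `+`)
  }
  if (length(runs) == 0) return(matrix(integer(0), ncol = n_cpgs))
  do.call(rbind, runs)
}

#' Permutation p-value from CpG-count-matched null regions
#'
#' Draws `B` null regions uniformly among all runs of exactly `n_cpgs`
#' consecutive probes in the filtered manifest (excluding the observed
#' region's own run when given), computes each run's per-sample mean Beta
#' and its Pearson correlation with the same log-expression vector, and
#' returns the two-sided permutation p-value
#' `(1 + #\{|r_null| >= |r_obs|\}) / (B + 1)`. Runs are drawn without
#' replacement when the candidate pool is at least `B`, with replacement
#' otherwise.
#'
#' @param r_obs the observed correlation.
#' @param n_cpgs the observed region's CpG count to match.
#' @param beta a Beta matrix covering the manifest probes.
#' @param log_expr named per-sample log-expression vector for the gene.
#' @param manifest the filtered probe manifest from which runs are drawn.
#' @param B number of null regions (default 10000).
#' @param seed integer seed.
#' @param exclude_probes probe ids of the observed region; any run with
#'   this exact probe set is excluded from the pool.
#' @param shared_samples sample ids to correlate over; defaults to the
#'   intersection of Beta columns and `log_expr` names.
#' @return a list with `p_corr`, `r_null` (length-B numeric), `n_runs`
#'   (candidate pool size), and `seed`.
#' @export
null_dmr_pvalue <- function(r_obs, n_cpgs, beta, log_expr, manifest,
                            B = 10000L, seed = 1L,
                            exclude_probes = NULL,
                            shared_samples = NULL) {
  validate_manifest(manifest)
  shared <- shared_samples %||%
    intersect(colnames(beta), names(log_expr))
  if (length(shared) < 3)
    stop_invalid("null-region p-value requires >= 3 shared samples")
  runs <- candidate_runs(manifest, n_cpgs)
  if (nrow(runs) == 0)
    stop_invalid("manifest has no run of %d consecutive probes", n_cpgs)
  if (!is.null(exclude_probes)) {
    probe_at <- matrix(manifest$probe_id[runs], nrow = nrow(runs))
    excl <- apply(probe_at, 1, function(p) setequal(p, exclude_probes))
    runs <- runs[!excl, , drop = FALSE]
    if (nrow(runs) == 0)
      stop_invalid("no candidate runs left after excluding the region")
  }
  set.seed(seed)
  n_runs <- nrow(runs)
  pick <- if (n_runs >= B) sample.int(n_runs, B)
          else sample.int(n_runs, B, replace = TRUE)
  ## per-chromosome prefix sums make run means O(1) each
  bsub <- beta[manifest$probe_id, shared, drop = FALSE]
  csum <- rbind(0, apply(bsub, 2, cumsum))
  first <- runs[pick, 1L]
  mean_mat <- (csum[first + n_cpgs, , drop = FALSE] -
               csum[first, , drop = FALSE]) / n_cpgs
  y <- as.numeric(log_expr[shared])
  r_null <- row_cors(mean_mat, y)
  r_null[!is.finite(r_null)] <- 0
  p_corr <- (1 + sum(abs(r_null) >= abs(r_obs))) / (B + 1)
  list(p_corr = p_corr, r_null = r_null, n_runs = n_runs, seed = seed)
}

#' Pairwise co-expression matrix
#'
#' Pearson correlations among the listed genes across samples, with pairs
#' whose absolute correlation exceeds the threshold flagged (attribute
#' `high_pairs`). Constant genes are dropped with a warning.
#'
#' @param log_expr a genes x samples log-expression matrix.
#' @param gene_set gene ids to include (default: all rows).
#' @param threshold flag threshold on `|r|` (default 0.7).
#' @return a symmetric correlation matrix with unit diagonal; attribute
#'   `high_pairs` is a data.frame of flagged pairs.
#' @export
coexpression_matrix <- function(log_expr, gene_set = rownames(log_expr),
                                threshold = 0.7) {
  if (ncol(log_expr) < 3)
    stop_invalid("co-expression screen requires >= 3 samples")
  missing_g <- setdiff(gene_set, rownames(log_expr))
  if (length(missing_g))
    stop_invalid("gene(s) absent from expression matrix: %s",
                 paste(missing_g, collapse = ", "))
  M <- log_expr[gene_set, , drop = FALSE]
  const <- apply(M, 1, sd) == 0
  if (any(const)) {
    warning("dropping constant gene(s): ",
            paste(rownames(M)[const], collapse = ", "), call. = FALSE)
    M <- M[!const, , drop = FALSE]
  }
  R <- cor(t(M))
  diag(R) <- 1
  hp <- which(abs(R) > threshold & upper.tri(R), arr.ind = TRUE)
  attr(R, "high_pairs") <- data.frame(
    gene_a = rownames(R)[hp[, 1]],
    gene_b = colnames(R)[hp[, 2]],
    r = R[hp],
    stringsAsFactors = FALSE
  )
  R
}

#' Run the full eQTM analysis over DMEG pairs
#'
#' For every DMR-gene pair, computes the Pearson correlation between the
#' region's per-sample mean Beta and the gene's log expression over the
#' samples shared between assays, a percentile bootstrap confidence
#' interval, and a CpG-count-matched null-region permutation p-value.
#'
#' @param dmegs a DMEG pair table from [find_dmegs()].
#' @param beta a Beta matrix.
#' @param log_expr a genes x samples log-expression matrix.
#' @param manifest the filtered probe manifest (null-region pool).
#' @param B_bootstrap,B_null resample counts (default 10000 each).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return a data.frame with one row per pair: `coordinates`
#'   (`chrom:start-end`, 1-based inclusive), `n_cpgs`, `gene_id`, `r`,
#'   `ci_low`, `ci_high`, `ci_excludes_r` (pathological-resample flag),
#'   `p_corr`, `p_de`, `p_dm`.
#' @export
eqtm_analysis <- function(dmegs, beta, log_expr, manifest,
                          B_bootstrap = 10000L, B_null = 10000L,
                          level = 0.95, seed = 1L) {
  shared <- intersect(colnames(beta), colnames(log_expr))
  rows <- vector("list", nrow(dmegs))
  for (i in seq_len(nrow(dmegs))) {
    region <- dmegs[i, , drop = FALSE]
    probes <- strsplit(region$probes, ",", fixed = TRUE)[[1]]
    mb <- dmr_mean_beta(beta, probes)
    le <- log_expr[region$gene_id, ]
    r <- eqtm_correlate(mb, le, shared)
    ci <- bootstrap_ci(mb, le, B = B_bootstrap, level = level,
                       shared_samples = shared, seed = seed + i)
    nullp <- null_dmr_pvalue(r, length(probes), beta, le, manifest,
                             B = B_null, seed = seed + i,
                             exclude_probes = probes,
                             shared_samples = shared)
    rows[[i]] <- data.frame(
      coordinates = sprintf("%s:%d-%d", region$chrom, region$start,
                            region$end),
      n_cpgs = region$n_cpgs,
      gene_id = region$gene_id,
      r = r,
      ci_low = ci[["ci_low"]],
      ci_high = ci[["ci_high"]],
      ci_excludes_r = r < ci[["ci_low"]] || r > ci[["ci_high"]],
      p_corr = nullp$p_corr,
      p_de = region$p_de,
      p_dm = region$p_region,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(coordinates = character(0), n_cpgs = integer(0),
               gene_id = character(0), r = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               ci_excludes_r = logical(0), p_corr = numeric(0),
               p_de = numeric(0), p_dm = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
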