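#' Planted effect constructors
#'
#' Convenience constructors for ground-truth effect tables used by the
#' simulators. `plant_regions()` picks `n_regions` non-overlapping runs of
#' `n_cpgs` consecutive probes and assigns each a Beta shift for one group;
#' `plant_genes()` picks genes and assigns log2 fold changes.
#'
#' @param manifest a probe manifest.
#' @param n_regions,n_cpgs number of regions and probes per region.
#' @param delta_beta signed methylation shift in \[-0.5, 0.5\] (recycled).
#' @param target_group group label receiving the shift.
#' @param seed integer seed.
#' @param gap_probes minimum number of untouched probes between regions.
#' @return a data.frame of planted region effects: `chrom`,
#'   `start_probe_index` (index among that chromosome's probes), `n_cpgs`,
#'   `delta_beta`, `target_group`.
#' @export
plant_regions <- function(manifest, n_regions, n_cpgs = 8,
                          delta_beta = 0.15, target_group = "STEN",
                          seed = 1L, gap_probes = 5L) {
  validate_manifest(manifest)
  if (any(abs(delta_beta) > 0.5))
    stop_invalid("delta_beta must lie in [-0.5, 0.5]")
  if (n_cpgs < 3) stop_invalid("planted regions need n_cpgs >= 3")
  set.seed(seed)
  per_chrom <- table(manifest$chrom)
  delta <- rep_len(delta_beta, n_regions)
  out <- vector("list", n_regions)
  used <- lapply(names(per_chrom), function(x) integer(0))
  names(used) <- names(per_chrom)
  stride <- n_cpgs + gap_probes
  for (i in seq_len(n_regions)) {
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      ch <- sample(names(per_chrom), 1L)
      max_start <- per_chrom[[ch]] - n_cpgs + 1L
      if (max_start < 1) next
      st <- sample.int(max_start, 1L)
      span <- seq(st - gap_probes, st + stride - 1L)
      if (length(intersect(span, used[[ch]])) == 0) {
        used[[ch]] <- c(used[[ch]], seq(st, st + n_cpgs - 1L))
        out[[i]] <- data.frame(chrom = ch, start_probe_index = st,
                               n_cpgs = n_cpgs, delta_beta = delta[i],
                               target_group = target_group)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_invalid("could not place %d non-overlapping regions", n_regions)
  }
  do.call(rbind, out)
}

#' @rdname plant_regions
#' @param genes a gene model.
#' @param n_genes number of genes to perturb.
#' @param lfc signed log2 fold change (recycled).
#' @export
plant_genes <- function(genes, n_genes, lfc = 1, target_group = "STEN",
                        seed = 1L) {
  set.seed(seed)
  idx <- sample.int(nrow(genes), n_genes)
  data.frame(gene_id = genes$gene_id[idx],
             log2_fold_change = rep_len(lfc, n_genes),
             target_group = target_group)
}

## resolve a region effect row to probe ids in the manifest
effect_probe_ids <- function(manifest, chrom, start_probe_index, n_cpgs) {
  rows <- which(manifest$chrom == chrom)
  if (length(rows) == 0)
    stop_invalid("chromosome %s absent from manifest", chrom)
  if (start_probe_index < 1 ||
      start_probe_index + n_cpgs - 1 > length(rows))
    stop_invalid(
      "effect region [%d, %d] exceeds the %d probes on %s",
      start_probe_index, start_probe_index + n_cpgs - 1, length(rows), chrom)
  manifest$probe_id[rows[seq(start_probe_index,
                             start_probe_index + n_cpgs - 1)]]
}

#' Simulate a normalized methylation Beta matrix
#'
#' Per-probe baseline Beta values are drawn from a mixture of two
#' logit-normals (modes near 0.1 and 0.9 by default), mimicking the
#' bimodality of array methylation. Per-sample noise is added on the logit
#' scale. Planted region effects shift the Beta values of the target
#' group's samples by `delta_beta` across the run of probes, with the
#' result clipped back into (0, 1).
#'
#' @param manifest a probe manifest.
#' @param sheet a sample sheet; only samples with assay `methylation` or
#'   `both` are included as columns.
#' @param effects a planted-region-effect data.frame (see
#'   [plant_regions()]) or NULL.
#' @param noise_sd per-sample noise standard deviation on the logit scale.
#' @param seed integer seed.
#' @param baseline list with `modes` (two Beta modes), `weights`
#'   (mixture weights), and `sd` (logit-scale spread around each mode).
#' @return a probes x samples numeric matrix with values strictly in
#'   (0, 1).
#' @export
simulate_methylation <- function(manifest, sheet, effects = NULL,
                                 noise_sd = 0.3, seed = 1L,
                                 baseline = list(modes = c(0.1, 0.9),
                                                 weights = c(0.5, 0.5),
                                                 sd = 0.5)) {
  validate_manifest(manifest)
  validate_sheet(sheet)
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  samples <- samples_for_assay(sheet, "methylation")
  if (length(samples) == 0) stop_invalid("no methylation samples in sheet")
  set.seed(seed)
  np <- nrow(manifest)
  comp <- sample.int(length(baseline$modes), np, replace = TRUE,
                     prob = baseline$weights)
  base_logit <- rnorm(np, mean = qlogis(baseline$modes)[comp],
                      sd = baseline$sd)
  eps <- matrix(rnorm(np * length(samples), sd = noise_sd),
                nrow = np)
  beta <- plogis(base_logit + eps)
  dimnames(beta) <- list(manifest$probe_id, samples)
  if (!is.null(effects) && nrow(effects) > 0) {
    ## planted regions must not overlap one another
    all_probes <- unlist(lapply(seq_len(nrow(effects)), function(i)
      effect_probe_ids(manifest, effects$chrom[i],
                       effects$start_probe_index[i], effects$n_cpgs[i])))
    if (anyDuplicated(all_probes))
      stop_invalid("planted region effects overlap")
    grp <- sheet$group[match(samples, sheet$sample_id)]
    for (i in seq_len(nrow(effects))) {
      probes <- effect_probe_ids(manifest, effects$chrom[i],
                                 effects$start_probe_index[i],
                                 effects$n_cpgs[i])
      target <- samples[grp == effects$target_group[i]]
      if (length(target))
        beta[probes, target] <- beta[probes, target] + effects$delta_beta[i]
    }
  }
  clip_unit(beta, 1e-3)
}

#' Simulate an RNA-seq count matrix
#'
#' Gene counts are negative binomial with variance mu + alpha * mu^2.
#' Per-gene baseline means are log-normal, scaled per sample by a
#' log-normal size factor and by `2^lfc` in the target group of any
#' planted gene effect. Dispersions below 1e-12 fall back to Poisson
#' sampling.
#'
#' @param genes a gene model.
#' @param sheet a sample sheet; columns are samples with assay
#'   `expression` or `both`.
#' @param effects planted gene effects (see [plant_genes()]) or NULL.
#' @param baseline list with either `mu` (explicit per-gene mean vector)
#'   or `mean_log`/`sd_log` for a log-normal draw, plus `dispersion`
#'   (scalar or per-gene alpha).
#' @param size_factor_spread standard deviation of log size factors.
#' @param seed integer seed.
#' @return a genes x samples integer matrix.
#' @export
simulate_counts <- function(genes, sheet, effects = NULL,
                            baseline = list(mean_log = log(200),
                                            sd_log = 1.2,
                                            dispersion = 0.1),
                            size_factor_spread = 0.3, seed = 1L) {
  validate_sheet(sheet)
  if (size_factor_spread < 0)
    stop_invalid("size_factor_spread must be >= 0")
  samples <- samples_for_assay(sheet, "expression")
  if (length(samples) == 0) stop_invalid("no expression samples in sheet")
  set.seed(seed)
  ng <- nrow(genes)
  ns <- length(samples)
  mu <- baseline$mu %||% rlnorm(ng, baseline$mean_log, baseline$sd_log)
  if (length(mu) == 1) mu <- rep(mu, ng)
  alpha <- rep_len(baseline$dispersion %||% 0.1, ng)
  if (any(alpha < 0)) stop_invalid("dispersions must be > 0")
  sf <- exp(rnorm(ns, 0, size_factor_spread))
  lfc_mat <- matrix(0, ng, ns)
  if (!is.null(effects) && nrow(effects) > 0) {
    if (any(!is.finite(effects$log2_fold_change)))
      stop_invalid("planted fold changes must be finite")
    grp <- sheet$group[match(samples, sheet$sample_id)]
    for (i in seq_len(nrow(effects))) {
      g <- match(effects$gene_id[i], genes$gene_id)
      if (is.na(g))
        stop_invalid("planted gene %s absent from gene model",
                     effects$gene_id[i])
      lfc_mat[g, grp == effects$target_group[i]] <-
        effects$log2_fold_change[i]
    }
  }
  mu_mat <- (mu %o% sf) * 2^lfc_mat
  counts <- matrix(0L, ng, ns)
  pois <- alpha < 1e-12
  if (any(pois))
    counts[pois, ] <- rpois(sum(pois) * ns, lambda = mu_mat[pois, ])
  if (any(!pois))
    counts[!pois, ] <- rnbinom(sum(!pois) * ns,
                               mu = mu_mat[!pois, ],
                               size = 1 / alpha[!pois])
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes$gene_id, samples)
  counts
}

#' Couple regional methylation to gene expression
#'
#' For each coupling, the per-sample signal already present in the region
#' (its standardized mean Beta `u` over the samples shared between both
#' assays) is rotated into the gene's log2 counts: the new log expression
#' is `mean(e) + sd(e) * (r * u + sqrt(1 - r^2) * e_perp)`, where
#' `e_perp` is the standardized component of the original log expression
#' orthogonal to `u`. The construction hits `target_r` exactly on the log
#' scale (integer rounding of the back-transformed counts adds a small
#' perturbation) and preserves the expression variance, so downstream
#' dispersion estimates are not inflated. If the region carries no
#' sample-level variation (zero-noise simulation), a standard-normal
#' latent factor is first injected into the region's probes on the logit
#' scale.
#'
#' @param beta a Beta matrix (probes x samples).
#' @param counts a count matrix (genes x samples).
#' @param couplings data.frame with columns `chrom`, `start_probe_index`,
#'   `n_cpgs`, `gene_id`, `target_r`.
#' @param manifest the probe manifest the Beta matrix rows follow.
#' @param seed integer seed.
#' @return list with elements `beta` and `counts`; unchanged when
#'   `couplings` is empty.
#' @export
couple_eqtm <- function(beta, counts, couplings, manifest, seed = 1L) {
  if (is.null(couplings) || nrow(couplings) == 0)
    return(list(beta = beta, counts = counts))
  if (any(abs(couplings$target_r) > 1))
    stop_invalid("|target_r| must be <= 1")
  shared <- intersect(colnames(beta), colnames(counts))
  if (length(shared) < 3)
    stop_invalid("coupling requires >= 3 samples shared between assays")
  set.seed(seed)
  for (i in seq_len(nrow(couplings))) {
    probes <- effect_probe_ids(manifest, couplings$chrom[i],
                               couplings$start_probe_index[i],
                               couplings$n_cpgs[i])
    if (!all(probes %in% rownames(beta)))
      stop_invalid("coupled region probes absent from Beta matrix")
    g <- couplings$gene_id[i]
    if (!g %in% rownames(counts))
      stop_invalid("coupled gene %s absent from count matrix", g)
    r <- couplings$target_r[i]
    m <- colMeans(beta[probes, shared, drop = FALSE])
    if (sd(m) < 1e-12) {
      ## flat region: inject a latent factor on the logit scale first
      f <- rnorm(ncol(beta))
      lg <- qlogis(clip_unit(beta[probes, , drop = FALSE], 1e-6))
      beta[probes, ] <- plogis(sweep(lg, 2, f, `+`))
      m <- colMeans(beta[probes, shared, drop = FALSE])
    }
    u <- as.numeric(scale(m))  # standardized methylation signal
    e <- log2(counts[g, shared] + 1)
    sigma_e <- max(sd(e), 1)
    ## residual of e orthogonal to u, standardized; falls back to an
    ## orthogonalized random draw when e is degenerate or collinear
    ec <- e - mean(e)
    res <- ec - u * sum(ec * u) / sum(u * u)
    if (sd(res) < 1e-12) {
      res <- rnorm(length(u))
      res <- res - mean(res)
      res <- res - u * sum(res * u) / sum(u * u)
    }
    res <- res / sd(res)
    e_new <- mean(e) + sigma_e * (r * u + sqrt(max(0, 1 - r^2)) * res)
    counts[g, shared] <- as.integer(pmax(0, round(2^e_new - 1)))
  }
  list(beta = beta, counts = counts)
}
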