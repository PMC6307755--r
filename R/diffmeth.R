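# Differential methylation: per-CpG moderated regressions with optional
# patient blocking, and region calling by gap clustering with signed
# Stouffer combination.

## -- design matrix -----------------------------------------------------

## Build the model matrix for a two-group contrast plus covariates.
## "medication" expands to the four drug indicators; drug columns that are
## confounded with the rest of the design collapse to a single
## any-medication indicator. Constant columns are dropped with a message.
build_design <- function(sheet, contrast, covariates) {
  a_groups <- expand_group(contrast[[1]])
  b_groups <- expand_group(contrast[[2]])
  grp <- as.integer(sheet$group %in% a_groups)
  cols <- list("(Intercept)" = rep(1, nrow(sheet)), group = grp)
  add_cov <- function(cols, name, x) {
    cols[[name]] <- x
    cols
  }
  med_requested <- "medication" %in% covariates
  for (cv in setdiff(covariates, "medication")) {
    x <- switch(cv,
      passage = as.numeric(sheet$passage),
      age = as.numeric(sheet$age),
      sex = as.integer(sheet$sex == "M"),
      smoker = as.integer(sheet$smoker),
      {
        if (!cv %in% names(sheet))
          stop_invalid("unknown covariate '%s'", cv)
        as.numeric(sheet[[cv]])
      })
    cols <- add_cov(cols, cv, x)
  }
  if (med_requested)
    for (m in MEDICATION_COLS)
      cols <- add_cov(cols, m, as.integer(sheet[[m]]))
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  ## drop constant covariate columns (never the intercept or the contrast)
  keep <- c(TRUE, TRUE,
            apply(X[, -(1:2), drop = FALSE], 2, function(x) sd(x) > 0))
  if (any(!keep))
    message("dropping constant covariate(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  if (qr(X)$rank < ncol(X) && med_requested) {
    ## collapse drug columns confounded with the contrast
    med_in <- intersect(MEDICATION_COLS, colnames(X))
    if (length(med_in)) {
      any_med <- as.integer(rowSums(sheet[, MEDICATION_COLS]) > 0)
      X <- X[, setdiff(colnames(X), med_in), drop = FALSE]
      if (sd(any_med) > 0) X <- cbind(X, medication = any_med)
      message("medication columns confounded with the design; ",
              "collapsed to a single any-medication indicator")
    }
    if (qr(X)$rank < ncol(X) && "medication" %in% colnames(X)) {
      ## the pooled indicator is itself confounded (e.g. it coincides
      ## with a CD-vs-control contrast): drop it rather than abort
      X <- X[, setdiff(colnames(X), "medication"), drop = FALSE]
      message("any-medication indicator still confounded; dropped")
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop_invalid("design matrix is rank deficient; collinear column(s): %s",
                 paste(dep, collapse = ", "))
  }
  X
}

## -- empirical-Bayes variance moderation -------------------------------

## Newton inversion of the trigamma function.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  y
}

## Method-of-moments fit of a scaled inverse-chi-square prior to residual
## variances (the log-variance moment equations of the moderated-t
## framework). Returns prior df d0 and prior variance s0^2; d0 = 0 means
## no moderation, d0 = Inf means all variances equal.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 50) return(list(d0 = 0, s02 = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- var(e) * (sum(ok) - 1) / sum(ok) - trigamma(df / 2)
  if (!is.finite(ev) || ev <= 0) {
    ## variances more concentrated than chi-square sampling noise alone
    return(list(d0 = Inf, s02 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(ev)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

## -- DMP fitting -------------------------------------------------------

#' Fit differentially methylated positions
#'
#' Per probe, M-values are regressed on the group contrast plus
#' covariates. When `blocking` names a patient column, repeated samples
#' from the same patient are handled by generalized least squares with a
#' single intra-patient residual correlation, pooled across probes via a
#' Fisher-z mean of per-probe moment estimates (two passes: OLS residuals
#' give the pooled rho, then the model is refit on whitened data).
#' Residual variances are shrunk by empirical-Bayes moderation (prior
#' estimated by method of moments on log variances; ordinary t when fewer
#' than 50 probes are available). Two-sided p-values come from the
#' moderated t; BH adjustment is applied across probes.
#'
#' @param m an M-value matrix (probes x samples).
#' @param sheet a sample sheet covering the matrix columns.
#' @param contrast character pair `c(groupA, groupB)`; the effect is A - B.
#'   `"CD"` expands to the union of NINF, INF and STEN.
#' @param covariates character vector among `passage`, `age`, `sex`,
#'   `smoker`, `medication` (the latter expands to the four drug flags).
#' @param blocking name of the patient column for intra-patient
#'   correlation, or NULL to disable blocking.
#' @return a data.frame of DMP records: `probe_id`, `effect` (M
#'   difference), `t`, `p`, `p_adj`, `delta_beta` (group mean Beta
#'   difference), plus attributes `rho` (pooled intra-patient correlation)
#'   and `prior_df`.
#' @export
fit_dmps <- function(m, sheet, contrast,
                     covariates = c("passage", "age", "sex", "medication"),
                     blocking = "patient_id") {
  assert_matrix_like(m, "m")
  validate_sheet(sheet)
  groups <- c(expand_group(contrast[[1]]), expand_group(contrast[[2]]))
  sel <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  if (any(is.na(sel$sample_id)))
    stop_invalid("samples in M matrix absent from sheet")
  keep <- sel$group %in% groups
  sel <- sel[keep, , drop = FALSE]
  Y <- m[, keep, drop = FALSE]
  in_a <- sel$group %in% expand_group(contrast[[1]])
  if (sum(in_a) < 2 || sum(!in_a) < 2)
    stop_invalid("both contrast groups need >= 2 samples")
  X <- build_design(sel, contrast, covariates)
  n <- nrow(X)
  p_rank <- ncol(X)
  df <- n - p_rank
  if (df < 1) stop_invalid("no residual degrees of freedom")

  ols <- lm.fit(X, t(Y))
  res <- ols$residuals                      # n x probes
  rho <- 0
  if (!is.null(blocking)) {
    pt <- sel[[blocking]]
    pairs <- same_patient_pairs(pt)
    if (nrow(pairs) >= 2) {
      s2 <- colSums(res^2) / df
      num <- colSums(res[pairs[, 1], , drop = FALSE] *
                     res[pairs[, 2], , drop = FALSE]) / nrow(pairs)
      ## n/df corrects the attenuation of residual cross-products by the
      ## fitted coefficients
      r_g <- pmin(pmax(num / s2 * (n / df), -0.99), 0.99)
      r_g <- r_g[is.finite(r_g)]
      rho <- tanh(mean(atanh(r_g)))
      if (rho <= -0.3 || rho >= 0.99) {
        warning("pooled intra-patient correlation ", signif(rho, 3),
                " outside (-0.3, 0.99); clipped", call. = FALSE)
        rho <- min(max(rho, -0.3 + 1e-6), 0.99)
      }
      V <- diag(n)
      V[cbind(pairs[, 1], pairs[, 2])] <- rho
      V[cbind(pairs[, 2], pairs[, 1])] <- rho
      Vc <- chol(V)
      Xw <- backsolve(Vc, X, transpose = TRUE)
      Yw <- backsolve(Vc, t(Y), transpose = TRUE)
      colnames(Xw) <- colnames(X)
      ols <- lm.fit(Xw, Yw)
      res <- ols$residuals
      X <- Xw
    }
  }
  coefs <- ols$coefficients
  if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1,
                                           dimnames = list(names(coefs)))
  if (is.null(dim(res))) res <- matrix(res, ncol = 1)
  effect <- coefs["group", ]
  s2 <- colSums(res^2) / df
  xtxi <- chol2inv(chol(crossprod(X)))
  v_gg <- xtxi[match("group", colnames(X)), match("group", colnames(X))]
  prior <- fit_variance_prior(s2, df)
  if (prior$d0 == 0) {
    s2_post <- s2
    df_total <- df
  } else if (is.infinite(prior$d0)) {
    s2_post <- rep(prior$s02, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
    df_total <- df + prior$d0
  }
  tstat <- effect / sqrt(v_gg * s2_post)
  pval <- 2 * pt(-abs(tstat), df_total)
  pval <- pmax(pval, .Machine$double.xmin)
  beta <- m_to_beta(Y)
  delta_beta <- rowMeans(beta[, in_a, drop = FALSE]) -
    rowMeans(beta[, !in_a, drop = FALSE])
  out <- data.frame(
    probe_id = rownames(m),
    effect = as.numeric(effect),
    t = as.numeric(tstat),
    p = as.numeric(pval),
    p_adj = p.adjust(pval, method = "BH"),
    delta_beta = as.numeric(delta_beta),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "rho") <- rho
  attr(out, "prior_df") <- prior$d0
  out
}

## all unordered index pairs of samples sharing a patient
same_patient_pairs <- function(patient) {
  pairs <- list()
  for (pt in unique(patient)) {
    idx <- which(patient == pt)
    if (length(idx) >= 2) {
      cmb <- utils::combn(idx, 2)
      pairs[[length(pairs) + 1L]] <- t(cmb)
    }
  }
  if (length(pairs) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

## -- Stouffer combination and region calling ---------------------------

#' Stouffer combination of z-scores
#'
#' Combines z-scores as `sum(z) / sqrt(length(z))`; on k copies of the
#' same z this equals `z * sqrt(k)`.
#'
#' @param z numeric vector of z-scores.
#' @return the combined z.
#' @export
stouffer_combine <- function(z) {
  if (length(z) == 0) stop_invalid("no z-scores to combine")
  sum(z) / sqrt(length(z))
}

## signed z for a two-sided p and an effect direction
signed_z <- function(p, effect) {
  p <- pmax(p, 1e-300)
  sign(effect) * qnorm(p / 2, lower.tail = FALSE)
}

#' Call differentially methylated regions
#'
#' Candidate regions are maximal runs of seed probes (per-CpG p <=
#' `seed_alpha`) in which successive seeds on the same chromosome lie
#' within `max_gap_bp`; all probes falling between the first and last
#' seed become members, and candidates with fewer than `min_cpgs` member
#' CpGs are discarded. The region statistic combines signed per-CpG
#' z-scores (`sign(effect) * qnorm(1 - p/2)`) by Stouffer's method, so
#' opposite-direction CpGs cancel; the two-sided region p-values are then
#' BH-adjusted across regions, with significance at `p_adj < 0.05`.
#'
#' @param dmps a DMP record data.frame from [fit_dmps()].
#' @param manifest the (filtered) probe manifest giving probe coordinates.
#' @param max_gap_bp maximum gap between successive seed CpGs (default
#'   1000).
#' @param seed_alpha per-CpG seed threshold (default 0.05).
#' @param min_cpgs minimum member CpGs per region (default 3).
#' @param seed_on whether the seed threshold applies to the BH-adjusted
#'   per-CpG p (`"p_adj"`, the default, matching FDR-based candidate
#'   selection in kernel region callers) or the raw p (`"p"`). Seeding on
#'   raw p admits chance same-direction triples whose combined statistic
#'   survives region-level BH, inflating the region false discovery rate.
#' @return a data.frame of DMR records: `chrom`, `start`, `end` (1-based
#'   inclusive CpG bounds), `n_cpgs`, `stouffer_z`, `p_region`, `p_adj`,
#'   `mean_delta_beta`, `probes` (comma-separated member probe ids).
#' @export
call_dmrs <- function(dmps, manifest, max_gap_bp = 1000L,
                      seed_alpha = 0.05, min_cpgs = 3L,
                      seed_on = c("p_adj", "p")) {
  validate_manifest(manifest)
  seed_on <- match.arg(seed_on)
  if (is.null(dmps) || nrow(dmps) == 0)
    return(empty_dmr_frame())
  idx <- match(dmps$probe_id, manifest$probe_id)
  if (any(is.na(idx)))
    stop_invalid("DMP probes absent from manifest")
  d <- dmps[order(idx), , drop = FALSE]
  mi <- manifest[sort(idx), , drop = FALSE]
  regions <- list()
  for (ch in unique(mi$chrom)) {
    on_ch <- mi$chrom == ch
    pos <- mi$pos[on_ch]
    dd <- d[on_ch, , drop = FALSE]
    seed <- which(dd[[seed_on]] <= seed_alpha)
    if (length(seed) == 0) next
    gap_new <- c(TRUE, diff(pos[seed]) > max_gap_bp)
    cluster <- cumsum(gap_new)
    for (cl in unique(cluster)) {
      s <- seed[cluster == cl]
      members <- which(pos >= pos[min(s)] & pos <= pos[max(s)])
      if (length(members) < min_cpgs) next
      z <- signed_z(dd$p[members], dd$effect[members])
      Z <- stouffer_combine(z)
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch,
        start = pos[min(members)],
        end = pos[max(members)],
        n_cpgs = length(members),
        stouffer_z = Z,
        p_region = 2 * pnorm(-abs(Z)),
        mean_delta_beta = mean(dd$delta_beta[members]),
        probes = paste(dd$probe_id[members], collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(regions) == 0) return(empty_dmr_frame())
  out <- do.call(rbind, regions)
  out$p_region <- pmax(out$p_region, .Machine$double.xmin)
  out$p_adj <- p.adjust(out$p_region, method = "BH")
  out <- out[, c("chrom", "start", "end", "n_cpgs", "stouffer_z",
                 "p_region", "p_adj", "mean_delta_beta", "probes")]
  rownames(out) <- NULL
  out
}

empty_dmr_frame <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             n_cpgs = integer(0), stouffer_z = numeric(0),
             p_region = numeric(0), p_adj = numeric(0),
             mean_delta_beta = numeric(0), probes = character(0),
             stringsAsFactors = FALSE)
}

#' Annotate regions with the nearest transcription start site
#'
#' Each region is assigned the same-chromosome gene whose TSS lies closest
#' to the region midpoint. The reported distance is 0 when the TSS falls
#' inside the region. Ties are broken by the lexicographically smallest
#' gene id.
#'
#' @param regions a DMR data.frame from [call_dmrs()].
#' @param genes a gene model (`gene_id`, `chrom`, `tss`, `strand`).
#' @return `regions` with added columns `gene_id` and `tss_distance`.
#' @export
annotate_nearest_tss <- function(regions, genes) {
  if (nrow(genes) == 0) stop_invalid("gene model is empty")
  gene_id <- character(nrow(regions))
  dist_out <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      gene_id[i] <- NA_character_
      dist_out[i] <- NA_real_
      next
    }
    mid <- (regions$start[i] + regions$end[i]) / 2
    dmid <- abs(g$tss - mid)
    best <- which(dmid == min(dmid))
    if (length(best) > 1)
      best <- best[order(g$gene_id[best])[1]]
    gene_id[i] <- g$gene_id[best]
    inside <- g$tss[best] >= regions$start[i] & g$tss[best] <= regions$end[i]
    dist_out[i] <- if (inside) 0 else dmid[best]
  }
  regions$gene_id <- gene_id
  regions$tss_distance <- dist_out
  regions
}
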