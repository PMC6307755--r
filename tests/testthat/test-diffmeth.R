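test_that("a perfectly separated probe yields a vanishing p-value", {
  sheet <- two_group_sheet(3, 3, seed = 51)
  m <- matrix(rep(c(2, 2, 2, -1, -1, -1), each = 1), nrow = 1,
              dimnames = list("p1", sheet$sample_id))
  m <- m[, sheet$sample_id, drop = FALSE]
  grp <- sheet$group[match(colnames(m), sheet$sample_id)]
  m[1, ] <- ifelse(grp == "STEN", 2, -1)
  dmps <- fit_dmps(m, sheet, c("STEN", "NINF"), covariates = character(0),
                   blocking = NULL)
  expect_equal(dmps$effect, 3)
  expect_lt(dmps$p, 1e-12)
})

test_that("moderated statistics agree with the limma cross-check", {
  library(limma)
  sheet <- two_group_sheet(8, 8, seed = 52)
  mf <- generate_manifest(500, c(chr1 = 5e5), seed = 53)
  beta <- simulate_methylation(mf, sheet, NULL, seed = 54)
  m <- beta_to_m(beta)
  dmps <- fit_dmps(m, sheet, c("STEN", "NINF"),
                   covariates = c("passage", "age", "sex"),
                   blocking = NULL)
  design <- model.matrix(~ I(group == "STEN") + passage + age +
                           I(sex == "M"),
                         data = sheet[match(colnames(m), sheet$sample_id), ])
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_gt(cor(dmps$t, fit$t[, 2]), 0.9999)
  expect_lt(max(abs(dmps$t - fit$t[, 2])), 0.05)
  expect_lt(max(abs(dmps$p - fit$p.value[, 2])), 0.01)
})

test_that("patient blocking estimates the duplicate correlation and curbs
           false positives", {
  ## paired duplicates: each patient contributes two near-identical
  ## samples, one per replicate draw; group assignment is by patient
  set.seed(55)
  n_pat <- 8
  n_probe <- 300
  pat_fx <- matrix(rnorm(n_probe * n_pat), n_probe, n_pat)
  m <- pat_fx[, rep(seq_len(n_pat), each = 2)] +
    matrix(rnorm(n_probe * 2 * n_pat, sd = 0.3), n_probe)
  sample_id <- sprintf("S%02d", seq_len(2 * n_pat))
  dimnames(m) <- list(sprintf("cg%03d", seq_len(n_probe)), sample_id)
  sheet <- data.frame(
    sample_id = sample_id,
    assay = "methylation",
    group = rep(c("STEN", "NINF"), each = n_pat),
    patient_id = sprintf("P%d", rep(seq_len(n_pat), each = 2)),
    passage = 1L, age = 40, sex = "M",
    azathioprine = FALSE, purinethol = FALSE, adalimumab = FALSE,
    infliximab = FALSE, smoker = FALSE,
    stringsAsFactors = FALSE
  )
  blocked <- fit_dmps(m, sheet, c("STEN", "NINF"),
                      covariates = character(0), blocking = "patient_id")
  unblocked <- fit_dmps(m, sheet, c("STEN", "NINF"),
                        covariates = character(0), blocking = NULL)
  expect_gt(attr(blocked, "rho"), 0.7)
  ## the data are null between groups: blocking must not inflate, and the
  ## unblocked fit (which overstates the effective n) rejects more
  expect_lte(sum(blocked$p < 0.05), sum(unblocked$p < 0.05))
  expect_lt(mean(blocked$p < 0.05), 0.15)
})

test_that("rank-deficient designs fail loudly, confounded medication
           collapses", {
  sheet <- two_group_sheet(4, 4, seed = 56)
  sheet$age <- sheet$passage  # force exact collinearity
  m <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(paste0("p", 1:10), sheet$sample_id))
  expect_error(
    fit_dmps(m, sheet, c("STEN", "NINF"), covariates = c("passage", "age"),
             blocking = NULL),
    "collinear.*(age|passage)")
  ## medication flags identical to the contrast collapse with a message
  sheet2 <- two_group_sheet(4, 4, seed = 57)
  sheet2$azathioprine <- sheet2$group == "STEN"
  sheet2$purinethol <- FALSE
  sheet2$purinethol[which(sheet2$group == "NINF")[1]] <- TRUE
  sheet2$adalimumab <- FALSE
  sheet2$infliximab <- FALSE
  m2 <- matrix(rnorm(10 * 8), 10, 8,
               dimnames = list(paste0("p", 1:10), sheet2$sample_id))
  expect_message(
    fit_dmps(m2, sheet2, c("STEN", "NINF"), covariates = "medication",
             blocking = NULL),
    "collapsed|constant")
})

test_that("Stouffer combination matches its closed forms", {
  z <- 1.7
  for (k in c(2, 3, 7)) expect_equal(stouffer_combine(rep(z, k)),
                                     z * sqrt(k))
  ## three same-direction CpGs at one-sided p = 0.05
  z3 <- rep(qnorm(0.95), 3)
  Z <- stouffer_combine(z3)
  expect_equal(Z, qnorm(0.95) * sqrt(3), tolerance = 1e-12)
  expect_lt(abs(pnorm(-Z) - 0.00219), 1e-5)
})

test_that("region calling enforces the CpG-count and gap rules", {
  mf <- tiny_manifest(10, step = 100)
  base <- data.frame(probe_id = mf$probe_id, effect = 1, t = 1,
                     p = 0.9, p_adj = 0.9, delta_beta = 0.1,
                     stringsAsFactors = FALSE)
  ## two adjacent seeds only: below the 3-CpG minimum, nothing emitted
  d2 <- base
  d2[3:4, c("p", "p_adj")] <- 1e-6
  expect_equal(nrow(call_dmrs(d2, mf)), 0)
  ## three seeds: region emitted spanning them
  d3 <- base
  d3[3:5, c("p", "p_adj")] <- 1e-6
  r3 <- call_dmrs(d3, mf)
  expect_equal(nrow(r3), 1)
  expect_equal(r3$n_cpgs, 3)
  expect_equal(c(r3$start, r3$end), c(300, 500))
  ## an interior non-seed probe between seeds becomes a member
  d4 <- base
  d4[c(3, 5, 6), c("p", "p_adj")] <- 1e-6
  r4 <- call_dmrs(d4, mf)
  expect_equal(r4$n_cpgs, 4)
  ## seeds separated beyond the gap form separate (dropped) candidates
  mf_far <- tiny_manifest(4, step = 10000)
  dfar <- data.frame(probe_id = mf_far$probe_id, effect = 1, t = 1,
                     p = 1e-6, p_adj = 1e-6, delta_beta = 0.1)
  expect_equal(nrow(call_dmrs(dfar, mf_far, max_gap_bp = 1000)), 0)
  ## empty input
  expect_equal(nrow(call_dmrs(base[0, ], mf)), 0)
})

test_that("opposite-direction CpGs cancel in the region statistic", {
  mf <- tiny_manifest(4, step = 100)
  d <- data.frame(probe_id = mf$probe_id,
                  effect = c(1, -1, 1, -1), t = 0,
                  p = 1e-4, p_adj = 1e-4, delta_beta = 0)
  r <- call_dmrs(d, mf)
  expect_equal(r$stouffer_z, 0, tolerance = 1e-12)
  expect_gt(r$p_region, 0.99)
})

test_that("nearest-TSS annotation follows midpoint distance and ties", {
  regions <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                        n_cpgs = 3L, stouffer_z = 3, p_region = 1e-3,
                        p_adj = 1e-3, mean_delta_beta = 0.2,
                        probes = "a,b,c", stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("B_GENE", "A_GENE", "FAR"),
                      chrom = "chr1",
                      tss = c(1400L, 1600L, 50000L),
                      strand = "+", stringsAsFactors = FALSE)
  ## TSS inside the region: distance zero; equidistant from midpoint 1500,
  ## so the lexicographically smaller id wins
  ann <- annotate_nearest_tss(regions, genes)
  expect_equal(ann$gene_id, "A_GENE")
  expect_equal(ann$tss_distance, 0)
  ## outside TSS reports its midpoint distance
  regions2 <- transform(regions, start = 40000L, end = 41000L)
  ann2 <- annotate_nearest_tss(regions2, genes)
  expect_equal(ann2$gene_id, "FAR")
  expect_equal(ann2$tss_distance, 50000 - 40500)
  expect_error(annotate_nearest_tss(regions, genes[0, ]), "empty")
})

test_that("a planted region annotates to the gene at its coordinates", {
  ## six CpGs spanning chr1:113054687-113056390 with the matching gene
  pos <- as.integer(round(seq(113054687, 113056390, length.out = 6)))
  mf <- data.frame(probe_id = sprintf("cg%d", 1:6), chrom = "chr1",
                   pos = pos, snp_flag = FALSE, crossreactive_flag = FALSE,
                   stringsAsFactors = FALSE)
  d <- data.frame(probe_id = mf$probe_id, effect = -1, t = -5,
                  p = 1e-5, p_adj = 1e-5, delta_beta = -0.2)
  genes <- data.frame(gene_id = c("WNT2B", "OTHER"), chrom = "chr1",
                      tss = c(113056000L, 113500000L), strand = "+",
                      stringsAsFactors = FALSE)
  dmr <- annotate_nearest_tss(call_dmrs(d, mf), genes)
  expect_equal(nrow(dmr), 1)
  expect_equal(dmr$n_cpgs, 6)
  expect_equal(dmr$gene_id, "WNT2B")
  expect_equal(format_coordinates(dmr), "chr1:113054687-113056390")
})
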