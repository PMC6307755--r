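test_that("manifest generation respects layout, flags, and determinism", {
  mf <- generate_manifest(100, c(chr1 = 1e6), seed = 3)
  expect_equal(nrow(mf), 100)
  expect_true(all(diff(mf$pos) > 0))
  ## zero flag fraction leaves every probe unflagged
  mf0 <- generate_manifest(200, c(chr1 = 1e6, chr2 = 1e6),
                           flag_fractions = c(snp = 0, crossreactive = 0),
                           seed = 4)
  expect_false(any(mf0$snp_flag))
  expect_false(any(mf0$crossreactive_flag))
  ## same seed twice: identical objects
  expect_identical(generate_manifest(150, c(chr1 = 1e6), seed = 9),
                   generate_manifest(150, c(chr1 = 1e6), seed = 9))
  ## flags appear at roughly the requested fraction
  mf2 <- generate_manifest(5000, c(chr1 = 5e6),
                           flag_fractions = c(snp = 0.2,
                                              crossreactive = 0.05),
                           seed = 5)
  expect_lt(abs(mean(mf2$snp_flag) - 0.2), 0.03)
  expect_error(generate_manifest(10, setNames(numeric(0), character(0))),
               "chrom_layout")
})

test_that("default cohort reproduces the dual-assay study design", {
  sheet <- generate_cohort(seed = 1)
  meth <- sheet[sheet$assay %in% c("methylation", "both"), ]
  expr <- sheet[sheet$assay %in% c("expression", "both"), ]
  expect_equal(nrow(meth), 18)
  expect_equal(length(unique(meth$patient_id)), 10)
  expect_equal(nrow(expr), 21)
  expect_equal(length(unique(expr$patient_id)), 14)
  shared <- sheet[sheet$assay == "both", ]
  expect_equal(nrow(shared), 9)
  expect_equal(length(unique(shared$patient_id)), 6)
  ## per-group per-assay composition
  expect_equal(as.vector(table(meth$group)[c("NINF", "INF", "STEN",
                                             "nonCD")]),
               c(7L, 2L, 4L, 5L))
  expect_equal(as.vector(table(expr$group)[c("NINF", "INF", "STEN",
                                             "nonCD")]),
               c(6L, 4L, 5L, 6L))
  ## non-CD patients carry no medication
  noncd <- sheet$group == "nonCD"
  expect_false(any(sheet$azathioprine[noncd] | sheet$purinethol[noncd] |
                     sheet$adalimumab[noncd] | sheet$infliximab[noncd]))
  expect_identical(generate_cohort(seed = 7), generate_cohort(seed = 7))
})

test_that("cohort plans handle edge designs and impossible sharing", {
  one <- generate_cohort(cohort_design(n_meth = c(NINF = 1)), seed = 2)
  expect_equal(nrow(one), 1)
  no_inf <- generate_cohort(cohort_design(n_meth = c(STEN = 3, NINF = 3)),
                            seed = 2)
  expect_false(any(no_inf$group == "INF"))
  expect_error(cohort_design(n_meth = c(NINF = 2), n_shared = 5),
               "n_shared")
})

test_that("methylation simulation honours noise, range, and planted shifts", {
  mf <- generate_manifest(50, c(chr1 = 5e4), seed = 1)
  sheet <- two_group_sheet(4, 4, seed = 1)
  ## zero noise, no effects: all samples identical per probe
  b0 <- simulate_methylation(mf, sheet, NULL, noise_sd = 0, seed = 2)
  expect_equal(max(apply(b0, 1, sd)), 0)
  ## values strictly inside (0, 1)
  b1 <- simulate_methylation(mf, sheet, NULL, seed = 3)
  expect_gt(min(b1), 0)
  expect_lt(max(b1), 1)
  expect_identical(simulate_methylation(mf, sheet, NULL, seed = 5),
                   simulate_methylation(mf, sheet, NULL, seed = 5))
})

test_that("planted regional shift reproduces the target Beta difference", {
  ## mid-range unimodal baseline so a +0.2 shift has headroom
  mf <- generate_manifest(40, c(chr1 = 4e4), seed = 11)
  sheet <- two_group_sheet(30, 30, seed = 11)
  eff <- data.frame(chrom = "chr1", start_probe_index = 10, n_cpgs = 8,
                    delta_beta = 0.2, target_group = "STEN")
  beta <- simulate_methylation(
    mf, sheet, eff, noise_sd = 0.2, seed = 12,
    baseline = list(modes = c(0.4), weights = c(1), sd = 0.2))
  grp <- sheet$group[match(colnames(beta), sheet$sample_id)]
  probes <- meqtm:::effect_probe_ids(mf, "chr1", 10, 8)
  diff_on <- rowMeans(beta[probes, grp == "STEN"]) -
    rowMeans(beta[probes, grp == "NINF"])
  expect_lt(max(abs(diff_on - 0.2)), 0.05)
  ## off-target probes stay null
  off <- setdiff(rownames(beta), probes)
  diff_off <- rowMeans(beta[off, grp == "STEN"]) -
    rowMeans(beta[off, grp == "NINF"])
  expect_lt(max(abs(diff_off)), 0.06)
  ## invalid regions rejected
  bad <- data.frame(chrom = "chr1", start_probe_index = 38, n_cpgs = 8,
                    delta_beta = 0.2, target_group = "STEN")
  expect_error(simulate_methylation(mf, sheet, bad, seed = 1), "exceeds")
  overlap <- rbind(eff, transform(eff, start_probe_index = 12))
  expect_error(simulate_methylation(mf, sheet, overlap, seed = 1),
               "overlap")
})

test_that("count simulation matches its negative-binomial contract", {
  genes <- generate_gene_model(40, c(chr1 = 1e5), seed = 21)
  sheet <- two_group_sheet(500, 500, seed = 21)
  sheet$assay <- "expression"
  ## dispersion -> 0, equal size factors: Poisson limit, variance ~ mean
  cts <- simulate_counts(genes, sheet, NULL,
                         baseline = list(mu = 100, dispersion = 0),
                         size_factor_spread = 0, seed = 22)
  ratio <- apply(cts, 1, var) / rowMeans(cts)
  expect_lt(max(abs(ratio - 1)), 0.25)
  expect_true(all(cts >= 0) && all(cts == round(cts)))
  ## planted lfc = 1 doubles the target group's mean
  sheet2 <- two_group_sheet(60, 60, seed = 23)
  sheet2$assay <- "expression"
  eff <- data.frame(gene_id = genes$gene_id[5], log2_fold_change = 1,
                    target_group = "STEN")
  cts2 <- simulate_counts(genes, sheet2, eff,
                          baseline = list(mu = 200, dispersion = 0.05),
                          size_factor_spread = 0, seed = 24)
  grp <- sheet2$group[match(colnames(cts2), sheet2$sample_id)]
  fold <- mean(cts2[5, grp == "STEN"]) / mean(cts2[5, grp == "NINF"])
  expect_lt(abs(fold - 2), 0.25)
  ## zero baseline mean gives an all-zero row
  cts3 <- simulate_counts(genes, sheet, NULL,
                          baseline = list(mu = c(0, rep(100, 39)),
                                          dispersion = 0.1),
                          seed = 25)
  expect_true(all(cts3[1, ] == 0))
})

test_that("eQTM coupling controls the realized correlation", {
  mf <- generate_manifest(30, c(chr1 = 3e4), seed = 31)
  ## 200 shared dual-assay samples for the asymptotic check
  plan <- cohort_design(n_meth = c(NINF = 200), n_expr = c(NINF = 200),
                        n_shared = 200)
  sheet <- generate_cohort(plan, seed = 31)
  genes <- generate_gene_model(5, c(chr1 = 3e4), seed = 32)
  beta <- simulate_methylation(mf, sheet, NULL, seed = 33)
  counts <- simulate_counts(genes, sheet, NULL, seed = 34)
  coup <- data.frame(chrom = "chr1", start_probe_index = 5, n_cpgs = 6,
                     gene_id = genes$gene_id[2], target_r = -0.8)
  cc <- couple_eqtm(beta, counts, coup, mf, seed = 35)
  probes <- meqtm:::effect_probe_ids(mf, "chr1", 5, 6)
  shared <- intersect(colnames(cc$beta), colnames(cc$counts))
  le <- log_expression(cc$counts, size_factors = rep(1, ncol(cc$counts)))
  colnames(le) <- colnames(cc$counts)
  r <- eqtm_correlate(dmr_mean_beta(cc$beta, probes), le[genes$gene_id[2], ],
                      shared)
  expect_lt(abs(r - (-0.8)), 0.1)
  ## empty couplings: both matrices unchanged
  un <- couple_eqtm(beta, counts, NULL, mf)
  expect_identical(un$beta, beta)
  expect_identical(un$counts, counts)
  ## zero-noise target -1: essentially collinear link
  beta0 <- simulate_methylation(mf, sheet, NULL, noise_sd = 0, seed = 36)
  coup1 <- transform(coup, target_r = -1)
  cc1 <- couple_eqtm(beta0, counts, coup1, mf, seed = 37)
  le1 <- log_expression(cc1$counts, size_factors = rep(1, ncol(cc1$counts)))
  colnames(le1) <- colnames(cc1$counts)
  r1 <- eqtm_correlate(dmr_mean_beta(cc1$beta, probes),
                       le1[genes$gene_id[2], ], shared)
  expect_lt(r1, -0.99)
  ## unknown gene rejected
  coup_bad <- transform(coup, gene_id = "NOPE")
  expect_error(couple_eqtm(beta, counts, coup_bad, mf), "NOPE")
})
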