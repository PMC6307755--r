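# Shared fixture builders. Everything is generated in code at test time.

tiny_manifest <- function(n = 6, chrom = "chr1", step = 100) {
  data.frame(
    probe_id = sprintf("p%02d", seq_len(n)),
    chrom = chrom,
    pos = as.integer(seq_len(n) * step),
    snp_flag = FALSE,
    crossreactive_flag = FALSE,
    stringsAsFactors = FALSE
  )
}

two_group_sheet <- function(n_a = 10, n_b = 10, group_a = "STEN",
                            group_b = "NINF", seed = 1) {
  plan <- cohort_design(n_meth = stats::setNames(c(n_a, n_b),
                                                 c(group_a, group_b)))
  generate_cohort(plan, seed = seed)
}

## A small dual-assay study with planted DMRs whose nearest genes carry
## planted fold changes and methylation-expression couplings, so that the
## DMEG/eQTM stages have known ground truth.
## regions are hypermethylated in STEN and their genes downregulated, so
## the negative coupling reinforces (rather than fights) the group signal
make_coupled_study <- function(seed = 1, n_probes = 600, n_regions = 3,
                               target_r = -0.8, lfc = -3,
                               delta_beta = 0.25) {
  sheet <- generate_cohort(seed = seed)
  manifest <- generate_manifest(n_probes, c(chr1 = 6e5), seed = seed + 1)
  effects <- plant_regions(manifest, n_regions, n_cpgs = 8,
                           delta_beta = delta_beta,
                           target_group = "STEN", seed = seed + 2)
  ## place one gene's TSS right at each planted region plus decoys
  genes <- generate_gene_model(30, c(chr1 = 6e5), seed = seed + 3)
  for (i in seq_len(n_regions)) {
    probes <- meqtm:::effect_probe_ids(manifest, effects$chrom[i],
                                       effects$start_probe_index[i],
                                       effects$n_cpgs[i])
    pos <- manifest$pos[match(probes, manifest$probe_id)]
    genes$tss[i] <- as.integer(round(mean(range(pos))))
    genes$chrom[i] <- effects$chrom[i]
  }
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  gene_effects <- data.frame(gene_id = genes$gene_id[seq_len(n_regions)],
                             log2_fold_change = lfc,
                             target_group = "STEN")
  beta <- simulate_methylation(manifest, sheet, effects, seed = seed + 4)
  counts <- simulate_counts(genes, sheet, gene_effects, seed = seed + 5)
  couplings <- data.frame(
    chrom = effects$chrom,
    start_probe_index = effects$start_probe_index,
    n_cpgs = effects$n_cpgs,
    gene_id = genes$gene_id[seq_len(n_regions)],
    target_r = target_r
  )
  cc <- couple_eqtm(beta, counts, couplings, manifest, seed = seed + 6)
  list(sheet = sheet, manifest = manifest, genes = genes,
       effects = effects, gene_effects = gene_effects,
       couplings = couplings, beta = cc$beta, counts = cc$counts)
}

## planted region spans in bp, for overlap bookkeeping
planted_spans <- function(manifest, effects) {
  lapply(seq_len(nrow(effects)), function(i) {
    probes <- meqtm:::effect_probe_ids(manifest, effects$chrom[i],
                                       effects$start_probe_index[i],
                                       effects$n_cpgs[i])
    pos <- manifest$pos[match(probes, manifest$probe_id)]
    list(chrom = effects$chrom[i], lo = min(pos), hi = max(pos))
  })
}

overlaps_any <- function(chrom, start, end, spans) {
  any(vapply(spans, function(sp)
    sp$chrom == chrom && start <= sp$hi && end >= sp$lo, logical(1)))
}
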