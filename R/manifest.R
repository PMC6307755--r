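#' Generate a synthetic CpG probe manifest
#'
#' Probes are allocated to chromosomes proportionally to the supplied
#' lengths and positioned by cumulative exponential inter-probe gaps
#' (default mean 500 bp), which makes gap-based region clustering
#' meaningful. SNP-overlap and cross-reactivity flags are drawn
#' independently at the requested fractions.
#'
#' @param n_probes total number of probes (>= 1).
#' @param chrom_layout named numeric vector mapping chromosome name to
#'   length in bp; autosomes plus optionally `chrX`/`chrY`.
#' @param flag_fractions named list/vector with elements `snp` and
#'   `crossreactive`, each a fraction in \[0, 1\].
#' @param seed integer seed.
#' @param gap_mean mean inter-probe gap in bp.
#' @return a manifest data.frame: `probe_id`, `chrom`, `pos`, `snp_flag`,
#'   `crossreactive_flag`, sorted by (chrom, pos).
#' @examples
#' mf <- generate_manifest(100, c(chr1 = 1e6), seed = 1)
#' head(mf)
#' @export
generate_manifest <- function(n_probes,
                              chrom_layout = c(chr1 = 5e6, chr2 = 5e6),
                              flag_fractions = c(snp = 0.05,
                                                 crossreactive = 0.02),
                              seed = 1L,
                              gap_mean = 500) {
  if (length(chrom_layout) == 0)
    stop_invalid("chrom_layout must name at least one chromosome")
  if (is.null(names(chrom_layout)) || any(!nzchar(names(chrom_layout))))
    stop_invalid("chrom_layout must be a named vector")
  if (n_probes < 1) stop_invalid("n_probes must be >= 1")
  ff <- as.list(flag_fractions)
  f_snp <- ff$snp %||% 0
  f_cross <- ff$crossreactive %||% 0
  if (f_snp < 0 || f_snp > 1 || f_cross < 0 || f_cross > 1)
    stop_invalid("flag fractions must lie in [0, 1]")
  set.seed(seed)
  ## allocate probes proportionally to chromosome length (largest remainder)
  w <- chrom_layout / sum(chrom_layout)
  alloc <- floor(w * n_probes)
  rem <- n_probes - sum(alloc)
  if (rem > 0) {
    extra <- order(w * n_probes - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  chroms <- rep(names(chrom_layout), alloc)
  pos <- unlist(lapply(names(chrom_layout), function(ch) {
    k <- alloc[[ch]]
    if (k == 0) return(integer(0))
    gaps <- pmax(1, round(rexp(k, rate = 1 / gap_mean)))
    cumsum(gaps)
  }), use.names = FALSE)
  manifest <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n_probes)),
    chrom = chroms,
    pos = as.integer(pos),
    snp_flag = rbinom(n_probes, 1, f_snp) == 1,
    crossreactive_flag = rbinom(n_probes, 1, f_cross) == 1,
    stringsAsFactors = FALSE
  )
  manifest <- manifest[order(manifest$chrom, manifest$pos), , drop = FALSE]
  rownames(manifest) <- NULL
  validate_manifest(manifest)
}

#' Generate a synthetic gene model
#'
#' Transcription start sites are placed uniformly along each chromosome;
#' strand is drawn at random. Used to drive nearest-TSS annotation and
#' count simulation.
#'
#' @param n_genes number of genes (>= 1).
#' @param chrom_layout named numeric vector of chromosome lengths.
#' @param seed integer seed.
#' @return a data.frame: `gene_id`, `chrom`, `tss`, `strand`.
#' @export
generate_gene_model <- function(n_genes,
                                chrom_layout = c(chr1 = 5e6, chr2 = 5e6),
                                seed = 1L) {
  if (length(chrom_layout) == 0)
    stop_invalid("chrom_layout must name at least one chromosome")
  if (n_genes < 1) stop_invalid("n_genes must be >= 1")
  set.seed(seed)
  chrom <- sample(names(chrom_layout), n_genes, replace = TRUE,
                  prob = chrom_layout / sum(chrom_layout))
  tss <- vapply(chrom, function(ch)
    sample.int(as.integer(chrom_layout[[ch]]), 1L), integer(1))
  genes <- data.frame(
    gene_id = sprintf("GENE%05d", seq_len(n_genes)),
    chrom = chrom,
    tss = as.integer(tss),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(genes) <- NULL
  genes
}
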