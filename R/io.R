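# File readers/writers and the stage-wise pipeline driver. Matrices are
# TSV with a single header line (row ids in the first column); sample
# sheets may be TSV or CSV; region exports are Table-style 1-based
# inclusive coordinate strings plus BED (0-based half-open).

read_table_auto <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ## skip leading provenance comment lines
  head_lines <- readLines(path, n = 50L)
  n_skip <- match(FALSE, startsWith(head_lines, "#")) - 1L
  as.data.frame(data.table::fread(path, sep = sep, header = TRUE,
                                  skip = n_skip, data.table = FALSE,
                                  check.names = FALSE))
}

read_matrix_tsv <- function(path) {
  df <- read_table_auto(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop_invalid("duplicate row ids in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop_invalid("duplicate sample ids in %s", path)
  m
}

#' Read and validate study matrices and metadata
#'
#' `read_beta_matrix()` requires all values in \[0, 1\] and reports the
#' first offending cell; `read_count_matrix()` requires non-negative
#' integers. When a sample sheet is supplied, matrix columns are checked
#' against it (cross-consistency).
#'
#' @param path file path (TSV; sample sheets may also be CSV).
#' @param sheet optional sample sheet for cross-consistency checks.
#' @return the validated object (matrix or data.frame).
#' @export
read_beta_matrix <- function(path, sheet = NULL) {
  m <- read_matrix_tsv(path)
  bad <- which(!is.finite(m) | m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_invalid("Beta value %s at probe '%s', sample '%s' is outside [0, 1]",
                 format(m[bad[1, 1], bad[1, 2]]),
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  check_samples_in_sheet(colnames(m), sheet, path)
  m
}

#' @rdname read_beta_matrix
#' @export
read_count_matrix <- function(path, sheet = NULL) {
  m <- read_matrix_tsv(path)
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_invalid(
      "count %s at gene '%s', sample '%s' is not a non-negative integer",
      format(m[bad[1, 1], bad[1, 2]]),
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  storage.mode(m) <- "integer"
  check_samples_in_sheet(colnames(m), sheet, path)
  m
}

check_samples_in_sheet <- function(samples, sheet, path) {
  if (is.null(sheet)) return(invisible(NULL))
  missing_s <- setdiff(samples, sheet$sample_id)
  if (length(missing_s))
    stop_invalid("sample(s) in %s absent from the sample sheet: %s",
                 path, paste(missing_s, collapse = ", "))
  invisible(NULL)
}

#' @rdname read_beta_matrix
#' @export
read_sample_sheet <- function(path) {
  df <- read_table_auto(path)
  for (cv in c(MEDICATION_COLS, "smoker"))
    if (cv %in% names(df)) df[[cv]] <- as.logical(df[[cv]])
  if ("age" %in% names(df)) df$age <- as.numeric(df$age)
  if ("passage" %in% names(df)) df$passage <- as.integer(df$passage)
  validate_sheet(df)
}

#' @rdname read_beta_matrix
#' @export
read_manifest <- function(path) {
  df <- read_table_auto(path)
  for (cv in c("snp_flag", "crossreactive_flag"))
    if (cv %in% names(df)) df[[cv]] <- as.logical(df[[cv]])
  validate_manifest(df)
}

#' @rdname read_beta_matrix
#' @export
read_gene_model <- function(path) {
  df <- read_table_auto(path)
  req <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_invalid("gene model is missing column(s): %s",
                 paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop_invalid("duplicate gene_id")
  if (any(df$tss < 1)) stop_invalid("tss must be >= 1")
  df
}

#' Read a clock coefficient table
#'
#' TSV with columns `probe_id` and `weight`; the row whose probe id is
#' `(Intercept)` supplies the intercept.
#'
#' @param path file path.
#' @param adult_age transform breakpoint (default 20).
#' @return a clock model list (see [predict_age()]).
#' @export
read_clock <- function(path, adult_age = 20) {
  df <- read_table_auto(path)
  if (!all(c("probe_id", "weight") %in% names(df)))
    stop_invalid("clock file needs columns probe_id, weight")
  ic <- df$probe_id == "(Intercept)"
  coefs <- df$weight[!ic]
  names(coefs) <- df$probe_id[!ic]
  list(intercept = if (any(ic)) df$weight[which(ic)[1]] else 0,
       coefficients = coefs, adult_age = adult_age)
}

#' Write tabular outputs
#'
#' `write_matrix_tsv()` writes a named matrix with an `id` first column;
#' `write_table_tsv()` writes a data.frame. Both can prepend provenance
#' comment lines (`#`-prefixed).
#'
#' @param x matrix or data.frame.
#' @param path output path.
#' @param provenance optional character vector of comment lines.
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(x, path, provenance = NULL) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_tsv(df, path, provenance)
}

#' @rdname write_matrix_tsv
#' @export
write_table_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse and format region coordinate strings
#'
#' The tabular convention is `chrom:start-end`, 1-based inclusive. The
#' parser accepts a hyphen or an en-dash separator; the writer always
#' emits a hyphen.
#'
#' @param x character vector of coordinate strings.
#' @return `parse_coordinates`: a data.frame `chrom`, `start`, `end`;
#'   `format_coordinates`: a character vector.
#' @export
parse_coordinates <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)[-–]([0-9]+)$", x))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad))
    stop_invalid("malformed coordinate string: %s", x[bad][1])
  data.frame(chrom = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' @rdname parse_coordinates
#' @param regions a data.frame with `chrom`, `start`, `end`.
#' @export
format_coordinates <- function(regions) {
  sprintf("%s:%d-%d", regions$chrom, as.integer(regions$start),
          as.integer(regions$end))
}

#' Export regions as BED
#'
#' BED intervals are 0-based half-open, so `start` is decremented by one
#' and `end` kept. The name field carries the annotated gene (or `.`),
#' the score `-log10(p_adj)` capped at 1000. An empty region set yields
#' an empty file.
#'
#' @param regions a DMR data.frame (optionally annotated).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  score <- pmin(round(-log10(pmax(regions$p_adj, .Machine$double.xmin)), 2),
                1000)
  bed <- data.frame(
    chrom = regions$chrom,
    start = as.integer(regions$start) - 1L,
    end = as.integer(regions$end),
    name = if ("gene_id" %in% names(regions)) regions$gene_id else ".",
    score = score,
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_region_bed
#' @export
read_region_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:5] <- c("chrom", "start", "end", "gene_id", "score")
  df$start <- df$start + 1L  # back to 1-based inclusive
  df
}

#' Export an eQTM table in the tabular report layout
#'
#' Writes one row per DMR-gene pair with columns `Coordinates`, `nCpGs`,
#' `Gene`, `Ensembl`, `Entrez`, `Correlation` (formatted as
#' `r [ci_low, ci_high]`), `p_correlation`, `p_DE`, and `p_DM`. Ensembl
#' and Entrez ids are filled from `gene_info` (a data.frame with
#' `gene_id`, `ensembl`, `entrez`) when given, otherwise left `NA`.
#'
#' @param eqtm an eQTM result from [eqtm_analysis()].
#' @param path output path.
#' @param gene_info optional gene id cross-reference.
#' @param provenance optional comment lines.
#' @return the path, invisibly.
#' @export
write_eqtm_tsv <- function(eqtm, path, gene_info = NULL,
                           provenance = NULL) {
  xref <- function(col) {
    if (is.null(gene_info) || !col %in% names(gene_info))
      return(rep(NA_character_, nrow(eqtm)))
    gene_info[[col]][match(eqtm$gene_id, gene_info$gene_id)]
  }
  out <- data.frame(
    Coordinates = eqtm$coordinates,
    nCpGs = eqtm$n_cpgs,
    Gene = eqtm$gene_id,
    Ensembl = xref("ensembl"),
    Entrez = xref("entrez"),
    Correlation = sprintf("%.2f [%.2f, %.2f]", eqtm$r, eqtm$ci_low,
                          eqtm$ci_high),
    p_correlation = eqtm$p_corr,
    p_DE = eqtm$p_de,
    p_DM = eqtm$p_dm,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  if (nrow(eqtm) == 0) out <- out[0, , drop = FALSE]
  write_table_tsv(out, path, provenance)
}

## deterministic checksum of a serialized object, for provenance lines
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- sum(raw * (seq_along(raw) %% 251 + 1)) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Assemble a run configuration
#'
#' Collects stage parameters and seeds with validated defaults. All
#' stochastic stages derive their seeds from `seed`.
#'
#' @param contrast group contrast, e.g. `c("STEN", "NINF")`.
#' @param covariates model covariates.
#' @param blocking patient column for blocking or NULL.
#' @param epsilon Beta clip bound.
#' @param max_gap_bp,seed_alpha,min_cpgs region-calling parameters.
#' @param cpm_threshold,max_below expression filter parameters.
#' @param B_bootstrap,B_null resample counts.
#' @param alpha significance level in (0, 1).
#' @param seed master integer seed.
#' @return a validated config list.
#' @export
run_config <- function(contrast = c("STEN", "NINF"),
                       covariates = c("passage", "age", "sex", "medication"),
                       blocking = "patient_id",
                       epsilon = 1e-6, max_gap_bp = 1000L,
                       seed_alpha = 0.05, min_cpgs = 3L,
                       cpm_threshold = 1, max_below = NULL,
                       B_bootstrap = 10000L, B_null = 10000L,
                       alpha = 0.05, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  if (epsilon <= 0 || epsilon >= 0.5)
    stop_invalid("epsilon must lie in (0, 0.5)")
  if (is.null(seed)) stop_invalid("an explicit seed is required")
  list(contrast = contrast, covariates = covariates, blocking = blocking,
       epsilon = epsilon, max_gap_bp = max_gap_bp,
       seed_alpha = seed_alpha, min_cpgs = min_cpgs,
       cpm_threshold = cpm_threshold, max_below = max_below,
       B_bootstrap = B_bootstrap, B_null = B_null, alpha = alpha,
       seed = seed)
}

#' Run the full pipeline on in-memory inputs
#'
#' Executes probe filtering, the PCA covariate screen, the DMP/DMR
#' analyses, differential expression, the DMEG intersection, and the eQTM
#' analysis, in order. Any stage failure halts with the stage name;
#' outputs of completed stages are kept (and already on disk when
#' `outdir` is given). Every written TSV carries a provenance comment
#' with the package version, a config hash, and the seed.
#'
#' @param beta Beta matrix (probes x methylation samples).
#' @param counts count matrix (genes x expression samples).
#' @param sheet sample sheet covering both assays.
#' @param manifest probe manifest.
#' @param genes gene model.
#' @param config a [run_config()] list.
#' @param outdir optional output directory for TSV exports.
#' @return a list with elements `manifest_filtered`, `screen_meth`,
#'   `screen_expr`, `dmps`, `dmrs`, `degs`, `dmegs`, `eqtm`, and `config`.
#' @export
run_pipeline <- function(beta, counts, sheet, manifest, genes,
                         config = run_config(), outdir = NULL) {
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  prov <- c(paste0("meqtm ", as.character(utils::packageVersion("meqtm"))),
            paste0("config_hash=", config_hash(config)),
            paste0("seed=", config$seed))
  emit <- function(obj, name) {
    if (!is.null(outdir))
      write_table_tsv(obj, file.path(outdir, paste0(name, ".tsv")), prov)
    obj
  }
  out <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out$manifest_filtered <- stage("filter", {
    mf <- filter_probes(manifest)
    mf[mf$probe_id %in% rownames(beta), , drop = FALSE]
  })
  beta_f <- beta[out$manifest_filtered$probe_id, , drop = FALSE]
  m <- beta_to_m(beta_f, config$epsilon)
  out$screen_meth <- stage("screen", emit(
    pc_covariate_screen(m, sheet, min(3L, ncol(m) - 1L)), "screen_meth"))
  out$dmps <- stage("dmp", emit(
    fit_dmps(m, sheet, config$contrast, config$covariates,
             config$blocking), "dmp"))
  out$dmrs <- stage("dmr", {
    d <- call_dmrs(out$dmps, out$manifest_filtered, config$max_gap_bp,
                   config$seed_alpha, config$min_cpgs)
    d <- annotate_nearest_tss(d, genes)
    if (!is.null(outdir)) {
      exp_d <- d
      exp_d$coordinates <- format_coordinates(d)
      emit(exp_d, "dmr")
      write_region_bed(d, file.path(outdir, "dmr.bed"))
    }
    d
  })
  counts_f <- stage("de", filter_low_expression(counts,
                                                config$cpm_threshold,
                                                config$max_below))
  out$degs <- stage("de", emit(
    fit_degs(counts_f, sheet, config$contrast, config$covariates), "deg"))
  log_expr <- stage("de", log_expression(counts_f))
  out$screen_expr <- stage("screen", pc_covariate_screen(
    log_expr, sheet, min(3L, ncol(log_expr) - 1L)))
  out$dmegs <- stage("dmeg", emit(
    find_dmegs(out$dmrs, out$degs, config$alpha), "dmeg"))
  out$eqtm <- stage("eqtm", emit(
    eqtm_analysis(out$dmegs, beta_f, log_expr, out$manifest_filtered,
                  config$B_bootstrap, config$B_null,
                  seed = config$seed), "eqtm"))
  out
}
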