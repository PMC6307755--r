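# Internal helpers shared across modules.

#' @importFrom stats cor median pnorm pt qnorm quantile rbinom rexp rlnorm
#'   rnbinom rnorm rpois sd var p.adjust plogis qlogis prcomp setNames
#'   as.formula
#' @importFrom utils write.table read.delim
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

## clamp a numeric vector/matrix into the open unit interval
clip_unit <- function(x, eps) {
  x[x < eps] <- eps
  x[x > 1 - eps] <- 1 - eps
  x
}

assert_matrix_like <- function(x, what) {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x)))
    stop_invalid("%s must be a matrix with row and column names", what)
  invisible(x)
}

## group labels used throughout; "CD" is the union of the three CD phenotypes
GROUP_LEVELS <- c("NINF", "INF", "STEN", "nonCD")
CD_GROUPS <- c("NINF", "INF", "STEN")
MEDICATION_COLS <- c("azathioprine", "purinethol", "adalimumab", "infliximab")

validate_sheet <- function(sheet) {
  req <- c("sample_id", "assay", "group", "patient_id", "passage",
           "age", "sex")
  miss <- setdiff(req, names(sheet))
  if (length(miss))
    stop_invalid("sample sheet is missing column(s): %s",
                 paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop_invalid("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(sheet$group), GROUP_LEVELS)
  if (length(bad))
    stop_invalid("unknown group label(s): %s", paste(bad, collapse = ", "))
  if (any(!is.na(sheet$passage) & (sheet$passage < 1 | sheet$passage > 5)))
    stop_invalid("passage must lie in [1, 5]")
  invisible(sheet)
}

validate_manifest <- function(manifest) {
  req <- c("probe_id", "chrom", "pos", "snp_flag", "crossreactive_flag")
  miss <- setdiff(req, names(manifest))
  if (length(miss))
    stop_invalid("probe manifest is missing column(s): %s",
                 paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$probe_id))
    stop_invalid("duplicate probe_id in manifest")
  ## sorted by (chrom, pos), strictly increasing positions within chromosome
  ord <- order(manifest$chrom, manifest$pos)
  if (!identical(ord, seq_len(nrow(manifest))))
    stop_invalid("manifest must be sorted by (chrom, pos)")
  dup <- unlist(tapply(manifest$pos, manifest$chrom,
                       function(p) any(diff(p) <= 0)), use.names = FALSE)
  if (any(dup))
    stop_invalid("positions must be strictly increasing within a chromosome")
  invisible(manifest)
}

## membership of samples in an assay ("methylation" or "expression");
## assay == "both" belongs to either
samples_for_assay <- function(sheet, assay) {
  sheet$sample_id[sheet$assay %in% c(assay, "both")]
}

## resolve a contrast group label to the set of sample-sheet group labels:
## "CD" expands to the three CD phenotypes
expand_group <- function(label) {
  if (identical(label, "CD")) CD_GROUPS else label
}
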