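# Age and sex imputation from molecular data, for samples whose metadata
# are missing (e.g. an anonymized control).

#' Epigenetic-clock age transform
#'
#' The clock's linear predictor `s` lives on a transformed age scale that
#' is logarithmic below adulthood and linear above:
#' `s = log((age + 1) / (adult_age + 1))` for `age <= adult_age`, and
#' `s = (age - adult_age) / (adult_age + 1)` above. `clock_inverse_age()`
#' maps a predictor back to years: `(1 + adult_age) * exp(s) - 1` for
#' `s <= 0`, else `(1 + adult_age) * s + adult_age`. The two are exact
#' mutual inverses.
#'
#' @param age age in years.
#' @param adult_age the breakpoint of the piecewise transform (default
#'   20).
#' @return the transformed value (`clock_transform_age`) or age in years
#'   (`clock_inverse_age`).
#' @export
clock_transform_age <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname clock_transform_age
#' @param s clock linear predictor.
#' @export
clock_inverse_age <- function(s, adult_age = 20) {
  ifelse(s <= 0,
         (1 + adult_age) * exp(s) - 1,
         (1 + adult_age) * s + adult_age)
}

#' Predict age from methylation with a linear clock
#'
#' Computes the linear predictor `intercept + sum(w_i * Beta_i)` over the
#' clock's CpGs and back-transforms it to years with
#' [clock_inverse_age()]. Clock probes missing from the matrix are imputed
#' by the cohort mean Beta of the present clock probes; if fewer than
#' `min_present` of the clock probes are present the prediction aborts,
#' listing the missing ids.
#'
#' @param beta a Beta matrix (probes x samples).
#' @param clock a list with `intercept` (numeric), `coefficients` (named
#'   numeric vector, names = probe ids), and optionally `adult_age`
#'   (default 20).
#' @param min_present minimum fraction of clock probes that must be
#'   present (default 0.5).
#' @return a data.frame with `sample_id`, `age_estimate`; attribute
#'   `n_missing_probes`.
#' @export
predict_age <- function(beta, clock, min_present = 0.5) {
  if (length(clock$coefficients) < 1)
    stop_invalid("clock has no coefficients")
  probes <- names(clock$coefficients)
  present <- probes %in% rownames(beta)
  if (mean(present) < min_present)
    stop_invalid("only %d/%d clock probes present; missing: %s",
                 sum(present), length(probes),
                 paste(utils::head(probes[!present], 10), collapse = ", "))
  adult_age <- clock$adult_age %||% 20
  B <- matrix(NA_real_, length(probes), ncol(beta),
              dimnames = list(probes, colnames(beta)))
  B[probes[present], ] <- beta[probes[present], , drop = FALSE]
  ## impute absent clock probes at the cohort mean of the present ones
  if (any(!present))
    B[probes[!present], ] <- mean(beta[probes[present], , drop = FALSE])
  s <- clock$intercept + as.numeric(crossprod(B, clock$coefficients))
  out <- data.frame(sample_id = colnames(beta),
                    age_estimate = clock_inverse_age(s, adult_age),
                    stringsAsFactors = FALSE)
  attr(out, "n_missing_probes") <- sum(!present)
  out
}

#' Remove clock probes from a manifest
#'
#' Drops the clock's CpGs from the manifest so that age-related probes
#' cannot confound downstream differential analyses. Idempotent.
#'
#' @param manifest a probe manifest.
#' @param clock a clock model (see [predict_age()]).
#' @return the reduced manifest; attribute `n_removed`.
#' @export
exclude_clock_probes <- function(manifest, clock) {
  drop <- manifest$probe_id %in% names(clock$coefficients)
  out <- manifest[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Infer sex from chromosome-Y methylation signal
#'
#' A sample is called male when the fraction of chromosome-Y probes with
#' detected signal exceeds `threshold_fraction`. "Detected" is
#' operationalized as Beta inside the informative band
#' `[band[1], band[2]]` (females show background-level chrY values near
#' the extremes after normalization against a male reference).
#'
#' @param beta a Beta matrix.
#' @param manifest the probe manifest locating chrY probes.
#' @param threshold_fraction detection fraction above which a sample is
#'   called male (default 0.5).
#' @param band the informative Beta band counted as detected signal
#'   (default `c(0.2, 0.8)`).
#' @return a data.frame with `sample_id`, `sex` (`"M"`/`"F"`), and
#'   `margin` (detected fraction minus threshold).
#' @export
infer_sex_from_methylation <- function(beta, manifest,
                                       threshold_fraction = 0.5,
                                       band = c(0.2, 0.8)) {
  chry <- manifest$probe_id[manifest$chrom %in% c("chrY", "Y")]
  chry <- intersect(chry, rownames(beta))
  if (length(chry) == 0)
    stop_invalid("no chromosome-Y probes available")
  if (length(chry) < 5)
    warning("fewer than 5 chrY probes; sex call may be unstable",
            call. = FALSE)
  sub <- beta[chry, , drop = FALSE]
  frac <- colMeans(sub >= band[1] & sub <= band[2])
  data.frame(sample_id = colnames(beta),
             sex = ifelse(frac > threshold_fraction, "M", "F"),
             margin = frac - threshold_fraction,
             stringsAsFactors = FALSE)
}

#' Infer sex from chromosome-Y gene expression
#'
#' A sample is called male when at least `min_genes` chromosome-Y genes
#' exceed `cpm_cutoff` counts per million.
#'
#' @param counts a count matrix.
#' @param chrY_genes gene ids located on chromosome Y.
#' @param cpm_cutoff CPM detection cutoff (default 1).
#' @param min_genes minimum number of detected chrY genes for a male call
#'   (default 2).
#' @return a data.frame with `sample_id`, `sex`, and `n_detected`.
#' @export
infer_sex_from_expression <- function(counts, chrY_genes, cpm_cutoff = 1,
                                      min_genes = 2L) {
  present <- intersect(chrY_genes, rownames(counts))
  if (length(present) < min_genes)
    stop_invalid("fewer than %d chromosome-Y genes in the matrix",
                 min_genes)
  cpm <- compute_cpm(counts)[present, , drop = FALSE]
  n_det <- colSums(cpm > cpm_cutoff)
  data.frame(sample_id = colnames(counts),
             sex = ifelse(n_det >= min_genes, "M", "F"),
             n_detected = as.integer(n_det),
             stringsAsFactors = FALSE)
}
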