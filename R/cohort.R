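#' Build a cohort sample plan
#'
#' A cohort design is a data frame with one row per biological sample and
#' columns `group` (`NINF`, `INF`, `STEN`, `nonCD`), `patient_id`, and
#' `assay` (`methylation`, `expression`, or `both`). Called with no
#' arguments it returns the frozen default plan mirroring the study the
#' package emulates: 18 methylation samples from 10 patients (7 NINF / 4
#' patients, 2 INF / 2, 4 STEN / 3, 5 non-CD / 3) and 21 expression samples
#' from 14 patients (6 NINF / 6, 4 INF / 4, 5 STEN / 4, 6 non-CD / 4), with
#' 9 samples from 6 unique patients measured on both assays.
#'
#' When per-group sample counts are given instead, a simple plan is
#' constructed: `n_meth` and `n_expr` are the total samples per group in
#' each assay, `n_shared` of which are measured on both. Shared samples
#' can only come from groups with samples in both assays; an infeasible
#' `n_shared` is rejected. Every sample receives its own patient.
#'
#' @param n_meth named integer vector of total methylation sample counts
#'   per group (names among `NINF`, `INF`, `STEN`, `nonCD`).
#' @param n_expr named integer vector of total expression sample counts
#'   per group.
#' @param n_shared total number of samples measured on both assays.
#' @return a data.frame with columns `group`, `patient_id`, `assay`.
#' @examples
#' plan <- cohort_design()
#' table(plan$assay)
#' @export
cohort_design <- function(n_meth = NULL, n_expr = NULL, n_shared = 0L) {
  if (is.null(n_meth) && is.null(n_expr) && n_shared == 0L)
    return(default_cohort_plan())
  n_meth <- n_meth %||% integer(0)
  n_expr <- n_expr %||% integer(0)
  if (any(c(n_meth, n_expr) < 0) || n_shared < 0)
    stop_invalid("sample counts must be non-negative")
  groups <- union(names(n_meth), names(n_expr))
  get0n <- function(v, g) if (g %in% names(v)) v[[g]] else 0L
  cap <- vapply(groups, function(g)
    min(get0n(n_meth, g), get0n(n_expr, g)), numeric(1))
  if (n_shared > sum(cap))
    stop_invalid(paste("impossible sharing constraint: n_shared (%d)",
                       "exceeds the %d samples available in both assays"),
                 n_shared, sum(cap))
  ## allocate shared samples round-robin across feasible groups
  shared <- setNames(rep(0L, length(groups)), groups)
  left <- n_shared
  while (left > 0) {
    for (g in groups) {
      if (left > 0 && shared[[g]] < cap[[g]]) {
        shared[[g]] <- shared[[g]] + 1L
        left <- left - 1L
      }
    }
  }
  rows <- list()
  pid <- 0L
  npt <- function() {
    pid <<- pid + 1L
    sprintf("PT%02d", pid)
  }
  for (gi in groups) {
    for (k in seq_len(shared[[gi]])) rows[[length(rows) + 1L]] <-
        data.frame(group = gi, patient_id = npt(), assay = "both")
    for (k in seq_len(get0n(n_meth, gi) - shared[[gi]]))
      rows[[length(rows) + 1L]] <-
        data.frame(group = gi, patient_id = npt(), assay = "methylation")
    for (k in seq_len(get0n(n_expr, gi) - shared[[gi]]))
      rows[[length(rows) + 1L]] <-
        data.frame(group = gi, patient_id = npt(), assay = "expression")
  }
  plan <- do.call(rbind, rows)
  bad <- setdiff(unique(plan$group), GROUP_LEVELS)
  if (length(bad))
    stop_invalid("unknown group label(s): %s", paste(bad, collapse = ", "))
  plan
}

## The frozen default plan. Group-by-patient overlap is under-determined by
## the marginal counts; this is one consistent allocation (see the vignette).
default_cohort_plan <- function() {
  p <- function(group, patient, assay)
    data.frame(group = group, patient_id = patient, assay = assay)
  rbind(
    ## samples measured on both assays: 9 samples, 6 unique patients
    p("NINF",  "CD01", "both"), p("NINF",  "CD02", "both"),
    p("NINF",  "CD03", "both"), p("INF",   "CD04", "both"),
    p("STEN",  "CD01", "both"), p("STEN",  "CD02", "both"),
    p("STEN",  "CD05", "both"), p("nonCD", "NC01", "both"),
    p("nonCD", "NC01", "both"),
    ## methylation-only: 9 samples
    p("NINF",  "CD01", "methylation"), p("NINF",  "CD02", "methylation"),
    p("NINF",  "CD03", "methylation"), p("NINF",  "CD06", "methylation"),
    p("INF",   "CD07", "methylation"), p("STEN",  "CD05", "methylation"),
    p("nonCD", "NC02", "methylation"), p("nonCD", "NC02", "methylation"),
    p("nonCD", "NC03", "methylation"),
    ## expression-only: 12 samples
    p("NINF",  "CD08", "expression"), p("NINF",  "CD09", "expression"),
    p("NINF",  "CD10", "expression"), p("INF",   "CD08", "expression"),
    p("INF",   "CD11", "expression"), p("INF",   "CD12", "expression"),
    p("STEN",  "CD02", "expression"), p("STEN",  "CD10", "expression"),
    p("nonCD", "NC04", "expression"), p("nonCD", "NC04", "expression"),
    p("nonCD", "NC05", "expression"), p("nonCD", "NC06", "expression")
  )
}

#' Generate a synthetic sample sheet from a cohort plan
#'
#' Fills a cohort plan (see [cohort_design()]) with per-patient demographics
#' and per-sample culture metadata: age (drawn around the reported cohort
#' means, CD younger than non-CD), sex, smoking, medication flags
#' (azathioprine, purinethol, adalimumab, infliximab; non-CD patients are
#' unmedicated), and passage number in 1--5.
#'
#' @param design a cohort plan data.frame; defaults to [cohort_design()].
#' @param seed integer seed; the same seed reproduces the sheet exactly.
#' @return a sample sheet data.frame with columns `sample_id`, `assay`,
#'   `group`, `patient_id`, `passage`, `age`, `sex`, the four medication
#'   flags, and `smoker`.
#' @examples
#' sheet <- generate_cohort(seed = 1)
#' nrow(sheet)
#' @export
generate_cohort <- function(design = cohort_design(), seed = 1L) {
  if (!is.data.frame(design) ||
      !all(c("group", "patient_id", "assay") %in% names(design)))
    stop_invalid("design must have columns group, patient_id, assay")
  bad <- setdiff(unique(design$assay), c("methylation", "expression", "both"))
  if (length(bad))
    stop_invalid("unknown assay label(s): %s", paste(bad, collapse = ", "))
  set.seed(seed)
  n <- nrow(design)
  patients <- unique(design$patient_id)
  is_cd_patient <- vapply(patients, function(pt)
    any(design$group[design$patient_id == pt] %in% CD_GROUPS), logical(1))
  ## patient-level draws
  age <- ifelse(is_cd_patient,
                round(pmin(pmax(rnorm(length(patients), 33, 12), 18), 85)),
                round(pmin(pmax(rnorm(length(patients), 50, 20), 18), 85)))
  sex <- ifelse(rbinom(length(patients), 1, 0.7) == 1, "M", "F")
  smoker <- is_cd_patient & rbinom(length(patients), 1, 0.25) == 1
  ## biological agent in ~2/3 of CD patients; thiopurines independently
  biological <- is_cd_patient & rbinom(length(patients), 1, 0.65) == 1
  which_bio <- rbinom(length(patients), 1, 0.5) == 1
  adalimumab <- biological & which_bio
  infliximab <- biological & !which_bio
  azathioprine <- is_cd_patient & rbinom(length(patients), 1, 0.3) == 1
  purinethol <- is_cd_patient & rbinom(length(patients), 1, 0.15) == 1
  idx <- match(design$patient_id, patients)
  sheet <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    assay = design$assay,
    group = design$group,
    patient_id = design$patient_id,
    passage = sample(1:5, n, replace = TRUE),
    age = age[idx],
    sex = sex[idx],
    azathioprine = azathioprine[idx],
    purinethol = purinethol[idx],
    adalimumab = adalimumab[idx],
    infliximab = infliximab[idx],
    smoker = smoker[idx],
    stringsAsFactors = FALSE
  )
  validate_sheet(sheet)
}
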