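# Small fixture builders shared across test files. Everything is built in
# code; heavier shared objects are cached for the test session.

make_mutations <- function(...) {
  rows <- list(...)
  defaults <- tibble::tibble(
    patient_id = "P1", chrom = "1", pos = 500L, ref = "C", alt = "T",
    gene = "TP53", consequence = "missense", protein_change = NA_character_,
    vaf = NA_real_, in_known_db = NA
  )
  dplyr::bind_rows(lapply(rows, function(r) {
    d <- defaults
    for (nm in names(r)) d[[nm]] <- r[[nm]]
    d
  }))
}

make_clinical <- function(patient_id, group, seed = 42) {
  n <- length(patient_id)
  withr::with_seed(seed, tibble::tibble(
    patient_id = patient_id, group = group,
    age_at_diagnosis = round(stats::rnorm(n, 34, 4), 1),
    date_of_diagnosis = as.Date("2000-01-01") + sample.int(3650, n, replace = TRUE),
    pathological_stage = sample(1:3, n, replace = TRUE),
    subtype_ihc = sample(c("LumA", "LumB", "HER2", "TN"), n, replace = TRUE),
    er_status = sample(c("pos", "neg"), n, replace = TRUE),
    pr_status = sample(c("pos", "neg"), n, replace = TRUE),
    dfs_time = round(stats::runif(n, 0.5, 14), 3),
    dfs_event = sample(0:1, n, replace = TRUE),
    os_time = round(stats::runif(n, 0.5, 14), 3),
    os_event = sample(0:1, n, replace = TRUE)
  ))
}

# one medium cohort shared by the generator-recovery acceptance checks
.acc_env <- new.env()
acceptance_cohort <- function() {
  if (is.null(.acc_env$cohort)) {
    .acc_env$cohort <- simulate_cohort(
      cohort_params(n_bcp = 500L, n_control = 500L, seed = 20260920L),
      stages = c("clinical", "mutations", "spectra")
    )
  }
  .acc_env$cohort
}
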