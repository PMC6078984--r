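# Per-sample burden metrics, the co-mutation (gene frequency) table, the
# MATH heterogeneity score, and group burden comparisons.

NON_SILENT <- c("missense", "nonsense", "splice", "frameshift", "inframe_indel")

#' Classify consequences as non-silent
#'
#' Non-silent = protein-altering or splice-affecting: missense, nonsense,
#' splice, frameshift, inframe_indel. Synonymous and noncoding are silent.
#'
#' @param consequence Character vector of consequence values.
#' @return Logical vector.
#' @export
classify_non_silent <- function(consequence) {
  bad <- setdiff(unique(consequence), CONSEQUENCE_LEVELS)
  if (length(bad)) {
    stop("classify_non_silent: unknown consequence(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  consequence %in% NON_SILENT
}

#' MATH intra-tumor heterogeneity score
#'
#' MATH = MAD(VAFs) / median(VAFs), where MAD is the raw median absolute
#' deviation (no 1.4826 normal-consistency constant, no x100), computed over
#' all mutations with a VAF. `scaled = TRUE` switches to the originally
#' published scaling, 1.4826 x MAD / median x 100, for cross-tool
#' comparison.
#'
#' @param vafs Numeric vector of variant allele fractions; at least one
#'   value, positive median.
#' @param scaled Use the 1.4826 x 100 scaling instead of the raw ratio.
#' @return Non-negative scalar.
#' @examples
#' math_score(c(0.1, 0.2, 0.3, 0.4, 0.5)) # 1/3
#' @export
math_score <- function(vafs, scaled = FALSE) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) == 0L) stop("math_score: no VAFs supplied", call. = FALSE)
  med <- stats::median(vafs)
  if (med <= 0) stop("math_score: median VAF is zero; score undefined", call. = FALSE)
  mad_raw <- stats::median(abs(vafs - med))
  if (scaled) 1.4826 * mad_raw / med * 100 else mad_raw / med
}

#' Per-sample catalog metrics
#'
#' Derives burden metrics from a mutation record table: SNV count (single
#' base ref and alt), indel count, non-silent count, known-database count,
#' and the MATH score from the records' VAFs (records with missing VAF are
#' excluded from MATH; their number is reported).
#'
#' @param mutations Mutation tibble.
#' @param vafs Optional tibble (`patient_id`, `vaf`) holding a genome-wide
#'   VAF sample per patient; when supplied it replaces the record VAFs for
#'   MATH (as when the records cover only part of the genome).
#' @return Tibble with one row per patient: `patient_id`, `n_snv`,
#'   `n_indel`, `n_nonsilent`, `n_known_db`, `math_score`, `n_vaf_missing`.
#' @export
summarize_catalogs <- function(mutations, vafs = NULL) {
  base <- mutations |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_snv = sum(nchar(.data$ref) == 1L & nchar(.data$alt) == 1L),
      n_indel = sum(nchar(.data$ref) != 1L | nchar(.data$alt) != 1L),
      n_nonsilent = sum(classify_non_silent(.data$consequence)),
      n_known_db = sum(.data$in_known_db %in% TRUE),
      n_vaf_missing = sum(is.na(.data$vaf)),
      math_score = if (all(is.na(.data$vaf))) NA_real_ else
        math_score(.data$vaf),
      .groups = "drop"
    )
  if (!is.null(vafs)) {
    m <- vafs |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(math_score = math_score(.data$vaf), .groups = "drop")
    base <- base |>
      dplyr::select(-"math_score") |>
      dplyr::left_join(m, by = "patient_id")
  }
  base
}

#' Gene-level carrier frequency table
#'
#' For each gene, the number and fraction of patients carrying at least one
#' non-silent mutation in it, per group and overall; a patient counts once
#' per gene regardless of how many mutations they carry. Genes with overall
#' carrier frequency >= `min_freq` are retained (closed bound), sorted by
#' overall frequency then gene name.
#'
#' @param mutations Mutation tibble.
#' @param clinical Clinical tibble supplying the patient universe and group
#'   labels (patients without mutations count in denominators).
#' @param min_freq Retention threshold on the overall carrier fraction.
#' @return Tibble: `gene`, `n_total`, `freq_total`, and per-group `n_`/
#'   `freq_` columns.
#' @export
gene_frequency_table <- function(mutations, clinical, min_freq = 0.05) {
  stopifnot(nrow(clinical) >= 1L)
  groups <- clinical |> dplyr::select("patient_id", "group")
  carriers <- mutations |>
    dplyr::filter(classify_non_silent(.data$consequence), !is.na(.data$gene)) |>
    dplyr::distinct(.data$patient_id, .data$gene) |>
    dplyr::inner_join(groups, by = "patient_id")
  n_by_group <- table(groups$group)
  denom_total <- nrow(groups)
  out <- carriers |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_BCP = sum(.data$group == "BCP"),
      n_control = sum(.data$group == "control"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      freq_total = .data$n_total / denom_total,
      freq_BCP = .data$n_BCP / max(1L, n_by_group[["BCP"]]),
      freq_control = .data$n_control / max(1L, n_by_group[["control"]])
    ) |>
    dplyr::filter(.data$freq_total >= min_freq) |>
    dplyr::arrange(dplyr::desc(.data$freq_total), .data$gene) |>
    dplyr::select("gene", "n_total", "freq_total", "n_BCP", "freq_BCP",
                  "n_control", "freq_control")
  out
}

#' Group comparison of a burden metric
#'
#' Compares a per-sample metric between BCP and control: group medians, the
#' Mann-Whitney two-sided p-value, and the covariate-adjusted p-value from
#' the nested-model comparison (linear regression with and without the group
#' term).
#'
#' @param metrics Per-sample metric tibble (see [summarize_catalogs()]).
#' @param clinical Clinical tibble with `patient_id`, `group` and the
#'   adjustment covariates.
#' @param metric Metric column to compare.
#' @param covariates Adjustment covariates present in `clinical`; covariates
#'   absent from the table are dropped with a warning.
#' @return One-row tibble: metric, group medians, MW p, adjusted p, n per
#'   group.
#' @export
burden_comparison <- function(metrics, clinical,
                              metric = c("n_nonsilent", "n_snv", "n_indel",
                                         "n_known_db", "math_score"),
                              covariates = c("age_at_diagnosis",
                                             "date_of_diagnosis",
                                             "pathological_stage",
                                             "subtype_ihc")) {
  metric <- match.arg(metric)
  d <- dplyr::inner_join(metrics, clinical, by = "patient_id")
  n_g <- table(factor(d$group, levels = c("BCP", "control")))
  if (any(n_g == 0L)) stop("burden_comparison: a group has no members", call. = FALSE)
  x <- d[[metric]][d$group == "BCP"]
  y <- d[[metric]][d$group == "control"]
  mw <- mann_whitney(x[!is.na(x)], y[!is.na(y)])
  covariates <- intersect(covariates, names(d))
  d$date_num <- if ("date_of_diagnosis" %in% covariates) {
    as.numeric(d$date_of_diagnosis)
  } else NULL
  covs <- c(setdiff(covariates, "date_of_diagnosis"),
            if ("date_of_diagnosis" %in% covariates) "date_num")
  adj <- if (length(covs)) {
    adjusted_association(d, outcome = metric, group = "group",
                         covariates = covs)$adjusted_p
  } else NA_real_
  tibble::tibble(
    metric = metric,
    median_bcp = stats::median(x, na.rm = TRUE),
    median_control = stats::median(y, na.rm = TRUE),
    statistic = mw$statistic, p_value = mw$p_value, adjusted_p = adj,
    n_bcp = unname(n_g["BCP"]), n_control = unname(n_g["control"])
  )
}
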