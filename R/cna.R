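# Copy-number array QC (MAPD, median autocorrelation), the QC gate with the
# study thresholds, and genome-wide CNA summaries (FGA, arm-level frequency
# comparison, gene-level calls).

#' Median absolute pairwise deviation (MAPD)
#'
#' The median over adjacent-probe absolute log2-ratio differences, computed
#' within chromosomes (no cross-chromosome adjacency) and pooled. An array
#' noise metric: insensitive to true copy-number steps, which affect only a
#' few adjacent pairs.
#'
#' @param probes One sample's probe tibble (`chrom`, `pos`, `log2_ratio`),
#'   positions sorted or sortable; at least 2 probes on some chromosome.
#' @return Non-negative scalar.
#' @export
mapd <- function(probes) {
  d <- probes |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(diffs = abs(diff(.data$log2_ratio)))
  if (nrow(d) == 0L) stop("mapd: need at least 2 probes on a chromosome", call. = FALSE)
  stats::median(d$diffs)
}

#' Median lag-1 autocorrelation of probe log2 ratios
#'
#' Lag-1 Pearson autocorrelation per chromosome (at least 3 probes;
#' zero-variance chromosomes are excluded with a message), median across
#' chromosomes. Long-range copy-number structure drives this metric up,
#' i.i.d. probe noise leaves it near zero.
#'
#' @param probes One sample's probe tibble (`chrom`, `pos`, `log2_ratio`).
#' @return Scalar in [-1, 1].
#' @export
median_autocorrelation <- function(probes) {
  per_chrom <- probes |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      n = dplyr::n(),
      ac = if (dplyr::n() < 3L || stats::sd(.data$log2_ratio) == 0) NA_real_ else
        stats::cor(.data$log2_ratio[-dplyr::n()], .data$log2_ratio[-1]),
      .groups = "drop"
    )
  dropped <- sum(is.na(per_chrom$ac))
  if (dropped > 0L) {
    message("median_autocorrelation: ", dropped,
            " chromosome(s) excluded (too short or zero variance)")
  }
  vals <- per_chrom$ac[!is.na(per_chrom$ac)]
  if (length(vals) == 0L) {
    stop("median_autocorrelation: no chromosome with computable autocorrelation",
         call. = FALSE)
  }
  stats::median(vals)
}

#' Per-sample array QC metrics
#'
#' @param probes Probe tibble with `sample_id`.
#' @return Tibble `sample_id`, `mapd`, `median_autocorr`.
#' @export
array_qc <- function(probes) {
  probes |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ tibble::tibble(
      mapd = mapd(.x),
      median_autocorr = median_autocorrelation(.x)
    )) |>
    dplyr::ungroup()
}

#' QC gate on arrays and cancer cell fraction
#'
#' A sample passes when MAPD <= `mapd_threshold`, median autocorrelation <=
#' `autocorr_threshold`, and CCF >= `min_ccf` (samples with CCF below 30%
#' are excluded in the study design). Failure reasons are enumerated.
#'
#' @param qc Tibble from [array_qc()].
#' @param ccf Tibble (`sample_id`, `ccf`).
#' @param mapd_threshold,autocorr_threshold,min_ccf Gate thresholds
#'   (defaults 0.30, 0.5, 0.30).
#' @return Tibble `sample_id`, `mapd`, `median_autocorr`, `ccf`, `pass`,
#'   `reasons` (comma-joined, empty when passing).
#' @export
qc_gate <- function(qc, ccf, mapd_threshold = 0.30, autocorr_threshold = 0.5,
                    min_ccf = 0.30) {
  d <- dplyr::inner_join(qc, ccf, by = "sample_id")
  d |>
    dplyr::mutate(
      fail_mapd = .data$mapd > mapd_threshold,
      fail_ac = .data$median_autocorr > autocorr_threshold,
      fail_ccf = .data$ccf < min_ccf,
      pass = !(.data$fail_mapd | .data$fail_ac | .data$fail_ccf),
      reasons = purrr::pmap_chr(
        list(.data$fail_mapd, .data$fail_ac, .data$fail_ccf),
        function(m, a, c) {
          paste(c(if (m) "MAPD", if (a) "autocorrelation", if (c) "CCF"),
                collapse = ",")
        })
    ) |>
    dplyr::select("sample_id", "mapd", "median_autocorr", "ccf", "pass",
                  "reasons")
}

#' Fraction of genome altered (FGA)
#'
#' Fraction of the segmented genome (autosomes only) whose segments have
#' |log2 ratio| above the neutral band.
#'
#' @param segments Segment tibble for one or more samples.
#' @param neutral_band Neutral |log2| band half-width (default 0.2).
#' @return Tibble `sample_id`, `fga`.
#' @export
fraction_genome_altered <- function(segments, neutral_band = 0.2) {
  segs <- dplyr::filter(segments, !(.data$chrom %in% c("X", "Y")))
  if (nrow(segs) == 0L) stop("fraction_genome_altered: no autosomal segments", call. = FALSE)
  segs |>
    dplyr::mutate(len = .data$end - .data$start + 1) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      fga = sum(.data$len[abs(.data$log2_ratio) > neutral_band]) / sum(.data$len),
      .groups = "drop"
    )
}

# per-sample, per-arm altered-length bookkeeping
arm_overlap <- function(segments, arms, neutral_band) {
  dplyr::inner_join(segments, arms, by = "chrom", suffix = c("", "_arm"),
                    relationship = "many-to-many") |>
    dplyr::mutate(
      ov = pmax(0, pmin(.data$end, .data$end_arm) -
                  pmax(.data$start, .data$start_arm) + 1)
    ) |>
    dplyr::filter(.data$ov > 0) |>
    dplyr::group_by(.data$sample_id, .data$chrom, .data$arm) |>
    dplyr::summarise(
      arm_len = .data$end_arm[1] - .data$start_arm[1] + 1,
      gain_len = sum(.data$ov[.data$log2_ratio > neutral_band]),
      loss_len = sum(.data$ov[.data$log2_ratio < -neutral_band]),
      .groups = "drop"
    )
}

#' Arm-level CNA frequency comparison between groups
#'
#' An arm is called gained (lost) in a sample when more than 50% of its
#' length is covered by segments above (below) the neutral band — a
#' consistent-sign majority rule. Per arm and direction, carrier frequencies
#' in BCP and control are compared by Fisher's exact test with a BH-FDR
#' column. Arms with no segment coverage in any sample are excluded with a
#' message.
#'
#' @param segments Segment tibble.
#' @param arms Arm definition tibble (`chrom`, `arm`, `start`, `end`);
#'   defaults to the synthetic genome's arms.
#' @param clinical Clinical tibble (`patient_id`, `group`); sample ids must
#'   match patient ids.
#' @param neutral_band Neutral |log2| band half-width.
#' @return Tibble: `chrom`, `arm`, `direction`, per-group counts and
#'   frequencies, `p_value`, `fdr`.
#' @export
arm_frequency_comparison <- function(segments, arms = genome_arms(), clinical,
                                     neutral_band = 0.2) {
  ov <- arm_overlap(segments, arms, neutral_band)
  uncovered <- dplyr::anti_join(arms, ov, by = c("chrom", "arm"))
  if (nrow(uncovered)) {
    message("arm_frequency_comparison: ", nrow(uncovered),
            " arm(s) without coverage excluded")
  }
  calls <- ov |>
    dplyr::mutate(
      gain = .data$gain_len > 0.5 * .data$arm_len,
      loss = .data$loss_len > 0.5 * .data$arm_len
    ) |>
    dplyr::inner_join(dplyr::select(clinical, "patient_id", "group"),
                      by = c(sample_id = "patient_id"))
  n_g <- calls |> dplyr::distinct(.data$sample_id, .data$group) |>
    dplyr::count(.data$group)
  n_bcp <- sum(n_g$n[n_g$group == "BCP"])
  n_ctl <- sum(n_g$n[n_g$group == "control"])
  long <- calls |>
    tidyr::pivot_longer(c("gain", "loss"), names_to = "direction",
                        values_to = "called")
  out <- long |>
    dplyr::group_by(.data$chrom, .data$arm, .data$direction) |>
    dplyr::summarise(
      n_BCP = sum(.data$called & .data$group == "BCP"),
      n_control = sum(.data$called & .data$group == "control"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      freq_BCP = .data$n_BCP / n_bcp,
      freq_control = .data$n_control / n_ctl,
      p_value = purrr::map2_dbl(.data$n_BCP, .data$n_control, function(a, b) {
        tab <- matrix(c(a, n_bcp - a, b, n_ctl - b), 2, byrow = TRUE)
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
        fisher_exact(tab)$p_value
      }),
      fdr = bh_fdr(.data$p_value)
    )
  out
}

#' Gene-level copy-number call
#'
#' The call derives from the length-weighted mean log2 ratio of the
#' segments overlapping the gene span: `deleted` at or below
#' `del_threshold`, `gained` at or above `gain_threshold`, otherwise
#' `neutral`; `NA` when the gene is uncovered.
#'
#' @param segments Segment tibble.
#' @param gene_region One-row tibble/list with `chrom`, `start`, `end`.
#' @param del_threshold,gain_threshold Call thresholds on the weighted mean
#'   log2 (defaults -0.3 / +0.3).
#' @return Tibble `sample_id`, `mean_log2`, `call`.
#' @export
gene_level_call <- function(segments, gene_region, del_threshold = -0.3,
                            gain_threshold = 0.3) {
  ov <- segments |>
    dplyr::filter(.data$chrom == gene_region$chrom) |>
    dplyr::mutate(
      ov = pmax(0, pmin(.data$end, gene_region$end) -
                  pmax(.data$start, gene_region$start) + 1)
    ) |>
    dplyr::filter(.data$ov > 0)
  all_samples <- unique(segments$sample_id)
  means <- ov |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(mean_log2 = sum(.data$log2_ratio * .data$ov) / sum(.data$ov),
                     .groups = "drop")
  tibble::tibble(sample_id = all_samples) |>
    dplyr::left_join(means, by = "sample_id") |>
    dplyr::mutate(call = dplyr::case_when(
      is.na(.data$mean_log2) ~ NA_character_,
      .data$mean_log2 <= del_threshold ~ "deleted",
      .data$mean_log2 >= gain_threshold ~ "gained",
      TRUE ~ "neutral"
    ))
}
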