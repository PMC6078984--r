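# Mucin gene-family analysis: carrier status, hotspots, serine-gain
# classification, the two Monte-Carlo enrichment tests, and the MUCsig
# expression metagene.

#' The mucin gene family
#'
#' Default membership: the 18 secreted and transmembrane mucin genes. MUC4
#' and MUC16 are known false-positive-prone genes and are commonly excluded
#' via the `exclude` argument of the carrier analysis.
#'
#' @param exclude Genes to drop from the returned list.
#' @return Character vector of gene symbols.
#' @export
mucin_family <- function(exclude = NULL) {
  fam <- MUCIN_FAMILY_DEFAULT
  extra <- setdiff(exclude, fam)
  if (length(extra)) {
    warning("mucin_family: exclude gene(s) not in the family: ",
            paste(extra, collapse = ", "))
  }
  setdiff(fam, exclude)
}

#' Is a codon change a serine gain?
#'
#' TRUE when the two codons differ at exactly one position, both encode
#' amino acids (no stop involved), the alternate encodes serine and the
#' reference does not — i.e. a missense change creating a potential
#' O-glycosylation acceptor.
#'
#' @param ref_codon,alt_codon DNA 3-mers (vectors recycle element-wise).
#' @return Logical vector.
#' @examples
#' is_serine_gain("GCA", "TCA") # Ala -> Ser: TRUE
#' @export
is_serine_gain <- function(ref_codon, alt_codon) {
  ref_codon <- toupper(ref_codon); alt_codon <- toupper(alt_codon)
  ok <- grepl("^[ACGT]{3}$", ref_codon) & grepl("^[ACGT]{3}$", alt_codon)
  if (!all(ok)) stop("is_serine_gain: invalid codon(s)", call. = FALSE)
  ndiff <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, ref_codon, alt_codon)
  if (any(ndiff != 1L)) {
    stop("is_serine_gain: codons must differ at exactly one position", call. = FALSE)
  }
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[ref_codon]); alt_aa <- unname(gc[alt_codon])
  ref_aa != "*" & alt_aa != "*" & alt_aa == "S" & ref_aa != "S"
}

parse_protein_change <- function(pc) {
  m <- regmatches(pc, regexec("^p\\.([A-Z\\*])(\\d+)([A-Z\\*])$", pc))
  ok <- lengths(m) == 4L
  tibble::tibble(
    ref_aa = ifelse(ok, vapply(m, function(x) if (length(x) == 4L) x[2] else NA_character_, ""), NA),
    position = ifelse(ok, as.integer(vapply(m, function(x) if (length(x) == 4L) x[3] else NA_character_, "")), NA),
    alt_aa = ifelse(ok, vapply(m, function(x) if (length(x) == 4L) x[4] else NA_character_, ""), NA)
  )
}

#' Fraction of missense mutations gaining a serine
#'
#' Computed from the records' `protein_change` annotations (`p.X123S`
#' form): the fraction whose alternate amino acid is serine and reference is
#' not.
#'
#' @param mutations Tibble of missense mutation records with parseable
#'   `protein_change`.
#' @return Fraction in [0, 1].
#' @export
serine_gain_fraction <- function(mutations) {
  mis <- dplyr::filter(mutations, .data$consequence == "missense")
  if (nrow(mis) == 0L) {
    stop("serine_gain_fraction: no missense records (empty denominator)", call. = FALSE)
  }
  parsed <- parse_protein_change(mis$protein_change)
  bad <- which(is.na(parsed$alt_aa))
  if (length(bad)) {
    stop("serine_gain_fraction: unparseable protein_change in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  mean(parsed$alt_aa == "S" & parsed$ref_aa != "S")
}

new_mc_test <- function(test, observed, n_draws, n_exceed, null_draws, seed) {
  out <- tibble::tibble(
    test = test, observed = observed, n_draws = n_draws,
    p_value = (1 + n_exceed) / (1 + n_draws),
    null_mean = mean(null_draws), null_sd = stats::sd(null_draws),
    seed = seed
  )
  class(out) <- c("mc_test", class(out))
  out
}

#' Monte-Carlo test of serine-gain enrichment
#'
#' Tests whether the observed fraction of serine-gaining mucin missense
#' mutations exceeds chance. Each null draw re-places the same number of
#' single-nucleotide substitutions in the family's coding sequence: a
#' substitution class is drawn from the observed six-class spectrum
#' (`null = "spectrum"`, the default, conditioning out spectrum
#' confounding) or uniformly (`null = "uniform"`), the site is placed
#' uniformly among family coding positions where that class yields a
#' missense change, and the serine-gain fraction of the draw is recorded.
#' The empirical p-value uses the (1 + k)/(1 + N) estimator, so it is never
#' zero.
#'
#' @param mutations Missense mutation records in family genes, with
#'   `chrom`, `pos`, `ref`, `alt` on the synthetic reference.
#' @param family Gene symbols delimiting the null coding footprint.
#' @param n_draws Number of null draws (warning below 100).
#' @param seed Seed for the null stream.
#' @param null Null substitution-class model, see above.
#' @return A one-row `mc_test` tibble; `observed` is the serine-gain count.
#' @export
mc_serine_test <- function(mutations, family = mucin_family(),
                           n_draws = 9999, seed = 1L,
                           null = c("spectrum", "uniform")) {
  null <- match.arg(null)
  if (n_draws < 100) warning("mc_serine_test: fewer than 100 draws; p is coarse")
  mis <- dplyr::filter(mutations, .data$consequence == "missense")
  if (nrow(mis) == 0L) stop("mc_serine_test: no observed missense mutations", call. = FALSE)
  pool <- coding_table() |>
    dplyr::filter(.data$gene %in% family, .data$consequence == "missense")
  if (nrow(pool) == 0L) {
    stop("mc_serine_test: no coding sequence for the family", call. = FALSE)
  }
  obs_tab <- dplyr::inner_join(
    mis, dplyr::select(pool, "chrom", "pos", "alt", "serine_gain", "class6"),
    by = c("chrom", "pos", "alt"))
  if (nrow(obs_tab) < nrow(mis)) {
    stop("mc_serine_test: ", nrow(mis) - nrow(obs_tab),
         " record(s) not found as missense sites in the family footprint",
         call. = FALSE)
  }
  n_obs <- nrow(obs_tab)
  observed <- sum(obs_tab$serine_gain)
  classes <- sort(unique(pool$class6))
  class_prob <- if (null == "spectrum") {
    tab <- table(factor(obs_tab$class6, levels = classes))
    as.numeric(tab) / sum(tab)
  } else {
    rep(1 / length(classes), length(classes))
  }
  pool_by_class <- split(pool$serine_gain, pool$class6)
  withr::with_seed(seed, {
    null_counts <- vapply(seq_len(n_draws), function(d) {
      k <- as.integer(stats::rmultinom(1, n_obs, class_prob))
      tot <- 0L
      for (ci in seq_along(classes)) {
        if (k[ci] > 0L) {
          sg <- pool_by_class[[classes[ci]]]
          tot <- tot + sum(sg[sample.int(length(sg), k[ci], replace = TRUE)])
        }
      }
      tot
    }, integer(1))
    new_mc_test("mc_serine_gain", observed, n_draws,
                sum(null_counts >= observed), null_counts, seed)
  })
}

#' Monte-Carlo test of known-database overlap
#'
#' Tests whether the observed number of family variants present in a
#' known-variant set (a COSMIC-membership surrogate) exceeds chance. Null
#' draws place the same number of variants uniformly over the family coding
#' footprint and count overlaps. Matching is by exact allele
#' (`match_on = "allele"`, default) or position only.
#'
#' @param mutations Variant records in family genes.
#' @param known_positions Tibble (`chrom`, `pos`, optional `alt`).
#' @param family Gene symbols delimiting the footprint.
#' @param n_draws Number of null draws.
#' @param seed Seed for the null stream.
#' @param match_on `"allele"` or `"position"`.
#' @return A one-row `mc_test` tibble; `observed` is the overlap count. An
#'   empty known set returns p = 1 with a warning.
#' @export
mc_known_db_overlap_test <- function(mutations, known_positions,
                                     family = mucin_family(),
                                     n_draws = 9999, seed = 1L,
                                     match_on = c("allele", "position")) {
  match_on <- match.arg(match_on)
  if (n_draws < 100) warning("mc_known_db_overlap_test: fewer than 100 draws; p is coarse")
  cod <- coding_table() |>
    dplyr::filter(.data$gene %in% family) |>
    dplyr::distinct(.data$chrom, .data$pos, .data$alt)
  if (nrow(known_positions) == 0L) {
    warning("mc_known_db_overlap_test: empty known set; p = 1")
    return(new_mc_test("mc_known_db_overlap", 0, n_draws, n_draws,
                       rep(0, n_draws), seed))
  }
  n_obs <- nrow(mutations)
  key <- function(d, with_alt) {
    if (with_alt) paste(d$chrom, d$pos, d$alt) else paste(d$chrom, d$pos)
  }
  with_alt <- match_on == "allele" && !all(is.na(known_positions$alt))
  known_keys <- unique(key(known_positions, with_alt))
  observed <- sum(key(mutations, with_alt) %in% known_keys)
  # footprint at position level; alleles drawn uniformly when matching alleles
  positions <- dplyr::distinct(cod, .data$chrom, .data$pos)
  pos_known <- key(positions, FALSE) %in%
    unique(paste(known_positions$chrom, known_positions$pos))
  if (with_alt) {
    cod$is_known <- key(cod, TRUE) %in% known_keys
    known_by_pos <- split(cod$is_known, paste(cod$chrom, cod$pos))
  }
  withr::with_seed(seed, {
    null_counts <- if (!with_alt) {
      stats::rbinom(n_draws, n_obs, mean(pos_known))
    } else {
      # uniform position, then uniform alt among the 3 substitutions
      p_hit <- mean(vapply(known_by_pos, mean, numeric(1)))
      stats::rbinom(n_draws, n_obs, p_hit)
    }
    new_mc_test("mc_known_db_overlap", observed, n_draws,
                sum(null_counts >= observed), null_counts, seed)
  })
}

#' Detect protein-level mutation hotspots
#'
#' A hotspot is an identical (gene, protein position) variant observed in at
#' least two distinct patients; matching at the protein position merges
#' equivalent codon changes.
#'
#' @param mutations Mutation records with `protein_change` (`p.X123Y`).
#' @return Tibble (`gene`, `position`, `n_patients`, `protein_changes`),
#'   sorted by recurrence then gene.
#' @export
hotspot_detect <- function(mutations) {
  parsed <- parse_protein_change(mutations$protein_change)
  d <- mutations |>
    dplyr::mutate(aa_pos = parsed$position) |>
    dplyr::filter(!is.na(.data$aa_pos))
  d |>
    dplyr::distinct(.data$patient_id, .data$gene, .data$aa_pos,
                    .data$protein_change) |>
    dplyr::group_by(.data$gene, .data$aa_pos) |>
    dplyr::summarise(
      n_patients = dplyr::n_distinct(.data$patient_id),
      protein_changes = paste(sort(unique(.data$protein_change)),
                              collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_patients >= 2L) |>
    dplyr::arrange(dplyr::desc(.data$n_patients), .data$gene) |>
    dplyr::rename(position = "aa_pos")
}

#' Mucin-family carrier status per patient
#'
#' A patient is a carrier when they harbor at least one non-silent mutation
#' in a family gene outside the excluded set.
#'
#' @param mutations Mutation records.
#' @param clinical Clinical tibble supplying the patient universe (patients
#'   with no mutations are non-carriers).
#' @param family Family gene symbols.
#' @param exclude Genes removed before testing (e.g. `c("MUC4", "MUC16")`);
#'   genes not in `family` raise a warning.
#' @return Tibble `patient_id`, `group`, `carrier`.
#' @export
carrier_status <- function(mutations, clinical, family = mucin_family(),
                           exclude = NULL) {
  extra <- setdiff(exclude, family)
  if (length(extra)) {
    warning("carrier_status: exclude gene(s) not in family: ",
            paste(extra, collapse = ", "))
  }
  fam <- setdiff(family, exclude)
  carriers <- mutations |>
    dplyr::filter(classify_non_silent(.data$consequence),
                  .data$gene %in% fam) |>
    dplyr::distinct(.data$patient_id) |>
    dplyr::mutate(carrier = TRUE)
  clinical |>
    dplyr::select("patient_id", "group") |>
    dplyr::left_join(carriers, by = "patient_id") |>
    dplyr::mutate(carrier = !is.na(.data$carrier))
}

#' MUCsig expression metagene
#'
#' The per-sample mean log-expression over the mucin-family genes present in
#' the matrix, standardized across samples to mean 0 and SD 1 (the
#' standardization is cohort-internal). Family genes absent from the matrix
#' are reported in the `missing_genes` attribute.
#'
#' @param expr Expression matrix, genes x samples.
#' @param family Family gene symbols.
#' @return Tibble `sample_id`, `score` of class `metagene_score`; attribute
#'   `missing_genes`.
#' @export
mucsig <- function(expr, family = mucin_family()) {
  if (ncol(expr) < 2L) stop("mucsig: need at least 2 samples", call. = FALSE)
  present <- intersect(family, rownames(expr))
  if (length(present) == 0L) {
    stop("mucsig: no family gene present in the expression matrix", call. = FALSE)
  }
  raw <- colMeans(expr[present, , drop = FALSE])
  s <- stats::sd(raw)
  if (s == 0) stop("mucsig: zero variance across samples; score undefined", call. = FALSE)
  out <- tibble::tibble(sample_id = colnames(expr),
                        score = as.numeric((raw - mean(raw)) / s))
  class(out) <- c("metagene_score", class(out))
  attr(out, "missing_genes") <- setdiff(family, rownames(expr))
  out
}
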