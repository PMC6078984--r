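# 96-channel trinucleotide spectra and mutational-signature refitting.

#' Canonical 96 substitution context labels
#'
#' The standard pyrimidine-convention channels, ordered by substitution class
#' (C>A, C>G, C>T, T>A, T>C, T>G) then alphabetically by flanking bases:
#' `A[C>A]A`, `A[C>A]C`, ..., `T[T>G]T`.
#'
#' @return Character vector of length 96.
#' @export
sbs_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(classes, function(cl) {
    ref <- substr(cl, 1, 1)
    as.vector(t(outer(bases, bases, function(l, r) paste0(l, "[", cl, "]", r))))
  }))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chars <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    paste(rev(unname(COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

# Collapse a (ref, alt, 5'-base, 3'-base) quadruple to its pyrimidine-strand
# channel label. ref/alt/up/down are single-character vectors.
pyrimidine_channel <- function(ref, alt, up, down) {
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, COMPLEMENT[ref], ref)
  a <- ifelse(pur, COMPLEMENT[alt], alt)
  u <- ifelse(pur, COMPLEMENT[down], up)
  d <- ifelse(pur, COMPLEMENT[up], down)
  paste0(u, "[", r, ">", a, "]", d)
}

#' Build 96-channel mutational spectra from SNV records
#'
#' Maps every single-nucleotide variant to its trinucleotide context on the
#' supplied reference, reverse-complementing purine-reference sites to the
#' pyrimidine convention. Indels (multi-base ref or alt) are excluded. The
#' reference base at each position must match the record's `ref` allele.
#'
#' @param mutations Mutation tibble (see [read_mutation_table()]).
#' @param genome A named `Biostrings::DNAStringSet` (names = chromosome
#'   labels) or path to a FASTA file.
#' @return A tibble with `sample_id`, `total_snv`, and one count column per
#'   canonical context; counts sum to the number of SNVs per sample.
#' @export
build_spectrum <- function(mutations, genome) {
  genome <- as_genome(genome)
  contexts <- sbs_contexts()
  snv <- dplyr::filter(mutations, nchar(.data$ref) == 1L, nchar(.data$alt) == 1L,
                       .data$ref %in% names(COMPLEMENT),
                       .data$alt %in% names(COMPLEMENT))
  samples <- unique(mutations$patient_id)
  if (nrow(snv) == 0L) {
    counts <- matrix(0L, nrow = length(samples), ncol = 96,
                     dimnames = list(NULL, contexts))
    return(dplyr::bind_cols(
      tibble::tibble(sample_id = samples, total_snv = 0L),
      tibble::as_tibble(counts)
    ))
  }
  bad_chrom <- !(snv$chrom %in% names(genome))
  if (any(bad_chrom)) {
    stop("build_spectrum: chromosome(s) absent from reference: ",
         paste(unique(snv$chrom[bad_chrom]), collapse = ", "), call. = FALSE)
  }
  lens <- Biostrings::width(genome)[match(snv$chrom, names(genome))]
  outside <- snv$pos < 2L | snv$pos > lens - 1L
  if (any(outside)) {
    stop(sprintf("build_spectrum: %d record(s) outside the reference (flank required)",
                 sum(outside)), call. = FALSE)
  }
  tri <- character(nrow(snv))
  for (chr in unique(snv$chrom)) {
    i <- which(snv$chrom == chr)
    v <- Biostrings::Views(genome[[chr]], start = snv$pos[i] - 1L,
                           end = snv$pos[i] + 1L)
    tri[i] <- as.character(v)
  }
  ref_obs <- substr(tri, 2, 2)
  mismatch <- ref_obs != snv$ref
  if (any(mismatch)) {
    bad <- snv[mismatch, , drop = FALSE]
    stop(sprintf(
      "build_spectrum: ref allele mismatch with FASTA for %d record(s) (e.g. %s:%d %s, FASTA has %s)",
      sum(mismatch), bad$chrom[1], bad$pos[1], bad$ref[1],
      ref_obs[mismatch][1]), call. = FALSE)
  }
  chan <- pyrimidine_channel(snv$ref, snv$alt, substr(tri, 1, 1), substr(tri, 3, 3))
  tab <- table(factor(snv$patient_id, levels = samples),
               factor(chan, levels = contexts))
  counts <- matrix(as.integer(tab), nrow = length(samples),
                   dimnames = list(NULL, contexts))
  dplyr::bind_cols(
    tibble::tibble(sample_id = samples, total_snv = as.integer(rowSums(counts))),
    tibble::as_tibble(counts)
  )
}

# accept a DNAStringSet or a FASTA path
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  stop("expected a DNAStringSet or FASTA path", call. = FALSE)
}

spectrum_matrix <- function(spectra) {
  m <- as.matrix(spectra[, sbs_contexts(), drop = FALSE])
  rownames(m) <- spectra$sample_id
  m
}

#' Refit per-sample signature exposures against a reference
#'
#' Each sample's normalized 96-channel spectrum is decomposed as a
#' non-negative mixture of the reference signatures by non-negative least
#' squares; weights below `cutoff` are discarded and the survivors
#' renormalized to sum to 1. Samples below `min_snv` mutations are still fit
#' but flagged low-confidence.
#'
#' @param spectra Spectrum tibble from [build_spectrum()], or a matrix of
#'   counts (samples x 96, context colnames).
#' @param reference 96 x S reference matrix (see
#'   [read_signature_reference()]).
#' @param cutoff Minimum retained exposure proportion (default 0.06, the
#'   refitting tool default in common use).
#' @param min_snv Low-confidence flag threshold on total SNV count.
#' @return A tibble of class `signature_exposures`: `sample_id`, one
#'   proportion column per signature, `residual` (L2 norm of the fit residual
#'   before thresholding), `total_snv`, `low_confidence`.
#' @export
refit_exposures <- function(spectra, reference, cutoff = 0.06, min_snv = 50) {
  if (is.matrix(spectra)) {
    spectra <- dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(spectra),
                     total_snv = as.integer(rowSums(spectra))),
      tibble::as_tibble(spectra)
    )
  }
  m <- spectrum_matrix(spectra)
  reference <- reference[sbs_contexts(), , drop = FALSE]
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("refit_exposures: all-zero spectrum for sample(s): ",
         paste(spectra$sample_id[totals == 0], collapse = ", "), call. = FALSE)
  }
  fits <- lapply(seq_len(nrow(m)), function(i) {
    p <- m[i, ] / totals[i]
    sol <- pracma::lsqnonneg(reference, p)
    w <- sol$x
    resid <- sqrt(sum((p - reference %*% w)^2))
    w <- w / sum(w)
    w[w < cutoff] <- 0
    if (sum(w) == 0) {
      # degenerate: keep the single largest pre-cutoff weight
      w <- sol$x / sum(sol$x)
      keep <- which.max(w)
      w[-keep] <- 0
    }
    w <- w / sum(w)
    list(w = w, resid = resid)
  })
  w_mat <- do.call(rbind, lapply(fits, `[[`, "w"))
  colnames(w_mat) <- colnames(reference)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = spectra$sample_id),
    tibble::as_tibble(w_mat),
    tibble::tibble(
      residual = vapply(fits, `[[`, numeric(1), "resid"),
      total_snv = as.integer(totals),
      low_confidence = totals < min_snv
    )
  )
  class(out) <- c("signature_exposures", class(out))
  attr(out, "signatures") <- colnames(reference)
  attr(out, "cutoff") <- cutoff
  out
}

#' Call presence of a signature
#'
#' A signature is called present in a sample when its post-cutoff exposure
#' proportion is greater than zero.
#'
#' @param exposures A `signature_exposures` tibble from [refit_exposures()].
#' @param signature Signature column name.
#' @return Logical vector, one element per sample, named by sample id.
#' @export
call_presence <- function(exposures, signature) {
  sigs <- attr(exposures, "signatures")
  if (is.null(sigs)) sigs <- setdiff(names(exposures),
                                     c("sample_id", "residual", "total_snv",
                                       "low_confidence"))
  if (!signature %in% sigs) {
    stop("call_presence: unknown signature label '", signature, "'", call. = FALSE)
  }
  stats::setNames(exposures[[signature]] > 0, exposures$sample_id)
}

#' @export
tidy.signature_exposures <- function(x, ...) {
  sigs <- attr(x, "signatures")
  tidyr::pivot_longer(tibble::as_tibble(x)[, c("sample_id", sigs)],
                      cols = dplyr::all_of(sigs),
                      names_to = "signature", values_to = "proportion") |>
    dplyr::mutate(present = .data$proportion > 0)
}

#' @export
glance.signature_exposures <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x),
                 n_signatures = length(attr(x, "signatures")),
                 mean_residual = mean(x$residual),
                 cutoff = attr(x, "cutoff"))
}

#' Stacked exposure bar plot
#'
#' @param object A `signature_exposures` tibble.
#' @param ... Unused.
#' @return A ggplot object, one stacked bar of signature proportions per
#'   sample.
#' @export
autoplot.signature_exposures <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample_id, y = .data$proportion,
                               fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Exposure proportion", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Association analyses for a signature's presence and exposure
#'
#' Runs the mismatch-repair deficiency (signature 20) association suite: the
#' Spearman correlation between the signature's exposure proportion and total
#' SNV load, a Mann-Whitney comparison of a target gene's expression by
#' presence, and a Fisher exact test of gene-level deletion calls by
#' presence. Tests whose groups have fewer than 3 samples are skipped with a
#' notice; p-values get a BH-FDR column.
#'
#' @param exposures A `signature_exposures` tibble.
#' @param signature Signature column to analyze (default `"Signature.20"`).
#' @param expr Optional expression matrix (genes x samples).
#' @param segments Optional segment tibble for deletion calling.
#' @param gene Gene symbol used for the expression and deletion tests
#'   (default `"MSH2"`).
#' @param gene_region Optional one-row tibble (`chrom`, `start`, `end`)
#'   locating `gene`; required for the deletion test.
#' @param del_threshold Deletion threshold on length-weighted mean log2
#'   ratio, passed to [gene_level_call()].
#' @return A tibble with one row per executed or skipped test: `test`,
#'   `statistic`, `p_value`, `fdr`, `note`.
#' @export
sig20_association_suite <- function(exposures, signature = "Signature.20",
                                    expr = NULL, segments = NULL,
                                    gene = "MSH2", gene_region = NULL,
                                    del_threshold = -0.3) {
  present <- call_presence(exposures, signature)
  rows <- list()
  # exposure proportion vs SNV load
  rows$load <- tryCatch({
    ct <- spearman_cor(exposures[[signature]], exposures$total_snv)
    tibble::tibble(test = "spearman_exposure_vs_snv_load",
                   statistic = ct$statistic, p_value = ct$p_value,
                   note = NA_character_)
  }, error = function(e) tibble::tibble(
    test = "spearman_exposure_vs_snv_load", statistic = NA_real_,
    p_value = NA_real_, note = conditionMessage(e)))
  skip_row <- function(test, why) {
    tibble::tibble(test = test, statistic = NA_real_, p_value = NA_real_,
                   note = why)
  }
  two_groups_ok <- length(unique(present)) == 2L && min(table(present)) >= 3L
  if (!is.null(expr)) {
    test_name <- paste0("mann_whitney_", gene, "_expression_by_presence")
    rows$expr <- if (!gene %in% rownames(expr)) {
      skip_row(test_name, paste0(gene, " absent from expression matrix"))
    } else if (!two_groups_ok) {
      skip_row(test_name, "presence groups too small or constant; test skipped")
    } else {
      e <- expr[gene, names(present)]
      mw <- mann_whitney(e[present], e[!present])
      tibble::tibble(test = test_name, statistic = mw$statistic,
                     p_value = mw$p_value, note = NA_character_)
    }
  }
  if (!is.null(segments) && !is.null(gene_region)) {
    test_name <- paste0("fisher_", gene, "_deletion_by_presence")
    rows$del <- if (!two_groups_ok) {
      skip_row(test_name, "presence groups too small or constant; test skipped")
    } else {
      calls <- gene_level_call(segments, gene_region, del_threshold = del_threshold)
      deleted <- stats::setNames(calls$call == "deleted", calls$sample_id)
      common <- intersect(names(present), names(deleted))
      tab <- table(present = present[common], deleted = deleted[common])
      if (any(dim(tab) < 2L)) {
        skip_row(test_name, "deletion calls constant; test skipped")
      } else {
        tab <- tab[c("TRUE", "FALSE"), c("TRUE", "FALSE")]
        fe <- fisher_exact(tab)
        tibble::tibble(test = test_name, statistic = fe$statistic,
                       p_value = fe$p_value, note = NA_character_)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$fdr <- NA_real_
  run <- !is.na(out$p_value)
  if (any(run)) out$fdr[run] <- bh_fdr(out$p_value[run])
  out
}
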