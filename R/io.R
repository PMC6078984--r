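# Readers and writers for every external table the pipeline touches.
# Coordinates are 1-based inclusive throughout (MAF/SEG convention); TSVs are
# tab-separated UTF-8 with "." or empty meaning missing.

CONSEQUENCE_LEVELS <- c("missense", "nonsense", "splice", "frameshift",
                        "inframe_indel", "synonymous", "noncoding")

#' Consequence dialect map
#'
#' Translation from foreign consequence vocabularies (MAF-style
#' `Variant_Classification` values and Sequence Ontology terms) to the fixed
#' internal enum. Extend or override entries to support another caller.
#'
#' @return Named character vector: foreign term -> internal consequence.
#' @export
consequence_dialect <- function() {
  c(
    Missense_Mutation = "missense", missense_variant = "missense",
    Nonsense_Mutation = "nonsense", stop_gained = "nonsense",
    Splice_Site = "splice", splice_acceptor_variant = "splice",
    splice_donor_variant = "splice",
    Frame_Shift_Del = "frameshift", Frame_Shift_Ins = "frameshift",
    frameshift_variant = "frameshift",
    In_Frame_Del = "inframe_indel", In_Frame_Ins = "inframe_indel",
    inframe_deletion = "inframe_indel", inframe_insertion = "inframe_indel",
    Silent = "synonymous", synonymous_variant = "synonymous",
    IGR = "noncoding", Intron = "noncoding", RNA = "noncoding",
    intergenic_variant = "noncoding", intron_variant = "noncoding",
    stats::setNames(CONSEQUENCE_LEVELS, CONSEQUENCE_LEVELS)
  )
}

#' Normalize chromosome labels
#'
#' Strips any `chr` prefix and maps `"23"` to `"X"`, `"24"` to `"Y"`.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Normalized character labels.
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, na = c("", ".", "NA"), show_col_types = FALSE,
                  progress = FALSE, ...)
}

require_columns <- function(d, required, what) {
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(d)
}

# report row-level failures with 1-based data line numbers (header = line 1)
row_errors <- function(bad_rows, messages, what) {
  if (!length(bad_rows)) return(invisible(NULL))
  detail <- paste(sprintf("line %d: %s", bad_rows + 1L, messages), collapse = "; ")
  stop(sprintf("%s: %d invalid row(s) [%s]", what, length(bad_rows), detail),
       call. = FALSE)
}

#' Read a somatic mutation table (MAF-like TSV)
#'
#' Required columns: `patient_id`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `consequence`. Optional: `protein_change`, `vaf`, `in_known_db`. Unknown
#' consequence strings (after dialect translation) and malformed coordinates
#' are rejected with the offending line numbers; no row is silently dropped.
#'
#' @param path Path to a tab-separated file.
#' @param dialect Named map translating foreign consequence vocabularies;
#'   see [consequence_dialect()].
#' @return A validated tibble of mutation records, one row per variant.
#' @export
read_mutation_table <- function(path, dialect = consequence_dialect()) {
  d <- read_tsv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  require_columns(d, c("patient_id", "chrom", "pos", "ref", "alt", "gene",
                       "consequence"), "read_mutation_table")
  pos_num <- suppressWarnings(as.numeric(d$pos))
  bad_pos <- which(is.na(pos_num) | pos_num < 1 | pos_num != round(pos_num))
  row_errors(bad_pos, sprintf("malformed position '%s'", d$pos[bad_pos]),
             "read_mutation_table")
  cons <- unname(dialect[d$consequence])
  bad_cons <- which(is.na(cons))
  row_errors(bad_cons, sprintf("unknown consequence '%s'", d$consequence[bad_cons]),
             "read_mutation_table")
  bad_allele <- which(toupper(d$ref) == toupper(d$alt))
  row_errors(bad_allele, rep("ref equals alt", length(bad_allele)),
             "read_mutation_table")
  out <- tibble::tibble(
    patient_id = d$patient_id,
    chrom = normalize_chrom(d$chrom),
    pos = as.integer(pos_num),
    ref = toupper(d$ref),
    alt = toupper(d$alt),
    gene = d$gene,
    consequence = cons,
    protein_change = if ("protein_change" %in% names(d)) d$protein_change else NA_character_,
    vaf = if ("vaf" %in% names(d)) suppressWarnings(as.numeric(d$vaf)) else NA_real_,
    in_known_db = if ("in_known_db" %in% names(d)) {
      tolower(d$in_known_db) %in% c("true", "t", "1", "yes")
    } else NA
  )
  if ("in_known_db" %in% names(d)) out$in_known_db[is.na(d$in_known_db)] <- NA
  bad_vaf <- which(!is.na(out$vaf) & (out$vaf < 0 | out$vaf > 1))
  row_errors(bad_vaf, sprintf("vaf %s outside [0,1]", out$vaf[bad_vaf]),
             "read_mutation_table")
  out
}

#' Write a mutation table
#' @param mutations Tibble as returned by [read_mutation_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(mutations, path) {
  readr::write_tsv(mutations, path, na = ".")
  invisible(path)
}

#' Read a copy-number segment table (SEG)
#'
#' Accepts both the internal header (`sample_id`, `chrom`, `start`, `end`,
#' `n_probes`, `log2_ratio`) and the classic SEG header (`ID`, `chrom`,
#' `loc.start`, `loc.end`, `num.mark`, `seg.mean`). Segments must satisfy
#' `start <= end`, have at least one probe, and be non-overlapping within a
#' sample and chromosome.
#'
#' @param path Path to the tab-separated segment file.
#' @return Validated tibble of segments, sorted by sample, chromosome, start.
#' @export
read_segment_table <- function(path) {
  d <- read_tsv_quiet(path)
  seg_alias <- c(ID = "sample_id", loc.start = "start", loc.end = "end",
                 num.mark = "n_probes", seg.mean = "log2_ratio",
                 copy_number = "copy_number")
  for (nm in names(seg_alias)) {
    if (nm %in% names(d) && !(seg_alias[[nm]] %in% names(d))) {
      names(d)[names(d) == nm] <- seg_alias[[nm]]
    }
  }
  require_columns(d, c("sample_id", "chrom", "start", "end", "n_probes",
                       "log2_ratio"), "read_segment_table")
  bad <- which(d$start > d$end)
  row_errors(bad, rep("start > end", length(bad)), "read_segment_table")
  bad <- which(d$n_probes < 1)
  row_errors(bad, rep("n_probes < 1", length(bad)), "read_segment_table")
  out <- tibble::tibble(
    sample_id = as.character(d$sample_id),
    chrom = normalize_chrom(d$chrom),
    start = as.integer(d$start), end = as.integer(d$end),
    n_probes = as.integer(d$n_probes),
    log2_ratio = as.numeric(d$log2_ratio),
    copy_number = if ("copy_number" %in% names(d)) as.integer(d$copy_number) else NA_integer_
  ) |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start)
  overlap <- out |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$start <= dplyr::lag(.data$end)) |>
    dplyr::ungroup()
  if (nrow(overlap)) {
    stop(sprintf(
      "read_segment_table: overlapping segments within sample/chromosome (e.g. %s chr%s at %d)",
      overlap$sample_id[1], overlap$chrom[1], overlap$start[1]), call. = FALSE)
  }
  out
}

#' Write a segment table
#' @param segments Tibble as returned by [read_segment_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(segments, path) {
  readr::write_tsv(segments, path, na = ".")
  invisible(path)
}

#' Read a probe-level log2-ratio table
#'
#' Columns: `sample_id`, `chrom`, `pos`, `log2_ratio`, optional `baf`.
#' Probe positions must be strictly increasing within each sample and
#' chromosome after sorting (duplicates are an error).
#'
#' @param path Path to the tab-separated probe file.
#' @return Validated tibble sorted by sample, chromosome, position.
#' @export
read_probe_table <- function(path) {
  d <- read_tsv_quiet(path)
  require_columns(d, c("sample_id", "chrom", "pos", "log2_ratio"),
                  "read_probe_table")
  out <- tibble::tibble(
    sample_id = as.character(d$sample_id),
    chrom = normalize_chrom(d$chrom),
    pos = as.integer(d$pos),
    log2_ratio = as.numeric(d$log2_ratio),
    baf = if ("baf" %in% names(d)) as.numeric(d$baf) else NA_real_
  ) |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$pos)
  dup <- out |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::filter(duplicated(.data$pos)) |>
    dplyr::ungroup()
  if (nrow(dup)) {
    stop("read_probe_table: duplicate probe positions within sample/chromosome",
         call. = FALSE)
  }
  out
}

#' Write a probe table
#' @param probes Tibble as returned by [read_probe_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  readr::write_tsv(probes, path, na = ".")
  invisible(path)
}

#' Read a 96-context reference signature matrix (CSV)
#'
#' The first column must hold the 96 trinucleotide context labels in
#' pyrimidine convention (e.g. `A[C>T]G`); remaining columns are signatures.
#' Rows are canonicalized to the standard context order; each signature
#' column must sum to 1 within 1e-3 and is renormalized to sum exactly 1.
#'
#' @param path Path to the CSV file.
#' @return A 96 x S numeric matrix with context rownames and signature
#'   colnames, each column summing to 1.
#' @export
read_signature_reference <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  labels <- as.character(d[[1]])
  mat <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (nrow(mat) != 96L) {
    stop(sprintf("read_signature_reference: expected 96 context rows, got %d",
                 nrow(mat)), call. = FALSE)
  }
  canon <- sbs_contexts()
  if (!setequal(labels, canon)) {
    stop("read_signature_reference: context labels do not match the 96 canonical contexts",
         call. = FALSE)
  }
  if (any(mat < 0)) stop("read_signature_reference: negative entries", call. = FALSE)
  rownames(mat) <- labels
  mat <- mat[canon, , drop = FALSE]
  sums <- colSums(mat)
  off <- which(abs(sums - 1) > 1e-3)
  if (length(off)) {
    stop(sprintf("read_signature_reference: column(s) not summing to 1: %s",
                 paste(colnames(mat)[off], collapse = ", ")), call. = FALSE)
  }
  sweep(mat, 2, sums, "/")
}

#' Write a reference signature matrix to CSV
#' @param reference 96 x S matrix with context rownames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signature_reference <- function(reference, path) {
  d <- tibble::as_tibble(reference)
  d <- dplyr::bind_cols(tibble::tibble(context = rownames(reference)), d)
  readr::write_csv(d, path)
  invisible(path)
}

#' Read a clinical/survival table
#'
#' Required: `patient_id`, `group` (`BCP`/`control`), `dfs_time`, `os_time`,
#' `dfs_event`, `os_event`. Covariates (`age_at_diagnosis`,
#' `date_of_diagnosis` ISO-8601, `pathological_stage`, `subtype_ihc`,
#' `er_status`, `pr_status`) are carried through when present. Duplicate
#' patient ids, negative times and non-binary events are errors.
#'
#' @param path Path to the tab-separated clinical file.
#' @return Validated tibble, one row per patient.
#' @export
read_clinical_table <- function(path) {
  d <- read_tsv_quiet(path)
  require_columns(d, c("patient_id", "group", "dfs_time", "os_time",
                       "dfs_event", "os_event"), "read_clinical_table")
  d$patient_id <- as.character(d$patient_id)
  if (anyDuplicated(d$patient_id)) {
    stop("read_clinical_table: duplicate patient_id: ",
         paste(unique(d$patient_id[duplicated(d$patient_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(d$group %in% c("BCP", "control"))) {
    stop("read_clinical_table: group must be 'BCP' or 'control'", call. = FALSE)
  }
  for (tc in c("dfs_time", "os_time")) {
    if (any(d[[tc]] < 0, na.rm = TRUE)) {
      stop("read_clinical_table: negative survival time in ", tc, call. = FALSE)
    }
  }
  for (ec in c("dfs_event", "os_event")) {
    if (!all(d[[ec]] %in% c(0, 1))) {
      stop("read_clinical_table: ", ec, " must be 0/1", call. = FALSE)
    }
  }
  if ("date_of_diagnosis" %in% names(d)) {
    d$date_of_diagnosis <- as.Date(d$date_of_diagnosis)
  }
  tibble::as_tibble(d)
}

#' Write a clinical table
#' @param clinical Tibble as returned by [read_clinical_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  readr::write_tsv(clinical, path, na = ".")
  invisible(path)
}

#' Read a gene-expression matrix (TSV, genes x samples)
#'
#' First column = gene identifiers, remaining columns = samples; log-scale
#' values. Duplicate gene or sample identifiers and non-finite values are
#' errors.
#'
#' @param path Path to the tab-separated expression file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path) {
  d <- read_tsv_quiet(path)
  genes <- as.character(d[[1]])
  mat <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyDuplicated(genes)) {
    stop("read_expression_matrix: duplicate gene identifiers", call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("read_expression_matrix: duplicate sample identifiers", call. = FALSE)
  }
  if (any(!is.finite(mat))) {
    stop("read_expression_matrix: non-finite values", call. = FALSE)
  }
  rownames(mat) <- genes
  mat
}

#' Write an expression matrix
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  d <- dplyr::bind_cols(tibble::tibble(gene = rownames(expr)),
                        tibble::as_tibble(expr))
  readr::write_tsv(d, path)
  invisible(path)
}

#' Read a known-variant position table (COSMIC-membership surrogate)
#'
#' Columns: `chrom`, `pos`, optional `alt` (needed for allele-level matching).
#'
#' @param path Path to the tab-separated file.
#' @return Tibble of known positions.
#' @export
read_known_positions <- function(path) {
  d <- read_tsv_quiet(path)
  require_columns(d, c("chrom", "pos"), "read_known_positions")
  tibble::tibble(
    chrom = normalize_chrom(d$chrom),
    pos = as.integer(d$pos),
    alt = if ("alt" %in% names(d)) toupper(d$alt) else NA_character_
  )
}
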