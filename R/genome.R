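# Synthetic reference resources: a small genome with annotated coding genes
# (enough for trinucleotide-context extraction and codon-level consequence
# lookup), a synthetic 96 x 12 breast signature matrix, and a synthetic
# known-variant position set standing in for a COSMIC extract. All are built
# deterministically from fixed internal seeds, independent of user seeds:
# they play the role of a fixed reference build.

GENOME_SEED <- 20180806L

MUCIN_FAMILY_DEFAULT <- c("MUC1", "MUC2", "MUC3A", "MUC3B", "MUC4", "MUC5AC",
                          "MUC5B", "MUC6", "MUC7", "MUC12", "MUC13", "MUC15",
                          "MUC16", "MUC17", "MUC19", "MUC20", "MUC21", "MUC22")

# genes carried on the synthetic genome (10 mucins + 10 drivers/background)
GENOME_GENES <- list(
  "1" = c("MUC1", "GATA3", "AKT1", "PTEN", "CDH1", "MAP3K1", "KMT2C"),
  "2" = c("MSH2", "MSH6", "TP53", "PIK3CA", "MUC4", "MUC16"),
  "3" = c("MUC2", "MUC5B", "MUC6", "MUC12", "MUC17", "MUC19", "MUC20")
)

#' The synthetic reference genome
#'
#' A three-chromosome synthetic genome carrying 20 contiguous coding genes
#' (10 mucin family members including MUC4 and MUC16, plus TP53, PIK3CA,
#' MSH2, MSH6 and six further breast cancer genes). Coding sequences are
#' random non-stop codons; intergenic sequence is random. The genome is
#' deterministic (fixed internal seed) and cached for the session.
#'
#' @return A list with `genome` (named `DNAStringSet`), `genes` (tibble:
#'   `gene`, `chrom`, `start`, `end`, 1-based inclusive CDS span) and
#'   `mucins` (character vector of mucin genes present).
#' @export
synthetic_genome <- function() {
  if (!is.null(.bcp_cache$genome)) return(.bcp_cache$genome)
  withr::with_seed(GENOME_SEED, {
    bases <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    stops <- c("TAA", "TAG", "TGA")
    sense <- setdiff(codons, stops)
    gene_len <- function(g) if (grepl("^MUC", g)) 1800L else 1200L
    seqs <- list(); gene_rows <- list()
    for (chr in names(GENOME_GENES)) {
      genes <- GENOME_GENES[[chr]]
      parts <- character(0)
      pos <- 1L
      intergenic <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
      spacer <- 400L
      parts <- c(parts, intergenic(spacer)); pos <- pos + spacer
      for (g in genes) {
        L <- gene_len(g)
        cds <- paste(sample(sense, L / 3L, replace = TRUE), collapse = "")
        gene_rows[[g]] <- tibble::tibble(gene = g, chrom = chr,
                                         start = pos, end = pos + L - 1L)
        parts <- c(parts, cds); pos <- pos + L
        parts <- c(parts, intergenic(spacer)); pos <- pos + spacer
      }
      seqs[[chr]] <- paste(parts, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(seqs)
    out <- list(genome = genome,
                genes = dplyr::bind_rows(gene_rows),
                mucins = intersect(MUCIN_FAMILY_DEFAULT, names(gene_rows)))
    .bcp_cache$genome <- out
    out
  })
}

#' Write the synthetic genome to FASTA
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(path) {
  Biostrings::writeXStringSet(synthetic_genome()$genome, path)
  invisible(path)
}

# Codon-level lookup of every possible single-nucleotide substitution in
# every coding gene: one row per (position, alt). Cached.
coding_table <- function() {
  if (!is.null(.bcp_cache$coding)) return(.bcp_cache$coding)
  ref <- synthetic_genome()
  gc <- Biostrings::GENETIC_CODE
  rows <- lapply(seq_len(nrow(ref$genes)), function(i) {
    g <- ref$genes[i, ]
    cds <- as.character(Biostrings::subseq(ref$genome[[g$chrom]], g$start, g$end))
    ch <- strsplit(cds, "")[[1]]
    L <- length(ch)
    codon_idx <- (seq_len(L) - 1L) %/% 3L + 1L
    pos_in_codon <- (seq_len(L) - 1L) %% 3L + 1L
    codons <- substring(cds, 3L * (seq_len(L %/% 3L)) - 2L, 3L * seq_len(L %/% 3L))
    ref_codon <- codons[codon_idx]
    tibble::tibble(
      gene = g$gene, chrom = g$chrom,
      pos = g$start + seq_len(L) - 1L,
      ref = ch, codon_index = codon_idx, pos_in_codon = pos_in_codon,
      ref_codon = ref_codon
    )
  })
  tab <- dplyr::bind_rows(rows)
  bases <- c("A", "C", "G", "T")
  expanded <- dplyr::bind_rows(lapply(1:3, function(k) {
    d <- tab
    d$alt <- bases[(match(d$ref, bases) - 1L + k) %% 4L + 1L]
    d
  }))
  alt_codon <- paste0(
    substr(expanded$ref_codon, 1, expanded$pos_in_codon - 1L),
    expanded$alt,
    substr(expanded$ref_codon, expanded$pos_in_codon + 1L, 3L)
  )
  ref_aa <- unname(gc[expanded$ref_codon])
  alt_aa <- unname(gc[alt_codon])
  consequence <- dplyr::case_when(
    ref_aa == "*" ~ NA_character_,
    alt_aa == "*" ~ "nonsense",
    alt_aa == ref_aa ~ "synonymous",
    TRUE ~ "missense"
  )
  pyr <- expanded$ref %in% c("C", "T")
  class6 <- ifelse(pyr,
                   paste0(expanded$ref, ">", expanded$alt),
                   paste0(COMPLEMENT[expanded$ref], ">", COMPLEMENT[expanded$alt]))
  out <- expanded |>
    dplyr::mutate(
      alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
      consequence = consequence, class6 = class6,
      serine_gain = !is.na(consequence) & consequence == "missense" &
        alt_aa == "S" & ref_aa != "S",
      protein_change = dplyr::if_else(
        is.na(consequence) | !(consequence %in% c("missense", "nonsense")),
        NA_character_,
        paste0("p.", ref_aa, codon_index, ifelse(alt_aa == "*", "X", alt_aa)))
    ) |>
    dplyr::select(-"ref_codon", -"alt_codon")
  .bcp_cache$coding <- out
  out
}

# Genome-wide trinucleotide index: for each interior position its
# pyrimidine-collapsed triplet and strand orientation. Cached; used to place
# simulated SNVs at positions whose context matches a drawn channel.
context_index <- function() {
  if (!is.null(.bcp_cache$ctx)) return(.bcp_cache$ctx)
  ref <- synthetic_genome()$genome
  per_chr <- lapply(names(ref), function(chr) {
    ch <- strsplit(as.character(ref[[chr]]), "")[[1]]
    n <- length(ch)
    i <- 2:(n - 1L)
    up <- ch[i - 1L]; base <- ch[i]; down <- ch[i + 1L]
    pyr <- base %in% c("C", "T")
    trip <- ifelse(pyr, paste0(up, base, down),
                   paste0(COMPLEMENT[down], COMPLEMENT[base], COMPLEMENT[up]))
    tibble::tibble(chrom = chr, pos = i, ref = base, pyr = pyr, trip = trip)
  })
  all <- dplyr::bind_rows(per_chr)
  .bcp_cache$ctx <- split(all, all$trip)
  .bcp_cache$ctx
}

# Sample n genomic positions realizing a given 96-channel label; returns a
# tibble with chrom, pos, ref, alt (actual strand alleles).
sample_channel_positions <- function(channel, n) {
  u <- substr(channel, 1, 1); r <- substr(channel, 3, 3)
  a <- substr(channel, 5, 5); d <- substr(channel, 7, 7)
  trip <- paste0(u, r, d)
  cand <- context_index()[[trip]]
  if (is.null(cand) || nrow(cand) == 0L) {
    stop("no genomic position with context ", trip, call. = FALSE)
  }
  idx <- sample.int(nrow(cand), n, replace = TRUE)
  hit <- cand[idx, ]
  tibble::tibble(
    chrom = hit$chrom, pos = hit$pos, ref = hit$ref,
    alt = ifelse(hit$pyr, a, unname(COMPLEMENT[a]))
  )
}

#' Synthetic breast cancer reference signature matrix
#'
#' A 96 x 12 matrix of substitution signature profiles labelled after the
#' twelve signatures operating in breast cancer (1, 2, 3, 5, 6, 8, 13, 17,
#' 18, 20, 26, 30). The profiles are synthetic: each signature concentrates
#' 60% of its mass on a disjoint block of eight channels plus a 40% random
#' background, which makes the set well conditioned for refitting. They do
#' not reproduce the empirical COSMIC profiles.
#'
#' @return 96 x 12 matrix, context rownames, columns summing to 1.
#' @export
synthetic_signature_reference <- function() {
  if (!is.null(.bcp_cache$sigref)) return(.bcp_cache$sigref)
  withr::with_seed(GENOME_SEED + 1L, {
    contexts <- sbs_contexts()
    labels <- paste0("Signature.", c(1, 2, 3, 5, 6, 8, 13, 17, 18, 20, 26, 30))
    perm <- sample(96L)
    mat <- sapply(seq_along(labels), function(s) {
      w <- 0.4 * {
        b <- stats::rexp(96); b / sum(b)
      }
      peaks <- perm[((s - 1L) * 8L + 1L):(s * 8L)]
      pk <- stats::rexp(8L)
      w[peaks] <- w[peaks] + 0.6 * pk / sum(pk)
      w / sum(w)
    })
    dimnames(mat) <- list(contexts, labels)
    .bcp_cache$sigref <- mat
    mat
  })
}

#' Load the bundled synthetic signature reference
#'
#' Reads the packaged CSV copy of [synthetic_signature_reference()] through
#' the validating reader, or a user-supplied CSV.
#'
#' @param path CSV path; defaults to the bundled synthetic matrix.
#' @return 96 x S signature matrix.
#' @export
load_signature_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "breast_signatures_synthetic.csv",
                        package = "bcpgenomics")
    if (!nzchar(path)) return(synthetic_signature_reference())
  }
  read_signature_reference(path)
}

#' Synthetic known-variant position set
#'
#' A deterministic sample of coding positions (8% of the coding footprint,
#' one alternate allele each) standing in for a COSMIC breast cancer
#' extract. Synthetic: membership carries no biological meaning.
#'
#' @return Tibble with `chrom`, `pos`, `alt`, `gene`.
#' @export
synthetic_known_positions <- function() {
  if (!is.null(.bcp_cache$known)) return(.bcp_cache$known)
  withr::with_seed(GENOME_SEED + 2L, {
    cod <- coding_table()
    bases <- c("A", "C", "G", "T")
    picked <- cod |>
      dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$gene) |>
      dplyr::slice_sample(prop = 0.08) |>
      dplyr::mutate(alt = bases[(match(.data$ref, bases) - 1L +
                                   sample(3L, dplyr::n(), replace = TRUE)) %% 4L + 1L]) |>
      dplyr::select("chrom", "pos", "alt", "gene") |>
      dplyr::arrange(.data$chrom, .data$pos)
    .bcp_cache$known <- picked
    picked
  })
}
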