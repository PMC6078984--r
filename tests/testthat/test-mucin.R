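test_that("serine-gain codon classification follows the genetic code", {
  expect_true(is_serine_gain("GCA", "TCA"))    # Ala -> Ser
  expect_false(is_serine_gain("AGT", "AGA"))   # Ser -> Arg: loss, not gain
  expect_false(is_serine_gain("TCA", "TCG"))   # Ser -> Ser: synonymous
  expect_false(is_serine_gain("TCA", "TGA"))   # stop involved
  expect_error(is_serine_gain("GCA", "TGA1"), "invalid codon")
  expect_error(is_serine_gain("GCA", "TCG"), "exactly one position")
})

test_that("serine-gain fraction parses protein changes", {
  m <- make_mutations(
    list(protein_change = "p.A5S"), list(protein_change = "p.T9S"),
    list(protein_change = "p.G12D"), list(protein_change = "p.S3T"),
    list(protein_change = "p.P7L", patient_id = "P2")
  )
  expect_equal(serine_gain_fraction(m), 2 / 5)
  all_ser <- make_mutations(list(protein_change = "p.A5S"),
                            list(protein_change = "p.A9S"))
  expect_equal(serine_gain_fraction(all_ser), 1)
  expect_error(serine_gain_fraction(make_mutations(
    list(consequence = "synonymous"))), "no missense")
  expect_error(serine_gain_fraction(make_mutations(
    list(protein_change = "banana"))), "unparseable")
})

test_that("hotspot detection uses the distinct-patient rule", {
  two <- make_mutations(
    list(patient_id = "P1", gene = "MUC17", protein_change = "p.T100S"),
    list(patient_id = "P2", gene = "MUC17", protein_change = "p.T100S")
  )
  hot <- hotspot_detect(two)
  expect_equal(nrow(hot), 1L)
  expect_equal(hot$n_patients, 2L)
  # same variant twice in one patient is not a hotspot
  one <- make_mutations(
    list(patient_id = "P1", gene = "MUC17", protein_change = "p.T100S"),
    list(patient_id = "P1", gene = "MUC17", protein_change = "p.T100S",
         pos = 900L)
  )
  expect_equal(nrow(hotspot_detect(one)), 0L)
  # different codon changes at the same protein position merge
  merged <- make_mutations(
    list(patient_id = "P1", gene = "MUC2", protein_change = "p.A50S"),
    list(patient_id = "P2", gene = "MUC2", protein_change = "p.A50T")
  )
  expect_equal(hotspot_detect(merged)$n_patients, 2L)
})

test_that("carrier status honors exclusions and silent mutations", {
  cl <- make_clinical(c("P1", "P2", "P3"), c("BCP", "BCP", "control"))
  m <- make_mutations(
    list(patient_id = "P1", gene = "MUC4"),
    list(patient_id = "P2", gene = "MUC2", consequence = "synonymous")
  )
  cs <- carrier_status(m, cl)
  expect_equal(cs$carrier, c(TRUE, FALSE, FALSE))
  # MUC4-only carrier becomes a non-carrier after the MUC4/MUC16 exclusion
  cs2 <- carrier_status(m, cl, exclude = c("MUC4", "MUC16"))
  expect_equal(cs2$carrier, c(FALSE, FALSE, FALSE))
  expect_warning(carrier_status(m, cl, exclude = "BRCA1"), "not in family")
  # larger exclusion sets can only shrink the carrier set
  withr::with_seed(7, {
    co <- simulate_cohort(cohort_params(n_bcp = 60, n_control = 30, seed = 5),
                          stages = "mutations")
    cl2 <- tibble::tibble(patient_id = co$truth$patient_id,
                          group = co$truth$group)
    c1 <- carrier_status(co$mutations, cl2, exclude = "MUC4")
    c12 <- carrier_status(co$mutations, cl2, exclude = c("MUC4", "MUC16"))
    expect_true(all(c1$carrier[c12$carrier]))
  })
})

test_that("MUCsig standardizes family-mean expression across samples", {
  expr <- rbind(
    MUC1 = c(0, 1, 2), MUC2 = c(2, 3, 4),
    TP53 = c(9, 9, 9)
  )
  colnames(expr) <- c("S1", "S2", "S3")
  sc <- mucsig(expr)
  # family-gene means (1, 2, 3) -> standardized (-1, 0, 1)
  expect_equal(sc$score, c(-1, 0, 1))
  expect_equal(mean(sc$score), 0, tolerance = 1e-9)
  expect_equal(sd(sc$score), 1, tolerance = 1e-9)
  expect_equal(attr(sc, "missing_genes"),
               setdiff(mucin_family(), c("MUC1", "MUC2")))
  same <- expr; same[1:2, ] <- 5
  expect_error(mucsig(same), "zero variance")
  expect_error(mucsig(rbind(TP53 = c(1, 2))), "no family gene")
})

test_that("Monte-Carlo serine test handles extreme observed statistics", {
  cod <- bcpgenomics:::coding_table()
  pool <- dplyr::filter(cod, gene %in% mucin_family(),
                        consequence == "missense")
  no_gain <- dplyr::slice_head(dplyr::filter(pool, !serine_gain), n = 15)
  obs0 <- tibble::tibble(chrom = no_gain$chrom, pos = no_gain$pos,
                         ref = no_gain$ref, alt = no_gain$alt,
                         consequence = "missense")
  res0 <- mc_serine_test(obs0, n_draws = 499, seed = 1)
  expect_equal(res0$p_value, 1)            # nothing exceeds an observed zero
  all_gain <- dplyr::slice_head(dplyr::filter(pool, serine_gain), n = 25)
  obs1 <- tibble::tibble(chrom = all_gain$chrom, pos = all_gain$pos,
                         ref = all_gain$ref, alt = all_gain$alt,
                         consequence = "missense")
  res1 <- mc_serine_test(obs1, n_draws = 999, seed = 1)
  expect_lt(res1$p_value, 0.01)            # maximal statistic, tiny p
  expect_gte(res1$p_value, 1 / 1000)       # +1 correction floor
  expect_warning(mc_serine_test(obs1, n_draws = 50, seed = 1), "100 draws")
  # reproducible given seed
  expect_equal(mc_serine_test(obs1, n_draws = 299, seed = 8),
               mc_serine_test(obs1, n_draws = 299, seed = 8))
})

test_that("Monte-Carlo tests are calibrated under their own nulls", {
  # draw observed sets from the null model itself; p must be ~ uniform
  cod <- bcpgenomics:::coding_table()
  pool <- dplyr::filter(cod, gene %in% mucin_family(),
                        consequence == "missense")
  by_class <- split(pool, pool$class6)
  classes <- names(by_class)
  withr::with_seed(99, {
    p_ser <- replicate(200, {
      cls <- sample(classes, 300, replace = TRUE)
      idx <- table(factor(cls, levels = classes))
      obs <- dplyr::bind_rows(lapply(classes, function(cl) {
        k <- idx[[cl]]
        if (k == 0) return(NULL)
        r <- by_class[[cl]][sample.int(nrow(by_class[[cl]]), k, TRUE), ]
        tibble::tibble(chrom = r$chrom, pos = r$pos, ref = r$ref,
                       alt = r$alt, consequence = "missense")
      }))
      mc_serine_test(obs, n_draws = 399, seed = sample.int(1e6, 1),
                     null = "uniform")$p_value
    })
    expect_gt(suppressWarnings(stats::ks.test(p_ser, "punif")$p.value), 0.01)

    footprint <- dplyr::distinct(pool, chrom, pos, ref)
    known <- synthetic_known_positions()
    p_db <- replicate(200, {
      r <- footprint[sample.int(nrow(footprint), 300, TRUE), ]
      obs <- tibble::tibble(chrom = r$chrom, pos = r$pos, ref = r$ref,
                            alt = "A", consequence = "missense")
      mc_known_db_overlap_test(obs, known, n_draws = 399,
                               seed = sample.int(1e6, 1),
                               match_on = "position")$p_value
    })
    expect_gt(suppressWarnings(stats::ks.test(p_db, "punif")$p.value), 0.01)
  })
})

test_that("known-database overlap test handles degenerate known sets", {
  cod <- bcpgenomics:::coding_table()
  fam_rows <- dplyr::slice_head(
    dplyr::filter(cod, gene %in% mucin_family()), n = 20)
  obs <- tibble::tibble(chrom = fam_rows$chrom, pos = fam_rows$pos,
                        ref = fam_rows$ref, alt = fam_rows$alt,
                        consequence = "missense")
  # empty known set: p = 1 with a warning
  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          alt = character())
  expect_warning(res <- mc_known_db_overlap_test(obs, empty, n_draws = 199,
                                                 seed = 1), "empty known set")
  expect_equal(res$p_value, 1)
  # known set covering every position saturates the null: p = 1
  all_pos <- dplyr::distinct(
    dplyr::filter(cod, gene %in% mucin_family()),
    chrom, pos)
  all_pos$alt <- NA_character_
  res2 <- mc_known_db_overlap_test(obs, all_pos, n_draws = 199, seed = 1,
                                   match_on = "position")
  expect_equal(res2$p_value, 1)
})
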