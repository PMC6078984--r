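test_that("non-silent classification follows the protein-altering rule", {
  expect_true(classify_non_silent("missense"))
  expect_false(classify_non_silent("synonymous"))
  expect_false(classify_non_silent("noncoding"))
  expect_equal(classify_non_silent(c("splice", "frameshift", "inframe_indel",
                                     "nonsense")),
               rep(TRUE, 4))
  expect_error(classify_non_silent("gibberish"), "unknown consequence")
})

test_that("MATH score matches hand computation and its invariants", {
  expect_equal(math_score(c(0.5, 0.5, 0.5)), 0)
  expect_equal(math_score(c(0.1, 0.2, 0.3, 0.4, 0.5)), 1 / 3)
  expect_equal(math_score(0.37), 0)             # any singleton is 0
  # scale invariance: math(c * v) = math(v)
  withr::with_seed(2, {
    v <- runif(40, 0.05, 0.6)
    expect_equal(math_score(2.3 * v), math_score(v), tolerance = 1e-12)
  })
  # published scaling = 1.4826 * 100 * raw
  expect_equal(math_score(c(0.1, 0.2, 0.3, 0.4, 0.5), scaled = TRUE),
               1.4826 * 100 / 3)
  expect_error(math_score(numeric(0)), "no VAFs")
  expect_error(math_score(c(0, 0, 0)), "median VAF is zero")
})

test_that("catalog summaries count SNVs, indels, non-silent and known variants", {
  m <- make_mutations(
    list(patient_id = "P1", consequence = "missense", vaf = 0.3,
         in_known_db = TRUE),
    list(patient_id = "P1", consequence = "synonymous", vaf = 0.35),
    list(patient_id = "P1", ref = "AC", alt = "A",
         consequence = "frameshift", vaf = 0.25),
    list(patient_id = "P2", consequence = "noncoding", vaf = 0.5)
  )
  s <- summarize_catalogs(m)
  p1 <- s[s$patient_id == "P1", ]
  expect_equal(p1$n_snv, 2L)
  expect_equal(p1$n_indel, 1L)
  expect_equal(p1$n_nonsilent, 2L)
  expect_equal(p1$n_known_db, 1L)
  expect_equal(p1$math_score, math_score(c(0.3, 0.35, 0.25)))
  expect_true(all(s$n_nonsilent <= s$n_snv + s$n_indel))
})

test_that("gene frequency table applies carrier semantics and the closed bound", {
  cl <- make_clinical(sprintf("P%02d", 1:20),
                      rep(c("BCP", "control"), each = 10))
  # gene mutated twice in the same patient counts once; 1/20 = 5% is kept
  m <- make_mutations(
    list(patient_id = "P01", gene = "TP53"),
    list(patient_id = "P01", gene = "TP53", pos = 600L),
    list(patient_id = "P02", gene = "GATA3", consequence = "synonymous")
  )
  tab <- gene_frequency_table(m, cl, min_freq = 0.05)
  expect_equal(tab$gene, "TP53")          # silent-only GATA3 dropped
  expect_equal(tab$n_total, 1L)
  expect_equal(tab$freq_total, 0.05)      # boundary retained
  expect_equal(gene_frequency_table(m, cl, min_freq = 0.051)$gene, character(0))

  # planted 30% carriers recovered within binomial tolerance, and the table
  # is invariant to patient order
  withr::with_seed(13, {
    ids <- sprintf("Q%03d", 1:200)
    cl2 <- make_clinical(ids, rep(c("BCP", "control"), 100))
    carriers <- ids[runif(200) < 0.3]
    m2 <- dplyr::bind_rows(lapply(carriers, function(p) {
      make_mutations(list(patient_id = p, gene = "TP53"))
    }))
    tab2 <- gene_frequency_table(m2, cl2)
    expect_equal(tab2$freq_total[tab2$gene == "TP53"], 0.3, tolerance = 0.17)
    perm <- m2[sample.int(nrow(m2)), ]
    expect_equal(gene_frequency_table(perm, cl2), tab2)
  })
})

test_that("burden comparison reports medians, MW and adjusted p-values", {
  # identical duplicated data: MW p = 1
  ids <- sprintf("P%02d", 1:12)
  cl <- make_clinical(ids, rep(c("BCP", "control"), each = 6))
  met <- tibble::tibble(patient_id = ids,
                        n_nonsilent = rep(c(5L, 9L, 14L, 20L, 3L, 7L), 2),
                        n_snv = 100L, n_indel = 2L, n_known_db = 1L,
                        math_score = 0.2)
  res <- burden_comparison(met, cl, "n_nonsilent")
  expect_equal(res$p_value, 1)
  expect_equal(res$median_bcp, res$median_control)
  expect_true(is.finite(res$adjusted_p))

  # a planted difference is detected in both raw and adjusted analyses
  withr::with_seed(17, {
    ids2 <- sprintf("R%03d", 1:160)
    cl2 <- make_clinical(ids2, rep(c("BCP", "control"), each = 80))
    met2 <- tibble::tibble(
      patient_id = ids2,
      n_nonsilent = c(rnbinom(80, size = 3, mu = 22), rnbinom(80, size = 3, mu = 12)),
      n_snv = 0L, n_indel = 0L, n_known_db = 0L, math_score = NA_real_
    )
    res2 <- burden_comparison(met2, cl2, "n_nonsilent")
    expect_lt(res2$p_value, 0.01)
    expect_lt(res2$adjusted_p, 0.01)
    expect_gt(res2$median_bcp, res2$median_control)
  })
  expect_error(
    burden_comparison(met, dplyr::mutate(cl, group = "BCP"), "n_nonsilent"),
    "no members")
})

test_that("burden comparison p-values are uniform under a null generator", {
  withr::with_seed(23, {
    ids <- sprintf("N%02d", 1:60)
    cl <- make_clinical(ids, rep(c("BCP", "control"), each = 30))
    pvals <- replicate(200, {
      met <- tibble::tibble(patient_id = ids,
                            n_nonsilent = rnbinom(60, size = 2, mu = 15),
                            n_snv = 0L, n_indel = 0L, n_known_db = 0L,
                            math_score = NA_real_)
      burden_comparison(met, cl, "n_nonsilent")$p_value
    })
    expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
  })
})
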