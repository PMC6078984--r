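one_sample_probes <- function(log2, chrom = "1", sample_id = "S1") {
  tibble::tibble(sample_id = sample_id, chrom = chrom,
                 pos = seq_along(log2), log2_ratio = log2, baf = NA_real_)
}

test_that("MAPD matches closed-form cases and the half-normal oracle", {
  expect_equal(mapd(one_sample_probes(rep(c(0, 0.1), 50))), 0.1)
  expect_equal(mapd(one_sample_probes(rep(0.3, 40))), 0)
  withr::with_seed(3, {
    sigma <- 0.12
    pr <- one_sample_probes(rnorm(1e5, 0, sigma))
    # adjacent differences are N(0, 2 sigma^2); median |diff| = 0.954 sigma
    expect_equal(mapd(pr), 0.954 * sigma, tolerance = 0.012)
  })
  expect_error(mapd(one_sample_probes(0.2)), "at least 2 probes")
})

test_that("median autocorrelation separates noise from long-range structure", {
  expect_equal(median_autocorrelation(one_sample_probes(rep(c(0.4, -0.4), 50))),
               -1, tolerance = 1e-6)
  withr::with_seed(4, {
    expect_equal(median_autocorrelation(one_sample_probes(rnorm(1e5))), 0,
                 tolerance = 0.01)
    # planted long segments push the autocorrelation up
    seg_means <- rep(rnorm(20, 0, 0.5), each = 200)
    pr <- one_sample_probes(seg_means + rnorm(4000, 0, 0.1))
    expect_gt(median_autocorrelation(pr), 0.2)
  })
  # zero-variance chromosome excluded with a notice; all excluded is an error
  flat <- one_sample_probes(rep(0.1, 10))
  noisy <- one_sample_probes(c(0.1, -0.2, 0.3, 0, -0.1), chrom = "2")
  expect_message(ac <- median_autocorrelation(dplyr::bind_rows(flat, noisy)),
                 "excluded")
  expect_error(suppressMessages(median_autocorrelation(flat)),
               "no chromosome")
})

test_that("MAPD and autocorrelation are invariant to constant offsets", {
  withr::with_seed(5, {
    pr <- one_sample_probes(rnorm(500, 0, 0.2))
    shifted <- dplyr::mutate(pr, log2_ratio = log2_ratio + 0.7)
    expect_equal(mapd(shifted), mapd(pr), tolerance = 1e-12)
    expect_equal(median_autocorrelation(shifted), median_autocorrelation(pr),
                 tolerance = 1e-9)
  })
})

test_that("QC gate applies the three thresholds with enumerated reasons", {
  qc <- tibble::tibble(
    sample_id = c("A", "B", "C", "D"),
    mapd = c(0.31, 0.30, 0.10, 0.40),
    median_autocorr = c(0.1, 0.5, 0.2, 0.6)
  )
  ccf <- tibble::tibble(sample_id = c("A", "B", "C", "D"),
                        ccf = c(0.8, 0.9, 0.29, 0.25))
  gate <- qc_gate(qc, ccf)
  expect_equal(gate$pass, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(gate$reasons[gate$sample_id == "A"], "MAPD")  # 0.31 boundary
  expect_equal(gate$reasons[gate$sample_id == "C"], "CCF")   # ccf 0.29
  expect_equal(gate$reasons[gate$sample_id == "D"],
               "MAPD,autocorrelation,CCF")
  # reasons are exhaustive and consistent with the pass flag
  expect_equal(gate$pass, gate$reasons == "")
})

test_that("FGA matches direct fractions and is invariant to segment splits", {
  segs <- tibble::tibble(
    sample_id = "S1", chrom = "1", start = c(1L, 301L), end = c(300L, 1000L),
    n_probes = 10L, log2_ratio = c(0.5, 0.0)
  )
  expect_equal(fraction_genome_altered(segs)$fga, 0.30)
  neutral <- dplyr::mutate(segs, log2_ratio = 0.05)
  expect_equal(fraction_genome_altered(neutral)$fga, 0)
  # splitting a segment without changing per-base values preserves FGA
  split_segs <- tibble::tibble(
    sample_id = "S1", chrom = "1",
    start = c(1L, 151L, 301L), end = c(150L, 300L, 1000L),
    n_probes = 5L, log2_ratio = c(0.5, 0.5, 0.0)
  )
  expect_equal(fraction_genome_altered(split_segs)$fga,
               fraction_genome_altered(segs)$fga)
  # sex chromosomes are excluded
  with_x <- dplyr::bind_rows(segs, tibble::tibble(
    sample_id = "S1", chrom = "X", start = 1L, end = 10000L,
    n_probes = 10L, log2_ratio = 0.9))
  expect_equal(fraction_genome_altered(with_x)$fga, 0.30)
  expect_error(fraction_genome_altered(with_x[3, ]), "no autosomal")
})

test_that("generator ground-truth FGA is reproduced exactly", {
  co <- simulate_cohort(cohort_params(n_bcp = 15, n_control = 10, seed = 6),
                        stages = "cna")
  fga <- fraction_genome_altered(co$segments)
  expect_equal(fga$fga[match(co$truth$patient_id, fga$sample_id)],
               co$truth$fga_true, tolerance = 1e-9)
})

test_that("arm-level comparison calls majorities and ranks planted events", {
  arms <- tibble::tibble(chrom = "1", arm = c("p", "q"),
                         start = c(1L, 5001L), end = c(5000L, 10000L))
  ids <- sprintf("S%03d", 1:200)
  cl <- make_clinical(ids, rep(c("BCP", "control"), each = 100))
  gain_ids <- c(ids[1:60], ids[101:110])   # 60% BCP vs 10% control on 1q
  segs <- dplyr::bind_rows(lapply(ids, function(s) {
    tibble::tibble(
      sample_id = s, chrom = "1", start = c(1L, 5001L),
      end = c(5000L, 10000L), n_probes = 50L,
      log2_ratio = c(0, ifelse(s %in% gain_ids, 0.5, 0))
    )
  }))
  cmp <- arm_frequency_comparison(segs, arms, cl)
  row_1q <- cmp[cmp$arm == "q" & cmp$direction == "gain", ]
  expect_equal(row_1q$freq_BCP, 0.6)
  expect_equal(row_1q$freq_control, 0.1)
  expect_lt(row_1q$fdr, 0.05)

  # identical group profiles: all p-values are 1
  segs_same <- dplyr::mutate(segs, log2_ratio = rep(c(0, 0.5), length(ids)))
  cmp_same <- arm_frequency_comparison(segs_same, arms, cl)
  expect_equal(min(cmp_same$p_value), 1)

  # an arm only 49% covered by gain is not called
  segs49 <- tibble::tibble(
    sample_id = "S001", chrom = "1", start = c(1L, 2451L),
    end = c(2450L, 5000L), n_probes = 25L, log2_ratio = c(0.5, 0)
  )
  cmp49 <- arm_frequency_comparison(
    segs49, arms[1, ], cl[1, ])
  expect_equal(cmp49$n_BCP[cmp49$direction == "gain"], 0L)
})

test_that("gene-level calls use the length-weighted mean log2", {
  gene <- list(chrom = "1", start = 1001L, end = 2000L)
  deep <- tibble::tibble(sample_id = "S1", chrom = "1", start = 1L,
                         end = 5000L, n_probes = 50L, log2_ratio = -0.8)
  expect_equal(gene_level_call(deep, gene)$call, "deleted")
  # -0.8 over 30% and 0.0 over 70% -> mean -0.24 -> neutral
  mixed <- tibble::tibble(
    sample_id = "S1", chrom = "1", start = c(1001L, 1301L),
    end = c(1300L, 2000L), n_probes = 10L, log2_ratio = c(-0.8, 0)
  )
  res <- gene_level_call(mixed, gene)
  expect_equal(res$mean_log2, -0.24)
  expect_equal(res$call, "neutral")
  # uncovered gene yields a missing call
  off <- tibble::tibble(sample_id = "S1", chrom = "2", start = 1L,
                        end = 100L, n_probes = 5L, log2_ratio = 0)
  expect_true(is.na(gene_level_call(off, gene)$call))
})

test_that("MSH2 deletion calls recover the generator truth", {
  co <- simulate_cohort(cohort_params(n_bcp = 120, n_control = 80, seed = 10),
                        stages = "cna")
  msh2 <- dplyr::filter(synthetic_genome()$genes, gene == "MSH2")
  calls <- gene_level_call(co$segments, msh2)
  truth <- co$truth$msh2_del[match(calls$sample_id, co$truth$patient_id)]
  agreement <- mean((calls$call == "deleted") == truth, na.rm = TRUE)
  expect_gte(agreement, 0.95)
})
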