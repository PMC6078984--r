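test_that("spectrum builder maps contexts with the pyrimidine convention", {
  genome <- Biostrings::DNAStringSet(c(z = "TACATGCAA"))
  # C>T at the centre of ACA -> A[C>T]A
  m <- make_mutations(list(chrom = "z", pos = 3L, ref = "C", alt = "T"))
  sp <- build_spectrum(m, genome)
  expect_equal(sp$`A[C>T]A`, 1L)
  expect_equal(sp$total_snv, 1L)
  # G>A at the centre of TGC reverse-complements to G[C>T]A
  m2 <- make_mutations(list(chrom = "z", pos = 6L, ref = "G", alt = "A"))
  sp2 <- build_spectrum(m2, genome)
  expect_equal(sp2$`G[C>T]A`, 1L)
  # ref mismatch with the FASTA is an error listing the record
  bad <- make_mutations(list(chrom = "z", pos = 3L, ref = "G", alt = "A"))
  expect_error(build_spectrum(bad, genome), "ref allele mismatch")
  # positions without a full flank are rejected
  edge <- make_mutations(list(chrom = "z", pos = 1L, ref = "T", alt = "C"))
  expect_error(build_spectrum(edge, genome), "outside the reference")
})

test_that("spectrum conserves mutation counts and handles empty catalogs", {
  co <- simulate_catalog(c(Signature.1 = 0.5, Signature.20 = 0.5), 400,
                         synthetic_signature_reference(), seed = 4)
  sp <- build_spectrum(co$mutations, synthetic_genome()$genome)
  expect_equal(sp$total_snv, 400L)
  counts <- as.integer(sp[1, sbs_contexts()])
  expect_equal(counts, unname(co$spectrum))   # placement realizes the channels
  empty <- simulate_catalog(c(Signature.1 = 1), 0,
                            synthetic_signature_reference(), seed = 1)
  expect_equal(sum(empty$spectrum), 0L)
  expect_equal(nrow(empty$mutations), 0L)
})

test_that("noiseless signature mixtures are recovered near-exactly", {
  ref <- synthetic_signature_reference()
  # single signature
  s1 <- matrix(ref[, "Signature.3"] * 1000, nrow = 1,
               dimnames = list("A", rownames(ref)))
  fit1 <- refit_exposures(s1, ref)
  expect_equal(unname(fit1$Signature.3), 1)
  expect_lt(fit1$residual, 1e-10)
  # exact 0.6 / 0.4 mix of two signatures
  w <- c(Signature.2 = 0.6, Signature.13 = 0.4)
  s2 <- matrix(as.numeric(ref[, names(w)] %*% w) * 5000, nrow = 1,
               dimnames = list("B", rownames(ref)))
  fit2 <- refit_exposures(s2, ref)
  expect_equal(unname(fit2$Signature.2), 0.6, tolerance = 1e-6)
  expect_equal(unname(fit2$Signature.13), 0.4, tolerance = 1e-6)
  # mixtures of up to 4 signatures: L-infinity error < 1e-4
  withr::with_seed(12, {
    for (k in 2:4) {
      picks <- sample(colnames(ref), k)
      wk <- rexp(k) + 0.4; wk <- wk / sum(wk)
      sk <- matrix(as.numeric(ref[, picks] %*% wk), nrow = 1,
                   dimnames = list("C", rownames(ref)))
      fitk <- refit_exposures(sk, ref)
      got <- as.numeric(fitk[1, picks])
      expect_lt(max(abs(got - wk)), 1e-4)
    }
  })
})

test_that("exposure cutoff discards small weights and renormalizes", {
  ref <- synthetic_signature_reference()
  w <- c(Signature.1 = 0.57, Signature.3 = 0.40, Signature.8 = 0.03)
  s <- matrix(as.numeric(ref[, names(w)] %*% w), nrow = 1,
              dimnames = list("S", rownames(ref)))
  fit <- refit_exposures(s, ref, cutoff = 0.06)
  expect_equal(unname(fit$Signature.8), 0)
  sigs <- attr(fit, "signatures")
  expect_equal(sum(as.numeric(fit[1, sigs])), 1, tolerance = 1e-9)
  # the realized residual is non-increasing as the cutoff shrinks
  p <- as.numeric(s) / sum(s)
  resid_at <- vapply(c(0.15, 0.06, 0), function(cutpt) {
    f <- refit_exposures(s, ref, cutoff = cutpt)
    sqrt(sum((p - as.numeric(ref %*% as.numeric(f[1, sigs])))^2))
  }, numeric(1))
  expect_true(all(diff(resid_at) <= 1e-12))
  expect_error(refit_exposures(matrix(0, 1, 96,
                                      dimnames = list("Z", rownames(ref))),
                               ref), "all-zero spectrum")
})

test_that("multinomial-sampled catalogs recover exposures within 0.03", {
  ref <- synthetic_signature_reference()
  truth <- c(Signature.1 = 0.45, Signature.3 = 0.25, Signature.20 = 0.20,
             Signature.13 = 0.10)
  probs <- as.numeric(ref[, names(truth)] %*% truth)
  errs <- sapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      counts <- matrix(as.integer(rmultinom(1, 10000, probs)), nrow = 1,
                       dimnames = list("S", rownames(ref)))
      fit <- refit_exposures(counts, ref)
      as.numeric(fit[1, names(truth)]) - truth
    })
  })
  expect_lt(max(abs(rowMeans(errs))), 0.03)
})

test_that("presence calls respect the cutoff boundary", {
  ref <- synthetic_signature_reference()
  w <- c(Signature.1 = 0.93, Signature.20 = 0.07)
  s <- matrix(as.numeric(ref[, names(w)] %*% w) * 10000, nrow = 1,
              dimnames = list("S", rownames(ref)))
  fit <- refit_exposures(s, ref, cutoff = 0.06)
  expect_true(call_presence(fit, "Signature.20")[["S"]])   # 0.07 > cutoff
  expect_false(call_presence(fit, "Signature.5")[["S"]])   # exact zero
  expect_error(call_presence(fit, "Signature.99"), "unknown signature")
  # low-count guard flags rather than refuses
  tiny <- matrix(as.integer(rmultinom(1, 30, ref[, 1])), nrow = 1,
                 dimnames = list("T", rownames(ref)))
  expect_true(refit_exposures(tiny, ref)$low_confidence)
})

test_that("tidy and glance methods expose exposures in long form", {
  ref <- synthetic_signature_reference()
  s <- matrix(as.numeric(ref[, "Signature.5"]) * 2000, nrow = 1,
              dimnames = list("S", rownames(ref)))
  fit <- refit_exposures(s, ref)
  td <- tidy(fit)
  expect_equal(nrow(td), 12L)
  expect_equal(sum(td$proportion), 1, tolerance = 1e-9)
  expect_equal(glance(fit)$n_samples, 1L)
})

test_that("signature-20 association suite runs and skips degenerate tests", {
  co <- acceptance_cohort()
  fit <- refit_exposures(co$spectra, synthetic_signature_reference())
  assoc <- sig20_association_suite(fit)
  rho <- assoc$statistic[assoc$test == "spearman_exposure_vs_snv_load"]
  expect_gt(rho, 0.3)
  expect_lt(assoc$p_value[assoc$test == "spearman_exposure_vs_snv_load"], 0.05)
  # constant presence: expression test is skipped with a notice
  all_pos <- fit
  all_pos$Signature.20 <- 0.5
  expr <- matrix(rnorm(2 * nrow(fit), 7), 2,
                 dimnames = list(c("MSH2", "TP53"), fit$sample_id))
  assoc2 <- sig20_association_suite(all_pos, expr = expr)
  expect_match(assoc2$note[grepl("MSH2", assoc2$test)], "skipped")
})
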