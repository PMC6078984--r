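# Synthetic cohort generator. Emits complete cohorts (clinical covariates and
# survival, mutation records, 96-channel spectra with true signature
# exposures, copy-number segments and probes, expression) with the case -
# control structure of the BCP study, plus the ground truth needed for
# recovery tests. Fully deterministic given the root seed: every component
# draws from its own child stream keyed by a stable label, so enabling or
# disabling one stage never perturbs another.

#' Cohort generator parameters
#'
#' Builds and validates the parameter set of the synthetic cohort generator.
#' Defaults encode the published statistical structure of the study cohort:
#' group-wise SNV and non-silent burden medians, mucin-carrier prevalences,
#' the serine-gain probability among mucin missense mutations, signature-20
#' prevalence and its load coupling, MSH2-deletion probabilities by
#' signature-20 status, the adjusted survival hazard ratios together with the
#' marginal Kaplan-Meier DFS medians, and the cancer-cell-fraction range.
#'
#' @param n_bcp,n_control Group sizes (study: 35 and 18).
#' @param median_snv Group SNV-count medians (BCP, control).
#' @param median_nonsilent Group non-silent burden medians.
#' @param nonsilent_size Negative-binomial size (dispersion) of the
#'   non-silent burden; 1.5 gives the heavy right tail typical of somatic
#'   burden data.
#' @param median_indel Group indel-count medians.
#' @param mucin_carrier_prob Per-group probability that a patient carries at
#'   least one non-silent mucin mutation.
#' @param serine_gain_prob_mucin Probability that a mucin missense mutation
#'   gains a serine.
#' @param sig20_prevalence Per-group probability of a signature-20-positive
#'   tumor.
#' @param sig20_snv_medians SNV medians by signature-20 status (positive,
#'   negative); only their ratio is used (see the methods vignette).
#' @param msh2_del_prob_by_sig20 MSH2-deletion probability for
#'   signature-20-positive and -negative tumors.
#' @param dfs_hr,os_hr Conditional (covariate-adjusted) group hazard ratios.
#' @param km_median_dfs Marginal Kaplan-Meier DFS medians in years (BCP,
#'   control) that the generator is calibrated to reproduce.
#' @param ccf_range Uniform range of the simulated cancer cell fraction.
#' @param vaf_overdispersion Beta overdispersion of VAFs around ccf/2.
#' @param mucsig_shift Mean log-expression upshift of mucin genes in BCP.
#' @param msh2_expr_shift Mean MSH2 log-expression shift in
#'   signature-20-positive tumors.
#' @param snv_sigma_log Log-scale SD of the per-status SNV-count log-normal.
#' @param mucin_known_db_prob Probability a planted mucin variant is flagged
#'   as known-database member; `background_known_db_prob` likewise for other
#'   non-silent variants.
#' @param background_known_db_prob See above.
#' @param plant_hotspots Plant three recurrent mucin protein changes (two in
#'   MUC17, one in MUC20) shared by two BCP patients each.
#' @param seed Root seed (integer).
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_bcp = 35L, n_control = 18L,
                          median_snv = c(13829, 10084),
                          median_nonsilent = c(20, 12),
                          nonsilent_size = 1.5,
                          median_indel = c(21, 26),
                          mucin_carrier_prob = c(0.457, 0.111),
                          serine_gain_prob_mucin = 0.409,
                          sig20_prevalence = c(0.371, 0.111),
                          sig20_snv_medians = c(31632, 7352),
                          msh2_del_prob_by_sig20 = c(0.333, 0.026),
                          dfs_hr = 1.81, os_hr = 2.53,
                          km_median_dfs = c(9.8, 12.5),
                          ccf_range = c(0.3, 1.0),
                          vaf_overdispersion = 0.05,
                          mucsig_shift = 0.5,
                          msh2_expr_shift = -0.8,
                          snv_sigma_log = 0.5,
                          mucin_known_db_prob = 0.5,
                          background_known_db_prob = 0.08,
                          plant_hotspots = TRUE,
                          seed = 1L) {
  p <- as.list(environment())
  probs <- c(p$mucin_carrier_prob, p$serine_gain_prob_mucin,
             p$sig20_prevalence, p$msh2_del_prob_by_sig20,
             p$mucin_known_db_prob, p$background_known_db_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("cohort_params: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(p$median_snv, p$median_nonsilent, p$median_indel,
            p$sig20_snv_medians) <= 0)) {
    stop("cohort_params: medians must be positive", call. = FALSE)
  }
  if (p$n_bcp < 1L || p$n_control < 1L) {
    stop("cohort_params: group sizes must be at least 1", call. = FALSE)
  }
  if (p$dfs_hr <= 0 || p$os_hr <= 0) {
    stop("cohort_params: hazard ratios must be positive", call. = FALSE)
  }
  if (length(p$ccf_range) != 2L || p$ccf_range[1] <= 0 ||
      p$ccf_range[2] > 1 || p$ccf_range[1] > p$ccf_range[2]) {
    stop("cohort_params: ccf_range must be an interval within (0, 1]", call. = FALSE)
  }
  structure(p, class = "cohort_params")
}

# deterministic child stream: stable string hash added to the root seed
child_seed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 + h) %% 2147480009) + 1L
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  stats::setNames(g / sum(g), names(alpha))
}

# smallest-mu calibration so the negative binomial population median equals m
nb_mu_for_median <- function(m, size) {
  root <- stats::uniroot(function(mu) stats::pnbinom(m - 1L, size = size, mu = mu) - 0.5,
                         c(1e-3, 50 * m + 100))$root
  root * 1.0005
}

# log-normal two-component mixture scale so the group SNV median is exact;
# the positive:negative ratio of component medians is fixed.
snv_scale_for_group <- function(target_median, prevalence, ratio, sigma) {
  stats::uniroot(function(m_neg) {
    (1 - prevalence) * stats::pnorm(log(target_median / m_neg) / sigma) +
      prevalence * stats::pnorm(log(target_median / (ratio * m_neg)) / sigma) - 0.5
  }, c(1, 10 * target_median))$root
}

# covariate model shared by the survival calibration and the simulator
SURV_EFFECTS <- list(
  beta_stage = 0.55, beta_age = 0.02, beta_year = -0.03,
  subtype_levels = c("LumA", "LumB", "HER2", "TN"),
  subtype_probs = c(0.45, 0.30, 0.10, 0.15),
  subtype_beta = c(LumA = 0, LumB = 0.25, HER2 = 0.45, TN = 0.65),
  stage_cut = c(stats::qlogis(0.25), stats::qlogis(0.70)),
  age_mean = c(BCP = 33, control = 34), age_sd = 4,
  year_range = c(1996, 2010)
)

surv_lp <- function(age, year, stage, subtype) {
  e <- SURV_EFFECTS
  e$beta_stage * (stage - 2) + e$beta_age * (age - 34) +
    e$beta_year * (year - 2003) + unname(e$subtype_beta[subtype])
}

# stage from a uniform draw under a cumulative-logit model; eta > 0 shifts
# the distribution toward lower stage
stage_from_uniform <- function(u, eta) {
  e <- SURV_EFFECTS
  p1 <- stats::plogis(e$stage_cut[1] + eta)
  p2 <- stats::plogis(e$stage_cut[2] + eta)
  1L + (u > p1) + (u > p2)
}

draw_covariates <- function(n, group, eta) {
  e <- SURV_EFFECTS
  age <- stats::rnorm(n, e$age_mean[[group]], e$age_sd)
  year <- stats::runif(n, e$year_range[1], e$year_range[2])
  subtype <- sample(e$subtype_levels, n, replace = TRUE, prob = e$subtype_probs)
  stage <- stage_from_uniform(stats::runif(n), eta)
  tibble::tibble(age_at_diagnosis = age, year = year,
                 pathological_stage = stage, subtype_ihc = subtype)
}

marginal_median_time <- function(rates) {
  stats::uniroot(function(t) mean(exp(-rates * t)) - 0.5, c(1e-8, 1e8))$root
}

# Calibrates (i) the DFS baseline hazard so the control marginal KM median is
# km_median_dfs[2], (ii) the BCP stage shift eta so the BCP marginal median
# is km_median_dfs[1] under the conditional group HR, and (iii) the OS
# baseline so control marginal 5-year OS is 0.88. Uses a fixed internal
# quasi-sample of the covariate distribution, independent of user seeds.
survival_calibration <- function(params) {
  key <- paste(params$dfs_hr, params$os_hr,
               paste(params$km_median_dfs, collapse = ","), sep = "|")
  if (!is.null(.bcp_cache$surv_cal[[key]])) return(.bcp_cache$surv_cal[[key]])
  cal <- withr::with_seed(GENOME_SEED + 3L, {
    m <- 20000L
    ctl <- draw_covariates(m, "control", eta = 0)
    lp_c <- surv_lp(ctl$age_at_diagnosis, ctl$year, ctl$pathological_stage,
                    ctl$subtype_ihc)
    e <- SURV_EFFECTS
    bcp_age <- stats::rnorm(m, e$age_mean[["BCP"]], e$age_sd)
    bcp_year <- stats::runif(m, e$year_range[1], e$year_range[2])
    bcp_subtype <- sample(e$subtype_levels, m, replace = TRUE, prob = e$subtype_probs)
    bcp_u <- stats::runif(m)
    lp_b <- function(eta) {
      surv_lp(bcp_age, bcp_year, stage_from_uniform(bcp_u, eta), bcp_subtype)
    }
    lambda_dfs <- stats::uniroot(function(l) {
      marginal_median_time(l * exp(lp_c)) - params$km_median_dfs[2]
    }, c(1e-5, 2))$root
    eta <- stats::uniroot(function(eta) {
      marginal_median_time(lambda_dfs * params$dfs_hr * exp(lp_b(eta))) -
        params$km_median_dfs[1]
    }, c(-4, 6))$root
    lambda_os <- stats::uniroot(function(l) {
      mean(exp(-l * exp(lp_c) * 5)) - 0.88
    }, c(1e-6, 2))$root
    list(lambda_dfs = lambda_dfs, lambda_os = lambda_os, eta = eta)
  })
  if (is.null(.bcp_cache$surv_cal)) .bcp_cache$surv_cal <- list()
  .bcp_cache$surv_cal[[key]] <- cal
  cal
}

# gene usage of planted mucin mutations; MUC4 + MUC16 weight (0.255)
# calibrated so the post-exclusion BCP carrier prevalence matches 37.1%
MUCIN_GENE_WEIGHTS <- c(MUC4 = 0.155, MUC16 = 0.10, MUC17 = 0.175,
                        MUC2 = 0.13, MUC12 = 0.10, MUC20 = 0.10,
                        MUC19 = 0.07, MUC5B = 0.06, MUC6 = 0.06, MUC1 = 0.05)

BACKGROUND_GENE_WEIGHTS <- c(TP53 = 0.22, PIK3CA = 0.18, GATA3 = 0.10,
                             AKT1 = 0.08, PTEN = 0.08, CDH1 = 0.08,
                             MAP3K1 = 0.08, KMT2C = 0.08, MSH2 = 0.05,
                             MSH6 = 0.05)

BACKGROUND_CONSEQUENCE_PROBS <- c(missense = 0.72, nonsense = 0.08,
                                  splice = 0.05, frameshift = 0.10,
                                  inframe_indel = 0.05)

#' Simulate one mutation catalog from a signature mixture
#'
#' Draws `n_mutations` SNVs whose 96-channel counts follow
#' Multinomial(n, reference x exposures) and places each at a genomic
#' position of the synthetic reference whose trinucleotide context realizes
#' its channel, so that [build_spectrum()] recovers the counts exactly.
#' Consequence and gene annotations come from the coding lookup where the
#' position is coding, `noncoding` otherwise.
#'
#' @param exposures Named non-negative vector over the reference's
#'   signatures, summing to 1 (within 1e-6).
#' @param n_mutations Number of SNVs (>= 0).
#' @param reference 96 x S signature matrix.
#' @param patient_id Sample label for the emitted records.
#' @param seed Optional seed for this draw.
#' @return List with `spectrum` (named 96-vector of counts) and `mutations`
#'   (tibble of mutation records).
#' @export
simulate_catalog <- function(exposures, n_mutations, reference,
                             patient_id = "S1", seed = NULL) {
  if (n_mutations < 0) stop("simulate_catalog: n_mutations must be >= 0", call. = FALSE)
  if (!is.null(names(exposures))) {
    unknown <- setdiff(names(exposures), colnames(reference))
    if (length(unknown)) {
      stop("simulate_catalog: unknown signature(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    full <- stats::setNames(numeric(ncol(reference)), colnames(reference))
    full[names(exposures)] <- exposures
    exposures <- full
  } else if (length(exposures) != ncol(reference)) {
    stop("simulate_catalog: exposures must be named or match the reference width",
         call. = FALSE)
  }
  if (abs(sum(exposures) - 1) > 1e-6) {
    stop("simulate_catalog: exposures must sum to 1", call. = FALSE)
  }
  if (any(exposures < 0)) stop("simulate_catalog: negative exposure", call. = FALSE)
  run <- function() {
    contexts <- sbs_contexts()
    probs <- as.vector(reference[contexts, , drop = FALSE] %*% exposures)
    counts <- if (n_mutations == 0L) {
      stats::setNames(integer(96), contexts)
    } else {
      stats::setNames(as.integer(stats::rmultinom(1, n_mutations, probs)), contexts)
    }
    nz <- which(counts > 0L)
    mut <- if (length(nz) == 0L) {
      tibble::tibble(patient_id = character(), chrom = character(),
                     pos = integer(), ref = character(), alt = character(),
                     gene = character(), consequence = character(),
                     protein_change = character(), vaf = numeric(),
                     in_known_db = logical())
    } else {
      placed <- dplyr::bind_rows(lapply(nz, function(i) {
        sample_channel_positions(contexts[i], counts[i])
      }))
      cod <- coding_table() |>
        dplyr::select("chrom", "pos", "alt", "gene", "consequence",
                      "protein_change")
      placed |>
        dplyr::left_join(cod, by = c("chrom", "pos", "alt")) |>
        dplyr::mutate(
          patient_id = patient_id,
          gene = dplyr::coalesce(.data$gene, NA_character_),
          consequence = dplyr::coalesce(.data$consequence, "noncoding"),
          vaf = NA_real_, in_known_db = NA
        ) |>
        dplyr::select("patient_id", "chrom", "pos", "ref", "alt", "gene",
                      "consequence", "protein_change", "vaf", "in_known_db")
    }
    list(spectrum = counts, mutations = mut)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate variant allele fractions for one tumor
#'
#' Diploid heterozygous model: VAFs are beta-distributed with mean ccf/2 and
#' precision 1/overdispersion.
#'
#' @param ccf Cancer cell fraction in (0, 1].
#' @param n Number of VAFs (>= 1).
#' @param overdispersion Beta overdispersion; as it approaches 0 the draws
#'   concentrate at ccf/2.
#' @param seed Optional seed.
#' @return Numeric vector of `n` VAFs, all strictly inside (0, 1).
#' @export
simulate_vafs <- function(ccf, n, overdispersion = 0.05, seed = NULL) {
  if (ccf <= 0 || ccf > 1) stop("simulate_vafs: ccf must be in (0, 1]", call. = FALSE)
  if (n < 1) stop("simulate_vafs: n must be >= 1", call. = FALSE)
  if (overdispersion <= 0) stop("simulate_vafs: overdispersion must be > 0", call. = FALSE)
  run <- function() {
    mu <- ccf / 2
    kappa <- 1 / overdispersion
    v <- stats::rbeta(n, mu * kappa, (1 - mu) * kappa)
    pmin(pmax(v, 1e-6), 1 - 1e-6)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

genome_substr <- function(chrom, pos, len = 1L) {
  g <- synthetic_genome()$genome
  vapply(seq_along(chrom), function(i) {
    as.character(Biostrings::subseq(g[[chrom[i]]], pos[i], pos[i] + len - 1L))
  }, character(1))
}

# sample k rows from a coding-table pool (already filtered), uniformly
sample_pool_rows <- function(pool, k) {
  pool[sample.int(nrow(pool), k, replace = TRUE), ]
}

#' Simulate a complete synthetic cohort
#'
#' Generates a two-group cohort with the configured statistical structure.
#' Stages can be toggled; ground truth (`$truth`, `$exposures_true`) is
#' always produced. Deterministic: the same `params` (including seed) yield
#' an identical object.
#'
#' @param params A [cohort_params()] object.
#' @param stages Character subset of
#'   `c("clinical", "mutations", "spectra", "cna", "probes", "expression")`.
#' @return A list of class `synthetic_cohort` with elements `params`,
#'   `truth`, `clinical`, `mutations`, `vafs`, `spectra`, `exposures_true`,
#'   `segments`, `probes`, `expression` (absent stages are `NULL`).
#' @export
simulate_cohort <- function(params = cohort_params(),
                            stages = c("clinical", "mutations", "spectra",
                                       "cna", "probes", "expression")) {
  stopifnot(inherits(params, "cohort_params"))
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- params$seed
  n <- c(params$n_bcp, params$n_control)
  ids <- c(sprintf("BCP%03d", seq_len(n[1])), sprintf("CTL%03d", seq_len(n[2])))
  group <- rep(c("BCP", "control"), n)
  gi <- ifelse(group == "BCP", 1L, 2L)

  truth <- withr::with_seed(child_seed(seed, "truth"), {
    sig20_pos <- stats::runif(sum(n)) < params$sig20_prevalence[gi]
    ratio <- params$sig20_snv_medians[1] / params$sig20_snv_medians[2]
    scale_bcp <- snv_scale_for_group(params$median_snv[1],
                                     params$sig20_prevalence[1], ratio,
                                     params$snv_sigma_log)
    scale_ctl <- snv_scale_for_group(params$median_snv[2],
                                     params$sig20_prevalence[2], ratio,
                                     params$snv_sigma_log)
    m_neg <- ifelse(group == "BCP", scale_bcp, scale_ctl)
    m_i <- ifelse(sig20_pos, m_neg * ratio, m_neg)
    n_snv <- pmax(50L, as.integer(round(stats::rlnorm(sum(n), log(m_i),
                                                      params$snv_sigma_log))))
    mu_ns <- vapply(params$median_nonsilent, nb_mu_for_median,
                    numeric(1), size = params$nonsilent_size)
    n_nonsilent <- stats::rnbinom(sum(n), size = params$nonsilent_size,
                                  mu = mu_ns[gi])
    mu_ind <- vapply(params$median_indel, nb_mu_for_median, numeric(1), size = 2)
    n_indel <- stats::rnbinom(sum(n), size = 2, mu = mu_ind[gi])
    mucin_carrier <- stats::runif(sum(n)) < params$mucin_carrier_prob[gi]
    n_mucin <- ifelse(mucin_carrier, 1L + stats::rpois(sum(n), 0.4), 0L)
    msh2_del <- stats::runif(sum(n)) <
      params$msh2_del_prob_by_sig20[2 - sig20_pos]
    ccf <- stats::runif(sum(n), params$ccf_range[1], params$ccf_range[2])
    ploidy <- stats::runif(sum(n), 1.8, 4.2)
    tibble::tibble(
      patient_id = ids, group = group, sig20_pos = sig20_pos,
      n_snv = n_snv, n_nonsilent = n_nonsilent, n_indel = n_indel,
      mucin_carrier = mucin_carrier, n_mucin = n_mucin,
      msh2_del = msh2_del, ccf = ccf, ploidy = ploidy
    )
  })

  out <- list(params = params, truth = truth, clinical = NULL,
              mutations = NULL, vafs = NULL, spectra = NULL,
              exposures_true = NULL, segments = NULL, probes = NULL,
              expression = NULL)

  if ("clinical" %in% stages) {
    out$clinical <- simulate_clinical_stage(params, truth,
                                            child_seed(seed, "clinical"))
  }
  if ("mutations" %in% stages) {
    mut <- simulate_mutation_stage(params, truth,
                                   child_seed(seed, "mutations"))
    out$mutations <- mut$mutations
    out$vafs <- mut$vafs
    out$truth$n_hotspots_planted <- mut$n_hotspots_planted
  }
  if ("spectra" %in% stages) {
    sp <- simulate_spectra_stage(params, truth, child_seed(seed, "spectra"))
    out$spectra <- sp$spectra
    out$exposures_true <- sp$exposures_true
  }
  if (any(c("cna", "probes") %in% stages)) {
    cna <- simulate_cna_stage(params, truth, child_seed(seed, "cna"),
                              probes = "probes" %in% stages)
    out$segments <- cna$segments
    out$probes <- cna$probes
    out$truth$fga_true <- cna$fga_true
  }
  if ("expression" %in% stages) {
    out$expression <- simulate_expression_stage(params, truth,
                                                child_seed(seed, "expression"))
  }
  structure(out, class = "synthetic_cohort")
}

simulate_clinical_stage <- function(params, truth, seed) {
  cal <- survival_calibration(params)
  withr::with_seed(seed, {
    n <- nrow(truth)
    bcp <- truth$group == "BCP"
    cov <- dplyr::bind_rows(
      draw_covariates(sum(bcp), "BCP", eta = cal$eta),
      draw_covariates(sum(!bcp), "control", eta = 0)
    )
    # rows were drawn BCP-block first; truth is already ordered BCP, control
    lp <- surv_lp(cov$age_at_diagnosis, cov$year, cov$pathological_stage,
                  cov$subtype_ihc)
    hr_dfs <- ifelse(bcp, params$dfs_hr, 1)
    hr_os <- ifelse(bcp, params$os_hr, 1)
    t_dfs <- stats::rexp(n, cal$lambda_dfs * hr_dfs * exp(lp))
    t_os <- stats::rexp(n, cal$lambda_os * hr_os * exp(lp))
    cens <- stats::runif(n, 5, 15)
    er <- sample(c("pos", "neg"), n, replace = TRUE, prob = c(0.7, 0.3))
    pr <- ifelse(er == "pos" & stats::runif(n) < 0.85, "pos",
                 ifelse(stats::runif(n) < 0.25, "pos", "neg"))
    tibble::tibble(
      patient_id = truth$patient_id, group = truth$group,
      age_at_diagnosis = round(cov$age_at_diagnosis, 1),
      date_of_diagnosis = as.Date(sprintf("%d-01-01", floor(cov$year))) +
        round(365 * (cov$year - floor(cov$year))),
      pathological_stage = cov$pathological_stage,
      subtype_ihc = cov$subtype_ihc, er_status = er, pr_status = pr,
      dfs_time = pmin(t_dfs, cens), dfs_event = as.integer(t_dfs <= cens),
      os_time = pmin(t_os, cens), os_event = as.integer(t_os <= cens)
    )
  })
}

simulate_spectra_stage <- function(params, truth, seed) {
  reference <- synthetic_signature_reference()
  withr::with_seed(seed, {
    sigs <- colnames(reference)
    alpha <- stats::setNames(rep(0.3, length(sigs)), sigs)
    alpha[c("Signature.1", "Signature.3", "Signature.5")] <- c(8, 5, 6)
    alpha[c("Signature.2", "Signature.13", "Signature.8")] <- c(2, 2, 3)
    alpha <- alpha[setdiff(sigs, "Signature.20")]
    expo <- t(vapply(seq_len(nrow(truth)), function(i) {
      base <- rdirichlet1(alpha)
      w <- stats::setNames(numeric(length(sigs)), sigs)
      if (truth$sig20_pos[i]) {
        share <- stats::runif(1, 0.15, 0.45)
        w[names(base)] <- base * (1 - share)
        w["Signature.20"] <- share
      } else {
        w[names(base)] <- base
      }
      w
    }, numeric(length(sigs))))
    counts <- t(vapply(seq_len(nrow(truth)), function(i) {
      as.integer(stats::rmultinom(1, truth$n_snv[i], reference %*% expo[i, ]))
    }, integer(96)))
    colnames(counts) <- rownames(reference)
    spectra <- dplyr::bind_cols(
      tibble::tibble(sample_id = truth$patient_id,
                     total_snv = as.integer(rowSums(counts))),
      tibble::as_tibble(counts)
    )
    exposures_true <- dplyr::bind_cols(
      tibble::tibble(sample_id = truth$patient_id),
      tibble::as_tibble(expo)
    )
    list(spectra = spectra, exposures_true = exposures_true)
  })
}

simulate_mutation_stage <- function(params, truth, seed) {
  cod <- coding_table()
  genes <- synthetic_genome()$genes
  mucins <- synthetic_genome()$mucins
  pools <- list(
    bg_missense = dplyr::filter(cod, !(.data$gene %in% mucins),
                                .data$consequence == "missense"),
    bg_nonsense = dplyr::filter(cod, !(.data$gene %in% mucins),
                                .data$consequence == "nonsense"),
    muc_sergain = dplyr::filter(cod, .data$gene %in% mucins, .data$serine_gain),
    muc_missense = dplyr::filter(cod, .data$gene %in% mucins,
                                 .data$consequence == "missense",
                                 !.data$serine_gain),
    muc_nonsense = dplyr::filter(cod, .data$gene %in% mucins,
                                 .data$consequence == "nonsense"),
    synonymous = dplyr::filter(cod, .data$consequence == "synonymous")
  )
  by_gene <- lapply(pools[c("bg_missense", "bg_nonsense", "muc_sergain",
                            "muc_missense", "muc_nonsense")],
                    function(p) split(p, p$gene))
  withr::with_seed(seed, {
    n <- nrow(truth)
    records <- vector("list", n)
    vafs_list <- vector("list", n)
    for (i in seq_len(n)) {
      pid <- truth$patient_id[i]
      mu_vaf <- truth$ccf[i] / 2
      kappa <- 1 / params$vaf_overdispersion
      rvaf <- function(k) {
        pmin(pmax(stats::rbeta(k, mu_vaf * kappa, (1 - mu_vaf) * kappa),
                  1e-6), 1 - 1e-6)
      }
      rows <- list()
      # planted mucin mutations
      k_muc <- truth$n_mucin[i]
      if (k_muc > 0L) {
        muc_genes <- sample(names(MUCIN_GENE_WEIGHTS), k_muc, replace = TRUE,
                            prob = MUCIN_GENE_WEIGHTS)
        muc_rows <- dplyr::bind_rows(lapply(muc_genes, function(g) {
          if (stats::runif(1) < 0.95) {
            if (stats::runif(1) < params$serine_gain_prob_mucin) {
              sample_pool_rows(by_gene$muc_sergain[[g]], 1L)
            } else {
              sample_pool_rows(by_gene$muc_missense[[g]], 1L)
            }
          } else {
            sample_pool_rows(by_gene$muc_nonsense[[g]], 1L)
          }
        }))
        rows$mucin <- tibble::tibble(
          patient_id = pid, chrom = muc_rows$chrom, pos = muc_rows$pos,
          ref = muc_rows$ref, alt = muc_rows$alt, gene = muc_rows$gene,
          consequence = muc_rows$consequence,
          protein_change = muc_rows$protein_change,
          vaf = rvaf(k_muc),
          in_known_db = stats::runif(k_muc) < params$mucin_known_db_prob
        )
      }
      # background non-silent mutations
      k_bg <- max(0L, truth$n_nonsilent[i] - k_muc)
      if (k_bg > 0L) {
        cons <- sample(names(BACKGROUND_CONSEQUENCE_PROBS), k_bg,
                       replace = TRUE, prob = BACKGROUND_CONSEQUENCE_PROBS)
        bg_gene <- sample(names(BACKGROUND_GENE_WEIGHTS), k_bg, replace = TRUE,
                          prob = BACKGROUND_GENE_WEIGHTS)
        bg <- dplyr::bind_rows(lapply(seq_len(k_bg), function(j) {
          g <- bg_gene[j]
          if (cons[j] %in% c("missense", "nonsense")) {
            pool <- if (cons[j] == "missense") by_gene$bg_missense[[g]] else
              by_gene$bg_nonsense[[g]]
            r <- sample_pool_rows(pool, 1L)
            tibble::tibble(chrom = r$chrom, pos = r$pos, ref = r$ref,
                           alt = r$alt, gene = g, consequence = cons[j],
                           protein_change = r$protein_change)
          } else if (cons[j] == "splice") {
            gr <- genes[genes$gene == g, ]
            p <- gr$start - 2L
            rb <- genome_substr(gr$chrom, p)
            tibble::tibble(chrom = gr$chrom, pos = p, ref = rb,
                           alt = sample(setdiff(c("A", "C", "G", "T"), rb), 1),
                           gene = g, consequence = "splice",
                           protein_change = NA_character_)
          } else {
            r <- sample_pool_rows(by_gene$bg_missense[[g]], 1L)
            if (cons[j] == "frameshift") {
              refs <- genome_substr(r$chrom, r$pos, 2L)
              tibble::tibble(chrom = r$chrom, pos = r$pos, ref = refs,
                             alt = substr(refs, 1, 1), gene = g,
                             consequence = "frameshift",
                             protein_change = paste0("p.", r$ref_aa,
                                                     r$codon_index, "fs"))
            } else {
              refs <- genome_substr(r$chrom, r$pos, 4L)
              tibble::tibble(chrom = r$chrom, pos = r$pos, ref = refs,
                             alt = substr(refs, 1, 1), gene = g,
                             consequence = "inframe_indel",
                             protein_change = paste0("p.", r$ref_aa,
                                                     r$codon_index, "del"))
            }
          }
        }))
        rows$background <- dplyr::mutate(
          bg, patient_id = pid, vaf = rvaf(k_bg),
          in_known_db = stats::runif(k_bg) < params$background_known_db_prob,
          .before = 1
        )
      }
      # a small sample of silent records for realism of the table
      k_syn <- stats::rpois(1, 8)
      if (k_syn > 0L) {
        r <- sample_pool_rows(pools$synonymous, k_syn)
        rows$silent <- tibble::tibble(
          patient_id = pid, chrom = r$chrom, pos = r$pos, ref = r$ref,
          alt = r$alt, gene = r$gene, consequence = "synonymous",
          protein_change = NA_character_, vaf = rvaf(k_syn),
          in_known_db = FALSE
        )
      }
      records[[i]] <- dplyr::bind_rows(rows)
      vafs_list[[i]] <- tibble::tibble(
        patient_id = pid,
        vaf = rvaf(min(max(truth$n_snv[i], 1L), 300L))
      )
    }
    mutations <- dplyr::bind_rows(records) |>
      dplyr::select("patient_id", "chrom", "pos", "ref", "alt", "gene",
                    "consequence", "protein_change", "vaf", "in_known_db")
    n_planted <- 0L
    if (params$plant_hotspots && any(truth$group == "BCP")) {
      for (spec in list(c("MUC17", 1L), c("MUC17", 2L), c("MUC20", 1L))) {
        g <- spec[1]
        idx <- which(mutations$gene == g & mutations$consequence == "missense" &
                       grepl("^BCP", mutations$patient_id))
        donors <- split(idx, mutations$patient_id[idx])
        if (length(donors) >= 2L) {
          pair_pos <- as.integer(spec[2])
          if (length(donors) < pair_pos * 2L) next
          a <- donors[[pair_pos * 2L - 1L]][1]
          b <- donors[[pair_pos * 2L]][1]
          keep <- c("chrom", "pos", "ref", "alt", "consequence",
                    "protein_change")
          mutations[b, keep] <- mutations[a, keep]
          n_planted <- n_planted + 1L
        }
      }
    }
    list(mutations = mutations, vafs = dplyr::bind_rows(vafs_list),
         n_hotspots_planted = n_planted)
  })
}

simulate_cna_stage <- function(params, truth, seed, probes = TRUE) {
  ref <- synthetic_genome()
  arms <- genome_arms()
  genes <- ref$genes
  msh2 <- genes[genes$gene == "MSH2", ]
  # 2p stays near-quiet so gene-level MSH2 calls reflect the planted focal
  # deletions rather than arm-level events
  arm_gain_prob <- c("1p" = 0.05, "1q" = 0.45, "2p" = 0.05, "2q" = 0.10,
                     "3p" = 0.05, "3q" = 0.35)
  arm_loss_prob <- c("1p" = 0.20, "1q" = 0.02, "2p" = 0.02, "2q" = 0.20,
                     "3p" = 0.35, "3q" = 0.02)
  withr::with_seed(seed, {
    n <- nrow(truth)
    seg_list <- vector("list", n)
    probe_list <- if (probes) vector("list", n) else NULL
    fga_true <- numeric(n)
    arm_key <- paste0(arms$chrom, arms$arm)
    for (i in seq_len(n)) {
      u <- stats::runif(nrow(arms))
      state <- ifelse(u < arm_gain_prob[arm_key], 1L,
                      ifelse(u < arm_gain_prob[arm_key] + arm_loss_prob[arm_key],
                             -1L, 0L))
      log2_arm <- ifelse(state == 1L, stats::rnorm(nrow(arms), 0.45, 0.05),
                         ifelse(state == -1L, stats::rnorm(nrow(arms), -0.45, 0.05),
                                stats::rnorm(nrow(arms), 0, 0.02)))
      segs <- tibble::tibble(
        sample_id = truth$patient_id[i], chrom = arms$chrom,
        start = arms$start, end = arms$end, log2_ratio = log2_arm
      )
      if (truth$msh2_del[i]) {
        focal_start <- max(1L, msh2$start - 200L)
        focal_end <- msh2$end + 200L
        host <- which(segs$chrom == msh2$chrom & segs$start <= focal_start &
                        segs$end >= focal_end)[1]
        h <- segs[host, ]
        pieces <- tibble::tibble(
          sample_id = h$sample_id, chrom = h$chrom,
          start = c(h$start, focal_start, focal_end + 1L),
          end = c(focal_start - 1L, focal_end, h$end),
          log2_ratio = c(h$log2_ratio, stats::rnorm(1, -0.7, 0.05),
                         h$log2_ratio)
        )
        pieces <- pieces[pieces$start <= pieces$end, ]
        segs <- dplyr::bind_rows(segs[-host, ], pieces) |>
          dplyr::arrange(.data$chrom, .data$start)
      }
      spacing <- 40L
      segs$n_probes <- pmax(1L, (segs$end - segs$start + 1L) %/% spacing)
      seg_list[[i]] <- segs
      lens <- segs$end - segs$start + 1L
      fga_true[i] <- sum(lens[abs(segs$log2_ratio) > 0.2]) / sum(lens)
      if (probes) {
        pr <- segs |>
          dplyr::rowwise() |>
          dplyr::mutate(ppos = list(seq(.data$start, .data$end, by = spacing))) |>
          dplyr::ungroup() |>
          tidyr::unnest("ppos")
        probe_list[[i]] <- tibble::tibble(
          sample_id = truth$patient_id[i], chrom = pr$chrom,
          pos = as.integer(pr$ppos),
          log2_ratio = pr$log2_ratio + stats::rnorm(nrow(pr), 0, 0.16),
          baf = NA_real_
        )
      }
    }
    list(
      segments = dplyr::bind_rows(seg_list) |>
        dplyr::select("sample_id", "chrom", "start", "end", "n_probes",
                      "log2_ratio"),
      probes = if (probes) dplyr::bind_rows(probe_list) else NULL,
      fga_true = fga_true
    )
  })
}

simulate_expression_stage <- function(params, truth, seed) {
  ref <- synthetic_genome()
  withr::with_seed(seed, {
    genes <- c(ref$genes$gene, sprintf("GENE%02d", 1:20))
    base <- stats::rnorm(length(genes), 7, 1.5)
    n <- nrow(truth)
    mat <- matrix(stats::rnorm(length(genes) * n, 0, 0.8),
                  nrow = length(genes)) + base
    dimnames(mat) <- list(genes, truth$patient_id)
    mucins <- intersect(MUCIN_FAMILY_DEFAULT, genes)
    mat[mucins, truth$group == "BCP"] <-
      mat[mucins, truth$group == "BCP"] + params$mucsig_shift
    mat["MSH2", truth$sig20_pos] <-
      mat["MSH2", truth$sig20_pos] + params$msh2_expr_shift
    mat
  })
}

#' Chromosome arm definitions of the synthetic genome
#'
#' Each synthetic chromosome is split at its midpoint into a p and a q arm.
#'
#' @return Tibble with `chrom`, `arm`, `start`, `end`.
#' @export
genome_arms <- function() {
  g <- synthetic_genome()$genome
  dplyr::bind_rows(lapply(names(g), function(chr) {
    len <- Biostrings::width(g[chr])
    mid <- len %/% 2L
    tibble::tibble(chrom = chr, arm = c("p", "q"),
                   start = c(1L, mid + 1L), end = c(mid, len))
  }))
}

#' Write all cohort tables to a directory
#'
#' Emits the cohort in the pipeline's external formats: `clinical.tsv`,
#' `mutations.tsv`, `spectra.tsv`, `segments.seg`, `probes.tsv`,
#' `expression.tsv`, `exposures_true.tsv`, plus `truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (!is.null(cohort$clinical)) write_clinical_table(cohort$clinical, p("clinical.tsv"))
  if (!is.null(cohort$mutations)) write_mutation_table(cohort$mutations, p("mutations.tsv"))
  if (!is.null(cohort$spectra)) readr::write_tsv(cohort$spectra, p("spectra.tsv"))
  if (!is.null(cohort$segments)) write_segment_table(cohort$segments, p("segments.seg"))
  if (!is.null(cohort$probes)) write_probe_table(cohort$probes, p("probes.tsv"))
  if (!is.null(cohort$expression)) write_expression_matrix(cohort$expression, p("expression.tsv"))
  if (!is.null(cohort$exposures_true)) readr::write_tsv(cohort$exposures_true, p("exposures_true.tsv"))
  jsonlite::write_json(cohort$truth, p("truth.json"), digits = NA)
  invisible(dir)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d BCP + %d control (seed %d)\n",
              x$params$n_bcp, x$params$n_control, x$params$seed))
  cat("Stages present:",
      paste(names(Filter(Negate(is.null),
                         x[c("clinical", "mutations", "spectra", "segments",
                             "probes", "expression")])), collapse = ", "), "\n")
  invisible(x)
}
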