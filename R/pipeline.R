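# End-to-end orchestration: one config drives simulate/load -> QC -> burden
# -> mucin -> signatures -> CNA -> survival and produces a machine-readable
# summary. Stage outputs are pure functions of (inputs, config, seed).

SUMMARY_SCHEMA_VERSION <- "1.0"

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_bcp = 35L, n_control = 18L),
    inputs = NULL,
    stages = c("qc", "burden", "mucin", "signatures", "cna", "survival"),
    thresholds = list(
      mapd = 0.30, autocorr = 0.5, min_ccf = 0.30,
      neutral_band = 0.2, del_threshold = -0.3,
      signature_cutoff = 0.06, min_freq = 0.05
    ),
    mucin_exclude = c("MUC4", "MUC16"),
    n_draws = 999L,
    out_dir = NULL
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else user[[nm]]
  }
  base
}

#' Run the full comparative-genomics pipeline
#'
#' Executes the enabled stages over a simulated or file-based cohort and
#' returns one report bundle; identical config and seed give identical
#' results. Any stage failure aborts with the stage name; when `out_dir` is
#' set, outputs written so far are retained and a `MANIFEST` file marks the
#' run incomplete.
#'
#' @param config A list, or path to a YAML file. Recognized fields:
#'   `seed` (required when simulating), `simulate` (arguments to
#'   [cohort_params()]), `inputs` (paths: `clinical`, `mutations`,
#'   `segments`, `probes`, `expression`, `spectra`, `ccf`), `stages`
#'   (subset of qc, burden, mucin, signatures, cna, survival),
#'   `thresholds`, `mucin_exclude`, `n_draws`, `out_dir`.
#' @return A list of class `pipeline_report` with per-stage results and a
#'   `summary` list (schema-versioned) holding every headline statistic.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  cfg$stages <- match.arg(cfg$stages,
                          c("qc", "burden", "mucin", "signatures", "cna",
                            "survival"), several.ok = TRUE)
  if (is.null(cfg$inputs) && is.null(cfg$seed)) {
    stop("run_pipeline: a seed is required when simulating", call. = FALSE)
  }
  report <- list(config = cfg)
  summary <- list(schema_version = SUMMARY_SCHEMA_VERSION, seed = cfg$seed,
                  stages = cfg$stages)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(obj, file) {
    if (!is.null(out_dir) && !is.null(obj)) {
      readr::write_tsv(obj, file.path(out_dir, file), na = ".")
    }
  }
  finish_incomplete <- function(stage, err) {
    if (!is.null(out_dir)) {
      writeLines(c("status: INCOMPLETE", paste0("failed_stage: ", stage),
                   paste0("error: ", conditionMessage(err))),
                 file.path(out_dir, "MANIFEST"))
    }
    stop(sprintf("run_pipeline: stage '%s' failed: %s", stage,
                 conditionMessage(err)), call. = FALSE)
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) finish_incomplete(stage, e))
  }

  # ---- data acquisition -------------------------------------------------
  data <- run_stage("data", {
    if (!is.null(cfg$inputs)) {
      inp <- cfg$inputs
      list(
        clinical = if (!is.null(inp$clinical)) read_clinical_table(inp$clinical),
        mutations = if (!is.null(inp$mutations)) read_mutation_table(inp$mutations),
        vafs = NULL,
        spectra = if (!is.null(inp$spectra)) {
          readr::read_tsv(inp$spectra, show_col_types = FALSE)
        } else NULL,
        segments = if (!is.null(inp$segments)) read_segment_table(inp$segments),
        probes = if (!is.null(inp$probes)) read_probe_table(inp$probes),
        expression = if (!is.null(inp$expression)) read_expression_matrix(inp$expression),
        ccf = if (!is.null(inp$ccf)) {
          readr::read_tsv(inp$ccf, show_col_types = FALSE)
        } else NULL
      )
    } else {
      params <- do.call(cohort_params, c(cfg$simulate, list(seed = cfg$seed)))
      cohort <- simulate_cohort(params)
      list(
        clinical = cohort$clinical, mutations = cohort$mutations,
        vafs = cohort$vafs, spectra = cohort$spectra,
        segments = cohort$segments, probes = cohort$probes,
        expression = cohort$expression,
        ccf = dplyr::select(cohort$truth, sample_id = "patient_id", "ccf"),
        truth = cohort$truth
      )
    }
  })
  report$data <- data
  th <- cfg$thresholds

  if ("qc" %in% cfg$stages && !is.null(data$probes)) {
    report$qc <- run_stage("qc", {
      qc <- array_qc(data$probes)
      gate <- qc_gate(qc, data$ccf, mapd_threshold = th$mapd,
                      autocorr_threshold = th$autocorr, min_ccf = th$min_ccf)
      emit(gate, "qc.tsv")
      gate
    })
    summary$qc <- list(n_samples = nrow(report$qc),
                       n_pass = sum(report$qc$pass),
                       retained = report$qc$sample_id[report$qc$pass])
  }

  if ("burden" %in% cfg$stages) {
    report$burden <- run_stage("burden", {
      metrics <- summarize_catalogs(data$mutations, data$vafs)
      if (!is.null(data$truth)) {
        # genome-wide SNV/indel totals exceed the emitted record table
        metrics <- metrics |>
          dplyr::select(-"n_snv", -"n_indel") |>
          dplyr::left_join(dplyr::select(data$truth, "patient_id", "n_snv",
                                         "n_indel"), by = "patient_id")
      }
      comparisons <- dplyr::bind_rows(lapply(
        c("n_nonsilent", "n_snv", "n_known_db", "math_score"),
        function(m) burden_comparison(metrics, data$clinical, metric = m)))
      freq <- gene_frequency_table(data$mutations, data$clinical,
                                   min_freq = th$min_freq)
      emit(metrics, "burden_metrics.tsv")
      emit(comparisons, "burden_comparisons.tsv")
      emit(freq, "gene_frequency.tsv")
      list(metrics = metrics, comparisons = comparisons, gene_frequency = freq)
    })
    summary$burden <- list(
      median_nonsilent_overall = stats::median(report$burden$metrics$n_nonsilent),
      comparisons = report$burden$comparisons
    )
  }

  if ("mucin" %in% cfg$stages) {
    report$mucin <- run_stage("mucin", {
      fam <- mucin_family()
      cs_all <- carrier_status(data$mutations, data$clinical, fam)
      cs_excl <- carrier_status(data$mutations, data$clinical, fam,
                                exclude = cfg$mucin_exclude)
      carrier_test <- fisher_exact(table(
        factor(cs_all$group, levels = c("BCP", "control")),
        factor(cs_all$carrier, levels = c(TRUE, FALSE))))
      muc_mis <- dplyr::filter(data$mutations, .data$gene %in% fam,
                               .data$consequence == "missense")
      ser_frac <- if (nrow(muc_mis)) serine_gain_fraction(muc_mis) else NA_real_
      hot <- hotspot_detect(dplyr::filter(data$mutations, .data$gene %in% fam))
      mc_ser <- if (nrow(muc_mis)) {
        mc_serine_test(muc_mis, fam, n_draws = cfg$n_draws,
                       seed = child_seed(cfg$seed, "mc_serine"))
      } else NULL
      muc_var <- dplyr::filter(data$mutations, .data$gene %in% fam,
                               classify_non_silent(.data$consequence),
                               nchar(.data$ref) == 1L, nchar(.data$alt) == 1L)
      mc_db <- if (nrow(muc_var)) {
        mc_known_db_overlap_test(muc_var, synthetic_known_positions(), fam,
                                 n_draws = cfg$n_draws,
                                 seed = child_seed(cfg$seed, "mc_known_db"))
      } else NULL
      msig <- if (!is.null(data$expression)) {
        sc <- mucsig(data$expression, fam)
        grp <- data$clinical$group[match(sc$sample_id, data$clinical$patient_id)]
        list(scores = sc,
             comparison = mann_whitney(sc$score[grp == "BCP"],
                                       sc$score[grp == "control"]))
      } else NULL
      emit(cs_all, "mucin_carriers.tsv")
      emit(hot, "mucin_hotspots.tsv")
      list(carriers = cs_all, carriers_excl = cs_excl,
           carrier_test = carrier_test, serine_fraction = ser_frac,
           hotspots = hot, mc_serine = mc_ser, mc_known_db = mc_db,
           mucsig = msig)
    })
    cs <- report$mucin
    summary$mucin <- list(
      carrier_freq_bcp = mean(cs$carriers$carrier[cs$carriers$group == "BCP"]),
      carrier_freq_control = mean(cs$carriers$carrier[cs$carriers$group == "control"]),
      carrier_freq_bcp_excl = mean(cs$carriers_excl$carrier[cs$carriers_excl$group == "BCP"]),
      carrier_p = cs$carrier_test$p_value,
      serine_gain_fraction = cs$serine_fraction,
      n_hotspots = nrow(cs$hotspots),
      mc_serine_p = if (!is.null(cs$mc_serine)) cs$mc_serine$p_value else NA,
      mc_known_db_p = if (!is.null(cs$mc_known_db)) cs$mc_known_db$p_value else NA,
      mucsig_p = if (!is.null(cs$mucsig)) cs$mucsig$comparison$p_value else NA
    )
  }

  if ("signatures" %in% cfg$stages && !is.null(data$spectra)) {
    report$signatures <- run_stage("signatures", {
      reference <- load_signature_reference()
      exp_fit <- refit_exposures(data$spectra, reference,
                                 cutoff = th$signature_cutoff)
      present <- call_presence(exp_fit, "Signature.20")
      grp <- data$clinical$group[match(exp_fit$sample_id,
                                       data$clinical$patient_id)]
      msh2_gr <- synthetic_genome()$genes |>
        dplyr::filter(.data$gene == "MSH2")
      assoc <- sig20_association_suite(
        exp_fit, expr = data$expression, segments = data$segments,
        gene_region = msh2_gr, del_threshold = th$del_threshold)
      emit(tibble::as_tibble(exp_fit), "signature_exposures.tsv")
      emit(assoc, "sig20_associations.tsv")
      list(exposures = exp_fit, sig20_present = present, group = grp,
           associations = assoc)
    })
    sg <- report$signatures
    summary$signatures <- list(
      sig20_prevalence_bcp = mean(sg$sig20_present[sg$group == "BCP"]),
      sig20_prevalence_control = mean(sg$sig20_present[sg$group == "control"]),
      associations = sg$associations
    )
  }

  if ("cna" %in% cfg$stages && !is.null(data$segments)) {
    report$cna <- run_stage("cna", {
      fga <- fraction_genome_altered(data$segments,
                                     neutral_band = th$neutral_band)
      arm_cmp <- arm_frequency_comparison(data$segments, genome_arms(),
                                          data$clinical,
                                          neutral_band = th$neutral_band)
      msh2_gr <- synthetic_genome()$genes |>
        dplyr::filter(.data$gene == "MSH2")
      msh2_calls <- gene_level_call(data$segments, msh2_gr,
                                    del_threshold = th$del_threshold)
      emit(fga, "fga.tsv")
      emit(arm_cmp, "arm_comparison.tsv")
      emit(msh2_calls, "msh2_calls.tsv")
      list(fga = fga, arm_comparison = arm_cmp, msh2_calls = msh2_calls)
    })
    summary$cna <- list(
      mean_fga = mean(report$cna$fga$fga),
      min_arm_fdr = suppressWarnings(min(report$cna$arm_comparison$fdr)),
      n_msh2_deleted = sum(report$cna$msh2_calls$call == "deleted",
                           na.rm = TRUE)
    )
  }

  if ("survival" %in% cfg$stages && !is.null(data$clinical)) {
    report$survival <- run_stage("survival", {
      cl <- data$clinical |>
        dplyr::mutate(date_num = as.numeric(.data$date_of_diagnosis),
                      group = factor(.data$group, levels = c("control", "BCP")))
      covs <- c("group", "age_at_diagnosis", "date_num",
                "pathological_stage", "subtype_ihc")
      km <- km_logrank(cl$dfs_time, cl$dfs_event, cl$group)
      cox_dfs <- cox_fit(cl, "dfs_time", "dfs_event", covs)
      cox_os <- cox_fit(cl, "os_time", "os_event", covs)
      if (!is.null(out_dir)) {
        readr::write_tsv(km$curves, file.path(out_dir, "km_curves.tsv"))
      }
      list(km_dfs = km, cox_dfs = cox_dfs, cox_os = cox_os)
    })
    sv <- report$survival
    grp_term <- grep("^group", sv$cox_dfs$terms$term, value = TRUE)[1]
    summary$survival <- list(
      km_median_dfs = sv$km_dfs$medians,
      logrank_p = sv$km_dfs$logrank$p_value,
      dfs_hr = sv$cox_dfs$terms$hr[sv$cox_dfs$terms$term == grp_term],
      os_hr = sv$cox_os$terms$hr[sv$cox_os$terms$term == grp_term]
    )
  }

  report$summary <- summary
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines("status: COMPLETE", file.path(out_dir, "MANIFEST"))
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (stages:",
      paste(x$summary$stages, collapse = ", "), ")\n")
  utils::str(x$summary, max.level = 2, give.attr = FALSE)
  invisible(x)
}
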