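#' Two-sample Mann-Whitney U comparison
#'
#' Two-sided rank-sum comparison of two numeric samples. The exact null
#' distribution is enumerated when the combined sample size is at most 12 and
#' there are no ties; otherwise the tie-corrected normal approximation is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A one-row tibble of class `comparison_result` with the test name,
#'   U statistic, two-sided p-value and the two group medians.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("mann_whitney: both groups must be non-empty", call. = FALSE)
  }
  exact <- (length(x) + length(y) <= 12L) && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = !exact))
  new_comparison_result(
    test = if (exact) "mann_whitney_exact" else "mann_whitney_normal",
    statistic = unname(wt$statistic),
    p_value = min(1, wt$p.value),
    estimate1 = stats::median(x),
    estimate2 = stats::median(y)
  )
}

#' Fisher exact test on a 2x2 table
#'
#' @param tab A 2x2 matrix of non-negative integer counts with all margins
#'   positive.
#' @param two_sided Two-sided p-value convention: `"minlike"` (sum of
#'   hypergeometric probabilities no larger than the observed table's, the R
#'   `fisher.test` convention) or `"doubling"` (twice the smaller one-sided
#'   tail, capped at 1). Conventions agree on symmetric tables but can differ
#'   roughly two-fold on skewed ones.
#' @return A one-row `comparison_result` tibble with the odds ratio
#'   (conditional MLE) and two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(5, 10, 1, 37), 2, byrow = TRUE))
#' @export
fisher_exact <- function(tab, two_sided = c("minlike", "doubling")) {
  two_sided <- match.arg(two_sided)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("fisher_exact: need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("fisher_exact: counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("fisher_exact: every margin must be positive", call. = FALSE)
  }
  ft <- stats::fisher.test(tab)
  p <- if (two_sided == "minlike") {
    ft$p.value
  } else {
    lo <- stats::fisher.test(tab, alternative = "less")$p.value
    hi <- stats::fisher.test(tab, alternative = "greater")$p.value
    min(1, 2 * min(lo, hi))
  }
  new_comparison_result(
    test = paste0("fisher_exact_", two_sided),
    statistic = unname(ft$estimate),
    p_value = min(1, p),
    estimate1 = tab[1, 1] / sum(tab[1, ]),
    estimate2 = tab[2, 1] / sum(tab[2, ])
  )
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties. The p-value uses the exact
#' permutation distribution for n <= 10 without ties and the t approximation
#' otherwise.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, neither constant.
#' @return A one-row `comparison_result` tibble; `statistic` is rho.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_cor: unequal lengths", call. = FALSE)
  if (length(x) < 3L) stop("spearman_cor: need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("spearman_cor: constant vector has undefined rank correlation", call. = FALSE)
  }
  exact <- length(x) <= 10L && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  new_comparison_result(
    test = "spearman",
    statistic = unname(ct$estimate),
    p_value = min(1, ct$p.value),
    estimate1 = NA_real_, estimate2 = NA_real_
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforced; output order matches input.
#'
#' @param p Numeric vector of raw p-values, all in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Covariate-adjusted association via nested-model comparison
#'
#' Tests the association between an outcome and a binary group after adjusting
#' for covariates, by comparing the models with and without the group term:
#' an F test for a continuous outcome (linear regression), a likelihood-ratio
#' test for a binary outcome (logistic regression). Rows with missing values
#' are dropped listwise.
#'
#' @param data A data frame containing all model columns.
#' @param outcome Name of the outcome column (continuous, or binary 0/1 /
#'   logical / two-level factor).
#' @param group Name of the binary group column.
#' @param covariates Character vector of covariate column names.
#' @return A one-row tibble with the adjusted p-value, group coefficient,
#'   model family, n used, and a `flag` column noting collinearity/separation.
#' @export
adjusted_association <- function(data, outcome, group, covariates) {
  stopifnot(is.data.frame(data))
  cols <- c(outcome, group, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("adjusted_association: missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- stats::na.omit(data[, cols, drop = FALSE])
  y <- d[[outcome]]
  binary <- is.logical(y) || (is.factor(y) && nlevels(y) == 2L) ||
    (is.numeric(y) && all(y %in% c(0, 1)))
  f_full <- stats::reformulate(c(group, covariates), response = outcome)
  f_red  <- stats::reformulate(covariates, response = outcome)
  flag <- NA_character_
  if (binary) {
    fit_full <- suppressWarnings(stats::glm(f_full, data = d, family = stats::binomial()))
    fit_red  <- suppressWarnings(stats::glm(f_red, data = d, family = stats::binomial()))
    if (!fit_full$converged) flag <- "non_convergence"
    if (any(abs(stats::coef(fit_full)) > 15, na.rm = TRUE)) flag <- "possible_separation"
    an <- stats::anova(fit_red, fit_full, test = "LRT")
    p <- an[["Pr(>Chi)"]][2]
    family <- "logistic"
  } else {
    fit_full <- stats::lm(f_full, data = d)
    fit_red  <- stats::lm(f_red, data = d)
    if (anyNA(stats::coef(fit_full))) flag <- "collinear_terms_dropped"
    an <- stats::anova(fit_red, fit_full)
    p <- an[["Pr(>F)"]][2]
    family <- "linear"
  }
  coef_names <- names(stats::coef(fit_full))
  grp_coef <- stats::coef(fit_full)[grep(paste0("^", group), coef_names)][1]
  tibble::tibble(
    outcome = outcome, family = family,
    adjusted_p = as.numeric(p),
    group_coefficient = unname(grp_coef),
    n = nrow(d), flag = flag
  )
}

#' Kaplan-Meier curves with log-rank comparison
#'
#' Product-limit survival estimates per group, group medians (earliest time
#' with S(t) <= 0.5; NA if the curve never reaches 0.5), and the log-rank
#' chi-square test on k - 1 degrees of freedom.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Group labels (coerced to factor).
#' @return An object of class `survival_comparison`: a list with `curves`
#'   (tibble: group, time, n_risk, surv), `medians` (tibble: group, median),
#'   and `logrank` (tibble: statistic, df, p_value).
#' @export
km_logrank <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  if (any(times < 0)) stop("km_logrank: negative times", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("km_logrank: events must be 0/1", call. = FALSE)
  groups <- factor(groups)
  if (any(table(groups) == 0L)) stop("km_logrank: empty group", call. = FALSE)
  if (sum(events) == 0) stop("km_logrank: no events observed", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata_names <- if (is.null(fit$strata)) levels(groups) else
    sub("^groups=", "", names(fit$strata))
  grp <- if (is.null(fit$strata)) rep(strata_names, length(fit$time)) else
    rep(strata_names, fit$strata)
  curves <- tibble::tibble(
    group = grp, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, surv = fit$surv
  )
  medians <- curves |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      median = {
        hit <- .data$time[.data$surv <= 0.5]
        if (length(hit)) min(hit) else NA_real_
      },
      .groups = "drop"
    )
  if (nlevels(groups) > 1L) {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    df <- nlevels(groups) - 1L
    lr <- tibble::tibble(
      statistic = sd$chisq, df = df,
      p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE)
    )
  } else {
    lr <- tibble::tibble(statistic = NA_real_, df = 0L, p_value = NA_real_)
  }
  structure(list(curves = curves, medians = medians, logrank = lr),
            class = "survival_comparison")
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit with Efron tie handling. Hazard ratios, Wald 95%
#' confidence intervals and p-values are reported per model term.
#'
#' @param data Data frame with the time, event and covariate columns.
#' @param time,event Column names for follow-up time and 0/1 event indicator.
#' @param covariates Character vector of covariate column names. Ordinal
#'   covariates should be numeric, categorical ones factors (dummy coded).
#' @return An object of class `cox_fit`: list with `terms` (tibble: term, hr,
#'   conf_low, conf_high, p_value), `n`, `n_events`, `converged`.
#' @export
cox_fit <- function(data, time, event, covariates) {
  stopifnot(is.data.frame(data))
  d <- stats::na.omit(data[, c(time, event, covariates), drop = FALSE])
  constant <- covariates[vapply(covariates, function(v) {
    length(unique(d[[v]])) < 2L
  }, logical(1))]
  if (length(constant)) {
    stop("cox_fit: constant covariate(s): ", paste(constant, collapse = ", "),
         call. = FALSE)
  }
  f <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(f, data = d, ties = "efron")
  converged <- is.null(fit$info) || !isTRUE(grepl("did not converge", fit$info))
  s <- summary(fit)
  if (any(!is.finite(s$coefficients[, "se(coef)"]))) {
    stop("cox_fit: non-finite standard errors (fit did not converge)", call. = FALSE)
  }
  terms_tbl <- tibble::tibble(
    term = rownames(s$coefficients),
    hr = s$coefficients[, "exp(coef)"],
    conf_low = s$conf.int[, "lower .95"],
    conf_high = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"]
  )
  structure(list(terms = terms_tbl, n = s$n, n_events = s$nevent,
                 converged = converged),
            class = "cox_fit")
}

new_comparison_result <- function(test, statistic, p_value, estimate1, estimate2) {
  out <- tibble::tibble(
    test = test, statistic = statistic, p_value = p_value,
    estimate1 = estimate1, estimate2 = estimate2
  )
  class(out) <- c("comparison_result", class(out))
  out
}

#' @export
tidy.survival_comparison <- function(x, ...) x$curves

#' @export
glance.survival_comparison <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$medians, names_from = "group",
                             values_from = "median", names_prefix = "median_")
  dplyr::bind_cols(wide, x$logrank)
}

#' @export
tidy.cox_fit <- function(x, ...) x$terms

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, converged = x$converged)
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("Kaplan-Meier comparison\n")
  print(x$medians)
  cat(sprintf("Log-rank: chi-square = %.3f (df %d), p = %.4g\n",
              x$logrank$statistic, x$logrank$df, x$logrank$p_value))
  invisible(x)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (n = %d, events = %d)\n",
              x$n, x$n_events))
  print(x$terms)
  invisible(x)
}

#' Kaplan-Meier plot for a survival comparison
#'
#' @param object A `survival_comparison` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot object with one step curve per group.
#' @export
autoplot.survival_comparison <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (years)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
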