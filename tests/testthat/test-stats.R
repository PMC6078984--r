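test_that("Mann-Whitney matches full permutation enumeration on small samples", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  # independent oracle: enumerate all C(6,3) = 20 group assignments
  vals <- 1:6
  splits <- utils::combn(6, 3)
  u_obs <- sum(outer(c(1, 2, 3), c(4, 5, 6), ">"))
  u_null <- apply(splits, 2, function(ix) {
    sum(outer(vals[ix], vals[-ix], ">"))
  })
  mu <- mean(u_null)
  p_enum <- mean(abs(u_null - mu) >= abs(u_obs - mu))
  expect_equal(p_enum, 0.1)
  expect_equal(res$p_value, p_enum)
  expect_equal(res$test, "mann_whitney_exact")

  # identical multisets give p = 1 on the tie-corrected path
  expect_equal(mann_whitney(c(1, 1, 2, 3), c(1, 1, 2, 3))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("two-sample tests are symmetric under group-label swap", {
  withr::with_seed(9, {
    x <- rnorm(25); y <- rnorm(30, 0.4)
    expect_equal(mann_whitney(x, y)$p_value, mann_whitney(y, x)$p_value)
    tab <- matrix(c(9, 12, 4, 20), 2, byrow = TRUE)
    expect_equal(fisher_exact(tab)$p_value, fisher_exact(tab[2:1, ])$p_value)
  })
})

test_that("Fisher exact handles endpoint and study tables", {
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  # both extreme diagonal tables have probability 1/C(20,10)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2))$p_value,
               2 / choose(20, 10))
  expect_error(fisher_exact(matrix(c(0, 0, 1, 1), 2, byrow = TRUE)), "margin")
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integers")
  # the two two-sided conventions differ about two-fold on a skewed table
  tab <- matrix(c(5, 10, 1, 37), 2, byrow = TRUE)
  expect_lt(fisher_exact(tab, "minlike")$p_value,
            fisher_exact(tab, "doubling")$p_value)
})

test_that("Spearman correlation handles perfect association and errors", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, x)$statistic, 1)
  expect_equal(spearman_cor(x, -x)$statistic, -1)
  expect_error(spearman_cor(x, rep(1, 6)), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("BH adjustment matches hand computation and is idempotent-safe", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  # monotone in input ranks; output order matches input order
  withr::with_seed(11, {
    p <- runif(20)
    adj <- bh_fdr(p)
    expect_equal(order(adj[order(p)]), seq_len(20))
  })
})

test_that("adjusted association detects saturated effects and is calibrated under the null", {
  withr::with_seed(5, {
    n <- 120
    d <- tibble::tibble(
      group = rep(c("BCP", "control"), each = n / 2),
      age = rnorm(n, 34, 4), stage = sample(1:3, n, TRUE),
      y = as.numeric(group == "BCP")
    )
    expect_lt(adjusted_association(d, "y", "group", c("age", "stage"))$adjusted_p,
              1e-10)
    # null calibration: p uniform over 200 replicates (KS at alpha = 0.01)
    pvals <- replicate(200, {
      d$y <- rnorm(n)
      adjusted_association(d, "y", "group", c("age", "stage"))$adjusted_p
    })
    expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
    # logistic outcome goes through the likelihood-ratio path
    d$z <- rbinom(n, 1, 0.4)
    res <- adjusted_association(d, "z", "group", c("age", "stage"))
    expect_equal(res$family, "logistic")
    expect_true(res$adjusted_p > 0 && res$adjusted_p <= 1)
  })
})

test_that("Kaplan-Meier estimator, medians and log-rank behave correctly", {
  # all events at t = 2, one group: S(2) = 0 and median 2
  fit <- km_logrank(c(2, 2, 2), c(1, 1, 1), rep("A", 3))
  expect_equal(fit$medians$median, 2)
  expect_equal(min(fit$curves$surv), 0)
  expect_true(all(diff(fit$curves$surv) <= 1e-12))

  # two identical groups: log-rank p = 1
  t2 <- c(1, 2, 3, 4, 5); e2 <- c(1, 0, 1, 1, 0)
  fit2 <- km_logrank(c(t2, t2), c(e2, e2), rep(c("A", "B"), each = 5))
  expect_equal(fit2$logrank$p_value, 1)

  # exponential groups with hazard ratio 2: KM median ratio ~ 2 (+/- 10%)
  withr::with_seed(21, {
    t <- c(rexp(2500, 1), rexp(2500, 2))
    g <- rep(c("slow", "fast"), each = 2500)
    fit3 <- km_logrank(t, rep(1, 5000), g)
    meds <- tidyr::pivot_wider(fit3$medians, names_from = "group",
                               values_from = "median")
    expect_equal(meds$slow / meds$fast, 2, tolerance = 0.1)
  })
  expect_error(km_logrank(1:3, c(0, 0, 0), rep("A", 3)), "no events")
})

test_that("Cox fit recovers a known hazard ratio and flags degeneracies", {
  withr::with_seed(31, {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.2 * exp(log(2) * x))
    d <- tibble::tibble(time = t, event = 1L, x = x)
    fit <- cox_fit(d, "time", "event", "x")
    expect_gt(fit$terms$hr, 1.8); expect_lt(fit$terms$hr, 2.2)
    expect_true(fit$terms$conf_low < 2 && fit$terms$conf_high > 2)
    # group-label swap inverts the hazard ratio
    d$xr <- 1L - d$x
    fitr <- cox_fit(d, "time", "event", "xr")
    expect_equal(fitr$terms$hr, 1 / fit$terms$hr, tolerance = 1e-6)
    d$const <- 1
    expect_error(cox_fit(d, "time", "event", "const"), "constant covariate")
  })
})
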