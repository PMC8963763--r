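# MSP classification, contingency engine, chi-square and survival machinery.

test_that("MSP band patterns map to the three-state status", {
  expect_equal(call_msp_status(TRUE, FALSE), "M")
  expect_equal(call_msp_status(FALSE, TRUE), "U")
  expect_equal(call_msp_status(TRUE, TRUE), "HM")
  expect_error(call_msp_status(FALSE, FALSE), "indeterminate",
               class = "methcascade_validation_error")
  expect_warning(
    out <- call_msp_status(c(TRUE, FALSE), c(FALSE, FALSE),
                           on_indeterminate = "na"),
    "indeterminate"
  )
  expect_equal(out, c("M", NA))
})

test_that("contingency tables count every classified sample once", {
  sim <- simulate_msp_cohort(cohort_sim_config(seed = 12))
  for (v in c("response", "stage_group", "tumor_size_group")) {
    tab <- build_contingency(sim$msp, sim$clinical, "BRD9", v)
    expect_equal(sum(tab), 70L)
    # nested-loop counting oracle
    joined <- merge(sim$msp[sim$msp$gene == "BRD9", ], sim$clinical,
                    by = "sample_id")
    for (lev in rownames(tab)) {
      for (st in colnames(tab)) {
        expect_equal(tab[lev, st],
                     sum(joined[[v]] == lev & joined$status == st))
      }
    }
  }
  # sample present in calls but absent from clinical
  expect_error(
    build_contingency(sim$msp, sim$clinical[-1, ], "BRD9", "response"),
    sim$clinical$sample_id[1], class = "methcascade_validation_error"
  )
  # empty cohort: zero-filled table with full dimensions
  tab0 <- build_contingency(sim$msp[0, ], sim$clinical, "BRD9", "response")
  expect_equal(sum(tab0), 0L)
  expect_equal(dim(tab0), c(2L, 3L))
})

test_that("chi-square engine matches expected-count arithmetic", {
  # proportional rows: statistic exactly 0, p = 1
  prop <- chi_square_test(matrix(c(10, 5, 20, 10), 2))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)

  # [[10,0],[0,10]]: expected counts all 5, chi2 = 4 * 25/5 = 20, df 1
  diag2 <- chi_square_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag2$statistic, 20)
  expect_equal(diag2$df, 1)

  # invariance under row/column permutation
  withr::local_seed(71)
  m <- matrix(rpois(12, 8), 3, 4)
  base <- chi_square_test(m)
  perm <- chi_square_test(m[sample(3), sample(4)])
  expect_equal(perm$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(perm$df, base$df)

  # all-zero line dropped before df computation
  z <- cbind(m, 0)
  expect_equal(chi_square_test(z)$df, base$df)
  expect_error(chi_square_test(matrix(c(3, 4, 0, 0), 2, 2)[, 1, drop = FALSE]),
               "degenerate", class = "methcascade_validation_error")
  expect_error(chi_square_test(matrix(c(1.5, 2, 3, 4), 2)),
               class = "methcascade_validation_error")

  # tidy/glance expose cells and summary
  td <- tidy(base)
  expect_equal(nrow(td), 12L)
  expect_equal(sum(td$observed), sum(m))
  expect_equal(glance(base)$statistic, base$statistic)
})

test_that("chi-square p-values are uniform under independence", {
  withr::local_seed(72)
  ps <- replicate(400, {
    status <- sample(c("M", "HM", "U"), 70, TRUE, prob = c(0.3, 0.4, 0.3))
    resp <- rep(c("CR", "TR"), c(40, 30))
    tab <- table(resp, factor(status, levels = c("M", "HM", "U")))
    chi_square_test(tab)$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Kaplan-Meier estimates match hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$steps$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)

  cens <- km_estimate(c(4, 5, 6), c(0, 0, 0))
  expect_true(all(cens$steps$survival == 1))
  expect_true(is.na(cens$median))

  # with no censoring, S(t) is the empirical survival fraction
  withr::local_seed(73)
  t <- round(rexp(40, 0.2), 3)
  km2 <- km_estimate(t, rep(1, 40))
  for (i in seq_len(nrow(km2$steps))) {
    expect_equal(km2$steps$survival[i], mean(t > km2$steps$time[i]))
  }
  # survival curve starts at full risk set, is non-increasing, in [0,1]
  expect_equal(km2$steps$n_risk[1], 40)
  expect_true(all(diff(km2$steps$survival) <= 0))
  expect_true(all(km2$steps$survival >= 0 & km2$steps$survival <= 1))

  expect_error(km_estimate(numeric(0), numeric(0)),
               class = "methcascade_validation_error")
  expect_error(km_estimate(c(-1, 2), c(1, 1)),
               class = "methcascade_validation_error")
})

test_that("log-rank test behaves at the null and detects hazard contrasts", {
  t <- c(1, 2, 3, 4, 5)
  same <- logrank_test(t, rep(1, 5), t, rep(1, 5))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  expect_error(logrank_test(numeric(0), numeric(0), t, rep(1, 5)),
               class = "methcascade_validation_error")

  # statistic consistent with a label-permutation null
  withr::local_seed(74)
  ta <- rexp(20, 0.2); tb <- rexp(20, 0.45)
  obs <- logrank_test(ta, rep(1, 20), tb, rep(1, 20))
  times <- c(ta, tb)
  perm_stats <- replicate(2000, {
    idx <- sample(40, 20)
    logrank_test(times[idx], rep(1, 20), times[-idx], rep(1, 20))$statistic
  })
  p_perm <- mean(perm_stats >= obs$statistic)
  se <- sqrt(max(p_perm, 1 / 2000) * (1 - min(p_perm, 1 - 1 / 2000)) / 2000)
  expect_lt(abs(p_perm - obs$p_value), 3 * se + 1 / 2000)
})

test_that("survival comparison picks the two most frequent status groups", {
  probs <- tibble::tibble(gene = "GX", group = c("CR", "TR"),
                          M = c(0.9, 0.05), HM = c(0.1, 0.15), U = c(0, 0.8))
  cfg <- cohort_sim_config(n_cr = 35, n_tr = 35,
                           status_probabilities = probs,
                           hazard_by_status = c(M = 0.05, HM = 0.2, U = 0.4),
                           seed = 15)
  sim <- simulate_msp_cohort(cfg)
  cmp <- compare_survival(sim$msp, sim$clinical, "GX", "pfs")
  freq <- sort(table(sim$msp$status), decreasing = TRUE)
  expect_setequal(cmp$groups, names(freq)[1:2])
  expect_s3_class(autoplot(cmp), "ggplot")
  gl <- glance(cmp)
  expect_equal(gl$p_value, cmp$logrank$p_value)
})
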